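## mhc_pseudosequence: represent each MHC class I allele by the residues of
## its two peptide-binding alpha helices, located by mapping reference
## positions through a multiple-sequence alignment.

#' Construct an aligned allele set
#'
#' @param entries named character vector: allele name -> aligned sequence
#'   (amino-acid letters plus `'-'` for gaps). All sequences must share one
#'   length and names must be unique.
#' @return an `aligned_alleles` object with fields `entries` and
#'   `column_count`.
#' @export
aligned_alleles <- function(entries) {
  stopifnot(is.character(entries), length(entries) >= 1)
  if (is.null(names(entries)) || any(!nzchar(names(entries)))) {
    stop("every aligned sequence needs an allele name")
  }
  dup <- names(entries)[duplicated(names(entries))]
  if (length(dup) > 0) stop("duplicate allele name(s): ", paste(unique(dup), collapse = ", "))
  widths <- nchar(entries)
  if (length(unique(widths)) != 1) {
    off <- names(entries)[widths != stats::median(widths)]
    stop("ragged alignment; offending record(s): ", paste(off, collapse = ", "))
  }
  entries <- toupper(entries)
  structure(list(entries = entries, column_count = unname(widths[1])),
            class = "aligned_alleles")
}

#' Read an aligned FASTA of MHC allele sequences
#'
#' Headers are taken as allele names (up to the first whitespace). Enforces
#' the equal-length alignment contract and unique names.
#'
#' @param path aligned FASTA file.
#' @return an `aligned_alleles` object.
#' @export
read_aligned_fasta <- function(path) {
  if (!file.exists(path)) stop("aligned FASTA not found: ", path)
  ss <- Biostrings::readAAStringSet(path)
  nm <- sub("[[:space:]].*$", "", names(ss))
  aligned_alleles(setNames(as.character(ss), nm))
}

#' @export
print.aligned_alleles <- function(x, ...) {
  cat(sprintf("aligned allele set: %d alleles x %d columns\n",
              length(x$entries), x$column_count))
  invisible(x)
}

#' Reference windows on an MHC class I heavy chain
#'
#' The default windows, residues 50--84 and 140--179 of HLA-B*35:01, cover
#' the two alpha helices that form the walls of the peptide-binding groove
#' (75 residues in total). Positions are 1-based on the *ungapped* reference
#' sequence as provided; the reference FASTA must therefore use the same
#' residue numbering (mature-protein vs. precursor numbering differ by the
#' signal peptide — the supplied reference sequence defines truth).
#'
#' @param reference allele name of the reference row in the alignment.
#' @param windows list of length-2 integer vectors, 1-based inclusive
#'   ranges, non-overlapping and ascending.
#' @return a `reference_windows` object.
#' @export
reference_windows <- function(reference = "HLA-B*35:01",
                              windows = list(c(50L, 84L), c(140L, 179L))) {
  stopifnot(is_string(reference), is.list(windows), length(windows) >= 1)
  prev_end <- 0L
  for (w in windows) {
    stopifnot(length(w) == 2, w[1] >= 1, w[2] >= w[1])
    if (w[1] <= prev_end) stop("windows must be ascending and non-overlapping")
    prev_end <- w[2]
  }
  structure(list(reference = reference, windows = lapply(windows, as.integer)),
            class = "reference_windows")
}

#' Alternative beta-sheet windows
#'
#' Residues 3--37 and 94--126 cover the beta-sheet floor of the binding
#' groove. Including the floor was found to worsen prediction performance,
#' so these windows are provided as an alternative only, never as defaults.
#'
#' @inheritParams reference_windows
#' @return a `reference_windows` object.
#' @export
beta_sheet_windows <- function(reference = "HLA-B*35:01") {
  reference_windows(reference, list(c(3L, 37L), c(94L, 126L)))
}

#' Map ungapped reference positions to alignment columns
#'
#' For each 1-based residue position of the (ungapped) reference sequence
#' named in `rw`, returns the 1-based alignment column holding that residue;
#' gap columns in the reference row are skipped when counting residues.
#'
#' @param aln an `aligned_alleles` object.
#' @param rw a `reference_windows` object.
#' @return integer vector of alignment columns, in window order.
#' @export
reference_positions_to_columns <- function(aln, rw) {
  stopifnot(inherits(aln, "aligned_alleles"), inherits(rw, "reference_windows"))
  row <- aln$entries[rw$reference]
  if (is.na(row)) stop("reference allele not in alignment: ", rw$reference)
  chars <- strsplit(unname(row), "")[[1]]
  residue_cols <- which(chars != GAP_TOKEN) # residue_cols[i] = column of residue i
  n_res <- length(residue_cols)
  positions <- unlist(lapply(rw$windows, function(w) seq.int(w[1], w[2])))
  if (max(positions) > n_res) {
    stop(sprintf("window position %d exceeds reference ungapped length %d",
                 max(positions), n_res))
  }
  residue_cols[positions]
}

#' Extract groove pseudo-sequences at mapped columns
#'
#' Concatenates, for every allele in the alignment, the characters at the
#' given columns. Gap characters are preserved, so all pseudo-sequences have
#' identical length and the gap becomes a regular vocabulary token
#' downstream.
#'
#' @param aln an `aligned_alleles` object.
#' @param cols integer alignment columns (from
#'   [reference_positions_to_columns()]).
#' @return a `data.table` with columns `allele` and `groove_sequence`.
#' @export
extract_pseudosequences <- function(aln, cols) {
  stopifnot(inherits(aln, "aligned_alleles"))
  cols <- as.integer(cols)
  if (any(cols < 1 | cols > aln$column_count)) {
    stop("column index outside alignment of width ", aln$column_count)
  }
  mat <- do.call(rbind, strsplit(unname(aln$entries), ""))
  data.table::data.table(
    allele = names(aln$entries),
    groove_sequence = apply(mat[, cols, drop = FALSE], 1, paste, collapse = "")
  )
}

#' One-call pseudo-sequence extraction
#'
#' @inheritParams reference_positions_to_columns
#' @return as [extract_pseudosequences()].
#' @export
pseudosequences <- function(aln, rw = reference_windows()) {
  extract_pseudosequences(aln, reference_positions_to_columns(aln, rw))
}

#' Align allele sequences with an external aligner
#'
#' Thin wrapper that shells out to a multiple-sequence aligner (e.g.
#' `muscle` or `mafft`) with default parameters and parses its aligned-FASTA
#' output. If `aligned` is given, the aligner is bypassed entirely and the
#' pre-aligned file is read. If no aligner is available the function refuses
#' with instructions to supply a pre-aligned FASTA.
#'
#' @param sequences path to an (unaligned) FASTA of allele sequences.
#' @param tool_path aligner executable; defaults to `muscle` or `mafft`
#'   found on `PATH`.
#' @param aligned optional pre-aligned FASTA path (bypasses the aligner).
#' @return an `aligned_alleles` object.
#' @export
run_alignment <- function(sequences = NULL, tool_path = NULL, aligned = NULL) {
  if (!is.null(aligned)) return(read_aligned_fasta(aligned))
  stopifnot(!is.null(sequences), file.exists(sequences))
  if (is.null(tool_path)) {
    for (cand in c("muscle", "mafft")) {
      p <- Sys.which(cand)
      if (nzchar(p)) { tool_path <- p; break }
    }
  }
  if (is.null(tool_path) || !nzchar(Sys.which(tool_path))) {
    stop("no multiple-sequence aligner found; install muscle/mafft or pass a ",
         "pre-aligned FASTA via `aligned=`")
  }
  out <- tempfile(fileext = ".afa")
  err <- tempfile(fileext = ".log")
  base <- basename(tool_path)
  status <- if (grepl("mafft", base)) {
    suppressWarnings(system2(tool_path, c("--auto", shQuote(sequences)),
                             stdout = out, stderr = err))
  } else {
    suppressWarnings(system2(tool_path,
                             c("-in", shQuote(sequences), "-out", shQuote(out)),
                             stdout = FALSE, stderr = err))
  }
  if (status != 0L || !file.exists(out) || file.size(out) == 0) {
    log_tail <- if (file.exists(err)) utils::tail(readLines(err, warn = FALSE), 5) else ""
    stop("aligner failed (exit ", status, "):\n", paste(log_tail, collapse = "\n"))
  }
  read_aligned_fasta(out)
}

#' Write / read a pseudo-sequence table
#'
#' TSV with columns `allele`, `groove_sequence`.
#' @param pseudo a `data.table` as returned by [pseudosequences()].
#' @param path file path.
#' @return `path` invisibly (write) or the table (read).
#' @export
write_pseudo_tsv <- function(pseudo, path) {
  stopifnot(all(c("allele", "groove_sequence") %in% names(pseudo)))
  data.table::fwrite(data.table::as.data.table(pseudo)[, .(allele, groove_sequence)],
                     path, sep = "\t")
  invisible(path)
}

#' @rdname write_pseudo_tsv
#' @export
read_pseudo_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, colClasses = "character")
  stopifnot(all(c("allele", "groove_sequence") %in% names(dt)))
  if (length(unique(nchar(dt$groove_sequence))) > 1) {
    stop("pseudo-sequences must all share one length")
  }
  dt
}
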