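## dataset_curation: parse qualitative binding tables, filter, map labels,
## resolve conflicting entries, and summarise the cleaned dataset.

#' Qualitative binding label taxonomy
#'
#' The five qualitative binding classes found in IEDB-style exports, from
#' strongest to weakest evidence of binding, plus the negative class.
#' @export
BINDING_LABELS <- c("Positive-High", "Positive", "Positive-Intermediate",
                    "Positive-Low", "Negative")

#' Column mapping for raw binding tables
#'
#' Raw qualitative binding tables come in several dialects; the mapping names
#' the columns holding the peptide sequence, the MHC allele name, the
#' qualitative label and the data-source identifier (e.g. a PubMed ID). The
#' defaults match the cleaned-dataset dialect this package writes.
#'
#' @param peptide,allele,label,source column names in the raw file.
#' @return a named list usable as the `columns` argument of
#'   [parse_binding_table()].
#' @export
binding_columns <- function(peptide = "peptide", allele = "allele",
                            label = "label", source = "source") {
  list(peptide = peptide, allele = allele, label = label, source = source)
}

#' Normalize an MHC allele name
#'
#' Strips whitespace, upper-cases, and truncates the colon-separated field
#' list to two fields (4-digit resolution), so that e.g. `"hla-a*02:01:01"`
#' becomes `"HLA-A*02:01"`. No attempt is made to expand non-specific names
#' such as `"HLA-A30"`; those are left as-is and rejected later by
#' [filter_record()].
#'
#' @param x character vector of allele names.
#' @return character vector of normalized names.
#' @export
normalize_allele_name <- function(x) {
  x <- toupper(gsub("[[:space:]]+", "", as.character(x)))
  # keep gene*group:protein, drop synonymous/non-coding fields beyond two
  sub("^([^*]+\\*[0-9]+:[0-9]+).*$", "\\1", x)
}

#' Test whether an allele name is fully specified
#'
#' A fully specified (4-digit resolution) class I allele name has the form
#' `gene*group:protein`, e.g. `"HLA-A*02:01"`. Names like `"HLA-A30"` or
#' `"MHC class I"` are non-specific.
#'
#' @param x character vector of (normalized) allele names.
#' @return logical vector.
#' @export
is_specific_allele <- function(x) {
  grepl("^[A-Z0-9]+(-[A-Z0-9]+)?\\*[0-9]+:[0-9]+$", x)
}

canonical_label <- function(x) {
  key <- tolower(gsub("[[:space:]_]+", "-", trimws(as.character(x))))
  BINDING_LABELS[match(key, tolower(BINDING_LABELS))]
}

#' Parse a raw qualitative binding table
#'
#' Reads a TSV (or CSV) with a header row, extracts the four configured
#' columns, normalizes allele names and canonicalizes qualitative labels.
#' Rows whose label is not one of the five recognized classes are returned
#' in a `rejects` table rather than silently dropped.
#'
#' @param path path to the table.
#' @param columns a mapping from [binding_columns()].
#' @param sep field separator (default tab).
#' @return a list with elements `records` (a `data.table` with columns
#'   `peptide`, `allele_name`, `qualitative_label`, `source_id`) and
#'   `rejects` (rows with unparseable labels, with a `reject_reason` column).
#' @export
parse_binding_table <- function(path, columns = binding_columns(), sep = "\t") {
  if (!file.exists(path)) stop("binding table not found: ", path)
  raw <- data.table::fread(path, sep = sep, header = TRUE,
                           colClasses = "character", data.table = TRUE)
  needed <- unlist(columns)
  missing <- setdiff(needed, names(raw))
  if (length(missing) > 0) {
    stop("missing column(s) in ", path, ": ", paste(missing, collapse = ", "))
  }
  if (nrow(raw) == 0) {
    warning("empty binding table: ", path)
    empty <- data.table::data.table(peptide = character(), allele_name = character(),
                                    qualitative_label = character(), source_id = character())
    return(list(records = empty, rejects = data.table::copy(empty)[, reject_reason := character()]))
  }
  dt <- data.table::data.table(
    peptide = toupper(trimws(raw[[columns$peptide]])),
    allele_name = normalize_allele_name(raw[[columns$allele]]),
    qualitative_label = canonical_label(raw[[columns$label]]),
    source_id = trimws(raw[[columns$source]])
  )
  bad <- is.na(dt$qualitative_label) | !nzchar(dt$peptide)
  rejects <- dt[bad]
  if (nrow(rejects) > 0) {
    rejects[, reject_reason := ifelse(!nzchar(peptide), "empty_peptide", "unparseable_label")]
    mhc_log("parse_binding_table: %d row(s) rejected", nrow(rejects))
  } else {
    rejects[, reject_reason := character()]
  }
  list(records = dt[!bad], rejects = rejects)
}

#' Filter a single binding record
#'
#' Applies the record-level exclusion rules in a fixed order and reports the
#' first failing rule: (1) non-specific allele name; (2, sequence mode only)
#' allele without a known groove sequence; (3) peptide length outside
#' `[min_len, max_len]`; (4) letters outside the 20 standard amino acids
#' (this covers the ambiguity codes B, X, J and Z). The order affects only
#' which reason is reported, never which records survive.
#'
#' @param peptide peptide sequence (string).
#' @param allele_name normalized allele name.
#' @param known_alleles optional character vector of alleles with available
#'   sequences; when supplied, records with other alleles are dropped
#'   (`unknown_allele_sequence`).
#' @param min_len,max_len allowed peptide length range (default 8--15).
#' @return `list(keep = TRUE)` or `list(keep = FALSE, reason = <code>)` with
#'   reason one of `"nonspecific_allele"`, `"unknown_allele_sequence"`,
#'   `"length"`, `"ambiguous_aa"`.
#' @export
filter_record <- function(peptide, allele_name, known_alleles = NULL,
                          min_len = 8L, max_len = 15L) {
  stopifnot(is_string(peptide), is_string(allele_name))
  reason <- filter_reasons(peptide, allele_name, known_alleles, min_len, max_len)
  if (is.na(reason)) list(keep = TRUE) else list(keep = FALSE, reason = reason)
}

# Vectorised rule engine shared by filter_record() and clean_binding_data().
# Returns NA for kept rows, else the first failing rule code.
filter_reasons <- function(peptide, allele_name, known_alleles = NULL,
                           min_len = 8L, max_len = 15L) {
  reason <- rep(NA_character_, length(peptide))
  bad <- !is_specific_allele(allele_name)
  reason[bad] <- "nonspecific_allele"
  if (!is.null(known_alleles)) {
    bad2 <- is.na(reason) & !(allele_name %in% known_alleles)
    reason[bad2] <- "unknown_allele_sequence"
  }
  len <- nchar(peptide)
  bad3 <- is.na(reason) & (len < min_len | len > max_len)
  reason[bad3] <- "length"
  bad4 <- is.na(reason) & !is_standard_peptide(peptide)
  reason[bad4] <- "ambiguous_aa"
  reason
}

#' Map a qualitative label to a binary target
#'
#' Under the default `"strict"` policy, high-confidence labels map to
#' binary classes (`Positive-High`/`Positive` to 1, `Negative` to 0) and the
#' low-confidence labels `Positive-Intermediate` and `Positive-Low` are
#' dropped, which was found to slightly improve prediction performance. The
#' `"lenient"` policy keeps the low-confidence labels as positives.
#'
#' @param q qualitative label (one of [BINDING_LABELS]).
#' @param policy `"strict"` (default) or `"lenient"`.
#' @return `1L`, `0L`, or the string `"drop"`.
#' @export
map_label <- function(q, policy = c("strict", "lenient")) {
  policy <- match.arg(policy)
  stopifnot(is_string(q))
  q <- canonical_label(q)
  if (is.na(q)) stop("unknown qualitative label: ", q)
  v <- map_labels(q, policy)
  if (is.na(v)) "drop" else v
}

map_labels <- function(q, policy = "strict") {
  pos <- c("Positive-High", "Positive")
  if (policy == "lenient") pos <- c(pos, "Positive-Intermediate", "Positive-Low")
  out <- rep(NA_integer_, length(q))
  out[q %in% pos] <- 1L
  out[q == "Negative"] <- 0L
  if (any(!q %in% BINDING_LABELS)) {
    stop("unknown qualitative label: ",
         paste(unique(q[!q %in% BINDING_LABELS]), collapse = ", "))
  }
  out
}

#' Resolve duplicated and conflicting binding records
#'
#' Given records with binary labels, (1) removes all records from
#' blacklisted sources, (2) collapses duplicate (peptide, allele) groups
#' with identical labels to one record, (3) reassigns mixed-label groups by
#' majority vote over distinct records, and (4) removes groups with an exact
#' positive/negative tie entirely. Step (1) precedes voting, so a blacklisted
#' source never influences a vote.
#'
#' @param records a `data.table`/`data.frame` with columns `peptide`,
#'   `allele_name`, `binary_label` (0/1) and optionally `source_id`.
#' @param blacklist character vector of `source_id` values to exclude wholesale.
#' @return a `cleaned_dataset`: list with `records` (unique
#'   (peptide, allele) rows with `binary_label`), `audit` (named drop counts)
#'   and `blacklist`.
#' @export
resolve_conflicts <- function(records, blacklist = character()) {
  dt <- data.table::as.data.table(records)
  req <- c("peptide", "allele_name", "binary_label")
  if (!all(req %in% names(dt))) {
    stop("records must have columns: ", paste(req, collapse = ", "))
  }
  if (anyNA(dt$binary_label)) stop("all records must have binary_label set")
  if (!"source_id" %in% names(dt)) dt[, source_id := NA_character_]
  n_in <- nrow(dt)

  drop_black <- dt$source_id %in% blacklist
  n_black <- sum(drop_black)
  dt <- dt[!drop_black]

  grp <- dt[, .(n_pos = sum(binary_label == 1L), n_neg = sum(binary_label == 0L)),
            by = .(peptide, allele_name)]
  grp[, n_tot := n_pos + n_neg]
  pure <- grp[n_pos == 0L | n_neg == 0L]
  mixed <- grp[n_pos > 0L & n_neg > 0L & n_pos != n_neg]
  tied <- grp[n_pos > 0L & n_pos == n_neg]

  out <- data.table::rbindlist(list(
    pure[, .(peptide, allele_name, binary_label = as.integer(n_pos > 0L))],
    mixed[, .(peptide, allele_name, binary_label = as.integer(n_pos > n_neg))]
  ))
  data.table::setkey(out, allele_name, peptide)

  audit <- c(
    blacklisted_source = n_black,
    duplicate_collapsed = sum(pure$n_tot) - nrow(pure),
    conflict_majority_dropped = if (nrow(mixed)) sum(mixed$n_tot) - nrow(mixed) else 0L,
    conflict_tie_removed = if (nrow(tied)) sum(tied$n_tot) else 0L
  )
  stopifnot(n_in == nrow(out) + sum(audit))
  structure(list(records = out[], audit = audit, blacklist = blacklist),
            class = "cleaned_dataset")
}

#' End-to-end curation of a raw binding table
#'
#' Convenience pipeline: [parse_binding_table()], [filter_record()] rules,
#' label mapping, and [resolve_conflicts()], with a combined audit that
#' satisfies the conservation property `rows_in = rows_out + sum(drops)`.
#'
#' @inheritParams parse_binding_table
#' @inheritParams resolve_conflicts
#' @param label_policy `"strict"` or `"lenient"`, see [map_label()].
#' @param known_alleles optional allele whitelist (sequence mode).
#' @param min_len,max_len peptide length bounds.
#' @return a `cleaned_dataset` whose `audit` covers every stage.
#' @export
clean_binding_data <- function(path, columns = binding_columns(), sep = "\t",
                               blacklist = character(),
                               label_policy = c("strict", "lenient"),
                               known_alleles = NULL, min_len = 8L, max_len = 15L) {
  label_policy <- match.arg(label_policy)
  parsed <- parse_binding_table(path, columns, sep)
  dt <- parsed$records
  n_reject <- nrow(parsed$rejects)

  reason <- filter_reasons(dt$peptide, dt$allele_name, known_alleles, min_len, max_len)
  filter_counts <- c(
    nonspecific_allele = sum(reason == "nonspecific_allele", na.rm = TRUE),
    unknown_allele_sequence = sum(reason == "unknown_allele_sequence", na.rm = TRUE),
    length = sum(reason == "length", na.rm = TRUE),
    ambiguous_aa = sum(reason == "ambiguous_aa", na.rm = TRUE)
  )
  dt <- dt[is.na(reason)]

  dt[, binary_label := map_labels(qualitative_label, label_policy)]
  n_lowconf <- sum(is.na(dt$binary_label))
  dt <- dt[!is.na(binary_label)]

  ds <- resolve_conflicts(dt[, .(peptide, allele_name, binary_label, source_id)],
                          blacklist = blacklist)
  ds$audit <- c(unparseable_row = n_reject, filter_counts,
                low_confidence_label = n_lowconf, ds$audit)
  ds$label_policy <- label_policy
  ds
}

#' @export
print.cleaned_dataset <- function(x, ...) {
  cat(sprintf("cleaned peptide-MHC dataset: %d entries, %d alleles\n",
              nrow(x$records), length(unique(x$records$allele_name))))
  cat("audit (dropped records per rule):\n")
  for (nm in names(x$audit)) cat(sprintf("  %-26s %d\n", nm, x$audit[[nm]]))
  invisible(x)
}

#' Summarise a cleaned dataset
#'
#' Reports total entries, distinct alleles per gene, the range of entries
#' per allele, and the fraction of entries per gene. Because "ligands per
#' allele" can be read as all entries or positives only, both counts are
#' reported.
#'
#' @param ds a `cleaned_dataset` (or its `records` table).
#' @param digits rounding for percentages.
#' @return a list with `n_records`, `alleles_per_gene`, `entries_per_allele`
#'   (min/max over all entries), `positives_per_allele` (min/max over
#'   positive entries), and `gene_fraction` (named percentages).
#' @export
dataset_summary <- function(ds, digits = 1L) {
  dt <- if (inherits(ds, "cleaned_dataset")) ds$records else data.table::as.data.table(ds)
  if (nrow(dt) == 0) {
    warning("empty dataset")
    return(list(n_records = 0L, alleles_per_gene = integer(),
                entries_per_allele = c(min = 0L, max = 0L),
                positives_per_allele = c(min = 0L, max = 0L),
                gene_fraction = numeric()))
  }
  dt <- data.table::copy(dt)
  dt[, gene := sub("\\*.*$", "", allele_name)]
  per_allele <- dt[, .(n_tot = .N, n_pos = sum(binary_label == 1L)), by = .(gene, allele_name)]
  genes <- per_allele[, .(n_alleles = .N), by = gene][order(gene)]
  gene_n <- dt[, .N, by = gene][order(gene)]
  list(
    n_records = nrow(dt),
    alleles_per_gene = setNames(genes$n_alleles, genes$gene),
    entries_per_allele = c(min = min(per_allele$n_tot), max = max(per_allele$n_tot)),
    positives_per_allele = c(min = min(per_allele$n_pos), max = max(per_allele$n_pos)),
    gene_fraction = setNames(round(100 * gene_n$N / nrow(dt), digits), gene_n$gene)
  )
}

#' Write / read a cleaned dataset as TSV
#'
#' The cleaned TSV has columns `allele`, `peptide`, `label` (0/1). The audit
#' is written as one `rule<TAB>count` line per rule.
#'
#' @param ds a `cleaned_dataset`.
#' @param path output TSV path.
#' @param audit_path optional path for the audit table.
#' @return `path`, invisibly.
#' @export
write_cleaned_tsv <- function(ds, path, audit_path = NULL) {
  stopifnot(inherits(ds, "cleaned_dataset"))
  out <- ds$records[, .(allele = allele_name, peptide, label = binary_label)]
  data.table::fwrite(out, path, sep = "\t")
  if (!is.null(audit_path)) {
    writeLines(sprintf("%s\t%d", names(ds$audit), ds$audit), audit_path)
  }
  invisible(path)
}

#' @rdname write_cleaned_tsv
#' @export
read_cleaned_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = c("allele", "peptide")))
  stopifnot(all(c("allele", "peptide", "label") %in% names(dt)))
  rec <- dt[, .(peptide, allele_name = allele, binary_label = as.integer(label))]
  structure(list(records = rec, audit = integer(0), blacklist = character()),
            class = "cleaned_dataset")
}
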