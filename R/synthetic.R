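## synthetic_data: motif-based synthetic alleles, binding records, corpora
## and peptidome samples with a known ground-truth rule, so the whole
## pipeline trains and tests offline.

# Fixed, documented pseudo-sequence positions that carry the binding rule:
# the residues found at RULE_POS_ANCHOR2 are the allele's preferred residues
# at peptide position 2; those at RULE_POS_CTERM are preferred at the
# C-terminus. Fixing the positions makes pseudo-sequence -> preference a
# deterministic, learnable function.
RULE_POS_ANCHOR2 <- 3:4
RULE_POS_CTERM <- 45:46

#' Generate synthetic MHC alleles with a motif-based binding rule
#'
#' Groove pseudo-sequences are built from one shared random template --
#' class I groove sequences are highly conserved across alleles -- with a
#' small fraction of positions mutated per allele
#' (`background_mutation_rate`) and four fixed rule-carrying positions
#' overwritten by the allele's preference profile: its preferred residues
#' for the two peptide anchors (position 2 and the C-terminus), mimicking
#' real MHC class I anchor biology. A peptide binds an allele iff both
#' anchor residues are in the allele's preference sets. Distinct profiles
#' use disjoint preference sets (as far as the alphabet allows), like the
#' largely non-overlapping anchor motifs of real supertypes. Alleles can
#' share a profile (`n_distinct_rules < n_alleles`), in which case they
#' carry identical residues at the rule positions but differ at their
#' polymorphic background positions; this is what makes sequence-based
#' generalization to a held-out allele learnable.
#'
#' @param n_alleles number of alleles.
#' @param pseudo_length pseudo-sequence length (75 mirrors the real groove).
#' @param n_distinct_rules number of distinct preference profiles; alleles
#'   are assigned profiles cyclically.
#' @param background_mutation_rate per-position probability that an allele
#'   deviates from the shared background template (real groove sequences
#'   differ at only a few percent of positions between alleles).
#' @param seed RNG seed (fully deterministic output).
#' @return a `synthetic_alleles` object: `registry` (allele names),
#'   `pseudo` (pseudo-sequence table), `preferences` (per allele, the two
#'   preference sets), and `rule` (a function `(peptide, allele) -> 0/1`).
#' @export
synthetic_alleles <- function(n_alleles = 8L, pseudo_length = 75L,
                              n_distinct_rules = n_alleles,
                              background_mutation_rate = 0.02, seed = 1L) {
  stopifnot(n_alleles >= 1, pseudo_length >= max(RULE_POS_CTERM),
            n_distinct_rules >= 1, n_distinct_rules <= n_alleles)
  set.seed(derive_seed(seed, "alleles"))
  # Distinct rule profiles use disjoint anchor-preference sets (as far as the
  # 20-letter alphabet allows), mirroring the largely non-overlapping anchor
  # motifs of real class I supertypes; this keeps the allele identity, not
  # the peptide alone, informative about binding.
  npref <- length(RULE_POS_ANCHOR2)
  perm_a <- sample(AA_LETTERS); perm_c <- sample(AA_LETTERS)
  profiles <- lapply(seq_len(n_distinct_rules), function(i) {
    idx <- ((i - 1L) * npref + seq_len(npref) - 1L) %% length(AA_LETTERS) + 1L
    list(anchor2 = perm_a[idx], cterm = perm_c[idx])
  })
  registry <- sprintf("SYN-%s*%02d:01", LETTERS[(seq_len(n_alleles) - 1L) %% 26 + 1L],
                      seq_len(n_alleles))
  template <- sample(AA_LETTERS, pseudo_length, replace = TRUE)
  prefs <- list(); rows <- character(n_alleles)
  for (i in seq_len(n_alleles)) {
    pr <- profiles[[(i - 1L) %% n_distinct_rules + 1L]]
    bg <- template
    mut <- runif(pseudo_length) < background_mutation_rate
    if (any(mut)) bg[mut] <- sample(AA_LETTERS, sum(mut), replace = TRUE)
    bg[RULE_POS_ANCHOR2] <- pr$anchor2
    bg[RULE_POS_CTERM] <- pr$cterm
    rows[i] <- paste(bg, collapse = "")
    prefs[[registry[i]]] <- pr
  }
  rule <- function(peptide, allele) {
    pr <- prefs[[allele]]
    if (is.null(pr)) stop("unknown synthetic allele: ", allele)
    p2 <- substr(peptide, 2L, 2L)
    pc <- substr(peptide, nchar(peptide), nchar(peptide))
    as.integer(p2 %in% pr$anchor2 & pc %in% pr$cterm)
  }
  structure(list(registry = registry,
                 pseudo = data.table::data.table(allele = registry,
                                                 groove_sequence = rows),
                 preferences = prefs, rule = rule,
                 spec = list(n_alleles = n_alleles, pseudo_length = pseudo_length,
                             n_distinct_rules = n_distinct_rules, seed = seed)),
            class = "synthetic_alleles")
}

random_peptide <- function(len) {
  paste(sample(AA_LETTERS, len, replace = TRUE), collapse = "")
}

positive_peptide <- function(len, pr) {
  p <- sample(AA_LETTERS, len, replace = TRUE)
  p[2L] <- sample(pr$anchor2, 1L)
  p[len] <- sample(pr$cterm, 1L)
  paste(p, collapse = "")
}

#' Generate a synthetic binding dataset
#'
#' Samples peptides with lengths uniform on `length_range` and alleles
#' uniform over the registry. A `positive_fraction` share of peptides is
#' constructed to satisfy the assigned allele's rule (anchors drawn from the
#' preference sets); labels always equal the re-evaluated rule output, then
#' each label is independently flipped with probability `noise`. The flip
#' mask is recorded so noise-level checks are exact. (Peptide, allele) pairs
#' are unique.
#'
#' @param alleles a [synthetic_alleles()] object.
#' @param n_records number of records.
#' @param length_range inclusive peptide length range (within 8--15).
#' @param positive_fraction fraction of peptides constructed to bind their
#'   assigned allele.
#' @param decoy_fraction fraction of peptides constructed to bind a
#'   *different* allele than the one they are paired with (usually yielding
#'   negatives). Such mismatched pairs are ubiquitous in real qualitative
#'   binding data -- a ligand of one allele tested against another -- and
#'   they force models to use the allele input rather than the peptide's
#'   marginal label frequency. The default equals `positive_fraction`, which
#'   balances matched and mismatched pairings exactly, so an anchor pattern
#'   alone carries no information about the label; the remaining records are
#'   unconstructed random peptides.
#' @param noise label-flip probability, in `[0, 0.5)`.
#' @param seed RNG seed.
#' @return a `synthetic_dataset`: list with `records` (a `data.table` of
#'   `peptide`, `allele_name`, `binary_label`), `truth` (noise-free rule
#'   labels), `flipped` (logical mask), and the generating `alleles`.
#' @export
synthetic_binding_data <- function(alleles, n_records = 5000L,
                                   length_range = c(8L, 15L),
                                   positive_fraction = 0.45,
                                   decoy_fraction = 0.45, noise = 0.05,
                                   seed = 1L) {
  stopifnot(inherits(alleles, "synthetic_alleles"),
            noise >= 0, noise < 0.5,
            length_range[1] >= 8L, length_range[2] <= 15L,
            positive_fraction >= 0, decoy_fraction >= 0,
            positive_fraction + decoy_fraction <= 1)
  n_constructed <- round(positive_fraction * n_records)
  if (positive_fraction > 0 && n_constructed < 1) {
    stop("infeasible positive fraction ", positive_fraction,
         " at n_records = ", n_records)
  }
  n_decoy <- round(decoy_fraction * n_records)
  n_alle <- length(alleles$registry)
  set.seed(derive_seed(seed, "binding_data"))
  seen <- new.env(hash = TRUE)
  pep <- character(n_records); alle <- character(n_records)
  i <- 0L
  while (i < n_records) {
    kind <- if ((i + 1L) <= n_constructed) "pos" else {
      if ((i + 1L) <= n_constructed + n_decoy && n_alle > 1L) "decoy" else "rand"
    }
    a <- sample(alleles$registry, 1L)
    len <- sample(length_range[1]:length_range[2], 1L)
    p <- switch(kind,
      pos = positive_peptide(len, alleles$preferences[[a]]),
      decoy = {
        donor <- sample(setdiff(alleles$registry, a), 1L)
        positive_peptide(len, alleles$preferences[[donor]])
      },
      rand = random_peptide(len))
    key <- paste0(p, "|", a)
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    i <- i + 1L
    pep[i] <- p; alle[i] <- a
  }
  truth <- mapply(alleles$rule, pep, alle, USE.NAMES = FALSE)
  flipped <- runif(n_records) < noise
  labels <- ifelse(flipped, 1L - truth, truth)
  structure(list(
    records = data.table::data.table(peptide = pep, allele_name = alle,
                                     binary_label = as.integer(labels)),
    truth = as.integer(truth), flipped = flipped, alleles = alleles,
    spec = list(n_records = n_records, length_range = length_range,
                positive_fraction = positive_fraction,
                decoy_fraction = decoy_fraction, noise = noise, seed = seed)
  ), class = "synthetic_dataset")
}

#' Generate a synthetic pre-training corpus
#'
#' Uniform-random protein sequences (FASTA) plus 9-mers cut from them at
#' random offsets, standing in for a large curated protein corpus and for
#' proteasome-cleaved peptide lists.
#'
#' @param n_proteins number of proteins.
#' @param length_range protein length range.
#' @param n_ninemers number of 9-mers to cut.
#' @param seed RNG seed.
#' @param fasta,peptides optional output paths; written when given.
#' @return list with `proteins` (named character) and `ninemers` (character),
#'   plus `fasta`/`peptides` paths when written.
#' @export
synthetic_corpus <- function(n_proteins = 50L, length_range = c(50L, 100L),
                             n_ninemers = 10L * n_proteins, seed = 1L,
                             fasta = NULL, peptides = NULL) {
  stopifnot(n_proteins >= 1, length_range[1] >= 9L)
  set.seed(derive_seed(seed, "corpus"))
  prot <- vapply(seq_len(n_proteins), function(i) {
    random_peptide(sample(length_range[1]:length_range[2], 1L))
  }, character(1))
  names(prot) <- sprintf("synprot%04d", seq_len(n_proteins))
  idx <- sample.int(n_proteins, n_ninemers, replace = TRUE)
  nine <- vapply(idx, function(i) {
    start <- sample.int(nchar(prot[i]) - 8L, 1L)
    substr(prot[i], start, start + 8L)
  }, character(1))
  out <- list(proteins = prot, ninemers = nine)
  if (!is.null(fasta)) {
    Biostrings::writeXStringSet(Biostrings::AAStringSet(prot), fasta)
    out$fasta <- fasta
  }
  if (!is.null(peptides)) {
    writeLines(nine, peptides)
    out$peptides <- peptides
  }
  out
}

#' Generate a synthetic peptidome sample
#'
#' Emulates one individual: positives satisfy the binding rule for at least
#' one of the sample's alleles, negatives satisfy it for none, and the two
#' sets are disjoint.
#'
#' @param alleles a [synthetic_alleles()] object.
#' @param sample_alleles allele names typed for this individual (defaults to
#'   the first three of the registry).
#' @param n_pos,n_neg set sizes.
#' @param length_range peptide length range.
#' @param seed RNG seed.
#' @param sample_id identifier.
#' @return a [peptidome_sample()].
#' @export
synthetic_peptidome <- function(alleles, sample_alleles = NULL,
                                n_pos = 100L, n_neg = 100L,
                                length_range = c(8L, 15L), seed = 1L,
                                sample_id = "SYN-IND-1") {
  stopifnot(inherits(alleles, "synthetic_alleles"))
  if (is.null(sample_alleles)) {
    sample_alleles <- head(alleles$registry, min(3L, length(alleles$registry)))
  }
  stopifnot(all(sample_alleles %in% alleles$registry), length(sample_alleles) >= 1)
  set.seed(derive_seed(seed, "peptidome"))
  passes_any <- function(p) {
    any(vapply(sample_alleles, function(a) alleles$rule(p, a) == 1L, logical(1)))
  }
  pos <- character(0)
  while (length(pos) < n_pos) {
    a <- sample(sample_alleles, 1L)
    p <- positive_peptide(sample(length_range[1]:length_range[2], 1L),
                          alleles$preferences[[a]])
    if (passes_any(p)) pos <- union(pos, p)
  }
  neg <- character(0)
  while (length(neg) < n_neg) {
    p <- random_peptide(sample(length_range[1]:length_range[2], 1L))
    if (!passes_any(p) && !p %in% pos) neg <- union(neg, p)
  }
  peptidome_sample(sample_id, sample_alleles, pos[seq_len(n_pos)], neg[seq_len(n_neg)])
}

#' Write a synthetic dataset in the pipeline's file formats
#'
#' Emits the cleaned-TSV binding table, the pseudo-sequence TSV, a corpus
#' FASTA and 9-mer list, and a ground-truth table (with the flip mask) into
#' `dir`.
#'
#' @param dataset a [synthetic_binding_data()] result.
#' @param dir output directory (created if needed).
#' @param corpus optionally also write a [synthetic_corpus()] (logical).
#' @param seed seed for the corpus.
#' @return `dir`, invisibly.
#' @export
write_synthetic_dataset <- function(dataset, dir, corpus = TRUE, seed = 1L) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ds <- structure(list(records = dataset$records, audit = integer(0),
                       blacklist = character()), class = "cleaned_dataset")
  write_cleaned_tsv(ds, file.path(dir, "binding.tsv"))
  write_pseudo_tsv(dataset$alleles$pseudo, file.path(dir, "pseudo.tsv"))
  truth <- data.table::copy(dataset$records)
  truth[, `:=`(truth = dataset$truth, flipped = dataset$flipped)]
  data.table::fwrite(truth, file.path(dir, "ground_truth.tsv"), sep = "\t")
  if (isTRUE(corpus)) {
    synthetic_corpus(seed = seed, fasta = file.path(dir, "corpus.fasta"),
                     peptides = file.path(dir, "ninemers.txt"))
  }
  invisible(dir)
}
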