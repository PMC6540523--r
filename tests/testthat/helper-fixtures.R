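# Shared fixture builders. Everything is generated in code; no binary data.

# A tiny model configuration that trains in seconds; used wherever the test
# is about a contract, not about accuracy.
tiny_config <- function(...) {
  base <- list(gru_units = 4L, mhc_fc_units = 6L, mhc_gru_units = 4L,
               head_fc_units = 8L, mhc_token_dim = 3L, pep_embed_dim = 4L,
               dropout_fc_out = 0, dropout_gru_in = 0,
               dropout_gru_recurrent = 0, dropout_mhc_pos = 0,
               batch_size = 64L, max_epochs = 3L, min_epochs = 1L,
               patience = 2L, seed = 1L)
  do.call(model_config, utils::modifyList(base, list(...)))
}

# Write an aligned FASTA to a temp file and return its path.
write_fasta <- function(seqs, path = tempfile(fileext = ".fasta")) {
  lines <- character(0)
  for (nm in names(seqs)) lines <- c(lines, paste0(">", nm), seqs[[nm]])
  writeLines(lines, path)
  path
}

# Brute-force all-pairs AUC oracle: P(score_pos > score_neg) + half ties.
auc_bruteforce <- function(scores, labels) {
  sp <- scores[labels == 1]; sn <- scores[labels == 0]
  tot <- 0
  for (p in sp) tot <- tot + sum(p > sn) + 0.5 * sum(p == sn)
  tot / (length(sp) * length(sn))
}

# Exhaustive best-F1 oracle: evaluate F1 at every distinct threshold.
best_f1_bruteforce <- function(scores, labels) {
  ths <- sort(unique(scores), decreasing = TRUE)
  f1s <- vapply(ths, function(th) {
    pred <- scores >= th
    tp <- sum(pred & labels == 1)
     2 * tp / (sum(pred) + sum(labels == 1))
  }, numeric(1))
  list(f1 = max(f1s), threshold = ths[which.max(f1s)])
}

# Small trained-free binding model over a synthetic allele set.
tiny_model <- function(seed = 1L, n_alleles = 3L, ...) {
  al <- synthetic_alleles(n_alleles = n_alleles, seed = seed)
  list(alleles = al, model = build_model(tiny_config(seed = seed, ...), pseudo = al$pseudo))
}
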