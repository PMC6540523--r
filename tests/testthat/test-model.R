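test_that("build_model propagates embedding shapes and validates inputs", {
  al <- synthetic_alleles(n_alleles = 3L, seed = 2L)
  emb <- train_skipgram(replicate(30, sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 10, TRUE),
                                  simplify = FALSE),
                        embedding_config(dim = 5L, epochs = 1L, seed = 1L))
  m <- build_model(tiny_config(), embeddings = emb, pseudo = al$pseudo)
  expect_equal(ncol(m$params$pep_emb), 5L)
  # pre-trained rows are copied where tokens match
  expect_equal(m$params$pep_emb["A", ], emb$vectors["A", ])

  bad <- structure(list(vectors = matrix(0, 5, 4,
                                         dimnames = list(c("ACD", "EFG", "HIK", "LMN", "PQR"), NULL)),
                        metadata = list()), class = "embedding_table")
  expect_error(build_model(tiny_config(peptide_repr = "gram3"), embeddings = bad,
                           pseudo = al$pseudo),
               "100.*4|4.*100")
  expect_error(build_model(tiny_config()), "pseudo")
  expect_error(build_model(tiny_config(mhc_repr = "one_hot_allele")), "registry")
})

test_that("prediction is deterministic, bounded, and length flexible", {
  tm <- tiny_model(seed = 4L)
  p8 <- predict_binding(tm$model, "ACDEFGHK", tm$alleles$registry[1])
  p15 <- predict_binding(tm$model, strrep("ACDEF", 3), tm$alleles$registry[1])
  expect_true(p8 > 0 && p8 < 1 && p15 > 0 && p15 < 1)
  expect_identical(p8, predict_binding(tm$model, "ACDEFGHK", tm$alleles$registry[1]))
  expect_error(predict_binding(tm$model, "ACDEFGXZ", tm$alleles$registry[1]),
               "non-standard")
})

test_that("one-hot allele mode rejects unseen alleles, sequence mode scores them", {
  al <- synthetic_alleles(n_alleles = 4L, seed = 3L)
  m_oh <- build_model(tiny_config(mhc_repr = "one_hot_allele"),
                      allele_registry = al$registry[1:3])
  expect_error(predict_binding(m_oh, "ACDEFGHK", al$registry[4]), "unsupported")
  m_seq <- build_model(tiny_config(), pseudo = al$pseudo)
  expect_silent(p <- predict_binding(m_seq, "ACDEFGHK", al$registry[4]))
  expect_true(p > 0 && p < 1)
  expect_error(predict_binding(m_seq, "ACDEFGHK", "HLA-A*99:99"), "pseudo-sequence")
})

test_that("train_fold validates inputs and restores best-validation weights", {
  al <- synthetic_alleles(n_alleles = 4L, seed = 6L)
  ds <- synthetic_binding_data(al, n_records = 600L, noise = 0, seed = 6L)
  rec <- ds$records
  split <- mhcbindr:::grouped_folds(rec$peptide, 5L, 1L)
  val <- split[rec$peptide] == 1L
  m <- build_model(tiny_config(max_epochs = 6L), pseudo = al$pseudo)

  expect_error(train_fold(m, rec[0], rec[val]), "empty")
  one_class <- rec[binary_label == 0L]
  expect_error(train_fold(m, one_class[1:50], rec[val]), "both classes")
  expect_error(train_fold(m, rec, rec[1:5]), "share peptide")

  fitted <- train_fold(m, rec[!val], rec[val])
  expect_s3_class(fitted$history, "data.frame")
  enc_val <- list(pep = mhcbindr:::encode_peptides(fitted, rec$peptide[val]),
                  mhc = mhcbindr:::encode_alleles(fitted, rec$allele_name[val]))
  restored <- mhcbindr:::eval_loss(fitted, enc_val$pep, enc_val$mhc,
                                   as.numeric(rec$binary_label[val]))
  expect_equal(restored, min(fitted$history$val_loss), tolerance = 1e-10)
  expect_lte(restored, fitted$history$val_loss[nrow(fitted$history)] + 1e-10)
})

test_that("the adaptation schedule runs three phases with 1-3 trainable epochs", {
  al <- synthetic_alleles(n_alleles = 3L, seed = 9L)
  ds <- synthetic_binding_data(al, n_records = 400L, noise = 0, seed = 9L)
  rec <- ds$records
  split <- mhcbindr:::grouped_folds(rec$peptide, 5L, 2L)
  val <- split[rec$peptide] == 1L
  m <- build_model(tiny_config(max_epochs = 4L), pseudo = al$pseudo)
  fitted <- train_fold(m, rec[!val], rec[val], schedule = finetune_schedule(2L))
  phases <- unique(fitted$history$phase)
  expect_equal(phases, c("frozen", "adapt", "refrozen"))
  n_adapt <- sum(fitted$history$phase == "adapt")
  expect_gte(n_adapt, 1L); expect_lte(n_adapt, 2L)
  expect_error(finetune_schedule(4L), "1, 2, or 3")
})

test_that("cross_validate groups peptides, covers every record once, balances folds", {
  al <- synthetic_alleles(n_alleles = 4L, seed = 12L)
  ds <- synthetic_binding_data(al, n_records = 500L, noise = 0.05, seed = 12L)
  # duplicate some peptides across alleles to exercise grouping
  extra <- data.table::copy(ds$records[1:40])
  extra[, allele_name := al$registry[(match(allele_name, al$registry) %% 4) + 1L]]
  rec <- unique(data.table::rbindlist(list(ds$records, extra)), by = c("peptide", "allele_name"))
  cv <- cross_validate(rec, tiny_config(max_epochs = 2L), pseudo = al$pseudo, k = 5L)
  preds <- cv$predictions
  expect_equal(nrow(preds), nrow(rec))
  expect_equal(anyDuplicated(preds[, .(peptide, allele)]), 0L)
  # no peptide appears in two folds
  fold_span <- preds[, data.table::uniqueN(fold), by = peptide]$V1
  expect_true(all(fold_span == 1L))
  # fold sizes within one largest-group size of each other
  sizes <- preds[, .N, by = fold]$N
  max_group <- max(table(rec$peptide))
  expect_lte(max(sizes) - min(sizes), max_group)
  expect_length(cv$ensemble$members, 5L)
  expect_error(cross_validate(rec[peptide %in% rec$peptide[1:3]],
                              tiny_config(), pseudo = al$pseudo, k = 5L),
               "fewer peptide groups")
})

test_that("ensemble aggregation is the member-wise median, bounded by member range", {
  al <- synthetic_alleles(n_alleles = 3L, seed = 21L)
  members <- lapply(1:5, function(s) {
    m <- build_model(tiny_config(seed = s), pseudo = al$pseudo)
    m$train_peptides <- character(0)
    m
  })
  ens <- structure(list(members = members, aggregation = "median",
                        train_peptides = character(0)), class = "ensemble_model")
  set.seed(31)
  peps <- replicate(20, paste(sample(c("A","C","D","E","F","G","H","I","K"), 9, TRUE),
                              collapse = ""))
  alls <- sample(al$registry, 20, TRUE)
  scores <- ensemble_predict(ens, peps, alls)
  member_scores <- sapply(members, function(m) predict_binding(m, peps, alls))
  expect_equal(scores, apply(member_scores, 1, median), tolerance = 1e-12)
  expect_true(all(scores >= apply(member_scores, 1, min) - 1e-12))
  expect_true(all(scores <= apply(member_scores, 1, max) + 1e-12))
})

test_that("model checkpoints round-trip through save/load", {
  tm <- tiny_model(seed = 14L)
  dir <- tempfile()
  save_model(tm$model, dir)
  expect_true(file.exists(file.path(dir, "config.json")))
  back <- load_model(dir)
  peps <- c("ACDEFGHK", "WYVMNPQRST")
  expect_identical(predict_binding(back, peps, tm$alleles$registry[1]),
                   predict_binding(tm$model, peps, tm$alleles$registry[1]))
})
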