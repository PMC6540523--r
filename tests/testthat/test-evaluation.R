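test_that("auc handles perfect separation, inversion, and rejects single-class input", {
  expect_equal(auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(auc(c(0.3, 0.7), c(1, 0)), 0.0)
  expect_equal(auc(c(0.5, 0.5), c(1, 0)), 0.5) # tie gets half credit
  expect_error(auc(c(0.1, 0.2), c(1, 1)), "undefined")
})

test_that("rank-based AUC equals the brute-force pairwise oracle", {
  set.seed(42)
  for (i in 1:300) {
    n <- sample(4:100, 1)
    labels <- c(0, 1, sample(0:1, n - 2, TRUE)) # both classes guaranteed
    # discrete score grid forces ties
    scores <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)
    expect_equal(auc(scores, labels), auc_bruteforce(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("auc agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(9)
  scores <- runif(200); labels <- rbinom(200, 1, plogis(3 * scores - 1.5))
  labels[1:2] <- c(0, 1)
  expect_equal(auc(scores, labels),
               as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-12)
})

test_that("best_f1 matches hand-worked examples and the exhaustive scan", {
  r <- best_f1(c(0.9, 0.8, 0.2), c(1, 1, 0))
  expect_equal(r$f1, 1.0)
  expect_equal(r$threshold, 0.8)
  # positives all scored below negatives: best is to call everything positive
  r2 <- best_f1(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 0, 0))
  expect_equal(r2$f1, 2 * 2 / (4 + 2))
  # all scores equal: single operating point, predict everything positive
  r3 <- best_f1(rep(0.4, 5), c(1, 1, 0, 0, 0))
  expect_equal(r3$threshold, 0.4)
  expect_equal(r3$f1, 2 * 2 / (2 * 2 + 3))
  set.seed(13)
  for (i in 1:300) {
    n <- sample(4:80, 1)
    labels <- c(0, 1, sample(0:1, n - 2, TRUE))
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)
    got <- best_f1(scores, labels)
    want <- best_f1_bruteforce(scores, labels)
    expect_equal(got$f1, want$f1, tolerance = 1e-12)
    expect_equal(got$threshold, want$threshold) # ties break to higher threshold
  }
})

test_that("best_f1 value dominates F1 at every distinct threshold", {
  set.seed(21)
  scores <- runif(60); labels <- c(0, 1, rbinom(58, 1, 0.4))
  best <- best_f1(scores, labels)$f1
  for (th in unique(scores)) {
    pred <- scores >= th
    f1 <- 2 * sum(pred & labels == 1) / (sum(pred) + sum(labels == 1))
    expect_gte(best + 1e-12, f1)
  }
})

test_that("per-allele eligibility is exact at its 30/5/5 boundaries", {
  mk <- function(allele, n_pos, n_neg) {
    data.frame(allele = allele,
               score = runif(n_pos + n_neg),
               label = rep(c(1, 0), c(n_pos, n_neg)))
  }
  set.seed(3)
  scored <- rbind(mk("A*1", 5, 25),   # exactly eligible
                  mk("A*2", 5, 24),   # n = 29
                  mk("A*3", 4, 36),   # too few positives
                  mk("A*4", 36, 4),   # too few negatives
                  mk("A*5", 20, 20))
  rep_ <- per_allele_report(scored)
  el <- setNames(rep_$per_allele$eligible, rep_$per_allele$allele)
  expect_true(el[["A*1"]]); expect_false(el[["A*2"]])
  expect_false(el[["A*3"]]); expect_false(el[["A*4"]]); expect_true(el[["A*5"]])
  expect_true(is.na(rep_$per_allele[allele == "A*2"]$auc))
  expect_equal(rep_$auc_kind, "pooled")
})

test_that("per-allele AUC averages over folds when fold labels exist", {
  scored <- data.frame(
    allele = "A*1",
    score = c(0.9, 0.1, 0.6, 0.8, 0.2, 0.3),
    label = c(1, 0, 0, 1, 0, 1),
    fold = c(1, 1, 1, 2, 2, 2)
  )
  scored <- scored[rep(1:6, 6), ] # inflate to pass the n >= 30 filter
  rep_ <- per_allele_report(scored)
  expect_equal(rep_$auc_kind, "fold_averaged")
  a1 <- auc(c(0.9, 0.1, 0.6), c(1, 0, 0))
  a2 <- auc(c(0.8, 0.2, 0.3), c(1, 0, 1))
  f1 <- scored[scored$fold == 1, ]; f2 <- scored[scored$fold == 2, ]
  expect_equal(rep_$per_allele$auc, mean(c(auc(f1$score, f1$label), auc(f2$score, f2$label))))
})

test_that("bootstrap AUC coefficient of variation is stable and seeded", {
  scores <- c(runif(100, 0.7, 1), runif(100, 0, 0.3))
  labels <- rep(c(1, 0), each = 100)
  bs <- bootstrap_auc_cv(scores, labels, n_boot = 50L, seed = 7L)
  expect_lt(bs$cv, 1e-6) # perfectly separated: AUC constant at 1
  expect_length(bs$aucs, 50L)
  bs2 <- bootstrap_auc_cv(scores, labels, n_boot = 50L, seed = 7L)
  expect_identical(bs$aucs, bs2$aucs)
  # nearly-single-class data forces redraws but keeps n_boot fixed
  sc <- c(runif(97), 0.99, 0.98, 0.97); lb <- c(rep(0, 97), 1, 1, 1)
  bs3 <- bootstrap_auc_cv(sc, lb, n_boot = 20L, frac = 0.2, seed = 1L)
  expect_length(bs3$aucs, 20L)
})

test_that("peptidome samples validate their invariants", {
  expect_error(peptidome_sample("s", character(0), "AAA", "CCC"))
  expect_error(peptidome_sample("s", "A*1", c("AAA", "CCC"), c("CCC", "DDD")),
               "disjoint")
  ps <- peptidome_sample("s", c("A*1", "A*1", "B*1"), "AAAA", "CCCC")
  expect_equal(ps$alleles, c("A*1", "B*1"))
})

test_that("peptidome scoring is a max over alleles: order-invariant and monotone", {
  tm <- tiny_model(seed = 33L, n_alleles = 3L)
  al <- tm$alleles
  samp <- synthetic_peptidome(al, n_pos = 15L, n_neg = 15L, seed = 2L)
  sc1 <- peptidome_score(tm$model, samp)
  # single allele equals plain predictions
  s_one <- peptidome_sample("one", al$registry[1], samp$positives, samp$negatives)
  sc_one <- peptidome_score(tm$model, s_one)
  expect_equal(sc_one$score,
               predict_binding(tm$model, sc_one$peptide, al$registry[1]))
  # allele order must not matter
  s_rev <- peptidome_sample("rev", rev(samp$alleles), samp$positives, samp$negatives)
  sc_rev <- peptidome_score(tm$model, s_rev)
  expect_equal(sc_rev$score, sc1$score)
  # adding an allele can only raise scores
  s_sub <- peptidome_sample("sub", samp$alleles[1:2], samp$positives, samp$negatives)
  sc_sub <- peptidome_score(tm$model, s_sub)
  expect_true(all(sc1$score >= sc_sub$score - 1e-12))
})

test_that("peptidome scoring removes training-overlap peptides first", {
  tm <- tiny_model(seed = 34L)
  samp <- synthetic_peptidome(tm$alleles, n_pos = 10L, n_neg = 10L, seed = 3L)
  overlap <- samp$positives[1:3]
  sc <- peptidome_score(tm$model, samp, training_peptides = overlap)
  expect_false(any(overlap %in% sc$peptide))
  expect_equal(nrow(sc), 17L)
})

test_that("leave-one-allele-out rejects degenerate held-out alleles", {
  al <- synthetic_alleles(n_alleles = 3L, seed = 40L)
  ds <- synthetic_binding_data(al, n_records = 300L, noise = 0, seed = 40L)
  rec <- ds$records[!(allele_name == al$registry[1] & binary_label == 1L)]
  expect_error(leave_one_allele_out(rec, tiny_config(), al$registry[1],
                                    n_restarts = 1L, pseudo = al$pseudo),
               "single class")
  expect_error(leave_one_allele_out(rec, tiny_config(), "NOPE*01:01",
                                    n_restarts = 1L, pseudo = al$pseudo),
               "not in dataset")
})
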