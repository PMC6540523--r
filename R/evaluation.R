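## evaluation: AUC, best-F1, per-allele reports with eligibility filtering,
## bootstrap stability, leave-one-allele-out generalization, and
## max-over-alleles peptidome scoring.

#' Area under the ROC curve (Mann-Whitney form)
#'
#' Computed with the rank formula, which equals the probability that a
#' random positive outscores a random negative with half credit for ties:
#' `AUC = (R_pos - n_pos (n_pos + 1) / 2) / (n_pos n_neg)` where `R_pos` is
#' the midrank sum of the positive scores.
#'
#' @param scores numeric scores (higher = more likely positive).
#' @param labels 0/1 labels.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("AUC undefined: need both classes (", n_pos, " positives, ",
         n_neg, " negatives)")
  }
  r <- rank(scores) # midranks handle ties with half credit
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Best F1 over all score thresholds
#'
#' Scans every distinct observed score as a threshold (predict positive when
#' `score >= threshold`) and returns the maximal F1; ties are broken toward
#' the higher threshold.
#'
#' @inheritParams auc
#' @return list with `f1` and `threshold`.
#' @export
best_f1 <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L)
  if (n_pos == 0L || sum(labels == 0L) == 0L) {
    stop("best F1 undefined: need both classes")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  tp <- cumsum(y)
  pred_pos <- seq_along(y)
  # operating points: last index of each tied-score block
  last <- which(c(s[-1] != s[-length(s)], TRUE))
  f1 <- 2 * tp[last] / (pred_pos[last] + n_pos)
  best <- last[which.max(f1)] # which.max takes the first max = highest threshold
  list(f1 = max(f1), threshold = s[best])
}

#' Per-allele evaluation report
#'
#' Groups scored predictions by allele and reports AUC for eligible alleles
#' only: those with at least `min_n` records, `min_pos` positives, and
#' `min_neg` negatives (30/5/5 by default). When a `fold` column is present,
#' per-fold AUCs are averaged (folds where the allele lacks a class are
#' skipped); otherwise the pooled AUC is reported and labelled as such.
#'
#' @param scored a `data.frame` with columns `allele`, `score`, `label`, and
#'   optionally `fold`.
#' @param min_n,min_pos,min_neg eligibility thresholds.
#' @return an `evaluation_report`: list with `overall_auc`, `overall_f1`
#'   (and its threshold), `per_allele` (`data.table`: allele, n, n_pos,
#'   n_neg, eligible, auc), and `auc_kind` (`"fold_averaged"` or
#'   `"pooled"`).
#' @export
per_allele_report <- function(scored, min_n = 30L, min_pos = 5L, min_neg = 5L) {
  dt <- data.table::as.data.table(scored)
  stopifnot(all(c("allele", "score", "label") %in% names(dt)))
  has_fold <- "fold" %in% names(dt)
  overall <- auc(dt$score, dt$label)
  bf <- best_f1(dt$score, dt$label)

  tallies <- dt[, .(n = .N, n_pos = sum(label == 1L), n_neg = sum(label == 0L)),
                by = allele]
  tallies[, eligible := n >= min_n & n_pos >= min_pos & n_neg >= min_neg]
  allele_auc <- function(a) {
    sub <- dt[allele == a]
    if (has_fold) {
      vals <- sub[, .(ok = length(unique(label)) == 2L), by = fold]
      per_fold <- vapply(vals[ok == TRUE]$fold,
                         function(f) auc(sub[fold == f]$score, sub[fold == f]$label),
                         numeric(1))
      if (length(per_fold) == 0) NA_real_ else mean(per_fold)
    } else {
      auc(sub$score, sub$label)
    }
  }
  tallies[, auc_value := ifelse(eligible, vapply(allele, allele_auc, numeric(1)), NA_real_)]
  data.table::setnames(tallies, "auc_value", "auc")
  structure(list(overall_auc = overall, overall_f1 = bf$f1,
                 f1_threshold = bf$threshold,
                 per_allele = tallies[order(allele)],
                 auc_kind = if (has_fold) "fold_averaged" else "pooled"),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("overall AUC %.4f  best F1 %.4f (threshold %.4f)  [%s per-allele AUC]\n",
              x$overall_auc, x$overall_f1, x$f1_threshold, x$auc_kind))
  cat(sprintf("%d/%d alleles eligible (>=30 records, >=5 per class)\n",
              sum(x$per_allele$eligible), nrow(x$per_allele)))
  invisible(x)
}

#' Bootstrap coefficient of variation of the AUC
#'
#' Draws `n_boot` resamples of `ceiling(frac * N)` records with replacement
#' and reports `sd/mean` of the resampled AUCs. Resamples that lose a class
#' are redrawn (with a log message), keeping `n_boot` fixed.
#'
#' @inheritParams auc
#' @param n_boot number of bootstrap resamples (100 by default).
#' @param frac resample size as a fraction of the data (0.8 by default).
#' @param seed RNG seed.
#' @return list with `cv`, `mean_auc`, `sd_auc`, and the resampled `aucs`.
#' @export
bootstrap_auc_cv <- function(scores, labels, n_boot = 100L, frac = 0.8, seed = 1L) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  if (!any(labels == 1L) || !any(labels == 0L)) stop("need both classes")
  set.seed(seed)
  n <- length(scores); m <- ceiling(frac * n)
  aucs <- numeric(n_boot)
  redraws <- 0L
  for (b in seq_len(n_boot)) {
    repeat {
      idx <- sample.int(n, m, replace = TRUE)
      if (length(unique(labels[idx])) == 2L) break
      redraws <- redraws + 1L
    }
    aucs[b] <- auc(scores[idx], labels[idx])
  }
  if (redraws > 0) mhc_log("bootstrap_auc_cv: %d single-class resamples redrawn", redraws)
  list(cv = sd(aucs) / mean(aucs), mean_auc = mean(aucs), sd_auc = sd(aucs),
       aucs = aucs)
}

#' Leave-one-allele-out generalization
#'
#' Removes every record of one allele from the dataset, trains a model on
#' the remaining alleles (with a peptide-grouped validation split for early
#' stopping), scores the omitted allele's records, and averages the AUC over
#' `n_restarts` random initialisations. In sequence mode the held-out allele
#' is scored from its pseudo-sequence; in one-hot mode the registry must
#' include the held-out allele (its embedding simply receives no training
#' signal), which serves as the uninformed baseline.
#'
#' @param ds a `cleaned_dataset` or records `data.frame`.
#' @param config a [model_config()].
#' @param allele the allele to hold out.
#' @param n_restarts random restarts to average over (5 by default).
#' @param embeddings,pseudo passed to [build_model()].
#' @param val_frac validation fraction of the training records.
#' @param verbose log progress.
#' @return list with `mean_auc`, per-restart `aucs`, and `n_heldout`.
#' @export
leave_one_allele_out <- function(ds, config, allele, n_restarts = 5L,
                                 embeddings = NULL, pseudo = NULL,
                                 val_frac = 0.2, verbose = FALSE) {
  records <- if (inherits(ds, "cleaned_dataset")) ds$records else data.table::as.data.table(ds)
  held <- records[allele_name == allele]
  rest <- records[allele_name != allele]
  if (nrow(held) == 0) stop("allele not in dataset: ", allele)
  if (length(unique(held$binary_label)) < 2) {
    stop("AUC undefined: held-out allele ", allele, " has a single class")
  }
  registry <- sort(unique(records$allele_name)) # includes the held-out allele
  aucs <- numeric(n_restarts)
  for (r in seq_len(n_restarts)) {
    cfg_r <- config
    cfg_r$seed <- derive_seed(config$seed, sprintf("loo_%s_%d", allele, r))
    vsplit <- grouped_folds(rest$peptide, max(2L, round(1 / val_frac)),
                            derive_seed(cfg_r$seed, "loo_val"))
    val_ids <- vsplit[rest$peptide] == 1L
    model <- build_model(cfg_r, embeddings, pseudo, registry)
    model <- train_fold(model, rest[!val_ids], rest[val_ids], verbose = verbose)
    scores <- predict_binding(model, held$peptide, held$allele_name)
    aucs[r] <- auc(scores, held$binary_label)
    mhc_log("LOO %s restart %d/%d: AUC %.4f", allele, r, n_restarts, aucs[r],
            verbose = verbose)
  }
  list(mean_auc = mean(aucs), aucs = aucs, n_heldout = nrow(held))
}

#' Peptidome sample container
#'
#' An individual's typed MHC class I alleles together with the peptides
#' detected (by mass spectrometry) as ligands and a negative peptide set.
#'
#' @param sample_id identifier.
#' @param alleles the individual's allele names (non-empty).
#' @param positives detected ligand peptides.
#' @param negatives non-binding peptides (disjoint from `positives`).
#' @return a `peptidome_sample` object.
#' @export
peptidome_sample <- function(sample_id, alleles, positives, negatives) {
  stopifnot(length(alleles) >= 1, length(positives) >= 1, length(negatives) >= 1)
  if (length(intersect(positives, negatives)) > 0) {
    stop("positives and negatives must be disjoint")
  }
  structure(list(sample_id = sample_id, alleles = unique(alleles),
                 positives = unique(positives), negatives = unique(negatives)),
            class = "peptidome_sample")
}

#' Score a peptidome sample by max over the individual's alleles
#'
#' A detected ligand may be bound to any of the individual's alleles, so
#' each peptide's score is the maximum predicted binding probability over
#' the allele set. Peptides overlapping the model's training data are
#' removed first to keep the evaluation independent.
#'
#' @param model an `ensemble_model` or `binding_model`.
#' @param sample a [peptidome_sample()].
#' @param training_peptides peptides to exclude; defaults to the peptides
#'   recorded in the model at training time.
#' @param on_unsupported `"error"` (default) or `"skip"` alleles the model
#'   cannot score (one-hot mode only; skipped alleles are logged).
#' @return a `data.table` with columns `peptide`, `label`, `score`.
#' @export
peptidome_score <- function(model, sample, training_peptides = NULL,
                            on_unsupported = c("error", "skip")) {
  on_unsupported <- match.arg(on_unsupported)
  stopifnot(inherits(sample, "peptidome_sample"))
  if (is.null(training_peptides)) training_peptides <- model$train_peptides %||% character(0)
  predict_fun <- if (inherits(model, "ensemble_model")) ensemble_predict else predict_binding

  alleles <- sample$alleles
  if (on_unsupported == "skip") {
    supported <- vapply(alleles, function(a) {
      !inherits(try(predict_fun(model, "ACDEFGHIK", a), silent = TRUE), "try-error")
    }, logical(1))
    if (any(!supported)) {
      mhc_log("peptidome_score: skipping unsupported allele(s): %s",
              paste(alleles[!supported], collapse = ", "))
    }
    alleles <- alleles[supported]
    if (length(alleles) == 0) stop("no supported allele in sample ", sample$sample_id)
  }
  dt <- data.table::data.table(
    peptide = c(sample$positives, sample$negatives),
    label = rep(c(1L, 0L), c(length(sample$positives), length(sample$negatives)))
  )
  dt <- dt[!peptide %in% training_peptides]
  if (nrow(dt) == 0) stop("all peptidome entries overlap the training data")
  score_mat <- vapply(alleles, function(a) predict_fun(model, dt$peptide, a),
                      numeric(nrow(dt)))
  dt[, score := if (length(alleles) == 1L) score_mat else apply(score_mat, 1, max)]
  dt[]
}
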