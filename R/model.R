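## binding_model: the dual-branch recurrent network mapping (peptide, allele)
## to a binding probability, plus training, cross-validation and ensembling.

#' Binding-model configuration
#'
#' The network has three parts: a peptide branch (token embedding feeding a
#' bi-directional GRU for 1-grams/one-hot, or three parallel GRUs for the
#' three 3-gram reading frames), an MHC branch (either an allele-identity
#' embedding, or a token embedding over the groove pseudo-sequence entered
#' through a fully connected or GRU layer), and a head of two ReLU fully
#' connected layers ending in a single sigmoid unit.
#'
#' Defaults are sized for desk-scale training (a few thousand records, a
#' handful of alleles): small layers, a large batch, an aggressive Adam
#' step, and no unit-level dropout, which at this scale only slows
#' convergence without improving held-out accuracy. For large datasets the
#' unit counts are typically raised substantially (GRU layers have been
#' explored up to 224 units, MHC fully connected layers up to 350, head
#' layers 64--512) and unit-level dropout of 0.3--0.4 on fully-connected
#' outputs and GRU inputs becomes worthwhile. Position-level MHC dropout
#' stays on by default because it is what lets the allele reader tolerate
#' the private polymorphisms of unseen alleles.
#'
#' @param peptide_repr `"gram1"` (residue tokens, default), `"one_hot"`
#'   (fixed identity embedding), or `"gram3"` (offset residue triplets).
#' @param mhc_repr `"sequence"` (groove pseudo-sequence; supports unseen
#'   alleles) or `"one_hot_allele"` (identity only; training alleles only).
#' @param mhc_entry entry layer for sequence mode: `"fully_connected"` or
#'   `"gru"`.
#' @param gru_units peptide GRU units per direction/offset.
#' @param mhc_fc_units width of the MHC fully connected entry layer (also the
#'   allele-embedding width in one-hot allele mode).
#' @param mhc_gru_units units of the MHC GRU entry layer.
#' @param head_fc_units width of each of the two head layers.
#' @param mhc_token_dim dimension of the (always randomly initialised) MHC
#'   residue embedding.
#' @param dropout_mhc_pos training-time probability of zeroing a whole
#'   pseudo-sequence position in the MHC branch. This trains the allele
#'   reader to tolerate a few unfamiliar residues, which is what an unseen
#'   allele's private polymorphisms look like at prediction time.
#' @param pep_embed_dim peptide embedding dimension when no pre-trained
#'   table is supplied (3-gram mode fixes 100).
#' @param dropout_fc_out,dropout_gru_in,dropout_gru_recurrent dropout rates.
#' @param learning_rate,batch_size,max_epochs,patience Adam step size,
#'   mini-batch size, epoch cap, and early-stopping patience (epochs without
#'   validation-loss improvement).
#' @param min_epochs epochs trained before early stopping may trigger; the
#'   binary cross-entropy surface has an initial plateau at chance level and
#'   stopping must not fire while a run is still on it.
#' @param seed integer seed controlling initialisation and batch order.
#' @return a `model_config` object.
#' @export
model_config <- function(peptide_repr = c("gram1", "one_hot", "gram3"),
                         mhc_repr = c("sequence", "one_hot_allele"),
                         mhc_entry = c("fully_connected", "gru"),
                         gru_units = 24L, mhc_fc_units = 48L,
                         mhc_gru_units = 16L, head_fc_units = 48L,
                         mhc_token_dim = 8L, pep_embed_dim = 5L,
                         dropout_fc_out = 0, dropout_gru_in = 0,
                         dropout_gru_recurrent = 0, dropout_mhc_pos = 0.15,
                         learning_rate = 6e-3, batch_size = 512L,
                         max_epochs = 80L, patience = 5L, min_epochs = 15L,
                         seed = 1L) {
  cfg <- list(peptide_repr = match.arg(peptide_repr),
              mhc_repr = match.arg(mhc_repr),
              mhc_entry = match.arg(mhc_entry),
              gru_units = as.integer(gru_units),
              mhc_fc_units = as.integer(mhc_fc_units),
              mhc_gru_units = as.integer(mhc_gru_units),
              head_fc_units = as.integer(head_fc_units),
              mhc_token_dim = as.integer(mhc_token_dim),
              pep_embed_dim = as.integer(pep_embed_dim),
              dropout_fc_out = dropout_fc_out,
              dropout_gru_in = dropout_gru_in,
              dropout_gru_recurrent = dropout_gru_recurrent,
              dropout_mhc_pos = dropout_mhc_pos,
              learning_rate = learning_rate,
              batch_size = as.integer(batch_size),
              max_epochs = as.integer(max_epochs),
              patience = as.integer(patience),
              min_epochs = as.integer(min_epochs),
              seed = as.integer(seed))
  with(cfg, stopifnot(gru_units >= 1, mhc_fc_units >= 1, mhc_gru_units >= 1,
                      head_fc_units >= 1, mhc_token_dim >= 1,
                      dropout_fc_out >= 0, dropout_fc_out < 1,
                      dropout_gru_in >= 0, dropout_gru_in < 1,
                      dropout_gru_recurrent >= 0, dropout_gru_recurrent < 1,
                      dropout_mhc_pos >= 0, dropout_mhc_pos < 1))
  structure(cfg, class = "model_config")
}

#' Embedding-adaptation (fine-tuning) schedule
#'
#' Three-phase transfer-learning schedule for large pre-trained peptide
#' embeddings: train with the embedding frozen until the validation loss
#' stops improving, unfreeze it for `k` epochs (1--3), then freeze again and
#' train to early stopping.
#'
#' @param k trainable-embedding epochs, in 1--3.
#' @return a `finetune_schedule` object.
#' @export
finetune_schedule <- function(k = 2L) {
  k <- as.integer(k)
  if (!k %in% 1:3) stop("k must be 1, 2, or 3")
  structure(list(k = k), class = "finetune_schedule")
}

pep_scheme_for <- function(config, embeddings = NULL) {
  if (config$peptide_repr %in% c("gram1", "one_hot")) {
    tokenization_scheme(1L)
  } else {
    vocab <- if (!is.null(embeddings)) rownames(embeddings$vectors) else {
      c(apply(expand.grid(AA_LETTERS, AA_LETTERS, AA_LETTERS)[, 3:1], 1, paste,
              collapse = ""))
    }
    tokenization_scheme(3L, vocabulary = vocab)
  }
}

init_embedding_matrix <- function(vocab, dim, table = NULL) {
  E <- matrix(runif(length(vocab) * dim, -0.05, 0.05), length(vocab), dim)
  rownames(E) <- vocab
  if (!is.null(table)) {
    hit <- intersect(vocab, rownames(table$vectors))
    E[hit, ] <- table$vectors[hit, , drop = FALSE]
  }
  E
}

#' Build a binding model
#'
#' Allocates and initialises all parameters. The peptide embedding is copied
#' from a pre-trained [train_skipgram()] table where tokens match and
#' randomly initialised otherwise; the MHC residue embedding is always
#' randomly initialised (alignment gaps have no pre-trainable context). In
#' one-hot peptide mode the identity embedding is fixed, never trained.
#'
#' @param config a [model_config()].
#' @param embeddings optional `embedding_table` for the peptide branch.
#' @param pseudo pseudo-sequence table (`allele`, `groove_sequence`);
#'   required in sequence mode. Alleles present here are scorable even if
#'   absent from training.
#' @param allele_registry character vector of allele names; required in
#'   one-hot allele mode.
#' @return a `binding_model` object.
#' @export
build_model <- function(config, embeddings = NULL, pseudo = NULL,
                        allele_registry = NULL) {
  stopifnot(inherits(config, "model_config"))
  if (config$mhc_repr == "sequence" && is.null(pseudo)) {
    stop("sequence mode requires a pseudo-sequence table")
  }
  if (config$mhc_repr == "one_hot_allele" && is.null(allele_registry)) {
    stop("one-hot allele mode requires an allele registry")
  }
  set.seed(derive_seed(config$seed, "init"))

  scheme <- pep_scheme_for(config, embeddings)
  if (config$peptide_repr == "one_hot") {
    embeddings <- one_hot_table(scheme)
  }
  pep_dim <- if (!is.null(embeddings)) ncol(embeddings$vectors) else {
    if (config$peptide_repr == "gram3") 100L else config$pep_embed_dim
  }
  if (config$peptide_repr == "gram3" && pep_dim != 100L) {
    stop("3-gram peptide embeddings must have dimension 100, got ", pep_dim)
  }

  H <- config$gru_units
  params <- list(pep_emb = init_embedding_matrix(scheme$vocabulary, pep_dim, embeddings))
  if (config$peptide_repr == "gram3") {
    for (o in 0:2) {
      params[[sprintf("pep_gru%d_W", o)]] <- glorot(pep_dim, 3 * H)
      params[[sprintf("pep_gru%d_U", o)]] <- orthogonal_block(H)
      params[[sprintf("pep_gru%d_b", o)]] <- numeric(3 * H)
    }
    pep_out <- 3L * H
  } else {
    for (dir in c("f", "b")) {
      params[[sprintf("pep_gru_%s_W", dir)]] <- glorot(pep_dim, 3 * H)
      params[[sprintf("pep_gru_%s_U", dir)]] <- orthogonal_block(H)
      params[[sprintf("pep_gru_%s_b", dir)]] <- numeric(3 * H)
    }
    pep_out <- 2L * H
  }

  pseudo_ids <- NULL; registry <- NULL
  mhc_vocab <- c(AA_LETTERS, GAP_TOKEN, UNK_TOKEN)
  if (config$mhc_repr == "sequence") {
    pseudo <- data.table::as.data.table(pseudo)
    stopifnot(all(c("allele", "groove_sequence") %in% names(pseudo)))
    L <- unique(nchar(pseudo$groove_sequence))
    if (length(L) != 1) stop("pseudo-sequences must all share one length")
    idmap <- setNames(seq_along(mhc_vocab), mhc_vocab)
    mat <- do.call(rbind, strsplit(toupper(pseudo$groove_sequence), ""))
    pseudo_ids <- matrix(idmap[mat], nrow(mat), ncol(mat))
    pseudo_ids[is.na(pseudo_ids)] <- idmap[[UNK_TOKEN]]
    rownames(pseudo_ids) <- pseudo$allele
    params$mhc_emb <- matrix(runif(length(mhc_vocab) * config$mhc_token_dim, -0.05, 0.05),
                             length(mhc_vocab), config$mhc_token_dim)
    if (config$mhc_entry == "fully_connected") {
      params$mhc_fc_W <- glorot(L * config$mhc_token_dim, config$mhc_fc_units)
      params$mhc_fc_b <- numeric(config$mhc_fc_units)
      mhc_out <- config$mhc_fc_units
    } else {
      params$mhc_gru_W <- glorot(config$mhc_token_dim, 3 * config$mhc_gru_units)
      params$mhc_gru_U <- orthogonal_block(config$mhc_gru_units)
      params$mhc_gru_b <- numeric(3 * config$mhc_gru_units)
      mhc_out <- config$mhc_gru_units
    }
  } else {
    registry <- unique(as.character(allele_registry))
    params$allele_W <- glorot(length(registry), config$mhc_fc_units)
    params$allele_b <- numeric(config$mhc_fc_units)
    mhc_out <- config$mhc_fc_units
  }

  hu <- config$head_fc_units
  params$fc1_W <- glorot(pep_out + mhc_out, hu); params$fc1_b <- numeric(hu)
  params$fc2_W <- glorot(hu, hu); params$fc2_b <- numeric(hu)
  params$out_W <- glorot(hu, 1L); params$out_b <- 0

  structure(list(
    config = config, params = params, scheme = scheme,
    pep_dim = pep_dim, pep_out = pep_out, mhc_out = mhc_out,
    mhc_vocab = mhc_vocab, pseudo_ids = pseudo_ids, registry = registry,
    embed_trainable = config$peptide_repr != "one_hot",
    train_peptides = character(0)
  ), class = "binding_model")
}

#' @export
print.binding_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, 1L))
  cat(sprintf("binding model: peptide=%s, mhc=%s%s, %d parameters\n",
              x$config$peptide_repr, x$config$mhc_repr,
              if (x$config$mhc_repr == "sequence") paste0("/", x$config$mhc_entry) else "",
              np))
  invisible(x)
}

## ---- encoding --------------------------------------------------------------

# Peptides -> padded id matrix (gram1/one_hot) or list of 3 matrices (gram3).
encode_peptides <- function(model, peptides) {
  sch <- model$scheme
  idmap <- setNames(seq_along(sch$vocabulary), sch$vocabulary)
  unk <- idmap[[UNK_TOKEN]]
  tok_ids <- function(offset) {
    toks <- lapply(peptides, function(p) suppressMessages(tokenize(p, sch, offset)))
    Tmax <- max(1L, vapply(toks, length, 1L))
    out <- matrix(0L, length(peptides), Tmax)
    for (i in seq_along(toks)) {
      tk <- toks[[i]]
      if (length(tk) > 0) {
        ids <- idmap[tk]; ids[is.na(ids)] <- unk
        out[i, seq_along(tk)] <- ids
      }
    }
    out
  }
  if (sch$n == 1L) tok_ids(0L) else lapply(0:2, tok_ids)
}

# Alleles -> row index into pseudo_ids (sequence mode) or registry index.
encode_alleles <- function(model, alleles) {
  if (model$config$mhc_repr == "sequence") {
    idx <- match(alleles, rownames(model$pseudo_ids))
    if (anyNA(idx)) {
      stop("no pseudo-sequence for allele(s): ",
           paste(unique(alleles[is.na(idx)]), collapse = ", "))
    }
  } else {
    idx <- match(alleles, model$registry)
    if (anyNA(idx)) {
      stop("unsupported allele(s) in one-hot mode: ",
           paste(unique(alleles[is.na(idx)]), collapse = ", "))
    }
  }
  idx
}

## ---- forward / backward ----------------------------------------------------

# batch: list(pep = encoded peptides, mhc = allele indices, rows = optional
# row subset into pep/mhc encodings).
model_forward <- function(model, pep_enc, mhc_idx, train = FALSE) {
  cfg <- model$config; P <- model$params
  B <- length(mhc_idx)
  cache <- list(train = train, mhc_idx = mhc_idx)

  p_in <- if (train) cfg$dropout_gru_in else 0
  p_rec <- if (train) cfg$dropout_gru_recurrent else 0
  p_fc <- if (train) cfg$dropout_fc_out else 0

  ## peptide branch
  if (cfg$peptide_repr == "gram3") {
    hs <- vector("list", 3); caches <- vector("list", 3)
    for (o in 1:3) {
      ids <- pep_enc[[o]]
      im <- dropout_mask(B, model$pep_dim, p_in)
      rm <- dropout_mask(B, cfg$gru_units, p_rec)
      emb <- embed_sequences(ids, P$pep_emb, im)
      fw <- gru_forward(emb$Xs, emb$mask, P[[sprintf("pep_gru%d_W", o - 1)]],
                        P[[sprintf("pep_gru%d_U", o - 1)]],
                        P[[sprintf("pep_gru%d_b", o - 1)]], rec_mask = rm)
      hs[[o]] <- fw$h_last
      caches[[o]] <- list(ids = ids, in_mask = im, fw = fw)
    }
    pep_repr <- do.call(cbind, hs)
    cache$pep <- caches
  } else {
    ids_f <- pep_enc
    ids_b <- reverse_ids(ids_f)
    im_f <- dropout_mask(B, model$pep_dim, p_in)
    im_b <- dropout_mask(B, model$pep_dim, p_in)
    rm_f <- dropout_mask(B, cfg$gru_units, p_rec)
    rm_b <- dropout_mask(B, cfg$gru_units, p_rec)
    emb_f <- embed_sequences(ids_f, P$pep_emb, im_f)
    emb_b <- embed_sequences(ids_b, P$pep_emb, im_b)
    fw_f <- gru_forward(emb_f$Xs, emb_f$mask, P$pep_gru_f_W, P$pep_gru_f_U,
                        P$pep_gru_f_b, rec_mask = rm_f)
    fw_b <- gru_forward(emb_b$Xs, emb_b$mask, P$pep_gru_b_W, P$pep_gru_b_U,
                        P$pep_gru_b_b, rec_mask = rm_b)
    pep_repr <- cbind(fw_f$h_last, fw_b$h_last)
    cache$pep <- list(ids_f = ids_f, ids_b = ids_b, in_mask_f = im_f,
                      in_mask_b = im_b, fw_f = fw_f, fw_b = fw_b)
  }

  ## MHC branch
  if (cfg$mhc_repr == "sequence") {
    ids <- model$pseudo_ids[mhc_idx, , drop = FALSE]
    L <- ncol(ids)
    # position-level dropout: zero whole pseudo-sequence positions so the
    # allele reader cannot depend on any single residue
    p_pos <- if (train) cfg$dropout_mhc_pos else 0
    pos_mask <- if (p_pos > 0) {
      matrix(rbinom(B * L, 1L, 1 - p_pos) / (1 - p_pos), B, L)
    } else NULL
    if (cfg$mhc_entry == "fully_connected") {
      td <- cfg$mhc_token_dim
      flat <- matrix(0, B, L * td)
      for (l in seq_len(L)) {
        block <- P$mhc_emb[ids[, l], , drop = FALSE]
        if (!is.null(pos_mask)) block <- block * pos_mask[, l]
        flat[, ((l - 1) * td + 1):(l * td)] <- block
      }
      fc <- dense_forward(flat, P$mhc_fc_W, P$mhc_fc_b, relu = TRUE)
      dm <- dropout_mask(B, cfg$mhc_fc_units, p_fc)
      mhc_repr <- apply_mask(fc$out, dm)
      cache$mhc <- list(ids = ids, fc = fc, drop = dm, pos_mask = pos_mask)
    } else {
      im <- dropout_mask(B, cfg$mhc_token_dim, p_in)
      rm <- dropout_mask(B, cfg$mhc_gru_units, p_rec)
      emb <- embed_sequences(ids, P$mhc_emb, im)
      if (!is.null(pos_mask)) {
        for (l in seq_len(L)) emb$Xs[[l]] <- emb$Xs[[l]] * pos_mask[, l]
      }
      fw <- gru_forward(emb$Xs, emb$mask, P$mhc_gru_W, P$mhc_gru_U, P$mhc_gru_b,
                        rec_mask = rm)
      mhc_repr <- fw$h_last
      cache$mhc <- list(ids = ids, in_mask = im, fw = fw, pos_mask = pos_mask)
    }
  } else {
    pre <- sweep(P$allele_W[mhc_idx, , drop = FALSE], 2L, P$allele_b, "+")
    act <- pmax(pre, 0)
    dm <- dropout_mask(B, cfg$mhc_fc_units, p_fc)
    mhc_repr <- apply_mask(act, dm)
    cache$mhc <- list(pre = pre, drop = dm)
  }

  ## head
  joint <- cbind(pep_repr, mhc_repr)
  fc1 <- dense_forward(joint, P$fc1_W, P$fc1_b, relu = TRUE)
  dm1 <- dropout_mask(B, cfg$head_fc_units, p_fc)
  h1 <- apply_mask(fc1$out, dm1)
  fc2 <- dense_forward(h1, P$fc2_W, P$fc2_b, relu = TRUE)
  dm2 <- dropout_mask(B, cfg$head_fc_units, p_fc)
  h2 <- apply_mask(fc2$out, dm2)
  out <- dense_forward(h2, P$out_W, P$out_b, relu = FALSE)
  logit <- drop(out$out)

  cache$head <- list(fc1 = fc1, dm1 = dm1, fc2 = fc2, dm2 = dm2, out = out)
  cache$pep_repr_cols <- ncol(pep_repr)
  list(logit = logit, prob = sigmoid(logit), cache = cache)
}

model_backward <- function(model, cache, dlogit) {
  cfg <- model$config; P <- model$params
  g <- list()
  hd <- cache$head
  d_out <- dense_backward(matrix(dlogit, ncol = 1), hd$out$cache, P$out_W)
  g$out_W <- d_out$dW; g$out_b <- d_out$db
  dh2 <- apply_mask(d_out$dX, hd$dm2)
  d_fc2 <- dense_backward(dh2, hd$fc2$cache, P$fc2_W)
  g$fc2_W <- d_fc2$dW; g$fc2_b <- d_fc2$db
  dh1 <- apply_mask(d_fc2$dX, hd$dm1)
  d_fc1 <- dense_backward(dh1, hd$fc1$cache, P$fc1_W)
  g$fc1_W <- d_fc1$dW; g$fc1_b <- d_fc1$db

  pc <- cache$pep_repr_cols
  d_pep <- d_fc1$dX[, seq_len(pc), drop = FALSE]
  d_mhc <- d_fc1$dX[, (pc + 1):ncol(d_fc1$dX), drop = FALSE]

  ## MHC branch
  if (cfg$mhc_repr == "sequence") {
    mc <- cache$mhc
    if (cfg$mhc_entry == "fully_connected") {
      dfc_out <- apply_mask(d_mhc, mc$drop)
      d_fc <- dense_backward(dfc_out, mc$fc$cache, P$mhc_fc_W)
      g$mhc_fc_W <- d_fc$dW; g$mhc_fc_b <- d_fc$db
      L <- ncol(mc$ids); td <- cfg$mhc_token_dim
      dE <- matrix(0, nrow(P$mhc_emb), td)
      for (l in seq_len(L)) {
        block <- d_fc$dX[, ((l - 1) * td + 1):(l * td), drop = FALSE]
        if (!is.null(mc$pos_mask)) block <- block * mc$pos_mask[, l]
        acc <- rowsum(block, group = mc$ids[, l])
        rows <- as.integer(rownames(acc))
        dE[rows, ] <- dE[rows, , drop = FALSE] + acc
      }
      g$mhc_emb <- dE
    } else {
      bk <- gru_backward(d_mhc, mc$fw)
      g$mhc_gru_W <- bk$dW; g$mhc_gru_U <- bk$dU; g$mhc_gru_b <- bk$db
      if (!is.null(mc$pos_mask)) {
        for (l in seq_along(bk$dXs)) bk$dXs[[l]] <- bk$dXs[[l]] * mc$pos_mask[, l]
      }
      g$mhc_emb <- embed_backward(bk$dXs, mc$ids, nrow(P$mhc_emb), mc$in_mask)
    }
  } else {
    mc <- cache$mhc
    dact <- apply_mask(d_mhc, mc$drop) * (mc$pre > 0)
    dW <- matrix(0, nrow(P$allele_W), ncol(P$allele_W))
    acc <- rowsum(dact, group = cache$mhc_idx)
    rows <- as.integer(rownames(acc))
    dW[rows, ] <- acc
    g$allele_W <- dW; g$allele_b <- colSums(dact)
  }

  ## peptide branch
  if (cfg$peptide_repr == "gram3") {
    H <- cfg$gru_units
    dE <- matrix(0, nrow(P$pep_emb), model$pep_dim)
    for (o in 1:3) {
      pcache <- cache$pep[[o]]
      dh <- d_pep[, ((o - 1) * H + 1):(o * H), drop = FALSE]
      bk <- gru_backward(dh, pcache$fw)
      g[[sprintf("pep_gru%d_W", o - 1)]] <- bk$dW
      g[[sprintf("pep_gru%d_U", o - 1)]] <- bk$dU
      g[[sprintf("pep_gru%d_b", o - 1)]] <- bk$db
      dE <- dE + embed_backward(bk$dXs, pcache$ids, nrow(P$pep_emb), pcache$in_mask)
    }
    if (model$embed_trainable) g$pep_emb <- dE
  } else {
    H <- cfg$gru_units
    pcache <- cache$pep
    bk_f <- gru_backward(d_pep[, 1:H, drop = FALSE], pcache$fw_f)
    bk_b <- gru_backward(d_pep[, (H + 1):(2 * H), drop = FALSE], pcache$fw_b)
    g$pep_gru_f_W <- bk_f$dW; g$pep_gru_f_U <- bk_f$dU; g$pep_gru_f_b <- bk_f$db
    g$pep_gru_b_W <- bk_b$dW; g$pep_gru_b_U <- bk_b$dU; g$pep_gru_b_b <- bk_b$db
    if (model$embed_trainable) {
      g$pep_emb <- embed_backward(bk_f$dXs, pcache$ids_f, nrow(P$pep_emb), pcache$in_mask_f) +
        embed_backward(bk_b$dXs, pcache$ids_b, nrow(P$pep_emb), pcache$in_mask_b)
    }
  }
  g
}

## ---- prediction ------------------------------------------------------------

validate_peptides <- function(peptides, n = 1L) {
  ok <- is_standard_peptide(peptides)
  if (any(!ok)) {
    stop("peptide(s) with non-standard letters: ",
         paste(unique(peptides[!ok]), collapse = ", "))
  }
  if (any(nchar(peptides) < n)) stop("peptide shorter than one token")
  invisible(TRUE)
}

#' Predict binding probabilities
#'
#' Deterministic inference (dropout disabled): identical calls return
#' identical values. In one-hot allele mode only registry alleles are
#' supported; in sequence mode any allele with a pseudo-sequence is
#' scorable, including alleles never seen in training.
#'
#' @param model a trained (or fresh) `binding_model`.
#' @param peptides character vector of peptide sequences (standard letters).
#' @param alleles character vector of allele names (recycled if length 1).
#' @return numeric vector of probabilities, strictly inside (0, 1).
#' @export
predict_binding <- function(model, peptides, alleles) {
  stopifnot(inherits(model, "binding_model"))
  if (length(alleles) == 1L) alleles <- rep(alleles, length(peptides))
  stopifnot(length(alleles) == length(peptides))
  validate_peptides(peptides, model$scheme$n)
  pep_enc <- encode_peptides(model, peptides)
  mhc_idx <- encode_alleles(model, alleles)
  # chunk to bound memory on long inputs
  out <- numeric(length(peptides))
  chunk <- 4096L
  for (s in seq(1L, length(peptides), by = chunk)) {
    e <- min(s + chunk - 1L, length(peptides))
    pe <- if (model$scheme$n == 1L) pep_enc[s:e, , drop = FALSE] else {
      lapply(pep_enc, function(m) m[s:e, , drop = FALSE])
    }
    out[s:e] <- model_forward(model, pe, mhc_idx[s:e], train = FALSE)$prob
  }
  out
}

#' @rdname predict_binding
#' @param peptide,allele single peptide and allele.
#' @export
predict_one <- function(model, peptide, allele) {
  predict_binding(model, peptide, allele)
}

## ---- training --------------------------------------------------------------

bce_loss <- function(prob, y) {
  eps <- 1e-12
  -mean(y * log(pmax(prob, eps)) + (1 - y) * log(pmax(1 - prob, eps)))
}

eval_loss <- function(model, pep_enc, mhc_idx, y, batch = 2048L) {
  n <- length(y); tot <- 0
  for (s in seq(1L, n, by = batch)) {
    e <- min(s + batch - 1L, n)
    pe <- if (model$scheme$n == 1L) pep_enc[s:e, , drop = FALSE] else {
      lapply(pep_enc, function(m) m[s:e, , drop = FALSE])
    }
    p <- model_forward(model, pe, mhc_idx[s:e], train = FALSE)$prob
    tot <- tot + bce_loss(p, y[s:e]) * (e - s + 1L)
  }
  tot / n
}

subset_enc <- function(pep_enc, rows, n) {
  if (n == 1L) pep_enc[rows, , drop = FALSE] else {
    lapply(pep_enc, function(m) m[rows, , drop = FALSE])
  }
}

# One early-stopped training phase; mutates and returns (model, adam, history).
train_phase <- function(model, adam, enc_tr, y_tr, enc_val, y_val,
                        max_epochs, patience, phase_label, epoch0,
                        verbose = FALSE) {
  cfg <- model$config
  n <- length(y_tr)
  best_val <- eval_loss(model, enc_val$pep, enc_val$mhc, y_val)
  best_params <- model$params
  wait <- 0L
  hist <- list()
  trainable <- setdiff(names(model$params),
                       if (model$embed_trainable) character(0) else "pep_emb")
  for (epoch in seq_len(max_epochs)) {
    ord <- sample.int(n)
    tr_loss <- 0
    for (s in seq(1L, n, by = cfg$batch_size)) {
      rows <- ord[s:min(s + cfg$batch_size - 1L, n)]
      pe <- subset_enc(enc_tr$pep, rows, model$scheme$n)
      fw <- model_forward(model, pe, enc_tr$mhc[rows], train = TRUE)
      y <- y_tr[rows]
      tr_loss <- tr_loss + bce_loss(fw$prob, y) * length(rows)
      dlogit <- (fw$prob - y) / length(rows)
      grads <- model_backward(model, fw$cache, dlogit)
      grads <- grads[intersect(names(grads), trainable)]
      upd <- adam_step(model$params, grads, adam, lr = cfg$learning_rate)
      model$params <- upd$params
      adam <- upd$state
    }
    val_loss <- eval_loss(model, enc_val$pep, enc_val$mhc, y_val)
    hist[[epoch]] <- data.frame(epoch = epoch0 + epoch, phase = phase_label,
                                train_loss = tr_loss / n, val_loss = val_loss)
    mhc_log("[%s] epoch %d  train %.4f  val %.4f", phase_label, epoch0 + epoch,
            tr_loss / n, val_loss, verbose = verbose)
    if (val_loss < best_val - 1e-6) {
      best_val <- val_loss; best_params <- model$params; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience && epoch >= (cfg$min_epochs %||% 0L)) break
    }
  }
  model$params <- best_params
  list(model = model, adam = adam,
       history = do.call(rbind, hist), best_val = best_val)
}

#' Train one model on a train/validation split
#'
#' Mini-batch Adam on binary cross-entropy with early stopping on the
#' validation loss (configured patience) and best-weights restoration.
#' Training and validation sets must be disjoint on peptide sequence. With a
#' [finetune_schedule()], the peptide embedding is frozen, briefly
#' unfrozen for `k` epochs, then frozen again (three early-stopped phases).
#'
#' @param model a `binding_model` from [build_model()].
#' @param train,val `data.frame`s with columns `peptide`, `allele_name`,
#'   `binary_label`.
#' @param schedule `NULL` (plain training) or a [finetune_schedule()].
#' @param verbose log per-epoch losses.
#' @return the trained model, with a `history` data.frame attached.
#' @export
train_fold <- function(model, train, val, schedule = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "binding_model"))
  train <- data.table::as.data.table(train)
  val <- data.table::as.data.table(val)
  if (nrow(train) == 0) stop("empty training set")
  if (length(unique(train$binary_label)) < 2) {
    stop("training set must contain both classes")
  }
  overlap <- intersect(train$peptide, val$peptide)
  if (length(overlap) > 0) {
    stop("train and validation sets share peptide(s), e.g. ", overlap[1])
  }
  validate_peptides(train$peptide, model$scheme$n)
  set.seed(derive_seed(model$config$seed, "train"))

  enc_tr <- list(pep = encode_peptides(model, train$peptide),
                 mhc = encode_alleles(model, train$allele_name))
  enc_val <- list(pep = encode_peptides(model, val$peptide),
                  mhc = encode_alleles(model, val$allele_name))
  y_tr <- as.numeric(train$binary_label)
  y_val <- as.numeric(val$binary_label)
  adam <- adam_init(model$params)
  cfg <- model$config

  if (is.null(schedule)) {
    ph <- train_phase(model, adam, enc_tr, y_tr, enc_val, y_val,
                      cfg$max_epochs, cfg$patience, "train", 0L, verbose)
    model <- ph$model
    model$history <- ph$history
  } else {
    stopifnot(inherits(schedule, "finetune_schedule"))
    model$embed_trainable <- FALSE
    p1 <- train_phase(model, adam, enc_tr, y_tr, enc_val, y_val,
                      cfg$max_epochs, cfg$patience, "frozen", 0L, verbose)
    model <- p1$model
    model$embed_trainable <- model$config$peptide_repr != "one_hot"
    e1 <- max(p1$history$epoch)
    p2 <- train_phase(model, p1$adam, enc_tr, y_tr, enc_val, y_val,
                      schedule$k, schedule$k + 1L, "adapt", e1, verbose)
    model <- p2$model
    model$embed_trainable <- FALSE
    e2 <- max(p2$history$epoch)
    p3 <- train_phase(model, p2$adam, enc_tr, y_tr, enc_val, y_val,
                      cfg$max_epochs, cfg$patience, "refrozen", e2, verbose)
    model <- p3$model
    model$history <- rbind(p1$history, p2$history, p3$history)
  }
  model$train_peptides <- unique(train$peptide)
  model
}

## ---- cross-validation & ensembling ----------------------------------------

# Greedy balanced assignment of peptide groups to k folds: groups (with
# their record counts) are taken in decreasing-size order (ties shuffled)
# and each goes to the currently lightest fold.
grouped_folds <- function(peptides, k = 5L, seed = 1L) {
  grp <- data.table::data.table(peptide = peptides)[, .N, by = peptide]
  if (nrow(grp) < k) stop("fewer peptide groups (", nrow(grp), ") than folds (", k, ")")
  set.seed(seed)
  grp <- grp[order(-N, sample.int(.N))]
  load <- numeric(k)
  fold <- integer(nrow(grp))
  for (i in seq_len(nrow(grp))) {
    f <- which.min(load)
    fold[i] <- f
    load[f] <- load[f] + grp$N[i]
  }
  setNames(fold, grp$peptide)
}

#' Peptide-grouped 5-fold cross-validation with a median ensemble
#'
#' Splits the dataset into `k` near-equal folds such that all records
#' sharing a peptide sequence land in the same fold (greedy balancing by
#' group size). Each fold is scored by a model trained on the other folds,
#' with 20% of the training data (again peptide-grouped) held out for early
#' stopping. Returns the `k` trained models as a median ensemble plus
#' out-of-fold predictions covering every record exactly once.
#'
#' @param ds a `cleaned_dataset` (or a records `data.frame`).
#' @param config a [model_config()].
#' @param embeddings,pseudo,allele_registry passed to [build_model()]; the
#'   registry defaults to all alleles in `ds` in one-hot mode.
#' @param k number of folds (5 by default).
#' @param val_frac fraction of training records held out for validation.
#' @param schedule optional [finetune_schedule()].
#' @param verbose log training progress.
#' @return list with `ensemble` (an `ensemble_model`) and `predictions`
#'   (`data.table`: peptide, allele, label, score, fold).
#' @export
cross_validate <- function(ds, config, embeddings = NULL, pseudo = NULL,
                           allele_registry = NULL, k = 5L, val_frac = 0.2,
                           schedule = NULL, verbose = FALSE) {
  records <- if (inherits(ds, "cleaned_dataset")) ds$records else data.table::as.data.table(ds)
  stopifnot(all(c("peptide", "allele_name", "binary_label") %in% names(records)))
  if (config$mhc_repr == "one_hot_allele" && is.null(allele_registry)) {
    allele_registry <- sort(unique(records$allele_name))
  }
  fold_of <- grouped_folds(records$peptide, k, derive_seed(config$seed, "folds"))
  records <- data.table::copy(records)[, fold := fold_of[peptide]]

  members <- vector("list", k)
  preds <- vector("list", k)
  for (f in seq_len(k)) {
    test <- records[fold == f]
    rest <- records[fold != f]
    vsplit <- grouped_folds(rest$peptide, max(2L, round(1 / val_frac)),
                            derive_seed(config$seed, sprintf("val%d", f)))
    val_ids <- vsplit[rest$peptide] == 1L
    cfg_f <- config
    cfg_f$seed <- derive_seed(config$seed, sprintf("fold%d", f))
    model <- build_model(cfg_f, embeddings, pseudo, allele_registry)
    model <- train_fold(model, rest[!val_ids], rest[val_ids], schedule, verbose)
    members[[f]] <- model
    preds[[f]] <- test[, .(peptide, allele = allele_name, label = binary_label,
                           score = predict_binding(model, peptide, allele_name),
                           fold = f)]
    mhc_log("fold %d/%d trained (%d epochs), test n=%d", f, k,
            max(model$history$epoch), nrow(test), verbose = verbose)
  }
  ens <- structure(list(members = members, aggregation = "median",
                        train_peptides = unique(records$peptide)),
                   class = "ensemble_model")
  list(ensemble = ens, predictions = data.table::rbindlist(preds))
}

#' Median-ensemble prediction
#'
#' The ensemble output is the member-wise median, so it always lies within
#' the min/max of the member outputs.
#'
#' @param ensemble an `ensemble_model` from [cross_validate()].
#' @param peptides,alleles as in [predict_binding()].
#' @return numeric vector of probabilities.
#' @export
ensemble_predict <- function(ensemble, peptides, alleles) {
  stopifnot(inherits(ensemble, "ensemble_model"))
  member_scores <- vapply(ensemble$members,
                          function(m) predict_binding(m, peptides, alleles),
                          numeric(length(peptides)))
  if (length(peptides) == 1L) median(member_scores) else apply(member_scores, 1, median)
}

#' @export
print.ensemble_model <- function(x, ...) {
  cat(sprintf("ensemble of %d binding models (aggregation: %s)\n",
              length(x$members), x$aggregation))
  invisible(x)
}

#' Save / load a model checkpoint directory
#'
#' The checkpoint directory holds the serialised model plus a plain-JSON
#' copy of the configuration for inspection.
#'
#' @param model a `binding_model` or `ensemble_model`.
#' @param dir checkpoint directory (created if needed).
#' @return `dir` invisibly (save); the model (load).
#' @export
save_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(model, file.path(dir, "model.rds"))
  cfg <- if (inherits(model, "ensemble_model")) model$members[[1]]$config else model$config
  jsonlite::write_json(list(format_version = 1L, class = class(model)[1],
                            config = unclass(cfg)),
                       file.path(dir, "config.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  readRDS(file.path(dir, "model.rds"))
}
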