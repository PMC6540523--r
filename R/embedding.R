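## aa_embedding: tokenize amino-acid sequences into 1-grams or offset
## 3-grams and pre-train skip-gram embeddings with negative sampling.

#' Tokenization scheme for amino-acid sequences
#'
#' A peptide or protein is treated as a sentence whose words are either
#' single residues (`n = 1`) or non-overlapping residue triplets (`n = 3`).
#' The 3-gram scheme has three reading frames, offset by 0, 1 or 2 residues
#' from the N-terminus; the 1-gram scheme has a single frame. The vocabulary
#' always carries the alignment gap character and an unknown-token sentinel.
#'
#' @param n gram size, 1 or 3.
#' @param vocabulary optional ordered character vector of tokens. Defaults to
#'   the 20 standard residues (plus specials) for `n = 1`; for `n = 3` the
#'   vocabulary is usually derived from the training corpus by
#'   [train_skipgram()] and may be left `NULL` here.
#' @return a `tokenization_scheme` object with fields `n`, `offsets`,
#'   `vocabulary`.
#' @export
tokenization_scheme <- function(n = 1L, vocabulary = NULL) {
  n <- as.integer(n)
  if (!n %in% c(1L, 3L)) stop("n must be 1 or 3")
  if (is.null(vocabulary) && n == 1L) vocabulary <- c(AA_LETTERS, GAP_TOKEN, UNK_TOKEN)
  if (!is.null(vocabulary)) {
    if (anyDuplicated(vocabulary)) stop("vocabulary has duplicate tokens")
    if (!UNK_TOKEN %in% vocabulary) vocabulary <- c(vocabulary, UNK_TOKEN)
  }
  structure(list(n = n, offsets = 0:(n - 1L), vocabulary = vocabulary),
            class = "tokenization_scheme")
}

#' Tokenize a sequence into non-overlapping n-grams
#'
#' Splits `seq` into consecutive, non-overlapping `n`-grams starting at
#' `offset` residues from the N-terminus; a trailing remainder shorter than
#' `n` is dropped. When the scheme carries a vocabulary, tokens outside it
#' are mapped to the unknown token.
#'
#' @param seq amino-acid string.
#' @param scheme a [tokenization_scheme()].
#' @param offset reading-frame offset, one of `scheme$offsets`.
#' @return character vector of tokens (possibly empty for short sequences).
#' @export
tokenize <- function(seq, scheme = tokenization_scheme(1L), offset = 0L) {
  stopifnot(is_string(seq), inherits(scheme, "tokenization_scheme"))
  offset <- as.integer(offset)
  if (!offset %in% scheme$offsets) stop("offset ", offset, " not in scheme offsets")
  seq <- toupper(seq)
  len <- nchar(seq)
  usable <- len - offset
  if (usable < scheme$n) {
    mhc_log("tokenize: sequence of length %d too short for n=%d offset=%d",
            len, scheme$n, offset)
    return(character(0))
  }
  k <- usable %/% scheme$n
  starts <- offset + 1L + scheme$n * (seq_len(k) - 1L)
  tokens <- substring(seq, starts, starts + scheme$n - 1L)
  if (!is.null(scheme$vocabulary)) {
    tokens[!tokens %in% scheme$vocabulary] <- UNK_TOKEN
  }
  tokens
}

#' Build a token-sentence corpus from FASTA and peptide-list files
#'
#' Every protein (FASTA record) or peptide (one per line) becomes one
#' sentence per reading-frame offset of the scheme; sources are
#' concatenated. Stands in for large pre-training corpora such as a
#' Swiss-Prot download plus simulated proteasome-cleaved 9-mers.
#'
#' @param fasta_paths character vector of FASTA files (may be empty).
#' @param peptide_list_paths character vector of plain-text peptide lists
#'   (one peptide per line; may be empty).
#' @param scheme a [tokenization_scheme()].
#' @return list of character vectors (token sentences), with attribute
#'   `source_counts` giving the sentence count per input file.
#' @export
build_corpus <- function(fasta_paths = character(), peptide_list_paths = character(),
                         scheme = tokenization_scheme(1L)) {
  if (length(fasta_paths) + length(peptide_list_paths) == 0) {
    stop("at least one FASTA or peptide-list source is required")
  }
  seqs_per_file <- list()
  for (p in fasta_paths) {
    if (!file.exists(p)) stop("unreadable FASTA: ", p)
    seqs_per_file[[p]] <- as.character(Biostrings::readAAStringSet(p))
  }
  for (p in peptide_list_paths) {
    if (!file.exists(p)) stop("unreadable peptide list: ", p)
    lines <- trimws(readLines(p))
    seqs_per_file[[p]] <- lines[nzchar(lines)]
  }
  sentences <- list()
  counts <- integer(0)
  for (p in names(seqs_per_file)) {
    before <- length(sentences)
    for (s in seqs_per_file[[p]]) {
      for (off in scheme$offsets) {
        toks <- suppressMessages(tokenize(s, scheme, off))
        if (length(toks) > 0) sentences[[length(sentences) + 1L]] <- toks
      }
    }
    counts[p] <- length(sentences) - before
    mhc_log("build_corpus: %s -> %d sentences", basename(p), counts[p])
  }
  attr(sentences, "source_counts") <- counts
  sentences
}

#' Skip-gram training configuration
#'
#' @param window symmetric context window in tokens (3, 5 and 7 are the
#'   usual choices for 1-grams).
#' @param dim embedding dimension (4--6 for 1-grams; 100 is the conventional
#'   3-gram/ProtVec dimension).
#' @param epochs passes over the pair list.
#' @param learning_rate initial step size for mean-gradient mini-batch SGD,
#'   decayed linearly to `learning_rate/100` over training.
#' @param negative negative samples per positive pair.
#' @param min_count tokens rarer than this are mapped to the unknown token.
#' @param batch pairs per vectorised SGD mini-batch.
#' @param seed RNG seed (training is deterministic given the seed).
#' @return an `embedding_config` list.
#' @export
embedding_config <- function(window = 5L, dim = 5L, epochs = 5L,
                             learning_rate = 0.25, negative = 5L,
                             min_count = 1L, batch = 512L, seed = 1L) {
  stopifnot(window >= 1, dim >= 1, epochs >= 1, negative >= 1)
  structure(list(window = as.integer(window), dim = as.integer(dim),
                 epochs = as.integer(epochs), learning_rate = learning_rate,
                 negative = as.integer(negative), min_count = as.integer(min_count),
                 batch = as.integer(batch), seed = as.integer(seed)),
            class = "embedding_config")
}

# Enumerate (center, context) index pairs for one sentence of token ids.
skipgram_pairs <- function(ids, window) {
  L <- length(ids)
  if (L < 2) return(NULL)
  res_c <- vector("list", L)
  for (i in seq_len(L)) {
    lo <- max(1L, i - window); hi <- min(L, i + window)
    ctx <- setdiff(lo:hi, i)
    res_c[[i]] <- cbind(rep.int(ids[i], length(ctx)), ids[ctx])
  }
  do.call(rbind, res_c)
}

#' Train skip-gram embeddings with negative sampling
#'
#' Stochastic gradient descent on the skip-gram objective with `negative`
#' noise samples per observed (center, context) pair, noise drawn from the
#' unigram distribution raised to the 3/4 power. Mini-batches are processed
#' with accumulated (summed) gradients, which keeps training fully
#' vectorised and deterministic under a fixed seed. Per-epoch loss is
#' logged.
#'
#' @param corpus list of token sentences from [build_corpus()].
#' @param config an [embedding_config()].
#' @param scheme optional [tokenization_scheme()]; its vocabulary (when
#'   present) is honoured, otherwise the vocabulary is derived from the
#'   corpus plus the gap and unknown tokens.
#' @param verbose log per-epoch loss.
#' @return an `embedding_table`: list with `vectors` (|vocabulary| x dim
#'   matrix, rownames = tokens) and `metadata`.
#' @export
train_skipgram <- function(corpus, config = embedding_config(),
                           scheme = NULL, verbose = FALSE) {
  tokens <- unlist(corpus, use.names = FALSE)
  if (length(tokens) == 0) stop("empty corpus")
  counts <- table(tokens)
  rare <- names(counts)[counts < config$min_count]
  vocab <- if (!is.null(scheme) && !is.null(scheme$vocabulary)) {
    scheme$vocabulary
  } else {
    sort(unique(c(setdiff(names(counts), rare), GAP_TOKEN, UNK_TOKEN)))
  }
  if (length(vocab) < 2) stop("vocabulary must contain at least 2 tokens")
  V <- length(vocab); d <- config$dim

  set.seed(config$seed)
  id_of <- setNames(seq_len(V), vocab)
  unk_id <- id_of[[UNK_TOKEN]]
  sent_ids <- lapply(corpus, function(s) {
    ids <- id_of[s]
    ids[is.na(ids)] <- unk_id
    unname(ids)
  })

  pairs <- do.call(rbind, lapply(sent_ids, skipgram_pairs, window = config$window))
  if (is.null(pairs) || nrow(pairs) == 0) stop("corpus yields no context pairs")

  # noise distribution: unigram^0.75 over tokens actually observed
  freq <- rep(1e-8, V)
  obs <- table(factor(unlist(sent_ids), levels = seq_len(V)))
  freq <- as.numeric(obs)^0.75
  if (sum(freq) == 0) freq <- rep(1, V)
  noise_p <- freq / sum(freq)

  v_in <- matrix(runif(V * d, -0.5 / d, 0.5 / d), V, d) # center vectors
  u_out <- matrix(0, V, d)                              # context vectors
  total_steps <- config$epochs * nrow(pairs)
  done <- 0
  K <- config$negative

  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(nrow(pairs))
    ep_loss <- 0
    for (start in seq(1L, nrow(pairs), by = config$batch)) {
      idx <- ord[start:min(start + config$batch - 1L, nrow(pairs))]
      B <- length(idx)
      lr <- config$learning_rate * max(1 - done / total_steps, 0.01)
      ctr <- pairs[idx, 1L]; ctx <- pairs[idx, 2L]
      neg <- matrix(sample.int(V, B * K, replace = TRUE, prob = noise_p), B, K)

      Vc <- v_in[ctr, , drop = FALSE]
      Uo <- u_out[ctx, , drop = FALSE]
      s_pos <- plogis(rowSums(Vc * Uo))
      ids_all <- c(ctx, as.vector(neg))
      Uall <- u_out[ids_all, , drop = FALSE]
      Vrep <- Vc[rep(seq_len(B), times = K + 1L), , drop = FALSE]
      s_all <- plogis(rowSums(Vrep * Uall))
      # gradient coefficient: sigma(s) - target (target 1 for pos, 0 for neg)
      coef <- s_all - c(rep(1, B), rep(0, B * K))
      ep_loss <- ep_loss - sum(log(pmax(s_pos, 1e-12))) -
        sum(log(pmax(1 - s_all[-(1:B)], 1e-12)))

      g_u <- coef * Vrep                             # d loss / d u_out rows
      g_v_rows <- coef * Uall                        # contributions to centers
      ctr_rep <- rep(ctr, times = K + 1L)
      # mean-gradient mini-batch step (summing over a batch diverges)
      gu_acc <- rowsum(g_u, group = ids_all) / B
      gv_acc <- rowsum(g_v_rows, group = ctr_rep) / B
      u_ids <- as.integer(rownames(gu_acc))
      v_ids <- as.integer(rownames(gv_acc))
      u_out[u_ids, ] <- u_out[u_ids, ] - lr * gu_acc
      v_in[v_ids, ] <- v_in[v_ids, ] - lr * gv_acc
      done <- done + B
    }
    mhc_log("skipgram epoch %d/%d  loss %.4f", epoch, config$epochs,
            ep_loss / nrow(pairs), verbose = verbose)
  }
  rownames(v_in) <- vocab
  structure(list(
    vectors = v_in,
    metadata = list(n = nchar(vocab[which(!vocab %in% c(GAP_TOKEN, UNK_TOKEN))][1]),
                    config = unclass(config),
                    corpus_sentences = length(corpus),
                    corpus_tokens = length(tokens))
  ), class = "embedding_table")
}

#' One-hot embedding table
#'
#' Identity-matrix embedding over the scheme's vocabulary: every token is a
#' unit binary vector, dimension equals the vocabulary size.
#'
#' @param scheme a [tokenization_scheme()] with a vocabulary.
#' @return an `embedding_table`.
#' @export
one_hot_table <- function(scheme = tokenization_scheme(1L)) {
  vocab <- scheme$vocabulary
  if (is.null(vocab)) stop("scheme has no vocabulary")
  m <- diag(length(vocab))
  rownames(m) <- vocab
  structure(list(vectors = m,
                 metadata = list(n = scheme$n, config = list(kind = "one_hot"))),
            class = "embedding_table")
}

#' @export
print.embedding_table <- function(x, ...) {
  cat(sprintf("embedding table: %d tokens x %d dims\n",
              nrow(x$vectors), ncol(x$vectors)))
  invisible(x)
}

#' Write / read an embedding table as TSV
#'
#' One row per token: the token followed by its vector components. Metadata
#' is stored in a small JSON sidecar (`<path>.meta.json`).
#'
#' @param table an `embedding_table`.
#' @param path TSV path.
#' @return `path` invisibly (write) or an `embedding_table` (read).
#' @export
write_embedding_tsv <- function(table, path) {
  stopifnot(inherits(table, "embedding_table"))
  dt <- data.table::data.table(token = rownames(table$vectors))
  dt <- cbind(dt, data.table::as.data.table(table$vectors))
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  jsonlite::write_json(table$metadata, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_embedding_tsv
#' @export
read_embedding_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = FALSE)
  vec <- as.matrix(dt[, -1])
  rownames(vec) <- dt[[1]]
  colnames(vec) <- NULL
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path, simplifyVector = TRUE) else list()
  structure(list(vectors = vec, metadata = meta), class = "embedding_table")
}
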