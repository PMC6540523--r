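## Internal neural-network primitives: masked GRU forward/backward, dense
## layers, inverted dropout, and Adam. Written in base R matrix code; the
## analytic gradients are verified against central finite differences in the
## test suite.

sigmoid <- function(x) 1 / (1 + exp(-x))

# column-wise bias add without sweep()'s aperm overhead
add_bias <- function(X, b) X + rep(b, each = nrow(X))

# Inverted-dropout mask: elements are 0 or 1/(1-p). p = 0 gives all ones.
dropout_mask <- function(nr, nc, p) {
  if (p <= 0) return(NULL)
  matrix(rbinom(nr * nc, 1L, 1 - p) / (1 - p), nr, nc)
}

apply_mask <- function(X, m) if (is.null(m)) X else X * m

## ---- dense -----------------------------------------------------------------

dense_forward <- function(X, W, b, relu = TRUE) {
  pre <- add_bias(X %*% W, b)
  out <- if (relu) pmax(pre, 0) else pre
  list(out = out, cache = list(X = X, pre = pre, relu = relu))
}

dense_backward <- function(dout, cache, W) {
  if (cache$relu) dout <- dout * (cache$pre > 0)
  list(dX = tcrossprod(dout, W),
       dW = crossprod(cache$X, dout),
       db = colSums(dout))
}

## ---- GRU -------------------------------------------------------------------
## Gate layout in W (d x 3H), U (H x 3H), b (3H): [update z | reset r | cand h].
## Update rule: h_t = (1 - z) * h_prev + z * c, with per-sequence masking so
## hidden states freeze once a sequence ends (right padding).
## rec_mask (B x H) is a variational recurrent-dropout mask applied to the
## hidden state entering the gate computations (not to the carried state).

gru_forward <- function(Xs, mask, W, U, b, rec_mask = NULL) {
  B <- nrow(Xs[[1]]); H <- nrow(U); Tn <- length(Xs)
  h <- matrix(0, B, H)
  izr <- 1:(2 * H); iz <- 1:H; ir <- (H + 1):(2 * H); ic <- (2 * H + 1):(3 * H)
  U_zr <- U[, izr, drop = FALSE]; U_c <- U[, ic, drop = FALSE]
  Xall <- do.call(rbind, Xs)
  AX <- add_bias(Xall %*% W, b)
  steps <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    ax <- AX[((t - 1) * B + 1):(t * B), , drop = FALSE]
    hd <- apply_mask(h, rec_mask)
    zr <- sigmoid(ax[, izr, drop = FALSE] + hd %*% U_zr)
    z <- zr[, iz, drop = FALSE]; r <- zr[, ir, drop = FALSE]
    cc <- tanh(ax[, ic, drop = FALSE] + (r * hd) %*% U_c)
    h_new <- (1 - z) * h + z * cc
    m <- mask[, t]
    h_next <- h_new * m + h * (1 - m)
    steps[[t]] <- list(h_prev = h, hd = hd, z = z, r = r, cc = cc, m = m)
    h <- h_next
  }
  list(h_last = h, steps = steps,
       cache = list(W = W, U = U, B = B, H = H, Tn = Tn, Xs = Xs,
                    rec_mask = rec_mask))
}

gru_backward <- function(dh_last, fw) {
  cache <- fw$cache
  W <- cache$W; U <- cache$U; H <- cache$H; Tn <- cache$Tn; B <- cache$B
  izr <- 1:(2 * H); iz <- 1:H; ir <- (H + 1):(2 * H); ic <- (2 * H + 1):(3 * H)
  U_zr <- U[, izr, drop = FALSE]; U_c <- U[, ic, drop = FALSE]
  dW <- matrix(0, nrow(W), ncol(W)); dU <- matrix(0, H, 3 * H); db <- numeric(3 * H)
  dXs <- vector("list", Tn)
  dh <- dh_last
  for (t in rev(seq_len(Tn))) {
    st <- fw$steps[[t]]
    m <- st$m
    dh_new <- dh * m
    dh_prev <- dh * (1 - m)
    dz <- dh_new * (st$cc - st$h_prev)
    dc <- dh_new * st$z
    dh_prev <- dh_prev + dh_new * (1 - st$z)
    da_c <- dc * (1 - st$cc^2)
    d_rhd <- tcrossprod(da_c, U_c)
    dr <- d_rhd * st$hd
    dhd <- d_rhd * st$r
    da_z <- dz * st$z * (1 - st$z)
    da_r <- dr * st$r * (1 - st$r)
    da_zr <- cbind(da_z, da_r)
    dhd <- dhd + tcrossprod(da_zr, U_zr)
    dh_prev <- dh_prev + apply_mask(dhd, cache$rec_mask)
    da <- cbind(da_zr, da_c)
    dU[, izr] <- dU[, izr] + crossprod(st$hd, da_zr)
    dU[, ic] <- dU[, ic] + crossprod(st$r * st$hd, da_c)
    dW <- dW + crossprod(cache$Xs[[t]], da)
    db <- db + colSums(da)
    dXs[[t]] <- tcrossprod(da, W)
    dh <- dh_prev
  }
  list(dXs = dXs, dW = dW, dU = dU, db = db)
}

## ---- sequence batching -----------------------------------------------------

# ids: B x T integer matrix (0 = padding); E: vocab x d embedding matrix.
# Returns list of T matrices (B x d) plus the 0/1 mask (B x T).
embed_sequences <- function(ids, E, in_mask = NULL) {
  B <- nrow(ids); Tn <- ncol(ids); d <- ncol(E)
  mask <- (ids > 0) * 1
  Xs <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    idt <- ids[, t]
    X <- matrix(0, B, d)
    nz <- idt > 0
    if (any(nz)) X[nz, ] <- E[idt[nz], , drop = FALSE]
    if (!is.null(in_mask)) X <- X * in_mask
    Xs[[t]] <- X
  }
  list(Xs = Xs, mask = mask)
}

# Accumulate embedding-row gradients from per-timestep input gradients.
embed_backward <- function(dXs, ids, vocab_size, in_mask = NULL) {
  d <- ncol(dXs[[1]])
  dE <- matrix(0, vocab_size, d)
  for (t in seq_along(dXs)) {
    idt <- ids[, t]
    nz <- which(idt > 0)
    if (length(nz) == 0) next
    dX <- dXs[[t]]
    if (!is.null(in_mask)) dX <- dX * in_mask
    acc <- rowsum(dX[nz, , drop = FALSE], group = idt[nz])
    rows <- as.integer(rownames(acc))
    dE[rows, ] <- dE[rows, , drop = FALSE] + acc
  }
  dE
}

# Reverse each row's occupied prefix (right padding preserved), so a backward
# GRU reads C-terminus first.
reverse_ids <- function(ids) {
  out <- ids
  for (i in seq_len(nrow(ids))) {
    len <- sum(ids[i, ] > 0)
    if (len > 1) out[i, 1:len] <- ids[i, len:1]
  }
  out
}

## ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# Glorot-uniform initialisation.
glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(runif(nr * nc, -lim, lim), nr, nc)
}

# Orthogonal initialisation for recurrent matrices (per gate block).
orthogonal_block <- function(H, gates = 3L) {
  blocks <- lapply(seq_len(gates), function(i) {
    A <- matrix(rnorm(H * H), H, H)
    qr.Q(qr(A))
  })
  do.call(cbind, blocks)
}
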