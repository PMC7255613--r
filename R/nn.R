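## Internal numerical engine of the convolutional classifier.
##
## All layers operate on "row-stacked" batch matrices: a batch of B sequence
## tensors (L positions x C channels) is stored as a (B*L) x C matrix whose
## row (i-1)*L + t holds position t of sample i.  1-D convolutions are
## computed as im2col gathers followed by a single GEMM, which hands the whole
## arithmetic load to BLAS.  Gradients use the exact transpose operations
## (col2im scatter via rowsum).

## Index matrix for a same-padded kernel-k convolution over B stacked
## sequences of length L.  Entry [r, j] is the source row of tap j for output
## row r, or the sentinel B*L+1 for out-of-range taps (zero-filled).
## Memoised: the same (B, L, k) recurs for every mini-batch.
.nn_cache <- new.env(parent = emptyenv())

conv_index <- function(B, L, k) {
  key <- paste0("c", B, "_", L, "_", k)
  hit <- .nn_cache[[key]]
  if (!is.null(hit)) return(hit)
  pad <- (k - 1L) %/% 2L
  t_out <- rep(seq_len(L), times = B)
  base <- rep((seq_len(B) - 1L) * L, each = L)
  idx <- matrix(0L, B * L, k)
  for (j in seq_len(k)) {
    t_in <- t_out + (j - 1L) - pad
    ok <- t_in >= 1L & t_in <= L
    col <- base + t_in
    col[!ok] <- B * L + 1L
    idx[, j] <- col
  }
  .nn_cache[[key]] <- idx
  idx
}

conv_forward <- function(X, W, b, idx) {
  k <- ncol(idx)
  C <- ncol(X)
  n <- nrow(idx)
  Xcol <- matrix(0, n, k * C)
  for (j in seq_len(k)) {
    src <- idx[, j]
    ok <- src <= n
    Xcol[ok, ((j - 1L) * C + 1L):(j * C)] <- X[src[ok], , drop = FALSE]
  }
  out <- Xcol %*% W
  out <- out + rep(b, each = nrow(out))
  list(out = out, Xcol = Xcol)
}

conv_backward <- function(dOut, W, Xcol, idx, nrow_X, C) {
  k <- ncol(idx)
  dW <- crossprod(Xcol, dOut)
  db <- colSums(dOut)
  dXcol <- tcrossprod(dOut, W)
  dX <- matrix(0, nrow_X, C)
  for (j in seq_len(k)) {
    part <- dXcol[, ((j - 1L) * C + 1L):(j * C), drop = FALSE]
    rs <- rowsum(part, group = idx[, j])
    rows <- as.integer(rownames(rs))
    keep <- rows <= nrow_X
    dX[rows[keep], ] <- dX[rows[keep], , drop = FALSE] +
      rs[keep, , drop = FALSE]
  }
  list(dX = dX, dW = dW, db = db)
}

## Non-overlapping max-pool of width 2 over stacked sequences; trailing odd
## position dropped.
pool_index <- function(B, L) {
  key <- paste0("p", B, "_", L)
  hit <- .nn_cache[[key]]
  if (!is.null(hit)) return(hit)
  Lout <- L %/% 2L
  t1 <- rep(2L * seq_len(Lout) - 1L, times = B)
  base <- rep((seq_len(B) - 1L) * L, each = Lout)
  out <- list(i1 = base + t1, i2 = base + t1 + 1L, Lout = Lout)
  .nn_cache[[key]] <- out
  out
}

pool_forward <- function(X, pidx) {
  A <- X[pidx$i1, , drop = FALSE]
  B2 <- X[pidx$i2, , drop = FALSE]
  M <- A >= B2
  list(out = A * M + B2 * !M, M = M)
}

pool_backward <- function(dOut, pidx, M, nrow_X, C) {
  dX <- matrix(0, nrow_X, C)
  dX[pidx$i1, ] <- dOut * M
  dX[pidx$i2, ] <- dOut * !M
  dX
}

## (B*L) x C row-stacked matrix -> B x (L*C) per-sample flat matrix
## (position-fastest ordering) and its inverse.
stack_to_flat <- function(X, B, L) {
  C <- ncol(X)
  t(matrix(aperm(array(X, dim = c(L, B, C)), c(1, 3, 2)), L * C, B))
}

flat_to_stack <- function(Xf, B, L) {
  C <- ncol(Xf) / L
  matrix(aperm(array(t(Xf), dim = c(L, C, B)), c(1, 3, 2)), B * L, C)
}

## Model input (B x 1890, position-major feature vectors) -> row-stacked.
input_to_stack <- function(X, L, C) {
  B <- nrow(X)
  matrix(aperm(array(t(X), dim = c(C, L, B)), c(2, 3, 1)), B * L, C)
}

relu <- function(x) x * (x > 0)

softmax2 <- function(logits) {
  m <- pmax(logits[, 1], logits[, 2])
  e1 <- exp(logits[, 1] - m)
  e2 <- exp(logits[, 2] - m)
  s <- e1 + e2
  cbind(e1 / s, e2 / s)
}

he_init <- function(nin, nout) {
  matrix(stats::rnorm(nin * nout, sd = sqrt(2 / nin)), nin, nout)
}

## Parameter initialisation for the 7-conv / 2-pool / 2-residual / 2-dense
## architecture.  `pg` appends an 18-value side input before the dense stack.
init_params <- function(config, pg = FALSE) {
  rzi <- !isFALSE(config$residual_identity_init)
  k <- config$kernel
  Fn <- config$filters
  C0 <- config$n_features
  L_flat <- ((config$window %/% 2L) %/% 2L)   # 21 -> 10 -> 5
  d_in <- L_flat * Fn + if (pg) 18L else 0L
  du <- config$dense_units
  ## W3 and W5 close the two residual blocks; starting them at zero makes
  ## each block an identity map at initialisation, which stabilises early
  ## training of the deep ReLU stack.
  list(
    W1 = he_init(k * C0, Fn), b1 = numeric(Fn),
    W2 = he_init(k * Fn, Fn), b2 = numeric(Fn),
    W3 = if (rzi) matrix(0, k * Fn, Fn) else he_init(k * Fn, Fn),
    b3 = numeric(Fn),
    W4 = he_init(k * Fn, Fn), b4 = numeric(Fn),
    W5 = if (rzi) matrix(0, k * Fn, Fn) else he_init(k * Fn, Fn),
    b5 = numeric(Fn),
    W6 = he_init(k * Fn, Fn), b6 = numeric(Fn),
    W7 = he_init(k * Fn, Fn), b7 = numeric(Fn),
    Wd1 = he_init(d_in, du), bd1 = numeric(du),
    Wd2 = he_init(du, du), bd2 = numeric(du),
    Wd3 = he_init(du, 2L), bd3 = numeric(2L))
}

## Forward pass.  X: B x (window*n_features) flat inputs; pg_x: optional
## B x 18 side input.  Returns class probabilities and, when `train`, the
## cache needed for backprop (dropout is only active when `train`).
nn_forward <- function(params, config, X, pg_x = NULL, train = FALSE) {
  B <- nrow(X)
  L1 <- config$window
  k <- config$kernel
  cache <- list(B = B)

  X0 <- input_to_stack(X, L1, config$n_features)
  idx1 <- conv_index(B, L1, k)

  c1 <- conv_forward(X0, params$W1, params$b1, idx1)
  a1 <- relu(c1$out)
  c2 <- conv_forward(a1, params$W2, params$b2, idx1)
  a2 <- relu(c2$out)
  c3 <- conv_forward(a2, params$W3, params$b3, idx1)
  s3 <- c3$out + a1                      # residual link 1
  a3 <- relu(s3)

  p1 <- pool_index(B, L1)
  q1 <- pool_forward(a3, p1)
  L2 <- p1$Lout
  idx2 <- conv_index(B, L2, k)

  c4 <- conv_forward(q1$out, params$W4, params$b4, idx2)
  a4 <- relu(c4$out)
  c5 <- conv_forward(a4, params$W5, params$b5, idx2)
  s5 <- c5$out + q1$out                  # residual link 2
  a5 <- relu(s5)

  p2 <- pool_index(B, L2)
  q2 <- pool_forward(a5, p2)
  L3 <- p2$Lout
  idx3 <- conv_index(B, L3, k)

  c6 <- conv_forward(q2$out, params$W6, params$b6, idx3)
  a6 <- relu(c6$out)
  c7 <- conv_forward(a6, params$W7, params$b7, idx3)
  a7 <- relu(c7$out)

  flat <- stack_to_flat(a7, B, L3)
  if (!is.null(pg_x)) flat <- cbind(flat, pg_x)

  z1 <- flat %*% params$Wd1
  z1 <- z1 + rep(params$bd1, each = B)
  h1 <- relu(z1)
  if (train && config$dropout > 0) {
    m1 <- matrix((stats::runif(length(h1)) >= config$dropout) /
                   (1 - config$dropout), nrow(h1), ncol(h1))
    h1 <- h1 * m1
    cache$m1 <- m1
  }
  z2 <- h1 %*% params$Wd2
  z2 <- z2 + rep(params$bd2, each = B)
  h2 <- relu(z2)
  if (train && config$dropout > 0) {
    m2 <- matrix((stats::runif(length(h2)) >= config$dropout) /
                   (1 - config$dropout), nrow(h2), ncol(h2))
    h2 <- h2 * m2
    cache$m2 <- m2
  }
  logits <- h2 %*% params$Wd3
  logits <- logits + rep(params$bd3, each = B)
  probs <- softmax2(logits)

  if (train) {
    cache <- c(cache, list(
      X0 = X0, idx1 = idx1, idx2 = idx2, idx3 = idx3,
      c1 = c1, a1 = a1, c2 = c2, a2 = a2, c3 = c3, s3 = s3, a3 = a3,
      p1 = p1, q1 = q1, c4 = c4, a4 = a4, c5 = c5, s5 = s5, a5 = a5,
      p2 = p2, q2 = q2, c6 = c6, a6 = a6, c7 = c7, a7 = a7,
      L1 = L1, L2 = L2, L3 = L3,
      flat = flat, z1 = z1, h1 = h1, z2 = z2, h2 = h2,
      has_pg = !is.null(pg_x)))
  }
  list(probs = probs, cache = cache)
}

## Backward pass; y in {0,1} (1 = pathogenic = class column 2).
nn_backward <- function(params, config, probs, y, cache) {
  B <- cache$B
  Fn <- config$filters
  Y <- cbind(1 - y, y)
  dlog <- (probs - Y) / B

  g <- list()
  g$Wd3 <- crossprod(cache$h2, dlog); g$bd3 <- colSums(dlog)
  dh2 <- tcrossprod(dlog, params$Wd3)
  if (!is.null(cache$m2)) dh2 <- dh2 * cache$m2
  dz2 <- dh2 * (cache$z2 > 0)
  g$Wd2 <- crossprod(cache$h1, dz2); g$bd2 <- colSums(dz2)
  dh1 <- tcrossprod(dz2, params$Wd2)
  if (!is.null(cache$m1)) dh1 <- dh1 * cache$m1
  dz1 <- dh1 * (cache$z1 > 0)
  g$Wd1 <- crossprod(cache$flat, dz1); g$bd1 <- colSums(dz1)
  dflat <- tcrossprod(dz1, params$Wd1)
  if (cache$has_pg) dflat <- dflat[, seq_len(ncol(dflat) - 18L), drop = FALSE]

  da7 <- flat_to_stack(dflat, B, cache$L3)
  n3 <- B * cache$L3
  dc7 <- da7 * (cache$c7$out > 0)
  bw7 <- conv_backward(dc7, params$W7, cache$c7$Xcol, cache$idx3, n3, Fn)
  g$W7 <- bw7$dW; g$b7 <- bw7$db
  dc6 <- bw7$dX * (cache$c6$out > 0)
  bw6 <- conv_backward(dc6, params$W6, cache$c6$Xcol, cache$idx3, n3, Fn)
  g$W6 <- bw6$dW; g$b6 <- bw6$db

  n2 <- B * cache$L2
  dq2 <- bw6$dX
  da5 <- pool_backward(dq2, cache$p2, cache$q2$M, n2, Fn)
  ds5 <- da5 * (cache$s5 > 0)
  bw5 <- conv_backward(ds5, params$W5, cache$c5$Xcol, cache$idx2, n2, Fn)
  g$W5 <- bw5$dW; g$b5 <- bw5$db
  dc4 <- bw5$dX * (cache$c4$out > 0)
  bw4 <- conv_backward(dc4, params$W4, cache$c4$Xcol, cache$idx2, n2, Fn)
  g$W4 <- bw4$dW; g$b4 <- bw4$db
  dq1 <- bw4$dX + ds5                     # residual link 2

  n1 <- B * cache$L1
  da3 <- pool_backward(dq1, cache$p1, cache$q1$M, n1, Fn)
  ds3 <- da3 * (cache$s3 > 0)
  bw3 <- conv_backward(ds3, params$W3, cache$c3$Xcol, cache$idx1, n1, Fn)
  g$W3 <- bw3$dW; g$b3 <- bw3$db
  dc2 <- bw3$dX * (cache$c2$out > 0)
  bw2 <- conv_backward(dc2, params$W2, cache$c2$Xcol, cache$idx1, n1, Fn)
  g$W2 <- bw2$dW; g$b2 <- bw2$db
  da1 <- bw2$dX + ds3                     # residual link 1
  dc1 <- da1 * (cache$c1$out > 0)
  bw1 <- conv_backward(dc1, params$W1, cache$c1$Xcol, cache$idx1, n1,
                       config$n_features)
  g$W1 <- bw1$dW; g$b1 <- bw1$db
  g
}

cross_entropy <- function(probs, y) {
  p <- probs[cbind(seq_along(y), y + 1L)]
  -mean(log(pmax(p, 1e-12)))
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

## Adam with decoupled weight decay (AdamW); decay is applied to weight
## matrices only, not biases.
adam_step <- function(params, grads, state, lr, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    step <- lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    if (weight_decay > 0 && substr(nm, 1L, 1L) == "W") {
      step <- step + lr * weight_decay * params[[nm]]
    }
    params[[nm]] <- params[[nm]] - step
  }
  list(params = params, state = state)
}
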