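## The convolutional pathogenicity classifier: configuration, fitting,
## prediction, cross-validation and ROC evaluation.

#' Network and training configuration
#'
#' The architecture follows the canonical layout: seven 1-D convolutional
#' layers (200 filters, kernel 3), two max-pooling layers, two residual links
#' (each adding a convolution block's input back to its output), and two
#' 100-unit dense layers with 0.5 dropout before a 2-class softmax.  Hidden
#' activations are ReLU.  Training uses Adam with cross-entropy loss,
#' mini-batches of 128 and optional early stopping on a held-out validation
#' split.
#'
#' @param filters Filters per convolutional layer (default 200).
#' @param kernel Convolution kernel size (default 3).
#' @param dense_units Units per dense layer (default 100).
#' @param dropout Dropout rate after each dense layer (default 0.5).
#' @param batch_size Mini-batch size (default 128).
#' @param epochs Maximum training epochs (default 14).
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param lr_decay Learning-rate reduction factor applied whenever the
#'   validation loss fails to improve (reduce-on-plateau; default 0.5, set 1
#'   to disable).
#' @param weight_decay Decoupled (AdamW-style) weight decay on the weight
#'   matrices (default 3e-3).
#' @param input_noise Standard deviation of Gaussian noise added to training
#'   inputs each step (augmentation regulariser; default 0.1).
#' @param residual_identity_init Start residual blocks as identity maps by
#'   zero-initialising their closing convolutions (default TRUE).
#' @param val_fraction Fraction of the training data held out for early
#'   stopping (default 0.1; ignored when `early_stopping = FALSE`).
#' @param patience Consecutive epochs without validation improvement before
#'   stopping (default 3); each non-improving epoch also triggers the
#'   learning-rate reduction.
#' @param min_epochs Epochs to run before early stopping may fire (default
#'   5); slow-starting runs are not cut off at chance level.
#' @param early_stopping Use validation-based early stopping (default TRUE).
#' @param window Input window length (default 21).
#' @param n_features Features per position (default 90).
#' @param seed Integer seed controlling initialisation, shuffling and dropout.
#' @return A list of class `deepsav_config`.
#' @export
deepsav_config <- function(filters = 200L, kernel = 3L, dense_units = 100L,
                           dropout = 0.5, batch_size = 128L, epochs = 14L,
                           learning_rate = 1e-3, lr_decay = 0.5,
                           weight_decay = 3e-3, input_noise = 0.1,
                           residual_identity_init = TRUE,
                           val_fraction = 0.1,
                           patience = 3L, min_epochs = 5L, early_stopping = TRUE,
                           window = 21L, n_features = 90L, seed = 1L) {
  stopifnot(filters >= 1, kernel >= 1, dense_units >= 1,
            dropout >= 0, dropout < 1, batch_size >= 1, epochs >= 1,
            learning_rate > 0, window >= 1, n_features >= 1)
  structure(list(filters = as.integer(filters), kernel = as.integer(kernel),
                 dense_units = as.integer(dense_units), dropout = dropout,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), learning_rate = learning_rate,
                 lr_decay = lr_decay, weight_decay = weight_decay,
                 input_noise = input_noise,
                 residual_identity_init = isTRUE(residual_identity_init),
                 val_fraction = val_fraction, patience = as.integer(patience),
                 min_epochs = as.integer(min_epochs),
                 early_stopping = isTRUE(early_stopping),
                 window = as.integer(window),
                 n_features = as.integer(n_features), seed = as.integer(seed)),
            class = "deepsav_config")
}

#' Build an (untrained) network
#'
#' Instantiates the architecture for a given configuration, with seeded
#' weight initialisation.  With `pg = TRUE` the network takes an additional
#' 18-value side input (transformed minor allele frequency plus 17 gene-level
#' features) concatenated ahead of the dense layers.
#'
#' @param config A [deepsav_config()].
#' @param pg Build the +PG variant (default FALSE).
#' @return An object of class `deepsav_model` (untrained).
#' @export
build_network <- function(config = deepsav_config(), pg = FALSE) {
  stopifnot(inherits(config, "deepsav_config"))
  if ((config$window %/% 2L) %/% 2L < 1L) {
    stop("window too short for two max-pooling layers", call. = FALSE)
  }
  set.seed(config$seed)
  params <- init_params(config, pg = pg)
  structure(list(params = params, config = config, pg = pg,
                 trained = FALSE, history = NULL,
                 param_count = sum(vapply(params, length, integer(1)))),
            class = "deepsav_model")
}

## Stratified train/validation split indices.
stratified_holdout <- function(y, fraction) {
  val <- integer(0)
  for (cl in unique(y)) {
    idx <- which(y == cl)
    n_val <- max(1L, round(length(idx) * fraction))
    val <- c(val, sample(idx, n_val))
  }
  sort(val)
}

#' Fit the pathogenicity classifier
#'
#' Trains the convolutional network on encoded variant windows.  Training is
#' reproducible: the configuration seed drives initialisation, mini-batch
#' shuffling and dropout, so the same seed and data give identical models.
#'
#' @param x Numeric matrix of flattened feature windows
#'   (`n x window*n_features`, from [encode_dataset()]).
#' @param y Labels: 1/`"pathogenic"` vs 0/`"benign"`.
#' @param config A [deepsav_config()].
#' @param pg_x Optional `n x 18` side-input matrix (see [pg_features()]);
#'   supplying it fits the +PG variant.
#' @param verbose Print per-epoch losses (default FALSE).
#' @return A fitted `deepsav_model` with elements `params`, `config`,
#'   `history` (per-epoch train/validation loss) and `pg`.
#' @export
deepsav_fit <- function(x, y, config = deepsav_config(), pg_x = NULL,
                        verbose = FALSE) {
  stopifnot(inherits(config, "deepsav_config"))
  x <- as.matrix(x)
  y <- as_binary_labels(y)
  if (length(y) != nrow(x)) stop("x and y lengths differ", call. = FALSE)
  if (length(unique(y)) < 2L) {
    stop("training data must contain both classes", call. = FALSE)
  }
  if (ncol(x) != config$window * config$n_features) {
    stop("x has ", ncol(x), " columns; expected ",
         config$window * config$n_features, call. = FALSE)
  }
  if (!is.null(pg_x)) {
    pg_x <- as.matrix(pg_x)
    stopifnot(nrow(pg_x) == nrow(x), ncol(pg_x) == 18L)
  }

  set.seed(config$seed)
  params <- init_params(config, pg = !is.null(pg_x))

  use_val <- config$early_stopping && config$val_fraction > 0
  if (use_val) {
    val_idx <- stratified_holdout(y, config$val_fraction)
    x_val <- x[val_idx, , drop = FALSE]
    y_val <- y[val_idx]
    pg_val <- if (!is.null(pg_x)) pg_x[val_idx, , drop = FALSE]
    tr_idx <- setdiff(seq_along(y), val_idx)
  } else {
    tr_idx <- seq_along(y)
  }
  x_tr <- x[tr_idx, , drop = FALSE]
  y_tr <- y[tr_idx]
  pg_tr <- if (!is.null(pg_x)) pg_x[tr_idx, , drop = FALSE]

  state <- adam_init(params)
  n <- length(y_tr)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  best <- list(loss = Inf, params = params, epoch = 0L)
  bad_epochs <- 0L
  lr <- config$learning_rate

  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    starts <- seq(1L, n, by = config$batch_size)
    ep_loss <- 0
    for (s in starts) {
      b_idx <- ord[s:min(s + config$batch_size - 1L, n)]
      xb <- x_tr[b_idx, , drop = FALSE]
      if (config$input_noise > 0) {
        xb <- xb + stats::rnorm(length(xb), 0, config$input_noise)
      }
      yb <- y_tr[b_idx]
      pgb <- if (!is.null(pg_x)) pg_tr[b_idx, , drop = FALSE]
      fw <- nn_forward(params, config, xb, pg_x = pgb, train = TRUE)
      ep_loss <- ep_loss + cross_entropy(fw$probs, yb) * length(b_idx)
      grads <- nn_backward(params, config, fw$probs, yb, fw$cache)
      upd <- adam_step(params, grads, state, lr,
                       weight_decay = config$weight_decay)
      params <- upd$params
      state <- upd$state
    }
    ep_loss <- ep_loss / n
    v_loss <- NA_real_
    if (use_val) {
      v_loss <- predict_loss(params, config, x_val, y_val, pg_val)
      if (v_loss < best$loss - 1e-6) {
        best <- list(loss = v_loss, params = params, epoch = ep)
        bad_epochs <- 0L
      } else {
        bad_epochs <- bad_epochs + 1L
        lr <- lr * config$lr_decay  # reduce on validation plateau
      }
    }
    history <- rbind(history, data.frame(epoch = ep, train_loss = ep_loss,
                                         val_loss = v_loss))
    if (verbose) {
      message(sprintf("epoch %d  train loss %.4f  val loss %.4f",
                      ep, ep_loss, v_loss))
    }
    if (use_val && ep >= config$min_epochs &&
        bad_epochs >= config$patience) break
  }
  if (use_val && best$epoch > 0L) params <- best$params

  structure(list(params = params, config = config, pg = !is.null(pg_x),
                 trained = TRUE, history = history,
                 param_count = sum(vapply(params, length, integer(1))),
                 n_train = length(y), class_balance = mean(y)),
            class = "deepsav_model")
}

## Batched forward pass without dropout; returns pathogenic probabilities.
predict_probs <- function(params, config, x, pg_x = NULL, chunk = 256L) {
  n <- nrow(x)
  out <- numeric(n)
  for (s in seq(1L, n, by = chunk)) {
    i <- s:min(s + chunk - 1L, n)
    pgb <- if (!is.null(pg_x)) pg_x[i, , drop = FALSE]
    out[i] <- nn_forward(params, config, x[i, , drop = FALSE],
                         pg_x = pgb, train = FALSE)$probs[, 2]
  }
  out
}

predict_loss <- function(params, config, x, y, pg_x = NULL) {
  p <- predict_probs(params, config, x, pg_x)
  -mean(log(pmax(ifelse(y == 1L, p, 1 - p), 1e-12)))
}

as_binary_labels <- function(y) {
  if (is.character(y) || is.factor(y)) {
    y <- as.character(y)
    bad <- setdiff(unique(y), c("pathogenic", "benign"))
    if (length(bad) > 0L) {
      stop("unknown label(s): ", paste(bad, collapse = ", "), call. = FALSE)
    }
    y <- as.integer(y == "pathogenic")
  }
  y <- as.integer(y)
  if (!all(y %in% c(0L, 1L))) stop("labels must be binary", call. = FALSE)
  y
}

#' Predict DeepSAV scores
#'
#' @param object A fitted (or built) `deepsav_model`.
#' @param newdata Matrix of flattened windows (`n x window*n_features`).
#' @param pg_x `n x 18` side-input matrix; required for +PG models and
#'   rejected by plain models.
#' @param ... Unused.
#' @return Numeric vector of DeepSAV scores in `[0, 1]` (softmax pathogenic
#'   class probabilities).
#' @export
predict.deepsav_model <- function(object, newdata, pg_x = NULL, ...) {
  newdata <- as.matrix(newdata)
  cfg <- object$config
  if (ncol(newdata) != cfg$window * cfg$n_features) {
    stop("newdata has ", ncol(newdata), " columns; expected ",
         cfg$window * cfg$n_features, call. = FALSE)
  }
  if (object$pg && is.null(pg_x)) {
    stop("this is a +PG model; supply pg_x", call. = FALSE)
  }
  if (!object$pg && !is.null(pg_x)) {
    stop("this model takes no PG side input", call. = FALSE)
  }
  if (!is.null(pg_x)) {
    pg_x <- as.matrix(pg_x)
    stopifnot(nrow(pg_x) == nrow(newdata), ncol(pg_x) == 18L)
  }
  predict_probs(object$params, cfg, newdata, pg_x)
}

#' @export
print.deepsav_model <- function(x, ...) {
  cat("DeepSAV convolutional pathogenicity classifier",
      if (x$pg) "(+PG)" else "", "\n")
  cat(sprintf("  7 conv1d layers (%d filters, kernel %d), 2 max-pool, 2 residual links\n",
              x$config$filters, x$config$kernel))
  cat(sprintf("  2 dense layers (%d units, dropout %.2f), softmax output\n",
              x$config$dense_units, x$config$dropout))
  cat(sprintf("  parameters: %s; %s\n", format(x$param_count, big.mark = ","),
              if (x$trained) sprintf("trained on %d variants", x$n_train)
              else "untrained"))
  invisible(x)
}

#' @export
summary.deepsav_model <- function(object, ...) {
  print(object)
  if (!is.null(object$history) && nrow(object$history) > 0) {
    cat("\nTraining history:\n")
    print(object$history, row.names = FALSE)
  }
  invisible(object)
}

#' Plot the training history of a fitted model
#' @param x A fitted `deepsav_model`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.deepsav_model <- function(x, ...) {
  h <- x$history
  if (is.null(h) || nrow(h) == 0) stop("no training history", call. = FALSE)
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "b",
                    pch = 1:2, lty = 1:2, xlab = "epoch",
                    ylab = "cross-entropy loss", ...)
  graphics::legend("topright", c("train", "validation"), pch = 1:2,
                   lty = 1:2, bty = "n")
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is one file holding the configuration and the weight
#' tensors; saving and re-loading round-trips bit-exactly.
#'
#' @param model A `deepsav_model`.
#' @param path Checkpoint file path.
#' @return `load_deepsav()` returns the restored `deepsav_model`.
#' @export
save_deepsav <- function(model, path) {
  stopifnot(inherits(model, "deepsav_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_deepsav
#' @export
load_deepsav <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "deepsav_model"))
  model
}

#' Area under the ROC curve
#'
#' Rank-based AUC equal to the probability that a random positive outscores a
#' random negative, counting ties as one half.  Invariant under strictly
#' increasing transforms of the scores.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Binary labels (1/`"pathogenic"` = positive).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as_binary_labels(labels)
  if (length(scores) != length(labels)) {
    stop("scores and labels lengths differ", call. = FALSE)
  }
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("both classes must be present", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Stratified k-fold cross-validation
#'
#' Splits each class into `k` near-equal folds (seeded shuffle), trains on
#' k-1 folds and scores the held-out fold, so that every variant is validated
#' exactly once.  Reports per-fold and pooled ROC AUC.
#'
#' @param x Encoded window matrix.
#' @param y Binary labels.
#' @param k Number of folds (default 4).
#' @param config A [deepsav_config()].
#' @param pg_x Optional `n x 18` side-input matrix.
#' @param seed Seed for the fold assignment (defaults to the config seed).
#' @param verbose Print fold progress.
#' @return A list of class `deepsav_cv`: `fold` (assignment per variant),
#'   `scores` (out-of-fold DeepSAV scores), `fold_auc` (length k),
#'   `pooled_auc`.
#' @export
cross_validate <- function(x, y, k = 4L, config = deepsav_config(),
                           pg_x = NULL, seed = config$seed,
                           verbose = FALSE) {
  x <- as.matrix(x)
  y <- as_binary_labels(y)
  if (min(table(y)) < k) {
    stop("each class needs at least k = ", k, " members", call. = FALSE)
  }
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in c(0L, 1L)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  scores <- numeric(length(y))
  fold_auc <- numeric(k)
  for (f in seq_len(k)) {
    tr <- fold != f
    cfg <- config
    cfg$seed <- config$seed + f  # independent init/shuffle per fold
    fit <- deepsav_fit(x[tr, , drop = FALSE], y[tr], cfg,
                       pg_x = if (!is.null(pg_x)) pg_x[tr, , drop = FALSE])
    te <- !tr
    scores[te] <- predict(fit, x[te, , drop = FALSE],
                          pg_x = if (!is.null(pg_x))
                            pg_x[te, , drop = FALSE])
    fold_auc[f] <- roc_auc(scores[te], y[te])
    if (verbose) message(sprintf("fold %d AUC %.3f", f, fold_auc[f]))
  }
  structure(list(fold = fold, scores = scores, fold_auc = fold_auc,
                 pooled_auc = roc_auc(scores, y), k = k),
            class = "deepsav_cv")
}

#' @export
print.deepsav_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation\n", x$k))
  cat("  per-fold AUC:", paste(sprintf("%.3f", x$fold_auc), collapse = ", "),
      "\n")
  cat(sprintf("  pooled AUC: %.3f\n", x$pooled_auc))
  invisible(x)
}

#' Assemble the 18-value +PG side input
#'
#' Combines the transformed minor allele frequency, `-log10(MAF + 1e-9)`,
#' with the 17 gene-level features.  Missing values are imputed with the
#' per-column medians of the supplied reference rows (use the training fold
#' medians when scoring held-out data).
#'
#' @param maf Numeric MAF per variant (NA allowed).
#' @param gene_features Data frame with `gene` plus the 17 gene-level
#'   columns.
#' @param gene Character vector mapping each variant to a gene.
#' @param medians Optional named numeric vector of imputation medians (as
#'   returned in the `medians` attribute); defaults to medians of the rows
#'   being encoded.
#' @return `n x 18` numeric matrix with a `medians` attribute.
#' @export
pg_features <- function(maf, gene_features, gene, medians = NULL) {
  stopifnot(length(maf) == length(gene))
  rows <- match(gene, gene_features$gene)
  gf <- as.matrix(gene_features[rows, GENE_FEATURE_COLUMNS, drop = FALSE])
  x <- cbind(maf_t = -log10(ifelse(is.na(maf), 1, maf) + 1e-9), gf)
  x[is.na(maf), "maf_t"] <- NA
  if (is.null(medians)) {
    medians <- apply(x, 2, stats::median, na.rm = TRUE)
    medians[is.na(medians)] <- 0
  }
  for (j in seq_len(ncol(x))) {
    x[is.na(x[, j]), j] <- medians[j]
  }
  attr(x, "medians") <- medians
  x
}
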