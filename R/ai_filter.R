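#' Extract the shape-filter feature vector
#'
#' The network judges shape only, never dose magnitude (that is handled by
#' the earlier filters), so the 200 channels are divided by the curve maximum
#' before anything else. Two distribution-shape moments are appended: the
#' standardized fourth moment (kurtosis) and third moment (skewness) of the
#' channel index treated as a random variable with probability mass
#' proportional to intensity.
#'
#' @param gc A [glow_curve].
#' @return Numeric vector of length 202: the 200 normalized channels, then
#'   kurtosis, then skewness. Scale-invariant: `extract_features(k * gc)` is
#'   identical for any `k > 0`.
#' @export
extract_features <- function(gc) {
  ch <- as.numeric(gc)
  mx <- max(ch)
  if (mx <= 0)
    stop("all-zero glow curve has no shape (should have been dose-filtered)")
  p <- ch / sum(ch)
  idx <- seq_len(GC_CHANNELS)
  mu <- sum(idx * p)
  v <- sum((idx - mu)^2 * p)
  if (v > 0) {
    skew <- sum((idx - mu)^3 * p) / v^1.5
    kurt <- sum((idx - mu)^4 * p) / v^2
  } else {
    skew <- 0
    kurt <- 0
  }
  c(ch / mx, kurt, skew)
}

feature_matrix <- function(curves) {
  t(vapply(curves, extract_features, numeric(GC_CHANNELS + 2L)))
}

## ---- minimal feed-forward network -------------------------------------
## The filter architecture is fixed: 202 inputs, hidden layers of 5, 15 and
## 5 ReLU units, one logistic output giving P(normal). Implemented directly
## with matrix algebra; trained full-batch with Adam and early stopping.

mlp_init <- function(sizes) {
  L <- length(sizes) - 1L
  W <- vector("list", L)
  b <- vector("list", L)
  for (l in seq_len(L)) {
    W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1L],
                                  sd = sqrt(2 / sizes[l])),
                     sizes[l], sizes[l + 1L])
    b[[l]] <- numeric(sizes[l + 1L])
  }
  list(W = W, b = b)
}

mlp_forward <- function(net, X) {
  L <- length(net$W)
  A <- vector("list", L + 1L)
  A[[1L]] <- X
  for (l in seq_len(L)) {
    Z <- sweep(A[[l]] %*% net$W[[l]], 2, net$b[[l]], "+")
    A[[l + 1L]] <- if (l < L) pmax(Z, 0) else 1 / (1 + exp(-Z))
  }
  A
}

# gradient of weighted binary cross-entropy wrt all parameters
mlp_grad <- function(net, A, y, w) {
  L <- length(net$W)
  n <- length(y)
  dW <- vector("list", L)
  db <- vector("list", L)
  # d(loss)/d(z_out) for sigmoid + BCE is (p - y), sample-weighted
  delta <- (A[[L + 1L]] - y) * w / sum(w)
  for (l in L:1) {
    dW[[l]] <- crossprod(A[[l]], delta)
    db[[l]] <- colSums(delta)
    if (l > 1L)
      delta <- (delta %*% t(net$W[[l]])) * (A[[l]] > 0)
  }
  list(W = dW, b = db)
}

mlp_loss <- function(p, y, w) {
  eps <- 1e-12
  -sum(w * (y * log(p + eps) + (1 - y) * log(1 - p + eps))) / sum(w)
}

#' Train the normal-shape filter network
#'
#' Fits the fixed 202-5-15-5-1 network that separates normal from anomalous
#' glow-curve shapes. The labeled curves are split 60/20/20 into
#' train/validation/test, stratified by class with train sizes rounded down;
#' inputs are standardized using training-split statistics (z-scores clipped
#' at +-8, since near-constant tail channels otherwise explode); the
#' anomalous class is up-weighted to balance the loss; training is full-batch
#' Adam with early stopping on validation loss. Everything is deterministic
#' given `seed`: two runs with the same seed persist byte-identical models.
#'
#' @param dataset A `gc_dataset` from [generate_labeled_dataset], or a list
#'   with `curves` and `labels` (`"NORMAL"` vs anything else).
#' @param seed Integer seed for the split and weight initialization.
#' @param config A [gc_config]; supplies the decision threshold and, unless
#'   `path` overrides it, the model file name.
#' @param epochs Maximum training epochs.
#' @param lr Adam learning rate.
#' @param patience Early-stopping patience (epochs without validation
#'   improvement).
#' @param path File to persist the trained model to; `NULL` skips
#'   persistence.
#' @return An object of class `gc_filter`: network weights, feature
#'   standardization, decision threshold, split indices and training
#'   metadata. Use [predict.gc_filter] or [classify_normal] on it.
#' @export
train_filter <- function(dataset, seed = 1, config = gc_config(),
                         epochs = 400L, lr = 0.01, patience = 60L,
                         path = NULL) {
  labels <- dataset$labels
  y <- as.numeric(labels == "NORMAL")
  if (length(unique(y)) < 2)
    stop("training needs both normal and anomalous curves")
  X <- feature_matrix(dataset$curves)

  set.seed(seed)
  split <- stratified_split(y)
  mu <- colMeans(X[split$train, , drop = FALSE])
  sd <- apply(X[split$train, , drop = FALSE], 2, stats::sd)
  sd[sd == 0 | !is.finite(sd)] <- 1
  Z <- pmin(pmax(sweep(sweep(X, 2, mu), 2, sd, "/"), -8), 8)

  ytr <- y[split$train]
  w_anom <- sum(ytr == 1) / max(sum(ytr == 0), 1)
  wtr <- ifelse(ytr == 1, 1, w_anom)
  Ztr <- Z[split$train, , drop = FALSE]
  Zval <- Z[split$val, , drop = FALSE]
  yval <- y[split$val]
  wval <- ifelse(yval == 1, 1, w_anom)

  sizes <- c(GC_CHANNELS + 2L, 5L, 15L, 5L, 1L)
  net <- mlp_init(sizes)
  m <- lapply(net, function(part) lapply(part, function(x) x * 0))
  v <- m
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  best <- list(loss = Inf, net = net, epoch = 0L)
  stall <- 0L
  for (epoch in seq_len(epochs)) {
    A <- mlp_forward(net, Ztr)
    g <- mlp_grad(net, A, ytr, wtr)
    for (part in c("W", "b")) for (l in seq_along(net[[part]])) {
      m[[part]][[l]] <- beta1 * m[[part]][[l]] + (1 - beta1) * g[[part]][[l]]
      v[[part]][[l]] <- beta2 * v[[part]][[l]] + (1 - beta2) * g[[part]][[l]]^2
      mhat <- m[[part]][[l]] / (1 - beta1^epoch)
      vhat <- v[[part]][[l]] / (1 - beta2^epoch)
      net[[part]][[l]] <- net[[part]][[l]] - lr * mhat / (sqrt(vhat) + eps)
    }
    pval <- mlp_forward(net, Zval)[[length(sizes)]]
    vloss <- mlp_loss(pval, yval, wval)
    if (vloss < best$loss - 1e-6) {
      best <- list(loss = vloss, net = net, epoch = epoch)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= patience) break
    }
  }

  model <- structure(list(
    sizes = sizes,
    W = best$net$W,
    b = best$net$b,
    feat_mu = mu,
    feat_sd = sd,
    threshold = config$ai_probability_threshold,
    split = split,
    meta = list(seed = seed, epochs_run = epoch, best_epoch = best$epoch,
                val_loss = best$loss,
                n_train = length(split$train), n_val = length(split$val),
                n_test = length(split$test))
  ), class = "gc_filter")
  if (!is.null(path)) write_filter_model(model, path)
  model
}

# Stratified 60/20/20 split; train sizes rounded down per class, the
# remainder halved between validation and test.
stratified_split <- function(y) {
  train <- integer(); val <- integer(); test <- integer()
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    n <- length(idx)
    n_tr <- floor(0.6 * n)
    n_val <- floor((n - n_tr) / 2)
    train <- c(train, idx[seq_len(n_tr)])
    val <- c(val, idx[n_tr + seq_len(n_val)])
    test <- c(test, idx[(n_tr + n_val + 1):n])
  }
  list(train = sort(train), val = sort(val), test = sort(test))
}

#' @export
print.gc_filter <- function(x, ...) {
  cat("<gc_filter> network", paste(x$sizes, collapse = "-"),
      "| threshold", x$threshold, "\n",
      "trained", x$meta$n_train, "/ validated", x$meta$n_val,
      "/ held out", x$meta$n_test,
      sprintf("| best epoch %d (val loss %.4f)\n",
              x$meta$best_epoch, x$meta$val_loss))
  invisible(x)
}

#' Predict normal-shape probability
#'
#' @param object A `gc_filter` model.
#' @param newdata A [glow_curve], a list of them, a `gc_dataset`, or a
#'   feature matrix with 202 columns.
#' @param ... Unused.
#' @return Numeric vector of probabilities in `[0, 1]` that each curve has a
#'   normal shape.
#' @export
predict.gc_filter <- function(object, newdata, ...) {
  X <- if (is.matrix(newdata)) newdata
       else if (inherits(newdata, "gc_dataset")) feature_matrix(newdata$curves)
       else if (is_glow_curve(newdata)) feature_matrix(list(newdata))
       else feature_matrix(newdata)
  Z <- pmin(pmax(sweep(sweep(X, 2, object$feat_mu), 2, object$feat_sd, "/"),
                 -8), 8)
  net <- list(W = object$W, b = object$b)
  as.numeric(mlp_forward(net, Z)[[length(object$sizes)]])
}

#' Normal/suspect decision for one glow curve
#'
#' A curve is accepted as normal only when the network's probability
#' strictly exceeds the decision threshold (0.91 by default). The threshold
#' is deliberately high: the filter prefers sending normal curves on to the
#' rule cascade (false negatives) over letting anomalous curves through as
#' normal (false positives). With `use_ai = FALSE` the filter is bypassed
#' and every curve is forwarded as suspect.
#'
#' @param gc A [glow_curve].
#' @param model A `gc_filter`.
#' @param threshold Decision threshold in (0, 1); defaults to the one stored
#'   in the model.
#' @param use_ai Bypass flag (`bUseAI`); when `FALSE` the decision is
#'   `"suspected_anomalous"` with probability `NA`.
#' @return A list with `decision` (`"normal"` or `"suspected_anomalous"`)
#'   and `probability`.
#' @export
classify_normal <- function(gc, model, threshold = model$threshold,
                            use_ai = TRUE) {
  if (!use_ai)
    return(list(decision = "suspected_anomalous", probability = NA_real_))
  p <- predict(model, gc)
  list(decision = if (p > threshold) "normal" else "suspected_anomalous",
       probability = p)
}

#' Persist or load a shape-filter model
#'
#' The model is stored as self-describing JSON: layer sizes, weight matrices,
#' biases, feature standardization, threshold and training metadata, written
#' at full double precision so a reloaded model predicts identically.
#'
#' @param model A `gc_filter`.
#' @param path File path.
#' @return `write_filter_model` returns `path` invisibly;
#'   `read_filter_model` returns the `gc_filter`.
#' @export
write_filter_model <- function(model, path) {
  payload <- list(
    format = "glowqc-filter",
    version = 1L,
    sizes = model$sizes,
    W = model$W,
    b = model$b,
    feat_mu = model$feat_mu,
    feat_sd = model$feat_sd,
    threshold = model$threshold,
    split = model$split,
    meta = model$meta
  )
  writeLines(jsonlite::toJSON(payload, digits = I(17), auto_unbox = TRUE,
                              pretty = FALSE), path)
  invisible(path)
}

#' @rdname write_filter_model
#' @export
read_filter_model <- function(path) {
  payload <- jsonlite::fromJSON(paste(readLines(path), collapse = "\n"),
                                simplifyVector = TRUE)
  if (!identical(payload$format, "glowqc-filter"))
    stop("not a glowqc filter model file: ", path)
  sizes <- as.integer(payload$sizes)
  W <- lapply(seq_along(payload$W), function(l) {
    w <- payload$W[[l]]
    matrix(as.numeric(w), sizes[l], sizes[l + 1L],
           byrow = !is.matrix(w) || nrow(w) != sizes[l])
  })
  structure(list(
    sizes = sizes,
    W = W,
    b = lapply(payload$b, as.numeric),
    feat_mu = as.numeric(payload$feat_mu),
    feat_sd = as.numeric(payload$feat_sd),
    threshold = payload$threshold,
    split = payload$split,
    meta = payload$meta
  ), class = "gc_filter")
}
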