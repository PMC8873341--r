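#' Instantiate a trainable network from a spec
#'
#' Validates the spec, then draws He-scaled Gaussian initial weights (zero
#' biases) under the given seed. The returned handle carries the parameters
#' in four named groups (`conv1`, `conv2`, `dense`, `output`) together with
#' their trainability flags, and is consumed by [train_network()] and
#' [predict_proba()]. Two builds with the same seed are identical.
#'
#' @param spec A [cnn_spec()].
#' @param rng_seed Integer seed for the initialization.
#' @return An `fnirs_cnn` model handle.
#' @export
build_network <- function(spec, rng_seed = 1L) {
  arch <- spec_to_arch(spec)
  h <- arch[1]; w <- arch[2]; d <- arch[3]
  k1h <- arch[4]; k1w <- arch[5]; K1 <- arch[7]
  k2h <- arch[8]; k2w <- arch[9]; K2 <- arch[11]
  rep_ <- validate_spec(spec)
  flat <- rep_$out_h[rep_$kind == "flatten"]
  units <- arch[14]; ncls <- arch[15]

  he <- function(nr, nc, fan_in) {
    matrix(rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)
  }
  params <- with_seed(rng_seed, list(
    conv1_W = he(k1h * k1w * d, K1, k1h * k1w * d),
    conv1_b = rep(0, K1),
    conv2_W = he(k2h * k2w * K1, K2, k2h * k2w * K1),
    conv2_b = rep(0, K2),
    dense_W = he(flat, units, flat),
    dense_b = rep(0, units),
    out_W = he(units, ncls, units),
    out_b = rep(0, ncls)
  ))
  structure(list(spec = spec, arch = arch, params = params,
                 trainable = c(conv1 = TRUE, conv2 = TRUE,
                               dense = TRUE, output = TRUE),
                 rng_seed = as.integer(rng_seed)),
            class = "fnirs_cnn")
}

#' @export
print.fnirs_cnn <- function(x, ...) {
  cat(sprintf("compact CNN: input %s, %d parameters; trainable: %s\n",
              paste(x$arch[1:3], collapse = "x"), n_params(x),
              paste(names(x$trainable)[x$trainable], collapse = ", ")))
  invisible(x)
}

#' Total number of parameters held by a model handle
#' @param model An `fnirs_cnn`.
#' @export
n_params <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

#' Extract one parameter group
#' @param model An `fnirs_cnn`.
#' @param group One of `"conv1"`, `"conv2"`, `"dense"`, `"output"`.
#' @export
group_params <- function(model, group) {
  key <- c(conv1 = "conv1", conv2 = "conv2", dense = "dense", output = "out")
  if (!group %in% names(key)) stop("unknown parameter group: ", group)
  model$params[paste0(key[[group]], c("_W", "_b"))]
}

#' Canonical parameter layout: weight matrices, plain bias vectors
#' @noRd
canonical_params <- function(params) {
  for (nm in names(params)) {
    if (grepl("_b$", nm)) params[[nm]] <- as.numeric(params[[nm]])
  }
  params
}

#' Convert an epoch set to the engine's input array
#' @noRd
epochs_to_input <- function(epochs, arch) {
  d <- dim(epochs$x)
  if (d[2] != arch[1] || d[4] != arch[2] || d[3] != arch[3]) {
    stop(sprintf(
      "epoch geometry (%d ch x %d chrom x %d samples) does not match network input %dx%dx%d",
      d[2], d[3], d[4], arch[1], arch[2], arch[3]))
  }
  aperm(epochs$x, c(2, 4, 3, 1))
}

#' @noRd
epochs_to_labels <- function(epochs, n_classes) {
  y <- as.integer(epochs$labels) - 1L
  if (any(is.na(y))) stop("epoch set contains unlabelled examples")
  if (nlevels(epochs$labels) != n_classes) {
    stop(sprintf("epoch set has %d classes but the network expects %d",
                 nlevels(epochs$labels), n_classes))
  }
  y
}

#' Class probabilities for an epoch set
#'
#' @param model An `fnirs_cnn`.
#' @param epochs An `epoch_set` matching the network's input geometry.
#' @return Matrix of softmax probabilities, one row per example, columns in
#'   class-level order.
#' @export
predict_proba <- function(model, epochs) {
  x <- epochs_to_input(epochs, model$arch)
  p <- cnn_forward_cpp(model$params, model$arch, as.numeric(x), dim(x)[4])
  colnames(p) <- levels(epochs$labels)[seq_len(model$arch[15])]
  p
}

#' Predicted class labels (ties break to the lowest class index)
#' @inheritParams predict_proba
#' @export
predict_classes <- function(model, epochs) {
  p <- predict_proba(model, epochs)
  factor(levels(epochs$labels)[max.col(p, ties.method = "first")],
         levels = levels(epochs$labels))
}

#' Train a network with minibatch Adam
#'
#' Softmax cross-entropy loss, minibatch Adam, deterministic under
#' `shuffle_seed` (which fixes the per-epoch batch permutations). Groups
#' whose trainability flag is off — see [apply_freeze()] — are provably left
#' untouched. When a test set and `record_at` checkpoints are supplied, test
#' accuracy and per-example predictions are recorded after each checkpoint
#' epoch, which yields a whole learning curve from a single run.
#'
#' @param model An `fnirs_cnn`.
#' @param train An `epoch_set` of training examples.
#' @param epochs Number of passes over the training data.
#' @param test Optional held-out `epoch_set` to evaluate at checkpoints.
#' @param record_at Integer epochs (0 allowed: before training) at which to
#'   evaluate on `test`; default: the final epoch.
#' @param lr,batch_size,beta1,beta2,epsilon Adam hyperparameters.
#' @param shuffle_seed Seed for the minibatch permutations.
#' @return List: `model` (trained handle), `loss` (per-epoch mean training
#'   loss), `test_acc` (percent at each checkpoint), `test_pred` (factor
#'   predictions per checkpoint column).
#' @export
train_network <- function(model, train, epochs,
                          test = NULL, record_at = NULL,
                          lr = 1e-3, batch_size = 32,
                          beta1 = 0.9, beta2 = 0.999, epsilon = 1e-8,
                          shuffle_seed = 1L) {
  stopifnot(inherits(model, "fnirs_cnn"), inherits(train, "epoch_set"))
  if (!any(model$trainable) && epochs > 0) {
    stop("no trainable parameters: every group is frozen")
  }
  epochs <- stop_if_not_count(epochs, "epochs", min = 0)
  xtr <- epochs_to_input(train, model$arch)
  ytr <- epochs_to_labels(train, model$arch[15])
  n <- length(ytr)
  if (is.null(record_at)) record_at <- if (!is.null(test)) epochs else integer(0)

  xte <- numeric(0); yte <- integer(0)
  if (!is.null(test)) {
    xte <- as.numeric(epochs_to_input(test, model$arch))
    yte <- epochs_to_labels(test, model$arch[15])
  }
  perms <- if (epochs > 0) {
    with_seed(shuffle_seed,
              vapply(seq_len(epochs), function(e) sample.int(n) - 1L,
                     integer(n)))
  } else {
    matrix(integer(0), nrow = n, ncol = 0)
  }
  if (epochs > 0 && !is.matrix(perms)) perms <- matrix(perms, nrow = n)

  fit <- cnn_fit_cpp(model$params, model$arch,
                     as.numeric(xtr), ytr, xte, yte,
                     as.integer(epochs), as.integer(record_at),
                     lr, as.integer(batch_size), perms,
                     unname(model$trainable),
                     beta1, beta2, epsilon)
  if (epochs > 0 && any(!is.finite(fit$loss))) {
    stop(sprintf(
      "training diverged (non-finite loss) [shuffle_seed=%d, lr=%g, batch=%d]",
      shuffle_seed, lr, batch_size))
  }
  model$params <- canonical_params(fit$params)
  preds <- NULL
  if (!is.null(test) && length(record_at) > 0) {
    preds <- apply(fit$test_pred, 2, function(col) {
      factor(levels(test$labels)[col + 1L], levels = levels(test$labels))
    }, simplify = FALSE)
    names(preds) <- as.character(record_at)
  }
  list(model = model, loss = fit$loss,
       test_acc = if (length(record_at)) {
         stats::setNames(fit$test_acc, record_at)
       } else NULL,
       test_pred = preds)
}
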