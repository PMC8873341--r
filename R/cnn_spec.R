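#' Convolution output size
#'
#' Size of the activation map produced by sliding a filter of size `f` with
#' the given stride over an input of size `n`: `(n - f)/stride + 1`.
#' Non-integer results are rejected rather than floored, so every layer of a
#' validated network tiles its input exactly.
#'
#' @param n Input map size (>= f).
#' @param f Filter size (>= 1).
#' @param stride Step size (>= 1).
#' @return Integer output size.
#' @examples
#' conv_output_size(5, 3, 1)  # 3
#' conv_output_size(7, 3, 2)  # 3
#' @export
conv_output_size <- function(n, f, stride = 1) {
  n <- stop_if_not_count(n, "n")
  f <- stop_if_not_count(f, "f")
  stride <- stop_if_not_count(stride, "stride")
  if (f > n) stop(sprintf("filter size %d exceeds input size %d", f, n))
  if ((n - f) %% stride != 0) {
    stop(sprintf("(%d - %d) is not divisible by stride %d", n, f, stride))
  }
  as.integer((n - f) / stride + 1L)
}

#' Convolution layer parameter count
#'
#' Two counting modes are provided. `"paper"` counts `W*H*K + K`, i.e. the
#' filter footprint times the number of filters plus biases, ignoring the
#' input depth; `"standard"` counts `W*H*depth*K + K`, which is what a
#' convolution with multi-channel input actually stores. `W` and `H` are the
#' filter dimensions.
#'
#' @param w,h Filter width and height.
#' @param k Number of filters.
#' @param input_depth Number of input channels (used by `"standard"`).
#' @param mode `"standard"` or `"paper"`.
#' @return Integer parameter count.
#' @export
layer_param_count <- function(w, h, k, input_depth = 1,
                              mode = c("standard", "paper")) {
  mode <- match.arg(mode)
  w <- stop_if_not_count(w, "w"); h <- stop_if_not_count(h, "h")
  k <- stop_if_not_count(k, "k")
  input_depth <- stop_if_not_count(input_depth, "input_depth")
  if (mode == "paper") w * h * k + k else w * h * input_depth * k + k
}

## ---- layer constructors ----------------------------------------------------

#' Layer constructors for a compact CNN description
#'
#' @param filters Number of convolution filters.
#' @param size `c(height, width)` of the filter or pooling window.
#' @param stride Sliding step (convolution only; pooling strides by its own
#'   window).
#' @param units Unit count of a dense layer.
#' @param activation Activation name.
#' @return A `layer_spec` list.
#' @name layer_spec
NULL

#' @rdname layer_spec
#' @export
layer_conv <- function(filters, size = c(3, 3), stride = 1,
                       activation = "relu") {
  structure(list(kind = "conv", filters = stop_if_not_count(filters, "filters"),
                 size = as.integer(size), stride = stop_if_not_count(stride, "stride"),
                 activation = activation),
            class = "layer_spec")
}

#' @rdname layer_spec
#' @export
layer_maxpool <- function(size = c(2, 2)) {
  structure(list(kind = "maxpool", size = as.integer(size)),
            class = "layer_spec")
}

#' @rdname layer_spec
#' @export
layer_flatten <- function() {
  structure(list(kind = "flatten"), class = "layer_spec")
}

#' @rdname layer_spec
#' @export
layer_dense <- function(units, activation = "relu") {
  structure(list(kind = "dense", units = stop_if_not_count(units, "units"),
                 activation = activation),
            class = "layer_spec")
}

#' @rdname layer_spec
#' @export
layer_output <- function(units, activation = "softmax") {
  structure(list(kind = "output", units = stop_if_not_count(units, "units"),
                 activation = activation),
            class = "layer_spec")
}

#' Describe a compact CNN
#'
#' The architecture is fixed to the topology conv, conv, maxpool, flatten,
#' dense, output; layer hyperparameters (filter counts and sizes, pool size,
#' dense width) are free. The input is treated as a 2-D map of channels x
#' window samples with the two chromophores as depth. Parameters fall into
#' four named groups used by the freezing plans: `conv1`, `conv2`, `dense`,
#' `output`.
#'
#' @param input_shape `c(height, width, depth)` of one example, i.e.
#'   channels, window samples, chromophores.
#' @param layers Ordered list of [layer_spec] objects.
#' @param n_classes Number of output classes.
#' @return A `cnn_spec` object.
#' @export
cnn_spec <- function(input_shape, layers, n_classes) {
  if (length(input_shape) != 3) {
    stop("`input_shape` must be c(height, width, depth)")
  }
  n_classes <- stop_if_not_count(n_classes, "n_classes", min = 2)
  kinds <- vapply(layers, function(l) l$kind, character(1))
  expected <- c("conv", "conv", "maxpool", "flatten", "dense", "output")
  if (!identical(kinds, expected)) {
    stop("layer topology must be: ", paste(expected, collapse = ", "))
  }
  if (layers[[6]]$units != n_classes) {
    stop("output layer units must equal `n_classes`")
  }
  structure(list(input_shape = as.integer(input_shape),
                 layers = layers,
                 n_classes = n_classes,
                 groups = c("conv1", "conv2", "dense", "output")),
            class = "cnn_spec")
}

#' Default full-resolution network
#'
#' Two convolution layers (16 and 32 filters of 3 x 5), 2 x 2 max-pooling,
#' a 64-unit dense layer and a softmax output, on 36-channel, 10 s windows
#' at 10 Hz (36 x 100 x 2 input).
#'
#' @param input_shape Input geometry `c(channels, samples, chromophores)`.
#' @param n_classes Number of workload classes.
#' @export
default_cnn_spec <- function(input_shape = c(36, 100, 2), n_classes = 3) {
  cnn_spec(input_shape,
           list(layer_conv(16, c(3, 5)),
                layer_conv(32, c(3, 5)),
                layer_maxpool(c(2, 2)),
                layer_flatten(),
                layer_dense(64),
                layer_output(n_classes)),
           n_classes)
}

#' Reduced network for decimated epochs
#'
#' A lighter variant used for the large seeded sweeps: 8 + 8 filters of
#' 3 x 3, 2 x 2 pooling and a 32-unit dense layer on 1 Hz-decimated 10 s
#' windows (36 x 10 x 2 input). The 0.2 Hz low-pass leaves no signal beyond
#' the decimated Nyquist, so the reduction discards no usable band.
#'
#' @inheritParams default_cnn_spec
#' @export
reduced_cnn_spec <- function(input_shape = c(36, 10, 2), n_classes = 3) {
  cnn_spec(input_shape,
           list(layer_conv(8, c(3, 3)),
                layer_conv(8, c(3, 3)),
                layer_maxpool(c(2, 2)),
                layer_flatten(),
                layer_dense(32),
                layer_output(n_classes)),
           n_classes)
}

#' Validate a CNN spec and report shapes and parameter counts
#'
#' Propagates the input shape layer by layer with [conv_output_size()],
#' failing fast (with the offending layer index) on any non-integer shape,
#' and tabulates per-layer output shapes with parameter counts in both
#' counting modes.
#'
#' @param spec A [cnn_spec()].
#' @param input_shape Optional override of the spec's input shape.
#' @return A `cnn_shape_report` data frame with one row per layer and a
#'   `total_params` attribute (standard mode).
#' @export
validate_spec <- function(spec, input_shape = spec$input_shape) {
  stopifnot(inherits(spec, "cnn_spec"))
  h <- input_shape[1]; w <- input_shape[2]; depth <- input_shape[3]
  rows <- list()
  for (i in seq_along(spec$layers)) {
    l <- spec$layers[[i]]
    res <- tryCatch({
      switch(l$kind,
        conv = {
          oh <- conv_output_size(h, l$size[1], l$stride)
          ow <- conv_output_size(w, l$size[2], l$stride)
          ps <- layer_param_count(l$size[1], l$size[2], l$filters, depth,
                                  "standard")
          pp <- layer_param_count(l$size[1], l$size[2], l$filters, depth,
                                  "paper")
          h <- oh; w <- ow; depth <- l$filters
          c(ps, pp)
        },
        maxpool = {
          oh <- conv_output_size(h, l$size[1], l$size[1])
          ow <- conv_output_size(w, l$size[2], l$size[2])
          h <- oh; w <- ow
          c(0L, 0L)
        },
        flatten = {
          h <- h * w * depth; w <- 1L; depth <- 1L
          c(0L, 0L)
        },
        dense = ,
        output = {
          p <- h * l$units + l$units
          h <- l$units
          c(p, p)
        },
        stop("unknown layer kind: ", l$kind))
    }, error = function(e) {
      stop(sprintf("layer %d (%s): %s", i, l$kind, conditionMessage(e)),
           call. = FALSE)
    })
    rows[[i]] <- data.frame(layer = i, kind = l$kind,
                            out_h = h, out_w = w, out_depth = depth,
                            params_standard = res[1], params_paper = res[2])
  }
  report <- do.call(rbind, rows)
  attr(report, "total_params") <- sum(report$params_standard)
  attr(report, "total_params_paper") <- sum(report$params_paper)
  class(report) <- c("cnn_shape_report", "data.frame")
  report
}

#' Engine layout vector for a validated spec
#' @noRd
spec_to_arch <- function(spec) {
  validate_spec(spec)  # fail fast on bad shapes
  l <- spec$layers
  as.integer(c(spec$input_shape,
               l[[1]]$size[1], l[[1]]$size[2], l[[1]]$stride, l[[1]]$filters,
               l[[2]]$size[1], l[[2]]$size[2], l[[2]]$stride, l[[2]]$filters,
               l[[3]]$size[1], l[[3]]$size[2],
               l[[5]]$units, spec$n_classes))
}

#' Serialize a CNN spec to / from JSON
#'
#' @param spec A [cnn_spec()].
#' @param path File path; when `NULL`, `spec_to_json` returns the JSON text.
#' @export
spec_to_json <- function(spec, path = NULL) {
  doc <- list(input_shape = spec$input_shape,
              n_classes = spec$n_classes,
              layers = lapply(spec$layers, function(l) unclass(l)))
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

#' @param json JSON text or file path produced by [spec_to_json()].
#' @rdname spec_to_json
#' @export
spec_from_json <- function(json) {
  doc <- jsonlite::fromJSON(json, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE)
  layers <- lapply(doc$layers, function(l) {
    switch(l$kind,
      conv = layer_conv(l$filters, unlist(l$size), l$stride, l$activation),
      maxpool = layer_maxpool(unlist(l$size)),
      flatten = layer_flatten(),
      dense = layer_dense(l$units, l$activation),
      output = layer_output(l$units, l$activation))
  })
  cnn_spec(unlist(doc$input_shape), layers, doc$n_classes)
}
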