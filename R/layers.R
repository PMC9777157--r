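# Declarative layer specifications, shape inference and closed-form parameter
# accounting. All convolutions are 3x3 with "same" padding and stride 1; all
# poolings are 2x2 with stride 2 — the printed output-size chain of the base
# network forces both choices.

#' Layer constructors for sequential architectures
#'
#' @param filters,units number of convolution filters / dense units.
#' @param activation activation name: "relu", "softmax", "sigmoid" or "none".
#' @param rate dropout fraction in \[0,1).
#' @return a `kneedhl_layer` list describing one layer.
#' @name layers
NULL

#' @rdname layers
#' @export
layer_conv2d <- function(filters, activation = "relu") {
  stopifnot(filters >= 1)
  structure(list(kind = "conv2d", filters = as.integer(filters),
                 kernel = c(3L, 3L), padding = "same", activation = activation),
            class = "kneedhl_layer")
}

#' @rdname layers
#' @export
layer_maxpool <- function() {
  structure(list(kind = "maxpool", pool = c(2L, 2L)), class = "kneedhl_layer")
}

#' @rdname layers
#' @export
layer_avgpool <- function() {
  structure(list(kind = "avgpool", pool = c(2L, 2L)), class = "kneedhl_layer")
}

#' @rdname layers
#' @export
layer_dropout <- function(rate) {
  stopifnot(rate >= 0, rate < 1)
  structure(list(kind = "dropout", rate = rate), class = "kneedhl_layer")
}

#' @rdname layers
#' @export
layer_flatten <- function() {
  structure(list(kind = "flatten"), class = "kneedhl_layer")
}

#' @rdname layers
#' @export
layer_dense <- function(units, activation = "none") {
  stopifnot(units >= 1)
  structure(list(kind = "dense", units = as.integer(units),
                 activation = activation), class = "kneedhl_layer")
}

#' The base CNN architecture for KL grading
#'
#' Input 112x112x1; three 3x3x32 convolutions, 2x2 max-pool (dropout 0.25);
#' one 3x3x64 convolution, 2x2 average-pool (dropout 0.5); one 3x3x128
#' convolution, 2x2 average-pool (dropout 0.75); flatten (25088); dense 200
#' with ReLU (dropout 0.5); dense `n_classes` with softmax. Total trainable
#' parameters for 5 classes: 5,129,973.
#'
#' @param n_classes number of output classes (>= 2).
#' @return an `architecture_spec`: list of layers with an `input_shape`
#'   attribute (C, H, W).
#' @export
architecture_base_cnn <- function(n_classes = 5L) {
  if (!is.numeric(n_classes) || n_classes < 2) {
    stop_kneedhl("n_classes must be >= 2", "kneedhl_config_error")
  }
  arch <- list(
    layer_conv2d(32), layer_conv2d(32), layer_conv2d(32),
    layer_maxpool(), layer_dropout(0.25),
    layer_conv2d(64), layer_avgpool(), layer_dropout(0.50),
    layer_conv2d(128), layer_avgpool(), layer_dropout(0.75),
    layer_flatten(),
    layer_dense(200, "relu"), layer_dropout(0.50),
    layer_dense(as.integer(n_classes), "softmax")
  )
  architecture_spec(arch, input_shape = c(1L, 112L, 112L))
}

#' Wrap a layer list into an architecture specification
#'
#' @param layers list of [layers] objects.
#' @param input_shape integer (channels, height, width); use
#'   `c(n_features, 1, 1)` for flat inputs.
#' @return an `architecture_spec`.
#' @export
architecture_spec <- function(layers, input_shape) {
  stopifnot(length(input_shape) == 3)
  structure(layers, input_shape = as.integer(input_shape),
            class = "architecture_spec")
}

#' Infer the output shape of every layer
#'
#' @param arch an `architecture_spec`.
#' @return list of integer shapes (C, H, W per layer; flat layers as
#'   (features, 1, 1)).
#' @export
infer_shapes <- function(arch) {
  s <- attr(arch, "input_shape")
  shapes <- vector("list", length(arch))
  for (i in seq_along(arch)) {
    l <- arch[[i]]
    s <- switch(l$kind,
      conv2d = c(l$filters, s[2], s[3]),
      maxpool = ,
      avgpool = {
        if (s[2] %% 2 || s[3] %% 2) {
          stop_kneedhl(sprintf("layer %d: 2x2 pooling needs even dims, got %dx%d",
                               i, s[2], s[3]), "kneedhl_invalid_geometry")
        }
        c(s[1], s[2] %/% 2, s[3] %/% 2)
      },
      dropout = s,
      flatten = c(prod(s), 1L, 1L),
      dense = c(l$units, 1L, 1L),
      stop_kneedhl(sprintf("unknown layer kind '%s'", l$kind), "kneedhl_config_error")
    )
    shapes[[i]] <- as.integer(s)
  }
  shapes
}

#' Count trainable parameters
#'
#' Closed form per layer: a 3x3 convolution from `c_in` to `c_out` channels
#' has `(9*c_in + 1) * c_out` parameters; a dense layer from `f` inputs to
#' `u` units has `(f + 1) * u`. Pooling, dropout and flatten carry none.
#'
#' @param x an `architecture_spec` or a built `kneedhl_model`.
#' @return integer: total weight + bias count over all layers.
#' @examples
#' count_parameters(architecture_base_cnn(5)) # 5129973
#' @export
count_parameters <- function(x) {
  arch <- if (inherits(x, "kneedhl_model")) {
    if (is.null(x$weights)) stop_kneedhl("model has no weights", "kneedhl_state_error")
    x$arch
  } else if (inherits(x, "architecture_spec")) {
    x
  } else {
    stop_kneedhl("need an architecture_spec or kneedhl_model", "kneedhl_invalid_input")
  }
  total <- 0
  s <- attr(arch, "input_shape")
  for (l in arch) {
    if (l$kind == "conv2d") {
      total <- total + (9 * s[1] + 1) * l$filters
      s <- c(l$filters, s[2], s[3])
    } else if (l$kind == "dense") {
      f <- prod(s)
      total <- total + (f + 1) * l$units
      s <- c(l$units, 1L, 1L)
    } else if (l$kind %in% c("maxpool", "avgpool")) {
      s <- c(s[1], s[2] %/% 2, s[3] %/% 2)
    } else if (l$kind == "flatten") {
      s <- c(prod(s), 1L, 1L)
    }
  }
  as.integer(total)
}

#' @export
print.architecture_spec <- function(x, ...) {
  s <- attr(x, "input_shape")
  cat(sprintf("architecture_spec: input %dx%dx%d\n", s[2], s[3], s[1]))
  shapes <- infer_shapes(x)
  for (i in seq_along(x)) {
    l <- x[[i]]
    o <- shapes[[i]]
    desc <- switch(l$kind,
      conv2d = sprintf("conv2d 3x3x%d same %s", l$filters, l$activation),
      maxpool = "maxpool 2x2",
      avgpool = "avgpool 2x2",
      dropout = sprintf("dropout %.2f", l$rate),
      flatten = "flatten",
      dense = sprintf("dense %d %s", l$units, l$activation)
    )
    cat(sprintf("  %2d. %-26s -> %s\n", i, desc,
                if (o[2] == 1 && o[3] == 1) o[1] else sprintf("%dx%dx%d", o[2], o[3], o[1])))
  }
  cat("  total parameters:", format(count_parameters(x), big.mark = ","), "\n")
  invisible(x)
}
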