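# Model construction, forward passes and Adam training on top of the C++
# engine. Weights are plain R matrices (conv: filters x 9*C_in; dense:
# features x units) so layer surgery for transfer learning is list surgery.

#' Build a trainable model from an architecture
#'
#' Weights are initialized Glorot-uniform (fan averages include the 3x3
#' kernel area for convolutions) under the given seed; biases start at zero.
#'
#' @param arch an [architecture_spec()].
#' @param seed integer seed for weight initialization.
#' @return a `kneedhl_model`: list with `arch`, `weights` (one `W`/`b` pair
#'   per parameterized layer), `frozen` flags and bookkeeping.
#' @export
build_model <- function(arch, seed = 1L) {
  stopifnot(inherits(arch, "architecture_spec"))
  s <- attr(arch, "input_shape")
  weights <- list()
  with_seed(seed, {
    for (l in arch) {
      if (l$kind == "conv2d") {
        fan_in <- 9 * s[1]; fan_out <- 9 * l$filters
        lim <- sqrt(6 / (fan_in + fan_out))
        weights[[length(weights) + 1L]] <- list(
          W = matrix(runif(l$filters * 9 * s[1], -lim, lim), l$filters, 9 * s[1]),
          b = numeric(l$filters))
        s <- c(l$filters, s[2], s[3])
      } else if (l$kind == "dense") {
        f <- prod(s)
        lim <- sqrt(6 / (f + l$units))
        weights[[length(weights) + 1L]] <- list(
          W = matrix(runif(f * l$units, -lim, lim), f, l$units),
          b = numeric(l$units))
        s <- c(l$units, 1L, 1L)
      } else if (l$kind %in% c("maxpool", "avgpool")) {
        s <- c(s[1], s[2] %/% 2, s[3] %/% 2)
      } else if (l$kind == "flatten") {
        s <- c(prod(s), 1L, 1L)
      }
    }
  })
  structure(list(arch = arch, weights = weights,
                 frozen = rep(FALSE, length(weights)),
                 n_classes = arch[[length(arch)]]$units,
                 init_seed = as.integer(seed), history = NULL),
            class = "kneedhl_model")
}

#' Build the base five-convolution CNN
#'
#' @param n_classes output classes (>= 2), default 5 (KL grades).
#' @param seed weight-initialization seed.
#' @return a `kneedhl_model` realizing [architecture_base_cnn()].
#' @examples
#' m <- build_base_cnn(5)
#' count_parameters(m)  # 5129973
#' @export
build_base_cnn <- function(n_classes = 5L, seed = 1L) {
  build_model(architecture_base_cnn(n_classes), seed = seed)
}

#' @export
print.kneedhl_model <- function(x, ...) {
  cat("kneedhl_model (", format(count_parameters(x), big.mark = ","),
      " parameters, ", sum(x$frozen), " frozen weight sets)\n", sep = "")
  print(x$arch)
  invisible(x)
}

# Pack a list of HxW matrices (or an N x F matrix of flat features) into the
# engine's sample-major tensor: list(x = numeric, dim = c(N, C, H, W)).
pack_tensor <- function(images) {
  if (is.matrix(images)) {  # flat features, one row per sample
    return(list(x = t(images), dim = c(nrow(images), ncol(images), 1L, 1L)))
  }
  stopifnot(is.list(images), length(images) > 0)
  H <- nrow(images[[1]]); W <- ncol(images[[1]])
  x <- vapply(images, function(m) {
    if (nrow(m) != H || ncol(m) != W) {
      stop_kneedhl("all images must share the same dimensions", "kneedhl_invalid_input")
    }
    as.numeric(t(m))  # row-major layout i*W + j, as the engine expects
  }, numeric(H * W))
  # kept as a (features x N) matrix so index subsets slice columns cheaply
  list(x = x, dim = c(length(images), 1L, H, W))
}

# Chunked inference: forward activations for a whole set would not fit in
# memory (each conv layer stores features x N floats), so evaluation and
# feature extraction stream the tensor through the engine in column chunks.
engine_forward_chunked <- function(model, tensor, upto = -1L, y = NULL,
                                   loss = 0L, chunk = 64L) {
  n <- tensor$dim[1]
  outs <- vector("list", ceiling(n / chunk))
  total_loss <- 0
  for (ci in seq_along(outs)) {
    idx <- ((ci - 1) * chunk + 1):min(ci * chunk, n)
    res <- engine_run(model, tensor, idx = idx, upto = upto,
                      y = if (!is.null(y)) y[idx, , drop = FALSE], loss = loss)
    outs[[ci]] <- res$output
    if (!is.null(y)) total_loss <- total_loss + res$loss * length(idx)
  }
  list(output = do.call(rbind, outs),
       loss = if (!is.null(y)) total_loss / n else NULL)
}

# Low-level engine call on a packed tensor (or sample index subset thereof)
engine_run <- function(model, tensor, idx = NULL, training = FALSE, seed = 0L,
                       upto = -1L, y = NULL, loss = 0L) {
  d <- tensor$dim
  if (!is.null(idx)) {
    x <- tensor$x[, idx, drop = FALSE]
    d[1] <- length(idx)
  } else {
    x <- tensor$x
  }
  res <- nn_run_cpp(x, as.integer(d), unclass(model$arch), model$weights,
                    training, as.integer(seed), as.integer(upto), y,
                    as.integer(loss))
  if (!is.null(res$grads)) {
    res$grads <- lapply(res$grads, function(g) { g$b <- as.numeric(g$b); g })
  }
  res
}

#' Forward pass: class probabilities
#'
#' Dropout is inactive, so repeated calls on identical input are
#' bit-identical.
#'
#' @param model a trained (or freshly built) `kneedhl_model`.
#' @param images list of preprocessed HxW matrices (values in \[0,1\]), or an
#'   N x F feature matrix for dense-only models.
#' @return N x k matrix of class probabilities (single column for a sigmoid
#'   output).
#' @export
predict_proba <- function(model, images) {
  engine_forward_chunked(model, pack_tensor(images))$output
}

#' Predict class labels
#'
#' @inheritParams predict_proba
#' @return integer labels in `0..k-1` (sigmoid output thresholded at 0.5).
#' @export
predict_classes <- function(model, images) {
  p <- predict_proba(model, images)
  if (ncol(p) == 1) as.integer(p[, 1] >= 0.5) else max.col(p) - 1L
}

# index (1-based) of the penultimate dense layer = deep-feature source
feature_layer_index <- function(arch) {
  dense_idx <- which(vapply(arch, function(l) l$kind == "dense", logical(1)))
  if (length(dense_idx) < 2) {
    stop_kneedhl("architecture has no penultimate dense layer to extract from",
                 "kneedhl_architecture_error")
  }
  dense_idx[length(dense_idx) - 1L]
}

#' Extract deep features from the penultimate dense layer
#'
#' Returns the post-ReLU activation of the dense layer feeding the output
#' layer (200-dim for the base CNN, 256-dim for fine-tuned models), with
#' dropout inactive — deterministic for fixed weights.
#'
#' @inheritParams predict_proba
#' @return a `feature_matrix`: numeric matrix (n images x n features) with
#'   attribute `source_layer`.
#' @export
extract_features <- function(model, images) {
  li <- feature_layer_index(model$arch)
  out <- engine_forward_chunked(model, pack_tensor(images), upto = li)$output
  structure(out, source_layer = li)
}

#' Training configuration
#'
#' Defaults are the published training recipe: Adam with learning rate 0.001,
#' beta1 0.9, beta2 0.999, batch size 256, categorical cross-entropy; 50
#' epochs for the base network (20 for fine-tuning).
#'
#' @param epochs number of epochs (>= 1).
#' @param batch_size mini-batch size (>= 1).
#' @param learning_rate,beta1,beta2,epsilon Adam hyperparameters.
#' @param loss "categorical" (softmax output) or "binary" (sigmoid output).
#' @param seed integer seed controlling shuffling, dropout and weight
#'   initialization downstream.
#' @param microbatch internal compute-batch size (memory knob; does not
#'   change the optimization, gradients are accumulated to `batch_size`).
#' @param verbose print one line per epoch.
#' @return a `train_config` list.
#' @export
train_config <- function(epochs = 50L, batch_size = 256L, learning_rate = 0.001,
                         beta1 = 0.9, beta2 = 0.999, epsilon = 1e-7,
                         loss = c("categorical", "binary"), seed = 1L,
                         microbatch = 64L, verbose = FALSE) {
  loss <- match.arg(loss)
  if (epochs < 1 || batch_size < 1) {
    stop_kneedhl("epochs and batch_size must be >= 1", "kneedhl_config_error")
  }
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 epsilon = epsilon, loss = loss, seed = as.integer(seed),
                 microbatch = as.integer(microbatch), verbose = isTRUE(verbose)),
            class = "train_config")
}

# one-hot (or single-column binary) target matrix
encode_labels <- function(y, n_classes, loss) {
  y <- as.integer(y)
  if (any(y < 0 | y >= max(n_classes, 2))) {
    stop_kneedhl("labels out of range for the model's output layer",
                 "kneedhl_invalid_input")
  }
  if (loss == "binary") {
    matrix(as.numeric(y), ncol = 1)
  } else {
    Y <- matrix(0, length(y), n_classes)
    Y[cbind(seq_along(y), y + 1L)] <- 1
    Y
  }
}

#' Train a model with Adam
#'
#' @param model a `kneedhl_model`.
#' @param images training images (list of matrices) or flat feature matrix.
#' @param labels integer class labels in `0..k-1`.
#' @param validation optional `list(images=, labels=)` monitored per epoch
#'   (never trained on).
#' @param config a [train_config()].
#' @return the model with updated weights and a `history` data.frame
#'   (epoch, loss, acc, val_loss, val_acc).
#' @export
train_model <- function(model, images, labels, validation = NULL,
                        config = train_config()) {
  tensor <- pack_tensor(images)
  n <- tensor$dim[1]
  if (n != length(labels)) {
    stop_kneedhl("number of images and labels differ", "kneedhl_invalid_input")
  }
  out_units <- model$arch[[length(model$arch)]]$units
  loss_code <- if (config$loss == "binary") 2L else 1L
  if (config$loss == "binary" && out_units != 1) {
    stop_kneedhl("binary loss requires a single sigmoid output unit",
                 "kneedhl_config_error")
  }
  Y <- encode_labels(labels, out_units, config$loss)
  if (!is.null(validation) && length(validation$labels) == 0) validation <- NULL
  vtensor <- NULL
  if (!is.null(validation)) {
    vtensor <- pack_tensor(validation$images)
    vY <- encode_labels(validation$labels, out_units, config$loss)
  }

  # Adam state
  mstate <- lapply(model$weights, function(w) list(W = w$W * 0, b = w$b * 0))
  vstate <- mstate
  tstep <- 0
  trainable <- which(!model$frozen)

  history <- data.frame(epoch = integer(0), loss = numeric(0), acc = numeric(0),
                        val_loss = numeric(0), val_acc = numeric(0))
  step_seed <- 0L
  with_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; ep_correct <- 0
      for (b0 in seq(1, n, by = config$batch_size)) {
        bidx <- ord[b0:min(b0 + config$batch_size - 1, n)]
        acc_grads <- NULL
        b_loss <- 0
        for (m0 in seq(1, length(bidx), by = config$microbatch)) {
          midx <- bidx[m0:min(m0 + config$microbatch - 1, length(bidx))]
          step_seed <- step_seed + 1L
          res <- engine_run(model, tensor, idx = midx, training = TRUE,
                            seed = derive_seed(config$seed, step_seed),
                            y = Y[midx, , drop = FALSE], loss = loss_code)
          if (!is.finite(res$loss)) {
            stop_kneedhl(sprintf(
              "training diverged: loss is %s at epoch %d (try a lower learning rate)",
              res$loss, epoch), "kneedhl_divergence_error")
          }
          wt <- length(midx)
          b_loss <- b_loss + res$loss * wt
          pred <- if (ncol(res$output) == 1) as.integer(res$output[, 1] >= 0.5)
                  else max.col(res$output) - 1L
          ep_correct <- ep_correct + sum(pred == labels[midx])
          g <- res$grads
          if (is.null(acc_grads)) {
            acc_grads <- lapply(seq_along(g), function(i)
              list(W = g[[i]]$W * wt, b = g[[i]]$b * wt))
          } else {
            for (i in seq_along(g)) {
              acc_grads[[i]]$W <- acc_grads[[i]]$W + g[[i]]$W * wt
              acc_grads[[i]]$b <- acc_grads[[i]]$b + g[[i]]$b * wt
            }
          }
        }
        nb <- length(bidx)
        ep_loss <- ep_loss + b_loss
        # Adam step on the batch-averaged gradient
        tstep <- tstep + 1
        lr_t <- config$learning_rate *
          sqrt(1 - config$beta2^tstep) / (1 - config$beta1^tstep)
        for (i in trainable) {
          gW <- acc_grads[[i]]$W / nb
          gb <- acc_grads[[i]]$b / nb
          mstate[[i]]$W <- config$beta1 * mstate[[i]]$W + (1 - config$beta1) * gW
          mstate[[i]]$b <- config$beta1 * mstate[[i]]$b + (1 - config$beta1) * gb
          vstate[[i]]$W <- config$beta2 * vstate[[i]]$W + (1 - config$beta2) * gW^2
          vstate[[i]]$b <- config$beta2 * vstate[[i]]$b + (1 - config$beta2) * gb^2
          model$weights[[i]]$W <- model$weights[[i]]$W -
            lr_t * mstate[[i]]$W / (sqrt(vstate[[i]]$W) + config$epsilon)
          model$weights[[i]]$b <- model$weights[[i]]$b -
            lr_t * mstate[[i]]$b / (sqrt(vstate[[i]]$b) + config$epsilon)
        }
      }
      row <- data.frame(epoch = epoch, loss = ep_loss / n, acc = ep_correct / n,
                        val_loss = NA_real_, val_acc = NA_real_)
      if (!is.null(vtensor)) {
        vres <- engine_forward_chunked(model, vtensor, y = vY, loss = loss_code)
        vpred <- if (ncol(vres$output) == 1) as.integer(vres$output[, 1] >= 0.5)
                 else max.col(vres$output) - 1L
        row$val_loss <- vres$loss
        row$val_acc <- mean(vpred == validation$labels)
      }
      history <- rbind(history, row)
      if (config$verbose) {
        cat(sprintf("epoch %3d/%d  loss %.4f  acc %.3f  val_loss %s  val_acc %s\n",
                    epoch, config$epochs, row$loss, row$acc,
                    ifelse(is.na(row$val_loss), "-", sprintf("%.4f", row$val_loss)),
                    ifelse(is.na(row$val_acc), "-", sprintf("%.3f", row$val_acc))))
      }
    }
  })
  model$history <- history
  model$train_config <- config
  model
}
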