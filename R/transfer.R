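# DHL-II: freeze the trained convolutional blocks, graft a new 512/256/k
# fully connected head, fine-tune on a coarser KL grouping, then reuse the
# dense-256 activation as the feature source for the same DHL head.

#' Fine-tuning specification
#'
#' The new head is dense-512 (ReLU) + dropout 0.5, dense-256 (ReLU), and a
#' k-way softmax output — or a single sigmoid unit with binary cross-entropy
#' when the grouping has two classes. Defaults mirror the published recipe:
#' Adam(0.001, 0.9, 0.999), batch 256, 20 epochs.
#'
#' @param scheme a [grouping_scheme()] or name in FOUR/THREE/TWO.
#' @param epochs fine-tuning epochs.
#' @param batch_size mini-batch size.
#' @param seed seed for head initialization and training.
#' @return a `fine_tune_spec`.
#' @export
fine_tune_spec <- function(scheme, epochs = 20L, batch_size = 256L, seed = 1L) {
  if (is.character(scheme)) scheme <- grouping_scheme(scheme)
  stopifnot(inherits(scheme, "grouping_scheme"))
  structure(list(scheme = scheme, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 head_units = c(512L, 256L)),
            class = "fine_tune_spec")
}

# index of the flatten layer (end of the frozen convolutional prefix)
flatten_index <- function(arch) {
  idx <- which(vapply(arch, function(l) l$kind == "flatten", logical(1)))
  if (length(idx) != 1) {
    stop_kneedhl("architecture must contain exactly one flatten layer",
                 "kneedhl_architecture_error")
  }
  idx
}

#' Fine-tune the base CNN for a coarser class grouping
#'
#' All convolutional/pooling layers (up to and including flatten) are frozen
#' — their weights are bit-identical before and after — and only the new
#' 512/256/k head is trained. Because the prefix is frozen its output is
#' deterministic, so the prefix activations are computed once and the head is
#' trained on them directly (dropout layers inside the frozen prefix are
#' inactive).
#'
#' @param model a trained 5-class `kneedhl_model`.
#' @param images training images (preprocessed matrices).
#' @param labels labels **already grouped** via the spec's scheme
#'   (`0..k-1`).
#' @param spec a [fine_tune_spec()].
#' @param validation optional `list(images=, labels=)` with grouped labels.
#' @param verbose print per-epoch training lines.
#' @return a fine-tuned `kneedhl_model` whose first weight sets are the
#'   frozen conv weights; `$history` holds the head-training history.
#' @export
fine_tune <- function(model, images, labels, spec, validation = NULL,
                      verbose = FALSE) {
  stopifnot(inherits(model, "kneedhl_model"), inherits(spec, "fine_tune_spec"))
  k <- spec$scheme$n_classes
  if (length(labels) && max(labels) >= k) {
    stop_kneedhl(sprintf(
      "labels exceed the scheme's %d classes; group them with map_grades() first", k),
      "kneedhl_config_error")
  }
  binary <- k == 2
  fi <- flatten_index(model$arch)
  prefix_arch <- model$arch[seq_len(fi)]
  n_prefix_w <- sum(vapply(prefix_arch, function(l) l$kind %in% c("conv2d", "dense"),
                           logical(1)))
  flat_dim <- prod(infer_shapes(model$arch)[[fi]])

  # frozen prefix -> deterministic features, computed once
  feats <- engine_forward_chunked(model, pack_tensor(images), upto = fi)$output
  if (!is.null(validation) && length(validation$labels) == 0) validation <- NULL
  vfeats <- NULL
  if (!is.null(validation)) {
    vfeats <- list(images = engine_forward_chunked(
                     model, pack_tensor(validation$images), upto = fi)$output,
                   labels = validation$labels)
  }

  head_arch <- architecture_spec(list(
    layer_dense(spec$head_units[1], "relu"), layer_dropout(0.5),
    layer_dense(spec$head_units[2], "relu"),
    if (binary) layer_dense(1L, "sigmoid") else layer_dense(k, "softmax")
  ), input_shape = c(flat_dim, 1L, 1L))
  head <- build_model(head_arch, seed = spec$seed)
  cfg <- train_config(epochs = spec$epochs, batch_size = spec$batch_size,
                      loss = if (binary) "binary" else "categorical",
                      seed = spec$seed, verbose = verbose)
  head <- train_model(head, feats, labels, validation = vfeats, config = cfg)

  tuned_arch <- architecture_spec(c(prefix_arch, unclass(head$arch)),
                                  input_shape = attr(model$arch, "input_shape"))
  tuned <- structure(list(
    arch = tuned_arch,
    weights = c(model$weights[seq_len(n_prefix_w)], head$weights),
    frozen = c(rep(TRUE, n_prefix_w), rep(FALSE, length(head$weights))),
    n_classes = k, init_seed = spec$seed, history = head$history,
    scheme = spec$scheme
  ), class = "kneedhl_model")
  tuned
}

#' Extract 256-dim deep features from a fine-tuned model
#'
#' Activations of the penultimate dense-256 layer, dropout inactive.
#'
#' @param model a fine-tuned `kneedhl_model` from [fine_tune()].
#' @param images preprocessed images.
#' @return n x 256 feature matrix.
#' @export
extract_tl_features <- function(model, images) {
  extract_features(model, images)
}

#' Run the DHL-II pipeline for a coarser grouping
#'
#' Groups the KL grades, fine-tunes the frozen-prefix model, extracts 256-dim
#' features and runs the MinMax -> PCA -> RBF-SVM head, evaluating on the
#' test partition.
#'
#' @param model a trained 5-class `kneedhl_model`.
#' @param train,test,validation lists with `images` and `labels` holding raw
#'   KL grades 0-4 (grouping is applied internally).
#' @param scheme grouping name or [grouping_scheme()] in FOUR/THREE/TWO.
#' @param epochs fine-tuning epochs (default 20).
#' @param seed fine-tuning seed.
#' @param variance_target,C,gamma DHL head hyperparameters.
#' @param verbose log stage dimensions.
#' @return a `dhl_result` with the fine-tuned model attached as `$model`.
#' @export
run_dhl2 <- function(model, train, test, scheme, validation = NULL,
                     epochs = 20L, seed = 1L, variance_target = 0.99,
                     C = 1000, gamma = 0.001, verbose = FALSE) {
  if (is.character(scheme)) scheme <- grouping_scheme(scheme)
  if (!scheme$name %in% c("FOUR", "THREE", "TWO")) {
    stop_kneedhl("transfer learning supports the FOUR, THREE and TWO groupings",
                 "kneedhl_config_error")
  }
  spec <- fine_tune_spec(scheme, epochs = epochs, seed = seed)
  gtrain <- list(images = train$images, labels = map_grades(train$labels, scheme))
  gval <- if (!is.null(validation)) {
    list(images = validation$images, labels = map_grades(validation$labels, scheme))
  }
  tuned <- fine_tune(model, gtrain$images, gtrain$labels, spec,
                     validation = gval, verbose = verbose)
  res <- run_dhl(tuned, gtrain,
                 list(images = test$images, labels = map_grades(test$labels, scheme)),
                 variance_target = variance_target, C = C, gamma = gamma,
                 verbose = verbose)
  res$model <- tuned
  res$scheme <- scheme$name
  res
}
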