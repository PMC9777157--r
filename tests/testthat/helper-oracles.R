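# Independent oracles and fixture builders used across the test files.
# Oracles are deliberately written against the definitions (profile scans,
# direct convolution arithmetic, pairwise Mann-Whitney counts) rather than
# against the package's own code paths.

# Joint-space gap width measured from the vertical mean-intensity profile:
# the longest contiguous run of rows whose mean lies below the midpoint of
# the profile's range.
measure_gap_width <- function(img) {
  prof <- rowMeans(img)
  thr <- (max(prof) + min(prof)) / 2
  r <- rle(prof < thr)
  if (!any(r$values)) return(0L)
  max(r$lengths[r$values])
}

# Osteophyte count proxy: saturated (255) pixel area divided by the disc area
# of the default blob radius. Exact at noise_sd = 0 because only blobs reach
# the 255 ceiling under the default schedules.
count_blobs <- function(img, radius = 3) {
  round(sum(img == 255) / sum(outer((-radius):radius, (-radius):radius,
                                    function(a, b) a^2 + b^2) <= radius^2))
}

rms_contrast <- function(img) stats::sd(as.numeric(img))

# Brute-force pairwise Mann-Whitney AUC: fraction of positive/negative pairs
# ranked correctly, ties counted 1/2.
mw_auc <- function(truth, scores) {
  pos <- scores[truth == 1]
  neg <- scores[truth == 0]
  if (!length(pos) || !length(neg)) return(NA_real_)
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# Direct double-precision forward pass for tiny test networks built from
# conv2d(3x3 same, ReLU) / maxpool / avgpool / flatten / dense layers.
# Activations are lists of per-channel matrices; flat stages are vectors.
oracle_forward <- function(model, img, upto = length(model$arch)) {
  pad <- function(m) rbind(0, cbind(0, m, 0), 0)
  act <- list(img)
  wi <- 0
  for (li in seq_len(upto)) {
    l <- model$arch[[li]]
    if (l$kind == "conv2d") {
      wi <- wi + 1
      W <- model$weights[[wi]]$W
      b <- model$weights[[wi]]$b
      H <- nrow(act[[1]]); Wd <- ncol(act[[1]])
      xp <- lapply(act, pad)
      act <- lapply(seq_len(l$filters), function(co) {
        acc <- matrix(b[co], H, Wd)
        for (ci in seq_along(xp)) {
          for (di in -1:1) for (dj in -1:1) {
            w <- W[co, (ci - 1) * 9 + (di + 1) * 3 + (dj + 1) + 1]
            acc <- acc + w * xp[[ci]][(2:(H + 1)) + di, (2:(Wd + 1)) + dj, drop = FALSE]
          }
        }
        if (identical(l$activation, "relu")) pmax(acc, 0) else acc
      })
    } else if (l$kind %in% c("maxpool", "avgpool")) {
      f <- if (l$kind == "maxpool") max else mean
      act <- lapply(act, function(a) {
        Ho <- nrow(a) / 2; Wo <- ncol(a) / 2
        out <- matrix(0, Ho, Wo)
        for (i in seq_len(Ho)) for (j in seq_len(Wo)) {
          out[i, j] <- f(a[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j)])
        }
        out
      })
    } else if (l$kind == "flatten") {
      act <- unlist(lapply(act, function(m) as.numeric(t(m))))
    } else if (l$kind == "dropout") {
      # inference mode: identity
    } else if (l$kind == "dense") {
      wi <- wi + 1
      v <- if (is.list(act)) unlist(lapply(act, function(m) as.numeric(t(m)))) else act
      z <- as.numeric(t(model$weights[[wi]]$W) %*% v + model$weights[[wi]]$b)
      act <- switch(l$activation,
        relu = pmax(z, 0),
        softmax = { e <- exp(z - max(z)); e / sum(e) },
        sigmoid = 1 / (1 + exp(-z)),
        z)
    }
  }
  act
}

# Small phantom set, preprocessed to network input. Grades may repeat.
make_phantom_inputs <- function(grades, seed = 1, noise_sd = 15,
                                image_size = c(224, 224),
                                config = preproc_config()) {
  imgs <- lapply(seq_along(grades), function(i) {
    preprocess_image(generate_phantom(
      phantom_params(grades[i], image_size = image_size, noise_sd = noise_sd,
                     seed = derive_test_seed(seed, i))), config)
  })
  list(images = imgs, labels = as.integer(grades))
}

derive_test_seed <- function(master, index) {
  as.integer(((master %% 100000) * 7919 + index * 104729) %% 2147483647)
}

# tiny architecture used for engine-vs-oracle and cheap training tests
tiny_arch <- function(n_classes = 3, input = c(1L, 8L, 8L)) {
  architecture_spec(list(
    layer_conv2d(2), layer_maxpool(), layer_conv2d(3), layer_avgpool(),
    layer_flatten(), layer_dense(4, "relu"),
    layer_dense(n_classes, "softmax")), input_shape = input)
}
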