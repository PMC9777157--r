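# Preprocessing: area resize, CLAHE contrast enhancement, stratified hold-out
# split and KL-grade grouping. The fixed chain is resize -> CLAHE -> rescale
# to [0,1]; the chain is not idempotent (CLAHE of a CLAHE'd image differs),
# which is documented rather than hidden.

#' Resize a grayscale image by area (box) interpolation
#'
#' Area interpolation averages each source region covered by an output pixel,
#' the standard anti-aliased choice for downsampling medical images. For an
#' exact integer factor (e.g. 224 -> 112) this is a block mean.
#'
#' @param image numeric/integer matrix.
#' @param target_size integer vector (height, width), or a single value used
#'   for both.
#' @return numeric matrix of dimension `target_size`.
#' @export
resize_image <- function(image, target_size = c(112, 112)) {
  if (!is.matrix(image) || any(dim(image) == 0)) {
    stop_kneedhl("image must be a non-empty matrix", "kneedhl_invalid_input")
  }
  if (length(target_size) == 1) target_size <- rep(target_size, 2)
  if (any(target_size < 1)) {
    stop_kneedhl("target_size must be positive", "kneedhl_invalid_input")
  }
  A <- area_weights(nrow(image), target_size[1])
  B <- area_weights(ncol(image), target_size[2])
  A %*% image %*% t(B)
}

# (out x in) row-stochastic overlap weights between output pixel intervals
# [ (i-1)*s, i*s ) and source pixel intervals [ j-1, j ), s = in/out
area_weights <- function(n_in, n_out) {
  s <- n_in / n_out
  Wm <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    lo <- (i - 1) * s
    hi <- i * s
    j0 <- floor(lo) + 1
    j1 <- min(ceiling(hi), n_in)
    for (j in j0:j1) {
      ov <- min(hi, j) - max(lo, j - 1)
      if (ov > 0) Wm[i, j] <- ov / s
    }
  }
  Wm
}

#' Contrast-limited adaptive histogram equalization (CLAHE)
#'
#' Tile-wise histogram equalization with clipping: each tile's 256-bin
#' histogram is clipped at `clip_limit` times the uniform bin height, the
#' excess is redistributed evenly, and per-tile mapping LUTs are bilinearly
#' interpolated across tile centres. Operates on (and returns) 8-bit values.
#' Images whose sides are not multiples of the tile grid are edge-padded for
#' the computation and cropped back.
#'
#' @param image integer/numeric matrix with values in 0-255.
#' @param clip_limit positive clip factor (histogram clip at
#'   `clip_limit * tile_pixels / 256`).
#' @param tile_grid integer pair: number of tiles (rows, cols).
#' @return integer matrix, same dimensions as the input.
#' @export
apply_clahe <- function(image, clip_limit = 5.0, tile_grid = c(8, 8)) {
  if (!is.matrix(image) || any(dim(image) == 0)) {
    stop_kneedhl("image must be a non-empty matrix", "kneedhl_invalid_input")
  }
  if (clip_limit <= 0) stop_kneedhl("clip_limit must be > 0", "kneedhl_invalid_input")
  if (length(tile_grid) == 1) tile_grid <- rep(tile_grid, 2)
  gy <- as.integer(tile_grid[1]); gx <- as.integer(tile_grid[2])
  if (gy < 1 || gx < 1) stop_kneedhl("tile_grid must be >= (1,1)", "kneedhl_invalid_input")
  H <- nrow(image); W <- ncol(image)
  if (H < gy || W < gx) {
    stop_kneedhl(sprintf("image (%dx%d) smaller than tile grid (%dx%d)", H, W, gy, gx),
                 "kneedhl_invalid_geometry")
  }
  img <- matrix(as.integer(round(clip255(image))), H, W)

  th <- ceiling(H / gy); tw <- ceiling(W / gx)
  Hp <- th * gy; Wp <- tw * gx
  padded <- img[c(seq_len(H), rep(H, Hp - H)), c(seq_len(W), rep(W, Wp - W)), drop = FALSE]

  # per-tile clipped-CDF LUTs, rows indexed by tile (ty, tx)
  npix <- th * tw
  limit <- max(1, clip_limit * npix / 256)
  luts <- matrix(0L, gy * gx, 256)
  for (ty in seq_len(gy)) {
    for (tx in seq_len(gx)) {
      tile <- padded[((ty - 1) * th + 1):(ty * th), ((tx - 1) * tw + 1):(tx * tw)]
      h <- tabulate(as.vector(tile) + 1L, nbins = 256)
      excess <- sum(pmax(h - limit, 0))
      h <- pmin(h, limit) + excess / 256
      luts[(ty - 1) * gx + tx, ] <- as.integer(round(cumsum(h) * 255 / npix))
    }
  }

  # bilinear interpolation of tile LUTs across tile centres
  pos_y <- (seq_len(Hp) - 0.5) / th + 0.5
  pos_x <- (seq_len(Wp) - 0.5) / tw + 0.5
  y1 <- pmin(pmax(floor(pos_y), 1), gy); y2 <- pmin(y1 + 1, gy)
  x1 <- pmin(pmax(floor(pos_x), 1), gx); x2 <- pmin(x1 + 1, gx)
  fy <- pmin(pmax(pos_y - y1, 0), 1)
  fx <- pmin(pmax(pos_x - x1, 0), 1)

  vi <- as.vector(padded) + 1L               # column-major pixel values
  Y1 <- rep(y1, times = Wp); Y2 <- rep(y2, times = Wp)
  FY <- rep(fy, times = Wp)
  X1 <- rep(x1, each = Hp); X2 <- rep(x2, each = Hp)
  FX <- rep(fx, each = Hp)
  out <- (1 - FY) * (1 - FX) * luts[cbind((Y1 - 1) * gx + X1, vi)] +
         (1 - FY) * FX       * luts[cbind((Y1 - 1) * gx + X2, vi)] +
         FY       * (1 - FX) * luts[cbind((Y2 - 1) * gx + X1, vi)] +
         FY       * FX       * luts[cbind((Y2 - 1) * gx + X2, vi)]
  out <- matrix(as.integer(round(out)), Hp, Wp)
  out[seq_len(H), seq_len(W), drop = FALSE]
}

#' Preprocessing configuration
#'
#' @param target_size network input size, default 112x112.
#' @param clahe_clip_limit CLAHE clip factor, default 5.0.
#' @param clahe_tile_grid CLAHE tile grid, default (8, 8).
#' @param intensity_rescale map 0-255 to 0-1 for network input.
#' @return a `preproc_config` list.
#' @export
preproc_config <- function(target_size = c(112, 112), clahe_clip_limit = 5.0,
                           clahe_tile_grid = c(8, 8), intensity_rescale = TRUE) {
  if (any(target_size < 1) || clahe_clip_limit <= 0 || any(clahe_tile_grid < 1)) {
    stop_kneedhl("invalid preprocessing configuration", "kneedhl_config_error")
  }
  structure(list(target_size = target_size, clahe_clip_limit = clahe_clip_limit,
                 clahe_tile_grid = clahe_tile_grid,
                 intensity_rescale = intensity_rescale),
            class = "preproc_config")
}

#' Apply the fixed preprocessing chain: resize -> CLAHE -> rescale
#'
#' @param image integer/numeric matrix (8-bit gray values).
#' @param config a [preproc_config()].
#' @return numeric matrix in \[0,1\] (or 0-255 if `intensity_rescale` is off).
#' @export
preprocess_image <- function(image, config = preproc_config()) {
  out <- resize_image(image, config$target_size)
  out <- apply_clahe(out, config$clahe_clip_limit, config$clahe_tile_grid)
  if (config$intensity_rescale) out <- out / 255
  out
}

#' Hold-out split specification
#'
#' 80/20 train/test with 10 percent of the training portion reserved for
#' validation, stratified by KL grade.
#'
#' @param test_fraction fraction of all records held out for testing.
#' @param valid_fraction_of_train fraction of the training portion used for
#'   validation.
#' @param stratified stratify by grade (default TRUE; the reference cohort's
#'   per-grade split counts match per-grade rounding of these fractions).
#' @param seed RNG seed for the random partition.
#' @return a `split_spec` list.
#' @export
split_spec <- function(test_fraction = 0.20, valid_fraction_of_train = 0.10,
                       stratified = TRUE, seed = 1L) {
  if (test_fraction <= 0 || test_fraction >= 1 ||
      valid_fraction_of_train < 0 || valid_fraction_of_train >= 1) {
    stop_kneedhl("split fractions must lie in (0,1)", "kneedhl_config_error")
  }
  structure(list(test_fraction = test_fraction,
                 valid_fraction_of_train = valid_fraction_of_train,
                 stratified = stratified, seed = as.integer(seed)),
            class = "split_spec")
}

#' Randomly partition a dataset into train/valid/test
#'
#' @param dataset a `labeled_image_set`.
#' @param spec a [split_spec()].
#' @return the dataset with its `split` column filled; the partition is
#'   disjoint, exhaustive and reproducible under the seed.
#' @export
holdout_split <- function(dataset, spec = split_spec()) {
  rec <- dataset$records
  if (nrow(rec) == 0) stop_kneedhl("dataset is empty", "kneedhl_invalid_split")
  split <- rep(NA_character_, nrow(rec))
  assign_group <- function(idx) {
    n <- length(idx)
    n_test <- round(spec$test_fraction * n)
    n_valid <- round(spec$valid_fraction_of_train * (n - n_test))
    shuffled <- idx[sample.int(n)]
    held <- n_test + n_valid
    list(test = shuffled[seq_len(n_test)],
         valid = shuffled[n_test + seq_len(n_valid)],
         train = if (held > 0) shuffled[-seq_len(held)] else shuffled)
  }
  with_seed(spec$seed, {
    groups <- if (spec$stratified) {
      lapply(sort(unique(rec$grade)), function(g) assign_group(which(rec$grade == g)))
    } else {
      list(assign_group(seq_len(nrow(rec))))
    }
    for (grp in groups) {
      split[grp$test] <- "test"
      split[grp$valid] <- "valid"
      split[grp$train] <- "train"
    }
  })
  if (!any(split == "train")) {
    stop_kneedhl("split left the training set empty", "kneedhl_invalid_split")
  }
  rec$split <- split
  labeled_image_set(rec, dir = dataset$dir)
}

#' KL-grade grouping schemes
#'
#' Order-preserving maps from KL grades 0-4 onto coarser class sets:
#' `FIVE` identity; `FOUR` no-OA \{0,1\} then mild/moderate/severe;
#' `THREE` no-OA \{0,1\}, early \{2\}, severe \{3,4\}; `TWO` normal \{0,1\}
#' vs abnormal \{2,3,4\}.
#'
#' @param name one of "FIVE", "FOUR", "THREE", "TWO" (case-insensitive).
#' @return a `grouping_scheme` with fields `name`, `mapping` (length-5
#'   integer vector indexed by grade+1) and `n_classes`.
#' @export
grouping_scheme <- function(name) {
  name <- toupper(name)
  mapping <- switch(name,
    FIVE  = c(0L, 1L, 2L, 3L, 4L),
    FOUR  = c(0L, 0L, 1L, 2L, 3L),
    THREE = c(0L, 0L, 1L, 2L, 2L),
    TWO   = c(0L, 0L, 1L, 1L, 1L),
    stop_kneedhl(sprintf("unknown grouping scheme '%s' (use FIVE/FOUR/THREE/TWO)", name),
                 "kneedhl_config_error")
  )
  structure(list(name = name, mapping = mapping, n_classes = max(mapping) + 1L),
            class = "grouping_scheme")
}

#' Map KL grades to the class labels of a grouping scheme
#'
#' @param labels integer KL grades in 0-4.
#' @param scheme a [grouping_scheme()] or scheme name.
#' @return integer class labels in `0..n_classes-1`.
#' @export
map_grades <- function(labels, scheme) {
  if (is.character(scheme)) scheme <- grouping_scheme(scheme)
  if (length(labels) && any(labels < 0 | labels > 4 | labels != as.integer(labels))) {
    stop_kneedhl("labels must be KL grades in 0..4", "kneedhl_invalid_grade")
  }
  scheme$mapping[as.integer(labels) + 1L]
}
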