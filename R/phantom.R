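# Synthetic knee-radiograph phantoms.
#
# A phantom is two bright "bone" bands (distal femur above, proximal tibia
# below) separated by a dark horizontal joint-space gap whose width shrinks
# with KL grade, bright marginal osteophyte blobs whose number grows with
# grade, a subchondral sclerosis band whose intensity grows with grade, and
# additive Gaussian noise. The schedules are artifact choices, not anatomy:
# they guarantee a monotone, learnable grade signal so every downstream stage
# can be exercised without clinical data.

.kl_jsw_schedule <- c(18, 14, 10, 6, 3)        # px, grades 0-4
.kl_osteophyte_schedule <- c(0, 1, 2, 4, 6)    # blob count
# additive gray levels; capped so bone + sclerosis stays below the 255
# ceiling and osteophyte blobs remain the only saturated pixels
.kl_sclerosis_schedule <- c(0, 12, 25, 40, 60)

#' Parameters of a synthetic knee-radiograph phantom
#'
#' Defaults follow grade-dependent schedules: joint-space width
#' 18/14/10/6/3 px, osteophyte count 0/1/2/4/6 and sclerosis intensity
#' 0/12/25/40/60 gray levels for KL grades 0-4.
#'
#' @param grade integer KL grade in 0-4.
#' @param image_size integer vector (height, width) in pixels, each >= 64.
#' @param joint_space_width gap width in pixels; default from the grade
#'   schedule.
#' @param osteophyte_count number of bright marginal blobs; default from the
#'   grade schedule.
#' @param osteophyte_radius blob radius in pixels.
#' @param sclerosis_intensity additive gray level (0-255) of the subchondral
#'   band; default from the grade schedule.
#' @param noise_sd standard deviation of additive Gaussian noise in gray
#'   levels; >= 0.
#' @param seed integer RNG seed; the phantom is deterministic given
#'   `params` + `seed`.
#' @return an object of class `phantom_params`.
#' @export
phantom_params <- function(grade,
                           image_size = c(224, 224),
                           joint_space_width = NULL,
                           osteophyte_count = NULL,
                           osteophyte_radius = 3,
                           sclerosis_intensity = NULL,
                           noise_sd = 15,
                           seed = 1L) {
  if (length(grade) != 1 || is.na(grade) || grade != as.integer(grade) ||
      grade < 0 || grade > 4) {
    stop_kneedhl(sprintf("KL grade must be an integer in 0..4, got %s", format(grade)),
                 "kneedhl_invalid_grade")
  }
  grade <- as.integer(grade)
  if (length(image_size) == 1) image_size <- rep(image_size, 2)
  if (any(image_size < 64)) {
    stop_kneedhl("image_size must be at least 64x64", "kneedhl_invalid_geometry")
  }
  p <- list(
    grade = grade,
    image_size = as.integer(image_size),
    joint_space_width = joint_space_width %||% .kl_jsw_schedule[grade + 1],
    osteophyte_count = osteophyte_count %||% .kl_osteophyte_schedule[grade + 1],
    osteophyte_radius = osteophyte_radius,
    sclerosis_intensity = sclerosis_intensity %||% .kl_sclerosis_schedule[grade + 1],
    noise_sd = noise_sd,
    seed = as.integer(seed)
  )
  if (p$noise_sd < 0) stop_kneedhl("noise_sd must be >= 0", "kneedhl_invalid_input")
  if (p$joint_space_width >= p$image_size[1]) {
    stop_kneedhl("joint_space_width must be smaller than the image height",
                 "kneedhl_invalid_geometry")
  }
  structure(p, class = "phantom_params")
}

#' Render a synthetic knee-radiograph phantom
#'
#' Renders two bright bone bands separated by a dark joint-space gap of the
#' configured width, `osteophyte_count` bright blobs at the gap margins, a
#' sclerosis band adjacent to the joint surfaces, and Gaussian noise. Output
#' is deterministic for fixed parameters and seed.
#'
#' @param params a [phantom_params()] object (or a KL grade, for defaults).
#' @return integer matrix (height x width) of gray values in 0-255.
#' @examples
#' img <- generate_phantom(phantom_params(grade = 2, seed = 7))
#' dim(img)
#' @export
generate_phantom <- function(params) {
  if (is.numeric(params) && length(params) == 1) params <- phantom_params(params)
  stopifnot(inherits(params, "phantom_params"))
  H <- params$image_size[1]
  W <- params$image_size[2]
  jsw <- params$joint_space_width
  with_seed(params$seed, {
    bone <- 170 + runif(1, -10, 10)
    gapv <- 35 + runif(1, -5, 5)
    centre <- round(H / 2 + runif(1, -8, 8))
    gap_top <- centre - floor(jsw / 2)
    gap_top <- max(2 + params$osteophyte_radius,
                   min(gap_top, H - jsw - params$osteophyte_radius - 1))
    gap_rows <- gap_top:(gap_top + jsw - 1)

    # bone with a mild vertical gradient (denser epiphysis near the joint)
    img <- matrix(bone, H, W) + matrix(seq(-8, 8, length.out = H), H, W)
    img[gap_rows, ] <- gapv

    # subchondral sclerosis: bright band hugging both joint surfaces
    if (params$sclerosis_intensity > 0) {
      depth <- 6
      top_band <- max(1, gap_top - depth):(gap_top - 1)
      bot_band <- (gap_top + jsw):min(H, gap_top + jsw - 1 + depth)
      img[top_band, ] <- img[top_band, ] + params$sclerosis_intensity
      img[bot_band, ] <- img[bot_band, ] + params$sclerosis_intensity
    }

    # marginal osteophytes: bright discs at the joint margins, protruding at
    # most 2 px into the gap so the intensity-profile gap oracle still holds
    k <- params$osteophyte_count
    if (k > 0) {
      r <- params$osteophyte_radius
      margin_cols <- c(
        sample(seq(8, max(9, round(W / 4))), ceiling(k / 2), replace = TRUE),
        sample(seq(min(W - 9, round(3 * W / 4)), W - 8), floor(k / 2), replace = TRUE)
      )
      for (t in seq_len(k)) {
        on_top <- t %% 2 == 1
        ci <- if (on_top) gap_top - r + 1 else gap_top + jsw - 2 + r
        cj <- margin_cols[t]
        ii <- max(1, ci - r):min(H, ci + r)
        jj <- max(1, cj - r):min(W, cj + r)
        disc <- outer((ii - ci)^2, (jj - cj)^2, `+`) <= r^2
        img[ii, jj][disc] <- 255
      }
    }

    if (params$noise_sd > 0) {
      img <- img + matrix(rnorm(H * W, 0, params$noise_sd), H, W)
    }
    matrix(as.integer(round(clip255(img))), H, W)
  })
}

#' Generate a labelled phantom dataset on disk
#'
#' Writes one 8-bit grayscale PNG per phantom plus a CSV manifest with
#' columns `path,grade`. Per-image seeds are derived deterministically from
#' the master seed, so regeneration with the same seed is byte-identical.
#'
#' @param n_per_grade integer vector of length 5: phantoms per KL grade 0-4.
#' @param seed master integer seed.
#' @param out_dir output directory (created if missing).
#' @param image_size passed to [phantom_params()].
#' @param noise_sd passed to [phantom_params()].
#' @return a `labeled_image_set`: list with `records` (data.frame
#'   `path,grade,split`) and `counts_per_grade`.
#' @export
generate_dataset <- function(n_per_grade, seed = 1L, out_dir = tempfile("phantoms"),
                             image_size = c(224, 224), noise_sd = 15) {
  if (length(n_per_grade) != 5 || any(n_per_grade < 0)) {
    stop_kneedhl("n_per_grade must be 5 non-negative counts (grades 0..4)",
                 "kneedhl_invalid_input")
  }
  n_per_grade <- as.integer(n_per_grade)
  ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    stop_kneedhl(sprintf("cannot create output directory '%s'", out_dir),
                 "kneedhl_io_error")
  }
  records <- data.frame(path = character(0), grade = integer(0),
                        stringsAsFactors = FALSE)
  idx <- 0L
  for (g in 0:4) {
    for (i in seq_len(n_per_grade[g + 1])) {
      idx <- idx + 1L
      p <- phantom_params(g, image_size = image_size, noise_sd = noise_sd,
                          seed = derive_seed(seed, idx))
      fn <- sprintf("grade%d_%04d.png", g, i)
      write_png(generate_phantom(p), file.path(out_dir, fn))
      records <- rbind(records, data.frame(path = fn, grade = g,
                                           stringsAsFactors = FALSE))
    }
  }
  manifest <- file.path(out_dir, "manifest.csv")
  write.csv(records, manifest, row.names = FALSE, quote = FALSE)
  labeled_image_set(records, dir = out_dir)
}

#' Construct a labelled image set
#'
#' @param records data.frame with columns `path`, `grade` and optionally
#'   `split` (one of train/valid/test).
#' @param dir base directory the paths are relative to.
#' @return an object of class `labeled_image_set`.
#' @export
labeled_image_set <- function(records, dir = ".") {
  stopifnot(is.data.frame(records), all(c("path", "grade") %in% names(records)))
  if (nrow(records) > 0) {
    if (any(records$grade < 0 | records$grade > 4)) {
      stop_kneedhl("grade labels must be in 0..4", "kneedhl_invalid_grade")
    }
    if (anyDuplicated(records$path)) {
      stop_kneedhl("image paths must be unique", "kneedhl_invalid_input")
    }
  }
  if (!"split" %in% names(records)) records$split <- rep(NA_character_, nrow(records))
  counts <- vapply(0:4, function(g) sum(records$grade == g), integer(1))
  structure(list(records = records, counts_per_grade = counts, dir = dir),
            class = "labeled_image_set")
}

#' Read a labelled image set from a manifest CSV
#'
#' @param manifest path to a CSV with header `path,grade` (and optionally
#'   `split`); image paths are taken relative to the manifest's directory.
#' @return a `labeled_image_set`.
#' @export
read_manifest <- function(manifest) {
  if (!file.exists(manifest)) {
    stop_kneedhl(sprintf("manifest not found: '%s'", manifest), "kneedhl_io_error")
  }
  labeled_image_set(read.csv(manifest, stringsAsFactors = FALSE),
                    dir = dirname(manifest))
}

#' @export
print.labeled_image_set <- function(x, ...) {
  cat("labeled_image_set:", nrow(x$records), "images\n")
  cat("  per-grade counts:", paste(x$counts_per_grade, collapse = ", "), "\n")
  if (!all(is.na(x$records$split))) {
    cat("  splits:", paste(names(table(x$records$split)),
                           table(x$records$split), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Load the pixel data of a labelled image set
#'
#' @param dataset a `labeled_image_set`.
#' @param split optional split tag to filter on.
#' @return list with `images` (list of integer matrices) and `grades`.
#' @export
load_images <- function(dataset, split = NULL) {
  rec <- dataset$records
  if (!is.null(split)) rec <- rec[!is.na(rec$split) & rec$split == split, ]
  imgs <- lapply(rec$path, function(p) read_png(file.path(dataset$dir, p)))
  list(images = imgs, grades = rec$grade)
}
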