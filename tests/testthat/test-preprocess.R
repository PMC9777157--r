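# Resize, CLAHE, hold-out split and grade grouping.

test_that("area resize honours shapes and averages blocks", {
  img <- matrix(runif(224 * 224, 0, 255), 224, 224)
  out <- resize_image(img, c(112, 112))
  expect_identical(dim(out), c(112L, 112L))
  # 2x downscale is an exact block mean
  expect_equal(out[3, 7], mean(img[5:6, 13:14]), tolerance = 1e-12)
  # identity size keeps dimensions (and values)
  same <- resize_image(img, c(224, 224))
  expect_identical(dim(same), c(224L, 224L))
  expect_equal(same, img, tolerance = 1e-12)
  # constant image stays constant under any rescale
  const <- resize_image(matrix(77, 100, 60), c(31, 17))
  expect_identical(dim(const), c(31L, 17L))
  expect_equal(range(const), c(77, 77), tolerance = 1e-12)
  expect_error(resize_image(matrix(numeric(0), 0, 0)), class = "kneedhl_invalid_input")
})

test_that("CLAHE preserves shape, handles degenerate input, raises contrast", {
  img <- generate_phantom(phantom_params(1, noise_sd = 5, seed = 3))
  out <- apply_clahe(img)
  expect_identical(dim(out), dim(img))
  expect_true(all(out >= 0 & out <= 255))
  # non-divisible sizes are padded and cropped back
  odd <- apply_clahe(img[1:211, 1:203])
  expect_identical(dim(odd), c(211L, 203L))

  const <- apply_clahe(matrix(128L, 64, 64))
  expect_equal(stats::sd(as.numeric(const)), 0)

  # low-contrast phantom compressed into [100, 130] gains RMS contrast
  low <- matrix(as.integer(round(100 + 30 * (img / 255))), nrow(img), ncol(img))
  enhanced <- apply_clahe(low, clip_limit = 5, tile_grid = c(8, 8))
  expect_gt(rms_contrast(enhanced), rms_contrast(low))

  expect_error(apply_clahe(matrix(1, 4, 4), tile_grid = c(8, 8)),
               class = "kneedhl_invalid_geometry")
  expect_error(apply_clahe(img, clip_limit = 0), class = "kneedhl_invalid_input")
})

test_that("preprocessing chain is ordered and not idempotent", {
  img <- generate_phantom(phantom_params(2, seed = 8))
  once <- preprocess_image(img)
  expect_identical(dim(once), c(112L, 112L))
  expect_true(all(once >= 0 & once <= 1))
  # manually applying the chain reproduces preprocess_image
  manual <- apply_clahe(resize_image(img, c(112, 112)), 5, c(8, 8)) / 255
  expect_equal(once, manual, tolerance = 1e-12)
  # a second CLAHE pass changes the image: the chain must be applied once
  twice <- apply_clahe(once * 255) / 255
  expect_false(isTRUE(all.equal(once, twice, tolerance = 1e-6)))
})

make_label_set <- function(counts) {
  grades <- rep(0:4, counts)
  labeled_image_set(data.frame(path = sprintf("img%05d.png", seq_along(grades)),
                               grade = grades))
}

test_that("hold-out split is disjoint, exhaustive, stratified and seeded", {
  # 100 records of one grade: 80 train+valid / 20 test
  one <- labeled_image_set(data.frame(path = sprintf("p%03d", 1:100),
                                      grade = rep(2, 100)))
  sp <- holdout_split(one, split_spec(seed = 4))
  tab <- table(sp$records$split)
  expect_equal(unname(tab["test"]), 20)
  expect_equal(unname(tab["train"] + tab["valid"]), 80)
  expect_equal(unname(tab["valid"]), 8)  # 10% of the 80 training records

  # reference cohort structure: per-grade totals imply the published
  # train/valid/test rows within +-1
  ds <- make_label_set(c(3857, 1770, 2578, 1286, 295))
  sp <- holdout_split(ds, split_spec(seed = 7))
  rec <- sp$records
  expect_false(any(is.na(rec$split)))            # exhaustive
  expect_equal(nrow(rec), 9786)                  # disjoint by construction
  per <- function(tag) vapply(0:4, function(g)
    sum(rec$split == tag & rec$grade == g), integer(1))
  expect_true(all(abs(per("test") - c(772, 354, 516, 257, 59)) <= 1))
  expect_true(all(abs(per("valid") - c(308, 142, 206, 103, 24)) <= 1))
  expect_true(all(abs(per("train") - c(2777, 1274, 1856, 926, 212)) <= 2))

  # same seed -> identical assignment; different seed -> different
  sp2 <- holdout_split(ds, split_spec(seed = 7))
  expect_identical(sp$records$split, sp2$records$split)
  sp3 <- holdout_split(ds, split_spec(seed = 8))
  expect_false(identical(sp$records$split, sp3$records$split))

  expect_error(holdout_split(labeled_image_set(
    data.frame(path = character(0), grade = integer(0)))),
    class = "kneedhl_invalid_split")
  expect_error(split_spec(test_fraction = 1.2), class = "kneedhl_config_error")
})

test_that("grade grouping schemes match their definitions and invariants", {
  g <- 0:4
  expect_identical(map_grades(g, "FIVE"), c(0L, 1L, 2L, 3L, 4L))
  expect_identical(map_grades(g, "FOUR"), c(0L, 0L, 1L, 2L, 3L))
  expect_identical(map_grades(g, "THREE"), c(0L, 0L, 1L, 2L, 2L))
  expect_identical(map_grades(g, "TWO"), c(0L, 0L, 1L, 1L, 1L))
  expect_error(grouping_scheme("SIX"), class = "kneedhl_config_error")
  expect_error(map_grades(c(0, 5), "TWO"), class = "kneedhl_invalid_grade")

  set.seed(1)
  for (name in c("FIVE", "FOUR", "THREE", "TWO")) {
    sch <- grouping_scheme(name)
    labs <- sample(0:4, 50, replace = TRUE)
    out <- map_grades(labs, sch)
    expect_length(out, 50)
    expect_true(all(out >= 0 & out < sch$n_classes))
    expect_identical(sort(unique(map_grades(0:4, sch))),
                     0:(sch$n_classes - 1L))          # surjective
    expect_true(all(diff(map_grades(0:4, sch)) >= 0)) # order-preserving
  }
})
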