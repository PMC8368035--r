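test_that("rolling-ball subtraction flattens backgrounds without artifacts", {
  flat <- matrix(500, 120, 120)
  out <- subtract_background(flat, 20)
  expect_lt(max(abs(out)), 1e-6)

  # smooth gradient + compact objects: objects recovered, gradient removed
  set.seed(71)
  h <- 200; w <- 200
  grad <- outer(seq(100, 900, length.out = h), rep(1, w)) +
    outer(rep(1, h), seq(0, 600, length.out = w))
  fg <- matrix(0, h, w)
  for (i in 1:30) {
    cx <- sample(10:(w - 10), 1); cy <- sample(10:(h - 10), 1)
    fg[(row(fg) - cy)^2 + (col(fg) - cx)^2 <= 16] <- 3000
  }
  img <- pmin(grad + fg, 65535)
  rec <- subtract_background(img, 30)
  expect_equal(mean(rec), mean(fg), tolerance = 0.05)
  # never negative, never raises the mean
  expect_true(all(rec >= 0))
  expect_lte(mean(rec), mean(img))
  # idempotent up to tolerance
  rec2 <- subtract_background(rec, 30)
  expect_lt(mean(abs(rec2 - rec)) / max(mean(rec), 1), 0.05)
  expect_error(subtract_background(flat, 120), "smaller")
  expect_error(subtract_background(flat, -3), "positive")
})

test_that("radius-150 subtraction recovers the object mean on a well frame", {
  set.seed(72)
  h <- 1024; w <- 1024
  grad <- 400 + outer(seq(0, 800, length.out = h), rep(1, w)) / 2 +
    outer(rep(1, h), seq(0, 500, length.out = w)) / 2
  fg <- matrix(0, h, w)
  for (i in 1:300) {
    cx <- sample(15:(w - 15), 1); cy <- sample(15:(h - 15), 1)
    fg[(row(fg) - cy)^2 + (col(fg) - cx)^2 <= 36] <- 2500
  }
  rec <- subtract_background(pmin(grad + fg, 65535), 150)
  expect_equal(mean(rec), mean(fg), tolerance = 0.05)
})

test_that("whole-well intensity is an exact mean and symmetric", {
  expect_identical(measure_well_intensity(matrix(0, 10, 10)), 0)
  half <- matrix(c(0, 100), 10, 10)
  expect_equal(measure_well_intensity(half), 50)
  f <- generate_images(field_config(n_cells = 4L, n_red_puncta = 5L),
                       0.5, seed = 73)$green
  m <- measure_well_intensity(f)
  expect_equal(measure_well_intensity(f[nrow(f):1, ]), m)
  expect_equal(measure_well_intensity(t(f)), m)
  expect_error(measure_well_intensity(matrix(numeric(0), 0, 0)), "non-empty")
})

test_that("cell-area metric recovers planted coverage and toxicity ratios", {
  expect_identical(measure_cell_area(matrix(0, 50, 50)), 0)
  fld <- generate_images(field_config(), 0.5, seed = 74)
  area <- measure_cell_area(subtract_background(fld$green, 60))
  expect_equal(area, fld$cell_area_fraction, tolerance = 0.03 / 0.3)
  # a "toxic" field with half the cells scores about half the area
  half <- generate_images(field_config(n_cells = 12L, n_red_puncta = 24L),
                          0.5, seed = 74)
  ratio <- measure_cell_area(subtract_background(half$green, 60)) / area
  expect_equal(ratio, 12 / 25, tolerance = 0.15)
})

test_that("segmentation counts planted cells and flags degenerate input", {
  one <- generate_images(field_config(n_cells = 1L, n_red_puncta = 3L,
                                      n_green_extra = 1L), 0.5, seed = 75)
  expect_identical(segment_cells(one$green, one$red)$cell_count, 1L)

  fifty <- generate_images(field_config(width = 600L, height = 600L,
                                        n_cells = 50L, n_red_puncta = 60L),
                           0.5, seed = 76)
  n <- segment_cells(fifty$green, fifty$red)$cell_count
  expect_gte(n, 45L); expect_lte(n, 55L)

  blank <- matrix(100, 64, 64)
  s0 <- segment_cells(blank, blank)
  expect_identical(s0$cell_count, 0L)
  expect_true(s0$low_confidence)
})

test_that("puncta detection hits planted objects with compartment labels", {
  fld <- generate_images(field_config(n_red_puncta = 25L,
                                      n_green_extra = 0L), 0, seed = 77)
  seg <- segment_cells(fld$green, fld$red)
  rp <- detect_puncta(fld$red, seg, channel = "red")
  expect_gte(nrow(rp$puncta), 24)           # recall >= 96%
  expect_lte(nrow(rp$puncta), 27)           # precision >= ~90%
  # no red puncta planted in green channel: blank cytoplasm
  gp <- detect_puncta(fld$green, seg, channel = "green")
  expect_lte(nrow(gp$puncta), 2)

  nuc <- generate_images(field_config(n_red_puncta = 10L, n_nuclear_red = 8L,
                                      n_green_extra = 0L), 0, seed = 78)
  segn <- segment_cells(nuc$green, nuc$red)
  rpn <- detect_puncta(nuc$red, segn, channel = "red")
  expect_gte(sum(rpn$puncta$compartment == "nuclear"), 6)
  expect_lte(sum(rpn$puncta$compartment == "cytoplasmic"), 12)
  expect_error(detect_puncta(nuc$red, segn,
                             params = list(min_area = 50, max_area = 5)),
               "size gate")
})

test_that("object colocalization matches the planted fraction", {
  fld <- generate_images(field_config(n_red_puncta = 100L), 0.7, seed = 79)
  seg <- segment_cells(fld$green, fld$red)
  rp <- detect_puncta(fld$red, seg, channel = "red")
  gp <- detect_puncta(fld$green, seg, channel = "green")
  co <- colocalize_puncta(rp, gp)
  expect_equal(co$colocalized_fraction, 0.70, tolerance = 0.05 / 0.7)

  # identical sets -> fraction 1; disjoint sets -> 0
  co1 <- colocalize_puncta(rp, rp)
  expect_equal(co1$colocalized_fraction, 1.0)
  empty <- detect_puncta(matrix(0, nrow(fld$red), ncol(fld$red)) + 10, seg,
                         channel = "green")
  co0 <- colocalize_puncta(rp, empty)
  expect_equal(co0$colocalized_fraction, 0)
  # no cytoplasmic red puncta: fraction undefined and flagged
  cou <- colocalize_puncta(empty, gp)
  expect_true(cou$fraction_undefined)
  expect_true(is.na(cou$colocalized_fraction))
})

test_that("colocalized fraction is invariant to affine intensity rescaling", {
  fld <- generate_images(field_config(n_red_puncta = 40L), 0.5, seed = 80)
  seg <- segment_cells(fld$green, fld$red)
  frac <- function(g, r) {
    rp <- detect_puncta(r, seg, channel = "red")
    gp <- detect_puncta(g, seg, channel = "green")
    colocalize_puncta(rp, gp)$colocalized_fraction
  }
  f0 <- frac(fld$green, fld$red)
  f1 <- frac(pmin(0.6 * fld$green + 150, 65535),
             pmin(0.6 * fld$red + 150, 65535))
  expect_equal(f0, f1, tolerance = 1e-12)
})

test_that("bafilomycin-like fields show more yellow puncta than vehicle", {
  veh <- generate_images(field_config(n_red_puncta = 60L), 0.2, seed = 81)
  baf <- generate_images(field_config(n_red_puncta = 60L), 0.8, seed = 81)
  fr <- vapply(list(veh, baf), function(f) {
    seg <- segment_cells(f$green, f$red)
    colocalize_puncta(detect_puncta(f$red, seg, channel = "red"),
                      detect_puncta(f$green, seg, channel = "green"))$colocalized_fraction
  }, numeric(1))
  expect_gt(fr[2], fr[1])
})

test_that("16-bit TIFF round-trip preserves frames to quantisation", {
  fld <- generate_images(field_config(n_cells = 4L, n_red_puncta = 6L),
                         0.5, seed = 82)
  path <- withr::local_tempfile(fileext = ".tif")
  write_frame_tiff(fld$red, path)
  back <- read_frame_tiff(path)
  expect_equal(dim(back), dim(fld$red))
  expect_lt(max(abs(back - fld$red)), 1)
})
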