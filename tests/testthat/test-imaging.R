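make_stack <- function(cfp, fret, interval = 1.5) {
  image_stack(cfp, fret, pixel_size = 1, interval = interval)
}

test_that("ratio stacks divide background-corrected channels and flag gaps", {
  cfp <- array(100, dim = c(3, 6, 6))
  fret <- 2 * cfp
  rs <- compute_ratio_stack(make_stack(cfp, fret))
  expect_true(all(rs$values == 2))
  expect_true(all(rs$valid))

  # everything at the floor: no valid pixel anywhere -> error
  expect_error(compute_ratio_stack(make_stack(cfp, fret), cfp_floor = 100),
               "valid")

  # exact algebra: fret = R*I + b, cfp = I + b with known background b
  I <- array(runif(3 * 6 * 6, 50, 150), dim = c(3, 6, 6))
  R <- 1.7; b <- 20
  rs <- compute_ratio_stack(make_stack(I + b, R * I + b),
                            background_cfp = b, background_fret = b)
  expect_equal(rs$values, array(R, dim = c(3, 6, 6)), tolerance = 1e-12)

  # scaling both channels leaves the ratio unchanged
  rs2 <- compute_ratio_stack(make_stack(3 * (I + b), 3 * (R * I + b)),
                             background_cfp = 3 * b, background_fret = 3 * b)
  expect_equal(rs2$values, rs$values, tolerance = 1e-12)

  # sub-floor pixels are NA-flagged, not zero
  cfp[1, 1, 1] <- 0.5
  rs <- compute_ratio_stack(make_stack(cfp, fret), cfp_floor = 1)
  expect_true(is.na(rs$values[1, 1, 1]))
  expect_false(rs$valid[1, 1, 1])
})

test_that("median filter removes impulses, keeps flats, skips NAs", {
  img <- matrix(1.5, 9, 9)
  expect_equal(median_filter(img), img)

  img[5, 5] <- 100                      # single-pixel impulse
  expect_equal(median_filter(img), matrix(1.5, 9, 9))

  # checkerboard: interior pixels take the 25-element window median
  cb <- outer(1:7, 1:7, function(i, j) (i + j) %% 2)
  got <- median_filter(cb, 5)
  for (i in 3:5) for (j in 3:5) {
    win <- cb[(i - 2):(i + 2), (j - 2):(j + 2)]
    expect_equal(got[i, j], median(win))
  }

  # idempotent on its own output for a piecewise-constant step image
  step <- cbind(matrix(1, 9, 4), matrix(2, 9, 5))
  once <- median_filter(step, 5)
  expect_equal(median_filter(once, 5), once)

  # NA pixels are excluded from the window, not propagated
  img <- matrix(2, 7, 7); img[4, 4] <- NA
  expect_equal(median_filter(img), matrix(2, 7, 7))

  expect_error(median_filter(matrix(1, 3, 3), 5), "smaller")
  expect_error(median_filter(matrix(1, 9, 9), 4), "odd")
})

test_that("maximum intensity projection is a per-pixel max over z", {
  one <- array(runif(25), dim = c(1, 5, 5))
  expect_equal(max_intensity_projection(one), one[1, , ])

  a <- matrix(5, 4, 4); b <- matrix(2, 4, 4)
  st <- array(c(a, b), dim = c(4, 4, 2))
  st <- aperm(st, c(3, 1, 2))
  expect_equal(max_intensity_projection(st), a)

  set.seed(11)
  z <- array(runif(3 * 6 * 4), dim = c(3, 6, 4))
  brute <- matrix(0, 6, 4)
  for (i in 1:6) for (j in 1:4) brute[i, j] <- max(z[, i, j])
  expect_equal(max_intensity_projection(z), brute)

  # monotone: adding a slice never decreases any pixel
  z2 <- array(c(z, runif(6 * 4)), dim = c(4, 6, 4))
  z2[1:3, , ] <- z
  expect_true(all(max_intensity_projection(z2) >=
                    max_intensity_projection(z)))
  expect_error(max_intensity_projection(array(1, c(0, 2, 2))), "slice")
})

test_that("IMD rendering bins hue by ratio and brightness by intensity", {
  n <- 4
  lo_img <- matrix(1.0, n, n)
  cfp <- matrix(500, n, n)
  rgb <- render_imd(lo_img, cfp, ratio_range = c(1, 2))
  # ratio = lo everywhere: hue index 0 = HSV 240 deg = blue
  expect_true(all(rgb[, , 3] > 0))       # blue channel lit
  expect_true(all(rgb[, , 1] == 0))      # no red

  hi_img <- matrix(2, n, n)
  rgb <- render_imd(hi_img, cfp, ratio_range = c(1, 2))
  expect_true(all(rgb[, , 1] == 1))      # red at full brightness
  expect_true(all(rgb[, , 3] == 0))

  # zero intensity renders black whatever the ratio
  rgb <- render_imd(hi_img, matrix(0, n, n), ratio_range = c(1, 2),
                    intensity_max = 100)
  expect_true(all(rgb == 0))

  # bit-exact dependence on bin indices only: values inside one bin agree
  a <- render_imd(matrix(1.01, n, n), cfp, c(1, 2))
  b <- render_imd(matrix(1.12, n, n), cfp, c(1, 2))  # same 1/8 bin
  expect_identical(a, b)
  expect_error(render_imd(lo_img, cfp, c(2, 2)), "lo < hi")
})

test_that("trace extraction averages label pixels frame by frame", {
  vals <- array(NA_real_, dim = c(2, 4, 4))
  vals[1, , ] <- 1.5; vals[2, , ] <- 1.5
  rs <- structure(list(values = vals, valid = array(TRUE, dim(vals)),
                       pixel_size = 1, interval = 2),
                  class = "ratio_stack")
  mk <- label_mask(matrix(c(1, 1, 0, 0,
                            1, 1, 0, 0,
                            0, 0, 2, 2,
                            0, 0, 2, 2), 4, 4, byrow = TRUE))
  vals[, 3:4, 3:4] <- 2
  rs$values <- vals
  tr <- extract_cell_traces(rs, mk)
  expect_equal(unique(tr$value[tr$cell_id == "cell_1"]), 1.5)
  expect_equal(unique(tr$value[tr$cell_id == "cell_2"]), 2)
  expect_equal(sort(unique(tr$time_min)), c(0, 2))

  # frames with no valid pixel for a cell are flagged missing
  rs$values[2, 1:2, 1:2] <- NA
  tr <- extract_cell_traces(rs, mk)
  expect_true(is.na(tr$value[tr$cell_id == "cell_1" & tr$time_min == 2]))
  expect_error(extract_cell_traces(rs, label_mask(matrix(0L, 4, 4))),
               "labels")
})

test_that("stacks and masks survive a TIFF round trip", {
  dir <- withr::local_tempdir()
  set.seed(3)
  cfp <- array(runif(2 * 5 * 6, 0, 1000), dim = c(2, 5, 6))
  fret <- array(runif(2 * 5 * 6, 0, 1000), dim = c(2, 5, 6))
  st <- image_stack(cfp, fret, pixel_size = 0.5, interval = 3)
  write_stack_tiff(st, file.path(dir, "c.tif"), file.path(dir, "f.tif"))
  back <- read_stack_tiff(file.path(dir, "c.tif"), file.path(dir, "f.tif"),
                          pixel_size = 0.5, interval = 3)
  expect_equal(back$cfp, cfp, tolerance = 1e-4)     # 32-bit float storage
  expect_equal(back$fret, fret, tolerance = 1e-4)

  mk <- label_mask(matrix(sample(0:3, 20, TRUE), 4, 5))
  write_mask_tiff(mk, file.path(dir, "m.tif"))
  expect_equal(unclass(read_mask_tiff(file.path(dir, "m.tif"))),
               unclass(mk), ignore_attr = TRUE)
})
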