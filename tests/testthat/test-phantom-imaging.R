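# independent HSB oracle: direct hue/saturation/brightness formulas on the
# 0-255 scale, written without grDevices
hsb_oracle <- function(r, g, b) {
  mx <- pmax(r, g, b); mn <- pmin(r, g, b); c_ <- mx - mn
  hdeg <- ifelse(c_ == 0, 0,
          ifelse(mx == r, ((g - b) / c_) %% 6,
          ifelse(mx == g, (b - r) / c_ + 2, (r - g) / c_ + 4))) * 60
  list(h = hdeg / 360 * 255,
       s = ifelse(mx == 0, 0, c_ / mx) * 255,
       v = mx)
}

test_that("HSB thresholding matches a brute-force per-pixel oracle", {
  set.seed(42)
  px <- array(sample(0:255, 10 * 10 * 3, replace = TRUE), c(10, 10, 3))
  img <- phantom_image(px, scale = 86)
  thr <- hsb_threshold_spec()
  got <- hsb_threshold(img, thr)
  o <- hsb_oracle(as.vector(px[, , 1]), as.vector(px[, , 2]),
                  as.vector(px[, , 3]))
  want <- matrix(o$h <= 217 & o$s >= 121 & o$v >= 68, 10, 10)
  expect_identical(got, want)
})

test_that("reference pixels behave as the threshold intends", {
  mk1 <- function(rgb) phantom_image(array(rep(rgb, each = 1), c(1, 1, 3)))
  expect_false(any(hsb_threshold(mk1(c(0, 0, 0)))))       # black: brightness 0
  expect_true(all(hsb_threshold(mk1(c(200, 20, 200)))))   # saturated magenta
  expect_false(any(hsb_threshold(mk1(c(252, 214, 228))))) # pale pink background
})

test_that("relaxing any bound never shrinks the passing set", {
  set.seed(9)
  px <- array(sample(0:255, 20 * 20 * 3, replace = TRUE), c(20, 20, 3))
  img <- phantom_image(px)
  base <- hsb_threshold(img)
  wider <- list(hsb_threshold_spec(hue_max = 255),
                hsb_threshold_spec(sat_min = 0),
                hsb_threshold_spec(bright_min = 0))
  for (thr in wider) expect_true(all(hsb_threshold(img, thr)[base]))
})

test_that("degenerate masks render to all-fail / all-pass images", {
  none <- render_synthetic_tcp(matrix(FALSE, 8, 8), spacing_mm = 0.25,
                               scale = 86, noise_sd = 4, seed = 1)
  expect_equal(sum(hsb_threshold(none)), 0)
  all_on <- render_synthetic_tcp(matrix(TRUE, 8, 8), spacing_mm = 0.25,
                                 scale = 86, noise_sd = 0, seed = 1)
  expect_true(all(hsb_threshold(all_on)))
  expect_error(render_synthetic_tcp(matrix(TRUE, 4, 4), spacing_mm = -1,
                                    scale = 86, noise_sd = 0, seed = 1),
               "positive")
  expect_error(render_synthetic_tcp(matrix(TRUE, 4, 4), spacing_mm = 1,
                                    scale = 86), "seed")
})

test_that("a rendered 2 mm disk measures pi r^2 within 3%", {
  h_mm <- 0.1
  n <- 81
  cc <- (seq_len(n) - (n + 1) / 2) * h_mm
  disk <- outer(cc^2, cc^2, "+") <= 2^2
  img <- render_synthetic_tcp(disk, spacing_mm = h_mm, scale = 86,
                              noise_sd = 4, seed = 5)
  meas <- measure_ablated_region(hsb_threshold(img), img$scale)
  expect_lt(abs(meas$area_mm2 / (pi * 4) - 1), 0.03)
  expect_lt(abs(meas$length_mm - 4), 0.2)
  expect_lt(abs(meas$width_mm - 4), 0.2)
})

test_that("round-trip area is within 5% across ten seeds", {
  h_mm <- 0.25
  m <- matrix(FALSE, 40, 40)
  m[11:30, 6:35] <- TRUE  # 20 x 30 cells = 5 x 7.5 mm = 37.5 mm^2
  true_area <- sum(m) * h_mm^2
  for (seed in 1:10) {
    img <- render_synthetic_tcp(m, spacing_mm = h_mm, scale = 86,
                                noise_sd = 4, seed = seed)
    a <- measure_ablated_region(hsb_threshold(img), img$scale)$area_mm2
    expect_lt(abs(a / true_area - 1), 0.05)
  }
})

test_that("rendering is deterministic in the seed", {
  m <- matrix(c(TRUE, FALSE, TRUE, TRUE), 2, 2)
  a <- render_synthetic_tcp(m, spacing_mm = 1, scale = 20, noise_sd = 4,
                            seed = 123)
  b <- render_synthetic_tcp(m, spacing_mm = 1, scale = 20, noise_sd = 4,
                            seed = 123)
  c_ <- render_synthetic_tcp(m, spacing_mm = 1, scale = 20, noise_sd = 4,
                             seed = 124)
  expect_identical(a$pixels, b$pixels)
  expect_false(identical(a$pixels, c_$pixels))
})

test_that("pixel-exact measurement arithmetic", {
  full <- matrix(TRUE, 86, 86)
  expect_equal(measure_ablated_region(full, 86)$area_mm2, 1)
  expect_equal(measure_ablated_region(matrix(FALSE, 10, 10), 86),
               list(area_mm2 = 0, length_mm = 0, width_mm = 0))
  rect <- matrix(FALSE, 1000, 300)
  rect[71:930, 101:272] <- TRUE  # 860 x 172 px at 86 px/mm = 10 x 2 mm
  meas <- measure_ablated_region(rect, 86)
  expect_equal(meas$length_mm, 10)
  expect_equal(meas$width_mm, 2)
  expect_equal(meas$area_mm2, 860 * 172 / 86^2)
})

test_that("PNG and TIFF round trips preserve the pixels", {
  m <- matrix(FALSE, 6, 9); m[2:4, 3:7] <- TRUE
  img <- render_synthetic_tcp(m, spacing_mm = 0.5, scale = 40, noise_sd = 3,
                              seed = 2)
  for (ext in c("png", "tiff")) {
    f <- tempfile(fileext = paste0(".", ext))
    write_phantom_image(img, f)
    back <- read_phantom_image(f, scale = img$scale)
    expect_equal(back$pixels, img$pixels)
    unlink(f)
  }
})
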