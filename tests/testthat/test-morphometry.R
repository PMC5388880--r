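test_that("component labeling agrees with the flood-fill oracle", {
  set.seed(10)
  for (i in 1:60) {
    m <- matrix(rbinom(64 * 64, 1, runif(1, 0.2, 0.6)), 64, 64)
    lab <- label_components(m)
    ora <- oracle_flood_fill(m)
    expect_equal(max(lab), max(ora))
    # identical partitions: every implementation component maps to exactly
    # one oracle component and vice versa
    fg <- m != 0
    expect_equal(length(unique(paste(lab[fg], ora[fg]))), max(lab))
    lab4 <- label_components(m, connectivity = 4)
    ora4 <- oracle_flood_fill(m, connectivity = 4)
    expect_equal(max(lab4), max(ora4))
  }
})

test_that("coverage fraction is the plain pixel ratio", {
  ref <- matrix(0L, 20, 20); ref[5:15, 5:15] <- 1L
  expect_equal(coverage_fraction(ref, ref)$value, 1)
  expect_equal(coverage_fraction(matrix(0L, 20, 20), ref)$value, 0)
  sig <- matrix(0L, 20, 20); sig[5:9, 5:15] <- 1L
  cv <- coverage_fraction(sig, ref)
  expect_equal(cv$value, sum(sig) / sum(ref))
  expect_error(coverage_fraction(sig, matrix(0L, 20, 20)), "empty")
  expect_error(coverage_fraction(sig, matrix(0L, 10, 10)), "shape")
})

test_that("coverage is invariant to cropping windows containing all foreground", {
  ref <- matrix(0L, 30, 30); ref[10:20, 10:20] <- 1L
  sig <- matrix(0L, 30, 30); sig[12:18, 10:20] <- 1L
  full <- coverage_fraction(sig, ref)$value
  crop <- coverage_fraction(sig[5:25, 5:25], ref[5:25, 5:25])$value
  expect_equal(full, crop)
})

test_that("detachment fraction follows the Chebyshev contact rule", {
  m <- matrix(0L, 20, 20)
  m[5:7, 5:7] <- 1L; m[5:7, 8:10] <- 2L       # share an edge
  expect_equal(detachment_fraction(m)$value, 0)
  m2 <- matrix(0L, 20, 20)
  m2[2:4, 2:4] <- 1L; m2[10:12, 10:12] <- 2L  # far apart
  expect_equal(detachment_fraction(m2)$value, 1)
  # diagonal corner contact counts at distance 1
  m3 <- matrix(0L, 20, 20)
  m3[5, 5] <- 1L; m3[6, 6] <- 2L; m3[15, 15] <- 3L
  d3 <- detachment_fraction(m3)
  expect_equal(d3$value, 1 / 3)
  expect_equal(d3$parameters$detached_labels, 3L)
  # monotone non-increasing in contact distance
  m4 <- matrix(0L, 20, 20)
  m4[2:3, 2:3] <- 1L; m4[2:3, 7:8] <- 2L  # gap of 3 columns
  expect_equal(detachment_fraction(m4, 1)$value, 1)
  expect_equal(detachment_fraction(m4, 4)$value, 0)
  expect_warning(ds <- detachment_fraction(matrix(c(0L, 1L), 1, 2)),
                 "single")
  expect_equal(ds$value, 1)
})

test_that("class pixel fraction uses instance flags and validates them", {
  m <- matrix(0L, 10, 10)
  m[1:2, 1:2] <- 1L; m[5:6, 5:8] <- 2L
  expect_equal(class_pixel_fraction(m, c(`1` = TRUE, `2` = TRUE))$value, 1)
  expect_equal(class_pixel_fraction(m, c(`1` = FALSE, `2` = FALSE))$value, 0)
  expect_equal(class_pixel_fraction(m, c(`1` = TRUE, `2` = FALSE))$value,
               4 / 12)
  expect_error(class_pixel_fraction(m, c(`1` = TRUE)), "missing")
})

test_that("plaque load filters components by area and counts survivors", {
  roi <- matrix(1L, 100, 100)
  pm <- matrix(0L, 100, 100)
  pm[10:29, 10:34] <- 1L  # 500 px
  r <- plaque_load(pm, roi, min_plaque_area = 100)
  expect_equal(r$value, 5)
  expect_equal(r$parameters$n_plaques, 1L)
  # 50/100/400 with min 100: two survive (component-size rule is >=)
  pm2 <- matrix(0L, 100, 100)
  pm2[2:11, 2:6] <- 1L                       # 50
  pm2[20:29, 20:29] <- 1L                    # 100
  pm2[50:69, 50:69] <- 1L                    # 400
  r2 <- plaque_load(pm2, roi, min_plaque_area = 100)
  expect_equal(r2$parameters$n_plaques, 2L)
  expect_equal(r2$value, 100 * (100 + 400) / 10000)
  r0 <- plaque_load(pm2, roi, min_plaque_area = 0)
  expect_equal(r0$parameters$n_plaques, 3L)
  expect_gte(r0$value, r2$value)
  expect_error(plaque_load(pm2, matrix(0L, 100, 100)), "empty ROI")
})

test_that("vascular amyloid load is the percent surface ratio", {
  expect_equal(vascular_amyloid_load(39, 100), 39.0)
  expect_equal(vascular_amyloid_load(0, 100), 0)
  expect_equal(vascular_amyloid_load(10.5, 100), 10.5)
  expect_error(vascular_amyloid_load(101, 100), "exceeds")
  expect_error(vascular_amyloid_load(5, 0), "positive")
})

test_that("background thresholding matches an exhaustive scan oracle", {
  set.seed(11)
  img <- matrix(round(runif(40 * 40, 0, 50)), 40, 40)
  bg <- matrix(FALSE, 40, 40); bg[1:40, 1:15] <- TRUE
  for (target in c(7, 8.5, 10)) {
    out <- threshold_by_background(img, bg, target_density = target)
    thr <- attr(out, "threshold")
    allowed <- floor(target * sum(bg) / 150)
    vals <- img[bg]
    # oracle: exhaustive scan over all observed levels
    cands <- sort(unique(c(min(vals) - 1, vals)))
    ok <- cands[sapply(cands, function(th) sum(vals > th) <= allowed)]
    expect_equal(thr, min(ok))
    expect_lte(sum(img[bg] > thr), allowed)
  }
  # lower target density cannot lower the threshold
  t1 <- attr(threshold_by_background(img, bg, 10), "threshold")
  t2 <- attr(threshold_by_background(img, bg, 7), "threshold")
  expect_gte(t2, t1)
})

test_that("all-zero background thresholds at the minimum positive level", {
  img <- matrix(0, 20, 20); img[5:10, 5:10] <- 3
  bg <- matrix(FALSE, 20, 20); bg[15:20, ] <- TRUE
  out <- threshold_by_background(img, bg)
  expect_equal(attr(out, "threshold"), 0)
  expect_equal(sum(out), 36)  # exactly the positive pixels
})
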