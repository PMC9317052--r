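test_that("moment fit recovers a rasterized ellipse's parameters", {
  e <- tumor_ellipse(c(40, 45), 20, 10, 0)
  f <- fit_ellipse(ellipse_mask(e, c(90, 90)))
  expect_lt(abs(f$semi_major - 20) / 20, 0.02)
  expect_lt(abs(f$semi_minor - 10) / 10, 0.02)
  expect_lt(abs(f$orientation), 0.05)
  expect_equal(f$center, c(40, 45), tolerance = 0.05)
})

test_that("a filled circle fits with equal semi-axes", {
  f <- fit_ellipse(ellipse_mask(tumor_ellipse(c(30, 30), 12, 12), c(60, 60)))
  expect_equal(f$semi_major, f$semi_minor, tolerance = 0.02)
  expect_equal(f$semi_major, 12, tolerance = 0.3)
})

test_that("orientation of a rotated ellipse is recovered", {
  e <- tumor_ellipse(c(50, 50), 25, 10, 30 * pi / 180)
  f <- fit_ellipse(ellipse_mask(e, c(100, 100)))
  expect_lt(abs(f$orientation - 30 * pi / 180), 0.05)
})

test_that("fit matches the EBImage moment features", {
  e <- tumor_ellipse(c(45, 40), 18, 9, 0.4)
  m <- ellipse_mask(e, c(90, 90))
  f <- fit_ellipse(m)
  ft <- EBImage::computeFeatures.moment(m)
  expect_equal(f$semi_major, ft[1, "m.majoraxis"] / 2, tolerance = 0.02)
  ecc <- sqrt(1 - (f$semi_minor / f$semi_major)^2)
  expect_equal(ecc, ft[1, "m.eccentricity"], tolerance = 0.02)
})

test_that("fit rejects degenerate inputs", {
  expect_input_error(fit_ellipse(matrix(0, 10, 10)))
  m <- matrix(0, 10, 10); m[2, 2] <- 1; m[3, 2:3] <- 1
  expect_input_error(fit_ellipse(m)) # < 5 pixels
  two <- matrix(0, 20, 20); two[2:5, 2:5] <- 1; two[12:15, 12:15] <- 1
  expect_input_error(fit_ellipse(two))
})

test_that("scaling multiplies semi-axes and preserves center and angle", {
  e <- tumor_ellipse(c(10, 10), 20, 10, 0.3)
  s <- scale_ellipse(e, 0.9)
  expect_equal(c(s$semi_major, s$semi_minor), c(18, 9))
  expect_equal(s$center, e$center)
  expect_equal(s$orientation, e$orientation)
  expect_equal(scale_ellipse(e, 1), e)
  expect_input_error(scale_ellipse(e, 0))
  expect_input_error(scale_ellipse(e, -2))
})

test_that("rasterized interior area scales as the squared factor", {
  e <- tumor_ellipse(c(100, 100), 30, 22, 0.5)
  a1 <- sum(ellipse_mask(e, c(200, 200)))
  a2 <- sum(ellipse_mask(scale_ellipse(e, 1.2), c(200, 200)))
  expect_lt(abs(a2 / a1 - 1.44) / 1.44, 0.05)
  # property over several ellipses with semi-axes >= 20
  set.seed(1)
  for (k in 1:5) {
    a <- runif(1, 20, 32); b <- runif(1, 20, a); f <- runif(1, 0.8, 1.3)
    e <- tumor_ellipse(c(110, 105), a, b, runif(1, -pi / 2, pi / 2))
    r <- sum(ellipse_mask(scale_ellipse(e, f), c(220, 220))) /
      sum(ellipse_mask(e, c(220, 220)))
    expect_lt(abs(r - f^2) / f^2, 0.05)
  }
})

test_that("fit-then-rasterize round trip recovers parameters within 2%", {
  set.seed(42)
  for (k in 1:8) {
    a <- runif(1, 15, 30); b <- runif(1, 10, a)
    th <- runif(1, -1.4, 1.4)
    e <- tumor_ellipse(c(60, 60) + runif(2, -5, 5), a, b, th)
    f <- fit_ellipse(ellipse_mask(e, c(120, 120)))
    expect_lt(abs(f$semi_major - a) / a, 0.02)
    expect_lt(abs(f$semi_minor - b) / b, 0.02)
    if (a / b > 1.1) # orientation ill-defined near circles
      expect_lt(min(abs(f$orientation - th), pi - abs(f$orientation - th)),
                0.05)
  }
})

test_that("trimap partitions the image into FG, BG and ignore", {
  tm <- make_trimap(tumor_ellipse(c(32, 32), 12, 8, 0.4), c(64, 64))
  expect_setequal(unique(as.vector(tm$labels)),
                  c(TRIMAP_FG, TRIMAP_BG, TRIMAP_IGNORE))
  expect_equal(length(tm$labels), 64 * 64)
  fg <- tm$labels == TRIMAP_FG
  small_int <- ellipse_mask(tm$small_ellipse, c(64, 64)) == 1
  large_int <- ellipse_mask(tm$large_ellipse, c(64, 64)) == 1
  expect_identical(fg, small_int)
  expect_identical(tm$labels == TRIMAP_BG, !large_int)
  expect_true(all(small_int[large_int == FALSE] == FALSE)) # nesting
})

test_that("trimap clips at the image border and validates scale factors", {
  tm <- make_trimap(tumor_ellipse(c(6, 6), 10, 7), c(32, 32))
  expect_equal(sum(tm$labels == TRIMAP_BG),
               sum(ellipse_mask(tm$large_ellipse, c(32, 32)) == 0))
  expect_input_error(make_trimap(tumor_ellipse(c(16, 16), 5, 4), c(32, 32),
                                 p1 = 1.2, p2 = 0.9))
  expect_input_error(make_trimap(tumor_ellipse(c(40, 16), 5, 4), c(32, 32)))
})

test_that("FG/BG nesting holds across random ellipses and p1 < p2", {
  set.seed(7)
  for (k in 1:10) {
    e <- tumor_ellipse(c(runif(1, 20, 44), runif(1, 20, 44)),
                       runif(1, 8, 16), runif(1, 4, 8),
                       runif(1, -pi / 2, pi / 2))
    p1 <- runif(1, 0.5, 0.95); p2 <- runif(1, 1.05, 1.6)
    tm <- make_trimap(e, c(64, 64), p1 = p1, p2 = p2)
    fg <- tm$labels == TRIMAP_FG
    large_int <- ellipse_mask(tm$large_ellipse, c(64, 64)) == 1
    expect_true(all(large_int[fg]))
    expect_equal(sort(unique(as.vector(tm$labels))),
                 sort(intersect(c(0, 1, 2), unique(as.vector(tm$labels)))))
  }
})

test_that("trimap FG is pure on an exactly elliptical tumor", {
  cfg <- phantom_config(n_patients = 3, noise_sigma = 0,
                        tumor_irregularity = 0, seed = 21)
  ph <- derive_weak_labels(generate_phantoms(cfg))
  q <- purrr::map2(ph$trimap, ph$mask, trimap_quality) |> dplyr::bind_rows()
  expect_true(all(q$fg_purity == 1))
})

test_that("trimap quality matches direct pixel counting", {
  tm <- make_trimap(tumor_ellipse(c(32, 32), 10, 6, 0.2), c(64, 64))
  truth <- ellipse_mask(tm$small_ellipse, c(64, 64))
  q <- trimap_quality(tm, truth)
  expect_equal(unlist(q), c(fg_purity = 1, bg_purity = 1, tumor_coverage = 1))
  far <- matrix(0, 64, 64); far[1:3, 1:3] <- 1
  q2 <- trimap_quality(tm, far)
  expect_equal(q2$fg_purity, 0)
  # brute-force agreement on an irregular truth
  set.seed(3)
  truth3 <- random_mask(64, 0.2)
  q3 <- trimap_quality(tm, truth3)
  fg <- tm$labels == TRIMAP_FG; bg <- tm$labels == TRIMAP_BG
  expect_equal(q3$fg_purity, sum(truth3 == 1 & fg) / sum(fg))
  expect_equal(q3$bg_purity, sum(truth3 == 0 & bg) / sum(bg))
  expect_equal(q3$tumor_coverage, sum(truth3 == 1 & fg) / sum(truth3))
  expect_input_error(trimap_quality(tm, truth[1:10, 1:10]))
})

test_that("quality is undefined when a trimap region is empty", {
  tm <- make_trimap(tumor_ellipse(c(32, 32), 60, 60), c(64, 64), p2 = 1.01)
  expect_error(trimap_quality(tm, matrix(0, 64, 64)),
               class = "ellipseg_metric_error")
})

test_that("trimaps round-trip through PNG + JSON sidecar", {
  tm <- make_trimap(tumor_ellipse(c(20, 24), 9, 5, -0.7), c(48, 48))
  path <- file.path(withr::local_tempdir(), "tm.png")
  write_trimap(tm, path)
  back <- read_trimap(path)
  expect_identical(back$labels, tm$labels)
  expect_equal(back$small_ellipse, tm$small_ellipse, tolerance = 1e-7)
  expect_equal(back$p2, 1.2)
})

test_that("initial ellipse surrounds the fitted region", {
  m <- ellipse_mask(tumor_ellipse(c(30, 30), 14, 8, 0.3), c(60, 60))
  e0 <- fit_ellipse(m)
  e1 <- initial_ellipse(m)
  expect_equal(e1$semi_major / e0$semi_major, 1.05)
  expect_equal(e1$center, e0$center)
})
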