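test_that("correlation behaves on identical, negated and independent images", {
  set.seed(26)
  a <- array(runif(1e4), c(100, 100))
  expect_equal(image_correlation(image_pair(a, a)), 1)
  expect_equal(image_correlation(a, -a + 2 * max(a)), -1, tolerance = 1e-12)
  b <- array(runif(1e4), c(100, 100))
  expect_lt(abs(image_correlation(a, b)), 0.05)   # ~3/sqrt(n)
  expect_error(image_correlation(array(1, c(10, 10)), a[1:10, 1:10]),
               "zero-variance")
})

test_that("sliding correlation finds constructed shifts and matches brute force", {
  set.seed(27)
  a <- .gauss_smooth_test(array(runif(64 * 64), c(64, 64)))
  expect_equal(as.numeric(sliding_correlation(a, a, max_shift = 0)),
               image_correlation(a, a))
  sh <- array(0, dim(a))
  sh[4:64, 1:62] <- a[1:61, 3:64]   # copy shifted by (+3, -2)
  s <- sliding_correlation(image_pair(sh, a), max_shift = 5)
  expect_equal(as.numeric(s), 1, tolerance = 1e-10)
  expect_equal(attr(s, "shift"), c(3L, -2L))
  # brute-force oracle: direct loop over all shifts with plain cor()
  b <- array(runif(64 * 64), c(64, 64))
  brute <- -Inf
  for (s1 in -3:3) for (s2 in -3:3) {
    ia <- max(1, 1 + s1):min(64, 64 + s1)
    ja <- max(1, 1 + s2):min(64, 64 + s2)
    cc <- stats::cor(as.numeric(a[ia, ja]), as.numeric(b[ia - s1, ja - s2]))
    brute <- max(brute, cc)
  }
  expect_equal(as.numeric(sliding_correlation(image_pair(a, b), max_shift = 3)),
               brute, tolerance = 1e-12)
  # sliding >= plain correlation (maximum over a superset)
  expect_gte(as.numeric(sliding_correlation(image_pair(a, b), max_shift = 4)),
             image_correlation(image_pair(a, b)))
  expect_error(sliding_correlation(a, b, max_shift = 40), "overlap")
})

test_that("SSIM matches its closed form and conventional limits", {
  set.seed(28)
  a <- array(runif(64 * 64), c(64, 64))
  expect_equal(image_ssim(image_pair(a, a, "none")), 1, tolerance = 1e-12)
  # constant images: closed-form SSIM with L = 1, a = 1, b = 0.5
  av <- 1; bv <- 0.5
  c1 <- (0.01)^2; c2 <- (0.03)^2
  want <- ((2 * av * bv + c1) * c2) / ((av^2 + bv^2 + c1) * c2)
  got <- image_ssim(image_pair(array(av, c(32, 32)), array(bv, c(32, 32)), "none"),
                    dynamic_range = 1)
  expect_equal(got, want, tolerance = 1e-12)
  b <- array(runif(64 * 64), c(64, 64))
  expect_lt(image_ssim(image_pair(a, b, "none")), 0.1)
  expect_error(image_ssim(image_pair(a[1:8, 1:8], b[1:8, 1:8], "none")),
               "window")
})

test_that("metrics are invariant to positive rescaling of both images", {
  set.seed(29)
  a <- abs(array(rnorm(32 * 32), c(32, 32)))
  b <- abs(array(rnorm(32 * 32), c(32, 32)))
  p1 <- image_pair(a, b)
  p2 <- image_pair(5 * a, 0.3 * b)
  expect_equal(image_correlation(p1), image_correlation(p2), tolerance = 1e-12)
  expect_equal(image_ssim(p1), image_ssim(p2), tolerance = 1e-12)
  expect_equal(as.numeric(sliding_correlation(p1, max_shift = 2)),
               as.numeric(sliding_correlation(p2, max_shift = 2)),
               tolerance = 1e-12)
  # symmetry of correlation and (fixed-range) SSIM
  expect_equal(image_correlation(image_pair(a, b, "none")),
               image_correlation(image_pair(b, a, "none")))
  expect_equal(image_ssim(image_pair(a, b, "none"), dynamic_range = 1),
               image_ssim(image_pair(b, a, "none"), dynamic_range = 1),
               tolerance = 1e-12)
})

test_that("amplitude projections equal the per-pixel maximum", {
  expect_equal(map_projection(array(2.5, c(6, 7, 4)), 3), array(2.5, c(6, 7)))
  v <- array(0, c(8, 8, 5)); v[3, 6, 2] <- 9
  m <- map_projection(v, 3)
  expect_equal(which(m == 9, arr.ind = TRUE), cbind(row = 3L, col = 6L))
  set.seed(30)
  r <- array(rnorm(8 * 8 * 4), c(8, 8, 4))
  brute <- matrix(0, 8, 8)
  for (i in 1:8) for (j in 1:8) brute[i, j] <- max(r[i, j, 2:3])
  expect_equal(map_projection(r, 3, slab = 2:3), brute)
  expect_error(map_projection(r, 3, slab = integer(0)), "slab")
  expect_error(map_projection(r, 3, slab = 9), "slab")
})

test_that("line profiles sample bilinearly along the segment", {
  g <- make_grid(c(32, 32), 1e-3)
  co <- grid_coords(g)
  ramp <- array(co[, 1], g$shape)   # linear in x
  p <- line_profile(ramp, g, c(-10e-3, 0), c(10e-3, 0), n_samples = 21)
  expect_equal(p, seq(-10e-3, 10e-3, length.out = 21), tolerance = 1e-12)
  same <- line_profile(ramp, g, c(2e-3, 3e-3), c(2e-3, 3e-3), n_samples = 7)
  expect_equal(same, rep(2e-3, 7), tolerance = 1e-12)
  # bilinear field: diagonal profile matches the closed form exactly
  bil <- array((1 + co[, 1] * 1e3) * (2 - co[, 2] * 1e3), g$shape)
  tseq <- seq(0, 1, length.out = 50)
  pts <- cbind(-8e-3 + tseq * 15e-3, -6e-3 + tseq * 10e-3)
  want <- (1 + pts[, 1] * 1e3) * (2 - pts[, 2] * 1e3)
  expect_equal(line_profile(bil, g, c(-8e-3, -6e-3), c(7e-3, 4e-3), 50), want,
               tolerance = 1e-10)
  expect_error(line_profile(ramp, g, c(0, 0), c(1, 0)), "outside")
})
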