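test_that("power iteration matches a dense decomposition of an explicit operator", {
  # build the dense matrix of a small measurement operator column by column
  g <- make_grid(c(16, 16), 2e-3)
  med <- water_medium(g)
  set.seed(16)
  pos <- matrix(runif(8 * 2, -9e-3, 9e-3), 8, 2)
  op <- forward_operator(med, sensor_array(pos), nt = 30, dt = 2.5e-7,
                         pml = pml_config(0))
  A <- matrix(0, 8 * 30, 16 * 16)
  for (j in seq_len(256)) {
    e <- array(0, g$shape); e[j] <- 1
    A[, j] <- as.vector(op$apply(e))
  }
  L_dense <- max(svd(A, nu = 0, nv = 0)$d)^2
  L_power <- as.numeric(power_iteration(op$apply, op$adjoint, g$shape,
                                        n_iter = 30, seed = 17))
  expect_lt(abs(L_power - L_dense) / L_dense, 0.01)
  # Rayleigh quotients are monotone non-decreasing
  tr <- attr(power_iteration(op$apply, op$adjoint, g$shape, n_iter = 15,
                             seed = 18), "trace")
  expect_true(all(diff(tr) > -1e-9 * max(tr)))
})

test_that("power iteration handles identity, diagonal and zero operators", {
  expect_equal(as.numeric(power_iteration(identity, identity, 100, 30, seed = 2)),
               1, tolerance = 1e-10)
  dg <- function(x) x * c(1, 2, 3)
  expect_equal(as.numeric(power_iteration(dg, dg, 3, 80, seed = 2)), 9,
               tolerance = 1e-8)
  zero <- function(x) x * 0
  expect_warning(L <- power_iteration(zero, zero, 10, 5, seed = 2), "0")
  expect_equal(as.numeric(L), 0)
})

test_that("the composite prox reduces to its closed-form special cases", {
  set.seed(19)
  x <- array(rnorm(64), c(8, 8))
  expect_equal(prox_composite(x, 0, 0, nonneg = FALSE), x)
  const2 <- array(2, c(10, 10))
  expect_equal(prox_composite(const2, l1 = 0.5, tv = 1),
               array(1.5, c(10, 10)))   # constants are TV fixed points
  # soft thresholding with nonnegativity
  expect_equal(prox_composite(array(c(-3, 0.2, 1), c(3, 1)), l1 = 0.5, tv = 0),
               array(c(0, 0, 0.5), c(3, 1)))
})

test_that("the iterative TV prox matches the exact taut-string solution in 1-D", {
  set.seed(20)
  y <- c(rep(0, 20), rep(2, 15), rep(0.5, 25)) + rnorm(60, sd = 0.1)
  lam <- 0.4
  xe <- tv1d_exact(y, lam)
  xa <- tv_denoise(array(y, 60), lam, n_iter = 400, nonneg = FALSE)
  expect_lt(max(abs(as.numeric(xa) - xe)), 1e-4)
  # and under the nonnegativity constraint against a projected oracle on a
  # nonnegative signal (constraint inactive -> same solution)
  y2 <- abs(y) + 0.5
  expect_lt(max(abs(as.numeric(tv_denoise(array(y2, 60), lam, 400, nonneg = TRUE)) -
                      tv1d_exact(y2, lam))), 1e-4)
})

test_that("TV forward differences and their transpose are adjoint", {
  set.seed(21)
  x <- array(rnorm(80), c(8, 10))
  g <- array(rnorm(80), c(8, 10))
  for (a in 1:2) {
    lhs <- sum(depact:::.fdiff(x, a) * g)
    rhs <- sum(x * depact:::.fdiff_t(g, a))
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})

test_that("UBP is linear, zero on zero data, and localises a point source", {
  g <- make_grid(c(128, 128), 0.5e-3)
  med <- water_medium(g, c0 = 1482)
  sens <- make_circular_array(25e-3, 256)
  zero <- sensor_data(matrix(0, 256, 400), 1e-7, positions = sens$positions)
  roi <- make_grid(c(64, 64), 0.5e-3)
  expect_true(all(ubp_reconstruct(zero, sens, 1482, roi) == 0))
  p0 <- array(0, g$shape); p0[70, 58] <- 1
  dat <- elastic_forward(p0, med, sens, 500, 1e-7, pml_config(10))
  img <- ubp_reconstruct(dat, sens, 1482, roi)
  pk <- which(img == max(img), arr.ind = TRUE)
  off <- abs(index_to_coord(roi, pk) - index_to_coord(g, matrix(c(70, 58), 1)))
  expect_lt(max(off), 0.5e-3 + 1e-12)     # within one voxel
  dat3 <- dat; dat3$d <- 3 * dat$d
  expect_equal(ubp_reconstruct(dat3, sens, 1482, roi), 3 * img,
               tolerance = 1e-12)
  short <- sensor_data(dat$d[, 1:40], 1e-7, positions = sens$positions)
  expect_error(ubp_reconstruct(short, sens, 1482, roi), "time axis too short")
})

test_that("iterative reconstruction recovers a water-only phantom", {
  g <- make_grid(c(64, 64), 1e-3)
  med <- water_medium(g)
  sens <- make_circular_array(20e-3, 128)
  p0 <- array(0, g$shape)
  p0[26:30, 30:34] <- 1; p0[35:38, 24:40] <- 0.7; p0[42, 42] <- 1
  dat <- elastic_forward(p0, med, sens, 280, 1e-7, pml_config(10))
  cfg <- recon_config(l1_weight = 1e-8, tv_weight = 1e-8, n_outer = 50,
                      power_iters = 10, seed = 3)
  rec <- pact_reconstruct(dat, sens, "iterative", medium = med, config = cfg)
  expect_lt(sqrt(sum((coef(rec) - p0)^2) / sum(p0^2)), 0.1)
  expect_gte(min(coef(rec)), 0)
  expect_true(all(diff(rec$objective_trace) <= 1e-9 * rec$objective_trace[1]))
})

test_that("zero data reconstructs to the zero image under any weights", {
  g <- make_grid(c(48, 48), 1e-3)
  med <- water_medium(g)
  sens <- make_circular_array(12e-3, 16)
  dat <- sensor_data(matrix(0, 16, 60), 1e-7, positions = sens$positions)
  rec <- pact_reconstruct(dat, sens, "iterative", medium = med,
                          config = recon_config(l1_weight = 0.3, tv_weight = 0.2,
                                                n_outer = 3, power_iters = 5))
  expect_true(all(coef(rec) == 0))
  adj <- pact_reconstruct(dat, sens, "adjoint", medium = med)
  expect_true(all(coef(adj) == 0))
})

test_that("pact_recon methods expose the fit the way a model object should", {
  g <- make_grid(c(48, 48), 1e-3)
  med <- water_medium(g)
  sens <- make_circular_array(12e-3, 24)
  p0 <- array(0, g$shape); p0[22:26, 20:28] <- 1
  dat <- elastic_forward(p0, med, sens, 100, 1e-7)
  rec <- pact_reconstruct(dat, sens, "iterative", medium = med,
                          config = recon_config(n_outer = 3, power_iters = 5))
  expect_s3_class(rec, "pact_recon")
  expect_identical(coef(rec), rec$p0_hat)
  fit <- fitted(rec)
  expect_equal(dim(fit), dim(dat$d))
  res <- residuals(rec)
  expect_equal(res, fit - dat$d, tolerance = 1e-14)
  # the final data misfit in the trace matches the residuals
  misfit <- 0.5 * sum(res^2)
  expect_lte(misfit, utils::tail(rec$objective_trace, 1) + 1e-9)
  expect_output(print(rec), "pact_recon")
  expect_output(summary(rec), "objective trace")
  f <- tempfile(fileext = ".png")
  grDevices::png(f); plot(rec); grDevices::dev.off()
  expect_true(file.exists(f)); unlink(f)
})
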