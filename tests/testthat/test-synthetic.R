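test_that("vessel phantoms are deterministic, confined and correctly sized", {
  g <- make_grid(c(128, 128), 0.5e-3)
  sp <- phantom_spec(thickness = 1.5e-3, extent = 30e-3, n_segments = 5, seed = 7)
  a <- make_vessel_phantom(sp, g)
  b <- make_vessel_phantom(sp, g)
  expect_identical(a, b)
  expect_true(all(a %in% c(0, 1)))
  frac <- mean(a > 0)
  expect_gt(frac, 0.005)
  expect_lt(frac, 0.15)
  # tube width (3-4 voxels for 1.5 mm at 0.5 mm spacing): away from
  # self-crossings every tube voxel is within 2 voxels of background
  one <- make_vessel_phantom(phantom_spec(thickness = 1.5e-3,
                                          extent = 30e-3, n_segments = 1,
                                          seed = 7), g)
  off <- depact:::.ball_offsets(2.01, 2)
  expect_gt(mean(depact:::.dilate(!(one > 0), off)[one > 0]), 0.95)
  # confinement to the extent box (half-extent + thickness margin)
  co <- grid_coords(g)
  expect_true(all(abs(co[as.vector(a > 0), ]) <= 15e-3 + 1.5e-3))
  expect_true(all(make_vessel_phantom(phantom_spec(n_segments = 0), g) == 0))
  d2 <- make_vessel_phantom(phantom_spec(seed = 8, extent = 30e-3), g)
  expect_false(identical(a, d2))
})

test_that("skull shells have the right wall thickness and property triples", {
  g <- make_grid(c(128, 128), 0.5e-3)
  model <- make_skull_shell(skull_shell_spec(), g)
  expect_equal(model$skull, c(1850, 2800, 1250))
  # radial wall along +x axis: 6.5 mm / 0.5 mm = 13 +- 1 voxels
  row <- model$mask$mask[, 64]
  runs <- rle(row)
  wall <- runs$lengths[runs$values]
  expect_true(all(abs(wall - 13) <= 1))
  # acoustic-only variant
  m0 <- make_skull_shell(skull_shell_spec(cs = 0), g)
  expect_true(all(m0$medium$mu == 0))
  expect_error(make_skull_shell(skull_shell_spec(inner_radius = 40e-3), g),
               "fit")
})

test_that("perturbations move, rotate, rescale or de-shear without touching the original", {
  g <- make_grid(c(128, 128), 0.5e-3)
  model <- make_skull_shell(skull_shell_spec(centre = c(1.5e-3, -1e-3)), g)
  com <- function(m) colMeans(grid_coords(g)[as.vector(m$mask$mask), ])
  tr <- perturb_model(model, "translate", c(3e-3, -2e-3))
  expect_lt(max(abs(com(tr) - com(model) - c(3e-3, -2e-3))), 0.5e-3)
  expect_equal(model$skull, c(1850, 2800, 1250))   # original untouched
  # the perturbation used in the published mismatch figure: -10% cp, +10% cs
  sp <- perturb_model(perturb_model(model, "cp_scale", -0.1), "cs_scale", 0.1)
  expect_equal(sp$skull[2:3], c(2520, 1375))
  rot <- perturb_model(perturb_model(model, "rotate", 10), "rotate", -10)
  expect_gte(jaccard(rot$mask, model$mask), 0.95)
  ac <- perturb_model(model, "acoustic_only")
  expect_true(all(ac$medium$mu == 0))
  expect_error(perturb_model(model, "stretch"), "arg")
  expect_warning(perturb_model(model, "translate", c(0.02, 0)), "1 cm")
})

test_that("simulated noise has the stated per-channel variance", {
  g <- make_grid(c(16, 16), 2e-3)
  med <- water_medium(g)
  set.seed(22)
  pos <- matrix(runif(8, -8e-3, 8e-3), 4, 2)
  p0 <- array(0, g$shape); p0[8, 8] <- 1
  clean <- simulate_dataset(p0, med, sensor_array(pos), nt = 4096, dt = 2.5e-7,
                            noise_sigma = 0, pml = pml_config(0))
  sig <- 0.1 * max(abs(clean$data$d))
  noisy <- simulate_dataset(p0, med, sensor_array(pos), nt = 4096, dt = 2.5e-7,
                            noise_sigma = sig, seed = 23, pml = pml_config(0))
  dn <- noisy$data$d - clean$data$d
  v <- apply(dn, 1, stats::var)
  expect_true(all(abs(v - sig^2) / sig^2 < 0.05))
  # different seeds: different noise, identical clean component
  noisy2 <- simulate_dataset(p0, med, sensor_array(pos), nt = 4096, dt = 2.5e-7,
                             noise_sigma = sig, seed = 24, pml = pml_config(0))
  expect_false(identical(noisy$data$d, noisy2$data$d))
  expect_equal(noisy$data$d - dn, noisy2$data$d - (noisy2$data$d - clean$data$d),
               tolerance = 1e-12)
})

test_that("skull background scales to the requested RMS and subtracts exactly", {
  g <- make_grid(c(64, 64), 1e-3)
  model <- make_skull_shell(skull_shell_spec(inner_radius = 10e-3,
                                             thickness = 6.5e-3), g,
                            margin = 10)
  sens <- make_circular_array(20e-3, 32)
  p0 <- array(0, g$shape); p0[30:34, 30:34] <- 1
  dat <- elastic_forward(p0, model$medium, sens, 150, 1e-7)
  expect_identical(add_skull_background(dat, model, sens, strength = 0), dat)
  noisy <- add_skull_background(dat, model, sens, strength = 3, seed = 25)
  added <- noisy$d - dat$d
  ratio <- sqrt(mean(added^2)) / sqrt(mean(dat$d^2))
  expect_lt(abs(ratio - 3) / 3, 0.02)
  # subtracting a separately simulated skull-only record recovers the
  # phantom-only data (linearity of the forward model)
  bg <- skull_background_signal(model, sens, 150, 1e-7, seed = 25)
  scale <- 3 * sqrt(mean(dat$d^2)) / sqrt(mean(bg$d^2))
  expect_lt(max(abs(noisy$d - scale * bg$d - dat$d)), 1e-10 * max(abs(dat$d)))
})

test_that("the standing fixture satisfies its data and medium invariants", {
  fx <- get_fixture()
  expect_true(all(fx$p0 >= 0))
  expect_true(all(fx$p0[fx$model$mask$mask] == 0))
  med <- fx$model$medium
  expect_true(all(med$rho > 0) && all(med$mu >= 0))
  expect_true(all(med$lam + med$mu > 0))
  expect_true(all(is.finite(fx$data$d)))
  expect_equal(dim(fx$data$d), c(256L, fx$nt))
  # reproducibility of the generated phantom
  fx2 <- transcranial_fixture(seed = 7, simulate = FALSE)
  expect_identical(fx2$p0, fx$p0)
})
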