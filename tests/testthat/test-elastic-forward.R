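test_that("spectral derivatives are exact on grid modes and compose across shifts", {
  g <- make_grid(c(64, 32), c(0.5e-3, 0.5e-3))
  const <- array(3.7, g$shape)
  d <- spectral_derivative(const, 1, 0.5e-3)
  expect_lt(max(abs(d)), 1e-12 * 3.7)
  ax <- grid_axes(g)[[1]]
  k <- 2 * pi * 4 / (64 * 0.5e-3)   # an exact grid mode
  f <- outer(sin(k * (ax - ax[1])), rep(1, 32))
  expect_equal(spectral_derivative(f, 1, 0.5e-3),
               outer(k * cos(k * (ax - ax[1])), rep(1, 32)),
               tolerance = 1e-10)
  # band-limited random field: +1/2 then -1/2 shift equals the unshifted derivative
  set.seed(6)
  spec <- matrix(0, 64, 32)
  spec[2:6, 2:6] <- complex(real = rnorm(25), imaginary = rnorm(25))
  fr <- Re(fft(spec, inverse = TRUE))
  h1 <- spectral_derivative(fr, 1, 0.5e-3, +0.5)
  # shifting +1/2 and then translating back by -1/2 recovers the centred derivative
  shift_back <- function(x) {
    n <- 64
    fidx <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))[1:n]
    kv <- 2 * pi * fidx / (n * 0.5e-3)
    ph <- exp(-1i * kv * 0.5e-3 / 2)
    Re(mvfft(mvfft(x) * ph, inverse = TRUE)) / n
  }
  expect_equal(shift_back(h1), spectral_derivative(fr, 1, 0.5e-3, 0),
               tolerance = 1e-10)
  expect_error(spectral_derivative(array(NaN, c(8, 8)), 1, 1e-3), "finite")
})

test_that("the photoacoustic initial condition maps p0 onto the stress diagonal", {
  g <- make_grid(c(16, 16, 16), 1e-3)
  st0 <- init_from_p0(array(0, g$shape), g)
  for (f in c(st0$v, st0$sigma)) expect_true(all(f == 0))
  st1 <- init_from_p0(array(1, g$shape), g)
  expect_true(all(st1$sigma$xx == -1) && all(st1$sigma$zz == -1))
  expect_true(all(st1$sigma$xy == 0))
  p0 <- array(0, g$shape); p0[4, 5, 6] <- 2
  st2 <- init_from_p0(p0, g)
  nz <- vapply(st2$sigma, function(s) sum(s != 0), 0L)
  expect_equal(unname(nz[c("xx", "yy", "zz")]), c(1L, 1L, 1L))
  expect_equal(st2$sigma$xx[4, 5, 6], -2)
  expect_error(init_from_p0(array(-1, g$shape), g), "non-negative")
  # pressure read-back is the identity on the initial state
  expect_equal(pressure_from_stress(st2), p0)
})

test_that("pressure is minus the mean normal stress; pure shear has none", {
  g <- make_grid(c(8, 8, 8), 1e-3)
  st <- wave_state(g)
  for (nm in c("xx", "yy", "zz")) st$sigma[[nm]] <- array(-1, g$shape)
  expect_equal(pressure_from_stress(st), array(1, g$shape))
  st2 <- wave_state(g)
  st2$sigma$xy <- array(5, g$shape)
  expect_equal(pressure_from_stress(st2), array(0, g$shape))
})

test_that("CFL numbers match the operating points of the discretisation", {
  g <- make_grid(c(16, 16), 0.5e-3)
  expect_equal(check_stability(solid_medium(g), g, dt = 50e-9), 0.28)
  expect_equal(check_stability(solid_medium(g), g, dt = 0), 0)
  gw <- make_grid(c(16, 16), 0.5e-3)
  expect_equal(check_stability(water_medium(gw), gw, dt = 100e-9), 0.3)
  expect_warning(check_stability(solid_medium(g), g, dt = 100e-9), "CFL")
})

test_that("the forward map is linear and zero maps to zero", {
  g <- make_grid(c(48, 48), 1e-3)
  med <- water_medium(g)
  sens <- make_circular_array(12e-3, 16)
  z <- elastic_forward(array(0, g$shape), med, sens, 60, 1e-7)
  expect_true(all(z$d == 0))
  op <- forward_operator(med, sens, 60, 1e-7)
  set.seed(7)
  a <- array(runif(48 * 48), g$shape)
  b <- array(runif(48 * 48), g$shape)
  Aa <- op$apply(a); Ab <- op$apply(b)
  expect_equal(op$apply(3.7 * a), 3.7 * Aa, tolerance = 1e-12)
  expect_equal(op$apply(a + b), Aa + Ab, tolerance = 1e-12)
})

test_that("energy is conserved in a periodic lossless homogeneous solid", {
  g <- make_grid(c(96, 96), 0.5e-3)
  med <- solid_medium(g)
  p0 <- exp(-outer(grid_axes(g)[[1]]^2, grid_axes(g)[[2]]^2, `+`) / (3e-3)^2)
  e <- run_elastic(init_from_p0(p0, g), med, nt = 500, dt = 5e-8, pml = NULL,
                   record = character(0), energy = TRUE)$energy
  drift <- abs(e[length(e)] - e[2]) / e[2]
  expect_lt(drift, 0.005)
  expect_lt((max(e[-1]) - min(e[-1])) / e[2], 0.005)
})

test_that("water-only first arrivals respect distance over sound speed", {
  g <- make_grid(c(96, 96), 1e-3)
  med <- water_medium(g, c0 = 1500)
  # disk source of radius 3 mm at the centre
  r <- sqrt(outer(grid_axes(g)[[1]]^2, grid_axes(g)[[2]]^2, `+`))
  p0 <- 1.0 * (r < 3e-3)
  dt <- 1.5e-7
  sensp <- matrix(c(30e-3, 0), 1)
  tr <- run_elastic(init_from_p0(p0, g), med, nt = 260, dt = dt,
                    pml = pml_config(10), sensors = sensp)$trace_p[1, ]
  # the waveform peak tracks the arrival of the nearest rasterised source
  # voxel; the onset itself is smeared over ~1.5 cells by the band limit of
  # the grid, so the peak is the robust timing feature
  src <- grid_coords(g)[as.vector(p0 > 0), ]
  d_min <- min(sqrt((src[, 1] - 30e-3)^2 + src[, 2]^2))
  i_pk <- peak_time(tr)
  expect_lt(abs(i_pk * dt - d_min / 1500), 2.5 * dt)
})

test_that("a pulse crossing the PML re-enters far below the outgoing peak", {
  g <- make_grid(c(128, 128), 0.5e-3)
  med <- water_medium(g, c0 = 1482)
  p0 <- exp(-outer(grid_axes(g)[[1]]^2, grid_axes(g)[[2]]^2, `+`) / (2e-3)^2)
  probe <- matrix(c(20e-3, 0), 1)
  tr <- run_elastic(init_from_p0(p0, g), med, nt = 400, dt = 1e-7,
                    pml = pml_config(10), sensors = probe)$trace_p[1, ]
  # reference: same physics on a domain so large that no boundary is seen
  gbig <- make_grid(c(512, 512), 0.5e-3)
  medb <- water_medium(gbig, c0 = 1482)
  p0b <- exp(-outer(grid_axes(gbig)[[1]]^2, grid_axes(gbig)[[2]]^2, `+`) / (2e-3)^2)
  trb <- run_elastic(init_from_p0(p0b, gbig), medb, nt = 400, dt = 1e-7,
                     pml = pml_config(0), sensors = probe)$trace_p[1, ]
  expect_lt(max(abs(tr - trb)), 0.01 * max(abs(trb)))
})

test_that("oblique incidence converts compression to shear; normal does not", {
  g <- make_grid(c(128, 128), 0.5e-3)
  mask <- array(FALSE, g$shape); mask[80:100, ] <- TRUE
  med <- assign_properties(mask, c(1850, 2800, 1250), c(1000, 1482), g)
  ax <- grid_axes(g)[[1]]; ay <- grid_axes(g)[[2]]
  shear_frac <- function(p0, pml) {
    st <- run_elastic(init_from_p0(p0, g), med, nt = 440, dt = 5e-8,
                      pml = pml, record = character(0))$state
    sum(st$sigma$xy[mask]^2) /
      sum(((st$sigma$xx[mask] + st$sigma$yy[mask]) / 2)^2)
  }
  stripe <- outer(exp(-((ax - ax[40]) / 1.5e-3)^2), rep(1, 128))
  expect_lt(shear_frac(stripe, pml_config(0)), 1e-6)
  blob <- exp(-outer((ax - ax[40])^2, (ay - 8e-3)^2, `+`) / (2e-3)^2)
  expect_gt(shear_frac(blob, pml_config(10)), 1e-2)
})

test_that("the solver aborts with a diagnostic when driven unstably", {
  g <- make_grid(c(48, 48), 0.5e-3)
  med <- solid_medium(g)
  p0 <- exp(-outer(grid_axes(g)[[1]]^2, grid_axes(g)[[2]]^2, `+`) / (2e-3)^2)
  expect_error(run_elastic(init_from_p0(p0, g), med, nt = 400, dt = 4e-7,
                           pml = pml_config(0), record = character(0)),
               "unstable")
})
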