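test_that("speeds_to_lame reproduces closed-form values and round-trips", {
  w <- speeds_to_lame(1000, 1500, 0)
  expect_equal(w$lam, 2.25e9)
  expect_equal(w$mu, 0)
  s1 <- speeds_to_lame(1850, 2800, 1250)   # cranial bone, skull 1
  expect_equal(s1$mu, 2.890625e9)
  expect_equal(s1$lam, 8.72275e9)
  s2 <- speeds_to_lame(1850, 2800, 1400)   # skull 2
  expect_equal(s2$mu, 3.626e9)
  expect_equal(s2$lam, 1850 * (2800^2 - 2 * 1400^2))  # 7.252e9
  # round-trip property on random valid inputs
  set.seed(1)
  for (i in 1:25) {
    rho <- runif(1, 900, 2500)
    cp <- runif(1, 1000, 4000)
    cs <- runif(1, 0, cp / sqrt(2) * 0.95)
    lm <- speeds_to_lame(rho, cp, cs)
    sp <- lame_to_speeds(rho, lm$lam, lm$mu)
    expect_equal(sp$cp, cp, tolerance = 1e-12)
    expect_equal(sp$cs, cs, tolerance = 1e-12)
  }
  expect_error(speeds_to_lame(1000, 1500, 1490), "bulk modulus")
  expect_error(speeds_to_lame(-1, 1500, 0), "density")
})

test_that("grid index/coordinate maps round-trip and invariants hold", {
  g <- make_grid(c(32, 40), c(0.5e-3, 1e-3), origin = c(-4e-3, 2e-3))
  idx <- cbind(c(1, 10, 32), c(1, 20, 40))
  xyz <- index_to_coord(g, idx)
  expect_equal(coord_to_index(g, xyz), idx, ignore_attr = TRUE)
  expect_equal(xyz[1, ], c(-4e-3, 2e-3))
  expect_error(make_grid(c(4, 32), 1e-3), ">= 8")
  expect_error(make_grid(c(32, 32), -1e-3), "positive")
})

test_that("six points per wavelength at the filter cutoff gives the grid spacing", {
  expect_equal(wavelength_spacing(0.5e6, sos = 1500), 0.5e-3)
})

test_that("Kabsch recovers exact rigid motions and reports zero residual", {
  set.seed(2)
  src <- matrix(rnorm(18, sd = 0.03), 6, 3)
  fit0 <- kabsch_register(src, src)
  expect_equal(fit0$rotation, diag(3), tolerance = 1e-12)
  expect_equal(fit0$translation, rep(0, 3), tolerance = 1e-12)
  expect_lt(fit0$rmsd, 1e-14)
  R90 <- rotation_about_axis(90, 3)
  tr <- rigid_transform(R90, c(0.01, 0, 0))
  fit <- kabsch_register(src, apply_rigid(tr, src))
  expect_lt(max(abs(fit$rotation - R90)), 1e-10)
  expect_lt(max(abs(fit$translation - c(0.01, 0, 0))), 1e-10)
})

test_that("Kabsch attains the brute-force optimum under noise (2-D)", {
  set.seed(3)
  src <- matrix(rnorm(12, sd = 0.04), 6, 2)
  ang0 <- 23 * pi / 180
  R0 <- matrix(c(cos(ang0), sin(ang0), -sin(ang0), cos(ang0)), 2, 2)
  dst <- src %*% t(R0) + matrix(c(0.011, -0.007), 6, 2, byrow = TRUE) +
    matrix(rnorm(12, sd = 1e-3), 6, 2)
  fit <- kabsch_register(src, dst)
  # exhaustive search over rotation angle; optimal translation is closed
  # form given the rotation (centroid matching)
  sse <- function(ang) {
    R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
    tt <- colMeans(dst) - as.numeric(R %*% colMeans(src))
    sum((sweep(src %*% t(R), 2, tt, `+`) - dst)^2)
  }
  angles <- seq(ang0 - 0.1, ang0 + 0.1, by = 1e-5)
  best <- min(vapply(angles, sse, 0))
  rmsd_brute <- sqrt(best / nrow(src))
  expect_lt(abs(fit$rmsd - rmsd_brute), 1e-9)
})

test_that("Kabsch is equivariant under pre-rotation and rejects degeneracy", {
  set.seed(4)
  for (i in 1:5) {
    src <- matrix(rnorm(15, sd = 0.02), 5, 3)
    tr <- rigid_transform(rotation_about_axis(runif(1, -40, 40), sample(3, 1)),
                          rnorm(3, sd = 5e-3))
    dst <- apply_rigid(tr, src)
    Q <- rotation_about_axis(runif(1, -90, 90), sample(3, 1))
    fit1 <- kabsch_register(src, dst)
    fit2 <- kabsch_register(src %*% t(Q), dst %*% t(Q))
    expect_equal(fit2$rotation, Q %*% fit1$rotation %*% t(Q), tolerance = 1e-9)
  }
  line <- cbind(seq_len(5), 0, 0) * 1e-3   # collinear points
  expect_error(kabsch_register(line, line + 1e-3), "degenerate")
})

test_that("binarization fills enclosed pores but preserves the cavity", {
  g <- make_grid(c(96, 96), 0.5e-3)
  r <- sqrt(outer(grid_axes(g)[[1]]^2, grid_axes(g)[[2]]^2, `+`))
  vol <- 1.0 * (r >= 12e-3 & r <= 19e-3)
  # puncture 10 pores inside the annulus wall
  set.seed(5)
  ang <- seq(0, 2 * pi, length.out = 11)[1:10]
  for (a in ang) {
    cx <- 15.5e-3 * cos(a); cy <- 15.5e-3 * sin(a)
    rp <- sqrt(outer((grid_axes(g)[[1]] - cx)^2, (grid_axes(g)[[2]] - cy)^2, `+`))
    vol[rp < 1e-3] <- 0
  }
  m <- binarize_fill_mask(vol, g, threshold = 0.5, closing_radius = 0)
  labs <- label_components(!m$mask)
  # only exterior + cavity remain as non-bone components
  expect_equal(max(labs), 2L)
  # cavity intact: centre voxel is non-bone
  expect_false(m$mask[48, 48])
  # pores filled: annulus interior solid
  expect_true(all(m$mask[r >= 13e-3 & r <= 18e-3]))
  # idempotent on a hole-free binary input
  clean <- 1.0 * (r >= 12e-3 & r <= 19e-3)
  m2 <- binarize_fill_mask(clean, g, threshold = 0.5, closing_radius = 0)
  expect_equal(m2$mask, clean > 0.5)
  expect_error(binarize_fill_mask(array(0, g$shape), g), "constant")
  expect_error(binarize_fill_mask(vol, g, threshold = -1), "uniformly")
})

test_that("mask rasterisation is exact for identity and integer shifts", {
  g <- make_grid(c(64, 64), 0.5e-3)
  r <- sqrt(outer(grid_axes(g)[[1]]^2, grid_axes(g)[[2]]^2, `+`))
  m <- skull_mask(r >= 8e-3 & r <= 14.5e-3, g)
  ident <- rigid_transform(diag(2), c(0, 0))
  expect_equal(rasterize_mask(m, ident, g)$mask, m$mask)
  shift <- rigid_transform(diag(2), c(3, -2) * 0.5e-3)
  shifted <- rasterize_mask(m, shift, g)$mask
  expect_equal(shifted[10:60, 10:60], m$mask[(10:60) - 3, (10:60) + 2])
  expect_error(rasterize_mask(m, rigid_transform(diag(2), c(1, 0)), g),
               "outside")
})

test_that("rotating a 6.5 mm shell by +10 then -10 degrees preserves it", {
  g <- make_grid(c(128, 128), 0.5e-3)
  r <- sqrt(outer((grid_axes(g)[[1]] - 2e-3)^2, (grid_axes(g)[[2]] + 1e-3)^2, `+`))
  m <- skull_mask(r >= 14e-3 & r <= 20.5e-3, g)
  rot <- function(deg) rigid_transform(rotation_about_axis(deg, dim = 2), c(0, 0))
  back <- rasterize_mask(rasterize_mask(m, rot(10), g), rot(-10), g)
  expect_gte(jaccard(back, m), 0.95)
})

test_that("property assignment produces exactly two phases and the acoustic variant", {
  g <- make_grid(c(32, 32), 1e-3)
  mask <- array(FALSE, g$shape); mask[10:20, 12:22] <- TRUE
  med <- assign_properties(mask, c(1850, 2800, 1250), c(1000, 1500), g)
  trip <- unique(data.frame(rho = as.vector(med$rho), lam = as.vector(med$lam),
                            mu = as.vector(med$mu)))
  expect_equal(nrow(trip), 2L)
  expect_true(all(med$mu[!mask] == 0))
  # empty mask: homogeneous water
  medw <- assign_properties(array(FALSE, g$shape), c(1850, 2800, 1250),
                            c(1000, 1500), g)
  expect_equal(length(unique(as.vector(medw$lam))), 1L)
  # acoustic-only: cs = 0 in bone
  meda <- assign_properties(mask, c(1850, 2800, 0), c(1000, 1500), g)
  expect_true(all(meda$mu == 0))
  expect_equal(unique(as.vector(meda$lam[mask])), 1850 * 2800^2)  # 1.4504e10
})

test_that("fiducial CSV round-trips through the documented format", {
  pts <- matrix(rnorm(9, sd = 0.02), 3, 3)
  f <- tempfile(fileext = ".csv")
  write_fiducials_csv(pts, f)
  back <- read_fiducials_csv(f)
  expect_equal(unname(back), unname(pts))
  expect_equal(colnames(back), c("x", "y", "z"))
  unlink(f)
})
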