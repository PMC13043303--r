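# lazily built, cached fixtures shared across test files (wave solves are
# the dominant cost; each is built at most once per test run)
.fx_cache <- new.env(parent = emptyenv())

get_fixture <- function() {
  if (is.null(.fx_cache$fx)) .fx_cache$fx <- transcranial_fixture(seed = 7)
  .fx_cache$fx
}

fx_crop <- function(fx, img) img[fx$roi_idx, fx$roi_idx]

get_fixture_ubp <- function() {
  fx <- get_fixture()
  if (is.null(.fx_cache$ubp))
    .fx_cache$ubp <- pact_reconstruct(fx$data, fx$sensors, "ubp",
                                      sos = fx$sos_water, roi = fx$roi_grid,
                                      fc = fx$fc)
  .fx_cache$ubp
}

get_fixture_adjoint <- function(model = NULL) {
  fx <- get_fixture()
  if (is.null(model)) {
    if (is.null(.fx_cache$adj))
      .fx_cache$adj <- adjoint_reconstruct(fx$data, fx$model$medium, fx$sensors,
                                           fx$pml, fx$fc, roi = fx$roi_mask)
    return(.fx_cache$adj)
  }
  adjoint_reconstruct(fx$data, model$medium, fx$sensors, fx$pml, fx$fc,
                      roi = fx$roi_mask)
}

get_fixture_iterative <- function() {
  fx <- get_fixture()
  if (is.null(.fx_cache$it))
    .fx_cache$it <- pact_reconstruct(fx$data, fx$sensors, "iterative",
                                     medium = fx$model$medium,
                                     config = fx$config, pml = fx$pml,
                                     fc = fx$fc, roi = fx$roi_mask)
  .fx_cache$it
}

.gauss_smooth_test <- function(x) depact:::.gauss_blur(x, 1.5)

.write_cfg <- function(lst) {
  f <- tempfile(fileext = ".yaml")
  yaml::write_yaml(lst, f)
  f
}

water_medium <- function(grid, rho = 1000, c0 = 1500) {
  assign_properties(array(FALSE, grid$shape), c(1850, 2800, 1250),
                    c(rho, c0), grid)
}

solid_medium <- function(grid, rho = 1850, cp = 2800, cs = 1250) {
  assign_properties(array(TRUE, grid$shape), c(rho, cp, cs), c(1000, 1500),
                    grid)
}
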