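.log <- function(stage, msg, logfile = NULL) {
  line <- sprintf("[%s] %s: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%OS3"),
                  stage, msg)
  message(line)
  if (!is.null(logfile)) cat(line, "\n", file = logfile, append = TRUE)
}

.cfg_medium <- function(cfg, grid) {
  water <- c(cfg$medium$water_rho, water_sos(cfg$medium$water_temperature))
  if (!is.null(cfg$medium$mask_file)) {
    mv <- read_volume_nii(cfg$medium$mask_file)
    mask <- skull_mask(mv$volume > 0, mv$grid, "CT")
    med <- assign_properties(mask, c(cfg$medium$skull_rho, cfg$medium$skull_cp,
                                     cfg$medium$skull_cs), water)
    structure(list(medium = med, mask = mask,
                   skull = c(cfg$medium$skull_rho, cfg$medium$skull_cp,
                             cfg$medium$skull_cs),
                   water = water, grid = mv$grid,
                   centre = rep(0, mv$grid$dim)),
              class = "skull_model")
  } else {
    make_skull_shell(skull_shell_spec(cfg$medium$shell_inner_radius,
                                      cfg$medium$shell_thickness,
                                      cfg$medium$skull_rho, cfg$medium$skull_cp,
                                      cfg$medium$skull_cs,
                                      centre = cfg$medium$shell_centre),
                     grid, water)
  }
}

.cfg_sensors <- function(cfg) {
  if (cfg$sensors$type == "circle")
    make_circular_array(cfg$sensors$radius, cfg$sensors$n_elements)
  else
    make_hemispherical_array(cfg$sensors$radius, cfg$sensors$n_arcs,
                             cfg$sensors$n_elements, cfg$sensors$n_rotations)
}

#' Run one pipeline stage
#'
#' Deterministic, seeded pipeline stages writing their artifacts to
#' `cfg$paths$out`:
#' \describe{
#'   \item{simulate}{phantom + skull shell forward simulation; writes
#'     `data.h5`, `p0_truth.nii.gz`, `skull_mask.nii.gz`, `manifest.yaml`}
#'   \item{reconstruct}{iterative or adjoint reconstruction of
#'     `paths$data`; writes `p0_hat.nii.gz` and `objective.csv`}
#'   \item{ubp}{universal backprojection baseline; writes `p0_ubp.nii.gz`}
#'   \item{register}{Kabsch registration of fiducial CSVs; writes
#'     `transform.yaml`}
#'   \item{perturb}{perturbed skull model; writes `skull_mask_perturbed.nii.gz`}
#'   \item{evaluate}{metrics CSV (`metrics.csv`) comparing `paths$test`
#'     with `paths$reference`}
#' }
#'
#' @param subcommand one of simulate, reconstruct, ubp, register, perturb,
#'   evaluate
#' @param config a `run_config` or path to a YAML file
#' @return named list of written artifact paths, invisibly
#' @export
run_pipeline <- function(subcommand = c("simulate", "reconstruct", "ubp",
                                        "register", "perturb", "evaluate"),
                         config) {
  subcommand <- match.arg(subcommand)
  cfg <- if (inherits(config, "run_config")) config else load_config(config)
  out_dir <- cfg$paths$out
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(out_dir, "log.txt")
  echo <- file.path(out_dir, "config_resolved.yaml")
  save_config(cfg, echo)
  .log(subcommand, sprintf("config hash %s", unname(tools::md5sum(echo))), logfile)
  grid <- make_grid(cfg$grid$shape, cfg$grid$spacing, cfg$grid$origin)
  pml <- pml_config(cfg$solver$pml_thickness, cfg$solver$pml_order)
  arts <- list(config = echo)
  if (subcommand == "simulate") {
    model <- .cfg_medium(cfg, grid)
    sensors <- .cfg_sensors(cfg)
    ph <- phantom_spec(seed = cfg$seeds$phantom)
    p0 <- make_vessel_phantom(ph, grid)
    p0[model$mask$mask] <- 0
    sim <- simulate_dataset(p0, model$medium, sensors, cfg$solver$nt,
                            cfg$solver$dt, noise_sigma = 0, pml = pml)
    sim$data$meta <- "pipeline simulate"
    arts$data <- file.path(out_dir, "data.h5")
    write_sensor_h5(sim$data, arts$data)
    arts$truth <- file.path(out_dir, "p0_truth.nii.gz")
    write_volume_nii(p0, grid, arts$truth)
    arts$mask <- file.path(out_dir, "skull_mask.nii.gz")
    write_volume_nii(model$mask$mask, grid, arts$mask, mask = TRUE)
    arts$manifest <- file.path(out_dir, "manifest.yaml")
    yaml::write_yaml(list(seeds = cfg$seeds, artifacts = lapply(arts, basename)),
                     arts$manifest)
    .log(subcommand, sprintf("wrote %s", paste(basename(unlist(arts)), collapse = ", ")),
         logfile)
  } else if (subcommand %in% c("reconstruct", "ubp")) {
    if (is.null(cfg$paths$data) || !file.exists(cfg$paths$data))
      stop(sprintf("reconstruct: data file '%s' not found", cfg$paths$data))
    data <- read_sensor_h5(cfg$paths$data)
    sensors <- sensor_array(data$positions)
    if (subcommand == "ubp") {
      sos <- if (!is.null(cfg$recon$sos)) cfg$recon$sos else
        water_sos(cfg$medium$water_temperature)
      rec <- pact_reconstruct(data, sensors, "ubp", sos = sos, roi = grid)
      arts$image <- file.path(out_dir, "p0_ubp.nii.gz")
    } else {
      model <- .cfg_medium(cfg, grid)
      rc <- recon_config(cfg$recon$l1_weight, cfg$recon$tv_weight,
                         cfg$recon$n_outer, cfg$recon$n_inner_tv,
                         cfg$recon$step_safety, cfg$recon$power_iters,
                         cfg$seeds$power, cfg$recon$nonneg)
      rec <- pact_reconstruct(data, sensors, cfg$recon$method,
                              medium = model$medium, config = rc, pml = pml,
                              fc = cfg$recon$fc,
                              filter_order = cfg$recon$filter_order)
      if (!is.null(rec$objective_trace)) {
        arts$objective <- file.path(out_dir, "objective.csv")
        utils::write.csv(data.frame(iteration = seq_along(rec$objective_trace) - 1,
                                    objective = rec$objective_trace),
                         arts$objective, row.names = FALSE)
      }
      arts$image <- file.path(out_dir, "p0_hat.nii.gz")
    }
    write_volume_nii(rec$p0_hat, grid, arts$image)
    .log(subcommand, sprintf("wrote %s", basename(arts$image)), logfile)
  } else if (subcommand == "register") {
    src <- read_fiducials_csv(cfg$paths$fiducials_src)
    dst <- read_fiducials_csv(cfg$paths$fiducials_dst)
    tr <- kabsch_register(src, dst)
    arts$transform <- file.path(out_dir, "transform.yaml")
    yaml::write_yaml(list(rotation = as.list(as.data.frame(tr$rotation)),
                          translation = as.numeric(tr$translation),
                          rmsd = tr$rmsd), arts$transform)
    .log(subcommand, sprintf("RMSD %.3g m", tr$rmsd), logfile)
  } else if (subcommand == "perturb") {
    model <- .cfg_medium(cfg, grid)
    pert <- perturb_model(model, cfg$perturb$kind,
                          magnitude = cfg$perturb$magnitude,
                          axis = cfg$perturb$axis)
    arts$mask <- file.path(out_dir, "skull_mask_perturbed.nii.gz")
    write_volume_nii(pert$mask$mask, grid, arts$mask, mask = TRUE)
    .log(subcommand, sprintf("%s applied", cfg$perturb$kind), logfile)
  } else if (subcommand == "evaluate") {
    tv <- read_volume_nii(cfg$paths$test)
    rv <- read_volume_nii(cfg$paths$reference)
    ti <- tv$volume; ri <- rv$volume
    if (length(dim(ti)) == 3) { ti <- map_projection(ti, 3); ri <- map_projection(ri, 3) }
    pair <- image_pair(ti, ri)
    met <- data.frame(cc = image_correlation(pair),
                      sliding_cc = as.numeric(sliding_correlation(pair)),
                      ssim = image_ssim(pair))
    arts$metrics <- file.path(out_dir, "metrics.csv")
    utils::write.csv(met, arts$metrics, row.names = FALSE)
    .log(subcommand, sprintf("CC %.3f, sliding %.3f, SSIM %.3f",
                             met$cc, met$sliding_cc, met$ssim), logfile)
  }
  invisible(arts)
}
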