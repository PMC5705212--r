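#' Scenario configuration
#'
#' Builds and validates the configuration of a named simulation scenario.
#' The registry covers the model's experiments: `control` (the full 90-step
#' looping model), `minimal_buckling` (homogeneous growth between fixed
#' poles, optional small single-pole asymmetry), `no_asymmetry` (the control
#' sweep setup with both pole asymmetries off), `free_poles`, `no_dm`,
#' `persistent_dm`, `reduced_lr` (both asymmetries scaled by `lr_scale`),
#' `arterial_burst_variant` (rotation replaced by a ventral-left
#' longitudinal burst at the arterial pole), and `sweep` (one cell of the
#' parameter sweeps: no ventricle inflation, 80 steps).
#'
#' @param scenario scenario id.
#' @param ... overrides of any configuration field (e.g. `n_steps`,
#'   `n_circ`, `n_axial`, `burst_peak`, `rotation_rate`, `rotation_sign`,
#'   `burst_azimuth`, `asym_fraction`, `lr_scale`, `schedule`, `material`,
#'   `params`, `seed`).
#' @return validated config list (class `scenario_config`).
#' @export
scenario_config <- function(scenario = "control", ...) {
  cfg <- list(
    scenario = scenario,
    n_steps = 90L,
    n_circ = 30L, n_axial = 30L,
    radius = 0.15, length = 1, thickness = 0.05,
    smoothing_width = 2,
    gradient_width = 0.5,
    burst_width = 0.3,
    variant = "standard",
    params = growth_params(),
    lr_scale = 1,
    asym_fraction = 0.05,
    burst_azimuth = 270,
    burst_peak = 0.07,
    rotation_rate = 0.011,
    rotation_sign = 1,
    schedule = list(start = 10L, half_free = 45L, full_free = 80L),
    material = list(E = 1, nu = 0.3),
    strain_retention = 0,
    growth_accumulation = "linear",
    recompute_polarizer = TRUE,
    tol = 1e-8,
    seed = 1L
  )
  defaults <- switch(scenario,
    control = list(),
    minimal_buckling = list(variant = "minimal", n_steps = 90L),
    no_asymmetry = list(n_steps = 80L, burst_peak = 0, rotation_rate = 0),
    free_poles = list(variant = "free_poles"),
    no_dm = list(variant = "no_dm"),
    persistent_dm = list(variant = "persistent_dm"),
    reduced_lr = list(lr_scale = 0.5),
    arterial_burst_variant = list(),
    sweep = list(n_steps = 80L),
    stop("unknown scenario: ", scenario)
  )
  cfg[names(defaults)] <- defaults
  ov <- list(...)
  bad <- setdiff(names(ov), names(cfg))
  if (length(bad)) stop("unknown config field(s): ",
                        paste(bad, collapse = ", "))
  cfg[names(ov)] <- ov
  validate_config(cfg)
}

validate_config <- function(cfg) {
  if (inherits(cfg, "scenario_config")) return(cfg)
  if (cfg$n_steps < 10) stop("n_steps must be >= 10")
  if (cfg$burst_azimuth < 0 || cfg$burst_azimuth >= 360)
    stop("burst_azimuth must be in [0, 360)")
  if (cfg$rotation_rate < 0 || cfg$rotation_rate > 0.05)
    stop("rotation_rate outside sanity bounds")
  if (cfg$burst_peak < 0 || cfg$burst_peak > 0.15)
    stop("burst_peak outside sanity bounds")
  if (!cfg$variant %in%
      c("standard", "free_poles", "no_dm", "persistent_dm", "minimal"))
    stop("unknown constraint variant: ", cfg$variant)
  if (cfg$lr_scale < 0) stop("lr_scale must be >= 0")
  if (!cfg$growth_accumulation %in% c("linear", "compound"))
    stop("growth_accumulation must be 'linear' or 'compound'")
  if (!is.numeric(cfg$seed)) stop("seed must be numeric")
  structure(cfg, class = "scenario_config")
}

# the per-step growth program function of a configured scenario
scenario_program <- function(cfg) {
  p <- cfg$params
  switch(cfg$scenario,
    control = function(step, regions)
      control_program(step, regions, p, rotation_sign = cfg$rotation_sign),
    persistent_dm = ,
    free_poles = ,
    no_dm = function(step, regions)
      control_program(step, regions, p, rotation_sign = cfg$rotation_sign),
    reduced_lr = function(step, regions)
      control_program(step, regions, p, lr_scale = cfg$lr_scale,
                      rotation_sign = cfg$rotation_sign),
    arterial_burst_variant = variant_program("arterial_burst_variant",
                                             params = p),
    minimal_buckling = function(step, regions)
      minimal_buckling_program(step, regions, cfg$asym_fraction, p),
    no_asymmetry = ,
    sweep = function(step, regions)
      sweep_program(step, regions, cfg$burst_azimuth, cfg$burst_peak,
                    cfg$rotation_rate, cfg$rotation_sign, p),
    stop("unknown scenario: ", cfg$scenario)
  )
}

#' Run a named scenario end to end
#'
#' Simulates the scenario, extracts the final-state morphometrics and
#' classifies the output shape.
#'
#' @param name scenario id (see [scenario_config()]).
#' @param ... configuration overrides.
#' @return list with `trajectory`, `report`, `shape`.
#' @export
run_named_scenario <- function(name, ...) {
  cfg <- scenario_config(name, ...)
  traj <- simulate_looping(cfg)
  rep <- morphometrics_report(traj)
  list(trajectory = traj, report = rep, shape = rep$shape_class)
}

#' Parameter-space sweep and phase diagram
#'
#' Runs the 80-step no-inflation model over a grid of pole-asymmetry
#' parameters and classifies every output shape.
#' Mode `position_intensity`: venous burst azimuth x intensity ratio, with
#' the arterial rotation fixed (both directions). Mode `pole_intensities`:
#' venous burst intensity x arterial rotation rate at fixed azimuth 270.
#'
#' @param mode `"position_intensity"` or `"pole_intensities"`.
#' @param azimuths,ratios,rotation_rates grid overrides.
#' @param rotation_signs directions of the arterial rotation to include.
#' @param ... configuration overrides applied to every cell (e.g. a reduced
#'   `n_circ`/`n_axial` resolution).
#' @return data.frame of class `phase_diagram`: one row per grid cell with
#'   the classification and key morphometrics.
#' @export
sweep_phase_space <- function(mode = c("position_intensity",
                                       "pole_intensities"),
                              azimuths = c(0, 90, 180, 270),
                              ratios = c(1, 1.8, 2.8, 3.8, 4.8),
                              rotation_rates = c(0, 0.011, 0.022, 0.03),
                              rotation_signs = 1,
                              ...) {
  mode <- match.arg(mode)
  baseline <- growth_params()$baseline
  grid <- switch(mode,
    position_intensity = expand.grid(azimuth = azimuths, ratio = ratios,
                                     rot_rate = 0.011,
                                     rot_sign = rotation_signs),
    pole_intensities = expand.grid(azimuth = 270, ratio = ratios,
                                   rot_rate = rotation_rates,
                                   rot_sign = rotation_signs))
  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    res <- run_named_scenario("sweep",
                              burst_azimuth = g$azimuth,
                              burst_peak = g$ratio * baseline,
                              rotation_rate = g$rot_rate,
                              rotation_sign = g$rot_sign, ...)
    rp <- res$report
    out[[i]] <- data.frame(
      azimuth = g$azimuth, ratio = g$ratio, rotation_rate = g$rot_rate,
      rotation_sign = g$rot_sign, shape = rp$shape_class,
      tube_length = rp$tube_length, sector = rp$transverse_sector_deg,
      planarity = rp$shape_metrics$planarity,
      torsion = rp$shape_metrics$torsion)
  }
  structure(do.call(rbind, out), class = c("phase_diagram", "data.frame"))
}

#' Control-vs-mutant comparison of the four geometric parameters
#'
#' Signed differences and ratios (mutant relative to control) of tube
#' length, RV-LV angle, mean perimeter and transverse sector - the four
#' quantitative predictions distinguishing a persistent dorsal mesocardium
#' from the control (length down, RV-LV angle down, perimeter up, sector
#' down).
#'
#' @param control,mutant `morphometrics_report` objects at the same mesh
#'   resolution.
#' @return data.frame with one row per parameter.
#' @export
compare_mutant <- function(control, mutant) {
  if (!identical(control$resolution, mutant$resolution))
    stop("reports come from different mesh resolutions")
  pars <- c(tube_length = "tube_length",
            rv_lv_angle_deg = "rv_lv_angle_deg",
            mean_perimeter = "mean_perimeter",
            transverse_sector_deg = "transverse_sector_deg")
  data.frame(
    parameter = names(pars),
    control = vapply(pars, function(p) control[[p]], numeric(1)),
    mutant = vapply(pars, function(p) mutant[[p]], numeric(1)),
    delta = vapply(pars, function(p) mutant[[p]] - control[[p]], numeric(1)),
    ratio = vapply(pars, function(p) mutant[[p]] / control[[p]], numeric(1)),
    row.names = NULL)
}

#' Centre of the helix-classified burst-intensity window
#'
#' Sweeps the venous burst intensity ratio at fixed arterial rotation and
#' burst azimuth, classifies each output, and returns the centre of the
#' contiguous helix-classified window (NA if no cell classifies as a helix).
#'
#' @param ratios burst intensity ratios (right/left growth) to sweep.
#' @param ... configuration overrides for each run (resolution etc.).
#' @return list with `centre`, `window` (ratio range), and the sweep table.
#' @export
helix_window <- function(ratios = c(1, 1.6, 2.2, 2.8, 3.4, 4, 4.6), ...) {
  tab <- sweep_phase_space("pole_intensities", ratios = ratios,
                           rotation_rates = 0.011, rotation_signs = 1, ...)
  hel <- tab$shape %in% c("helix_ccw", "helix_cw")
  if (!any(hel)) return(list(centre = NA_real_, window = c(NA, NA),
                             table = tab))
  runs <- rle(hel)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  wi <- which(runs$values)
  wi <- wi[which.max(runs$lengths[wi])]
  idx <- starts[wi]:ends[wi]
  window <- range(tab$ratio[idx])
  list(centre = mean(window), window = window, table = tab)
}
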