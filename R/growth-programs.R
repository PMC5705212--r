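#' Default growth parameters of the looping model
#'
#' The six growth inputs of the control simulation, as per-step fractional
#' rates, plus the phase windows on the absolute step counter (steps are
#' 0-based; steps 0-9 are field-setup steps with zero growth):
#' \itemize{
#'   \item `baseline` 2.5\%/step longitudinal growth in every element;
#'   \item `ventral_peak` 5\%/step total at the centre of the ventral spot,
#'     active until `ventral_until` (step 40);
#'   \item `rot_rate` 1.1\%/step circumferential growth, positive on the
#'     left and negative on the right, in a gradient from the arterial pole
#'     to mid-length, active until `rot_until` (step 30) - calibrated to
#'     rotate the arterial pole by about 25 degrees;
#'   \item `burst_peak` 7\%/step longitudinal growth at the right side
#'     (azimuth 270) of the venous pole, decaying smoothly to the 2.5\%
#'     baseline on the left, active steps `burst_from`-`burst_until` (30-60);
#'   \item `rv_inflation` 0.9\% and `lv_inflation` 1.4\% circumferential
#'     growth in the right/left ventricle bands, the RV rate reduced to
#'     0.4\% (`inhibited_rate`) in the dorsal-left inhibition zone.
#' }
#' @param ... overrides of any default.
#' @return named list of parameters.
#' @export
growth_params <- function(...) {
  p <- list(
    baseline = 0.025,
    ventral_peak = 0.05,
    rot_rate = 0.011,
    burst_peak = 0.07,
    burst_azimuth = 270,
    rv_inflation = 0.009,
    lv_inflation = 0.014,
    inhibited_rate = 0.004,
    setup_steps = 10L,
    ventral_until = 40L,
    rot_until = 30L,
    burst_from = 30L,
    burst_until = 60L
  )
  ov <- list(...)
  bad <- setdiff(names(ov), names(p))
  if (length(bad)) stop("unknown growth parameter(s): ",
                        paste(bad, collapse = ", "))
  p[names(ov)] <- ov
  p
}

empty_spec <- function(m) {
  list(k_par = numeric(m), k_per = numeric(m), k_thk = numeric(m))
}

sanity_check_spec <- function(spec) {
  if (any(!is.finite(spec$k_par)) || any(!is.finite(spec$k_per)))
    stop("non-finite growth rate")
  if (any(spec$k_par < -0.01 - 1e-12) || any(spec$k_par > 0.15 + 1e-12) ||
      any(abs(spec$k_per) > 0.05 + 1e-12))
    stop("growth rates outside sanity bounds")
  spec
}

#' Control-scenario growth program
#'
#' Per-step, per-element specified growth for the full looping model:
#' baseline longitudinal growth, ventral spot, arterial rotation by
#' left/right circumferential asymmetry, venous right-sided burst, and
#' ventricle inflation, each in its phase window. Steps below
#' `params$setup_steps` return zero growth.
#'
#' @param step 0-based step index (0..90).
#' @param regions [build_region_fields()] output.
#' @param params [growth_params()] list.
#' @param lr_scale scale applied to both left-right asymmetries (arterial
#'   circumferential amplitude and the venous burst's excess over baseline);
#'   1 is the control, 0.5 the reduced-asymmetry condition.
#' @param rotation_sign +1 for the control rightward arterial rotation.
#' @param inflation logical; include ventricle inflation (the parameter
#'   sweeps exclude it).
#' @return list with per-element `k_par`, `k_per`, `k_thk`.
#' @export
control_program <- function(step, regions, params = growth_params(),
                            lr_scale = 1, rotation_sign = 1,
                            inflation = TRUE) {
  if (step < 0 || step > 200) stop("step out of range")
  m <- length(regions$azimuth)
  spec <- empty_spec(m)
  if (step < params$setup_steps) return(spec)

  spec$k_par <- rep(params$baseline, m)
  if (step < params$ventral_until)
    spec$k_par <- spec$k_par +
      (params$ventral_peak - params$baseline) * regions$ventral_spot
  if (step >= params$burst_from && step < params$burst_until)
    spec$k_par <- spec$k_par +
      lr_scale * (params$burst_peak - params$baseline) *
      burst_profile(regions$azimuth, params$burst_azimuth) *
      regions$venous_gradient
  if (step < params$rot_until)
    spec$k_per <- spec$k_per +
      rotation_sign * lr_scale * params$rot_rate *
      regions$sin_azimuth * regions$arterial_gradient
  if (inflation) {
    rv_rate <- params$rv_inflation -
      (params$rv_inflation - params$inhibited_rate) *
      regions$dorsal_left_inhibition
    spec$k_per <- spec$k_per + regions$rv_band * rv_rate +
      regions$lv_band * params$lv_inflation
  }
  sanity_check_spec(spec)
}

#' Minimal buckling growth program
#'
#' Homogeneous longitudinal growth of a tube between fixed poles, optionally
#' with a small time-limited left-sided burst at the arterial pole
#' (`asym_fraction` of the baseline rate, default window steps 10-20) that
#' seeds the buckling direction, mimicking stochastic left-right variation.
#'
#' @param step 0-based step index.
#' @param regions [build_region_fields()] output.
#' @param asym_fraction extra growth on the burst side as a fraction of
#'   baseline (0 = perfectly symmetric; the minimal model uses 0.05).
#' @param params [growth_params()].
#' @param burst_window step window of the asymmetric burst.
#' @param burst_azimuth azimuth of the burst centre (90 = left).
#' @return growth spec list.
#' @export
minimal_buckling_program <- function(step, regions, asym_fraction = 0,
                                     params = growth_params(),
                                     burst_window = c(10L, 20L),
                                     burst_azimuth = 90) {
  if (asym_fraction < 0) stop("asym_fraction must be >= 0")
  m <- length(regions$azimuth)
  spec <- empty_spec(m)
  if (step < params$setup_steps) return(spec)
  spec$k_par <- rep(params$baseline, m)
  if (asym_fraction > 0 && step >= burst_window[1] && step < burst_window[2])
    spec$k_par <- spec$k_par + asym_fraction * params$baseline *
      burst_profile(regions$azimuth, burst_azimuth) *
      regions$arterial_gradient
  sanity_check_spec(spec)
}

#' Parameter-sweep growth program
#'
#' The control program without ventricle inflation, with the venous burst's
#' azimuth and peak rate and the arterial rotation rate and direction as
#' free parameters. With `burst_azimuth = 270`, `burst_peak = 0.07`,
#' `rotation_rate = 0.011` and `rotation_sign = +1` it coincides with the
#' control program minus inflation.
#'
#' @param step 0-based step index.
#' @param regions [build_region_fields()] output.
#' @param burst_azimuth burst azimuth in `[0, 360)` degrees (270 = right).
#' @param burst_peak peak longitudinal rate of the venous burst
#'   (fraction/step; the burst intensity ratio is `burst_peak / baseline`).
#' @param rotation_rate circumferential asymmetry amplitude (fraction/step).
#' @param rotation_sign +1 rightward (control), -1 leftward.
#' @param params [growth_params()].
#' @return growth spec list.
#' @export
sweep_program <- function(step, regions, burst_azimuth = 270,
                          burst_peak = 0.07, rotation_rate = 0.011,
                          rotation_sign = 1, params = growth_params()) {
  if (burst_azimuth < 0 || burst_azimuth >= 360)
    stop("burst_azimuth must be in [0, 360)")
  if (burst_peak < 0 || burst_peak > 0.15 || rotation_rate < 0 ||
      rotation_rate > 0.05)
    stop("sweep rates outside sanity bounds")
  params$burst_azimuth <- burst_azimuth
  params$burst_peak <- max(burst_peak, params$baseline)
  params$rot_rate <- rotation_rate
  control_program(step, regions, params,
                  rotation_sign = rotation_sign, inflation = FALSE)
}

#' Variant growth programs (mutant hypotheses)
#'
#' Returns the per-step growth program for the named variant scenario:
#' `arterial_burst_variant` replaces the arterial rotation by a longitudinal
#' burst positioned 120 degrees from the venous burst (azimuth 150, a
#' ventral-left position) during the rotation window; `reduced_lr` scales
#' both pole asymmetries by `lr_scale`.
#'
#' @param scenario `"arterial_burst_variant"` or `"reduced_lr"`.
#' @param lr_scale asymmetry scale for `reduced_lr` (default 0.5).
#' @param params [growth_params()].
#' @return `function(step, regions)` returning a growth spec.
#' @export
variant_program <- function(scenario, lr_scale = 0.5,
                            params = growth_params()) {
  if (scenario == "reduced_lr") {
    force(lr_scale)
    return(function(step, regions)
      control_program(step, regions, params, lr_scale = lr_scale))
  }
  if (scenario == "arterial_burst_variant") {
    art_azimuth <- (params$burst_azimuth - 120) %% 360  # 150: ventral-left
    return(function(step, regions) {
      spec <- control_program(step, regions, params, lr_scale = 1,
                              rotation_sign = 0)
      if (step >= params$setup_steps && step < params$rot_until)
        spec$k_par <- spec$k_par +
          (params$burst_peak - params$baseline) *
          burst_profile(regions$azimuth, art_azimuth) *
          regions$arterial_gradient
      sanity_check_spec(spec)
    })
  }
  stop("unknown scenario: ", scenario)
}

#' Specified-growth tensor of one element
#'
#' The symmetric 3x3 tensor with eigenvalues `(1 + k_par, 1 + k_per,
#' 1 + k_thk)` along the element frame's longitudinal, circumferential and
#' wall-normal axes. Negative `k_per` encodes circumferential contraction.
#'
#' @param k_par,k_per,k_thk fractional growth rates.
#' @param frame length-9 orthonormal frame (columns l, c, n).
#' @return 3x3 symmetric positive-definite matrix.
#' @export
growth_tensor <- function(k_par, k_per, k_thk = 0, frame) {
  Fm <- matrix(frame, 3, 3)
  if (max(abs(crossprod(Fm) - diag(3))) > 1e-8)
    stop("frame is not orthonormal")
  Fm %*% diag(c(1 + k_par, 1 + k_per, 1 + k_thk)) %*% t(Fm)
}

# vectorised: m x 9 world-frame growth tensors (column-major per row)
growth_tensors <- function(spec, frames) {
  l <- frames[, 1:3]; cc <- frames[, 4:6]; nn <- frames[, 7:9]
  a <- 1 + spec$k_par; b <- 1 + spec$k_per; d <- 1 + spec$k_thk
  G <- matrix(0, nrow(frames), 9)
  idx <- function(i, j) i + 3 * (j - 1)
  for (i in 1:3) for (j in 1:3)
    G[, idx(i, j)] <- a * l[, i] * l[, j] + b * cc[, i] * cc[, j] +
      d * nn[, i] * nn[, j]
  G
}
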