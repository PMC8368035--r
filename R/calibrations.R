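#' Calibration presets for the synthetic OPL generators
#'
#' Returns the named calibration presets used by [generate_plate()],
#' [generate_dilution_series()] and [generate_neuron_tracks()]. Each preset is
#' a complete parameter set for one well condition; compound-specific truth is
#' expressed as overrides on top of a preset.
#'
#' Presets shipped:
#' \describe{
#'   \item{vehicle}{DMSO-treated wells. Red (photoconverted) Dendra2-LC3 pool
#'     decays with half-life 7.5 h (`k = log(2)/7.5` per hour). Green-channel
#'     photoconversion dip is 40\% (`phi = 0.4`) and the green pool
#'     re-equilibrates with its own turnover rate `k_green` chosen so the dip
#'     recovers to within 5\% of the preconversion level by 13.5 h.
#'     Well-to-well noise CV 6.4\%.}
#'   \item{torin1}{mTOR-inhibitor positive control for induction:
#'     `flux_multiplier = 3`, i.e. red half-life 2.5 h.}
#'   \item{bafilomycin}{V-ATPase-inhibitor positive control for late-stage
#'     inhibition: `flux_multiplier = 0` (no decay) plus a slow late red rise
#'     (`clustering_rate`) mimicking puncta clustering, and
#'     `puncta_clustering = TRUE`.}
#'   \item{cortical, spinal}{Primary-neuron single-cell presets: mean
#'     Dendra2-LC3 half-lives 33.2 h and 37.1 h respectively, common SD 8 h
#'     (the SD is a package default, not a literature value), death hazard
#'     increasing with half-life.}
#' }
#'
#' @return named list of preset parameter lists.
#' @export
opl_calibrations <- function() {
  vehicle <- list(
    half_life_h     = 7.5,            # red (converted pool) half-life, hours
    flux_multiplier = 1,              # scales the decay rate k
    phi             = 0.40,           # green dip at photoconversion
    yield           = 2.5,            # red AU produced per green AU converted
    green_ss        = 1000,           # preconversion green steady state, AU
    k_green         = log(0.40 / 0.05) / 13.5, # green re-equilibration rate /h
    red_bg          = 50,             # preconversion red background, AU
    noise_cv        = 0.064,          # multiplicative log-normal CV
    base_area       = 0.35,           # healthy cell-occupied area fraction
    toxic           = FALSE,
    toxicity_onset_h = 5,
    toxicity_ramp_h  = 5,
    toxicity_floor   = 0.4,           # viability floor for toxic wells
    autofl_offset_green = 0,          # AU added by intrinsic fluorescence
    autofl_offset_red   = 0,
    puncta_clustering   = FALSE,
    clustering_rate     = 0           # fractional red rise per hour
  )
  torin1 <- modifyList(vehicle, list(flux_multiplier = 3))
  bafilomycin <- modifyList(vehicle, list(
    flux_multiplier = 0, puncta_clustering = TRUE, clustering_rate = 0.02))
  neuron_base <- list(
    mean_half_life_h = 33.2,
    sd_half_life_h   = 8,
    baseline_hazard  = 3e-4,   # h0, per hour
    hazard_beta      = 0.05,   # log-hazard per hour of half-life
    initial_intensity = 2000,  # converted-pool amplitude at t = 0, AU
    plateau           = 700,   # living-cell red baseline (preconversion), AU
    noise_cv          = 0.05,
    dead_floor        = 10,    # residual AU after death
    preconversion_h   = -0.5,
    observation_h     = 168,
    interval_h        = 1,
    opl_window_h      = 36
  )
  list(
    vehicle     = vehicle,
    torin1      = torin1,
    bafilomycin = bafilomycin,
    cortical    = neuron_base,
    spinal      = modifyList(neuron_base, list(mean_half_life_h = 37.1))
  )
}

#' Resolve a well-truth specification against the calibration presets
#'
#' @param spec a preset name, or a list of overrides (optionally with a
#'   `preset` element naming the base preset).
#' @param calibrations preset list from [opl_calibrations()].
#' @return full parameter list.
#' @keywords internal
resolve_truth <- function(spec, calibrations = opl_calibrations()) {
  if (is.null(spec)) return(calibrations$vehicle)
  if (is.character(spec) && length(spec) == 1L) {
    if (!spec %in% names(calibrations))
      stop("unknown calibration preset: ", spec)
    return(calibrations[[spec]])
  }
  stopifnot(is.list(spec))
  base <- calibrations[[spec$preset %||% "vehicle"]]
  if (is.null(base)) stop("unknown calibration preset: ", spec$preset)
  spec$preset <- NULL
  truth <- modifyList(base, spec)
  validate_truth(truth)
  truth
}

validate_truth <- function(truth) {
  with(truth, {
    if (half_life_h <= 0) stop("half_life_h must be positive")
    if (flux_multiplier < 0) stop("flux_multiplier must be non-negative")
    if (phi < 0 || phi > 1) stop("phi (conversion fraction) must lie in [0, 1]")
    if (noise_cv < 0) stop("noise_cv must be non-negative")
    if (yield <= 0) stop("yield must be positive")
  })
  invisible(truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Disable the photoconversion pulse in a calibration set
#'
#' The primary screening modality images the native green pool only; no
#' pulse is applied. This helper zeroes the conversion fraction of every
#' preset so control wells and compounds alike are simulated unconverted.
#'
#' @param calibrations preset list from [opl_calibrations()].
#' @return the preset list with `phi = 0` everywhere.
#' @export
no_pulse <- function(calibrations = opl_calibrations()) {
  lapply(calibrations, function(p) {
    if (!is.null(p$phi)) p$phi <- 0
    p
  })
}
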