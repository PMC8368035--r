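#' Default OPL imaging schedule
#'
#' One preconversion anchor frame followed by a post-conversion time-lapse
#' loop. The screening default images every 1.5 h from the conversion pulse
#' (t = 0) out to 13.5 h.
#'
#' @param preconversion_h time of the preconversion frame (negative hours).
#' @param times_h post-conversion sampling times; must start at 0 and contain
#'   at least two later times.
#' @return a list with elements `preconversion_h` and `times_h`.
#' @export
opl_schedule <- function(preconversion_h = -0.5,
                         times_h = seq(0, 13.5, by = 1.5)) {
  if (preconversion_h >= 0)
    stop("schedule must include a preconversion time (< 0)")
  times_h <- sort(unique(as.numeric(times_h)))
  if (!any(times_h == 0))
    stop("schedule must include a t = 0 postconversion anchor")
  if (sum(times_h > 0) < 2)
    stop("schedule must include at least two post-conversion timepoints")
  list(preconversion_h = preconversion_h, times_h = times_h)
}

# viability multiplier for toxic wells: 1 until onset, then a linear ramp
# down to the floor
viability <- function(t, truth) {
  if (!isTRUE(truth$toxic)) return(rep(1, length(t)))
  v <- 1 - (1 - truth$toxicity_floor) *
    pmax(0, t - truth$toxicity_onset_h) / truth$toxicity_ramp_h
  pmax(truth$toxicity_floor, v)
}

# noiseless channel means for one well at times t (post-conversion times >= 0;
# negative t = preconversion)
well_mean_intensity <- function(t, channel, truth) {
  m <- truth$flux_multiplier
  k_red <- log(2) / truth$half_life_h * m
  v <- viability(t, truth)
  if (channel == "green") {
    off <- truth$autofl_offset_green
    pre <- truth$green_ss
    s <- truth$green_ss * truth$k_green          # synthesis, AU/h
    i0 <- (1 - truth$phi) * truth$green_ss       # just after the pulse
    k_g <- truth$k_green * m
    post <- if (k_g > 0) {
      s / k_g + (i0 - s / k_g) * exp(-k_g * pmax(t, 0))
    } else i0 + s * pmax(t, 0)
    ifelse(t < 0, pre, post) * v + off
  } else {
    off <- truth$autofl_offset_red
    bg <- truth$red_bg
    post_amp <- truth$phi * truth$green_ss * truth$yield
    decay <- exp(-k_red * pmax(t, 0))
    rise <- truth$clustering_rate * pmax(t, 0)   # puncta-clustering artifact
    post <- bg + post_amp * (decay + rise)
    ifelse(t < 0, bg, (post - bg) * v + bg) + off
  }
}

lognormal_noise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate a two-channel OPL plate time series with known ground truth
#'
#' Generates per-well green and red (photoconverted) intensity time series
#' under the OPL model: the green pool sits at a synthesis/turnover steady
#' state, drops by the conversion fraction `phi` at the pulse and relaxes to
#' its (possibly drug-shifted) steady state; the red pool jumps from
#' background by `phi * green_ss * yield` at the pulse and then decays
#' first-order, `I(t) = I_bg + (I_post - I_bg) * exp(-k t)`. Toxic wells lose
#' cell area and intensity after their onset; intrinsically fluorescent
#' compounds add constant channel offsets; all measurements carry
#' multiplicative log-normal noise.
#'
#' @param layout an [plate_layout()] object.
#' @param truth_config named list mapping compound ids to truth
#'   specifications (preset name or override list, see [resolve_truth()]).
#'   Vehicle-control wells use the `vehicle` preset; positive controls use
#'   `positive_preset`.
#' @param schedule an [opl_schedule()].
#' @param seed integer run seed; output is bit-identical for a fixed seed.
#' @param calibrations preset list, see [opl_calibrations()].
#' @param noise_cv optional override of the per-preset noise CV.
#' @param positive_preset preset name for positive-control wells.
#' @return a list of class `opl_plate` with elements `timeseries` (long
#'   data.frame: `plate_id, well, channel, time_h, intensity,
#'   cell_area_fraction, background_preconversion, postconversion_intensity`),
#'   `truth` (per-well ground-truth data.frame) and `layout`. Anchor columns
#'   are populated for the red channel only; the preconversion frame is the
#'   row with negative `time_h`.
#' @examples
#' plate <- generate_plate(layout_90_10(), seed = 1)
#' head(plate$timeseries)
#' @export
generate_plate <- function(layout, truth_config = list(),
                           schedule = opl_schedule(), seed,
                           calibrations = opl_calibrations(),
                           noise_cv = NULL, positive_preset = "torin1") {
  stopifnot(inherits(layout, "opl_layout"))
  if (missing(seed)) stop("an explicit seed is required")
  if (!is.list(schedule) || is.null(schedule$times_h))
    stop("schedule must come from opl_schedule()")
  layout <- layout[layout$role != "empty", , drop = FALSE]
  t_all <- c(schedule$preconversion_h, schedule$times_h)

  ts_list <- vector("list", nrow(layout))
  truth_rows <- vector("list", nrow(layout))
  for (i in seq_len(nrow(layout))) {
    w <- layout[i, ]
    spec <- switch(w$role,
      vehicle_control  = "vehicle",
      positive_control = positive_preset,
      compound         = truth_config[[w$compound_id]] %||% "vehicle")
    truth <- resolve_truth(spec, calibrations)
    if (!is.null(noise_cv)) truth$noise_cv <- noise_cv
    set.seed(derive_seed(seed, "plate", w$plate_id, w$well))

    rows <- lapply(c("green", "red"), function(ch) {
      mu <- well_mean_intensity(t_all, ch, truth)
      y <- mu * lognormal_noise(length(mu), truth$noise_cv)
      area <- truth$base_area * viability(t_all, truth) *
        lognormal_noise(length(mu), truth$noise_cv / 2)
      data.frame(
        plate_id = w$plate_id, well = w$well, channel = ch,
        time_h = t_all, intensity = y,
        cell_area_fraction = pmin(1, area),
        background_preconversion = NA_real_,
        postconversion_intensity = NA_real_,
        stringsAsFactors = FALSE)
    })
    red <- rows[[2]]
    red$background_preconversion <- red$intensity[red$time_h < 0][1]
    red$postconversion_intensity <- red$intensity[red$time_h == 0][1]
    rows[[2]] <- red
    ts_list[[i]] <- do.call(rbind, rows)

    k_eff <- log(2) / truth$half_life_h * truth$flux_multiplier
    truth_rows[[i]] <- data.frame(
      plate_id = w$plate_id, well = w$well, role = w$role,
      compound_id = w$compound_id,
      k = k_eff,
      half_life_h = if (k_eff > 0) log(2) / k_eff else Inf,
      flux_multiplier = truth$flux_multiplier,
      phi = truth$phi, yield = truth$yield,
      toxic = isTRUE(truth$toxic),
      autofl_offset_green = truth$autofl_offset_green,
      autofl_offset_red = truth$autofl_offset_red,
      puncta_clustering = isTRUE(truth$puncta_clustering),
      noise_cv = truth$noise_cv,
      stringsAsFactors = FALSE)
  }
  out <- list(timeseries = do.call(rbind, ts_list),
              truth = do.call(rbind, truth_rows),
              layout = layout, schedule = schedule, seed = seed)
  class(out) <- "opl_plate"
  out
}

#' @export
print.opl_plate <- function(x, ...) {
  cat("OPL plate simulation:", length(unique(x$timeseries$well)), "wells,",
      length(unique(x$timeseries$time_h)), "timepoints, seed", x$seed, "\n")
  invisible(x)
}

#' Extract one well/channel series from a simulated plate
#'
#' @param plate an `opl_plate`.
#' @param well well id (e.g. `"A01"`).
#' @param channel `"green"` or `"red"`.
#' @param plate_id optional plate id when the object holds several plates.
#' @return data.frame of the requested series (anchor columns included).
#' @export
well_series <- function(plate, well, channel = c("red", "green"),
                        plate_id = NULL) {
  channel <- match.arg(channel)
  ts <- plate$timeseries
  sel <- ts$well == well & ts$channel == channel
  if (!is.null(plate_id)) sel <- sel & ts$plate_id == plate_id
  out <- ts[sel, , drop = FALSE]
  if (!nrow(out)) stop("no series for well ", well, " channel ", channel)
  out[order(out$time_h), ]
}

#' Four-parameter logistic response in dose
#'
#' `bottom + (top - bottom) / (1 + (ec50 / dose)^slope)`; the standard
#' Hill/4PL sigmoid, increasing in dose for positive `slope`.
#'
#' @param dose molar doses (> 0).
#' @param bottom,top plateau values.
#' @param ec50 midpoint dose (molar).
#' @param slope Hill slope.
#' @return numeric responses.
#' @export
hill_response <- function(dose, bottom, top, ec50, slope) {
  stopifnot(all(dose > 0), ec50 > 0)
  bottom + (top - bottom) / (1 + (ec50 / dose)^slope)
}

#' Simulate an OPL dilution series for one compound
#'
#' The compound's flux multiplier follows a four-parameter logistic in dose
#' between `bottom` and `top`; each dose is simulated as `n_replicates`
#' wells via [generate_plate()].
#'
#' @param compound_truth truth specification for the compound at full effect;
#'   its `flux_multiplier` is overridden per dose.
#' @param concentrations molar doses (>= 4, spanning >= 2 log units).
#' @param hill_params list with `ec50`, `slope`, `bottom`, `top` describing
#'   the dose -> flux-multiplier curve.
#' @param seed integer seed.
#' @param n_replicates wells per dose.
#' @param schedule an [opl_schedule()].
#' @param calibrations preset list.
#' @return an `opl_plate` whose layout/truth carry `concentration_M`.
#' @export
generate_dilution_series <- function(compound_truth = "vehicle",
                                     concentrations,
                                     hill_params, seed,
                                     n_replicates = 8L,
                                     schedule = opl_schedule(),
                                     calibrations = opl_calibrations()) {
  concentrations <- as.numeric(concentrations)
  if (any(concentrations <= 0)) stop("concentrations must be positive")
  if (length(unique(concentrations)) < 4)
    stop("need at least 4 distinct concentrations")
  if (diff(range(log10(concentrations))) < 2)
    stop("concentrations must span at least 2 log units")
  hp <- hill_params
  stopifnot(all(c("ec50", "slope", "bottom", "top") %in% names(hp)))

  base <- resolve_truth(compound_truth, calibrations)
  mult <- hill_response(concentrations, hp$bottom, hp$top, hp$ec50, hp$slope)

  grid <- expand.grid(rep = seq_len(n_replicates),
                      dose_idx = seq_along(concentrations))
  wells <- all_wells()
  wells <- wells[order(wells$col, wells$row), ][seq_len(nrow(grid)), ]
  ids <- sprintf("dose_%02d", grid$dose_idx)
  layout <- plate_layout("dilution", wells$row, wells$col,
                         role = "compound", compound_id = ids,
                         concentration_M = concentrations[grid$dose_idx],
                         replicate = grid$rep)
  truth_config <- lapply(seq_along(concentrations), function(j)
    modifyList(base, list(flux_multiplier = mult[j])))
  names(truth_config) <- sprintf("dose_%02d", seq_along(concentrations))
  plate <- generate_plate(layout, truth_config, schedule, seed,
                          calibrations)
  plate$truth$concentration_M <-
    layout$concentration_M[match(plate$truth$well, layout$well)]
  plate$hill_params <- hp
  plate
}
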