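#' Call time of death from a single-cell intensity track
#'
#' A cell is scored dead at the first time its red intensity falls below
#' `threshold` times its initial intensity (the first post-conversion
#' sample) and stays there for at least `persistence` consecutive frames;
#' otherwise it is right-censored at the last observation. The intensity
#' criterion is a deterministic, automatable proxy for the morphology-based
#' visual scoring used at the microscope; it is valid because a living
#' cell's red signal never falls below its preconversion baseline, which
#' sits above the threshold.
#'
#' @param track data.frame with `time_h`, `red_intensity` (>= 3 rows).
#' @param threshold fraction of the initial intensity (default 0.2).
#' @param persistence consecutive sub-threshold frames required (default 2).
#' @return list: `event_time` (hours), `event_observed` (FALSE = censored).
#' @export
call_death_time <- function(track, threshold = 0.2, persistence = 2L) {
  stopifnot(nrow(track) >= 3)
  o <- order(track$time_h)
  t <- track$time_h[o]; y <- track$red_intensity[o]
  post <- which(t >= 0)
  init <- if (length(post)) y[post[1]] else y[1]
  if (!is.finite(init) || init <= 0)
    stop("initial intensity must be positive; rejecting track")
  below <- y < threshold * init & t >= 0
  run <- 0L
  for (j in seq_along(below)) {
    run <- if (below[j]) run + 1L else 0L
    if (run >= persistence)
      return(list(event_time = t[j - persistence + 1L], event_observed = TRUE))
  }
  list(event_time = max(t), event_observed = FALSE)
}

#' Fit per-cell half-lives over the OPL window
#'
#' Runs [fit_half_life()] on each cell's samples within `[0, opl_window_h]`.
#' When the track contains preconversion frames (negative times) their mean
#' is used as the fixed background anchor — the same normalization as the
#' well-level assay; without them the background is a free fit parameter.
#'
#' @param neurons an `opl_neurons` object or a tracks data.frame.
#' @param opl_window_h OPL imaging window in hours.
#' @return data.frame `neuron_id, half_life_h, no_decay, fit_r2`.
#' @export
fit_track_half_lives <- function(neurons, opl_window_h = 36) {
  tracks <- if (inherits(neurons, "opl_neurons")) neurons$tracks else neurons
  by_cell <- split(tracks, tracks$neuron_id)
  rows <- lapply(by_cell, function(tr) {
    bg <- if (any(tr$time_h < 0)) mean(tr$red_intensity[tr$time_h < 0])
          else NULL
    tr <- tr[tr$time_h >= 0 & tr$time_h <= opl_window_h, ]
    fit <- tryCatch(fit_half_life(tr$time_h, tr$red_intensity,
                                  background = bg),
                    error = function(e) no_decay_fit(tr$red_intensity))
    data.frame(neuron_id = tr$neuron_id[1], half_life_h = fit$half_life_h,
               no_decay = fit$no_decay, fit_r2 = fit$r_squared,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build survival records joining half-lives to death times
#'
#' Applies [call_death_time()] to every track, joins the fitted half-lives,
#' and excludes cells that died within the OPL imaging window (their
#' half-life fit would be contaminated by the death transition, so only
#' cells that lived through the whole OPL window enter the survival
#' analysis). Cells with a no-decay fit are also excluded.
#'
#' @param neurons an `opl_neurons` object or tracks data.frame.
#' @param half_lives data.frame from [fit_track_half_lives()].
#' @param opl_window_h OPL window in hours.
#' @param threshold,persistence death-call rule, see [call_death_time()].
#' @return data.frame of class `opl_records`: `neuron_id, population,
#'   half_life_h, event_time_h, event_observed`; attribute `exclusions`
#'   counts the dropped cells by reason.
#' @export
build_records <- function(neurons, half_lives, opl_window_h = 36,
                          threshold = 0.2, persistence = 2L) {
  tracks <- if (inherits(neurons, "opl_neurons")) neurons$tracks else neurons
  by_cell <- split(tracks, tracks$neuron_id)
  if (!all(names(by_cell) %in% half_lives$neuron_id))
    stop("mismatched neuron ids between tracks and half-life table")
  rows <- lapply(by_cell, function(tr) {
    d <- call_death_time(tr, threshold, persistence)
    data.frame(neuron_id = tr$neuron_id[1], population = tr$population[1],
               event_time_h = d$event_time, event_observed = d$event_observed,
               stringsAsFactors = FALSE)
  })
  ev <- do.call(rbind, rows)
  ev$half_life_h <- half_lives$half_life_h[match(ev$neuron_id,
                                                 half_lives$neuron_id)]
  died_in_window <- ev$event_observed & ev$event_time_h <= opl_window_h
  no_decay <- !is.finite(ev$half_life_h)
  keep <- !died_in_window & !no_decay
  out <- ev[keep, c("neuron_id", "population", "half_life_h",
                    "event_time_h", "event_observed")]
  rownames(out) <- NULL
  attr(out, "exclusions") <- c(died_in_opl_window = sum(died_in_window),
                               no_decay_fit = sum(no_decay & !died_in_window))
  class(out) <- c("opl_records", "data.frame")
  out
}

#' Cox proportional hazards fit with half-life as a linear covariate
#'
#' Partial-likelihood fit (Efron ties) of death risk on the fitted
#' Dendra2-LC3 half-life. The hazard ratio is reported per 1 h of half-life:
#' values above 1 mean slower autophagic flux carries a higher risk of
#' death.
#'
#' @param records an `opl_records` data.frame (needs >= 2 observed events
#'   and non-degenerate half-life variance).
#' @return list of class `opl_cox`: `beta`, `hazard_ratio`, `ci95`
#'   (hazard-ratio scale), `p_value`, `n`, `n_events`, `unstable` flag and
#'   the underlying `fit`.
#' @export
fit_cox_linear <- function(records) {
  check_cox_input(records)
  fit <- coxph(Surv(event_time_h, event_observed) ~ half_life_h,
               data = records, ties = "efron")
  s <- summary(fit)
  beta <- unname(coef(fit)[1])
  se <- s$coefficients[1, "se(coef)"]
  structure(list(
    beta = beta,
    hazard_ratio = exp(beta),
    ci95 = exp(beta + c(-1, 1) * qnorm(0.975) * se),
    p_value = s$coefficients[1, "Pr(>|z|)"],
    n = nrow(records), n_events = sum(records$event_observed),
    unstable = !is.finite(se) || se > 10 * max(abs(beta), 1e-3),
    fit = fit), class = "opl_cox")
}

check_cox_input <- function(records) {
  if (sum(records$event_observed) < 2)
    stop("need at least 2 observed death events")
  if (!is.finite(var(records$half_life_h)) || var(records$half_life_h) == 0)
    stop("half-life covariate has no variance")
  invisible(records)
}

#' @export
print.opl_cox <- function(x, ...) {
  cat(sprintf(
    "Cox PH: HR %.4f per h of half-life (95%% CI %.4f-%.4f), beta %.4g, p %.3g, %d events / %d cells%s\n",
    x$hazard_ratio, x$ci95[1], x$ci95[2], x$beta, x$p_value,
    x$n_events, x$n, if (isTRUE(x$unstable)) " [unstable]" else ""))
  invisible(x)
}

#' Penalized-spline Cox fit: relative risk across the half-life range
#'
#' Fits `coxph(Surv(...) ~ pspline(half_life_h, df))` and evaluates the
#' relative risk of death over a grid spanning the 1st-99th percentile of
#' observed half-lives, normalized to risk 1 at the cohort median, with a
#' pointwise 95% band. Falls back to the linear fit (with a warning) when
#' there are too few unique half-life values to support the spline.
#'
#' @param records an `opl_records` data.frame (n >= 100 recommended).
#' @param df spline degrees of freedom (default 4).
#' @param grid_length number of grid points.
#' @return an `opl_cox` list with an additional `spline_curve` data.frame:
#'   `half_life_h, relative_risk, lower, upper`.
#' @export
fit_cox_spline <- function(records, df = 4, grid_length = 101L) {
  check_cox_input(records)
  if (length(unique(records$half_life_h)) < 3 * df) {
    warning("too few unique half-life values for a penalized spline; ",
            "falling back to the linear Cox fit")
    lin <- fit_cox_linear(records)
    med <- median(records$half_life_h)
    grid <- seq(min(records$half_life_h), max(records$half_life_h),
                length.out = grid_length)
    lin$spline_curve <- data.frame(
      half_life_h = grid,
      relative_risk = exp(lin$beta * (grid - med)),
      lower = NA_real_, upper = NA_real_)
    return(lin)
  }
  fit <- coxph(Surv(event_time_h, event_observed) ~ pspline(half_life_h, df = df),
               data = records, ties = "efron")
  qs <- quantile(records$half_life_h, c(0.01, 0.99), names = FALSE)
  med <- median(records$half_life_h)
  grid <- sort(unique(c(med, seq(qs[1], qs[2], length.out = grid_length))))
  nd <- data.frame(half_life_h = c(med, grid),
                   event_time_h = 1, event_observed = TRUE)
  pr <- predict(fit, newdata = nd, type = "terms", se.fit = TRUE)
  eta <- as.numeric(pr$fit[, 1]); se <- as.numeric(pr$se.fit[, 1])
  rel <- eta[-1] - eta[1]
  lin <- fit_cox_linear(records)
  structure(list(
    beta = lin$beta, hazard_ratio = lin$hazard_ratio, ci95 = lin$ci95,
    p_value = lin$p_value, n = lin$n, n_events = lin$n_events,
    unstable = lin$unstable, fit = fit,
    spline_curve = data.frame(
      half_life_h = grid,
      relative_risk = exp(rel),
      lower = exp(rel - qnorm(0.975) * se[-1]),
      upper = exp(rel + qnorm(0.975) * se[-1]))), class = "opl_cox")
}

#' Welch's t-test comparing single-cell half-lives of two populations
#'
#' @param records_a,records_b `opl_records` (or any data.frames with a
#'   `half_life_h` column), >= 2 rows each.
#' @return list: `t`, `p_value`, `mean_a`, `mean_b`, `df`.
#' @export
compare_populations <- function(records_a, records_b) {
  a <- records_a$half_life_h; b <- records_b$half_life_h
  if (length(a) < 2 || length(b) < 2)
    stop("need at least 2 records per group")
  if (var(a) == 0 && var(b) == 0)
    stop("degenerate variance in both groups")
  tt <- t.test(a, b, var.equal = FALSE)
  list(t = unname(tt$statistic), p_value = tt$p.value,
       mean_a = mean(a), mean_b = mean(b), df = unname(tt$parameter))
}

#' End-to-end single-cell half-life recovery for one neuron population
#'
#' Convenience pipeline used by the acceptance analysis: generate tracks,
#' fit per-cell half-lives over the OPL window, call deaths, build records
#' (excluding cells dying within the window) and summarise.
#'
#' @param n cells.
#' @param preset `"cortical"` or `"spinal"`.
#' @param seed integer seed.
#' @param calibrations preset list.
#' @return list: `records`, `mean_half_life`, `se_half_life`, `neurons`,
#'   `half_lives`.
#' @export
neuron_halflife_pipeline <- function(n, preset, seed,
                                     calibrations = opl_calibrations()) {
  neurons <- generate_neuron_tracks(n, preset, seed = seed,
                                    calibrations = calibrations)
  hl <- fit_track_half_lives(neurons, neurons$params$opl_window_h)
  rec <- build_records(neurons, hl, neurons$params$opl_window_h)
  list(records = rec,
       mean_half_life = mean(rec$half_life_h),
       se_half_life = sd(rec$half_life_h) / sqrt(nrow(rec)),
       neurons = neurons, half_lives = hl)
}
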