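#' GFP flux ratio between two timepoints
#'
#' The primary-screen readout: the ratio of background-subtracted green
#' intensity at `t1` (default 15 h after drug) to that at `t0` (baseline).
#' Flux enhancers push the ratio down (faster clearance of the reporter),
#' late-stage inhibitors push it up.
#'
#' @param ts a green-channel well series (data.frame with `time_h`,
#'   `intensity`).
#' @param t0,t1 requested timepoints in hours; the nearest sample within half
#'   the median sampling interval is used.
#' @return the ratio, or `NA` with attribute `invalid = TRUE` when the
#'   baseline intensity is non-positive.
#' @export
gfp_flux_ratio <- function(ts, t0 = 0, t1 = 15) {
  i0 <- intensity_at(ts, t0)
  i1 <- intensity_at(ts, t1)
  if (!is.finite(i0) || i0 <= 0) {
    out <- NA_real_
    attr(out, "invalid") <- TRUE
    return(out)
  }
  i1 / i0
}

# nearest sample to a requested time, within half the sampling interval
intensity_at <- function(ts, t) {
  tt <- ts$time_h
  d <- abs(tt - t)
  j <- which.min(d)
  tol <- median(diff(sort(unique(tt)))) / 2
  if (d[j] > tol + 1e-9)
    stop("no sample within ", signif(tol, 3), " h of requested t = ", t)
  ts$intensity[j]
}

#' Normalized photoconverted (red) intensity
#'
#' Scales a red-channel series to its anchors: the preconversion background
#' maps to 0 and the immediate postconversion intensity to 1,
#' `R(t) = (I(t) - I_bg) / (I_post - I_bg)`. Values above 1 are possible and
#' meaningful (late-stage inhibition with puncta clustering).
#'
#' @param ts a red-channel well series with `background_preconversion` and
#'   `postconversion_intensity` anchor columns.
#' @param t requested time in hours (vectorised).
#' @return normalized intensity at `t`; errors with "failed conversion" when
#'   the postconversion anchor does not exceed background.
#' @export
normalized_red <- function(ts, t) {
  an <- red_anchors(ts)
  vapply(t, function(ti)
    (intensity_at(ts, ti) - an$bg) / (an$post - an$bg), numeric(1))
}

red_anchors <- function(ts) {
  bg <- ts$background_preconversion[1]
  post <- ts$postconversion_intensity[1]
  if (!is.finite(bg) || !is.finite(post))
    stop("red series lacks preconversion/postconversion anchors")
  if (post <= bg)
    stop("failed conversion: postconversion intensity does not exceed background")
  list(bg = bg, post = post)
}

#' Normalize a whole red-channel series to its anchors
#'
#' @param ts red-channel well series with anchors.
#' @return the series with `intensity` replaced by its normalized value and
#'   anchors rewritten to 0/1.
#' @export
normalize_red_series <- function(ts) {
  an <- red_anchors(ts)
  ts$intensity <- (ts$intensity - an$bg) / (an$post - an$bg)
  ts$background_preconversion <- 0
  ts$postconversion_intensity <- 1
  ts
}

#' Fit a first-order exponential decay and report the half-life
#'
#' Least-squares fit of `I(t) = I_bg + (I_post - I_bg) * exp(-k t)` to
#' post-conversion samples. When `background` is supplied (a measured
#' preconversion anchor, or 0 for background-subtracted single-cell tracks)
#' it is held fixed and only the amplitude and rate are fitted; otherwise the
#' background is a third fitted parameter bounded at zero. Fits with
#' `k <= 0`, essentially flat data, or relative decay below the noise are
#' reported as no-decay (half-life `Inf`).
#'
#' @param times hours (>= 3 post-conversion samples).
#' @param intensities observed intensities (same length).
#' @param background optional fixed background level.
#' @return a list with `half_life_h` (`Inf` when no decay), `k`, `no_decay`
#'   flag, `r_squared`, and the fitted `background`/`amplitude`.
#' @examples
#' t <- seq(0, 13.5, 1.5)
#' fit_half_life(t, 50 + 950 * exp(-log(2) / 7.5 * t), background = 50)
#' @export
fit_half_life <- function(times, intensities, background = NULL) {
  keep <- is.finite(times) & is.finite(intensities) & times >= 0
  t <- times[keep]; y <- intensities[keep]
  if (length(t) < 3) stop("need at least 3 post-conversion timepoints")
  o <- order(t); t <- t[o]; y <- y[o]
  if (diff(range(y)) < .Machine$double.eps * max(abs(y), 1))
    return(no_decay_fit(y))

  bg0 <- if (is.null(background)) max(0, min(y) * 0.5) else background
  # log-linear initialisation on the background-deficit
  pos <- y - bg0 > max(y - bg0, 0) * 1e-4
  k0 <- if (sum(pos) >= 2) {
    sl <- -coef(lm(log(y[pos] - bg0) ~ t[pos]))[[2]]
    max(sl, 1e-4)
  } else 1e-3
  a0 <- max(y[1] - bg0, .Machine$double.eps)

  fit <- if (is.null(background)) {
    try(nlsLM(y ~ bg + a * exp(-k * t),
              start = list(bg = bg0, a = a0, k = k0),
              lower = c(0, 0, 0), upper = c(Inf, Inf, 20),
              control = nls.lm.control(maxiter = 200)), silent = TRUE)
  } else {
    try(nlsLM(y ~ bg0 + a * exp(-k * t),
              start = list(a = a0, k = k0),
              lower = c(0, 0), upper = c(Inf, 20),
              control = nls.lm.control(maxiter = 200)), silent = TRUE)
  }
  if (inherits(fit, "try-error")) return(no_decay_fit(y))
  p <- as.list(coef(fit))
  p$bg <- p$bg %||% bg0
  resid <- y - (p$bg + p$a * exp(-p$k * t))
  r2 <- 1 - sum(resid^2) / max(sum((y - mean(y))^2), .Machine$double.eps)
  # a rate this slow is indistinguishable from no decay over the window
  if (p$k <= 1e-3 / diff(range(t)) || p$a <= 0) return(no_decay_fit(y, r2))
  list(half_life_h = log(2) / p$k, k = p$k, no_decay = FALSE,
       r_squared = r2, background = p$bg, amplitude = p$a)
}

no_decay_fit <- function(y, r2 = NA_real_) {
  list(half_life_h = Inf, k = 0, no_decay = TRUE, r_squared = r2,
       background = min(y), amplitude = 0)
}

#' Half-life fit for a simulated well's red channel
#'
#' Convenience wrapper: normalizes the series to its anchors and fits with
#' the background fixed at 0 (equivalently, fits the raw series with the
#' measured background anchor fixed — the two give the same rate).
#'
#' @param ts red-channel well series with anchors.
#' @return see [fit_half_life()].
#' @export
fit_well_half_life <- function(ts) {
  ns <- normalize_red_series(ts)
  keep <- ns$time_h >= 0
  fit_half_life(ns$time_h[keep], ns$intensity[keep], background = 0)
}

#' Torin1-equivalents effect scaling
#'
#' Scales a drug's OPL clearance effect to the Torin1 positive control:
#' `(1 - R_drug) / (1 - R_torin1)` where `R` is the 9 h / 0 h normalized red
#' ratio. 1 means Torin1-strength induction, 0 no clearance, negative values
#' indicate stabilisation (inhibitors) and are reported as-is.
#'
#' @param drug_ratio drug's normalized red ratio at the readout time.
#' @param torin1_ratio positive-control ratio (must be < 1).
#' @return unitless Torin1 equivalents.
#' @export
torin1_equivalents <- function(drug_ratio, torin1_ratio) {
  if (any(torin1_ratio >= 1))
    stop("positive control failed: Torin1 ratio must be < 1")
  (1 - drug_ratio) / (1 - torin1_ratio)
}

#' Percent-of-control effect size
#'
#' Expresses a drug's signed deviation from the vehicle mean as a percentage
#' of the matching control's deviation: enhancers are scaled to the Torin1
#' effect, inhibitors to the bafilomycin-A1 effect.
#'
#' @param drug_effect signed deviation of the drug's flux metric from the
#'   vehicle mean.
#' @param control_effect signed deviation of the scaling control (non-zero).
#' @param mode `"enhancer"` or `"inhibitor"` (recorded on the result).
#' @return percent (100 = control-strength effect).
#' @export
percent_of_control <- function(drug_effect, control_effect,
                               mode = c("enhancer", "inhibitor")) {
  mode <- match.arg(mode)
  if (any(control_effect == 0)) stop("control effect must be non-zero")
  out <- 100 * drug_effect / control_effect
  attr(out, "mode") <- mode
  out
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Fits `bottom + (top - bottom) / (1 + 10^(slope * (log10(ec50) - log10(dose))))`
#' by least squares in log10 dose, initialised from the data quartiles and
#' with the midpoint bounded within 100x of the tested dose range. The
#' orientation (EC50 for rising responses, IC50 for falling) is inferred from
#' the fitted slope sign.
#'
#' @param doses molar doses (>= 4 distinct).
#' @param responses responses (same length).
#' @return a list of class `opl_4pl` with `bottom`, `top`, `ec50`,
#'   `hill_slope`, `kind` (`"EC50"`/`"IC50"`), `r_squared`, `converged`, and
#'   `extrapolated` (TRUE when the midpoint falls outside the tested range).
#' @examples
#' d <- 10^seq(-9, -6, length.out = 8)
#' fit_4pl(d, hill_response(d, 0, 1, 1e-8, 1))
#' @export
fit_4pl <- function(doses, responses) {
  keep <- is.finite(doses) & is.finite(responses) & doses > 0
  doses <- doses[keep]; responses <- responses[keep]
  if (length(unique(doses)) < 4) stop("need at least 4 distinct doses")
  lx <- log10(doses); y <- responses
  qs <- quantile(y, c(0.05, 0.95), names = FALSE)
  rng <- range(lx)
  starts <- list(
    list(bottom = qs[1], top = qs[2], lec50 = mean(rng), slope = 1),
    list(bottom = qs[2], top = qs[1], lec50 = mean(rng), slope = 1),
    list(bottom = qs[1], top = qs[2], lec50 = median(lx), slope = 3)
  )
  lower <- c(-Inf, -Inf, rng[1] - 2, -50)
  upper <- c(Inf, Inf, rng[2] + 2, 50)
  best <- NULL
  for (st in starts) {
    fit <- try(nlsLM(
      y ~ bottom + (top - bottom) / (1 + 10^(slope * (lec50 - lx))),
      start = st, lower = lower, upper = upper,
      control = nls.lm.control(maxiter = 500, ftol = 1e-14, ptol = 1e-14)),
      silent = TRUE)
    if (inherits(fit, "try-error")) next
    rss <- sum(resid(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  tss <- max(sum((y - mean(y))^2), .Machine$double.eps)
  if (is.null(best)) {
    return(structure(list(bottom = NA, top = NA, ec50 = NA, hill_slope = NA,
                          kind = NA_character_, r_squared = NA,
                          converged = FALSE, extrapolated = NA,
                          diagnostics = "no start converged"),
                     class = "opl_4pl"))
  }
  p <- as.list(coef(best$fit))
  r2 <- 1 - best$rss / tss
  # orient so bottom <= top; a negative slope on an increasing curve is the
  # same sigmoid with plateaus swapped
  bottom <- p$bottom; top <- p$top; slope <- p$slope
  if (bottom > top) { tmp <- bottom; bottom <- top; top <- tmp; slope <- -slope }
  rising_in_dose <- slope > 0
  flat <- abs(top - bottom) < 1e-3 * max(abs(c(top, bottom, 1)))
  structure(list(
    bottom = bottom, top = top, ec50 = 10^p$lec50, hill_slope = slope,
    kind = if (rising_in_dose) "EC50" else "IC50",
    r_squared = r2,
    converged = !flat && r2 > 0.5,
    extrapolated = p$lec50 < rng[1] || p$lec50 > rng[2],
    diagnostics = if (flat) "flat response" else NULL),
    class = "opl_4pl")
}

#' @export
print.opl_4pl <- function(x, ...) {
  cat(sprintf("4PL fit: %s = %.3g M, slope %.3g, plateaus [%.3g, %.3g], R2 %.4f%s\n",
              x$kind %||% "midpoint", x$ec50, x$hill_slope, x$bottom, x$top,
              x$r_squared,
              if (isTRUE(x$converged)) "" else " (unconverged)"))
  invisible(x)
}

#' Per-well flux metrics table for a simulated plate
#'
#' Computes the standard readouts for every non-empty well of an
#' [generate_plate()] result: the GFP ratio between `gfp_t0`/`gfp_t1`, the
#' normalized red ratio at `readout_h`, the fitted half-life, and
#' Torin1-equivalents when positive-control wells are present.
#'
#' @param plate an `opl_plate`.
#' @param readout_h red-channel readout time (default 9 h, the time of
#'   maximal screening window).
#' @param gfp_t0,gfp_t1 green-channel ratio timepoints.
#' @param fit_half_lives whether to run the per-well exponential fit.
#' @return data.frame: `plate_id, well, compound_id, role, gfp_ratio,
#'   red_ratio_9h, half_life_h, no_decay_flag, torin1_equivalents, fit_r2,
#'   cell_area, mean_red, mean_green`.
#' @export
flux_metrics <- function(plate, readout_h = 9, gfp_t0 = 0, gfp_t1 = NULL,
                         fit_half_lives = TRUE) {
  stopifnot(inherits(plate, "opl_plate"))
  times <- sort(unique(plate$timeseries$time_h[plate$timeseries$time_h >= 0]))
  if (is.null(gfp_t1)) gfp_t1 <- max(times)
  wells <- unique(plate$timeseries[c("plate_id", "well")])
  res <- lapply(seq_len(nrow(wells)), function(i) {
    g <- well_series(plate, wells$well[i], "green", wells$plate_id[i])
    r <- well_series(plate, wells$well[i], "red", wells$plate_id[i])
    gr <- gfp_flux_ratio(g, gfp_t0, gfp_t1)
    rr <- tryCatch(normalized_red(r, readout_h), error = function(e) NA_real_)
    hl <- if (fit_half_lives)
      tryCatch(fit_well_half_life(r), error = function(e) no_decay_fit(r$intensity))
    else no_decay_fit(r$intensity)
    area <- mean(r$cell_area_fraction[r$time_h >= 0], na.rm = TRUE)
    data.frame(plate_id = wells$plate_id[i], well = wells$well[i],
               gfp_ratio = as.numeric(gr), red_ratio_9h = rr,
               half_life_h = hl$half_life_h, no_decay_flag = hl$no_decay,
               fit_r2 = hl$r_squared, cell_area = area,
               mean_red = mean(r$intensity[r$time_h >= 0]),
               mean_green = mean(g$intensity[g$time_h >= 0]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  meta <- plate$layout[match(paste(out$plate_id, out$well),
                             paste(plate$layout$plate_id, plate$layout$well)), ]
  out$compound_id <- meta$compound_id
  out$role <- meta$role
  pos <- out$role == "positive_control"
  pos_ratio <- mean(out$red_ratio_9h[pos], na.rm = TRUE)
  out$torin1_equivalents <- if (any(pos) && is.finite(pos_ratio) && pos_ratio < 1)
    torin1_equivalents(out$red_ratio_9h, pos_ratio)
  else NA_real_
  out[c("plate_id", "well", "compound_id", "role", "gfp_ratio",
        "red_ratio_9h", "half_life_h", "no_decay_flag",
        "torin1_equivalents", "fit_r2", "cell_area", "mean_red",
        "mean_green")]
}
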