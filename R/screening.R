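#' Z'-factor plate quality control
#'
#' `Z' = 1 - 3 (sd_pos + sd_neg) / |mean_pos - mean_neg|` with sample SDs.
#' Z' >= 0.5 indicates an excellent screening window. Also reports the
#' negative-control CV and mean separation.
#'
#' @param neg_values negative-control (DMSO) metric values (>= 2).
#' @param pos_values positive-control metric values (>= 2).
#' @return a list of class `opl_plateqc`: `z_prime` (`-Inf` when the group
#'   means coincide), `mean_neg`, `mean_pos`, `sd_neg`, `sd_pos`, `n_neg`,
#'   `n_pos`, `cv_neg` (percent), `separation`.
#' @examples
#' zprime(rnorm(320, 1, 0.06), rnorm(32, 0.4, 0.06))
#' @export
zprime <- function(neg_values, pos_values) {
  neg_values <- neg_values[is.finite(neg_values)]
  pos_values <- pos_values[is.finite(pos_values)]
  if (length(neg_values) < 2 || length(pos_values) < 2)
    stop("need at least 2 values per control group")
  mu_n <- mean(neg_values); mu_p <- mean(pos_values)
  sd_n <- sd(neg_values); sd_p <- sd(pos_values)
  sep <- abs(mu_p - mu_n)
  z <- if (sep == 0) -Inf else 1 - 3 * (sd_p + sd_n) / sep
  structure(list(z_prime = z, mean_neg = mu_n, mean_pos = mu_p,
                 sd_neg = sd_n, sd_pos = sd_p,
                 n_neg = length(neg_values), n_pos = length(pos_values),
                 cv_neg = 100 * sd_n / mu_n, separation = mu_n - mu_p),
            class = "opl_plateqc")
}

#' @export
print.opl_plateqc <- function(x, ...) {
  cat(sprintf("Z' = %.3f (neg: %.3g +/- %.3g, n=%d; pos: %.3g +/- %.3g, n=%d; CV_neg %.2f%%)\n",
              x$z_prime, x$mean_neg, x$sd_neg, x$n_neg,
              x$mean_pos, x$sd_pos, x$n_pos, x$cv_neg))
  invisible(x)
}

dmso_stats <- function(values, min_n = 8L, what = "DMSO wells") {
  values <- values[is.finite(values)]
  if (length(values) < min_n)
    stop("need at least ", min_n, " ", what, " on the plate")
  s <- sd(values)
  if (s == 0) stop("degenerate plate: zero variance across ", what)
  list(mean = mean(values), sd = s, n = length(values))
}

#' 3 SD hit calling against within-plate DMSO controls
#'
#' A compound well is an enhancer when its metric falls below the DMSO mean
#' minus 3 SD, an inhibitor when above the mean plus 3 SD, otherwise none.
#' The z-score (fold SD from the DMSO mean) is reported for every well.
#' For clearance-type metrics (GFP ratio, normalized red ratio) a low value
#' means faster flux, so "enhancer" is the low tail.
#'
#' @param metrics data.frame with at least `compound_id` and the metric
#'   column; one row per well or per compound.
#' @param dmso_values numeric metric values of the DMSO wells on the same
#'   plate (>= 8).
#' @param metric column name to threshold (e.g. `"gfp_ratio"`,
#'   `"red_ratio_9h"`).
#' @param stage stage label recorded on the calls.
#' @param n_sd threshold in SD units (default 3).
#' @return data.frame of hit calls: `compound_id, stage, classification,
#'   z_score, metric_value, puncta_change_flag` (flag `NA` here; see
#'   [puncta_hit_call()]).
#' @export
call_hits <- function(metrics, dmso_values, metric = "gfp_ratio",
                      stage = "primary", n_sd = 3) {
  stopifnot(metric %in% names(metrics))
  st <- dmso_stats(dmso_values)
  x <- metrics[[metric]]
  z <- (x - st$mean) / st$sd
  cls <- ifelse(!is.finite(x), "none",
         ifelse(z < -n_sd, "enhancer",
         ifelse(z > n_sd, "inhibitor", "none")))
  data.frame(compound_id = metrics$compound_id, stage = stage,
             classification = cls, z_score = z, metric_value = x,
             puncta_change_flag = NA, stringsAsFactors = FALSE)
}

#' Toxicity filter on the cell-area metric
#'
#' Wells whose cell-occupied area falls at least 3 SD below the DMSO mean
#' area are classified toxic and removed before hit calling: compounds that
#' kill cells lower the GFP signal and would otherwise masquerade as
#' enhancers. Wells between `audit_sd` and the threshold are listed for
#' manual review.
#'
#' @param calls hit-call data.frame from [call_hits()].
#' @param area_values named numeric vector of cell-area metrics, names =
#'   `compound_id`.
#' @param dmso_area_values DMSO-well area metrics.
#' @param n_sd exclusion threshold (default 3 SD below the mean).
#' @param audit_sd borderline band reported for review (default 2.5).
#' @param min_effect minimum fractional area reduction (default 0.15)
#'   required in addition to the SD threshold. This is the deterministic
#'   stand-in for the protocol's visual verification step: it keeps wells
#'   that merely drift past 3 SD on a tight-control plate, without any
#'   biologically meaningful area loss, from being discarded as toxic.
#' @return the calls with toxic compounds reclassified `"toxic"` (toxicity
#'   preempts enhancer/inhibitor); attributes `excluded` (compound ids) and
#'   `audit` (borderline ids). Compounds without area data pass through with
#'   a warning.
#' @export
toxicity_filter <- function(calls, area_values, dmso_area_values,
                            n_sd = 3, audit_sd = 2.5, min_effect = 0.15) {
  st <- dmso_stats(dmso_area_values, what = "DMSO area values")
  idx <- match(calls$compound_id, names(area_values))
  if (anyNA(idx))
    warning("no cell-area data for ",
            sum(is.na(idx)), " compound(s); passed through unfiltered")
  area <- as.numeric(area_values)[idx]
  area_z <- (area - st$mean) / st$sd
  toxic <- !is.na(area_z) & area_z < -n_sd &
    area < (1 - min_effect) * st$mean
  audit <- !is.na(area_z) & area_z < -audit_sd & area_z >= -(n_sd + 0.5)
  calls$classification[toxic] <- "toxic"
  attr(calls, "excluded") <- calls$compound_id[toxic]
  attr(calls, "audit") <- setdiff(calls$compound_id[audit],
                                  calls$compound_id[toxic])
  calls
}

#' Autofluorescence counterscreen in reporter-free cells
#'
#' Compounds re-tested in unmodified cells (no Dendra2) that still raise the
#' red (or green) signal above the DMSO mean + 3 SD are intrinsically
#' fluorescent; their apparent stabilisation of the reporter is an artifact
#' and they are flagged and removed from the candidate pool.
#'
#' @param calls hit-call data.frame (survivors entering the counterscreen).
#' @param counterscreen_values named numeric vector of reporter-free-cell
#'   intensities per compound.
#' @param dmso_values DMSO-well intensities from the counterscreen plate.
#' @param n_sd threshold (default 3).
#' @return calls with flagged compounds reclassified `"autofluorescent"`;
#'   attribute `flagged` lists them. Compounds missing from the counterscreen
#'   keep their class but gain attribute `unverified`.
#' @export
autofluorescence_counterscreen <- function(calls, counterscreen_values,
                                           dmso_values, n_sd = 3) {
  st <- dmso_stats(dmso_values, what = "counterscreen DMSO wells")
  idx <- match(calls$compound_id, names(counterscreen_values))
  z <- (as.numeric(counterscreen_values)[idx] - st$mean) / st$sd
  flagged <- !is.na(z) & z > n_sd
  calls$classification[flagged] <- "autofluorescent"
  attr(calls, "flagged") <- calls$compound_id[flagged]
  attr(calls, "unverified") <- calls$compound_id[is.na(idx)]
  calls
}

#' Puncta-count hit criterion
#'
#' Flags compounds whose per-well LC3 puncta count exceeds the DMSO mean +
#' 3 SD. Both flux enhancers and late-stage inhibitors accumulate puncta, so
#' the flag is reported alongside — never instead of — the flux
#' classification.
#'
#' @param calls hit-call data.frame.
#' @param puncta_counts named numeric vector of puncta counts per compound
#'   (from the imaging module).
#' @param dmso_counts DMSO-well puncta counts.
#' @param n_sd threshold (default 3).
#' @return calls with `puncta_change_flag` filled (`NA` where no counts).
#' @export
puncta_hit_call <- function(calls, puncta_counts, dmso_counts, n_sd = 3) {
  st <- dmso_stats(dmso_counts, what = "DMSO puncta counts")
  idx <- match(calls$compound_id, names(puncta_counts))
  z <- (as.numeric(puncta_counts)[idx] - st$mean) / st$sd
  calls$puncta_change_flag <- ifelse(is.na(z), NA, z > n_sd)
  calls
}

#' Funnel bookkeeping across screening stages
#'
#' Tallies the multi-stage screening hierarchy: each stage evaluates only
#' the survivors of the previous one (compounds classified enhancer or
#' inhibitor there, and not toxic or autofluorescent); evaluating a
#' non-survivor is a protocol violation and is rejected.
#'
#' @param stage_results ordered named list of hit-call data.frames, one per
#'   stage in pipeline order.
#' @param library_size total number of compounds entering the funnel.
#' @return a `data.frame` funnel table: `stage, n_compounds,
#'   percent_of_library, n_enhancers, n_inhibitors`; attribute `survivors`
#'   holds the final surviving compound ids with their classifications.
#' @export
run_funnel <- function(stage_results, library_size) {
  stopifnot(is.list(stage_results), length(stage_results) >= 1,
            !is.null(names(stage_results)))
  surviving <- NULL
  rows <- vector("list", length(stage_results))
  for (i in seq_along(stage_results)) {
    calls <- stage_results[[i]]
    if (i > 1) {
      extra <- setdiff(calls$compound_id, surviving)
      if (length(extra))
        stop("protocol violation: stage '", names(stage_results)[i],
             "' evaluates compound(s) not surviving the previous stage: ",
             paste(head(extra, 5), collapse = ", "))
    }
    n_enh <- sum(calls$classification == "enhancer")
    n_inh <- sum(calls$classification == "inhibitor")
    rows[[i]] <- data.frame(
      stage = names(stage_results)[i],
      n_compounds = nrow(calls),
      percent_of_library = if (library_size > 0)
        100 * nrow(calls) / library_size else 0,
      n_enhancers = n_enh, n_inhibitors = n_inh,
      stringsAsFactors = FALSE)
    surviving <- calls$compound_id[calls$classification %in%
                                     c("enhancer", "inhibitor")]
  }
  out <- do.call(rbind, rows)
  if (any(diff(out$n_compounds) > 0))
    stop("funnel invariant violated: compound counts must be non-increasing")
  final <- stage_results[[length(stage_results)]]
  attr(out, "survivors") <-
    final[final$classification %in% c("enhancer", "inhibitor"),
          c("compound_id", "classification")]
  out
}

#' Simulate and screen a compound library through the full funnel
#'
#' End-to-end driver over the synthetic generator: a library of mostly inert
#' compounds with planted enhancers, inhibitors, toxic and autofluorescent
#' compounds is screened through (1) a green-channel primary screen at 15 h
#' with the toxicity filter, (2) a primary confirmation rerun, (3) a
#' photoconversion secondary screen on the 9 h normalized red ratio, (4) a
#' secondary confirmation, and (5) an autofluorescence counterscreen in
#' reporter-free cells.
#'
#' @param n_compounds library size.
#' @param n_enhancers,n_inhibitors,n_toxic planted true positives; planted
#'   enhancers use the `torin1` preset, inhibitors `bafilomycin`, toxic
#'   compounds the vehicle preset with `toxic = TRUE`.
#' @param n_autofluorescent how many of the planted inhibitors additionally
#'   get a red-channel autofluorescence offset (caught only by the
#'   counterscreen).
#' @param seed integer run seed.
#' @param calibrations preset list.
#' @return list with `funnel` (the [run_funnel()] table), `stages` (per-stage
#'   hit calls), `truth` (planted classification per compound) and `qc`
#'   (primary-plate Z' per plate).
#' @export
screen_library <- function(n_compounds = 1000, n_enhancers = 10,
                           n_inhibitors = 20, n_toxic = 5,
                           n_autofluorescent = 0, seed,
                           calibrations = opl_calibrations()) {
  if (missing(seed)) stop("an explicit seed is required")
  ids <- sprintf("cpd_%04d", seq_len(n_compounds))
  planted <- rep("inert", n_compounds)
  stopifnot(n_enhancers + n_inhibitors + n_toxic <= n_compounds)
  set.seed(derive_seed(seed, "library-plant"))
  special <- sample.int(n_compounds, n_enhancers + n_inhibitors + n_toxic)
  planted[special[seq_len(n_enhancers)]] <- "enhancer"
  planted[special[n_enhancers + seq_len(n_inhibitors)]] <- "inhibitor"
  planted[special[n_enhancers + n_inhibitors + seq_len(n_toxic)]] <- "toxic"
  autofl_ids <- head(ids[planted == "inhibitor"], n_autofluorescent)

  truth_config <- list()
  for (i in seq_len(n_compounds)) {
    spec <- switch(planted[i],
      inert = list(preset = "vehicle"),
      enhancer = list(preset = "torin1"),
      inhibitor = list(preset = "bafilomycin"),
      toxic = list(preset = "vehicle", toxic = TRUE))
    if (ids[i] %in% autofl_ids) spec$autofl_offset_red <- 600
    truth_config[[ids[i]]] <- spec
  }

  per_plate <- 352L
  plate_of <- split(ids, ceiling(seq_along(ids) / per_plate))

  primary_schedule <- opl_schedule(-0.5, c(0, 7.5, 15))
  # the primary screen images the native green pool without photoconversion
  cal_nopulse <- no_pulse(calibrations)
  run_gfp_stage <- function(stage, eval_ids, stream) {
    calls <- list(); qc <- list()
    for (p in seq_along(plate_of)) {
      batch <- intersect(plate_of[[p]], eval_ids)
      if (!length(batch)) next
      lay <- layout_screen(sprintf("%s-P%02d", stage, p), batch)
      cfg <- lapply(truth_config[batch], function(s) {
        s$phi <- 0; s })
      plate <- generate_plate(lay, cfg, primary_schedule,
                              derive_seed(seed, stream, p), cal_nopulse)
      fm <- flux_metrics(plate, gfp_t0 = 0, gfp_t1 = 15,
                         fit_half_lives = FALSE)
      dm <- fm$role == "vehicle_control"
      cm <- fm$role == "compound"
      qc[[p]] <- zprime(fm$gfp_ratio[dm], fm$gfp_ratio[fm$role == "positive_control"])
      calls[[p]] <- call_hits(fm[cm, ], fm$gfp_ratio[dm],
                              metric = "gfp_ratio", stage = stage)
      calls[[p]] <- toxicity_filter(calls[[p]],
                                    setNames(fm$cell_area[cm], fm$compound_id[cm]),
                                    fm$cell_area[dm])
    }
    list(calls = do.call(rbind, calls), qc = qc)
  }
  run_red_stage <- function(stage, eval_ids, stream) {
    calls <- list()
    for (p in seq_along(plate_of)) {
      batch <- intersect(plate_of[[p]], eval_ids)
      if (!length(batch)) next
      lay <- layout_screen(sprintf("%s-P%02d", stage, p), batch)
      plate <- generate_plate(lay, truth_config[batch], opl_schedule(),
                              derive_seed(seed, stream, p), calibrations)
      fm <- flux_metrics(plate, readout_h = 9, fit_half_lives = FALSE)
      dm <- fm$role == "vehicle_control"
      calls[[p]] <- call_hits(fm[fm$role == "compound", ],
                              fm$red_ratio_9h[dm],
                              metric = "red_ratio_9h", stage = stage)
    }
    do.call(rbind, calls)
  }

  s1 <- run_gfp_stage("primary", ids, "stage1")
  surv1 <- s1$calls$compound_id[s1$calls$classification %in%
                                  c("enhancer", "inhibitor")]
  s2 <- run_gfp_stage("primary_confirmation", surv1, "stage2")
  surv2 <- s2$calls$compound_id[s2$calls$classification %in%
                                  c("enhancer", "inhibitor")]
  s3 <- run_red_stage("secondary", surv2, "stage3")
  surv3 <- s3$compound_id[s3$classification %in% c("enhancer", "inhibitor")]
  s4 <- run_red_stage("secondary_confirmation", surv3, "stage4")
  surv4 <- s4$compound_id[s4$classification %in% c("enhancer", "inhibitor")]

  # counterscreen in reporter-free cells: only intrinsic fluorescence and
  # noise remain; compounds are measured in triplicate wells and averaged
  set.seed(derive_seed(seed, "counterscreen"))
  n_dmso <- 24L
  cs_dmso <- 100 * lognormal_noise(n_dmso, 0.064)
  offs <- vapply(truth_config[surv4], function(s)
    s$autofl_offset_red %||% 0, numeric(1))
  cs_vals <- (100 + offs) *
    rowMeans(matrix(lognormal_noise(3L * length(surv4), 0.064),
                    ncol = 3L))
  names(cs_vals) <- surv4
  s5 <- s4[s4$compound_id %in% surv4, ]
  s5$stage <- "counterscreen"
  s5 <- autofluorescence_counterscreen(s5, cs_vals, cs_dmso)

  stages <- list(primary = s1$calls, primary_confirmation = s2$calls,
                 secondary = s3, secondary_confirmation = s4,
                 counterscreen = s5)
  funnel <- run_funnel(stages, n_compounds)
  list(funnel = funnel, stages = stages,
       truth = data.frame(compound_id = ids, planted = planted,
                          autofluorescent = ids %in% autofl_ids,
                          stringsAsFactors = FALSE),
       qc = s1$qc)
}
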