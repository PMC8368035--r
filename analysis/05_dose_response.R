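#!/usr/bin/env Rscript
# Dose-response characterisation: ten serial dilutions of a Torin1-like
# enhancer and a bafilomycin-like inhibitor, read out in both channels
# (normalized red ratio at 9 h; GFP ratio at 15 h), fitted with the
# four-parameter logistic. Checks that the two channels report concordant
# midpoints (EC50/IC50).

suppressMessages(library(oplflux))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 2 && args[1] == "--seed") as.integer(args[2]) else 1L
dir.create("results", showWarnings = FALSE)

doses <- 10^seq(-9.5, -6.5, length.out = 10)
drugs <- list(
  torin1_like = list(ec50 = 3e-8, slope = 1, bottom = 1, top = 3),
  bafilomycin_like = list(ec50 = 1e-8, slope = -1.5, bottom = 0.02, top = 1))

rows <- list()
for (drug in names(drugs)) {
  ds <- generate_dilution_series("vehicle", doses, drugs[[drug]],
                                 seed = derive_seed(seed, "dilution", drug),
                                 n_replicates = 6,
                                 schedule = opl_schedule(-0.5, seq(0, 15, 1.5)))
  fm <- flux_metrics(ds, fit_half_lives = FALSE, gfp_t1 = 15)
  fm$dose <- ds$truth$concentration_M[match(fm$well, ds$truth$well)]
  red <- tapply(fm$red_ratio_9h, fm$dose, mean)
  green <- tapply(fm$gfp_ratio, fm$dose, mean)
  f_red <- fit_4pl(as.numeric(names(red)), as.numeric(red))
  f_green <- fit_4pl(as.numeric(names(green)), as.numeric(green))
  cat(sprintf("%s: red %s = %.3g M, green %s = %.3g M, |delta log10| = %.3f\n",
              drug, f_red$kind, f_red$ec50, f_green$kind, f_green$ec50,
              abs(log10(f_red$ec50) - log10(f_green$ec50))))
  rows[[drug]] <- data.frame(
    drug = drug, channel = c("red", "green"),
    kind = c(f_red$kind, f_green$kind),
    midpoint_M = c(f_red$ec50, f_green$ec50),
    hill_slope = c(f_red$hill_slope, f_green$hill_slope),
    r_squared = c(f_red$r_squared, f_green$r_squared))
}
write.csv(do.call(rbind, rows), "results/dose_response.csv",
          row.names = FALSE)
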