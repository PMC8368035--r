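#!/usr/bin/env Rscript
# Simulate the core OPL validation experiments: a three-condition calibration
# plate (vehicle / Torin1 / bafilomycin-A1) imaged every 1.5 h after
# photoconversion, and a "90/10" assay-validation plate (320 DMSO + 32
# Torin1 wells). Writes the plate maps and two-channel time series under
# results/.

suppressMessages(library(oplflux))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 2 && args[1] == "--seed") as.integer(args[2]) else 1L
dir.create("results", showWarnings = FALSE)

cfg <- default_run_config(seed = seed)
meta <- c(seed = seed, config_hash = config_hash(cfg))

# calibration plate: 24 wells per condition
wells <- expand.grid(row = LETTERS[1:6], col = 1:12,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
wells <- wells[order(wells$col, wells$row), ]
role <- rep(c("vehicle_control", "positive_control", "compound"), each = 24)
lay <- plate_layout("calibration", wells$row, wells$col, role,
                    compound_id = ifelse(role == "compound", "bafA1", NA))
plate <- generate_plate(lay, truth_config = list(bafA1 = "bafilomycin"),
                        seed = derive_seed(seed, "calibration-plate"))
write_plate_map(lay, "results/calibration_plate_map.csv", meta)
write_timeseries(plate, "results/calibration_timeseries.csv", meta)

v <- subset(plate$truth, role == "vehicle_control")
cat(sprintf("calibration plate: %d wells, vehicle true t1/2 %.2f h, Torin1 %.2f h, bafilomycin-like wells non-decaying\n",
            nrow(plate$truth), v$half_life_h[1],
            subset(plate$truth, role == "positive_control")$half_life_h[1]))

# 90/10 assay-validation plate: green channel read at 0 and 15 h, no
# photoconversion (the primary screening modality)
p9010 <- generate_plate(layout_90_10(), schedule = opl_schedule(-0.5, c(0, 7.5, 15)),
                        seed = derive_seed(seed, "90-10"),
                        calibrations = no_pulse())
write_timeseries(p9010, "results/plate_9010_timeseries.csv", meta)
cat("90/10 plate:", nrow(p9010$layout), "treated wells written\n")
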