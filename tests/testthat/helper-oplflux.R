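# shared fixtures built in code

# a small rectangular block of wells with one role
block_layout <- function(n, role = "vehicle_control", plate_id = "test",
                         compound_id = NA_character_) {
  w <- expand.grid(row = LETTERS[1:16], col = 1:24,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  w <- w[order(w$col, w$row), ][seq_len(n), ]
  plate_layout(plate_id, w$row, w$col, role, compound_id = compound_id)
}

# single noiseless well under a given truth override
one_well_plate <- function(seed = 1, schedule = opl_schedule(), ...) {
  over <- list(...)
  lay <- block_layout(1, "compound", compound_id = "x")
  generate_plate(lay, truth_config = list(x = c(list(preset = "vehicle"), over)),
                 schedule = schedule, seed = seed)
}

# independent log-linear regression oracle for exponential decay
loglin_halflife <- function(t, y, bg) {
  keep <- y - bg > 0 & t >= 0
  log(2) / (-coef(lm(log(y[keep] - bg) ~ t[keep]))[[2]])
}

# independent grid-search SSE oracle for the decay rate
gridsearch_halflife <- function(t, y, bg, k_grid = seq(0.005, 2, by = 5e-4)) {
  a <- vapply(k_grid, function(k) {
    e <- exp(-k * t)
    sum(e * (y - bg)) / sum(e^2)
  }, numeric(1))
  sse <- vapply(seq_along(k_grid), function(i)
    sum((y - bg - a[i] * exp(-k_grid[i] * t))^2), numeric(1))
  log(2) / k_grid[which.min(sse)]
}
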