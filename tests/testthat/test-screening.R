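test_that("Z' matches the formula oracle and its edge cases", {
  # zero-variance groups give the ideal window
  expect_identical(zprime(c(1, 1, 1), c(4, 4, 4))$z_prime, 1)
  # direct formula evaluation: sd 0.1 each, separation 1.2
  set.seed(91)
  a <- rnorm(2000, 0, 1); a <- (a - mean(a)) / sd(a) * 0.1
  b <- rnorm(2000, 0, 1); b <- (b - mean(b)) / sd(b) * 0.1 + 1.2
  qc <- zprime(a, b)
  expect_equal(qc$z_prime, 1 - 3 * (0.1 + 0.1) / 1.2, tolerance = 1e-9)
  expect_equal(qc$z_prime, 0.5, tolerance = 1e-9)
  # coincident means: flagged -Inf
  expect_identical(zprime(c(1, 2, 3), c(3, 2, 1))$z_prime, -Inf)
  expect_error(zprime(1, c(1, 2)), "at least 2")
})

test_that("Z' is invariant under a common affine transform", {
  set.seed(92)
  neg <- rnorm(320, 1, 0.064); pos <- rnorm(32, 0.4, 0.05)
  z0 <- zprime(neg, pos)$z_prime
  z1 <- zprime(5 * neg + 7, 5 * pos + 7)$z_prime
  expect_equal(z0, z1, tolerance = 1e-12)
})

test_that("simulated 90/10 plates give screening-grade Z' values", {
  sched <- opl_schedule(-0.5, c(0, 7.5, 15))
  zs <- vapply(1:3, function(i) {
    plate <- generate_plate(layout_90_10(sprintf("9010-%d", i)),
                            schedule = sched, seed = 93 + i,
                            calibrations = no_pulse())
    fm <- flux_metrics(plate, gfp_t1 = 15, fit_half_lives = FALSE)
    zprime(fm$gfp_ratio[fm$role == "vehicle_control"],
           fm$gfp_ratio[fm$role == "positive_control"])$z_prime
  }, numeric(1))
  expect_true(all(zs > 0.3) && all(zs < 0.75))
})

test_that("3 SD hit calling implements the symmetric rule with z-scores", {
  set.seed(94)
  dmso <- rnorm(24, 1, 0.05); dmso <- (dmso - mean(dmso)) / sd(dmso) * 0.05 + 1
  m <- data.frame(compound_id = c("a", "b", "c"),
                  gfp_ratio = c(1.0, 0.80, 1.10))
  calls <- call_hits(m, dmso)
  expect_identical(calls$classification, c("none", "enhancer", "none"))
  expect_equal(calls$z_score, c(0, -4, 2), tolerance = 1e-9)
  expect_error(call_hits(m, rep(1, 24)), "zero variance")
  expect_error(call_hits(m, dmso[1:5]), "at least 8")
})

test_that("toxicity filter removes planted toxic wells before hit calling", {
  set.seed(95)
  dmso_area <- rnorm(24, 0.35, 0.35 * 0.05)
  area <- c(t1 = 0.14, t2 = 0.14, ok = 0.35)     # 40% of control
  m <- data.frame(compound_id = names(area), gfp_ratio = c(0.5, 0.6, 1.0))
  calls <- call_hits(m, rnorm(24, 1, 0.05))
  filtered <- toxicity_filter(calls, area, dmso_area)
  expect_identical(filtered$classification[1:2], c("toxic", "toxic"))
  # toxicity preempts the enhancer call the lowered GFP would have produced
  expect_identical(calls$classification[1], "enhancer")
  expect_setequal(attr(filtered, "excluded"), c("t1", "t2"))
  # wells at the DMSO mean are untouched
  expect_identical(filtered$classification[3], "none")
  expect_warning(toxicity_filter(calls, area[1:2], dmso_area), "no cell-area")
})

test_that("autofluorescence counterscreen flags exactly the planted offsets", {
  scr <- screen_library(n_compounds = 120, n_enhancers = 4, n_inhibitors = 8,
                        n_toxic = 2, n_autofluorescent = 4, seed = 96)
  planted <- scr$truth$compound_id[scr$truth$autofluorescent]
  expect_length(planted, 4)
  cs <- scr$stages$counterscreen
  expect_setequal(cs$compound_id[cs$classification == "autofluorescent"],
                  planted)
  # and they are removed from the surviving pool
  expect_length(intersect(attr(scr$funnel, "survivors")$compound_id,
                          planted), 0)
})

test_that("puncta hit flag rides alongside the flux classification", {
  set.seed(97)
  dmso_counts <- rnorm(24, 20, 2)
  m <- data.frame(compound_id = c("baf_like", "enh", "quiet"),
                  red_ratio_9h = c(1.4, 0.1, 0.44))
  calls <- call_hits(m, rnorm(24, 0.44, 0.03), metric = "red_ratio_9h",
                     stage = "secondary")
  calls <- puncta_hit_call(calls, c(baf_like = 60, enh = 45, quiet = 21),
                           dmso_counts)
  expect_identical(calls$classification, c("inhibitor", "enhancer", "none"))
  expect_identical(calls$puncta_change_flag, c(TRUE, TRUE, FALSE))
})

test_that("the 3 SD rule flags about 0.27% of null wells", {
  set.seed(98)
  flagged <- 0L; total <- 0L
  for (p in 1:200) {
    vals <- rnorm(384, 1, 0.064)
    m <- data.frame(compound_id = sprintf("w%03d", 1:384), gfp_ratio = vals)
    calls <- call_hits(m, vals)
    flagged <- flagged + sum(calls$classification != "none")
    total <- total + 384L
  }
  rate <- flagged / total
  ci <- rate + c(-1, 1) * 1.96 * sqrt(rate * (1 - rate) / total)
  expect_true(ci[1] <= 0.0027 && 0.0027 <= ci[2])
})

test_that("filters only ever shrink the hit set", {
  set.seed(99)
  m <- data.frame(compound_id = sprintf("c%02d", 1:40),
                  gfp_ratio = rnorm(40, 1, 0.2))
  calls <- call_hits(m, rnorm(24, 1, 0.05))
  hits0 <- calls$compound_id[calls$classification %in%
                               c("enhancer", "inhibitor")]
  area <- setNames(runif(40, 0.1, 0.4), m$compound_id)
  f1 <- toxicity_filter(calls, area, rnorm(24, 0.35, 0.02))
  hits1 <- f1$compound_id[f1$classification %in% c("enhancer", "inhibitor")]
  expect_true(all(hits1 %in% hits0))
  cs <- setNames(runif(40, 80, 400), m$compound_id)
  f2 <- autofluorescence_counterscreen(f1, cs, rnorm(24, 100, 6))
  hits2 <- f2$compound_id[f2$classification %in% c("enhancer", "inhibitor")]
  expect_true(all(hits2 %in% hits1))
})

test_that("funnel bookkeeping enforces the screening protocol", {
  empty_calls <- data.frame(compound_id = character(0), stage = character(0),
                            classification = character(0),
                            z_score = numeric(0), metric_value = numeric(0),
                            puncta_change_flag = logical(0))
  tab <- run_funnel(list(primary = empty_calls), 0)
  expect_identical(tab$n_compounds, 0L)
  expect_identical(tab$n_enhancers + tab$n_inhibitors, 0L)

  s1 <- data.frame(compound_id = c("a", "b"), stage = "primary",
                   classification = c("enhancer", "none"), z_score = c(-4, 0),
                   metric_value = c(0.5, 1), puncta_change_flag = NA)
  bad <- data.frame(compound_id = "b", stage = "secondary",
                    classification = "enhancer", z_score = -5,
                    metric_value = 0.4, puncta_change_flag = NA)
  expect_error(run_funnel(list(primary = s1, secondary = bad), 2),
               "protocol violation")
})

test_that("a 1000-compound screen recovers planted hits through the funnel", {
  scr <- screen_library(n_compounds = 1000, n_enhancers = 10,
                        n_inhibitors = 20, n_toxic = 5, seed = 42)
  expect_true(all(diff(scr$funnel$n_compounds) <= 0))
  surv <- attr(scr$funnel, "survivors")
  truth <- scr$truth
  true_hits <- truth$compound_id[truth$planted %in% c("enhancer", "inhibitor")]
  recovered <- sum(surv$compound_id %in% true_hits)
  expect_gte(recovered / length(true_hits), 0.9)
  false_surv <- sum(!surv$compound_id %in% true_hits)
  expect_lte(false_surv / 1000, 0.01)
  # planted toxic compounds never survive
  expect_length(intersect(surv$compound_id,
                          truth$compound_id[truth$planted == "toxic"]), 0)
})
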