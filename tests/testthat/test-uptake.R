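# Gating, uptake fractions, the meandering shape test and the model fit.

toy_events <- function(focus, aspect = 0.9, area = 100, count = 0,
                       rigidity = 8, replicate = "rep1") {
  n <- max(lengths(list(focus, aspect, area, count)))
  data.frame(focus_rms = rep_len(focus, n),
             aspect_ratio = rep_len(aspect, n),
             area_px = rep_len(area, n),
             bead_count = rep_len(count, n),
             bead_intensity = rep_len(count, n) * 100,
             rigidity_kpa = rep_len(rigidity, n),
             radius_um = 0.4,
             replicate = rep_len(replicate, n))
}

test_that("gating keeps focused singlets and logs counts", {
  ev <- toy_events(focus = rep(60, 20))
  g <- gate_events(ev)
  expect_identical(nrow(g), 20L)
  expect_identical(unname(attr(g, "gating_counts")["input"]), 20L)
  expect_identical(nrow(gate_events(toy_events(focus = rep(10, 20)))), 0L)
  expect_identical(nrow(gate_events(toy_events(rep(60, 3))[0, ])), 0L)
})

test_that("gating is idempotent on simulated tables", {
  sim <- sim_uptake_events(n_cells = 400, n_replicates = 1, radii = 0.4,
                           seed = 5)
  g1 <- gate_events(sim$events)
  g2 <- gate_events(g1)
  expect_identical(g1$focus_rms, g2$focus_rms)
  expect_identical(nrow(g1), nrow(g2))
})

test_that("the focus gate removes the configured out-of-focus share", {
  sim <- sim_uptake_events(n_cells = 5000, n_replicates = 1, radii = 0.4,
                           panel = c(0.5, 8), out_of_focus_frac = 0.3,
                           doublet_frac = 0, seed = 9)
  kept <- nrow(gate_events(sim$events)) / nrow(sim$events)
  se <- sqrt(0.3 * 0.7 / nrow(sim$events))
  expect_lt(abs(kept - 0.7), 3 * se)
})

test_that("uptake fractions are the share of cells with any bead", {
  expect_identical(uptake_fraction(toy_events(60, count = rep(0, 50)))$fraction_pct,
                   0)
  ev <- toy_events(60, count = c(rep(1, 95), rep(0, 5)))
  expect_identical(uptake_fraction(ev)$fraction_pct, 95)
})

test_that("uptake fractions ignore event order and replicate labels", {
  sim <- sim_uptake_events(n_cells = 300, radii = 0.4, seed = 13)
  f1 <- uptake_fraction(sim$events)
  shuffled <- sim$events[sample(nrow(sim$events)), ]
  f2 <- uptake_fraction(shuffled)
  expect_equal(f1, f2)
  relab <- sim$events
  relab$replicate <- paste0("well_", relab$replicate)
  f3 <- uptake_fraction(relab)
  expect_equal(f3$fraction_pct, f1$fraction_pct)
})

test_that("empirical fractions obey the Poisson zero-class identity", {
  lam <- 0.8
  n <- 10000
  draws <- uptakemech:::with_seed(99, stats::rpois(n, lam))
  ev <- toy_events(60, count = draws)
  f <- uptake_fraction(ev)$fraction_pct / 100
  p <- 1 - exp(-lam)
  expect_lt(abs(f - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("weighted PAVA agrees with stats::isoreg when weights are equal", {
  set.seed(4)
  for (i in 1:20) {
    y <- rnorm(8)
    expect_equal(uptakemech:::pava(y), stats::isoreg(y)$yf, tolerance = 1e-12)
  }
})

test_that("shape verdicts classify clean curves", {
  mk <- function(v) data.frame(rigidity_kpa = rep(seq_along(v), each = 2),
                               replicate = rep(c("a", "b"), length(v)),
                               fraction_pct = rep(v, each = 2))
  up <- detect_nonmonotonicity(mk(c(10, 20, 30, 40, 50, 60)), n_boot = 99)
  expect_identical(up$verdict, "monotone")
  expect_identical(up$monotone_direction, "increasing")
  tent <- detect_nonmonotonicity(mk(c(10, 40, 70, 50, 30, 20)), n_boot = 999)
  expect_identical(tent$verdict, "unimodal_rise_fall")
  expect_lt(tent$p_value, 0.05)
  valley <- detect_nonmonotonicity(mk(c(60, 30, 10, 20, 40, 70)), n_boot = 99)
  expect_identical(valley$verdict, "other")
  expect_error(detect_nonmonotonicity(mk(c(1, 2, 3))), "insufficient")
})

test_that("the monotone RSS dominates the rise-fall RSS on a tent", {
  # exhaustive property behind the tent example: rise-fall fits a tent
  # exactly, monotone cannot
  y <- c(1, 3, 5, 4, 2)
  w <- rep(1, 5)
  mono <- uptakemech:::fit_monotone(y, w)
  rf <- uptakemech:::fit_rise_fall(y, w)
  expect_gt(mono$rss, 0)
  expect_equal(rf$rss, 0, tolerance = 1e-12)
})

test_that("the model fit recovers truth from noiseless fractions", {
  panel <- c(0.5, 2, 8, 16, 32, 64)
  p <- mechanics_params()
  for (R in c(0.4, 1.2)) {
    prob <- 1 - exp(-2 * uptake_propensity(panel, R, p))
    counts <- data.frame(rigidity_kpa = panel, radius_um = R,
                         k = round(1e6 * prob), n = 1e6)
    fit <- fit_uptake_model(counts, p, free = "lambda_scale", lambda0 = 0.5)
    expect_true(fit$converged)
    expect_equal(unname(fit$estimates["lambda_scale"]), 2, tolerance = 1e-2)
    expect_gte(2, fit$ci["lambda_scale", "lower"])
    expect_lte(2, fit$ci["lambda_scale", "upper"])
  }
})

test_that("all-zero counts drive the calibration to its boundary", {
  counts <- data.frame(rigidity_kpa = c(0.5, 2, 8, 16), radius_um = 0.4,
                       k = 0L, n = 500L)
  fit <- fit_uptake_model(counts, lambda0 = 1)
  expect_true(fit$boundary)
  expect_lt(fit$estimates["lambda_scale"], 1e-6)
})

test_that("multistart never worsens the best likelihood", {
  sim <- sim_uptake_events(n_cells = 300, radii = c(0.4, 1.2), seed = 17)
  counts <- uptake_counts(gate_events(sim$events))
  f1 <- fit_uptake_model(counts, n_starts = 1, seed = 3)
  f5 <- fit_uptake_model(counts, n_starts = 5, seed = 3)
  expect_gte(f5$loglik, f1$loglik - 1e-9)
})

test_that("an over-parameterised fit is flagged", {
  counts <- data.frame(rigidity_kpa = c(0.5, 2, 8, 16), radius_um = 0.4,
                       k = c(10, 40, 80, 60), n = 300L)
  fit <- fit_uptake_model(counts,
                          free = c("lambda_scale", "beta_func", "xi_half",
                                   "E_max"),
                          n_starts = 2)
  expect_true(fit$identifiability_warning)
})

test_that("event tables round-trip through CSV", {
  sim <- sim_uptake_events(n_cells = 50, n_replicates = 1, radii = 0.4,
                           seed = 23)
  path <- tempfile(fileext = ".csv")
  write_event_table(sim$events, path)
  back <- read_event_table(path)
  expect_equal(back$bead_count, sim$events$bead_count)
  expect_equal(uptake_fraction(back)$fraction_pct,
               uptake_fraction(sim$events)$fraction_pct)
})
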