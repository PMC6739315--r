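# Dynamics summaries, phase segmentation, memory metrics, rates and the
# replicate statistics.

test_that("dynamics summary: ramp, constant, plateau ties", {
  d <- summarize_dynamics(c(0, 100, 200, 300, 400, 500),
                          c(0, 2, 4, 6, 8, 10))
  expect_identical(d$E_max, 10)
  expect_identical(d$t_E_max, 500)
  expect_identical(d$EC50, 5)
  expect_identical(d$t_EC50, 300)
  d2 <- summarize_dynamics(0:5 * 100, rep(7, 6))
  expect_identical(d2$t_E_max, 0)
  expect_identical(d2$t_EC50, 0)
  d3 <- summarize_dynamics(0:4 * 100, c(0, 9, 3, 9, 1))
  expect_identical(d3$t_E_max, 100)  # first attainment wins
  expect_error(summarize_dynamics(0, 1), "2")
  expect_error(summarize_dynamics(c(0, 0), c(1, 2)), "increasing")
})

test_that("EC50 identity holds for arbitrary series", {
  set.seed(5)
  for (i in 1:25) {
    v <- rpois(50, sample(5:500, 1))
    d <- summarize_dynamics(seq_along(v) * 100, v)
    expect_identical(d$EC50, d$E_max / 2)
    expect_lte(d$t_EC50, d$t_E_max)
  }
})

test_that("phase segmentation recovers constructed changepoints", {
  fx <- make_fixture("triphasic_trace")
  ph <- detect_phases(fx$time, fx$values)
  expect_identical(ph$label, c("active", "deactivation", "stable"))
  dt <- diff(fx$time)[1]
  expect_lte(abs(ph$end[1] - fx$changepoints$active_end), 2 * dt)
  expect_lte(abs(ph$start[3] - fx$changepoints$stable_start), 2 * dt)
  # step-up then flat: one activation phase and one stable plateau
  t2 <- seq(0, 5900, by = 100)
  v2 <- c(0, 50, rep(100, 58))
  ph2 <- detect_phases(t2, v2)
  expect_identical(ph2$label[nrow(ph2)], "stable")
  expect_true("active" %in% ph2$label)
  # all-zero and too-short series
  expect_identical(detect_phases(t2, rep(0, 60))$label, "null")
  expect_identical(detect_phases(1:5 * 100, c(0, 1, 2, 1, 0))$label,
                   "undetermined")
})

test_that("phase lists partition the time axis without gaps or overlaps", {
  set.seed(11)
  for (i in 1:10) {
    t <- seq(0, 7900, by = 100)
    v <- pmax(0, round(cumsum(rnorm(80, 0, 5)) + 50))
    ph <- detect_phases(t, v)
    expect_identical(ph$start[1], t[1])
    expect_identical(ph$end[nrow(ph)], t[length(t)])
    if (nrow(ph) > 1)
      expect_true(all(ph$start[-1] - ph$end[-nrow(ph)] == 100))
  }
})

test_that("memory metrics: baseline, folds and guard rails", {
  t <- seq(0, 36000, by = 100)
  v <- c(rep(500, 325), rep(20, 36))
  m <- memory_metrics(t, v, basal_level = 0.25, e_max = 669)
  expect_identical(m$baseline, 20)
  expect_equal(m$fold_change, 80)
  expect_equal(m$pct_of_emax, 100 * 20 / 669, tolerance = 1e-10)
  expect_equal(m$pct_of_emax, 2.99, tolerance = 1e-3)
  m0 <- memory_metrics(t, rep(0, length(t)), basal_level = 0.25)
  expect_identical(m0$baseline, 0)
  mi <- memory_metrics(t, v, basal_level = 0)
  expect_true(mi$infinite_fold)
  expect_true(is.na(mi$fold_change))
  expect_error(memory_metrics(1:10 * 100, 1:10, 0.2, tail_window = 5000),
               "longer")
})

test_that("deposition rate is exact on linear and piecewise-linear input", {
  expect_identical(ecmp_rate(c(0, 60, 120, 180), c(0, 13, 26, 39)), 13)
  expect_identical(ecmp_rate(c(0, 60, 120), c(7, 7, 7)), 0)
  fx <- make_fixture("linear_ecmp_trace")
  r1 <- ecmp_rate(fx$time, fx$cumulative, c(0, fx$breakpoint))
  r2 <- ecmp_rate(fx$time, fx$cumulative, c(fx$breakpoint, max(fx$time)))
  expect_equal(r1, fx$rates[1], tolerance = 0.01)
  expect_equal(r2, fx$rates[2], tolerance = 0.01)
})

fake_repset <- function(values_by_rep, time = c(0, 100)) {
  runs <- lapply(values_by_rep, function(v) {
    structure(list(series = data.frame(time = time,
                                       pERK = rep(v, length(time))),
                   config = run_config()), class = "mech_abm_sim")
  })
  structure(list(runs = runs, config = run_config(), partial = FALSE),
            class = "mech_abm_replicates")
}

test_that("replicate aggregation gives median with IQR", {
  rs <- fake_repset(list(1, 2, 3, 4, 5))
  agg <- aggregate_replicates(rs, "pERK")
  expect_identical(agg$median[1], 3)
  expect_identical(agg$q25[1], 2)
  expect_identical(agg$q75[1], 4)
  expect_identical(agg$n[1], 5L)
  rs1 <- fake_repset(list(1))
  expect_error(aggregate_replicates(rs1), "2")
})

test_that("group comparison picks the right test and detects real shifts", {
  set.seed(21)
  x <- rnorm(16); y <- rnorm(16)
  r <- compare_groups(x, y)
  expect_identical(r$test, "Welch t")
  expect_gt(r$p_value, 0.05)
  # identical groups are never significant
  expect_gte(compare_groups(x, x)$p_value, 0.999)
  # power: unit shift of five sigma detected essentially always
  hits <- 0
  for (i in 1:100) {
    a <- rnorm(16, 0, 1); b <- rnorm(16, 5, 1)
    if (compare_groups(a, b)$p_value < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 99)
  # non-normal data routes to the rank test
  skewed <- rexp(16)^3
  r2 <- compare_groups(skewed, skewed + 0.01)
  expect_identical(r2$test, "Mann-Whitney")
})

test_that("variant comparison: ANOVA with Tukey, or Kruskal-Wallis", {
  set.seed(31)
  g <- rep(c("SM", "USM", "HM10", "HM1"), each = 16)
  v <- rnorm(64)
  r <- compare_variants(v, g)
  expect_identical(r$test, "one-way ANOVA")
  expect_gt(r$p_value, 0.05)
  expect_true(!is.null(r$posthoc))
  v2 <- v + (g == "HM1") * 5
  r2 <- compare_variants(v2, g)
  expect_lt(r2$p_value, 0.001)
  v3 <- rexp(64)^3
  expect_identical(compare_variants(v3, g)$test, "Kruskal-Wallis")
})

test_that("hill steepness recovers the exponent of synthetic curves", {
  t <- seq(100, 30000, by = 100)
  fit <- vapply(c(1, 2, 4), function(h)
    hill_steepness(t, t^h / (1500^h + t^h)), numeric(1))
  # renormalising by the observed maximum biases the exponent upward a
  # little; recovery within 25% and strict ordering is what we rely on
  expect_equal(fit, c(1, 2, 4), tolerance = 0.25)
  expect_true(all(diff(fit) > 0))
})
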