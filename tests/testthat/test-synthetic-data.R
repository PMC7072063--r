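test_that("copy-number sampling follows the Poisson transduction model", {
  p <- case1_panel()
  m <- vector_copy_model(moi = c(mCherry = 1, Venus = 1, Cerulean = 1))
  n <- 20000
  s <- draw_transduced_events(m, n, p, seed = 1)
  # zero copies of all three vectors occurs at the Poisson zero class e^-3
  none_frac <- mean(rowSums(s$truth$copies) == 0)
  expect_lt(abs(none_frac - exp(-3)),
            3 * sqrt(exp(-3) * (1 - exp(-3)) / n))
  # MOI 0 leaves only autofluorescence: everything gates as "none"
  m0 <- vector_copy_model(moi = c(mCherry = 0, Venus = 0, Cerulean = 0))
  s0 <- compensate(draw_transduced_events(m0, 500, p, seed = 2), p)
  expect_true(all(classify_events_octant(s0, p) == "none"))
  expect_error(vector_copy_model(moi = c(mCherry = -1)), "MOI")
})

test_that("a fixed seed reproduces event tables bit-identically", {
  p <- case1_panel()
  a <- draw_cluster_events(case1_day0_composition(), 1000, p, seed = 99)
  b <- draw_cluster_events(case1_day0_composition(), 1000, p, seed = 99)
  expect_identical(a$events, b$events)
  m <- vector_copy_model(moi = c(mCherry = 1, Venus = 1, Cerulean = 1))
  expect_identical(draw_transduced_events(m, 500, p, seed = 4)$events,
                   draw_transduced_events(m, 500, p, seed = 4)$events)
})

test_that("repeated-batch fractions follow the replicator closed form", {
  pops <- list(clone_population("slow", mu = 0.030, initial_fraction = 0.99),
               clone_population("fast", mu = 0.035, initial_fraction = 0.01))
  sim <- simulate_repeated_batch(pops, n_passages = 26,
                                 passage_interval_h = 120)
  fr <- sim$fractions
  for (t in unique(fr$t_h)) {
    want <- replicator2(c(0.99, 0.01), c(0.030, 0.035), t)
    got <- fr$fraction[fr$t_h == t][match(c("slow", "fast"),
                                          fr$population[fr$t_h == t])]
    expect_lt(max(abs(got - want)), 1e-9)
  }
})

test_that("repeated-batch invariants: conservation, neutrality, single population", {
  # fractions sum to 1 at every recorded time
  pops <- case1_reference_populations()
  sim <- simulate_repeated_batch(pops, n_passages = 26, cap = 11.5e6)
  sums <- tapply(sim$fractions$fraction, sim$fractions$t_h, sum)
  expect_lt(max(abs(sums - 1)), 1e-9)
  # equal growth rates freeze the composition (130 days)
  neutral <- lapply(c("a", "b", "c"), function(l)
    clone_population(l, mu = 0.03,
                     initial_fraction = c(a = 0.5, b = 0.3, c = 0.2)[[l]]))
  ns <- simulate_repeated_batch(neutral, n_passages = 26)
  fr <- ns$fractions
  for (lab in c("a", "b", "c")) {
    v <- fr$fraction[fr$population == lab]
    expect_lt(max(abs(v - v[1])), 1e-12)
  }
  # a single population is the whole culture at all times
  one <- simulate_repeated_batch(
    list(clone_population("only", mu = 0.03, initial_fraction = 1)),
    n_passages = 5)
  expect_true(all(one$fractions$fraction == 1))
  # malformed fractions are rejected
  expect_error(simulate_repeated_batch(
    list(clone_population("x", mu = 0.03, initial_fraction = 0.6),
         clone_population("y", mu = 0.03, initial_fraction = 0.5))),
    "sum to 1")
})

test_that("mixed-culture densities follow the delayed exponential", {
  pops <- afc_reference_populations()
  sim <- simulate_mixed_culture(pops, 0:48, noise_cv = 0)
  ts <- sim$population_ts
  # hand evaluation: 18 h lag, then 30 h growth at 0.037 1/h
  v48 <- ts$X_v[ts$population == "Venus-SP" & ts$t_h == 48]
  expect_equal(v48, 0.25e6 * exp(0.037 * 30), tolerance = 1e-12)
  # density is flat during the lag
  early <- ts$X_v[ts$population == "Venus-SP" & ts$t_h <= 18]
  expect_true(all(early == 0.25e6))
  # lag 0, mu 0 is a constant series
  const <- simulate_mixed_culture(
    list(clone_population("flat", mu = 0, lag = 0)),
    0:10, inoculum_density = 1e6, noise_cv = 0)
  expect_true(all(const$population_ts$X_v == 1e6))
})

test_that("noiseless synthetic data round-trips (lag, mu) through the fit", {
  sim <- simulate_mixed_culture(afc_reference_populations(), 0:48,
                                noise_cv = 0)
  fits <- fit_population_growth(sim$population_ts)
  lags <- c("Cerulean-EX" = 3, "mOrange2-LE" = 13, "mTagBFP-TP" = 15,
            "Venus-SP" = 18)
  for (i in seq_len(nrow(fits))) {
    expect_lt(abs(fits$mu_per_h[i] - 0.037) / 0.037, 1e-6)
    expect_lt(abs(fits$lag_h[i] - lags[[fits$population[i]]]), 1e-6)
  }
})

test_that("bulk kinetics integration matches the analytic linear solution", {
  # zero uptake leaves the concentration untouched
  still <- integrate_bulk_kinetics(
    list(clone_population("p", mu = 0.03, q_glc = 0, initial_fraction = 1)),
    x0 = 1e6, times = seq(0, 48, by = 12))
  expect_true(all(still$c_Glc == 40))
  # constant density: delta c = q * X * dt (X = 5e9 cells/l over 24 h)
  const <- integrate_bulk_kinetics(
    list(clone_population("p", mu = 0, q_glc = 5.00e-11,
                          initial_fraction = 1)),
    x0 = 5e6, times = c(0, 24))
  expect_equal(40 - const$c_Glc[2], 6.0, tolerance = 1e-8)
  # concentrations are floored at zero
  starved <- integrate_bulk_kinetics(
    list(clone_population("p", mu = 0, q_glc = 5.00e-9,
                          initial_fraction = 1)),
    x0 = 5e6, times = c(0, 24))
  expect_equal(starved$c_Glc[2], 0)
  expect_error(integrate_bulk_kinetics(
    list(clone_population("p", mu = 0)), x0 = 1e6, times = c(0, 1),
    dt = 0), "dt")
})

test_that("forward model and rate estimator agree for slowly varying density", {
  q_true <- 4e-11
  pops <- list(clone_population("p", mu = 0.028, q_glc = q_true,
                                q_ab = 1.5e-10, initial_fraction = 1))
  times <- seq(0, 96, by = 12)
  conc <- integrate_bulk_kinetics(pops, x0 = 0.3e6, times = times)
  X <- 0.3e6 * exp(0.028 * times)
  ser <- cbind(data.frame(t_h = times, X_v = X), conc[-1])
  q_est <- specific_rate(ser, "Glc")$q
  expect_lt(max(abs(q_est - q_true) / q_true), 0.02)
  q_ab <- specific_rate(ser, "Ab")$q
  expect_lt(max(abs(q_ab - 1.5e-10) / 1.5e-10), 0.02)
})

test_that("culture sampling reproduces fractions and injects aberrant events", {
  p <- case2_panel()
  labs <- rownames(p$centroids)
  # a pure sample is all one population
  pure <- sample_events_from_culture(stats::setNames(c(1, 0, 0, 0), labs),
                                     p, 500, seed = 30)
  expect_true(all(pure$truth$label == labs[1]))
  # balanced fractions recovered within 3 SE
  n <- 20000
  s <- sample_events_from_culture(stats::setNames(rep(0.25, 4), labs),
                                  p, n, seed = 31)
  for (lab in labs)
    expect_lt(abs(100 * mean(s$truth$label == lab) - 25),
              three_se_pct(25, n))
  # injected doublets fail the FSC-H/FSC-A gate at their rate
  sd_ <- sample_events_from_culture(stats::setNames(rep(0.25, 4), labs),
                                    p, n, seed = 32, doublet_rate = 0.05)
  g <- exclude_debris_doublets(sd_)
  expect_lt(abs(100 * g$exclusions[["doublets"]] / n - 5),
            three_se_pct(5, n))
  # malformed inputs
  expect_error(sample_events_from_culture(
    stats::setNames(c(0.7, 0.7, 0, 0), labs), p, 10), "sum to 1")
})
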