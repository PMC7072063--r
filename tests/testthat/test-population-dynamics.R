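make_series <- function(frac_by_pop, times = 0:9) {
  do.call(rbind, lapply(names(frac_by_pop), function(p)
    data.frame(t_h = times, population = p,
               fraction_pct = rep_len(frac_by_pop[[p]], length(times)))))
}

test_that("population change separates total (points) from individual (relative) shifts", {
  # a constant series changes by (0, 0)
  const <- make_series(list(a = 25, b = 75))
  ch <- population_change(const)
  expect_equal(ch$total_change_pts, c(0, 0))
  expect_equal(ch$individual_change_pct, c(0, 0))
  # 25 % baseline with a -5.01 point shift is a -20.04 % individual change
  s1 <- make_series(list(v = c(rep(25, 5), rep(25 - 5.01, 5))))
  c1 <- population_change(s1, baseline_n = 1, final_n = 1)
  expect_equal(c1$total_change_pts, -5.01)
  expect_equal(c1$individual_change_pct, -20.04)
  # 25 % baseline with a -1.77 point shift is a -7.08 % individual change
  s2 <- make_series(list(m = c(rep(25, 5), rep(25 - 1.77, 5))))
  c2 <- population_change(s2, baseline_n = 1, final_n = 1)
  expect_equal(c2$individual_change_pct, -7.08)
  # linearity: doubling fractions doubles the total change and leaves the
  # individual change unchanged
  set.seed(41)
  fr <- runif(10, 10, 30)
  s <- data.frame(t_h = 0:9, population = "x", fraction_pct = fr)
  s2x <- transform(s, fraction_pct = 2 * fraction_pct)
  a <- population_change(s); b <- population_change(s2x)
  expect_equal(b$total_change_pts, 2 * a$total_change_pts)
  expect_equal(b$individual_change_pct, a$individual_change_pct)
  # guards
  expect_error(population_change(make_series(list(a = 25), times = 0:4),
                                 baseline_n = 3, final_n = 3), "overlap")
  expect_error(population_change(make_series(list(a = c(0, 0, 1, 1)),
                                             times = 0:3),
                                 baseline_n = 1, final_n = 1), "zero")
})

test_that("sum of absolute changes adds printed components and ignores population order", {
  # components 7.95, 2.05, -0.41, -9.59 sum (in magnitude) to 20.00
  s <- make_series(list(
    "Cerulean-EX" = c(rep(25, 5), rep(25 + 7.95, 5)),
    "mOrange2-LE" = c(rep(25, 5), rep(25 + 2.05, 5)),
    "mTagBFP-TP" = c(rep(25, 5), rep(25 - 0.41, 5)),
    "Venus-SP" = c(rep(25, 5), rep(25 - 9.59, 5))))
  expect_equal(sum_abs_changes(s, baseline_n = 1, final_n = 1), 20.00)
  shuffled <- s[sample(nrow(s)), ]
  expect_equal(sum_abs_changes(shuffled, baseline_n = 1, final_n = 1), 20.00)
  expect_equal(sum_abs_changes(make_series(list(a = 20, b = 80))), 0)
  expect_error(sum_abs_changes(make_series(list(a = 25))), "two populations")
})

test_that("broken-stick fit recovers exact and zero-lag series", {
  t <- 0:48
  x <- 2e5 * exp(0.037 * pmax(0, t - 18))
  f <- fit_lag_exponential(t, x)
  expect_lt(abs(f$lag - 18), 1e-9)
  expect_lt(abs(f$mu - 0.037) / 0.037, 1e-9)
  expect_lt(f$rss, 1e-18)
  # pure exponential: lag 0, slope as configured
  f0 <- fit_lag_exponential(0:20, 1e5 * exp(0.05 * (0:20)))
  expect_equal(f0$lag, 0)
  expect_equal(f0$mu, 0.05, tolerance = 1e-9)
  # declining series flags no growth
  expect_warning(fd <- fit_lag_exponential(0:10, 1e5 * exp(-0.02 * (0:10))),
                 "no growth")
  expect_false(fd$growth)
  expect_error(fit_lag_exponential(0:3, rep(1, 4)), "5")
})

test_that("broken-stick fit equals a brute-force two-parameter search per breakpoint", {
  set.seed(52)
  t <- seq(0, 40, by = 4)
  x <- 3e5 * exp(0.04 * pmax(0, t - 12)) * exp(rnorm(length(t), 0, 0.05))
  f <- fit_lag_exponential(t, x)
  # oracle: numeric minimization of the same loss at every candidate lag
  loss <- function(par, L) sum((log(x) - (par[1] + par[2] *
                                            pmax(0, t - L)))^2)
  rss <- vapply(t[seq_len(length(t) - 2)], function(L)
    stats::optim(c(log(3e5), 0.03), loss, L = L)$value, numeric(1))
  best <- t[which.min(rss)]
  expect_equal(f$lag, best)
  expect_equal(f$rss, min(rss), tolerance = 1e-5)
})

test_that("noisy replicates still recover the growth rate in the median", {
  mus <- vapply(1:10, function(s) {
    sim <- simulate_mixed_culture(afc_reference_populations(), 0:48,
                                  noise_cv = 0.05, seed = 100 + s)
    stats::median(fit_population_growth(sim$population_ts)$mu_per_h)
  }, numeric(1))
  expect_lt(abs(stats::median(mus) - 0.037) / 0.037, 0.10)
})

test_that("timeseries assembly computes densities and is order-invariant", {
  pt <- data.frame(t_h = c(0, 0, 24, 24),
                   population = c("a", "b", "a", "b"),
                   fraction_pct = c(25, 75, 40, 60))
  cult <- data.frame(t_h = c(0, 24), X_v = c(4e6, 8e6))
  ts <- assemble_timeseries(pt, cult)
  expect_equal(ts$X_v_population[ts$t_h == 0 & ts$population == "a"], 1e6)
  shuffled <- assemble_timeseries(pt[c(3, 1, 4, 2), ], cult)
  expect_equal(ts, shuffled)
  # single sample works
  one <- assemble_timeseries(pt[1, ], cult)
  expect_equal(nrow(one), 1)
  # agreeing duplicates collapse; conflicting ones error
  expect_equal(nrow(assemble_timeseries(pt[c(1, 1, 2), ], cult)), 2)
  bad <- rbind(pt, data.frame(t_h = 0, population = "a",
                              fraction_pct = 30))
  expect_error(assemble_timeseries(bad, cult), "conflict")
  expect_error(assemble_timeseries(pt, data.frame(t_h = 5, X_v = 1e6)),
               "no culture measurement")
})
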