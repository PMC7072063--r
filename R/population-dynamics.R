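#' Assemble a population time series from sample tables and bulk counts
#'
#' Combines per-sample gated population tables with the bulk viable-density
#' measurements of the same culture: each population's viable density is
#' the total X_v times its fraction. Rows are sorted by time; duplicated
#' (time, population) rows must agree (within `conflict_tol` percentage
#' points) and are collapsed.
#'
#' @param population_tables Data frame (or list of data frames, rbound)
#'   with columns `t_h`, `population`, `fraction_pct`.
#' @param culture Data frame with columns `t_h` and `X_v` (cells/ml).
#' @param conflict_tol Tolerance for duplicated rows, percentage points.
#' @return Data frame of class `population_timeseries` with columns `t_h`,
#'   `population`, `fraction_pct`, `X_v_population` (cells/ml).
#' @export
assemble_timeseries <- function(population_tables, culture,
                                conflict_tol = 1e-9) {
  if (is.list(population_tables) && !is.data.frame(population_tables))
    population_tables <- do.call(rbind, population_tables)
  pt <- as.data.frame(population_tables)
  stopifnot(all(c("t_h", "population", "fraction_pct") %in% names(pt)),
            all(c("t_h", "X_v") %in% names(culture)))
  pt <- pt[order(pt$t_h, pt$population), , drop = FALSE]
  key <- paste(pt$t_h, pt$population)
  if (anyDuplicated(key)) {
    spread <- tapply(pt$fraction_pct, key, function(v) diff(range(v)))
    if (any(spread > conflict_tol))
      stop("conflicting fractions for the same time and population")
    pt <- pt[!duplicated(key), , drop = FALSE]
  }
  idx <- match(pt$t_h, culture$t_h)
  if (anyNA(idx))
    stop("no culture measurement for t_h = ",
         paste(unique(pt$t_h[is.na(idx)]), collapse = ", "))
  out <- data.frame(t_h = pt$t_h, population = pt$population,
                    fraction_pct = pt$fraction_pct,
                    X_v_population = culture$X_v[idx] * pt$fraction_pct / 100,
                    row.names = NULL)
  class(out) <- c("population_timeseries", "data.frame")
  out
}

#' Total and individual population changes
#'
#' For each population, the total change is the mean fraction over the
#' final window minus the mean over the baseline window, in percentage
#' points of all cells; the individual change expresses the same shift
#' relative to the population's own baseline share,
#' `100 * total_change / baseline`.
#'
#' @param series Long data frame with columns `t_h`, `population`,
#'   `fraction_pct` (e.g. from [assemble_timeseries()] or
#'   [simulate_mixed_culture()]`$population_ts`).
#' @param baseline_n,final_n Number of earliest/latest samples averaged as
#'   baseline and final windows. Defaults (3/3) match hourly automated
#'   sampling; use 1/1 for sparse offline sampling. The two windows must
#'   not overlap.
#' @return Data frame with columns `population`, `baseline_pct`,
#'   `final_pct`, `total_change_pts`, `individual_change_pct`.
#' @export
population_change <- function(series, baseline_n = 3, final_n = 3) {
  series <- as.data.frame(series)
  stopifnot(all(c("t_h", "population", "fraction_pct") %in% names(series)),
            baseline_n >= 1, final_n >= 1)
  pops <- unique(as.character(series$population))
  res <- lapply(pops, function(p) {
    s <- series[series$population == p, , drop = FALSE]
    s <- s[order(s$t_h), , drop = FALSE]
    n <- nrow(s)
    if (baseline_n + final_n > n)
      stop("baseline and final windows overlap (", n, " samples for ",
           p, ")")
    base <- mean(s$fraction_pct[seq_len(baseline_n)])
    fin <- mean(s$fraction_pct[seq(n - final_n + 1, n)])
    if (base == 0) stop("baseline fraction is zero for ", p)
    total <- fin - base
    data.frame(population = p, baseline_pct = base, final_pct = fin,
               total_change_pts = total,
               individual_change_pct = 100 * total / base)
  })
  do.call(rbind, res)
}

#' Sum of absolute population changes
#'
#' A scalar heterogeneity-shift summary: the sum over populations of the
#' absolute total changes (percentage points) between the baseline and
#' final windows. Invariant under reordering of the populations.
#'
#' @inheritParams population_change
#' @return Single numeric value (percentage points).
#' @export
sum_abs_changes <- function(series, baseline_n = 3, final_n = 3) {
  if (length(unique(series$population)) < 2)
    stop("need at least two populations")
  sum(abs(population_change(series, baseline_n, final_n)$total_change_pts))
}

#' Broken-stick lag + exponential growth fit
#'
#' Fits log density with a flat segment (the inoculation level) followed by
#' a straight line of slope mu, joined at a breakpoint (the lag time). The
#' breakpoint is searched over the observed sample times; for each
#' candidate L the model `log X(t) = a + mu * max(0, t - L)` is a linear
#' least-squares fit, and the L with the smallest residual sum of squares
#' wins (ties go to the smaller lag). mu is therefore the least-squares
#' slope on the post-lag points, constrained to join the pre-lag level.
#'
#' @param time Sampling times, h (>= 5 points, sorted).
#' @param density Positive viable densities (any consistent unit).
#' @param min_post Minimum number of post-lag points for a reliable slope;
#'   fewer triggers a warning.
#' @return Object of class `growth_fit`: list with `lag` (h), `mu` (1/h),
#'   `log_x0`, `rss`, `n_post`, `growth` (`FALSE` when the best slope is
#'   non-positive, flagged with a warning).
#' @export
fit_lag_exponential <- function(time, density, min_post = 3) {
  stopifnot(length(time) == length(density), length(time) >= 5)
  if (any(density <= 0)) stop("densities must be > 0")
  o <- order(time)
  time <- time[o]; density <- density[o]
  if (anyDuplicated(time)) stop("duplicated time points")
  ly <- log(density)
  n <- length(time)
  cands <- time[seq_len(n - 2)]  # need >= 2 post-lag points for a slope
  best <- NULL
  for (L in cands) {
    x <- pmax(0, time - L)
    fit <- stats::lm.fit(cbind(1, x), ly)
    rss <- sum(fit$residuals^2)
    if (is.null(best) || rss < best$rss - 1e-12) {
      best <- list(lag = L, coef = fit$coefficients, rss = rss,
                   n_post = sum(x > 0))
    }
  }
  mu <- unname(best$coef[2])
  growth <- TRUE
  if (!is.finite(mu) || mu <= 0) {
    warning("no growth detected: fitted slope is non-positive")
    growth <- FALSE
  }
  if (best$n_post < min_post)
    warning("only ", best$n_post, " post-lag points; fit may be unreliable")
  structure(list(lag = best$lag, mu = mu, log_x0 = unname(best$coef[1]),
                 rss = best$rss, n_post = best$n_post, growth = growth),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("<growth_fit> lag = %.3g h, mu = %.4g 1/h (rss %.3g, %d post-lag points)\n",
              x$lag, x$mu, x$rss, x$n_post))
  if (!x$growth) cat("  no growth detected\n")
  invisible(x)
}

#' Fit lag and growth rate for every population in a series
#'
#' Applies [fit_lag_exponential()] to each population's viable-density
#' trajectory.
#'
#' @param series Long data frame with columns `t_h`, `population`, and a
#'   density column.
#' @param density_col Name of the density column (default `"X_v"`).
#' @inheritParams fit_lag_exponential
#' @return Data frame with columns `population`, `lag_h`, `mu_per_h`,
#'   `rss`.
#' @export
fit_population_growth <- function(series, density_col = "X_v",
                                  min_post = 3) {
  stopifnot(density_col %in% names(series))
  pops <- unique(as.character(series$population))
  res <- lapply(pops, function(p) {
    s <- series[series$population == p, , drop = FALSE]
    f <- fit_lag_exponential(s$t_h, s[[density_col]], min_post = min_post)
    data.frame(population = p, lag_h = f$lag, mu_per_h = f$mu, rss = f$rss)
  })
  do.call(rbind, res)
}
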