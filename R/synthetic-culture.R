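#' A marked clonal (sub-)population and its kinetic parameters
#'
#' @param label Population identifier.
#' @param mu Specific growth rate, 1/h (>= 0).
#' @param lag Lag phase, h (>= 0): the population holds its inoculation
#'   density until `lag` and then grows exponentially at `mu`.
#' @param q_glc,q_lac Cell-specific glucose uptake and lactate production
#'   rates, mmol/cell/h (magnitudes, both >= 0).
#' @param q_ab Cell-specific antibody production rate, mg/cell/h (>= 0).
#' @param initial_fraction Share of the inoculum in \[0, 1\] (may be `NA`
#'   when the simulator is given absolute per-population densities).
#' @param marker_profile Optional per-channel log10 intensity distribution
#'   used when sampling cytometry events (see
#'   [sample_events_from_culture()]).
#' @return An object of class `clone_population`.
#' @export
clone_population <- function(label, mu, lag = 0,
                             q_glc = 0, q_lac = 0, q_ab = 0,
                             initial_fraction = NA_real_,
                             marker_profile = NULL) {
  stopifnot(is.character(label), length(label) == 1,
            mu >= 0, lag >= 0, q_glc >= 0, q_lac >= 0, q_ab >= 0)
  if (!is.na(initial_fraction))
    stopifnot(initial_fraction >= 0, initial_fraction <= 1)
  structure(list(label = label, mu = mu, lag = lag,
                 q_glc = q_glc, q_lac = q_lac, q_ab = q_ab,
                 initial_fraction = initial_fraction,
                 marker_profile = marker_profile),
            class = "clone_population")
}

pop_field <- function(populations, field)
  vapply(populations, function(p) p[[field]], numeric(1))

pop_labels <- function(populations)
  vapply(populations, function(p) p$label, character(1))

validate_populations <- function(populations, need_fractions = TRUE) {
  stopifnot(length(populations) >= 1,
            all(vapply(populations, inherits, logical(1),
                       "clone_population")))
  if (anyDuplicated(pop_labels(populations)))
    stop("duplicated population labels")
  if (need_fractions) {
    f <- pop_field(populations, "initial_fraction")
    if (anyNA(f)) stop("all populations need an initial_fraction")
    if (abs(sum(f) - 1) > 1e-9)
      stop("initial fractions must sum to 1 (tolerance 1e-9)")
  }
  invisible(populations)
}

#' Fresh-medium concentrations used at inoculation and after each passage
#'
#' Defaults typical of a chemically defined CHO medium: 40 mmol/l glucose,
#' 6 mmol/l glutamine, no lactate, ammonium or antibody.
#' @return Named numeric vector `c_Glc`, `c_Gln`, `c_Lac`, `c_Amm`, `c_Ab`.
#' @export
default_fresh_medium <- function()
  c(c_Glc = 40, c_Gln = 6, c_Lac = 0, c_Amm = 0, c_Ab = 0)

# Exact integral of x0 * exp(mu * max(0, t - lag)) over [t1, t2].
exp_integral <- function(x0, mu, lag, t1, t2) {
  stopifnot(t2 >= t1)
  a <- min(t2, lag)
  flat <- if (a > t1) x0 * (a - t1) else 0
  b <- max(t1, lag)
  grow <- 0
  if (t2 > b) {
    grow <- if (mu == 0) x0 * (t2 - b)
            else (x0 / mu) * (exp(mu * (t2 - lag)) - exp(mu * (b - lag)))
  }
  flat + grow
}

# Per-population densities (cells/ml) on a time grid, with the optional
# carrying-capacity cap applied as a proportional rescaling of the total
# (composition is not affected by the cap).
population_densities <- function(populations, x0, times, cap = NULL) {
  mus <- pop_field(populations, "mu")
  lags <- pop_field(populations, "lag")
  X <- vapply(seq_along(populations), function(i)
    x0[i] * exp(mus[i] * pmax(0, times - lags[i])),
    numeric(length(times)))
  X <- matrix(X, nrow = length(times),
              dimnames = list(NULL, pop_labels(populations)))
  if (!is.null(cap)) {
    total <- rowSums(X)
    scale <- pmin(1, cap / total)
    X <- X * scale
  }
  X
}

#' Forward-integrate bulk metabolite and product concentrations
#'
#' Integrates d c_Glc/dt = -sum_p q_Glc,p X_p, d c_Lac/dt = +sum_p
#' q_Lac,p X_p and d c_Ab/dt = +sum_p q_Ab,p X_p over a time grid, given
#' the populations' lag/exponential growth. Without a carrying-capacity
#' cap the piecewise-exponential densities are integrated in closed form;
#' with a cap, a trapezoidal rule on a fine sub-grid is used.
#' Concentrations are floored at zero. Glutamine and ammonium are carried
#' through unchanged.
#'
#' @param populations List of [clone_population()].
#' @param x0 Per-population inoculation densities, cells/ml.
#' @param times Strictly increasing time grid, h.
#' @param initial Named initial concentrations (see
#'   [default_fresh_medium()]); mmol/l, antibody mg/l. All must be >= 0.
#' @param cap Optional carrying capacity on the total density, cells/ml.
#' @param dt Sub-grid step (h, > 0) for the capped (numerical) branch.
#' @return Data frame `t_h`, `c_Glc`, `c_Gln`, `c_Lac`, `c_Amm`, `c_Ab`.
#' @export
integrate_bulk_kinetics <- function(populations, x0, times,
                                    initial = default_fresh_medium(),
                                    cap = NULL, dt = 0.05) {
  validate_populations(populations, need_fractions = FALSE)
  stopifnot(length(x0) == length(populations), all(x0 >= 0),
            length(times) >= 1, !is.unsorted(times, strictly = TRUE),
            dt > 0)
  if (any(initial < 0)) stop("initial concentrations must be >= 0")
  q_glc <- pop_field(populations, "q_glc")
  q_lac <- pop_field(populations, "q_lac")
  q_ab <- pop_field(populations, "q_ab")
  mus <- pop_field(populations, "mu")
  lags <- pop_field(populations, "lag")
  k <- length(populations)
  n <- length(times)
  glc <- lac <- ab <- numeric(n)
  glc[1] <- initial[["c_Glc"]]; lac[1] <- initial[["c_Lac"]]
  ab[1] <- initial[["c_Ab"]]
  if (n > 1) for (j in 2:n) {
    t1 <- times[j - 1]; t2 <- times[j]
    if (is.null(cap)) {
      ints <- vapply(seq_len(k), function(i)
        exp_integral(x0[i], mus[i], lags[i], t1, t2), numeric(1))
    } else {
      grid <- unique(c(seq(t1, t2, by = dt), t2))
      X <- population_densities(populations, x0, grid, cap = cap)
      w <- diff(grid)
      ints <- vapply(seq_len(k), function(i)
        sum(w * (X[-1, i] + X[-length(grid), i]) / 2), numeric(1))
    }
    ints_l <- ints * 1e3           # cell h / ml -> cell h / l
    glc[j] <- max(0, glc[j - 1] - sum(q_glc * ints_l))
    lac[j] <- max(0, lac[j - 1] + sum(q_lac * ints_l))
    ab[j] <- max(0, ab[j - 1] + sum(q_ab * ints_l))
  }
  data.frame(t_h = times, c_Glc = glc,
             c_Gln = rep(initial[["c_Gln"]], n),
             c_Lac = lac, c_Amm = rep(initial[["c_Amm"]], n), c_Ab = ab)
}

#' Simulate a long-term repeated-batch (high-passage) culture
#'
#' Within each passage every population grows exponentially at its own rate
#' (lags are ignored here: cells are transferred in exponential phase); at
#' each passage the total density is reset to `seed_density` with the
#' population composition preserved, and the medium is reset to fresh
#' values (supernatant concentrations just before transfer are recorded).
#' The resulting composition follows the replicator dynamics
#' f_p(t) = f_p(0) exp(mu_p t) / sum_q f_q(0) exp(mu_q t).
#'
#' The simulation itself is deterministic; measurement noise belongs to the
#' sampling stage.
#'
#' @param populations List of [clone_population()] with initial fractions
#'   summing to 1.
#' @param n_passages Number of passages (> 0).
#' @param passage_interval_h Passage interval, h (default 120 h = 5 days).
#' @param seed_density Post-passage total density, cells/ml.
#' @param record_every_h Spacing of recorded culture timepoints within a
#'   passage.
#' @param fresh_medium Concentrations after each medium reset.
#' @param cap Optional carrying capacity, cells/ml.
#' @param viability Constant viability fraction reported in the series.
#' @return List of class `repeated_batch_sim`: `culture` (data frame
#'   `t_h`, `t_day`, `passage`, `X_v` cells/ml, `viability`,
#'   concentrations), `fractions` (long data frame `t_h`, `t_day`,
#'   `population`, `fraction` in \[0,1\]), `passage_times_h`, and the
#'   input `populations`.
#' @export
simulate_repeated_batch <- function(populations, n_passages = 26,
                                    passage_interval_h = 120,
                                    seed_density = 0.3e6,
                                    record_every_h = 120,
                                    fresh_medium = default_fresh_medium(),
                                    cap = NULL, viability = 0.97) {
  validate_populations(populations, need_fractions = TRUE)
  stopifnot(n_passages >= 1, passage_interval_h > 0, seed_density > 0,
            record_every_h > 0)
  labels <- pop_labels(populations)
  f <- pop_field(populations, "initial_fraction")
  rel <- unique(c(seq(0, passage_interval_h, by = record_every_h),
                  passage_interval_h))
  culture <- list(); fracs <- list()
  for (pass in seq_len(n_passages)) {
    x0 <- seed_density * f
    tt <- if (pass == 1) rel else rel[-1]  # keep times strictly increasing
    X <- population_densities(populations, x0, tt, cap = cap)
    conc <- integrate_bulk_kinetics(populations, x0,
                                    unique(c(0, tt)),
                                    initial = fresh_medium, cap = cap)
    conc <- conc[match(tt, conc$t_h), , drop = FALSE]
    t_global <- (pass - 1) * passage_interval_h + tt
    total <- rowSums(X)
    culture[[pass]] <- data.frame(
      t_h = t_global, t_day = t_global / 24, passage = pass,
      X_v = total, viability = viability,
      conc[, c("c_Glc", "c_Gln", "c_Lac", "c_Amm", "c_Ab")],
      row.names = NULL)
    frac_mat <- X / total
    fracs[[pass]] <- data.frame(
      t_h = rep(t_global, times = length(labels)),
      t_day = rep(t_global / 24, times = length(labels)),
      population = rep(labels, each = length(tt)),
      fraction = as.vector(frac_mat), row.names = NULL)
    # composition carried into the next passage (cap rescaling cancels)
    Xe <- population_densities(populations, x0, passage_interval_h)
    f <- as.vector(Xe) / sum(Xe)
  }
  structure(list(culture = do.call(rbind, culture),
                 fractions = do.call(rbind, fracs),
                 passage_times_h = passage_interval_h * seq_len(n_passages - 1),
                 populations = populations),
            class = "repeated_batch_sim")
}

#' Simulate a mixed culture of populations with individual lag phases
#'
#' Each population holds its inoculation density until its lag time and
#' then grows exponentially: X_p(t) = X_p(0) for t < lag_p and
#' X_p(0) exp(mu_p (t - lag_p)) after. An optional cap limits the total
#' density. Multiplicative log-normal measurement noise (coefficient of
#' variation `noise_cv`) is applied to densities and concentrations at the
#' sampling times only; the noiseless truth is returned alongside.
#'
#' @param populations List of [clone_population()].
#' @param schedule_h Strictly increasing sampling times, h.
#' @param inoculum_density Per-population inoculation density, cells/ml
#'   (scalar recycled, or vector in population order).
#' @param noise_cv Coefficient of variation of the multiplicative
#'   log-normal measurement noise (0 disables noise).
#' @param cap Optional carrying capacity on the total density, cells/ml.
#' @param seed Optional integer seed.
#' @param initial_medium Concentrations at inoculation.
#' @param viability Constant viability fraction reported in the series.
#' @return List of class `mixed_culture_sim`: `population_ts` (long data
#'   frame `t_h`, `population`, `X_v_true`, `X_v`, `fraction_pct`),
#'   `culture` (bulk series `t_h`, `X_v`, `viability`, concentrations,
#'   with noise), `truth` (noiseless bulk series), and the inputs.
#' @export
simulate_mixed_culture <- function(populations, schedule_h = 0:48,
                                   inoculum_density = 0.25e6,
                                   noise_cv = 0.05, cap = NULL,
                                   seed = NULL,
                                   initial_medium = default_fresh_medium(),
                                   viability = 0.97) {
  validate_populations(populations, need_fractions = FALSE)
  stopifnot(length(schedule_h) >= 1,
            !is.unsorted(schedule_h, strictly = TRUE), noise_cv >= 0)
  if (!is.null(seed)) set.seed(seed)
  labels <- pop_labels(populations)
  k <- length(populations)
  x0 <- rep_len(inoculum_density, k)
  X <- population_densities(populations, x0, schedule_h, cap = cap)
  conc <- integrate_bulk_kinetics(populations, x0, schedule_h,
                                  initial = initial_medium, cap = cap)
  noisy <- function(v) {
    if (noise_cv == 0) return(v)
    sdlog <- sqrt(log(1 + noise_cv^2))
    v * exp(stats::rnorm(length(v), 0, sdlog))
  }
  X_obs <- apply(X, 2, noisy)
  X_obs <- matrix(X_obs, nrow = length(schedule_h),
                  dimnames = dimnames(X))
  total_obs <- rowSums(X_obs)
  pop_ts <- data.frame(
    t_h = rep(schedule_h, times = k),
    population = rep(labels, each = length(schedule_h)),
    X_v_true = as.vector(X),
    X_v = as.vector(X_obs),
    fraction_pct = 100 * as.vector(X_obs / total_obs),
    row.names = NULL)
  culture <- data.frame(
    t_h = schedule_h, X_v = total_obs, viability = viability,
    c_Glc = noisy(conc$c_Glc), c_Gln = noisy(conc$c_Gln),
    c_Lac = noisy(conc$c_Lac), c_Amm = noisy(conc$c_Amm),
    c_Ab = noisy(conc$c_Ab), row.names = NULL)
  truth <- cbind(data.frame(t_h = schedule_h, X_v = rowSums(X),
                            viability = viability),
                 conc[, c("c_Glc", "c_Gln", "c_Lac", "c_Amm", "c_Ab")])
  structure(list(population_ts = pop_ts, culture = culture, truth = truth,
                 populations = populations, schedule_h = schedule_h,
                 noise_cv = noise_cv),
            class = "mixed_culture_sim")
}

#' Reference mixed-growth-phase populations for the bioreactor experiment
#'
#' The four singly marked populations inoculated at 0.25e6 cells/ml each:
#' Cerulean-EX (exponential-phase preculture, lag 3 h), mOrange2-LE (late
#' exponential, 13 h), mTagBFP-TP (transition, 15 h) and Venus-SP
#' (stationary, 18 h), all sharing the common post-lag growth rate
#' mu = 0.037 1/h. Cell-specific rates are set to magnitudes typical of an
#' antibody-producing CHO line.
#'
#' @param mu Common post-lag specific growth rate, 1/h.
#' @param lags Named or positional numeric vector of lag times, h.
#' @return List of four [clone_population()].
#' @export
afc_reference_populations <- function(mu = 0.037,
                                      lags = c("Cerulean-EX" = 3,
                                               "mOrange2-LE" = 13,
                                               "mTagBFP-TP" = 15,
                                               "Venus-SP" = 18)) {
  mapply(function(lab, lag)
    clone_population(lab, mu = mu, lag = lag,
                     q_glc = 4e-11, q_lac = 2e-11, q_ab = 1.5e-10,
                     initial_fraction = 0.25),
    names(lags), lags, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Reference sub-populations for the high-passage culture
#'
#' The eight octant clusters at their typical day-0 shares, plus a faster
#' Venus/Cerulean double-positive variant clone carved out of the GB
#' cluster. The variant is seeded at a small share (already present at
#' inoculation) with a growth-rate and productivity advantage, so it
#' overgrows the culture over repeated passaging.
#'
#' @param base_mu Growth rate of the bulk populations, 1/h.
#' @param variant_mu Growth rate of the variant clone, 1/h.
#' @param variant_fraction Initial share of the variant clone.
#' @return List of nine [clone_population()]; the variant is labelled
#'   `"GB-variant"`.
#' @export
case1_reference_populations <- function(base_mu = 0.028,
                                        variant_mu = 0.033,
                                        variant_fraction = 0.001) {
  comp <- case1_day0_composition()
  f <- comp / sum(comp)
  f["GB"] <- f["GB"] - variant_fraction
  stopifnot(f["GB"] > 0)
  pops <- lapply(names(f), function(lab)
    clone_population(lab, mu = base_mu,
                     q_glc = 4.5e-11, q_lac = 2e-11, q_ab = 1.5e-10,
                     initial_fraction = unname(f[lab])))
  c(pops, list(clone_population("GB-variant", mu = variant_mu,
                                q_glc = 3.5e-11, q_lac = 1.8e-11,
                                q_ab = 3.5e-10,
                                initial_fraction = variant_fraction)))
}
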