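#' Reference octant composition of a freshly RGB-marked culture
#'
#' Default eight-cluster composition (percent of gated events) used by the
#' simulator to emulate a culture co-transduced with three colour vectors at
#' an effective MOI near one per vector: 13.8 unstained, 8.56 R, 8.66 G,
#' 7.76 B, 10.8 RG, 7.19 BR, 20.6 GB, 22.7 RGB. The values sum to 100.07
#' because each is rounded independently; generators renormalize.
#'
#' @return Named numeric vector over [octant_levels()].
#' @export
case1_day0_composition <- function()
  c(none = 13.8, R = 8.56, G = 8.66, B = 7.76,
    RG = 10.8, GB = 20.6, BR = 7.19, RGB = 22.7)

#' Reference end-of-study marginal positives (day 130)
#'
#' Marginal channel-positive percentages after 130 days of repeated-batch
#' culture, once a single Venus/Cerulean double-positive clone has overgrown
#' the culture: mCherry 4.01, Venus 84.3, Cerulean 84.8.
#'
#' @return Named numeric vector of percentages per channel.
#' @export
case1_day130_marginals <- function()
  c(mCherry = 4.01, Venus = 84.3, Cerulean = 84.8)

octant_color_sets <- function()
  list(none = character(0), R = "R", G = "G", B = "B",
       RG = c("R", "G"), GB = c("G", "B"), BR = c("B", "R"),
       RGB = c("R", "G", "B"))

#' Marginal positives implied by an octant composition
#'
#' The marginal percentage for a colour is the sum of the fractions of all
#' octants whose label contains that colour.
#'
#' @param composition Named numeric vector over [octant_levels()] (percent).
#' @return Named numeric vector `c(R=, G=, B=)` of percentages.
#' @export
marginals_from_composition <- function(composition) {
  sets <- octant_color_sets()
  vapply(c("R", "G", "B"), function(col)
    sum(composition[vapply(sets[names(composition)],
                           function(s) col %in% s, logical(1))]),
    numeric(1))
}

#' Octant composition from independent marginals
#'
#' Builds an eight-cluster composition assuming the three colours are
#' positive independently of each other — appropriate when only the
#' marginal positive percentages are known.
#'
#' @param marginals Named numeric vector `c(R=, G=, B=)` of percentages.
#' @return Named numeric vector over [octant_levels()] summing to 100.
#' @export
composition_from_marginals <- function(marginals) {
  p <- marginals / 100
  sets <- octant_color_sets()
  out <- vapply(names(sets), function(lab) {
    pos <- sets[[lab]]
    prod(p[pos], 1 - p[setdiff(c("R", "G", "B"), pos)])
  }, numeric(1))
  100 * out[octant_levels()]
}

# Scatter signal generator: singlets centred at FSC-A ~ 5e5 with
# FSC-H/FSC-A ~ 1; debris gets low scatter (outside the FSC/SSC
# rectangle), doublets double FSC-A at unchanged FSC-H.
make_scatter <- function(n, doublet_rate = 0, debris_rate = 0) {
  fsc <- pmax(stats::rnorm(n, 5e5, 5e4), 2e5)
  fsch <- fsc * stats::rnorm(n, 1, 0.02)
  ssc <- pmax(stats::rnorm(n, 4e5, 8e4), 1e5)
  debris <- stats::runif(n) < debris_rate
  if (any(debris)) {
    nd <- sum(debris)
    fsc[debris] <- pmin(pmax(stats::rnorm(nd, 6e4, 1.5e4), 1e3), 1.2e5)
    fsch[debris] <- fsc[debris] * stats::rnorm(nd, 1, 0.05)
    ssc[debris] <- pmin(pmax(stats::rnorm(nd, 2e4, 5e3), 1e3), 4e4)
  }
  doublet <- !debris & stats::runif(n) < doublet_rate
  fsc[doublet] <- fsc[doublet] * 2
  list(scatter = data.frame(`FSC-A` = fsc, `FSC-H` = fsch, `SSC-A` = ssc,
                            check.names = FALSE),
       debris = debris, doublet = doublet)
}

# Core intensity generator shared by the cluster- and marginal-driven
# event simulators: given a per-event/channel positivity flag matrix, draw
# log-normal intensities above or below the panel threshold, then apply
# forward spillover so the preprocessing stage has real work to undo.
draw_events_from_flags <- function(flags, panel,
                                   positive_log10_mean = 4.3,
                                   positive_log10_sd = 0.3,
                                   negative_log10_mean = 2.0,
                                   negative_log10_sd = 0.3,
                                   debris_rate = 0, doublet_rate = 0,
                                   apply_spillover = TRUE,
                                   time_h = NA_real_,
                                   culture_id = NA_character_) {
  channels <- colnames(flags)
  if (is.null(channels)) stop("flag matrix needs channel column names")
  n <- nrow(flags)
  expand <- function(x) {
    if (is.null(names(x))) stats::setNames(rep_len(x, length(channels)),
                                           channels)
    else x[channels]
  }
  pm <- expand(positive_log10_mean); ps <- expand(positive_log10_sd)
  nm <- expand(negative_log10_mean); ns <- expand(negative_log10_sd)
  ev <- as.data.frame(matrix(0, n, length(channels),
                             dimnames = list(NULL, channels)))
  for (ch in channels) {
    pos <- flags[, ch]
    x <- stats::rnorm(n, ifelse(pos, pm[ch], nm[ch]),
                      ifelse(pos, ps[ch], ns[ch]))
    intensity <- 10^x
    thr <- panel$thresholds[[ch]]
    # keep draws on the correct side of the positivity boundary
    intensity <- ifelse(pos, pmax(intensity, thr * 1.05),
                        pmin(intensity, thr * 0.95))
    ev[[ch]] <- intensity
  }
  sc <- make_scatter(n, doublet_rate = doublet_rate,
                     debris_rate = debris_rate)
  s <- flow_sample(cbind(sc$scatter, ev), time_h = time_h,
                   culture_id = culture_id)
  has_spill <- !is.null(panel$spillover) && nrow(panel$spillover) > 0
  if (apply_spillover && has_spill) {
    s <- add_spillover(s, panel)
  } else if (has_spill) {
    s$compensated <- TRUE
  }
  s$truth <- list(debris = sc$debris, doublet = sc$doublet)
  s
}

#' Simulate events with a prescribed octant composition
#'
#' Draws event cluster memberships multinomially from `composition`, gives
#' each event log-normal intensities above (positive colours) or below
#' (negative colours) the panel thresholds, applies forward spillover, and
#' adds scatter signals (optionally with debris and doublet events whose
#' cluster truth is retained).
#'
#' @param composition Named numeric vector over (a subset of)
#'   [octant_levels()]; renormalized to sum to 1.
#' @param n_events Number of events (> 0).
#' @param panel A [panel_config()] with an R/G/B colour map, e.g.
#'   [case1_panel()].
#' @param seed Optional integer seed for reproducibility.
#' @param positive_log10_mean,positive_log10_sd,negative_log10_mean,negative_log10_sd
#'   Log10-intensity distribution parameters, scalar or named per channel.
#' @param debris_rate,doublet_rate Fractions of events given debris scatter
#'   or doubled FSC-A.
#' @return A raw [flow_sample()]; `$truth$label` holds the generating
#'   octant per event.
#' @export
draw_cluster_events <- function(composition, n_events, panel = case1_panel(),
                                seed = NULL,
                                positive_log10_mean =
                                  c(mCherry = 4.3, Venus = 5.0,
                                    Cerulean = 4.2),
                                positive_log10_sd = 0.3,
                                negative_log10_mean = 2.0,
                                negative_log10_sd = 0.3,
                                debris_rate = 0, doublet_rate = 0,
                                time_h = NA_real_,
                                culture_id = NA_character_) {
  stopifnot(n_events > 0, all(composition >= 0), sum(composition) > 0)
  bad <- setdiff(names(composition), octant_levels())
  if (length(bad)) stop("unknown octant label(s): ", paste(bad, collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  p <- composition / sum(composition)
  labels <- sample(names(p), n_events, replace = TRUE, prob = p)
  sets <- octant_color_sets()
  chans <- panel$colors[c("R", "G", "B")]
  flags <- matrix(FALSE, n_events, 3, dimnames = list(NULL, unname(chans)))
  for (col in c("R", "G", "B")) {
    in_set <- vapply(sets, function(s) col %in% s, logical(1))
    flags[, chans[[col]]] <- in_set[labels]
  }
  s <- draw_events_from_flags(flags, panel,
                              positive_log10_mean = positive_log10_mean,
                              positive_log10_sd = positive_log10_sd,
                              negative_log10_mean = negative_log10_mean,
                              negative_log10_sd = negative_log10_sd,
                              debris_rate = debris_rate,
                              doublet_rate = doublet_rate,
                              time_h = time_h, culture_id = culture_id)
  s$truth$label <- labels
  s
}

#' Simulate events with prescribed independent marginals
#'
#' Each channel is set positive independently with the given marginal
#' probability — the natural generator when only per-channel positive
#' percentages are known (e.g. late-culture samples dominated by one
#' multi-positive clone plus an unstained residue are still described by
#' their marginals).
#'
#' @param marginals Named numeric vector of channel-positive percentages.
#' @inheritParams draw_cluster_events
#' @return A raw [flow_sample()]; `$truth$flags` holds the generating flags.
#' @export
draw_marginal_events <- function(marginals, n_events, panel = case1_panel(),
                                 seed = NULL,
                                 positive_log10_mean =
                                   c(mCherry = 4.3, Venus = 5.0,
                                     Cerulean = 4.2),
                                 positive_log10_sd = 0.3,
                                 negative_log10_mean = 2.0,
                                 negative_log10_sd = 0.3,
                                 debris_rate = 0, doublet_rate = 0,
                                 time_h = NA_real_,
                                 culture_id = NA_character_) {
  stopifnot(n_events > 0, all(marginals >= 0), all(marginals <= 100))
  bad <- setdiff(names(marginals), panel$channels)
  if (length(bad)) stop("unknown channel(s): ", paste(bad, collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  chans <- names(marginals)
  flags <- matrix(FALSE, n_events, length(chans),
                  dimnames = list(NULL, chans))
  for (ch in chans)
    flags[, ch] <- stats::runif(n_events) < marginals[[ch]] / 100
  s <- draw_events_from_flags(flags, panel,
                              positive_log10_mean = positive_log10_mean,
                              positive_log10_sd = positive_log10_sd,
                              negative_log10_mean = negative_log10_mean,
                              negative_log10_sd = negative_log10_sd,
                              debris_rate = debris_rate,
                              doublet_rate = doublet_rate,
                              time_h = time_h, culture_id = culture_id)
  s$truth$flags <- flags
  s
}

#' Poisson copy-number model for multi-vector transduction
#'
#' Describes stochastic co-transduction with one lentiviral vector per
#' colour channel: the integrated copy number of each vector is Poisson
#' with its effective (functional) MOI, independently across vectors, and
#' each copy contributes an independent log-normal signal added linearly on
#' top of log-normal autofluorescence.
#'
#' @param moi Named non-negative numeric vector of effective MOIs, one per
#'   channel.
#' @param per_copy_log10_mean,per_copy_log10_sd Log10 parameters of the
#'   per-copy signal (scalar or named per channel); SDs must be >= 0.
#' @param autofluorescence_log10_mean,autofluorescence_log10_sd Log10
#'   parameters of the unstained background.
#' @return An object of class `vector_copy_model`.
#' @export
vector_copy_model <- function(moi,
                              per_copy_log10_mean = 4.0,
                              per_copy_log10_sd = 0.25,
                              autofluorescence_log10_mean = 2.0,
                              autofluorescence_log10_sd = 0.25) {
  if (is.null(names(moi))) stop("moi must be named by channel")
  if (any(moi < 0)) stop("effective MOI must be >= 0")
  if (any(c(per_copy_log10_sd, autofluorescence_log10_sd) < 0))
    stop("log10 SDs must be >= 0")
  structure(list(moi = moi,
                 per_copy_log10_mean = per_copy_log10_mean,
                 per_copy_log10_sd = per_copy_log10_sd,
                 autofluorescence_log10_mean = autofluorescence_log10_mean,
                 autofluorescence_log10_sd = autofluorescence_log10_sd),
            class = "vector_copy_model")
}

#' Draw events from a transduction copy-number model
#'
#' Samples per-vector copy counts (Poisson), builds linear channel
#' intensities as autofluorescence plus the sum of per-copy log-normal
#' signals, applies forward spillover per the panel, and attaches scatter
#' signals.
#'
#' @param model A [vector_copy_model()] whose `moi` names are panel
#'   channels.
#' @param n_events Number of events (> 0).
#' @param panel A [panel_config()].
#' @param seed Optional integer seed.
#' @inheritParams draw_cluster_events
#' @return A raw [flow_sample()]; `$truth$copies` holds the per-event copy
#'   count matrix.
#' @export
draw_transduced_events <- function(model, n_events, panel = case1_panel(),
                                   seed = NULL,
                                   debris_rate = 0, doublet_rate = 0,
                                   time_h = NA_real_,
                                   culture_id = NA_character_) {
  stopifnot(inherits(model, "vector_copy_model"), n_events > 0)
  if (!is.null(seed)) set.seed(seed)
  channels <- names(model$moi)
  bad <- setdiff(channels, panel$channels)
  if (length(bad)) stop("unknown channel(s): ", paste(bad, collapse = ", "))
  expand <- function(x) {
    if (is.null(names(x))) stats::setNames(rep_len(x, length(channels)),
                                           channels)
    else x[channels]
  }
  cm <- expand(model$per_copy_log10_mean)
  cs <- expand(model$per_copy_log10_sd)
  am <- expand(model$autofluorescence_log10_mean)
  as_ <- expand(model$autofluorescence_log10_sd)
  copies <- matrix(0L, n_events, length(channels),
                   dimnames = list(NULL, channels))
  ev <- as.data.frame(matrix(0, n_events, length(channels),
                             dimnames = list(NULL, channels)))
  for (ch in channels) {
    k <- stats::rpois(n_events, model$moi[[ch]])
    copies[, ch] <- k
    signal <- numeric(n_events)
    tot <- sum(k)
    if (tot > 0) {
      draws <- 10^stats::rnorm(tot, cm[ch], cs[ch])
      idx <- rep(seq_len(n_events), k)
      agg <- rowsum(draws, idx)
      signal[as.integer(rownames(agg))] <- agg[, 1]
    }
    ev[[ch]] <- 10^stats::rnorm(n_events, am[ch], as_[ch]) + signal
  }
  sc <- make_scatter(n_events, doublet_rate = doublet_rate,
                     debris_rate = debris_rate)
  s <- flow_sample(cbind(sc$scatter, ev), time_h = time_h,
                   culture_id = culture_id)
  if (!is.null(panel$spillover) && nrow(panel$spillover) > 0)
    s <- add_spillover(s, panel)
  s$truth <- list(copies = copies, debris = sc$debris, doublet = sc$doublet)
  s
}

#' Sample a cytometry acquisition from known population fractions
#'
#' Links the culture simulators to the cytometry stages: event population
#' memberships are multinomial in the supplied fractions, intensities are
#' drawn from each population's marker profile (by default log-normal
#' clusters at the panel centroids), and debris/doublet events are injected
#' at the configured rates.
#'
#' @param fractions Named numeric vector of population fractions summing to
#'   1 (tolerance 1e-6).
#' @param panel A [panel_config()]; its `centroids` provide default marker
#'   profiles.
#' @param events_per_sample Number of events (> 0).
#' @param profiles Optional named list per population:
#'   `list(log10_mean = <named per channel>, log10_sd = <scalar or named>)`.
#' @param seed Optional integer seed.
#' @inheritParams draw_cluster_events
#' @return A [flow_sample()]; `$truth$label` holds the generating
#'   population.
#' @export
sample_events_from_culture <- function(fractions, panel, events_per_sample,
                                       profiles = NULL, seed = NULL,
                                       debris_rate = 0, doublet_rate = 0,
                                       time_h = NA_real_,
                                       culture_id = NA_character_) {
  stopifnot(inherits(panel, "panel_config"), events_per_sample > 0)
  if (length(panel$channels) == 0) stop("empty panel")
  if (abs(sum(fractions) - 1) > 1e-6)
    stop("population fractions must sum to 1")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(profiles)) {
    if (is.null(panel$centroids))
      stop("no profiles given and panel has no centroids")
    profiles <- lapply(rownames(panel$centroids), function(p)
      list(log10_mean = panel$centroids[p, ], log10_sd = 0.15))
    names(profiles) <- rownames(panel$centroids)
  }
  bad <- setdiff(names(fractions), names(profiles))
  if (length(bad)) stop("no marker profile for: ", paste(bad, collapse = ", "))
  n <- events_per_sample
  membership <- sample(names(fractions), n, replace = TRUE, prob = fractions)
  channels <- panel$channels
  ev <- as.data.frame(matrix(0, n, length(channels),
                             dimnames = list(NULL, channels)))
  for (ch in channels) {
    mu <- vapply(profiles, function(p) p$log10_mean[[ch]], numeric(1))
    sd_ <- vapply(profiles, function(p) {
      s <- p$log10_sd
      if (is.null(names(s))) s[1] else s[[ch]]
    }, numeric(1))
    ev[[ch]] <- 10^stats::rnorm(n, mu[membership], sd_[membership])
  }
  sc <- make_scatter(n, doublet_rate = doublet_rate,
                     debris_rate = debris_rate)
  s <- flow_sample(cbind(sc$scatter, ev), time_h = time_h,
                   culture_id = culture_id)
  if (!is.null(panel$spillover) && nrow(panel$spillover) > 0)
    s <- add_spillover(s, panel)
  s$truth <- list(label = membership, debris = sc$debris,
                  doublet = sc$doublet)
  s
}
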