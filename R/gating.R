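#' Per-event positivity flags
#'
#' An event is positive for a channel when its (compensated) intensity is
#' strictly above the panel's positivity threshold for that channel; an
#' intensity exactly at the threshold is negative.
#'
#' @param sample A [flow_sample()]; must be compensated when the panel
#'   defines spillover terms.
#' @param panel A [panel_config()] with `thresholds`.
#' @param channels Channels to flag (default: all threshold-bearing panel
#'   channels).
#' @return Logical matrix, one row per event, one column per channel.
#' @export
positivity_flags <- function(sample, panel, channels = NULL) {
  stopifnot(inherits(sample, "flow_sample"), inherits(panel, "panel_config"))
  if (is.null(panel$thresholds)) stop("panel has no positivity thresholds")
  if (!is.null(panel$spillover) && nrow(panel$spillover) > 0 &&
      !isTRUE(sample$compensated))
    stop("sample must be compensated before gating")
  if (is.null(channels)) channels <- names(panel$thresholds)
  bad <- setdiff(channels, names(sample$events))
  if (length(bad)) stop("unknown channel(s): ", paste(bad, collapse = ", "))
  n <- nrow(sample$events)
  flags <- matrix(FALSE, n, length(channels),
                  dimnames = list(NULL, channels))
  for (ch in channels)
    flags[, ch] <- sample$events[[ch]] > panel$thresholds[[ch]]
  flags
}

#' Octant population labels
#'
#' The eight canonical octant labels, in the conventional order: unstained
#' first, the three single colours, then the pairwise combinations and the
#' triple-positive class.
#' @return Character vector of length 8.
#' @export
octant_levels <- function()
  c("none", "R", "G", "B", "RG", "GB", "BR", "RGB")

#' Classify events into colour octants
#'
#' Maps the on/off state of the three colour flags onto the 2^3 = 8
#' octant labels: the label is the set of positive colours (`none` when all
#' are negative; the two-colour classes are written `RG`, `GB` and `BR`).
#' The classification is exhaustive and mutually exclusive.
#'
#' @param flags Logical matrix with three columns in R, G, B order (any
#'   column names are accepted; order is what counts), one row per event.
#' @return Factor of octant labels with levels [octant_levels()].
#' @export
classify_octant <- function(flags) {
  flags <- as.matrix(flags)
  if (ncol(flags) != 3 || !is.logical(flags))
    stop("flags must be a logical matrix with three columns (R, G, B)")
  key <- flags[, 1] * 4L + flags[, 2] * 2L + flags[, 3] * 1L
  lut <- c("none", "B", "G", "GB", "R", "BR", "RG", "RGB")
  factor(lut[key + 1L], levels = octant_levels())
}

#' Octant-classify a compensated sample
#'
#' Convenience wrapper: computes [positivity_flags()] on the panel's three
#' colour channels (via `panel$colors`) and classifies each event with
#' [classify_octant()].
#'
#' @inheritParams positivity_flags
#' @return Factor of octant labels, one per event.
#' @export
classify_events_octant <- function(sample, panel) {
  if (is.null(panel$colors) || !all(c("R", "G", "B") %in% names(panel$colors)))
    stop("panel needs an R/G/B colour map for octant gating")
  chans <- panel$colors[c("R", "G", "B")]
  flags <- positivity_flags(sample, panel, channels = unname(chans))
  classify_octant(flags)
}

#' Classify events of a four-population mixed culture
#'
#' Assigns each event to one of the panel's populations by nearest centroid
#' in log10 intensity space (Euclidean distance over the panel's two
#' detector channels), or by rectangular gates. Distance ties, and events
#' falling into zero or several rectangles, are labelled `"unassigned"`.
#'
#' @param sample A [flow_sample()].
#' @param panel A [panel_config()] carrying `centroids` (log10 units).
#' @param method `"centroid"` (default) or `"rectangle"`.
#' @param gates For `method = "rectangle"`: named list, one element per
#'   population, each a named list of `c(lo, hi)` raw-intensity ranges per
#'   channel.
#' @param tie_tol Absolute tolerance on squared log-distance below which two
#'   centroids are considered equidistant.
#' @return Factor with the population labels plus level `"unassigned"`.
#' @export
classify_four_color <- function(sample, panel,
                                method = c("centroid", "rectangle"),
                                gates = NULL, tie_tol = 1e-9) {
  stopifnot(inherits(sample, "flow_sample"), inherits(panel, "panel_config"))
  method <- match.arg(method)
  if (method == "centroid") {
    if (is.null(panel$centroids)) stop("panel has no centroids")
    cen <- panel$centroids
    chans <- colnames(cen)
    bad <- setdiff(chans, names(sample$events))
    if (length(bad)) stop("missing channel(s): ", paste(bad, collapse = ", "))
    li <- log10(pmax(as.matrix(sample$events[chans]), panel$floor_value))
    d2 <- sapply(rownames(cen), function(p)
      rowSums((li - matrix(cen[p, ], nrow(li), ncol(li), byrow = TRUE))^2))
    d2 <- matrix(d2, nrow = nrow(li),
                 dimnames = list(NULL, rownames(cen)))
    best <- max.col(-d2, ties.method = "first")
    lab <- rownames(cen)[best]
    dmin <- d2[cbind(seq_len(nrow(d2)), best)]
    d2[cbind(seq_len(nrow(d2)), best)] <- Inf
    second <- apply(d2, 1, min)
    lab[second - dmin <= tie_tol] <- "unassigned"
    factor(lab, levels = c(rownames(cen), "unassigned"))
  } else {
    if (is.null(gates)) stop("rectangle mode needs gates")
    n <- nrow(sample$events)
    hits <- sapply(names(gates), function(p) {
      inside <- rep(TRUE, n)
      for (ch in names(gates[[p]])) {
        rng <- gates[[p]][[ch]]
        v <- sample$events[[ch]]
        inside <- inside & v >= rng[1] & v <= rng[2]
      }
      inside
    })
    hits <- matrix(hits, nrow = n, dimnames = list(NULL, names(gates)))
    nhit <- rowSums(hits)
    lab <- rep("unassigned", n)
    one <- nhit == 1
    lab[one] <- colnames(hits)[max.col(hits[one, , drop = FALSE])]
    factor(lab, levels = c(names(gates), "unassigned"))
  }
}

#' Gated population sizes
#'
#' Counts and percentages per population over all retained (gated) events.
#' The population size is the number of events carrying a label, expressed
#' as a percentage of the retained events.
#'
#' @param labels Factor (or character vector) of per-event population
#'   labels; factor levels define which populations are reported (including
#'   empty ones).
#' @return Data frame with columns `population`, `count`, `fraction_pct`.
#' @export
population_sizes <- function(labels) {
  if (length(labels) == 0) stop("empty assignment")
  tab <- table(labels)
  data.frame(population = names(tab),
             count = as.integer(tab),
             fraction_pct = 100 * as.integer(tab) / length(labels),
             row.names = NULL)
}

#' Marginal channel-positive percentages
#'
#' The percentage of retained events positive for each channel
#' individually (e.g. "% mCherry-positive"). Marginal gates overlap across
#' octants: the marginal for a colour equals the sum of the fractions of
#' every octant containing that colour.
#'
#' @param flags Logical positivity matrix from [positivity_flags()].
#' @return Named numeric vector of percentages.
#' @export
marginal_positive_pct <- function(flags) {
  flags <- as.matrix(flags)
  if (nrow(flags) == 0) stop("empty sample")
  100 * colMeans(flags)
}
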