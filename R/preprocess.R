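#' Exclude debris and doublets by scatter gating
#'
#' Debris is excluded with a rectangular gate on SSC-A vs FSC-A; doublets
#' are then excluded by requiring the FSC-H/FSC-A ratio to fall inside
#' `ratio_range` (a doublet carries roughly twice the area signal of a
#' singlet at similar height, so its ratio drops to about one half).
#'
#' @param sample A [flow_sample()].
#' @param fsc_range,ssc_range Numeric length-2 inclusive gates on FSC-A and
#'   SSC-A. Use `c(-Inf, Inf)` for an identity gate.
#' @param ratio_range Inclusive bounds on FSC-H/FSC-A for singlets.
#'
#' @return The filtered `flow_sample`, with `$exclusions` holding named
#'   counts `debris` and `doublets`. Errors if every event is excluded.
#' @export
exclude_debris_doublets <- function(sample,
                                    fsc_range = c(1.5e5, 1.5e6),
                                    ssc_range = c(5e4, 1.5e6),
                                    ratio_range = c(0.8, 1.25)) {
  stopifnot(inherits(sample, "flow_sample"))
  ev <- sample$events
  miss <- setdiff(scatter_columns(), names(ev))
  if (length(miss))
    stop("missing scatter column(s): ", paste(miss, collapse = ", "))
  fsc <- ev[["FSC-A"]]
  ssc <- ev[["SSC-A"]]
  debris <- fsc < fsc_range[1] | fsc > fsc_range[2] |
            ssc < ssc_range[1] | ssc > ssc_range[2]
  ratio <- ev[["FSC-H"]] / fsc
  doublet <- !debris & (ratio < ratio_range[1] | ratio > ratio_range[2])
  keep <- !debris & !doublet
  if (!any(keep))
    stop("all events excluded as debris or doublets; empty sample")
  out <- sample
  out$events <- ev[keep, , drop = FALSE]
  if (!is.null(out$truth) && !is.null(out$truth$label))
    out$truth$label <- out$truth$label[keep]
  out$exclusions <- c(debris = sum(debris), doublets = sum(doublet))
  out
}

#' Apply spillover compensation
#'
#' Subtracts linear spillover sequentially in the row order of
#' `panel$spillover`: each target channel has `coefficient x source`
#' subtracted, using the already-compensated source signal by default
#' (the standard triangularized-matrix behaviour; set
#' `use_compensated_source = FALSE` to subtract raw source signals
#' instead). Results are floored at `panel$floor_value` so later log
#' transforms remain defined; the floor sits below every positivity
#' threshold, so classification is unaffected.
#'
#' @param sample A [flow_sample()]; must not already be compensated.
#' @param panel A [panel_config()] with a `spillover` table.
#' @param use_compensated_source Use the progressively compensated source
#'   signal (default) or the raw one.
#' @return The compensated `flow_sample` (`$compensated` set to `TRUE`).
#' @export
compensate <- function(sample, panel, use_compensated_source = TRUE) {
  stopifnot(inherits(sample, "flow_sample"), inherits(panel, "panel_config"))
  if (isTRUE(sample$compensated))
    stop("sample is already compensated; refusing to compensate twice")
  ev <- sample$events
  sp <- panel$spillover
  if (!is.null(sp) && nrow(sp) > 0) {
    raw <- ev
    for (i in seq_len(nrow(sp))) {
      src <- if (use_compensated_source) ev[[sp$source[i]]]
             else raw[[sp$source[i]]]
      ev[[sp$target[i]]] <- ev[[sp$target[i]]] - sp$coefficient[i] * src
    }
    for (ch in intersect(panel$channels, names(ev)))
      ev[[ch]] <- pmax(ev[[ch]], panel$floor_value)
  }
  sample$events <- ev
  sample$compensated <- TRUE
  sample
}

#' Re-apply spillover to compensated (or true) intensities
#'
#' The forward counterpart of [compensate()], used by the synthetic event
#' generators: spillover terms are added back in reverse panel order so that
#' sequential compensation inverts the operation exactly (up to flooring).
#'
#' @inheritParams compensate
#' @return A `flow_sample` holding raw (uncompensated) intensities.
#' @export
add_spillover <- function(sample, panel) {
  stopifnot(inherits(sample, "flow_sample"), inherits(panel, "panel_config"))
  ev <- sample$events
  sp <- panel$spillover
  if (!is.null(sp) && nrow(sp) > 0) {
    for (i in rev(seq_len(nrow(sp))))
      ev[[sp$target[i]]] <- ev[[sp$target[i]]] +
        sp$coefficient[i] * ev[[sp$source[i]]]
  }
  sample$events <- ev
  sample$compensated <- FALSE
  sample
}

#' Bounded logarithmic intensity normalization
#'
#' Maps a raw fluorescence intensity onto \[0, 1\] between a lower and an
#' upper boundary on the log scale. In the default ascending orientation
#' `I_lower` maps to 0 and `I_upper` to 1,
#' \deqn{I_{norm} = \frac{\log I - \log I_{lower}}
#'                       {\log I_{upper} - \log I_{lower}},}
#' which places bright events near 1. The descending orientation is the
#' exact complement (`I_lower` to 1, `I_upper` to 0). The value is
#' independent of the log base. Values outside the boundaries are clipped
#' to \[0, 1\] unless `clip = FALSE`.
#'
#' @param intensity Positive numeric vector of measured intensities.
#' @param lower,upper Normalization boundaries, `0 < lower < upper`.
#' @param orientation `"ascending"` (default) or `"descending"`.
#' @param clip Clip the result into \[0, 1\]?
#' @return Numeric vector of normalized intensities.
#' @export
normalize_intensity <- function(intensity, lower, upper,
                                orientation = c("ascending", "descending"),
                                clip = TRUE) {
  orientation <- match.arg(orientation)
  stopifnot(is.numeric(intensity), length(lower) == 1, length(upper) == 1,
            0 < lower, lower < upper)
  if (any(intensity <= 0))
    stop("intensities must be > 0 (floor them before normalizing)")
  x <- (log10(intensity) - log10(lower)) / (log10(upper) - log10(lower))
  if (orientation == "descending") x <- 1 - x
  if (clip) x <- pmin(1, pmax(0, x))
  x
}

#' Normalized RGB cube coordinates
#'
#' Normalizes the three colour channels of a compensated sample with
#' [normalize_intensity()] and returns the per-event coordinates in the
#' unit cube used for 3-D population plots (I_R = red/mCherry,
#' I_G = green/Venus, I_B = blue/Cerulean).
#'
#' @param sample A compensated [flow_sample()].
#' @param panel A [panel_config()] with `colors` and `bounds`.
#' @param orientation Passed to [normalize_intensity()].
#' @return Data frame with columns `event_id`, `I_R`, `I_G`, `I_B`.
#' @export
cube_coordinates <- function(sample, panel, orientation = "ascending") {
  stopifnot(inherits(sample, "flow_sample"), inherits(panel, "panel_config"))
  if (is.null(panel$colors) || is.null(panel$bounds))
    stop("panel needs colors and bounds for cube coordinates")
  if (!is.null(panel$spillover) && nrow(panel$spillover) > 0 &&
      !isTRUE(sample$compensated))
    stop("sample must be compensated before normalization")
  out <- data.frame(event_id = sample$events$event_id)
  for (col in c("R", "G", "B")) {
    ch <- panel$colors[[col]]
    b <- panel$bounds[[ch]]
    val <- pmax(sample$events[[ch]], panel$floor_value)
    out[[paste0("I_", col)]] <-
      normalize_intensity(val, b[1], b[2], orientation = orientation)
  }
  out
}
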