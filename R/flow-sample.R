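#' A single flow-cytometry acquisition
#'
#' Wraps one event table together with its acquisition time, culture
#' identity and processing provenance flags. Event tables carry scatter
#' columns `FSC-A`, `FSC-H`, `SSC-A` plus one column per fluorescence
#' channel; an `event_id` column is added if absent.
#'
#' @param events Data frame of per-event measurements. All measurement
#'   columns must be finite numerics; at least one event is required.
#' @param time_h Acquisition time in hours (may be `NA`).
#' @param culture_id Identifier of the originating culture.
#' @param compensated,normalized Provenance flags; [compensate()] refuses to
#'   run twice on the same sample.
#'
#' @return An object of class `flow_sample` with elements `events`,
#'   `time_h`, `culture_id`, `compensated`, `normalized`, and optionally
#'   `exclusions` (set by [exclude_debris_doublets()]) and `truth` (set by
#'   the synthetic generators).
#' @export
flow_sample <- function(events, time_h = NA_real_, culture_id = NA_character_,
                        compensated = FALSE, normalized = FALSE) {
  events <- as.data.frame(events)
  if (nrow(events) == 0) stop("event table is empty")
  if (!"event_id" %in% names(events))
    events <- cbind(event_id = seq_len(nrow(events)), events)
  num <- vapply(events, is.numeric, logical(1))
  for (nm in names(events)[num])
    if (!all(is.finite(events[[nm]])))
      stop("non-finite values in column ", nm)
  structure(
    list(events = events, time_h = time_h, culture_id = culture_id,
         compensated = isTRUE(compensated), normalized = isTRUE(normalized),
         exclusions = NULL, truth = NULL),
    class = "flow_sample")
}

#' @export
print.flow_sample <- function(x, ...) {
  cat("<flow_sample>", nrow(x$events), "events")
  if (!is.na(x$time_h)) cat(" at t =", x$time_h, "h")
  if (!is.na(x$culture_id)) cat(" (culture ", x$culture_id, ")", sep = "")
  cat("\n  columns:", paste(setdiff(names(x$events), "event_id"),
                            collapse = ", "), "\n")
  cat("  compensated:", x$compensated, " normalized:", x$normalized, "\n")
  if (!is.null(x$exclusions))
    cat("  excluded:", paste(names(x$exclusions), x$exclusions,
                             collapse = ", "), "\n")
  invisible(x)
}

scatter_columns <- function() c("FSC-A", "FSC-H", "SSC-A")
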