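#' Write a flow sample to the CSV event dialect
#'
#' Writes the event table as plain CSV with columns `event_id`, `FSC-A`,
#' `FSC-H`, `SSC-A` and one column per fluorescence channel. Numeric
#' values are serialized at 9 significant digits, so a write/read round
#' trip is value-identical on the stored representation.
#'
#' @param sample A [flow_sample()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_events <- function(sample, path) {
  stopifnot(inherits(sample, "flow_sample"))
  ev <- sample$events
  num <- vapply(ev, is.numeric, logical(1))
  ev[num] <- lapply(ev[num], signif, digits = 9)
  utils::write.csv(ev, path, row.names = FALSE)
  invisible(path)
}

#' Read a flow sample from the CSV event dialect
#'
#' Reads an event table written by [write_events()] (or any CSV in the
#' same dialect). When a panel is supplied, every non-scatter measurement
#' column must be a panel channel; an unknown column is an error naming
#' the column. Rows with missing or non-finite measurements are dropped
#' with a message.
#'
#' @param path CSV file path.
#' @param panel Optional [panel_config()] used to validate channel names.
#' @param time_h,culture_id Acquisition metadata for the returned sample.
#' @param compensated Provenance flag of the stored intensities.
#' @return A [flow_sample()].
#' @export
read_events <- function(path, panel = NULL, time_h = NA_real_,
                        culture_id = NA_character_, compensated = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  ev <- utils::read.csv(path, check.names = FALSE)
  if (nrow(ev) == 0) stop("empty event file: ", path)
  if (!is.null(panel)) {
    known <- c("event_id", scatter_columns(), panel$channels)
    bad <- setdiff(names(ev), known)
    if (length(bad))
      stop("unknown column(s) in ", path, ": ", paste(bad, collapse = ", "))
  }
  num <- vapply(ev, is.numeric, logical(1))
  ok <- rowSums(!is.finite(as.matrix(ev[num]))) == 0
  if (!all(ok)) {
    message("dropping ", sum(!ok), " malformed row(s)")
    ev <- ev[ok, , drop = FALSE]
  }
  flow_sample(ev, time_h = time_h, culture_id = culture_id,
              compensated = compensated)
}

#' Write / read a culture timepoint series as CSV
#'
#' Culture series hold bulk measurements per timepoint: `t_h`, `X_v`
#' (cells/ml), `viability`, and the concentrations `c_Glc`, `c_Gln`,
#' `c_Lac`, `c_Amm` (mmol/l) and `c_Ab` (mg/l). Values are serialized at
#' 9 significant digits.
#'
#' @param series Data frame of culture timepoints.
#' @param path CSV file path.
#' @return `write_culture_series()` returns `path` invisibly;
#'   `read_culture_series()` returns the data frame.
#' @export
write_culture_series <- function(series, path) {
  stopifnot(is.data.frame(series), "t_h" %in% names(series))
  num <- vapply(series, is.numeric, logical(1))
  series[num] <- lapply(series[num], signif, digits = 9)
  utils::write.csv(series, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_culture_series
#' @export
read_culture_series <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  utils::read.csv(path, check.names = FALSE)
}
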