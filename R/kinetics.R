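#' Cell-specific consumption and production rates
#'
#' Two-point rate estimates between consecutive culture timepoints,
#' normalized by the trapezoidal mean viable density:
#' \deqn{q(t_i, t_{i+1}) = \frac{\pm(c_i - c_{i+1})}{t_{i+1} - t_i}
#'       \cdot \frac{2}{X_{v,i+1} + X_{v,i}},}
#' with the positive orientation `c_i - c_{i+1}` for consumed analytes
#' (glucose, glutamine) and `c_{i+1} - c_i` for produced ones (lactate,
#' ammonium, antibody). Intervals spanning a passage (medium reset) are
#' excluded because the concentration difference across a reset is not a
#' biological rate.
#'
#' @param series Data frame with columns `t_h` (strictly increasing),
#'   `X_v`, and the analyte concentration column `c_<analyte>` (mmol/l;
#'   mg/l for `Ab`).
#' @param analyte One of `"Glc"`, `"Lac"`, `"Ab"`, `"Gln"`, `"Amm"`.
#' @param mode `"auto"` (consumption for Glc/Gln, production for
#'   Lac/Amm/Ab), `"consumption"`, or `"production"`.
#' @param xv_unit Unit of the `X_v` column: `"per_ml"` (default; converted
#'   to cells/l internally) or `"per_l"`.
#' @param passage_times Optional times (h) at which the medium was reset.
#'   A measurement at a passage time is taken just before the reset, so
#'   the interval starting there is excluded too.
#' @param exclude_intervals Optional integer indices of further intervals
#'   to exclude (e.g. visually flagged outliers).
#' @return Data frame with one row per interval: `t_start`, `t_end`,
#'   `t_mid` (h), `q` (mmol/cell/h, or mg/cell/h for antibody; `NA` for
#'   excluded intervals), `excluded`.
#' @export
specific_rate <- function(series, analyte = c("Glc", "Lac", "Ab", "Gln",
                                              "Amm"),
                          mode = c("auto", "consumption", "production"),
                          xv_unit = c("per_ml", "per_l"),
                          passage_times = NULL,
                          exclude_intervals = NULL) {
  analyte <- match.arg(analyte)
  mode <- match.arg(mode)
  xv_unit <- match.arg(xv_unit)
  col <- paste0("c_", analyte)
  stopifnot(all(c("t_h", "X_v", col) %in% names(series)),
            nrow(series) >= 2)
  t <- series$t_h
  if (is.unsorted(t, strictly = TRUE))
    stop("times must be strictly increasing")
  X <- series$X_v * if (xv_unit == "per_ml") 1e3 else 1
  conc <- series[[col]]
  if (mode == "auto")
    mode <- if (analyte %in% c("Glc", "Gln")) "consumption" else "production"
  n <- length(t)
  dt <- diff(t)
  dc <- if (mode == "consumption") conc[-n] - conc[-1] else diff(conc)
  xbar <- (X[-n] + X[-1]) / 2
  if (any(xbar <= 0)) stop("mean viable density must be > 0")
  q <- dc / dt / xbar
  excluded <- rep(FALSE, n - 1)
  if (!is.null(passage_times))
    for (p in passage_times)
      excluded <- excluded | (p >= t[-n] & p < t[-1])
  if (!is.null(exclude_intervals)) excluded[exclude_intervals] <- TRUE
  q[excluded] <- NA_real_
  data.frame(t_start = t[-n], t_end = t[-1], t_mid = (t[-n] + t[-1]) / 2,
             q = q, excluded = excluded, row.names = NULL)
}

#' Relative change between two values, in percent
#'
#' Two conventions are used when reporting shifts in titers or specific
#' rates: `"delta"` is the signed relative difference
#' `100 (end - start)/start`; `"ratio"` expresses the end value as a
#' percentage of the start, `100 end/start` (an end value 2.19x the start
#' is "an increase of 220%" at two significant figures under this
#' convention).
#'
#' @param value_start,value_end Numeric scalars; `value_start` must be
#'   nonzero.
#' @param mode `"delta"` or `"ratio"`.
#' @return Percent change (numeric scalar).
#' @export
relative_change <- function(value_start, value_end,
                            mode = c("delta", "ratio")) {
  mode <- match.arg(mode)
  stopifnot(length(value_start) == 1, length(value_end) == 1)
  if (value_start == 0) stop("start value must be nonzero")
  if (mode == "delta") 100 * (value_end - value_start) / value_start
  else 100 * value_end / value_start
}
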