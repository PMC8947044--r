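#' Inverse prediction: response to concentration
#'
#' Solves the calibration curve for the concentration producing a given
#' response. The linear model inverts in closed form,
#' \eqn{\hat c = (y - \beta_0)/\beta_1}; the smoothers are inverted by
#' bisection on the calibrated range to a tolerance of
#' \eqn{10^{-8} (x_{max} - x_{min})}, which is valid because the fitted
#' curve is required to be strictly monotone there.
#'
#' Responses outside the calibrated response range are clamped to the
#' nearest range endpoint and flagged (`above_range` on the high side,
#' `extrapolated` on the low side) rather than extrapolated — the safe
#' behaviour in a diagnostics context. When `metrics` with detection
#' limits are supplied, estimates below the limits are flagged
#' `below_LOB` / `below_LOD` / `below_LOQ` (each implying the next:
#' a response below the blank limit is necessarily below the detection
#' and quantification limits).
#'
#' @param model a strictly monotone `calibration_model`.
#' @param y response value(s).
#' @param metrics optional `calibration_metrics` carrying the
#'   response-domain detection limits.
#' @return Data frame with columns `response`, `concentration`, `flags`
#'   (comma-separated flag string, empty when none).
#' @export
invert_calibration <- function(model, y, metrics = NULL) {
  stopifnot(inherits(model, "calibration_model"))
  if (!isTRUE(model$monotone))
    stop("calibration curve is not strictly monotone; inversion undefined",
         call. = FALSE)
  if (model$kind == "linear" && model$coefficients[2] == 0)
    stop("degenerate linear model: zero slope", call. = FALSE)
  xr <- model$x_range
  yr <- predict(model, xr) # responses at the range ends
  dir <- if (yr[2] >= yr[1]) 1 else -1
  y_lo <- min(yr); y_hi <- max(yr)
  one <- function(yi) {
    flags <- character()
    yc <- yi
    if (yi > y_hi || yi < y_lo) {
      # clamp; which flag depends on whether the miss is on the high- or
      # low-concentration side of the curve
      high_side <- (dir == 1 && yi > y_hi) || (dir == -1 && yi < y_lo)
      flags <- c(flags, if (high_side) "above_range" else "extrapolated")
      yc <- min(max(yi, y_lo), y_hi)
    }
    ci <- if (model$kind == "linear")
      (yc - model$coefficients[1]) / model$coefficients[2]
    else
      bisect_inverse(model, yc, xr)
    ci <- min(max(ci, xr[1]), xr[2])
    if (!is.null(metrics) && !is.null(metrics$lob_response)) {
      below <- function(lim_y) (dir == 1 && yi < lim_y) ||
        (dir == -1 && yi > lim_y)
      if (below(metrics$loq_response)) flags <- c(flags, "below_LOQ")
      if (below(metrics$lod_response))
        flags <- union(c("below_LOD", "below_LOQ"), flags)
      if (below(metrics$lob_response))
        flags <- union(c("below_LOB", "below_LOD", "below_LOQ"), flags)
      ord <- c("below_LOB", "below_LOD", "below_LOQ", "above_range",
               "extrapolated")
      flags <- ord[ord %in% flags]
    }
    data.frame(response = yi, concentration = ci,
               flags = paste(flags, collapse = ","))
  }
  out <- do.call(rbind, lapply(as.numeric(y), one))
  rownames(out) <- NULL
  out
}

bisect_inverse <- function(model, y, xr, tol_frac = 1e-8) {
  f <- function(x) predict(model, x) - y
  lo <- xr[1]; hi <- xr[2]
  flo <- f(lo); fhi <- f(hi)
  if (flo == 0) return(lo)
  if (fhi == 0) return(hi)
  tol <- tol_frac * (hi - lo)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (fm == 0) return(mid)
    if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
  }
  (lo + hi) / 2
}

#' Quantify an intensity table through a calibration model
#'
#' Appends, without touching the input columns, the estimated
#' concentration, the quality flags of [invert_calibration()] and a
#' model identifier for provenance.
#'
#' @param table data frame carrying a response column.
#' @param model a `calibration_model`.
#' @param metrics optional `calibration_metrics` (enables detection-limit
#'   flags).
#' @param response_col name of the response column (default
#'   `"response"`).
#' @param model_id identifier written into the `model` column; defaults
#'   to kind plus response expression.
#' @return The table with three appended columns: `concentration_est`,
#'   `flags`, `model`.
#' @export
quantify_table <- function(table, model, metrics = NULL,
                           response_col = "response", model_id = NULL) {
  if (!response_col %in% names(table))
    stop("response column '", response_col, "' not found", call. = FALSE)
  if (is.null(model_id))
    model_id <- paste0(model$kind,
                       if (!is.null(model$response_definition))
                         paste0(":", model$response_definition$expression))
  q <- invert_calibration(model, table[[response_col]], metrics)
  table$concentration_est <- q$concentration
  table$flags <- q$flags
  table$model <- model_id
  table
}
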