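#' Response definition over line labels
#'
#' The quantity plotted on the y axis of a calibration curve, built from
#' the per-line signals of a wide intensity table. Supported forms are
#' the ones in common LFA use: a single line (`"tl"`, `"cl"`), a ratio
#' of two lines (`"tl/cl"`, `"cl/tl"` — ratios normalize run-to-run
#' variation), and a normalized fraction (`"tl/(tl+cl)"`). Any label
#' pair is allowed, not only tl/cl.
#'
#' @param expression response expression, e.g. `"tl"`, `"cl/tl"`,
#'   `"tl/(tl+cl)"`.
#' @param statistic which per-line statistic to use: `"mean"` or
#'   `"median"`.
#' @return A `response_definition` object.
#' @export
response_definition <- function(expression, statistic = c("mean", "median")) {
  statistic <- match.arg(statistic)
  lab <- "[A-Za-z_][A-Za-z0-9_]*"
  e <- gsub(" ", "", expression)
  parsed <-
    if (grepl(paste0("^", lab, "$"), e))
      list(form = "single", labels = e)
    else if (grepl(paste0("^", lab, "/", lab, "$"), e))
      list(form = "ratio", labels = strsplit(e, "/", fixed = TRUE)[[1]])
    else if (grepl(paste0("^(", lab, ")/\\((\\1)\\+(", lab, ")\\)$"), e)) {
      m <- regmatches(e, regexec(paste0("^(", lab, ")/\\(\\1\\+(", lab,
                                        ")\\)$"), e))[[1]]
      list(form = "fraction", labels = m[2:3])
    } else
      stop("unsupported response expression '", expression,
           "'; use a label, label/label, or label/(label+label)",
           call. = FALSE)
  structure(c(parsed, list(expression = e, statistic = statistic)),
            class = "response_definition")
}

#' Build calibration data from a wide intensity table
#'
#' Evaluates the response definition rowwise on the `<label>_<statistic>`
#' columns and pairs it with the concentration column. Rows with a zero
#' denominator are dropped with a message (their response is undefined).
#'
#' @param wide_table wide table from [reshape_wide()], merged with
#'   experiment data so it carries a concentration column.
#' @param defn a [response_definition()].
#' @param conc_col name of the concentration column.
#' @return A `calibration_data` data frame with columns `concentration`
#'   and `response` (plus attribute `n_dropped`).
#' @export
make_response <- function(wide_table, defn, conc_col) {
  stopifnot(inherits(defn, "response_definition"))
  if (!conc_col %in% names(wide_table))
    stop("concentration column '", conc_col, "' not found", call. = FALSE)
  cols <- paste0(defn$labels, "_", defn$statistic)
  missing <- setdiff(cols, names(wide_table))
  if (length(missing))
    stop("wide table lacks response column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  v <- lapply(cols, function(cl) wide_table[[cl]])
  y <- switch(defn$form,
    single = v[[1]],
    ratio = v[[1]] / v[[2]],
    fraction = v[[1]] / (v[[1]] + v[[2]]))
  denom_zero <- switch(defn$form,
    single = rep(FALSE, nrow(wide_table)),
    ratio = v[[2]] == 0,
    fraction = (v[[1]] + v[[2]]) == 0)
  drop <- denom_zero | !is.finite(y) | is.na(wide_table[[conc_col]])
  if (any(drop))
    message(sum(drop), " row(s) dropped (zero denominator or missing value)")
  out <- data.frame(concentration = wide_table[[conc_col]][!drop],
                    response = y[!drop])
  attr(out, "n_dropped") <- sum(drop)
  attr(out, "response_definition") <- defn
  class(out) <- c("calibration_data", "data.frame")
  out
}

#' Fit a calibration curve
#'
#' Fits the concentration-to-response relationship with one of three
#' model families:
#' \describe{
#'   \item{linear}{ordinary least squares `lm(response ~ concentration)`;
#'     the only family for which R-squared is reported.}
#'   \item{local_poly}{local polynomial regression (`loess`), degree 2,
#'     tricube weights, default span 0.75.}
#'   \item{spline_additive}{additive model with a penalized cubic
#'     regression spline (`mgcv::gam`), smoothness chosen by generalized
#'     cross-validation.}
#' }
#' Optionally the concentration axis is log10-transformed before
#' fitting (common when calibrations span decades); blanks (x = 0) are
#' excluded from a log fit but still used for the detection limits.
#'
#' Detection limits (LOB/LOD/LOQ) are attached when blank replicates are
#' present and the fitted curve is strictly monotone; see
#' [detection_limits()].
#'
#' @param data a `calibration_data` (or any data frame with
#'   `concentration` and `response` columns).
#' @param kind `"linear"`, `"local_poly"` or `"spline_additive"`.
#' @param span loess span (local_poly only).
#' @param log10_x fit against log10(concentration)?
#' @param limit_multipliers passed to [detection_limits()].
#' @return List with elements `model` (a `calibration_model`) and
#'   `metrics` (a `calibration_metrics`).
#' @export
fit_calibration <- function(data,
                            kind = c("linear", "local_poly",
                                     "spline_additive"),
                            span = 0.75, log10_x = FALSE,
                            limit_multipliers = c(lob = 1.645, lod = 1.645,
                                                  loq = 10)) {
  kind <- match.arg(kind)
  x <- data$concentration; y <- data$response
  if (any(!is.finite(x)) || any(!is.finite(y)) || any(x < 0))
    stop("calibration data must be finite with non-negative concentrations",
         call. = FALSE)
  fit_idx <- if (log10_x) x > 0 else rep(TRUE, length(x))
  xf <- x[fit_idx]; yf <- y[fit_idx]
  tx <- if (log10_x) log10(xf) else xf
  n_distinct <- length(unique(xf))
  min_needed <- if (kind == "linear") 2L else 5L
  if (n_distinct < min_needed)
    stop(kind, " calibration needs at least ", min_needed,
         " distinct concentrations, got ", n_distinct, call. = FALSE)
  fit <- switch(kind,
    linear = stats::lm(yf ~ tx),
    local_poly = stats::loess(yf ~ tx, span = span, degree = 2,
                              family = "gaussian",
                              control = stats::loess.control(
                                surface = "direct")),
    spline_additive = mgcv::gam(yf ~ s(tx, bs = "cs",
                                       k = min(10L, n_distinct)),
                                method = "GCV.Cp"))
  if (kind == "linear" && !is.finite(stats::coef(fit)[2]))
    stop("singular linear fit", call. = FALSE)
  model <- structure(list(
    kind = kind,
    coefficients = if (kind == "linear") unname(stats::coef(fit)) else NULL,
    training = data.frame(x = xf, y = yf),
    span = if (kind == "local_poly") span else NULL,
    x_range = range(xf),
    log10_x = log10_x,
    response_definition = attr(data, "response_definition"),
    fit = fit), class = "calibration_model")
  model$monotone <- is_monotone(model)
  r2 <- if (kind == "linear") {
    ss_res <- sum(stats::residuals(fit)^2)
    ss_tot <- sum((yf - mean(yf))^2)
    1 - ss_res / ss_tot
  } else NULL
  limits <- tryCatch(detection_limits(model, data, limit_multipliers),
                     error = function(e) {
                       message("detection limits unavailable: ",
                               conditionMessage(e))
                       NULL
                     })
  metrics <- structure(list(
    r_squared = r2,
    lob = limits$lob, lod = limits$lod, loq = limits$loq,
    lob_response = limits$lob_response, lod_response = limits$lod_response,
    loq_response = limits$loq_response,
    mean_blank = limits$mean_blank, sd_blank = limits$sd_blank,
    n_blank = limits$n_blank,
    limit_multipliers = limit_multipliers),
    class = "calibration_metrics")
  list(model = model, metrics = metrics)
}

#' Predict responses from a calibration model
#'
#' @param object a `calibration_model`.
#' @param x concentrations (in the model's x range for smoothers).
#' @param ... unused.
#' @return Predicted responses.
#' @export
predict.calibration_model <- function(object, x, ...) {
  tx <- if (object$log10_x) log10(x) else x
  as.numeric(switch(object$kind,
    linear = object$coefficients[1] + object$coefficients[2] * tx,
    local_poly = stats::predict(object$fit, data.frame(tx = tx)),
    spline_additive = stats::predict(object$fit,
                                     newdata = data.frame(tx = tx))))
}

is_monotone <- function(model, n_grid = 201L) {
  g <- seq(model$x_range[1], model$x_range[2], length.out = n_grid)
  d <- diff(predict(model, g))
  all(d > 0) || all(d < 0)
}

curve_direction <- function(model) {
  p <- predict(model, model$x_range)
  if (p[2] >= p[1]) 1 else -1
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model> %s on [%g, %g]%s%s\n", x$kind,
              x$x_range[1], x$x_range[2],
              if (x$log10_x) ", log10 x" else "",
              if (isTRUE(x$monotone)) ", monotone" else ""))
  if (x$kind == "linear")
    cat(sprintf("  response = %.6g + %.6g * x\n",
                x$coefficients[1], x$coefficients[2]))
  invisible(x)
}

#' @export
print.calibration_metrics <- function(x, ...) {
  if (!is.null(x$r_squared)) cat(sprintf("  R^2 = %.4f\n", x$r_squared))
  fmt <- function(v) if (is.null(v)) "n/a" else
    if (is.character(v)) v else sprintf("%.6g", v)
  cat(sprintf("  LOB = %s, LOD = %s, LOQ = %s (concentration units)\n",
              fmt(x$lob), fmt(x$lod), fmt(x$loq)))
  invisible(x)
}

#' Limits of blank, detection and quantification
#'
#' Blank-based scheme in the response domain, then inverse-mapped to
#' concentration through the calibration curve:
#' \deqn{LOB_y = \bar y_{blank} + 1.645\, s_{blank}}
#' \deqn{LOD_y = LOB_y + 1.645\, s_{low}}
#' \deqn{LOQ_y = \bar y_{blank} + 10\, s_{blank}}
#' where \eqn{s_{low}} is the standard deviation of the replicates at
#' the lowest nonzero concentration (falling back to \eqn{s_{blank}}
#' when absent). The LOQ is floored at the LOD (quantification is never
#' claimed below detection), which matters when \eqn{s_{low}} is large
#' relative to \eqn{s_{blank}}. For a calibration curve that *decreases* with
#' concentration the multiples are subtracted instead of added, so the
#' limit responses always lie in the direction of increasing
#' concentration. The multipliers (1.645 for a one-sided 95% bound, 10
#' for quantification) are configurable.
#'
#' Limits whose response falls beyond the calibrated range are reported
#' as the string `"> x_max"` rather than extrapolated.
#'
#' @param model a `calibration_model`, strictly monotone on its range.
#' @param data the `calibration_data` used for the fit (must contain at
#'   least 2 blank replicates, x = 0).
#' @param multipliers named numeric vector `c(lob=, lod=, loq=)`.
#' @return List with `lob`, `lod`, `loq` (concentration units), their
#'   response-domain counterparts and the blank statistics.
#' @export
detection_limits <- function(model, data,
                             multipliers = c(lob = 1.645, lod = 1.645,
                                             loq = 10)) {
  blanks <- data$response[data$concentration == 0]
  if (length(blanks) < 2L)
    stop("need at least 2 blank replicates (concentration 0)",
         call. = FALSE)
  if (!isTRUE(model$monotone))
    stop("calibration curve is not strictly monotone; limits undefined",
         call. = FALSE)
  dir <- curve_direction(model)
  mean_blank <- mean(blanks); sd_blank <- stats::sd(blanks)
  low_x <- suppressWarnings(min(data$concentration[data$concentration > 0]))
  sd_low <- if (is.finite(low_x)) {
    reps <- data$response[data$concentration == low_x]
    if (length(reps) >= 2L) stats::sd(reps) else sd_blank
  } else sd_blank
  lob_y <- mean_blank + dir * multipliers[["lob"]] * sd_blank
  lod_y <- lob_y + dir * multipliers[["lod"]] * sd_low
  loq_y <- mean_blank + dir * multipliers[["loq"]] * sd_blank
  # quantification cannot be claimed below detection: when low-level
  # replicate noise dominates blank noise, floor the LOQ at the LOD
  loq_y <- if (dir == 1) max(loq_y, lod_y) else min(loq_y, lod_y)
  to_conc <- function(yv) {
    rng <- sort(predict(model, model$x_range))
    if (yv > rng[2] || yv < rng[1]) {
      # beyond the calibrated response range on the high-x side?
      high_y <- predict(model, model$x_range[2])
      if ((dir == 1 && yv > high_y) || (dir == -1 && yv < high_y))
        return(paste(">", model$x_range[2]))
      return(model$x_range[1]) # below the blank end: clamp to x_min
    }
    invert_calibration(model, yv)$concentration
  }
  list(lob = to_conc(lob_y), lod = to_conc(lod_y), loq = to_conc(loq_y),
       lob_response = lob_y, lod_response = lod_y, loq_response = loq_y,
       mean_blank = mean_blank, sd_blank = sd_blank,
       n_blank = length(blanks))
}

# ---- model persistence ---------------------------------------------------

model_format_version <- 1L

#' Save / load a calibration model
#'
#' Models are serialized as a small JSON document: the linear model
#' stores its coefficients; the smoothers store their training points
#' and hyperparameters and are refit deterministically on load, which
#' reproduces their predictions exactly.
#'
#' @param model a `calibration_model`.
#' @param path JSON file path.
#' @return `save_model()`: `path` invisibly; `load_model()`: the
#'   restored `calibration_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "calibration_model"))
  doc <- list(format = "lfaquant_calibration_model",
              version = model_format_version,
              kind = model$kind,
              coefficients = model$coefficients,
              training = model$training,
              span = model$span,
              x_range = model$x_range,
              log10_x = model$log10_x,
              response_definition =
                if (!is.null(model$response_definition))
                  list(expression = model$response_definition$expression,
                       statistic = model$response_definition$statistic))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    stop("not a valid model file: ", path, " (",
                         conditionMessage(e), ")", call. = FALSE))
  if (!identical(doc$format, "lfaquant_calibration_model"))
    stop("not a calibration model file: ", path, call. = FALSE)
  if (!identical(as.integer(doc$version), model_format_version))
    stop("unsupported model format version ", doc$version, call. = FALSE)
  defn <- if (!is.null(doc$response_definition))
    response_definition(doc$response_definition$expression,
                        doc$response_definition$statistic)
  tr <- as.data.frame(doc$training)
  dat <- data.frame(concentration = if (isTRUE(doc$log10_x)) 10^tr$x else tr$x,
                    response = tr$y)
  attr(dat, "response_definition") <- defn
  class(dat) <- c("calibration_data", "data.frame")
  refit <- fit_calibration(dat, kind = doc$kind,
                           span = if (!is.null(doc$span)) doc$span else 0.75,
                           log10_x = isTRUE(doc$log10_x))
  model <- refit$model
  if (model$kind == "linear" && !is.null(doc$coefficients))
    model$coefficients <- as.numeric(doc$coefficients)
  model
}

# ---- report --------------------------------------------------------------

#' Markdown calibration report
#'
#' Writes a self-contained markdown report of a calibration analysis:
#' model family, response definition, coefficients or hyperparameters,
#' R-squared (linear fits), the detection limits with the blank
#' statistics they derive from, the calibration data table and a
#' calibration plot saved as PNG next to the report.
#'
#' @param model a `calibration_model`.
#' @param metrics the matching `calibration_metrics`.
#' @param data the `calibration_data`.
#' @param out_path output path of the markdown file; the plot is written
#'   alongside with extension `.png`.
#' @return `out_path`, invisibly.
#' @export
calibration_report <- function(model, metrics, data, out_path) {
  png_path <- sub("\\.[A-Za-z]+$", ".png", out_path)
  if (identical(png_path, out_path)) png_path <- paste0(out_path, ".png")
  plot_calibration(model, data, png_path)
  fmt <- function(v, digits = 6) {
    if (is.null(v)) "not available"
    else if (is.character(v)) v
    else format(signif(v, digits))
  }
  defn <- model$response_definition
  lines <- c(
    "# Calibration report",
    "",
    sprintf("- Model family: %s", model$kind),
    sprintf("- Response: %s (%s of per-line signal)",
            if (is.null(defn)) "response" else defn$expression,
            if (is.null(defn)) "statistic" else defn$statistic),
    sprintf("- Concentration range: [%g, %g]%s", model$x_range[1],
            model$x_range[2],
            if (model$log10_x) " (fitted on log10 axis)" else ""),
    sprintf("- Monotone fit: %s", if (isTRUE(model$monotone)) "yes" else "no"),
    if (model$kind == "linear")
      sprintf("- Coefficients: intercept = %s, slope = %s",
              fmt(model$coefficients[1]), fmt(model$coefficients[2])),
    if (model$kind == "local_poly")
      sprintf("- Span: %s (degree 2 local polynomial)", fmt(model$span)),
    if (model$kind == "spline_additive")
      "- Penalized cubic regression spline, penalty by GCV",
    if (!is.null(metrics$r_squared))
      sprintf("- R^2 = %s", fmt(metrics$r_squared)),
    "",
    "## Detection limits",
    "",
    sprintf("- LOB = %s, LOD = %s, LOQ = %s (concentration units)",
            fmt(metrics$lob), fmt(metrics$lod), fmt(metrics$loq)),
    sprintf("- Blanks: n = %s, mean = %s, sd = %s",
            fmt(metrics$n_blank), fmt(metrics$mean_blank),
            fmt(metrics$sd_blank)),
    "",
    "## Calibration plot",
    "",
    sprintf("![calibration curve](%s)", basename(png_path)),
    "",
    "## Data",
    "",
    "| concentration | response |",
    "| ---: | ---: |",
    sprintf("| %g | %g |", data$concentration, data$response),
    "")
  ok <- tryCatch({
    writeLines(lines, out_path); TRUE
  }, error = function(e) FALSE)
  if (!ok)
    stop("cannot write report to ", out_path, call. = FALSE)
  invisible(out_path)
}

plot_calibration <- function(model, data, png_path, width = 800,
                             height = 600) {
  grDevices::png(png_path, width = width, height = height, res = 120)
  on.exit(grDevices::dev.off())
  g <- seq(model$x_range[1], model$x_range[2], length.out = 200)
  graphics::plot(data$concentration, data$response,
                 xlab = "concentration", ylab = "response",
                 main = sprintf("Calibration (%s)", model$kind),
                 pch = 19, col = "grey30")
  graphics::lines(g, predict(model, g), col = "firebrick", lwd = 2)
  invisible(png_path)
}
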