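#' Threshold settings for background correction
#'
#' Bundles the background-correction method with its parameters and the
#' grayscale conversion used before thresholding, so a measurement can be
#' reproduced from its settings alone.
#'
#' Methods:
#' \describe{
#'   \item{otsu}{fully automatic; maximizes between-class variance of the
#'     intensity histogram. Best for bimodal histograms.}
#'   \item{li}{fully automatic; iteratively minimizes the cross entropy
#'     between original and thresholded image.}
#'   \item{quantile}{semi-automatic; empirical quantile of the pixel
#'     intensities of the inter-line background rectangles (the grid
#'     segments without bands).}
#'   \item{triangle}{semi-automatic geometric search; best for unimodal,
#'     skewed histograms.}
#' }
#' An additive `offset` refines any computed threshold; the result is
#' clipped back to \eqn{[0, 1]}.
#'
#' @param method one of `"otsu"`, `"li"`, `"quantile"`, `"triangle"`.
#' @param offset additive threshold offset (default 0).
#' @param quantile_prob quantile probability in (0, 1), quantile method
#'   only. Default 0.75.
#' @param mode grayscale conversion mode, see [to_grayscale()].
#' @param inverted analyze the photographic negative (bright bands)?
#' @return A `threshold_spec` object.
#' @export
threshold_spec <- function(method = c("otsu", "li", "quantile", "triangle"),
                           offset = 0, quantile_prob = 0.75,
                           mode = "luminance", inverted = FALSE) {
  method <- match.arg(method)
  if (!is.finite(offset))
    stop("offset must be finite", call. = FALSE)
  if (method == "quantile" &&
      (!is.finite(quantile_prob) || quantile_prob <= 0 || quantile_prob >= 1))
    stop("quantile_prob must lie strictly in (0, 1)", call. = FALSE)
  structure(list(method = method, offset = offset,
                 quantile_prob = quantile_prob, mode = mode,
                 inverted = isTRUE(inverted)),
            class = "threshold_spec")
}

#' Intensity histogram on [0, 1]
#'
#' Equal-width bins over \eqn{[0, 1]}; a pixel p falls into bin
#' `floor(p * n_bins)`, with p = 1 assigned to the last bin. 256 bins by
#' default, for comparability with 8-bit imagers.
#'
#' @param pixels non-empty numeric vector in \eqn{[0, 1]}.
#' @param n_bins number of bins.
#' @return List with `counts` (length `n_bins`), `mids` (bin centers)
#'   and `breaks` (length `n_bins + 1`).
#' @export
intensity_histogram <- function(pixels, n_bins = 256L) {
  if (length(pixels) == 0L)
    stop("cannot build a histogram from an empty pixel set", call. = FALSE)
  idx <- pmin(floor(pixels * n_bins), n_bins - 1L)
  counts <- tabulate(idx + 1L, nbins = n_bins)
  list(counts = counts,
       mids = (seq_len(n_bins) - 0.5) / n_bins,
       breaks = (0:n_bins) / n_bins)
}

#' Otsu threshold
#'
#' Exhaustive search over the `n_bins - 1` interior bin boundaries for
#' the split maximizing the between-class variance
#' \eqn{\omega_0 \omega_1 (\mu_0 - \mu_1)^2} of the binned intensities.
#' Ties are broken towards the smallest threshold.
#'
#' @param pixels numeric vector in \eqn{[0, 1]} with at least two
#'   distinct values.
#' @param n_bins histogram resolution.
#' @return Threshold in \eqn{[0, 1]} (a bin boundary).
#' @export
threshold_otsu <- function(pixels, n_bins = 256L) {
  check_nondegenerate(pixels)
  h <- intensity_histogram(pixels, n_bins)
  n <- sum(h$counts)
  # cumulative weight/mean below each interior boundary k/n_bins
  w0 <- cumsum(h$counts)[-n_bins]
  s0 <- cumsum(h$counts * h$mids)[-n_bins]
  w1 <- n - w0
  s_tot <- sum(h$counts * h$mids)
  valid <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, n_bins - 1L)
  mu0 <- s0[valid] / w0[valid]
  mu1 <- (s_tot - s0[valid]) / w1[valid]
  bcv[valid] <- (w0[valid] / n) * (w1[valid] / n) * (mu0 - mu1)^2
  k <- which.max(bcv) # first maximum = smallest threshold on ties
  k / n_bins
}

check_nondegenerate <- function(pixels) {
  if (length(pixels) == 0L)
    stop("empty pixel set", call. = FALSE)
  if (max(pixels) - min(pixels) == 0)
    stop("constant image: no separating threshold exists", call. = FALSE)
  invisible(pixels)
}

#' Li minimum cross-entropy threshold
#'
#' Iterates the fixed-point update
#' \deqn{t' = (\mu_{low} - \mu_{high}) / (\log \mu_{low} - \log \mu_{high})}
#' where \eqn{\mu_{low}}/\eqn{\mu_{high}} are the means of the pixels at
#' or below / above the current threshold, starting from the global mean,
#' until the change falls below `tol`. The fixed point minimizes the
#' cross entropy between the original and the thresholded image.
#'
#' Zero intensities would put a log(0) into the update, so when any pixel
#' is 0 all pixels are shifted up by eps = 1/512 (half an 8-bit grey
#' level) before iterating and the shift is subtracted from the result.
#'
#' @param pixels numeric vector in \eqn{[0, 1]}, at least two distinct
#'   values.
#' @param tol convergence tolerance on the threshold.
#' @param max_iter iteration cap; exceeding it is an error that names the
#'   last iterate.
#' @return Threshold (numeric scalar) with attribute `iterations`.
#' @export
threshold_li <- function(pixels, tol = 1e-6, max_iter = 100L) {
  check_nondegenerate(pixels)
  eps <- if (any(pixels <= 0)) 1 / 512 else 0
  p <- pixels + eps
  t_cur <- mean(p)
  for (it in seq_len(max_iter)) {
    mu_low <- mean(p[p <= t_cur])
    mu_high <- mean(p[p > t_cur])
    if (!is.finite(mu_high)) # nothing above: already at the top
      return(structure(t_cur - eps, iterations = it))
    t_new <- if (mu_low == mu_high) mu_low else
      (mu_low - mu_high) / (log(mu_low) - log(mu_high))
    if (abs(t_new - t_cur) < tol)
      return(structure(t_new - eps, iterations = it))
    t_cur <- t_new
  }
  stop(sprintf(paste0("Li threshold did not converge within %d iterations",
                      " (last iterate %.6f)"), max_iter, t_cur - eps),
       call. = FALSE)
}

#' Quantile background threshold
#'
#' Empirical quantile (linear interpolation, the default quantile
#' definition of R) of the intensities of the background-role grid
#' cells, i.e. the inter-line rectangles without bands. Needs a grid
#' with at least two lines, otherwise no background rectangles exist.
#'
#' @param background_pixels intensities from background cells; non-empty.
#' @param prob quantile probability in (0, 1).
#' @return Threshold in \eqn{[0, 1]}.
#' @export
threshold_quantile <- function(background_pixels, prob = 0.75) {
  if (length(background_pixels) == 0L)
    stop("no background pixels: the quantile method needs a grid with ",
         "at least 2 lines (inter-line background rectangles)",
         call. = FALSE)
  if (!is.finite(prob) || prob <= 0 || prob >= 1)
    stop("quantile probability must lie strictly in (0, 1)", call. = FALSE)
  unname(stats::quantile(background_pixels, probs = prob, type = 7))
}

#' Triangle threshold
#'
#' Geometric search on the intensity histogram: a line is drawn from the
#' peak bin (maximum count) to the farthest nonzero tail bin on the
#' longer side of the peak, and the threshold is the center of the bin
#' with maximal perpendicular distance below that line. Coordinates are
#' normalized before the distance search (bin index by the peak-to-tail
#' span, count by the peak count) so the result does not depend on the
#' scale of either axis. Ties break towards the smallest threshold.
#' Suited to unimodal, skewed histograms where variance-based splits
#' fail.
#'
#' @param pixels numeric vector in \eqn{[0, 1]}, at least two distinct
#'   values.
#' @param n_bins histogram resolution.
#' @return Threshold in \eqn{[0, 1]} (a bin center).
#' @export
threshold_triangle <- function(pixels, n_bins = 256L) {
  check_nondegenerate(pixels)
  h <- intensity_histogram(pixels, n_bins)
  counts <- h$counts
  nz <- which(counts > 0)
  peak <- which.max(counts) # first maximum
  left <- peak - min(nz)
  right <- max(nz) - peak
  end <- if (right >= left) max(nz) else min(nz)
  span <- abs(end - peak)
  if (span == 0L) return(h$mids[peak]) # everything in one bin side
  between <- if (end > peak) peak:end else end:peak
  # normalized coordinates: x in [0,1] along the span, y = count / peak
  x <- (between - peak) / (end - peak)
  y <- counts[between] / counts[peak]
  # line through (0, 1) and (1, y_end); signed area distance to it
  y_end <- counts[end] / counts[peak]
  d <- abs((y_end - 1) * x - (y - 1)) / sqrt((y_end - 1)^2 + 1)
  best <- between[which(d == max(d))]
  h$mids[min(best)]
}

#' Offset adjustment of a threshold
#'
#' @param t threshold in \eqn{[0, 1]}.
#' @param offset additive offset.
#' @return `t + offset`, clipped to \eqn{[0, 1]}.
#' @export
apply_offset <- function(t, offset) {
  min(max(t + offset, 0), 1)
}

#' Per-strip threshold computation
#'
#' Applies the grayscale conversion and optional inversion from the
#' spec, pools the pixels of the selected strip — all of its cells for
#' Otsu/Li/triangle, only the background-role cells for the quantile
#' method — computes the threshold and applies the offset.
#'
#' @param img an `lfa_image` (RGB or grayscale).
#' @param grid an `lfa_grid`.
#' @param strip 0-based strip column index.
#' @param spec a [threshold_spec()].
#' @return A `threshold_result`: list with `strip`, `threshold` (after
#'   offset, clipped to \eqn{[0,1]}), `spec`, `n_iterations` (Li only,
#'   else `NA`).
#' @export
compute_threshold <- function(img, grid, strip, spec) {
  stopifnot(inherits(spec, "threshold_spec"))
  gimg <- prepare_gray(img, spec)
  pool_role <- if (spec$method == "quantile") "background" else "all"
  px <- strip_pixels(gimg, grid, strip, roles = pool_role)
  if (spec$method == "quantile" && length(px) == 0L)
    stop("quantile method unavailable: grid has no background rectangles ",
         "(single-line grid)", call. = FALSE)
  t_raw <- switch(spec$method,
    otsu = threshold_otsu(px),
    li = threshold_li(px),
    quantile = threshold_quantile(px, spec$quantile_prob),
    triangle = threshold_triangle(px))
  structure(list(strip = as.integer(strip),
                 threshold = apply_offset(as.numeric(t_raw), spec$offset),
                 spec = spec,
                 n_iterations = if (spec$method == "li")
                   attr(t_raw, "iterations") else NA_integer_),
            class = "threshold_result")
}

prepare_gray <- function(img, spec) {
  g <- if (n_channels(img) == 3L)
    to_grayscale(img, spec$mode) else img
  if (spec$inverted) invert_image(g) else g
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("<threshold_result> strip %d: t = %.4f (%s%s)\n",
              x$strip, x$threshold, x$spec$method,
              if (x$spec$offset != 0)
                sprintf(", offset %+g", x$spec$offset) else ""))
  invisible(x)
}

#' Per-line band intensities after background subtraction
#'
#' For each line-role cell of the strip, top to bottom, the pixels above
#' the threshold are taken as signal; the background level is subtracted
#' (s = p - t) and the mean and median of the subtracted values are
#' reported, together with the count of above-threshold pixels. Lines
#' with no pixel above the threshold report zero signal.
#'
#' With `statistic_on = "raw"` the mean/median are computed on the raw
#' above-threshold intensities instead of the subtracted values. With
#' `statistic_on = "subtracted_all"` they are computed on the clipped
#' subtraction `max(p - t, 0)` over *all* cell pixels; unlike the
#' default survivor-only mean, this variant is exactly non-increasing
#' in the threshold (each pixel's contribution is), at the cost of
#' diluting the band signal by the cell area.
#'
#' @param img a 1-channel `lfa_image` (already converted/inverted).
#' @param grid an `lfa_grid`.
#' @param strip 0-based strip column index.
#' @param threshold background threshold in \eqn{[0, 1]}, e.g. from
#'   [compute_threshold()].
#' @param statistic_on `"subtracted"` (default) or `"raw"`.
#' @return Data frame with one row per line (top to bottom): `strip`,
#'   `line`, `mean_signal`, `median_signal`, `n_above`.
#' @export
extract_line_intensities <- function(img, grid, strip, threshold,
                                     statistic_on = c("subtracted", "raw",
                                                      "subtracted_all")) {
  statistic_on <- match.arg(statistic_on)
  if (inherits(threshold, "threshold_result")) threshold <- threshold$threshold
  stopifnot(is.numeric(threshold), length(threshold) == 1L)
  line_rows <- (seq_len(grid$n_rows) - 1L)[grid$roles == "line"]
  out <- lapply(seq_along(line_rows), function(i) {
    px <- cell_pixels(img, grid, line_rows[i], strip)
    n_above <- sum(px > threshold)
    sig <- switch(statistic_on,
                  subtracted = px[px > threshold] - threshold,
                  raw = px[px > threshold],
                  subtracted_all = if (n_above) pmax(px - threshold, 0)
                                   else numeric())
    data.frame(strip = as.integer(strip), line = i - 1L,
               mean_signal = if (length(sig)) mean(sig) else 0,
               median_signal = if (length(sig)) stats::median(sig) else 0,
               n_above = n_above)
  })
  do.call(rbind, out)
}
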