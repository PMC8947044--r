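#' Synthetic strip image specification
#'
#' Describes a simulated image of one or more LFA strips: each strip is
#' a vertical column with `n_lines` horizontal bands of Gaussian
#' cross-section on a uniform background with additive Gaussian pixel
#' noise. Band amplitude is the ground-truth signal; with
#' `polarity = "bright_bands"` the bands rise above the background
#' (fluorescent labels), with `"dark_bands"` they fall below it
#' (colorimetric labels, to be analyzed after inversion).
#'
#' The defaults emulate a modest phone-camera crop: 90 px tall strips of
#' 30 px width, two lines with 3 px Gaussian half-width centered in the
#' top and bottom thirds, background level 0.10 and pixel noise standard
#' deviation 0.02.
#'
#' @param height image height in pixels.
#' @param strip_width width of each strip in pixels.
#' @param n_strips number of side-by-side strips.
#' @param n_lines signal bands per strip.
#' @param band_centers band center rows (0-based); default: centers of
#'   the line-role rows of the matching analysis grid.
#' @param band_sigma Gaussian cross-section standard deviation (pixels).
#' @param amplitudes `n_strips x n_lines` matrix (or recyclable vector)
#'   of band amplitudes in \eqn{[0, 1]}.
#' @param background uniform background level in \eqn{[0, 1]}.
#' @param noise_sd additive Gaussian noise standard deviation.
#' @param polarity `"bright_bands"` or `"dark_bands"`.
#' @param tint optional length-3 RGB weights in \eqn{[0, 1]}; when given,
#'   a 3-channel image is produced with each channel scaled by its
#'   weight (`NULL` = single-channel grayscale).
#' @param seed integer seed making the render deterministic.
#' @return A `strip_spec` object.
#' @export
strip_spec <- function(height = 90L, strip_width = 30L, n_strips = 1L,
                       n_lines = 2L, band_centers = NULL, band_sigma = 3,
                       amplitudes = 0.5, background = 0.1,
                       noise_sd = 0.02,
                       polarity = c("bright_bands", "dark_bands"),
                       tint = NULL, seed = 1L) {
  polarity <- match.arg(polarity)
  n_rows <- 2L * n_lines - 1L
  if (is.null(band_centers)) {
    # centers of the line-role rows of the equal-subdivision grid
    step <- height %/% n_rows
    row_lo <- step * (0:(n_rows - 1L))
    row_hi <- c(row_lo[-1L], height)
    line_rows <- seq(1L, n_rows, by = 2L)
    band_centers <- (row_lo[line_rows] + row_hi[line_rows]) / 2
  }
  if (length(band_centers) != n_lines)
    stop("need one band center per line", call. = FALSE)
  if (any(band_centers < 0) || any(band_centers > height))
    stop("band centers must lie inside the image", call. = FALSE)
  amp <- matrix(amplitudes, nrow = n_strips, ncol = n_lines)
  if (any(amp < 0) || any(amp > 1))
    stop("band amplitudes must lie in [0, 1]", call. = FALSE)
  peak <- background + max(amp) * if (polarity == "bright_bands") 1 else -1
  if (peak > 1 || peak < 0)
    stop("background and amplitudes would clip: peak level ",
         signif(peak, 4), " outside [0, 1]", call. = FALSE)
  if (!is.null(tint) &&
      (length(tint) != 3L || any(tint < 0) || any(tint > 1)))
    stop("tint must be 3 RGB weights in [0, 1]", call. = FALSE)
  structure(list(height = as.integer(height),
                 strip_width = as.integer(strip_width),
                 n_strips = as.integer(n_strips),
                 n_lines = as.integer(n_lines),
                 band_centers = band_centers, band_sigma = band_sigma,
                 amplitudes = amp, background = background,
                 noise_sd = noise_sd, polarity = polarity, tint = tint,
                 seed = as.integer(seed)),
            class = "strip_spec")
}

#' Render a synthetic strip image
#'
#' Deterministic render of a [strip_spec()]: for every strip column the
#' pixel value at image row r is
#' \deqn{b \pm \sum_j a_j \exp(-(r - c_j)^2 / (2\sigma^2)) + \epsilon}
#' with \eqn{\epsilon \sim N(0, \sigma_{noise}^2)}, clipped to
#' \eqn{[0, 1]}. The same seed always produces the bit-identical image.
#'
#' @param spec a [strip_spec()].
#' @return List with `image` (an `lfa_image`), `truth` (data frame of
#'   per strip/line true amplitudes) and `grid_spec` (the matching
#'   [grid_spec()] covering the whole image).
#' @export
render_strip_image <- function(spec) {
  stopifnot(inherits(spec, "strip_spec"))
  H <- spec$height; W <- spec$strip_width * spec$n_strips
  sgn <- if (spec$polarity == "bright_bands") 1 else -1
  rows <- seq_len(H) - 0.5 # pixel centers, 0-based coordinates
  clean <- matrix(spec$background, nrow = H, ncol = W)
  for (s in seq_len(spec$n_strips)) {
    profile <- rep(0, H)
    for (j in seq_len(spec$n_lines))
      profile <- profile + spec$amplitudes[s, j] *
        exp(-(rows - spec$band_centers[j])^2 / (2 * spec$band_sigma^2))
    cols <- ((s - 1L) * spec$strip_width + 1L):(s * spec$strip_width)
    clean[, cols] <- clean[, cols] + sgn * profile
  }
  noisy <- withr_seed(spec$seed, {
    clean + matrix(stats::rnorm(H * W, sd = spec$noise_sd), H, W)
  })
  px <- pmin(pmax(noisy, 0), 1)
  img <- if (is.null(spec$tint)) {
    lfa_image(array(px, dim = c(H, W, 1L)))
  } else {
    arr <- array(0, dim = c(H, W, 3L))
    for (ch in 1:3) arr[, , ch] <- px * spec$tint[ch]
    lfa_image(arr)
  }
  truth <- expand.grid(line = seq_len(spec$n_lines) - 1L,
                       strip = seq_len(spec$n_strips) - 1L,
                       KEEP.OUT.ATTRS = FALSE)[, c(2, 1)]
  truth$amplitude <- as.vector(t(spec$amplitudes))
  gspec <- grid_spec(img_rect(0L, 0L, H, W), n_lines = spec$n_lines,
                     n_strips = spec$n_strips)
  list(image = img, truth = truth, grid_spec = gspec)
}

# evaluate expr under a local RNG seed without disturbing the caller's
# RNG state
withr_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Render a calibration series of synthetic strips
#'
#' One image per (concentration, replicate), with the first line's band
#' amplitude set to `response_fn(concentration)` plus a small
#' between-replicate jitter, emulating run-to-run variation. Any further
#' lines keep the base spec's amplitude (a constant control line).
#' Image seeds are derived deterministically from `seed`.
#'
#' @param concentrations numeric vector of true concentrations (include
#'   0 replicates to enable detection limits).
#' @param response_fn function mapping concentration to band amplitude
#'   in \eqn{[0, 1]}.
#' @param spec_base a [strip_spec()] used as template (its `n_strips`
#'   must be 1).
#' @param replicates technical replicates per concentration.
#' @param seed master seed.
#' @param amplitude_jitter_sd standard deviation of the replicate
#'   amplitude jitter (truth table records the jittered value).
#' @return List with `images` (list of render results) and `truth`
#'   (data frame: image index, concentration, replicate, amplitude).
#' @export
render_calibration_series <- function(concentrations, response_fn,
                                      spec_base = strip_spec(),
                                      replicates = 3L, seed = 1L,
                                      amplitude_jitter_sd = 0.005) {
  stopifnot(inherits(spec_base, "strip_spec"), spec_base$n_strips == 1L)
  amps <- vapply(concentrations, response_fn, numeric(1))
  if (any(amps < 0) || any(amps > 1))
    stop("response_fn produced amplitudes outside [0, 1]", call. = FALSE)
  grid <- expand.grid(replicate = seq_len(replicates),
                      conc_idx = seq_along(concentrations),
                      KEEP.OUT.ATTRS = FALSE)
  jitter <- withr_seed(seed,
    stats::rnorm(nrow(grid), sd = amplitude_jitter_sd))
  images <- vector("list", nrow(grid))
  truth <- data.frame(image = seq_len(nrow(grid)),
                      concentration = concentrations[grid$conc_idx],
                      replicate = grid$replicate,
                      amplitude = NA_real_)
  for (i in seq_len(nrow(grid))) {
    a <- min(max(amps[grid$conc_idx[i]] + jitter[i], 0), 1)
    sp <- spec_base
    sp$amplitudes[1, 1] <- a
    sp$seed <- spec_base$seed + 1000L * i + seed
    images[[i]] <- render_strip_image(sp)
    truth$amplitude[i] <- a
  }
  list(images = images, truth = truth)
}
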