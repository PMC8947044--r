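# Shared fixtures and independent oracles for the threshold algorithms.
# The oracles recompute the target quantity by exhaustive search straight
# from the definitions, without reusing the package's search code.

random_gray_image <- function(h = 16, w = 16, seed = 1) {
  set.seed(seed)
  lfa_image(array(runif(h * w), dim = c(h, w, 1)))
}

random_rgb_image <- function(h = 16, w = 16, seed = 1) {
  set.seed(seed)
  lfa_image(array(runif(h * w * 3), dim = c(h, w, 3)))
}

# Otsu oracle: for every interior bin boundary k/n_bins classify the
# quantized pixels directly and evaluate w0 * w1 * (mu0 - mu1)^2.
brute_force_otsu <- function(pixels, n_bins = 256L) {
  bin <- pmin(floor(pixels * n_bins), n_bins - 1L)
  q <- (bin + 0.5) / n_bins # quantized values (bin centers)
  best_k <- NA_integer_; best_v <- -Inf
  for (k in seq_len(n_bins - 1L)) {
    lo <- q[bin < k]; hi <- q[bin >= k]
    if (!length(lo) || !length(hi)) next
    w0 <- length(lo) / length(q); w1 <- 1 - w0
    v <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (v > best_v + 1e-15) { best_v <- v; best_k <- k }
  }
  best_k / n_bins
}

# Triangle oracle: rebuild the histogram independently, pick peak and
# farthest nonzero tail bin on the longer side, and maximize the exact
# point-to-line distance on the normalized coordinates.
brute_force_triangle <- function(pixels, n_bins = 256L) {
  bin <- pmin(floor(pixels * n_bins), n_bins - 1L)
  counts <- as.vector(table(factor(bin, levels = 0:(n_bins - 1L))))
  nz <- which(counts > 0)
  peak <- which.max(counts)
  end <- if (max(nz) - peak >= peak - min(nz)) max(nz) else min(nz)
  if (end == peak) return((peak - 0.5) / n_bins)
  idx <- if (end > peak) peak:end else end:peak
  x1 <- 0; y1 <- 1
  x2 <- 1; y2 <- counts[end] / counts[peak]
  best_d <- -Inf; best <- integer()
  for (b in idx) {
    x0 <- (b - peak) / (end - peak); y0 <- counts[b] / counts[peak]
    d <- abs((y2 - y1) * x0 - (x2 - x1) * y0 + x2 * y1 - y2 * x1) /
      sqrt((y2 - y1)^2 + (x2 - x1)^2)
    if (d > best_d + 1e-12) { best_d <- d; best <- b }
    else if (abs(d - best_d) <= 1e-12) best <- c(best, b)
  }
  (min(best) - 0.5) / n_bins
}

# Li update step, straight from the cross-entropy fixed-point formula.
li_update <- function(pixels, t) {
  mu_low <- mean(pixels[pixels <= t]); mu_high <- mean(pixels[pixels > t])
  (mu_low - mu_high) / (log(mu_low) - log(mu_high))
}

# Noise-free linear calibration data on a given design.
exact_line_data <- function(x = 0:3, intercept = 1, slope = 2) {
  d <- data.frame(concentration = x, response = intercept + slope * x)
  class(d) <- c("calibration_data", "data.frame")
  d
}

# Simulated replicated calibration: y = intercept + slope * x + noise.
simulate_calibration <- function(seed, n_conc = 8, replicates = 3,
                                 sigma = 0.05, slope = 1, intercept = 0) {
  set.seed(seed)
  x <- rep(seq_len(n_conc) - 1, each = replicates)
  d <- data.frame(concentration = x,
                  response = intercept + slope * x + rnorm(length(x), 0, sigma))
  class(d) <- c("calibration_data", "data.frame")
  d
}

make_long_table <- function(n_files = 2, n_strips = 1, n_lines = 2,
                            seed = 1) {
  set.seed(seed)
  g <- expand.grid(line = seq_len(n_lines) - 1L,
                   strip = seq_len(n_strips) - 1L,
                   file = sprintf("img%02d.png", seq_len(n_files)),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  data.frame(file = g$file, strip = g$strip, line = g$line,
             method = "otsu", offset = 0, quantile_prob = NA_real_,
             mode = "luminance", inverted = FALSE,
             mean_signal = round(runif(nrow(g)), 4),
             median_signal = round(runif(nrow(g)), 4),
             stringsAsFactors = FALSE)
}
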