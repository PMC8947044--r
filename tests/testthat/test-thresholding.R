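test_that("histogram bins partition [0,1] with the floor rule", {
  h <- intensity_histogram(rep(0.5, 4))
  expect_equal(sum(h$counts > 0), 1L)
  expect_equal(max(h$counts), 4L)
  set.seed(1)
  p <- runif(500)
  expect_equal(sum(intensity_histogram(p)$counts), 500L)
  expect_equal(which(intensity_histogram(1)$counts > 0), 256L)
  expect_equal(which(intensity_histogram(0.5)$counts > 0), 129L) # floor(.5*256)+1
  expect_error(intensity_histogram(numeric()), "empty")
})

test_that("Otsu separates a bimodal image between its modes", {
  p <- c(rep(0.2, 100), rep(0.8, 100))
  t <- threshold_otsu(p)
  expect_gt(t, 0.2); expect_lt(t, 0.8)
  expect_equal(sum(p > t), 100L)
  expect_error(threshold_otsu(rep(0.4, 10)), "constant")
})

test_that("Otsu matches the brute-force between-class variance argmax", {
  set.seed(20)
  for (i in 1:20) {
    p <- switch(1 + i %% 3,
      runif(200),
      c(rnorm(150, 0.3, 0.05), rnorm(50, 0.8, 0.03)),
      c(rep(0.1, 190), rep(0.9, 10)))
    p <- pmin(pmax(p, 0), 1)
    expect_equal(threshold_otsu(p), brute_force_otsu(p))
  }
})

test_that("Li converges to the cross-entropy fixed point", {
  p <- c(rep(0.2, 50), rep(0.8, 50))
  t <- threshold_li(p)
  closed_form <- (0.2 - 0.8) / (log(0.2) - log(0.8))
  expect_equal(as.numeric(t), closed_form, tolerance = 1e-9)
  expect_equal(round(closed_form, 4), 0.4328)
  expect_true(attr(t, "iterations") <= 100)
  set.seed(7)
  for (i in 1:15) {
    p <- pmin(pmax(rbeta(300, 2, 5) + (i %% 2) * 0.3, 0.001), 1)
    t <- as.numeric(threshold_li(p))
    expect_lt(abs(t - li_update(p, t)), 1e-6)
  }
})

test_that("Li on symmetric bimodal data stays at or below the midpoint", {
  set.seed(3)
  p <- c(rnorm(200, 0.3, 0.02), rnorm(200, 0.7, 0.02))
  p <- pmin(pmax(p, 0.01), 1)
  expect_lte(as.numeric(threshold_li(p)), 0.5)
})

test_that("Li shifts zero intensities before taking logs", {
  p <- c(rep(0, 50), rep(0.6, 50))
  t <- as.numeric(threshold_li(p))
  expect_true(is.finite(t))
  expect_gt(t, 0); expect_lt(t, 0.6)
})

test_that("quantile threshold uses linear-interpolation quantiles", {
  s <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  expect_equal(threshold_quantile(s, 0.5), 0.3)
  expect_equal(threshold_quantile(s, 0.99), 0.496)
  expect_equal(threshold_quantile(rep(0.25, 9), 0.9), 0.25)
  expect_error(threshold_quantile(s, 1), "strictly")
  expect_error(threshold_quantile(numeric(), 0.5), "background")
})

test_that("triangle matches the brute-force distance maximization", {
  set.seed(33)
  for (i in 1:15) {
    # skewed unimodal data: exponential-decay style histograms
    p <- pmin(rexp(400, rate = 8 + i), 1)
    expect_equal(threshold_triangle(p), brute_force_triangle(p))
  }
  # two well-separated bins: threshold falls between them
  p2 <- c(rep(0.1, 90), rep(0.9, 10))
  t2 <- threshold_triangle(p2)
  expect_gt(t2, 0.1); expect_lt(t2, 0.9)
  expect_error(threshold_triangle(rep(0.3, 5)), "constant")
})

test_that("triangle threshold mirrors with the histogram", {
  set.seed(4)
  p <- pmin(rexp(500, 10), 1)
  t_fwd <- threshold_triangle(p)
  t_rev <- threshold_triangle(1 - p)
  expect_lt(abs(t_rev - (1 - t_fwd)), 1 / 256 + 1e-12)
})

test_that("offset shifts and clips the threshold", {
  expect_equal(apply_offset(0.4, 0.05), 0.45)
  expect_equal(apply_offset(0.99, 0.05), 1)
  expect_equal(apply_offset(0.03, -0.1), 0)
  expect_equal(apply_offset(0.7, 0), 0.7)
})

test_that("compute_threshold pools strip pixels per method", {
  r <- render_strip_image(strip_spec(n_strips = 2, amplitudes = c(0.5, 0.3),
                                     noise_sd = 0.01, seed = 8))
  grid <- build_grid(r$grid_spec)
  tq <- compute_threshold(r$image, grid, 0,
                          threshold_spec("quantile", quantile_prob = 0.5))
  # quantile method samples only the inter-line background rectangle
  bg <- strip_pixels(r$image, grid, 0, "background")
  expect_equal(tq$threshold, unname(stats::quantile(bg, 0.5)))
  to <- compute_threshold(r$image, grid, 0, threshold_spec("otsu"))
  expect_equal(to$threshold,
               threshold_otsu(strip_pixels(r$image, grid, 0, "all")))
  tl <- compute_threshold(r$image, grid, 0, threshold_spec("li"))
  expect_false(is.na(tl$n_iterations))
  # offset is applied after the method
  toff <- compute_threshold(r$image, grid, 0,
                            threshold_spec("otsu", offset = 0.1))
  expect_equal(toff$threshold, apply_offset(to$threshold, 0.1))
  # single-line grids have no background cells for the quantile method
  r1 <- render_strip_image(strip_spec(n_lines = 1, amplitudes = 0.4,
                                      seed = 2))
  g1 <- build_grid(r1$grid_spec)
  expect_error(compute_threshold(r1$image, g1, 0,
                                 threshold_spec("quantile")),
               "no background")
})

test_that("line intensities subtract the background threshold", {
  img <- lfa_image(array(c(0.9, 0.9, 0.1, 0.1), dim = c(2, 2, 1)))
  g <- build_grid(grid_spec(img_rect(0, 0, 2, 2), 1, 1))
  li <- extract_line_intensities(img, g, 0, 0.4)
  expect_equal(li$n_above, 2L)
  expect_equal(li$mean_signal, 0.5)
  expect_equal(li$median_signal, 0.5)
  # saturated threshold: all lines report zero signal
  sat <- extract_line_intensities(img, g, 0, 1.0)
  expect_equal(sat$mean_signal, 0)
  expect_equal(sat$n_above, 0L)
  # raw statistic variant reports unsubtracted intensities
  raw <- extract_line_intensities(img, g, 0, 0.4, statistic_on = "raw")
  expect_equal(raw$mean_signal, 0.9)
})

test_that("stronger bands yield stronger extracted signal", {
  r <- render_strip_image(strip_spec(amplitudes = matrix(c(0.6, 0.25), 1),
                                     noise_sd = 0.01, seed = 12))
  grid <- build_grid(r$grid_spec)
  li <- extract_line_intensities(r$image, grid, 0, 0.12)
  expect_gt(li$mean_signal[1], li$mean_signal[2])
})

test_that("clipped-mean signal is non-increasing in the threshold", {
  # exact theorem: every pixel's clipped contribution max(p - t, 0) is
  # non-increasing in t, hence so is the all-pixels mean
  for (seed in 1:5) {
    r <- render_strip_image(strip_spec(amplitudes = c(0.5, 0.3),
                                       noise_sd = 0.02, seed = seed))
    grid <- build_grid(r$grid_spec)
    ts <- seq(0.02, 0.98, by = 0.02)
    sig <- sapply(ts, function(t)
      extract_line_intensities(r$image, grid, 0, t,
                               statistic_on = "subtracted_all")$mean_signal)
    expect_true(all(diff(t(sig))[, 1] <= 1e-12))
    expect_true(all(diff(t(sig))[, 2] <= 1e-12))
  }
})

test_that("total above-threshold signal is non-increasing in the threshold", {
  # the survivor-only mean can tick up when weak pixels drop out of the
  # survivor set, but the line's total signal (mean * count) cannot
  for (seed in 1:5) {
    r <- render_strip_image(strip_spec(amplitudes = c(0.5, 0.3),
                                       noise_sd = 0.02, seed = seed))
    grid <- build_grid(r$grid_spec)
    ts <- seq(0.02, 0.98, by = 0.02)
    tot <- sapply(ts, function(t) {
      li <- extract_line_intensities(r$image, grid, 0, t)
      li$mean_signal * li$n_above
    })
    expect_true(all(diff(t(tot))[, 1] <= 1e-9))
    expect_true(all(diff(t(tot))[, 2] <= 1e-9))
  }
})

test_that("growing offsets never strengthen the reported line signal", {
  for (seed in 1:5) {
    r <- render_strip_image(strip_spec(seed = seed))
    grid <- build_grid(r$grid_spec)
    offs <- seq(0, 0.5, by = 0.05)
    sig <- sapply(offs, function(o) {
      tres <- compute_threshold(r$image, grid, 0,
                                threshold_spec("otsu", offset = o))
      extract_line_intensities(r$image, grid, 0, tres)$mean_signal
    })
    expect_true(all(diff(t(sig))[, 1] <= 1e-12))
    expect_true(all(diff(t(sig))[, 2] <= 1e-12))
  }
})

test_that("bright-band analysis after inversion equals dark-band analysis", {
  amp <- matrix(c(0.5, 0.3), 1)
  bright <- render_strip_image(strip_spec(amplitudes = amp, background = 0.1,
                                          noise_sd = 0, polarity = "bright_bands"))
  dark <- render_strip_image(strip_spec(amplitudes = amp, background = 0.9,
                                        noise_sd = 0, polarity = "dark_bands"))
  expect_equal(unclass(invert_image(dark$image)), unclass(bright$image))
  grid <- build_grid(bright$grid_spec)
  spec_inv <- threshold_spec("otsu", inverted = TRUE)
  t_dark <- compute_threshold(dark$image, grid, 0, spec_inv)
  t_bright <- compute_threshold(bright$image, grid, 0, threshold_spec("otsu"))
  expect_equal(t_dark$threshold, t_bright$threshold)
  li_dark <- extract_line_intensities(invert_image(dark$image), grid, 0,
                                      t_dark$threshold)
  li_bright <- extract_line_intensities(bright$image, grid, 0,
                                        t_bright$threshold)
  expect_equal(li_dark, li_bright)
})
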