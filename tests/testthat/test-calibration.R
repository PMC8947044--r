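test_that("response definitions evaluate the standard LFA ratios", {
  wide <- data.frame(file = "a", concentration = c(1, 2, 3),
                     tl_mean = c(0.4, 0.4, 0), cl_mean = c(0.2, 0, 0.2),
                     tl_median = c(0.4, 0.4, 0), cl_median = c(0.2, 0, 0.2))
  d <- make_response(wide[1, ], response_definition("tl/cl"),
                     "concentration")
  expect_equal(d$response, 2)
  d2 <- make_response(wide[1, ], response_definition("tl/(tl+cl)"),
                      "concentration")
  expect_equal(d2$response, 0.4 / 0.6)
  d3 <- make_response(wide[1, ], response_definition("tl"), "concentration")
  expect_equal(d3$response, 0.4)
  # zero denominators are dropped, not propagated
  expect_message(d4 <- make_response(wide, response_definition("cl/tl"),
                                     "concentration"), "dropped")
  expect_equal(nrow(d4), 2L)
  expect_equal(attr(d4, "n_dropped"), 1L)
  # median statistic reads the *_median columns
  d5 <- make_response(wide[1, ], response_definition("tl/cl", "median"),
                      "concentration")
  expect_equal(d5$response, 2)
  expect_error(make_response(wide, response_definition("xx"), "concentration"),
               "xx_mean")
  expect_error(response_definition("tl+cl"), "unsupported")
  expect_error(make_response(wide, response_definition("tl"), "conc"),
               "conc")
})

test_that("a noise-free line is fit exactly with R^2 = 1", {
  f <- fit_calibration(exact_line_data(), "linear")
  expect_equal(f$model$coefficients, c(1, 2), tolerance = 1e-10)
  expect_equal(f$metrics$r_squared, 1, tolerance = 1e-12)
  expect_true(f$model$monotone)
})

test_that("linear R^2 equals the squared correlation of y and y-hat", {
  d <- simulate_calibration(seed = 31, sigma = 0.3)
  f <- fit_calibration(d, "linear")
  yhat <- predict(f$model, d$concentration)
  expect_equal(f$metrics$r_squared, cor(d$response, yhat)^2,
               tolerance = 1e-10)
})

test_that("noisy simulations recover the slope within 3 standard errors", {
  d <- simulate_calibration(seed = 11, sigma = 0.05, slope = 2,
                            intercept = 1)
  f <- fit_calibration(d, "linear")
  se <- summary(f$model$fit)$coefficients[, "Std. Error"]
  expect_lt(abs(f$model$coefficients[1] - 1), 3 * se[1])
  expect_lt(abs(f$model$coefficients[2] - 2), 3 * se[2])
})

test_that("the additive spline reproduces noise-free smooth data", {
  x <- seq(0, 4, length.out = 9)
  d <- data.frame(concentration = x, response = 0.2 + 0.1 * x^2)
  f <- fit_calibration(d, "spline_additive")
  expect_lt(max(abs(predict(f$model, x) - d$response)), 1e-3)
  expect_null(f$metrics$r_squared) # R^2 reported for linear fits only
})

test_that("the local polynomial smoother tracks a curved calibration", {
  set.seed(5)
  x <- rep(seq(0, 4, length.out = 8), each = 3)
  d <- data.frame(concentration = x,
                  response = 0.1 + 0.3 * sqrt(x) + rnorm(length(x), 0, 0.01))
  f <- fit_calibration(d, "local_poly")
  expect_null(f$metrics$r_squared)
  g <- seq(0.5, 3.5, length.out = 20)
  expect_lt(max(abs(predict(f$model, g) - (0.1 + 0.3 * sqrt(g)))), 0.05)
})

test_that("degenerate inputs are rejected with data errors", {
  d1 <- data.frame(concentration = c(1, 1, 1), response = c(1, 2, 3))
  expect_error(fit_calibration(d1, "linear"), "distinct")
  d2 <- exact_line_data(x = 0:3)
  expect_error(fit_calibration(d2, "spline_additive"), "at least 5")
})

test_that("detection limits follow the blank-based closed form", {
  # blanks with mean 0 and sd 0.02 on a unit-slope line
  blanks <- c(-0.02, 0.02) / sqrt(2)
  d <- data.frame(concentration = c(0, 0, 1, 2, 3, 4),
                  response = c(blanks, 1, 2, 3, 4))
  f <- fit_calibration(d, "linear")
  expect_equal(stats::sd(blanks), 0.02)
  lim <- detection_limits(f$model, d)
  b <- f$model$coefficients
  expect_equal(lim$lob_response, 1.645 * 0.02)
  expect_equal(lim$lob, (1.645 * 0.02 - b[1]) / b[2])
  expect_equal(lim$lob, 0.0329, tolerance = 1e-2)
  # no low-concentration replicates: sd_low falls back to sd_blank
  expect_equal(lim$lod_response, 2 * 1.645 * 0.02)
  expect_equal(lim$loq_response, 10 * 0.02)
  expect_true(lim$lob <= lim$lod && lim$lod <= lim$loq)
})

test_that("zero blank noise collapses all three limits", {
  d <- data.frame(concentration = c(0, 0, 1, 2, 3),
                  response = c(0.1, 0.1, 1.1, 2.1, 3.1))
  f <- fit_calibration(d, "linear")
  lim <- detection_limits(f$model, d)
  expect_equal(lim$lob, lim$lod)
  expect_equal(lim$lod, lim$loq)
  expect_equal(lim$lob, 0, tolerance = 1e-9) # blank response maps to x = 0
})

test_that("limit ordering holds across seeded simulated calibrations", {
  for (seed in 1:25) {
    d <- simulate_calibration(seed, sigma = 0.03, slope = 0.5)
    f <- fit_calibration(d, "linear")
    lim <- f$metrics
    if (is.numeric(lim$lob) && is.numeric(lim$lod) && is.numeric(lim$loq)) {
      expect_lte(lim$lob, lim$lod)
      expect_lte(lim$lod, lim$loq)
    }
  }
})

test_that("limits need blanks and a monotone curve", {
  d <- data.frame(concentration = 1:5, response = 1:5)
  f <- fit_calibration(d, "linear")
  expect_error(detection_limits(f$model, d), "blank")
})

test_that("decreasing calibrations place limits below the blank response", {
  # cl/tl-style response: decreases with concentration
  set.seed(17)
  d <- data.frame(concentration = rep(0:5, each = 3),
                  response = 5 - 0.8 * rep(0:5, each = 3) +
                    rnorm(18, 0, 0.02))
  f <- fit_calibration(d, "linear")
  lim <- f$metrics
  expect_lt(lim$lob_response, lim$mean_blank)
  expect_true(lim$lob <= lim$lod && lim$lod <= lim$loq)
})

test_that("models survive a JSON round trip with identical predictions", {
  grid_x <- seq(0, 7, length.out = 100)
  # linear: identical coefficients
  f <- fit_calibration(simulate_calibration(3), "linear")
  p <- withr::local_tempfile(fileext = ".json")
  save_model(f$model, p)
  m2 <- load_model(p)
  expect_equal(m2$coefficients, f$model$coefficients)
  # smoothers: identical predictions on a dense grid
  for (kind in c("local_poly", "spline_additive")) {
    fk <- fit_calibration(simulate_calibration(4, sigma = 0.02), kind)
    pk <- withr::local_tempfile(fileext = ".json")
    save_model(fk$model, pk)
    mk <- load_model(pk)
    expect_lt(max(abs(predict(mk, grid_x) - predict(fk$model, grid_x))),
              1e-9)
  }
  # truncated/garbage files raise format errors, not crashes
  bad <- withr::local_tempfile(fileext = ".json")
  writeLines('{"format": "lfaquant_calib', bad)
  expect_error(load_model(bad), "not a valid model file")
  other <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(format = "something_else"), other,
                       auto_unbox = TRUE)
  expect_error(load_model(other), "not a calibration model")
})

test_that("the calibration report documents fit, limits and settings", {
  d <- exact_line_data(x = c(0, 0, 1, 2, 3))
  f <- fit_calibration(d, "linear")
  out <- file.path(withr::local_tempdir(), "report.md")
  calibration_report(f$model, f$metrics, d, out)
  txt <- readLines(out)
  expect_true(any(grepl("R\\^2 = 1", txt)))
  expect_true(any(grepl("LOB = ", txt)))
  expect_true(any(grepl("linear", txt)))
  expect_true(file.exists(sub("\\.md$", ".png", out)))
  # regenerating from the same inputs is byte-identical
  out2 <- file.path(withr::local_tempdir(), "report.md")
  calibration_report(f$model, f$metrics, d, out2)
  expect_identical(readLines(out2), txt)
})
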