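test_that("correction passes through clean traces and inverts acquisition decay", {
  tr <- make_frap_trace(acquisition_bleach_rate = 0, background_level = 0,
                        seed = 1)$trace
  expect_equal(correct_trace(tr), tr$bleach)

  # reference decaying ~20% over the run, plus background
  sim <- make_frap_trace(m1 = 100, m2 = -100, m3 = 0.08, dt = 0.33,
                         n_post = 150, acquisition_bleach_rate = 0.0015,
                         background_level = 25, seed = 2)
  corrected <- correct_trace(sim$trace)
  # the planted bleach-free signal, up to the pre-bleach reference scale
  n_pre <- sim$trace$n_prebleach
  scale <- mean(corrected[seq_len(n_pre)]) / 100
  clean <- c(rep(100, n_pre),
             100 - 100 * exp(-0.08 * (0:149) * 0.33))
  expect_equal(corrected / scale, clean, tolerance = 1e-9)

  bad <- sim$trace
  bad$reference[10] <- bad$background[10]
  expect_error(correct_trace(bad), "timepoint 10")
})

test_that("normalization anchors 100%/0% and is idempotent", {
  corrected <- c(rep(200, 5), 80, 140, 170, 185, 200)
  norm <- normalize_trace(corrected, 5)
  expect_equal(norm[6], 0)
  expect_equal(mean(norm[1:5]), 100)
  expect_equal(norm[7], 50)           # (140 - 80) / (200 - 80) * 100
  expect_equal(normalize_trace(norm, 5), norm)
  expect_error(normalize_trace(c(rep(10, 5), 50, 60, 70, 80, 90), 5),
               "no bleach")
})

test_that("the rolling average is a centred mean with shrinking edges", {
  expect_equal(rolling_average(rep(4, 10)), rep(4, 10))
  expect_equal(rolling_average(c(0, 3, 6))[2], 3)
  set.seed(7)
  v <- rnorm(40)
  sm <- rolling_average(v, 3)
  oracle <- vapply(seq_along(v), function(i) {
    mean(v[max(1, i - 1):min(length(v), i + 1)])
  }, numeric(1))
  expect_equal(sm, oracle)
  # pre-bleach points untouched
  sm2 <- rolling_average(v, 3, n_prebleach = 5)
  expect_identical(sm2[1:5], v[1:5])
  expect_error(rolling_average(v, 4), "odd")
})

test_that("noiseless exponential fits recover planted kinetics to 1e-6", {
  x <- (0:149) * 0.33
  y <- 100 - 100 * exp(-0.1 * x)
  fit <- fit_recovery(x, y)
  expect_equal(fit$m1, 100, tolerance = 1e-6)
  expect_equal(fit$m2, -100, tolerance = 1e-6)
  expect_equal(fit$m3, 0.1, tolerance = 1e-6)
  expect_equal(fit$t_half, log(2) / 0.1, tolerance = 1e-6)
  expect_true(fit$converged)

  half <- fit_recovery(x, 60 - 60 * exp(-log(2) * x))
  expect_equal(half$t_half, 1, tolerance = 1e-6)

  expect_error(fit_recovery(x[1:4], y[1:4]), "at least 5")
  expect_error(fit_recovery(x, rep(5, 150)), "all values equal")
})

test_that("t_half times m3 is ln 2 at machine precision across fits", {
  for (seed in 1:10) {
    tr <- make_frap_trace(m3 = 0.02 + 0.03 * seed, noise_sd = 1.5,
                          seed = seed)
    fit <- frap_fit_pipeline(tr$trace)$fit
    expect_equal(fit$t_half * fit$m3, log(2), tolerance = 1e-12)
  }
})

test_that("the full pipeline is exactly invertible on noiseless traces", {
  designs <- list(list(dt = 0.33, n_post = 150L), list(dt = 10, n_post = 70L))
  for (d in designs) {
    sim <- make_frap_trace(m1 = 100, m2 = -100, m3 = 0.05, dt = d$dt,
                           n_post = d$n_post,
                           acquisition_bleach_rate = 0.002,
                           background_level = 15, seed = 3)
    res <- frap_fit_pipeline(sim$trace, window = 3, smooth = TRUE)
    expect_equal(res$fit$m1, 100, tolerance = 1e-6)
    expect_equal(res$fit$m2, -100, tolerance = 1e-6)
    expect_equal(res$fit$m3, 0.05, tolerance = 1e-6)
    raw <- frap_fit_pipeline(sim$trace, smooth = FALSE)
    expect_equal(raw$fit$m3, 0.05, tolerance = 1e-6)
  }
})

test_that("traces round-trip through CSV", {
  sim <- make_frap_trace(noise_sd = 2, seed = 9)
  path <- tempfile(fileext = ".csv")
  write_frap_trace(sim$trace, path)
  back <- read_frap_trace(path)
  expect_equal(back$bleach, sim$trace$bleach)
  expect_identical(back$n_prebleach, sim$trace$n_prebleach)
  unlink(path)
})
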