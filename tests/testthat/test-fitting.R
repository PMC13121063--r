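# Per-pixel decay fitting: exact recovery, failure sentinels, equivariance,
# stack/pixel equivalence, Monte-Carlo accuracy, an independent
# Levenberg-Marquardt cross-check, and model comparison.

test_that("a noiseless single-exponential trace is recovered exactly", {
  t <- 0:19
  y <- 100 * exp(-t / 5) + 50
  fit <- fit_pixel(t, y)
  expect_equal(fit$A, 100, tolerance = 1e-6)
  expect_equal(fit$tau, 5, tolerance = 1e-6)
  expect_equal(fit$C, 50, tolerance = 1e-6)
  expect_equal(fit$status, "ok")
  expect_lt(fit$rss, 1e-8)
})

test_that("unfittable and degenerate traces carry the documented sentinels", {
  t <- 0:9
  zero <- fit_pixel(t, rep(0, 10))
  expect_equal(c(zero$A, zero$tau, zero$C), c(0, 0, 0))
  expect_equal(zero$status, "unfittable")

  sat <- fit_pixel(t, rep(255, 10), bit_depth = 8)
  expect_equal(sat$status, "unfittable")
  expect_equal(c(sat$A, sat$tau, sat$C), c(0, 0, 0))

  const <- fit_pixel(t, rep(80, 10))
  expect_equal(const$status, "poor")
  expect_equal(const$A, 0)   # amplitude at its lower bound

  expect_error(fit_pixel(t, c(rep(1, 9), NA)), "NaN")
  expect_error(fit_pixel(t, 1:5), "equal length")
  expect_error(fit_pixel(c(0, 1, 1, 2), c(1, 2, 3, 4)), "strictly increasing")
})

test_that("fitted parameters obey time- and intensity-unit equivariance", {
  t <- 0:19
  y <- 80 * exp(-t / 7) + 30
  base <- fit_pixel(t, y)
  scaled_t <- fit_pixel(t * 3, y)
  expect_equal(scaled_t$tau, base$tau * 3, tolerance = 1e-5)
  expect_equal(scaled_t$A, base$A, tolerance = 1e-5)
  expect_equal(scaled_t$C, base$C, tolerance = 1e-5)
  scaled_y <- fit_pixel(t, y * 2.5)
  expect_equal(scaled_y$A, base$A * 2.5, tolerance = 1e-5)
  expect_equal(scaled_y$C, base$C * 2.5, tolerance = 1e-5)
  expect_equal(scaled_y$tau, base$tau, tolerance = 1e-5)
})

test_that("fit_stack equals looped fit_pixel on a small grid", {
  ph <- generate_phantom(noisy_phantom_spec(height = 16, width = 16, seed = 4,
                                            defect_fraction = 0))
  crop <- frame_stack(ph$stack$data[1:5, 1:5, ], times = ph$stack$times,
                      bit_depth = 8L)
  settings <- fit_settings(A_max = 2000, C_max = 2000, sat_level = 255)
  maps <- fit_stack(crop, settings = settings)
  for (i in 1:5) for (j in 1:5) {
    px <- fit_pixel(crop$times, crop$data[i, j, ], settings = settings,
                    bit_depth = 8)
    expect_identical(maps$A[i, j], if (px$status == "ok") px$A else 0)
    expect_identical(maps$tau[i, j], if (px$status == "ok") px$tau else 0)
    expect_identical(maps$C[i, j], if (px$status == "ok") px$C else 0)
  }
})

test_that("AF0 is the verbatim first frame and sentinels populate the maps", {
  spec <- noisy_phantom_spec(height = 32, width = 32, defect_fraction = 0.08,
                             seed = 9)
  ph <- generate_phantom(spec)
  maps <- fit_stack(ph$stack)
  expect_identical(maps$AF0, ph$stack$data[, , 1])
  bad <- !maps$mask
  expect_true(all(maps$A[bad] == 0 & maps$tau[bad] == 0 & maps$C[bad] == 0))
  # flagged fraction tracks the programmed defect fraction (binomial 95% CI)
  n <- length(bad); p <- 0.08
  expect_lt(abs(mean(bad) - p), 1.96 * sqrt(p * (1 - p) / n) + 1e-3)
})

test_that("fitted t = 0 value matches A + C within the residual scale", {
  set.seed(31)
  t <- 0:19
  for (i in 1:10) {
    y <- 60 * exp(-t / 4) + 40 + rnorm(20, 0, 2)
    fit <- fit_pixel(t, y)
    expect_equal(fit$status, "ok")
    expect_lt(abs(fit$A + fit$C - y[1]), 4 * sqrt(fit$rss / length(t)) + 1e-9)
  }
})

test_that("median tau over noisy replicates is within 5% of truth", {
  set.seed(42)
  t <- 0:19
  taus <- replicate(500, fit_pixel(t, 100 * exp(-t / 5) + 50 + rnorm(20, 0, 2))$tau)
  expect_lt(abs(median(taus) - 5) / 5, 0.05)
})

test_that("steeper programmed decay yields monotonically smaller fitted tau", {
  set.seed(17)
  t <- 0:19
  fitted <- vapply(c(2, 4, 8, 16), function(tau_true) {
    median(replicate(40, fit_pixel(t, 90 * exp(-t / tau_true) + 40 +
                                     rnorm(20, 0, 2))$tau))
  }, 0)
  expect_true(all(diff(fitted) > 0))
})

test_that("the profiled solver matches an independent Levenberg-Marquardt fit", {
  set.seed(55)
  t <- 0:19
  for (i in 1:15) {
    A0 <- runif(1, 30, 150); tau0 <- runif(1, 2, 12); C0 <- runif(1, 10, 80)
    y <- A0 * exp(-t / tau0) + C0 + rnorm(20, 0, 2)
    mine <- fit_pixel(t, y)
    lm_fit <- tryCatch(
      minpack.lm::nlsLM(y ~ A * exp(-t / tau) + C,
                        start = list(A = A0, tau = tau0, C = C0),
                        lower = c(0, 1e-3, 0)),
      error = function(e) NULL)
    if (is.null(lm_fit)) next
    rss_lm <- sum(residuals(lm_fit)^2)
    # the profiled global search must never be beaten beyond round-off
    expect_lte(mine$rss, rss_lm * (1 + 1e-6))
    expect_equal(mine$tau, coef(lm_fit)[["tau"]], tolerance = 1e-3)
  }
})

test_that("normalize_curve divides by the initial value", {
  expect_equal(normalize_curve(c(200, 100, 50)), c(1, 0.5, 0.25))
  expect_equal(normalize_curve(c(80, 80, 80)), c(1, 1, 1))
  expect_error(normalize_curve(c(0, 1, 2)), "must be > 0")
  expect_error(normalize_curve(c(-5, 1)), "must be > 0")
})

test_that("normalized skin curves lie above normalized SCC-core curves", {
  presets <- three_class_presets(height = 64, width = 64, seed = 3,
                                 lesion_geometry = list(center = c(32, 32),
                                                        axes = c(14, 11),
                                                        junction_width = 4))
  ph <- generate_phantom(presets$scc)
  mean_curve <- function(region) {
    px <- ph$truth$region == region
    vapply(seq_len(dim(ph$stack$data)[3]),
           function(k) mean(ph$stack$data[, , k][px]), 0)
  }
  skin_n <- normalize_curve(mean_curve("skin"))
  core_n <- normalize_curve(mean_curve("core"))
  expect_true(all(skin_n[-1] > core_n[-1]))
})

test_that("model comparison prefers the generating model", {
  t <- 0:19
  cmp <- compare_models(t, 100 * exp(-t / 5) + 50)
  expect_equal(cmp$winner, "single_exp")
  cmp_lin <- compare_models(t, -1 * t + 100)
  expect_equal(cmp_lin$winner, "linear")
  expect_lt(cmp_lin$rss[["linear"]], 1e-8)
  expect_error(compare_models(0:4, 1:5), "at least 6")
})
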