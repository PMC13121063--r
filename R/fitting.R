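# Per-pixel photobleaching model fitting. The working model is the
# single-exponential decay I(t) = A * exp(-t / tau) + C: A is the bleaching
# amplitude, tau the decay constant (seconds), C the residual (non-bleaching)
# component. The solver profiles tau (log-spaced grid + golden-section
# refinement) and solves the remaining bounded linear subproblem for A and C
# exactly, which is robust for monotone decays and needs no starting guess.
# Linear and double-exponential comparator fits exist for model selection
# only; their parameter maps are not pipeline outputs.

#' Fit settings for per-pixel decay fitting
#'
#' Bounds and failure thresholds for [fit_pixel()] / [fit_stack()].
#' `A_max`/`C_max` default to 4x the data maximum; `tau` is bounded to
#' `[frame_interval / 10, 50 * total duration]`. A fit is *unfittable* when
#' the trace is constant zero, constant saturated, or non-finite (its
#' parameters are set to the 0 sentinel); *poor* when the optimizer hits the
#' divergence flags: `tau` at `tau_max`, `A + C > 2 *` data maximum, or
#' residual sum of squares above `poor_rss_frac` of the trace's total sum of
#' squares (the fit explains almost none of the variance).
#'
#' @param A_max,C_max upper bounds for A and C in intensity units
#'   (`NULL`: 4x data maximum).
#' @param tau_min,tau_max decay-constant bounds in seconds (`NULL`: derived
#'   from the time base as above).
#' @param sat_level saturation intensity (`NULL`: `2^bit_depth - 1`, or the
#'   data maximum for float stacks).
#' @param poor_rss_frac poor-fit threshold as a fraction of total variance
#'   (default 0.95).
#' @param n_grid,n_refine tau grid size and golden-section iterations.
#' @return A list of class `fit_settings`.
#' @export
fit_settings <- function(A_max = NULL, C_max = NULL, tau_min = NULL,
                         tau_max = NULL, sat_level = NULL,
                         poor_rss_frac = 0.95, n_grid = 48L, n_refine = 60L) {
  structure(list(A_max = A_max, C_max = C_max, tau_min = tau_min,
                 tau_max = tau_max, sat_level = sat_level,
                 poor_rss_frac = poor_rss_frac,
                 n_grid = as.integer(n_grid), n_refine = as.integer(n_refine)),
            class = "fit_settings")
}

.resolve_settings <- function(settings, times, data_max, bit_depth = NA) {
  duration <- max(times) - min(times)
  interval <- min(diff(times))
  s <- settings
  if (is.null(s$A_max)) s$A_max <- 4 * data_max
  if (is.null(s$C_max)) s$C_max <- 4 * data_max
  if (is.null(s$tau_min)) s$tau_min <- interval / 10
  if (is.null(s$tau_max)) s$tau_max <- 50 * duration
  if (is.null(s$sat_level))
    # saturation is only identifiable for integer stacks; float traces are
    # never treated as saturated-constant
    s$sat_level <- if (!is.na(bit_depth)) 2^bit_depth - 1 else Inf
  s$data_max <- data_max
  s
}

.status_label <- function(code) {
  c("ok", "unfittable", "poor")[code + 1L]
}

#' Fit the photobleaching model to a single pixel trace
#'
#' @param times frame times in seconds, strictly increasing.
#' @param intensities intensity trace, same length as `times`.
#' @param model `"single_exp"` (the working model `A*exp(-t/tau) + C`),
#'   `"linear"` (`a*t + b`) or `"double_exp"`
#'   (`A1*exp(-t/tau1) + A2*exp(-t/tau2) + C`, `tau1 < tau2`).
#' @param settings a [fit_settings()].
#' @param bit_depth source bit depth used to derive the saturation level
#'   (`NA` for float data).
#' @return For `single_exp`, a `pixel_fit` list with `A`, `tau`, `C`, `rss`
#'   and `status` (`"ok"`, `"unfittable"`, `"poor"`); for the comparator
#'   models, a list with `coef`, `rss` and `status`.
#' @export
fit_pixel <- function(times, intensities, model = c("single_exp", "linear", "double_exp"),
                      settings = fit_settings(), bit_depth = NA) {
  model <- match.arg(model)
  npar <- c(single_exp = 3L, linear = 2L, double_exp = 5L)[[model]]
  if (length(times) != length(intensities)) stop("`times` and `intensities` must have equal length")
  if (length(times) < npar + 1L) stop("need at least ", npar + 1L, " observations")
  if (any(diff(times) <= 0)) stop("`times` must be strictly increasing")
  if (anyNA(times) || anyNA(intensities)) stop("NaN/NA in inputs")

  if (model == "linear") return(.fit_linear(times, intensities))
  if (model == "double_exp") return(.fit_double_exp(times, intensities, settings))

  s <- .resolve_settings(settings, times, max(intensities, 1e-9), bit_depth)
  res <- .fit_exp_cpp(matrix(intensities, ncol = 1), times,
                      s$tau_min, s$tau_max, s$A_max, s$C_max,
                      s$sat_level, s$data_max, s$poor_rss_frac,
                      s$n_grid, s$n_refine)
  structure(list(A = res[1, 1], tau = res[2, 1], C = res[3, 1],
                 rss = res[4, 1], status = .status_label(res[5, 1])),
            class = "pixel_fit")
}

.fit_linear <- function(times, y) {
  fit <- lm.fit(cbind(1, times), y)
  rss <- sum(fit$residuals^2)
  list(coef = c(a = unname(fit$coefficients[2]), b = unname(fit$coefficients[1])),
       rss = rss, status = "ok")
}

.fit_double_exp <- function(times, y, settings) {
  s <- .resolve_settings(settings, times, max(y, 1e-9))
  single <- fit_pixel(times, y, "single_exp", settings)
  start <- list(A1 = max(single$A / 2, 1e-6), tau1 = max(single$tau / 2, s$tau_min),
                A2 = max(single$A / 2, 1e-6), tau2 = min(single$tau * 2, s$tau_max),
                C = max(single$C, 0))
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A1 * exp(-times / tau1) + A2 * exp(-times / tau2) + C,
                      start = start,
                      lower = c(0, s$tau_min, 0, s$tau_min, 0),
                      upper = c(s$A_max, s$tau_max, s$A_max, s$tau_max, s$C_max),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    # degenerate to the nested single-exponential solution (A2 = 0)
    coef <- c(A1 = single$A, tau1 = single$tau, A2 = 0, tau2 = s$tau_max,
              C = single$C)
    return(list(coef = coef, rss = single$rss, status = single$status))
  }
  cf <- stats::coef(fit)
  if (cf[["tau1"]] > cf[["tau2"]]) # identifiability: enforce tau1 < tau2
    cf <- c(A1 = cf[["A2"]], tau1 = cf[["tau2"]], A2 = cf[["A1"]],
            tau2 = cf[["tau1"]], C = cf[["C"]])
  rss <- sum(stats::residuals(fit)^2)
  single_rss <- single$rss
  if (single_rss < rss) {
    # global nesting: the optimizer must never beat its nested special case
    cf <- c(A1 = single$A, tau1 = single$tau, A2 = 0, tau2 = s$tau_max,
            C = single$C)
    rss <- single_rss
  }
  list(coef = cf, rss = rss, status = "ok")
}

#' Fit the decay model to every pixel of a stack
#'
#' Produces the pipeline's central product: co-registered parameter maps
#' `AF0` (the frame at t = 0, copied verbatim), `A`, `tau`, `C` and `error`
#' (residual sum of squares), plus a validity mask that is `TRUE` only where
#' the fit converged with acceptable parameters. Pixels flagged unfittable
#' or poor carry the sentinel value 0 in all parameter maps; pixels
#' invalidated by stabilization are treated as unfittable. Per-pixel
#' failures are recorded, never raised. Deterministic given stack and
#' settings.
#'
#' @param stack a [frame_stack()] (stabilized, or raw if stabilization is
#'   deliberately bypassed).
#' @param model only `"single_exp"` maps are produced; comparator models are
#'   available through [fit_pixel()] and [compare_models()].
#' @param settings a [fit_settings()].
#' @return A `pb_maps` object.
#' @export
fit_stack <- function(stack, model = "single_exp", settings = fit_settings()) {
  stopifnot(inherits(stack, "pb_stack"))
  if (model != "single_exp")
    stop("parameter maps are produced for the single-exponential model only")
  d <- dim(stack$data)
  H <- d[1]; W <- d[2]; nT <- d[3]
  Y <- t(matrix(stack$data, H * W, nT))          # T x N pixel traces
  if (!is.null(stack$valid)) Y[, !as.vector(stack$valid)] <- NA_real_
  data_max <- max(stack$data[is.finite(stack$data)], 1e-9)
  s <- .resolve_settings(settings, stack$times, data_max, stack$bit_depth)
  res <- .fit_exp_cpp(Y, stack$times, s$tau_min, s$tau_max, s$A_max, s$C_max,
                      s$sat_level, s$data_max, s$poor_rss_frac,
                      s$n_grid, s$n_refine)
  status <- matrix(as.integer(res[5, ]), H, W)
  mask <- status == .STATUS_OK
  shape <- function(v) { m <- matrix(v, H, W); m[!mask] <- 0; m }
  new_pb_maps(AF0 = stack$data[, , 1],
              A = shape(res[1, ]), tau = shape(res[2, ]), C = shape(res[3, ]),
              error = shape(res[4, ]), mask = mask, status = status,
              model = model, frame_interval = min(diff(stack$times)),
              settings = s[c("A_max", "C_max", "tau_min", "tau_max",
                             "sat_level", "poor_rss_frac")])
}

#' Normalize a decay curve by its initial value
#'
#' @param intensities numeric vector; the first element (the t = 0 value)
#'   must be positive.
#' @return `intensities / intensities[1]`; the first element is exactly 1.
#' @export
normalize_curve <- function(intensities) {
  if (length(intensities) < 1 || !is.finite(intensities[1]) || intensities[1] <= 0)
    stop("first element must be > 0")
  intensities / intensities[1]
}

# second-order AIC; rss floored at the numerical-noise scale so that exact
# fits compare by parameter count rather than by log(0)
.aicc <- function(rss, n, k, scale) {
  floor_rss <- n * (1e-9 * max(scale, 1))^2
  rss <- max(rss, floor_rss)
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Compare decay models on one pixel trace
#'
#' Fits the linear, single-exponential and double-exponential models and
#' ranks them by AICc (second-order Akaike criterion; the parameter count
#' includes the residual variance). The winner is the model with the
#' smallest AICc.
#'
#' @inheritParams fit_pixel
#' @return A `model_comparison` list: per-model `rss`, `n_par`, `aicc`, and
#'   `winner`.
#' @export
compare_models <- function(times, intensities, settings = fit_settings()) {
  if (length(times) < 6L) stop("need at least 6 observations for the double-exponential model")
  lin <- fit_pixel(times, intensities, "linear", settings)
  single <- fit_pixel(times, intensities, "single_exp", settings)
  dbl <- fit_pixel(times, intensities, "double_exp", settings)
  n <- length(times)
  scale <- max(abs(intensities))
  rss <- c(linear = lin$rss, single_exp = single$rss, double_exp = dbl$rss)
  npar <- c(linear = 3, single_exp = 4, double_exp = 6)  # + residual variance
  aicc <- vapply(names(rss), function(m) .aicc(rss[[m]], n, npar[[m]], scale), 0)
  structure(list(rss = rss, n_par = npar, aicc = aicc,
                 winner = names(which.min(aicc))),
            class = "model_comparison")
}
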