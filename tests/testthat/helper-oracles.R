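# Independent brute-force oracles and small fixture builders used across
# the suite. The oracles are written directly from the rank-statistic
# definitions and share no code with the package implementations.

# Kruskal-Wallis H from first principles: H = (12/(N(N+1))) * sum n_i
# (Rbar_i - (N+1)/2)^2, divided by the tie correction
# 1 - sum(t^3 - t)/(N^3 - N).
brute_kruskal_H <- function(groups) {
  y <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  N <- length(y)
  r <- rank(y)
  H <- 0
  for (i in seq_along(groups)) {
    ri <- r[g == i]
    H <- H + length(ri) * (mean(ri) - (N + 1) / 2)^2
  }
  H <- H * 12 / (N * (N + 1))
  ties <- table(y)
  corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  H / corr
}

# Dunn z for one pair, from the definition on pooled ranks.
brute_dunn_z <- function(groups, i, j) {
  y <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  N <- length(y)
  r <- rank(y)
  ties <- table(y)
  tcorr <- sum(ties^3 - ties) / (12 * (N - 1))
  se <- sqrt((N * (N + 1) / 12 - tcorr) *
               (1 / sum(g == i) + 1 / sum(g == j)))
  (mean(r[g == i]) - mean(r[g == j])) / se
}

# small drift-free noiseless float phantom with exact kinetics
clean_phantom_spec <- function(height = 32, width = 32, ...) {
  phantom_spec(height = height, width = width,
               noise = list(shot_scale = 0, read_sd = 0),
               defect_fraction = 0, bit_depth = NA,
               lesion_geometry = list(center = c(height / 2, width / 2),
                                      axes = c(height / 4, width / 5),
                                      junction_width = 3),
               ...)
}

# default noisy 8-bit phantom at reduced size
noisy_phantom_spec <- function(height = 96, width = 96, ...) {
  args <- list(...)
  if (is.null(args$lesion_geometry))
    args$lesion_geometry <- list(center = c(height / 2, width / 2),
                                 axes = c(0.22 * height, 0.18 * width),
                                 junction_width = max(3, round(height / 16)))
  do.call(phantom_spec, c(list(height = height, width = width), args))
}

# textured scene for registration experiments: correlated random field with
# a short correlation length (a flatter texture flattens the correlation
# dome and the apex location becomes noise-limited rather than
# estimator-limited)
textured_scene <- function(H = 96, W = 96, seed = 1) {
  set.seed(seed)
  base <- matrix(rnorm(H * W), H, W)
  k <- EBImage::makeBrush(7, shape = "gaussian", sigma = 1)
  sm <- EBImage::filter2(EBImage::Image(base), k)
  100 + 30 * matrix(sm, H, W)
}
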