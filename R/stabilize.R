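# Frame-to-frame rigid stabilization. Motion over a 20 s contact-probe
# acquisition is small, so a translation-only model is used: the shift of
# each frame against the reference frame is estimated by cross-correlation
# (FFT, mean-subtracted) with subpixel refinement via a locally upsampled
# DFT of the cross-power spectrum, then removed by bilinear resampling.

.fft2 <- function(x) stats::fft(x)

# upsampled DFT evaluation of the cross-correlation around (dy0, dx0)
# (matrix-multiply DFT; usfac = upsampling factor)
.refine_shift <- function(CP, dy0, dx0, usfac, halfwidth = 1.5) {
  H <- nrow(CP); W <- ncol(CP)
  n <- ceiling(2 * halfwidth * usfac) + 1
  dys <- dy0 + (seq_len(n) - (n + 1) / 2) / usfac
  dxs <- dx0 + (seq_len(n) - (n + 1) / 2) / usfac
  wy <- ifelse(seq_len(H) - 1 <= H / 2, seq_len(H) - 1, seq_len(H) - 1 - H)
  wx <- ifelse(seq_len(W) - 1 <= W / 2, seq_len(W) - 1, seq_len(W) - 1 - W)
  Ey <- exp(2i * pi * outer(dys, wy) / H)       # n x H
  Ex <- exp(2i * pi * outer(wx, dxs) / W)       # W x n
  cc <- Re(Ey %*% CP %*% Ex) / (H * W)
  peak <- arrayInd(which.max(cc), dim(cc))
  c(dys[peak[1]], dxs[peak[2]])
}

#' Estimate the rigid shift between a frame and a reference
#'
#' Returns the translation `(dy, dx)` such that `frame` best matches the
#' reference displaced by `(dy, dx)`, i.e. the cross-correlation peak of the
#' mean-subtracted images. The integer peak is located on the full FFT
#' cross-correlation surface and refined on an upsampled local DFT grid.
#'
#' @param frame,reference 2-D intensity matrices of identical size.
#' @param precision subpixel precision in pixels (default 0.1 px).
#' @return Numeric `(dy, dx)` with attribute `flagged = TRUE` when the frame
#'   has zero variance (shift undefined; (0, 0) returned with a warning).
#' @export
estimate_shift <- function(frame, reference, precision = 0.1) {
  stopifnot(identical(dim(frame), dim(reference)))
  if (stats::var(as.vector(reference)) == 0)
    stop("constant reference: shift is undefined")
  if (stats::var(as.vector(frame)) == 0) {
    warning("constant frame: returning zero shift")
    return(structure(c(0, 0), flagged = TRUE))
  }
  H <- nrow(frame); W <- ncol(frame)
  Fa <- .fft2(frame - mean(frame))
  Fb <- .fft2(reference - mean(reference))
  CP <- Fa * Conj(Fb)
  cc <- Re(stats::fft(CP, inverse = TRUE)) / (H * W)
  peak <- arrayInd(which.max(cc), dim(cc)) - 1L
  dy0 <- if (peak[1] > H / 2) peak[1] - H else peak[1]
  dx0 <- if (peak[2] > W / 2) peak[2] - W else peak[2]
  usfac <- max(1, ceiling(1 / precision))
  if (usfac > 1) {
    sh <- .refine_shift(CP, dy0, dx0, usfac)
  } else {
    sh <- c(dy0, dx0)
  }
  structure(as.numeric(sh), flagged = FALSE)
}

#' Stabilize a frame stack against its first frame
#'
#' Estimates each frame's shift relative to the reference frame and resamples
#' it by the negated shift (bilinear interpolation). Pixels sampled from
#' outside the field of view in any frame are flagged invalid in the stack's
#' validity mask and propagate to the fit mask downstream; frame count and
#' timestamps are never modified.
#'
#' @param stack a [frame_stack()].
#' @param reference_index 1-based index of the reference frame (default 1,
#'   anchoring the t = 0 intensity origin).
#' @param precision subpixel precision passed to [estimate_shift()].
#' @return A list with `stack` (stabilized [frame_stack()] with updated
#'   `valid` mask) and `shifts`, a `shift_trace` data.frame with per-frame
#'   `dy`, `dx` and a post-alignment residual dissimilarity score.
#' @export
stabilize_stack <- function(stack, reference_index = 1L, precision = 0.1) {
  stopifnot(inherits(stack, "pb_stack"))
  d <- dim(stack$data)
  ref <- stack$data[, , reference_index]
  valid <- if (is.null(stack$valid)) matrix(TRUE, d[1], d[2]) else stack$valid
  # temporally constant pixels (dead/saturated/specular defects) are static
  # high-amplitude outliers that anchor the correlation at zero lag; they
  # are replaced by the frame median for shift estimation only
  X <- matrix(stack$data, d[1] * d[2], d[3])
  static <- rowSums((X - rowMeans(X))^2) == 0
  clean <- function(frame) {
    if (any(static)) frame[static] <- stats::median(frame[!static])
    frame
  }
  ref_est <- clean(ref)
  out <- stack$data
  shifts <- matrix(0, d[3], 2)
  resid <- numeric(d[3])
  flagged <- logical(d[3])
  for (k in seq_len(d[3])) {
    if (k == reference_index) next
    sh <- estimate_shift(clean(stack$data[, , k]), ref_est,
                         precision = precision)
    flagged[k] <- isTRUE(attr(sh, "flagged"))
    # shifts at or below the estimator resolution are not actionable:
    # resampling on them would only blur the frame
    if (max(abs(sh)) <= precision) sh <- c(0, 0)
    shifts[k, ] <- sh
    if (any(sh != 0)) {
      # frame = scene shifted by sh; sampling the frame at +sh undoes it
      aligned <- .shift_image(stack$data[, , k], -sh[1], -sh[2], fill = "na")
      valid <- valid & !is.na(aligned)
      aligned[is.na(aligned)] <- 0
      out[, , k] <- aligned
    }
    resid[k] <- mean(abs(out[, , k] - ref)) / max(mean(abs(ref)), .Machine$double.eps)
  }
  st <- stack
  st$data <- out
  st$valid <- valid
  trace <- data.frame(frame = seq_len(d[3]), dy = shifts[, 1], dx = shifts[, 2],
                      residual_metric = resid, flagged = flagged)
  class(trace) <- c("shift_trace", "data.frame")
  list(stack = st, shifts = trace)
}
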