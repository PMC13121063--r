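# Synthetic time-lapse autofluorescence phantoms with known per-pixel
# photobleaching kinetics. Every pixel follows I(t) = A*exp(-t/tau) + C
# before noise, drift and quantization; ground truth is returned alongside
# the rendered stack so downstream stages can be validated end to end.

.default_skin <- list(A = c(120, 10), tau = c(10, 1), C = c(70, 8))

.core_presets <- list(
  sporadic_bcc = list(A = c(60, 10), tau = c(6, 0.8), C = c(40, 8)),
  nbccs_bcc    = list(A = c(65, 8),  tau = c(9.5, 0.6), C = c(30, 6)),
  scc          = list(A = c(75, 25), tau = c(4, 2), C = c(45, 15))
)

.midpoint_params <- function(a, b) {
  lapply(setNames(names(a), names(a)), function(nm)
    c((a[[nm]][1] + b[[nm]][1]) / 2, (a[[nm]][2] + b[[nm]][2]) / 2))
}

#' Specify a synthetic photobleaching phantom
#'
#' Defines the geometry, per-region decay kinetics, noise, drift, defect and
#' quantization model of a simulated autofluorescence acquisition. Defaults
#' mirror a clinical protocol of 466 x 448 px frames at 1 frame/s over 20 s,
#' with an elliptical lesion core surrounded by a junction annulus inside
#' healthy skin. Region kinetics are simulator choices encoding the
#' qualitative tumor-vs-skin contrasts (lower initial intensity, faster or
#' comparable decay); they are not measured tissue values.
#'
#' @param height,width image size in pixels.
#' @param n_frames number of frames (>= 3).
#' @param frame_interval seconds between frames (> 0).
#' @param lesion_geometry list with `center` (y, x), `axes` (semi-axes a, b
#'   in px), `rotation` (degrees), `junction_width` (annulus width in px,
#'   from morphological dilation of the core).
#' @param region_params per-region `(A, tau, C)` distributions: a list with
#'   entries `skin`, `junction`, `core`, each a list of length-2 vectors
#'   `c(mean, spatial_sd)` in intensity units (A, C) and seconds (tau).
#' @param noise list with `shot_scale` (signal-proportional variance per
#'   intensity unit, Gaussian approximation of shot noise) and `read_sd`
#'   (additive Gaussian read noise SD, intensity units).
#' @param drift `n_frames x 2` matrix of per-frame (dy, dx) rigid scene
#'   displacements in pixels, or `NULL` for none.
#' @param texture_sigma correlation length (Gaussian sigma, px) of the
#'   spatial parameter fields; tissue parameter variation is spatially
#'   structured, so the per-pixel draws are smoothed to this scale while
#'   keeping the marginal per-pixel SD at the `region_params` value
#'   (0 = white fields).
#' @param defect_fraction fraction of pixels rendered unfittable (constant
#'   zero or constant saturated across all frames).
#' @param bit_depth output quantization depth (default 8); `NA` disables
#'   quantization and yields floating-point frames.
#' @param seed integer RNG seed; generation is deterministic given the spec.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(height = 466, width = 448, n_frames = 20,
                         frame_interval = 1,
                         lesion_geometry = list(),
                         region_params = list(),
                         noise = list(shot_scale = 0.25, read_sd = 2),
                         drift = NULL,
                         texture_sigma = 2,
                         defect_fraction = 0.01,
                         bit_depth = 8L,
                         seed = 1L) {
  geom <- modifyList(list(center = c(height / 2, width / 2),
                          axes = c(0.22 * height, 0.18 * width),
                          rotation = 0, junction_width = 8), lesion_geometry)
  core <- .core_presets$sporadic_bcc
  rp <- list(skin = .default_skin, core = core,
             junction = .midpoint_params(.default_skin, core))
  rp <- modifyList(rp, region_params)
  noise <- modifyList(list(shot_scale = 0.25, read_sd = 2), noise)
  spec <- structure(list(height = height, width = width, n_frames = n_frames,
                         frame_interval = frame_interval,
                         lesion_geometry = geom, region_params = rp,
                         noise = noise, drift = drift,
                         texture_sigma = texture_sigma,
                         defect_fraction = defect_fraction,
                         bit_depth = bit_depth, seed = as.integer(seed)),
                    class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

#' Validate a phantom specification
#'
#' @param spec a [phantom_spec()].
#' @return `spec`, invisibly; otherwise an error naming the offending field.
#' @export
validate_phantom_spec <- function(spec) {
  if (!is.numeric(spec$height) || spec$height < 8) .stop_field("height", "must be >= 8 px")
  if (!is.numeric(spec$width) || spec$width < 8) .stop_field("width", "must be >= 8 px")
  if (spec$n_frames < 3) .stop_field("n_frames", "must be >= 3")
  if (spec$frame_interval <= 0) .stop_field("frame_interval", "must be > 0")
  for (region in names(spec$region_params)) {
    p <- spec$region_params[[region]]
    if (p$tau[1] <= 0) .stop_field(paste0("region_params$", region, "$tau"), "mean must be > 0")
    if (p$A[1] < 0) .stop_field(paste0("region_params$", region, "$A"), "mean must be >= 0")
    if (p$C[1] < 0) .stop_field(paste0("region_params$", region, "$C"), "mean must be >= 0")
  }
  if (spec$defect_fraction < 0 || spec$defect_fraction > 1)
    .stop_field("defect_fraction", "must lie in [0, 1]")
  if (is.null(spec$texture_sigma) || spec$texture_sigma < 0)
    .stop_field("texture_sigma", "must be >= 0")
  g <- spec$lesion_geometry
  reach <- max(g$axes) + g$junction_width
  if (g$center[1] - reach < 1 || g$center[1] + reach > spec$height ||
      g$center[2] - reach < 1 || g$center[2] + reach > spec$width)
    .stop_field("lesion_geometry", "core plus junction annulus exceeds image bounds")
  if (!is.null(spec$drift)) {
    d <- spec$drift
    if (!is.matrix(d) || nrow(d) != spec$n_frames || ncol(d) != 2)
      .stop_field("drift", "must be an n_frames x 2 matrix of (dy, dx)")
  }
  if (!is.na(spec$bit_depth) && (spec$bit_depth < 1 || spec$bit_depth > 16))
    .stop_field("bit_depth", "must be in [1, 16] or NA for float output")
  invisible(spec)
}

# evaluate expr with a local RNG seed, restoring global RNG state
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

.ellipse_mask <- function(H, W, center, axes, rotation_deg) {
  th <- rotation_deg * pi / 180
  y <- matrix(seq_len(H) - center[1], H, W)
  x <- matrix(rep(seq_len(W) - center[2], each = H), H, W)
  u <- x * cos(th) + y * sin(th)
  v <- -x * sin(th) + y * cos(th)
  (u / axes[2])^2 + (v / axes[1])^2 <= 1
}

.dilate_mask <- function(mask, width) {
  if (width <= 0) return(mask)
  brush <- EBImage::makeBrush(2 * ceiling(width) + 1, shape = "disc")
  EBImage::dilate(EBImage::Image(mask * 1), brush) > 0.5
}

# bilinear translation of an image by (dy, dx); fill = "edge" replicates
# borders, fill = "na" marks samples outside the source as NA
.shift_image <- function(img, dy, dx, fill = c("edge", "na")) {
  fill <- match.arg(fill)
  H <- nrow(img); W <- ncol(img)
  ys <- seq_len(H) - dy; xs <- seq_len(W) - dx
  y0 <- floor(ys); fy <- ys - y0
  x0 <- floor(xs); fx <- xs - x0
  grab <- function(yy, xx) {
    oy <- yy < 1 | yy > H; ox <- xx < 1 | xx > W
    m <- img[pmin(pmax(yy, 1), H), pmin(pmax(xx, 1), W), drop = FALSE]
    if (fill == "na") { m[oy, ] <- NA_real_; m[, ox] <- NA_real_ }
    m
  }
  term <- function(w, g) { out <- w * g; out[w == 0] <- 0; out }
  term(outer(1 - fy, 1 - fx), grab(y0, x0)) +
    term(outer(1 - fy, fx), grab(y0, x0 + 1)) +
    term(outer(fy, 1 - fx), grab(y0 + 1, x0)) +
    term(outer(fy, fx), grab(y0 + 1, x0 + 1))
}

#' Render a synthetic phantom stack with ground truth
#'
#' Draws per-pixel `(A, tau, C)` parameter maps from the per-region
#' distributions, renders noiseless single-exponential decay frames,
#' applies rigid drift (bilinear resampling, edge replication), adds
#' signal-proportional shot noise plus read noise, stamps in defect pixels
#' (constant zero or constant saturated), and quantizes. Identical spec and
#' seed yield bit-identical output.
#'
#' @param spec a [phantom_spec()].
#' @return A list with `stack` (a [frame_stack()]) and `truth`, a
#'   `phantom_truth` object carrying `A`, `tau`, `C` ground-truth maps and a
#'   `region` character matrix with values skin/junction/core/defect.
#' @export
generate_phantom <- function(spec) {
  validate_phantom_spec(spec)
  H <- spec$height; W <- spec$width; nT <- spec$n_frames
  g <- spec$lesion_geometry
  quantize <- !is.na(spec$bit_depth)
  sat <- if (quantize) 2^spec$bit_depth - 1 else 255

  .with_seed(spec$seed, {
    core <- .ellipse_mask(H, W, g$center, g$axes, g$rotation)
    junction <- .dilate_mask(core, g$junction_width) & !core
    region <- matrix("skin", H, W)
    region[junction] <- "junction"
    region[core] <- "core"

    # unit-variance correlated Gaussian field: white draw, Gaussian blur,
    # rescaled so the per-pixel marginal SD stays 1
    unit_field <- function() {
      z <- matrix(rnorm(H * W), H, W)
      if (spec$texture_sigma <= 0) return(z)
      size <- 2 * ceiling(3 * spec$texture_sigma) + 1
      k <- EBImage::makeBrush(size, shape = "gaussian",
                              sigma = spec$texture_sigma)
      k <- k / sum(k)
      matrix(EBImage::filter2(EBImage::Image(z), k), H, W) / sqrt(sum(k^2))
    }
    draw <- function(field) {
      base <- unit_field()
      m <- matrix(0, H, W)
      for (rg in c("skin", "junction", "core")) {
        p <- spec$region_params[[rg]][[field]]
        idx <- region == rg
        m[idx] <- p[1] + p[2] * base[idx]
      }
      m
    }
    A <- pmax(draw("A"), 0)
    tau <- pmax(draw("tau"), 0.05)
    C <- pmax(draw("C"), 0)

    n_defect <- round(spec$defect_fraction * H * W)
    defect_idx <- if (n_defect > 0) sample.int(H * W, n_defect) else integer(0)
    defect_kind <- if (n_defect > 0) sample(c(0, sat), n_defect, replace = TRUE) else numeric(0)
    region[defect_idx] <- "defect"

    times <- (seq_len(nT) - 1) * spec$frame_interval
    data <- array(0, dim = c(H, W, nT))
    for (k in seq_len(nT)) {
      frame <- A * exp(-times[k] / tau) + C
      if (!is.null(spec$drift)) {
        d <- spec$drift[k, ]
        if (any(d != 0)) frame <- .shift_image(frame, d[1], d[2], fill = "edge")
      }
      sd_noise <- sqrt(spec$noise$shot_scale * pmax(frame, 0) + spec$noise$read_sd^2)
      if (any(sd_noise > 0)) frame <- frame + rnorm(H * W, 0, sd_noise)
      frame[defect_idx] <- defect_kind
      if (quantize) frame <- pmin(pmax(floor(frame + 0.5), 0), sat)
      data[, , k] <- frame
    }

    truth <- structure(list(A = A, tau = tau, C = C, region = region,
                            spec = spec),
                       class = "phantom_truth")
    stack <- frame_stack(data, times = times,
                         source_channel = "gray",
                         bit_depth = if (quantize) as.integer(spec$bit_depth)
                                     else NA_integer_)
    list(stack = stack, truth = truth)
  })
}

#' Three-class lesion phantom presets
#'
#' Returns phantom specifications for the three simulated tumor classes.
#' All share the same skin kinetics; core kinetics are ordered so that the
#' normalized decay is steepest for SCC, then NBCCS-associated BCC, then
#' sporadic BCC, then skin, while the raw decay constant of the NBCCS core
#' stays close to skin (its contrast lives in the bleachable fraction, not
#' the rate). Core initial intensity (A + C) lies below skin in all classes,
#' and the SCC core has the largest spatial parameter spreads
#' (intratumoral heterogeneity).
#'
#' @param ... arguments forwarded to [phantom_spec()] (e.g. `height`,
#'   `width`, `seed`) applied to every preset.
#' @return Named list of [phantom_spec()] objects
#'   (`sporadic_bcc`, `nbccs_bcc`, `scc`).
#' @export
three_class_presets <- function(...) {
  lapply(setNames(names(.core_presets), names(.core_presets)), function(cls) {
    core <- .core_presets[[cls]]
    phantom_spec(region_params = list(
      core = core,
      junction = .midpoint_params(.default_skin, core)
    ), ...)
  })
}

#' Summarize the region masks of a phantom ground truth
#' @param x a `phantom_truth` object.
#' @param ... unused.
#' @export
print.phantom_truth <- function(x, ...) {
  cat("phantom_truth regions:\n")
  print(table(x$region))
  invisible(x)
}
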