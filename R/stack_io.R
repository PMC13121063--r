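#' Construct a frame stack
#'
#' A frame stack is the pipeline's raw input: an ordered set of co-registered
#' grayscale frames with a time base. Data are stored as an `H x W x T` array
#' (rows, columns, frames), with `times[1] == 0` at the first frame.
#'
#' @param data numeric `H x W x T` array of non-negative intensities.
#' @param times numeric vector of frame times in seconds, strictly
#'   increasing, starting at 0. Defaults to `0:(T-1) * frame_interval`.
#' @param frame_interval frame spacing in seconds, used when `times` is
#'   missing.
#' @param source_channel `"G"` if the stack was extracted from the green
#'   plane of RGB input, `"gray"` otherwise.
#' @param bit_depth integer bit depth of the source data (`NA` for
#'   floating-point stacks).
#' @param valid optional `H x W` logical matrix of pixels considered valid
#'   (e.g. after stabilization); `NULL` means all valid.
#' @return An object of class `pb_stack`.
#' @export
frame_stack <- function(data, times = NULL, frame_interval = 1,
                        source_channel = c("gray", "G"), bit_depth = NA_integer_,
                        valid = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be an H x W x T array")
  nT <- dim(data)[3]
  if (nT < 3L) stop("fewer than 3 frames")
  if (is.null(times)) times <- (seq_len(nT) - 1) * frame_interval
  if (length(times) != nT) stop("`times` length must equal frame count")
  if (times[1] != 0) stop("`times` must start at 0")
  if (any(diff(times) <= 0)) stop("`times` must be strictly increasing")
  if (!is.null(valid)) {
    if (!is.logical(valid) || !identical(dim(valid), dim(data)[1:2]))
      stop("`valid` must be an H x W logical matrix")
  }
  structure(list(data = data, times = as.numeric(times),
                 source_channel = match.arg(source_channel),
                 bit_depth = bit_depth, valid = valid),
            class = "pb_stack")
}

#' @export
print.pb_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("pb_stack: %d x %d px, %d frames (%.3g s .. %.3g s), channel %s, bit depth %s\n",
              d[1], d[2], d[3], x$times[1], x$times[length(x$times)],
              x$source_channel, as.character(x$bit_depth)))
  invisible(x)
}

#' @export
dim.pb_stack <- function(x) dim(x$data)

.read_frame <- function(path) {
  low <- tolower(path)
  if (grepl("\\.png$", low)) {
    img <- png::readPNG(path)
    # readPNG rescales to [0,1]; restore native 8-bit values exactly
    img <- round(img * 255)
    attr(img, "bit_depth") <- 8L
  } else if (grepl("\\.(tif|tiff)$", low)) {
    img <- tiff::readTIFF(path, as.is = TRUE)
    attr(img, "bit_depth") <- attr(img, "bits.per.sample")
  } else {
    stop(sprintf("unreadable file (unsupported format): %s", path))
  }
  img
}

.extract_channel <- function(img) {
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] < 2L) return(list(plane = img[, , 1], channel = "gray"))
    # AF signal lives in the G channel of RGB input; pure projection,
    # no rescaling
    list(plane = img[, , 2], channel = "G")
  } else {
    list(plane = img, channel = "gray")
  }
}

#' Load a frame stack from disk
#'
#' Reads a multi-page TIFF or a directory of identically sized PNG/TIFF
#' frames (lexicographic filename order). RGB input is reduced to its green
#' plane, which carries the bulk of the skin autofluorescence signal;
#' grayscale input passes through unchanged. Frame `k` (0-based) is assigned
#' time `k * frame_interval`.
#'
#' @param path a multi-page TIFF file or a frame directory.
#' @param frame_interval seconds between consecutive frames.
#' @return A [frame_stack()].
#' @export
load_stack <- function(path, frame_interval = 1) {
  if (!file.exists(path)) stop(sprintf("unreadable file: %s", path))
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(png|tif|tiff)$",
                        ignore.case = TRUE, full.names = TRUE)
    files <- sort(files)
    if (length(files) < 3L) stop("fewer than 3 frames")
    frames <- lapply(files, .read_frame)
  } else {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    if (length(pages) < 3L) stop("fewer than 3 frames")
    bd <- attr(tiff::readTIFF(path, as.is = TRUE, info = TRUE), "bits.per.sample")
    frames <- lapply(pages, function(p) { attr(p, "bit_depth") <- bd; p })
  }
  planes <- lapply(frames, .extract_channel)
  dims <- vapply(planes, function(p) dim(p$plane), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("mixed frame sizes")
  channel <- planes[[1]]$channel
  bd <- attr(frames[[1]], "bit_depth")
  if (is.null(bd)) bd <- NA_integer_
  data <- array(0, dim = c(dims[1, 1], dims[2, 1], length(planes)))
  for (k in seq_along(planes)) data[, , k] <- planes[[k]]$plane
  frame_stack(data, frame_interval = frame_interval,
              source_channel = if (channel == "G") "G" else "gray",
              bit_depth = as.integer(bd[1]))
}

#' Write a frame stack as a multi-page TIFF
#'
#' Integer stacks (bit depth 8 or 16) are written natively; floating-point
#' stacks are written as 16-bit after scaling would be lossy, so they are
#' refused — quantize first (see [generate_phantom()]'s `bit_depth`).
#'
#' @param stack a [frame_stack()].
#' @param path output `.tif` path.
#' @return `path`, invisibly.
#' @export
save_stack <- function(stack, path) {
  stopifnot(inherits(stack, "pb_stack"))
  bd <- stack$bit_depth
  if (is.na(bd) || !bd %in% c(8L, 16L))
    stop("only 8- or 16-bit integer stacks can be written as TIFF")
  maxv <- 2^bd - 1
  pages <- lapply(seq_len(dim(stack$data)[3]),
                  function(k) stack$data[, , k] / maxv)
  tiff::writeTIFF(pages, path, bits.per.sample = bd, compression = "none")
  invisible(path)
}

# scale-normalized 32-bit TIFF: values stored as v/scale in [0,1] with a
# power-of-two scale, exact to one part in 2^32 of the scale on round trip
.write_map_tiff <- function(map, path) {
  finite <- map[is.finite(map)]
  mx <- if (length(finite)) max(abs(finite), 0) else 0
  scale <- 2^max(0, ceiling(log2(max(mx, 1e-12))))
  m <- map / scale
  m[!is.finite(m) | m < 0] <- 0
  tiff::writeTIFF(m, path, bits.per.sample = 32L, compression = "none")
  scale
}

.read_map_tiff <- function(path, scale) {
  tiff::readTIFF(path) * scale
}

#' Save parameter maps to a directory
#'
#' Writes one single-page TIFF per map (`AF0.tif`, `A.tif`, `tau.tif`,
#' `C.tif`, `error.tif`), the validity mask as an 8-bit TIFF (`mask.tif`,
#' 255 = valid), and a JSON manifest (`manifest.json`) recording the map
#' scale factors, frame interval, model, fit settings, provenance and
#' software version. Map TIFFs are scale-normalized 32-bit rasters; the
#' recorded power-of-two scale restores values to one part in 2^32.
#'
#' @param maps a `pb_maps` object from [fit_stack()].
#' @param out_dir output directory (created if missing).
#' @param input a provenance string recorded in the manifest.
#' @return The manifest, invisibly (a list).
#' @export
save_maps <- function(maps, out_dir, input = NA_character_) {
  stopifnot(inherits(maps, "pb_maps"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(out_dir)) stop(sprintf("unwritable directory: %s", out_dir))
  }
  map_names <- c("AF0", "A", "tau", "C", "error")
  scales <- vapply(map_names, function(nm)
    .write_map_tiff(maps[[nm]], file.path(out_dir, paste0(nm, ".tif"))), 0)
  tiff::writeTIFF((maps$mask * 1), file.path(out_dir, "mask.tif"),
                  bits.per.sample = 8L, compression = "none")
  manifest <- list(
    format = "pbmap-maps/1",
    input = input,
    model = maps$model,
    frame_interval = maps$frame_interval,
    fit_settings = maps$settings,
    map_scales = as.list(scales),
    n_invalid = sum(!maps$mask),
    software = paste0("pbmap ", as.character(utils::packageVersion("pbmap")))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Load parameter maps written by [save_maps()]
#'
#' @param dir directory containing the map TIFFs and `manifest.json`.
#' @return A `pb_maps` object.
#' @export
load_maps <- function(dir) {
  mf_path <- file.path(dir, "manifest.json")
  if (!file.exists(mf_path)) stop(sprintf("no manifest.json in %s", dir))
  manifest <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  maps <- lapply(names(manifest$map_scales), function(nm)
    .read_map_tiff(file.path(dir, paste0(nm, ".tif")),
                   manifest$map_scales[[nm]]))
  names(maps) <- names(manifest$map_scales)
  mask <- tiff::readTIFF(file.path(dir, "mask.tif")) > 0.5
  new_pb_maps(AF0 = maps$AF0, A = maps$A, tau = maps$tau, C = maps$C,
              error = maps$error, mask = mask,
              status = ifelse(mask, .STATUS_OK, .STATUS_UNFITTABLE),
              model = manifest$model, frame_interval = manifest$frame_interval,
              settings = manifest$fit_settings)
}

new_pb_maps <- function(AF0, A, tau, C, error, mask, status,
                        model, frame_interval, settings) {
  structure(list(AF0 = AF0, A = A, tau = tau, C = C, error = error,
                 mask = mask, status = status, model = model,
                 frame_interval = frame_interval, settings = settings),
            class = "pb_maps")
}

#' @export
print.pb_maps <- function(x, ...) {
  cat(sprintf("pb_maps: %d x %d px, model %s, %d invalid pixels\n",
              nrow(x$AF0), ncol(x$AF0), x$model, sum(!x$mask)))
  invisible(x)
}
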