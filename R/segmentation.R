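# Superpixel partitioning of parameter maps and core/junction/skin
# designation. Superpixels come from SLIC (k-means in a joint feature +
# position space with a compactness weight); designation z-scores each
# superpixel's mean of a driving map against a skin reference distribution:
# sharp deviations become lesion core, deviated neighbours of core become
# junction, the rest stays skin.

.normalize01 <- function(m) {
  fin <- m[is.finite(m)]
  if (!length(fin)) return(m * 0)
  rng <- range(fin)
  if (diff(rng) == 0) return(m * 0)
  (m - rng[1]) / diff(rng)
}

#' SLIC superpixel segmentation of co-registered maps
#'
#' Partitions the valid pixels of one or more co-registered 2-D maps into
#' connected superpixels. Each map is min-max normalized to `[0, 1]` before
#' clustering; the spatial term is weighted by
#' `compactness / grid_step`. Deterministic given inputs and parameters.
#'
#' @param maps a single matrix or a list of co-registered matrices.
#' @param n_segments target number of superpixels (>= 2); the realized count
#'   lies in `[1, n_segments]` after connectivity enforcement.
#' @param compactness spatial regularization weight (unitless); larger
#'   values give squarer superpixels.
#' @param valid optional logical matrix; invalid pixels receive label 0.
#' @param max_iter k-means iterations.
#' @return Integer label matrix (0 = invalid, 1..K = superpixels).
#' @export
slic_segment <- function(maps, n_segments = 300, compactness = 0.1,
                         valid = NULL, max_iter = 10L) {
  if (is.matrix(maps)) maps <- list(maps)
  stopifnot(length(maps) >= 1, n_segments >= 2)
  dims <- dim(maps[[1]])
  for (m in maps) stopifnot(identical(dim(m), dims))
  if (is.null(valid)) valid <- matrix(TRUE, dims[1], dims[2])
  valid <- valid & Reduce(`&`, lapply(maps, is.finite))
  if (!any(valid)) stop("all pixels invalid; nothing to segment")
  feat <- vapply(maps, function(m) as.vector(.normalize01(m)), numeric(prod(dims)))
  if (is.null(dim(feat))) feat <- matrix(feat, ncol = 1)
  .slic_cpp(feat, as.vector(valid), dims[1], dims[2],
            as.integer(n_segments), compactness, as.integer(max_iter))
}

# superpixel 8-adjacency from a label image: unique label pairs of
# horizontally / vertically / diagonally neighbouring pixels
.label_adjacency <- function(labels) {
  pair <- function(a, b) {
    keep <- a != b & a > 0 & b > 0
    cbind(pmin(a[keep], b[keep]), pmax(a[keep], b[keep]))
  }
  H <- nrow(labels); W <- ncol(labels)
  p <- rbind(
    pair(labels[-H, ], labels[-1, ]),
    pair(labels[, -W], labels[, -1]),
    pair(labels[-H, -W], labels[-1, -1]),
    pair(labels[-H, -1], labels[-1, -W])
  )
  unique(p)
}

.border_band_mask <- function(H, W, frac = 0.15) {
  by <- ceiling(frac * H); bx <- ceiling(frac * W)
  m <- matrix(FALSE, H, W)
  m[c(seq_len(by), H - seq_len(by) + 1), ] <- TRUE
  m[, c(seq_len(bx), W - seq_len(bx) + 1)] <- TRUE
  m
}

new_region_labels <- function(labels, designation, source_map, skin_reference) {
  structure(list(labels = labels, designation = designation,
                 source_map = source_map, skin_reference = skin_reference),
            class = "region_labels")
}

#' Designate core, junction and skin superpixels
#'
#' Scores each superpixel's mean of a driving map as a z-value against the
#' skin reference distribution. Superpixels with `|z| >= z_core` become
#' lesion core; superpixels 8-adjacent to a core superpixel with
#' `|z| >= z_junction` become junction; superpixels with fewer than
#' `min_valid_frac` valid pixels are excluded; everything else is skin.
#' When no skin mask is supplied, the reference is computed from valid
#' pixels in the outer 15% border band of the image (lesions are centered
#' in the field of view by acquisition design).
#'
#' @param labels superpixel label matrix from [slic_segment()].
#' @param map the driving 2-D map (e.g. the AF0 intensity image).
#' @param skin_mask optional logical matrix marking reference skin pixels;
#'   `NULL` uses the border band.
#' @param valid optional validity matrix; defaults to all valid.
#' @param z_core core threshold on `|z|` (default 3).
#' @param z_junction junction threshold on `|z|` (default 1.5).
#' @param min_valid_frac minimum valid-pixel fraction per superpixel.
#' @param source_map name recorded for provenance.
#' @return A `region_labels` object: the label matrix, a per-superpixel
#'   designation factor (`core`/`junction`/`skin`/`excluded`), the source
#'   map name, and the skin reference `(mean, sd)`.
#' @export
designate_regions <- function(labels, map, skin_mask = NULL, valid = NULL,
                              z_core = 3, z_junction = 1.5,
                              min_valid_frac = 0.5, source_map = "AF0") {
  stopifnot(identical(dim(labels), dim(map)))
  H <- nrow(map); W <- ncol(map)
  if (is.null(valid)) valid <- matrix(TRUE, H, W)
  valid <- valid & is.finite(map) & labels > 0
  if (is.null(skin_mask)) skin_mask <- .border_band_mask(H, W)
  ref_px <- map[skin_mask & valid]
  if (length(ref_px) < 2) stop("no valid skin reference pixels")
  skin_ref <- c(mean = mean(ref_px), sd = stats::sd(ref_px))
  if (skin_ref[["sd"]] == 0) stop("degenerate skin reference: zero variance")

  K <- max(labels)
  lab_v <- as.vector(labels)
  val_v <- as.vector(valid)
  n_all <- tabulate(lab_v[lab_v > 0], K)
  n_valid <- tabulate(lab_v[lab_v > 0 & val_v], K)
  sums <- rep(0, K)
  t0 <- tapply(as.vector(map)[lab_v > 0 & val_v], lab_v[lab_v > 0 & val_v], sum)
  sums[as.integer(names(t0))] <- t0
  sp_mean <- ifelse(n_valid > 0, sums / n_valid, NA_real_)
  z <- (sp_mean - skin_ref[["mean"]]) / skin_ref[["sd"]]

  designation <- rep("skin", K)
  designation[n_all == 0 | n_valid < min_valid_frac * pmax(n_all, 1)] <- "excluded"
  core <- !is.na(z) & abs(z) >= z_core & designation != "excluded"
  designation[core] <- "core"
  adj <- .label_adjacency(labels)
  if (any(core) && nrow(adj) > 0) {
    core_ids <- which(core)
    touches_core <- union(adj[adj[, 1] %in% core_ids, 2],
                          adj[adj[, 2] %in% core_ids, 1])
    junction <- setdiff(touches_core, core_ids)
    junction <- junction[!is.na(z[junction]) & abs(z[junction]) >= z_junction &
                           designation[junction] == "skin"]
    designation[junction] <- "junction"
  }
  designation <- factor(designation, levels = c("core", "junction", "skin", "excluded"))
  attr(designation, "z") <- z
  new_region_labels(labels, designation, source_map, skin_ref)
}

#' Load a manual region-of-interest label image
#'
#' Reads a co-registered label image (PNG or TIFF) with pixel values
#' 0 = skin, 1 = junction, 2 = core, and wraps it as a `region_labels`
#' object with one pseudo-superpixel per connected region.
#'
#' @param path label image path.
#' @param dims expected `(H, W)`; mismatches are rejected.
#' @return A `region_labels` object.
#' @export
load_manual_roi <- function(path, dims = NULL) {
  img <- .read_frame(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img <- round(img)
  if (!is.null(dims) && !identical(dim(img), as.integer(dims)))
    stop(sprintf("ROI size %d x %d does not match expected %d x %d",
                 nrow(img), ncol(img), dims[1], dims[2]))
  bad <- setdiff(unique(as.vector(img)), c(0, 1, 2))
  if (length(bad))
    stop(sprintf("unknown label value(s) in ROI: %s",
                 paste(bad, collapse = ", ")))
  labels <- matrix(0L, nrow(img), ncol(img))
  designation <- character(0)
  next_id <- 0L
  for (value in c(0, 1, 2)) {
    cls <- c("skin", "junction", "core")[value + 1]
    comp <- EBImage::bwlabel(EBImage::Image((img == value) * 1))
    comp <- matrix(as.integer(comp), nrow(img), ncol(img))
    k <- max(comp)
    if (k == 0) next
    labels[comp > 0] <- comp[comp > 0] + next_id
    designation <- c(designation, rep(cls, k))
    next_id <- next_id + k
  }
  designation <- factor(designation, levels = c("core", "junction", "skin", "excluded"))
  new_region_labels(labels, designation, source_map = "manual",
                    skin_reference = c(mean = NA_real_, sd = NA_real_))
}

#' Pixel mask of a designated region
#'
#' @param regions a `region_labels` object.
#' @param designation one of `"core"`, `"junction"`, `"skin"`, `"excluded"`.
#' @return Logical matrix marking pixels of superpixels with that
#'   designation.
#' @export
region_mask <- function(regions, designation) {
  ids <- which(regions$designation == designation)
  matrix(regions$labels %in% ids, nrow(regions$labels), ncol(regions$labels))
}

#' @export
print.region_labels <- function(x, ...) {
  cat(sprintf("region_labels: %d superpixels on %d x %d px (driver: %s)\n",
              length(x$designation), nrow(x$labels), ncol(x$labels),
              x$source_map))
  print(table(x$designation))
  invisible(x)
}
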