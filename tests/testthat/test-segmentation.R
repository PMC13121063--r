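# SLIC superpixels and core/junction/skin designation.

test_that("a constant image splits into near-equal connected tiles", {
  img <- matrix(5, 40, 40)
  lab <- slic_segment(img, n_segments = 4, compactness = 0.1)
  expect_gte(max(lab), 1)
  expect_lte(max(lab), 4)
  expect_true(all(lab > 0))
  sizes <- tabulate(lab)
  expect_lt(max(sizes) / min(sizes), 2.5)
  means <- tapply(as.vector(img), as.vector(lab), mean)
  expect_true(all(means == 5))
})

test_that("superpixels respect a sharp two-valued boundary", {
  img <- cbind(matrix(0, 60, 30), matrix(100, 60, 30))
  lab <- slic_segment(img, n_segments = 36, compactness = 0.1)
  purity <- tapply(as.vector(img), as.vector(lab),
                   function(v) max(table(v)) / length(v))
  expect_gt(mean(purity), 0.99)
  means <- tapply(as.vector(img), as.vector(lab), mean)
  expect_true(all(means < 5 | means > 95))  # bimodal superpixel means
})

test_that("superpixels are connected and partition the valid pixels", {
  ph <- generate_phantom(noisy_phantom_spec(height = 64, width = 64, seed = 8))
  maps <- fit_stack(ph$stack)
  lab <- slic_segment(maps$tau, n_segments = 50, valid = maps$mask)
  expect_true(all((lab == 0) == !maps$mask))
  for (k in unique(as.vector(lab[lab > 0]))) {
    comp <- EBImage::bwlabel(EBImage::Image((lab == k) * 1))
    expect_equal(max(comp), 1)
  }
})

test_that("phantom tau superpixel means are bimodal near the programmed values", {
  ph <- generate_phantom(noisy_phantom_spec(height = 96, width = 96, seed = 10,
                                            defect_fraction = 0))
  maps <- fit_stack(ph$stack)
  lab <- slic_segment(maps$tau, n_segments = 120)
  means <- tapply(maps$tau[lab > 0], lab[lab > 0], mean)
  near_skin <- mean(abs(means - 10) < 2)
  near_core <- mean(abs(means - 6) < 2)
  expect_gt(near_skin, 0.4)   # most superpixels sit on skin
  expect_gt(near_core, 0.03)  # a clear second mode at the core value
  expect_gt(near_skin + near_core, 0.85)
})

make_tile_labels <- function(values, tile = 10) {
  # 3x3 grid of superpixels with prescribed mean values
  H <- 3 * tile; W <- 3 * tile
  lab <- matrix(0L, H, W); img <- matrix(0, H, W)
  k <- 0
  for (i in 1:3) for (j in 1:3) {
    k <- k + 1
    rows <- ((i - 1) * tile + 1):(i * tile)
    cols <- ((j - 1) * tile + 1):(j * tile)
    lab[rows, cols] <- k
    img[rows, cols] <- values[k]
  }
  list(lab = lab, img = img)
}

test_that("designation follows the z-threshold and adjacency rules", {
  # tile 5 (center) strongly deviated; tile 2 (top middle, adjacent to the
  # core) mildly deviated; an isolated mild deviation must stay skin
  set.seed(101)
  tiles <- make_tile_labels(c(0, 2, 0,
                              0, 5, 0,
                              0, 0, 0))
  # skin reference: mean 0, sd 1 via explicit mask of the zero tiles
  ref_mask <- tiles$img == 0
  img <- tiles$img + matrix(rnorm(900, 0, 1e-6), 30, 30)  # avoid sd = 0
  img[ref_mask] <- rnorm(sum(ref_mask), 0, 1)
  rg <- designate_regions(tiles$lab, img, skin_mask = ref_mask)
  expect_equal(as.character(rg$designation[5]), "core")       # z ~ 5
  expect_equal(as.character(rg$designation[2]), "junction")   # z ~ 2, adjacent
  # the same mild deviation far from any core stays skin
  tiles2 <- make_tile_labels(c(2, 0, 0,
                               0, 0, 0,
                               0, 0, 0))
  img2 <- tiles2$img
  ref2 <- tiles2$img == 0
  img2[ref2] <- rnorm(sum(ref2), 0, 1)
  rg2 <- designate_regions(tiles2$lab, img2, skin_mask = ref2)
  expect_equal(as.character(rg2$designation[1]), "skin")
  expect_true(all(rg2$designation != "core"))
})

test_that("designations partition superpixels and respect validity", {
  set.seed(102)
  tiles <- make_tile_labels(c(0, 0, 0, 0, 6, 0, 0, 0, 0))
  img <- tiles$img
  ref <- img == 0
  img[ref] <- rnorm(sum(ref))
  valid <- matrix(TRUE, 30, 30)
  valid[tiles$lab == 3] <- FALSE   # tile 3 fully invalid -> excluded
  rg <- designate_regions(tiles$lab, img, skin_mask = ref, valid = valid)
  expect_equal(as.character(rg$designation[3]), "excluded")
  expect_true(all(levels(rg$designation) ==
                    c("core", "junction", "skin", "excluded")))
  expect_false(anyNA(rg$designation))
})

test_that("raising z_core never increases the core count; z-scores are affine-invariant", {
  ph <- generate_phantom(noisy_phantom_spec(height = 64, width = 64, seed = 15))
  maps <- fit_stack(ph$stack)
  lab <- slic_segment(maps$AF0, n_segments = 60)
  counts <- vapply(c(1.5, 2, 3, 4, 6), function(zc) {
    sum(designate_regions(lab, maps$AF0, valid = maps$mask,
                          z_core = zc)$designation == "core")
  }, 0L)
  expect_true(all(diff(counts) <= 0))
  a <- designate_regions(lab, maps$AF0, valid = maps$mask)
  b <- designate_regions(lab, maps$AF0 * 3.7 + 12, valid = maps$mask)
  expect_equal(as.character(a$designation), as.character(b$designation))
})

test_that("degenerate skin references are rejected", {
  tiles <- make_tile_labels(rep(1, 9))
  expect_error(designate_regions(tiles$lab, tiles$img,
                                 skin_mask = matrix(TRUE, 30, 30)),
               "degenerate skin reference")
})

test_that("manual ROI masks round-trip and invalid labels are rejected", {
  dir <- withr::local_tempdir()
  # all-zero mask: everything skin
  png::writePNG(matrix(0, 20, 20), file.path(dir, "zero.png"))
  rg0 <- load_manual_roi(file.path(dir, "zero.png"))
  expect_true(all(rg0$designation == "skin"))

  # phantom ground-truth regions round-trip to identical designation
  ph <- generate_phantom(noisy_phantom_spec(height = 40, width = 40,
                                            defect_fraction = 0, seed = 2))
  code <- matrix(0, 40, 40)
  code[ph$truth$region == "junction"] <- 1
  code[ph$truth$region == "core"] <- 2
  png::writePNG(code / 255, file.path(dir, "roi.png"))
  rg <- load_manual_roi(file.path(dir, "roi.png"))
  got <- matrix("skin", 40, 40)
  got[region_mask(rg, "junction")] <- "junction"
  got[region_mask(rg, "core")] <- "core"
  expect_equal(got, ph$truth$region)

  png::writePNG(matrix(7 / 255, 20, 20), file.path(dir, "bad.png"))
  expect_error(load_manual_roi(file.path(dir, "bad.png")), "7")
  expect_error(load_manual_roi(file.path(dir, "roi.png"), dims = c(10, 10)),
               "does not match")
})

test_that("automatic designation agrees with phantom ground truth away from boundaries", {
  ph <- generate_phantom(noisy_phantom_spec(height = 128, width = 128, seed = 1,
                                            defect_fraction = 0))
  maps <- fit_stack(ph$stack)
  lab <- slic_segment(maps$AF0, n_segments = 150)
  rg <- designate_regions(lab, maps$AF0, valid = maps$mask)
  lesion_pred <- region_mask(rg, "core") | region_mask(rg, "junction")
  lesion_true <- ph$truth$region %in% c("core", "junction")
  dim(lesion_true) <- dim(lesion_pred)
  # score only pixels farther than one superpixel step from the true boundary
  S <- ceiling(sqrt(128 * 128 / 150))
  brush <- EBImage::makeBrush(2 * S + 1, "disc")
  inner <- EBImage::erode(EBImage::Image(lesion_true * 1), brush) > 0.5
  outer <- EBImage::dilate(EBImage::Image(lesion_true * 1), brush) > 0.5
  scored <- matrix(inner | !outer, 128, 128)
  agree <- mean(lesion_pred[scored] == lesion_true[scored])
  expect_gte(agree, 0.9)
})
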