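# End-to-end orchestration: simulate (or load) -> stabilize -> fit ->
# segment -> boundary, with a validated config, per-stage outputs and a
# JSON manifest carrying settings, seeds and file checksums so a run can be
# replayed bit-identically.

#' Build a validated pipeline configuration
#'
#' @param input path to a stack (multi-page TIFF or frame directory), or
#'   `NULL` to simulate a phantom.
#' @param preset phantom preset name (`"sporadic_bcc"`, `"nbccs_bcc"`,
#'   `"scc"`) used when `input` is `NULL`.
#' @param seed integer seed for the simulated phantom.
#' @param frame_interval seconds between frames.
#' @param phantom named list of [phantom_spec()] overrides (e.g. `height`,
#'   `width`).
#' @param stabilize logical stage toggle.
#' @param fit named list of [fit_settings()] overrides.
#' @param segment named list: `n_segments`, `compactness`, `z_core`,
#'   `z_junction`, `driver` (one of `"AF0"`, `"A"`, `"tau"`, `"C"`).
#' @param boundary named list: `kinetic` (`"tau"` or `"A"`), `z_threshold`,
#'   `closing_radius`.
#' @param out_dir output directory.
#' @return A validated `run_config` list.
#' @export
pipeline_config <- function(input = NULL, preset = "sporadic_bcc", seed = 1L,
                            frame_interval = 1, phantom = list(),
                            stabilize = TRUE, fit = list(),
                            segment = list(), boundary = list(),
                            out_dir = tempfile("pbmap_run_")) {
  cfg <- list(schema = "pbmap-run/1", input = input, preset = preset,
              seed = as.integer(seed), frame_interval = frame_interval,
              phantom = phantom, stabilize = isTRUE(stabilize),
              fit = fit,
              segment = modifyList(list(n_segments = 300, compactness = 0.1,
                                        z_core = 3, z_junction = 1.5,
                                        driver = "AF0"), segment),
              boundary = modifyList(list(kinetic = "tau", z_threshold = 3,
                                         closing_radius = 2, smooth_sigma = 2),
                                    boundary),
              out_dir = out_dir)
  validate_config(cfg)
  cfg
}

#' Validate a pipeline configuration before any stage runs
#' @param cfg a `run_config` list (e.g. from [pipeline_config()] or
#'   [yaml::read_yaml()]).
#' @return `cfg`, invisibly; errors name the offending setting.
#' @export
validate_config <- function(cfg) {
  if (cfg$frame_interval <= 0) .stop_field("frame_interval", "must be > 0")
  f <- cfg$fit
  if (!is.null(f$tau_min) && f$tau_min <= 0) .stop_field("fit$tau_min", "must be > 0")
  if (!is.null(f$tau_max) && f$tau_max <= 0) .stop_field("fit$tau_max", "must be > 0")
  if (!is.null(f$tau_min) && !is.null(f$tau_max) && f$tau_min >= f$tau_max)
    .stop_field("fit$tau_min", "must be < fit$tau_max")
  s <- cfg$segment
  if (s$n_segments < 2) .stop_field("segment$n_segments", "must be >= 2")
  if (s$z_core <= 0) .stop_field("segment$z_core", "must be > 0")
  if (s$z_junction <= 0) .stop_field("segment$z_junction", "must be > 0")
  if (!s$driver %in% c("AF0", "A", "tau", "C"))
    .stop_field("segment$driver", "must be one of AF0, A, tau, C")
  b <- cfg$boundary
  if (!b$kinetic %in% c("tau", "A")) .stop_field("boundary$kinetic", "must be tau or A")
  if (b$z_threshold <= 0) .stop_field("boundary$z_threshold", "must be > 0")
  if (is.null(cfg$input) &&
      !cfg$preset %in% c("sporadic_bcc", "nbccs_bcc", "scc"))
    .stop_field("preset", "unknown phantom preset")
  invisible(cfg)
}

#' Run the full photobleaching-mapping pipeline
#'
#' Executes simulate/load -> stabilize -> fit -> segment -> boundary in
#' fixed order, writes parameter maps, region labels and metrics under
#' `cfg$out_dir`, and returns (and writes) a manifest with all settings and
#' md5 checksums of every written file. A stage failure halts the run with
#' the stage name; earlier outputs are retained.
#'
#' @param cfg a validated configuration from [pipeline_config()].
#' @return The manifest list (also written as `manifest.json`), with the
#'   in-memory stage results attached as attribute `"results"`.
#' @export
run_pipeline <- function(cfg) {
  validate_config(cfg)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  inp <- stage("input", {
    if (!is.null(cfg$input)) {
      list(stack = load_stack(cfg$input, cfg$frame_interval), truth = NULL)
    } else {
      spec <- do.call(phantom_spec, modifyList(
        list(seed = cfg$seed, frame_interval = cfg$frame_interval,
             region_params = list(core = .core_presets[[cfg$preset]],
                                  junction = .midpoint_params(
                                    .default_skin, .core_presets[[cfg$preset]]))),
        cfg$phantom))
      ph <- generate_phantom(spec)
      list(stack = ph$stack, truth = ph$truth)
    }
  })
  stack <- inp$stack
  truth <- inp$truth

  shifts <- NULL
  if (cfg$stabilize) {
    st <- stage("stabilize", stabilize_stack(stack))
    stack <- st$stack
    shifts <- st$shifts
  }

  maps <- stage("fit", fit_stack(stack, settings = do.call(fit_settings, cfg$fit)))
  stage("save_maps", save_maps(maps, file.path(cfg$out_dir, "maps"),
                               input = if (is.null(cfg$input)) paste0("phantom:", cfg$preset)
                                       else cfg$input))

  regions <- stage("segment", {
    driver <- maps[[cfg$segment$driver]]
    labels <- slic_segment(driver, n_segments = cfg$segment$n_segments,
                           compactness = cfg$segment$compactness,
                           valid = maps$mask | cfg$segment$driver == "AF0")
    designate_regions(labels, driver, valid = maps$mask,
                      z_core = cfg$segment$z_core,
                      z_junction = cfg$segment$z_junction,
                      source_map = cfg$segment$driver)
  })

  boundary <- stage("boundary", {
    skin_px_af <- region_mask(regions, "skin") & maps$mask
    # both maps are smoothed with the same kernel so the two contours see
    # identical boundary blurring and the area comparison stays unbiased
    af_map <- smooth_map(maps$AF0, sigma = cfg$boundary$smooth_sigma)
    ref_af <- c(mean(af_map[skin_px_af]), stats::sd(af_map[skin_px_af]))
    kin_map <- smooth_map(maps[[cfg$boundary$kinetic]],
                          sigma = cfg$boundary$smooth_sigma,
                          valid = maps$mask)
    ref_kin <- c(mean(kin_map[skin_px_af]), stats::sd(kin_map[skin_px_af]))
    m_af <- lesion_mask(af_map, ref_af, "below",
                        z_threshold = cfg$boundary$z_threshold,
                        closing_radius = cfg$boundary$closing_radius)
    m_kin <- lesion_mask(kin_map, ref_kin, "two_sided",
                         z_threshold = cfg$boundary$z_threshold,
                         closing_radius = cfg$boundary$closing_radius,
                         valid = maps$mask)
    if (!any(m_af) || !any(m_kin)) list(comparison = NULL, flagged = TRUE)
    else list(comparison = compare_boundaries(m_af, m_kin), flagged = FALSE)
  })

  metrics <- list(
    n_invalid_pixels = sum(!maps$mask),
    n_superpixels = length(regions$designation),
    designation_counts = as.list(table(regions$designation)),
    boundary = if (!is.null(boundary$comparison))
      boundary$comparison[c("area_af", "area_kinetic", "area_ratio", "dice",
                            "mean_boundary_offset")] else NULL)
  jsonlite::write_json(metrics, file.path(cfg$out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(shifts))
    utils::write.csv(shifts, file.path(cfg$out_dir, "shifts.csv"),
                     row.names = FALSE)

  files <- list.files(cfg$out_dir, recursive = TRUE, full.names = TRUE)
  files <- setdiff(files, file.path(cfg$out_dir, "manifest.json"))
  checksums <- as.list(tools::md5sum(files))
  names(checksums) <- sub(paste0("^", cfg$out_dir, "/?"), "", files)
  manifest <- list(schema = cfg$schema, config = cfg[setdiff(names(cfg), "out_dir")],
                   checksums = checksums,
                   software = paste0("pbmap ",
                                     as.character(utils::packageVersion("pbmap"))))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  attr(manifest, "results") <- list(stack = stack, truth = truth, maps = maps,
                                    regions = regions, boundary = boundary,
                                    shifts = shifts)
  manifest
}

#' Simulate and analyze a three-class phantom cohort
#'
#' Renders `n_per_class` phantom lesions for each tumor-class preset,
#' fits each stack, designates regions against the phantom's true region
#' layout-free auto reference, summarizes region means, and runs the group
#' analysis. Used for end-to-end validation of the programmed contrasts.
#'
#' @param n_per_class lesions per class.
#' @param seed base seed; lesion `i` of class `j` uses a deterministic
#'   offset.
#' @param height,width phantom size in pixels (cohort runs use a reduced
#'   field for tractability).
#' @param stabilize run the stabilization stage (off by default: cohort
#'   phantoms are drift-free).
#' @param ... further [phantom_spec()] overrides applied to every lesion.
#' @return List with `summary` (the bound region summary table), `analysis`
#'   (from [run_group_analysis()]), and `per_lesion` diagnostics.
#' @export
run_cohort <- function(n_per_class = 15, seed = 1L, height = 128, width = 128,
                       stabilize = FALSE, ...) {
  presets <- three_class_presets(height = height, width = width,
                                 lesion_geometry = list(
                                   center = c(height / 2, width / 2),
                                   axes = c(0.22 * height, 0.18 * width),
                                   junction_width = max(3, round(height / 16))),
                                 ...)
  rows <- list(); diag <- list()
  for (ci in seq_along(presets)) {
    cls <- names(presets)[ci]
    for (i in seq_len(n_per_class)) {
      spec <- presets[[cls]]
      spec$seed <- as.integer(seed + 1000L * ci + i)
      ph <- generate_phantom(spec)
      stack <- ph$stack
      if (stabilize) stack <- stabilize_stack(stack)$stack
      maps <- fit_stack(stack)
      n_seg <- max(2, round(150 * height * width / (466 * 448)))
      labels <- slic_segment(maps$AF0, n_segments = max(n_seg, 60),
                             compactness = 0.1)
      regions <- designate_regions(labels, maps$AF0, valid = maps$mask)
      lesion <- sprintf("%s_%02d", cls, i)
      rows[[lesion]] <- summarize_regions(maps, regions, lesion, cls)
      diag[[lesion]] <- list(truth = ph$truth, regions = regions, maps = maps)
    }
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  list(summary = summary, analysis = run_group_analysis(summary),
       per_lesion = diag)
}
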