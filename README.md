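# pbmap — autofluorescence photobleaching kinetics mapping

Skin autofluorescence (AF) under continuous 405 nm excitation photobleaches
over tens of seconds, and the *kinetics* of that fading differ between
tumor and healthy tissue even where the static intensity image is
ambiguous. `pbmap` is an R package for turning a time-lapse AF acquisition
(8-bit frames, ~1 frame/s over ~20 s, AF signal in the green channel of RGB
input) into spatially resolved photobleaching parameter maps and downstream
lesion analyses. It is aimed at researchers in biomedical optics and skin
imaging who need a tested, reproducible reference pipeline for
photobleaching-based contrast.

Every pixel's temporal profile is fitted with the single-exponential decay

```
I(t) = A · exp(−t/τ) + C
```

(`A` bleaching amplitude, `τ` decay constant in seconds, `C` residual
non-bleaching component), producing four co-registered functional images
per lesion — the initial intensity AF₀ plus the `A`, `τ`, `C` maps — with a
per-pixel residual error and validity mask. On top of the maps the package
provides:

* **Stabilization** — translation-only frame registration
  (FFT cross-correlation, subpixel refinement to 0.1 px), with
  out-of-view pixels flagged invalid rather than zero-filled.
* **Fitting** — a bounded variable-projection solver (exact linear
  subproblem in `A`, `C`; global grid + golden-section search over `τ`)
  with explicit unfittable/poor failure handling, plus linear and
  double-exponential comparator fits ranked by AICc.
* **Region designation** — SLIC superpixels on the parameter maps;
  superpixels deviating sharply from the skin reference (|z| ≥ 3) become
  lesion core, deviated neighbours (|z| ≥ 1.5) junction; manual ROI masks
  are supported as a fallback.
* **Statistics** — per-lesion region means compared with Levene,
  Kruskal–Wallis and Dunn–Bonferroni tests (lesion-level observation
  units).
* **Boundary mismatch** — z-threshold lesion masks from the AF₀ and
  kinetic maps compared by area ratio, Dice and mean boundary offset.
* **Synthetic phantoms** — a fully parameterized generator of time-lapse
  stacks with known per-pixel ground truth (three tumor-class presets,
  shot + read noise, rigid drift, defect pixels, 8-bit quantization),
  which backs the entire test suite since no clinical data are bundled.

## Worked example

Simulate a sporadic-BCC-like phantom, fit it, designate regions and
compare boundaries:

```r
library(pbmap)

presets <- three_class_presets(height = 128, width = 128,
  lesion_geometry = list(center = c(64, 64), axes = c(28, 23),
                         junction_width = 8))
ph <- generate_phantom(presets$sporadic_bcc)
ph$stack
#> pb_stack: 128 x 128 px, 20 frames (0 s .. 19 s), channel gray, bit depth 8

maps <- fit_stack(ph$stack)
maps
#> pb_maps: 128 x 128 px, model single_exp, 164 invalid pixels

labels  <- slic_segment(maps$AF0, n_segments = 150)
regions <- designate_regions(labels, maps$AF0, valid = maps$mask)
regions
#> region_labels: 143 superpixels on 128 x 128 px (driver: AF0)
#>     core junction     skin excluded
#>       25        9      109        0

tab <- summarize_regions(maps, regions, "lesion_01", "sporadic_bcc")
tab[tab$parameter == "tau", ]
#>  lesion_id        group   region parameter      mean n_pixels
#>  lesion_01 sporadic_bcc    inner       tau  6.656788     2654
#>  lesion_01 sporadic_bcc junction       tau  8.492525      899
#>  lesion_01 sporadic_bcc     skin       tau 10.531151    12667
```

The phantom programs core τ = 6 s against skin τ = 10 s; the recovered
region means (6.66 s inner, 10.53 s skin, junction in between) show the
fitted maps reproduce the programmed kinetic contrast. The 164 invalid
pixels are the phantom's simulated defect pixels (≈1% of the field)
caught by the failure handling. Boundary comparison of the smoothed AF₀
and τ masks then quantifies how well the two contours agree:

```r
skin_px <- region_mask(regions, "skin") & maps$mask
af <- smooth_map(maps$AF0, sigma = 2)
tu <- smooth_map(maps$tau, sigma = 2, valid = maps$mask)
m_af  <- lesion_mask(af, c(mean(af[skin_px]), sd(af[skin_px])), "below")
m_tau <- lesion_mask(tu, c(mean(tu[skin_px]), sd(tu[skin_px])), "below",
                     valid = maps$mask)
compare_boundaries(m_af, m_tau)
#> boundary_comparison: area AF 3146 px, kinetic 2384 px (ratio 0.758),
#>   Dice 0.847, offset 3.47 px
```

An end-to-end run (simulate → stabilize → fit → segment → boundary, with
maps, metrics and a checksummed manifest on disk) is one call:

```r
manifest <- run_pipeline(pipeline_config(preset = "scc", seed = 1,
                                         out_dir = "scc_run"))
```

A thin command-line wrapper over the same functions lives at
`inst/scripts/pbmap.R` (`simulate`, `fit`, `run` subcommands, YAML config).

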