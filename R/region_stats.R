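# Region statistics across lesions: per-lesion region means of the four
# maps, then the homogeneity / omnibus / post-hoc chain used for group
# comparisons — Levene's test (group-mean centering), Kruskal-Wallis, and
# Dunn's pairwise z-tests with Bonferroni adjustment. The observation unit
# is the per-lesion region mean: pixels within a lesion are spatially
# autocorrelated, so pixel-level testing would badly overstate the
# effective sample size.

#' Summarize parameter maps over designated regions
#'
#' Computes the mean of each parameter map (`AF0`, `A`, `tau`, `C`) over the
#' valid pixels of each designated region (`inner` = core superpixels,
#' `junction`, `skin`), yielding up to 12 rows per lesion. Regions left
#' empty after validity masking are omitted with a warning.
#'
#' @param maps a `pb_maps` object.
#' @param regions a `region_labels` object co-registered with `maps`.
#' @param lesion_id identifier recorded in the table.
#' @param group lesion group label (e.g. `"sporadic_bcc"`, `"nbccs_bcc"`,
#'   `"scc"`).
#' @return A data.frame with columns `lesion_id`, `group`, `region`,
#'   `parameter`, `mean`, `n_pixels`.
#' @export
summarize_regions <- function(maps, regions, lesion_id, group) {
  stopifnot(inherits(maps, "pb_maps"), inherits(regions, "region_labels"))
  stopifnot(identical(dim(maps$AF0), dim(regions$labels)))
  region_defs <- c(inner = "core", junction = "junction", skin = "skin")
  params <- c("AF0", "A", "tau", "C")
  rows <- list()
  for (rg in names(region_defs)) {
    px <- region_mask(regions, region_defs[[rg]]) & maps$mask
    n <- sum(px)
    if (n == 0) {
      warning(sprintf("region '%s' empty after validity masking; omitted", rg))
      next
    }
    for (p in params) {
      rows[[length(rows) + 1L]] <- data.frame(
        lesion_id = lesion_id, group = group, region = rg, parameter = p,
        mean = mean(maps[[p]][px]), n_pixels = n,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

.as_group_data <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) stop("need >= 2 groups")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  data.frame(y = unlist(groups, use.names = FALSE),
             g = factor(rep(names(groups), lengths(groups)),
                        levels = names(groups)))
}

#' Levene's test for homogeneity of variances
#'
#' Original Levene formulation: a one-way ANOVA F on absolute deviations
#' from the group means (computed via [car::leveneTest] with
#' `center = mean`).
#'
#' @param groups list of numeric vectors (>= 2 groups, each with >= 2
#'   observations).
#' @return List with `statistic` (Levene's W, an F value), `df` (numerator,
#'   denominator), and `p.value`.
#' @export
levene_test <- function(groups) {
  d <- .as_group_data(groups)
  if (any(lengths(groups) < 2)) stop("each group needs >= 2 observations")
  dev <- abs(d$y - stats::ave(d$y, d$g))
  k <- nlevels(d$g); n <- nrow(d)
  if (all(dev == 0))
    stop("zero within-group deviation spread in every group: statistic undefined")
  dev_means <- tapply(dev, d$g, mean)
  ss_between <- sum(lengths(groups) * (dev_means - mean(dev))^2)
  ss_within <- sum((dev - stats::ave(dev, d$g))^2)
  if (ss_between == 0)
    # equal mean absolute deviations in every group: no spread difference
    return(list(statistic = 0, df = c(k - 1, n - k), p.value = 1))
  if (ss_within == 0)
    # deviations constant within groups but unequal between: F diverges
    return(list(statistic = Inf, df = c(k - 1, n - k), p.value = 0))
  res <- car::leveneTest(y ~ g, data = d, center = mean)
  W <- res$`F value`[1]
  if (!is.finite(W)) stop("Levene statistic undefined for these groups")
  list(statistic = W, df = c(res$Df[1], res$Df[2]), p.value = res$`Pr(>F)`[1])
}

#' Kruskal-Wallis rank-sum test
#'
#' Tie-corrected H with a chi-square reference on k - 1 degrees of freedom
#' (via [stats::kruskal.test]).
#'
#' @param groups list of numeric vectors (>= 2 groups, total n >= 3).
#' @return List with `statistic` (H), `df`, `p.value`.
#' @export
kruskal_wallis <- function(groups) {
  d <- .as_group_data(groups)
  if (nrow(d) < 3) stop("need total n >= 3")
  if (length(unique(d$y)) == 1)
    stop("all observations identical: H undefined after tie correction")
  res <- stats::kruskal.test(d$y, d$g)
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p.value = res$p.value)
}

#' Dunn's post-hoc test with Bonferroni adjustment
#'
#' Pairwise z-statistics on the pooled ranks with tie correction:
#' `z = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T) (1/n_i + 1/n_j))` with
#' `T = sum(t^3 - t) / (12 (N - 1))` over tie groups. Two-sided normal
#' p-values; adjusted p = `min(1, m * p)` for `m = k(k-1)/2` pairs.
#'
#' @inheritParams kruskal_wallis
#' @return data.frame with columns `group1`, `group2`, `z`, `p.value`,
#'   `p.adj`.
#' @export
dunn_bonferroni <- function(groups) {
  d <- .as_group_data(groups)
  if (nrow(d) < 3) stop("need total n >= 3")
  if (length(unique(d$y)) == 1)
    stop("all observations identical: ranks carry no information")
  N <- nrow(d)
  r <- rank(d$y)
  rbar <- tapply(r, d$g, mean)
  n <- tapply(r, d$g, length)
  ties <- table(d$y)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  lv <- levels(d$g)
  pairs <- utils::combn(lv, 2)
  z <- apply(pairs, 2, function(pr) {
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / n[[pr[1]]] + 1 / n[[pr[2]]]))
    (rbar[[pr[1]]] - rbar[[pr[2]]]) / se
  })
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], z = z, p.value = p,
             p.adj = stats::p.adjust(p, method = "bonferroni"),
             stringsAsFactors = FALSE)
}

.stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Group-level statistical analysis of a region summary table
#'
#' For each parameter, runs (i) the inner-vs-junction-vs-skin comparison
#' within each lesion group and (ii) the inner-region comparison across
#' groups, each as Kruskal-Wallis followed by Dunn-Bonferroni pairwise
#' tests. Observations are per-lesion region means. Contrasts with fewer
#' than two observations per cell are skipped with a warning.
#'
#' @param table a region summary table from [summarize_regions()] rows bound
#'   together.
#' @param alpha significance ladder for stars (fixed at 0.05/0.01/0.001).
#' @return List with `omnibus` (one row per contrast: H, df, p) and
#'   `pairwise` (Dunn rows with stars), both data.frames (possibly empty).
#' @export
run_group_analysis <- function(table, alpha = 0.05) {
  stopifnot(all(c("lesion_id", "group", "region", "parameter", "mean") %in%
                  names(table)))
  omnibus <- list(); pairwise <- list()
  add_contrast <- function(samples, contrast, parameter, scope) {
    samples <- samples[lengths(samples) > 0]
    if (length(samples) < 2 || any(lengths(samples) < 2)) {
      warning(sprintf("contrast '%s' (%s): < 2 observations per cell; skipped",
                      contrast, parameter))
      return(invisible())
    }
    kw <- tryCatch(kruskal_wallis(samples), error = function(e) NULL)
    if (is.null(kw)) return(invisible())
    omnibus[[length(omnibus) + 1L]] <<- data.frame(
      contrast = contrast, scope = scope, parameter = parameter,
      H = kw$statistic, df = kw$df, p.value = kw$p.value,
      stringsAsFactors = FALSE)
    dn <- tryCatch(dunn_bonferroni(samples), error = function(e) NULL)
    if (!is.null(dn)) {
      dn$contrast <- contrast; dn$scope <- scope; dn$parameter <- parameter
      dn$stars <- .stars(dn$p.adj)
      pairwise[[length(pairwise) + 1L]] <<- dn
    }
  }
  for (param in unique(table$parameter)) {
    tp <- table[table$parameter == param, ]
    for (grp in unique(tp$group)) {
      tg <- tp[tp$group == grp, ]
      samples <- split(tg$mean, factor(tg$region,
                                       levels = c("inner", "junction", "skin")))
      add_contrast(samples, "regions_within_group", param, grp)
    }
    ti <- tp[tp$region == "inner", ]
    if (length(unique(ti$group)) >= 2) {
      samples <- split(ti$mean, factor(ti$group))
      add_contrast(samples, "inner_across_groups", param, "all")
    }
  }
  list(omnibus = if (length(omnibus)) do.call(rbind, omnibus) else
         data.frame(),
       pairwise = if (length(pairwise)) do.call(rbind, pairwise) else
         data.frame())
}
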