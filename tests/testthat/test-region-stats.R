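# Region summaries and the nonparametric statistics chain, checked against
# brute-force rank-definition oracles.

make_regions_from_truth <- function(truth) {
  lab <- matrix(0L, nrow(truth$region), ncol(truth$region))
  lab[truth$region == "skin"] <- 1L
  lab[truth$region == "junction"] <- 2L
  lab[truth$region == "core"] <- 3L
  designation <- factor(c("skin", "junction", "core"),
                        levels = c("core", "junction", "skin", "excluded"))
  structure(list(labels = lab, designation = designation,
                 source_map = "truth",
                 skin_reference = c(mean = NA, sd = NA)),
            class = "region_labels")
}

test_that("region summaries report per-region means of every parameter", {
  ph <- generate_phantom(noisy_phantom_spec(height = 48, width = 48,
                                            defect_fraction = 0, seed = 3))
  maps <- fit_stack(ph$stack)
  regions <- make_regions_from_truth(ph$truth)
  tab <- summarize_regions(maps, regions, "lesion_A", "sporadic_bcc")
  expect_equal(nrow(tab), 12)
  expect_setequal(unique(tab$region), c("inner", "junction", "skin"))
  expect_setequal(unique(tab$parameter), c("AF0", "A", "tau", "C"))
  expect_true(all(tab$n_pixels > 0))
  # programmed contrasts: inner tau and AF0 below skin
  get <- function(rg, p) tab$mean[tab$region == rg & tab$parameter == p]
  expect_lt(get("inner", "tau"), get("skin", "tau"))
  expect_lt(get("inner", "AF0"), get("skin", "AF0"))
  # region means within 5% of the programmed means at default noise
  expect_lt(abs(get("inner", "tau") - 6) / 6, 0.05)
  expect_lt(abs(get("skin", "tau") - 10) / 10, 0.05)
  expect_lt(abs(get("skin", "AF0") - 190) / 190, 0.05)
})

test_that("a constant map yields identical region means everywhere", {
  ph <- generate_phantom(noisy_phantom_spec(height = 32, width = 32,
                                            defect_fraction = 0, seed = 5))
  maps <- fit_stack(ph$stack)
  maps$tau[] <- 5
  tab <- summarize_regions(maps, make_regions_from_truth(ph$truth), "x", "scc")
  expect_true(all(tab$mean[tab$parameter == "tau"] == 5))
})

test_that("Levene's test handles equal-spread, divergent and generic cases", {
  eq <- levene_test(list(c(1, 5), c(11, 15)))
  expect_equal(eq$statistic, 0)
  # absolute deviations {5,5} vs {1,1}: within-group SS is 0, F diverges
  dv <- levene_test(list(c(0, 10), c(4, 6)))
  expect_equal(dv$statistic, Inf)
  expect_equal(dv$p.value, 0)
  expect_error(levene_test(list(c(3, 3), c(7, 7))), "undefined")
  expect_error(levene_test(list(1, 2)), ">= 2 observations")
  # generic case agrees with a hand-computed one-way F on |y - mean|
  set.seed(1)
  g1 <- rnorm(10); g2 <- rnorm(12, sd = 3)
  res <- levene_test(list(g1, g2))
  d1 <- abs(g1 - mean(g1)); d2 <- abs(g2 - mean(g2))
  f_hand <- anova(lm(c(d1, d2) ~ factor(rep(1:2, c(10, 12)))))$`F value`[1]
  expect_equal(res$statistic, f_hand, tolerance = 1e-10)
})

test_that("Kruskal-Wallis H matches the closed form and the brute-force oracle", {
  res <- kruskal_wallis(list(1:3, 4:6, 7:9))
  expect_equal(res$statistic, 7.2, tolerance = 1e-10)
  expect_equal(res$df, 2)

  # exhaustive small-instance sweep: compositions of n <= 12 into 2-3
  # groups, integer data with ties
  set.seed(7)
  for (rep in 1:60) {
    k <- sample(2:3, 1)
    sizes <- sample(2:5, k, replace = TRUE)
    while (sum(sizes) > 12) sizes <- sample(2:5, k, replace = TRUE)
    groups <- lapply(sizes, function(n) sample(1:6, n, replace = TRUE))
    if (length(unique(unlist(groups))) == 1) next
    expect_equal(kruskal_wallis(groups)$statistic, brute_kruskal_H(groups),
                 tolerance = 1e-12)
  }
  expect_error(kruskal_wallis(list(c(2, 2), c(2, 2))), "identical")
})

test_that("Kruskal-Wallis H is invariant under strictly monotone transforms", {
  set.seed(8)
  groups <- list(rnorm(8), rnorm(6, 1), rnorm(7, 2))
  h0 <- kruskal_wallis(groups)$statistic
  expect_equal(kruskal_wallis(lapply(groups, exp))$statistic, h0)
  expect_equal(kruskal_wallis(lapply(groups, function(x) 3 * x - 100))$statistic, h0)
})

test_that("Dunn z matches the brute-force oracle and Bonferroni is exact", {
  set.seed(9)
  for (rep in 1:40) {
    k <- sample(2:3, 1)
    sizes <- sample(2:4, k, replace = TRUE)
    groups <- lapply(sizes, function(n) sample(1:5, n, replace = TRUE))
    if (length(unique(unlist(groups))) == 1) next
    tab <- dunn_bonferroni(groups)
    m <- k * (k - 1) / 2
    expect_equal(tab$p.adj, pmin(1, m * tab$p.value))
    expect_true(all(tab$p.adj >= tab$p.value))
    idx <- t(utils::combn(seq_len(k), 2))
    for (r in seq_len(nrow(tab))) {
      i <- as.integer(sub("g", "", tab$group1[r]))
      j <- as.integer(sub("g", "", tab$group2[r]))
      expect_equal(tab$z[r], brute_dunn_z(groups, i, j), tolerance = 1e-12)
    }
  }
})

test_that("Dunn separates well-separated groups and not identical ones", {
  tab <- dunn_bonferroni(list(1:10, 101:110, 201:210))
  expect_true(all(tab$p.adj < 0.05))
  set.seed(10)
  x <- rnorm(12)
  tab2 <- dunn_bonferroni(list(x, x, rnorm(12, 5)))
  z_same <- tab2$z[tab2$group1 == "g1" & tab2$group2 == "g2"]
  expect_lt(abs(z_same), 1e-10)
})

test_that("group analysis skips degenerate contrasts without crashing", {
  ph <- generate_phantom(noisy_phantom_spec(height = 32, width = 32,
                                            defect_fraction = 0, seed = 4))
  maps <- fit_stack(ph$stack)
  tab <- summarize_regions(maps, make_regions_from_truth(ph$truth),
                           "only_lesion", "sporadic_bcc")
  w <- capture_warnings(res <- run_group_analysis(tab))
  expect_true(length(w) > 0 && all(grepl("skipped", w)))
  expect_equal(nrow(res$omnibus), 0)
  expect_equal(nrow(res$pairwise), 0)
})

test_that("group analysis finds programmed region contrasts in a small cohort", {
  rows <- list()
  for (i in 1:8) {
    ph <- generate_phantom(noisy_phantom_spec(height = 40, width = 40,
                                              defect_fraction = 0,
                                              seed = 100 + i))
    maps <- fit_stack(ph$stack)
    rows[[i]] <- summarize_regions(maps, make_regions_from_truth(ph$truth),
                                   paste0("lesion_", i), "sporadic_bcc")
  }
  res <- run_group_analysis(do.call(rbind, rows))
  pw <- res$pairwise
  inner_skin <- pw[pw$contrast == "regions_within_group" &
                     pw$group1 == "inner" & pw$group2 == "skin", ]
  expect_equal(nrow(inner_skin), 4)  # one per parameter
  expect_true(all(inner_skin$p.adj < 0.05))
  expect_true(all(inner_skin$stars != ""))
})
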