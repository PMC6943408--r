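# Independent oracle for two-group PERMANOVA on a distance matrix:
# Anderson's direct within-group formulation, SS_W = sum over groups of
# (1/n_g) * sum of squared within-group distances, SS_T computed over all
# pairs. Completely separate from the hat-matrix route in the package.
anderson_f <- function(d, groups) {
  n <- nrow(d); k <- length(unique(groups))
  ss_t <- sum(d[upper.tri(d)]^2) / n
  ss_w <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    dg <- d[idx, idx, drop = FALSE]
    ss_w <- ss_w + sum(dg[upper.tri(dg)]^2) / length(idx)
  }
  ss_a <- ss_t - ss_w
  (ss_a / (k - 1)) / (ss_w / (n - k))
}

test_that("one-way ANOVA matches lm and the two-group t statistic", {
  set.seed(14)
  v <- rnorm(15, rep(c(0, 1, 3), each = 5))
  g <- rep(c("a", "b", "c"), each = 5)
  got <- one_way_anova(v, g)
  ref <- anova(lm(v ~ g))
  expect_equal(got$F, ref$`F value`[1])
  expect_equal(got$p, ref$`Pr(>F)`[1])
  expect_equal(got$df, c(2, 12))
  # two groups: F = t^2 and p-values coincide with the pooled t test
  v2 <- rnorm(12, rep(c(0, 0.8), each = 6)); g2 <- rep(c("x", "y"), each = 6)
  tt <- t.test(v2 ~ g2, var.equal = TRUE)
  got2 <- one_way_anova(v2, g2)
  expect_equal(got2$F, unname(tt$statistic)^2)
  expect_equal(got2$p, tt$p.value)
})

test_that("degenerate ANOVA (zero within-group variance) is flagged", {
  got <- one_way_anova(c(1, 1, 2, 2), c("a", "a", "b", "b"))
  expect_true(got$degenerate)
  expect_equal(got$p, 0)
  same <- one_way_anova(c(3, 3, 3, 3), c("a", "a", "b", "b"))
  expect_equal(same$p, 1)
})

test_that("PERMANOVA partition matches vegan::adonis2 term by term", {
  cfg <- sim_config(seed = 31)
  mb <- simulate_microbiome(cfg)
  d <- bray_curtis(mb$counts)
  meta <- mb$metadata
  got <- permanova(d, ~ moss_species * desert_class, meta, n_perm = 49,
                   seed = 1)
  ref <- vegan::adonis2(as.dist(d) ~ moss_species * desert_class,
                        data = meta, permutations = 49, by = "terms")
  expect_equal(got$SumOfSqs[1:3], ref$SumOfSqs[1:3], tolerance = 1e-10)
  expect_equal(got$R2[1:3], ref$R2[1:3], tolerance = 1e-10)
  expect_equal(got$F[1:3], ref$F[1:3], tolerance = 1e-10)
  expect_equal(got$df[1:3], ref$Df[1:3])
  # continuous covariate route
  got2 <- permanova(d, ~ SOD, meta, n_perm = 49, seed = 1)
  ref2 <- vegan::adonis2(as.dist(d) ~ SOD, data = meta,
                         permutations = 49, by = "terms")
  expect_equal(got2$SumOfSqs[1], ref2$SumOfSqs[1], tolerance = 1e-10)
  expect_equal(got2$R2[1], ref2$R2[1], tolerance = 1e-10)
})

test_that("R2 components sum to one and SS to the total", {
  cfg <- sim_config(seed = 32)
  mb <- simulate_microbiome(cfg)
  d <- bray_curtis(mb$counts)
  got <- permanova(d, ~ moss_species + desert_class, mb$metadata,
                   n_perm = 19, seed = 2)
  expect_equal(sum(got$R2[got$term != "Total"]), 1)
  expect_equal(sum(got$SumOfSqs[!got$term %in% "Total"]),
               got$SumOfSqs[got$term == "Total"])
})

test_that("permutation enumeration generates each arrangement exactly once", {
  for (n in 2:5) {
    pm <- mosscrust:::all_permutations(n)
    expect_equal(nrow(pm), factorial(n))
    expect_equal(anyDuplicated(pm), 0)
    expect_true(all(apply(pm, 1, function(r) identical(sort(r), 1:n))))
  }
})

test_that("exact PERMANOVA p equals the partition-enumeration oracle", {
  set.seed(77)
  pts <- matrix(rnorm(12), 6, 2)
  d <- as.matrix(dist(pts))
  dimnames(d) <- list(paste0("s", 1:6), paste0("s", 1:6))
  groups <- rep(c("A", "B"), each = 3)
  meta <- data.frame(grp = groups, row.names = rownames(d))
  got <- permanova(d, ~ grp, meta, exact = TRUE)
  f_obs <- anderson_f(d, groups)
  expect_equal(got$F[1], f_obs, tolerance = 1e-10)
  # enumerate the 20 balanced partitions; each corresponds to 3! * 3! of
  # the 720 label permutations, so the oracle p equals the exact p
  combos <- combn(6, 3)
  f_all <- apply(combos, 2, function(a) {
    lab <- rep("B", 6); lab[a] <- "A"
    anderson_f(d, lab)
  })
  expect_equal(got$p[1], mean(f_all >= f_obs - 1e-12))
})

test_that("PERMANOVA rejects aliased and underpopulated designs", {
  d <- as.matrix(dist(matrix(rnorm(12), 6)))
  dimnames(d) <- list(paste0("s", 1:6), paste0("s", 1:6))
  meta <- data.frame(a = rep(c("x", "y"), each = 3),
                     b = rep(c("x", "y"), each = 3),  # alias of a
                     single = c("u", rep("v", 5)),
                     row.names = rownames(d))
  expect_error(permanova(d, ~ a + b, meta, n_perm = 9), "aliased")
  expect_error(permanova(d, ~ single, meta, n_perm = 9), "< 2 samples")
})

test_that("spearman p-values match cor.test in both regimes", {
  set.seed(99)
  # exact regime: n <= 10, no ties
  x <- rnorm(8); y <- rnorm(8)
  got <- spearman_test(x, y)
  ref <- cor.test(x, y, method = "spearman", exact = TRUE)
  expect_equal(got$rho, unname(ref$estimate))
  expect_equal(got$p, ref$p.value)
  # t-approximation regime: n > 10
  x2 <- rnorm(25); y2 <- 0.5 * x2 + rnorm(25)
  got2 <- spearman_test(x2, y2)
  ref2 <- cor.test(x2, y2, method = "spearman", exact = FALSE)
  expect_equal(got2$rho, unname(ref2$estimate))
  expect_equal(got2$p, ref2$p.value, tolerance = 1e-10)
  # constant input: undefined correlation, not an error
  expect_true(is.na(spearman_test(rep(1, 9), rnorm(9))$rho))
  # perfect monotone association
  expect_equal(spearman_test(1:12, (1:12)^3)$rho, 1)
})

test_that("spearman test is calibrated under the null", {
  set.seed(123)
  p <- replicate(400, spearman_test(rnorm(18), rnorm(18))$p)
  expect_gt(mean(p < 0.05), 0.02)
  expect_lt(mean(p < 0.05), 0.09)
})

test_that("lefse recovers planted biomarker genera with the right class", {
  cfg <- sim_config(seed = 41)
  mb <- simulate_microbiome(cfg)
  res <- lefse(mb$counts, mb$taxonomy, mb$metadata$moss_species, seed = 1)
  expect_true(all(c("taxon", "level", "enriched_class", "kw_p",
                    "lda_score") %in% names(res)))
  expect_true(all(res$kw_p < 0.05))
  expect_true(all(res$lda_score > 2))
  found <- paste0("g__", mb$truth$biomarker_genera) %in% res$taxon
  expect_gte(mean(found), 0.9)
  hit <- res[match(paste0("g__", mb$truth$biomarker_genera), res$taxon), ]
  ok <- !is.na(hit$taxon)
  expect_identical(hit$enriched_class[ok],
                   unname(mb$truth$biomarker_class)[ok])
})

test_that("lefse returns an empty frame when classes are exchangeable", {
  cfg <- sim_config(seed = 42, species_effect = 0, class_effect = 0,
                    biomarker_fold = 1)
  mb <- simulate_microbiome(cfg)
  # scramble labels so any finding is a false positive; the frame may be
  # non-empty but must be small relative to the number of taxa scanned
  set.seed(5)
  res <- lefse(mb$counts, mb$taxonomy,
               sample(mb$metadata$moss_species), seed = 2)
  n_taxa <- length(unique(unlist(lapply(lefse_levels(), function(lv)
    paste0(substr(lv, 1, 1), "__",
           colnames(aggregate_taxa(mb$counts, mb$taxonomy, lv)))))))
  expect_lt(nrow(res), 0.25 * n_taxa)
})

test_that("significance stars follow the conventional binning", {
  expect_identical(significance_stars(c(0.0005, 0.005, 0.03, 0.2, NA)),
                   c("***", "**", "*", "", ""))
})

test_that("factor-taxon heatmap returns clustered rho/p/star matrices", {
  cfg <- sim_config(seed = 43)
  mb <- simulate_microbiome(cfg)
  gen <- aggregate_taxa(mb$counts, mb$taxonomy, "genus")
  cov <- mb$metadata[, c("SOD", "Pro", "POD", "MP", "MDA")]
  hm <- factor_taxon_heatmap(gen, cov, top_n = 20)
  expect_equal(dim(hm$rho), c(20, 5))
  expect_identical(dimnames(hm$rho), dimnames(hm$p))
  expect_identical(dimnames(hm$rho), dimnames(hm$stars))
  expect_true(all(abs(hm$rho) <= 1, na.rm = TRUE))
  # stars agree with the p matrix entrywise
  expect_identical(hm$stars,
                   matrix(significance_stars(hm$p), nrow(hm$p),
                          dimnames = dimnames(hm$p)))
  expect_error(factor_taxon_heatmap(gen, cov, taxa = "no_such_taxon"),
               "unknown taxa")
})

test_that("module-linked genera correlate with the enzymatic covariates", {
  # the generator mixes the first module's latent factor into SOD/Pro/POD;
  # with the moss-species and class effects switched off (they move SOD
  # and all genera at once, masking the channel under test) the module's
  # member genera must correlate with SOD more strongly than background
  cfg <- sim_config(seed = 44, species_effect = 0, class_effect = 0,
                    biomarker_fold = 1)
  mb <- simulate_microbiome(cfg)
  gen <- aggregate_taxa(mb$counts, mb$taxonomy, "genus")
  rel <- gen / rowSums(gen)
  m1 <- names(mb$truth$modules)[mb$truth$modules == 1]
  bg <- setdiff(colnames(gen), names(mb$truth$modules))
  bg <- bg[apply(rel[, bg, drop = FALSE], 2, sd) > 0]
  r_mod <- sapply(m1, function(g) abs(cor(rel[, g], mb$metadata$SOD,
                                          method = "spearman")))
  r_bg <- sapply(bg, function(g) abs(cor(rel[, g], mb$metadata$SOD,
                                         method = "spearman")))
  expect_gt(mean(r_mod), mean(r_bg))
})
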