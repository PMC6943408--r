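test_that("otu_table validation catches malformed count matrices", {
  m <- toy_otu()
  expect_silent(otu_table(m))
  bad <- m; bad[1, 1] <- -1
  expect_error(otu_table(bad), "non-negative")
  bad <- m; rownames(bad) <- NULL
  expect_error(otu_table(bad), "names")
  bad <- m; bad[1, ] <- 0
  expect_error(otu_table(bad), "total")
})

test_that("chao1 matches the bias-corrected closed form", {
  # 3 singletons, 1 doubleton, 2 higher-count taxa -> 6 + 3*2/(2*2)
  x <- c(1, 1, 1, 2, 5, 9)
  expect_equal(chao1_index(x), 6 + 3 * 2 / (2 * 2))
  # no singletons: chao1 equals observed richness
  expect_equal(chao1_index(c(3, 4, 2)), 3)
  # no doubletons stays finite
  expect_equal(chao1_index(c(1, 1, 5)), 3 + 2 * 1 / 2)
  # cross-check against vegan's bias-corrected estimator
  set.seed(30)
  y <- rpois(50, 2)
  y[1] <- 5  # ensure positive total
  expect_equal(chao1_index(y),
               unname(vegan::estimateR(y)["S.chao1"]))
})

test_that("shannon matches the closed form and vegan", {
  x <- c(2, 2, 4)
  expect_equal(shannon_index(x),
               -sum(c(0.25, 0.25, 0.5) * log(c(0.25, 0.25, 0.5))))
  expect_equal(shannon_index(x), unname(vegan::diversity(x)))
  # zeros are ignored, equal abundances maximize entropy at log(S)
  expect_equal(shannon_index(c(5, 5, 5, 5, 0)), log(4))
})

test_that("Good's coverage is one minus singleton fraction", {
  expect_equal(goods_coverage_index(c(1, 1, 8)), 1 - 2 / 10)
  expect_equal(goods_coverage_index(c(4, 6)), 1)
})

test_that("Faith's PD matches a hand-enumerated 4-leaf tree", {
  tr <- ape::read.tree(text = "((a:1,b:2):3,(c:4,d:5):6);")
  tab <- otu_table(matrix(c(1, 1, 0, 0,
                            1, 0, 1, 0,
                            1, 1, 1, 1),
                          nrow = 3, byrow = TRUE,
                          dimnames = list(paste0("s", 1:3), letters[1:4])))
  pd <- alpha_diversity(tab, "faith_pd", tree = tr)$faith_pd
  # s1 = {a,b}: edges a(1) + b(2) + their stem(3) = 6
  # s2 = {a,c}: a(1) + stem(3) + c(4) + stem(6) = 14
  # s3 = all: total branch length = 21
  expect_equal(pd, c(6, 14, 21))
})

test_that("bray-curtis matches the min-sum formula", {
  x <- c(2, 2, 0); y <- c(0, 2, 2)
  tab <- otu_table(matrix(c(x, y), 2, byrow = TRUE,
                          dimnames = list(c("s1", "s2"), c("f1", "f2", "f3"))))
  d <- bray_curtis(tab)
  expect_equal(d["s1", "s2"], 1 - 2 * sum(pmin(x, y)) / (sum(x) + sum(y)))
  expect_equal(d["s1", "s2"], 0.5)
  expect_equal(diag(d), c(s1 = 0, s2 = 0))
})

test_that("unweighted unifrac matches branch enumeration on a 4-leaf tree", {
  tr <- ape::read.tree(text = "((a:1,b:2):3,(c:4,d:5):6);")
  tab <- otu_table(matrix(c(5, 1, 0, 0,
                            0, 0, 2, 7,
                            3, 0, 4, 0),
                          nrow = 3, byrow = TRUE,
                          dimnames = list(paste0("s", 1:3), letters[1:4])))
  d <- unweighted_unifrac(tab, tr)
  # s1 = {a,b}, s2 = {c,d}: no shared branch -> distance 1
  expect_equal(d["s1", "s2"], 1)
  # s1 = {a,b}, s3 = {a,c}: unique = b(2) + c(4) + b-stem? no --
  # union edges: a(1), b(2), ab-stem(3), c(4), cd-stem(6) = 16
  # shared edges: a(1), ab-stem(3) -> unique = 2 + 4 + 6 = 12
  expect_equal(d["s1", "s3"], 12 / 16)
  # counts do not matter, only presence
  tab2 <- tab; tab2[tab2 > 0] <- 999
  expect_equal(unweighted_unifrac(otu_table(tab2), tr), d)
})

test_that("unweighted unifrac agrees with picante on random data", {
  cfg <- sim_config(seed = 21)
  mb <- simulate_microbiome(cfg)
  sub <- mb$counts[1:6, ]
  keep <- colSums(sub > 0) > 0
  tab <- otu_table(sub[, keep])
  tr <- ape::keep.tip(mb$tree, colnames(tab))
  got <- unweighted_unifrac(tab, tr)
  ref <- as.matrix(picante::unifrac(tab, root_tree(tr)))
  expect_equal(got[rownames(ref), colnames(ref)], ref, tolerance = 1e-10)
})

test_that("upgma cophenetic heights match hand agglomeration", {
  # d(a,b)=2, d(a,c)=8, d(b,c)=6: merge {a,b} at 2, then c joins at
  # mean(8, 6) = 7
  d <- matrix(c(0, 2, 8,
                2, 0, 6,
                8, 6, 0), 3, dimnames = list(c("a", "b", "c"),
                                             c("a", "b", "c")))
  res <- upgma(d)
  expect_equal(res$heights, c(2, 7))
  expect_equal(res$cophenetic["a", "b"], 2)
  expect_equal(res$cophenetic["a", "c"], 7)
  expect_equal(res$cophenetic["b", "c"], 7)
  expect_true(grepl("^\\(", res$newick))
})

test_that("upgma merge heights are monotone on simulated distances", {
  cfg <- sim_config(seed = 13)
  mb <- simulate_microbiome(cfg)
  res <- upgma(bray_curtis(mb$counts))
  expect_false(is.unsorted(res$heights))
  # ultrametric: cophenetic distances satisfy the three-point condition
  cp <- res$cophenetic
  ids <- rownames(cp)[1:6]
  for (i in ids) for (j in ids) for (k in ids)
    expect_lte(cp[i, j], max(cp[i, k], cp[j, k]) + 1e-12)
})

test_that("venn decomposition matches a power-set oracle", {
  set.seed(8)
  tab <- matrix(rbinom(6 * 30, 3, 0.3), 6, 30,
                dimnames = list(paste0("s", 1:6), paste0("f", 1:30)))
  tab[, 1] <- pmax(tab[, 1], 1)  # avoid empty samples
  tab <- otu_table(tab)
  groups <- setNames(rep(c("g1", "g2", "g3"), each = 2), rownames(tab))
  res <- core_and_exclusive(tab, groups)
  # oracle: recompute presence per group by brute force
  for (f in colnames(tab)) {
    in_g <- sapply(c("g1", "g2", "g3"), function(g)
      any(tab[groups == g, f] > 0))
    expect_identical(unname(res$presence[f, ]), unname(in_g))
  }
  oracle_core <- colnames(tab)[apply(res$presence, 1, all)]
  expect_identical(res$core, oracle_core)
  expect_equal(sum(res$regions$n_otus), ncol(tab))
  for (g in c("g1", "g2", "g3")) {
    excl <- sum(res$presence[, g] & rowSums(res$presence) == 1)
    expect_equal(unname(res$exclusive[g]), excl)
  }
})

test_that("taxonomy aggregation pools unclassified lineages by deepest rank", {
  tax <- data.frame(
    feature_id = c("f1", "f2", "f3"),
    lineage = c("d;pA;cA;oA;fA;gA;sA",
                "d;pA;cA;;;;",
                "d;pB;;;;;"),
    stringsAsFactors = FALSE
  )
  tax <- parse_taxonomy(tax)
  tab <- otu_table(matrix(c(1, 2, 3, 4, 5, 6), 2, 3,
                          dimnames = list(c("s1", "s2"),
                                          c("f1", "f2", "f3"))))
  agg <- aggregate_taxa(tab, tax, "genus")
  expect_setequal(colnames(agg),
                  c("gA", "unclassified_cA", "unclassified_pB"))
  expect_equal(rowSums(agg), rowSums(tab))
  expect_equal(agg[, "gA"], c(s1 = 1, s2 = 2))
})

test_that("dominant taxa pass a strict mean relative abundance cut", {
  tax <- parse_taxonomy(data.frame(
    feature_id = c("f1", "f2", "f3"),
    lineage = c("d;pA;;;;;", "d;pB;;;;;", "d;pB;;;;;")))
  tab <- otu_table(matrix(c(99, 1, 0,
                            97, 2, 1), 2, 3, byrow = TRUE,
                          dimnames = list(c("s1", "s2"),
                                          c("f1", "f2", "f3"))))
  dom <- dominant_taxa(tab, tax, rank = "phylum", threshold = 0.01)
  expect_identical(dom$taxon, c("pA", "pB"))
  dom5 <- dominant_taxa(tab, tax, rank = "phylum", threshold = 0.05)
  expect_identical(dom5$taxon, "pA")
})

test_that("rarefaction preserves sample ids and hits the target depth", {
  tab <- toy_otu()
  r <- rarefy_table(tab, depth = 10, seed = 99)
  expect_equal(dimnames(r), dimnames(tab))
  expect_true(all(rowSums(r) == pmin(10, rowSums(tab))))
  expect_true(all(r <= tab))
})

test_that("otu tsv round-trips through disk byte-identically", {
  tab <- toy_otu()
  p <- tempfile(fileext = ".tsv")
  write_otu_tsv(tab, p)
  back <- read_otu_tsv(p)
  expect_equal(back, tab)
})
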