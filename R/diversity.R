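# OTU-table model: validation, taxonomy aggregation, alpha diversity,
# distance matrices (Bray-Curtis, unweighted UniFrac), UPGMA, Venn
# core/exclusive decomposition.

#' Validate an OTU count table
#'
#' @param counts samples x features matrix of non-negative counts with
#'   unique row (sample) and column (feature) names; every row sum must
#'   be positive.
#' @return the validated numeric matrix.
#' @export
otu_table <- function(counts) {
  counts <- as.matrix(counts)
  if (!is.numeric(counts)) stop("counts must be numeric")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry sample (row) and feature (column) names")
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts)))
    stop("sample and feature ids must be unique")
  if (any(rowSums(counts) <= 0)) stop("every sample's total must be > 0")
  counts
}

#' Aggregate an OTU table to a taxonomic rank
#'
#' Sums feature counts into taxa at the requested rank. Features without
#' an assignment at that rank are pooled under
#' `unclassified_<deepest assigned name>` (or `"unclassified"` when the
#' whole lineage is empty), so partially classified lineages stay
#' distinguishable.
#'
#' @param table OTU table (samples x features).
#' @param taxonomy data.frame with `feature_id` and rank columns
#'   (`domain` ... `species`).
#' @param rank rank to aggregate to.
#' @return samples x taxa matrix.
#' @export
aggregate_taxa <- function(table, taxonomy, rank = "genus") {
  lab <- taxon_labels(taxonomy, rank)
  feats <- colnames(table)
  if (!all(feats %in% names(lab)))
    stop("taxonomy does not cover feature(s): ",
         paste(utils::head(setdiff(feats, names(lab)), 3), collapse = ", "))
  grp <- lab[feats]
  t(rowsum(t(table), group = grp))
}

#' Per-feature taxon labels at a rank
#'
#' Returns one label per feature at the requested rank; features with a
#' blank or missing entry get `unclassified_<deepest named ancestor>`
#' (or `unclassified` when the whole lineage is empty), matching the
#' grouping used by [aggregate_taxa()].
#'
#' @param taxonomy data.frame with `feature_id` and rank columns.
#' @param rank rank to label at.
#' @return named character vector (names are feature ids).
#' @export
taxon_labels <- function(taxonomy, rank = "genus") {
  ranks <- rank_names()
  if (!rank %in% ranks) stop("unknown rank: ", rank)
  if (!all(c("feature_id", rank) %in% names(taxonomy)))
    stop("taxonomy must have feature_id and rank columns")
  upto <- ranks[seq_len(match(rank, ranks))]
  lab <- as.character(taxonomy[[rank]])
  blank <- is.na(lab) | lab == ""
  if (any(blank)) {
    deepest <- apply(taxonomy[blank, upto, drop = FALSE], 1, function(r) {
      r <- r[!is.na(r) & r != ""]
      if (length(r)) paste0("unclassified_", r[length(r)]) else "unclassified"
    })
    lab[blank] <- deepest
  }
  stats::setNames(lab, taxonomy$feature_id)
}

#' Parse semicolon-delimited lineages into rank columns
#'
#' @param taxonomy data.frame with `feature_id` and `lineage`
#'   (seven-rank, semicolon-delimited).
#' @return data.frame with `feature_id` plus the seven rank columns.
#' @export
parse_taxonomy <- function(taxonomy) {
  stopifnot(all(c("feature_id", "lineage") %in% names(taxonomy)))
  parts <- strsplit(as.character(taxonomy$lineage), ";", fixed = TRUE)
  mat <- t(vapply(parts, function(p) {
    p <- trimws(p)
    length(p) <- 7
    p
  }, character(7)))
  colnames(mat) <- rank_names()
  mat[mat == "" | is.na(mat)] <- NA_character_
  cbind(data.frame(feature_id = taxonomy$feature_id,
                   stringsAsFactors = FALSE),
        as.data.frame(mat, stringsAsFactors = FALSE))
}

#' Single-sample alpha-diversity indices
#'
#' `chao1_index` is the bias-corrected Chao1 richness estimator
#' S_obs + F1(F1-1)/(2(F2+1)); `shannon_index` is -sum p ln p over
#' positive counts (natural log); `goods_coverage_index` is 1 - F1/N,
#' the estimated fraction of reads from already-seen taxa.
#'
#' @param x numeric count vector for one sample.
#' @return a single number.
#' @export
chao1_index <- function(x) {
  s_obs <- sum(x > 0)
  f1 <- sum(x == 1); f2 <- sum(x == 2)
  s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' @rdname chao1_index
#' @export
shannon_index <- function(x) {
  p <- x[x > 0] / sum(x)
  -sum(p * log(p))
}

#' @rdname chao1_index
#' @export
goods_coverage_index <- function(x) 1 - sum(x == 1) / sum(x)

#' Per-sample alpha diversity
#'
#' Supported metrics: bias-corrected `chao1`
#' (S_obs + F1(F1-1)/(2(F2+1)), finite even without doubletons),
#' `shannon` (-sum p ln p, natural log), `goods_coverage` (1 - F1/N) and
#' `faith_pd` (total branch length of the subtree spanning a sample's
#' observed OTUs and the root; requires `tree`).
#'
#' @param table OTU table (samples x features).
#' @param metrics subset of the four metric names.
#' @param tree rooted `phylo` over the features; needed for `faith_pd`.
#'   Unrooted trees are midpoint rooted.
#' @return data.frame, one row per sample.
#' @export
alpha_diversity <- function(table,
                            metrics = c("chao1", "shannon", "goods_coverage"),
                            tree = NULL) {
  table <- otu_table(table)
  metrics <- match.arg(metrics,
                       c("chao1", "shannon", "goods_coverage", "faith_pd"),
                       several.ok = TRUE)
  out <- data.frame(sample_id = rownames(table), stringsAsFactors = FALSE)
  if ("chao1" %in% metrics) out$chao1 <- apply(table, 1, chao1_index)
  if ("shannon" %in% metrics) out$shannon <- apply(table, 1, shannon_index)
  if ("goods_coverage" %in% metrics)
    out$goods_coverage <- apply(table, 1, goods_coverage_index)
  if ("faith_pd" %in% metrics) {
    if (is.null(tree)) stop("faith_pd requires a phylogenetic tree")
    tree <- root_tree(tree)
    miss <- setdiff(colnames(table), tree$tip.label)
    if (length(miss))
      stop("tree is missing leaf for feature(s): ",
           paste(utils::head(miss, 3), collapse = ", "))
    pdres <- picante::pd(table[, tree$tip.label, drop = FALSE], tree,
                         include.root = TRUE)
    out$faith_pd <- pdres$PD[match(rownames(table), rownames(pdres))]
  }
  rownames(out) <- out$sample_id
  out
}

#' Validate and root a phylogenetic tree
#'
#' Checks for finite non-negative branch lengths and midpoint-roots
#' unrooted trees (the rooted form is required by unweighted UniFrac and
#' Faith's PD).
#'
#' @param tree a `phylo` object.
#' @return a rooted `phylo`.
#' @export
root_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("tree must be a 'phylo' object")
  if (is.null(tree$edge.length) || any(!is.finite(tree$edge.length)) ||
      any(tree$edge.length < 0))
    stop("tree must have finite non-negative branch lengths")
  if (!ape::is.rooted(tree)) tree <- phangorn::midpoint(tree)
  tree
}

check_distance <- function(d) {
  d <- as.matrix(d)
  stopifnot(isSymmetric(unname(d)), all(diag(d) == 0), all(d >= 0))
  d
}

#' Bray-Curtis dissimilarity matrix
#'
#' d(x, y) = 1 - 2 sum_i min(x_i, y_i) / (sum x + sum y), computed with
#' `vegan::vegdist`.
#'
#' @param table OTU table (samples x features).
#' @return symmetric samples x samples matrix in [0, 1].
#' @export
bray_curtis <- function(table) {
  table <- otu_table(table)
  check_distance(as.matrix(vegan::vegdist(table, method = "bray")))
}

# per-edge clade presence: for every edge of the rooted tree, whether any
# descendant tip of that edge is present (count > 0) in each sample
edge_presence <- function(table, tree) {
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  pres <- matrix(FALSE, nnode, nrow(table))
  pres[seq_len(ntip), ] <- t(table[, tree$tip.label, drop = FALSE] > 0)
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1]; child <- tree$edge[e, 2]
    pres[par, ] <- pres[par, ] | pres[child, ]
  }
  list(tree = tree, node_presence = pres)
}

#' Unweighted UniFrac distance matrix
#'
#' Presence-absence phylogenetic beta diversity: for a pair of samples,
#' the branch length leading only to leaves observed in exactly one of
#' them, divided by the branch length leading to leaves observed in
#' either. Counts beyond presence (count > 0) do not matter. Unrooted
#' trees are midpoint rooted first.
#'
#' @param table OTU table (samples x features).
#' @param tree `phylo` whose tips cover all features.
#' @return symmetric samples x samples matrix in [0, 1].
#' @export
unweighted_unifrac <- function(table, tree) {
  table <- otu_table(table)
  tree <- root_tree(tree)
  miss <- setdiff(colnames(table), tree$tip.label)
  if (length(miss))
    stop("tree is missing leaf for feature(s): ",
         paste(utils::head(miss, 3), collapse = ", "))
  ep <- edge_presence(table, tree)
  bl <- ep$tree$edge.length
  P <- ep$node_presence[ep$tree$edge[, 2], , drop = FALSE]  # edges x samples
  n <- nrow(table)
  d <- matrix(0, n, n, dimnames = list(rownames(table), rownames(table)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    union_len <- sum(bl[P[, i] | P[, j]])
    if (union_len == 0)
      stop("samples ", rownames(table)[i], " and ", rownames(table)[j],
           " share no tree branch length (both empty?)")
    d[i, j] <- d[j, i] <- sum(bl[xor(P[, i], P[, j])]) / union_len
  }
  check_distance(d)
}

#' UPGMA (average-linkage) clustering of a distance matrix
#'
#' Agglomerates samples by unweighted average linkage, yielding an
#' ultrametric dendrogram with non-decreasing merge heights. Samples are
#' put in lexicographic order before clustering so ties merge the
#' lexicographically smallest pair first.
#'
#' @param dist symmetric distance matrix with labels.
#' @return list with `hclust`, `newick` (string), `heights`, and the
#'   ultrametric `cophenetic` matrix.
#' @export
upgma <- function(dist) {
  d <- check_distance(dist)
  if (nrow(d) < 2) stop("need at least 2 samples")
  ord <- order(rownames(d))
  d <- d[ord, ord]
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  list(hclust = hc,
       newick = ape::write.tree(ape::as.phylo(hc)),
       heights = hc$height,
       cophenetic = as.matrix(stats::cophenetic(hc)))
}

#' Core and exclusive OTUs across sample groups (Venn decomposition)
#'
#' An OTU belongs to a group when it has a positive count in at least one
#' of the group's samples. Returns the OTUs shared by every group (the
#' core microbiome), the count exclusive to each group, and the full
#' 2^k - 1 region decomposition.
#'
#' @param table OTU table (samples x features).
#' @param groups named character/factor mapping every sample to a group.
#' @return list with `core` (feature ids), `core_count`, `exclusive`
#'   (named counts), `regions` (data.frame pattern -> count), and the
#'   per-group presence matrix.
#' @export
core_and_exclusive <- function(table, groups) {
  table <- otu_table(table)
  groups <- stats::setNames(as.character(groups), names(groups))
  if (is.null(names(groups)) || !all(rownames(table) %in% names(groups)))
    stop("groups must be named and cover every sample")
  groups <- groups[rownames(table)]
  lev <- sort(unique(groups))
  pres <- vapply(lev, function(g)
    colSums(table[groups == g, , drop = FALSE] > 0) > 0,
    logical(ncol(table)))
  if (any(colSums(pres) == 0) || length(lev) < 1)
    stop("empty group in the mapping")
  if (any(tabulate(factor(groups, lev)) == 0)) stop("empty group")
  pattern <- apply(pres, 1, function(r) paste(lev[r], collapse = "&"))
  pattern[pattern == ""] <- "(absent)"
  regions <- as.data.frame(table(pattern), stringsAsFactors = FALSE)
  names(regions) <- c("region", "n_otus")
  core <- rownames(pres)[rowSums(pres) == length(lev)]
  exclusive <- vapply(lev, function(g)
    sum(pres[, g] & rowSums(pres) == 1), integer(1))
  list(core = core, core_count = length(core), exclusive = exclusive,
       regions = regions, presence = pres)
}

#' Dominant taxa by mean relative abundance
#'
#' Aggregates to `rank` and reports taxa whose mean relative abundance
#' across samples strictly exceeds `threshold` (1 percent by default).
#'
#' @param table OTU table.
#' @param taxonomy taxonomy table.
#' @param rank taxonomic rank.
#' @param threshold strict lower bound on mean relative abundance.
#' @return data.frame `taxon`, `mean_rel_abundance`, sorted descending.
#' @export
dominant_taxa <- function(table, taxonomy, rank = "phylum",
                          threshold = 0.01) {
  agg <- aggregate_taxa(otu_table(table), taxonomy, rank)
  rel <- agg / rowSums(agg)
  m <- colMeans(rel)
  keep <- m > threshold
  out <- data.frame(taxon = names(m)[keep],
                    mean_rel_abundance = unname(m[keep]),
                    stringsAsFactors = FALSE)
  out[order(-out$mean_rel_abundance, out$taxon), , drop = FALSE]
}

#' Rarefy an OTU table to even depth
#'
#' Optional pre-processing (off by default throughout the package):
#' subsamples each sample without replacement to `depth` reads (the
#' minimum library size when `NULL`).
#'
#' @param table OTU table.
#' @param depth target depth.
#' @param seed RNG seed.
#' @return rarefied integer matrix.
#' @export
rarefy_table <- function(table, depth = NULL, seed = NULL) {
  table <- otu_table(table)
  if (is.null(depth)) depth <- min(rowSums(table))
  if (!is.null(seed)) set.seed(seed)
  t(apply(table, 1, function(x) {
    reads <- rep(seq_along(x), x)
    take <- sample(reads, min(depth, length(reads)))
    tabulate(take, nbins = length(x))
  })) -> out
  dimnames(out) <- dimnames(table)
  out
}
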