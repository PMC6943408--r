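# Co-occurrence networks: top-genus selection, thresholded Spearman
# edge construction, and the topology metrics used to characterize
# microbial association structure.

#' Select the most abundant taxa for network construction
#'
#' Aggregates to `rank` (unclassified lineages pooled under their
#' deepest assigned name) and keeps the `n` taxa with the largest total
#' abundance, ties broken lexicographically. Returns everything with a
#' message when fewer than `n` taxa exist.
#'
#' @param table OTU table.
#' @param taxonomy taxonomy table; `NULL` when `table` is already at the
#'   desired rank.
#' @param rank taxonomic rank to aggregate to.
#' @param n number of taxa to keep.
#' @return samples x taxa abundance matrix.
#' @export
select_top_features <- function(table, taxonomy = NULL, rank = "genus",
                                n = 50) {
  table <- otu_table(table)
  agg <- if (is.null(taxonomy)) table else aggregate_taxa(table, taxonomy, rank)
  if (ncol(agg) < n) {
    message("only ", ncol(agg), " taxa available (requested ", n,
            "); returning all")
    n <- ncol(agg)
  }
  ord <- order(-colSums(agg), colnames(agg))
  agg[, ord[seq_len(n)], drop = FALSE]
}

#' Build a thresholded Spearman co-occurrence network
#'
#' Computes all pairwise Spearman correlations among taxa and keeps an
#' undirected edge when p <= `p_cut` and |rho| > `rho_cut`, recording
#' the sign. Constant taxa are excluded with a warning. P-values follow
#' [spearman_test()] (exact for n <= 10 without ties, t approximation
#' otherwise).
#'
#' @param abundances samples x taxa matrix (e.g. from
#'   [select_top_features()]).
#' @param rho_cut absolute correlation threshold in (0, 1); the field
#'   convention is 0.6 for bacteria and 0.7 for fungi.
#' @param p_cut significance threshold.
#' @param phylum optional named taxon -> phylum vector for node
#'   attributes.
#' @return list of class `co_network` with `nodes` (taxon, phylum,
#'   mean_abundance), `edges` (source, target, rho, p, sign), and the
#'   `igraph` object (unsigned skeleton; rho and sign kept as edge
#'   attributes).
#' @export
build_network <- function(abundances, rho_cut = 0.6, p_cut = 0.01,
                          phylum = NULL) {
  x <- as.matrix(abundances)
  if (nrow(x) < 4) stop("need at least 4 samples")
  if (rho_cut <= 0 || rho_cut >= 1) stop("rho_cut must be in (0, 1)")
  const <- apply(x, 2, function(v) stats::sd(v) == 0)
  if (any(const)) {
    warning("excluding constant taxa: ",
            paste(colnames(x)[const], collapse = ", "))
    x <- x[, !const, drop = FALSE]
  }
  taxa <- colnames(x)
  k <- length(taxa)
  edges <- list(); e <- 0L
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    st <- spearman_test(x[, i], x[, j])
    if (!is.na(st$rho) && st$p <= p_cut && abs(st$rho) > rho_cut) {
      e <- e + 1L
      edges[[e]] <- data.frame(source = taxa[i], target = taxa[j],
                               rho = st$rho, p = st$p,
                               sign = if (st$rho > 0) "positive" else "negative",
                               stringsAsFactors = FALSE)
    }
  }
  edges <- if (e) do.call(rbind, edges) else
    data.frame(source = character(), target = character(), rho = numeric(),
               p = numeric(), sign = character(), stringsAsFactors = FALSE)
  nodes <- data.frame(taxon = taxa,
                      phylum = if (is.null(phylum)) NA_character_
                               else unname(phylum[taxa]),
                      mean_abundance = colMeans(x),
                      stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes)
  structure(list(nodes = nodes, edges = edges, graph = g,
                 rho_cut = rho_cut, p_cut = p_cut),
            class = "co_network")
}

#' @export
print.co_network <- function(x, ...) {
  cat("co-occurrence network: ", nrow(x$nodes), " nodes, ",
      nrow(x$edges), " edges (", sum(x$edges$sign == "positive"),
      " positive, ", sum(x$edges$sign == "negative"),
      " negative) at |rho| > ", x$rho_cut, ", p <= ", x$p_cut, "\n",
      sep = "")
  invisible(x)
}

#' Topology metrics of a co-occurrence network
#'
#' On the unsigned, unweighted skeleton: average shortest path length
#' and diameter on the largest connected component; global transitivity
#' (3 x triangles / connected triples); modularity and module membership
#' from greedy modularity maximization; per-node degree, betweenness and
#' closeness centrality; modules with more than `major_module_min` nodes
#' labelled major; and the `keystone_k` top-betweenness taxa (ties by
#' degree, then name) as keystone candidates.
#'
#' @param net a `co_network` from [build_network()]; must have >= 1 edge.
#' @param major_module_min a module is "major" when it has more than
#'   this many nodes.
#' @param keystone_k how many keystone taxa to report.
#' @return list with `average_path_length`, `diameter`, `transitivity`,
#'   `modularity`, `n_major_modules`, `modules` (named membership),
#'   `module_sizes`, `node_metrics` (degree/betweenness/closeness),
#'   `keystone_taxa`, `largest_component_size`, `n_components`.
#' @export
network_metrics <- function(net, major_module_min = 10, keystone_k = 3) {
  stopifnot(inherits(net, "co_network"))
  g <- net$graph
  if (igraph::ecount(g) == 0)
    stop("network has no edges; topology metrics are undefined")
  comp <- igraph::components(g)
  lcc_ids <- which(comp$membership == which.max(comp$csize))
  lcc <- igraph::induced_subgraph(g, lcc_ids)
  apl <- igraph::mean_distance(lcc, directed = FALSE, weights = NA)
  diam <- igraph::diameter(lcc, directed = FALSE, weights = NA)
  trans <- igraph::transitivity(g, type = "global")
  if (is.nan(trans)) trans <- 0
  cm <- igraph::cluster_fast_greedy(g, weights = NULL)
  membership <- igraph::membership(cm)
  msizes <- as.integer(table(membership))
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, directed = FALSE, weights = NA)
  cls <- suppressWarnings(igraph::closeness(g, weights = NA))
  node_metrics <- data.frame(taxon = igraph::V(g)$name,
                             degree = unname(deg),
                             betweenness = unname(btw),
                             closeness = unname(cls),
                             module = unname(as.integer(membership)),
                             stringsAsFactors = FALSE)
  ord <- order(-node_metrics$betweenness, -node_metrics$degree,
               node_metrics$taxon)
  keystone <- node_metrics$taxon[ord[seq_len(min(keystone_k,
                                                 nrow(node_metrics)))]]
  list(average_path_length = apl,
       diameter = diam,
       transitivity = trans,
       modularity = igraph::modularity(cm),
       n_major_modules = sum(msizes > major_module_min),
       modules = stats::setNames(as.integer(membership),
                                 igraph::V(g)$name),
       module_sizes = sort(msizes, decreasing = TRUE),
       node_metrics = node_metrics,
       keystone_taxa = keystone,
       largest_component_size = max(comp$csize),
       n_components = comp$no)
}

#' Export a co-occurrence network as GraphML
#'
#' @param net a `co_network`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(net, path) {
  stopifnot(inherits(net, "co_network"))
  igraph::write_graph(net$graph, path, format = "graphml")
  invisible(path)
}
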