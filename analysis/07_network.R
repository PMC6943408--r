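#!/usr/bin/env Rscript
# Genus co-occurrence network: Spearman edges among the top-50 genera
# (|rho| > 0.6, p <= 0.01), global topology metrics, modules and
# betweenness keystones, and a GraphML export.

source("analysis/00_common.R")

counts <- read_otu_tsv(file.path(data_dir, "otu_table.tsv"))
tax <- read_taxonomy_tsv(file.path(data_dir, "taxonomy.tsv"))

genus <- select_top_features(counts, tax, "genus", 50)
tl <- taxon_labels(tax, "genus")
phyl <- tapply(tax$phylum, tl[tax$feature_id], function(x) x[1])
net <- build_network(genus, rho_cut = 0.6, p_cut = 0.01, phylum = phyl)
met <- network_metrics(net)

write_tsv(net$edges, file.path(table_dir, "network_edges.tsv"))
write_tsv(met$node_metrics, file.path(table_dir, "network_nodes.tsv"))
write_graphml(net, file.path(table_dir, "network.graphml"))

cat(sprintf("%d nodes, %d edges (%d positive / %d negative)\n",
            nrow(met$node_metrics), nrow(net$edges),
            sum(net$edges$sign == "positive"),
            sum(net$edges$sign == "negative")))
cat(sprintf(
  "modularity %.3f (%d major modules); APL %.3f; keystones: %s\n",
  met$modularity, met$n_major_modules, met$average_path_length,
  paste(met$keystone_taxa, collapse = ", ")))
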