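#!/usr/bin/env Rscript
# Community diversity: alpha metrics (Chao1, Shannon, Good's coverage,
# Faith PD), Bray-Curtis and unweighted UniFrac distances, NMDS,
# UPGMA sample clustering, core/exclusive OTU partition, and the
# dominant phyla.

source("analysis/00_common.R")

counts <- read_otu_tsv(file.path(data_dir, "otu_table.tsv"))
tax <- read_taxonomy_tsv(file.path(data_dir, "taxonomy.tsv"))
meta <- read_tsv(file.path(data_dir, "metadata.tsv"))
tree <- ape::read.tree(file.path(data_dir, "tree.nwk"))

alpha <- alpha_diversity(counts, c("chao1", "shannon", "goods_coverage",
                                   "faith_pd"), tree = tree)
bc <- bray_curtis(counts)
uf <- unweighted_unifrac(counts, tree)
nm <- nmds(uf, dims = 2, restarts = 10, seed = analysis_seed)
up <- upgma(uf)
groups <- stats::setNames(paste(meta$moss_species, meta$desert_class,
                                sep = "-"), meta$sample_id)
venn <- core_and_exclusive(counts, groups)
dom <- dominant_taxa(counts, tax, "phylum")

write_tsv(alpha, file.path(table_dir, "alpha_diversity.tsv"))
write_distance_tsv(bc, file.path(table_dir, "bray_curtis.tsv"))
write_distance_tsv(uf, file.path(table_dir, "unifrac.tsv"))
write_tsv(data.frame(sample_id = rownames(nm$points), nm$points,
                     check.names = FALSE),
          file.path(table_dir, "nmds_points.tsv"))
writeLines(up$newick, file.path(table_dir, "upgma.nwk"))
write_tsv(dom, file.path(table_dir, "dominant_phyla.tsv"))

cat(sprintf("mean Chao1 %.2f, Shannon %.3f, Good's coverage %.4f\n",
            mean(alpha$chao1), mean(alpha$shannon),
            mean(alpha$goods_coverage)))
cat(sprintf("NMDS stress %.4f; core OTUs %d\n", nm$stress, venn$core_count))
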