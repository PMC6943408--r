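#!/usr/bin/env Rscript
# Hypothesis tests: ANOVA on the physiological covariates, PERMANOVA on
# Bray-Curtis, LEfSe biomarker discovery, DCA gradient-length selection
# of the constrained ordination (RDA or CCA), and the genus-covariate
# Spearman heatmap.

source("analysis/00_common.R")

counts <- read_otu_tsv(file.path(data_dir, "otu_table.tsv"))
tax <- read_taxonomy_tsv(file.path(data_dir, "taxonomy.tsv"))
meta <- read_tsv(file.path(data_dir, "metadata.tsv"))

bc <- bray_curtis(counts)
perm <- permanova(bc, ~ moss_species * desert_class, meta,
                  n_perm = 999, seed = analysis_seed)
anova_tab <- do.call(rbind, lapply(c("SOD", "Pro", "POD", "MP", "MDA"),
  function(v) {
    a <- one_way_anova(meta[[v]], meta$moss_species)
    data.frame(index = v, F = a$F, p = a$p, stringsAsFactors = FALSE)
  }))
lef <- lefse(counts, tax, stats::setNames(meta$moss_species,
                                          meta$sample_id),
             seed = analysis_seed)
sel <- gradient_length_select(counts)
covs <- meta[, c("SOD", "Pro", "POD", "MP", "MDA", "rain", "TEM", "sun",
                 "elevation")]
ord <- constrained_ordination(counts, covs, method = sel$method,
                              n_perm = 999, seed = analysis_seed)
genus <- select_top_features(counts, tax, "genus", 50)
hm <- factor_taxon_heatmap(genus, covs[, c("SOD", "Pro", "POD", "MP",
                                           "MDA")])

write_tsv(perm, file.path(table_dir, "permanova.tsv"))
write_tsv(anova_tab, file.path(table_dir, "anova.tsv"))
write_tsv(lef, file.path(table_dir, "biomarkers.tsv"))
write_tsv(ord$covariates, file.path(table_dir, "ordination_covariates.tsv"))
write_tsv(data.frame(taxon = rownames(hm$rho), hm$rho, check.names = FALSE),
          file.path(table_dir, "heatmap_rho.tsv"))

cat("PERMANOVA:\n"); print(perm, row.names = FALSE)
cat(sprintf("DCA axis-1 length %.2f -> %s; %d LEfSe biomarkers\n",
            sel$axis1_length, sel$method, nrow(lef)))
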