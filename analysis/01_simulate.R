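#!/usr/bin/env Rscript
# Simulate the full synthetic study and write the raw inputs that the
# downstream drivers consume: the quadrat survey, the physiological
# assay values, the OTU table with taxonomy, metadata and phylogeny,
# and the guild annotation rules.

source("analysis/00_common.R")

sv <- simulate_survey(analysis_cfg)
ph <- simulate_physiology(analysis_cfg)
mb <- simulate_microbiome(analysis_cfg)
gr <- simulate_guild_rules(analysis_cfg, mb$taxonomy)

write_tsv(sv$records, file.path(data_dir, "survey.tsv"))
write_tsv(ph$values, file.path(data_dir, "physiology.tsv"))
write_otu_tsv(mb$counts, file.path(data_dir, "otu_table.tsv"))
write_taxonomy_tsv(mb$taxonomy, file.path(data_dir, "taxonomy.tsv"))
write_tsv(mb$metadata, file.path(data_dir, "metadata.tsv"))
ape::write.tree(mb$tree, file.path(data_dir, "tree.nwk"))
write_tsv(gr$rules, file.path(data_dir, "guild_rules.tsv"))

cat("simulated inputs written to", data_dir, "\n")
cat("  survey records:", nrow(sv$records), "\n")
cat("  samples x features:", nrow(mb$counts), "x", ncol(mb$counts), "\n")
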