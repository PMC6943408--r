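#!/usr/bin/env Rscript
# Dominance screening of the quadrat survey: species frequency and the
# three dominance indices (S_N/S, S_N/N_a, N_a/T_a), plus the top-k
# candidate species carried forward to the physiology assays.

source("analysis/00_common.R")

records <- read_tsv(file.path(data_dir, "survey.tsv"))
ds <- survey_dataset(records,
                     total_quadrats = sum(analysis_cfg$quadrats_per_site),
                     total_samples = nrow(records),
                     total_sites = analysis_cfg$n_sites)
tab <- dominance_indices(ds)
summ <- summarize_dominants(tab, top_k = min(20L, nrow(tab)))

write_tsv(tab, file.path(table_dir, "dominance_indices.tsv"))
write_tsv(summ$selection, file.path(table_dir, "dominant_species.tsv"))

cat("dominance table:", nrow(tab), "species\n")
cat(sprintf("top-%d totals: sum(S_N/S) = %.3f, sum(N_a/T_a) = %.3f\n",
            nrow(summ$selection), summ$total_sn_s, summ$total_na_ta))
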