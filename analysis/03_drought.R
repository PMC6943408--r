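#!/usr/bin/env Rscript
# Drought-resistance evaluation: fuzzy membership transform of the five
# physiological indices, comprehensive scores and ranking, grey
# relational grades against the score vector, and the three-way
# resistance classification.

source("analysis/00_common.R")

values <- read_tsv(file.path(data_dir, "physiology.tsv"))
means <- physiology_means(values)
z <- membership_matrix(means, default_directions())
sc <- comprehensive_score(z)
gr <- grey_relational_grades(sc$score[match(rownames(z), sc$species)], z)
cls <- classify_resistance(stats::setNames(sc$score, sc$species))

write_tsv(data.frame(species = rownames(z), z, check.names = FALSE),
          file.path(table_dir, "membership_matrix.tsv"))
write_tsv(cbind(sc, class = cls[sc$species]),
          file.path(table_dir, "drought_scores.tsv"))
write_tsv(gr, file.path(table_dir, "grey_relation.tsv"))

cat("drought ranking (best to worst):\n")
print(cbind(sc, class = cls[sc$species]), row.names = FALSE)
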