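# Shared helpers for the mosscrust test suite.

fixture_path <- function(name) {
  p <- system.file("extdata", name, package = "mosscrust")
  if (!nzchar(p)) p <- file.path("..", "..", "inst", "extdata", name)
  p
}

read_fixture <- function(name) {
  utils::read.table(fixture_path(name), sep = "\t", header = TRUE,
                    check.names = FALSE, stringsAsFactors = FALSE)
}

# Reference dominance indices for the top-20 biocrust bryophytes of a
# 185-quadrat, 14-site karst rocky desertification survey (S = 675
# collected samples).
dominance_reference <- function() read_fixture("dominance_reference.tsv")

# Reference fuzzy-membership matrix (five drought indexes x seven
# candidate mosses) from the same survey's physiology assays.
membership_reference <- function() {
  df <- read_fixture("membership_reference.tsv")
  z <- as.matrix(df[, -1])
  rownames(z) <- df$species
  z
}

# A tiny hand-checkable survey: 2 sites x 3 quadrats, 3 species.
toy_survey <- function() {
  records <- data.frame(
    site_id = c("s1", "s1", "s1", "s1", "s2", "s2", "s2"),
    quadrat_id = c("q1", "q2", "q3", "q1", "q1", "q2", "q2"),
    species_id = c("A", "A", "A", "B", "A", "B", "C"),
    stringsAsFactors = FALSE
  )
  survey_dataset(records, total_quadrats = 6L, total_samples = 10L,
                 total_sites = 2L)
}

# Deterministic small OTU table (4 samples x 5 features).
toy_otu <- function() {
  m <- matrix(c(10, 0, 5, 1, 0,
                8, 2, 0, 3, 1,
                0, 6, 4, 0, 2,
                1, 7, 0, 0, 4),
              nrow = 4, byrow = TRUE,
              dimnames = list(paste0("samp", 1:4), paste0("otu", 1:5)))
  otu_table(m)
}
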