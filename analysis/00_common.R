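# Shared setup for the numbered analysis drivers. Each driver is a thin
# wrapper over the mosscrust package: all computation lives in R/, the
# drivers only wire inputs to outputs. Run them in order from the repo
# root, e.g. `Rscript analysis/01_simulate.R`. Set MOSSCRUST_SEED to
# change the master seed (default 1); every script derives its
# randomness from it, so a fixed seed reproduces every file.

suppressMessages(library(mosscrust))

analysis_seed <- as.integer(Sys.getenv("MOSSCRUST_SEED", "1"))
data_dir <- file.path("results", "data")
table_dir <- file.path("results", "tables")
for (d in c(data_dir, table_dir))
  dir.create(d, recursive = TRUE, showWarnings = FALSE)

# the same config in every driver so totals/truth line up with the
# simulated files written by 01_simulate.R
analysis_cfg <- sim_config(seed = analysis_seed)
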