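#!/usr/bin/env Rscript
# Stage 1: generate the synthetic GWAS summary statistics for the three
# study pairs and write them in the package's TSV dialect, with a JSON
# sidecar recording each scenario's true parameters.

source("analysis/00_config.R")
dir.create(DATA_DIR, recursive = TRUE, showWarnings = FALSE)

for (label in names(STUDY_PAIRS)) {
  cfg <- STUDY_PAIRS[[label]]
  cfg$mr$seed <- pair_seed(label)
  sim <- simulate_mr_dataset(cfg$mr)
  write_tsv(as.data.frame(sim$exposure),
            file.path(DATA_DIR, paste0(label, "_exposure.tsv")))
  write_tsv(as.data.frame(sim$outcome),
            file.path(DATA_DIR, paste0(label, "_outcome.tsv")))
  write_tsv(sim$annotations,
            file.path(DATA_DIR, paste0(label, "_annotations.tsv")))
  truth <- cfg$mr
  class(truth) <- NULL
  jsonlite::write_json(truth,
                       file.path(DATA_DIR, paste0(label, "_scenario.json")),
                       auto_unbox = TRUE, digits = NA)
  cat(sprintf("%s: %d exposure variants, true causal effect %.3f\n",
              label, nrow(sim$exposure), cfg$mr$beta_causal))
}
cat("wrote summary statistics to", DATA_DIR, "\n")
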