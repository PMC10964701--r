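#!/usr/bin/env Rscript
# Stage 2: read each pair's exposure statistics back from disk, select
# instruments by significance thresholding and greedy LD clumping
# (p < 5e-8, r2 < 0.001, 10 Mb window), compute strength statistics, and
# drop instruments annotated to confounder traits.

source("analysis/00_config.R")

rows <- list()
for (label in names(STUDY_PAIRS)) {
  cfg <- STUDY_PAIRS[[label]]
  cfg$mr$seed <- pair_seed(label)
  exposure <- read_summary_stats(
    file.path(DATA_DIR, paste0(label, "_exposure.tsv")),
    trait_type = "binary", trait_label = paste0(label, "_exposure"))
  panel <- simulate_ld_panel(cfg$mr$m_instruments, seed = cfg$mr$seed + 1L)
  ann <- data.table::fread(file.path(DATA_DIR,
                                     paste0(label, "_annotations.tsv")),
                           data.table = FALSE)

  iv <- select_instruments(exposure, panel)
  strength <- instrument_strength(iv)
  filtered <- remove_confounder_snps(iv, ann, DEFAULT_CONFOUNDERS)
  write_tsv(filtered$instruments,
            file.path(RESULTS_DIR, paste0(label, "_instruments.tsv")))
  rows[[label]] <- data.frame(
    pair = label, n_selected = nrow(iv$instruments),
    n_after_confounder_filter = nrow(filtered$instruments),
    total_r2 = strength$total_r2, total_f = strength$total_f,
    min_f = strength$min_f,
    weak_instrument_risk = strength$weak_instrument_risk)
  cat(sprintf("%s: %d instruments (%d after confounder filter), min F = %.0f\n",
              label, nrow(iv$instruments), nrow(filtered$instruments),
              strength$min_f))
}
write_tsv(do.call(rbind, rows),
          file.path(RESULTS_DIR, "instrument_strength.tsv"))
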