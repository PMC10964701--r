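# Shared configuration for the analysis scripts: three synthetic
# exposure-outcome pairs spanning the evidence patterns the framework is
# built to separate. Sourced by every numbered stage so seeds and
# scenario parameters are defined once.

library(triangulateMR)

ANALYSIS_SEED <- 20260925L
RESULTS_DIR <- "results"
DATA_DIR <- file.path(RESULTS_DIR, "data")

# Instrument counts and sample sizes are in the range of consortium-scale
# immune-disease and cancer GWAS (tens of genome-wide-significant loci,
# tens of thousands of samples); each pair also defines the true state of
# the LDSC and colocalization tracks.
STUDY_PAIRS <- list(
  # true causal effect, correlated traits, shared causal variants
  causal_shared = pair_config(
    "causal_shared",
    mr = mr_scenario(m_instruments = 40, beta_causal = 0.15,
                     n_exposure = 30000, n_outcome = 200000,
                     outcome_type = "binary", case_fraction = 0.03),
    ldsc = ldsc_scenario(m_snps = 20000, rg_true = 0.4),
    coloc = coloc_scenario(q_snps = 200, causal_config = "shared"),
    n_coloc_regions = 10),
  # MR signal driven by pleiotropy: no genetic correlation, no shared
  # causal variant (the false-positive pattern)
  mr_only = pair_config(
    "mr_only",
    mr = mr_scenario(m_instruments = 40, beta_causal = 0,
                     pleiotropy_mean = 0.02, pleiotropy_sd = 0.01,
                     n_exposure = 30000, n_outcome = 200000,
                     outcome_type = "binary", case_fraction = 0.03),
    ldsc = ldsc_scenario(m_snps = 20000, rg_true = 0),
    coloc = coloc_scenario(q_snps = 200, causal_config = "distinct"),
    n_coloc_regions = 10),
  # nothing anywhere
  all_null = pair_config(
    "all_null",
    mr = mr_scenario(m_instruments = 40, beta_causal = 0,
                     n_exposure = 30000, n_outcome = 200000,
                     outcome_type = "binary", case_fraction = 0.03),
    ldsc = ldsc_scenario(m_snps = 20000, rg_true = 0),
    coloc = coloc_scenario(q_snps = 200, causal_config = "none"),
    n_coloc_regions = 10)
)

pair_seed <- function(label) {
  ANALYSIS_SEED + match(label, names(STUDY_PAIRS)) * 101L
}
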