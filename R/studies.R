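# Replicate studies over the synthetic scenarios: calibration, recovery,
# pleiotropy diagnostics, directionality, colocalization and LDSC
# operating characteristics. These back the analysis scripts and the
# package's own verification suite.

sim_pairs_for <- function(scenario) {
  sim <- simulate_mr_dataset(scenario)
  harmonized_kept(harmonize_pair(sim$exposure, sim$outcome))
}

#' Type-I error of the MR suite under the null
#'
#' Simulates `n_rep` null datasets (no causal effect, no pleiotropy) and
#' reports each estimator's rejection rate at `alpha`, plus the rate at
#' which the MR-PRESSO global test flags pleiotropy.
#'
#' @param n_rep replicates.
#' @param m_instruments,n sample scenario (defaults 30 instruments, 50000
#'   per GWAS).
#' @param alpha nominal level (default 0.05).
#' @param n_boot bootstrap resamples for the median estimators.
#' @param n_sim MR-PRESSO simulations.
#' @param seed integer seed.
#' @return data.frame with method and rejection rate.
#' @export
study_mr_calibration <- function(n_rep = 2000, m_instruments = 30,
                                 n = 50000, alpha = 0.05, n_boot = 300,
                                 n_sim = 300, seed = 1) {
  methods <- c("IVW", "Egger", "WM", "PWM", "RAPS", "PRESSO_global")
  rej <- matrix(FALSE, n_rep, length(methods),
                dimnames = list(NULL, methods))
  for (i in seq_len(n_rep)) {
    sc <- mr_scenario(m_instruments = m_instruments, beta_causal = 0,
                      n_exposure = n, n_outcome = n, seed = seed + i)
    p <- sim_pairs_for(sc)
    rej[i, "IVW"] <- mr_ivw(p)$pvalue < alpha
    rej[i, "Egger"] <- mr_egger(p)$pvalue < alpha
    rej[i, "WM"] <- mr_weighted_median(p, FALSE, n_boot,
                                       seed = seed + i)$pvalue < alpha
    rej[i, "PWM"] <- mr_weighted_median(p, TRUE, n_boot,
                                        seed = seed + i + 1L)$pvalue < alpha
    rej[i, "RAPS"] <- mr_raps(p)$pvalue < alpha
    pres <- suppressWarnings(mr_presso(p, n_sim = n_sim, seed = seed + i))
    rej[i, "PRESSO_global"] <- pres$extras$global_p < 0.05
  }
  data.frame(method = methods, rejection_rate = colMeans(rej),
             n_rep = n_rep, row.names = NULL)
}

#' IVW recovery of a nonzero causal effect
#'
#' @param n_rep replicates.
#' @param beta_causal true effect (default 0.2).
#' @param m_instruments,n scenario sizes (defaults 50 and 50000).
#' @param seed integer seed.
#' @return list: mean_estimate, bias, coverage_95, n_rep.
#' @export
study_ivw_recovery <- function(n_rep = 1000, beta_causal = 0.2,
                               m_instruments = 50, n = 50000, seed = 1) {
  est <- se <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    sc <- mr_scenario(m_instruments = m_instruments,
                      beta_causal = beta_causal, n_exposure = n,
                      n_outcome = n, seed = seed + i)
    fit <- mr_ivw(sim_pairs_for(sc))
    est[i] <- fit$beta; se[i] <- fit$se
  }
  covered <- abs(est - beta_causal) <= Z975 * se
  list(mean_estimate = mean(est), bias = mean(est) - beta_causal,
       coverage_95 = mean(covered), n_rep = n_rep)
}

#' Multivariable MR joint coverage of known conditional effects
#'
#' @param n_rep replicates.
#' @param beta_conditional true conditional effects (default (0.2, -0.1)).
#' @param m_instruments,n scenario sizes.
#' @param seed integer seed.
#' @return list: mean_estimates, joint_coverage_95 (Wald ellipse), n_rep.
#' @export
study_mvmr_recovery <- function(n_rep = 500,
                                beta_conditional = c(0.2, -0.1),
                                m_instruments = 50, n = 50000, seed = 1) {
  K <- length(beta_conditional)
  est <- matrix(NA_real_, n_rep, K)
  inside <- logical(n_rep)
  crit <- stats::qchisq(0.95, K)
  for (i in seq_len(n_rep)) {
    d <- simulate_mvmr_dataset(m_instruments, beta_conditional,
                               n = n, seed = seed + i)
    fits <- mr_mvmr(d$exposures, d$outcome, panel = NULL)
    b <- vapply(fits, `[[`, 0, "beta")
    s <- vapply(fits, `[[`, 0, "se")
    est[i, ] <- b
    # independent-normal Wald ellipse on the conditional estimates
    inside[i] <- sum(((b - beta_conditional) / s)^2) <= crit
  }
  list(mean_estimates = colMeans(est), joint_coverage_95 = mean(inside),
       n_rep = n_rep)
}

#' Mean MR-Egger intercept under directional pleiotropy
#'
#' @param n_rep replicates.
#' @param pleiotropy_mean configured directional pleiotropy (default 0.05).
#' @param m_instruments,n scenario sizes.
#' @param seed integer seed.
#' @return list: mean_intercept, n_rep.
#' @export
study_egger_intercept <- function(n_rep = 500, pleiotropy_mean = 0.05,
                                  m_instruments = 50, n = 50000, seed = 1) {
  ic <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    sc <- mr_scenario(m_instruments = m_instruments, beta_causal = 0.1,
                      pleiotropy_mean = pleiotropy_mean,
                      pleiotropy_sd = 0.01, n_exposure = n, n_outcome = n,
                      seed = seed + i)
    ic[i] <- mr_egger(sim_pairs_for(sc))$extras$egger_intercept
  }
  list(mean_intercept = mean(ic), n_rep = n_rep)
}

#' MR-PRESSO detection of a single injected pleiotropic outlier
#'
#' Each replicate holds `m_clean` clean variants plus one variant whose
#' outcome beta is shifted by `outlier_se_mult` times its SE; reports how
#' often that variant is flagged, and the absolute bias of the raw versus
#' outlier-corrected estimates.
#'
#' @param n_rep replicates.
#' @param m_clean clean instruments (default 30).
#' @param outlier_se_mult pleiotropic shift in outcome-SE units (default 10).
#' @param beta_causal true effect (default 0.1).
#' @param n sample size per GWAS.
#' @param n_sim MR-PRESSO simulations (default 1000).
#' @param seed integer seed.
#' @return list: detection_rate, mean_abs_bias_raw,
#'   mean_abs_bias_corrected, n_rep.
#' @export
study_presso_outlier <- function(n_rep = 200, m_clean = 30,
                                 outlier_se_mult = 10, beta_causal = 0.1,
                                 n = 50000, n_sim = 1000, seed = 1) {
  detected <- logical(n_rep)
  bias_raw <- bias_corr <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    sc <- mr_scenario(m_instruments = m_clean + 1L,
                      beta_causal = beta_causal, n_exposure = n,
                      n_outcome = n, seed = seed + i)
    p <- sim_pairs_for(sc)
    j <- nrow(p)  # deterministic target variant
    p$outcome_beta[j] <- p$outcome_beta[j] +
      outlier_se_mult * p$outcome_se[j]
    fit <- suppressWarnings(mr_presso(p, n_sim = n_sim, seed = seed + i))
    detected[i] <- p$SNP[j] %in% fit$extras$outliers
    bias_raw[i] <- abs(fit$extras$raw_beta - beta_causal)
    bias_corr[i] <- abs(fit$beta - beta_causal)
  }
  list(detection_rate = mean(detected),
       mean_abs_bias_raw = mean(bias_raw),
       mean_abs_bias_corrected = mean(bias_corr), n_rep = n_rep)
}

#' Steiger direction accuracy under forward causation
#'
#' @param n_rep replicates.
#' @param beta_causal true forward effect (default 0.2).
#' @param m_instruments,n scenario sizes.
#' @param seed integer seed.
#' @return list: correct_rate, n_rep.
#' @export
study_steiger_direction <- function(n_rep = 500, beta_causal = 0.2,
                                    m_instruments = 50, n = 50000,
                                    seed = 1) {
  ok <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    sc <- mr_scenario(m_instruments = m_instruments,
                      beta_causal = beta_causal, n_exposure = n,
                      n_outcome = n, seed = seed + i)
    ok[i] <- mr_steiger(sim_pairs_for(sc), n, n)$direction_correct
  }
  list(correct_rate = mean(ok), n_rep = n_rep)
}

#' Colocalization hypothesis recovery rates
#'
#' Simulates `n_rep` regions under a causal configuration and reports how
#' often each posterior hypothesis dominates.
#'
#' @param n_rep replicates.
#' @param causal_config configuration passed to [coloc_scenario()].
#' @param q_snps,causal_effect_size,ld_autocorrelation region parameters.
#' @param seed integer seed.
#' @return list: dominant_rates (named, h0..h4), mean_pph4, n_rep.
#' @export
study_coloc_recovery <- function(n_rep = 100, causal_config = "shared",
                                 q_snps = 200, causal_effect_size = 8,
                                 ld_autocorrelation = 0.9, seed = 1) {
  hyp <- c("pph0", "pph1", "pph2", "pph3", "pph4")
  dominant <- matrix(FALSE, n_rep, 5, dimnames = list(NULL, hyp))
  pph4 <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    sc <- coloc_scenario(q_snps = q_snps, causal_config = causal_config,
                         causal_effect_size = causal_effect_size,
                         ld_autocorrelation = ld_autocorrelation,
                         seed = seed + i)
    reg <- simulate_coloc_region(sc)
    fit <- coloc_region(reg$trait1, reg$trait2)
    post <- unlist(fit[hyp])
    dominant[i, which.max(post)] <- TRUE
    pph4[i] <- fit$pph4
  }
  list(dominant_rates = colMeans(dominant), mean_pph4 = mean(pph4),
       n_rep = n_rep)
}

#' LDSC genetic-correlation recovery
#'
#' @param n_rep replicates.
#' @param rg_true true genetic correlation (default 0.25).
#' @param m_snps regression SNPs (default 20000).
#' @param tolerance recovery half-width (default 0.1).
#' @param n_jackknife_blocks jackknife blocks.
#' @param seed integer seed.
#' @return list: within_tolerance_rate, ci_coverage_95, mean_rg, n_rep.
#' @export
study_ldsc_recovery <- function(n_rep = 100, rg_true = 0.25,
                                m_snps = 20000, tolerance = 0.1,
                                n_jackknife_blocks = 200, seed = 1) {
  rg <- se <- rep(NA_real_, n_rep)
  for (i in seq_len(n_rep)) {
    sc <- ldsc_scenario(m_snps = m_snps, rg_true = rg_true,
                        seed = seed + i)
    d <- simulate_ldsc_dataset(sc)
    fit <- estimate_rg(data.frame(SNP = d$z$SNP, Z = d$z$Z1),
                       data.frame(SNP = d$z$SNP, Z = d$z$Z2),
                       d$scores, n1 = sc$n1, n2 = sc$n2, M = d$M,
                       n_jackknife_blocks = n_jackknife_blocks)
    if (fit$status == "ok") { rg[i] <- fit$rg; se[i] <- fit$rg_se }
  }
  ok <- !is.na(rg)
  list(within_tolerance_rate = mean(abs(rg[ok] - rg_true) <= tolerance),
       ci_coverage_95 = mean(abs(rg[ok] - rg_true) <= Z975 * se[ok]),
       mean_rg = mean(rg[ok]), na_rate = mean(!ok), n_rep = n_rep)
}

#' Mean-PPH4 summary of per-region colocalization posteriors
#'
#' The cross-region aggregation rule in one place: the unweighted mean of
#' per-region PPH4 values and the call against the threshold.
#'
#' @param pph4 numeric vector of per-region PPH4 values.
#' @param threshold call level (default 0.75).
#' @return list: mean_pph4, shared_call.
#' @export
summarize_pph4 <- function(pph4, threshold = 0.75) {
  stopifnot(length(pph4) >= 1, all(pph4 >= 0 & pph4 <= 1))
  m <- mean(pph4)
  list(mean_pph4 = m, shared_call = m > threshold)
}
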