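# Seeded generators for LD panels and GWAS summary statistics under
# controlled causal, pleiotropic, confounded and colocalization scenarios.
# Defaults emulate consortium-scale case-control GWAS: tens of genome-wide
# significant instruments, per-variant standard errors from the standard
# 1/(2*maf*(1-maf)*n) variance approximation (times 1/(cf*(1-cf)) for binary
# traits on the log-odds scale).

#' Simulate a block-diagonal LD reference panel
#'
#' Builds a variant grid with a block-diagonal allelic correlation matrix in
#' which, within a block, r(i, j) = rho^|i-j| (AR(1) decay) and cross-block
#' correlations are zero. Minor-allele frequencies are drawn uniformly from
#' `maf_range`. Variants are placed on one chromosome at 10 kb spacing.
#'
#' @param n_variants total number of variants; must equal the sum of block
#'   lengths when `block_spec` is given.
#' @param block_spec data.frame with columns `length` and `rho` (one row per
#'   block, |rho| < 1), or NULL for independent variants (identity LD).
#' @param maf_range length-2 numeric, MAF bounds within (0, 0.5].
#' @param seed integer seed; the panel is deterministic given it.
#' @param spacing_bp distance between adjacent variants in base pairs.
#' @return an `ld_panel`: list with `variants` (SNP, CHR, POS, MAF, block)
#'   and `R` (correlation matrix).
#' @export
simulate_ld_panel <- function(n_variants, block_spec = NULL,
                              maf_range = c(0.05, 0.5), seed,
                              spacing_bp = 10000L) {
  stopifnot(n_variants >= 1)
  if (is.null(block_spec))
    block_spec <- data.frame(length = rep(1L, n_variants), rho = 0)
  if (any(abs(block_spec$rho) >= 1))
    stop("within-block autocorrelation must lie in (-1, 1)")
  if (sum(block_spec$length) != n_variants)
    stop("block lengths must sum to n_variants")
  set.seed(seed)
  maf <- stats::runif(n_variants, maf_range[1], maf_range[2])
  block <- rep(seq_len(nrow(block_spec)), block_spec$length)
  R <- matrix(0, n_variants, n_variants)
  off <- 0L
  for (b in seq_len(nrow(block_spec))) {
    len <- block_spec$length[b]
    idx <- off + seq_len(len)
    R[idx, idx] <- block_spec$rho[b]^abs(outer(seq_len(len), seq_len(len), "-"))
    off <- off + len
  }
  diag(R) <- 1
  variants <- data.frame(
    SNP = sprintf("rs%06d", seq_len(n_variants)),
    CHR = "1",
    POS = spacing_bp * seq_len(n_variants),
    MAF = maf, block = block,
    stringsAsFactors = FALSE
  )
  structure(list(variants = variants, R = R), class = "ld_panel")
}

#' @export
print.ld_panel <- function(x, ...) {
  cat(sprintf("LD panel: %d variants, %d block(s)\n",
              nrow(x$variants), length(unique(x$variants$block))))
  invisible(x)
}

#' Define a two-sample MR simulation scenario
#'
#' Bundles the true data-generating parameters for a pair of exposure and
#' outcome GWAS. Instrument effects on the exposure are drawn with magnitude
#' uniform in `exposure_effect_scale * [0.5, 1.5]` and random sign, which at
#' the default sample sizes yields per-variant F statistics well above the
#' conventional weak-instrument bound of 10.
#'
#' @param m_instruments number of causal instruments (>= 2).
#' @param beta_causal true causal effect of exposure on outcome.
#' @param exposure_effect_scale typical instrument effect magnitude on the
#'   exposure (default 0.1 log-odds per allele).
#' @param pleiotropy_mean,pleiotropy_sd mean and SD of horizontal pleiotropic
#'   effects on the outcome (directional when the mean is nonzero).
#' @param inside_violation if TRUE pleiotropic effects are correlated with
#'   instrument strength (InSIDE assumption violated).
#' @param confounder_effect effect of a latent confounder on the outcome;
#'   when nonzero, 20% of instruments act through the confounder and are
#'   recorded in the trait-annotation table.
#' @param n_exposure,n_outcome GWAS sample sizes.
#' @param outcome_type `"quantitative"` or `"binary"`.
#' @param case_fraction case proportion for binary outcomes.
#' @param seed integer seed.
#' @return a list of class `mr_scenario`.
#' @export
mr_scenario <- function(m_instruments = 50, beta_causal = 0,
                        exposure_effect_scale = 0.1,
                        pleiotropy_mean = 0, pleiotropy_sd = 0,
                        inside_violation = FALSE, confounder_effect = 0,
                        n_exposure = 50000, n_outcome = 50000,
                        outcome_type = c("quantitative", "binary"),
                        case_fraction = 0.1, seed = 1) {
  outcome_type <- match.arg(outcome_type)
  stopifnot(m_instruments >= 2, n_exposure > 0, n_outcome > 0,
            case_fraction > 0, case_fraction < 1)
  structure(as.list(environment()), class = "mr_scenario")
}

se_approx <- function(maf, n, case_fraction = NULL) {
  v <- 2 * maf * (1 - maf) * n
  if (!is.null(case_fraction)) v <- v * case_fraction * (1 - case_fraction)
  1 / sqrt(v)
}

#' Simulate exposure and outcome GWAS summary statistics for MR
#'
#' Generates instrument-level summary statistics under the scenario's causal
#' structure. Each instrument occupies its own LD block of `panel` (blocks
#' beyond the instrument count carry null variants); marginal effects of a
#' block's non-instrument variants are the LD-propagated instrument effect,
#' so greedy clumping on the panel recovers one variant per block. Exposure
#' betas are drawn around the true instrument effects with the standard
#' summary-statistic sampling variance; outcome betas combine the causal
#' path, horizontal pleiotropy, and an optional latent-confounder path whose
#' instruments are listed in the returned trait-annotation table under
#' adiposity trait names.
#'
#' @param scenario an [mr_scenario()].
#' @param panel optional [simulate_ld_panel()] output with at least
#'   `m_instruments` blocks; by default an identity panel with one variant
#'   per instrument is built from the scenario seed.
#' @return list with `exposure` and `outcome` (`summary_stats`),
#'   `annotations` (data.frame SNP/TRAIT/P/PROXY_R2), `truth` (per-variant
#'   true effects) and `panel`.
#' @export
simulate_mr_dataset <- function(scenario, panel = NULL) {
  s <- scenario
  if (is.null(panel))
    panel <- simulate_ld_panel(s$m_instruments, seed = s$seed + 1L)
  v <- panel$variants
  n_blocks <- length(unique(v$block))
  if (s$m_instruments > n_blocks)
    stop("m_instruments (", s$m_instruments, ") exceeds available LD blocks (",
         n_blocks, ")")
  set.seed(s$seed)
  m <- s$m_instruments
  # instrument = central variant of each of the first m blocks
  iv_idx <- vapply(seq_len(m), function(b) {
    ix <- which(v$block == b); ix[ceiling(length(ix) / 2)]
  }, integer(1))

  gamma <- numeric(nrow(v))
  sign_g <- sample(c(-1, 1), m, replace = TRUE)
  gamma[iv_idx] <- sign_g * s$exposure_effect_scale * stats::runif(m, 0.5, 1.5)

  # latent-confounder path: a subset of instruments act on exposure only via
  # a confounder that also affects the outcome
  conf_snps <- integer(0)
  conf_path <- numeric(nrow(v))
  if (s$confounder_effect != 0) {
    n_conf <- max(1L, round(0.2 * m))
    conf_snps <- iv_idx[sample.int(m, n_conf)]
    conf_path[conf_snps] <- s$confounder_effect * gamma[conf_snps]
  }

  # horizontal pleiotropy on the outcome, optionally correlated with
  # instrument strength (InSIDE violation); "directional" is defined
  # relative to the exposure-increasing allele, so the drawn effect is
  # applied on that orientation (a fixed shift on arbitrary allele coding
  # would cancel over random instrument signs and not be directional)
  alpha <- numeric(nrow(v))
  if (s$pleiotropy_sd > 0 || s$pleiotropy_mean != 0) {
    z <- stats::rnorm(m)
    if (s$inside_violation && stats::sd(gamma[iv_idx]) > 0) {
      g_std <- as.numeric(scale(abs(gamma[iv_idx])))
      z <- 0.6 * g_std + sqrt(1 - 0.36) * z
    }
    alpha[iv_idx] <- sign_g * (s$pleiotropy_mean + s$pleiotropy_sd * z)
  }

  # marginal (LD-propagated) effects across whole blocks
  gamma_marg <- as.numeric(panel$R %*% gamma)
  alpha_marg <- as.numeric(panel$R %*% alpha)
  conf_marg <- as.numeric(panel$R %*% conf_path)

  se_x <- se_approx(v$MAF, s$n_exposure)
  cf <- if (s$outcome_type == "binary") s$case_fraction else NULL
  se_y <- se_approx(v$MAF, s$n_outcome, cf)

  beta_x <- stats::rnorm(nrow(v), gamma_marg, se_x)
  mu_y <- s$beta_causal * gamma_marg + alpha_marg + conf_marg
  beta_y <- stats::rnorm(nrow(v), mu_y, se_y)

  mk <- function(beta, se, n, type, cfr) {
    df <- data.frame(SNP = v$SNP, CHR = v$CHR, POS = v$POS,
                     EA = "A", OA = "G", EAF = v$MAF,
                     BETA = beta, SE = se,
                     P = 2 * stats::pnorm(-abs(beta / se)),
                     N = n, stringsAsFactors = FALSE)
    if (type == "binary") {
      df$N_CASE <- round(n * cfr)
      df$N_CONTROL <- n - round(n * cfr)
    }
    df
  }
  exposure <- as_summary_stats(mk(beta_x, se_x, s$n_exposure,
                                  "quantitative", NULL),
                               trait_label = "exposure", trait_type = "binary")
  outcome <- as_summary_stats(mk(beta_y, se_y, s$n_outcome, s$outcome_type,
                                 s$case_fraction),
                              trait_label = "outcome",
                              trait_type = s$outcome_type)

  annotations <- if (length(conf_snps) > 0) {
    conf_traits <- c("body mass index", "waist circumference",
                     "hip circumference", "smoking", "alcohol consumption")
    data.frame(SNP = v$SNP[conf_snps],
               TRAIT = conf_traits[(seq_along(conf_snps) - 1L) %%
                                     length(conf_traits) + 1L],
               P = stats::runif(length(conf_snps), 1e-12, 1e-9),
               PROXY_R2 = stats::runif(length(conf_snps), 0.8, 1),
               stringsAsFactors = FALSE)
  } else {
    data.frame(SNP = character(0), TRAIT = character(0), P = numeric(0),
               PROXY_R2 = numeric(0))
  }

  list(exposure = exposure, outcome = outcome, annotations = annotations,
       truth = data.frame(SNP = v$SNP, gamma = gamma_marg,
                          alpha = alpha_marg, confounder = conf_marg,
                          is_instrument = seq_len(nrow(v)) %in% iv_idx),
       panel = panel, scenario = s)
}

#' Simulate summary statistics for multivariable MR
#'
#' Two correlated exposures with known conditional effects on the outcome.
#' Each instrument affects both exposures (correlated instrument effects),
#' so univariable estimates are biased while the joint regression recovers
#' the conditional effects.
#'
#' @param m_instruments number of instruments.
#' @param beta_conditional length-2 numeric of true conditional effects.
#' @param effect_cor correlation between the two exposures' instrument
#'   effects.
#' @param n sample size of each GWAS.
#' @param seed integer seed.
#' @return list with `exposures` (list of two `summary_stats`), `outcome`,
#'   and `truth`.
#' @export
simulate_mvmr_dataset <- function(m_instruments = 50,
                                  beta_conditional = c(0.2, -0.1),
                                  effect_cor = 0.3, n = 50000, seed = 1) {
  set.seed(seed)
  m <- m_instruments
  maf <- stats::runif(m, 0.05, 0.5)
  g1 <- sample(c(-1, 1), m, TRUE) * 0.1 * stats::runif(m, 0.5, 1.5)
  g2 <- effect_cor * g1 +
    sqrt(1 - effect_cor^2) * sample(c(-1, 1), m, TRUE) * 0.1 *
      stats::runif(m, 0.5, 1.5)
  se_x <- se_approx(maf, n)
  se_y <- se_approx(maf, n)
  bx1 <- stats::rnorm(m, g1, se_x)
  bx2 <- stats::rnorm(m, g2, se_x)
  by <- stats::rnorm(m, beta_conditional[1] * g1 + beta_conditional[2] * g2,
                     se_y)
  snp <- sprintf("rs%06d", seq_len(m))
  mk <- function(beta, se, lab) {
    as_summary_stats(data.frame(SNP = snp, CHR = "1", POS = 10000 * seq_len(m),
                                EA = "A", OA = "G", EAF = maf, BETA = beta,
                                SE = se, P = 2 * stats::pnorm(-abs(beta / se)),
                                N = n, stringsAsFactors = FALSE),
                     trait_label = lab)
  }
  list(exposures = list(mk(bx1, se_x, "exposure1"), mk(bx2, se_x, "exposure2")),
       outcome = mk(by, se_y, "outcome"),
       truth = list(beta_conditional = beta_conditional, gamma1 = g1,
                    gamma2 = g2))
}

#' Define a colocalization simulation scenario
#'
#' @param q_snps variants in the region (>= 3); split into two equal LD
#'   blocks so `distinct` configurations can place the two causal variants
#'   in uncorrelated blocks.
#' @param causal_config one of `none`, `trait1_only`, `trait2_only`,
#'   `distinct`, `shared` (mirrors hypotheses H0-H4).
#' @param causal_effect_size expected marginal z-score at the causal variant.
#' @param n1,n2 per-trait sample sizes (set the beta/se scale).
#' @param ld_autocorrelation AR(1) within-block correlation.
#' @param seed integer seed.
#' @return list of class `coloc_scenario`.
#' @export
coloc_scenario <- function(q_snps = 200,
                           causal_config = c("none", "trait1_only",
                                             "trait2_only", "distinct",
                                             "shared"),
                           causal_effect_size = 8, n1 = 50000, n2 = 50000,
                           ld_autocorrelation = 0.9, seed = 1) {
  causal_config <- match.arg(causal_config)
  stopifnot(q_snps >= 3)
  structure(as.list(environment()), class = "coloc_scenario")
}

#' Simulate a colocalization region for two traits
#'
#' Builds marginal z-scores as LD-propagated signals from the configured
#' causal variant(s) plus correlated standard-normal noise (noise covariance
#' equals the LD matrix, as for marginal association z-scores), then converts
#' to beta/se with unit-variance scaling (se = 1/sqrt(n)).
#'
#' @param scenario a [coloc_scenario()].
#' @return list with `trait1`, `trait2` (`summary_stats` restricted to the
#'   region), `panel`, and `truth` (causal configuration and indices).
#' @export
simulate_coloc_region <- function(scenario) {
  s <- scenario
  q <- s$q_snps
  len1 <- ceiling(q / 2)
  panel <- simulate_ld_panel(
    q, block_spec = data.frame(length = c(len1, q - len1),
                               rho = s$ld_autocorrelation),
    seed = s$seed + 1L)
  R <- panel$R
  set.seed(s$seed)
  idx1 <- idx2 <- NA_integer_
  lam1 <- lam2 <- numeric(q)
  mid1 <- ceiling(len1 / 2)
  mid2 <- len1 + ceiling((q - len1) / 2)
  if (s$causal_config %in% c("trait1_only", "distinct", "shared")) {
    idx1 <- mid1; lam1[idx1] <- s$causal_effect_size
  }
  if (s$causal_config == "trait2_only") { idx2 <- mid1; lam2[idx2] <- s$causal_effect_size }
  if (s$causal_config == "shared") { idx2 <- idx1; lam2[idx2] <- s$causal_effect_size }
  if (s$causal_config == "distinct") { idx2 <- mid2; lam2[idx2] <- s$causal_effect_size }

  U <- chol(R + diag(1e-10, q))
  z1 <- as.numeric(R %*% lam1 + t(U) %*% stats::rnorm(q))
  z2 <- as.numeric(R %*% lam2 + t(U) %*% stats::rnorm(q))

  mk <- function(z, n, lab) {
    as_summary_stats(data.frame(
      SNP = panel$variants$SNP, CHR = panel$variants$CHR,
      POS = panel$variants$POS, EA = "A", OA = "G",
      EAF = panel$variants$MAF, BETA = z / sqrt(n), SE = 1 / sqrt(n),
      P = 2 * stats::pnorm(-abs(z)), N = n, stringsAsFactors = FALSE),
      trait_label = lab)
  }
  list(trait1 = mk(z1, s$n1, "trait1"), trait2 = mk(z2, s$n2, "trait2"),
       panel = panel,
       truth = list(config = s$causal_config, idx1 = idx1, idx2 = idx2))
}

#' Define an LD-score regression simulation scenario
#'
#' @param m_snps number of regression SNPs M.
#' @param h2_trait1,h2_trait2 SNP heritabilities in [0, 1].
#' @param rg_true genetic correlation in [-1, 1].
#' @param n1,n2 per-trait sample sizes.
#' @param n_overlap shared samples between the two GWAS.
#' @param rho_pheno phenotypic correlation in the overlapping samples;
#'   defaults to the genetic covariance rg * sqrt(h2_1 * h2_2).
#' @param ld_shape,ld_scale gamma parameters for per-SNP LD scores
#'   (ld score = 1 + Gamma(shape, scale); defaults give mean ~ 39).
#' @param seed integer seed.
#' @return list of class `ldsc_scenario`.
#' @export
ldsc_scenario <- function(m_snps = 20000, h2_trait1 = 0.3, h2_trait2 = 0.3,
                          rg_true = 0, n1 = 50000, n2 = 50000, n_overlap = 0,
                          rho_pheno = NULL, ld_shape = 1.5, ld_scale = 25,
                          seed = 1) {
  stopifnot(h2_trait1 >= 0, h2_trait1 <= 1, h2_trait2 >= 0, h2_trait2 <= 1,
            abs(rg_true) <= 1, n_overlap <= min(n1, n2))
  if (is.null(rho_pheno))
    rho_pheno <- rg_true * sqrt(h2_trait1 * h2_trait2)
  structure(as.list(environment()), class = "ldsc_scenario")
}

#' Simulate per-SNP LD scores and bivariate z-scores
#'
#' Draws LD scores from a shifted gamma distribution and, per SNP, a
#' bivariate normal z-score pair with Var(z1) = 1 + n1 h2_1 l/M,
#' Var(z2) = 1 + n2 h2_2 l/M and
#' Cov = sqrt(n1 n2) rg sqrt(h2_1 h2_2) l/M + n_overlap rho_pheno /
#' sqrt(n1 n2) (the sample-overlap intercept term).
#'
#' @param scenario an [ldsc_scenario()].
#' @return list with `scores` (data.frame SNP, L2, MAF), `z` (data.frame
#'   SNP, Z1, Z2), `M`, and the scenario.
#' @export
simulate_ldsc_dataset <- function(scenario) {
  s <- scenario
  set.seed(s$seed)
  M <- s$m_snps
  ell <- 1 + stats::rgamma(M, shape = s$ld_shape, scale = s$ld_scale)
  v1 <- 1 + s$n1 * s$h2_trait1 * ell / M
  v2 <- 1 + s$n2 * s$h2_trait2 * ell / M
  cv <- sqrt(s$n1 * s$n2) * s$rg_true * sqrt(s$h2_trait1 * s$h2_trait2) *
    ell / M + s$n_overlap * s$rho_pheno / sqrt(s$n1 * s$n2)
  bad <- which(cv^2 >= v1 * v2)
  if (length(bad) > 0)
    stop("implied z-score covariance not positive definite at SNP index ",
         bad[1])
  u1 <- stats::rnorm(M)
  u2 <- stats::rnorm(M)
  z1 <- sqrt(v1) * u1
  z2 <- (cv / sqrt(v1)) * u1 + sqrt(v2 - cv^2 / v1) * u2
  maf <- stats::runif(M, 0.01, 0.5)
  list(scores = data.frame(SNP = sprintf("rs%07d", seq_len(M)), L2 = ell,
                           MAF = maf, stringsAsFactors = FALSE),
       z = data.frame(SNP = sprintf("rs%07d", seq_len(M)), Z1 = z1, Z2 = z2,
                      stringsAsFactors = FALSE),
       M = M, scenario = s)
}
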