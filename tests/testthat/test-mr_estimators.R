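test_that("Wald ratios follow the first-order formula", {
  p <- make_pairs(bx = c(0.5, -0.5), by = c(0.1, 0.1),
                  sy = c(0.05, 0.05))
  r <- ratio_estimates(p)
  expect_equal(r$ratio, c(0.2, -0.2))
  expect_equal(r$ratio_se, c(0.1, 0.1))
  # direct re-evaluation on random inputs
  set.seed(1)
  p2 <- make_pairs(bx = rnorm(10, 0.3, 0.1), by = rnorm(10, 0.05, 0.02),
                   sy = runif(10, 0.01, 0.05))
  r2 <- ratio_estimates(p2)
  expect_equal(r2$ratio, p2$outcome_beta / p2$exposure_beta)
  expect_equal(r2$ratio_se, p2$outcome_se / abs(p2$exposure_beta))
})

test_that("zero exposure betas are excluded with a warning", {
  p <- make_pairs(bx = c(0.5, 0), by = c(0.1, 0.1))
  expect_warning(r <- ratio_estimates(p), "zero exposure beta")
  expect_equal(nrow(r), 1)
})

test_that("IVW equals a weighted regression through the origin", {
  set.seed(2)
  bx <- rnorm(10, 0.3, 0.1)
  sy <- runif(10, 0.01, 0.05)
  by <- 0.25 * bx + rnorm(10, 0, sy)
  p <- make_pairs(bx, by, sy = sy)
  fit <- mr_ivw(p)
  ora <- lm(by ~ 0 + bx, weights = 1 / sy^2)
  expect_equal(fit$beta, unname(coef(ora)), tolerance = 1e-10)
  unit_se <- sqrt(vcov(ora)[1, 1]) / summary(ora)$sigma
  expect_equal(fit$se, unit_se * sqrt(max(1, summary(ora)$sigma^2)),
               tolerance = 1e-10)
})

test_that("IVW on exactly proportional data has zero heterogeneity", {
  bx <- c(0.2, 0.3, 0.4)
  p <- make_pairs(bx, by = 0.3 * bx, sy = rep(0.02, 3))
  fit <- mr_ivw(p)
  expect_equal(fit$beta, 0.3)
  expect_equal(fit$heterogeneity_q, 0, tolerance = 1e-20)
  expect_equal(fit$extras$re_scale, 1)  # floored at the fixed-effect SE
})

test_that("a single variant falls back to the labelled Wald ratio", {
  p <- make_pairs(bx = 0.5, by = 0.1, sy = 0.05)
  fit <- mr_ivw(p)
  expect_equal(fit$method, "Wald")
  expect_equal(fit$beta, 0.2)
  expect_equal(fit$se, 0.1)
})

test_that("Egger recovers an exactly linear construction", {
  bx <- c(0.1, 0.2, 0.3, 0.4)
  p <- make_pairs(bx, by = 0.1 + 0.4 * bx)
  fit <- mr_egger(p)
  expect_equal(fit$beta, 0.4, tolerance = 1e-10)
  expect_equal(fit$extras$egger_intercept, 0.1, tolerance = 1e-10)
})

test_that("Egger equals an independent weighted regression", {
  set.seed(3)
  bx <- abs(rnorm(15, 0.3, 0.1))
  sy <- runif(15, 0.01, 0.05)
  by <- 0.05 + 0.3 * bx + rnorm(15, 0, 2 * sy)
  p <- make_pairs(bx, by, sy = sy)
  fit <- mr_egger(p)
  ora <- lm(by ~ bx, weights = 1 / sy^2)
  expect_equal(fit$beta, unname(coef(ora)[2]), tolerance = 1e-10)
  expect_equal(fit$extras$egger_intercept, unname(coef(ora)[1]),
               tolerance = 1e-10)
  sig <- summary(ora)$sigma
  unit <- sqrt(diag(vcov(ora))) / sig
  expect_equal(fit$se, unname(unit[2]) * sqrt(max(1, sig^2)),
               tolerance = 1e-10)
})

test_that("Egger needs at least three variants", {
  p <- make_pairs(bx = c(0.2, 0.3), by = c(0.1, 0.1))
  fit <- mr_egger(p)
  expect_true(is.na(fit$beta))
  expect_match(fit$extras$not_estimable, "fewer than 3")
})

test_that("weighted median matches the brute-force percentile oracle", {
  # equal weights: plain median
  p <- make_pairs(bx = c(1, 1, 1), by = c(0.1, 0.2, 0.3),
                  sy = c(0.05, 0.05, 0.05))
  expect_equal(mr_weighted_median(p, n_boot = 100)$beta, 0.2)
  # unequal weights against the oracle
  set.seed(4)
  for (i in 1:5) {
    bx <- abs(rnorm(4, 0.4, 0.1))
    sy <- runif(4, 0.01, 0.06)
    by <- rnorm(4, 0.2 * bx, sy)
    p <- make_pairs(bx, by, sy = sy)
    r <- by / bx
    w <- (bx / sy)^2
    expect_equal(mr_weighted_median(p, n_boot = 100)$beta,
                 oracle_weighted_median(r, w), tolerance = 1e-12)
  }
})

test_that("penalization is inactive on homogeneous data", {
  bx <- c(0.2, 0.3, 0.4, 0.5)
  p <- make_pairs(bx, by = 0.3 * bx + c(1, -1, 1, -1) * 1e-6)
  wm <- mr_weighted_median(p, penalized = FALSE, n_boot = 100, seed = 9)
  pwm <- mr_weighted_median(p, penalized = TRUE, n_boot = 100, seed = 9)
  expect_equal(wm$beta, pwm$beta, tolerance = 1e-12)
})

test_that("PRESSO leaves clean data alone and equals IVW", {
  bx <- seq(0.1, 0.5, length.out = 8)
  p <- make_pairs(bx, by = 0.3 * bx + rnorm(8, 0, 1e-4))
  fit <- suppressWarnings(mr_presso(p, n_sim = 300, seed = 1))
  expect_gt(fit$extras$global_p, 0.05)
  expect_equal(length(fit$extras$outliers), 0)
  expect_equal(fit$beta, mr_ivw(p)$beta)
})

test_that("PRESSO flags a gross outlier and reports the corrected fit", {
  set.seed(5)
  sc <- mr_scenario(m_instruments = 30, beta_causal = 0.1, seed = 55)
  sim <- simulate_mr_dataset(sc)
  p <- harmonized_kept(harmonize_pair(sim$exposure, sim$outcome))
  j <- 7
  p$outcome_beta[j] <- p$outcome_beta[j] + 10 * p$outcome_se[j]
  fit <- mr_presso(p, n_sim = 1000, seed = 5)
  expect_lt(fit$extras$global_p, 0.05)
  expect_true(p$SNP[j] %in% fit$extras$outliers)
  expect_true(fit$extras$outlier_corrected)
  # headline estimate is the outlier-removed IVW
  corrected <- mr_ivw(p[!p$SNP %in% fit$extras$outliers, ])
  expect_equal(fit$beta, corrected$beta)
  expect_lt(abs(fit$beta - 0.1), abs(fit$extras$raw_beta - 0.1))
})

test_that("PRESSO warns when n_sim cannot resolve the outlier threshold", {
  p <- make_pairs(seq(0.1, 0.5, length.out = 10),
                  0.3 * seq(0.1, 0.5, length.out = 10))
  expect_warning(mr_presso(p, n_sim = 100, seed = 1), "n_sim")
})

test_that("RAPS solves the profile score on clean data", {
  bx <- seq(0.1, 0.6, length.out = 10)
  p <- make_pairs(bx, by = 0.25 * bx, sx = rep(0.01, 10))
  fit <- mr_raps(p)
  expect_equal(fit$beta, 0.25, tolerance = 1e-6)
})

test_that("RAPS with zero exposure SE reduces to fixed-effect IVW", {
  set.seed(6)
  bx <- rnorm(12, 0.3, 0.1)
  sy <- runif(12, 0.01, 0.05)
  by <- 0.2 * bx + rnorm(12, 0, sy)
  p <- make_pairs(bx, by, sx = rep(0, 12), sy = sy)
  fit <- mr_raps(p)
  ivw_fixed <- lm(by ~ 0 + bx, weights = 1 / sy^2)
  expect_equal(fit$beta, unname(coef(ivw_fixed)), tolerance = 1e-8)
  expect_equal(fit$se, sqrt(vcov(ivw_fixed)[1, 1]) /
                 summary(ivw_fixed)$sigma, tolerance = 1e-6)
})

test_that("RAPS estimates overdispersion on pleiotropic data", {
  set.seed(7)
  sc <- mr_scenario(m_instruments = 50, beta_causal = 0.2,
                    pleiotropy_sd = 0.01, seed = 77)
  sim <- simulate_mr_dataset(sc)
  p <- harmonized_kept(harmonize_pair(sim$exposure, sim$outcome))
  fit <- mr_raps(p, overdispersion = TRUE)
  expect_gt(fit$extras$tau2, 0)
  expect_lt(abs(fit$beta - 0.2), 0.05)
  # huber loss stays close to the simple-loss estimate here
  fit_h <- mr_raps(p, overdispersion = TRUE, loss = "huber")
  expect_lt(abs(fit_h$beta - fit$beta), 0.02)
})

test_that("Steiger compares explained variances as stated", {
  p <- make_pairs(bx = c(0.3, 0.3), by = c(0.02, 0.02), eafx = 0.4)
  s <- mr_steiger(p, 50000, 50000)
  expect_true(s$direction_correct)
  expect_equal(s$r2_exposure, 2 * (2 * 0.4 * 0.6 * 0.09))
  # equal variance explained: z = 0 and p = 1 exactly
  p2 <- make_pairs(bx = 0.3, by = 0.3, eafx = 0.4)
  s2 <- mr_steiger(p2, 50000, 50000)
  expect_equal(s2$z_statistic, 0)
  expect_equal(s2$pvalue, 1)
  expect_true(s2$indeterminate)
})

test_that("Steiger rejects un-standardized betas", {
  p <- make_pairs(bx = 3, by = 0.1, eafx = 0.5)
  expect_error(mr_steiger(p, 50000, 50000), "standardized")
})

test_that("MVMR matches a multivariable weighted regression oracle", {
  d <- simulate_mvmr_dataset(m_instruments = 40, seed = 8)
  fits <- mr_mvmr(d$exposures, d$outcome, panel = NULL)
  snps <- fits[[1]]$extras$instruments
  BX <- cbind(d$exposures[[1]]$BETA[match(snps, d$exposures[[1]]$SNP)],
              d$exposures[[2]]$BETA[match(snps, d$exposures[[2]]$SNP)])
  by <- d$outcome$BETA[match(snps, d$outcome$SNP)]
  w <- 1 / d$outcome$SE[match(snps, d$outcome$SNP)]^2
  ora <- lm(by ~ 0 + BX, weights = w)
  expect_equal(vapply(fits, `[[`, 0, "beta"), unname(coef(ora)),
               tolerance = 1e-10)
  expect_gt(min(vapply(fits, function(f) f$extras$conditional_f, 0)), 10)
})

test_that("an irrelevant second exposure gets a near-zero coefficient", {
  set.seed(9)
  m <- 40
  maf <- runif(m, 0.1, 0.5)
  g1 <- 0.1 * runif(m, 0.5, 1.5)
  se <- 1 / sqrt(2 * maf * (1 - maf) * 50000)
  bx1 <- g1                      # noiseless observed effects
  bx2 <- rnorm(m, 0, 0.01)       # no true effect anywhere
  by <- 0.3 * g1                 # outcome driven by exposure 1 only
  mk <- function(b, lab) make_sumstats(b, se, eaf = maf, label = lab)
  fits <- mr_mvmr(list(mk(bx1, "e1"), mk(bx2, "e2")), mk(by, "y"),
                  panel = NULL, p_threshold = 1e-4)
  expect_equal(fits[[1]]$beta, 0.3, tolerance = 1e-2)
  expect_lt(abs(fits[[2]]$beta), 0.05)
})

test_that("collinear exposures are reported by name", {
  d <- simulate_mvmr_dataset(m_instruments = 20, seed = 10)
  dup <- list(d$exposures[[1]], d$exposures[[1]])
  expect_error(mr_mvmr(dup, d$outcome, panel = NULL), "collinear")
})

test_that("confidence intervals are the exponentiated normal bounds", {
  set.seed(11)
  sc <- mr_scenario(m_instruments = 20, beta_causal = 0.1, seed = 11)
  sim <- simulate_mr_dataset(sc)
  p <- harmonized_kept(harmonize_pair(sim$exposure, sim$outcome))
  for (fit in list(mr_ivw(p), mr_egger(p),
                   mr_weighted_median(p, n_boot = 100),
                   mr_raps(p))) {
    expect_equal(fit$ci_low, exp(fit$beta - qnorm(0.975) * fit$se))
    expect_equal(fit$ci_high, exp(fit$beta + qnorm(0.975) * fit$se))
    expect_equal(fit$or_value, exp(fit$beta))
    expect_true(fit$ci_low <= fit$or_value && fit$or_value <= fit$ci_high)
  }
})

test_that("estimators are equivariant under exposure sign flips", {
  set.seed(12)
  sc <- mr_scenario(m_instruments = 25, beta_causal = 0.15, seed = 12)
  sim <- simulate_mr_dataset(sc)
  p <- harmonized_kept(harmonize_pair(sim$exposure, sim$outcome))
  pf <- p
  pf$exposure_beta <- -pf$exposure_beta   # recode every effect allele
  pf$exposure_eaf <- 1 - pf$exposure_eaf
  expect_equal(mr_ivw(pf)$beta, -mr_ivw(p)$beta, tolerance = 1e-12)
  expect_equal(mr_egger(pf)$beta, -mr_egger(p)$beta, tolerance = 1e-12)
  expect_equal(mr_weighted_median(pf, n_boot = 50, seed = 1)$beta,
               -mr_weighted_median(p, n_boot = 50, seed = 1)$beta,
               tolerance = 1e-12)
  expect_equal(mr_raps(pf)$beta, -mr_raps(p)$beta, tolerance = 1e-6)
})

test_that("estimators agree on clean strong-instrument data", {
  # with no pleiotropy, every estimator's mean estimate sits within
  # Monte-Carlo error of the shared truth
  n_rep <- 100
  est <- matrix(NA_real_, n_rep, 5,
                dimnames = list(NULL, c("ivw", "egger", "wm", "pwm",
                                        "raps")))
  for (i in seq_len(n_rep)) {
    sc <- mr_scenario(m_instruments = 50, beta_causal = 0.2,
                      n_exposure = 2e5, n_outcome = 2e5, seed = 1300 + i)
    sim <- simulate_mr_dataset(sc)
    p <- harmonized_kept(harmonize_pair(sim$exposure, sim$outcome))
    est[i, ] <- c(mr_ivw(p)$beta, mr_egger(p)$beta,
                  mr_weighted_median(p, n_boot = 50, seed = i)$beta,
                  mr_weighted_median(p, TRUE, n_boot = 50,
                                     seed = i)$beta,
                  mr_raps(p)$beta)
  }
  mc_se <- apply(est, 2, sd) / sqrt(n_rep)
  for (j in 1:5)
    expect_lt(abs(mean(est[, j]) - 0.2), 3 * mc_se[j])
})

test_that("weighted median tolerates invalid instruments better than IVW", {
  # 40% of instruments carry a strong pleiotropic shift
  set.seed(14)
  bias_ivw <- bias_wm <- numeric(60)
  for (i in 1:60) {
    sc <- mr_scenario(m_instruments = 30, beta_causal = 0.2,
                      seed = 1400 + i)
    sim <- simulate_mr_dataset(sc)
    p <- harmonized_kept(harmonize_pair(sim$exposure, sim$outcome))
    bad <- seq_len(12)
    # pleiotropic shift on the exposure-increasing allele, so the ratio
    # bias does not cancel over allele codings
    p$outcome_beta[bad] <- p$outcome_beta[bad] +
      0.02 * sign(p$exposure_beta[bad])
    bias_ivw[i] <- mr_ivw(p)$beta - 0.2
    bias_wm[i] <- mr_weighted_median(p, n_boot = 50, seed = i)$beta - 0.2
  }
  expect_lt(abs(mean(bias_wm)), abs(mean(bias_ivw)))
})
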