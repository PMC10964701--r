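# Two-sample MR estimators and sensitivity suite: IVW (multiplicative
# random effects), MR-Egger, (penalized) weighted median, MR-PRESSO,
# MR-RAPS, Steiger directionality, multivariable MR.
#
# All estimators consume harmonized exposure/outcome pairs and use
# first-order Wald-ratio SEs (outcome_se / |exposure_beta|); RAPS is the
# estimator in the suite that additionally models exposure-side noise.

Z975 <- stats::qnorm(0.975)

mr_result <- function(method, beta, se, n_snps, q = NA_real_,
                      q_df = NA_real_, extras = list()) {
  pvalue <- 2 * stats::pnorm(-abs(beta / se))
  structure(list(
    method = method, beta = beta, se = se, pvalue = pvalue,
    or_value = exp(beta), ci_low = exp(beta - Z975 * se),
    ci_high = exp(beta + Z975 * se), n_snps = n_snps,
    heterogeneity_q = q,
    heterogeneity_p = if (is.na(q) || q_df < 1) NA_real_ else
      stats::pchisq(q, q_df, lower.tail = FALSE),
    extras = extras), class = "mr_estimate")
}

mr_not_estimable <- function(method, reason, n_snps = 0) {
  structure(list(method = method, beta = NA_real_, se = NA_real_,
                 pvalue = NA_real_, or_value = NA_real_, ci_low = NA_real_,
                 ci_high = NA_real_, n_snps = n_snps,
                 heterogeneity_q = NA_real_, heterogeneity_p = NA_real_,
                 extras = list(not_estimable = reason)),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  if (is.na(x$beta)) {
    cat(sprintf("%s: not estimable (%s)\n", x$method,
                x$extras$not_estimable))
    return(invisible(x))
  }
  cat(sprintf("%s: beta = %.4f (SE %.4f), OR = %.3f [%.3f, %.3f], p = %.3g, m = %d\n",
              x$method, x$beta, x$se, x$or_value, x$ci_low, x$ci_high,
              x$pvalue, x$n_snps))
  invisible(x)
}

pairs_kept <- function(pairs) {
  if ("action" %in% names(pairs))
    pairs <- pairs[pairs$action %in% c("kept_as_is", "flipped"), ,
                   drop = FALSE]
  pairs
}

#' Per-variant Wald ratio estimates
#'
#' ratio_j = outcome_beta_j / exposure_beta_j with first-order standard
#' error outcome_se_j / |exposure_beta_j| (exposure-side noise ignored;
#' see [mr_raps()] for an estimator that models it). Variants with a zero
#' exposure beta are excluded with a warning.
#'
#' @param pairs harmonized pairs (rows with a dropped action are ignored).
#' @return data.frame with SNP, ratio, ratio_se.
#' @export
ratio_estimates <- function(pairs) {
  p <- pairs_kept(pairs)
  zero <- p$exposure_beta == 0
  if (any(zero)) {
    warning(sum(zero), " variant(s) with zero exposure beta excluded")
    p <- p[!zero, , drop = FALSE]
  }
  data.frame(SNP = p$SNP, ratio = p$outcome_beta / p$exposure_beta,
             ratio_se = p$outcome_se / abs(p$exposure_beta),
             stringsAsFactors = FALSE)
}

#' Inverse-variance weighted estimate (multiplicative random effects)
#'
#' Precision-weighted mean of the per-variant Wald ratios with weights
#' 1/ratio_se^2. The standard error is the fixed-effect SE scaled by
#' sqrt(max(1, Q/(m-1))) where Q is Cochran's heterogeneity statistic, so
#' it never falls below the fixed-effect SE. With a single variant the
#' result is the Wald ratio, labelled as such.
#'
#' @param pairs harmonized pairs.
#' @return an `mr_estimate`.
#' @export
mr_ivw <- function(pairs) {
  r <- ratio_estimates(pairs)
  m <- nrow(r)
  if (m == 0) return(mr_not_estimable("IVW", "no usable variants"))
  w <- 1 / r$ratio_se^2
  beta <- sum(w * r$ratio) / sum(w)
  se_fixed <- 1 / sqrt(sum(w))
  if (m == 1)
    return(mr_result("Wald", r$ratio, r$ratio_se, 1,
                     extras = list(single_variant_fallback = TRUE)))
  q <- sum(w * (r$ratio - beta)^2)
  scale <- sqrt(max(1, q / (m - 1)))
  mr_result("IVW", beta, se_fixed * scale, m, q = q, q_df = m - 1,
            extras = list(se_fixed = se_fixed, re_scale = scale))
}

#' MR-Egger regression
#'
#' Orients every pair so the exposure beta is non-negative, then runs a
#' weighted regression of outcome betas on exposure betas with a free
#' intercept (weights 1/outcome_se^2). The slope is the causal estimate;
#' the intercept and its p-value form the directional-pleiotropy test.
#' Both SEs are inflated by sqrt(max(1, Q'/(m-2))).
#'
#' @param pairs harmonized pairs.
#' @return an `mr_estimate` with `egger_intercept`, `egger_intercept_se`,
#'   `egger_intercept_p` in `extras`.
#' @export
mr_egger <- function(pairs) {
  p <- pairs_kept(pairs)
  m <- nrow(p)
  if (m < 3) return(mr_not_estimable("Egger", "fewer than 3 variants", m))
  s <- sign(p$exposure_beta)
  s[s == 0] <- 1
  bx <- p$exposure_beta * s
  by <- p$outcome_beta * s
  w <- 1 / p$outcome_se^2
  X <- cbind(intercept = 1, slope = bx)
  XtWX <- crossprod(X, X * w)
  XtWy <- crossprod(X, by * w)
  coef <- solve(XtWX, XtWy)
  resid <- by - X %*% coef
  qp <- sum(w * resid^2)
  sigma <- sqrt(max(1, qp / (m - 2)))
  ses <- unname(sqrt(diag(solve(XtWX)))) * sigma
  intercept_p <- 2 * stats::pnorm(-abs(coef[1] / ses[1]))
  mr_result("Egger", coef[2], ses[2], m, q = qp, q_df = m - 2,
            extras = list(egger_intercept = coef[1],
                          egger_intercept_se = ses[1],
                          egger_intercept_p = intercept_p))
}

weighted_median_point <- function(r, w) {
  o <- order(r)
  r <- r[o]; w <- w[o]
  p <- (cumsum(w) - 0.5 * w) / sum(w)
  if (p[1] >= 0.5) return(r[1])
  n <- length(r)
  if (p[n] < 0.5) return(r[n])
  j <- max(which(p < 0.5))
  r[j] + (r[j + 1] - r[j]) * (0.5 - p[j]) / (p[j + 1] - p[j])
}

penalize_weights <- function(r, w, penalty_factor) {
  beta0 <- sum(w * r) / sum(w)
  qj <- w * (r - beta0)^2
  pj <- stats::pchisq(qj, df = 1, lower.tail = FALSE)
  w * pmin(1, penalty_factor * pj)
}

#' Weighted median and penalized weighted median estimates
#'
#' The weight-interpolated 50th percentile of the Wald ratios, with weights
#' proportional to inverse ratio variance. Penalization multiplies each
#' weight by min(1, penalty_factor * q_j) where q_j is the upper-tail
#' chi-squared(1) probability of the variant's Cochran Q contribution,
#' down-weighting heterogeneous variants. The SE comes from a seeded
#' parametric bootstrap of the ratio estimates. Consistent while up to half
#' the weight lies on invalid instruments.
#'
#' @param pairs harmonized pairs.
#' @param penalized use heterogeneity-penalized weights.
#' @param n_boot bootstrap resamples for the SE (default 1000).
#' @param seed bootstrap seed.
#' @param penalty_factor penalty multiplier (default 20).
#' @return an `mr_estimate` (method `WM` or `PWM`).
#' @export
mr_weighted_median <- function(pairs, penalized = FALSE, n_boot = 1000,
                               seed = 1, penalty_factor = 20) {
  r <- ratio_estimates(pairs)
  m <- nrow(r)
  method <- if (penalized) "PWM" else "WM"
  if (m < 3) return(mr_not_estimable(method, "fewer than 3 variants", m))
  w0 <- 1 / r$ratio_se^2
  w <- if (penalized) penalize_weights(r$ratio, w0, penalty_factor) else w0
  if (all(w == 0))
    return(mr_not_estimable(method, "all weights zero after penalization", m))
  est <- weighted_median_point(r$ratio, w)

  # model-based parametric bootstrap: ratios resampled around the fitted
  # estimate (resampling around the observed ratios would double-count
  # their dispersion and overstate the SE of an order statistic)
  set.seed(seed)
  draws <- matrix(stats::rnorm(n_boot * m, mean = est,
                               sd = rep(r$ratio_se, each = n_boot)),
                  nrow = n_boot)
  boot <- vapply(seq_len(n_boot), function(i) {
    ri <- draws[i, ]
    wi <- if (penalized) penalize_weights(ri, w0, penalty_factor) else w0
    if (all(wi == 0)) return(NA_real_)
    weighted_median_point(ri, wi)
  }, numeric(1))
  se <- stats::sd(boot, na.rm = TRUE)
  mr_result(method, est, se, m,
            extras = list(n_boot = n_boot, penalized = penalized))
}

loo_slopes <- function(bx, by, w) {
  sxy <- sum(w * bx * by)
  sxx <- sum(w * bx^2)
  (sxy - w * bx * by) / (sxx - w * bx^2)
}

#' MR-PRESSO: pleiotropy residual sum and outlier test
#'
#' The observed residual sum of squares uses leave-one-out IVW slopes:
#' RSS = sum_j w_j (by_j - b_(-j) bx_j)^2 with w_j = 1/outcome_se_j^2. A
#' null distribution is built from `n_sim` parametric simulations drawing
#' exposure and outcome betas from their sampling distributions under the
#' leave-one-out fits; the global p-value is the fraction of simulated RSS
#' at or above the observed one. Per-variant outlier p-values compare each
#' variant's weighted squared residual to its simulated distribution with
#' Bonferroni correction at `outlier_alpha`. When the global test is
#' significant (p < 0.05) the headline estimate is IVW recomputed on the
#' outlier-free set, with the raw estimate and a distortion-test p-value
#' kept in `extras`.
#'
#' @param pairs harmonized pairs (>= 4 variants).
#' @param n_sim simulations for the null distribution (>= 100).
#' @param outlier_alpha familywise outlier significance level.
#' @param seed simulation seed.
#' @return an `mr_estimate` with `global_p`, `outliers`, `raw_beta`,
#'   `raw_se`, `distortion_p` in `extras`.
#' @export
mr_presso <- function(pairs, n_sim = 1000, outlier_alpha = 0.05, seed = 1) {
  p <- pairs_kept(pairs)
  m <- nrow(p)
  if (m < 4) return(mr_not_estimable("PRESSO", "fewer than 4 variants", m))
  if (n_sim < 100) stop("n_sim must be at least 100")
  min_p <- 1 / (n_sim + 1)
  if (min_p > outlier_alpha / m)
    warning(sprintf(paste0("n_sim = %d resolves outlier p-values only down ",
                           "to %.2g; the Bonferroni threshold %g/%d needs ",
                           "n_sim >= %d"),
                    n_sim, min_p, outlier_alpha, m,
                    ceiling(m / outlier_alpha)))
  bx <- p$exposure_beta; by <- p$outcome_beta
  sx <- p$exposure_se; sy <- p$outcome_se
  w <- 1 / sy^2
  b_loo <- loo_slopes(bx, by, w)
  res_obs <- w * (by - b_loo * bx)^2
  rss_obs <- sum(res_obs)

  set.seed(seed)
  BX <- matrix(stats::rnorm(n_sim * m, rep(bx, each = n_sim),
                            rep(sx, each = n_sim)), n_sim)
  BY <- matrix(stats::rnorm(n_sim * m, rep(b_loo * bx, each = n_sim),
                            rep(sy, each = n_sim)), n_sim)
  W <- matrix(w, n_sim, m, byrow = TRUE)
  sxy <- rowSums(W * BX * BY)
  sxx <- rowSums(W * BX^2)
  BLOO <- (sxy - W * BX * BY) / (sxx - W * BX^2)
  RES <- W * (BY - BLOO * BX)^2
  rss_sim <- rowSums(RES)
  global_p <- mean(rss_sim >= rss_obs)

  p_var <- (colSums(RES >= matrix(res_obs, n_sim, m, byrow = TRUE)) + 1) /
    (n_sim + 1)
  outlier <- p_var * m < outlier_alpha

  raw <- mr_ivw(p)
  if (global_p < 0.05 && any(outlier) && sum(!outlier) >= 2) {
    corrected <- mr_ivw(p[!outlier, , drop = FALSE])
    # distortion test: observed shift vs shifts from removing random
    # same-sized subsets
    k <- sum(outlier)
    n_draw <- min(n_sim, 1000L)
    d_obs <- raw$beta - corrected$beta
    # IVW slopes after removing random same-sized subsets, via weighted
    # sums (w here are ratio weights bx^2/sy^2 on the ratio scale)
    wr <- w * bx^2
    rr <- by / bx
    swr <- sum(wr); swrr <- sum(wr * rr)
    d_sim <- vapply(seq_len(n_draw), function(i) {
      drop <- sample.int(m, k)
      raw$beta - (swrr - sum(wr[drop] * rr[drop])) / (swr - sum(wr[drop]))
    }, numeric(1))
    distortion_p <- mean(abs(d_sim) >= abs(d_obs))
    out <- mr_result("PRESSO", corrected$beta, corrected$se, corrected$n_snps,
                     q = corrected$heterogeneity_q, q_df = corrected$n_snps - 1,
                     extras = list(global_p = global_p,
                                   outliers = p$SNP[outlier],
                                   outlier_p = p_var,
                                   raw_beta = raw$beta, raw_se = raw$se,
                                   distortion_p = distortion_p,
                                   outlier_corrected = TRUE))
  } else {
    out <- mr_result("PRESSO", raw$beta, raw$se, raw$n_snps,
                     q = raw$heterogeneity_q, q_df = raw$n_snps - 1,
                     extras = list(global_p = global_p,
                                   outliers = character(0),
                                   outlier_p = p_var,
                                   raw_beta = raw$beta, raw_se = raw$se,
                                   distortion_p = NA_real_,
                                   outlier_corrected = FALSE))
  }
  out
}

#' MR-RAPS: robust adjusted profile score estimate
#'
#' Solves the profile-score equation sum_j psi(t_j(beta)) * d_j(beta) = 0
#' with t_j = (by_j - beta bx_j) / sqrt(sy_j^2 + beta^2 sx_j^2 + tau^2) and
#' d_j = -dt_j/dbeta, accounting for exposure-side sampling error. psi is
#' the identity (`simple`) or a Huber score with tuning constant 1.345
#' (`huber`). With `overdispersion = TRUE` the systematic-pleiotropy
#' variance tau^2 is estimated jointly by moment-matching the profiled
#' residuals to unit variance. The SE is the sandwich of the profile score.
#'
#' @param pairs harmonized pairs (>= 3 variants).
#' @param overdispersion estimate tau^2 jointly.
#' @param loss `"simple"` or `"huber"`.
#' @return an `mr_estimate` with `tau2` in `extras`.
#' @export
mr_raps <- function(pairs, overdispersion = FALSE,
                    loss = c("simple", "huber")) {
  loss <- match.arg(loss)
  p <- pairs_kept(pairs)
  m <- nrow(p)
  if (m < 3) return(mr_not_estimable("RAPS", "fewer than 3 variants", m))
  bx <- p$exposure_beta; by <- p$outcome_beta
  sx2 <- p$exposure_se^2; sy2 <- p$outcome_se^2
  cc <- 1.345
  psi <- if (loss == "simple") identity else
    function(t) pmin(pmax(t, -cc), cc)
  # E[psi(Z)^2] and E[psi'(Z)] under Z ~ N(0,1), for the sandwich SE
  if (loss == "simple") {
    a_const <- 1; b_const <- 1
  } else {
    b_const <- 1 - 2 * stats::pnorm(-cc)
    a_const <- b_const - 2 * cc * stats::dnorm(cc) +
      2 * cc^2 * stats::pnorm(-cc)
  }

  score <- function(beta, tau2) {
    v <- sy2 + beta^2 * sx2 + tau2
    t <- (by - beta * bx) / sqrt(v)
    d <- (bx * v + (by - beta * bx) * beta * sx2) / v^1.5
    sum(psi(t) * d)
  }
  solve_tau2 <- function(beta) {
    f <- function(tau2) {
      v <- sy2 + beta^2 * sx2 + tau2
      sum((by - beta * bx)^2 / v - 1)
    }
    if (f(0) <= 0) return(0)
    upper <- stats::var(by - beta * bx) * 10 + 1
    while (f(upper) > 0) upper <- upper * 10
    stats::uniroot(f, c(0, upper), tol = 1e-12)$root
  }
  solve_beta <- function(tau2) {
    r0 <- stats::median(by / ifelse(bx == 0, NA, bx), na.rm = TRUE)
    half <- 1
    repeat {
      lo <- r0 - half; hi <- r0 + half
      flo <- score(lo, tau2); fhi <- score(hi, tau2)
      if (is.finite(flo) && is.finite(fhi) && sign(flo) != sign(fhi)) break
      half <- half * 2
      if (half > 1024)
        stop("profile score has no sign change over the search bracket")
    }
    stats::uniroot(function(b) score(b, tau2), c(lo, hi), tol = 1e-12)$root
  }

  tau2 <- 0
  beta <- tryCatch(solve_beta(tau2), error = function(e) NA_real_)
  if (is.na(beta))
    return(mr_not_estimable("RAPS", "no sign change in the profile score", m))
  if (overdispersion) {
    for (it in seq_len(50)) {
      tau2_new <- solve_tau2(beta)
      beta_new <- solve_beta(tau2_new)
      done <- abs(beta_new - beta) < 1e-10 && abs(tau2_new - tau2) < 1e-12
      beta <- beta_new; tau2 <- tau2_new
      if (done) break
    }
  }
  v <- sy2 + beta^2 * sx2 + tau2
  d <- (bx * v + (by - beta * bx) * beta * sx2) / v^1.5
  se <- sqrt(a_const / (b_const^2 * sum(d^2)))
  mr_result("RAPS", beta, se, m,
            extras = list(tau2 = tau2, loss = loss,
                          overdispersion = overdispersion))
}

#' Steiger directionality test
#'
#' Compares the variance the instrument set explains in the exposure with
#' the variance it explains in the outcome, each as sum of
#' 2 EAF (1-EAF) beta^2 (log-odds scale for binary traits). The test
#' statistic compares Fisher-transformed correlations:
#' z = (atanh(sqrt(r2_exp)) - atanh(sqrt(r2_out))) /
#' sqrt(1/(n_exp-3) + 1/(n_out-3)). The causal direction is judged correct
#' when the exposure r-squared exceeds the outcome r-squared.
#'
#' @param pairs harmonized pairs with exposure and outcome EAFs.
#' @param n_exposure,n_outcome GWAS sample sizes (>= 4).
#' @return list of class `steiger_result` with r2 values, z, p,
#'   `direction_correct` and an indeterminate flag when the r2 are equal.
#' @export
mr_steiger <- function(pairs, n_exposure, n_outcome) {
  stopifnot(n_exposure >= 4, n_outcome >= 4)
  p <- pairs_kept(pairs)
  r2x <- sum(2 * p$exposure_eaf * (1 - p$exposure_eaf) * p$exposure_beta^2)
  r2y <- sum(2 * p$outcome_eaf * (1 - p$outcome_eaf) * p$outcome_beta^2)
  if (r2x >= 1 || r2y >= 1)
    stop("instrument r-squared is ", signif(max(r2x, r2y), 4),
         " (>= 1); betas do not look standardized to the allelic scale")
  z <- (atanh(sqrt(r2x)) - atanh(sqrt(r2y))) /
    sqrt(1 / (n_exposure - 3) + 1 / (n_outcome - 3))
  structure(list(r2_exposure = r2x, r2_outcome = r2y,
                 direction_correct = r2x > r2y,
                 indeterminate = r2x == r2y,
                 z_statistic = z, pvalue = 2 * stats::pnorm(-abs(z))),
            class = "steiger_result")
}

#' @export
print.steiger_result <- function(x, ...) {
  cat(sprintf("Steiger: r2(exposure) = %.4g, r2(outcome) = %.4g -> direction %s (p = %.3g)\n",
              x$r2_exposure, x$r2_outcome,
              if (x$indeterminate) "indeterminate" else
                if (x$direction_correct) "correct" else "reversed",
              x$pvalue))
  invisible(x)
}

#' Multivariable MR
#'
#' Instruments are the union of per-exposure genome-wide-significant
#' variants, jointly clumped on the supplied LD panel (ranking by each
#' variant's smallest p-value across exposures). The outcome betas are then
#' regressed on the matrix of exposure betas without intercept, with
#' weights 1/outcome_se^2; SEs are inflated multiplicatively by
#' sqrt(max(1, Q/(m-K))). Conditional instrument-strength F statistics
#' (residualizing each exposure's betas on the others') are reported in
#' `extras`.
#'
#' @param exposures list of >= 2 `summary_stats`, sharing variant ids and
#'   the same effect-allele convention with `outcome`.
#' @param outcome a `summary_stats`.
#' @param panel LD panel for joint clumping (NULL skips clumping).
#' @param p_threshold,r2_threshold,window_kb clumping parameters as in
#'   [select_instruments()].
#' @return list of `mr_estimate` objects (method `MVMR`), one per exposure.
#' @export
mr_mvmr <- function(exposures, outcome, panel = NULL, p_threshold = 5e-8,
                    r2_threshold = 0.001, window_kb = 10000) {
  K <- length(exposures)
  stopifnot(K >= 2)
  sig <- unique(unlist(lapply(exposures, function(e) e$SNP[e$P < p_threshold])))
  shared <- Reduce(intersect, c(lapply(exposures, function(e) e$SNP),
                                list(outcome$SNP)))
  sig <- intersect(sig, shared)
  if (length(sig) <= K)
    stop("need more jointly available significant instruments (",
         length(sig), ") than exposures (", K, ")")
  pmin_tab <- do.call(pmin, lapply(exposures,
                                   function(e) e$P[match(sig, e$SNP)]))
  e1 <- exposures[[1]]
  cand <- data.frame(SNP = sig, CHR = e1$CHR[match(sig, e1$SNP)],
                     POS = e1$POS[match(sig, e1$SNP)],
                     EAF = e1$EAF[match(sig, e1$SNP)],
                     BETA = e1$BETA[match(sig, e1$SNP)],
                     SE = e1$SE[match(sig, e1$SNP)], P = pmin_tab,
                     stringsAsFactors = FALSE)
  if (!is.null(panel)) {
    sel <- select_instruments(as_summary_stats(cand), panel,
                              p_threshold = 1, r2_threshold = r2_threshold,
                              window_kb = window_kb)
    snps <- sel$instruments$SNP
  } else snps <- sort(sig)
  m <- length(snps)
  if (m <= K) stop("fewer clumped instruments (", m, ") than exposures")

  BX <- vapply(exposures, function(e) e$BETA[match(snps, e$SNP)], numeric(m))
  SX <- vapply(exposures, function(e) e$SE[match(snps, e$SNP)], numeric(m))
  by <- outcome$BETA[match(snps, outcome$SNP)]
  w <- 1 / outcome$SE[match(snps, outcome$SNP)]^2

  qr_bx <- qr(BX)
  if (qr_bx$rank < K) {
    labs <- vapply(exposures, function(e) attr(e, "trait_label"), "")
    stop("exposure beta matrix is rank deficient; collinear exposures: ",
         paste(labs, collapse = ", "))
  }
  XtWX <- crossprod(BX, BX * w)
  coef <- solve(XtWX, crossprod(BX, by * w))
  resid <- by - BX %*% coef
  q <- sum(w * resid^2)
  sigma <- sqrt(max(1, q / (m - K)))
  ses <- sqrt(diag(solve(XtWX))) * sigma

  # conditional instrument strength: residualize each exposure's betas on
  # the other exposures' and average the squared residual z-scores
  f_cond <- vapply(seq_len(K), function(k) {
    others <- BX[, -k, drop = FALSE]
    wk <- 1 / SX[, k]^2
    ck <- solve(crossprod(others, others * wk),
                crossprod(others, BX[, k] * wk))
    rk <- BX[, k] - others %*% ck
    sum(rk^2 / SX[, k]^2) / (m - K + 1)
  }, numeric(1))

  lapply(seq_len(K), function(k) {
    mr_result("MVMR", coef[k], ses[k], m, q = q, q_df = m - K,
              extras = list(exposure = attr(exposures[[k]], "trait_label"),
                            conditional_f = f_cond[k],
                            instruments = snps))
  })
}

#' Run the full MR sensitivity suite on one harmonized pair set
#'
#' @param pairs harmonized pairs.
#' @param n_exposure,n_outcome sample sizes for the Steiger test.
#' @param n_boot,n_sim,seed stochastic-procedure controls.
#' @return list with every `mr_estimate` plus the `steiger_result`, and a
#'   `table` data.frame (one row per method) for serialization.
#' @export
mr_all <- function(pairs, n_exposure, n_outcome, n_boot = 1000,
                   n_sim = 1000, seed = 1) {
  fits <- list(
    IVW = mr_ivw(pairs),
    Egger = mr_egger(pairs),
    WM = mr_weighted_median(pairs, penalized = FALSE, n_boot = n_boot,
                            seed = seed),
    PWM = mr_weighted_median(pairs, penalized = TRUE, n_boot = n_boot,
                             seed = seed + 1L),
    PRESSO = mr_presso(pairs, n_sim = n_sim, seed = seed + 2L),
    RAPS = mr_raps(pairs, overdispersion = TRUE)
  )
  steiger <- mr_steiger(pairs, n_exposure, n_outcome)
  tab <- do.call(rbind, lapply(fits, function(f) {
    data.frame(method = f$method, beta = f$beta, se = f$se, p = f$pvalue,
               or_value = f$or_value, ci_low = f$ci_low, ci_high = f$ci_high,
               n_snps = f$n_snps, q = f$heterogeneity_q,
               q_p = f$heterogeneity_p,
               egger_intercept_p = f$extras$egger_intercept_p %||% NA_real_,
               global_p = f$extras$global_p %||% NA_real_,
               stringsAsFactors = FALSE)
  }))
  tab$steiger_direction_correct <- steiger$direction_correct
  tab$steiger_p <- steiger$pvalue
  rownames(tab) <- NULL
  list(fits = fits, steiger = steiger, table = tab)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
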