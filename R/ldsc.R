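# Bivariate LD-score regression: heritabilities, genetic covariance and
# genetic correlation with delete-a-block jackknife standard errors.

#' Compute LD scores from a reference panel
#'
#' The LD score of variant j is the sum of squared allelic correlations
#' with every panel variant including itself, so every score is >= 1.
#'
#' @param panel an `ld_panel`.
#' @return data.frame with SNP, L2, MAF; attribute `M` is the row count.
#' @export
compute_ld_scores <- function(panel) {
  l2 <- rowSums(panel$R^2)
  out <- data.frame(SNP = panel$variants$SNP, L2 = l2,
                    MAF = panel$variants$MAF, stringsAsFactors = FALSE)
  attr(out, "M") <- nrow(out)
  out
}

# weighted simple regression (free intercept) from sufficient statistics;
# returns per-block sums so delete-a-block slopes are cheap
wreg_blocks <- function(x, y, w, block) {
  g <- function(v) vapply(split(v, block), sum, numeric(1))
  cbind(sw = g(w), swx = g(w * x), swxx = g(w * x^2), swy = g(w * y),
        swxy = g(w * x * y))
}

slope_from_sums <- function(s) {
  # s: named numeric vector or matrix row of the five sums
  (s[["sw"]] * s[["swxy"]] - s[["swx"]] * s[["swy"]]) /
    (s[["sw"]] * s[["swxx"]] - s[["swx"]]^2)
}

intercept_from_sums <- function(s) {
  (s[["swy"]] - slope_from_sums(s) * s[["swx"]]) / s[["sw"]]
}

#' Bivariate LD-score regression
#'
#' Estimates each trait's SNP heritability from the regression of squared
#' z-scores on LD scores (E[z^2] = 1 + n h2 l/M, free intercept), the
#' genetic covariance from the regression of z1*z2 on LD scores
#' (E[z1 z2] = intercept + sqrt(n1 n2) rho_g l/M, free intercept so sample
#' overlap is absorbed rather than assumed away), and reports
#' rg = rho_g / sqrt(h2_1 h2_2). Weights follow standard two-step LDSC
#' practice: an unweighted pass gives provisional h2 values, and the final
#' regressions use heteroskedasticity weights 1/(1 + n h2 l/M)^2 (their
#' product, for the covariance regression). Standard errors come from a
#' delete-a-block jackknife over contiguous variant blocks. If either
#' heritability estimate is at or below `h2_floor` the genetic correlation
#' is not identified and the result status is `na_low_heritability`.
#'
#' @param z1,z2 data.frames with columns SNP and Z.
#' @param scores data.frame with SNP, L2 and (optionally) MAF.
#' @param n1,n2 GWAS sample sizes.
#' @param M number of reference SNPs for the heritability scale (defaults
#'   to the filtered variant count).
#' @param maf_min minimum minor-allele frequency (default 0.01; ignored if
#'   `scores` has no MAF column).
#' @param reference_snps optional variant-id whitelist (HapMap3-style
#'   merge); NULL keeps all.
#' @param n_jackknife_blocks contiguous jackknife blocks (default 200).
#' @param h2_floor heritability at or below which rg is reported NA
#'   (default 0).
#' @param h2_z_floor optional z-score floor: when set, rg is also NA if
#'   either h2 estimate divided by its jackknife SE falls below this
#'   (e.g. 1); NULL (default) applies only the point-estimate floor.
#' @param truncate_rg clamp the estimate into [-1, 1] (default FALSE; an
#'   estimate beyond +/-1.25 raises a warning either way).
#' @return list of class `rg_result`: rg, rg_se, rg_p, h2_1, h2_1_se,
#'   h2_2, h2_2_se, gcov, gcov_intercept, status, n_snps, n_blocks.
#' @export
estimate_rg <- function(z1, z2, scores, n1, n2, M = NULL, maf_min = 0.01,
                        reference_snps = NULL, n_jackknife_blocks = 200,
                        h2_floor = 0, h2_z_floor = NULL,
                        truncate_rg = FALSE) {
  stopifnot(n_jackknife_blocks >= 2)
  snps <- intersect(intersect(z1$SNP, z2$SNP), scores$SNP)
  if (!is.null(reference_snps)) snps <- intersect(snps, reference_snps)
  sc <- scores[match(snps, scores$SNP), , drop = FALSE]
  if ("MAF" %in% names(sc) && !all(is.na(sc$MAF))) {
    keep <- pmin(sc$MAF, 1 - sc$MAF) >= maf_min
    snps <- snps[keep]
    sc <- sc[keep, , drop = FALSE]
  }
  n_snps <- length(snps)
  if (n_snps < n_jackknife_blocks)
    stop("only ", n_snps, " variants after filtering; choose fewer than ",
         n_jackknife_blocks, " jackknife blocks")
  if (is.null(M)) M <- n_snps
  ell <- sc$L2
  za <- z1$Z[match(snps, z1$SNP)]
  zb <- z2$Z[match(snps, z2$SNP)]
  block <- ceiling(seq_len(n_snps) / (n_snps / n_jackknife_blocks))

  h2_from_slope <- function(slope, n) slope * M / n
  # pass 1: unweighted provisional heritabilities (clamped for weighting)
  w1 <- rep(1, n_snps)
  h2a_1 <- min(max(h2_from_slope(slope_from_sums(
    colSums(wreg_blocks(ell, za^2, w1, block))), n1), 0), 1)
  h2a_2 <- min(max(h2_from_slope(slope_from_sums(
    colSums(wreg_blocks(ell, zb^2, w1, block))), n2), 0), 1)
  # pass 2: heteroskedasticity weights from the provisional fits
  e1 <- 1 + n1 * h2a_1 * ell / M
  e2 <- 1 + n2 * h2a_2 * ell / M
  bs_h1 <- wreg_blocks(ell, za^2, 1 / e1^2, block)
  bs_h2 <- wreg_blocks(ell, zb^2, 1 / e2^2, block)
  bs_g <- wreg_blocks(ell, za * zb, 1 / (e1 * e2), block)

  tot_h1 <- colSums(bs_h1); tot_h2 <- colSums(bs_h2); tot_g <- colSums(bs_g)
  h2_1 <- h2_from_slope(slope_from_sums(tot_h1), n1)
  h2_2 <- h2_from_slope(slope_from_sums(tot_h2), n2)
  gcov <- slope_from_sums(tot_g) * M / sqrt(n1 * n2)
  gcov_intercept <- intercept_from_sums(tot_g)

  jack <- function(bs, f) {
    vapply(seq_len(n_jackknife_blocks),
           function(b) f(colSums(bs[-b, , drop = FALSE])), numeric(1))
  }
  jk_se <- function(theta_d) {
    d <- theta_d[is.finite(theta_d)]
    B <- length(d)
    if (B < 2) return(NA_real_)
    sqrt((B - 1) / B * sum((d - mean(d))^2))
  }
  h1_d <- jack(bs_h1, function(s) h2_from_slope(slope_from_sums(s), n1))
  h2_d <- jack(bs_h2, function(s) h2_from_slope(slope_from_sums(s), n2))
  g_d <- vapply(seq_len(n_jackknife_blocks), function(b)
    slope_from_sums(colSums(bs_g[-b, , drop = FALSE])) * M / sqrt(n1 * n2),
    numeric(1))

  res <- list(rg = NA_real_, rg_se = NA_real_, rg_p = NA_real_,
              h2_1 = h2_1, h2_1_se = jk_se(h1_d),
              h2_2 = h2_2, h2_2_se = jk_se(h2_d),
              gcov = gcov, gcov_intercept = gcov_intercept,
              status = "ok", n_snps = n_snps,
              n_blocks = n_jackknife_blocks)
  too_low <- h2_1 <= h2_floor || h2_2 <= h2_floor
  if (!too_low && !is.null(h2_z_floor))
    too_low <- h2_1 / res$h2_1_se < h2_z_floor ||
      h2_2 / res$h2_2_se < h2_z_floor
  if (too_low) {
    res$status <- "na_low_heritability"
    return(structure(res, class = "rg_result"))
  }
  rg <- gcov / sqrt(h2_1 * h2_2)
  rg_d <- g_d / sqrt(pmax(h1_d, .Machine$double.eps) *
                       pmax(h2_d, .Machine$double.eps))
  rg_se <- jk_se(rg_d)
  if (abs(rg) > 1.25)
    warning("genetic correlation estimate ", signif(rg, 4),
            " lies outside [-1.25, 1.25]")
  if (truncate_rg) rg <- min(max(rg, -1), 1)
  res$rg <- rg
  res$rg_se <- rg_se
  res$rg_p <- 2 * stats::pnorm(-abs(rg / rg_se))
  structure(res, class = "rg_result")
}

#' @export
print.rg_result <- function(x, ...) {
  if (x$status == "na_low_heritability") {
    cat(sprintf("LDSC rg: NA (too low heritability; h2 = %.4f / %.4f)\n",
                x$h2_1, x$h2_2))
  } else {
    cat(sprintf("LDSC rg = %.4f (SE %.4f, p = %.3g); h2 = %.4f / %.4f; gcov intercept = %.4f\n",
                x$rg, x$rg_se, x$rg_p, x$h2_1, x$h2_2, x$gcov_intercept))
  }
  invisible(x)
}
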