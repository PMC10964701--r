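# Bayesian colocalization with per-variant approximate Bayes factors,
# per-instrument region windows, and cross-region PPH4 averaging.

#' Approximate (Wakefield) log Bayes factor for one association
#'
#' log ABF = 0.5 log(V/(V+W)) + 0.5 z^2 W/(V+W), with V the squared
#' standard error, W the squared prior effect SD and z = beta/se. Monotone
#' increasing in |z| for fixed V and W.
#'
#' @param beta effect estimate (vectorized).
#' @param se standard error (> 0).
#' @param prior_sd prior SD of the true effect (> 0).
#' @return log Bayes factor in favour of association.
#' @export
wakefield_log_abf <- function(beta, se, prior_sd) {
  if (any(se <= 0)) stop("standard errors must be positive")
  if (any(prior_sd <= 0)) stop("prior SD must be positive")
  V <- se^2
  W <- prior_sd^2
  z2 <- (beta / se)^2
  0.5 * log(V / (V + W)) + 0.5 * z2 * W / (V + W)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b; -Inf when the difference underflows
logdiffexp <- function(a, b) {
  if (b >= a) return(-Inf)
  a + log1p(-exp(b - a))
}

#' Colocalization posteriors for one region
#'
#' Evaluates the five-hypothesis model for a region shared by two traits:
#' H0 no causal variant for either trait, H1/H2 one causal variant for one
#' trait only, H3 two distinct causal variants, H4 one shared causal
#' variant. Evidence terms are per-variant approximate Bayes factors
#' combined by configuration sums, evaluated in log space with
#' log-sum-exp, then normalized with the per-configuration priors p1, p2
#' and p12.
#'
#' @param trait1,trait2 data.frames with columns SNP, BETA, SE, restricted
#'   to the region; variants are matched on SNP.
#' @param p1,p2 prior probability that a variant is causal for trait 1
#'   (resp. 2) only (default 1e-4).
#' @param p12 prior probability that a variant is causal for both traits
#'   (default 1e-5).
#' @param prior_sd1,prior_sd2 prior effect SDs (default 0.2; for binary
#'   traits this is on the log-odds scale).
#' @return list of class `coloc_posterior`: pph0..pph4 (sum to 1),
#'   n_snps, priors.
#' @export
coloc_region <- function(trait1, trait2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                         prior_sd1 = 0.2, prior_sd2 = 0.2) {
  stopifnot(p1 > 0, p2 > 0, p12 > 0)
  if (p1 + p2 + p12 >= 0.1)
    stop("per-variant priors look implausibly large (p1 + p2 + p12 >= 0.1)")
  snps <- intersect(trait1$SNP, trait2$SNP)
  q <- length(snps)
  if (q < 1) stop("no shared variants in the region")
  t1 <- trait1[match(snps, trait1$SNP), ]
  t2 <- trait2[match(snps, trait2$SNP), ]
  l1 <- wakefield_log_abf(t1$BETA, t1$SE, prior_sd1)
  l2 <- wakefield_log_abf(t2$BETA, t2$SE, prior_sd2)

  ls1 <- logsumexp(l1)
  ls2 <- logsumexp(l2)
  ls12 <- logsumexp(l1 + l2)
  lh <- c(h0 = 0,
          h1 = log(p1) + ls1,
          h2 = log(p2) + ls2,
          h3 = if (q > 1) log(p1) + log(p2) + logdiffexp(ls1 + ls2, ls12)
               else -Inf,
          h4 = log(p12) + ls12)
  post <- exp(lh - logsumexp(lh))
  structure(list(pph0 = post[["h0"]], pph1 = post[["h1"]],
                 pph2 = post[["h2"]], pph3 = post[["h3"]],
                 pph4 = post[["h4"]], n_snps = q,
                 priors = c(p1 = p1, p2 = p2, p12 = p12),
                 prior_sd = c(prior_sd1, prior_sd2)),
            class = "coloc_posterior")
}

#' @export
print.coloc_posterior <- function(x, ...) {
  cat(sprintf("Coloc (%d SNPs): PPH0-4 = %.3f %.3f %.3f %.3f %.3f\n",
              x$n_snps, x$pph0, x$pph1, x$pph2, x$pph3, x$pph4))
  invisible(x)
}

#' Build per-instrument colocalization regions
#'
#' One region per instrument: all variants shared by the two tables lying
#' within `window_bp` of the instrument on its chromosome (a window of
#' that half-width upstream and downstream).
#'
#' @param exposure,outcome `summary_stats` objects.
#' @param instrument_snps character vector of instrument variant ids.
#' @param window_bp half-width in base pairs (default 500 kb).
#' @return list of regions, each a list with `region_id`, `center`,
#'   `trait1`, `trait2`.
#' @export
make_coloc_regions <- function(exposure, outcome, instrument_snps,
                               window_bp = 500000) {
  lapply(instrument_snps, function(snp) {
    i <- match(snp, exposure$SNP)
    if (is.na(i)) return(NULL)
    chr <- exposure$CHR[i]; pos <- exposure$POS[i]
    in_win <- function(tab) tab[tab$CHR == chr &
                                  abs(tab$POS - pos) <= window_bp, ,
                                drop = FALSE]
    list(region_id = paste0("region_", snp), center = snp,
         trait1 = in_win(as.data.frame(exposure)),
         trait2 = in_win(as.data.frame(outcome)))
  })
}

#' Aggregate colocalization evidence across instrument regions
#'
#' Runs [coloc_region()] on every region and averages PPH4 across regions
#' (unweighted arithmetic mean); the pair is called colocalized when the
#' mean exceeds `threshold`. Regions with no shared variants are dropped
#' with a warning and excluded from the mean.
#'
#' @param regions list of regions as from [make_coloc_regions()], or any
#'   list of lists with `trait1`/`trait2` elements.
#' @param p1,p2,p12,prior_sd1,prior_sd2 see [coloc_region()].
#' @param threshold mean-PPH4 call threshold (default 0.75).
#' @return list of class `coloc_summary`: `per_region` data.frame,
#'   `mean_pph4`, `shared_call`, `threshold`.
#' @export
aggregate_coloc <- function(regions, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                            prior_sd1 = 0.2, prior_sd2 = 0.2,
                            threshold = 0.75) {
  regions <- Filter(Negate(is.null), regions)
  if (length(regions) == 0) stop("no regions to colocalize")
  rows <- list()
  for (k in seq_along(regions)) {
    r <- regions[[k]]
    fit <- tryCatch(
      coloc_region(r$trait1, r$trait2, p1, p2, p12, prior_sd1, prior_sd2),
      error = function(e) e)
    if (inherits(fit, "error")) {
      warning("region ", r$region_id %||% k, " dropped: ",
              conditionMessage(fit))
      next
    }
    rows[[length(rows) + 1]] <- data.frame(
      region_id = r$region_id %||% paste0("region_", k),
      center = r$center %||% NA_character_, n_snps = fit$n_snps,
      pph0 = fit$pph0, pph1 = fit$pph1, pph2 = fit$pph2, pph3 = fit$pph3,
      pph4 = fit$pph4, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) stop("no usable regions after dropping empties")
  per_region <- do.call(rbind, rows)
  agg <- summarize_pph4(per_region$pph4, threshold)
  structure(list(per_region = per_region, mean_pph4 = agg$mean_pph4,
                 shared_call = agg$shared_call, threshold = threshold,
                 priors = c(p1 = p1, p2 = p2, p12 = p12)),
            class = "coloc_summary")
}

#' @export
print.coloc_summary <- function(x, ...) {
  cat(sprintf("Coloc summary: %d region(s), mean PPH4 = %.3f -> %s (threshold %.2f)\n",
              nrow(x$per_region), x$mean_pph4,
              if (x$shared_call) "shared causal variant" else "not shared",
              x$threshold))
  invisible(x)
}
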