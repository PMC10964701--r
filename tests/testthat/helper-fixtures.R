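# Shared fixtures and independent oracles for the test suite.

# harmonized-pairs table straight from effect vectors
make_pairs <- function(bx, by, sx = rep(0.02, length(bx)),
                       sy = rep(0.02, length(bx)),
                       eafx = rep(0.3, length(bx)), eafy = eafx) {
  m <- length(bx)
  data.frame(SNP = sprintf("rs%04d", seq_len(m)), CHR = "1",
             POS = 10000 * seq_len(m), EA = "A", OA = "G",
             exposure_beta = bx, exposure_se = sx, exposure_eaf = eafx,
             exposure_p = 2 * pnorm(-abs(bx / sx)),
             outcome_beta = by, outcome_se = sy, outcome_eaf = eafy,
             outcome_p = 2 * pnorm(-abs(by / sy)),
             palindromic = FALSE, action = "kept_as_is",
             stringsAsFactors = FALSE)
}

# summary_stats table from vectors
make_sumstats <- function(beta, se, eaf = rep(0.3, length(beta)),
                          snp = sprintf("rs%04d", seq_along(beta)),
                          chr = "1", pos = 10000 * seq_along(beta),
                          ea = "A", oa = "G", n = 50000,
                          label = "trait") {
  as_summary_stats(data.frame(
    SNP = snp, CHR = chr, POS = pos, EA = ea, OA = oa, EAF = eaf,
    BETA = beta, SE = se, P = 2 * pnorm(-abs(beta / se)), N = n,
    stringsAsFactors = FALSE), trait_label = label)
}

# independent weighted-percentile oracle: scan the weighted empirical cdf
# for the 0.5 crossing and interpolate linearly
oracle_weighted_median <- function(r, w) {
  o <- order(r)
  rs <- r[o]; ws <- w[o]
  n <- length(rs)
  cdf <- numeric(n)
  for (j in seq_len(n)) cdf[j] <- (sum(ws[seq_len(j)]) - ws[j] / 2) / sum(ws)
  if (cdf[1] >= 0.5) return(rs[1])
  if (cdf[n] < 0.5) return(rs[n])
  for (j in seq_len(n - 1)) {
    if (cdf[j] < 0.5 && cdf[j + 1] >= 0.5)
      return(rs[j] + (rs[j + 1] - rs[j]) * (0.5 - cdf[j]) /
               (cdf[j + 1] - cdf[j]))
  }
}

# plain-arithmetic enumeration oracle for a small colocalization region:
# every single-causal-variant configuration per trait, truncated to at
# most one causal variant each
oracle_coloc <- function(b1, s1, b2, s2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                         w1 = 0.2, w2 = 0.2) {
  abf <- function(b, s, w) {
    V <- s^2; W <- w^2
    exp(0.5 * log(V / (V + W)) + 0.5 * (b / s)^2 * W / (V + W))
  }
  a1 <- abf(b1, s1, w1)
  a2 <- abf(b2, s2, w2)
  q <- length(a1)
  h0 <- 1
  h1 <- p1 * sum(a1)
  h2 <- p2 * sum(a2)
  h3 <- 0
  for (j in seq_len(q)) for (k in seq_len(q)) {
    if (j != k) h3 <- h3 + a1[j] * a2[k]
  }
  h3 <- p1 * p2 * h3
  h4 <- p12 * sum(a1 * a2)
  tot <- h0 + h1 + h2 + h3 + h4
  c(h0, h1, h2, h3, h4) / tot
}

# evidence profile with prescribed track states
make_profile <- function(ldsc = c("not_sig", "sig_pos", "sig_neg",
                                  "not_available"),
                         mr = c("not_sig", "sig_pos", "sig_neg"),
                         coloc = c("not_shared", "shared")) {
  ldsc <- match.arg(ldsc); mr <- match.arg(mr); coloc <- match.arg(coloc)
  rg <- switch(ldsc, sig_pos = 0.2, sig_neg = -0.2, not_sig = 0.01,
               not_available = NA_real_)
  rg_p <- switch(ldsc, sig_pos = 0.001, sig_neg = 0.001, not_sig = 0.8,
                 not_available = NA_real_)
  mr_beta <- switch(mr, sig_pos = 0.1, sig_neg = -0.1, not_sig = 0.01)
  mr_p <- switch(mr, sig_pos = 0.001, sig_neg = 0.001, not_sig = 0.6)
  pph4 <- if (coloc == "shared") 0.9 else 0.1
  evidence_profile("test_pair", rg, rg_p, mr_beta, mr_p, pph4)
}
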