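# Statistical power of two-sample MR with a binary outcome.

#' Closed-form power of a binary-outcome MR analysis
#'
#' Power of the two-sided Wald test of the causal log odds ratio at level
#' `alpha`, from the non-centrality parameter of the IV estimator:
#' ncp = n_outcome * case_fraction * (1 - case_fraction) * r2_xz *
#' log(true_or)^2, giving
#' power = Phi(-z_{1-alpha/2} + sqrt(ncp)) + Phi(-z_{1-alpha/2} - sqrt(ncp)).
#' The variance behind the ncp is the standard log-odds summary-statistic
#' approximation, the same one the package's generators use, so the closed
#' form can be checked against a Monte-Carlo rejection rate
#' ([mr_power_binary_mc()]).
#'
#' @param n_outcome outcome GWAS sample size.
#' @param case_fraction case proportion in the outcome GWAS, in (0,1).
#' @param r2_xz variance of the exposure explained by the instruments.
#' @param true_or assumed true causal odds ratio per exposure unit.
#' @param alpha two-sided significance level (default 0.05).
#' @return list of class `power_result`: power, ncp, alpha and the echoed
#'   inputs.
#' @export
mr_power_binary <- function(n_outcome, case_fraction, r2_xz, true_or,
                            alpha = 0.05) {
  stopifnot(n_outcome > 0, case_fraction > 0, case_fraction < 1,
            r2_xz >= 0, r2_xz <= 1, true_or > 0, alpha > 0, alpha < 1)
  if (r2_xz == 0 && true_or != 1)
    warning("r2_xz = 0: the instrument carries no signal; power equals alpha")
  ncp <- n_outcome * case_fraction * (1 - case_fraction) * r2_xz *
    log(true_or)^2
  zc <- stats::qnorm(1 - alpha / 2)
  power <- stats::pnorm(-zc + sqrt(ncp)) + stats::pnorm(-zc - sqrt(ncp))
  structure(list(power = power, ncp = ncp, alpha = alpha,
                 n_outcome = n_outcome, case_fraction = case_fraction,
                 r2_xz = r2_xz, true_or = true_or),
            class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf("MR power: %.3f (ncp %.3f) at alpha %.3g | n = %d, cases %.0f%%, r2 = %.3g, OR = %.3g\n",
              x$power, x$ncp, x$alpha, x$n_outcome,
              100 * x$case_fraction, x$r2_xz, x$true_or))
  invisible(x)
}

#' Monte-Carlo power of binary-outcome MR
#'
#' Simulates the full two-sample summary-statistic pipeline (instrument
#' effects scaled so they explain `r2_xz` of the exposure, outcome betas on
#' the log-odds scale with the binary-trait variance approximation, IVW
#' test at `alpha`) and returns the rejection rate. Serves as the
#' simulation cross-check of [mr_power_binary()].
#'
#' @inheritParams mr_power_binary
#' @param m_instruments instruments carrying the signal (default 30).
#' @param n_exposure exposure GWAS size (default 5e5, so exposure-side
#'   noise is negligible, as the closed form assumes).
#' @param n_rep replicates (default 2000).
#' @param seed integer seed.
#' @return rejection proportion.
#' @export
mr_power_binary_mc <- function(n_outcome, case_fraction, r2_xz, true_or,
                               alpha = 0.05, m_instruments = 30,
                               n_exposure = 5e5, n_rep = 2000, seed = 1) {
  set.seed(seed)
  m <- m_instruments
  b1 <- log(true_or)
  rej <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    maf <- stats::runif(m, 0.1, 0.5)
    gamma <- stats::runif(m, 0.5, 1.5) * sample(c(-1, 1), m, TRUE)
    # rescale so the instruments explain exactly r2_xz of the exposure
    gamma <- gamma * sqrt(r2_xz / sum(2 * maf * (1 - maf) * gamma^2))
    se_x <- se_approx(maf, n_exposure)
    se_y <- se_approx(maf, n_outcome, case_fraction)
    bx <- stats::rnorm(m, gamma, se_x)
    by <- stats::rnorm(m, b1 * gamma, se_y)
    w <- bx^2 / se_y^2
    beta <- sum(w * (by / bx)) / sum(w)
    se <- 1 / sqrt(sum(w))
    rej[i] <- 2 * stats::pnorm(-abs(beta / se)) < alpha
  }
  mean(rej)
}

#' Power table over a grid of odds ratios
#'
#' @inheritParams mr_power_binary
#' @param or_grid odds ratios to tabulate.
#' @return data.frame with or_value, ncp, power.
#' @export
mr_power_table <- function(n_outcome, case_fraction, r2_xz,
                           or_grid = c(0.8, 0.9, 1.1, 1.2, 1.5),
                           alpha = 0.05) {
  rows <- lapply(or_grid, function(or_value) {
    p <- mr_power_binary(n_outcome, case_fraction, r2_xz, or_value, alpha)
    data.frame(or_value = or_value, ncp = p$ncp, power = p$power)
  })
  do.call(rbind, rows)
}
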