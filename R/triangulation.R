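# Decision table combining genetic-correlation, MR and colocalization
# outcomes into ten evidence patterns and nine explanations, plus the
# eight-domain risk-of-bias structure.

EXPLANATION_TEXT <- c(
  i = "strong genetic evidence for a causal association",
  ii = "genetic evidence is contradictory (significant but in opposite directions)",
  iii = "causal association without shared causal genetic variants",
  iv = "possible false positive causal association",
  v = "possible false negative causal association",
  vi = "pleiotropy without shared causal genetic variants",
  vii = "weak genetic evidence for a causal association",
  viii = "shared causal genetic variants but not enough evidence of causality",
  ix = "no genetic evidence for a causal association"
)

#' Assemble an evidence profile for one exposure-outcome pair
#'
#' Converts the three tracks' numeric results into significance states at
#' the framework's thresholds: genetic correlation and MR significant when
#' p < `p_threshold` (signed by the estimate), colocalization shared when
#' the mean PPH4 exceeds `pph4_threshold`. An unavailable genetic
#' correlation (low heritability) is recorded as `not_available`.
#'
#' @param pair_id label for the exposure-outcome pair.
#' @param rg,rg_p genetic correlation estimate and p-value (NA when the
#'   LDSC result is unavailable).
#' @param mr_beta,mr_p causal log-OR estimate and p-value.
#' @param mean_pph4 cross-region average colocalization PPH4.
#' @param mr_source which MR result feeds the framework: the primary IVW
#'   estimate or a pleiotropy-adjusted one.
#' @param p_threshold significance level for LDSC and MR (default 0.05,
#'   no multiple-testing correction).
#' @param pph4_threshold colocalization call level (default 0.75).
#' @return list of class `evidence_profile`.
#' @export
evidence_profile <- function(pair_id, rg, rg_p, mr_beta, mr_p, mean_pph4,
                             mr_source = c("primary_ivw",
                                           "pleiotropy_adjusted"),
                             p_threshold = 0.05, pph4_threshold = 0.75) {
  mr_source <- match.arg(mr_source)
  ldsc_state <- if (is.na(rg) || is.na(rg_p)) "not_available"
    else if (rg_p >= p_threshold) "not_sig"
    else if (rg >= 0) "sig_pos" else "sig_neg"
  mr_state <- if (mr_p >= p_threshold) "not_sig"
    else if (mr_beta >= 0) "sig_pos" else "sig_neg"
  coloc_state <- if (mean_pph4 > pph4_threshold) "shared" else "not_shared"
  structure(list(pair_id = pair_id, ldsc_state = ldsc_state,
                 mr_state = mr_state, mr_source = mr_source,
                 coloc_state = coloc_state,
                 rg = rg, rg_p = rg_p, mr_beta = mr_beta, mr_p = mr_p,
                 mean_pph4 = mean_pph4, p_threshold = p_threshold,
                 pph4_threshold = pph4_threshold),
            class = "evidence_profile")
}

#' Classify an evidence profile into a pattern and explanation
#'
#' Deterministic, total mapping of the three tracks' states onto ten
#' patterns and nine explanations. Direction agreement compares the sign
#' of the genetic correlation with the sign of the causal log odds ratio;
#' colocalization carries no direction. An unavailable genetic correlation
#' is treated as not significant and flagged `ldsc_na_treated_as_ns`.
#'
#' Patterns (L = genetic correlation, M = MR, C = colocalization):
#' 1 L+M significant same direction, C shared -> i; 2 same but opposite
#' directions -> ii; 3 L+M significant same direction, C not shared ->
#' iii; 4 L+M significant opposite directions, C not shared -> iv; 5 only
#' M significant, C not shared -> iv; 6 only L significant, C shared ->
#' v; 7 only L significant, C not shared -> vi; 8 only M significant, C
#' shared -> vii; 9 neither significant, C shared -> viii; 10 nothing ->
#' ix.
#'
#' @param profile an [evidence_profile()].
#' @return list of class `verdict`: pattern_index (1-10),
#'   explanation_code (i-ix), explanation_text, flags.
#' @export
classify_evidence <- function(profile) {
  stopifnot(inherits(profile, "evidence_profile"))
  flags <- character(0)
  L <- profile$ldsc_state
  if (L == "not_available") {
    flags <- c(flags, "ldsc_na_treated_as_ns")
    L <- "not_sig"
  }
  l_sig <- L %in% c("sig_pos", "sig_neg")
  m_sig <- profile$mr_state %in% c("sig_pos", "sig_neg")
  shared <- profile$coloc_state == "shared"
  same_dir <- l_sig && m_sig && (L == profile$mr_state)
  if (profile$mr_source == "pleiotropy_adjusted")
    flags <- c(flags, "mr_pleiotropy_adjusted")

  key <- if (l_sig && m_sig && shared && same_dir) c(1L, "i")
    else if (l_sig && m_sig && shared) c(2L, "ii")
    else if (l_sig && m_sig && !shared && same_dir) c(3L, "iii")
    else if (l_sig && m_sig && !shared) c(4L, "iv")
    else if (!l_sig && m_sig && !shared) c(5L, "iv")
    else if (l_sig && !m_sig && shared) c(6L, "v")
    else if (l_sig && !m_sig && !shared) c(7L, "vi")
    else if (!l_sig && m_sig && shared) c(8L, "vii")
    else if (!l_sig && !m_sig && shared) c(9L, "viii")
    else c(10L, "ix")

  structure(list(pair_id = profile$pair_id,
                 pattern_index = as.integer(key[1]),
                 explanation_code = key[2],
                 explanation_text = unname(EXPLANATION_TEXT[key[2]]),
                 flags = flags),
            class = "verdict")
}

#' @export
print.verdict <- function(x, ...) {
  cat(sprintf("%s: pattern %d, explanation %s — %s%s\n",
              x$pair_id %||% "pair", x$pattern_index, x$explanation_code,
              x$explanation_text,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ", "),
                                          "]") else ""))
  invisible(x)
}

BIAS_DOMAINS <- c("weak_instrument", "pleiotropy", "sample_overlap",
                  "population_stratification", "sensitivity_inconsistency",
                  "lack_of_repeatability",
                  "inconsistency_with_other_designs", "reporting")

#' Overall risk-of-bias judgment over eight domains
#'
#' Each domain is judged low, moderate or high; a domain without
#' information defaults to moderate (flagged). The overall judgment is the
#' worst domain: high if any domain is high, else moderate if any is
#' moderate, else low.
#'
#' @param domains named character vector or list; names from
#'   `weak_instrument`, `pleiotropy`, `sample_overlap`,
#'   `population_stratification`, `sensitivity_inconsistency`,
#'   `lack_of_repeatability`, `inconsistency_with_other_designs`,
#'   `reporting`; values `low`/`moderate`/`high`.
#' @return list of class `bias_assessment`: per-domain judgments,
#'   `overall`, `flags`.
#' @export
overall_risk_of_bias <- function(domains) {
  domains <- unlist(domains)
  unknown <- setdiff(names(domains), BIAS_DOMAINS)
  if (length(unknown) > 0)
    stop("unknown bias domain(s): ", paste(unknown, collapse = ", "),
         "; valid domains are: ", paste(BIAS_DOMAINS, collapse = ", "))
  bad <- !domains %in% c("low", "moderate", "high")
  if (any(bad))
    stop("judgments must be low/moderate/high; got: ",
         paste(unique(domains[bad]), collapse = ", "))
  flags <- character(0)
  full <- stats::setNames(rep(NA_character_, length(BIAS_DOMAINS)),
                          BIAS_DOMAINS)
  full[names(domains)] <- domains
  if (anyNA(full)) {
    flags <- paste0("no_information_", names(full)[is.na(full)])
    full[is.na(full)] <- "moderate"
  }
  overall <- if (any(full == "high")) "high"
    else if (any(full == "moderate")) "moderate" else "low"
  structure(list(domains = full, overall = overall, flags = flags),
            class = "bias_assessment")
}

#' @export
print.bias_assessment <- function(x, ...) {
  cat("Risk of bias:", x$overall, "\n")
  for (d in names(x$domains)) cat(sprintf("  %-33s %s\n", d, x$domains[d]))
  invisible(x)
}
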