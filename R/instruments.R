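# Instrument selection: significance thresholding, greedy LD clumping,
# strength statistics, and confounder-associated SNP removal.

#' Select independent instrumental variables by greedy LD clumping
#'
#' Candidates with p-value below `p_threshold` are ranked by ascending
#' p-value (ties broken by ascending variant id for determinism). The best
#' remaining candidate is kept and all remaining candidates on the same
#' chromosome within `window_kb` kilobases whose LD r-squared with it is at
#' least `r2_threshold` are discarded; this repeats until no candidate
#' remains. Variants absent from the LD panel are treated as independent of
#' everything (kept) with a warning.
#'
#' @param table a `summary_stats` object.
#' @param panel an `ld_panel` covering (ideally) all candidates.
#' @param p_threshold genome-wide significance cutoff (default 5e-8).
#' @param r2_threshold LD r-squared above which variants are considered
#'   dependent (default 0.001).
#' @param window_kb clumping window half-width in kilobases (default 10000).
#' @return an `instrument_set`: list with `instruments` (data.frame SNP,
#'   CHR, POS, EAF, BETA, SE, P) and `params`.
#' @export
select_instruments <- function(table, panel, p_threshold = 5e-8,
                               r2_threshold = 0.001, window_kb = 10000) {
  cand <- as.data.frame(table)[table$P < p_threshold, , drop = FALSE]
  params <- list(p_threshold = p_threshold, r2_threshold = r2_threshold,
                 window_kb = window_kb)
  if (nrow(cand) == 0) {
    warning("no variants pass the significance threshold")
    return(structure(list(instruments = cand, params = params),
                     class = "instrument_set"))
  }
  cand <- cand[order(cand$P, cand$SNP), , drop = FALSE]
  in_panel <- cand$SNP %in% panel$variants$SNP
  if (!all(in_panel))
    warning(sum(!in_panel), " candidate variant(s) missing from the LD ",
            "panel are treated as independent of all others")
  ridx <- match(cand$SNP, panel$variants$SNP)

  keep <- logical(nrow(cand))
  alive <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!alive[i]) next
    keep[i] <- TRUE
    alive[i] <- FALSE
    later <- which(alive)
    if (length(later) == 0) break
    same_chr <- cand$CHR[later] == cand$CHR[i]
    in_window <- same_chr &
      abs(cand$POS[later] - cand$POS[i]) <= window_kb * 1000
    r2 <- rep(0, length(later))
    if (!is.na(ridx[i])) {
      ok <- !is.na(ridx[later])
      r2[ok] <- panel$R[ridx[i], ridx[later][ok]]^2
    }
    alive[later[in_window & r2 >= r2_threshold]] <- FALSE
  }
  sel <- cand[keep, , drop = FALSE]
  sel <- sel[order(sel$SNP), , drop = FALSE]
  rownames(sel) <- NULL
  structure(list(instruments = sel, params = params),
            class = "instrument_set")
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("Instrument set: %d variants (p < %g, clump r2 < %g, window %d kb)\n",
              nrow(x$instruments), x$params$p_threshold,
              x$params$r2_threshold, x$params$window_kb))
  invisible(x)
}

#' Instrument strength: per-variant and summed R-squared and F statistics
#'
#' Per variant, the variance explained is R2 = 2 EAF (1-EAF) beta^2 and the
#' strength statistic is F = beta^2 / se^2; the report sums both across the
#' set. Sets whose minimum or mean F is 10 or below are flagged as at risk
#' of weak-instrument bias (reported, never auto-filtered). Summed R2 above
#' 1 is arithmetically possible for unstandardized betas and triggers a
#' warning.
#'
#' @param set an `instrument_set`.
#' @return a `strength_report`: list with `per_variant` (SNP, r2, f),
#'   `total_r2`, `total_f`, `min_f`, `mean_f`, `weak_instrument_risk`.
#' @export
instrument_strength <- function(set) {
  iv <- set$instruments
  if (any(is.na(iv$EAF)))
    stop("missing EAF for variant(s): ",
         paste(iv$SNP[is.na(iv$EAF)], collapse = ", "))
  r2 <- 2 * iv$EAF * (1 - iv$EAF) * iv$BETA^2
  f <- iv$BETA^2 / iv$SE^2
  total_r2 <- sum(r2)
  if (isTRUE(total_r2 > 1))
    warning("summed R2 exceeds 100% (", signif(total_r2 * 100, 4),
            "%); per-variant R2 values are not jointly standardized")
  structure(list(per_variant = data.frame(SNP = iv$SNP, r2 = r2, f = f,
                                          stringsAsFactors = FALSE),
                 total_r2 = total_r2, total_f = sum(f),
                 min_f = if (length(f)) min(f) else NA_real_,
                 mean_f = if (length(f)) mean(f) else NA_real_,
                 weak_instrument_risk = length(f) > 0 &&
                   (min(f) <= 10 || mean(f) <= 10)),
            class = "strength_report")
}

#' @export
print.strength_report <- function(x, ...) {
  cat(sprintf("Instrument strength: m = %d, total R2 = %.4f, total F = %.1f, min F = %.1f%s\n",
              nrow(x$per_variant), x$total_r2, x$total_f, x$min_f,
              if (x$weak_instrument_risk) " [weak-instrument risk]" else ""))
  invisible(x)
}

#' Remove instruments associated with confounding traits
#'
#' Drops any instrument having an annotation row whose trait name matches a
#' listed confounder (case-insensitive, whitespace-normalized exact match)
#' with proxy r-squared at least `proxy_r2_min` and p-value at most `p_max`.
#' Mirrors a PhenoScanner-style lookup of secondary trait associations.
#'
#' @param set an `instrument_set`.
#' @param annotations data.frame with columns SNP, TRAIT, P, PROXY_R2.
#' @param confounder_names character vector of confounder trait names.
#' @param proxy_r2_min minimum proxy r-squared (default 0.8).
#' @param p_max maximum association p-value (default 5e-8).
#' @return the filtered `instrument_set`, with a `removal_log` element
#'   (data.frame of removed SNP / matched trait / P / PROXY_R2).
#' @export
remove_confounder_snps <- function(set, annotations, confounder_names,
                                   proxy_r2_min = 0.8, p_max = 5e-8) {
  norm <- function(x) tolower(gsub("\\s+", " ", trimws(x)))
  conf <- norm(confounder_names)
  unmatched <- confounder_names[!conf %in% norm(annotations$TRAIT)]
  if (length(unmatched) > 0 && nrow(annotations) > 0)
    warning("confounder name(s) not present in the annotation table: ",
            paste(unmatched, collapse = ", "))
  hit <- annotations[norm(annotations$TRAIT) %in% conf &
                       annotations$PROXY_R2 >= proxy_r2_min &
                       annotations$P <= p_max, , drop = FALSE]
  removed <- set$instruments$SNP %in% hit$SNP
  out <- set
  out$removal_log <- hit[hit$SNP %in% set$instruments$SNP, , drop = FALSE]
  out$instruments <- set$instruments[!removed, , drop = FALSE]
  rownames(out$instruments) <- NULL
  out$params$confounder_filter <- list(confounder_names = confounder_names,
                                       proxy_r2_min = proxy_r2_min,
                                       p_max = p_max)
  out
}
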