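# Reading, validating and harmonizing GWAS summary statistics.

CANONICAL_COLS <- c("SNP", "CHR", "POS", "EA", "OA", "EAF", "BETA", "SE", "P",
                    "N", "N_CASE", "N_CONTROL")

#' Read and validate a GWAS summary-statistics table
#'
#' Reads a tab-separated file of per-variant association records, maps its
#' headers onto the canonical fields, and validates every row. Rows violating
#' the invariants (non-positive standard error, allele frequency outside
#' (0,1), p-value outside (0,1], identical effect/other alleles, inconsistent
#' case/control counts) are dropped and counted; duplicated variant ids are
#' rejected. Gzip-compressed input is accepted.
#'
#' @param path path to a tab-separated file with a header row.
#' @param column_map named character vector mapping canonical field names
#'   (`SNP`, `CHR`, `POS`, `EA`, `OA`, `EAF`, `BETA`, `SE`, `P`, `N`,
#'   `N_CASE`, `N_CONTROL`) to the file's headers. Defaults to the identity
#'   mapping, i.e. the file already uses canonical names.
#' @param trait_type `"quantitative"` or `"binary"`. For binary traits `BETA`
#'   is interpreted as a log odds ratio.
#' @param trait_label human-readable trait name carried through reports.
#' @return an object of class `summary_stats`: a `data.frame` with canonical
#'   columns plus attributes `trait_label`, `trait_type` and `rejected`
#'   (named integer vector of per-reason rejection counts).
#' @export
read_summary_stats <- function(path, column_map = NULL,
                               trait_type = c("quantitative", "binary"),
                               trait_label = basename(path)) {
  trait_type <- match.arg(trait_type)
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.gz$", path)) {
    con <- gzfile(path, "rt")
    on.exit(close(con))
    dt <- data.table::fread(text = readLines(con), sep = "\t",
                            header = TRUE, data.table = FALSE,
                            showProgress = FALSE)
  } else {
    dt <- data.table::fread(path, sep = "\t", header = TRUE,
                            data.table = FALSE, showProgress = FALSE)
  }
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      idx <- match(column_map[[canon]], names(dt))
      if (!is.na(idx)) names(dt)[idx] <- canon
    }
  }
  mandatory <- c("SNP", "EA", "OA", "EAF", "BETA", "SE", "P")
  missing <- setdiff(mandatory, names(dt))
  if (length(missing) > 0)
    stop("missing mandatory column(s): ", paste(missing, collapse = ", "))
  for (opt in setdiff(CANONICAL_COLS, names(dt))) dt[[opt]] <- NA
  dt <- dt[CANONICAL_COLS]
  for (num in c("POS", "EAF", "BETA", "SE", "P", "N", "N_CASE", "N_CONTROL"))
    dt[[num]] <- suppressWarnings(as.numeric(dt[[num]]))
  dt$SNP <- as.character(dt$SNP)
  dt$CHR <- as.character(dt$CHR)
  dt$EA <- toupper(as.character(dt$EA))
  dt$OA <- toupper(as.character(dt$OA))

  as_summary_stats(dt, trait_label = trait_label, trait_type = trait_type)
}

#' Construct a validated summary_stats object from a data frame
#'
#' Applies the same row-level validation as [read_summary_stats()]; used by
#' the synthetic-data generators and by callers who already hold a table in
#' memory.
#'
#' @param df data.frame with canonical columns (`SNP`, `EA`, `OA`, `EAF`,
#'   `BETA`, `SE`, `P` mandatory).
#' @param trait_label,trait_type see [read_summary_stats()].
#' @return a `summary_stats` object.
#' @export
as_summary_stats <- function(df, trait_label = "trait",
                             trait_type = c("quantitative", "binary")) {
  trait_type <- match.arg(trait_type)
  for (opt in setdiff(CANONICAL_COLS, names(df))) df[[opt]] <- NA
  df <- df[CANONICAL_COLS]

  bad_num  <- is.na(df$BETA) | is.na(df$SE) | is.na(df$P) | is.na(df$SNP)
  bad_se   <- !bad_num & df$SE <= 0
  bad_eaf  <- !is.na(df$EAF) & (df$EAF <= 0 | df$EAF >= 1)
  bad_p    <- !bad_num & (df$P <= 0 | df$P > 1)
  bad_all  <- !is.na(df$EA) & !is.na(df$OA) & df$EA == df$OA
  has_cc   <- !is.na(df$N_CASE) & !is.na(df$N_CONTROL) & !is.na(df$N)
  bad_cc   <- has_cc & (df$N_CASE + df$N_CONTROL != df$N)
  dup      <- duplicated(df$SNP)

  reject <- bad_num | bad_se | bad_eaf | bad_p | bad_all | bad_cc | dup
  rejected <- c(unparseable = sum(bad_num), se_nonpositive = sum(bad_se),
                eaf_out_of_range = sum(bad_eaf), p_out_of_range = sum(bad_p),
                identical_alleles = sum(bad_all), case_control_mismatch = sum(bad_cc),
                duplicate_id = sum(dup))
  out <- df[!reject, , drop = FALSE]
  if (nrow(out) == 0)
    stop("no valid rows after validation (", sum(reject), " rejected)")
  rownames(out) <- NULL
  structure(out, class = c("summary_stats", "data.frame"),
            trait_label = trait_label, trait_type = trait_type,
            rejected = rejected)
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("GWAS summary statistics: %s (%s), %d variants, %d rejected\n",
              attr(x, "trait_label"), attr(x, "trait_type"), nrow(x),
              sum(attr(x, "rejected"))))
  print.data.frame(utils::head(as.data.frame(x), 6))
  invisible(x)
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

is_palindromic <- function(a1, a2) {
  unname(COMPLEMENT[a1] == a2)
}

#' Harmonize exposure and outcome summary statistics to a shared effect allele
#'
#' For every variant present in both tables, aligns the outcome effect to the
#' exposure's effect allele. Matching alleles are kept as-is; swapped alleles
#' flip the outcome beta's sign and replace its EAF by 1 - EAF; a
#' strand-complement pair that is not palindromic is complemented and then
#' matched. Palindromic variants (A/T or C/G) are resolved by allele
#' frequency: when the minor-allele frequency on either trait exceeds
#' `palindromic_eaf_limit` the strand is ambiguous and the variant is dropped
#' (also when either EAF is missing); otherwise the frequencies infer the
#' strand. Any other allele configuration is dropped as a mismatch.
#'
#' @param exposure,outcome `summary_stats` objects.
#' @param palindromic_eaf_limit drop palindromic variants whose minor-allele
#'   frequency exceeds this on either trait (default 0.42).
#' @return data.frame of class `harmonized_pairs` with exposure/outcome
#'   effects on the shared allele, a `palindromic` flag and an `action`
#'   column (`kept_as_is`, `flipped`, `dropped_palindromic`,
#'   `dropped_mismatch`). Attribute `n_intersection` records the shared
#'   variant count.
#' @export
harmonize_pair <- function(exposure, outcome, palindromic_eaf_limit = 0.42) {
  if (nrow(exposure) == 0 || nrow(outcome) == 0)
    stop("both tables must be non-empty")
  shared <- intersect(exposure$SNP, outcome$SNP)
  if (length(shared) == 0)
    stop("no shared variant ids between exposure and outcome; ",
         "check that both use the same variant-id convention")
  ex <- exposure[match(shared, exposure$SNP), ]
  ou <- outcome[match(shared, outcome$SNP), ]

  n <- length(shared)
  action <- character(n)
  o_beta <- ou$BETA
  o_eaf <- ou$EAF
  pal <- is_palindromic(ex$EA, ex$OA)

  valid <- ex$EA %in% names(COMPLEMENT) & ex$OA %in% names(COMPLEMENT) &
    ou$EA %in% names(COMPLEMENT) & ou$OA %in% names(COMPLEMENT)

  same <- valid & ou$EA == ex$EA & ou$OA == ex$OA
  swap <- valid & ou$EA == ex$OA & ou$OA == ex$EA
  # strand-complemented representations of the same variant
  comp_same <- valid & !pal & COMPLEMENT[ou$EA] == ex$EA & COMPLEMENT[ou$OA] == ex$OA
  comp_swap <- valid & !pal & COMPLEMENT[ou$EA] == ex$OA & COMPLEMENT[ou$OA] == ex$EA

  action[same | comp_same] <- "kept_as_is"
  action[swap | comp_swap] <- "flipped"
  o_beta[swap | comp_swap] <- -o_beta[swap | comp_swap]
  o_eaf[swap | comp_swap] <- 1 - o_eaf[swap | comp_swap]
  action[!valid | action == ""] <- "dropped_mismatch"

  # palindromic variants: alleles alone cannot resolve strand; use frequency
  amb <- pal & action %in% c("kept_as_is", "flipped")
  if (any(amb)) {
    maf_ex <- pmin(ex$EAF, 1 - ex$EAF)
    maf_ou <- pmin(o_eaf, 1 - o_eaf)
    unresolvable <- amb & (is.na(maf_ex) | is.na(maf_ou) |
                             maf_ex > palindromic_eaf_limit |
                             maf_ou > palindromic_eaf_limit)
    action[unresolvable] <- "dropped_palindromic"
    # frequency-inferred strand: if the (aligned) frequencies disagree in
    # which allele is minor, the outcome record is on the other strand,
    # which for a palindromic variant means the alleles are swapped
    infer <- amb & !unresolvable
    strand_flip <- infer & ((ex$EAF < 0.5) != (o_eaf < 0.5))
    o_beta[strand_flip] <- -o_beta[strand_flip]
    o_eaf[strand_flip] <- 1 - o_eaf[strand_flip]
    action[strand_flip] <- "flipped"
  }

  out <- data.frame(
    SNP = shared, CHR = ex$CHR, POS = ex$POS,
    EA = ex$EA, OA = ex$OA,
    exposure_beta = ex$BETA, exposure_se = ex$SE, exposure_eaf = ex$EAF,
    exposure_p = ex$P,
    outcome_beta = o_beta, outcome_se = ou$SE, outcome_eaf = o_eaf,
    outcome_p = ou$P,
    palindromic = pal, action = action,
    stringsAsFactors = FALSE
  )
  structure(out, class = c("harmonized_pairs", "data.frame"),
            n_intersection = n)
}

#' Keep only retained harmonized pairs
#'
#' @param pairs output of [harmonize_pair()].
#' @return the rows whose action is `kept_as_is` or `flipped`.
#' @export
harmonized_kept <- function(pairs) {
  pairs[pairs$action %in% c("kept_as_is", "flipped"), , drop = FALSE]
}

#' Write a table in the package's TSV dialect
#'
#' @param x data.frame.
#' @param path output path.
#' @export
write_tsv <- function(x, path) {
  data.table::fwrite(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     na = "NA")
  invisible(path)
}
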