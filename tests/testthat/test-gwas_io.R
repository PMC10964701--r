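write_fixture <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

header <- "SNP\tCHR\tPOS\tEA\tOA\tEAF\tBETA\tSE\tP\tN"
row <- function(snp, eaf = 0.3, beta = 0.1, se = 0.02, p = 1e-9) {
  sprintf("%s\t1\t%d\tA\tG\t%s\t%s\t%s\t%s\t50000", snp,
          match(snp, sprintf("rs%d", 1:100)) * 1000, eaf, beta, se, p)
}

test_that("well-formed file parses with zero rejections", {
  path <- write_fixture(c(header, row("rs1"), row("rs2"), row("rs3")))
  tab <- read_summary_stats(path)
  expect_s3_class(tab, "summary_stats")
  expect_equal(nrow(tab), 3)
  expect_equal(sum(attr(tab, "rejected")), 0)
})

test_that("rows violating invariants are rejected and counted", {
  path <- write_fixture(c(header,
                          row("rs1"),
                          row("rs2", se = 0),        # se must be positive
                          row("rs3", eaf = 1.2),     # eaf outside (0,1)
                          row("rs4", p = 0),         # p outside (0,1]
                          row("rs5")))
  tab <- read_summary_stats(path)
  expect_equal(nrow(tab), 2)
  rej <- attr(tab, "rejected")
  expect_equal(unname(rej["se_nonpositive"]), 1)
  expect_equal(unname(rej["eaf_out_of_range"]), 1)
  expect_equal(unname(rej["p_out_of_range"]), 1)
})

test_that("duplicate variant ids are rejected", {
  path <- write_fixture(c(header, row("rs1"), row("rs1"), row("rs2")))
  tab <- read_summary_stats(path)
  expect_equal(nrow(tab), 2)
  expect_equal(unname(attr(tab, "rejected")["duplicate_id"]), 1)
})

test_that("missing mandatory column and zero valid rows raise errors", {
  no_se <- write_fixture(c("SNP\tEA\tOA\tEAF\tBETA\tP",
                           "rs1\tA\tG\t0.3\t0.1\t1e-9"))
  expect_error(read_summary_stats(no_se), "SE")
  all_bad <- write_fixture(c(header, row("rs1", se = 0)))
  expect_error(read_summary_stats(all_bad), "no valid rows")
})

test_that("column mapping renames nonstandard headers", {
  path <- write_fixture(c("rsid\tchrom\tbp\tref\talt\tfreq\tb\tstderr\tpval\tn",
                          "rs1\t1\t100\tA\tG\t0.3\t0.1\t0.02\t1e-9\t50000"))
  tab <- read_summary_stats(path, column_map = c(
    SNP = "rsid", CHR = "chrom", POS = "bp", EA = "ref", OA = "alt",
    EAF = "freq", BETA = "b", SE = "stderr", P = "pval", N = "n"))
  expect_equal(tab$SNP, "rs1")
  expect_equal(tab$BETA, 0.1)
})

test_that("gzip-compressed input is accepted", {
  path <- tempfile(fileext = ".tsv.gz")
  con <- gzfile(path, "wt")
  writeLines(c(header, row("rs1"), row("rs2")), con)
  close(con)
  expect_equal(nrow(read_summary_stats(path)), 2)
})

test_that("matching alleles are kept and swapped alleles are flipped", {
  ex <- make_sumstats(c(0.1, 0.1), c(0.02, 0.02), snp = c("rs1", "rs2"))
  ou <- as_summary_stats(data.frame(
    SNP = c("rs1", "rs2"), CHR = "1", POS = c(10000, 20000),
    EA = c("A", "G"), OA = c("G", "A"), EAF = c(0.3, 0.3),
    BETA = c(0.05, 0.05), SE = 0.02, P = 0.01, N = 50000,
    stringsAsFactors = FALSE))
  h <- harmonize_pair(ex, ou)
  expect_equal(h$action, c("kept_as_is", "flipped"))
  expect_equal(h$outcome_beta, c(0.05, -0.05))
  expect_equal(h$outcome_eaf, c(0.3, 0.7))
})

test_that("palindromic variants follow the frequency rule table", {
  mk_pair <- function(eaf_ex, eaf_ou, ea_ou = "A", oa_ou = "T") {
    ex <- as_summary_stats(data.frame(
      SNP = "rs1", CHR = "1", POS = 1000, EA = "A", OA = "T",
      EAF = eaf_ex, BETA = 0.1, SE = 0.02, P = 1e-9, N = 50000))
    ou <- as_summary_stats(data.frame(
      SNP = "rs1", CHR = "1", POS = 1000, EA = ea_ou, OA = oa_ou,
      EAF = eaf_ou, BETA = 0.05, SE = 0.02, P = 0.01, N = 50000))
    harmonize_pair(ex, ou, palindromic_eaf_limit = 0.42)
  }
  # ambiguous frequency on either side -> dropped
  expect_equal(mk_pair(0.50, 0.50)$action, "dropped_palindromic")
  expect_equal(mk_pair(0.10, 0.45)$action, "dropped_palindromic")
  # clear minor allele, frequencies agree -> kept unchanged
  h <- mk_pair(0.10, 0.12)
  expect_equal(h$action, "kept_as_is")
  expect_equal(h$outcome_beta, 0.05)
  # frequencies disagree in which allele is minor -> strand flip
  h2 <- mk_pair(0.10, 0.90)
  expect_equal(h2$action, "flipped")
  expect_equal(h2$outcome_beta, -0.05)
  expect_equal(h2$outcome_eaf, 0.10)
  expect_true(h$palindromic)
})

test_that("strand-complement representations are resolved", {
  ex <- make_sumstats(0.1, 0.02, snp = "rs1")  # A/G
  # outcome recorded on the other strand: T/C == complement of A/G
  ou_same <- as_summary_stats(data.frame(
    SNP = "rs1", CHR = "1", POS = 10000, EA = "T", OA = "C", EAF = 0.3,
    BETA = 0.05, SE = 0.02, P = 0.01, N = 50000))
  h <- harmonize_pair(ex, ou_same)
  expect_equal(h$action, "kept_as_is")
  expect_equal(h$outcome_beta, 0.05)
  # complement of the swapped coding: C/T -> flip
  ou_swap <- as_summary_stats(data.frame(
    SNP = "rs1", CHR = "1", POS = 10000, EA = "C", OA = "T", EAF = 0.7,
    BETA = 0.05, SE = 0.02, P = 0.01, N = 50000))
  h2 <- harmonize_pair(ex, ou_swap)
  expect_equal(h2$action, "flipped")
  expect_equal(h2$outcome_beta, -0.05)
  expect_equal(h2$outcome_eaf, 0.3)
})

test_that("unresolvable allele sets are dropped as mismatches", {
  ex <- make_sumstats(0.1, 0.02, snp = "rs1")  # A/G
  ou <- as_summary_stats(data.frame(
    SNP = "rs1", CHR = "1", POS = 10000, EA = "A", OA = "C", EAF = 0.3,
    BETA = 0.05, SE = 0.02, P = 0.01, N = 50000))
  expect_equal(harmonize_pair(ex, ou)$action, "dropped_mismatch")
})

test_that("empty intersection raises an instructive error", {
  ex <- make_sumstats(0.1, 0.02, snp = "rs1")
  ou <- make_sumstats(0.1, 0.02, snp = "rs2")
  expect_error(harmonize_pair(ex, ou), "variant-id convention")
})

test_that("harmonization is idempotent and double-flip is the identity", {
  set.seed(42)
  sim <- simulate_mr_dataset(mr_scenario(m_instruments = 20, seed = 42))
  h1 <- harmonize_pair(sim$exposure, sim$outcome)
  # feed the harmonized outcome back through: nothing changes
  ou2 <- as_summary_stats(data.frame(
    SNP = h1$SNP, CHR = h1$CHR, POS = h1$POS, EA = h1$EA, OA = h1$OA,
    EAF = h1$outcome_eaf, BETA = h1$outcome_beta, SE = h1$outcome_se,
    P = h1$outcome_p, N = 50000, stringsAsFactors = FALSE))
  h2 <- harmonize_pair(sim$exposure, ou2)
  expect_equal(h2$outcome_beta, h1$outcome_beta)
  expect_true(all(h2$action == "kept_as_is"))
  # flip outcome alleles twice -> original harmonized betas
  flip <- function(tab) as_summary_stats(data.frame(
    SNP = tab$SNP, CHR = tab$CHR, POS = tab$POS, EA = tab$OA, OA = tab$EA,
    EAF = 1 - tab$EAF, BETA = -tab$BETA, SE = tab$SE, P = tab$P,
    N = tab$N, stringsAsFactors = FALSE))
  twice <- flip(flip(sim$outcome))
  h3 <- harmonize_pair(sim$exposure, twice)
  expect_equal(h3$outcome_beta, h1$outcome_beta)
})

test_that("kept plus dropped rows equal the variant intersection", {
  ex <- make_sumstats(rep(0.1, 4), rep(0.02, 4),
                      snp = c("rs1", "rs2", "rs3", "rs4"),
                      ea = c("A", "A", "A", "A"), oa = c("G", "T", "G", "G"))
  ou <- as_summary_stats(data.frame(
    SNP = c("rs1", "rs2", "rs3", "rs5"), CHR = "1",
    POS = c(10000, 20000, 30000, 50000),
    EA = c("A", "A", "A", "A"), OA = c("G", "T", "C", "G"),
    EAF = c(0.3, 0.5, 0.3, 0.3), BETA = 0.05, SE = 0.02, P = 0.01,
    N = 50000, stringsAsFactors = FALSE))
  h <- harmonize_pair(ex, ou)
  expect_equal(nrow(h), attr(h, "n_intersection"))
  expect_equal(nrow(h), 3)
  expect_setequal(h$action[h$SNP == "rs2"], "dropped_palindromic")
  expect_setequal(h$action[h$SNP == "rs3"], "dropped_mismatch")
})
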