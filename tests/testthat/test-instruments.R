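test_that("clumping keeps the stronger of two variants in perfect LD", {
  panel <- simulate_ld_panel(2, data.frame(length = 2, rho = 0.999999),
                             seed = 1)
  panel$R[1, 2] <- panel$R[2, 1] <- 1
  tab <- make_sumstats(c(0.12, 0.11), c(0.015, 0.015),
                       snp = panel$variants$SNP)
  tab$P <- c(1e-10, 1e-9)
  sel <- select_instruments(as_summary_stats(as.data.frame(tab)), panel)
  expect_equal(sel$instruments$SNP, "rs000001")
})

test_that("the significance threshold is a strict cutoff", {
  panel <- simulate_ld_panel(2, seed = 1)
  tab <- make_sumstats(c(0.12, 0.11), c(0.015, 0.015),
                       snp = panel$variants$SNP)
  tab$P <- c(6e-8, 4e-8)
  sel <- select_instruments(as_summary_stats(as.data.frame(tab)), panel)
  expect_equal(sel$instruments$SNP, "rs000002")
})

test_that("empty candidate set yields an empty set with a warning", {
  panel <- simulate_ld_panel(2, seed = 1)
  tab <- make_sumstats(c(0.01, 0.01), c(0.02, 0.02),
                       snp = panel$variants$SNP)
  expect_warning(sel <- select_instruments(
    as_summary_stats(as.data.frame(tab)), panel), "threshold")
  expect_equal(nrow(sel$instruments), 0)
})

test_that("selection on identity LD reduces to p-value thresholding", {
  panel <- simulate_ld_panel(30, seed = 2)
  set.seed(2)
  beta <- rnorm(30, 0, 0.15)
  tab <- make_sumstats(beta, rep(0.01, 30), snp = panel$variants$SNP)
  sel <- select_instruments(tab, panel)
  expect_setequal(sel$instruments$SNP, tab$SNP[tab$P < 5e-8])
})

# straightforward reference clumper: ordered scan, quadratic search
oracle_clump <- function(tab, panel, p_thr, r2_thr, window_kb) {
  cand <- tab[tab$P < p_thr, ]
  cand <- cand[order(cand$P, cand$SNP), ]
  kept <- character(0)
  dropped <- character(0)
  for (i in seq_len(nrow(cand))) {
    if (cand$SNP[i] %in% dropped) next
    kept <- c(kept, cand$SNP[i])
    ii <- match(cand$SNP[i], panel$variants$SNP)
    for (j in seq_len(nrow(cand))) {
      if (j == i || cand$SNP[j] %in% c(kept, dropped)) next
      jj <- match(cand$SNP[j], panel$variants$SNP)
      if (cand$CHR[j] == cand$CHR[i] &&
          abs(cand$POS[j] - cand$POS[i]) <= window_kb * 1000 &&
          panel$R[ii, jj]^2 >= r2_thr)
        dropped <- c(dropped, cand$SNP[j])
    }
  }
  sort(kept)
}

test_that("greedy clumping matches the reference implementation", {
  panel <- simulate_ld_panel(20, data.frame(length = c(8, 6, 6),
                                            rho = c(0.9, 0.7, 0.95)),
                             seed = 3)
  set.seed(3)
  tab <- make_sumstats(rnorm(20, 0, 0.12), rep(0.012, 20),
                       snp = panel$variants$SNP)
  for (r2_thr in c(0.001, 0.1, 0.5)) {
    sel <- select_instruments(tab, panel, r2_threshold = r2_thr)
    expect_equal(sel$instruments$SNP,
                 oracle_clump(as.data.frame(tab), panel, 5e-8, r2_thr,
                              10000))
  }
})

test_that("clumping is invariant to input row order", {
  panel <- simulate_ld_panel(20, data.frame(length = c(10, 10),
                                            rho = c(0.9, 0.8)), seed = 4)
  set.seed(4)
  tab <- make_sumstats(rnorm(20, 0, 0.12), rep(0.012, 20),
                       snp = panel$variants$SNP)
  shuffled <- as_summary_stats(as.data.frame(tab)[sample(20), ])
  expect_equal(select_instruments(tab, panel)$instruments,
               select_instruments(shuffled, panel)$instruments)
})

test_that("variants absent from the panel are kept with a warning", {
  panel <- simulate_ld_panel(2, seed = 1)
  tab <- make_sumstats(c(0.12, 0.11, 0.13), c(0.015, 0.015, 0.015),
                       snp = c(panel$variants$SNP, "rs_unknown"))
  expect_warning(sel <- select_instruments(tab, panel), "missing from the LD")
  expect_true("rs_unknown" %in% sel$instruments$SNP)
})

test_that("strength statistics follow the stated formulas", {
  set <- structure(list(instruments = data.frame(
    SNP = c("a", "b", "c"), EAF = c(0.5, 0.2, 0.4),
    BETA = c(0.1, 0.1, 0.04), SE = c(0.02, 0.01, 0.01),
    stringsAsFactors = FALSE), params = list()),
    class = "instrument_set")
  rep <- instrument_strength(set)
  expect_equal(rep$per_variant$f[1], 25)           # (0.1/0.02)^2
  expect_equal(rep$per_variant$r2[1], 0.005)       # 2*0.5*0.5*0.01
  expect_equal(rep$total_f, 25 + 100 + 16)
  expect_equal(rep$min_f, 16)
  expect_false(rep$weak_instrument_risk)
  # F = 9 on any variant flips the weak-instrument flag
  set$instruments$BETA[3] <- 0.03
  expect_true(instrument_strength(set)$weak_instrument_risk)
})

test_that("summed R2 above 100% triggers a warning", {
  set <- structure(list(instruments = data.frame(
    SNP = c("a", "b"), EAF = c(0.5, 0.5), BETA = c(1.2, 1.1),
    SE = c(0.02, 0.02), stringsAsFactors = FALSE), params = list()),
    class = "instrument_set")
  expect_warning(instrument_strength(set), "exceeds 100%")
})

test_that("confounder filter applies both thresholds", {
  set <- structure(list(instruments = data.frame(
    SNP = c("rs1", "rs2", "rs3"), CHR = "1", POS = 1:3, EAF = 0.3,
    BETA = 0.1, SE = 0.02, P = 1e-9, stringsAsFactors = FALSE),
    params = list()), class = "instrument_set")
  ann <- data.frame(SNP = c("rs1", "rs2"),
                    TRAIT = c("Body Mass Index", "body mass index"),
                    P = c(1e-9, 1e-6), PROXY_R2 = c(0.9, 0.9),
                    stringsAsFactors = FALSE)
  out <- remove_confounder_snps(set, ann, "body mass index")
  # rs1 removed (matches case-insensitively at both thresholds);
  # rs2 retained because p = 1e-6 > 5e-8
  expect_setequal(out$instruments$SNP, c("rs2", "rs3"))
  expect_equal(out$removal_log$SNP, "rs1")
  # empty annotation table leaves the set unchanged
  empty <- remove_confounder_snps(set, ann[0, ], "body mass index")
  expect_equal(empty$instruments$SNP, set$instruments$SNP)
  # proxy r2 below the floor is not a hit
  ann2 <- data.frame(SNP = "rs3", TRAIT = "body mass index", P = 1e-9,
                     PROXY_R2 = 0.5, stringsAsFactors = FALSE)
  expect_equal(nrow(remove_confounder_snps(set, ann2,
                                           "body mass index")$removal_log),
               0)
})

test_that("unmatched confounder names raise a warning", {
  set <- structure(list(instruments = data.frame(
    SNP = "rs1", CHR = "1", POS = 1, EAF = 0.3, BETA = 0.1, SE = 0.02,
    P = 1e-9, stringsAsFactors = FALSE), params = list()),
    class = "instrument_set")
  ann <- data.frame(SNP = "rs1", TRAIT = "body mass index", P = 1e-9,
                    PROXY_R2 = 0.9, stringsAsFactors = FALSE)
  expect_warning(remove_confounder_snps(set, ann, c("body mass index",
                                                    "not a trait")),
                 "not a trait")
})

test_that("removing a candidate never introduces new selections", {
  panel <- simulate_ld_panel(20, data.frame(length = c(10, 10),
                                            rho = c(0.9, 0.8)), seed = 5)
  set.seed(5)
  tab <- make_sumstats(rnorm(20, 0, 0.12), rep(0.012, 20),
                       snp = panel$variants$SNP)
  full_pool <- tab$SNP[tab$P < 5e-8]
  sel_full <- select_instruments(tab, panel)$instruments$SNP
  for (drop in sel_full) {
    reduced <- as_summary_stats(
      as.data.frame(tab)[tab$SNP != drop, ])
    sel_red <- select_instruments(reduced, panel)$instruments$SNP
    expect_true(all(sel_red %in% full_pool))
  }
})
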