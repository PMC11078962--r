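make_ds <- function(df, id = "exp", n_total = 7824) {
  make_summary_dataset(df, trait_id = id, n_total = n_total)
}

snp_df <- function(snp, chrom, pos, pval, beta = 0.1, se = 0.01) {
  k <- length(snp)
  data.frame(snp_id = snp, chrom = as.character(chrom), pos = pos,
             effect_allele = "A", other_allele = "G", eaf = 0.3,
             beta = rep(beta, length.out = k), se = rep(se, length.out = k),
             pval = pval, n = 7824, stringsAsFactors = FALSE)
}

test_that("p-value filtering keeps exactly the sub-threshold records", {
  ds <- make_ds(snp_df(c("rs1", "rs2"), 1, c(1e6, 2e6), c(5e-6, 2e-5)))
  kept <- filter_by_pvalue(ds, 1e-5)
  expect_equal(kept$records$snp_id, "rs1")
  expect_equal(n_variants(ds), 2L)  # input untouched

  ds0 <- filter_by_pvalue(ds, 1e-7)
  expect_equal(n_variants(ds0), 0L)

  set.seed(4)
  pv <- runif(1000)
  big <- make_ds(snp_df(sprintf("rs%04d", 1:1000), 1, seq_len(1000) * 1e6,
                        pmax(pv, 1e-12)))
  # brute-force scan oracle
  expect_equal(n_variants(filter_by_pvalue(big, 0.05)),
               sum(pmax(pv, 1e-12) < 0.05))
})

test_that("greedy clumping follows the p-value order, window and r2 rules", {
  cfg_nold <- clump_config()
  one <- make_ds(snp_df("rs1", 1, 1e6, 1e-8))
  expect_equal(clump(one, cfg_nold)$records$snp_id, "rs1")

  # three same-chromosome SNPs within 100 kb, pairwise r2 = 0.5
  trio <- make_ds(snp_df(c("rs1", "rs2", "rs3"), 2,
                         c(1e6, 1.05e6, 1.1e6), c(1e-8, 1e-7, 1e-6)))
  ld <- expand.grid(snp_a = c("rs1", "rs2", "rs3"),
                    snp_b = c("rs1", "rs2", "rs3"),
                    stringsAsFactors = FALSE)
  ld <- ld[ld$snp_a < ld$snp_b, ]
  ld$r2 <- 0.5
  kept <- clump(trio, clump_config(ld = ld))
  expect_equal(kept$records$snp_id, "rs1")

  # two SNPs 600 kb apart stay independent even at r2 = 0.9
  far <- make_ds(snp_df(c("rs1", "rs2"), 3, c(1e6, 1.6e6), c(1e-8, 1e-7)))
  kept2 <- clump(far, clump_config(ld = data.frame(snp_a = "rs1",
                                                   snp_b = "rs2", r2 = 0.9)))
  expect_setequal(kept2$records$snp_id, c("rs1", "rs2"))

  # distance-only mode is conservative: one SNP per window
  kept3 <- clump(trio, cfg_nold)
  expect_equal(kept3$records$snp_id, "rs1")

  # in-window pair below the r2 cutoff is retained
  kept4 <- clump(far, clump_config(window_bp = 1e6,
                                   ld = data.frame(snp_a = "rs1",
                                                   snp_b = "rs2",
                                                   r2 = 0.005)))
  expect_setequal(kept4$records$snp_id, c("rs1", "rs2"))

  nopos <- trio
  nopos$records$pos <- NA_real_
  expect_error(clump(nopos, cfg_nold), "chrom and pos")
})

test_that("clumping is idempotent and honours the pairwise invariant", {
  sim <- simulate_pair(sim_config(n_snp_instrument = 15L,
                                  n_snp_background = 300L, seed = 21))
  sig <- filter_by_pvalue(sim$exposure, 0.01)
  cfg <- clump_config(p_threshold = 0.01)
  once <- clump(sig, cfg)
  twice <- clump(once, cfg)
  expect_equal(twice$records, once$records)
  # every retained same-chromosome pair is at least window_bp apart
  r <- once$records
  for (ch in unique(r$chrom)) {
    pos <- sort(r$pos[r$chrom == ch])
    if (length(pos) > 1) expect_true(all(diff(pos) > cfg$window_bp))
  }
})

test_that("per-SNP strength follows the squared-z / variance-explained form", {
  z0 <- per_snp_strength(0, 0.02, 1000)
  expect_equal(z0$f_stat, 0)
  expect_equal(z0$r2_explained, 0)
  st <- per_snp_strength(0.1, 0.02, 7824)
  expect_equal(st$f_stat, 25)
  expect_equal(st$r2_explained, 25 / (25 + 7822))
  expect_error(per_snp_strength(0.1, 0.02, 2), "n > 2")
})

test_that("outcome-associated and outcome-absent instruments are excluded", {
  ivs <- make_ds(snp_df(c("rs1", "rs2", "rs3"), 1, c(1, 2, 3) * 1e6,
                        rep(1e-9, 3)))
  outcome <- make_ds(snp_df(c("rs1", "rs3"), 1, c(1, 3) * 1e6,
                            c(1e-7, 0.3)), id = "out")
  res <- exclude_outcome_associated(ivs, outcome, 1e-5)
  expect_equal(res$ivs$records$snp_id, "rs3")
  expect_equal(res$removed$reason[res$removed$snp_id == "rs1"],
               "outcome_associated")
  expect_equal(res$removed$reason[res$removed$snp_id == "rs2"],
               "not_in_outcome")
})

test_that("select_instruments flags exposures with too few survivors", {
  empty <- make_ds(snp_df("rs1", 1, 1e6, 0.5))  # nothing significant
  out <- make_ds(snp_df("rs1", 1, 1e6, 0.5), id = "out")
  flag <- select_instruments(empty, out)
  expect_true(is_insufficient(flag))
  expect_equal(flag$count, 0L)

  three <- make_ds(snp_df(c("rs1", "rs2", "rs3"), c(1, 2, 3),
                          rep(1e6, 3), rep(1e-9, 3)))
  out3 <- make_ds(snp_df(c("rs1", "rs2", "rs3"), c(1, 2, 3),
                         rep(1e6, 3), rep(0.4, 3), beta = 0.001, se = 0.03),
                  id = "out")
  flag3 <- select_instruments(three, out3, min_ivs = 4L)
  expect_true(is_insufficient(flag3))
  expect_equal(flag3$count, 3L)
  # the same exposure passes with min_ivs = 3
  ok <- select_instruments(three, out3, min_ivs = 3L)
  expect_false(is_insufficient(ok))
  expect_true(all(ok$records$f_stat > 10))
})

test_that("strong synthetic instruments survive selection end to end", {
  sim <- simulate_pair(sim_config(n_snp_instrument = 20L, theta = 0,
                                  gamma_min_z = 8, palindrome_frac = 0,
                                  mismatch_frac = 0, seed = 31))
  sel <- select_instruments(sim$exposure, sim$outcome)
  expect_false(is_insufficient(sel))
  expect_equal(sort(sel$records$snp_id), sort(sim$truth$per_snp$snp_id))
  expect_true(all(sel$records$f_stat > 10))
})

test_that("selection is invariant to input row order and monotone in the
          significance threshold", {
  sim <- simulate_pair(sim_config(n_snp_instrument = 12L, gamma_min_z = 6,
                                  seed = 41))
  expo <- sim$exposure
  shuffled <- expo
  set.seed(9)
  shuffled$records <- shuffled$records[sample(nrow(shuffled$records)), ]
  sel_a <- select_instruments(expo, sim$outcome)
  sel_b <- select_instruments(shuffled, sim$outcome)
  expect_equal(sel_b$records$snp_id, sel_a$records$snp_id)

  counts <- vapply(c(1e-5, 1e-6, 1e-8), function(th) {
    s <- select_instruments(expo, sim$outcome,
                            clump_config(p_threshold = th), min_ivs = 1L)
    if (is_insufficient(s)) s$count else n_variants(s)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})
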