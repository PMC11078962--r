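screen_fixture <- function(n_null = 3, n_effect = 2, seed = 301,
                           theta = 0.6) {
  exposures <- list()
  outcome <- NULL
  k <- 1
  for (i in seq_len(n_null + n_effect)) {
    th <- if (i <= n_effect) theta else 0
    sim <- simulate_pair(sim_config(n_snp_instrument = 15L,
                                    n_snp_background = 100L, theta = th,
                                    gamma_min_z = 7, palindrome_frac = 0,
                                    mismatch_frac = 0, seed = seed + i))
    ds <- sim$exposure
    ds$trait_id <- sprintf("met%02d", i)
    if (i == 1) {
      outcome <- sim$outcome
    } else {
      # splice this exposure's outcome-side records into the shared outcome
      ids <- ds$records$snp_id
      extra <- sim$outcome$records
      extra$snp_id <- paste0(extra$snp_id, "_", i)
      ds$records$snp_id <- paste0(ds$records$snp_id, "_", i)
      outcome$records <- rbind(outcome$records, extra)
    }
    exposures[[k]] <- ds
    k <- k + 1
  }
  outcome$records <- outcome$records[!duplicated(outcome$records$snp_id), ]
  list(exposures = exposures, outcome = outcome)
}

test_that("the decision rule is evaluated in order with short-circuit verdicts", {
  ivw_sig <- data.frame(beta = 0.5, se = 0.1, pval = 0.001)
  ivw_ns <- data.frame(beta = 0.1, se = 0.2, pval = 0.5)
  sens_ok <- list(heterogeneity = FALSE, pleiotropy = FALSE,
                  loo_stable = TRUE)
  sens_het <- list(heterogeneity = TRUE, pleiotropy = FALSE,
                   loo_stable = TRUE)
  sens_unstable <- list(heterogeneity = FALSE, pleiotropy = FALSE,
                        loo_stable = FALSE)

  expect_equal(apply_decision_rule(ivw_sig, sens_ok)$verdict, "validated")
  expect_equal(apply_decision_rule(ivw_ns, sens_het)$verdict, "failed_c1")
  expect_equal(apply_decision_rule(ivw_sig, sens_het)$verdict, "failed_c2")
  expect_equal(apply_decision_rule(ivw_sig, sens_unstable)$verdict,
               "failed_c3")
  expect_equal(apply_decision_rule(ivw_sig, sens_ok,
                                   reverse_pleiotropic = TRUE)$verdict,
               "excluded_reverse_pleiotropy")
})

test_that("an empty exposure list yields an empty, well-formed screen", {
  sim <- simulate_pair(sim_config(n_snp_instrument = 5L, seed = 311))
  scr <- run_forward_screen(list(), sim$outcome)
  expect_s3_class(scr, "mr_screen")
  expect_equal(nrow(scr$table), 0L)
})

test_that("exposures with too few instruments receive the insufficient verdict", {
  fx <- screen_fixture(n_null = 1, n_effect = 0, seed = 321)
  weak <- fx$exposures[[1]]
  # keep only 3 candidate instruments above the significance threshold
  sig <- weak$records$pval < 1e-5
  weak$records <- rbind(weak$records[sig, ][1:3, ], weak$records[!sig, ])
  scr <- run_forward_screen(list(weak), fx$outcome,
                            mr_screen_config(presso_nsim = 1000L, seed = 5))
  expect_equal(scr$table$verdict, "insufficient_ivs")
  expect_equal(scr$table$n_iv, 3L)
})

test_that("effect-bearing metabolites and only those reach criterion 1", {
  fx <- screen_fixture(n_null = 3, n_effect = 2, seed = 331)
  scr <- run_forward_screen(fx$exposures, fx$outcome,
                            mr_screen_config(presso_nsim = 1000L, seed = 7))
  tab <- scr$table
  expect_equal(nrow(tab), 5L)
  expect_true(all(tab$criterion1[tab$metabolite_id %in% c("met01", "met02")]))
  # null exposures: at most one chance 5%-level false positive among three
  expect_lte(sum(tab$criterion1[tab$metabolite_id %in%
                                  c("met03", "met04", "met05")]), 1L)
  # verdict accounting: categories sum to the number of exposures
  expect_equal(sum(table(tab$verdict)), 5L)
  # paper-faithful mode: secondary estimators only for IVW-significant hits
  n_methods <- vapply(scr$records, function(r) {
    if (is.null(r$fit)) 0L else nrow(r$fit$estimates)
  }, integer(1))
  expect_true(all(n_methods[tab$criterion1] == 5L))
  expect_true(all(n_methods[!tab$criterion1] <= 1L))
  # the informational FDR column never affects the verdicts
  expect_true(all(tab$ivw_p_fdr >= tab$ivw_pval - 1e-15))
})

test_that("reverse MR detects a disease-to-metabolite effect", {
  sim <- simulate_pair(sim_config(n_snp_instrument = 12L, theta = 0.5,
                                  gamma_min_z = 7, palindrome_frac = 0,
                                  mismatch_frac = 0, seed = 341))
  # roles swapped: the simulated "exposure" acts as the disease trait
  cfg <- mr_screen_config(presso_nsim = 1000L, seed = 11)
  rev <- run_reverse_mr(sim$exposure, sim$outcome, cfg)
  expect_lt(rev$ivw$pval, 0.05)
  expect_gte(rev$n_iv, 4L)
  expect_lt(abs(rev$ivw$beta - 0.5), 3 * rev$ivw$se)

  # no reverse signal when the outcome trait has no usable instruments
  expect_error(run_reverse_mr(sim$outcome, sim$exposure, cfg),
               "instruments")
})

test_that("the screen is deterministic given config and seeds", {
  fx <- screen_fixture(n_null = 1, n_effect = 1, seed = 351)
  cfg <- mr_screen_config(presso_nsim = 1000L, seed = 13)
  s1 <- run_forward_screen(fx$exposures, fx$outcome, cfg)
  s2 <- run_forward_screen(fx$exposures, fx$outcome, cfg)
  p1 <- tempfile(); p2 <- tempfile()
  write_results_table(s1$table, p1)
  write_results_table(s2$table, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("the command-line driver runs simulate and screen end to end", {
  out_sim <- file.path(tempdir(), "cli_sim")
  code <- cli_main(c("simulate", "--out", out_sim, "--seed", "77"))
  expect_equal(code, 0L)
  expect_true(file.exists(file.path(out_sim, "exposure.tsv")))

  cfgp <- tempfile(fileext = ".yaml")
  writeLines(c("presso_nsim: 1000", "min_ivs: 4"), cfgp)
  out_scr <- file.path(tempdir(), "cli_scr")
  code2 <- cli_main(c("screen",
                      "--exposures", file.path(out_sim, "exposure.tsv"),
                      "--outcome", file.path(out_sim, "outcome.tsv"),
                      "--config", cfgp, "--seed", "77",
                      "--out", out_scr))
  expect_equal(code2, 0L)
  expect_true(file.exists(file.path(out_scr, "decisions.tsv")))
  expect_true(file.exists(file.path(out_scr, "manifest.txt")))
  dec <- read_results_table(file.path(out_scr, "decisions.tsv"))
  expect_equal(nrow(dec), 1L)

  # byte-identical on re-run with the same config and seed
  out_scr2 <- file.path(tempdir(), "cli_scr2")
  cli_main(c("screen", "--exposures", file.path(out_sim, "exposure.tsv"),
             "--outcome", file.path(out_sim, "outcome.tsv"),
             "--config", cfgp, "--seed", "77", "--out", out_scr2))
  expect_identical(readLines(file.path(out_scr2, "decisions.tsv")),
                   readLines(file.path(out_scr, "decisions.tsv")))
})

test_that("usage errors exit with status 2 and name the problem", {
  expect_equal(suppressMessages(cli_main(character())), 2L)
  expect_equal(suppressMessages(cli_main("frobnicate")), 2L)
  expect_equal(suppressMessages(
    cli_main(c("screen", "--exposures", tempfile(), "--outcome",
               tempfile(), "--out", tempdir()))), 2L)
  expect_message(cli_main(c("screen", "--exposures", "nope.tsv",
                            "--outcome", "nope2.tsv", "--out", tempdir())),
                 "missing or unreadable")
})
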