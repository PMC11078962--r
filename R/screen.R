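#' Configuration for a Mendelian randomization screen
#'
#' Gathers every tunable threshold of the pipeline in one validated object.
#'
#' @param p_threshold instrument significance cutoff (default 1e-5).
#' @param r2_max,window_bp LD clumping parameters (defaults 0.01, 500 kb).
#' @param ld optional pairwise-r2 table or file path (see [clump_config()]).
#' @param f_min minimum instrument F statistic (default 10).
#' @param min_ivs minimum instrument count per exposure (default 4).
#' @param maf_band palindromic ambiguity band (default `c(0.40, 0.60)`).
#' @param strict_palindromes drop all palindromic SNPs (default `FALSE`).
#' @param alpha decision-rule significance level (default 0.05).
#' @param n_boot bootstrap replicates for median/mode estimators.
#' @param presso_nsim MR-PRESSO simulation count (default 10000).
#' @param mode `"paper_faithful"` computes weighted-median/Egger/mode
#'   estimates only for IVW-significant exposures; `"full"` computes them
#'   for all.
#' @param fdr also report Benjamini-Hochberg adjusted IVW p-values across
#'   the screen (informational; the decision rule itself uses raw p-values,
#'   default `TRUE`).
#' @param ldsc_scope run LDSC for `"validated"` exposures only (default) or
#'   for `"all"`.
#' @param seed master integer seed for every stochastic component.
#' @return object of class `mr_screen_config`.
#' @export
mr_screen_config <- function(p_threshold = 1e-5, r2_max = 0.01,
                             window_bp = 500000L, ld = NULL, f_min = 10,
                             min_ivs = 4L, maf_band = c(0.40, 0.60),
                             strict_palindromes = FALSE, alpha = 0.05,
                             n_boot = 1000L, presso_nsim = 10000L,
                             mode = c("paper_faithful", "full"),
                             fdr = TRUE,
                             ldsc_scope = c("validated", "all"),
                             seed = 1L) {
  mode <- match.arg(mode)
  ldsc_scope <- match.arg(ldsc_scope)
  stopifnot(alpha > 0, alpha < 1, is.numeric(seed), length(seed) == 1L)
  structure(list(
    clump = clump_config(p_threshold, r2_max, window_bp, ld),
    f_min = f_min, min_ivs = as.integer(min_ivs), maf_band = maf_band,
    strict_palindromes = strict_palindromes, alpha = alpha,
    n_boot = as.integer(n_boot), presso_nsim = as.integer(presso_nsim),
    mode = mode, fdr = fdr, ldsc_scope = ldsc_scope,
    seed = as.integer(seed)),
    class = "mr_screen_config")
}

#' Apply the three-criterion causal decision rule
#'
#' An exposure's causal claim is validated when (1) the primary IVW
#' analysis is significant (p < alpha), (2) no heterogeneity (Cochran's Q
#' and the MR-PRESSO global test) and no horizontal pleiotropy (Egger
#' intercept) are detected, (3) the leave-one-out analysis is stable, and
#' additionally the reverse analysis shows no pronounced instrument
#' pleiotropy.  The criteria are evaluated in order; the first failure
#' names the verdict.
#'
#' @param ivw one-row IVW estimate data.frame.
#' @param sens a `sensitivity_report`.
#' @param reverse_significant,reverse_pleiotropic logical flags from the
#'   reverse analysis (default `FALSE` when no reverse run was done).
#' @param alpha significance level (default 0.05).
#' @return list with logical `criterion1..3`, the input flags and
#'   `verdict`, one of `validated`, `failed_c1`, `failed_c2`, `failed_c3`,
#'   `excluded_reverse_pleiotropy`.
#' @export
apply_decision_rule <- function(ivw, sens, reverse_significant = FALSE,
                                reverse_pleiotropic = FALSE, alpha = 0.05) {
  c1 <- ivw$pval < alpha
  c2 <- !(sens$heterogeneity || sens$pleiotropy)
  c3 <- isTRUE(sens$loo_stable)
  verdict <- if (!c1) "failed_c1"
  else if (!c2) "failed_c2"
  else if (!c3) "failed_c3"
  else if (reverse_pleiotropic) "excluded_reverse_pleiotropy"
  else "validated"
  list(criterion1 = c1, criterion2 = c2, criterion3 = c3,
       reverse_significant = reverse_significant,
       reverse_pleiotropic = reverse_pleiotropic, verdict = verdict)
}

# derive a distinct, bounded seed per exposure from the master seed
exposure_seed <- function(master, i) {
  (as.integer(master) + 7919L * (i %% 260000L)) %% .Machine$integer.max
}

# analyze one harmonized exposure: estimators + sensitivity (internal)
analyze_exposure <- function(h, config, seed) {
  ivw <- mr_ivw(h)
  run_secondary <- config$mode == "full" || ivw$pval < config$alpha
  methods <- if (run_secondary) {
    c("ivw", "egger", "weighted_median", "simple_mode", "weighted_mode")
  } else "ivw"
  fit <- mr_fit(h, methods = methods, n_boot = config$n_boot, seed = seed)
  sens <- sensitivity_report(h, seed = seed + 1L,
                             presso_nsim = config$presso_nsim,
                             alpha = config$alpha)
  list(fit = fit, ivw = ivw, sens = sens)
}

#' Run the forward Mendelian randomization screen
#'
#' For every exposure: instrument selection, harmonization against the
#' outcome, the five-estimator fit (secondary estimators restricted to
#' IVW-significant exposures in `paper_faithful` mode), the sensitivity
#' battery, optionally a reverse analysis and LDSC, and the three-criterion
#' decision rule.
#'
#' @param exposures list of `summary_dataset` objects (e.g. one per
#'   metabolite).
#' @param outcome `summary_dataset` for the disease outcome.
#' @param config an [mr_screen_config()].
#' @param reverse optional: the outcome dataset re-used as an exposure for
#'   reverse MR (its instruments are selected against each metabolite);
#'   pass `outcome` itself to enable reverse analyses, or `NULL` to skip.
#' @param ldscores optional LD-score table (`snp`, `l2` columns or file
#'   path) enabling LDSC heritability/correlation annotation.
#' @return object of class `mr_screen`: list with `records` (one
#'   `decision_record` per exposure), `table` (flat results data.frame) and
#'   `log`.
#' @export
run_forward_screen <- function(exposures, outcome, config = mr_screen_config(),
                               reverse = NULL, ldscores = NULL) {
  stopifnot(inherits(config, "mr_screen_config"),
            inherits(outcome, "summary_dataset"))
  if (length(exposures) == 0L) {
    return(structure(list(records = list(),
                          table = empty_screen_table(),
                          log = list(n_exposures = 0L)),
                     class = "mr_screen"))
  }
  outcome_ld <- if (!is.null(ldscores)) {
    ldsc_input_from_sumstats(outcome, ldscores)
  } else NULL
  records <- vector("list", length(exposures))
  for (i in seq_along(exposures)) {
    exp_i <- exposures[[i]]
    seed_i <- exposure_seed(config$seed, i)
    sel <- select_instruments(exp_i, outcome, config$clump,
                              f_min = config$f_min, min_ivs = config$min_ivs)
    if (is_insufficient(sel)) {
      records[[i]] <- decision_record(exp_i$trait_id, verdict = "insufficient_ivs",
                                      n_iv = sel$count)
      next
    }
    h <- harmonize(sel, outcome, maf_band = config$maf_band,
                   strict_palindromes = config$strict_palindromes)
    if (n_snps(h) < config$min_ivs) {
      records[[i]] <- decision_record(exp_i$trait_id, verdict = "insufficient_ivs",
                                      n_iv = n_snps(h))
      next
    }
    an <- analyze_exposure(h, config, seed_i)
    rev_sig <- FALSE; rev_pleio <- FALSE; rev_res <- NULL
    if (!is.null(reverse)) {
      rev_res <- tryCatch(
        run_reverse_mr(reverse, exp_i, config, seed = seed_i + 2L),
        error = function(e) NULL)
      if (!is.null(rev_res)) {
        rev_sig <- rev_res$ivw$pval < config$alpha
        rev_pleio <- rev_res$egger_intercept_pval < config$alpha
      }
    }
    rule <- apply_decision_rule(an$ivw, an$sens, rev_sig, rev_pleio,
                                alpha = config$alpha)
    h2 <- rg <- NULL
    if (!is.null(outcome_ld) &&
        (config$ldsc_scope == "all" || rule$verdict == "validated")) {
      exp_ld <- tryCatch(ldsc_input_from_sumstats(exp_i, ldscores),
                         error = function(e) NULL)
      if (!is.null(exp_ld) && length(exp_ld$z) >= 4L) {
        h2 <- tryCatch(estimate_h2(exp_ld), error = function(e) NULL)
        rg <- tryCatch(estimate_rg(exp_ld, outcome_ld),
                       error = function(e) NULL)
      }
    }
    records[[i]] <- decision_record(
      exp_i$trait_id, verdict = rule$verdict, n_iv = n_snps(h),
      fit = an$fit, ivw = an$ivw, sens = an$sens, rule = rule,
      reverse = rev_res, ldsc_h2 = h2, ldsc_rg = rg)
  }
  tab <- do.call(rbind, lapply(records, as.data.frame.decision_record))
  rownames(tab) <- NULL
  if (config$fdr) {
    tab$ivw_p_fdr <- stats::p.adjust(tab$ivw_pval, method = "BH")
  }
  verdicts <- vapply(records, function(r) r$verdict, character(1))
  structure(list(records = records, table = tab,
                 log = list(n_exposures = length(exposures),
                            verdict_counts = table(verdicts),
                            config = config)),
            class = "mr_screen")
}

decision_record <- function(metabolite_id, verdict, n_iv, fit = NULL,
                            ivw = NULL, sens = NULL, rule = NULL,
                            reverse = NULL, ldsc_h2 = NULL, ldsc_rg = NULL) {
  structure(list(metabolite_id = metabolite_id, verdict = verdict,
                 n_iv = as.integer(n_iv), fit = fit, ivw = ivw, sens = sens,
                 rule = rule, reverse = reverse, ldsc_h2 = ldsc_h2,
                 ldsc_rg = ldsc_rg),
            class = "decision_record")
}

empty_screen_table <- function() {
  data.frame(metabolite_id = character(), verdict = character(),
             n_iv = integer(), ivw_beta = numeric(), ivw_se = numeric(),
             ivw_pval = numeric(), ivw_or = numeric(),
             ivw_ci_low = numeric(), ivw_ci_high = numeric(),
             q_pval = numeric(), egger_intercept_pval = numeric(),
             presso_global_pval = numeric(), loo_stable = logical(),
             criterion1 = logical(), criterion2 = logical(),
             criterion3 = logical(), reverse_significant = logical(),
             reverse_pleiotropic = logical(), ldsc_h2 = numeric(),
             ldsc_h2_pval = numeric(), ldsc_rg = numeric(),
             ldsc_rg_pval = numeric(), stringsAsFactors = FALSE)
}

#' @export
as.data.frame.decision_record <- function(x, ...) {
  na_if_null <- function(v, f) if (is.null(v)) NA else f(v)
  data.frame(
    metabolite_id = x$metabolite_id, verdict = x$verdict, n_iv = x$n_iv,
    ivw_beta = na_if_null(x$ivw, function(v) v$beta),
    ivw_se = na_if_null(x$ivw, function(v) v$se),
    ivw_pval = na_if_null(x$ivw, function(v) v$pval),
    ivw_or = na_if_null(x$ivw, function(v) v$or_),
    ivw_ci_low = na_if_null(x$ivw, function(v) v$ci_low),
    ivw_ci_high = na_if_null(x$ivw, function(v) v$ci_high),
    q_pval = na_if_null(x$sens, function(v) v$q_pval),
    egger_intercept_pval = na_if_null(x$sens,
                                      function(v) v$egger_intercept_pval),
    presso_global_pval = na_if_null(x$sens, function(v) v$presso_global_pval),
    loo_stable = na_if_null(x$sens, function(v) v$loo_stable),
    criterion1 = na_if_null(x$rule, function(v) v$criterion1),
    criterion2 = na_if_null(x$rule, function(v) v$criterion2),
    criterion3 = na_if_null(x$rule, function(v) v$criterion3),
    reverse_significant = na_if_null(x$rule,
                                     function(v) v$reverse_significant),
    reverse_pleiotropic = na_if_null(x$rule,
                                     function(v) v$reverse_pleiotropic),
    ldsc_h2 = if (!is.null(x$ldsc_h2) && x$ldsc_h2$reliable) {
      x$ldsc_h2$h2
    } else NA_real_,
    ldsc_h2_pval = if (!is.null(x$ldsc_h2) && x$ldsc_h2$reliable) {
      x$ldsc_h2$h2_pval
    } else NA_real_,
    ldsc_rg = if (!is.null(x$ldsc_rg) && x$ldsc_rg$reliable) {
      x$ldsc_rg$rg
    } else NA_real_,
    ldsc_rg_pval = if (!is.null(x$ldsc_rg) && x$ldsc_rg$reliable) {
      x$ldsc_rg$rg_pval
    } else NA_real_,
    stringsAsFactors = FALSE)
}

#' @export
print.mr_screen <- function(x, ...) {
  cat("MR screen over", x$log$n_exposures, "exposures\n")
  if (x$log$n_exposures > 0L) {
    print(x$log$verdict_counts)
  }
  invisible(x)
}

#' Run a reverse (outcome-to-exposure) Mendelian randomization analysis
#'
#' The same per-exposure pipeline with roles swapped: instruments are
#' selected on the disease trait, harmonized against the metabolite, and
#' the IVW estimate plus Egger intercept are returned.  Its flags feed the
#' decision rule: a significant reverse IVW indicates possible reverse
#' causation; a significant reverse Egger intercept marks the exposure for
#' exclusion due to pronounced pleiotropy.
#'
#' @param outcome_as_exposure the disease `summary_dataset`, used as the
#'   exposure side.
#' @param metabolite the metabolite `summary_dataset`, used as the outcome
#'   side.
#' @param config an [mr_screen_config()].
#' @param seed integer seed (defaults to `config$seed`).
#' @return list with `ivw` (one-row estimate), `egger_intercept_pval`,
#'   `sens` (a `sensitivity_report`) and `n_iv`.
#' @export
run_reverse_mr <- function(outcome_as_exposure, metabolite,
                           config = mr_screen_config(), seed = config$seed) {
  sel <- select_instruments(outcome_as_exposure, metabolite, config$clump,
                            f_min = config$f_min, min_ivs = config$min_ivs)
  if (is_insufficient(sel)) {
    stop("reverse analysis: only ", sel$count, " instruments for ",
         outcome_as_exposure$trait_id)
  }
  h <- harmonize(sel, metabolite, maf_band = config$maf_band,
                 strict_palindromes = config$strict_palindromes)
  if (n_snps(h) < config$min_ivs) {
    stop("reverse analysis: fewer than ", config$min_ivs,
         " SNPs after harmonization")
  }
  ivw <- mr_ivw(h)
  sens <- sensitivity_report(h, seed = seed,
                             presso_nsim = config$presso_nsim,
                             alpha = config$alpha)
  list(ivw = ivw, egger_intercept_pval = sens$egger_intercept_pval,
       sens = sens, n_iv = n_snps(h))
}
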