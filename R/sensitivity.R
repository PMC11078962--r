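#' Cochran's Q heterogeneity test
#'
#' Weighted sum of squared deviations of the per-SNP Wald ratios from a
#' reference slope, with first-order weights `1/se_ratio^2 =
#' beta_x^2/se_y^2`, referred to a chi-square distribution with `J - 1`
#' degrees of freedom.
#'
#' @param h a `harmonized_set` with at least 2 SNPs.
#' @param beta_ref reference causal slope; defaults to the IVW estimate.
#' @return list with `q_stat`, `q_df`, `q_pval`.
#' @export
cochran_q <- function(h, beta_ref = NULL) {
  s <- h$snps
  J <- nrow(s)
  if (J < 2L) stop("Cochran's Q requires at least 2 SNPs")
  if (is.null(beta_ref)) beta_ref <- ivw_core(s$beta_x, s$beta_y, s$se_y)$beta
  wr <- wald_ratios(h)
  q <- sum((wr$ratio - beta_ref)^2 / wr$se^2)
  df <- J - 1L
  list(q_stat = q, q_df = df, q_pval = stats::pchisq(q, df,
                                                     lower.tail = FALSE))
}

#' MR-Egger intercept test for directional pleiotropy
#'
#' The intercept of the MR-Egger regression with its standard error and a
#' two-sided t test on `J - 2` degrees of freedom.  A significant intercept
#' (conventionally p < 0.05) indicates directional horizontal pleiotropy.
#'
#' @param h a `harmonized_set` with at least 3 SNPs.
#' @return list with `intercept`, `se`, `pval`.
#' @export
egger_intercept_test <- function(h) {
  eg <- mr_egger(h)
  list(intercept = eg$intercept$estimate, se = eg$intercept$se,
       pval = eg$intercept$pval)
}

#' Radial MR outlier diagnostics
#'
#' Re-expresses the IVW fit in the radial frame — response `ratio_j *
#' sqrt(w_j)` on predictor `sqrt(w_j)` with `w_j = beta_x_j^2/se_y_j^2` —
#' so each SNP's contribution to Cochran's Q, `Q_j = w_j (ratio_j -
#' slope)^2`, is exposed.  A SNP is flagged as an outlier when `Q_j`
#' exceeds the chi-square(1) quantile at `alpha`.  The per-SNP
#' contributions sum to Cochran's Q.
#'
#' @param h a `harmonized_set` with at least 2 SNPs.
#' @param alpha per-SNP outlier significance level (default 0.05; no
#'   multiplicity correction, matching the method's common default).
#' @return list with `slope`, `modified_q`, `per_snp_q` (named vector) and
#'   `radial_outliers` (character vector of rsIDs).
#' @export
radial_mr <- function(h, alpha = 0.05) {
  s <- h$snps
  if (nrow(s) < 2L) stop("radial MR requires at least 2 SNPs")
  wr <- wald_ratios(h)
  w <- 1 / wr$se^2
  # zero-intercept fit of ratio*sqrt(w) on sqrt(w) == IVW slope
  slope <- sum(sqrt(w) * wr$ratio * sqrt(w)) / sum(w)
  qj <- w * (wr$ratio - slope)^2
  names(qj) <- wr$snp_id
  cut <- stats::qchisq(1 - alpha, df = 1)
  list(slope = slope, modified_q = sum(qj), per_snp_q = qj,
       radial_outliers = wr$snp_id[qj > cut])
}

# leave-one-out IVW slopes for all J SNPs at once via sufficient statistics
loo_slopes <- function(beta_x, beta_y, se_y) {
  w <- 1 / se_y^2
  sxy <- sum(w * beta_x * beta_y)
  sxx <- sum(w * beta_x^2)
  (sxy - w * beta_x * beta_y) / (sxx - w * beta_x^2)
}

#' MR-PRESSO global, outlier and distortion tests
#'
#' Simulation-based residual-sum-of-squares framework for horizontal
#' pleiotropy.  The observed statistic is `RSS = sum_j w_j (beta_y_j -
#' b_(-j) beta_x_j)^2` with `w_j = 1/se_y_j^2` and `b_(-j)` the IVW slope
#' excluding SNP j.  Its null distribution is built from `n_sim` parametric
#' simulations drawing `beta_x* ~ N(beta_x, se_x^2)` and `beta_y* ~
#' N(b_(-j) beta_x, se_y^2)` and recomputing RSS; the global p-value is the
#' rank of the observed RSS (floored at `1/n_sim`).  Per-SNP outliers are
#' flagged when the Bonferroni-corrected empirical p-value of the j-th
#' residual term falls below `alpha_outlier`.  When outliers are found, the
#' distortion test compares the shift between the all-SNP and
#' outlier-removed IVW estimates against shifts from removing equally many
#' randomly chosen SNPs, and `corrected` re-estimates IVW without the
#' outliers.
#'
#' @param h a `harmonized_set` with at least 4 SNPs.
#' @param n_sim simulation replicates (default 10000, minimum 1000).
#' @param seed integer seed (mandatory).
#' @param alpha_outlier per-SNP outlier level after Bonferroni (default
#'   0.05).
#' @return list with `global_pval`, `global_pval_floor` (logical: p hit the
#'   `1/n_sim` floor), `outliers` (rsIDs), `distortion_pval`, `corrected`
#'   (one-row IVW estimate without outliers, or `NULL`).
#' @export
mr_presso <- function(h, n_sim = 10000L, seed, alpha_outlier = 0.05) {
  s <- h$snps
  J <- nrow(s)
  if (J < 4L) stop("MR-PRESSO requires at least 4 SNPs")
  stopifnot(n_sim >= 1000L)
  if (missing(seed)) stop("a simulation seed is required")
  # canonical SNP order, so the seeded p-values do not depend on row order
  s <- s[order(s$snp_id), , drop = FALSE]
  w <- 1 / s$se_y^2
  b_loo <- loo_slopes(s$beta_x, s$beta_y, s$se_y)
  res_obs <- w * (s$beta_y - b_loo * s$beta_x)^2
  rss_obs <- sum(res_obs)

  sim <- local_seed(seed, {
    bx <- matrix(stats::rnorm(J * n_sim, s$beta_x, s$se_x), nrow = J)
    by <- matrix(stats::rnorm(J * n_sim, b_loo * s$beta_x, s$se_y), nrow = J)
    # per-simulation leave-one-out slopes from column sums
    sxy <- colSums(w * bx * by)
    sxx <- colSums(w * bx^2)
    bl <- (rep(sxy, each = J) - w * bx * by) /
      (rep(sxx, each = J) - w * bx^2)
    res <- w * (by - matrix(bl, nrow = J) * bx)^2
    list(rss = colSums(res), res = res)
  })

  n_ge <- sum(sim$rss >= rss_obs)
  global_pval <- max(n_ge, 1L) / n_sim
  # per-SNP empirical p of observed residual term vs its simulated draws
  p_snp <- (rowSums(sim$res >= res_obs) + 1) / (n_sim + 1)
  p_adj <- pmin(1, p_snp * J)
  outliers <- s$snp_id[p_adj < alpha_outlier]

  distortion_pval <- NA_real_
  corrected <- NULL
  if (length(outliers) > 0L) {
    if (length(outliers) == J) stop("all SNPs flagged as MR-PRESSO outliers")
    keep <- !(s$snp_id %in% outliers)
    b_all <- ivw_core(s$beta_x, s$beta_y, s$se_y)$beta
    b_out <- ivw_core(s$beta_x[keep], s$beta_y[keep], s$se_y[keep])$beta
    d_obs <- b_all - b_out
    k <- length(outliers)
    d_null <- local_seed(seed + 1L, {
      vapply(seq_len(min(n_sim, 5000L)), function(b) {
        drop <- sample.int(J, k)
        b_all - ivw_core(s$beta_x[-drop], s$beta_y[-drop],
                         s$se_y[-drop])$beta
      }, numeric(1))
    })
    distortion_pval <- mean(abs(d_null) >= abs(d_obs))
    h_kept <- h
    h_kept$snps <- s[keep, , drop = FALSE]
    corrected <- mr_ivw(h_kept)
  }
  list(global_pval = global_pval, global_pval_floor = n_ge == 0L,
       outliers = outliers, distortion_pval = distortion_pval,
       corrected = corrected)
}

#' Leave-one-out IVW analysis
#'
#' Refits the IVW estimator excluding each SNP in turn.  The analysis is
#' stable when every leave-one-out estimate keeps the sign of the full
#' estimate and, when the full estimate is nominally significant (p <
#' 0.05), each leave-one-out estimate remains significant too — i.e. no
#' single SNP drives the finding.
#'
#' @param h a `harmonized_set` with at least 3 SNPs.
#' @return list with `loo_estimates` (data.frame: `snp_id`, `beta`, `se`,
#'   `pval` for each left-out SNP), `full` (the all-SNP IVW row) and
#'   `loo_stable` (logical).
#' @export
leave_one_out <- function(h) {
  s <- h$snps
  J <- nrow(s)
  if (J < 3L) stop("leave-one-out requires at least 3 SNPs")
  full <- mr_ivw(h)
  rows <- lapply(seq_len(J), function(j) {
    hj <- h
    hj$snps <- s[-j, , drop = FALSE]
    e <- mr_ivw(hj)
    data.frame(snp_id = s$snp_id[j], beta = e$beta, se = e$se,
               pval = e$pval, stringsAsFactors = FALSE)
  })
  loo <- do.call(rbind, rows)
  stable <- all(sign(loo$beta) == sign(full$beta)) &&
    (full$pval >= 0.05 || all(loo$pval < 0.05))
  list(loo_estimates = loo, full = full, loo_stable = stable)
}

#' Full sensitivity report for one harmonized analysis
#'
#' Bundles Cochran's Q, the Egger intercept test, Radial MR, MR-PRESSO and
#' leave-one-out into one record, together with the derived flags used by
#' the causal decision rule: heterogeneity is declared when Cochran's Q or
#' the PRESSO global test reject at `alpha`, pleiotropy when the Egger
#' intercept rejects at `alpha`.
#'
#' @param h a `harmonized_set` (at least 4 SNPs for the PRESSO component).
#' @param seed integer seed for MR-PRESSO.
#' @param presso_nsim PRESSO simulation count (default 10000).
#' @param alpha significance level for the derived flags (default 0.05).
#' @param radial_alpha per-SNP Radial outlier level (default 0.05).
#' @param presso_alpha_outlier PRESSO outlier level (default 0.05).
#' @return object of class `sensitivity_report`.
#' @export
sensitivity_report <- function(h, seed, presso_nsim = 10000L, alpha = 0.05,
                               radial_alpha = 0.05,
                               presso_alpha_outlier = 0.05) {
  if (missing(seed)) stop("a seed is required (MR-PRESSO simulations)")
  q <- cochran_q(h)
  eg <- egger_intercept_test(h)
  rad <- radial_mr(h, alpha = radial_alpha)
  pr <- if (n_snps(h) >= 4L) {
    mr_presso(h, n_sim = presso_nsim, seed = seed,
              alpha_outlier = presso_alpha_outlier)
  } else NULL
  loo <- leave_one_out(h)
  het <- q$q_pval < alpha || (!is.null(pr) && pr$global_pval < alpha)
  pleio <- eg$pval < alpha
  structure(list(
    q_stat = q$q_stat, q_df = q$q_df, q_pval = q$q_pval,
    egger_intercept = eg$intercept, egger_intercept_se = eg$se,
    egger_intercept_pval = eg$pval,
    presso_global_pval = if (is.null(pr)) NA_real_ else pr$global_pval,
    presso_outliers = if (is.null(pr)) character() else pr$outliers,
    presso_distortion_pval = if (is.null(pr)) NA_real_ else pr$distortion_pval,
    presso_corrected = if (is.null(pr)) NULL else pr$corrected,
    radial_outliers = rad$radial_outliers,
    loo_estimates = loo$loo_estimates, loo_stable = loo$loo_stable,
    heterogeneity = het, pleiotropy = pleio),
    class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf("Cochran's Q = %.3g (df %d, p = %.3g)\n",
              x$q_stat, x$q_df, x$q_pval))
  cat(sprintf("Egger intercept = %.3g (se %.3g, p = %.3g)\n",
              x$egger_intercept, x$egger_intercept_se,
              x$egger_intercept_pval))
  cat(sprintf("MR-PRESSO global p = %.3g; outliers: %s\n",
              x$presso_global_pval,
              if (length(x$presso_outliers)) {
                paste(x$presso_outliers, collapse = ", ")
              } else "none"))
  cat(sprintf("Radial outliers: %s\n",
              if (length(x$radial_outliers)) {
                paste(x$radial_outliers, collapse = ", ")
              } else "none"))
  cat(sprintf("Leave-one-out stable: %s\n", x$loo_stable))
  cat(sprintf("Flags: heterogeneity=%s, pleiotropy=%s\n",
              x$heterogeneity, x$pleiotropy))
  invisible(x)
}
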