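#' Per-SNP Wald ratio estimates
#'
#' The Wald ratio for SNP j is the SNP-outcome effect divided by the
#' SNP-exposure effect, `beta_y / beta_x`.  Its first-order standard error
#' is `se_y / |beta_x|`; the second-order form adds the exposure-side
#' uncertainty, `sqrt(se_y^2/beta_x^2 + beta_y^2 * se_x^2 / beta_x^4)`.
#' SNPs with `beta_x = 0` are excluded and reported in the `excluded`
#' attribute.
#'
#' @param h a `harmonized_set`.
#' @param se_order `1` (default) or `2`.
#' @return data.frame with columns `snp_id`, `ratio`, `se`; excluded
#'   zero-`beta_x` rsIDs in `attr(, "excluded")`.
#' @export
wald_ratios <- function(h, se_order = 1L) {
  stopifnot(inherits(h, "harmonized_set"), se_order %in% c(1L, 2L))
  s <- h$snps
  zero <- s$beta_x == 0
  if (all(zero)) stop("all instruments have zero exposure effect")
  s <- s[!zero, , drop = FALSE]
  se <- if (se_order == 1L) {
    s$se_y / abs(s$beta_x)
  } else {
    sqrt(s$se_y^2 / s$beta_x^2 + s$beta_y^2 * s$se_x^2 / s$beta_x^4)
  }
  out <- data.frame(snp_id = s$snp_id, ratio = s$beta_y / s$beta_x, se = se,
                    stringsAsFactors = FALSE)
  attr(out, "excluded") <- h$snps$snp_id[zero]
  out
}

# one estimate row on the log-odds and odds-ratio scales (internal)
mr_estimate <- function(method, beta, se, pval, n_snp) {
  data.frame(method = method, beta = beta, se = se, pval = pval,
             or_ = exp(beta), ci_low = exp(beta - 1.96 * se),
             ci_high = exp(beta + 1.96 * se), n_snp = as.integer(n_snp),
             stringsAsFactors = FALSE)
}

# IVW slope and Cochran's Q from aligned effects (internal core).
# Zero-intercept weighted regression of beta_y on beta_x, weights 1/se_y^2;
# equivalently an inverse-variance meta-analysis of the Wald ratios.
ivw_core <- function(beta_x, beta_y, se_y) {
  w <- 1 / se_y^2
  sxx <- sum(w * beta_x^2)
  beta <- sum(w * beta_x * beta_y) / sxx
  q <- sum(w * (beta_y - beta * beta_x)^2)  # == Q of Wald ratios about beta
  list(beta = beta, sxx = sxx, q = q)
}

#' Multiplicative random-effects IVW estimate
#'
#' Inverse-variance-weighted meta-analysis of the per-SNP Wald ratios,
#' computed as the zero-intercept weighted regression of outcome on exposure
#' effects with weights `1/se_y^2`.  The multiplicative random-effects model
#' inflates the fixed-effect variance by the overdispersion implied by
#' Cochran's Q: `phi = max(1, Q/(J-1))`, `se = sqrt(phi / sum(w beta_x^2))`.
#' The p-value uses the normal approximation.
#'
#' @param h a `harmonized_set` with at least 2 SNPs.
#' @return one-row estimate data.frame (see [mr_fit()]).
#' @export
mr_ivw <- function(h) {
  s <- h$snps
  if (nrow(s) < 2L) stop("IVW requires at least 2 SNPs")
  fit <- ivw_core(s$beta_x, s$beta_y, s$se_y)
  phi <- max(1, fit$q / (nrow(s) - 1))
  se <- sqrt(phi / fit$sxx)
  p <- 2 * stats::pnorm(-abs(fit$beta / se))
  mr_estimate("ivw", fit$beta, se, p, nrow(s))
}

# weighted least squares with intercept via normal equations (internal)
wls_line <- function(x, y, w) {
  sw <- sum(w); sx <- sum(w * x); sy <- sum(w * y)
  sxx <- sum(w * x^2); sxy <- sum(w * x * y)
  den <- sw * sxx - sx^2
  slope <- (sw * sxy - sx * sy) / den
  intercept <- (sy - slope * sx) / sw
  rss <- sum(w * (y - intercept - slope * x)^2)
  list(intercept = intercept, slope = slope, rss = rss,
       var_slope = sw / den, var_intercept = sxx / den)
}

#' MR-Egger regression
#'
#' Weighted least-squares regression of outcome on exposure effects with a
#' free intercept (weights `1/se_y^2`), after orienting every SNP so its
#' exposure effect is non-negative (sign-flipping `beta_x` and `beta_y`
#' jointly).  A non-zero intercept indicates directional horizontal
#' pleiotropy; the slope is the pleiotropy-adjusted causal estimate.  Both
#' slope standard error is inflated by the overdispersion `phi = max(1,
#' RSS/(J-2))`; the intercept uses the untruncated residual variance
#' `RSS/(J-2)` so its pleiotropy test is exactly t-calibrated under the
#' null.  Both are tested against a t distribution with `J - 2` degrees of
#' freedom.
#'
#' @param h a `harmonized_set` with at least 3 SNPs.
#' @return list with `slope` (one-row estimate data.frame, method
#'   `"egger"`) and `intercept` (list with `estimate`, `se`, `pval`).
#' @export
mr_egger <- function(h) {
  s <- h$snps
  J <- nrow(s)
  if (J < 3L) stop("MR-Egger requires at least 3 SNPs")
  flip <- sign(s$beta_x); flip[flip == 0] <- 1
  x <- s$beta_x * flip; y <- s$beta_y * flip
  w <- 1 / s$se_y^2
  fit <- wls_line(x, y, w)
  phi <- max(1, fit$rss / (J - 2))
  se_b <- sqrt(phi * fit$var_slope)
  # the intercept (pleiotropy) test uses the untruncated residual variance,
  # so it is exactly t-distributed under the no-pleiotropy null
  se_a <- sqrt((fit$rss / (J - 2)) * fit$var_intercept)
  p_b <- 2 * stats::pt(-abs(fit$slope / se_b), df = J - 2)
  p_a <- 2 * stats::pt(-abs(fit$intercept / se_a), df = J - 2)
  list(slope = mr_estimate("egger", fit$slope, se_b, p_b, J),
       intercept = list(estimate = fit$intercept, se = se_a, pval = p_a))
}

# orient every SNP so beta_x >= 0 (flip beta_x and beta_y jointly); the
# Wald ratios are unchanged and bootstrap draws become orientation-invariant
orient_positive <- function(s) {
  flip <- sign(s$beta_x); flip[flip == 0] <- 1
  s$beta_x <- s$beta_x * flip
  s$beta_y <- s$beta_y * flip
  s
}

# weighted median of sorted values by cumulative-weight interpolation
weighted_median_point <- function(ratio, w) {
  o <- order(ratio)
  r <- ratio[o]; ww <- w[o] / sum(w)
  s <- cumsum(ww) - ww / 2
  if (s[1] >= 0.5) return(r[1])
  if (s[length(s)] <= 0.5) return(r[length(r)])
  k <- max(which(s < 0.5))
  r[k] + (r[k + 1] - r[k]) * (0.5 - s[k]) / (s[k + 1] - s[k])
}

#' Weighted median estimate
#'
#' Orders the per-SNP Wald ratios and takes the weighted median under
#' normalized inverse-variance weights `beta_x^2 / se_y^2`, linearly
#' interpolating where the cumulative weight crosses one half.  Consistent
#' when instruments carrying at least half the weight are valid.  The
#' standard error comes from a parametric bootstrap: exposure and outcome
#' effects are resampled from normal distributions centred on the observed
#' values with their reported standard errors.
#'
#' @param h a `harmonized_set` with at least 3 SNPs.
#' @param n_boot bootstrap replicates (default 1000, minimum 100).
#' @param seed integer seed for the bootstrap (mandatory, for
#'   reproducibility).
#' @return one-row estimate data.frame, method `"weighted_median"`.
#' @export
mr_weighted_median <- function(h, n_boot = 1000L, seed) {
  s <- h$snps
  J <- nrow(s)
  if (J < 3L) stop("weighted median requires at least 3 SNPs")
  stopifnot(n_boot >= 100L)
  if (missing(seed)) stop("a bootstrap seed is required")
  s <- orient_positive(s)
  w <- s$beta_x^2 / s$se_y^2
  est <- weighted_median_point(s$beta_y / s$beta_x, w)
  boot <- local_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      bx <- stats::rnorm(J, s$beta_x, s$se_x)
      by <- stats::rnorm(J, s$beta_y, s$se_y)
      bx[bx == 0] <- .Machine$double.eps
      weighted_median_point(by / bx, bx^2 / s$se_y^2)
    }, numeric(1))
  })
  se <- stats::sd(boot)
  p <- 2 * stats::pnorm(-abs(est / se))
  mr_estimate("weighted_median", est, se, p, J)
}

# evaluate-and-restore RNG scoping so seeded helpers do not disturb the
# caller's RNG stream
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  expr
}

# mode of a weighted normal-kernel density over the Wald ratios
kernel_mode <- function(ratio, w, bandwidth_factor) {
  if (length(unique(ratio)) == 1L) return(ratio[1])
  s_mad <- stats::mad(ratio)
  if (s_mad == 0) s_mad <- stats::sd(ratio)
  bw <- bandwidth_factor * 0.9 * min(stats::sd(ratio), s_mad) *
    length(ratio)^(-1 / 5)
  if (bw <= 0 || !is.finite(bw)) return(stats::median(ratio))
  grid <- seq(min(ratio) - 3 * bw, max(ratio) + 3 * bw, length.out = 512L)
  dens <- vapply(grid, function(g) sum(w * stats::dnorm((g - ratio) / bw)),
                 numeric(1))
  grid[which.max(dens)]
}

#' Simple and weighted mode estimates
#'
#' The mode of the smoothed empirical density of the per-SNP Wald ratios:
#' unweighted for the simple mode, inverse-variance weighted
#' (`beta_x^2/se_y^2`, normalized) for the weighted mode.  The kernel is
#' normal with bandwidth `bandwidth_factor` times a median-absolute-
#' deviation-based plug-in rule.  Standard errors come from the same
#' parametric bootstrap as the weighted median.
#'
#' @param h a `harmonized_set` with at least 3 SNPs.
#' @param bandwidth_factor positive multiplier on the plug-in bandwidth
#'   (default 1).
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed integer bootstrap seed (mandatory).
#' @return two-row estimate data.frame, methods `"simple_mode"` and
#'   `"weighted_mode"`.
#' @export
mr_modes <- function(h, bandwidth_factor = 1, n_boot = 1000L, seed) {
  s <- h$snps
  J <- nrow(s)
  if (J < 3L) stop("mode estimators require at least 3 SNPs")
  stopifnot(bandwidth_factor > 0)
  if (missing(seed)) stop("a bootstrap seed is required")
  s <- orient_positive(s)
  ratio <- s$beta_y / s$beta_x
  w_iv <- s$beta_x^2 / s$se_y^2
  est_s <- kernel_mode(ratio, rep(1 / J, J), bandwidth_factor)
  est_w <- kernel_mode(ratio, w_iv / sum(w_iv), bandwidth_factor)
  boot <- local_seed(seed, {
    t(vapply(seq_len(n_boot), function(b) {
      bx <- stats::rnorm(J, s$beta_x, s$se_x)
      by <- stats::rnorm(J, s$beta_y, s$se_y)
      bx[bx == 0] <- .Machine$double.eps
      r <- by / bx
      wi <- bx^2 / s$se_y^2
      c(kernel_mode(r, rep(1 / J, J), bandwidth_factor),
        kernel_mode(r, wi / sum(wi), bandwidth_factor))
    }, numeric(2)))
  })
  se_s <- stats::sd(boot[, 1]); se_w <- stats::sd(boot[, 2])
  rbind(
    mr_estimate("simple_mode", est_s, se_s,
                2 * stats::pnorm(-abs(est_s / se_s)), J),
    mr_estimate("weighted_mode", est_w, se_w,
                2 * stats::pnorm(-abs(est_w / se_w)), J))
}

#' Fit two-sample Mendelian randomization estimators
#'
#' The central fitting function: given a harmonized exposure-outcome SNP
#' set, computes the requested causal-effect estimators and returns a
#' classed model object with the usual accessor methods (`print`,
#' `summary`, `coef`, `confint`, `plot`, `residuals`).
#'
#' Available methods: multiplicative random-effects inverse-variance
#' weighted (`"ivw"`, the primary analysis), MR-Egger (`"egger"`), weighted
#' median (`"weighted_median"`), and the simple and weighted modes
#' (`"simple_mode"`, `"weighted_mode"`).  Estimates are reported on the
#' log-odds (`beta`) and odds-ratio (`or_`) scales with 95% confidence
#' intervals `exp(beta +- 1.96 se)`.
#'
#' @param h a `harmonized_set`.
#' @param methods character vector of estimator names (see above).
#' @param n_boot parametric-bootstrap replicates for the median and mode
#'   standard errors.
#' @param seed integer seed driving the bootstrap; required whenever a
#'   bootstrap-based method is requested.
#' @param bandwidth_factor kernel bandwidth multiplier for the modes.
#' @return an object of class `mr_fit`: list with `estimates` (one row per
#'   method), `egger_intercept` (when Egger was fitted), `harmonized` (the
#'   input), and `wald` (per-SNP ratios).
#' @examples
#' h <- harmonized_set(beta_x = c(0.08, 0.1, 0.12, 0.09, 0.11),
#'                     se_x = rep(0.01, 5),
#'                     beta_y = c(0.041, 0.052, 0.058, 0.047, 0.054),
#'                     se_y = rep(0.01, 5))
#' fit <- mr_fit(h, seed = 1)
#' coef(fit)
#' @export
mr_fit <- function(h, methods = c("ivw", "egger", "weighted_median",
                                  "simple_mode", "weighted_mode"),
                   n_boot = 1000L, seed = NULL, bandwidth_factor = 1) {
  stopifnot(inherits(h, "harmonized_set"))
  methods <- match.arg(methods, several.ok = TRUE)
  needs_boot <- any(methods %in% c("weighted_median", "simple_mode",
                                   "weighted_mode"))
  if (needs_boot && is.null(seed)) {
    stop("`seed` is required for bootstrap-based estimators")
  }
  est <- list()
  intercept <- NULL
  if ("ivw" %in% methods) est$ivw <- mr_ivw(h)
  if ("egger" %in% methods) {
    eg <- mr_egger(h)
    est$egger <- eg$slope
    intercept <- eg$intercept
  }
  if ("weighted_median" %in% methods) {
    est$wm <- mr_weighted_median(h, n_boot = n_boot, seed = seed)
  }
  if (any(c("simple_mode", "weighted_mode") %in% methods)) {
    md <- mr_modes(h, bandwidth_factor = bandwidth_factor,
                   n_boot = n_boot, seed = seed + 1L)
    est$modes <- md[md$method %in% methods, , drop = FALSE]
  }
  estimates <- do.call(rbind, est)
  rownames(estimates) <- NULL
  structure(list(estimates = estimates, egger_intercept = intercept,
                 harmonized = h, wald = wald_ratios(h)),
            class = "mr_fit")
}

#' @export
print.mr_fit <- function(x, digits = 4, ...) {
  cat("Two-sample MR fit:", x$harmonized$exposure_id, "->",
      x$harmonized$outcome_id, sprintf("(%d SNPs)\n", n_snps(x$harmonized)))
  tab <- x$estimates
  tab[c("beta", "se", "or_", "ci_low", "ci_high")] <-
    lapply(tab[c("beta", "se", "or_", "ci_low", "ci_high")], signif,
           digits = digits)
  tab$pval <- format.pval(tab$pval, digits = digits)
  print(tab, row.names = FALSE)
  if (!is.null(x$egger_intercept)) {
    cat(sprintf("Egger intercept: %.4g (se %.3g, p %.3g)\n",
                x$egger_intercept$estimate, x$egger_intercept$se,
                x$egger_intercept$pval))
  }
  invisible(x)
}

#' @export
coef.mr_fit <- function(object, ...) {
  stats::setNames(object$estimates$beta, object$estimates$method)
}

#' @export
confint.mr_fit <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  est <- object$estimates
  out <- cbind(est$beta - z * est$se, est$beta + z * est$se)
  dimnames(out) <- list(est$method,
                        sprintf("%.1f %%", c((1 - level) / 2,
                                             1 - (1 - level) / 2) * 100))
  if (!missing(parm)) out <- out[parm, , drop = FALSE]
  out
}

#' @export
summary.mr_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.mr_fit")
}

#' @export
print.summary.mr_fit <- function(x, ...) {
  print(x$fit)
  w <- x$fit$wald
  cat(sprintf("Wald ratios: median %.4g, range [%.4g, %.4g]\n",
              stats::median(w$ratio), min(w$ratio), max(w$ratio)))
  invisible(x)
}

#' @export
residuals.mr_fit <- function(object, method = "ivw", ...) {
  est <- object$estimates
  if (!method %in% est$method) stop("method not fitted: ", method)
  b <- est$beta[est$method == method]
  s <- object$harmonized$snps
  stats::setNames((s$beta_y - b * s$beta_x) / s$se_y, s$snp_id)
}

#' @export
plot.mr_fit <- function(x, ...) {
  s <- x$harmonized$snps
  flip <- sign(s$beta_x); flip[flip == 0] <- 1
  bx <- s$beta_x * flip; by <- s$beta_y * flip
  graphics::plot(bx, by, xlab = "SNP effect on exposure",
                 ylab = "SNP effect on outcome",
                 main = paste(x$harmonized$exposure_id, "->",
                              x$harmonized$outcome_id), ...)
  graphics::segments(bx, by - 1.96 * s$se_y, bx, by + 1.96 * s$se_y,
                     col = "grey70")
  est <- x$estimates
  cols <- stats::setNames(seq_len(nrow(est)) + 1L, est$method)
  for (m in est$method) {
    a <- if (m == "egger") x$egger_intercept$estimate else 0
    graphics::abline(a = a, b = est$beta[est$method == m], col = cols[[m]])
  }
  graphics::legend("topleft", legend = est$method, col = cols, lty = 1,
                   bty = "n", cex = 0.8)
  invisible(x)
}
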