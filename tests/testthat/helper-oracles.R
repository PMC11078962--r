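# Independent oracle implementations used to cross-check the estimators.
# These deliberately use a different computational route (explicit design
# matrices and solve()) than the package's sufficient-statistic code.

# weighted least squares via explicit normal equations
oracle_wls <- function(x, y, w, intercept = TRUE) {
  X <- if (intercept) cbind(1, x) else cbind(x)
  A <- t(X) %*% (w * X)
  b <- t(X) %*% (w * y)
  coefs <- drop(solve(A, b))
  fitted <- drop(X %*% coefs)
  list(coef = coefs, rss = sum(w * (y - fitted)^2),
       xtx_inv = solve(A))
}

# IVW slope + multiplicative random-effects SE, from the oracle WLS
oracle_ivw <- function(bx, by, sy) {
  w <- 1 / sy^2
  fit <- oracle_wls(bx, by, w, intercept = FALSE)
  J <- length(bx)
  q <- fit$rss
  phi <- max(1, q / (J - 1))
  list(beta = fit$coef[[1]], se = sqrt(phi * fit$xtx_inv[1, 1]), q = q)
}

# Egger slope/intercept with the package's overdispersion conventions,
# computed from the explicit normal equations
oracle_egger <- function(bx, by, sy) {
  flip <- ifelse(bx < 0, -1, 1)
  x <- bx * flip; y <- by * flip
  w <- 1 / sy^2
  fit <- oracle_wls(x, y, w, intercept = TRUE)
  J <- length(bx)
  sigma2 <- fit$rss / (J - 2)
  phi <- max(1, sigma2)
  list(intercept = fit$coef[[1]], slope = fit$coef[[2]],
       se_slope = sqrt(phi * fit$xtx_inv[2, 2]),
       se_intercept = sqrt(sigma2 * fit$xtx_inv[1, 1]))
}

# weighted median by explicit enumeration of the cumulative-weight walk
oracle_weighted_median <- function(ratio, w) {
  o <- order(ratio)
  r <- ratio[o]
  p <- w[o] / sum(w)
  cum <- 0
  s <- numeric(length(r))
  for (k in seq_along(r)) {
    s[k] <- cum + p[k] / 2
    cum <- cum + p[k]
  }
  if (s[1] >= 0.5) return(r[1])
  if (s[length(s)] <= 0.5) return(r[length(r)])
  k <- max(which(s < 0.5))
  r[k] + (r[k + 1] - r[k]) * (0.5 - s[k]) / (s[k + 1] - s[k])
}

# a small fixed harmonized set used across estimator tests
fixture_h5 <- function() {
  harmonized_set(
    beta_x = c(0.12, -0.08, 0.15, 0.09, 0.20),
    se_x = c(0.010, 0.012, 0.011, 0.015, 0.009),
    beta_y = c(0.055, -0.050, 0.080, 0.035, 0.110),
    se_y = c(0.020, 0.025, 0.018, 0.030, 0.015))
}

fixture_h4 <- function() {
  harmonized_set(
    beta_x = c(0.10, 0.14, -0.11, 0.09),
    se_x = c(0.012, 0.010, 0.013, 0.011),
    beta_y = c(0.048, 0.075, -0.061, 0.040),
    se_y = c(0.022, 0.019, 0.024, 0.021))
}

# write a canonical sumstats file; returns the path
write_sumstats_fixture <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# minimal valid record rows for IO tests
sumstat_rows <- function(n = 3) {
  data.frame(
    snp = sprintf("rs%d", seq_len(n)),
    chrom = rep("1", n), pos = seq_len(n) * 1e6,
    effect_allele = rep(c("A", "C", "G"), length.out = n),
    other_allele = rep(c("G", "T", "A"), length.out = n),
    eaf = seq(0.2, 0.4, length.out = n),
    beta = seq(0.05, 0.15, length.out = n),
    se = rep(0.02, n),
    pval = 2 * pnorm(-abs(seq(0.05, 0.15, length.out = n) / 0.02)),
    n = rep(5000, n), stringsAsFactors = FALSE)
}
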