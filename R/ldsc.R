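#' Assemble an LD score regression input
#'
#' @param snp_id character rsIDs.
#' @param z per-SNP z-statistics (`beta/se`).
#' @param ell per-SNP LD scores, non-negative.
#' @param n per-SNP GWAS sample sizes (scalar recycled).
#' @param m total number of SNPs the heritability is scaled to (at least
#'   the number supplied).
#' @return object of class `ldsc_input`.
#' @export
ldsc_input <- function(snp_id, z, ell, n, m) {
  J <- length(z)
  if (length(n) == 1L) n <- rep(n, J)
  stopifnot(length(snp_id) == J, length(ell) == J, length(n) == J,
            all(ell >= 0), m >= J)
  structure(list(snp_id = as.character(snp_id), z = as.numeric(z),
                 ell = as.numeric(ell), n = as.numeric(n), m = m),
            class = "ldsc_input")
}

#' Derive an LDSC input from a summary dataset and an LD-score table
#'
#' z-statistics are computed as `beta/se`; records without an LD score are
#' dropped.
#'
#' @param ds a `summary_dataset` with per-record or trait-level sample
#'   sizes.
#' @param ldscores data.frame with columns `snp` and `l2`, or a path to a
#'   delimited file with those columns.
#' @param m total SNP count for scaling; defaults to the number of matched
#'   SNPs.
#' @return an `ldsc_input`.
#' @export
ldsc_input_from_sumstats <- function(ds, ldscores, m = NULL) {
  stopifnot(inherits(ds, "summary_dataset"))
  if (is.character(ldscores)) {
    ldscores <- utils::read.table(ldscores, header = TRUE, sep = "\t",
                                  quote = "", stringsAsFactors = FALSE)
  }
  stopifnot(all(c("snp", "l2") %in% names(ldscores)))
  rec <- ds$records
  idx <- match(rec$snp_id, ldscores$snp)
  keep <- !is.na(idx)
  rec <- rec[keep, , drop = FALSE]
  ell <- ldscores$l2[idx[keep]]
  n <- ifelse(is.na(rec$n), ds$n_total, rec$n)
  if (anyNA(n)) stop("LDSC requires per-SNP or trait-level sample sizes")
  if (is.null(m)) m <- nrow(rec)
  ldsc_input(rec$snp_id, rec$beta / rec$se, ell, n, m)
}

# block boundaries: `n_blocks` contiguous, nearly equal blocks over 1..J
jackknife_blocks <- function(J, n_blocks) {
  n_blocks <- max(2L, min(n_blocks, floor(J / 2)))
  cut_points <- floor(seq(0, J, length.out = n_blocks + 1L))
  lapply(seq_len(n_blocks), function(b) {
    seq.int(cut_points[b] + 1L, cut_points[b + 1L])
  })
}

# WLS line fit from sufficient statistics, plus per-block sums enabling
# O(blocks) delete-one-block refits
wls_blockwise <- function(x, y, w, blocks) {
  sw <- sum(w); sx <- sum(w * x); sy <- sum(w * y)
  sxx <- sum(w * x^2); sxy <- sum(w * x * y)
  per_block <- vapply(blocks, function(ix) {
    c(sum(w[ix]), sum(w[ix] * x[ix]), sum(w[ix] * y[ix]),
      sum(w[ix] * x[ix]^2), sum(w[ix] * x[ix] * y[ix]))
  }, numeric(5))
  full <- solve_line(sw, sx, sy, sxx, sxy)
  loo <- vapply(seq_along(blocks), function(b) {
    d <- per_block[, b]
    solve_line(sw - d[1], sx - d[2], sy - d[3], sxx - d[4], sxy - d[5])
  }, numeric(2))
  list(full = full, loo = loo)  # rows of loo: intercept, slope
}

solve_line <- function(sw, sx, sy, sxx, sxy) {
  den <- sw * sxx - sx^2
  slope <- (sw * sxy - sx * sy) / den
  c(intercept = (sy - slope * sx) / sw, slope = slope)
}

# delete-one-block jackknife SE from leave-block-out estimates
jackknife_se <- function(theta_loo, theta_full) {
  g <- length(theta_loo)
  pseudo <- g * theta_full - (g - 1) * theta_loo
  sqrt(stats::var(pseudo) / g)
}

#' SNP heritability by LD score regression
#'
#' Regresses the per-SNP chi-square statistic `z^2` on the LD score under
#' the polygenic model `E[chi2_j] = 1 + intercept offset + n_j h2 ell_j /
#' m`.  The fit is two-step: an OLS pass gives a provisional `h2`, then the
#' regression is re-fit with the heteroskedasticity weights `w_j = 1 /
#' [max(ell_j, 1) * (1 + n_j h2 ell_j / m)^2]`.  The slope is converted to
#' heritability as `slope * m / mean(n)`.  Standard errors come from a
#' delete-one-block jackknife over `n_blocks` contiguous SNP blocks
#' (auto-shrunk to `floor(J/2)` for small inputs).  The estimate is marked
#' unreliable — and should be reported as NA — when the jackknife fails or
#' the point estimate leaves `[-0.5, 1.5]`.
#'
#' @param inp an `ldsc_input` (at least 4 SNPs).
#' @param n_blocks jackknife block count (default 200).
#' @return object of class `ldsc_h2`: list with `h2`, `h2_se`, `h2_pval`,
#'   `intercept`, `intercept_se`, `n_snp`, `reliable`.
#' @export
estimate_h2 <- function(inp, n_blocks = 200L) {
  stopifnot(inherits(inp, "ldsc_input"), n_blocks >= 2L)
  J <- length(inp$z)
  if (J < 4L) stop("LDSC heritability requires at least 4 SNPs")
  chi2 <- inp$z^2
  x <- inp$ell
  nbar <- mean(inp$n)
  blocks <- jackknife_blocks(J, n_blocks)

  # step 1: OLS
  ols <- solve_line(J, sum(x), sum(chi2), sum(x^2), sum(x * chi2))
  h2_0 <- ols[["slope"]] * inp$m / nbar
  # step 2: model-based weights at the provisional h2
  pred <- 1 + inp$n * h2_0 * x / inp$m
  pred[pred < 1] <- 1
  w <- 1 / (pmax(x, 1) * pred^2)
  fit <- wls_blockwise(x, chi2, w, blocks)
  slope <- fit$full[["slope"]]
  h2 <- slope * inp$m / nbar
  intercept <- fit$full[["intercept"]]
  h2_loo <- fit$loo["slope", ] * inp$m / nbar
  h2_se <- jackknife_se(h2_loo, h2)
  int_se <- jackknife_se(fit$loo["intercept", ], intercept)
  reliable <- is.finite(h2_se) && h2_se > 0 && h2 >= -0.5 && h2 <= 1.5
  pval <- if (reliable) stats::pnorm(-abs(h2 / h2_se)) * 2 else NA_real_
  structure(list(h2 = h2, h2_se = h2_se, h2_pval = pval,
                 intercept = intercept, intercept_se = int_se,
                 n_snp = J, reliable = reliable),
            class = "ldsc_h2")
}

#' @export
print.ldsc_h2 <- function(x, ...) {
  if (x$reliable) {
    cat(sprintf("LDSC h2 = %.4g (se %.3g, p = %.3g); intercept %.3g (%d SNPs)\n",
                x$h2, x$h2_se, x$h2_pval, x$intercept, x$n_snp))
  } else {
    cat("LDSC h2 = NA (estimate unreliable;", x$n_snp, "SNPs)\n")
  }
  invisible(x)
}

#' Cross-trait genetic correlation by LD score regression
#'
#' Aligns the two inputs on their shared SNPs, regresses the z-score
#' product `z1 z2` on the LD score, scales the slope to a genetic
#' covariance by `m / sqrt(mean(n1) mean(n2))`, and normalizes by the
#' per-trait heritabilities (estimated on the same SNP intersection) to a
#' genetic correlation `rg = gencov / sqrt(h2_1 h2_2)`.  The regression
#' intercept — absorbing sample overlap — is estimated, not constrained.
#' The standard error is a delete-one-block jackknife of the whole `rg`
#' pipeline; the result is unreliable when either heritability is
#' unreliable or non-positive, and softly flagged when `|rg| > 1.25`.
#'
#' @param inp1,inp2 `ldsc_input` objects sharing at least 4 SNPs.
#' @param n_blocks jackknife block count (default 200).
#' @return object of class `ldsc_rg`: list with `rg`, `rg_se`, `rg_pval`,
#'   `gencov`, `h2_1`, `h2_2`, `n_snp`, `reliable`.
#' @export
estimate_rg <- function(inp1, inp2, n_blocks = 200L) {
  stopifnot(inherits(inp1, "ldsc_input"), inherits(inp2, "ldsc_input"))
  common <- intersect(inp1$snp_id, inp2$snp_id)
  if (length(common) < 4L) {
    stop("genetic correlation requires at least 4 shared SNPs")
  }
  i1 <- match(common, inp1$snp_id)
  i2 <- match(common, inp2$snp_id)
  # keep inp1's SNP order for the shared set so rg(a,b) == rg(b,a)
  ord <- order(i1)
  i1 <- i1[ord]; i2 <- i2[ord]
  z1 <- inp1$z[i1]; z2 <- inp2$z[i2]
  ell <- inp1$ell[i1]
  n1 <- inp1$n[i1]; n2 <- inp2$n[i2]
  m <- min(inp1$m, inp2$m)
  J <- length(common)

  sub1 <- ldsc_input(common, z1, ell, n1, m)
  sub2 <- ldsc_input(common, z2, ell, n2, m)
  h1 <- estimate_h2(sub1, n_blocks)
  h2 <- estimate_h2(sub2, n_blocks)

  y <- z1 * z2
  scale <- m / sqrt(mean(n1) * mean(n2))
  # weights symmetric in the two traits, from the per-trait model variances
  v1 <- pmax(1 + n1 * max(h1$h2, 0) * ell / m, 1)
  v2 <- pmax(1 + n2 * max(h2$h2, 0) * ell / m, 1)
  w <- 1 / (pmax(ell, 1) * v1 * v2)
  blocks <- jackknife_blocks(J, n_blocks)
  fit <- wls_blockwise(ell, y, w, blocks)
  gencov <- fit$full[["slope"]] * scale

  denom_ok <- h1$h2 > 0 && h2$h2 > 0
  if (denom_ok) {
    rg <- gencov / sqrt(h1$h2 * h2$h2)
    # jackknife rg: re-derive gencov and both h2 slopes without each block
    chi1 <- z1^2; chi2v <- z2^2
    w1 <- 1 / (pmax(ell, 1) * v1^2)
    w2 <- 1 / (pmax(ell, 1) * v2^2)
    f1 <- wls_blockwise(ell, chi1, w1, blocks)
    f2 <- wls_blockwise(ell, chi2v, w2, blocks)
    h1_loo <- f1$loo["slope", ] * m / mean(n1)
    h2_loo <- f2$loo["slope", ] * m / mean(n2)
    gc_loo <- fit$loo["slope", ] * scale
    ok <- h1_loo > 0 & h2_loo > 0
    rg_loo <- ifelse(ok, gc_loo / sqrt(pmax(h1_loo, 1e-12) *
                                         pmax(h2_loo, 1e-12)), NA_real_)
    if (all(ok)) {
      rg_se <- jackknife_se(rg_loo, rg)
      rg_pval <- if (is.finite(rg_se) && rg_se > 0) {
        2 * stats::pnorm(-abs(rg / rg_se))
      } else NA_real_
      reliable <- is.finite(rg_se) && rg_se > 0 && abs(rg) <= 1.25 &&
        h1$reliable && h2$reliable
    } else {
      rg_se <- NA_real_; rg_pval <- NA_real_; reliable <- FALSE
    }
  } else {
    rg <- NA_real_; rg_se <- NA_real_; rg_pval <- NA_real_
    reliable <- FALSE
  }
  structure(list(rg = rg, rg_se = rg_se, rg_pval = rg_pval, gencov = gencov,
                 h2_1 = h1, h2_2 = h2, n_snp = J, reliable = reliable),
            class = "ldsc_rg")
}

#' @export
print.ldsc_rg <- function(x, ...) {
  if (x$reliable) {
    cat(sprintf("LDSC rg = %.4g (se %.3g, p = %.3g); gencov %.4g (%d SNPs)\n",
                x$rg, x$rg_se, x$rg_pval, x$gencov, x$n_snp))
  } else {
    cat("LDSC rg = NA (estimate unreliable;", x$n_snp, "shared SNPs)\n")
  }
  invisible(x)
}
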