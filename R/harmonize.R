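#' Harmonize exposure instruments against an outcome dataset
#'
#' Aligns per-SNP exposure and outcome effects onto the exposure's
#' effect-allele frame.  For every instrument found in the outcome:
#'
#' * identical allele pairs are kept as-is (`aligned`);
#' * swapped pairs (effect and other allele exchanged) have the outcome
#'   effect negated and its frequency complemented (`flipped`);
#' * incompatible allele sets are dropped (`dropped_mismatch`);
#' * palindromic pairs (A/T or C/G) are dropped when either source's
#'   effect-allele frequency lies inside the ambiguity band around 0.5 or
#'   is missing (`dropped_palindromic`); outside the band they are oriented
#'   by matching frequency sides — if, after label alignment, the two
#'   frequencies fall on opposite sides of 0.5 the outcome effect is flipped
#'   once more (strand correction).
#'
#' Instruments absent from the outcome are flagged `not_in_outcome`.
#'
#' @param ivs an `instrument_set` or `summary_dataset` of exposure
#'   instruments.
#' @param outcome `summary_dataset` for the outcome trait.
#' @param maf_band ambiguity band on the effect-allele-frequency scale for
#'   palindromic SNPs, default `c(0.40, 0.60)`.
#' @param strict_palindromes drop every palindromic SNP regardless of
#'   frequency (default `FALSE`).
#' @return an object of class `harmonized_set`: a list with `exposure_id`,
#'   `outcome_id`, a data.frame `snps` (columns `snp_id`, `beta_x`, `se_x`,
#'   `beta_y`, `se_y`, `eaf_x`, `eaf_y`, `flag`) holding the retained SNPs,
#'   and `flags`, a data.frame recording the fate of every input instrument.
#' @export
harmonize <- function(ivs, outcome, maf_band = c(0.40, 0.60),
                      strict_palindromes = FALSE) {
  stopifnot(inherits(ivs, "summary_dataset"),
            inherits(outcome, "summary_dataset"),
            length(maf_band) == 2L, maf_band[1] < maf_band[2],
            maf_band[1] > 0, maf_band[2] < 1)
  ex <- ivs$records
  m <- match(ex$snp_id, outcome$records$snp_id)
  oc <- outcome$records[m, , drop = FALSE]

  n <- nrow(ex)
  flag <- character(n)
  beta_y <- se_y <- eaf_y <- rep(NA_real_, n)

  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (i in seq_len(n)) {
    if (is.na(m[i])) { flag[i] <- "not_in_outcome"; next }
    ea_x <- ex$effect_allele[i]; oa_x <- ex$other_allele[i]
    ea_y <- oc$effect_allele[i]; oa_y <- oc$other_allele[i]
    palindromic <- ea_x == comp[[oa_x]]
    if (ea_y == ea_x && oa_y == oa_x) {
      b <- oc$beta[i]; f <- oc$eaf[i]; lab <- "aligned"
    } else if (ea_y == oa_x && oa_y == ea_x) {
      b <- -oc$beta[i]
      f <- if (is.na(oc$eaf[i])) NA_real_ else 1 - oc$eaf[i]
      lab <- "flipped"
    } else if (!palindromic && ea_y == comp[[ea_x]] && oa_y == comp[[oa_x]]) {
      # opposite-strand report of the same variant
      b <- oc$beta[i]; f <- oc$eaf[i]; lab <- "aligned"
    } else if (!palindromic && ea_y == comp[[oa_x]] && oa_y == comp[[ea_x]]) {
      b <- -oc$beta[i]
      f <- if (is.na(oc$eaf[i])) NA_real_ else 1 - oc$eaf[i]
      lab <- "flipped"
    } else {
      flag[i] <- "dropped_mismatch"; next
    }
    if (palindromic) {
      if (strict_palindromes) { flag[i] <- "dropped_palindromic"; next }
      fx <- ex$eaf[i]
      ambiguous <- function(p) is.na(p) ||
        (p >= maf_band[1] && p <= maf_band[2])
      if (ambiguous(fx) || ambiguous(f)) {
        flag[i] <- "dropped_palindromic"; next
      }
      if ((fx < 0.5) != (f < 0.5)) {  # strand flip: re-orient by frequency
        b <- -b; f <- 1 - f
      }
    }
    flag[i] <- lab; beta_y[i] <- b; eaf_y[i] <- f; se_y[i] <- oc$se[i]
  }

  keep <- flag %in% c("aligned", "flipped")
  if (!any(keep)) {
    stop("harmonization retained no SNPs for ", ivs$trait_id, " vs ",
         outcome$trait_id)
  }
  snps <- data.frame(snp_id = ex$snp_id[keep],
                     beta_x = ex$beta[keep], se_x = ex$se[keep],
                     beta_y = beta_y[keep], se_y = se_y[keep],
                     eaf_x = ex$eaf[keep], eaf_y = eaf_y[keep],
                     flag = flag[keep], stringsAsFactors = FALSE)
  rownames(snps) <- NULL
  structure(list(exposure_id = ivs$trait_id, outcome_id = outcome$trait_id,
                 snps = snps,
                 flags = data.frame(snp_id = ex$snp_id, flag = flag,
                                    stringsAsFactors = FALSE)),
            class = "harmonized_set")
}

#' Construct a harmonized set directly from aligned effect arrays
#'
#' Convenience constructor for simulation studies and tests where the
#' exposure and outcome effects are already on a common allele frame.
#'
#' @param beta_x,se_x,beta_y,se_y equal-length numeric vectors of aligned
#'   per-SNP effects and standard errors; all `se > 0`.
#' @param snp_id optional rsID labels (defaults to `snp1..snpJ`).
#' @param exposure_id,outcome_id trait labels.
#' @return a `harmonized_set`.
#' @export
harmonized_set <- function(beta_x, se_x, beta_y, se_y,
                           snp_id = paste0("snp", seq_along(beta_x)),
                           exposure_id = "exposure", outcome_id = "outcome") {
  J <- length(beta_x)
  stopifnot(J >= 1L, length(se_x) == J, length(beta_y) == J,
            length(se_y) == J, length(snp_id) == J,
            all(se_x > 0), all(se_y > 0))
  snps <- data.frame(snp_id = as.character(snp_id),
                     beta_x = beta_x, se_x = se_x,
                     beta_y = beta_y, se_y = se_y,
                     eaf_x = NA_real_, eaf_y = NA_real_,
                     flag = "aligned", stringsAsFactors = FALSE)
  structure(list(exposure_id = exposure_id, outcome_id = outcome_id,
                 snps = snps,
                 flags = snps[, c("snp_id", "flag")]),
            class = "harmonized_set")
}

#' @export
print.harmonized_set <- function(x, ...) {
  tab <- table(x$flags$flag)
  cat("Harmonized set:", x$exposure_id, "->", x$outcome_id, "\n")
  cat("  retained", nrow(x$snps), "SNPs;",
      paste(names(tab), as.integer(tab), collapse = ", "), "\n")
  invisible(x)
}

#' Number of retained SNPs in a harmonized set
#' @param h a `harmonized_set`.
#' @return integer.
#' @export
n_snps <- function(h) nrow(h$snps)
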