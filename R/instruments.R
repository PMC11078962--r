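#' Clumping / instrument-selection configuration
#'
#' Thresholds used when selecting approximately independent instrumental
#' variables: a genome-wide-suggestive significance filter, greedy LD
#' clumping within a physical window, and an optional pairwise-r2 table.
#' When no LD source is supplied, clumping is distance-only within
#' `window_bp` (conservative: one SNP per window).
#'
#' @param p_threshold instrument significance cutoff (default 1e-5).
#' @param r2_max LD cutoff: same-window SNP pairs with r2 at or above this
#'   are clumped together (default 0.01).
#' @param window_bp physical clumping window in base pairs (default 500 kb).
#' @param ld optional LD source: a data.frame with columns `snp_a`, `snp_b`,
#'   `r2` (pairs accepted in either order), or a path to such a delimited
#'   file.
#' @return an object of class `clump_config`.
#' @export
clump_config <- function(p_threshold = 1e-5, r2_max = 0.01,
                         window_bp = 500000L, ld = NULL) {
  stopifnot(p_threshold > 0, p_threshold < 1,
            r2_max > 0, r2_max < 1, window_bp > 0)
  if (is.character(ld)) ld <- read_ld_table(ld)
  if (!is.null(ld)) {
    stopifnot(is.data.frame(ld),
              all(c("snp_a", "snp_b", "r2") %in% names(ld)))
  }
  structure(list(p_threshold = p_threshold, r2_max = r2_max,
                 window_bp = as.numeric(window_bp), ld = ld),
            class = "clump_config")
}

#' Read a pairwise LD (r2) table
#'
#' @param path delimited file with header columns `snp_a`, `snp_b`, `r2`.
#' @return data.frame with those three columns.
#' @export
read_ld_table <- function(path) {
  ld <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE)
  if (!all(c("snp_a", "snp_b", "r2") %in% names(ld))) {
    stop("LD table must have columns snp_a, snp_b, r2: ", path)
  }
  ld
}

# pairwise r2 lookup; symmetric; unlisted pairs are treated as independent
ld_r2 <- function(ld, a, b) {
  if (is.null(ld) || length(a) == 0L) return(numeric(length(a)))
  key <- paste(pmin(a, b), pmax(a, b), sep = "\r")
  tab_key <- paste(pmin(ld$snp_a, ld$snp_b), pmax(ld$snp_a, ld$snp_b),
                   sep = "\r")
  r2 <- ld$r2[match(key, tab_key)]
  r2[is.na(r2)] <- 0
  r2
}

#' Filter a summary dataset by association p-value
#'
#' @param ds a `summary_dataset`.
#' @param threshold keep records with `pval < threshold`; must lie in (0,1).
#' @return a `summary_dataset` holding exactly the passing records (possibly
#'   zero rows); the input is not modified.
#' @export
filter_by_pvalue <- function(ds, threshold) {
  stopifnot(inherits(ds, "summary_dataset"), threshold > 0, threshold < 1)
  replace_records(ds, ds$records[ds$records$pval < threshold, , drop = FALSE])
}

#' Greedy LD clumping
#'
#' Iterates records by ascending p-value (ties broken by lexicographic
#' rsID) and retains a record unless it falls within `window_bp` of an
#' already-retained record on the same chromosome and is in LD with it —
#' where "in LD" means r2 >= `r2_max` when an LD source is configured, and
#' is assumed for every same-window pair when it is not.  Deterministic and
#' idempotent.
#'
#' @param ds a `summary_dataset` (typically already p-value filtered); all
#'   records must carry `chrom` and `pos`.
#' @param cfg a [clump_config()].
#' @return the retained subset as a `summary_dataset`, ordered by ascending
#'   p-value.
#' @export
clump <- function(ds, cfg = clump_config()) {
  stopifnot(inherits(ds, "summary_dataset"), inherits(cfg, "clump_config"))
  rec <- ds$records
  if (nrow(rec) == 0L) return(replace_records(ds, rec))
  if (anyNA(rec$chrom) || anyNA(rec$pos)) {
    stop("clumping requires chrom and pos on every record")
  }
  ord <- order(rec$pval, rec$snp_id)
  rec <- rec[ord, , drop = FALSE]
  keep <- logical(nrow(rec))
  for (i in seq_len(nrow(rec))) {
    kept <- which(keep)
    near <- kept[rec$chrom[kept] == rec$chrom[i] &
                   abs(rec$pos[kept] - rec$pos[i]) <= cfg$window_bp]
    if (length(near) == 0L) {
      keep[i] <- TRUE
    } else if (is.null(cfg$ld)) {
      keep[i] <- FALSE
    } else {
      r2 <- ld_r2(cfg$ld, rec$snp_id[near], rep(rec$snp_id[i], length(near)))
      keep[i] <- all(r2 < cfg$r2_max)
    }
  }
  replace_records(ds, rec[keep, , drop = FALSE])
}

#' Per-SNP instrument strength
#'
#' First-order instrument strength from summary statistics: the F statistic
#' is the squared z-score, `(beta/se)^2`, and the fraction of exposure
#' variance explained is `F / (F + n - 2)`.
#'
#' @param beta,se per-allele effect and its standard error (`se > 0`).
#' @param n exposure GWAS sample size (`n > 2`).
#' @return list with numeric vectors `f_stat` and `r2_explained`.
#' @export
per_snp_strength <- function(beta, se, n) {
  stopifnot(all(se > 0))
  if (any(n <= 2)) stop("per-SNP strength requires n > 2")
  f <- (beta / se)^2
  list(f_stat = f, r2_explained = f / (f + n - 2))
}

#' Remove instruments associated with the outcome
#'
#' Drops instruments whose rsID attains `pval < threshold` in the outcome
#' dataset (they may act on the outcome directly), and instruments absent
#' from the outcome dataset altogether (they cannot be harmonized).
#'
#' @param ivs `summary_dataset` of candidate instruments (exposure side).
#' @param outcome `summary_dataset` for the outcome trait.
#' @param threshold outcome-association cutoff in (0,1).
#' @return list with `ivs` (the retained `summary_dataset`) and `removed`
#'   (data.frame of dropped rsIDs with a `reason` of
#'   `"outcome_associated"` or `"not_in_outcome"`).
#' @export
exclude_outcome_associated <- function(ivs, outcome, threshold = 1e-5) {
  stopifnot(inherits(ivs, "summary_dataset"),
            inherits(outcome, "summary_dataset"),
            threshold > 0, threshold < 1)
  rec <- ivs$records
  m <- match(rec$snp_id, outcome$records$snp_id)
  absent <- is.na(m)
  assoc <- !absent & outcome$records$pval[m] < threshold
  reason <- rep(NA_character_, nrow(rec))
  reason[absent] <- "not_in_outcome"
  reason[assoc] <- "outcome_associated"
  drop <- absent | assoc
  removed <- data.frame(snp_id = rec$snp_id[drop], reason = reason[drop],
                        stringsAsFactors = FALSE)
  list(ivs = replace_records(ivs, rec[!drop, , drop = FALSE]),
       removed = removed)
}

#' Select instrumental variables for one exposure
#'
#' Composes the full instrument-selection pipeline: significance filter
#' (`pval < cfg$p_threshold`), greedy LD [clump()]ing, per-SNP strength
#' filter (`F > f_min`), and exclusion of outcome-associated or
#' outcome-absent SNPs.  When fewer than `min_ivs` instruments survive the
#' exposure is flagged insufficient rather than analyzed.
#'
#' @param exposure,outcome `summary_dataset` objects.
#' @param cfg a [clump_config()].
#' @param f_min minimum per-SNP F statistic (default 10; strictly greater
#'   than).
#' @param min_ivs minimum surviving instrument count required to proceed
#'   (default 4, i.e. exposures with fewer than four instruments are
#'   omitted).
#' @param outcome_p_threshold cutoff for the outcome-association exclusion
#'   (defaults to `cfg$p_threshold`).
#' @return an object of class `instrument_set` (a `summary_dataset` whose
#'   records gain `f_stat` and `r2_explained` columns, with a `selection_log`
#'   of per-stage counts), or of class `insufficient_ivs` carrying the
#'   surviving `count`.
#' @export
select_instruments <- function(exposure, outcome, cfg = clump_config(),
                               f_min = 10, min_ivs = 4L,
                               outcome_p_threshold = cfg$p_threshold) {
  stopifnot(min_ivs >= 1L)
  sig <- filter_by_pvalue(exposure, cfg$p_threshold)
  log <- list(n_input = n_variants(exposure), n_significant = n_variants(sig))
  if (n_variants(sig) == 0L) {
    return(insufficient_ivs(exposure$trait_id, 0L, log))
  }
  cl <- clump(sig, cfg)
  log$n_clumped <- n_variants(cl)
  n_eff <- ifelse(is.na(cl$records$n),
                  if (is.na(exposure$n_total)) NA_real_ else exposure$n_total,
                  cl$records$n)
  if (anyNA(n_eff)) {
    stop("instrument strength requires a per-SNP or trait-level sample size")
  }
  st <- per_snp_strength(cl$records$beta, cl$records$se, n_eff)
  cl$records$f_stat <- st$f_stat
  cl$records$r2_explained <- st$r2_explained
  cl <- replace_records(cl, cl$records[st$f_stat > f_min, , drop = FALSE])
  log$n_strong <- n_variants(cl)
  ex <- exclude_outcome_associated(cl, outcome, outcome_p_threshold)
  log$n_after_outcome_exclusion <- n_variants(ex$ivs)
  log$removed <- ex$removed
  if (n_variants(ex$ivs) < min_ivs) {
    return(insufficient_ivs(exposure$trait_id, n_variants(ex$ivs), log))
  }
  out <- ex$ivs
  # canonical order: by rsID, so selection is invariant to input row order
  out <- replace_records(out, out$records[order(out$records$snp_id), ,
                                          drop = FALSE])
  out$selection_log <- log
  class(out) <- c("instrument_set", class(out))
  out
}

insufficient_ivs <- function(trait_id, count, log = NULL) {
  structure(list(trait_id = trait_id, count = as.integer(count),
                 selection_log = log),
            class = "insufficient_ivs")
}

#' Test whether instrument selection flagged an exposure as insufficient
#' @param x result of [select_instruments()].
#' @return logical.
#' @export
is_insufficient <- function(x) inherits(x, "insufficient_ivs")

#' @export
print.insufficient_ivs <- function(x, ...) {
  cat("Exposure", x$trait_id, "omitted: only", x$count,
      "instruments survive selection\n")
  invisible(x)
}

#' @export
print.instrument_set <- function(x, ...) {
  cat("Instrument set for", x$trait_id, "-", nrow(x$records), "SNPs\n")
  cat(sprintf("  F statistics %.1f-%.1f; summed R^2 = %.3g\n",
              min(x$records$f_stat), max(x$records$f_stat),
              sum(x$records$r2_explained)))
  invisible(x)
}
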