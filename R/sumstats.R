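#' Read GWAS summary statistics from delimited text
#'
#' Reads a delimited summary-statistics file (tab-separated by default) into
#' a validated `summary_dataset`.  Column names are adapted through
#' `column_map`, so FinnGen-style, metabolomics-server-style or generic
#' headers can be consumed without bespoke parsers.  Rows that violate the
#' per-variant invariants (non-ACGT or identical alleles, non-positive
#' standard error, p-value outside (0, 1], allele frequency outside \[0, 1\])
#' are dropped and counted; duplicated rsIDs keep the first occurrence.
#'
#' Records whose p-value disagrees with the two-sided normal p implied by
#' `beta/se` by more than `zp_tol` (absolute) are retained but flagged in
#' the load report: a unit mistake is detected, never auto-corrected.
#'
#' @param path path to a delimited text file with a header row.
#' @param column_map named character vector mapping canonical field names
#'   (`snp`, `effect_allele`, `other_allele`, `beta`, `se`, `pval`, and
#'   optionally `chrom`, `pos`, `eaf`, `n`) to the column names present in
#'   the file.  Defaults to the identity mapping on the canonical names.
#' @param trait_id,trait_label identifiers for the trait; `trait_label`
#'   defaults to `trait_id`.
#' @param trait_type `"quantitative"` or `"binary"`.
#' @param n_total,n_cases total sample size and (binary traits only) case
#'   count; `n_cases` must be missing for quantitative traits.
#' @param sep field separator, default tab.
#' @param zp_tol absolute tolerance for the p-value versus z-score
#'   consistency check.
#' @return an object of class `summary_dataset`: a list with elements
#'   `trait_id`, `trait_label`, `trait_type`, `n_total`, `n_cases`,
#'   `records` (a data.frame with columns `snp_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`) and
#'   `load_report` (counts of valid / invalid / duplicate / z-p flagged
#'   rows).
#' @export
read_sumstats <- function(path, column_map = NULL,
                          trait_id = basename(path), trait_label = trait_id,
                          trait_type = c("quantitative", "binary"),
                          n_total = NA_integer_, n_cases = NA_integer_,
                          sep = "\t", zp_tol = 0.01) {
  trait_type <- match.arg(trait_type)
  if (!file.exists(path)) {
    stop("cannot read summary statistics: file not found: ", path)
  }
  raw <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, quote = "",
                      comment.char = "", stringsAsFactors = FALSE,
                      check.names = FALSE),
    error = function(e) stop("failed to parse '", path, "': ",
                             conditionMessage(e)))
  df <- map_sumstat_columns(raw, column_map, path)
  make_summary_dataset(df, trait_id = trait_id, trait_label = trait_label,
                       trait_type = trait_type, n_total = n_total,
                       n_cases = n_cases, zp_tol = zp_tol)
}

# canonical record fields; eaf/n/chrom/pos may be absent in the source
.sumstat_mandatory <- c("snp", "effect_allele", "other_allele",
                        "beta", "se", "pval")
.sumstat_optional  <- c("chrom", "pos", "eaf", "n")

# common header spellings accepted when no explicit column_map is given
.sumstat_aliases <- list(
  snp = c("snp", "snp_id", "rsid", "rsids", "markername", "variant_id"),
  chrom = c("chrom", "chr", "chromosome", "#chrom"),
  pos = c("pos", "position", "bp", "base_pair_location"),
  effect_allele = c("effect_allele", "alt", "a1", "allele1"),
  other_allele = c("other_allele", "ref", "a2", "allele2"),
  eaf = c("eaf", "af_alt", "effect_allele_frequency", "af"),
  beta = c("beta", "effect"),
  se = c("se", "sebeta", "standard_error", "stderr"),
  pval = c("pval", "p", "pvalue", "p_value"),
  n = c("n", "nsamples", "sample_size"))

# resolve each canonical field to the first alias present in the header
resolve_aliases <- function(header) {
  hits <- vapply(.sumstat_aliases, function(al) {
    m <- match(al, tolower(header))
    m <- m[!is.na(m)]
    if (length(m)) header[m[1]] else NA_character_
  }, character(1))
  hits[!is.na(hits)]
}

map_sumstat_columns <- function(raw, column_map, path) {
  all_fields <- c(.sumstat_mandatory, .sumstat_optional)
  if (is.null(column_map)) column_map <- resolve_aliases(names(raw))
  if (is.null(names(column_map)) || any(!names(column_map) %in% all_fields)) {
    stop("column_map names must be among: ", paste(all_fields, collapse = ", "))
  }
  missing_mand <- setdiff(.sumstat_mandatory, names(column_map))
  # identity fallback for mandatory fields not in an explicit partial map
  for (f in missing_mand) column_map[f] <- f
  unresolved <- setdiff(column_map[.sumstat_mandatory], names(raw))
  if (length(unresolved)) {
    stop("mandatory column(s) not found in '", path, "': ",
         paste(unresolved, collapse = ", "))
  }
  out <- data.frame(
    snp_id = as.character(raw[[column_map[["snp"]]]]),
    effect_allele = toupper(as.character(raw[[column_map[["effect_allele"]]]])),
    other_allele = toupper(as.character(raw[[column_map[["other_allele"]]]])),
    beta = as.numeric(raw[[column_map[["beta"]]]]),
    se = as.numeric(raw[[column_map[["se"]]]]),
    pval = as.numeric(raw[[column_map[["pval"]]]]),
    stringsAsFactors = FALSE)
  for (f in .sumstat_optional) {
    col <- if (f %in% names(column_map)) column_map[[f]] else f
    if (col %in% names(raw)) {
      out[[target_name(f)]] <- if (f == "chrom") {
        as.character(raw[[col]])
      } else {
        as.numeric(raw[[col]])
      }
    } else {
      out[[target_name(f)]] <- if (f == "chrom") NA_character_ else NA_real_
    }
  }
  out[c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
        "eaf", "beta", "se", "pval", "n")]
}

target_name <- function(f) f  # canonical names double as record column names

#' Assemble a summary_dataset from an in-memory record table
#'
#' Applies the same validation as [read_sumstats()] to a data.frame already
#' holding the canonical record columns.  Used by the synthetic-data
#' generator and by tests.
#'
#' @param df data.frame with columns `snp_id`, `effect_allele`,
#'   `other_allele`, `beta`, `se`, `pval` and optionally `chrom`, `pos`,
#'   `eaf`, `n`.
#' @inheritParams read_sumstats
#' @return a `summary_dataset`; see [read_sumstats()].
#' @export
make_summary_dataset <- function(df, trait_id, trait_label = trait_id,
                                 trait_type = c("quantitative", "binary"),
                                 n_total = NA_integer_, n_cases = NA_integer_,
                                 zp_tol = 0.01) {
  trait_type <- match.arg(trait_type)
  if (trait_type == "quantitative" && !is.na(n_cases)) {
    stop("n_cases may only be supplied for binary traits")
  }
  for (f in c("chrom", "pos", "eaf", "n")) {
    if (!f %in% names(df)) df[[f]] <- if (f == "chrom") NA_character_ else NA_real_
  }
  df <- df[c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
             "eaf", "beta", "se", "pval", "n")]
  n_lines <- nrow(df)

  ok_alleles <- df$effect_allele %in% c("A", "C", "G", "T") &
    df$other_allele %in% c("A", "C", "G", "T") &
    df$effect_allele != df$other_allele
  ok_se <- is.finite(df$se) & df$se > 0
  ok_p <- is.finite(df$pval) & df$pval > 0 & df$pval <= 1
  ok_eaf <- is.na(df$eaf) | (df$eaf >= 0 & df$eaf <= 1)
  ok_beta <- is.finite(df$beta)
  valid <- ok_alleles & ok_se & ok_p & ok_eaf & ok_beta &
    !is.na(df$snp_id) & nzchar(df$snp_id)
  n_invalid <- sum(!valid)
  df <- df[valid, , drop = FALSE]

  dup <- duplicated(df$snp_id)
  n_dup <- sum(dup)
  df <- df[!dup, , drop = FALSE]
  rownames(df) <- NULL

  if (nrow(df) == 0L) {
    stop("no valid summary-statistic rows for trait '", trait_id, "'")
  }

  p_implied <- 2 * stats::pnorm(-abs(df$beta / df$se))
  zp_flag <- abs(df$pval - p_implied) > zp_tol

  structure(list(
    trait_id = trait_id, trait_label = trait_label, trait_type = trait_type,
    n_total = n_total, n_cases = if (trait_type == "binary") n_cases else NA_integer_,
    records = df,
    load_report = list(n_lines = n_lines, n_valid = nrow(df),
                       n_invalid = n_invalid, n_duplicate = n_dup,
                       n_zp_flagged = sum(zp_flag),
                       zp_flagged = df$snp_id[zp_flag])),
    class = "summary_dataset")
}

#' @export
print.summary_dataset <- function(x, ...) {
  cat("GWAS summary dataset: ", x$trait_label, " [", x$trait_id, "], ",
      x$trait_type, "\n", sep = "")
  if (!is.na(x$n_total)) {
    cat("  n =", x$n_total,
        if (!is.na(x$n_cases)) paste0("(", x$n_cases, " cases)"), "\n")
  }
  cat("  variants:", nrow(x$records),
      sprintf("(dropped %d invalid, %d duplicate)",
              x$load_report$n_invalid, x$load_report$n_duplicate), "\n")
  invisible(x)
}

#' Number of variant records in a summary dataset
#' @param ds a `summary_dataset`.
#' @return integer record count.
#' @export
n_variants <- function(ds) nrow(ds$records)

# replace the record table, keeping trait metadata (internal)
replace_records <- function(ds, records) {
  ds$records <- records
  rownames(ds$records) <- NULL
  ds
}

#' Write a results table as tab-separated text
#'
#' Serializes a data.frame with a header row; numeric columns are written
#' at full double precision (17 significant digits) so the table round-trips
#' through [read_results_table()] without value change.  An empty table
#' yields a header-only file.
#'
#' @param rows data.frame of result records sharing one schema.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_results_table <- function(rows, path) {
  stopifnot(is.data.frame(rows))
  out <- rows
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      v <- out[[j]]
      s <- sprintf("%.17g", v)
      s[is.na(v)] <- "NA"
      out[[j]] <- s
    }
  }
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE, na = "NA")
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) stop("cannot write results table to '", path, "': ",
                        conditionMessage(ok))
  invisible(path)
}

#' Read back a results table written by [write_results_table()]
#' @param path path to a tab-separated table with header.
#' @return data.frame.
#' @export
read_results_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    comment.char = "", stringsAsFactors = FALSE)
}
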