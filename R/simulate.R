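#' Configuration for the synthetic GWAS summary-statistics generator
#'
#' Defines the ground-truth model from which two-sample MR inputs are
#' drawn.  Per instrument j, the true SNP-exposure effect is `gamma_j ~
#' N(0, gamma_sd^2)` (optionally rejection-sampled to instrument strength,
#' see `gamma_min_z`), the horizontal-pleiotropy effect is `alpha_j ~
#' N(pleio_mean, pleio_sd^2)`, and a planted-outlier subset of size
#' `round(outlier_frac * J)` receives an extra pleiotropy offset of
#' magnitude `outlier_scale * se_y` with random sign.  Observed effects are
#' `beta_x = gamma + e_x`, `beta_y = theta * gamma + alpha + e_y` with
#' independent normal measurement errors of scale `se_x`, `se_y`; p-values
#' are the exact two-sided normal p of `beta/se`.  Background SNPs are
#' drawn under the global null so the significance filter and clumping have
#' realistic work to do.
#'
#' @param n_snp_instrument number of instrument SNPs J (default 20).
#' @param n_snp_background null SNPs added per dataset (default `50 * J`).
#' @param theta true causal slope of exposure on outcome (log-odds per
#'   exposure SD; default 0).
#' @param gamma_sd scale of true instrument effects (default 0.08,
#'   exposure-SD units per allele).
#' @param gamma_min_z when positive, instrument `gamma` values are redrawn
#'   until `|gamma|/se_x` exceeds this, yielding genome-wide-strength
#'   instruments by construction (default 0: plain normal draws).
#' @param se_x,se_y measurement-error scales of the exposure and outcome
#'   effect estimates (defaults 0.012 and 0.03, matching GWAS of a few
#'   thousand and a few hundred thousand samples respectively).
#' @param pleio_mean,pleio_sd directional and balanced pleiotropy
#'   parameters (defaults 0, 0).
#' @param outlier_frac,outlier_scale planted-outlier fraction and offset
#'   scale in units of `se_y` (defaults 0, 10).
#' @param palindrome_frac fraction of SNPs assigned A/T or C/G allele
#'   pairs (default 0.1); half of these get an effect-allele frequency
#'   inside the ambiguity band so both palindrome branches are exercised.
#' @param mismatch_frac fraction of instruments whose outcome record
#'   carries an incompatible allele pair (default 0.02).
#' @param swap_frac fraction of outcome records reported on the swapped
#'   allele orientation, exercising harmonization flips (default 0.25).
#' @param n_exposure,n_outcome GWAS sample sizes (defaults 7824 and
#'   365120).
#' @param h2_true per-trait SNP heritabilities for the LDSC generator
#'   (length 1 or 2, default 0.3).
#' @param rg_true true genetic correlation (default 0).
#' @param m_total total SNP count M for the LDSC generator (default 2000).
#' @param ell_shape,ell_scale shifted-gamma LD-score model: `ell = 1 +
#'   Gamma(shape, scale)` (defaults 2 and 10).
#' @param orient_gamma when `TRUE`, instrument effects are taken on the
#'   exposure-increasing orientation (`|gamma|`).  Directional pleiotropy
#'   (`pleio_mean != 0`) is defined relative to that orientation — with
#'   sign-symmetric instruments its apparent direction cancels — so
#'   directional-pleiotropy experiments enable this switch (default
#'   `FALSE`).
#' @param inside_violation when `TRUE`, pleiotropy is correlated with
#'   instrument strength (alpha gains a `0.5 * gamma` component), breaking
#'   the InSIDE assumption to probe MR-Egger's failure mode.
#' @param seed mandatory integer seed.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_snp_instrument = 20L,
                       n_snp_background = 50L * n_snp_instrument,
                       theta = 0, gamma_sd = 0.08, gamma_min_z = 0,
                       se_x = 0.012, se_y = 0.03,
                       pleio_mean = 0, pleio_sd = 0,
                       outlier_frac = 0, outlier_scale = 10,
                       palindrome_frac = 0.1, mismatch_frac = 0.02,
                       swap_frac = 0.25,
                       n_exposure = 7824L, n_outcome = 365120L,
                       h2_true = 0.3, rg_true = 0, m_total = 2000L,
                       ell_shape = 2, ell_scale = 10,
                       inside_violation = FALSE, orient_gamma = FALSE,
                       seed) {
  if (missing(seed)) stop("a seed is mandatory in sim_config()")
  fracs <- c(outlier_frac, palindrome_frac, mismatch_frac, swap_frac)
  stopifnot(all(fracs >= 0 & fracs <= 1), gamma_sd >= 0, pleio_sd >= 0,
            se_x >= 0, se_y >= 0, n_snp_instrument >= 1,
            abs(rg_true) <= 1, all(h2_true >= 0 & h2_true <= 1))
  if (length(h2_true) == 1L) h2_true <- rep(h2_true, 2L)
  structure(list(
    n_snp_instrument = as.integer(n_snp_instrument),
    n_snp_background = as.integer(n_snp_background),
    theta = theta, gamma_sd = gamma_sd, gamma_min_z = gamma_min_z,
    se_x = se_x, se_y = se_y, pleio_mean = pleio_mean, pleio_sd = pleio_sd,
    outlier_frac = outlier_frac, outlier_scale = outlier_scale,
    palindrome_frac = palindrome_frac, mismatch_frac = mismatch_frac,
    swap_frac = swap_frac, n_exposure = as.integer(n_exposure),
    n_outcome = as.integer(n_outcome), h2_true = h2_true,
    rg_true = rg_true, m_total = as.integer(m_total),
    ell_shape = ell_shape, ell_scale = ell_scale,
    inside_violation = isTRUE(inside_violation),
    orient_gamma = isTRUE(orient_gamma), seed = as.integer(seed)),
    class = "sim_config")
}

# draw the latent instrument model shared by simulate_pair and
# simulate_harmonized; assumes the RNG is already seeded
draw_instrument_model <- function(cfg) {
  J <- cfg$n_snp_instrument
  gamma <- stats::rnorm(J, 0, cfg$gamma_sd)
  if (cfg$orient_gamma) gamma <- abs(gamma)
  if (cfg$gamma_min_z > 0 && cfg$se_x > 0) {
    for (j in seq_len(J)) {
      while (abs(gamma[j]) / cfg$se_x <= cfg$gamma_min_z) {
        gamma[j] <- stats::rnorm(1, 0, cfg$gamma_sd)
        if (cfg$orient_gamma) gamma[j] <- abs(gamma[j])
      }
    }
  }
  alpha <- stats::rnorm(J, cfg$pleio_mean, cfg$pleio_sd)
  if (cfg$inside_violation) alpha <- alpha + 0.5 * gamma
  n_out <- round(cfg$outlier_frac * J)
  outlier_idx <- if (n_out > 0) sample.int(J, n_out) else integer()
  if (n_out > 0) {
    alpha[outlier_idx] <- alpha[outlier_idx] +
      cfg$outlier_scale * cfg$se_y * sample(c(-1, 1), n_out, replace = TRUE)
  }
  eps_x <- stats::rnorm(J, 0, cfg$se_x)
  eps_y <- stats::rnorm(J, 0, cfg$se_y)
  list(gamma = gamma, alpha = alpha, outlier_idx = sort(outlier_idx),
       eps_x = eps_x, eps_y = eps_y,
       beta_x = gamma + eps_x,
       beta_y = cfg$theta * gamma + alpha + eps_y)
}

#' Simulate an already-harmonized instrument set with known truth
#'
#' Draws the instrument model of [sim_config()] and returns the aligned
#' effect arrays directly as a `harmonized_set`, bypassing allele
#' assignment and selection.  This is the workhorse for estimator
#' calibration and parameter-recovery experiments.
#'
#' @param cfg a [sim_config()].
#' @return list with `h` (a `harmonized_set`) and `truth` (gamma, alpha,
#'   outlier rsIDs, theta).
#' @export
simulate_harmonized <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  mod <- local_seed(cfg$seed, draw_instrument_model(cfg))
  se_x <- rep(max(cfg$se_x, 1e-12), cfg$n_snp_instrument)
  se_y <- rep(max(cfg$se_y, 1e-12), cfg$n_snp_instrument)
  ids <- sprintf("rs%06d", seq_len(cfg$n_snp_instrument))
  h <- harmonized_set(mod$beta_x, se_x, mod$beta_y, se_y, snp_id = ids,
                      exposure_id = "sim_exposure", outcome_id = "sim_outcome")
  list(h = h,
       truth = list(theta = cfg$theta, gamma = mod$gamma,
                    alpha = mod$alpha, outliers = ids[mod$outlier_idx]))
}

# random biallelic pair; palindromic pairs are A/T or C/G
draw_alleles <- function(n, palindromic) {
  bases <- c("A", "C", "G", "T")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ea <- bases[sample.int(4, n, replace = TRUE)]
  oa <- character(n)
  for (i in seq_len(n)) {
    if (palindromic[i]) {
      oa[i] <- comp[[ea[i]]]
    } else {
      choices <- setdiff(bases, c(ea[i], comp[[ea[i]]]))
      oa[i] <- choices[sample.int(2, 1)]
    }
  }
  cbind(ea, oa)
}

#' Simulate a two-sample GWAS summary-statistics pair with known truth
#'
#' Generates exposure and outcome `summary_dataset` objects realizing the
#' model of [sim_config()]: instrument SNPs with true effects, background
#' SNPs under the null, exact normal p-values, allele assignments including
#' palindromic and deliberately mismatched pairs, and a fraction of
#' outcome records reported on the swapped allele orientation.  Instruments
#' are placed on alternating chromosomes more than one clumping window
#' apart, so they are mutually independent by construction; background
#' SNPs are scattered uniformly.
#'
#' @param cfg a [sim_config()].
#' @return list with `exposure`, `outcome` (both `summary_dataset`) and
#'   `truth` (data.frame of per-instrument ground truth plus `theta` and
#'   the planted-outlier rsIDs).
#' @export
simulate_pair <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  local_seed(cfg$seed, {
    J <- cfg$n_snp_instrument
    B <- cfg$n_snp_background
    mod <- draw_instrument_model(cfg)

    ids_i <- sprintf("rs%06d", seq_len(J))
    ids_b <- if (B > 0) sprintf("rs9%05d", seq_len(B)) else character()
    chrom_i <- as.character(((seq_len(J) - 1L) %% 22L) + 1L)
    pos_i <- 1e6 + 2e6 * ((seq_len(J) - 1L) %/% 22L) +
      3e6 * ((seq_len(J) - 1L) %% 22L)
    chrom_b <- as.character(sample.int(22L, B, replace = TRUE))
    pos_b <- round(stats::runif(B, 5e7, 2.4e8))

    pal <- stats::runif(J + B) < cfg$palindrome_frac
    al <- draw_alleles(J + B, pal)
    maf <- stats::runif(J + B, 0.05, 0.5)
    eaf <- ifelse(stats::runif(J + B) < 0.5, maf, 1 - maf)
    # half the palindromic hazards sit inside the ambiguity band
    in_band <- pal & (stats::runif(J + B) < 0.5)
    eaf[in_band] <- stats::runif(sum(in_band), 0.41, 0.59)

    se_x <- rep(max(cfg$se_x, 1e-12), J + B)
    se_y <- rep(max(cfg$se_y, 1e-12), J + B)
    bx <- c(mod$beta_x, stats::rnorm(B, 0, cfg$se_x))
    by <- c(mod$beta_y, stats::rnorm(B, 0, cfg$se_y))

    expo <- data.frame(
      snp_id = c(ids_i, ids_b), chrom = c(chrom_i, chrom_b),
      pos = c(pos_i, pos_b), effect_allele = al[, 1], other_allele = al[, 2],
      eaf = eaf, beta = bx, se = se_x,
      pval = pmax(2 * stats::pnorm(-abs(bx / se_x)), 1e-300),
      n = rep(cfg$n_exposure, J + B), stringsAsFactors = FALSE)

    out <- data.frame(
      snp_id = c(ids_i, ids_b), chrom = c(chrom_i, chrom_b),
      pos = c(pos_i, pos_b), effect_allele = al[, 1], other_allele = al[, 2],
      eaf = eaf, beta = by, se = se_y,
      pval = pmax(2 * stats::pnorm(-abs(by / se_y)), 1e-300),
      n = rep(cfg$n_outcome, J + B), stringsAsFactors = FALSE)

    # swapped-orientation reporting on the outcome side
    swap <- stats::runif(J + B) < cfg$swap_frac
    out$effect_allele[swap] <- al[swap, 2]
    out$other_allele[swap] <- al[swap, 1]
    out$beta[swap] <- -out$beta[swap]
    out$eaf[swap] <- 1 - out$eaf[swap]

    # deliberately incompatible outcome allele pairs on some instruments
    n_mm <- round(cfg$mismatch_frac * J)
    mm_idx <- if (n_mm > 0) sample.int(J, n_mm) else integer()
    for (i in mm_idx) {
      bad <- setdiff(c("A", "C", "G", "T"),
                     c(out$effect_allele[i], out$other_allele[i]))
      out$other_allele[i] <- bad[1]
    }

    truth <- data.frame(snp_id = ids_i, gamma = mod$gamma,
                        alpha = mod$alpha, eps_x = mod$eps_x,
                        eps_y = mod$eps_y,
                        outlier = seq_len(J) %in% mod$outlier_idx,
                        stringsAsFactors = FALSE)
    list(
      exposure = make_summary_dataset(expo, trait_id = "sim_metabolite",
                                      trait_label = "simulated metabolite",
                                      trait_type = "quantitative",
                                      n_total = cfg$n_exposure),
      outcome = make_summary_dataset(out, trait_id = "sim_disease",
                                     trait_label = "simulated disease",
                                     trait_type = "binary",
                                     n_total = cfg$n_outcome,
                                     n_cases = round(cfg$n_outcome * 0.02)),
      truth = list(theta = cfg$theta, per_snp = truth,
                   outliers = ids_i[mod$outlier_idx],
                   mismatched = ids_i[sort(mm_idx)]))
  })
}

#' Simulate LD score regression inputs with known heritability and
#' genetic correlation
#'
#' LD scores follow a shifted gamma distribution (`ell = 1 + Gamma(shape,
#' scale)`).  Per SNP, the z-statistics of the two traits are drawn from a
#' bivariate normal with variances `1 + n_t h2_t ell / m` and covariance
#' `sqrt(n1 n2) rg sqrt(h2_1 h2_2) ell / m` — the LDSC regression model
#' with unit intercepts (non-overlapping cohorts).
#'
#' @param cfg a [sim_config()]; uses `m_total`, `h2_true`, `rg_true`,
#'   `n_exposure`, `n_outcome`, `ell_shape`, `ell_scale`, `seed`.
#' @return list with `inp1`, `inp2` (`ldsc_input` objects) and `truth`
#'   (`h2` length-2 and `rg`).
#' @export
simulate_ldsc_inputs <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  local_seed(cfg$seed, {
    m <- cfg$m_total
    ell <- 1 + stats::rgamma(m, shape = cfg$ell_shape, scale = cfg$ell_scale)
    n1 <- as.numeric(cfg$n_exposure); n2 <- as.numeric(cfg$n_outcome)
    h1 <- cfg$h2_true[1]; h2 <- cfg$h2_true[2]
    v1 <- 1 + n1 * h1 * ell / m
    v2 <- 1 + n2 * h2 * ell / m
    cv <- sqrt(n1 * n2) * cfg$rg_true * sqrt(h1 * h2) * ell / m
    u1 <- stats::rnorm(m); u2 <- stats::rnorm(m)
    z1 <- sqrt(v1) * u1
    z2 <- (cv / sqrt(v1)) * u1 + sqrt(pmax(v2 - cv^2 / v1, 0)) * u2
    ids <- sprintf("rs%06d", seq_len(m))
    list(inp1 = ldsc_input(ids, z1, ell, n1, m),
         inp2 = ldsc_input(ids, z2, ell, n2, m),
         truth = list(h2 = c(h1, h2), rg = cfg$rg_true))
  })
}

#' Write a simulated dataset bundle to delimited text files
#'
#' Emits `exposure.tsv`, `outcome.tsv`, `ldscores.tsv` (LD scores for the
#' union of simulated SNPs, drawn from the configured LD-score model) and
#' `truth.tsv` into `dir`.
#'
#' @param cfg a [sim_config()].
#' @param dir output directory, created if needed.
#' @return invisibly, the named vector of written paths.
#' @export
write_simulated_study <- function(cfg, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sim <- simulate_pair(cfg)
  p <- c(exposure = file.path(dir, "exposure.tsv"),
         outcome = file.path(dir, "outcome.tsv"),
         ldscores = file.path(dir, "ldscores.tsv"),
         truth = file.path(dir, "truth.tsv"))
  write_results_table(sim$exposure$records, p[["exposure"]])
  write_results_table(sim$outcome$records, p[["outcome"]])
  ell <- local_seed(cfg$seed + 1L, {
    1 + stats::rgamma(nrow(sim$exposure$records), shape = cfg$ell_shape,
                      scale = cfg$ell_scale)
  })
  write_results_table(data.frame(snp = sim$exposure$records$snp_id,
                                 l2 = ell, stringsAsFactors = FALSE),
                      p[["ldscores"]])
  tr <- sim$truth$per_snp
  tr$theta <- sim$truth$theta
  write_results_table(tr, p[["truth"]])
  invisible(p)
}
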