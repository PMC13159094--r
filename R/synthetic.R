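# Seeded simulator for two-sample GWAS summary statistics with a known
# exposure -> mediator -> outcome causal structure.

#' Simulation configuration
#'
#' Describes a ground-truth causal system from which two-sample GWAS summary
#' statistics are generated: `n_snps` exposure instruments jointly explaining
#' `h2_exp` of exposure variance, `n_med_snps` mediator-specific instruments
#' explaining `h2_med` of mediator variance, causal paths
#' exposure -> mediator (`theta_em`), mediator -> outcome (`theta_mo`) and a
#' direct exposure -> outcome path (`theta_direct`), plus optional
#' horizontal pleiotropy on a fraction of the exposure instruments and
#' optional block LD structure.
#'
#' Default sample sizes mirror the regime of published molecular-trait and
#' disease GWAS this simulator emulates: ~15k for a plasma-protein panel,
#' ~8k for a metabolomics cohort, and a biobank-scale binary outcome
#' (~412k with ~7% cases). Continuous traits are on the standardized scale;
#' outcome effects are log odds, with standard errors scaled by case/control
#' imbalance through `binary_outcome_prevalence`.
#'
#' @param n_snps exposure instrument count (default 100).
#' @param n_med_snps mediator-specific instrument count (default `n_snps`).
#' @param n_exp,n_med,n_out GWAS sample sizes (defaults 14824, 8299,
#'   412181).
#' @param h2_exp exposure variance explained by its instruments
#'   (default 0.3).
#' @param h2_med mediator variance explained by its own instruments
#'   (default `h2_exp`).
#' @param theta_em,theta_mo,theta_direct causal path coefficients
#'   (defaults 0).
#' @param pleio_mean,pleio_sd distribution of direct SNP-outcome effects for
#'   invalid instruments (defaults 0; `pleio_mean != 0` gives directional
#'   pleiotropy).
#' @param prop_invalid fraction of exposure instruments with pleiotropic
#'   outcome effects (default 0).
#' @param ld_block_size SNPs per LD block (default 1 = no LD).
#' @param ld_r2 within-block r-squared (default 0).
#' @param binary_outcome_prevalence case fraction of the outcome GWAS
#'   (default 0.072).
#' @param seed mandatory integer seed.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_snps = 100, n_med_snps = n_snps,
                       n_exp = 14824, n_med = 8299, n_out = 412181,
                       h2_exp = 0.3, h2_med = h2_exp,
                       theta_em = 0, theta_mo = 0, theta_direct = 0,
                       pleio_mean = 0, pleio_sd = 0, prop_invalid = 0,
                       ld_block_size = 1, ld_r2 = 0,
                       binary_outcome_prevalence = 0.072,
                       seed) {
  if (missing(seed)) stop("seed is mandatory")
  cfg <- list(n_snps = as.integer(n_snps), n_med_snps = as.integer(n_med_snps),
              n_exp = n_exp, n_med = n_med, n_out = n_out,
              h2_exp = h2_exp, h2_med = h2_med,
              theta_em = theta_em, theta_mo = theta_mo,
              theta_direct = theta_direct,
              pleio_mean = pleio_mean, pleio_sd = pleio_sd,
              prop_invalid = prop_invalid,
              ld_block_size = as.integer(ld_block_size), ld_r2 = ld_r2,
              binary_outcome_prevalence = binary_outcome_prevalence,
              seed = as.integer(seed))
  with(cfg, {
    if (n_snps < 1) stop("n_snps must be >= 1")
    if (any(c(n_exp, n_med, n_out) <= 0)) stop("sample sizes must be > 0")
    if (h2_exp <= 0 || h2_exp > 1) stop("h2_exp must lie in (0, 1]")
    if (h2_med < 0 || h2_med > 1) stop("h2_med must lie in [0, 1]")
    if (prop_invalid < 0 || prop_invalid > 1) {
      stop("prop_invalid must lie in [0, 1]")
    }
    if (ld_r2 < 0 || ld_r2 > 1) stop("ld_r2 must lie in [0, 1]")
    if (binary_outcome_prevalence <= 0 || binary_outcome_prevalence >= 1) {
      stop("binary_outcome_prevalence must lie in (0, 1)")
    }
  })
  class(cfg) <- "sim_config"
  cfg
}

# Correlated per-block estimation noise: equicorrelated with r = sqrt(r2).
.block_noise <- function(n, block_size, r2) {
  if (block_size <= 1L || r2 <= 0) return(rnorm(n))
  r <- sqrt(r2)
  blocks <- split(seq_len(n), ceiling(seq_len(n) / block_size))
  z <- numeric(n)
  for (b in blocks) {
    shared <- rnorm(1)
    z[b] <- sqrt(r) * shared + sqrt(1 - r) * rnorm(length(b))
  }
  z
}

#' Simulate a two-sample GWAS summary-statistic triple
#'
#' Generates exposure, mediator and outcome summary statistics over a shared
#' SNP panel under the causal system described by a [sim_config()]:
#' \itemize{
#'   \item true SNP-exposure effects are drawn and rescaled so the
#'     instruments jointly explain `h2_exp` of exposure variance;
#'   \item true SNP-mediator effects are `theta_em` times the exposure
#'     effects, plus mediator-specific instruments scaled to `h2_med`;
#'   \item true SNP-outcome effects are `theta_direct * b_exp + theta_mo *
#'     b_med`, plus a direct pleiotropic effect drawn from
#'     `N(pleio_mean, pleio_sd)` for the invalid fraction of exposure
#'     instruments;
#'   \item observed effects add estimation noise with the analytic GWAS
#'     standard error `1 / sqrt(2 p (1-p) n)` (continuous traits,
#'     standardized) or `1 / sqrt(2 p (1-p) n v)` with `v = prev (1-prev)`
#'     (binary outcome, log-odds scale); noise is equicorrelated within LD
#'     blocks when configured.
#' }
#' SNPs are placed more than one clumping window apart (block members
#' adjacent) so that instrument counts are controlled by the configuration,
#' not by incidental clumping. Regeneration with the same seed is
#' bit-identical; the caller's RNG state is untouched.
#'
#' @param cfg a [sim_config()].
#' @return List with elements `exposure`, `mediator`, `outcome` (each a
#'   [summary_stats()] object), `truth` (per-SNP true effects, the theta
#'   values, and invalid-instrument ids), and `ld` (an [ld_info()] object, or
#'   `NULL` when no LD was configured).
#' @export
simulate_triple <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    j_exp <- cfg$n_snps
    j_med <- cfg$n_med_snps
    n <- j_exp + j_med
    maf <- runif(n, 0.05, 0.5)
    var_g <- 2 * maf * (1 - maf)  # per-SNP genotype variance

    idx_exp <- seq_len(j_exp)
    idx_med <- if (j_med > 0) j_exp + seq_len(j_med) else integer(0)

    # exposure architecture: effect magnitudes |N(1, 0.5)| emulate an
    # ascertained instrument panel (sizes bounded away from zero), oriented
    # effect-allele-positive (the convention under which directional
    # pleiotropy is directional on the ratio scale), scaled to hit h2_exp
    b_exp <- numeric(n)
    raw <- abs(rnorm(j_exp, 1, 0.5))
    b_exp[idx_exp] <- raw * sqrt(cfg$h2_exp / sum(var_g[idx_exp] * raw^2))

    b_med <- cfg$theta_em * b_exp
    if (j_med > 0 && cfg$h2_med > 0) {
      raw_m <- abs(rnorm(j_med, 1, 0.5))
      b_med[idx_med] <- raw_m *
        sqrt(cfg$h2_med / sum(var_g[idx_med] * raw_m^2))
    }

    n_invalid <- floor(cfg$prop_invalid * j_exp)
    invalid <- if (n_invalid > 0) sort(sample(idx_exp, n_invalid)) else
      integer(0)
    alpha <- numeric(n)
    if (n_invalid > 0) {
      alpha[invalid] <- rnorm(n_invalid, cfg$pleio_mean, cfg$pleio_sd)
    }
    b_out <- cfg$theta_direct * b_exp + cfg$theta_mo * b_med + alpha

    v_case <- cfg$binary_outcome_prevalence *
      (1 - cfg$binary_outcome_prevalence)
    se_exp <- 1 / sqrt(var_g * cfg$n_exp)
    se_med <- 1 / sqrt(var_g * cfg$n_med)
    se_out <- 1 / sqrt(var_g * cfg$n_out * v_case)

    bhat_exp <- b_exp + se_exp * .block_noise(n, cfg$ld_block_size, cfg$ld_r2)
    bhat_med <- b_med + se_med * .block_noise(n, cfg$ld_block_size, cfg$ld_r2)
    bhat_out <- b_out + se_out * .block_noise(n, cfg$ld_block_size, cfg$ld_r2)

    # genomic placement: blocks are adjacent (2 kb spacing), distinct blocks
    # sit >10 Mb apart across 22 chromosomes
    block <- ceiling(seq_len(n) / max(1L, cfg$ld_block_size))
    within <- seq_len(n) - (block - 1L) * max(1L, cfg$ld_block_size)
    chrom <- as.character((block - 1L) %% 22L + 1L)
    pos <- ((block - 1L) %/% 22L) * 20000000L + within * 2000L + 1L

    snp_id <- sprintf("rs%07d", seq_len(n))
    alleles <- cbind(effect = sample(c("A", "C", "G", "T"), n, replace = TRUE),
                     other = NA_character_)
    # draw a distinct, non-complementary other allele: avoids palindromic
    # ambiguity so harmonization is exercised deterministically
    non_pal <- list(A = c("C", "G"), C = c("A", "T"),
                    G = c("A", "T"), T = c("C", "G"))
    alleles[, "other"] <- vapply(alleles[, "effect"], function(a) {
      sample(non_pal[[a]], 1)
    }, character(1))

    mk <- function(beta, se, n_samp, id) {
      p <- 2 * pnorm(-abs(beta / se))
      summary_stats(data.frame(
        snp_id = snp_id, chrom = chrom, pos = pos,
        effect_allele = alleles[, "effect"], other_allele = alleles[, "other"],
        eaf = maf, beta = beta, se = se,
        pval = pmax(p, 1e-300), n = n_samp,
        stringsAsFactors = FALSE), trait_id = id)
    }

    ld <- NULL
    if (cfg$ld_block_size > 1L && cfg$ld_r2 > 0) {
      r2 <- diag(n)
      for (b in split(seq_len(n), block)) r2[b, b] <- cfg$ld_r2
      diag(r2) <- 1
      ld <- ld_info(snp_id, r2)
    }

    list(exposure = mk(bhat_exp, se_exp, cfg$n_exp, "exposure"),
         mediator = mk(bhat_med, se_med, cfg$n_med, "mediator"),
         outcome = mk(bhat_out, se_out, cfg$n_out, "outcome"),
         truth = list(snp_id = snp_id,
                      b_exp = b_exp, b_med = b_med, b_out = b_out,
                      pleiotropy = alpha,
                      invalid_snp_ids = snp_id[invalid],
                      theta_em = cfg$theta_em, theta_mo = cfg$theta_mo,
                      theta_direct = cfg$theta_direct,
                      theta_total = cfg$theta_direct +
                        cfg$theta_em * cfg$theta_mo,
                      config = cfg),
         ld = ld)
  })
}

#' Published worked example of a mediated cytokine-disease path
#'
#' The reference three-path estimate set used by the mediation tests: total
#' effect of the cytokine on the disease, cytokine-to-metabolite effect, and
#' metabolite-to-disease effect, each with its published 95% interval
#' (standard errors back-derived from the interval half-width / 1.96).
#'
#' @return List of three elements `beta_all`, `beta1`, `beta2`, each
#'   `c(beta, ci_low, ci_high, se)`.
#' @export
make_worked_example <- function() {
  path <- function(beta, lo, hi) {
    c(beta = beta, ci_low = lo, ci_high = hi, se = (hi - lo) / (2 * qnorm(0.975)))
  }
  list(beta_all = path(-0.0704, -0.1247, -0.0161),
       beta1 = path(0.1162, 0.0305, 0.2020),
       beta2 = path(0.1020, 0.0271, 0.1769))
}
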