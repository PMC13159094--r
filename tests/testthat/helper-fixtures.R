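# Shared fixtures built in code.

# Minimal well-formed summary-stats data frame.
make_sumstats_df <- function(n = 5, beta = NULL, se = NULL, pval = NULL,
                             chrom = NULL, pos = NULL, eaf = NULL,
                             snp_id = sprintf("rs%03d", seq_len(n))) {
  data.frame(
    snp_id = snp_id,
    chrom = if (is.null(chrom)) as.character(seq_len(n)) else chrom,
    pos = if (is.null(pos)) seq_len(n) * 1000L else pos,
    effect_allele = rep(c("A", "C", "G", "T"), length.out = n),
    other_allele = rep(c("G", "T", "A", "C"), length.out = n),
    eaf = if (is.null(eaf)) rep(0.3, n) else eaf,
    beta = if (is.null(beta)) seq(0.1, by = 0.01, length.out = n) else beta,
    se = if (is.null(se)) rep(0.02, n) else se,
    pval = if (is.null(pval)) rep(1e-8, n) else pval,
    n = rep(10000L, n),
    stringsAsFactors = FALSE
  )
}

# Harmonized set straight from per-SNP effects (bypasses allele logic).
make_h <- function(beta_exp, se_exp, beta_out, se_out,
                   snp_id = sprintf("rs%03d", seq_along(beta_exp))) {
  structure(
    data.frame(snp_id = snp_id, beta_exp = beta_exp, se_exp = se_exp,
               beta_out = beta_out, se_out = se_out,
               f_stat = (beta_exp / se_exp)^2, flipped = FALSE,
               stringsAsFactors = FALSE),
    exposure_id = "exp", outcome_id = "out",
    audit = c(not_in_outcome = 0L, allele_mismatch = 0L,
              palindromic_dropped = 0L),
    class = c("harmonized_set", "data.frame")
  )
}

# Harmonized set with exact Wald ratios `wald` and ratio-scale standard
# errors `wald_se`; exposure effects vary so Egger is well defined.
make_h_from_ratios <- function(wald, wald_se,
                               beta_exp = seq(0.8, 1.2,
                                              length.out = length(wald))) {
  make_h(beta_exp = beta_exp, se_exp = rep(0.01, length(wald)),
         beta_out = wald * beta_exp, se_out = wald_se * abs(beta_exp))
}

# Select + harmonize + IVW for one simulated pair; returns mr_estimate row.
quick_ivw <- function(exp_stats, out_stats, p_threshold = 1e-5,
                      random_effects = TRUE) {
  iv <- suppressWarnings(select_instruments(exp_stats, p_threshold))
  h <- harmonize(iv, out_stats)
  mr_ivw(h, random_effects = random_effects)
}
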