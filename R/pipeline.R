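# Three-step screening pipeline: forward MR of many exposures, reverse-MR
# exclusion, mediator screening, and mediation assembly.

#' Pipeline configuration
#'
#' All thresholds and seeds used by the screening pipeline, in one place so
#' each run can be recorded in a manifest. Defaults follow common two-sample
#' MR practice for molecular exposures: relaxed instrument p-value threshold
#' (1e-5) with an F >= 10 strength guard, clumping at r2 < 0.001 within
#' 10 Mb, nominal screening alphas (0.05 for the cytokine stage, a stricter
#' 0.01 for the much larger metabolite panel, 0.05 for reverse-MR
#' exclusion), and no multiple-testing correction (`p_adjust = "none"`;
#' `"bonferroni"` or `"fdr"` are available but change the stated screening
#' behaviour).
#'
#' @param p_threshold instrument selection p-value (default 1e-5).
#' @param clump_r2 clumping r-squared threshold (default 0.001).
#' @param clump_kb clumping window in kb (default 10000).
#' @param f_min minimum instrument F-statistic (default 10).
#' @param palindromic_eaf_window see [harmonize()] (default 0.08).
#' @param alpha_stage1 screening alpha for primary exposures (default 0.05).
#' @param alpha_mediators stricter screening alpha for mediator candidates
#'   (default 0.01).
#' @param alpha_reverse reverse-MR exclusion alpha (default 0.05).
#' @param alpha_em alpha for the exposure-to-mediator link required to form
#'   a mediation triple (default 0.05).
#' @param p_adjust multiple-testing adjustment across a screened panel
#'   (default `"none"`).
#' @param n_sim_presso MR-PRESSO simulation count (default 1000).
#' @param boot_reps bootstrap replicates for median/mode estimators
#'   (default 1000).
#' @param random_effects IVW random-effects switch (default TRUE).
#' @param seed master integer seed; per-exposure seeds are derived from it
#'   deterministically.
#' @return An `mr_config` list.
#' @export
mr_config <- function(p_threshold = 1e-5, clump_r2 = 0.001, clump_kb = 10000,
                      f_min = 10, palindromic_eaf_window = 0.08,
                      alpha_stage1 = 0.05, alpha_mediators = 0.01,
                      alpha_reverse = 0.05, alpha_em = 0.05,
                      p_adjust = c("none", "bonferroni", "fdr"),
                      n_sim_presso = 1000, boot_reps = 1000,
                      random_effects = TRUE, seed = 1) {
  p_adjust <- match.arg(p_adjust)
  alphas <- c(alpha_stage1, alpha_mediators, alpha_reverse, alpha_em)
  if (any(alphas <= 0 | alphas >= 1)) stop("alphas must lie in (0, 1)")
  structure(list(p_threshold = p_threshold, clump_r2 = clump_r2,
                 clump_kb = clump_kb, f_min = f_min,
                 palindromic_eaf_window = palindromic_eaf_window,
                 alpha_stage1 = alpha_stage1,
                 alpha_mediators = alpha_mediators,
                 alpha_reverse = alpha_reverse, alpha_em = alpha_em,
                 p_adjust = p_adjust, n_sim_presso = n_sim_presso,
                 boot_reps = boot_reps, random_effects = random_effects,
                 seed = as.integer(seed)),
            class = "mr_config")
}

# deterministic sub-seed derivation, kept below 2^31
.sub_seed <- function(seed, i) (as.integer(seed) * 1009L + i * 31L) %% 2147483647L

#' Instrument and harmonize one exposure-outcome pair
#'
#' Applies the full instrument-selection chain: p-value threshold, greedy
#' clumping, allele harmonization against the outcome, and the F-statistic
#' filter.
#'
#' @param exposure,outcome `summary_stats` objects.
#' @param config an [mr_config()].
#' @param ld optional [ld_info()].
#' @return A `harmonized_set` (possibly with zero rows).
#' @export
instrument_pair <- function(exposure, outcome, config = mr_config(),
                            ld = NULL) {
  empty_set <- function(reason) {
    h <- data.frame(snp_id = character(0), beta_exp = numeric(0),
                    se_exp = numeric(0), beta_out = numeric(0),
                    se_out = numeric(0), f_stat = numeric(0),
                    flipped = logical(0))
    structure(h, exposure_id = trait_id(exposure),
              outcome_id = trait_id(outcome),
              audit = setNames(1L, reason),
              class = c("harmonized_set", "data.frame"))
  }
  iv <- suppressWarnings(select_instruments(exposure, config$p_threshold))
  if (nrow(iv) == 0L) return(empty_set("no_instruments"))
  iv <- clump(iv, ld = ld, r2_max = config$clump_r2,
              window_kb = config$clump_kb)
  h <- tryCatch(
    harmonize(iv, outcome,
              palindromic_eaf_window = config$palindromic_eaf_window),
    error = function(e) empty_set("no_shared_snps"))
  if (nrow(h) == 0L) return(h)
  filter_weak_instruments(h, f_min = config$f_min)
}

#' MR analysis of one exposure-outcome pair
#'
#' Instruments, harmonizes and runs the estimators (all five when enough
#' SNPs are available) plus the sensitivity diagnostics.
#'
#' @inheritParams instrument_pair
#' @param seed integer seed for the bootstrap and MR-PRESSO randomness.
#' @param sensitivity compute the sensitivity report (default TRUE).
#' @return List with `harmonized`, `estimates` (table from
#'   [mr_all_methods()], or NULL when no instruments survive), and
#'   `sensitivity` (a [sensitivity_report()], or NULL).
#' @export
mr_pair <- function(exposure, outcome, config = mr_config(), ld = NULL,
                    seed = config$seed, sensitivity = TRUE) {
  h <- instrument_pair(exposure, outcome, config, ld)
  if (nrow(h) == 0L) {
    return(list(harmonized = h, estimates = NULL, sensitivity = NULL))
  }
  est <- mr_all_methods(h, boot_reps = config$boot_reps, seed = seed,
                        random_effects = config$random_effects)
  sens <- if (sensitivity && nrow(h) >= 2L) {
    sensitivity_report(h, n_sim = config$n_sim_presso, seed = seed)
  }
  list(harmonized = h, estimates = est, sensitivity = sens)
}

.adjust_p <- function(p, method) {
  switch(method,
         none = p,
         bonferroni = p.adjust(p, "bonferroni"),
         fdr = p.adjust(p, "BH"))
}

#' Screen many exposures against one outcome
#'
#' Runs [mr_pair()] for each exposure and flags those whose IVW p-value
#' falls below `alpha`. IVW is the gating estimator; the other four methods
#' are reported alongside without gating. Exposures yielding zero surviving
#' instruments are kept in the output with status `"no_instruments"` rather
#' than dropped.
#'
#' @param exposures named list of `summary_stats` objects (names default to
#'   each table's trait id).
#' @param outcome a `summary_stats` object.
#' @param config an [mr_config()].
#' @param alpha screening alpha (default `config$alpha_stage1`).
#' @param ld optional [ld_info()] shared by all exposures.
#' @param sensitivity compute per-exposure sensitivity reports
#'   (default TRUE).
#' @return A `screen_result` list: `summary` (one row per exposure: ivw
#'   beta/se/p, OR columns, n_snps, status, significant flag, ordered by
#'   IVW p then id), `estimates` (all-methods table per exposure),
#'   `sensitivity` (per-exposure reports), `config`.
#' @export
screen_exposures <- function(exposures, outcome, config = mr_config(),
                             alpha = config$alpha_stage1, ld = NULL,
                             sensitivity = TRUE) {
  if (!is.list(exposures) || length(exposures) == 0L) {
    stop("'exposures' must be a nonempty list of summary_stats objects")
  }
  if (is.null(names(exposures)) || any(names(exposures) == "")) {
    names(exposures) <- vapply(exposures, trait_id, character(1))
  }
  rows <- list()
  estimates <- list()
  sens <- list()
  for (i in seq_along(exposures)) {
    id <- names(exposures)[i]
    res <- mr_pair(exposures[[i]], outcome, config, ld = ld,
                   seed = .sub_seed(config$seed, i),
                   sensitivity = sensitivity)
    if (is.null(res$estimates)) {
      rows[[id]] <- data.frame(exposure = id, status = "no_instruments",
                               n_snps = 0L, beta = NA_real_, se = NA_real_,
                               pval = NA_real_, or = NA_real_,
                               or_low = NA_real_, or_high = NA_real_,
                               stringsAsFactors = FALSE)
    } else {
      ivw <- res$estimates[res$estimates$method == "ivw", ]
      rows[[id]] <- data.frame(exposure = id, status = "ok",
                               n_snps = ivw$n_snps, beta = ivw$beta,
                               se = ivw$se, pval = ivw$pval, or = ivw$or,
                               or_low = ivw$or_low, or_high = ivw$or_high,
                               stringsAsFactors = FALSE)
      estimates[[id]] <- res$estimates
      sens[[id]] <- res$sensitivity
    }
  }
  summary <- do.call(rbind, rows)
  summary$pval_adj <- .adjust_p(summary$pval, config$p_adjust)
  summary$significant <- !is.na(summary$pval_adj) & summary$pval_adj < alpha
  summary <- summary[order(summary$pval, summary$exposure), ]
  rownames(summary) <- NULL
  structure(list(summary = summary, estimates = estimates,
                 sensitivity = sens, config = config, alpha = alpha),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat("MR screen:", nrow(x$summary), "exposures,",
      sum(x$summary$significant), "significant at alpha =", x$alpha, "\n")
  print(utils::head(x$summary, 10))
  invisible(x)
}

#' Reverse-MR exclusion screen
#'
#' Treats the outcome as the exposure and tests each candidate trait for a
#' reverse causal path (outcome -> trait) using IVW on the outcome's own
#' instruments. Traits with reverse p below `alpha` are excluded from
#' mediation candidacy, since a significant reverse path undermines the
#' forward causal claim.
#'
#' @param outcome_stats `summary_stats` of the outcome (instrumented as an
#'   exposure with the same selection thresholds).
#' @param targets named list of `summary_stats` for the candidate traits.
#' @param config an [mr_config()].
#' @param alpha exclusion alpha (default `config$alpha_reverse`).
#' @param ld optional [ld_info()].
#' @return Data frame with one row per target: `target`, `n_snps`, `beta`,
#'   `se`, `pval`, `excluded`.
#' @export
reverse_mr <- function(outcome_stats, targets, config = mr_config(),
                       alpha = config$alpha_reverse, ld = NULL) {
  if (is.null(names(targets)) || any(names(targets) == "")) {
    names(targets) <- vapply(targets, trait_id, character(1))
  }
  rows <- lapply(seq_along(targets), function(i) {
    res <- mr_pair(outcome_stats, targets[[i]], config, ld = ld,
                   seed = .sub_seed(config$seed, 10000L + i),
                   sensitivity = FALSE)
    if (is.null(res$estimates)) {
      return(data.frame(target = names(targets)[i], n_snps = 0L,
                        beta = NA_real_, se = NA_real_, pval = NA_real_,
                        excluded = FALSE, stringsAsFactors = FALSE))
    }
    ivw <- res$estimates[res$estimates$method == "ivw", ]
    data.frame(target = names(targets)[i], n_snps = ivw$n_snps,
               beta = ivw$beta, se = ivw$se, pval = ivw$pval,
               excluded = ivw$pval < alpha, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Assemble mediation triples from screened exposures and mediators
#'
#' For every (exposure, mediator) pair in which the exposure-to-mediator IVW
#' link is significant at `config$alpha_em`, extracts the three path
#' estimates — total (exposure -> outcome), beta1 (exposure -> mediator, on
#' the exposure's instruments) and beta2 (mediator -> outcome, on the
#' mediator's own instruments) — and runs [mediate()]. Pairs without a
#' significant exposure-mediator link are omitted.
#'
#' @param exposures named list of `summary_stats` for exposures that
#'   survived forward and reverse screening.
#' @param mediators named list of `summary_stats` for significant mediator
#'   candidates.
#' @param outcome `summary_stats` of the outcome.
#' @param config an [mr_config()].
#' @param ld optional [ld_info()].
#' @param ci_method passed to [mediate()].
#' @return List with `table` (stacked one-row data frames, Table-style
#'   layout; NULL when no pair qualifies) and `results` (the full
#'   `mediation_result` objects, named `exposure|mediator`).
#' @export
find_mediations <- function(exposures, mediators, outcome,
                            config = mr_config(), ld = NULL,
                            ci_method = "delta") {
  if (is.null(names(exposures)) || any(names(exposures) == "")) {
    names(exposures) <- vapply(exposures, trait_id, character(1))
  }
  if (is.null(names(mediators)) || any(names(mediators) == "")) {
    names(mediators) <- vapply(mediators, trait_id, character(1))
  }
  results <- list()
  k <- 0L
  for (e in names(exposures)) {
    for (m in names(mediators)) {
      if (identical(e, m)) next  # self-pairs are meaningless
      k <- k + 1L
      total <- mr_pair(exposures[[e]], outcome, config, ld = ld,
                       seed = .sub_seed(config$seed, 20000L + k),
                       sensitivity = FALSE)
      em <- mr_pair(exposures[[e]], mediators[[m]], config, ld = ld,
                    seed = .sub_seed(config$seed, 30000L + k),
                    sensitivity = FALSE)
      mo <- mr_pair(mediators[[m]], outcome, config, ld = ld,
                    seed = .sub_seed(config$seed, 40000L + k),
                    sensitivity = FALSE)
      if (is.null(total$estimates) || is.null(em$estimates) ||
            is.null(mo$estimates)) next
      em_ivw <- em$estimates[em$estimates$method == "ivw", ]
      if (em_ivw$pval >= config$alpha_em) next
      paths <- extract_path_betas(total$estimates, em$estimates,
                                  mo$estimates)
      med <- mediate(paths$beta_all, paths$se_all, paths$beta1, paths$se1,
                     paths$beta2, paths$se2, ci_method = ci_method,
                     seed = .sub_seed(config$seed, 50000L + k),
                     exposure_id = e, mediator_id = m,
                     outcome_id = trait_id(outcome))
      results[[paste(e, m, sep = "|")]] <- med
    }
  }
  tab <- if (length(results) > 0) {
    out <- do.call(rbind, lapply(results, as.data.frame))
    rownames(out) <- NULL
    out
  }
  list(table = tab, results = results)
}

#' Run the full three-step screen
#'
#' Step 1: forward MR of every exposure on the outcome, keeping those
#' significant at `alpha_stage1`. Reverse-MR then excludes exposures the
#' outcome feeds back onto. Step 2: forward MR of every mediator candidate
#' on the outcome at the stricter `alpha_mediators`. Step 3: mediation
#' triples for the surviving exposures and significant mediators.
#'
#' @param exposures,mediators named lists of `summary_stats`.
#' @param outcome a `summary_stats` object.
#' @param config an [mr_config()].
#' @param ld optional [ld_info()].
#' @param sensitivity compute sensitivity reports during screening.
#' @return List with `stage1` (exposure screen), `reverse` (exclusion
#'   table), `stage2` (mediator screen), `mediation` (triples), and
#'   `config`.
#' @export
run_three_step <- function(exposures, mediators, outcome,
                           config = mr_config(), ld = NULL,
                           sensitivity = FALSE) {
  stage1 <- screen_exposures(exposures, outcome, config,
                             alpha = config$alpha_stage1, ld = ld,
                             sensitivity = sensitivity)
  hits <- stage1$summary$exposure[stage1$summary$significant]
  rev_tab <- if (length(hits) > 0) {
    reverse_mr(outcome, exposures[hits], config, ld = ld)
  } else {
    data.frame(target = character(0), excluded = logical(0))
  }
  surviving <- setdiff(hits, rev_tab$target[rev_tab$excluded])
  stage2 <- screen_exposures(mediators, outcome, config,
                             alpha = config$alpha_mediators, ld = ld,
                             sensitivity = sensitivity)
  med_hits <- stage2$summary$exposure[stage2$summary$significant]
  mediation <- if (length(surviving) > 0 && length(med_hits) > 0) {
    find_mediations(exposures[surviving], mediators[med_hits], outcome,
                    config, ld = ld)
  } else {
    list(table = NULL, results = list())
  }
  list(stage1 = stage1, reverse = rev_tab, stage2 = stage2,
       mediation = mediation, config = config)
}
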