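# Product-of-coefficients mediation on MR path estimates.

#' Product-of-coefficients mediation analysis
#'
#' Combines three path estimates — the total effect of the exposure on the
#' outcome (`beta_all`), the exposure-to-mediator effect (`beta1`) and the
#' mediator-to-outcome effect (`beta2`) — into an indirect effect
#' `beta1 * beta2`, a direct effect `beta_all - beta1 * beta2`, and a
#' mediated proportion `indirect / beta_all`.
#'
#' The indirect-effect standard error uses the first-order delta (Sobel)
#' expansion `sqrt(beta1^2 se2^2 + beta2^2 se1^2)`; `second_order = TRUE`
#' adds the `se1^2 se2^2` term. The Sobel z test is `indirect / se`. With
#' `ci_method = "bootstrap"` the interval is instead the percentile interval
#' of the product over independent normal redraws of the two path estimates.
#' The proportion interval uses the delta expansion of a ratio with the
#' numerator and denominator treated as independent (an approximation: the
#' same outcome GWAS enters both, but the cross-covariance is not available
#' from summary data).
#'
#' When the indirect and total effects have opposite signs the proportion is
#' negative; this "inconsistent mediation" is reported as-is (flagged, never
#' clamped to \[0, 1\]).
#'
#' @param beta_all,se_all total exposure-outcome effect and its standard
#'   error.
#' @param beta1,se1 exposure-mediator effect and standard error.
#' @param beta2,se2 mediator-outcome effect and standard error.
#' @param ci_method `"delta"` (synonym `"sobel"`) or `"bootstrap"`.
#' @param second_order include the second-order delta term (default FALSE).
#' @param boot_reps bootstrap draws (default 10000).
#' @param seed integer seed for the bootstrap.
#' @param exposure_id,mediator_id,outcome_id optional labels.
#' @return A `mediation_result` list with elements `beta_all`, `beta1`,
#'   `beta2` (each `c(beta, se, ci_low, ci_high)`), `indirect`,
#'   `indirect_se`, `indirect_ci`, `sobel_z`, `sobel_p`, `direct`,
#'   `proportion`, `proportion_se`, `proportion_ci`, `inconsistent`,
#'   `ci_method`. The proportion is `NA` (not an error) when
#'   `beta_all == 0`.
#' @export
mediate <- function(beta_all, se_all, beta1, se1, beta2, se2,
                    ci_method = c("delta", "sobel", "bootstrap"),
                    second_order = FALSE, boot_reps = 10000, seed = 1,
                    exposure_id = "exposure", mediator_id = "mediator",
                    outcome_id = "outcome") {
  ci_method <- match.arg(ci_method)
  beta_all <- unname(beta_all); se_all <- unname(se_all)
  beta1 <- unname(beta1); se1 <- unname(se1)
  beta2 <- unname(beta2); se2 <- unname(se2)
  if (!all(c(se_all, se1, se2) > 0)) stop("all standard errors must be > 0")
  z <- qnorm(0.975)

  indirect <- beta1 * beta2
  var_ind <- beta1^2 * se2^2 + beta2^2 * se1^2
  if (second_order) var_ind <- var_ind + se1^2 * se2^2
  indirect_se <- sqrt(var_ind)
  sobel_z <- indirect / indirect_se
  sobel_p <- 2 * pnorm(-abs(sobel_z))
  direct <- beta_all - indirect

  if (beta_all != 0) {
    proportion <- indirect / beta_all
    # delta method for a ratio, numerator and denominator independent
    proportion_se <- abs(proportion) *
      sqrt(var_ind / indirect^2 + se_all^2 / beta_all^2)
    if (indirect == 0) proportion_se <- sqrt(var_ind / beta_all^2)
    proportion_ci <- proportion + c(-1, 1) * z * proportion_se
  } else {
    proportion <- proportion_se <- NA_real_
    proportion_ci <- c(NA_real_, NA_real_)
  }

  if (ci_method == "bootstrap") {
    draws <- with_seed(seed, {
      b1 <- rnorm(boot_reps, beta1, se1)
      b2 <- rnorm(boot_reps, beta2, se2)
      ba <- rnorm(boot_reps, beta_all, se_all)
      list(ind = b1 * b2, prop = b1 * b2 / ba)
    })
    indirect_ci <- unname(quantile(draws$ind, c(0.025, 0.975)))
    if (beta_all != 0) {
      proportion_ci <- unname(quantile(draws$prop, c(0.025, 0.975)))
    }
  } else {
    indirect_ci <- indirect + c(-1, 1) * z * indirect_se
  }

  path <- function(b, s) c(beta = b, se = s, ci_low = b - z * s,
                           ci_high = b + z * s)
  out <- list(exposure_id = exposure_id, mediator_id = mediator_id,
              outcome_id = outcome_id,
              beta_all = path(beta_all, se_all),
              beta1 = path(beta1, se1),
              beta2 = path(beta2, se2),
              indirect = indirect, indirect_se = indirect_se,
              indirect_ci = indirect_ci,
              sobel_z = sobel_z, sobel_p = sobel_p,
              direct = direct,
              proportion = proportion, proportion_se = proportion_se,
              proportion_ci = proportion_ci,
              inconsistent = is.finite(proportion) && proportion < 0,
              ci_method = ci_method)
  class(out) <- "mediation_result"
  out
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("Mediation: %s -> %s -> %s\n", x$exposure_id, x$mediator_id,
              x$outcome_id))
  cat(sprintf("  total effect      %.4f (%.4f, %.4f)\n",
              x$beta_all["beta"], x$beta_all["ci_low"], x$beta_all["ci_high"]))
  cat(sprintf("  indirect (b1*b2)  %.4f (%.4f, %.4f)  Sobel p = %s\n",
              x$indirect, x$indirect_ci[1], x$indirect_ci[2],
              format.pval(x$sobel_p)))
  cat(sprintf("  direct            %.4f\n", x$direct))
  cat(sprintf("  mediated proportion %.1f%% (%.1f%%, %.1f%%)%s\n",
              100 * x$proportion, 100 * x$proportion_ci[1],
              100 * x$proportion_ci[2],
              if (isTRUE(x$inconsistent)) "  [inconsistent mediation]" else ""))
  invisible(x)
}

#' Flatten a mediation result into a report row
#'
#' Column layout follows the conventional mediation table: `beta.1`,
#' `beta.2`, `beta.all`, mediated effect, mediated proportion (percent),
#' each with its interval.
#'
#' @param x a [mediate()] result.
#' @return One-row data frame.
#' @export
as.data.frame.mediation_result <- function(x, ...) {
  data.frame(exposure = x$exposure_id, mediator = x$mediator_id,
             outcome = x$outcome_id,
             beta.1 = x$beta1[["beta"]], beta.1.low = x$beta1[["ci_low"]],
             beta.1.high = x$beta1[["ci_high"]],
             beta.2 = x$beta2[["beta"]], beta.2.low = x$beta2[["ci_low"]],
             beta.2.high = x$beta2[["ci_high"]],
             beta.all = x$beta_all[["beta"]],
             beta.all.low = x$beta_all[["ci_low"]],
             beta.all.high = x$beta_all[["ci_high"]],
             mediated.effect = x$indirect,
             mediated.effect.low = x$indirect_ci[1],
             mediated.effect.high = x$indirect_ci[2],
             mediated.proportion.pct = 100 * x$proportion,
             mediated.proportion.low.pct = 100 * x$proportion_ci[1],
             mediated.proportion.high.pct = 100 * x$proportion_ci[2],
             sobel_p = x$sobel_p,
             inconsistent = x$inconsistent,
             stringsAsFactors = FALSE)
}

#' Extract the three mediation path estimates from estimator tables
#'
#' Pulls the (beta, se) pair for one named method from each of the three
#' estimator tables produced by [mr_all_methods()]: exposure-to-outcome
#' (total), exposure-to-mediator, and mediator-to-outcome.
#'
#' @param tab_total,tab_exp_med,tab_med_out estimator tables containing a
#'   `method` column.
#' @param method estimator to extract (default `"ivw"`).
#' @return List with `beta_all`, `se_all`, `beta1`, `se1`, `beta2`, `se2`.
#' @export
extract_path_betas <- function(tab_total, tab_exp_med, tab_med_out,
                               method = "ivw") {
  pick <- function(tab, label) {
    i <- which(tab$method == method)
    if (length(i) != 1L) {
      stop("method '", method, "' not found in the ", label, " table")
    }
    c(beta = tab$beta[i], se = tab$se[i])
  }
  all <- pick(tab_total, "exposure-outcome (total)")
  b1 <- pick(tab_exp_med, "exposure-mediator")
  b2 <- pick(tab_med_out, "mediator-outcome")
  list(beta_all = all[["beta"]], se_all = all[["se"]],
       beta1 = b1[["beta"]], se1 = b1[["se"]],
       beta2 = b2[["beta"]], se2 = b2[["se"]])
}
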