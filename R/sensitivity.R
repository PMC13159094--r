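# Heterogeneity, pleiotropy, outlier and influence diagnostics.

#' Cochran's Q heterogeneity test
#'
#' `Q = sum_j w_j (wald_j - beta_fixed)^2` with inverse-variance weights and
#' the fixed-effect IVW estimate as the pooled value; under instrument
#' validity Q is chi-square with `J - 1` degrees of freedom. `Q / (J - 1)`
#' is exactly the variance-inflation factor applied by the random-effects
#' [mr_ivw()] (before flooring at 1).
#'
#' @param h a [harmonize()]d set with at least 2 usable SNPs.
#' @return List with `q_stat`, `q_df`, `q_pval`.
#' @export
cochran_q <- function(h) {
  r <- ratio_estimates(h)
  j <- nrow(r)
  if (j < 2L) stop("Cochran's Q requires at least 2 SNPs")
  w <- 1 / r$wald_se^2
  beta_fixed <- sum(w * r$wald) / sum(w)
  q <- sum(w * (r$wald - beta_fixed)^2)
  list(q_stat = q, q_df = j - 1L,
       q_pval = pchisq(q, df = j - 1L, lower.tail = FALSE))
}

#' Leave-one-out IVW series
#'
#' Recomputes the IVW estimate with each instrument removed in turn; a large
#' shift when one SNP is dropped marks that SNP as influential.
#'
#' @param h a [harmonize()]d set with at least 3 usable SNPs.
#' @param random_effects passed to [mr_ivw()].
#' @return Data frame with one row per left-out SNP: `left_out_snp`, `beta`,
#'   `se`.
#' @export
leave_one_out <- function(h, random_effects = TRUE) {
  stopifnot(inherits(h, "harmonized_set"))
  if (nrow(h) < 3L) stop("leave-one-out requires at least 3 SNPs")
  rows <- lapply(seq_len(nrow(h)), function(i) {
    e <- mr_ivw(h[-i, , drop = FALSE], random_effects = random_effects)
    data.frame(left_out_snp = h$snp_id[i], beta = e$beta, se = e$se,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Leave-one-out fixed-effect slopes of the zero-intercept weighted regression
# beta_out ~ beta_exp (weights 1/se_out^2), vectorized over SNPs. `y` may be
# a matrix (n_sim x J) of outcome effects for the simulated null.
.loo_slopes <- function(x, w, y) {
  if (is.matrix(y)) {
    swxy <- drop(y %*% (w * x))
    swxx <- sum(w * x^2)
    num <- sweep(-sweep(y, 2, w * x, `*`), 1, swxy, `+`)  # swxy - w_j x_j y_ij
    den <- swxx - matrix(w * x^2, nrow(y), length(x), byrow = TRUE)
    num / den
  } else {
    swxy <- sum(w * x * y)
    swxx <- sum(w * x^2)
    (swxy - w * x * y) / (swxx - w * x^2)
  }
}

#' MR-PRESSO pleiotropy residual sum of squares and outlier test
#'
#' Simulation-based detection of pleiotropic outlier instruments, following
#' the published three-test structure:
#' \describe{
#'   \item{global test}{the observed weighted residual sum of squares (RSS),
#'     with each SNP's outcome effect predicted by the leave-one-out IVW
#'     slope, is compared against `n_sim` simulated datasets in which every
#'     outcome effect is redrawn from a normal centred on its leave-one-out
#'     prediction with its own standard error; the global p is the fraction
#'     of simulated RSS at or above the observed one.}
#'   \item{outlier test}{each SNP's observed weighted squared residual is
#'     compared against its own simulated distribution; SNPs are flagged when
#'     the Bonferroni-corrected empirical p falls below `outlier_alpha`.}
#'   \item{distortion test}{the relative change in the IVW estimate after
#'     removing the flagged outliers is compared against the distribution of
#'     changes obtained by removing equally many SNPs at random.}
#' }
#' Empirical p-values use the add-one rule `(1 + #{sim >= obs}) / (1 +
#' n_sim)`, so the global p can never be exactly zero; when it hits the
#' `1/(n_sim+1)` floor, rerun with a larger `n_sim`.
#'
#' @param h a [harmonize()]d set with at least 4 usable SNPs.
#' @param n_sim simulated null datasets (default 1000; must be > 0).
#' @param seed integer seed; results are bit-reproducible given
#'   `(n_sim, seed)`.
#' @param outlier_alpha familywise level of the Bonferroni outlier test
#'   (default 0.05).
#' @return List with `presso_global_p`, `presso_rss_obs`, `presso_outliers`
#'   (character vector of flagged snp_ids), `presso_outlier_p` (named
#'   per-SNP p-values, Bonferroni-corrected), `presso_distortion_p` (NA when
#'   no outlier is flagged), and `beta_outlier_corrected` (IVW after removing
#'   flagged outliers; NA when none).
#' @export
mr_presso <- function(h, n_sim = 1000, seed = 1, outlier_alpha = 0.05) {
  stopifnot(inherits(h, "harmonized_set"))
  if (n_sim <= 0) stop("n_sim must be a positive integer")
  keep <- h$beta_exp != 0
  hh <- h[keep, , drop = FALSE]
  j <- nrow(hh)
  if (j < 4L) {
    return(list(presso_global_p = NA_real_, presso_rss_obs = NA_real_,
                presso_outliers = character(0),
                presso_outlier_p = setNames(numeric(0), character(0)),
                presso_distortion_p = NA_real_,
                beta_outlier_corrected = NA_real_,
                note = "global test unavailable: fewer than 4 SNPs"))
  }
  x <- hh$beta_exp
  y <- hh$beta_out
  se <- hh$se_out
  w <- 1 / se^2

  slopes_obs <- .loo_slopes(x, w, y)
  resid_obs <- y - slopes_obs * x
  sq_obs <- w * resid_obs^2
  rss_obs <- sum(sq_obs)

  with_seed(seed, {
    mu <- matrix(slopes_obs * x, n_sim, j, byrow = TRUE)
    ysim <- mu + matrix(rnorm(n_sim * j), n_sim, j) *
      matrix(se, n_sim, j, byrow = TRUE)
    slopes_sim <- .loo_slopes(x, w, ysim)
    resid_sim <- ysim - slopes_sim * matrix(x, n_sim, j, byrow = TRUE)
    sq_sim <- sweep(resid_sim^2, 2, w, `*`)
    rss_sim <- rowSums(sq_sim)

    global_p <- (1 + sum(rss_sim >= rss_obs)) / (1 + n_sim)
    outlier_p_raw <- (1 + colSums(sq_sim >= matrix(sq_obs, n_sim, j,
                                                   byrow = TRUE))) /
      (1 + n_sim)
    outlier_p <- pmin(1, outlier_p_raw * j)
    names(outlier_p) <- hh$snp_id
    outliers <- hh$snp_id[outlier_p < outlier_alpha]

    distortion_p <- NA_real_
    beta_corr <- NA_real_
    k <- length(outliers)
    if (k > 0L && j - k >= 2L) {
      ivw_without <- function(drop_idx) {
        xx <- x[-drop_idx]; yy <- y[-drop_idx]; ww <- w[-drop_idx]
        sum(ww * xx * yy) / sum(ww * xx^2)
      }
      beta_all <- sum(w * x * y) / sum(w * x^2)
      beta_corr <- ivw_without(match(outliers, hh$snp_id))
      d_obs <- (beta_corr - beta_all) / abs(beta_all)
      d_sim <- vapply(seq_len(n_sim), function(i) {
        (ivw_without(sample.int(j, k)) - beta_all) / abs(beta_all)
      }, numeric(1))
      distortion_p <- (1 + sum(abs(d_sim) >= abs(d_obs))) / (1 + n_sim)
    }
    list(presso_global_p = global_p, presso_rss_obs = rss_obs,
         presso_outliers = outliers, presso_outlier_p = outlier_p,
         presso_distortion_p = distortion_p,
         beta_outlier_corrected = beta_corr)
  })
}

#' Full sensitivity report for one exposure-outcome pair
#'
#' Bundles Cochran's Q, the MR-Egger intercept test, MR-PRESSO and the
#' leave-one-out series, with pass flags at `alpha` (a diagnostic *passes*
#' when its p-value exceeds `alpha`, i.e. no significant heterogeneity or
#' pleiotropy is detected).
#'
#' @param h a [harmonize()]d set.
#' @param n_sim,seed,outlier_alpha passed to [mr_presso()].
#' @param alpha diagnostic significance level (default 0.05).
#' @return A `sensitivity_report` list: `q_stat`, `q_df`, `q_pval`,
#'   `q_pass`, `egger_intercept`, `egger_intercept_se`, `egger_intercept_p`,
#'   `egger_pass`, the `presso_*` fields of [mr_presso()], `presso_pass`,
#'   and `loo` (the [leave_one_out()] table). Components needing more SNPs
#'   than available are NA.
#' @export
sensitivity_report <- function(h, n_sim = 1000, seed = 1,
                               outlier_alpha = 0.05, alpha = 0.05) {
  stopifnot(inherits(h, "harmonized_set"))
  j <- sum(h$beta_exp != 0)
  q <- if (j >= 2L) cochran_q(h) else
    list(q_stat = NA_real_, q_df = NA_integer_, q_pval = NA_real_)
  eg <- if (j >= 3L) mr_egger(h) else NULL
  pr <- mr_presso(h, n_sim = n_sim, seed = seed,
                  outlier_alpha = outlier_alpha)
  loo <- if (j >= 3L) leave_one_out(h) else NULL
  rep <- c(q,
           list(q_pass = if (is.na(q$q_pval)) NA else q$q_pval > alpha,
                egger_intercept = if (is.null(eg)) NA_real_ else eg$intercept,
                egger_intercept_se = if (is.null(eg)) NA_real_ else
                  eg$intercept_se,
                egger_intercept_p = if (is.null(eg)) NA_real_ else
                  eg$intercept_p,
                egger_pass = if (is.null(eg)) NA else eg$intercept_p > alpha),
           pr,
           list(presso_pass = if (is.na(pr$presso_global_p)) NA else
             pr$presso_global_p > alpha,
             loo = loo))
  class(rep) <- "sensitivity_report"
  rep
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat("Sensitivity diagnostics\n")
  cat(sprintf("  Cochran's Q: %.3f (df %s), p = %s [%s]\n",
              x$q_stat, x$q_df, format.pval(x$q_pval),
              if (isTRUE(x$q_pass)) "pass" else "FAIL"))
  cat(sprintf("  Egger intercept: %.4f (se %.4f), p = %s [%s]\n",
              x$egger_intercept, x$egger_intercept_se,
              format.pval(x$egger_intercept_p),
              if (isTRUE(x$egger_pass)) "pass" else "FAIL"))
  cat(sprintf("  MR-PRESSO global p = %s; outliers: %s\n",
              format.pval(x$presso_global_p),
              if (length(x$presso_outliers)) {
                paste(x$presso_outliers, collapse = ", ")
              } else "none"))
  invisible(x)
}
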