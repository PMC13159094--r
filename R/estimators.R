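# Two-sample MR causal-effect estimators operating on a harmonized set.

.Z95 <- qnorm(0.975)  # fixed 1.96 convention for reported intervals

# Evaluate `code` under a temporary seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

.mr_estimate <- function(method, beta, se, pval, n_snps,
                         intercept = NA_real_, intercept_se = NA_real_,
                         intercept_p = NA_real_, extra = list()) {
  out <- data.frame(method = method, n_snps = as.integer(n_snps),
                    beta = beta, se = se,
                    ci_low = beta - .Z95 * se, ci_high = beta + .Z95 * se,
                    pval = pval,
                    intercept = intercept, intercept_se = intercept_se,
                    intercept_p = intercept_p,
                    stringsAsFactors = FALSE)
  for (nm in names(extra)) attr(out, nm) <- extra[[nm]]
  class(out) <- c("mr_estimate", "data.frame")
  out
}

#' Per-SNP Wald ratio estimates
#'
#' The ratio `beta_out / beta_exp` per instrument with its first-order
#' standard error `se_out / |beta_exp|` (uncertainty in the SNP-exposure
#' association is ignored, the usual approximation for strong instruments).
#' Rows with `beta_exp == 0` are dropped and counted in the returned audit
#' attribute.
#'
#' @param h a [harmonize()]d set.
#' @return Data frame with columns `snp_id`, `wald`, `wald_se` and an `audit`
#'   attribute.
#' @export
ratio_estimates <- function(h) {
  stopifnot(inherits(h, "harmonized_set"))
  zero <- h$beta_exp == 0
  hh <- h[!zero, , drop = FALSE]
  out <- data.frame(snp_id = hh$snp_id,
                    wald = hh$beta_out / hh$beta_exp,
                    wald_se = hh$se_out / abs(hh$beta_exp),
                    stringsAsFactors = FALSE)
  attr(out, "audit") <- c(zero_exposure_beta = sum(zero))
  out
}

#' Inverse-variance weighted estimator
#'
#' The weighted average of per-SNP Wald ratios with inverse-variance weights
#' `w_j = 1 / wald_se_j^2`; algebraically identical to the slope of a
#' zero-intercept regression of `beta_out` on `beta_exp` weighted by
#' `1 / se_out^2`. By default a multiplicative random-effects model is used:
#' the standard error is inflated by `sqrt(Q / (J - 1))` when Cochran's Q
#' exceeds its degrees of freedom (floored at 1, so heterogeneity can only
#' widen the interval).
#'
#' @param h a [harmonize()]d set with at least 2 usable SNPs.
#' @param random_effects inflate the standard error under heterogeneity
#'   (default `TRUE`); `FALSE` gives the fixed-effect model.
#' @return An `mr_estimate` row (`method = "ivw"`); attributes `q_stat` and
#'   `phi` carry Cochran's Q and the inflation factor actually applied.
#' @export
mr_ivw <- function(h, random_effects = TRUE) {
  r <- ratio_estimates(h)
  j <- nrow(r)
  if (j < 2L) stop("IVW requires at least 2 SNPs; use mr_wald() for one")
  w <- 1 / r$wald_se^2
  beta <- sum(w * r$wald) / sum(w)
  q <- sum(w * (r$wald - beta)^2)
  phi <- if (random_effects) max(1, q / (j - 1)) else 1
  se <- sqrt(phi / sum(w))
  pval <- 2 * pnorm(-abs(beta / se))
  .mr_estimate("ivw", beta, se, pval, j, extra = list(q_stat = q, phi = phi))
}

#' Wald ratio estimate for a single instrument
#'
#' Used by the screening pipeline when clumping leaves one SNP; reported with
#' `method = "ivw"` and `n_snps = 1` so every exposure gets a primary answer.
#'
#' @param h a [harmonize()]d set with exactly 1 usable SNP.
#' @return An `mr_estimate` row.
#' @export
mr_wald <- function(h) {
  r <- ratio_estimates(h)
  if (nrow(r) != 1L) stop("mr_wald() expects exactly 1 SNP")
  beta <- r$wald
  se <- r$wald_se
  .mr_estimate("ivw", beta, se, 2 * pnorm(-abs(beta / se)), 1L)
}

#' MR-Egger regression
#'
#' Weighted regression of `beta_out` on `beta_exp` with a free intercept and
#' weights `1 / se_out^2`. The slope is the causal estimate under the InSiDE
#' assumption; a non-zero intercept indicates directional pleiotropy. Rows
#' are oriented to non-negative exposure effects internally (the estimator is
#' not invariant to per-SNP sign conventions). The slope and intercept
#' standard errors carry a multiplicative heterogeneity inflation
#' `sqrt(max(1, Q_egger / (J - 2)))`; p-values use a t distribution with
#' `J - 2` degrees of freedom, while the reported confidence bounds keep the
#' fixed 1.96 convention used throughout.
#'
#' @param h a [harmonize()]d set with at least 3 SNPs.
#' @return An `mr_estimate` row (`method = "egger"`) with `intercept`,
#'   `intercept_se`, `intercept_p` populated; attribute `q_stat` is the Egger
#'   residual heterogeneity statistic.
#' @export
mr_egger <- function(h) {
  stopifnot(inherits(h, "harmonized_set"))
  keep <- h$beta_exp != 0
  x <- h$beta_exp[keep]
  y <- h$beta_out[keep]
  w <- 1 / h$se_out[keep]^2
  j <- length(x)
  if (j < 3L) stop("MR-Egger requires at least 3 SNPs")
  flip <- sign(x) < 0
  x[flip] <- -x[flip]
  y[flip] <- -y[flip]

  sw <- sum(w)
  xbar <- sum(w * x) / sw
  ybar <- sum(w * y) / sw
  sxx <- sum(w * (x - xbar)^2)
  if (sxx <= 0) stop("MR-Egger undefined: no variation in exposure effects")
  slope <- sum(w * (x - xbar) * (y - ybar)) / sxx
  inter <- ybar - slope * xbar
  resid <- y - inter - slope * x
  q <- sum(w * resid^2)
  phi <- max(1, q / (j - 2))
  se_slope <- sqrt(phi / sxx)
  se_inter <- sqrt(phi * (1 / sw + xbar^2 / sxx))
  p_slope <- 2 * pt(-abs(slope / se_slope), df = j - 2)
  p_inter <- 2 * pt(-abs(inter / se_inter), df = j - 2)
  .mr_estimate("egger", slope, se_slope, p_slope, j,
               intercept = inter, intercept_se = se_inter,
               intercept_p = p_inter, extra = list(q_stat = q))
}

# Interpolated weighted median of `b` with weights `w` (need not sum to 1).
.weighted_median <- function(b, w) {
  ord <- order(b)
  b <- b[ord]
  w <- w[ord] / sum(w)
  p <- cumsum(w) - w / 2
  if (0.5 <= p[1]) return(b[1])
  if (0.5 >= p[length(p)]) return(b[length(b)])
  approx(p, b, xout = 0.5, ties = "ordered")$y
}

.boot_se <- function(wald, wald_se, boot_reps, seed, statistic) {
  with_seed(seed, {
    reps <- vapply(seq_len(boot_reps), function(i) {
      statistic(rnorm(length(wald), wald, wald_se))
    }, numeric(1))
    sd(reps)
  })
}

#' Weighted-median estimator
#'
#' The inverse-variance weighted median of the per-SNP Wald ratios: ratios
#' are ordered and the estimate interpolates between the two ratios
#' bracketing cumulative normalized weight one half. Consistent when at least
#' half of the total weight comes from valid instruments, giving it a 50%
#' breakdown point against pleiotropy. The standard error comes from a
#' parametric bootstrap: each replicate redraws every Wald ratio from a
#' normal with its own standard error and recomputes the weighted median.
#'
#' @param h a [harmonize()]d set with at least 3 SNPs.
#' @param boot_reps bootstrap replicates for the standard error
#'   (default 1000).
#' @param seed integer seed for the bootstrap (RNG state is restored).
#' @return An `mr_estimate` row (`method = "weighted_median"`).
#' @export
mr_weighted_median <- function(h, boot_reps = 1000, seed = 1) {
  r <- ratio_estimates(h)
  if (nrow(r) < 3L) stop("weighted median requires at least 3 SNPs")
  w <- 1 / r$wald_se^2
  beta <- .weighted_median(r$wald, w)
  se <- .boot_se(r$wald, r$wald_se, boot_reps, seed,
                 function(b) .weighted_median(b, w))
  pval <- 2 * pnorm(-abs(beta / se))
  .mr_estimate("weighted_median", beta, se, pval, nrow(r))
}

.mode_point <- function(wald, weights, bw, grid_points) {
  grid <- seq(min(wald) - 3 * bw, max(wald) + 3 * bw,
              length.out = grid_points)
  dens <- vapply(grid, function(g) {
    sum(weights * dnorm(g, mean = wald, sd = bw))
  }, numeric(1))
  grid[which.max(dens)]
}

.mode_bandwidth <- function(wald, bandwidth_factor) {
  s_mad <- mad(wald)  # 1.4826 * median absolute deviation
  s_sd <- sd(wald)
  scale <- if (s_mad > 0) min(s_sd, s_mad) else s_sd
  bandwidth_factor * 0.9 * scale * length(wald)^(-1 / 5)
}

#' Mode-based estimator (simple and weighted)
#'
#' The mode of the smoothed empirical density of per-SNP Wald ratios:
#' consistent when the largest group of instruments sharing the same ratio is
#' valid (zero modal pleiotropy assumption). Kernel: normal, with bandwidth
#' `bandwidth_factor * 0.9 * min(sd, mad) * J^(-1/5)` (a robust
#' modified-MAD rule); the estimate is the density argmax on a fixed
#' evaluation grid spanning the ratios plus three bandwidths. `weighted =
#' TRUE` weights each kernel contribution by inverse variance. Standard error
#' by the same parametric bootstrap as [mr_weighted_median()].
#'
#' If all ratios are identical the bandwidth degenerates to zero and the
#' common ratio is returned directly (bootstrap still supplies the se).
#'
#' @param h a [harmonize()]d set with at least 3 SNPs.
#' @param weighted inverse-variance weight the kernel contributions
#'   (`FALSE` = simple mode).
#' @param bandwidth_factor multiplier on the data-driven bandwidth
#'   (default 1).
#' @param boot_reps bootstrap replicates (default 1000).
#' @param seed integer seed for the bootstrap.
#' @param grid_points density evaluation grid size (default 512).
#' @return An `mr_estimate` row (`method = "simple_mode"` or
#'   `"weighted_mode"`).
#' @export
mr_mode <- function(h, weighted = FALSE, bandwidth_factor = 1,
                    boot_reps = 1000, seed = 1, grid_points = 512) {
  r <- ratio_estimates(h)
  if (nrow(r) < 3L) stop("mode estimator requires at least 3 SNPs")
  w <- if (weighted) 1 / r$wald_se^2 else rep(1, nrow(r))
  w <- w / sum(w)
  point <- function(b) {
    bw <- .mode_bandwidth(b, bandwidth_factor)
    if (!is.finite(bw) || bw <= 0) return(b[which.max(w)])
    .mode_point(b, w, bw, grid_points)
  }
  beta <- point(r$wald)
  se <- .boot_se(r$wald, r$wald_se, boot_reps, seed, point)
  pval <- 2 * pnorm(-abs(beta / se))
  .mr_estimate(if (weighted) "weighted_mode" else "simple_mode",
               beta, se, pval, nrow(r))
}

#' Convert a log-odds estimate to the odds-ratio scale
#'
#' `or = exp(beta)`, `or_low = exp(beta - 1.96 se)`,
#' `or_high = exp(beta + 1.96 se)`.
#'
#' @param e an `mr_estimate` row (or any data frame with `beta` and `se`).
#' @return The input with columns `or`, `or_low`, `or_high` appended.
#' @export
to_odds_ratio <- function(e) {
  e$or <- exp(e$beta)
  e$or_low <- exp(e$beta - .Z95 * e$se)
  e$or_high <- exp(e$beta + .Z95 * e$se)
  e
}

#' Run all five estimators on one harmonized set
#'
#' IVW (primary), MR-Egger, weighted median, simple mode and weighted mode,
#' stacked into one table with odds-ratio columns. A single-SNP set falls
#' back to the Wald ratio; sets too small for a given method simply omit it.
#'
#' @param h a [harmonize()]d set.
#' @param boot_reps bootstrap replicates for median/mode standard errors.
#' @param seed integer seed shared by the bootstraps.
#' @param random_effects passed to [mr_ivw()].
#' @return Data frame of `mr_estimate` rows, one per applicable method,
#'   with odds-ratio columns.
#' @export
mr_all_methods <- function(h, boot_reps = 1000, seed = 1,
                           random_effects = TRUE) {
  r <- ratio_estimates(h)
  j <- nrow(r)
  if (j == 0L) stop("no usable instruments")
  ests <- list()
  if (j == 1L) {
    ests$ivw <- mr_wald(h)
  } else {
    ests$ivw <- mr_ivw(h, random_effects = random_effects)
  }
  if (j >= 3L) {
    ests$egger <- mr_egger(h)
    ests$weighted_median <- mr_weighted_median(h, boot_reps, seed)
    ests$simple_mode <- mr_mode(h, weighted = FALSE, boot_reps = boot_reps,
                                seed = seed + 1L)
    ests$weighted_mode <- mr_mode(h, weighted = TRUE, boot_reps = boot_reps,
                                  seed = seed + 2L)
  }
  out <- do.call(rbind, lapply(ests, as.data.frame))
  rownames(out) <- NULL
  to_odds_ratio(out)
}
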