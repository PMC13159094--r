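# Instrument selection and exposure-outcome harmonization.

#' Pairwise linkage-disequilibrium information
#'
#' A symmetric matrix of pairwise r-squared values used by [clump()]. When no
#' LD information is available, clumping degrades to distance-only pruning
#' (see [clump()]).
#'
#' @param snp_ids character vector of variant identifiers (row/col order).
#' @param r2 square symmetric matrix of r-squared in \[0, 1\] with unit
#'   diagonal.
#' @return An `ld_info` object.
#' @export
ld_info <- function(snp_ids, r2) {
  r2 <- as.matrix(r2)
  n <- length(snp_ids)
  stopifnot(nrow(r2) == n, ncol(r2) == n)
  if (any(r2 < 0 | r2 > 1, na.rm = TRUE)) stop("r2 values must lie in [0, 1]")
  if (max(abs(r2 - t(r2))) > 1e-8) stop("r2 matrix must be symmetric")
  if (max(abs(diag(r2) - 1)) > 1e-8) stop("r2 diagonal must be 1")
  dimnames(r2) <- list(snp_ids, snp_ids)
  structure(list(snp_ids = as.character(snp_ids), r2 = r2),
            class = "ld_info")
}

#' Read an LD matrix from a TSV file
#'
#' Expects a square numeric matrix with a header row of SNP identifiers and
#' matching order across rows and columns.
#'
#' @param path TSV path (gzip-transparent).
#' @return An [ld_info()] object.
#' @export
read_ld_matrix <- function(path) {
  m <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                                   check.names = FALSE))
  ld_info(colnames(m), m)
}

#' Select candidate instruments by association p-value
#'
#' Keeps exactly the rows with `pval < p_threshold`, preserving input order.
#' The conventional genome-wide threshold (5e-8) typically leaves too few
#' variants for molecular traits measured in cohorts of ~10k; a relaxed
#' threshold of 1e-5 is the screening default here, with instrument strength
#' then guarded by the F-statistic filter.
#'
#' @param stats a [summary_stats()] object.
#' @param p_threshold keep rows with p strictly below this value
#'   (default 1e-5).
#' @return A `summary_stats` subset; a warning is emitted when empty.
#' @export
select_instruments <- function(stats, p_threshold = 1e-5) {
  stopifnot(inherits(stats, "summary_stats"))
  keep <- stats$pval < p_threshold
  out <- stats[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L) {
    warning("no instruments at p < ", format(p_threshold), " for trait '",
            trait_id(stats), "'")
  }
  attr(out, "trait_id") <- trait_id(stats)
  attr(out, "audit") <- audit_log(stats)
  class(out) <- c("summary_stats", "data.frame")
  out
}

#' Greedy LD clumping
#'
#' Standard greedy pruning: repeatedly take the remaining SNP with the lowest
#' p-value as an index SNP and discard all remaining SNPs on the same
#' chromosome within `window_kb` that are correlated with it. Ties in p are
#' broken by lexicographic `snp_id`, which makes the result invariant to
#' input row order.
#'
#' With `ld` supplied, a neighbour is discarded when its r-squared with the
#' index is `>= r2_max` (pairs absent from the matrix count as r2 = 0, i.e.
#' independent). With `ld = NULL` no LD is known, and the honest conservative
#' degradation is distance-only clumping: every neighbour inside the window
#' is discarded.
#'
#' @param stats a [summary_stats()] object.
#' @param ld an [ld_info()] object or `NULL`.
#' @param r2_max r-squared threshold at/above which neighbours are removed
#'   (default 0.001).
#' @param window_kb clumping distance in kilobases (default 10000).
#' @return `summary_stats` subset containing the index SNPs, sorted by
#'   p-value then snp_id.
#' @export
clump <- function(stats, ld = NULL, r2_max = 0.001, window_kb = 10000) {
  stopifnot(inherits(stats, "summary_stats"))
  if (!is.null(ld)) stopifnot(inherits(ld, "ld_info"))
  if (nrow(stats) == 0L) return(stats)
  ord <- order(stats$pval, stats$snp_id)
  x <- stats[ord, , drop = FALSE]
  window_bp <- window_kb * 1000
  n <- nrow(x)
  alive <- rep(TRUE, n)
  keep <- logical(n)
  for (i in seq_len(n)) {
    if (!alive[i]) next
    keep[i] <- TRUE
    alive[i] <- FALSE
    cand <- which(alive & x$chrom == x$chrom[i] &
                    abs(x$pos - x$pos[i]) <= window_bp)
    if (length(cand) == 0L) next
    if (is.null(ld)) {
      alive[cand] <- FALSE
    } else {
      r2 <- rep(0, length(cand))
      in_ld <- x$snp_id[i] %in% ld$snp_ids
      if (in_ld) {
        hit <- x$snp_id[cand] %in% ld$snp_ids
        r2[hit] <- ld$r2[x$snp_id[i], x$snp_id[cand][hit]]
      }
      alive[cand[r2 >= r2_max]] <- FALSE
    }
  }
  out <- x[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "trait_id") <- trait_id(stats)
  attr(out, "audit") <- audit_log(stats)
  class(out) <- c("summary_stats", "data.frame")
  out
}

#' Per-instrument F-statistic
#'
#' Instrument strength approximated per SNP as `(beta / se)^2`, the square of
#' the association z-score; instruments with F below ~10 are conventionally
#' considered weak. Note this is the ratio of the squared effect to the
#' squared standard error, i.e. scale-invariant.
#'
#' @param beta SNP-exposure effect estimate(s).
#' @param se corresponding standard error(s), all `> 0`.
#' @return Numeric vector of F-statistics.
#' @export
f_statistic <- function(beta, se) {
  if (any(!(se > 0))) stop("all standard errors must be > 0")
  (beta / se)^2
}

.complement <- c(A = "T", T = "A", C = "G", G = "C")

.is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Harmonize exposure and outcome summary statistics
#'
#' Inner join on `snp_id`, aligning the outcome effect to the exposure's
#' effect allele. Outcome rows whose alleles are the swap of the exposure's
#' (directly or after strand complement) have their effect sign flipped and
#' are marked `flipped`; rows whose alleles match neither way are dropped and
#' audited. Palindromic variants (A/T or C/G) cannot be resolved by alleles
#' alone: they are kept only when both allele frequencies are available and
#' fall outside the ambiguity window around 0.5, with a strand flip inferred
#' when the frequencies sit on opposite sides of 0.5; otherwise they are
#' dropped and audited.
#'
#' The per-SNP F-statistic is computed from the exposure association. When
#' `orient_exposure` is `TRUE` (default) each row is finally re-oriented so
#' `beta_exp >= 0` (flipping `beta_out` in tandem); MR-Egger requires a
#' consistent orientation, and ratio-based estimators are unaffected.
#'
#' @param exp,out `summary_stats` for the exposure and the outcome.
#' @param palindromic_eaf_window palindromic SNPs are dropped when either
#'   trait's allele frequency lies within this distance of 0.5
#'   (default 0.08, i.e. drop inside \[0.42, 0.58\]).
#' @param orient_exposure re-orient rows so the exposure effect is
#'   non-negative (default `TRUE`).
#' @return A `harmonized_set`: data frame with columns `snp_id`, `beta_exp`,
#'   `se_exp`, `beta_out`, `se_out`, `f_stat`, `flipped`, plus attributes
#'   `exposure_id`, `outcome_id`, `audit`.
#' @export
harmonize <- function(exp, out, palindromic_eaf_window = 0.08,
                      orient_exposure = TRUE) {
  stopifnot(inherits(exp, "summary_stats"), inherits(out, "summary_stats"))
  idx <- match(exp$snp_id, out$snp_id)
  shared <- !is.na(idx)
  if (!any(shared)) stop("no shared SNPs between '", trait_id(exp),
                         "' and '", trait_id(out), "'")
  e <- exp[shared, , drop = FALSE]
  o <- out[idx[shared], , drop = FALSE]

  n <- nrow(e)
  beta_out <- o$beta
  eaf_out <- o$eaf
  flipped <- rep(FALSE, n)
  drop <- rep(FALSE, n)
  reason <- rep(NA_character_, n)

  pal <- .is_palindromic(e$effect_allele, e$other_allele)

  # Allele alignment for non-palindromic variants (strand-aware).
  same <- o$effect_allele == e$effect_allele & o$other_allele == e$other_allele
  swap <- o$effect_allele == e$other_allele & o$other_allele == e$effect_allele
  comp_same <- o$effect_allele == .complement[e$effect_allele] &
    o$other_allele == .complement[e$other_allele]
  comp_swap <- o$effect_allele == .complement[e$other_allele] &
    o$other_allele == .complement[e$effect_allele]

  do_flip <- !pal & (swap | comp_swap)
  beta_out[do_flip] <- -beta_out[do_flip]
  eaf_out[do_flip] <- 1 - eaf_out[do_flip]
  flipped[do_flip] <- TRUE
  mism <- !pal & !(same | swap | comp_same | comp_swap)
  drop[mism] <- TRUE
  reason[mism] <- "allele_mismatch"

  # Palindromic variants: allele labels are strand-ambiguous; align the
  # listed order first, then use allele frequency to detect a strand flip.
  if (any(pal)) {
    pal_same <- pal & same
    pal_swap <- pal & swap
    beta_out[pal_swap] <- -beta_out[pal_swap]
    eaf_out[pal_swap] <- 1 - eaf_out[pal_swap]
    flipped[pal_swap] <- TRUE
    pal_mism <- pal & !(pal_same | pal_swap)
    drop[pal_mism] <- TRUE
    reason[pal_mism] <- "allele_mismatch"

    w <- palindromic_eaf_window
    informative <- !is.na(e$eaf) & !is.na(eaf_out) &
      abs(e$eaf - 0.5) > w & abs(eaf_out - 0.5) > w
    amb <- pal & !pal_mism & !informative
    drop[amb] <- TRUE
    reason[amb] <- "palindromic_dropped"
    strand_flip <- pal & !pal_mism & informative &
      ((e$eaf - 0.5) * (eaf_out - 0.5) < 0)
    beta_out[strand_flip] <- -beta_out[strand_flip]
    flipped[strand_flip] <- !flipped[strand_flip]
  }

  h <- data.frame(snp_id = e$snp_id,
                  beta_exp = e$beta, se_exp = e$se,
                  beta_out = beta_out, se_out = o$se,
                  f_stat = f_statistic(e$beta, e$se),
                  flipped = flipped,
                  stringsAsFactors = FALSE)
  h <- h[!drop, , drop = FALSE]
  if (orient_exposure) {
    neg <- h$beta_exp < 0
    h$beta_exp[neg] <- -h$beta_exp[neg]
    h$beta_out[neg] <- -h$beta_out[neg]
  }
  rownames(h) <- NULL
  audit <- c(not_in_outcome = sum(!shared),
             allele_mismatch = sum(reason %in% "allele_mismatch"),
             palindromic_dropped = sum(reason %in% "palindromic_dropped"))
  structure(h,
            exposure_id = trait_id(exp),
            outcome_id = trait_id(out),
            audit = audit,
            class = c("harmonized_set", "data.frame"))
}

#' Filter a harmonized set on instrument strength
#'
#' @param h a [harmonize()]d set.
#' @param f_min minimum per-SNP F-statistic (default 10).
#' @return The subset with `f_stat >= f_min`; drop count appended to the
#'   audit log.
#' @export
filter_weak_instruments <- function(h, f_min = 10) {
  stopifnot(inherits(h, "harmonized_set"))
  weak <- h$f_stat < f_min
  out <- h[!weak, , drop = FALSE]
  rownames(out) <- NULL
  attributes(out)[c("exposure_id", "outcome_id")] <-
    attributes(h)[c("exposure_id", "outcome_id")]
  attr(out, "audit") <- c(audit_log(h), weak_instrument = sum(weak))
  class(out) <- class(h)
  out
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat("Harmonized instrument set: ", attr(x, "exposure_id"), " -> ",
      attr(x, "outcome_id"), ", ", nrow(x), " SNPs\n", sep = "")
  NextMethod()
}
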