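test_that("select_instruments filters strictly below threshold", {
  ss <- summary_stats(make_sumstats_df(3, pval = c(1e-6, 2e-5, 1e-8)))
  expect_identical(select_instruments(ss, 1e-5)$snp_id, c("rs001", "rs003"))
  expect_identical(nrow(select_instruments(ss, 1.0)), 3L)
  expect_warning(sel <- select_instruments(ss, 1e-12), "no instruments")
  expect_identical(nrow(sel), 0L)
})

test_that("selection count on a simulated strong trait", {
  # 30 instruments jointly explaining 30% of variance at n = 20000: nearly
  # all should clear p < 1e-5
  sim <- simulate_triple(sim_config(n_snps = 30, n_med_snps = 0,
                                    n_exp = 20000, h2_exp = 0.3, seed = 5))
  sel <- select_instruments(sim$exposure, 1e-5)
  expect_gte(nrow(sel), 25L)
})

test_that("greedy clumping follows the p-value order and LD/distance rules", {
  ids <- c("a", "b", "c")
  ss <- summary_stats(make_sumstats_df(3, snp_id = ids,
                                       pval = c(1e-8, 1e-7, 1e-6),
                                       chrom = rep("1", 3),
                                       pos = c(1e6, 2e6, 3e6)))
  r2 <- matrix(0.9, 3, 3); diag(r2) <- 1
  ld <- ld_info(ids, r2)
  expect_identical(clump(ss, ld)$snp_id, "a")

  # different chromosomes: always retained
  ss2 <- summary_stats(make_sumstats_df(2, chrom = c("1", "2"),
                                        pos = c(1e6, 1e6)))
  expect_identical(nrow(clump(ss2, ld = NULL)), 2L)

  # no LD info degrades to distance-only pruning
  ss3 <- summary_stats(make_sumstats_df(3, pval = c(1e-8, 1e-7, 1e-6),
                                        chrom = rep("1", 3),
                                        pos = c(1e6, 2e6, 3e7)))
  expect_identical(sort(clump(ss3, ld = NULL)$snp_id), c("rs001", "rs003"))
})

test_that("clump satisfies the brute-force greedy invariants", {
  # random 50-SNP instances: no retained pair conflicts, every removed SNP
  # conflicts with a better-ranked retained SNP
  for (seed in 1:5) {
    set.seed(seed)
    n <- 50
    df <- make_sumstats_df(n, pval = runif(n, 1e-10, 1e-2),
                           chrom = as.character(sample(1:3, n, TRUE)),
                           pos = sample.int(3e7, n))
    ss <- summary_stats(df)
    r2 <- matrix(runif(n * n), n)
    r2 <- (r2 + t(r2)) / 2
    diag(r2) <- 1
    ld <- ld_info(df$snp_id, r2)
    r2_max <- 0.5
    window_kb <- 5000
    kept <- clump(ss, ld, r2_max = r2_max, window_kb = window_kb)$snp_id

    conflicts <- function(i, j) {
      ss$chrom[i] == ss$chrom[j] &&
        abs(ss$pos[i] - ss$pos[j]) <= window_kb * 1000 &&
        r2[i, j] >= r2_max
    }
    idx_kept <- match(kept, ss$snp_id)
    for (i in idx_kept) for (j in idx_kept) {
      if (i != j) expect_false(conflicts(i, j))
    }
    rank_key <- order(ss$pval, ss$snp_id)
    for (i in setdiff(seq_len(n), idx_kept)) {
      better <- idx_kept[which(match(idx_kept, rank_key) <
                                 match(i, rank_key))]
      expect_true(any(vapply(better, conflicts, logical(1), i = i)))
    }
  }
})

test_that("clump result is invariant to input row order", {
  set.seed(99)
  n <- 40
  df <- make_sumstats_df(n, pval = sample(rep(c(1e-8, 1e-6), n / 2)),
                         chrom = as.character(sample(1:2, n, TRUE)),
                         pos = sample.int(2e7, n))
  ss <- summary_stats(df)
  shuffled <- summary_stats(df[sample.int(n), ])
  expect_identical(clump(ss, ld = NULL)$snp_id,
                   clump(shuffled, ld = NULL)$snp_id)
})

test_that("f_statistic arithmetic, boundary and scale invariance", {
  expect_equal(f_statistic(0.1, 0.01), 100)
  expect_equal(f_statistic(0, 0.3), 0)
  f <- f_statistic(0.0316, 0.01)
  expect_lt(f, 10)
  expect_equal(f, 9.9856, tolerance = 1e-6)
  expect_error(f_statistic(0.1, 0), "> 0")
  # scale invariance
  b <- rnorm(20); s <- runif(20, 0.01, 0.1)
  expect_equal(f_statistic(3.7 * b, 3.7 * s), f_statistic(b, s))
})

test_that("harmonize aligns alleles, flips swaps, and resolves palindromes", {
  e <- make_sumstats_df(1, beta = 0.1)
  e$effect_allele <- "A"; e$other_allele <- "G"
  o <- e; o$effect_allele <- "G"; o$other_allele <- "A"; o$beta <- 0.2
  h <- harmonize(summary_stats(e, "e"), summary_stats(o, "o"))
  expect_equal(h$beta_out, -0.2)
  expect_true(h$flipped)

  # strand-complement swap also flips: exposure A/G vs outcome C/T
  o2 <- e; o2$effect_allele <- "C"; o2$other_allele <- "T"; o2$beta <- 0.2
  h2 <- harmonize(summary_stats(e, "e"), summary_stats(o2, "o"))
  expect_equal(h2$beta_out, -0.2)

  # palindromic, informative eaf on the same side: retained unflipped
  pal <- make_sumstats_df(1, beta = 0.1, eaf = 0.10)
  pal$effect_allele <- "A"; pal$other_allele <- "T"
  palo <- pal; palo$beta <- 0.3; palo$eaf <- 0.11
  hp <- harmonize(summary_stats(pal, "e"), summary_stats(palo, "o"),
                  orient_exposure = FALSE)
  expect_identical(nrow(hp), 1L)
  expect_equal(hp$beta_out, 0.3)
  expect_false(hp$flipped)

  # opposite sides of 0.5: strand flip inferred
  palo2 <- palo; palo2$eaf <- 0.9
  hp2 <- harmonize(summary_stats(pal, "e"), summary_stats(palo2, "o"),
                   orient_exposure = FALSE)
  expect_equal(hp2$beta_out, -0.3)

  # ambiguous eaf or missing eaf: dropped and audited -> empty join errors
  pal49 <- pal; pal49$eaf <- 0.49
  expect_error(harmonize(summary_stats(pal49, "e"), summary_stats(palo, "o")),
               NA)  # other row absent; see multi-row case below
  two <- rbind(pal, make_sumstats_df(1, snp_id = "rs999", beta = 0.2))
  two$eaf[1] <- 0.49
  twoo <- two; twoo$beta <- c(0.3, 0.25); twoo$eaf <- c(NA, 0.3)
  h3 <- harmonize(summary_stats(two, "e"), summary_stats(twoo, "o"))
  expect_identical(nrow(h3), 1L)
  expect_identical(h3$snp_id, "rs999")
  expect_identical(unname(audit_log(h3)["palindromic_dropped"]), 1L)

  # mismatched alleles (A/G vs A/C: neither swap nor strand complement)
  mm <- make_sumstats_df(2)
  mmo <- mm; mmo$effect_allele[1] <- "A"; mmo$other_allele[1] <- "C"
  mm$effect_allele[1] <- "A"; mm$other_allele[1] <- "G"
  h4 <- harmonize(summary_stats(mm, "e"), summary_stats(mmo, "o"))
  expect_identical(unname(audit_log(h4)["allele_mismatch"]), 1L)
})

test_that("harmonize(x, x) is the identity and orientation works", {
  sim <- simulate_triple(sim_config(n_snps = 40, seed = 3))
  x <- sim$exposure
  h <- harmonize(x, x, orient_exposure = FALSE)
  expect_equal(h$beta_out, h$beta_exp)
  expect_false(any(h$flipped))

  ho <- harmonize(x, x, orient_exposure = TRUE)
  expect_true(all(ho$beta_exp >= 0))
  expect_equal(ho$beta_out, ho$beta_exp)

  expect_error(harmonize(x, summary_stats(make_sumstats_df(2), "z")),
               "no shared SNPs")
})

test_that("weak-instrument filter enforces the F cutoff", {
  h <- make_h(beta_exp = c(0.5, 0.02), se_exp = c(0.01, 0.01),
              beta_out = c(0.05, 0.01), se_out = c(0.01, 0.01))
  hf <- filter_weak_instruments(h, f_min = 10)
  expect_identical(nrow(hf), 1L)
  expect_true(all(hf$f_stat >= 10))
  expect_identical(unname(audit_log(hf)["weak_instrument"]), 1L)
})
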