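test_that("ratio estimates match hand arithmetic and drop zero exposures", {
  h <- make_h(beta_exp = c(0.5, 0.2, 0.4), se_exp = rep(0.01, 3),
              beta_out = c(0.05, 0, -0.02), se_out = c(0.01, 0.02, 0.008))
  r <- ratio_estimates(h)
  expect_equal(r$wald, c(0.1, 0, -0.05))
  expect_equal(r$wald_se, c(0.02, 0.1, 0.02))

  hz <- make_h(beta_exp = c(0.5, 0), se_exp = rep(0.01, 2),
               beta_out = c(0.05, 0.01), se_out = rep(0.01, 2))
  rz <- ratio_estimates(hz)
  expect_identical(nrow(rz), 1L)
  expect_identical(unname(attr(rz, "audit")["zero_exposure_beta"]), 1L)
})

test_that("IVW equals zero-intercept weighted least squares (oracle)", {
  # degenerate agreement
  h0 <- make_h_from_ratios(c(0.1, 0.1), c(0.02, 0.05))
  e0 <- mr_ivw(h0)
  expect_equal(e0$beta, 0.1)
  expect_equal(attr(e0, "q_stat"), 0)

  set.seed(202)
  for (i in 1:20) {
    j <- sample(3:30, 1)
    h <- make_h(beta_exp = runif(j, 0.05, 0.5), se_exp = runif(j, 0.005, 0.02),
                beta_out = rnorm(j, 0.02, 0.02), se_out = runif(j, 0.005, 0.05))
    fit <- lm(beta_out ~ 0 + beta_exp, data = h, weights = 1 / h$se_out^2)
    expect_equal(mr_ivw(h)$beta, unname(coef(fit)), tolerance = 1e-10)
  }
  expect_error(mr_ivw(make_h_from_ratios(0.1, 0.02)), "at least 2")
})

test_that("fixed- vs random-effects IVW differ only in the se inflation", {
  set.seed(7)
  h <- make_h_from_ratios(rnorm(10, 0.1, 0.1), rep(0.02, 10))
  fe <- mr_ivw(h, random_effects = FALSE)
  re <- mr_ivw(h, random_effects = TRUE)
  q <- cochran_q(h)
  expect_equal(fe$beta, re$beta)
  expect_equal(re$se / fe$se, sqrt(max(1, q$q_stat / q$q_df)))
})

test_that("MR-Egger recovers an exact affine relation and matches lm", {
  # exact line: intercept and slope to 1e-10
  x <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  a <- 0.03; b <- 0.2
  h <- make_h(beta_exp = x, se_exp = rep(0.01, 5),
              beta_out = a + b * x, se_out = runif(5, 0.01, 0.03))
  e <- mr_egger(h)
  expect_equal(e$beta, b, tolerance = 1e-10)
  expect_equal(e$intercept, a, tolerance = 1e-10)

  # closed-form oracle on a noisy 5-SNP instance
  set.seed(11)
  h2 <- make_h(beta_exp = x, se_exp = rep(0.01, 5),
               beta_out = a + b * x + rnorm(5, 0, 0.02),
               se_out = rep(0.02, 5))
  fit <- lm(beta_out ~ beta_exp, data = h2, weights = 1 / h2$se_out^2)
  e2 <- mr_egger(h2)
  expect_equal(e2$beta, unname(coef(fit)[2]), tolerance = 1e-10)
  expect_equal(e2$intercept, unname(coef(fit)[1]), tolerance = 1e-10)
  # lm se is scaled by sqrt(sigma2); ours floors the scaling at 1
  s2 <- summary(fit)$sigma^2
  expect_equal(e2$se, summary(fit)$coefficients[2, 2] *
                 sqrt(max(1, s2) / s2), tolerance = 1e-8)
  expect_error(mr_egger(make_h_from_ratios(c(0.1, 0.2), c(0.02, 0.02))),
               "at least 3")
})

test_that("MR-Egger intercept recovers injected directional pleiotropy", {
  # mean pleiotropic effect 0.02 on every instrument; slope unbiased only
  # under InSiDE, intercept should centre on 0.02
  reps <- 100
  ints <- vapply(seq_len(reps), function(i) {
    set.seed(3000 + i)
    j <- 40
    bx <- runif(j, 0.05, 0.3)
    alpha <- rnorm(j, 0.02, 0.004)
    se_out <- rep(0.01, j)
    h <- make_h(beta_exp = bx, se_exp = rep(0.005, j),
                beta_out = 0.1 * bx + alpha + rnorm(j, 0, se_out),
                se_out = se_out)
    mr_egger(h)$intercept
  }, numeric(1))
  expect_lt(abs(mean(ints) - 0.02), 0.005)
})

test_that("weighted median interpolates cumulative weight 0.5", {
  h <- make_h_from_ratios(c(0.1, 0.2, 0.9), rep(0.02, 3))
  wm <- mr_weighted_median(h, boot_reps = 200, seed = 1)
  expect_equal(wm$beta, 0.2)

  # equal weights equal the plain interpolated median (property)
  set.seed(44)
  for (i in 1:10) {
    j <- sample(4:15, 1)
    ratios <- rnorm(j, 0.2, 0.3)
    h2 <- make_h_from_ratios(ratios, rep(0.05, j))
    wm2 <- mr_weighted_median(h2, boot_reps = 10, seed = 1)
    ord <- sort(ratios)
    p <- (seq_len(j) - 0.5) / j
    expect_equal(wm2$beta, approx(p, ord, xout = 0.5)$y, tolerance = 1e-12)
  }
  expect_error(mr_weighted_median(make_h_from_ratios(c(0.1, 0.2),
                                                     c(0.02, 0.02))),
               "at least 3")
})

test_that("weighted median resists 50% invalid instruments (breakdown)", {
  reps <- 60
  res <- vapply(seq_len(reps), function(i) {
    sim <- simulate_triple(sim_config(n_snps = 50, n_med_snps = 0,
                                      n_exp = 20000, n_out = 80000,
                                      binary_outcome_prevalence = 0.5,
                                      theta_direct = 0.1,
                                      prop_invalid = 0.5, pleio_mean = 0.03,
                                      pleio_sd = 0.1, seed = 6000 + i))
    h <- instrument_pair(sim$exposure, sim$outcome)
    c(ivw = mr_ivw(h)$beta,
      wm = mr_weighted_median(h, boot_reps = 10, seed = i)$beta)
  }, numeric(2))
  bias_ivw <- abs(mean(res["ivw", ]) - 0.1)
  bias_wm <- abs(mean(res["wm", ]) - 0.1)
  expect_gt(bias_ivw, 0.05)
  expect_lt(bias_wm, 0.03)
})

test_that("weighted median bootstrap se is stable in boot_reps", {
  set.seed(77)
  h <- make_h_from_ratios(rnorm(30, 0.1, 0.05), runif(30, 0.02, 0.06))
  se1 <- mr_weighted_median(h, boot_reps = 1000, seed = 5)$se
  se2 <- mr_weighted_median(h, boot_reps = 2000, seed = 6)$se
  expect_lt(abs(se1 - se2) / se1, 0.05)
})

test_that("mode estimators: degenerate case, grid oracle, plurality rule", {
  h0 <- make_h_from_ratios(rep(0.25, 4), rep(0.02, 4))
  m0 <- mr_mode(h0, boot_reps = 50, seed = 1)
  expect_equal(m0$beta, 0.25)

  # argmax agrees with dense brute-force grid search on a 10-SNP instance
  set.seed(10)
  ratios <- rnorm(10, 0.2, 0.1)
  ses <- runif(10, 0.02, 0.08)
  h <- make_h_from_ratios(ratios, ses)
  for (weighted in c(FALSE, TRUE)) {
    fine <- mr_mode(h, weighted = weighted, boot_reps = 10, seed = 1,
                    grid_points = 20001)
    w <- if (weighted) 1 / (ses / 1)^2 else rep(1, 10)
    w <- w / sum(w)
    bw <- 0.9 * min(sd(ratios), mad(ratios)) * 10^(-1 / 5)
    grid <- seq(min(ratios) - 3 * bw, max(ratios) + 3 * bw, by = 1e-4)
    dens <- colSums(w * outer(ratios, grid, function(r, g)
      dnorm(g, r, bw)))
    expect_lt(abs(fine$beta - grid[which.max(dens)]), 2e-4)
  }

  # 60/40 mixture: mode tracks the plurality component
  set.seed(21)
  hmix <- make_h_from_ratios(c(rnorm(18, 0.1, 0.01), rnorm(12, 0.5, 0.01)),
                             rep(0.03, 30))
  m <- mr_mode(hmix, boot_reps = 50, seed = 2)
  expect_lt(abs(m$beta - 0.1), 0.05)
  expect_error(mr_mode(make_h_from_ratios(c(0.1, 0.2), c(0.02, 0.02))),
               "at least 3")
})

test_that("all five estimators are sign-flip equivariant", {
  set.seed(33)
  j <- 20
  h <- make_h(beta_exp = runif(j, 0.05, 0.4), se_exp = rep(0.01, j),
              beta_out = rnorm(j, 0.05, 0.03), se_out = runif(j, 0.01, 0.04))
  hflip <- h
  hflip$beta_exp <- -hflip$beta_exp
  hflip$beta_out <- -hflip$beta_out
  t1 <- mr_all_methods(h, boot_reps = 200, seed = 9)
  t2 <- mr_all_methods(hflip, boot_reps = 200, seed = 9)
  expect_equal(t1$beta, t2$beta, tolerance = 1e-10)
  expect_equal(t1$se, t2$se, tolerance = 1e-10)
})

test_that("no-pleiotropy strong-instrument consistency across estimators", {
  # n_exp 50k keeps I2_GX high enough that Egger regression-dilution stays
  # inside the bias bound; at pQTL-panel strength (n ~ 15-20k, mean F ~ 60)
  # Egger attenuates by ~ (1 - I2_GX), a documented limitation
  reps <- 300
  res <- vapply(seq_len(reps), function(i) {
    sim <- simulate_triple(sim_config(n_snps = 100, n_med_snps = 0,
                                      n_exp = 50000, n_out = 20000,
                                      binary_outcome_prevalence = 0.5,
                                      theta_direct = 0.1, seed = 7000 + i))
    h <- instrument_pair(sim$exposure, sim$outcome)
    tab <- mr_all_methods(h, boot_reps = 10, seed = i)
    setNames(tab$beta, tab$method)
  }, setNames(numeric(5), c("ivw", "egger", "weighted_median",
                            "simple_mode", "weighted_mode")))
  bias <- abs(rowMeans(res) - 0.1)
  expect_true(all(bias < 0.1 * 0.1))  # < 10% of the effect
})

test_that("odds-ratio conversion reproduces the published identities", {
  e <- data.frame(beta = c(-0.0704, 0.1020, 0.1162, 0),
                  se = rep(0.001, 4))
  o <- to_odds_ratio(e)
  expect_equal(round(o$or, 3), c(0.932, 1.107, 1.123, 1))
  expect_equal(round(exp(-0.1247), 3), 0.883)
})

test_that("single-SNP Wald fallback reports method ivw with n_snps 1", {
  h <- make_h(beta_exp = 0.5, se_exp = 0.01, beta_out = 0.05, se_out = 0.01)
  w <- mr_wald(h)
  expect_identical(w$method, "ivw")
  expect_identical(w$n_snps, 1L)
  expect_equal(w$beta, 0.1)
  tab <- mr_all_methods(h)
  expect_identical(nrow(tab), 1L)
})
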