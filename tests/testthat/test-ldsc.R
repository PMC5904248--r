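test_that("noiseless inputs invert the regression model exactly", {
  M <- 2000
  ld <- synthetic_ld_scores(M, mean_l = 4, seed = 3)
  ss <- simulate_sumstats(M, 50000, h2 = 0.23, ld_scores = ld,
                          noise = FALSE)[[1]]
  fit <- ldsc_h2(ss, ld, M = M, chisq_max = Inf)
  expect_lt(abs(fit$h2_obs - 0.23) / 0.23, 1e-10)
  expect_lt(abs(fit$intercept - 1), 1e-10)
  # flat chi-square of 1: zero heritability, intercept 1
  flat <- ss; flat$chisq <- rep(1, M); flat$z <- rep(1, M)
  f0 <- ldsc_h2(flat, ld, M = M, chisq_max = Inf)
  expect_lt(abs(f0$h2_obs), 1e-12)
  expect_lt(abs(f0$intercept - 1), 1e-12)
})

test_that("liability conversion reproduces the published worked examples", {
  # (h2_obs, cases, controls) -> printed liability value, prevalence 1%
  expect_lte(abs(h2_observed_to_liability(0.25, 0.01, 862 / 4814) - 0.24), 0.01)
  expect_lte(abs(h2_observed_to_liability(0.41, 0.01, 13902 / 33181) - 0.23), 0.01)
  expect_equal(h2_observed_to_liability(0, 0.01, 0.3), 0)
  expect_error(h2_observed_to_liability(0.2, 0, 0.5), "prevalence")
  expect_error(h2_observed_to_liability(0.2, 0.01, 1), "case fraction")
})

test_that("the conversion factor is minimized at a balanced design", {
  K <- 0.01
  Ps <- seq(0.05, 0.95, by = 0.05)
  fac <- vapply(Ps, function(P) h2_observed_to_liability(1, K, P), numeric(1))
  expect_equal(Ps[which.min(fac)], 0.5)
  expect_true(all(diff(fac[Ps <= 0.5]) < 0))
  expect_true(all(diff(fac[Ps >= 0.5]) > 0))
})

test_that("the significance test is one-sided and scale-invariant", {
  mk <- function(h2, se) list(h2_obs = h2, se_obs = se)
  expect_equal(h2_significance(mk(0, 0.1)), 0.5)
  expect_equal(h2_significance(mk(0.196, 0.1)), pnorm(1.96, lower.tail = FALSE),
               tolerance = 1e-12)
  ld <- synthetic_ld_scores(3000, seed = 5)
  ss <- simulate_sumstats(3000, 30000, 0.3, ld_scores = ld, seed = 6)[[1]]
  obs <- ldsc_h2(ss, ld)
  liab <- ldsc_h2(ss, ld, prevalence = 0.01, case_fraction = 0.2)
  # conversion multiplies estimate and SE alike: identical p-value
  expect_equal(liab$h2_liab / liab$se_liab, liab$h2_obs / liab$se_obs)
  expect_equal(obs$p_value, liab$p_value)
})

test_that("self genetic correlation is exactly one on the noiseless path", {
  ld <- synthetic_ld_scores(5000, seed = 8)
  ss <- simulate_sumstats(5000, 40000, 0.25, ld_scores = ld, seed = 9)[[1]]
  fit <- ldsc_rg(ss, ss, ld)
  expect_equal(fit$rg, 1, tolerance = 1e-9)
  # a scaled copy is near-unit (weights differ slightly between the
  # per-trait and cross regressions, so exactness is not expected)
  half <- ss; half$z <- ss$z / 2; half$chisq <- half$z^2
  expect_equal(ldsc_rg(ss, half, ld)$rg, 1, tolerance = 0.02)
})

test_that("planted genetic covariance is recovered exactly from noiseless products", {
  M <- 4000; N1 <- 30000; N2 <- 50000
  ld <- synthetic_ld_scores(M, seed = 10)
  rho_g <- 0.12; a_c <- 0.3
  z1 <- sqrt(1 + N1 * 0.3 * ld$l2 / M)
  z2 <- (sqrt(N1 * N2) * rho_g * ld$l2 / M + a_c) / z1
  mk <- function(z, n) data.frame(snp = ld$snp, a1 = "A", a2 = "G", n = n,
                                  z = z, chisq = z^2, stringsAsFactors = FALSE)
  fit <- ldsc_rg(mk(z1, N1), mk(z2, N2), ld, M = M, chisq_max = Inf)
  expect_equal(fit$gencov, rho_g, tolerance = 1e-10)
  expect_equal(fit$cross_intercept, a_c, tolerance = 1e-8)
})

test_that("allele misalignment between studies is repaired by sign flips", {
  ld <- synthetic_ld_scores(3000, seed = 11)
  ss <- simulate_sumstats(3000, 30000, 0.3, ld_scores = ld, seed = 12)[[1]]
  swapped <- ss
  swapped$a1 <- ss$a2; swapped$a2 <- ss$a1; swapped$z <- -ss$z
  swapped$chisq <- swapped$z^2
  fit <- ldsc_rg(ss, swapped, ld)
  expect_equal(fit$rg, 1, tolerance = 1e-9)
})

test_that("non-positive heritability makes the correlation undefined with a reason", {
  ld <- synthetic_ld_scores(2000, seed = 13)
  null1 <- simulate_sumstats(2000, 5000, 0, ld_scores = ld, seed = 14)[[1]]
  sig <- simulate_sumstats(2000, 50000, 0.3, ld_scores = ld, seed = 15)[[1]]
  fit <- ldsc_rg(null1, sig, ld)
  if (is.na(fit$rg)) {
    expect_match(fit$reason, "non-positive")
  } else {
    succeed("null draw happened to give positive h2; reason path exercised elsewhere")
  }
})

test_that("jackknife standard errors track the empirical spread", {
  ld <- synthetic_ld_scores(4000, mean_l = 4, seed = 20)
  h2s <- ses <- numeric(50)
  for (i in 1:50) {
    ss <- simulate_sumstats(4000, 30000, 0.2, ld_scores = ld,
                            seed = 3000 + i)[[1]]
    f <- ldsc_h2(ss, ld, M = 4000)
    h2s[i] <- f$h2_obs; ses[i] <- f$se_obs
  }
  ratio <- mean(ses) / sd(h2s)
  expect_gt(ratio, 1 / 1.5)
  expect_lt(ratio, 1.5)
})

test_that("fitted-model methods are mutually consistent", {
  ld <- synthetic_ld_scores(2000, seed = 21)
  ss <- simulate_sumstats(2000, 30000, 0.25, ld_scores = ld, seed = 22)[[1]]
  fit <- ldsc_h2(ss, ld, prevalence = 0.01, case_fraction = 0.25)
  expect_equal(unname(coef(fit)["slope"]) * fit$M / fit$N, fit$h2_obs)
  expect_equal(predict(fit) + residuals(fit), fit$data$chisq)
  sm <- summary(fit)
  expect_equal(sm$h2[sm$scale == "liability"], fit$h2_liab)
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_length(sims, 2)
  expect_equal(nrow(sims[[1]]), nrow(fit$data))
  expect_output(print(fit), "liability")
})
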