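test_that("configuration invariants are enforced", {
  expect_error(geno_config(h2_liability = 1.2), "h2_liability")
  expect_error(geno_config(rg_true = 1.5), "rg_true")
  expect_error(geno_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(geno_config(within_block_r = 1), "within_block_r")
})

test_that("population-mode ascertainment respects the liability threshold", {
  cfg <- geno_config(n_snps = 150, n_cases = 40, n_controls = 400,
                     h2_liability = 0.3, prevalence = 0.01, seed = 3)
  pan <- simulate_panel(cfg, mode = "population")
  thr <- qnorm(0.99)
  st <- pan$samples$status
  expect_true(all(pan$truth$liability[st == 1] > thr))
  expect_true(all(pan$truth$liability[st == 0] <= thr))
  expect_true(all(pan$truth$true_case[st == 1]))
  # infeasible ascertainment is a simulation error
  expect_error(simulate_panel(geno_config(n_snps = 50, n_cases = 500,
                                          n_controls = 10, prevalence = 0.001,
                                          seed = 1),
                              mode = "population", max_population = 5000),
               "population mode")
})

test_that("genotype frequencies follow Hardy-Weinberg proportions", {
  cfg <- geno_config(n_snps = 40, n_cases = 0, n_controls = 10000,
                     h2_liability = 0, within_block_r = 0.4,
                     ld_block_size = 8, seed = 19)
  pan <- simulate_panel(cfg, mode = "population")
  ps <- vapply(seq_len(40), function(j) {
    g <- pan$dosages[, j]
    p <- mean(g) / 2
    expd <- 10000 * c((1 - p)^2, 2 * p * (1 - p), p^2)
    obs <- c(sum(g == 0), sum(g == 1), sum(g == 2))
    suppressWarnings(chisq.test(obs, p = expd / sum(expd))$p.value)
  }, numeric(1))
  expect_true(all(ps > 0.001 / 40))  # Bonferroni over SNPs at alpha 0.001
})

test_that("misclassified case slots carry non-case genotypes", {
  cfg <- geno_config(n_snps = 100, n_cases = 200, n_controls = 100,
                     misclassification_rate = 0.3, seed = 8)
  pan <- simulate_panel(cfg)
  st <- pan$samples$status
  expect_equal(sum(st == 1), 200)
  expect_equal(sum(pan$truth$true_case[st == 1]), 140)  # 30% swapped
  expect_false(any(pan$truth$true_case[st == 0]))
})

test_that("simulation is deterministic and architecture is seed-shared", {
  cfg <- geno_config(n_snps = 60, n_cases = 30, n_controls = 30, seed = 77)
  expect_identical(simulate_panel(cfg), simulate_panel(cfg))
  p1 <- simulate_panel(cfg, trait = 1L)
  p2 <- simulate_panel(cfg, trait = 2L)
  expect_identical(p1$truth$beta, p2$truth$beta)  # shared effects
  expect_false(identical(p1$dosages, p2$dosages)) # independent samples
})

test_that("LD scores: independence limit, duplicated SNPs, brute-force oracle", {
  # mutually independent SNPs at large n: l_j near 1
  cfg <- geno_config(n_snps = 120, n_cases = 0, n_controls = 3000,
                     h2_liability = 0, within_block_r = 0, ld_block_size = 1,
                     seed = 4)
  pan <- simulate_panel(cfg, mode = "population")
  ld <- compute_ld_scores(pan, window_snps = 120)
  expect_lt(max(abs(ld$l2 - 1)), 0.05)
  # two perfectly duplicated SNPs have l near 2
  dup <- pan
  dup$dosages[, 2] <- dup$dosages[, 1]
  ld2 <- compute_ld_scores(dup, window_snps = 120)
  expect_lt(abs(ld2$l2[1] - 2), 0.06)
  expect_lt(abs(ld2$l2[2] - 2), 0.06)
  # windowed computation equals the full pairwise brute force when the
  # window covers the LD blocks
  cfg3 <- geno_config(n_snps = 90, n_cases = 0, n_controls = 2000,
                      h2_liability = 0, within_block_r = 0.6,
                      ld_block_size = 10, seed = 6)
  p3 <- simulate_panel(cfg3, mode = "population")
  X <- p3$dosages; storage.mode(X) <- "double"
  r2 <- cor(X)^2
  radj <- r2 - (1 - r2) / (nrow(X) - 2)
  oracle <- unname(rowSums(radj))
  windowed <- compute_ld_scores(p3, window_snps = 90)$l2
  expect_equal(windowed, oracle, tolerance = 1e-12)
  near <- compute_ld_scores(p3, window_snps = 20)$l2
  expect_lt(max(abs(near - oracle)), 0.05)
})

test_that("monomorphic SNPs contribute only their self term with a warning", {
  G <- cbind(rep(1L, 50), rbinom(50, 2, 0.4), rbinom(50, 2, 0.4))
  pan <- panel_from_matrix(G)
  expect_warning(ld <- compute_ld_scores(pan, window_snps = 3), "monomorphic")
  expect_equal(ld$l2[1], 1)
})

test_that("summary-statistic simulator matches its closed forms", {
  M <- 5000
  ld <- synthetic_ld_scores(M, mean_l = 4, seed = 2)
  # null model: mean chi-square 1
  null <- simulate_sumstats(M, 20000, h2 = 0, ld_scores = ld, seed = 3)[[1]]
  expect_lt(abs(mean(null$chisq) - 1), 3 * sqrt(2 / M))
  # noiseless mode: chisq exactly 1 + N h2 l / M
  nl <- simulate_sumstats(M, 30000, h2 = 0.4, ld_scores = ld,
                          noise = FALSE)[[1]]
  expect_equal(nl$chisq, 1 + 30000 * 0.4 * ld$l2 / M, tolerance = 1e-12)
  # degenerate correlation with full overlap: z1 equals z2
  pair <- simulate_sumstats(M, c(10000, 10000), h2 = c(0.3, 0.3), rg = 1,
                            ld_scores = ld, cross_intercept = 1, seed = 5)
  expect_equal(pair[[1]]$z, pair[[2]]$z, tolerance = 1e-9)
  # mean chi-square matches 1 + N h2 mean(l) / M
  s <- simulate_sumstats(M, 50000, h2 = 0.23, ld_scores = ld, seed = 7)[[1]]
  expect_lt(abs(mean(s$chisq) - (1 + 50000 * 0.23 * mean(ld$l2) / M)),
            5 * sqrt(2 * mean((1 + 50000 * 0.23 * ld$l2 / M)^2) / M))
  # non-positive-definite covariance is rejected
  expect_error(simulate_sumstats(100, c(100, 100), h2 = c(0, 0), rg = 0,
                                 cross_intercept = 5, seed = 1),
               "positive definite")
})
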