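test_that("null GWAS p-values are uniformly calibrated", {
  cfg <- geno_config(n_snps = 1000, n_cases = 1000, n_controls = 1000,
                     h2_liability = 0, seed = 12)
  pan <- simulate_panel(cfg)
  ss <- run_gwas(pan, method = "score")
  frac <- mean(ss$p < 0.05, na.rm = TRUE)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / 1000))
})

test_that("a planted large-effect SNP attains the minimum p-value", {
  cfg <- geno_config(n_snps = 300, n_cases = 300, n_controls = 300,
                     h2_liability = 0, seed = 14)
  pan <- simulate_panel(cfg)
  st <- pan$samples$status
  # plant: cases enriched for the alternate allele at SNP 7
  pan$dosages[st == 1, 7] <- pmin(pan$dosages[st == 1, 7] + rbinom(300, 1, 0.6), 2L)
  ss <- run_gwas(pan, method = "wald")
  expect_equal(which.min(ss$p), 7L)
})

test_that("Wald z agrees with an independent allelic score-test oracle", {
  cfg <- geno_config(n_snps = 20, n_cases = 700, n_controls = 700,
                     h2_liability = 0.5, within_block_r = 0, ld_block_size = 1,
                     seed = 15)
  pan <- simulate_panel(cfg)
  ss <- run_gwas(pan, method = "wald")
  y <- pan$samples$status
  # oracle: signed 2x3 allelic (Armitage trend on allele counts) z
  oracle_z <- vapply(seq_len(20), function(j) {
    g <- pan$dosages[, j]
    a1 <- sum(g[y == 1]); n1 <- 2 * sum(y == 1)
    a0 <- sum(g[y == 0]); n0 <- 2 * sum(y == 0)
    p1 <- a1 / n1; p0 <- a0 / n0; pb <- (a1 + a0) / (n1 + n0)
    (p1 - p0) / sqrt(pb * (1 - pb) * (1 / n1 + 1 / n0))
  }, numeric(1))
  expect_gt(cor(ss$z, oracle_z, method = "spearman"), 0.99)
  # on null SNPs the two tests agree to O(1/sqrt(n))
  cfg0 <- geno_config(n_snps = 20, n_cases = 700, n_controls = 700,
                      h2_liability = 0, within_block_r = 0, ld_block_size = 1,
                      seed = 25)
  pan0 <- simulate_panel(cfg0)
  ss0 <- run_gwas(pan0, method = "wald")
  y0 <- pan0$samples$status
  oracle_z0 <- vapply(seq_len(20), function(j) {
    g <- pan0$dosages[, j]
    a1 <- sum(g[y0 == 1]); n1 <- 2 * sum(y0 == 1)
    a0 <- sum(g[y0 == 0]); n0 <- 2 * sum(y0 == 0)
    p1 <- a1 / n1; p0 <- a0 / n0; pb <- (a1 + a0) / (n1 + n0)
    (p1 - p0) / sqrt(pb * (1 - pb) * (1 / n1 + 1 / n0))
  }, numeric(1))
  expect_lt(max(abs(ss0$z - oracle_z0)), 0.35)
})

test_that("the effect-allele convention leaves chi-square invariant", {
  cfg <- geno_config(n_snps = 100, n_cases = 200, n_controls = 200, seed = 16)
  pan <- simulate_panel(cfg)
  ss <- run_gwas(pan, method = "score")
  flipped <- ss
  flipped$a1 <- ss$a2; flipped$a2 <- ss$a1
  flipped$beta <- -ss$beta; flipped$z <- -ss$z
  expect_equal(flipped$chisq, ss$chisq)
  ld <- compute_ld_scores(pan)
  f1 <- ldsc_h2(ss, ld)
  f2 <- ldsc_h2(flipped, ld)
  expect_equal(f1$h2_obs, f2$h2_obs)
  # and chisq = z^2 consistency on the sumstats themselves
  expect_equal(ss$chisq, ss$z^2, tolerance = 1e-9)
})

test_that("sumstats files round-trip and malformed input is rejected", {
  cfg <- geno_config(n_snps = 50, n_cases = 100, n_controls = 100, seed = 18)
  ss <- run_gwas(simulate_panel(cfg), cohort = "demo")
  path <- withr::local_tempfile(fileext = ".sumstats")
  write_sumstats(ss, path)
  back <- read_sumstats(path)
  expect_equal(back$snp, ss$snp)
  expect_equal(back$z, ss$z, tolerance = 1e-5)  # 6 significant digits
  expect_equal(attr(back, "cohort"), "demo")
  # missing required column
  d <- utils::read.table(path, header = TRUE, comment.char = "#")
  d$N <- NULL
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_sumstats(path), "N")
  # NA Z rows dropped with a message; duplicate ids rejected
  d2 <- data.frame(SNP = c("rs1", "rs2", "rs3"), A1 = "A", A2 = "G",
                   N = 100, Z = c("1.0", "NA", "2.0"))
  utils::write.table(d2, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_message(b2 <- read_sumstats(path), "dropped 1")
  expect_equal(nrow(b2), 2)
  d3 <- data.frame(SNP = c("rs1", "rs1"), A1 = "A", A2 = "G", N = 100, Z = 1)
  utils::write.table(d3, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_sumstats(path), "duplicate")
})

test_that("effective sample size convention is optional and recorded", {
  cfg <- geno_config(n_snps = 30, n_cases = 50, n_controls = 150, seed = 19)
  pan <- simulate_panel(cfg)
  tot <- run_gwas(pan, n_convention = "total")
  eff <- run_gwas(pan, n_convention = "effective")
  expect_equal(tot$n[1], 200)
  expect_equal(eff$n[1], 4 / (1 / 50 + 1 / 150))
  expect_equal(attr(eff, "n_convention"), "effective")
})
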