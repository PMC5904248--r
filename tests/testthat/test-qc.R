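test_that("Hardy-Weinberg exact test matches hand cases and guards input", {
  expect_equal(hwe_exact_test(c(100, 0, 0)), 1.0)   # monomorphic
  expect_lt(hwe_exact_test(c(300, 0, 100)), 1e-6)   # gross het deficit
  expect_equal(hwe_exact_test(c(25, 50, 25)), oracle_hwe(c(25, 50, 25)))
  expect_error(hwe_exact_test(c(-1, 2, 3)), "nonnegative")
  expect_error(hwe_exact_test(c(0, 0, 0)), "positive")
})

test_that("QC cascade removes planted failures at the printed thresholds", {
  set.seed(10)
  n <- 400; M <- 60
  G <- matrix(rbinom(n * M, 2, 0.3), n, M)
  # SNP 1: 6% missing (fails the 0.05 pre-sample filter)
  G[sample(n, 24), 1] <- NA
  # sample 1: all heterozygous (heterozygosity F deviation far beyond 0.2)
  G[1, -1] <- 1L
  # SNP 2: controls with genotype counts (300, 0, 100) -> HWE p << 1e-6
  G[2:301, 2] <- rep(c(0L, 2L), c(225, 75))
  G[302:400, 2] <- rbinom(99, 2, 0.25)
  pan <- panel_from_matrix(G, status = rep(c(0L, 1L), c(301, 99)))
  suppressMessages(res <- qc_pipeline(pan))
  expect_true("rs000001" %in% res$report$removed_snps$snp_missing_pre)
  expect_true("S00001" %in% res$report$removed_samples$sample_qc$id)
  post <- res$report$removed_snps$snp_qc_post
  expect_true("rs000002" %in% post$id)
  expect_equal(post$reason[post$id == "rs000002"], "hwe_controls")
})

test_that("QC report conserves counts and the cascade is idempotent", {
  cfg <- geno_config(n_snps = 4000, n_cases = 400, n_controls = 400,
                     n_batches = 3, missing_rate = 0.003, seed = 21)
  pan <- simulate_panel(cfg)
  suppressMessages(res <- qc_pipeline(pan))
  st <- res$report$steps
  expect_true(all(st$before - st$removed == st$after))
  # panel sizes reconcile with the final step counts
  expect_equal(ncol(res$panel$dosages), st$after[nrow(st)])
  snp_steps <- st[st$what == "snps", ]
  expect_equal(snp_steps$before[-1], snp_steps$after[-nrow(snp_steps)])
  # every removed SNP appears in exactly one reason list
  rem <- c(res$report$removed_snps$snp_missing_pre,
           res$report$removed_snps$snp_qc_post$id,
           res$report$removed_snps$batch_qc$id)
  expect_equal(length(rem), length(unique(rem)))
  expect_equal(length(rem), sum(snp_steps$removed))
  # re-running on the filtered panel removes nothing
  suppressMessages(res2 <- qc_pipeline(res$panel))
  expect_true(all(res2$report$steps$removed == 0))
})

test_that("an emptied panel raises an error naming the step", {
  G <- matrix(1L, 30, 20)  # everyone fully heterozygous
  G[, 1] <- rbinom(30, 2, 0.4)
  pan <- panel_from_matrix(G, status = rep(c(0L, 1L), 15))
  expect_error(suppressMessages(qc_pipeline(pan)), "sample_qc")
})

test_that("PCA ancestry selection keeps the target cluster and drops outliers", {
  set.seed(4)
  M <- 5000
  p_eur <- runif(M, 0.05, 0.5)
  shift <- function(d) pmin(pmax(p_eur + runif(M, -d, d), 0.01), 0.99)
  p_afr <- shift(0.4); p_asn <- shift(0.4)
  drawpop <- function(n, p) matrix(rbinom(n * M, 2, rep(p, each = n)), n, M)
  ref <- panel_from_matrix(drawpop(180, c(0)))  # placeholder, replaced below
  ref$dosages <- rbind(drawpop(60, p_eur), drawpop(60, p_afr), drawpop(60, p_asn))
  rownames(ref$dosages) <- sprintf("H%03d", 1:180)
  ref$samples <- data.frame(id = sprintf("H%03d", 1:180),
                            population = rep(c("EUR", "AFR", "ASN"), each = 60))
  colnames(ref$dosages) <- ref$snp$id
  study <- panel_from_matrix(rbind(drawpop(80, p_eur), drawpop(10, p_afr)))
  res <- pca_ancestry_filter(study, ref)
  eur_ids <- study$samples$id[1:80]
  afr_ids <- study$samples$id[81:90]
  expect_gte(mean(eur_ids %in% res$kept), 0.95)
  expect_false(any(afr_ids %in% res$kept))
  # the inequality is strict: a sample exactly at the threshold is dropped
  d1 <- res$distance[[1]]
  res_eq <- pca_ancestry_filter(study, ref, distance_threshold = d1)
  expect_false(study$samples$id[1] %in% res_eq$kept)
  # the target centroid itself is at distance zero
  expect_gt(min(res$distance), 0)
})

test_that("relatedness pruning flags duplicates and first-degree pairs only", {
  cfg <- geno_config(n_snps = 5000, n_cases = 0, n_controls = 30,
                     h2_liability = 0, within_block_r = 0, ld_block_size = 1,
                     seed = 8)
  pan <- simulate_panel(cfg, mode = "population")
  G <- pan$dosages
  maf <- pan$truth$maf
  set.seed(9)
  dup <- G[1, ]
  # parent-offspring: one haplotype transmitted, one drawn at the SNP MAF
  transmitted <- ifelse(G[2, ] == 2, 1L, ifelse(G[2, ] == 0, 0L,
                                                rbinom(5000, 1, 0.5)))
  child <- transmitted + rbinom(5000, 1, maf)
  pan2 <- panel_from_matrix(rbind(G, dup, child))
  pruned <- relatedness_prune(pan2)
  pw <- pruned$pihat
  dup_hat <- pw$pihat[pw$id1 == "S00001" & pw$id2 == "S00031"]
  po_hat <- pw$pihat[pw$id1 == "S00002" & pw$id2 == "S00032"]
  expect_gt(dup_hat, 0.9)
  expect_lt(abs(po_hat - 0.5), 0.05)
  expect_setequal(pruned$removed, c("S00031", "S00032"))
  # a fully unrelated panel loses nobody
  none <- relatedness_prune(panel_from_matrix(G))
  expect_length(none$removed, 0)
  expect_lt(max(none$pihat$pihat), 0.2)
})
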