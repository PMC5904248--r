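#' Genotype quality-control thresholds
#'
#' Threshold set for the staged QC cascade: pre-sample SNP missingness,
#' sample missingness and heterozygosity deviation, post-sample SNP
#' missingness, case-control differential missingness, Hardy-Weinberg exact
#' p-values (controls and cases separately), cross-batch differential
#' missingness and control-vs-control batch association, the PCA ancestry
#' distance cut, and the relatedness pi-hat cut.
#'
#' @param snp_miss_pre SNP missing-rate threshold before sample QC (0.05).
#' @param sample_miss Sample missing-rate threshold (0.02).
#' @param het_abs Absolute bound on the per-sample method-of-moments
#'   heterozygosity F statistic (0.2).
#' @param snp_miss_post SNP missing-rate threshold after sample QC (0.02).
#' @param diff_miss_case_control Case-control differential missingness (0.02).
#' @param hwe_p_controls,hwe_p_cases Hardy-Weinberg exact-test p-value
#'   thresholds in controls (1e-6) and cases (1e-10).
#' @param batch_diff_miss Cross-batch differential missing rate (0.005).
#' @param batch_assoc_p Control-vs-control allelic batch-association p (5e-8).
#' @param pca_distance PCA ancestry distance threshold (0.01, strict `<`).
#' @param pihat Relatedness pruning threshold on pi-hat (0.2, strict `>`).
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(snp_miss_pre = 0.05, sample_miss = 0.02,
                          het_abs = 0.2, snp_miss_post = 0.02,
                          diff_miss_case_control = 0.02,
                          hwe_p_controls = 1e-6, hwe_p_cases = 1e-10,
                          batch_diff_miss = 0.005, batch_assoc_p = 5e-8,
                          pca_distance = 0.01, pihat = 0.2) {
  thr <- list(snp_miss_pre = snp_miss_pre, sample_miss = sample_miss,
              het_abs = het_abs, snp_miss_post = snp_miss_post,
              diff_miss_case_control = diff_miss_case_control,
              hwe_p_controls = hwe_p_controls, hwe_p_cases = hwe_p_cases,
              batch_diff_miss = batch_diff_miss, batch_assoc_p = batch_assoc_p,
              pca_distance = pca_distance, pihat = pihat)
  if (any(unlist(thr) <= 0)) stop_config("all QC thresholds must be positive")
  structure(thr, class = "qc_thresholds")
}

#' Hardy-Weinberg equilibrium exact test
#'
#' Two-sided exact test conditional on the allele counts: the p-value is the
#' sum of probabilities of all heterozygote-count configurations whose
#' conditional probability does not exceed that of the observed
#' configuration. A monomorphic table (zero minor alleles) returns 1.
#'
#' @param counts Integer vector `(hom_ref, het, hom_alt)`.
#' @return The exact two-sided p-value.
#' @examples
#' hwe_exact_test(c(300, 0, 100))  # gross heterozygote deficit
#' @export
hwe_exact_test <- function(counts) {
  if (length(counts) != 3 || any(counts < 0) || any(counts != floor(counts)))
    stop_config("counts must be three nonnegative integers (hom_ref, het, hom_alt)")
  n <- sum(counts)
  if (n == 0) stop_config("total genotype count must be positive")
  n1 <- 2 * counts[3] + counts[2]      # minor-ish allele count (alt)
  n2 <- 2 * counts[1] + counts[2]
  na <- min(n1, n2)
  if (na == 0) return(1.0)
  # valid heterozygote counts share the parity of the minor allele count
  h_all <- seq(na %% 2, na, by = 2)
  hom_alt <- (n1 - h_all) / 2
  hom_ref <- (n2 - h_all) / 2
  logp <- lfactorial(n) - lfactorial(hom_ref) - lfactorial(h_all) -
    lfactorial(hom_alt) + h_all * log(2) +
    lfactorial(n1) + lfactorial(n2) - lfactorial(2 * n)
  p_obs <- logp[h_all == counts[2]]
  sum(exp(logp[logp <= p_obs + 1e-10]))
}

snp_missing_rate <- function(G) colMeans(is.na(G))

hwe_p_by_col <- function(G) {
  vapply(seq_len(ncol(G)), function(j) {
    g <- G[, j]; g <- g[!is.na(g)]
    if (!length(g)) return(1.0)
    hwe_exact_test(c(sum(g == 0L), sum(g == 1L), sum(g == 2L)))
  }, numeric(1))
}

# Pearson chi-square on the 2x2 allele-count table of two groups (allelic test)
allelic_chisq_p <- function(g1, g2) {
  g1 <- g1[!is.na(g1)]; g2 <- g2[!is.na(g2)]
  a <- c(sum(g1), 2 * length(g1) - sum(g1))
  b <- c(sum(g2), 2 * length(g2) - sum(g2))
  tab <- rbind(a, b)
  if (any(colSums(tab) == 0) || any(rowSums(tab) == 0)) return(1.0)
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stats::pchisq(sum((tab - e)^2 / e), df = 1, lower.tail = FALSE)
}

subset_panel <- function(panel, samples = NULL, snps = NULL) {
  if (!is.null(samples)) {
    panel$dosages <- panel$dosages[samples, , drop = FALSE]
    panel$samples <- panel$samples[samples, , drop = FALSE]
    rownames(panel$samples) <- NULL
  }
  if (!is.null(snps)) {
    panel$dosages <- panel$dosages[, snps, drop = FALSE]
    panel$snp <- panel$snp[snps, , drop = FALSE]
    rownames(panel$snp) <- NULL
    if (!is.null(panel$truth$beta)) {
      panel$truth$beta <- panel$truth$beta[snps, , drop = FALSE]
      panel$truth$maf <- panel$truth$maf[snps]
    }
  }
  panel
}

#' Staged genotype QC cascade
#'
#' Applies, per genotyping batch and in order: (1) SNP missingness above
#' `snp_miss_pre`; (2) sample missingness above `sample_miss` and absolute
#' heterozygosity-F deviation above `het_abs` (the sex check is skipped with
#' a message when the panel carries no X-chromosome SNPs); (3) SNP
#' missingness above `snp_miss_post`, case-control differential missingness,
#' and Hardy-Weinberg exact-test failures (thresholds for controls and cases
#' separately). Batches are then merged and SNPs with cross-batch
#' differential missingness above `batch_diff_miss` or control-vs-control
#' batch association below `batch_assoc_p` are removed. A SNP failing a
#' per-batch filter in any batch is removed globally (only SNPs clean in
#' every batch survive the merge).
#'
#' @param panel A `geno_panel` with `status` and `batch` sample columns.
#' @param thr A [qc_thresholds()] list.
#' @return A list with the filtered `panel` and a `report` (per-step counts
#'   that conserve `before - removed = after`, plus removal reason tables).
#' @export
qc_pipeline <- function(panel, thr = qc_thresholds()) {
  steps <- list()
  removed_snps <- list(); removed_samples <- list()
  batches <- sort(unique(panel$samples$batch))

  record <- function(step, what, before, removed, after) {
    steps[[length(steps) + 1L]] <<- data.frame(
      step = step, what = what, before = before,
      removed = removed, after = after, stringsAsFactors = FALSE)
    if (after == 0)
      stop_config("QC produced an empty panel at step '%s'", step)
  }

  # --- step 1: per-batch SNP missingness before sample QC
  fail <- rep(FALSE, ncol(panel$dosages))
  for (b in batches) {
    rows <- panel$samples$batch == b
    fail <- fail | snp_missing_rate(panel$dosages[rows, , drop = FALSE]) > thr$snp_miss_pre
  }
  removed_snps$snp_missing_pre <- panel$snp$id[fail]
  record("snp_missingness_pre", "snps", length(fail), sum(fail), sum(!fail))
  panel <- subset_panel(panel, snps = !fail)

  # --- step 2: sample missingness + heterozygosity deviation (+ sex check)
  G <- panel$dosages
  smiss <- rowMeans(is.na(G))
  p <- colMeans(G, na.rm = TRUE) / 2
  exp_het <- 2 * p * (1 - p)
  nonmiss <- !is.na(G)
  ehet_i <- as.vector(nonmiss %*% exp_het)          # expected het count per sample
  ohet_i <- rowSums(G == 1L, na.rm = TRUE)
  n_i <- rowSums(nonmiss)
  # method-of-moments inbreeding-style F: (E - O) / E on het counts
  Fstat <- ifelse(ehet_i > 0, (ehet_i - ohet_i) / ehet_i, 0)
  has_x <- any(panel$snp$chrom %in% c("X", "23", 23L))
  if (!has_x) message("no X-chromosome SNPs: sex check skipped")
  fail_s <- smiss > thr$sample_miss | abs(Fstat) > thr$het_abs
  removed_samples$sample_qc <- data.frame(
    id = panel$samples$id[fail_s],
    reason = ifelse(smiss[fail_s] > thr$sample_miss, "missingness", "heterozygosity"),
    stringsAsFactors = FALSE)
  record("sample_qc", "samples", length(fail_s), sum(fail_s), sum(!fail_s))
  panel <- subset_panel(panel, samples = !fail_s)

  # --- step 3: per-batch SNP filters after sample QC
  fail <- rep(FALSE, ncol(panel$dosages))
  reason <- rep(NA_character_, ncol(panel$dosages))
  for (b in batches) {
    rows <- panel$samples$batch == b
    if (!any(rows)) next
    Gb <- panel$dosages[rows, , drop = FALSE]
    st <- panel$samples$status[rows]
    miss <- snp_missing_rate(Gb)
    f <- miss > thr$snp_miss_post
    reason[f & is.na(reason)] <- "snp_missingness_post"
    if (any(st == 1) && any(st == 0)) {
      dmiss <- abs(snp_missing_rate(Gb[st == 1, , drop = FALSE]) -
                   snp_missing_rate(Gb[st == 0, , drop = FALSE]))
      f2 <- dmiss > thr$diff_miss_case_control
      reason[f2 & is.na(reason)] <- "differential_missingness"
      f <- f | f2
    }
    if (any(st == 0)) {
      pc <- hwe_p_by_col(Gb[st == 0, , drop = FALSE])
      f3 <- pc < thr$hwe_p_controls
      reason[f3 & is.na(reason)] <- "hwe_controls"
      f <- f | f3
    }
    if (any(st == 1)) {
      pa <- hwe_p_by_col(Gb[st == 1, , drop = FALSE])
      f4 <- pa < thr$hwe_p_cases
      reason[f4 & is.na(reason)] <- "hwe_cases"
      f <- f | f4
    }
    fail <- fail | f
  }
  removed_snps$snp_qc_post <- data.frame(
    id = panel$snp$id[fail], reason = reason[fail], stringsAsFactors = FALSE)
  record("snp_qc_post", "snps", length(fail), sum(fail), sum(!fail))
  panel <- subset_panel(panel, snps = !fail)

  # --- batch merge QC
  if (length(batches) > 1) {
    Mn <- ncol(panel$dosages)
    miss_by_batch <- sapply(batches, function(b)
      snp_missing_rate(panel$dosages[panel$samples$batch == b, , drop = FALSE]))
    dmiss <- apply(miss_by_batch, 1, function(x) max(x) - min(x))
    fail <- dmiss > thr$batch_diff_miss
    reason <- ifelse(fail, "batch_differential_missingness", NA_character_)
    ctrl <- panel$samples$status == 0
    pairs <- utils::combn(batches, 2)
    pmin_assoc <- rep(1, Mn)
    todo <- which(!fail)
    for (k in seq_len(ncol(pairs))) {
      r1 <- ctrl & panel$samples$batch == pairs[1, k]
      r2 <- ctrl & panel$samples$batch == pairs[2, k]
      if (!any(r1) || !any(r2)) next
      for (j in todo) {
        pj <- allelic_chisq_p(panel$dosages[r1, j], panel$dosages[r2, j])
        pmin_assoc[j] <- min(pmin_assoc[j], pj)
      }
    }
    f2 <- pmin_assoc < thr$batch_assoc_p
    reason[f2 & is.na(reason)] <- "batch_association"
    fail <- fail | f2
    removed_snps$batch_qc <- data.frame(
      id = panel$snp$id[fail], reason = reason[fail], stringsAsFactors = FALSE)
    record("batch_merge_qc", "snps", length(fail), sum(fail), sum(!fail))
    panel <- subset_panel(panel, snps = !fail)
  }

  report <- list(steps = do.call(rbind, steps),
                 removed_snps = removed_snps,
                 removed_samples = removed_samples,
                 thresholds = thr)
  class(report) <- "qc_report"
  list(panel = panel, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Genotype QC report\n")
  print(x$steps, row.names = FALSE)
  invisible(x)
}

#' PCA-based ancestry selection against a labelled reference panel
#'
#' Combines study and reference genotypes on their shared SNPs, computes the
#' top two principal components of the standardized genotype matrix (unit-norm
#' eigenvectors of the sample-sample relationship matrix, the PLINK /
#' EIGENSTRAT coordinate convention), and keeps each study sample whose
#' Euclidean distance on (PC1, PC2) to the centroid of the target reference
#' population is strictly below `distance_threshold`.
#'
#' The absolute threshold only carries meaning relative to the eigenvector
#' coordinate convention (entries of a unit-norm vector over all samples);
#' with well-separated ancestry clusters the between-cluster distance dwarfs
#' the within-cluster spread and the default 0.01 cleanly separates them.
#'
#' @param panel Study `geno_panel`.
#' @param reference_panel A `geno_panel` whose `samples` carry a
#'   `population` column.
#' @param target_population Reference population defining the centroid.
#' @param distance_threshold Keep iff distance `<` this (strict).
#' @return A list: `kept` (study sample ids), `coords` (PC1/PC2 for all
#'   samples with a `set` column), `distance` (per study sample).
#' @export
pca_ancestry_filter <- function(panel, reference_panel,
                                target_population = "EUR",
                                distance_threshold = 0.01) {
  shared <- intersect(panel$snp$id, reference_panel$snp$id)
  if (length(shared) < 2) stop_config("fewer than 2 shared SNPs for PCA")
  Xs <- panel$dosages[, match(shared, panel$snp$id), drop = FALSE]
  Xr <- reference_panel$dosages[, match(shared, reference_panel$snp$id), drop = FALSE]
  X <- rbind(Xr, Xs)
  if (nrow(Xr) < 2) stop_config("reference panel must have at least 2 samples")
  if (anyNA(X)) {
    mu <- colMeans(X, na.rm = TRUE)
    idx <- which(is.na(X), arr.ind = TRUE)
    X[idx] <- mu[idx[, 2]]
  }
  storage.mode(X) <- "double"
  sds <- apply(X, 2, stats::sd)
  keep_col <- sds > 0
  Z <- scale(X[, keep_col, drop = FALSE])
  K <- tcrossprod(Z) / ncol(Z)
  ev <- eigen(K, symmetric = TRUE)
  pcs <- ev$vectors[, 1:2, drop = FALSE]
  colnames(pcs) <- c("PC1", "PC2")
  is_ref <- rep(c(TRUE, FALSE), c(nrow(Xr), nrow(Xs)))
  pop <- reference_panel$samples$population
  if (is.null(pop)) stop_config("reference panel samples need a 'population' column")
  cen <- colMeans(pcs[is_ref, , drop = FALSE][pop == target_population, , drop = FALSE])
  d <- sqrt((pcs[!is_ref, 1] - cen[1])^2 + (pcs[!is_ref, 2] - cen[2])^2)
  kept <- panel$samples$id[d < distance_threshold]
  coords <- data.frame(
    id = c(reference_panel$samples$id, panel$samples$id),
    set = rep(c("reference", "study"), c(nrow(Xr), nrow(Xs))),
    PC1 = pcs[, 1], PC2 = pcs[, 2], stringsAsFactors = FALSE)
  list(kept = kept, coords = coords,
       distance = stats::setNames(d, panel$samples$id),
       centroid = cen, threshold = distance_threshold)
}

# Pairwise PLINK-style method-of-moments IBD (pi-hat) from IBS counts and
# allele frequencies. Uncorrected for finite-sample frequency estimation;
# pass `allele_freq` for exact frequencies when known.
estimate_pihat <- function(panel, allele_freq = NULL) {
  G <- panel$dosages
  n <- nrow(G)
  p <- allele_freq %||% (colMeans(G, na.rm = TRUE) / 2)
  q <- 1 - p
  poly <- p > 0 & p < 1
  e0 <- 2 * p^2 * q^2
  e1_0 <- 4 * p^3 * q + 4 * p * q^3
  e2_0 <- p^4 + q^4 + 4 * p^2 * q^2
  e1_1 <- 2 * p^2 * q + 2 * p * q^2
  e2_1 <- p^3 + q^3 + p^2 * q + p * q^2
  ids <- panel$samples$id
  out <- data.frame()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    use <- poly & !is.na(G[i, ]) & !is.na(G[j, ])
    d <- abs(G[i, use] - G[j, use])
    L <- sum(use)
    ibs0 <- sum(d == 2); ibs1 <- sum(d == 1); ibs2 <- L - ibs0 - ibs1
    P0 <- ibs0 / sum(e0[use])
    P1 <- (ibs1 - P0 * sum(e1_0[use])) / sum(e1_1[use])
    P2 <- (ibs2 - P0 * sum(e2_0[use]) - P1 * sum(e2_1[use])) / L
    pr <- pmax(c(P0, P1, P2), 0); pr <- pr / sum(pr)
    out <- rbind(out, data.frame(
      id1 = ids[i], id2 = ids[j], pihat = pr[2] / 2 + pr[3],
      stringsAsFactors = FALSE))
  }
  out
}

#' Relatedness pruning by pairwise pi-hat
#'
#' Estimates pairwise genome-sharing (pi-hat) by PLINK-style
#' method-of-moments IBD from identity-by-state counts and allele
#' frequencies, then greedily removes, from each remaining pair with pi-hat
#' strictly above the threshold, the member with higher genotype missingness
#' (ties broken by removing the lexicographically later id).
#'
#' @param panel A QC'd `geno_panel`.
#' @param pihat_threshold Remove one of each pair with pi-hat `>` this.
#' @param allele_freq Optional known allele frequencies (length = SNPs).
#' @return A list: `kept` ids, `removed` ids, and the pairwise `pihat` table.
#' @export
relatedness_prune <- function(panel, pihat_threshold = 0.2, allele_freq = NULL) {
  pw <- estimate_pihat(panel, allele_freq)
  miss <- stats::setNames(rowMeans(is.na(panel$dosages)), panel$samples$id)
  removed <- character(0)
  active <- pw
  repeat {
    live <- active[!(active$id1 %in% removed) & !(active$id2 %in% removed) &
                     active$pihat > pihat_threshold, , drop = FALSE]
    if (!nrow(live)) break
    top <- live[which.max(live$pihat), ]
    pair <- c(top$id1, top$id2)
    m <- miss[pair]
    drop_id <- if (m[1] != m[2]) pair[which.max(m)] else sort(pair)[2]
    removed <- c(removed, drop_id)
  }
  list(kept = setdiff(panel$samples$id, removed), removed = removed, pihat = pw)
}
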