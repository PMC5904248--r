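#' Configuration for the liability-threshold genotype simulator
#'
#' Collects the generative parameters of the synthetic genotype substrate:
#' block-exchangeable LD, an infinitesimal bivariate effect model with given
#' per-trait liability heritability and genetic correlation, a 1% population
#' prevalence liability threshold, case oversampling, genotyping batches,
#' and case misclassification (a fraction of labelled cases drawn from the
#' non-case liability distribution, emulating imperfect phenotyping PPV).
#'
#' @param n_snps Number of SNPs (M).
#' @param n_cases,n_controls Labelled cases and controls to draw.
#' @param ld_block_size SNPs per exchangeable-correlation LD block.
#' @param within_block_r Latent (copula) correlation within a block, in [0, 1).
#' @param maf_range Minor-allele-frequency range, within (0, 0.5].
#' @param h2_liability Liability-scale heritability per trait (length 1 or 2).
#' @param rg_true Genetic correlation between the two traits' effects.
#' @param prevalence Population prevalence K (liability threshold).
#' @param misclassification_rate Fraction of labelled cases drawn as non-cases.
#' @param n_batches Genotyping batches (assigned round-robin within status).
#' @param missing_rate Per-genotype missing probability; 0 disables.
#' @param seed Integer seed; identical config + seed gives identical output.
#' @return A list of class `geno_config`.
#' @export
geno_config <- function(n_snps = 2000, n_cases = 500, n_controls = 500,
                        ld_block_size = 20, within_block_r = 0.5,
                        maf_range = c(0.05, 0.5),
                        h2_liability = 0.23, rg_true = 0.83,
                        prevalence = 0.01, misclassification_rate = 0,
                        n_batches = 1, missing_rate = 0, seed = 1) {
  assert_count(n_snps, "n_snps"); assert_count(n_cases, "n_cases", 0L)
  assert_count(n_controls, "n_controls", 0L)
  assert_count(ld_block_size, "ld_block_size")
  if (within_block_r < 0 || within_block_r >= 1)
    stop_config("within_block_r must lie in [0, 1)")
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    stop_config("maf_range must be (min, max) within (0, 0.5]")
  h2_liability <- rep_len(h2_liability, 2)
  if (any(h2_liability < 0 | h2_liability > 1)) stop_config("h2_liability must lie in [0, 1]")
  if (abs(rg_true) > 1) stop_config("|rg_true| must be <= 1")
  assert_prob(prevalence, "prevalence")
  assert_prob(misclassification_rate, "misclassification_rate")
  assert_count(n_batches, "n_batches")
  assert_prob(missing_rate, "missing_rate")
  structure(list(n_snps = as.integer(n_snps), n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 ld_block_size = as.integer(ld_block_size),
                 within_block_r = within_block_r, maf_range = maf_range,
                 h2_liability = h2_liability, rg_true = rg_true,
                 prevalence = prevalence,
                 misclassification_rate = misclassification_rate,
                 n_batches = as.integer(n_batches),
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "geno_config")
}

# Draw bivariate per-SNP effects on the standardized-genotype scale:
# Var(beta_t) = h2_t / M, Cor(beta_1, beta_2) = rg.
draw_effects <- function(M, h2, rg) {
  b1 <- stats::rnorm(M)
  b2 <- rg * b1 + sqrt(max(0, 1 - rg^2)) * stats::rnorm(M)
  cbind(b1 * sqrt(h2[1] / M), b2 * sqrt(h2[2] / M))
}

# The genetic architecture implied by a geno_config: MAFs, LD block index,
# and the bivariate effect draws. Depends on config$seed only, so distinct
# cohorts built from one config share it.
genetic_architecture <- function(cf) {
  set.seed(cf$seed)
  M <- cf$n_snps
  list(maf = stats::runif(M, cf$maf_range[1], cf$maf_range[2]),
       blk = ceiling(seq_len(M) / cf$ld_block_size),
       beta = draw_effects(M, cf$h2_liability, cf$rg_true))
}

# Haplotype-indicator covariance between two thresholded latent normals with
# correlation rho and thresholds a, b: 3-term Mehler (tetrachoric) expansion
# of Phi2(a, b; rho) - Phi(a) Phi(b).
mehler_cov <- function(a, b, rho) {
  stats::dnorm(a) * stats::dnorm(b) *
    (rho + rho^2 * a * b / 2 + rho^3 * (a^2 - 1) * (b^2 - 1) / 6)
}

# Draw genotype rows conditional on case/control status (retrospective
# approximation). The marginal conditional allele frequency of SNP j
# aggregates the LD-weighted effects of its block:
#   p_j + Cov(x_j, L) * i / 2,  Cov(x_j, L) = sum_k beta_k Cov(x_j, x_k)/sd_k
# with selection intensity i = phi(t)/K for cases, -phi(t)/(1-K) for
# controls, and within-block dosage covariances from the Mehler expansion.
# This reproduces E[chisq_j] = 1 + N h2 l_j / M marginally while preserving
# block LD. `true_case` is a logical vector, one row drawn per element.
draw_genotypes_conditional <- function(cf, arch, true_case, trait = 1L) {
  M <- cf$n_snps
  maf <- arch$maf; blk <- arch$blk
  beta <- arch$beta[, trait]
  sd_g <- sqrt(2 * maf * (1 - maf))
  a <- stats::qnorm(maf)
  # LD-aggregated per-SNP liability covariance
  cov_xl <- beta * sd_g
  rho <- cf$within_block_r
  if (rho > 0) {
    for (b in unique(blk)) {
      j <- which(blk == b)
      if (length(j) < 2) next
      Ch <- outer(seq_along(j), seq_along(j), function(u, v)
        mehler_cov(a[j][u], a[j][v], rho))
      diag(Ch) <- 0
      # dosage covariance = 2 * haplotype covariance
      cov_xl[j] <- cov_xl[j] + as.vector((2 * Ch) %*% (beta[j] / sd_g[j]))
    }
  }
  K <- cf$prevalence
  t_thr <- stats::qnorm(1 - K)
  shift_for <- function(i_sel) {
    p_new <- pmin(pmax(maf + cov_xl * i_sel / 2, 1e-4), 0.9999)
    stats::qnorm(p_new) - stats::qnorm(maf)
  }
  sh_case <- shift_for(stats::dnorm(t_thr) / K)
  sh_ctrl <- shift_for(-stats::dnorm(t_thr) / (1 - K))
  n <- length(true_case)
  G <- matrix(0L, n, M)
  for (st in c(TRUE, FALSE)) {
    rows <- which(true_case == st)
    if (!length(rows)) next
    sh <- if (st) sh_case else sh_ctrl
    for (b in unique(blk)) {
      j <- which(blk == b)
      G[rows, j] <- draw_block(length(rows), maf[j], cf$within_block_r,
                               shift = matrix(sh[j], length(rows), length(j),
                                              byrow = TRUE))
    }
  }
  G
}

# Draw n haplotype/genotype rows for one LD block: latent exchangeable
# Gaussian copula per haplotype, thresholded at qnorm(maf) per SNP, two
# independent haplotypes summed (Hardy-Weinberg by construction). `shift`
# moves the per-SNP latent threshold, implementing conditional allele
# frequencies for retrospective case-control draws.
draw_block <- function(n, maf, r, shift = NULL) {
  b <- length(maf)
  thr <- stats::qnorm(maf)
  g <- matrix(0L, n, b)
  for (h in 1:2) {
    shared <- stats::rnorm(n)
    z <- sqrt(r) * shared + sqrt(1 - r) * matrix(stats::rnorm(n * b), n, b)
    tm <- if (is.null(shift)) matrix(thr, n, b, byrow = TRUE) else
      matrix(thr, n, b, byrow = TRUE) + shift
    g <- g + (z < tm)
  }
  g
}

#' Simulate a case-control genotype panel under the liability-threshold model
#'
#' Generates genotypes in LD blocks (exchangeable latent-Gaussian copula,
#' thresholded to Hardy-Weinberg genotype frequencies at each SNP's MAF),
#' draws infinitesimal bivariate effects with the configured heritabilities
#' and genetic correlation, forms liabilities, and ascertains cases above the
#' \eqn{\Phi^{-1}(1-K)} threshold.
#'
#' Two sampling modes are available. `"population"` draws unascertained
#' individuals in chunks and keeps cases/controls until the requested counts
#' are met — exact, but requires simulating roughly `n_cases / K` individuals.
#' `"retrospective"` draws genotypes conditional on case/control status via
#' the standard small-effect approximation (per-SNP allele frequencies
#' shifted by \eqn{\beta_j \sqrt{2 p q}\, i / 2}, with selection intensity
#' \eqn{i = \phi(t)/K} for cases and \eqn{-\phi(t)/(1-K)} for controls),
#' which preserves the expected per-SNP association signal and block LD at a
#' cost linear in the number of sampled individuals — the default for large
#' ascertained panels.
#'
#' A `misclassification_rate` fraction of labelled cases is drawn from the
#' non-case distribution (label swap at sampling time), emulating phenotyping
#' algorithms with PPV below 1.
#'
#' @param config A [geno_config()].
#' @param mode `"population"` or `"retrospective"` (see Details).
#' @param trait Which trait's effects drive the liability (1 or 2). The
#'   genetic architecture (MAFs and the bivariate effects) is reproducible
#'   from `config$seed` alone, so panels for trait 1 and trait 2 built from
#'   the same config share correlated effects — the substrate for genetic
#'   correlation between independently sampled cohorts.
#' @param sample_seed Seed for the sampling randomness (individual draws,
#'   missingness); defaults to a child of `config$seed` and `trait`. Distinct
#'   values give independent cohorts under the same architecture.
#' @param max_population Abort `"population"` mode if more than this many
#'   individuals would need to be drawn.
#' @return A list of class `geno_panel`: integer `dosages` (samples x SNPs,
#'   `NA` = missing), `snp` metadata (id, chrom, pos, a1, a2, maf, block),
#'   `samples` metadata (id, status, batch), and a `truth` list (effects,
#'   MAFs, true status, liabilities where available).
#' @export
simulate_panel <- function(config, mode = c("retrospective", "population"),
                           trait = 1L, sample_seed = NULL,
                           max_population = 2e6) {
  mode <- match.arg(mode)
  cf <- config
  set.seed(cf$seed)
  M <- cf$n_snps
  maf <- stats::runif(M, cf$maf_range[1], cf$maf_range[2])
  blk <- ceiling(seq_len(M) / cf$ld_block_size)
  beta_all <- draw_effects(M, cf$h2_liability, cf$rg_true)
  beta <- cbind(beta_all[, trait])
  set.seed(sample_seed %||% derive_seed(cf$seed, 1000L + trait))
  h2 <- cf$h2_liability[trait]
  K <- cf$prevalence
  t_thr <- stats::qnorm(1 - K)

  n_cases <- cf$n_cases; n_controls <- cf$n_controls
  n_mis <- round(cf$misclassification_rate * n_cases)
  need_true_case <- n_cases - n_mis
  need_non_case <- n_controls + n_mis

  sd_g <- sqrt(2 * maf * (1 - maf))
  if (mode == "population") {
    rows <- list(); liab_all <- c(); status_all <- c(); drawn <- 0L
    got_case <- 0L; got_ctrl <- 0L
    chunk <- max(1000L, min(20000L, as.integer(ceiling(need_true_case / max(K, 1e-4)) / 4)))
    while (got_case < need_true_case || got_ctrl < need_non_case) {
      if (drawn > max_population)
        stop_config("population mode needs more than %g draws to ascertain %d cases at K = %g",
                    max_population, n_cases, K)
      g <- matrix(0L, chunk, M)
      for (b in unique(blk)) {
        j <- which(blk == b)
        g[, j] <- draw_block(chunk, maf[j], cf$within_block_r)
      }
      gs <- sweep(sweep(g, 2, 2 * maf), 2, sd_g, "/")
      gv <- as.vector(gs %*% beta[, 1])
      liab <- gv + stats::rnorm(chunk, 0, sqrt(1 - h2))
      is_case <- liab > t_thr
      take_case <- which(is_case)[seq_len(min(sum(is_case), need_true_case - got_case))]
      take_ctrl <- which(!is_case)[seq_len(min(sum(!is_case), need_non_case - got_ctrl))]
      take <- c(take_case, take_ctrl)
      if (length(take)) {
        rows[[length(rows) + 1L]] <- g[take, , drop = FALSE]
        liab_all <- c(liab_all, liab[take])
        status_all <- c(status_all, is_case[take])
      }
      got_case <- got_case + length(take_case)
      got_ctrl <- got_ctrl + length(take_ctrl)
      drawn <- drawn + chunk
    }
    G <- do.call(rbind, rows)
    true_case <- status_all
    liab_out <- liab_all
  } else {
    true_case <- rep(c(TRUE, FALSE), c(need_true_case, need_non_case))
    arch <- list(maf = maf, blk = blk, beta = beta_all)
    G <- draw_genotypes_conditional(cf, arch, true_case, trait = trait)
    liab_out <- rep(NA_real_, nrow(G))
  }

  # assemble labelled panel: true cases first, then (mislabelled) non-cases
  # filling the remaining case slots, then controls
  case_idx <- which(true_case)[seq_len(need_true_case)]
  non_idx <- which(!true_case)
  mis_idx <- non_idx[seq_len(n_mis)]
  ctrl_idx <- setdiff(non_idx, mis_idx)[seq_len(n_controls)]
  ord <- c(case_idx, mis_idx, ctrl_idx)
  G <- G[ord, , drop = FALSE]
  status <- rep(c(1L, 0L), c(n_cases, n_controls))
  truth_status <- true_case[ord]
  liab_out <- liab_out[ord]

  n <- nrow(G)
  batch <- rep_len(seq_len(cf$n_batches), n)
  if (cf$missing_rate > 0) {
    miss <- matrix(stats::runif(n * M) < cf$missing_rate, n, M)
    G[miss] <- NA_integer_
  }

  snp <- data.frame(
    id = sprintf("rs%06d", seq_len(M)), chrom = 1L, pos = seq_len(M) * 1000L,
    a1 = "A", a2 = "G", maf = maf, block = blk, stringsAsFactors = FALSE)
  samples <- data.frame(
    id = sprintf("S%05d", seq_len(n)), status = status, batch = batch,
    stringsAsFactors = FALSE)
  rownames(G) <- samples$id; colnames(G) <- snp$id

  structure(list(
    dosages = G, snp = snp, samples = samples,
    truth = list(beta = beta_all, trait = trait, maf = maf,
                 true_case = truth_status,
                 liability = liab_out, config = cf, mode = mode)
  ), class = "geno_panel")
}

#' Compute LD scores from a genotype panel
#'
#' The LD score of SNP j is \eqn{\ell_j = \sum_k \tilde r^2_{jk}} over SNPs k
#' within `window_snps` of j (self term included), where
#' \eqn{\tilde r^2 = r^2 - (1 - r^2)/(n - 2)} is the small-sample
#' bias-adjusted squared correlation.
#'
#' @param panel A `geno_panel` (missing dosages are mean-imputed per SNP).
#' @param window_snps One-sided window in SNP count; default twice the
#'   generating LD block size when known, else 100.
#' @return A data frame of class `ld_scores` with columns `snp`, `l2`;
#'   attribute `window_snps`.
#' @export
compute_ld_scores <- function(panel, window_snps = NULL) {
  X <- panel$dosages
  if (anyNA(X)) {
    mu <- colMeans(X, na.rm = TRUE)
    idx <- which(is.na(X), arr.ind = TRUE)
    X[idx] <- mu[idx[, 2]]
  }
  storage.mode(X) <- "double"
  n <- nrow(X); M <- ncol(X)
  if (is.null(window_snps))
    window_snps <- if (!is.null(panel$truth$config$ld_block_size))
      2L * panel$truth$config$ld_block_size else 100L
  sds <- apply(X, 2, stats::sd)
  mono <- sds == 0
  if (any(mono)) {
    warning(sprintf("%d monomorphic SNP(s): pairwise terms set to 0", sum(mono)))
    sds[mono] <- 1
  }
  Xs <- scale(X, center = TRUE, scale = sds)
  Xs[, mono] <- 0
  l2 <- numeric(M)
  step <- max(64L, window_snps)
  for (s in seq(1L, M, by = step)) {
    e <- min(M, s + step - 1L)
    lo <- max(1L, s - window_snps); hi <- min(M, e + window_snps)
    R <- crossprod(Xs[, s:e, drop = FALSE], Xs[, lo:hi, drop = FALSE]) / (n - 1)
    r2 <- R^2
    radj <- r2 - (1 - r2) / (n - 2)
    for (j in s:e) {
      cols <- max(lo, j - window_snps):min(hi, j + window_snps)
      l2[j] <- sum(radj[j - s + 1L, cols - lo + 1L])
    }
  }
  l2[mono] <- 1  # a monomorphic SNP is defined to be in LD only with itself
  out <- data.frame(snp = panel$snp$id, l2 = l2, stringsAsFactors = FALSE)
  attr(out, "window_snps") <- window_snps
  class(out) <- c("ld_scores", "data.frame")
  out
}

#' Synthetic LD scores with realistic spread
#'
#' Draws per-SNP LD scores \eqn{\ell_j = 1 + E_j} with `E_j` exponential of
#' mean `mean_l - 1`, giving the heterogeneity LD score regression needs for
#' slope/intercept identifiability without simulating genotypes.
#'
#' @param M Number of SNPs.
#' @param mean_l Mean LD score (>= 1).
#' @param seed Integer seed.
#' @export
synthetic_ld_scores <- function(M, mean_l = 4, seed = 1) {
  set.seed(seed)
  data.frame(snp = sprintf("rs%06d", seq_len(M)),
             l2 = 1 + stats::rexp(M, rate = 1 / (mean_l - 1)),
             stringsAsFactors = FALSE)
}

#' Simulate GWAS summary statistics under the LD score regression model
#'
#' Generative inverse of LD score regression: per SNP j, z-scores for one or
#' two traits are drawn (bivariate) normal with
#' \deqn{Var(z_{tj}) = 1 + N_t h^2_t \ell_j / M + (a_t - 1)}
#' \deqn{Cov(z_{1j}, z_{2j}) = r_g \sqrt{h^2_1 h^2_2 N_1 N_2}\, \ell_j / M + a_c}
#' With `noise = FALSE` the chi-square equals its expectation exactly
#' (`z = sqrt(E[chisq])`), giving noiseless closed-form inputs for exact
#' recovery tests.
#'
#' @param M Number of SNPs.
#' @param n_samples Per-trait sample sizes (length 1 or 2).
#' @param h2 Per-trait heritabilities (length matches `n_samples`).
#' @param rg Genetic correlation (used when two traits are requested).
#' @param ld_scores Numeric vector of LD scores, or a `snp`/`l2` data frame,
#'   or `NULL` for `l2 = 1` throughout.
#' @param intercepts Per-trait LDSC intercepts (default 1).
#' @param cross_intercept Cross-trait intercept (sample-overlap term).
#' @param noise If `FALSE`, return the exact expected statistics.
#' @param seed Integer seed.
#' @return A list with one summary-statistics data frame per trait
#'   (columns `snp`, `a1`, `a2`, `n`, `z`, `chisq`, `p`).
#' @export
simulate_sumstats <- function(M, n_samples, h2, rg = 0, ld_scores = NULL,
                              intercepts = 1, cross_intercept = 0,
                              noise = TRUE, seed = 1) {
  n_traits <- length(n_samples)
  h2 <- rep_len(h2, n_traits)
  intercepts <- rep_len(intercepts, n_traits)
  if (is.null(ld_scores)) {
    l <- rep(1, M); ids <- sprintf("rs%06d", seq_len(M))
  } else if (is.data.frame(ld_scores)) {
    l <- ld_scores$l2[seq_len(M)]; ids <- ld_scores$snp[seq_len(M)]
  } else {
    l <- rep_len(ld_scores, M); ids <- sprintf("rs%06d", seq_len(M))
  }
  v <- lapply(seq_len(n_traits), function(t)
    intercepts[t] + n_samples[t] * h2[t] * l / M)
  set.seed(seed)
  if (n_traits == 1) {
    z1 <- if (noise) stats::rnorm(M, 0, sqrt(v[[1]])) else sqrt(v[[1]])
    zs <- list(z1)
  } else {
    cv <- rg * sqrt(h2[1] * h2[2] * n_samples[1] * n_samples[2]) * l / M +
      cross_intercept
    if (noise) {
      rho <- cv / sqrt(v[[1]] * v[[2]])
      if (any(abs(rho) > 1 + 1e-12))
        stop_config("implied per-SNP correlation exceeds 1: covariance not positive definite")
      rho <- pmin(pmax(rho, -1), 1)
      e1 <- stats::rnorm(M); e2 <- stats::rnorm(M)
      z1 <- sqrt(v[[1]]) * e1
      z2 <- sqrt(v[[2]]) * (rho * e1 + sqrt(1 - rho^2) * e2)
    } else {
      z1 <- sqrt(v[[1]]); z2 <- sqrt(v[[2]])
    }
    zs <- list(z1, z2)
  }
  lapply(seq_len(n_traits), function(t) {
    z <- zs[[t]]
    data.frame(snp = ids, a1 = "A", a2 = "G", n = n_samples[t],
               z = z, chisq = z^2,
               p = 2 * stats::pnorm(-abs(z)), stringsAsFactors = FALSE)
  })
}
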