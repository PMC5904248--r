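#' Select SNPs by association p-value in a reference study
#'
#' Returns the ids of SNPs whose reference p-value is strictly below the
#' threshold. Selecting on the reference study only (never on the cohorts
#' being compared) avoids selection-induced heterogeneity and excludes SNPs
#' whose effect direction is weakly determined.
#'
#' @param reference A `sumstats` frame with columns `snp` and `p`.
#' @param p_threshold Strict upper bound on the reference p-value.
#' @return Character vector of SNP ids.
#' @export
select_snps <- function(reference, p_threshold = 0.001) {
  reference$snp[!is.na(reference$p) & reference$p < p_threshold]
}

#' Cochran's Q heterogeneity test for two effect estimates
#'
#' Fixed-effect heterogeneity statistic: with inverse-variance weights
#' \eqn{w_i = 1/se_i^2} and pooled effect \eqn{\bar\beta = \sum w_i \beta_i /
#' \sum w_i}, \eqn{Q = \sum w_i (\beta_i - \bar\beta)^2} is chi-square with
#' one degree of freedom (two studies) under homogeneity. Vectorized over
#' SNPs.
#'
#' @param beta_1,se_1,beta_2,se_2 Effects and standard errors, aligned to
#'   the same allele.
#' @return A data frame with columns `Q` and `p`.
#' @export
cochran_q <- function(beta_1, se_1, beta_2, se_2) {
  if (any(se_1 <= 0 | se_2 <= 0, na.rm = TRUE))
    stop_config("standard errors must be positive")
  w1 <- 1 / se_1^2; w2 <- 1 / se_2^2
  bbar <- (w1 * beta_1 + w2 * beta_2) / (w1 + w2)
  Q <- w1 * (beta_1 - bbar)^2 + w2 * (beta_2 - bbar)^2
  data.frame(Q = Q, p = stats::pchisq(Q, df = 1, lower.tail = FALSE))
}

#' Genome-wide Cochran's Q heterogeneity scan
#'
#' Selects SNPs with reference association p-value strictly below
#' `p_threshold`, aligns the two cohorts' effects to the same allele,
#' applies [cochran_q()] per SNP, and flags SNPs with Q p-value below the
#' Bonferroni level `alpha / n_tested` (denominator = SNPs actually tested
#' after allele alignment).
#'
#' @param stats_a,stats_b `sumstats` frames with `beta` and `se` columns.
#' @param reference `sumstats` frame used only for SNP selection.
#' @param p_threshold Reference selection threshold (strict `<`).
#' @param alpha Family-wise error level for the Bonferroni cut.
#' @return An object of class `q_scan`: per-SNP table (`snp`, `beta_1`,
#'   `se_1`, `beta_2`, `se_2`, `Q`, `p_q`, `significant`), `n_selected`,
#'   `n_tested`, `bonferroni_alpha`, and the significant id set.
#' @export
q_scan <- function(stats_a, stats_b, reference, p_threshold = 0.001,
                   alpha = 0.05) {
  sel <- select_snps(reference, p_threshold)
  a <- stats_a[stats_a$snp %in% sel, , drop = FALSE]
  al <- align_sumstats(a, stats_b)
  a <- al$ss1; b <- al$ss2
  ok <- is.finite(a$beta) & is.finite(b$beta) &
    is.finite(a$se) & is.finite(b$se) & a$se > 0 & b$se > 0
  a <- a[ok, , drop = FALSE]; b <- b[ok, , drop = FALSE]
  if (!nrow(a)) stop_config("no overlapping selected SNPs between the two cohorts")
  qq <- cochran_q(a$beta, a$se, b$beta, b$se)
  n_tested <- nrow(a)
  bonf <- alpha / n_tested
  tab <- data.frame(snp = a$snp, beta_1 = a$beta, se_1 = a$se,
                    beta_2 = b$beta, se_2 = b$se,
                    Q = qq$Q, p_q = qq$p,
                    significant = qq$p < bonf, stringsAsFactors = FALSE)
  structure(list(table = tab, n_selected = length(sel), n_tested = n_tested,
                 bonferroni_alpha = bonf, alpha = alpha,
                 significant = tab$snp[tab$significant]),
            class = "q_scan")
}

#' @export
print.q_scan <- function(x, ...) {
  cat(sprintf("Cochran's Q scan: %d SNPs selected, %d tested\n",
              x$n_selected, x$n_tested))
  cat(sprintf("Bonferroni level %.3g; %d significant SNP(s)\n",
              x$bonferroni_alpha, length(x$significant)))
  if (length(x$significant)) print(utils::head(
    x$table[x$table$significant, ], 10), row.names = FALSE)
  invisible(x)
}

#' Manhattan-style plot of a heterogeneity scan
#'
#' Plots -log10 of the per-SNP Q-test p-values in SNP order with the
#' Bonferroni-corrected significance level as a horizontal line.
#'
#' @param x A `q_scan` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.q_scan <- function(x, ...) {
  y <- -log10(x$table$p_q)
  graphics::plot(seq_along(y), y, pch = 20, cex = 0.6,
                 xlab = "SNP index", ylab = expression(-log[10](p[Q])),
                 main = "Cochran's Q heterogeneity scan", ...)
  graphics::abline(h = -log10(x$bonferroni_alpha), col = "red")
  invisible(x)
}
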