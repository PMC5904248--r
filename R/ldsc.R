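#' Convert heritability from the observed to the liability scale
#'
#' Case-control GWAS estimate heritability on the observed (0/1) scale, which
#' depends on the population prevalence `K` and the (typically ascertained)
#' sample case fraction `P`. Under the liability-threshold model the
#' observed-scale estimate is rescaled to the liability scale by
#' \deqn{h^2_{liab} = h^2_{obs} \frac{K^2 (1-K)^2}{z^2 P (1-P)}}
#' where `z` is the standard normal density at the liability threshold
#' \eqn{\Phi^{-1}(1-K)}. Standard errors scale by the same factor.
#'
#' @param h2_obs Observed-scale heritability estimate (may be a vector).
#' @param K Population prevalence, in (0, 1).
#' @param P Sample case fraction, in (0, 1).
#' @return Liability-scale heritability, same length as `h2_obs`.
#' @examples
#' h2_observed_to_liability(0.41, K = 0.01, P = 13902 / 33181)
#' @export
h2_observed_to_liability <- function(h2_obs, K, P) {
  h2_obs * liability_factor(K, P)
}

# Multiplicative observed -> liability conversion factor (Lee et al. form).
# Vectorized over P.
liability_factor <- function(K, P) {
  if (!is.numeric(K) || length(K) != 1L || K <= 0 || K >= 1)
    stop_config("prevalence K must lie strictly in (0, 1)")
  if (!is.numeric(P) || any(P <= 0) || any(P >= 1))
    stop_config("case fraction P must lie strictly in (0, 1)")
  thr <- stats::qnorm(1 - K)
  z <- stats::dnorm(thr)
  K^2 * (1 - K)^2 / (z^2 * P * (1 - P))
}

# Merge summary statistics with LD scores on SNP id. `ld` may be a numeric
# vector already aligned to `ss`, or a data.frame with columns snp, l2.
merge_sumstats_ld <- function(ss, ld) {
  ss <- as.data.frame(ss)
  if (is.numeric(ld)) {
    if (length(ld) != nrow(ss))
      stop_config("numeric LD scores must align with sumstats (%d vs %d rows)",
                  length(ld), nrow(ss))
    return(cbind(ss, l2 = as.numeric(ld)))
  }
  ld <- as.data.frame(ld)
  if (!all(c("snp", "l2") %in% names(ld)))
    stop_config("LD score table must have columns 'snp' and 'l2'")
  idx <- match(ss$snp, ld$snp)
  keep <- !is.na(idx)
  if (mean(keep) < 0.5)
    stop_config("fewer than 50%% of sumstats SNPs match the LD score table")
  out <- cbind(ss[keep, , drop = FALSE], l2 = ld$l2[idx[keep]])
  rownames(out) <- NULL
  out
}

# Weighted least squares of y on (1, l); returns per-block cross-products so
# callers can form delete-a-block jackknife estimates cheaply.
ldsc_wls_blocks <- function(y, l, w, n_blocks) {
  M <- length(y)
  blk <- block_index(M, n_blocks)
  x0 <- w
  x1 <- w * l
  A11 <- rowsum(x0, blk); A12 <- rowsum(x1, blk); A22 <- rowsum(w * l * l, blk)
  b1 <- rowsum(w * y, blk); b2 <- rowsum(x1 * y, blk)
  list(blk = blk,
       A = cbind(A11, A12, A22), b = cbind(b1, b2),
       At = c(sum(A11), sum(A12), sum(A22)), bt = c(sum(b1), sum(b2)))
}

solve_2x2 <- function(a11, a12, a22, b1, b2) {
  det <- a11 * a22 - a12 * a12
  c(intercept = (a22 * b1 - a12 * b2) / det,
    slope = (a11 * b2 - a12 * b1) / det)
}

# Two-step heteroskedasticity-weighted LDSC regression of y on l.
# n_equiv is N for the single-trait regression and sqrt(N1 N2) for the
# cross-trait regression; the step-1 fit supplies the variance term used in
# the step-2 weights. Returns full-fit coefficients plus delete-a-block ones.
ldsc_regress <- function(y, l, n_equiv, M, n_blocks) {
  lf <- pmax(l, 1)
  w <- 1 / (2 * lf)
  cp <- ldsc_wls_blocks(y, l, w, n_blocks)
  co <- solve_2x2(cp$At[1], cp$At[2], cp$At[3], cp$bt[1], cp$bt[2])
  s0 <- min(max(co[["slope"]] * M / n_equiv, -1), 1)
  w <- 1 / (2 * lf * (1 + n_equiv * abs(s0) * lf / M)^2)
  cp <- ldsc_wls_blocks(y, l, w, n_blocks)
  co <- solve_2x2(cp$At[1], cp$At[2], cp$At[3], cp$bt[1], cp$bt[2])
  B <- nrow(cp$A)
  del <- matrix(NA_real_, B, 2, dimnames = list(NULL, c("intercept", "slope")))
  for (k in seq_len(B)) {
    del[k, ] <- solve_2x2(cp$At[1] - cp$A[k, 1], cp$At[2] - cp$A[k, 2],
                          cp$At[3] - cp$A[k, 3],
                          cp$bt[1] - cp$b[k, 1], cp$bt[2] - cp$b[k, 2])
  }
  list(intercept = co[["intercept"]], slope = co[["slope"]], delete = del,
       n_blocks = B, weights = w)
}

jackknife_se <- function(theta_del) {
  B <- length(theta_del)
  sqrt((B - 1) / B * sum((theta_del - mean(theta_del))^2))
}

default_n_blocks <- function(M, n_blocks = NULL) {
  if (!is.null(n_blocks)) return(max(2L, as.integer(n_blocks)))
  max(2L, min(200L, floor(M / 50)))
}

#' SNP-based heritability by LD score regression
#'
#' Fits the LD score regression model
#' \deqn{E[\chi^2_j] = \frac{N h^2}{M} \ell_j + a}
#' by two-step heteroskedasticity-weighted least squares: step-1 weights
#' \eqn{1/(2\max(\ell_j,1))}, step-2 weights
#' \eqn{1/(2\max(\ell_j,1)(1 + N h^2_0 \ell_j / M)^2)} with \eqn{h^2_0} the
#' step-1 estimate. The intercept is free and absorbs confounding and
#' population stratification. Standard errors come from a delete-a-block
#' jackknife over contiguous SNP blocks; the p-value is the one-sided normal
#' test of \eqn{h^2 > 0}. Supplying `prevalence` and `case_fraction` adds the
#' liability-scale estimate via [h2_observed_to_liability()].
#'
#' @param sumstats Summary statistics: data frame with columns `snp`, `n`,
#'   and either `z` or `chisq` (see [read_sumstats()]).
#' @param ld LD scores: data frame with columns `snp`, `l2`, or a numeric
#'   vector aligned with `sumstats`.
#' @param M Number of SNPs the heritability is spread over; defaults to the
#'   number of regression SNPs.
#' @param n_blocks Jackknife blocks (default 200, shrunk to `M/50` for small
#'   panels, minimum 2).
#' @param prevalence,case_fraction Population prevalence `K` and sample case
#'   fraction `P` for the liability-scale conversion; both or neither.
#' @param chisq_max Drop SNPs with `chisq` above this before fitting.
#'   Default `max(80, 0.001 N)`; use `Inf` to disable (e.g. for noiseless
#'   closed-form inputs).
#' @return An object of class `ldsc_h2` with components `h2_obs`, `se_obs`,
#'   `h2_liab`, `se_liab`, `intercept`, `intercept_se`, `p_value`, `K`, `P`,
#'   `M`, `N`, `n_blocks`, and the per-SNP regression frame.
#' @seealso [ldsc_rg()], [h2_observed_to_liability()], [simulate_sumstats()]
#' @export
ldsc_h2 <- function(sumstats, ld, M = NULL, n_blocks = NULL,
                    prevalence = NULL, case_fraction = NULL,
                    chisq_max = NULL) {
  d <- merge_sumstats_ld(sumstats, ld)
  if (is.null(d$chisq)) {
    if (is.null(d$z)) stop_config("sumstats need a 'z' or 'chisq' column")
    d$chisq <- d$z^2
  }
  N <- stats::median(d$n)
  if (is.null(chisq_max)) chisq_max <- max(80, 0.001 * N)
  d <- d[is.finite(d$chisq) & d$chisq <= chisq_max, , drop = FALSE]
  if (nrow(d) < 10) stop_config("too few SNPs (%d) for LD score regression", nrow(d))
  M <- M %||% nrow(d)
  n_blocks <- default_n_blocks(nrow(d), n_blocks)

  fit <- ldsc_regress(d$chisq, d$l2, N, M, n_blocks)
  h2 <- fit$slope * M / N
  h2_del <- fit$delete[, "slope"] * M / N
  se <- jackknife_se(h2_del)
  int_se <- jackknife_se(fit$delete[, "intercept"])
  p <- if (se > 0) stats::pnorm(h2 / se, lower.tail = FALSE) else as.numeric(h2 <= 0)

  h2_liab <- se_liab <- NA_real_
  if (!is.null(prevalence) || !is.null(case_fraction)) {
    if (is.null(prevalence) || is.null(case_fraction))
      stop_config("supply both 'prevalence' and 'case_fraction' or neither")
    fac <- liability_factor(prevalence, case_fraction)
    h2_liab <- h2 * fac
    se_liab <- se * fac
  }

  structure(list(
    h2_obs = h2, se_obs = se, h2_liab = h2_liab, se_liab = se_liab,
    intercept = fit$intercept, intercept_se = int_se,
    p_value = p, K = prevalence, P = case_fraction,
    M = M, N = N, n_blocks = fit$n_blocks,
    h2_jackknife = h2_del,
    data = d[, c("snp", "l2", "chisq")]
  ), class = "ldsc_h2")
}

#' One-sided significance test for SNP heritability
#'
#' One-sided normal test of \eqn{h^2 > 0} from the observed-scale estimate
#' and its jackknife standard error. The liability conversion multiplies the
#' estimate and its SE by the same factor, so the p-value is scale-invariant.
#'
#' @param est An `ldsc_h2` object or a list with `h2_obs` and `se_obs`.
#' @return The one-sided p-value.
#' @export
h2_significance <- function(est) {
  stats::pnorm(est$h2_obs / est$se_obs, lower.tail = FALSE)
}

# Align two sumstats frames on SNP id and effect allele. Where the allele
# pair is swapped, z (and beta) of the second study are negated; mismatching
# allele pairs are dropped.
align_sumstats <- function(ss1, ss2) {
  ss1 <- as.data.frame(ss1); ss2 <- as.data.frame(ss2)
  idx <- match(ss1$snp, ss2$snp)
  keep <- !is.na(idx)
  if (!any(keep)) stop_config("no overlapping SNPs between the two sumstats")
  s1 <- ss1[keep, , drop = FALSE]
  s2 <- ss2[idx[keep], , drop = FALSE]
  if (!is.null(s1$a1) && !is.null(s2$a1)) {
    same <- s1$a1 == s2$a1 & s1$a2 == s2$a2
    flip <- s1$a1 == s2$a2 & s1$a2 == s2$a1
    s2$z[flip] <- -s2$z[flip]
    if (!is.null(s2$beta)) s2$beta[flip] <- -s2$beta[flip]
    ok <- same | flip
    s1 <- s1[ok, , drop = FALSE]
    s2 <- s2[ok, , drop = FALSE]
  }
  list(ss1 = s1, ss2 = s2)
}

#' Genetic correlation by cross-trait LD score regression
#'
#' Regresses per-SNP z-score products on LD scores,
#' \deqn{E[z_{1j} z_{2j}] = \frac{\sqrt{N_1 N_2}\,\rho_g}{M} \ell_j + a_c,}
#' to estimate the genetic covariance \eqn{\rho_g}; the genetic correlation is
#' \eqn{r_g = \rho_g / \sqrt{h^2_1 h^2_2}} with per-trait heritabilities from
#' [ldsc_h2()] on the same SNP set. The free cross-trait intercept absorbs
#' sample overlap. The standard error is a delete-a-block jackknife of the
#' full ratio (per-trait slopes and the cross-product slope are all
#' re-estimated in each leave-one-block-out fit); the p-value is the
#' two-sided normal test of \eqn{r_g \ne 0}.
#'
#' If either trait's estimated heritability is non-positive the correlation
#' is undefined and is returned as `NA` with an explanatory `reason`.
#'
#' @param sumstats1,sumstats2 Summary-statistic frames (columns `snp`, `a1`,
#'   `a2`, `n`, `z`). Effect alleles are aligned; swapped allele pairs have
#'   their z sign flipped, mismatches are dropped.
#' @inheritParams ldsc_h2
#' @return An object of class `ldsc_rg` with components `rg`, `se`,
#'   `p_value`, `gencov`, `h2_1`, `h2_2`, `M`, `n_blocks`, `reason`.
#' @export
ldsc_rg <- function(sumstats1, sumstats2, ld, M = NULL, n_blocks = NULL,
                    chisq_max = NULL) {
  al <- align_sumstats(sumstats1, sumstats2)
  d1 <- merge_sumstats_ld(al$ss1, ld)
  d2 <- merge_sumstats_ld(al$ss2, ld)
  N1 <- stats::median(d1$n); N2 <- stats::median(d2$n)
  if (is.null(chisq_max)) chisq_max <- max(80, 0.001 * min(N1, N2))
  ok <- is.finite(d1$z) & is.finite(d2$z) &
    d1$z^2 <= chisq_max & d2$z^2 <= chisq_max
  d1 <- d1[ok, , drop = FALSE]; d2 <- d2[ok, , drop = FALSE]
  Mreg <- nrow(d1)
  if (Mreg < 10) stop_config("too few aligned SNPs (%d) for rg estimation", Mreg)
  M <- M %||% Mreg
  n_blocks <- default_n_blocks(Mreg, n_blocks)
  l <- d1$l2

  f1 <- ldsc_regress(d1$z^2, l, N1, M, n_blocks)
  f2 <- ldsc_regress(d2$z^2, l, N2, M, n_blocks)
  fx <- ldsc_regress(d1$z * d2$z, l, sqrt(N1 * N2), M, n_blocks)

  h2_1 <- f1$slope * M / N1
  h2_2 <- f2$slope * M / N2
  gencov <- fx$slope * M / sqrt(N1 * N2)

  if (h2_1 <= 0 || h2_2 <= 0) {
    return(structure(list(
      rg = NA_real_, se = NA_real_, p_value = NA_real_,
      gencov = gencov, h2_1 = h2_1, h2_2 = h2_2,
      cross_intercept = fx$intercept, M = M, n_blocks = fx$n_blocks,
      reason = "genetic correlation not estimated: non-positive SNP-heritability estimate"
    ), class = "ldsc_rg"))
  }

  rg <- gencov / sqrt(h2_1 * h2_2)
  h1_del <- f1$delete[, "slope"] * M / N1
  h2_del <- f2$delete[, "slope"] * M / N2
  gc_del <- fx$delete[, "slope"] * M / sqrt(N1 * N2)
  denom_ok <- h1_del > 0 & h2_del > 0
  if (mean(denom_ok) >= 0.9) {
    rg_del <- gc_del[denom_ok] / sqrt(h1_del[denom_ok] * h2_del[denom_ok])
    se <- jackknife_se(rg_del)
  } else {
    # ratio jackknife unstable: fall back to rescaled covariance jackknife
    se <- jackknife_se(gc_del) / sqrt(h2_1 * h2_2)
  }
  if (abs(rg) > 1.25)
    warning(sprintf("estimated |rg| = %.2f exceeds 1.25; estimate is noise-dominated", abs(rg)))
  p <- if (se > 0) 2 * stats::pnorm(-abs(rg / se)) else 0

  structure(list(
    rg = rg, se = se, p_value = p, gencov = gencov,
    h2_1 = h2_1, h2_2 = h2_2, cross_intercept = fx$intercept,
    M = M, n_blocks = fx$n_blocks, reason = NA_character_
  ), class = "ldsc_rg")
}

#' @export
print.ldsc_h2 <- function(x, digits = 4, ...) {
  cat("LD score regression: SNP-based heritability\n")
  cat(sprintf("  M = %d SNPs, N = %s, %d jackknife blocks\n",
              x$M, format(x$N), x$n_blocks))
  cat(sprintf("  h2 (observed):  %s (SE %s)\n",
              format(x$h2_obs, digits = digits), format(x$se_obs, digits = digits)))
  if (!is.na(x$h2_liab))
    cat(sprintf("  h2 (liability): %s (SE %s)   [K = %s, P = %s]\n",
                format(x$h2_liab, digits = digits), format(x$se_liab, digits = digits),
                format(x$K), format(x$P, digits = 3)))
  cat(sprintf("  intercept:      %s (SE %s)\n",
              format(x$intercept, digits = digits), format(x$intercept_se, digits = digits)))
  cat(sprintf("  one-sided P(h2 > 0): %s\n", format(x$p_value, digits = 3)))
  invisible(x)
}

#' @export
summary.ldsc_h2 <- function(object, ...) {
  out <- data.frame(
    scale = c("observed", "liability"),
    h2 = c(object$h2_obs, object$h2_liab),
    se = c(object$se_obs, object$se_liab),
    p_value = rep(object$p_value, 2)
  )
  out <- out[!is.na(out$h2), , drop = FALSE]
  attr(out, "intercept") <- c(estimate = object$intercept, se = object$intercept_se)
  out
}

#' @export
coef.ldsc_h2 <- function(object, ...) {
  c(intercept = object$intercept, slope = object$h2_obs * object$N / object$M)
}

#' @export
predict.ldsc_h2 <- function(object, newdata = NULL, ...) {
  l <- if (is.null(newdata)) object$data$l2 else newdata
  object$intercept + object$N * object$h2_obs * l / object$M
}

#' @export
residuals.ldsc_h2 <- function(object, ...) {
  object$data$chisq - predict(object)
}

#' Simulate summary statistics from a fitted heritability model
#'
#' Draws new per-SNP chi-square statistics from the fitted LD score
#' regression model (fitted `h2`, intercept, `N`, `M`, and the LD scores of
#' the regression SNPs), one data frame per replicate.
#'
#' @param object An `ldsc_h2` fit.
#' @param nsim Number of replicates.
#' @param seed Integer seed.
#' @param ... Unused.
#' @export
simulate.ldsc_h2 <- function(object, nsim = 1, seed = 1, ...) {
  l <- object$data$l2
  out <- vector("list", nsim)
  for (i in seq_len(nsim)) {
    ss <- simulate_sumstats(M = length(l), n_samples = object$N,
                            h2 = max(object$h2_obs, 0), ld_scores = l,
                            intercept = object$intercept,
                            seed = derive_seed(seed, i))[[1]]
    ss$snp <- object$data$snp
    out[[i]] <- ss
  }
  out
}

#' @export
print.ldsc_rg <- function(x, digits = 4, ...) {
  cat("Cross-trait LD score regression: genetic correlation\n")
  if (!is.na(x$reason)) {
    cat(sprintf("  rg: NA (%s)\n", x$reason))
    cat(sprintf("  h2 trait 1: %s, h2 trait 2: %s\n",
                format(x$h2_1, digits = digits), format(x$h2_2, digits = digits)))
    return(invisible(x))
  }
  cat(sprintf("  rg = %s (SE %s), two-sided p = %s\n",
              format(x$rg, digits = digits), format(x$se, digits = digits),
              format(x$p_value, digits = 3)))
  cat(sprintf("  genetic covariance %s; h2: %s / %s; %d blocks\n",
              format(x$gencov, digits = digits),
              format(x$h2_1, digits = digits), format(x$h2_2, digits = digits),
              x$n_blocks))
  invisible(x)
}
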