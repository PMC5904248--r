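#' Configuration of the end-to-end validation pipeline
#'
#' Bundles the stage configurations of the full experiment: synthetic EHR
#' population, phenotyping rules and classifier training, genotype
#' architecture, QC thresholds, LDSC and Q-scan settings, and a global seed
#' from which every stage seed is derived. Unknown arguments are rejected.
#'
#' @param n_patients Synthetic EHR population size.
#' @param n_controls Genotyped controls for the case-control panel.
#' @param n_snps,ld_block_size,within_block_r Genotype architecture.
#' @param h2_liability Liability-scale heritability of the trait (both the
#'   EHR trait and the reference-consortium trait).
#' @param rg_true Genetic correlation between the EHR trait and the
#'   reference-consortium trait.
#' @param prevalence Population prevalence K (default 0.01).
#' @param n_batches Genotyping batches.
#' @param missing_rate Per-genotype missingness (gives the QC stage signal).
#' @param reference_n_cases,reference_n_controls Reference consortium cohort.
#' @param nlp_train_n Chart-review-labelled patients for classifier training.
#' @param n_pcs Principal components used as GWAS covariates.
#' @param gwas_method `"score"` (fast, default at pipeline scale) or `"wald"`.
#' @param qscan_p_threshold,qscan_alpha Q-scan selection threshold and
#'   family-wise level.
#' @param n_blocks LDSC jackknife blocks (`NULL` = automatic).
#' @param seed Global seed.
#' @param ehr_overrides,rule_overrides Named lists forwarded to
#'   [ehr_config()] / [rule_config()].
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_patients = 20000, n_controls = 1500,
                            n_snps = 5000, ld_block_size = 25,
                            within_block_r = 0.5,
                            h2_liability = 0.23, rg_true = 0.83,
                            prevalence = 0.01, n_batches = 3,
                            missing_rate = 0.003,
                            reference_n_cases = 2500,
                            reference_n_controls = 2500,
                            nlp_train_n = 400, n_pcs = 2,
                            gwas_method = "score",
                            qscan_p_threshold = 0.001, qscan_alpha = 0.05,
                            n_blocks = NULL, seed = 1,
                            ehr_overrides = list(), rule_overrides = list()) {
  ehr_args <- c(list(n_patients = n_patients, prevalence_bd = prevalence,
                     seed = derive_seed(seed, 1)), ehr_overrides)
  ehr <- do.call(ehr_config, ehr_args)
  rules <- do.call(rule_config, rule_overrides)
  geno <- geno_config(n_snps = n_snps, n_cases = 1, n_controls = 1,
                      ld_block_size = ld_block_size,
                      within_block_r = within_block_r,
                      h2_liability = h2_liability, rg_true = rg_true,
                      prevalence = prevalence, n_batches = n_batches,
                      missing_rate = missing_rate, seed = derive_seed(seed, 2))
  structure(list(ehr = ehr, rules = rules, geno = geno,
                 qc = qc_thresholds(),
                 n_controls = as.integer(n_controls),
                 reference_n_cases = as.integer(reference_n_cases),
                 reference_n_controls = as.integer(reference_n_controls),
                 nlp_train_n = as.integer(nlp_train_n),
                 n_pcs = as.integer(n_pcs),
                 gwas_method = match.arg(gwas_method, c("score", "wald")),
                 qscan_p_threshold = qscan_p_threshold,
                 qscan_alpha = qscan_alpha, n_blocks = n_blocks,
                 seed = as.integer(seed)), class = "pipeline_config")
}

pipeline_cohorts <- function(assign) {
  nlp <- !is.na(assign$nlp95) & assign$nlp95
  list(nlp95 = nlp,
       coded_strict = assign$coded_strict,
       coded_broad = assign$coded_broad,
       coded_broad_sv = assign$coded_broad_sv,
       all = nlp | assign$coded_strict | assign$coded_broad | assign$coded_broad_sv,
       all_except_sv = nlp | assign$coded_strict | assign$coded_broad)
}

# Top principal components of the sample relationship matrix (covariates).
panel_pcs <- function(panel, n_pcs) {
  if (n_pcs < 1) return(NULL)
  X <- panel$dosages
  if (anyNA(X)) {
    mu <- colMeans(X, na.rm = TRUE)
    idx <- which(is.na(X), arr.ind = TRUE)
    X[idx] <- mu[idx[, 2]]
  }
  storage.mode(X) <- "double"
  sds <- apply(X, 2, stats::sd)
  Z <- scale(X[, sds > 0, drop = FALSE])
  K <- tcrossprod(Z) / ncol(Z)
  ev <- eigen(K, symmetric = TRUE)
  pcs <- ev$vectors[, seq_len(n_pcs), drop = FALSE]
  colnames(pcs) <- paste0("PC", seq_len(n_pcs))
  pcs
}

#' Run the full synthetic validation experiment
#'
#' Orchestrates: synthetic EHR generation; phenotyping (coded rules, control
#' rule, adaptive-LASSO classifier trained on a chart-review-labelled
#' subset) with realized PPV against the latent truth; genotype simulation
#' conditioned on each genotyped individual's latent diagnosis (so
#' phenotyping errors become genetic-signal dilution); the QC cascade;
#' per-cohort GWAS with PC covariates; LD score regression heritability
#' (observed and liability scales) and genetic correlation of every cohort
#' against an independently sampled reference-consortium cohort sharing the
#' configured genetic architecture; the pairwise cohort correlation matrix;
#' and a genome-wide Cochran's Q scan of the combined cohort against the
#' reference. All intermediate artifacts are written under `out_dir`
#' (`ehr/`, `phenotype/`, `geno/`, `qc/`, `gwas/`, `ldsc/`, `qscan/`), and
#' `report.json` / `report.md` summarize estimates against the configured
#' truth, flagging any estimate more than 3 SE from it.
#'
#' With `resume = TRUE` the expensive synthetic-EHR stage is reloaded from
#' its artifact when present; every later stage is recomputed
#' deterministically from its stage seed, so a resumed run reproduces the
#' original byte-for-byte.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @param resume Reuse existing stage artifacts when present.
#' @return The report as a list (invisibly also written to disk).
#' @export
run_pipeline <- function(config, out_dir, resume = FALSE) {
  cf <- config
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "pipeline.log")
  logline <- function(stage, msg) {
    cat(sprintf("[%s] %s: %s\n", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                stage, msg), file = log_path, append = TRUE)
  }
  stage_dir <- function(s) {
    d <- file.path(out_dir, s); dir.create(d, showWarnings = FALSE); d
  }
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_config("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }

  # --- stage 1: synthetic EHR
  ehr_dir <- stage_dir("ehr")
  ehr <- run_stage("ehr_sim", {
    if (resume && file.exists(file.path(ehr_dir, "patients.tsv"))) {
      read_ehr_tables(ehr_dir)
    } else {
      e <- generate_ehr(cf$ehr)
      write_ehr_tables(e, ehr_dir)
      e
    }
  })
  logline("ehr_sim", sprintf("%d patients", nrow(ehr$patients)))

  # --- stage 2: phenotyping
  ph_dir <- stage_dir("phenotype")
  ph <- run_stage("phenotyping", {
    dm <- build_datamart(ehr)
    set.seed(derive_seed(cf$seed, 3))
    n_lab <- min(cf$nlp_train_n, nrow(dm$patients))
    lab_idx <- sample.int(nrow(dm$patients), n_lab)
    nlp <- train_nlp95(dm$note_features[lab_idx, , drop = FALSE],
                       dm$patients$latent_true_dx[lab_idx] == "BD",
                       seed = derive_seed(cf$seed, 4))
    assign <- assign_phenotypes(ehr, cf$rules, nlp)
    utils::write.table(assign, file.path(ph_dir, "assignments.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    ppv <- evaluate_ppv(assign, ehr$patients)
    utils::write.table(ppv, file.path(ph_dir, "ppv.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(assign = assign, ppv = ppv, nlp = nlp)
  })
  logline("phenotyping", sprintf("%d case labels",
                                 sum(pipeline_cohorts(ph$assign)$all)))

  # --- stage 3: genotype panel conditioned on latent truth
  geno_dir <- stage_dir("geno")
  panel <- run_stage("geno_sim", {
    coh <- pipeline_cohorts(ph$assign)
    case_ids <- ph$assign$patient_id[coh$all]
    ctrl_pool <- ph$assign$patient_id[ph$assign$control]
    set.seed(derive_seed(cf$seed, 5))
    ctrl_ids <- sample(ctrl_pool, min(cf$n_controls, length(ctrl_pool)))
    ids <- c(case_ids, ctrl_ids)
    latent <- ehr$patients$latent_true_dx[match(ids, ehr$patients$patient_id)]
    true_case <- latent == "BD"
    arch <- genetic_architecture(cf$geno)
    set.seed(derive_seed(cf$seed, 6))
    G <- draw_genotypes_conditional(cf$geno, arch, true_case, trait = 1L)
    n <- nrow(G)
    batch <- rep_len(seq_len(cf$geno$n_batches), n)
    if (cf$geno$missing_rate > 0) {
      miss <- matrix(stats::runif(n * cf$geno$n_snps) < cf$geno$missing_rate, n)
      G[miss] <- NA_integer_
    }
    snp <- data.frame(id = sprintf("rs%06d", seq_len(cf$geno$n_snps)),
                      chrom = 1L, pos = seq_len(cf$geno$n_snps) * 1000L,
                      a1 = "A", a2 = "G", maf = arch$maf, block = arch$blk,
                      stringsAsFactors = FALSE)
    samples <- data.frame(id = ids,
                          status = as.integer(ids %in% case_ids),
                          batch = batch, stringsAsFactors = FALSE)
    rownames(G) <- ids; colnames(G) <- snp$id
    p <- structure(list(dosages = G, snp = snp, samples = samples,
                        truth = list(beta = arch$beta, maf = arch$maf,
                                     true_case = true_case,
                                     config = cf$geno, mode = "conditional")),
                   class = "geno_panel")
    write_panel(p, geno_dir)
    p
  })
  logline("geno_sim", sprintf("%d samples x %d SNPs",
                              nrow(panel$dosages), ncol(panel$dosages)))

  # --- stage 4: QC
  qc_dir <- stage_dir("qc")
  qc <- run_stage("qc", {
    res <- qc_pipeline(panel, cf$qc)
    jsonlite::write_json(
      list(steps = res$report$steps, thresholds = unclass(res$report$thresholds)),
      file.path(qc_dir, "qc_report.json"), auto_unbox = TRUE, digits = NA)
    res
  })
  panel_qc <- qc$panel
  logline("qc", sprintf("%d SNPs, %d samples retained",
                        ncol(panel_qc$dosages), nrow(panel_qc$dosages)))

  # --- stage 5: per-cohort GWAS
  gwas_dir <- stage_dir("gwas")
  coh <- pipeline_cohorts(ph$assign)
  pcs <- run_stage("gwas", panel_pcs(panel_qc, cf$n_pcs))
  sumstats <- run_stage("gwas", {
    out <- list()
    kept <- match(panel_qc$samples$id, ph$assign$patient_id)
    for (nm in names(coh)) {
      is_case <- coh[[nm]][kept]
      is_ctrl <- panel_qc$samples$status == 0
      use <- is_case | is_ctrl
      sub <- subset_panel(panel_qc, samples = use)
      ss <- run_gwas(sub, phenotype = as.integer(is_case[use]),
                     covariates = if (is.null(pcs)) NULL else
                       pcs[use, , drop = FALSE],
                     method = cf$gwas_method, cohort = nm)
      write_sumstats(ss, file.path(gwas_dir, paste0(nm, ".sumstats")))
      out[[nm]] <- ss
    }
    out
  })
  logline("gwas", sprintf("%d cohorts", length(sumstats)))

  # --- stage 6: reference consortium cohort (trait 2, shared architecture)
  ref_dir <- stage_dir("reference")
  ref <- run_stage("reference", {
    arch <- genetic_architecture(cf$geno)
    set.seed(derive_seed(cf$seed, 7))
    tc <- rep(c(TRUE, FALSE), c(cf$reference_n_cases, cf$reference_n_controls))
    G <- draw_genotypes_conditional(cf$geno, arch, tc, trait = 2L)
    snp <- panel$snp
    samples <- data.frame(id = sprintf("R%05d", seq_along(tc)),
                          status = as.integer(tc), batch = 1L,
                          stringsAsFactors = FALSE)
    rownames(G) <- samples$id; colnames(G) <- snp$id
    rp <- structure(list(dosages = G, snp = snp, samples = samples,
                         truth = NULL), class = "geno_panel")
    ss <- run_gwas(rp, method = cf$gwas_method, cohort = "reference")
    write_sumstats(ss, file.path(ref_dir, "reference.sumstats"))
    ss
  })

  # --- stage 7: LD scores + LDSC
  ldsc_dir <- stage_dir("ldsc")
  ld <- run_stage("ld_scores", compute_ld_scores(panel_qc))
  utils::write.table(ld, file.path(ldsc_dir, "ld_scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  Mqc <- nrow(ld)
  K <- cf$geno$prevalence
  h2_tab <- run_stage("ldsc_h2", {
    rows <- lapply(names(sumstats), function(nm) {
      ss <- sumstats[[nm]]
      n_case <- sum(coh[[nm]][match(panel_qc$samples$id, ph$assign$patient_id)],
                    na.rm = TRUE)
      n_ctrl <- sum(panel_qc$samples$status == 0)
      fit <- ldsc_h2(ss, ld, M = Mqc, n_blocks = cf$n_blocks,
                     prevalence = K, case_fraction = n_case / (n_case + n_ctrl))
      data.frame(cohort = nm, n_cases = n_case, n_controls = n_ctrl,
                 h2_obs = fit$h2_obs, se_obs = fit$se_obs,
                 h2_liab = fit$h2_liab, se_liab = fit$se_liab,
                 intercept = fit$intercept, p_value = fit$p_value,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  rg_tab <- run_stage("ldsc_rg", {
    rows <- lapply(names(sumstats), function(nm) {
      fit <- ldsc_rg(sumstats[[nm]], ref, ld, M = Mqc, n_blocks = cf$n_blocks)
      data.frame(cohort = nm, rg = fit$rg, se = fit$se, p_value = fit$p_value,
                 reason = fit$reason, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  pair_rg <- run_stage("pairwise_rg",
                       pairwise_rg_matrix(sumstats[c("nlp95", "coded_strict",
                                                     "coded_broad",
                                                     "coded_broad_sv")],
                                          ld, M = Mqc, n_blocks = cf$n_blocks))
  utils::write.table(h2_tab, file.path(ldsc_dir, "h2.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(rg_tab, file.path(ldsc_dir, "rg_vs_reference.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  logline("ldsc", "h2 and rg tables written")

  # --- stage 8: Q scan (combined cohort vs reference)
  qs_dir <- stage_dir("qscan")
  qscan <- run_stage("q_scan", {
    q <- q_scan(sumstats$all_except_sv, ref, ref,
                p_threshold = cf$qscan_p_threshold, alpha = cf$qscan_alpha)
    utils::write.table(q$table, file.path(qs_dir, "qscan.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    q
  })

  # --- report
  truth_h2 <- cf$geno$h2_liability[1]
  h2_tab$flag_3se <- abs(h2_tab$h2_liab - truth_h2) > 3 * h2_tab$se_liab
  rg_tab$flag_3se <- !is.na(rg_tab$rg) &
    abs(rg_tab$rg - cf$geno$rg_true) > 3 * rg_tab$se
  report <- list(
    config = list(seed = cf$seed, n_patients = cf$ehr$n_patients,
                  n_snps = cf$geno$n_snps,
                  h2_liability_true = truth_h2, rg_true = cf$geno$rg_true,
                  prevalence = K),
    ppv = ph$ppv,
    qc_steps = qc$report$steps,
    h2 = h2_tab,
    rg_vs_reference = rg_tab,
    pairwise_rg = list(rg = pair_rg$rg, se = pair_rg$se),
    qscan = list(n_selected = qscan$n_selected, n_tested = qscan$n_tested,
                 bonferroni_alpha = qscan$bonferroni_alpha,
                 n_significant = length(qscan$significant)))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       dataframe = "rows")
  write_report_md(report, file.path(out_dir, "report.md"))
  logline("report", "written")
  invisible(report)
}

write_report_md <- function(report, path) {
  md_table <- function(d) {
    d <- as.data.frame(d)
    num <- vapply(d, is.numeric, logical(1))
    d[num] <- lapply(d[num], function(x) signif(x, 4))
    c(paste0("| ", paste(names(d), collapse = " | "), " |"),
      paste0("|", paste(rep("---", ncol(d)), collapse = "|"), "|"),
      apply(d, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |")))
  }
  lines <- c("# Synthetic EHR genetic-validation report", "",
             sprintf("Configured truth: liability h2 = %s, rg = %s, prevalence = %s",
                     report$config$h2_liability_true, report$config$rg_true,
                     report$config$prevalence), "",
             "## Phenotyping PPV (against latent truth)", "",
             md_table(report$ppv), "",
             "## SNP-based heritability per cohort", "",
             md_table(report$h2), "",
             "## Genetic correlation vs reference consortium", "",
             md_table(report$rg_vs_reference), "",
             "## Cochran's Q scan", "",
             sprintf("%d SNPs selected, %d tested, %d significant at Bonferroni level %.3g",
                     report$qscan$n_selected, report$qscan$n_tested,
                     report$qscan$n_significant, report$qscan$bonferroni_alpha))
  writeLines(lines, path)
  invisible(path)
}

#' Pairwise genetic correlation matrix across cohorts
#'
#' Symmetric matrix of [ldsc_rg()] estimates across a list of summary
#' statistics; the diagonal is 1 by definition, entries where either
#' trait's heritability estimate is non-positive are `NA`.
#'
#' @param sumstats_list Named list of `sumstats` frames.
#' @param ld LD scores shared by all cohorts.
#' @param M SNP count for the regressions.
#' @param n_blocks Jackknife blocks.
#' @return A list with matrices `rg` and `se`.
#' @export
pairwise_rg_matrix <- function(sumstats_list, ld, M = NULL, n_blocks = NULL) {
  k <- length(sumstats_list)
  nms <- names(sumstats_list) %||% paste0("cohort", seq_len(k))
  rg <- matrix(NA_real_, k, k, dimnames = list(nms, nms))
  se <- matrix(NA_real_, k, k, dimnames = list(nms, nms))
  diag(rg) <- 1; diag(se) <- 0
  if (k > 1) {
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      fit <- ldsc_rg(sumstats_list[[i]], sumstats_list[[j]], ld,
                     M = M, n_blocks = n_blocks)
      rg[i, j] <- rg[j, i] <- fit$rg
      se[i, j] <- se[j, i] <- fit$se
    }
  }
  list(rg = rg, se = se)
}
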