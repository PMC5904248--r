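# Hand-built EHR fixtures for rule tracing. Builds a one-patient ehr_set
# from compact event descriptions.
tiny_ehr <- function(codes = list(), meds = list(), encounters = NULL,
                     birth_date = "1960-06-01", latent = "BD",
                     clinic = "general_psych") {
  # codes: list of c(date, icd9[, encounter_id]); meds: list of c(date, class)
  if (is.null(encounters)) {
    if (length(codes)) {
      dates <- vapply(codes, `[`, character(1), 1)
      encounters <- data.frame(
        encounter_id = vapply(codes, function(x)
          if (length(x) >= 3) x[3] else paste0("E_", x[1]), character(1)),
        patient_id = "P1", start_date = as.Date(dates),
        end_date = as.Date(dates), setting = "outpatient",
        clinic_type = clinic, stringsAsFactors = FALSE)
      encounters <- encounters[!duplicated(encounters$encounter_id), ]
    } else {
      encounters <- data.frame(
        encounter_id = "E0", patient_id = "P1",
        start_date = as.Date("2005-01-01"), end_date = as.Date("2005-01-01"),
        setting = "outpatient", clinic_type = "primary_care",
        stringsAsFactors = FALSE)
    }
  }
  diagnoses <- if (length(codes)) data.frame(
    patient_id = "P1",
    date = as.Date(vapply(codes, `[`, character(1), 1)),
    icd9_code = vapply(codes, `[`, character(1), 2),
    encounter_id = vapply(codes, function(x)
      if (length(x) >= 3) x[3] else paste0("E_", x[1]), character(1)),
    stringsAsFactors = FALSE)
  else data.frame(patient_id = character(0), date = as.Date(character(0)),
                  icd9_code = character(0), encounter_id = character(0))
  medications <- if (length(meds)) data.frame(
    patient_id = "P1",
    date = as.Date(vapply(meds, `[`, character(1), 1)),
    drug_name = vapply(meds, `[`, character(1), 2),
    drug_class = vapply(meds, `[`, character(1), 2),
    stringsAsFactors = FALSE)
  else data.frame(patient_id = character(0), date = as.Date(character(0)),
                  drug_name = character(0), drug_class = character(0))
  structure(list(
    patients = data.frame(patient_id = "P1",
                          birth_date = as.Date(birth_date),
                          latent_true_dx = latent, stringsAsFactors = FALSE),
    encounters = encounters, diagnoses = diagnoses, medications = medications,
    note_features = matrix(0, 1, 3, dimnames = list("P1", paste0("f", 1:3))),
    config = NULL), class = "ehr_set")
}

# Minimal geno_panel from a dosage matrix.
panel_from_matrix <- function(G, status = NULL, batch = NULL, maf = NULL) {
  n <- nrow(G); M <- ncol(G)
  snp <- data.frame(id = sprintf("rs%06d", seq_len(M)), chrom = 1L,
                    pos = seq_len(M) * 1000L, a1 = "A", a2 = "G",
                    stringsAsFactors = FALSE)
  if (!is.null(maf)) snp$maf <- maf
  samples <- data.frame(id = sprintf("S%05d", seq_len(n)),
                        status = status %||% rep(0L, n),
                        batch = batch %||% rep(1L, n),
                        stringsAsFactors = FALSE)
  rownames(G) <- samples$id; colnames(G) <- snp$id
  structure(list(dosages = G, snp = snp, samples = samples, truth = NULL),
            class = "geno_panel")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Full-enumeration Hardy-Weinberg exact oracle (independent of the package
# implementation): enumerates every heterozygote configuration conditional
# on the allele counts via factorial probabilities.
oracle_hwe <- function(counts) {
  n <- sum(counts)
  n1 <- 2 * counts[3] + counts[2]
  n2 <- 2 * counts[1] + counts[2]
  if (min(n1, n2) == 0) return(1.0)
  hs <- seq(min(n1, n2) %% 2, min(n1, n2), 2)
  pr <- vapply(hs, function(h) {
    ha <- (n1 - h) / 2; hr <- (n2 - h) / 2
    exp(lfactorial(n) - lfactorial(hr) - lfactorial(h) - lfactorial(ha) +
          h * log(2) + lfactorial(n1) + lfactorial(n2) - lfactorial(2 * n))
  }, numeric(1))
  po <- pr[hs == counts[2]]
  sum(pr[pr <= po + 1e-12])
}

# Summary statistics triple sharing true per-SNP effects: a reference with
# small sampling error plus two cohorts with independent noise. Used for
# heterogeneity-scan null calibration.
shared_effect_sumstats <- function(M, tau = 0.05, se_ref = 0.005,
                                   se_ab = 0.02, seed = 1) {
  set.seed(seed)
  b <- rnorm(M, 0, tau)
  mk <- function(bh, se) {
    z <- bh / se
    data.frame(snp = sprintf("rs%06d", seq_len(M)), a1 = "A", a2 = "G",
               n = 10000, beta = bh, se = se, z = z, chisq = z^2,
               p = 2 * pnorm(-abs(z)), stringsAsFactors = FALSE)
  }
  list(ref = mk(b + rnorm(M, 0, se_ref), se_ref),
       a = mk(b + rnorm(M, 0, se_ab), se_ab),
       b = mk(b + rnorm(M, 0, se_ab), se_ab))
}
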