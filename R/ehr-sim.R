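# Code vocabularies for the synthetic EHR. ICD-9 bipolar/manic codes are the
# 296.0*-296.1* (manic) and 296.4*-296.8* (bipolar) ranges; 296.2*/296.3*
# (major depression) are deliberately present as confusers.
BD_CODES <- c("296.0", "296.10", "296.40", "296.44", "296.5",
              "296.62", "296.7", "296.80", "296.89")
OTHER_PSYCH_CODES <- c("296.2", "296.30", "295.1", "295.3",
                       "300.00", "300.4", "311")
NON_PSYCH_CODES <- c("401.1", "250.00", "786.2", "729.5")

MED_VOCAB <- list(
  lithium = "lithium",
  valproate = "valproate",
  carbamazepine = "carbamazepine",
  atypical_antipsychotic = c("risperidone", "olanzapine", "quetiapine",
                             "aripiprazole", "ziprasidone"),
  antidepressant = c("fluoxetine", "sertraline", "citalopram"),
  anxiolytic = c("lorazepam", "clonazepam"),
  antihypertensive = "lisinopril",
  statin = "atorvastatin")

#' Configuration for the synthetic EHR generator
#'
#' Parameters of the longitudinal-record generator with latent diagnostic
#' truth. Each patient carries a hidden label in `{BD, OTHER_PSYCH, NONE}`;
#' coded diagnoses, medication orders, encounter structure and note features
#' are drawn conditional on it. Two diagnostic-error mechanisms scale with
#' `coding_noise`: per-encounter miscoding, and two chronically ambiguous
#' patient subtypes among the other-psychiatric group — a "BD-like"
#' subtype whose record resembles a bipolar patient's (polluting the coded
#' algorithms), and a "single-visit mimic" whose record holds one rule-out
#' episode with two bipolar codes and mood-stabilizer plus antipsychotic
#' orders (polluting only the single-visit relaxation). These mechanisms are
#' what make the phenotyping algorithms' positive predictive values fall
#' below 1 in a structured way, with the single-visit algorithm near 0.5.
#'
#' @param n_patients Number of patients (>= 1).
#' @param prevalence_bd Latent bipolar-disorder prevalence (default 0.01).
#' @param p_other_psych Latent other-psychiatric prevalence (default 0.10).
#' @param seed Integer master seed; each patient gets a child stream derived
#'   from `(seed, patient index)`, so records are stable when `n_patients`
#'   grows.
#' @param date_range Two `Date`s (or strings) bounding all events.
#' @param mean_encounters Mean encounters per patient (>= 1).
#' @param coding_noise Probability a true-BD encounter emits a non-BD
#'   psychiatric code (and, scaled, vice versa); also scales the ambiguous
#'   subtype frequencies (`0.25 x` BD-like, `0.7 x` single-visit mimic).
#' @param med_adherence Probability a true case receives lithium/valproate.
#' @param sparse_bd_prob Probability a true-BD record is a single episode
#'   (captured only by the single-visit relaxation).
#' @param atypical_bd_prob,carbamazepine_bd_prob Additional medication-class
#'   probabilities for true cases.
#' @param clinic_bd_prob Per-encounter probability a BD(-like) patient is
#'   seen at a bipolar specialty clinic.
#' @param n_note_features Length of the note-feature vector.
#' @param n_informative Leading features carrying class signal.
#' @param feature_effect_size Per-feature mean shift for true cases
#'   (class-conditional Gaussian surrogates for NLP-extracted counts); the
#'   default gives a single-index separation of about 2.1 SD, i.e. an
#'   oracle AUC near 0.93.
#' @return A list of class `ehr_config`.
#' @export
ehr_config <- function(n_patients, prevalence_bd = 0.01, p_other_psych = 0.10,
                       seed = 1,
                       date_range = c("2000-01-01", "2015-12-31"),
                       mean_encounters = 8, coding_noise = 0.10,
                       med_adherence = 0.85, sparse_bd_prob = 0.15,
                       atypical_bd_prob = 0.65, carbamazepine_bd_prob = 0.15,
                       clinic_bd_prob = 0.25,
                       n_note_features = 50, n_informative = 10,
                       feature_effect_size = 0.66) {
  assert_count(n_patients, "n_patients")
  assert_prob(prevalence_bd, "prevalence_bd")
  assert_prob(p_other_psych, "p_other_psych")
  assert_prob(coding_noise, "coding_noise")
  assert_prob(med_adherence, "med_adherence")
  assert_prob(sparse_bd_prob, "sparse_bd_prob")
  assert_prob(clinic_bd_prob, "clinic_bd_prob")
  if (prevalence_bd + p_other_psych > 1)
    stop_config("prevalence_bd + p_other_psych must not exceed 1")
  dr <- as.Date(date_range)
  if (anyNA(dr) || length(dr) != 2 || dr[1] > dr[2])
    stop_config("date_range must be two valid dates with start <= end")
  if (mean_encounters < 1) stop_config("mean_encounters must be >= 1")
  if (feature_effect_size < 0) stop_config("feature_effect_size must be nonnegative")
  structure(list(
    n_patients = as.integer(n_patients), prevalence_bd = prevalence_bd,
    p_other_psych = p_other_psych, seed = as.integer(seed), date_range = dr,
    mean_encounters = mean_encounters, coding_noise = coding_noise,
    med_adherence = med_adherence, sparse_bd_prob = sparse_bd_prob,
    atypical_bd_prob = atypical_bd_prob,
    carbamazepine_bd_prob = carbamazepine_bd_prob,
    clinic_bd_prob = clinic_bd_prob,
    n_note_features = as.integer(n_note_features),
    n_informative = as.integer(min(n_informative, n_note_features)),
    feature_effect_size = feature_effect_size), class = "ehr_config")
}

pick <- function(x) if (length(x) == 1) x else x[sample.int(length(x), 1)]

#' Generate a synthetic longitudinal EHR population
#'
#' Draws `n_patients` patient records under an [ehr_config()]: latent truth,
#' encounters with setting and clinic type, coded diagnoses, medication
#' orders, and a note-feature vector. Deterministic given the config
#' (including its seed); patient `i`'s record depends only on
#' `(seed, i)`, so prefixes of larger populations reproduce smaller ones.
#'
#' @param config An [ehr_config()].
#' @return A list of class `ehr_set` with data frames `patients` (including
#'   the hidden `latent_true_dx`), `encounters`, `diagnoses`, `medications`,
#'   a `note_features` matrix (rows = patients), and the `config`.
#' @export
generate_ehr <- function(config) {
  cf <- config
  n <- cf$n_patients
  day0 <- as.integer(cf$date_range[1])
  day1 <- as.integer(cf$date_range[2])
  span <- max(day1 - day0, 1L)
  p_bdlike <- 0.25 * cf$coding_noise
  p_mimic <- 0.7 * cf$coding_noise

  pat_id <- sprintf("P%06d", seq_len(n))
  birth <- integer(n); latent <- character(n)
  enc <- list(); dx <- list(); med <- list()
  feats <- matrix(0, n, cf$n_note_features,
                  dimnames = list(pat_id, sprintf("f%03d", seq_len(cf$n_note_features))))
  mu_dir <- c(rep(1, cf$n_informative),
              rep(0, cf$n_note_features - cf$n_informative))

  for (i in seq_len(n)) {
    set.seed(derive_seed(cf$seed, i))
    age0 <- stats::runif(1, 18, 80)
    birth[i] <- day0 - as.integer(round(age0 * 365.25))
    u <- stats::runif(1)
    lt <- if (u < cf$prevalence_bd) "BD" else
      if (u < cf$prevalence_bd + cf$p_other_psych) "OTHER_PSYCH" else "NONE"
    latent[i] <- lt
    subtype <- "plain"
    if (lt == "OTHER_PSYCH") {
      v <- stats::runif(1)
      subtype <- if (v < p_bdlike) "bdlike" else
        if (v < p_bdlike + p_mimic) "mimic" else "plain"
    }
    sparse <- lt == "BD" && stats::runif(1) < cf$sparse_bd_prob

    n_enc <- if (sparse) 1L else 1L + stats::rpois(1, cf$mean_encounters - 1)
    days <- sort(sample.int(span, n_enc, replace = FALSE)) + day0 - 1L
    inpat <- stats::runif(n_enc) < ifelse(lt == "NONE", 0.05, 0.15)
    if (sparse) inpat[1] <- TRUE
    mimic_enc <- if (subtype == "mimic") 1L else 0L
    if (mimic_enc) inpat[1] <- TRUE
    e_end <- days + ifelse(inpat, sample.int(14, n_enc, replace = TRUE), 0L)
    clinic <- rep("primary_care", n_enc)
    if (lt == "BD" || subtype == "bdlike") {
      clinic <- ifelse(stats::runif(n_enc) < cf$clinic_bd_prob,
                       "bipolar_specialty", "general_psych")
    } else if (lt == "OTHER_PSYCH") {
      clinic <- rep("general_psych", n_enc)
      if (subtype == "mimic" && n_enc > 1)
        clinic[-1] <- "primary_care"
    }
    eid <- sprintf("%s_E%02d", pat_id[i], seq_len(n_enc))

    # coded diagnoses
    d_code <- character(0); d_day <- integer(0); d_eid <- character(0)
    emit <- function(code, day, id) {
      d_code <<- c(d_code, code); d_day <<- c(d_day, day); d_eid <<- c(d_eid, id)
    }
    if (lt == "BD") {
      for (k in seq_len(n_enc)) {
        if (sparse && k == 1L) {
          nrep <- 2L + (stats::runif(1) < 0.5)
          for (r in seq_len(nrep)) emit(pick(BD_CODES), days[k], eid[k])
        } else if (stats::runif(1) < 1 - cf$coding_noise) {
          emit(pick(BD_CODES), days[k], eid[k])
        } else {
          emit(pick(OTHER_PSYCH_CODES), days[k], eid[k])
        }
      }
    } else if (lt == "OTHER_PSYCH") {
      if (subtype == "mimic") {
        emit(pick(BD_CODES), days[1], eid[1])
        emit(pick(BD_CODES), days[1], eid[1])
        for (k in seq_len(n_enc)[-1]) {
          if (stats::runif(1) < 0.3) emit(pick(NON_PSYCH_CODES), days[k], eid[k])
        }
      } else if (subtype == "bdlike") {
        for (k in seq_len(n_enc)) {
          code <- if (stats::runif(1) < 0.7) pick(BD_CODES) else pick(OTHER_PSYCH_CODES)
          emit(code, days[k], eid[k])
        }
      } else {
        for (k in seq_len(n_enc)) {
          code <- if (stats::runif(1) < cf$coding_noise) pick(BD_CODES) else
            pick(OTHER_PSYCH_CODES)
          emit(code, days[k], eid[k])
        }
      }
    } else {
      for (k in seq_len(n_enc)) {
        if (stats::runif(1) < 0.5) emit(pick(NON_PSYCH_CODES), days[k], eid[k])
      }
    }

    # medication orders
    m_drug <- character(0); m_class <- character(0); m_day <- integer(0)
    order_med <- function(class, day) {
      m_drug <<- c(m_drug, pick(MED_VOCAB[[class]]))
      m_class <<- c(m_class, class); m_day <<- c(m_day, day)
    }
    bd_days <- d_day[is_bd_code(d_code)]
    first_bd <- if (length(bd_days)) min(bd_days) else NA_integer_
    if (lt == "BD") {
      anchor <- if (is.na(first_bd)) days[1] else first_bd
      if (stats::runif(1) < cf$med_adherence)
        order_med(if (stats::runif(1) < 0.6) "lithium" else "valproate",
                  anchor + sample.int(300, 1) - 1L)
      if (stats::runif(1) < cf$atypical_bd_prob)
        order_med("atypical_antipsychotic", anchor + sample.int(400, 1) - 1L)
      if (stats::runif(1) < cf$carbamazepine_bd_prob)
        order_med("carbamazepine", anchor + sample.int(400, 1) - 1L)
    } else if (subtype == "bdlike") {
      anchor <- if (is.na(first_bd)) days[1] else first_bd
      if (stats::runif(1) < 0.5) order_med("valproate", anchor + sample.int(300, 1) - 1L)
      if (stats::runif(1) < 0.15) order_med("lithium", anchor + sample.int(300, 1) - 1L)
      if (stats::runif(1) < 0.6) order_med("atypical_antipsychotic",
                                           anchor + sample.int(400, 1) - 1L)
    } else if (subtype == "mimic") {
      if (stats::runif(1) < 0.85) order_med("valproate", days[1])
      if (stats::runif(1) < 0.85) order_med("atypical_antipsychotic", days[1])
    } else if (lt == "OTHER_PSYCH") {
      if (stats::runif(1) < 0.7) order_med("antidepressant", days[1] + sample.int(200, 1))
      if (stats::runif(1) < 0.3) order_med("anxiolytic", days[1] + sample.int(200, 1))
      if (stats::runif(1) < 0.25) order_med("atypical_antipsychotic",
                                            days[1] + sample.int(200, 1))
      if (stats::runif(1) < 0.05) order_med("valproate", days[1] + sample.int(200, 1))
    } else {
      if (stats::runif(1) < 0.3) order_med("antihypertensive", days[1])
      if (stats::runif(1) < 0.2) order_med("statin", days[1])
    }

    shift <- switch(lt, BD = cf$feature_effect_size,
                    OTHER_PSYCH = switch(subtype, bdlike = 0.3 * cf$feature_effect_size,
                                         mimic = 0.15 * cf$feature_effect_size, 0),
                    0)
    feats[i, ] <- stats::rnorm(cf$n_note_features) + shift * mu_dir

    enc[[i]] <- list(eid, rep(pat_id[i], n_enc), days, e_end,
                     ifelse(inpat, "inpatient", "outpatient"), clinic)
    ord <- order(d_day)
    dx[[i]] <- list(rep(pat_id[i], length(d_code)), d_day[ord], d_code[ord], d_eid[ord])
    med[[i]] <- list(rep(pat_id[i], length(m_drug)),
                     pmin(m_day, day1), m_drug, m_class)
  }

  cat_col <- function(lst, k) unlist(lapply(lst, `[[`, k), use.names = FALSE)
  encounters <- data.frame(
    encounter_id = cat_col(enc, 1), patient_id = cat_col(enc, 2),
    start_date = as.Date(cat_col(enc, 3), origin = "1970-01-01"),
    end_date = as.Date(cat_col(enc, 4), origin = "1970-01-01"),
    setting = cat_col(enc, 5), clinic_type = cat_col(enc, 6),
    stringsAsFactors = FALSE)
  diagnoses <- data.frame(
    patient_id = cat_col(dx, 1),
    date = as.Date(cat_col(dx, 2), origin = "1970-01-01"),
    icd9_code = cat_col(dx, 3), encounter_id = cat_col(dx, 4),
    stringsAsFactors = FALSE)
  medications <- data.frame(
    patient_id = cat_col(med, 1),
    date = as.Date(cat_col(med, 2), origin = "1970-01-01"),
    drug_name = cat_col(med, 3), drug_class = cat_col(med, 4),
    stringsAsFactors = FALSE)
  patients <- data.frame(
    patient_id = pat_id,
    birth_date = as.Date(birth, origin = "1970-01-01"),
    latent_true_dx = latent, stringsAsFactors = FALSE)

  structure(list(patients = patients, encounters = encounters,
                 diagnoses = diagnoses, medications = medications,
                 note_features = feats, config = cf),
            class = "ehr_set")
}

#' @export
print.ehr_set <- function(x, ...) {
  cat(sprintf("Synthetic EHR set: %d patients, %d encounters, %d diagnoses, %d medication orders\n",
              nrow(x$patients), nrow(x$encounters), nrow(x$diagnoses),
              nrow(x$medications)))
  if (!is.null(x$patients$latent_true_dx))
    print(table(latent = x$patients$latent_true_dx))
  invisible(x)
}

# Bipolar/manic ICD-9 ranges: 296.0*-296.1* and 296.4*-296.8*, by string
# prefix on the first digit after "296."
is_bd_code <- function(code) {
  startsWith(code, "296.") &
    substr(code, 5, 5) %in% c("0", "1", "4", "5", "6", "7", "8")
}

icd_major <- function(code) suppressWarnings(as.integer(substr(code, 1, 3)))

is_psych_code <- function(code) {
  m <- icd_major(code)
  !is.na(m) & m >= 290 & m <= 319
}

is_psych_or_neuro_code <- function(code) {
  m <- icd_major(code)
  !is.na(m) & m >= 290 & m <= 359
}

#' Restrict an EHR set to the bipolar datamart
#'
#' Keeps patients with at least one diagnosis code in the bipolar
#' (296.4*-296.8*) or manic (296.0*-296.1*) ICD-9 ranges, matching by string
#' prefix on the first digit after "296." (so "296.4" matches "296.4",
#' "296.40", "296.44"). Idempotent.
#'
#' @param ehr An `ehr_set`.
#' @return The filtered `ehr_set`.
#' @export
build_datamart <- function(ehr) {
  hit <- unique(ehr$diagnoses$patient_id[is_bd_code(ehr$diagnoses$icd9_code)])
  keep <- ehr$patients$patient_id %in% hit
  subset_ehr(ehr, keep)
}

subset_ehr <- function(ehr, keep) {
  ids <- ehr$patients$patient_id[keep]
  out <- ehr
  out$patients <- ehr$patients[keep, , drop = FALSE]
  out$encounters <- ehr$encounters[ehr$encounters$patient_id %in% ids, , drop = FALSE]
  out$diagnoses <- ehr$diagnoses[ehr$diagnoses$patient_id %in% ids, , drop = FALSE]
  out$medications <- ehr$medications[ehr$medications$patient_id %in% ids, , drop = FALSE]
  if (!is.null(ehr$note_features))
    out$note_features <- ehr$note_features[keep, , drop = FALSE]
  rownames(out$patients) <- rownames(out$encounters) <-
    rownames(out$diagnoses) <- rownames(out$medications) <- NULL
  out
}

#' Write an EHR set as delimited-text tables
#'
#' One UTF-8 tab-separated table per entity: `patients.tsv` (without the
#' latent label), `encounters.tsv`, `diagnoses.tsv`, `medications.tsv`,
#' `note_features.tsv`, and the withheld-truth file `truth.tsv` holding
#' `patient_id` and `latent_true_dx`. Dates are ISO-8601.
#'
#' @param ehr An `ehr_set`.
#' @param directory Output directory (created if needed).
#' @export
write_ehr_tables <- function(ehr, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  w <- function(d, f) utils::write.table(
    d, file.path(directory, f), sep = "\t", quote = FALSE, row.names = FALSE,
    fileEncoding = "UTF-8")
  pat <- ehr$patients
  w(data.frame(patient_id = pat$patient_id,
               birth_date = as.character(pat$birth_date)), "patients.tsv")
  enc <- ehr$encounters
  enc$start_date <- as.character(enc$start_date)
  enc$end_date <- as.character(enc$end_date)
  w(enc, "encounters.tsv")
  dx <- ehr$diagnoses; dx$date <- as.character(dx$date)
  w(dx, "diagnoses.tsv")
  md <- ehr$medications; md$date <- as.character(md$date)
  w(md, "medications.tsv")
  nf <- data.frame(patient_id = pat$patient_id, ehr$note_features,
                   check.names = FALSE)
  w(nf, "note_features.tsv")
  if (!is.null(pat$latent_true_dx))
    w(data.frame(patient_id = pat$patient_id,
                 latent_true_dx = pat$latent_true_dx), "truth.tsv")
  invisible(directory)
}

#' Read an EHR set from delimited-text tables
#'
#' Inverse of [write_ehr_tables()]. The truth file is optional: when absent,
#' `latent_true_dx` is left unset. A diagnosis row referencing an unknown
#' encounter id is a parse error naming the row.
#'
#' @param directory Directory holding the tables.
#' @return An `ehr_set`.
#' @export
read_ehr_tables <- function(directory) {
  rd <- function(f, colClasses = NA) {
    path <- file.path(directory, f)
    if (!file.exists(path)) stop_config("missing EHR table file: %s", f)
    utils::read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE, check.names = FALSE,
                      colClasses = colClasses)
  }
  patients <- rd("patients.tsv")
  encounters <- rd("encounters.tsv")
  # ICD codes are strings ("296.40" is not the number 296.4)
  diagnoses <- rd("diagnoses.tsv", c(icd9_code = "character"))
  medications <- rd("medications.tsv")
  nf <- rd("note_features.tsv")
  patients$birth_date <- as.Date(patients$birth_date)
  if (anyNA(patients$birth_date)) stop_config("malformed birth_date in patients.tsv")
  encounters$start_date <- as.Date(encounters$start_date)
  encounters$end_date <- as.Date(encounters$end_date)
  diagnoses$date <- as.Date(diagnoses$date)
  diagnoses$icd9_code <- as.character(diagnoses$icd9_code)
  medications$date <- as.Date(medications$date)
  bad <- which(!diagnoses$encounter_id %in% encounters$encounter_id)
  if (length(bad))
    stop_config("diagnoses.tsv row %d references unknown encounter_id '%s'",
                bad[1], diagnoses$encounter_id[bad[1]])
  feats <- as.matrix(nf[, -1, drop = FALSE])
  rownames(feats) <- nf$patient_id
  truth_path <- file.path(directory, "truth.tsv")
  if (file.exists(truth_path)) {
    tr <- utils::read.table(truth_path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    patients$latent_true_dx <- tr$latent_true_dx[match(patients$patient_id,
                                                       tr$patient_id)]
  }
  structure(list(patients = patients, encounters = encounters,
                 diagnoses = diagnoses, medications = medications,
                 note_features = feats, config = NULL),
            class = "ehr_set")
}
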