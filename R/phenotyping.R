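#' Configuration of the coded phenotyping rules
#'
#' Rule constants for the coded case definitions and the control definition.
#' "Predominance of BD diagnoses" is operationalized as: count of bipolar
#' ICD codes strictly greater than `predominance_threshold` times the count
#' of all psychiatric ICD codes (290-319). "Within a year of BD diagnosis"
#' means within `med_window_days` after the earliest bipolar code date.
#'
#' @param predominance_threshold Fraction of psychiatric codes that bipolar
#'   codes must strictly exceed (default 0.5).
#' @param med_window_days Days after the first bipolar code within which a
#'   lithium/valproate order satisfies the strict rule (default 365).
#' @param bipolar_clinic_types Clinic types counting as bipolar specialty.
#' @param strict_med_classes Medication classes satisfying the strict rule.
#' @param bd_med_classes Bipolar medication classes for the broad rules
#'   (two distinct classes required).
#' @param control_min_age Minimum age in years for controls (default 30).
#' @param exclusion_code_ranges Two-column matrix of inclusive ICD-9 major
#'   ranges excluding a patient from the control group (psychiatric 290-319
#'   and neurological 320-359 by default).
#' @param exclusion_med_classes Medication classes excluding controls.
#' @param distinct_dates Collapse same-day duplicate bipolar codes when
#'   counting the strict rule's three codes (default TRUE).
#' @return A list of class `rule_config`.
#' @export
rule_config <- function(predominance_threshold = 0.5, med_window_days = 365,
                        bipolar_clinic_types = "bipolar_specialty",
                        strict_med_classes = c("lithium", "valproate"),
                        bd_med_classes = c("lithium", "valproate",
                                           "carbamazepine",
                                           "atypical_antipsychotic"),
                        control_min_age = 30,
                        exclusion_code_ranges = rbind(c(290, 319), c(320, 359)),
                        exclusion_med_classes = c("lithium", "valproate",
                                                  "carbamazepine",
                                                  "atypical_antipsychotic",
                                                  "antidepressant",
                                                  "anxiolytic"),
                        distinct_dates = TRUE) {
  if (predominance_threshold < 0) stop_config("predominance_threshold must be nonnegative")
  if (!length(bd_med_classes)) stop_config("bd_med_classes must be non-empty")
  structure(list(predominance_threshold = predominance_threshold,
                 med_window_days = as.integer(med_window_days),
                 bipolar_clinic_types = bipolar_clinic_types,
                 strict_med_classes = strict_med_classes,
                 bd_med_classes = bd_med_classes,
                 control_min_age = control_min_age,
                 exclusion_code_ranges = exclusion_code_ranges,
                 exclusion_med_classes = exclusion_med_classes,
                 distinct_dates = distinct_dates), class = "rule_config")
}

# Per-patient summaries of the coded record, computed once and shared by all
# rule classifiers. Pure function of the record sets (order-invariant).
code_summaries <- function(ehr, rules) {
  ids <- ehr$patients$patient_id
  dx <- ehr$diagnoses
  bd <- is_bd_code(dx$icd9_code)
  psych <- is_psych_code(dx$icd9_code)
  f <- factor(dx$patient_id, levels = ids)
  n_bd <- tapply(bd, f, sum, default = 0)
  n_psych <- tapply(psych, f, sum, default = 0)
  bd_dates <- tapply(as.integer(dx$date)[bd], factor(dx$patient_id[bd], levels = ids),
                     function(x) length(unique(x)), default = 0)
  bd_encs <- tapply(dx$encounter_id[bd], factor(dx$patient_id[bd], levels = ids),
                    function(x) length(unique(x)), default = 0)
  first_bd <- tapply(as.integer(dx$date)[bd], factor(dx$patient_id[bd], levels = ids),
                     min, default = NA_integer_)
  md <- ehr$medications
  fm <- factor(md$patient_id, levels = ids)
  med_classes <- lapply(split(md$drug_class, fm), unique)
  sel <- md$drug_class %in% rules$strict_med_classes
  strict_days <- split(as.integer(md$date)[sel],
                       factor(md$patient_id[sel], levels = ids))
  ec <- ehr$encounters
  fe <- factor(ec$patient_id, levels = ids)
  bp_clinic <- tapply(ec$clinic_type %in% rules$bipolar_clinic_types, fe, any,
                      default = FALSE)
  list(ids = ids, n_bd = as.vector(n_bd), n_psych = as.vector(n_psych),
       bd_dates = as.vector(bd_dates), bd_encs = as.vector(bd_encs),
       first_bd = as.vector(first_bd), med_classes = med_classes,
       strict_days = strict_days, bp_clinic = as.vector(bp_clinic))
}

predominant <- function(s, rules) {
  s$n_bd > rules$predominance_threshold * s$n_psych
}

#' Coded-strict case rule
#'
#' TRUE iff the record has (i) at least three bipolar ICD codes on three
#' distinct dates, (ii) a predominance of bipolar over all psychiatric
#' codes, and (iii) a lithium or valproate order within `med_window_days`
#' after the first bipolar code, or any encounter at a bipolar specialty
#' clinic.
#'
#' @param ehr An `ehr_set` (typically after [build_datamart()]).
#' @param rules A [rule_config()].
#' @return Named logical vector over the patients in `ehr`.
#' @export
classify_coded_strict <- function(ehr, rules = rule_config()) {
  s <- code_summaries(ehr, rules)
  count_ok <- if (rules$distinct_dates) s$bd_dates >= 3 else s$n_bd >= 3
  med_ok <- mapply(function(first, days) {
    !is.na(first) && length(days) > 0 &&
      any(days >= first & days <= first + rules$med_window_days)
  }, s$first_bd, s$strict_days)
  out <- count_ok & predominant(s, rules) & (med_ok | s$bp_clinic)
  stats::setNames(as.vector(out), s$ids)
}

#' Coded-broad case rule
#'
#' TRUE iff at least two bipolar ICD codes on two distinct encounters, a
#' predominance of bipolar diagnoses, and orders from at least two distinct
#' bipolar medication classes (lithium, valproate, carbamazepine, atypical
#' antipsychotic).
#'
#' @inheritParams classify_coded_strict
#' @return Named logical vector.
#' @export
classify_coded_broad <- function(ehr, rules = rule_config()) {
  s <- code_summaries(ehr, rules)
  meds_ok <- vapply(s$med_classes, function(cl)
    sum(rules$bd_med_classes %in% cl) >= 2, logical(1))
  out <- s$bd_encs >= 2 & predominant(s, rules) & meds_ok
  stats::setNames(as.vector(out), s$ids)
}

#' Coded-broad single-visit relaxation
#'
#' Identical to [classify_coded_broad()] except the two bipolar codes may
#' occur during the same inpatient or outpatient episode of illness, so any
#' two codes qualify regardless of encounter.
#'
#' @inheritParams classify_coded_strict
#' @return Named logical vector.
#' @export
classify_coded_broad_sv <- function(ehr, rules = rule_config()) {
  s <- code_summaries(ehr, rules)
  meds_ok <- vapply(s$med_classes, function(cl)
    sum(rules$bd_med_classes %in% cl) >= 2, logical(1))
  out <- s$n_bd >= 2 & predominant(s, rules) & meds_ok
  stats::setNames(as.vector(out), s$ids)
}

#' Control rule
#'
#' TRUE iff the patient is at least `control_min_age` years old at the
#' reference date, has no ICD code in the psychiatric or neurological
#' exclusion ranges, and no order from an excluded medication class.
#' Controls are drawn from the full population, not the datamart.
#'
#' @inheritParams classify_coded_strict
#' @param reference_date Date at which age is evaluated (defaults to the
#'   latest encounter date in the set).
#' @return Named logical vector.
#' @export
classify_control <- function(ehr, rules = rule_config(), reference_date = NULL) {
  if (anyNA(ehr$patients$birth_date))
    stop_config("missing birth_date for patient(s): %s",
                ehr$patients$patient_id[which(is.na(ehr$patients$birth_date))[1]])
  ref <- as.Date(reference_date %||% max(ehr$encounters$start_date))
  age <- as.numeric(ref - ehr$patients$birth_date) / 365.25
  ids <- ehr$patients$patient_id
  dx_hit <- unique(ehr$diagnoses$patient_id[
    code_in_ranges(ehr$diagnoses$icd9_code, rules$exclusion_code_ranges)])
  md_hit <- unique(ehr$medications$patient_id[
    ehr$medications$drug_class %in% rules$exclusion_med_classes])
  stats::setNames(age >= rules$control_min_age &
                    !(ids %in% dx_hit) & !(ids %in% md_hit), ids)
}

code_in_ranges <- function(codes, ranges) {
  m <- icd_major(codes)
  hit <- rep(FALSE, length(codes))
  for (r in seq_len(nrow(ranges)))
    hit <- hit | (!is.na(m) & m >= ranges[r, 1] & m <= ranges[r, 2])
  hit
}

#' Train the note-feature classifier (adaptive LASSO at fixed specificity)
#'
#' Two-stage adaptive LASSO logistic regression over note features:
#' stage 1 fits an unpenalized (or, when features are many relative to
#' samples, ridge) logistic model for initial coefficients \eqn{\hat b_j};
#' stage 2 solves the L1-penalized fit with per-feature penalty weights
#' \eqn{1/|\hat b_j|^\gamma} (\eqn{\gamma = 1}), penalty strength chosen by
#' k-fold cross-validated deviance. The decision threshold is the smallest
#' probability cutoff achieving the target specificity on a held-out split.
#'
#' @param features Numeric matrix (rows = patients).
#' @param labels Logical/0-1 gold labels (TRUE = case).
#' @param specificity_target Held-out specificity the threshold must reach.
#' @param gamma Adaptive-weight exponent (default 1).
#' @param nfolds Cross-validation folds (default 5).
#' @param holdout_fraction Fraction reserved for threshold calibration.
#' @param seed Integer seed (fold assignment and split).
#' @return An object of class `nlp95_model`: sparse coefficient vector,
#'   `threshold`, held-out `auc` and `sensitivity`, and the glmnet fit.
#' @export
train_nlp95 <- function(features, labels, specificity_target = 0.95,
                        gamma = 1, nfolds = 5, holdout_fraction = 0.3,
                        seed = 1) {
  y <- as.integer(labels)
  if (length(unique(y)) < 2) stop_config("training labels contain a single class")
  v <- apply(features, 2, stats::var)
  if (all(v == 0)) stop_config("feature matrix has zero variance everywhere")
  set.seed(seed)
  n <- nrow(features)
  hold <- sample.int(n, max(2, round(holdout_fraction * n)))
  while (length(unique(y[-hold])) < 2 || length(unique(y[hold])) < 2)
    hold <- sample.int(n, max(2, round(holdout_fraction * n)))
  Xtr <- features[-hold, , drop = FALSE]; ytr <- y[-hold]
  Xho <- features[hold, , drop = FALSE]; yho <- y[hold]

  # stage 1: initial coefficients
  if (ncol(Xtr) < nrow(Xtr) / 5) {
    b0 <- tryCatch(
      suppressWarnings(stats::glm.fit(cbind(1, Xtr), ytr,
                                      family = stats::binomial())$coefficients[-1]),
      error = function(e) NULL)
  } else b0 <- NULL
  if (is.null(b0) || anyNA(b0) || any(abs(b0) > 50)) {
    rf <- glmnet::cv.glmnet(Xtr, ytr, family = "binomial", alpha = 0,
                            nfolds = nfolds,
                            foldid = rep_len(seq_len(nfolds), nrow(Xtr)))
    b0 <- as.vector(stats::coef(rf, s = "lambda.min"))[-1]
  }
  w <- 1 / pmax(abs(b0), 1e-6)^gamma
  w <- w / min(w)

  cv <- glmnet::cv.glmnet(Xtr, ytr, family = "binomial", alpha = 1,
                          penalty.factor = w, nfolds = nfolds,
                          foldid = rep_len(seq_len(nfolds), nrow(Xtr)),
                          type.measure = "deviance")
  coefs <- as.vector(stats::coef(cv, s = "lambda.min"))
  names(coefs) <- c("(Intercept)", colnames(features) %||%
                      sprintf("f%03d", seq_len(ncol(features))))

  p_ho <- as.vector(stats::predict(cv, newx = Xho, s = "lambda.min",
                                   type = "response"))
  p0 <- p_ho[yho == 0]; p1 <- p_ho[yho == 1]
  cand <- sort(unique(c(p_ho, 1)))
  fpr <- vapply(cand, function(t) mean(p0 >= t), numeric(1))
  thr <- cand[which(fpr <= 1 - specificity_target)[1]]
  sens <- mean(p1 >= thr)
  auc <- if (length(p0) && length(p1))
    mean(outer(p1, p0, ">") + 0.5 * outer(p1, p0, "==")) else NA_real_

  structure(list(coefficients = coefs, threshold = thr,
                 specificity_target = specificity_target,
                 auc = auc, sensitivity = sens,
                 n_selected = sum(coefs[-1] != 0), fit = cv),
            class = "nlp95_model")
}

#' @export
print.nlp95_model <- function(x, ...) {
  cat(sprintf("Adaptive-LASSO note-feature classifier: %d features selected\n",
              x$n_selected))
  cat(sprintf("  threshold %.4f at specificity >= %.2f (held-out)\n",
              x$threshold, x$specificity_target))
  cat(sprintf("  held-out AUC %.3f, sensitivity %.3f\n", x$auc, x$sensitivity))
  invisible(x)
}

#' @export
predict.nlp95_model <- function(object, features, ...) {
  as.vector(stats::predict(object$fit, newx = features, s = "lambda.min",
                           type = "response"))
}

#' Non-hierarchical phenotype assignment
#'
#' Every datamart patient receives every case label whose classifier returns
#' TRUE (the NLP95 label iff the classifier probability reaches the model's
#' threshold); patients outside the datamart are tested against the control
#' rule. A patient can never satisfy both a case rule and the control rule
#' (controls require zero psychiatric codes); this is asserted.
#'
#' @param ehr The full-population `ehr_set`.
#' @param rules A [rule_config()].
#' @param nlp_model Optional `nlp95_model`; without it the NLP95 label is NA.
#' @param reference_date Passed to [classify_control()].
#' @return A data frame of class `phenotype_assignment`: `patient_id`,
#'   logical columns `nlp95`, `coded_strict`, `coded_broad`,
#'   `coded_broad_sv`, `control`, and `nlp_probability`.
#' @export
assign_phenotypes <- function(ehr, rules = rule_config(), nlp_model = NULL,
                              reference_date = NULL) {
  dm <- build_datamart(ehr)
  in_dm <- ehr$patients$patient_id %in% dm$patients$patient_id
  ids <- ehr$patients$patient_id
  n <- length(ids)
  out <- data.frame(patient_id = ids,
                    nlp95 = NA, coded_strict = FALSE, coded_broad = FALSE,
                    coded_broad_sv = FALSE, control = FALSE,
                    nlp_probability = NA_real_, stringsAsFactors = FALSE)
  if (nrow(dm$patients)) {
    idx <- match(dm$patients$patient_id, ids)
    out$coded_strict[idx] <- classify_coded_strict(dm, rules)
    out$coded_broad[idx] <- classify_coded_broad(dm, rules)
    out$coded_broad_sv[idx] <- classify_coded_broad_sv(dm, rules)
    if (!is.null(nlp_model)) {
      pr <- predict(nlp_model, dm$note_features)
      out$nlp_probability[idx] <- pr
      out$nlp95[idx] <- pr >= nlp_model$threshold
    }
  }
  ctrl <- classify_control(ehr, rules, reference_date)
  out$control <- as.vector(ctrl) & !in_dm
  any_case <- out$coded_strict | out$coded_broad | out$coded_broad_sv |
    (!is.na(out$nlp95) & out$nlp95)
  stopifnot("case and control labels must be disjoint" =
              !any(any_case & out$control))
  class(out) <- c("phenotype_assignment", "data.frame")
  out
}

#' Positive predictive value and sensitivity against withheld truth
#'
#' For each case algorithm, PPV is the fraction of labelled cases whose
#' latent diagnosis is bipolar disorder, and sensitivity the fraction of
#' latent bipolar patients the algorithm labels. For the control algorithm,
#' concordance means a latent diagnosis of `NONE`. Empty label groups are
#' reported with `n = 0` and missing PPV.
#'
#' @param assignments A [assign_phenotypes()] result.
#' @param truth Data frame with `patient_id` and `latent_true_dx`.
#' @return Data frame with columns `algorithm`, `ppv`, `sensitivity`, `n`.
#' @export
evaluate_ppv <- function(assignments, truth) {
  lt <- truth$latent_true_dx[match(assignments$patient_id, truth$patient_id)]
  is_bd <- lt == "BD"
  algs <- c(nlp95 = "nlp95", coded_strict = "coded_strict",
            coded_broad = "coded_broad", coded_broad_sv = "coded_broad_sv",
            control = "control")
  rows <- lapply(names(algs), function(a) {
    lab <- assignments[[a]]
    lab[is.na(lab)] <- FALSE
    n <- sum(lab)
    concordant <- if (a == "control") lt == "NONE" else is_bd
    data.frame(algorithm = a,
               ppv = if (n > 0) sum(lab & concordant) / n else NA_real_,
               sensitivity = if (a == "control") NA_real_ else
                 if (sum(is_bd) > 0) sum(lab & is_bd) / sum(is_bd) else NA_real_,
               n = n, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
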