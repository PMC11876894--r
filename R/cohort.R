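# New-user cohort construction: index date, enrollment requirements,
# exclusions, follow-up truncation, and attrition accounting.

RULE_NAMES <- c("min_opioid_fill_dates", "pre_index_enrollment_days",
                "post_index_enrollment_days", "min_age_years",
                "excluded_diagnosis_categories", "excluded_prior_drug_classes")

#' Eligibility rules for the opioid new-user cohort
#'
#' Encodes the cohort-entry algorithm: at least two oral opioid fills on
#' distinct dates (the earliest defines the index date), 12 months of
#' continuous enrollment before and 2 months after the index date, adult age
#' at index, no cancer diagnosis on or before the index date, and no
#' buprenorphine fill strictly before the index date.  Follow-up is capped
#' at 9 years (9 x 365 days) or the end of the enrollment span containing
#' the index date, whichever comes first.
#'
#' @param min_opioid_fill_dates Minimum distinct oral-opioid fill dates.
#' @param pre_index_enrollment_days Continuous-enrollment days required
#'   before (and including) the index date.
#' @param post_index_enrollment_days Continuous-enrollment days required
#'   after the index date.
#' @param min_age_years Minimum age (completed years) on the index date.
#' @param max_follow_up_days Follow-up cap from the index date.
#' @param allowed_routes Routes counted as eligible opioid fills.
#' @param excluded_prior_drug_classes Drug classes whose pre-index fills
#'   exclude the patient.
#' @param excluded_diagnosis_categories Diagnosis categories whose presence
#'   on or before index excludes the patient.
#' @param enrollment_grace_days Maximum gap (days) between consecutive
#'   enrollment spans that is still merged into one continuous span.
#' @return An `eligibility_rules` object.
#' @export
eligibility_rules <- function(min_opioid_fill_dates = 2L,
                              pre_index_enrollment_days = 365L,
                              post_index_enrollment_days = 60L,
                              min_age_years = 18L,
                              max_follow_up_days = 9L * 365L,
                              allowed_routes = "oral",
                              excluded_prior_drug_classes = "buprenorphine",
                              excluded_diagnosis_categories = "cancer",
                              enrollment_grace_days = 0L) {
  for (f in c("min_opioid_fill_dates", "pre_index_enrollment_days",
              "post_index_enrollment_days", "min_age_years",
              "max_follow_up_days")) {
    v <- get(f)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0)
      stop_config(f, "must be a single positive number")
  }
  if (length(allowed_routes) < 1L)
    stop_config("allowed_routes", "must be nonempty")
  structure(list(
    min_opioid_fill_dates = as.integer(min_opioid_fill_dates),
    pre_index_enrollment_days = as.integer(pre_index_enrollment_days),
    post_index_enrollment_days = as.integer(post_index_enrollment_days),
    min_age_years = as.integer(min_age_years),
    max_follow_up_days = as.integer(max_follow_up_days),
    allowed_routes = allowed_routes,
    excluded_prior_drug_classes = excluded_prior_drug_classes,
    excluded_diagnosis_categories = excluded_diagnosis_categories,
    enrollment_grace_days = as.integer(enrollment_grace_days),
    # complete 30-day windows available under the follow-up cap
    max_windows = as.integer(floor(max_follow_up_days * 12 / 365))
  ), class = "eligibility_rules")
}

#' Index date: first eligible oral opioid fill
#'
#' @param prescriptions Fills for one patient (columns `day`, `drug_class`,
#'   `route`).
#' @param rules An [eligibility_rules()] object.
#' @return The earliest day with an opioid fill on an allowed route, or
#'   `NA_integer_` if there is none.
#' @export
find_index_date <- function(prescriptions, rules = eligibility_rules()) {
  keep <- prescriptions$drug_class == "opioid" &
    prescriptions$route %in% rules$allowed_routes
  if (!any(keep)) return(NA_integer_)
  as.integer(min(prescriptions$day[keep]))
}

# merge adjacent enrollment spans; error on overlap
merge_spans <- function(enrollment, grace, patient_id = "?") {
  if (nrow(enrollment) == 0L)
    return(data.frame(start_day = integer(0), end_day = integer(0)))
  o <- order(enrollment$start_day)
  s <- enrollment$start_day[o]; e <- enrollment$end_day[o]
  if (length(s) > 1L) {
    if (any(s[-1L] <= e[-length(e)]))
      stop_data_quality(patient_id,
                        "overlapping enrollment spans (must be disjoint)")
    merged_s <- s[1L]; merged_e <- e[1L]
    for (k in 2L:length(s)) {
      if (s[k] - merged_e[length(merged_e)] - 1L <= grace) {
        merged_e[length(merged_e)] <- e[k]
      } else {
        merged_s <- c(merged_s, s[k]); merged_e <- c(merged_e, e[k])
      }
    }
    s <- merged_s; e <- merged_e
  }
  data.frame(start_day = s, end_day = e)
}

#' Evaluate cohort eligibility for one patient
#'
#' Rules are checked in a fixed order; the first failure is reported:
#' (1) enough distinct oral-opioid fill dates, (2) one continuous enrollment
#' span covering the full pre-index period, (3) the same for the post-index
#' period, (4) minimum age at index, (5) no excluded diagnosis category on
#' or before index, (6) no excluded drug-class fill strictly before index.
#'
#' @param prescriptions,enrollment,diagnoses One patient's records.
#' @param patient One row of the patients table (`patient_id`,
#'   `birth_offset_days`, `sex`, `region`).
#' @param rules An [eligibility_rules()] object.
#' @return A list with `eligible` (flag), `first_failed_rule` (name or
#'   `NA`), and `member` (one-row data frame or `NULL`) carrying
#'   `index_date`, `follow_up_end`, `n_windows`, `age_at_index`, `sex`,
#'   `region`.
#' @export
check_eligibility <- function(prescriptions, enrollment, diagnoses, patient,
                              rules = eligibility_rules()) {
  fail <- function(rule) list(eligible = FALSE, first_failed_rule = rule,
                              member = NULL)
  oral_op <- prescriptions$drug_class == "opioid" &
    prescriptions$route %in% rules$allowed_routes
  fill_dates <- sort(unique(prescriptions$day[oral_op]))
  if (length(fill_dates) < rules$min_opioid_fill_dates)
    return(fail("min_opioid_fill_dates"))
  index <- fill_dates[1L]

  spans <- merge_spans(enrollment, rules$enrollment_grace_days,
                       patient$patient_id)
  hit <- which(spans$start_day <= index & spans$end_day >= index)
  if (length(hit) != 1L ||
      spans$start_day[hit] > index - rules$pre_index_enrollment_days)
    return(fail("pre_index_enrollment_days"))
  if (spans$end_day[hit] < index + rules$post_index_enrollment_days)
    return(fail("post_index_enrollment_days"))

  age <- floor((index - patient$birth_offset_days) / 365.25)
  if (age < rules$min_age_years) return(fail("min_age_years"))

  if (nrow(diagnoses) > 0L &&
      any(diagnoses$category %in% rules$excluded_diagnosis_categories &
          diagnoses$day <= index))
    return(fail("excluded_diagnosis_categories"))

  if (any(prescriptions$drug_class %in% rules$excluded_prior_drug_classes &
          prescriptions$day < index))
    return(fail("excluded_prior_drug_classes"))

  follow_up_end <- min(index + rules$max_follow_up_days, spans$end_day[hit])
  n_windows <- min((follow_up_end - index) %/% 30L, rules$max_windows)
  list(eligible = TRUE, first_failed_rule = NA_character_,
       member = data.frame(
         patient_id = patient$patient_id,
         index_date = as.integer(index),
         follow_up_end = as.integer(follow_up_end),
         n_windows = as.integer(n_windows),
         age_at_index = as.integer(age),
         sex = patient$sex, region = patient$region,
         stringsAsFactors = FALSE))
}

#' Build the study cohort with a full attrition report
#'
#' Applies [check_eligibility()] to every patient in the dataset and
#' tallies, in rule order, how many patients are excluded at each rule.
#'
#' @param dataset A `claims_dataset` (or any list with `patients`,
#'   `enrollment`, `prescriptions`, `diagnoses` tables in the standard
#'   layout).
#' @param rules An [eligibility_rules()] object.
#' @return A `cohort_result` list: `cohort` (one row per eligible patient)
#'   and `attrition` (columns `rule`, `n_excluded`, `n_remaining`; the
#'   counts partition the input population).
#' @export
build_cohort <- function(dataset, rules = eligibility_rules()) {
  pats <- dataset$patients
  n <- nrow(pats)
  rx_split <- split(seq_len(nrow(dataset$prescriptions)),
                    dataset$prescriptions$patient_id)
  en_split <- split(seq_len(nrow(dataset$enrollment)),
                    dataset$enrollment$patient_id)
  dx_split <- split(seq_len(nrow(dataset$diagnoses)),
                    dataset$diagnoses$patient_id)
  excluded <- stats::setNames(integer(length(RULE_NAMES)), RULE_NAMES)
  members <- vector("list", n)
  for (k in seq_len(n)) {
    pid <- pats$patient_id[k]
    res <- check_eligibility(
      dataset$prescriptions[rx_split[[pid]] %||% integer(0), , drop = FALSE],
      dataset$enrollment[en_split[[pid]] %||% integer(0), , drop = FALSE],
      dataset$diagnoses[dx_split[[pid]] %||% integer(0), , drop = FALSE],
      pats[k, , drop = FALSE], rules)
    if (res$eligible) members[[k]] <- res$member
    else excluded[res$first_failed_rule] <- excluded[res$first_failed_rule] + 1L
  }
  cohort <- do.call(rbind, members[!vapply(members, is.null, TRUE)])
  if (is.null(cohort))
    cohort <- empty_df(c(patient_id = "character", index_date = "integer",
                         follow_up_end = "integer", n_windows = "integer",
                         age_at_index = "integer", sex = "character",
                         region = "character"))
  rownames(cohort) <- NULL
  remaining <- n - cumsum(excluded)
  attrition <- data.frame(rule = RULE_NAMES,
                          n_excluded = as.integer(excluded),
                          n_remaining = as.integer(remaining),
                          stringsAsFactors = FALSE)
  structure(list(cohort = cohort, attrition = attrition,
                 n_input = n, rules = rules),
            class = "cohort_result")
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf("Opioid new-user cohort: %d of %d patients eligible\n",
              nrow(x$cohort), x$n_input))
  print(x$attrition, row.names = FALSE)
  invisible(x)
}
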