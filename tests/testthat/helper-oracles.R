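# Shared fixtures and independent oracles used across the test files.

make_member <- function(patient_id = "P1", index_date = 0L, n_windows = 6L,
                        follow_up_end = NULL, age_at_index = 40L,
                        sex = "female", region = "South") {
  data.frame(patient_id = patient_id, index_date = as.integer(index_date),
             follow_up_end = as.integer(follow_up_end %||%
                                          (index_date + 30L * n_windows)),
             n_windows = as.integer(n_windows),
             age_at_index = as.integer(age_at_index),
             sex = sex, region = region, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

make_fills <- function(patient_id = "P1", day, drug_class = "opioid",
                       route = "oral", strength_mg = 5, quantity = 60,
                       days_supply = 30L, mme_factor = 1) {
  n <- length(day)
  data.frame(patient_id = rep_len(patient_id, n), day = as.integer(day),
             drug_id = rep_len("fixture", n),
             drug_class = rep_len(drug_class, n), route = rep_len(route, n),
             strength_mg = rep_len(strength_mg, n),
             quantity = rep_len(quantity, n),
             days_supply = as.integer(rep_len(days_supply, n)),
             mme_factor = rep_len(mme_factor, n), stringsAsFactors = FALSE)
}

# brute-force day-level dose oracle, independent of the implementation
oracle_dose_series <- function(member, fills, mode) {
  index <- member$index_date
  n <- member$n_windows
  f <- fills[fills$drug_class == "opioid" & fills$route == "oral" &
               fills$day >= index & fills$day <= member$follow_up_end, ,
             drop = FALSE]
  values <- numeric(n)
  if (mode == "dispense_date") {
    for (w in seq_len(n) - 1L) {
      tot <- 0
      for (k in seq_len(nrow(f))) {
        if (f$day[k] >= index + 30 * w && f$day[k] < index + 30 * (w + 1))
          tot <- tot + f$strength_mg[k] * f$quantity[k] * f$mme_factor[k]
      }
      values[w + 1L] <- tot / 30
    }
  } else {
    n_days <- 30L * n
    daily <- numeric(n_days)
    for (k in seq_len(nrow(f))) {
      dd <- f$strength_mg[k] * (f$quantity[k] / f$days_supply[k]) *
        f$mme_factor[k]
      for (d in f$day[k]:(f$day[k] + f$days_supply[k] - 1L)) {
        pos <- d - index + 1L
        if (pos >= 1L && pos <= n_days) daily[pos] <- daily[pos] + dd
      }
    }
    for (w in seq_len(n))
      values[w] <- sum(daily[(30L * (w - 1L) + 1L):(30L * w)]) / 30
  }
  values
}

# a small clean catalog (one oral opioid) for degenerate generator tests
flat_catalog <- function() {
  data.frame(drug_id = "hydrocodone_5", drug_class = "opioid",
             route = "oral", strength_mg = 5, mme_factor = 1,
             stringsAsFactors = FALSE)
}

# map generator exclusion reasons to the eligibility rule each must trip,
# in rule-evaluation order; returns the expected per-rule excluded counts
expected_attrition <- function(injections, rule_names) {
  reason_rule <- c(single_fill = "min_opioid_fill_dates",
                   short_pre_enrollment = "pre_index_enrollment_days",
                   short_post_enrollment = "post_index_enrollment_days",
                   minor = "min_age_years",
                   cancer = "excluded_diagnosis_categories",
                   prior_buprenorphine = "excluded_prior_drug_classes")
  counts <- stats::setNames(integer(length(rule_names)), rule_names)
  for (pid in unique(injections$patient_id)) {
    rules <- reason_rule[injections$reason[injections$patient_id == pid]]
    first <- rule_names[min(match(rules, rule_names))]
    counts[first] <- counts[first] + 1L
  }
  counts
}

# match fitted groups to true labels by majority vote in the confusion table
match_groups <- function(true, fitted, K) {
  map <- integer(K)
  for (j in seq_len(K)) {
    tb <- table(true[fitted == j])
    map[j] <- as.integer(names(tb)[which.max(tb)])
  }
  map
}
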