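# Fill-level MME conversion, 30-day window aggregation, dose summaries,
# time-varying stimulant covariates, and comorbidity flags.
#
# Dates are integer day offsets; windows are half-open [start, start + 30).

#' Daily morphine-milligram-equivalent dose of an opioid fill
#'
#' Computes `strength_per_unit x (quantity / days_supply) x MME factor`
#' (mg/day of oral morphine equivalents), vectorised over the rows of a
#' fill table.
#'
#' @param records Data frame of opioid fills with columns `drug_class`,
#'   `strength_mg`, `quantity`, `days_supply`, `mme_factor`.
#' @return Numeric vector of mg/day doses.
#' @export
mme_daily_dose <- function(records) {
  if (any(records$drug_class != "opioid"))
    stop("mme_daily_dose is defined for opioid records only")
  with(records, {
    if (any(is.na(mme_factor) | mme_factor <= 0))
      stop("opioid records must carry a positive mme_factor")
    if (any(quantity <= 0) || any(days_supply <= 0) || any(strength_mg <= 0))
      stop("quantity, days_supply and strength_mg must be positive")
    strength_mg * (quantity / days_supply) * mme_factor
  })
}

#' Attach MME conversion factors from a drug catalog
#'
#' @param prescriptions Fill table carrying `drug_id`.
#' @param drug_catalog Catalog mapping `drug_id` to `mme_factor`.
#' @return The fill table with an `mme_factor` column.
#' @export
add_mme_factors <- function(prescriptions, drug_catalog = default_drug_catalog()) {
  prescriptions$mme_factor <-
    drug_catalog$mme_factor[match(prescriptions$drug_id, drug_catalog$drug_id)]
  prescriptions
}

#' Per-patient monthly mean daily MME series
#'
#' Aggregates a patient's oral opioid fills into consecutive non-overlapping
#' 30-day windows from the index date.  In `dispense_date` mode (default)
#' window w receives the total MME dispensed on days inside the window,
#' divided by 30.  In `supply_spread` mode each fill contributes its daily
#' dose on each covered day `[date, date + days_supply)` and the window
#' value is the sum of covered-day doses divided by 30.  Fills after the
#' follow-up end are ignored; fills before the index date are ignored with
#' a warning (pre-index fills define the index only).
#'
#' @param member One cohort row (fields `index_date`, `follow_up_end`,
#'   `n_windows`).
#' @param fills The patient's fill table (with `mme_factor` attached; see
#'   [add_mme_factors()]).
#' @param mode `"dispense_date"` or `"supply_spread"`.
#' @param allowed_routes Routes counted into the dose series.
#' @return Numeric vector of length `n_windows` of mean daily MME (mg/day).
#' @export
monthly_dose_series <- function(member, fills,
                                mode = c("dispense_date", "supply_spread"),
                                allowed_routes = "oral") {
  mode <- match.arg(mode)
  index <- member$index_date
  n_win <- member$n_windows
  values <- numeric(n_win)
  keep <- fills$drug_class == "opioid" & fills$route %in% allowed_routes
  f <- fills[keep, , drop = FALSE]
  if (nrow(f) == 0L) return(values)
  if (any(f$day < index)) {
    warning(sprintf("%d pre-index opioid fill(s) ignored", sum(f$day < index)))
    f <- f[f$day >= index, , drop = FALSE]
  }
  f <- f[f$day <= member$follow_up_end, , drop = FALSE]
  if (nrow(f) == 0L) return(values)

  if (mode == "dispense_date") {
    w <- (f$day - index) %/% 30L
    tot <- f$strength_mg * f$quantity * f$mme_factor
    ok <- w >= 0L & w < n_win
    if (any(ok)) {
      agg <- rowsum(tot[ok], w[ok])
      values[as.integer(rownames(agg)) + 1L] <- agg[, 1L] / 30
    }
  } else {
    daily <- mme_daily_dose(f)
    for (k in seq_len(nrow(f))) {
      a <- f$day[k]; b <- f$day[k] + f$days_supply[k]   # covered [a, b)
      for (w in seq(max(0L, (a - index) %/% 30L),
                    min(n_win - 1L, (b - 1L - index) %/% 30L))) {
        lo <- max(a, index + 30L * w)
        hi <- min(b, index + 30L * (w + 1L))
        if (hi > lo) values[w + 1L] <- values[w + 1L] + daily[k] * (hi - lo) / 30
      }
    }
  }
  values
}

#' Summary of a patient's dose series
#'
#' @param values Mean daily MME per 30-day window.
#' @return A list: `prsc_no` (windows with any dispensing), `avg_mme`
#'   (mean over positive windows, 0 if none), `total_mme` (sum over all
#'   windows).
#' @export
summarize_dosing <- function(values) {
  pos <- values > 0
  list(prsc_no = sum(pos),
       avg_mme = if (any(pos)) mean(values[pos]) else 0,
       total_mme = sum(values))
}

#' Time-varying stimulant covariate series for one patient
#'
#' `cumulative[w]` counts stimulant fills dated in
#' `[index - 365, index + 30 (w + 1))`, i.e. the cumulative number of
#' stimulant prescriptions from one year before the index date up to the
#' end of window w.
#'
#' @param member One cohort row.
#' @param fills The patient's fill table.
#' @return A list: `cumulative` (integer vector, one per window),
#'   `stim_count_pre_index` (fills in `[index - 365, index)`), and
#'   `stim_count_between` (fills between the first and last oral opioid
#'   fill dates within follow-up, inclusive).
#' @export
stimulant_covariates <- function(member, fills) {
  index <- member$index_date
  n_win <- member$n_windows
  sd_ <- fills$day[fills$drug_class == "stimulant"]
  ends <- index + 30L * seq_len(n_win)
  cumulative <- vapply(ends, function(e)
    sum(sd_ >= index - 365L & sd_ < e), 1L)
  op <- fills$day[fills$drug_class == "opioid" & fills$route == "oral" &
                    fills$day >= index & fills$day <= member$follow_up_end]
  between <- if (length(op) > 0L)
    sum(sd_ >= min(op) & sd_ <= max(op)) else 0L
  list(cumulative = as.integer(cumulative),
       stim_count_pre_index = sum(sd_ >= index - 365L & sd_ < index),
       stim_count_between = as.integer(between))
}

#' Pre/post-index comorbidity flags for one patient
#'
#' Pre-index covers the 1-year baseline `[index - 365, index)`; post-index
#' covers any day on or after the index date (a diagnosis exactly on the
#' index date counts as post-index only).
#'
#' @param member One cohort row.
#' @param diagnoses The patient's diagnoses (column `category`).
#' @param categories Categories to flag.
#' @return Data frame with columns `category`, `pre_index`, `post_index`.
#' @export
comorbidity_flags <- function(member, diagnoses,
                              categories = COMORBIDITY_CATEGORIES) {
  index <- member$index_date
  known <- diagnoses$category %in% c(categories, "cancer")
  if (any(!known))
    message(sprintf("ignoring %d diagnoses with unknown categories",
                    sum(!known)))
  d <- diagnoses[known, , drop = FALSE]
  pre <- vapply(categories, function(cg)
    any(d$category == cg & d$day >= index - 365L & d$day < index), TRUE)
  post <- vapply(categories, function(cg)
    any(d$category == cg & d$day >= index), TRUE)
  data.frame(category = categories, pre_index = unname(pre),
             post_index = unname(post), stringsAsFactors = FALSE)
}

# ---- cohort-level wrappers (long-format tables) ----

#' Dose series for a whole cohort (long format)
#'
#' @param cohort Cohort table from [build_cohort()].
#' @param prescriptions Fill table for all patients (with or without
#'   `mme_factor`; attached from `drug_catalog` when absent).
#' @param drug_catalog Catalog used to attach MME factors.
#' @param mode Windowing mode, as in [monthly_dose_series()].
#' @return Long data frame (`patient_id`, `window`, `mme`) with one row per
#'   complete 30-day window per patient (windows are 0-based).
#' @export
dose_series_table <- function(cohort, prescriptions,
                              drug_catalog = default_drug_catalog(),
                              mode = c("dispense_date", "supply_spread")) {
  mode <- match.arg(mode)
  if (!"mme_factor" %in% names(prescriptions))
    prescriptions <- add_mme_factors(prescriptions, drug_catalog)
  if (nrow(cohort) == 0L)
    return(empty_df(c(patient_id = "character", window = "integer",
                      mme = "double")))
  if (mode == "dispense_date") {
    # vectorised across patients
    idx <- match(prescriptions$patient_id, cohort$patient_id)
    keep <- !is.na(idx) & prescriptions$drug_class == "opioid" &
      prescriptions$route == "oral"
    p <- prescriptions[keep, , drop = FALSE]; idx <- idx[keep]
    w <- (p$day - cohort$index_date[idx]) %/% 30L
    ok <- w >= 0L & w < cohort$n_windows[idx] &
      p$day <= cohort$follow_up_end[idx]
    n_pre <- sum(p$day < cohort$index_date[idx])
    if (n_pre > 0L)
      warning(sprintf("%d pre-index opioid fill(s) ignored", n_pre))
    key <- paste(cohort$patient_id[idx[ok]], w[ok], sep = "\r")
    tot <- rowsum(p$strength_mg[ok] * p$quantity[ok] * p$mme_factor[ok], key)
    out <- data.frame(
      patient_id = rep(cohort$patient_id, cohort$n_windows),
      window = unlist(lapply(cohort$n_windows, function(m) seq_len(m) - 1L),
                      use.names = FALSE) %||% integer(0),
      stringsAsFactors = FALSE)
    out$mme <- 0
    hit <- match(paste(out$patient_id, out$window, sep = "\r"),
                 rownames(tot))
    out$mme[!is.na(hit)] <- tot[hit[!is.na(hit)], 1L] / 30
    out
  } else {
    rx_split <- split(seq_len(nrow(prescriptions)), prescriptions$patient_id)
    res <- lapply(seq_len(nrow(cohort)), function(k) {
      m <- cohort[k, , drop = FALSE]
      v <- monthly_dose_series(
        m, prescriptions[rx_split[[m$patient_id]] %||% integer(0), ,
                         drop = FALSE], mode = mode)
      data.frame(patient_id = m$patient_id,
                 window = seq_along(v) - 1L, mme = v,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, res)
  }
}

#' Per-patient dose summaries for a cohort
#'
#' @param doses Long dose table from [dose_series_table()].
#' @return Data frame `patient_id`, `prsc_no`, `avg_mme`, `total_mme`.
#' @export
dose_summary_table <- function(doses) {
  sp <- split(doses$mme, doses$patient_id)
  out <- do.call(rbind, lapply(sp, function(v) {
    s <- summarize_dosing(v)
    data.frame(prsc_no = s$prsc_no, avg_mme = s$avg_mme,
               total_mme = s$total_mme)
  }))
  data.frame(patient_id = names(sp), out, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Stimulant covariates for a whole cohort
#'
#' @param cohort Cohort table.
#' @param prescriptions Fill table for all patients.
#' @return A list: `series` (long data frame `patient_id`, `window`,
#'   `cumulative`) and `counts` (`patient_id`, `stim_count_pre_index`,
#'   `stim_count_between`, `stim_count_end`).
#' @export
covariate_table <- function(cohort, prescriptions) {
  rx_split <- split(seq_len(nrow(prescriptions)), prescriptions$patient_id)
  ser <- vector("list", nrow(cohort)); cnt <- vector("list", nrow(cohort))
  for (k in seq_len(nrow(cohort))) {
    m <- cohort[k, , drop = FALSE]
    cv <- stimulant_covariates(
      m, prescriptions[rx_split[[m$patient_id]] %||% integer(0), ,
                       drop = FALSE])
    ser[[k]] <- data.frame(patient_id = m$patient_id,
                           window = seq_along(cv$cumulative) - 1L,
                           cumulative = cv$cumulative,
                           stringsAsFactors = FALSE)
    cnt[[k]] <- data.frame(patient_id = m$patient_id,
                           stim_count_pre_index = cv$stim_count_pre_index,
                           stim_count_between = cv$stim_count_between,
                           stim_count_end =
                             cv$cumulative[length(cv$cumulative)] %||% 0L,
                           stringsAsFactors = FALSE)
  }
  list(series = do.call(rbind, ser) %||%
         empty_df(c(patient_id = "character", window = "integer",
                    cumulative = "integer")),
       counts = do.call(rbind, cnt) %||%
         empty_df(c(patient_id = "character",
                    stim_count_pre_index = "integer",
                    stim_count_between = "integer",
                    stim_count_end = "integer")))
}

#' Comorbidity flags for a whole cohort
#'
#' @param cohort Cohort table.
#' @param diagnoses Diagnoses for all patients.
#' @param categories Categories to flag.
#' @return Wide data frame with a `patient_id` column and, per category,
#'   `pre_<category>` and `post_<category>` logical columns.
#' @export
comorbidity_table <- function(cohort, diagnoses,
                              categories = COMORBIDITY_CATEGORIES) {
  dx_split <- split(seq_len(nrow(diagnoses)), diagnoses$patient_id)
  rows <- lapply(seq_len(nrow(cohort)), function(k) {
    m <- cohort[k, , drop = FALSE]
    fl <- comorbidity_flags(
      m, diagnoses[dx_split[[m$patient_id]] %||% integer(0), , drop = FALSE],
      categories)
    v <- c(fl$pre_index, fl$post_index)
    names(v) <- c(paste0("pre_", categories), paste0("post_", categories))
    as.data.frame(as.list(v))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- as.data.frame(stats::setNames(
      rep(list(logical(0)), 2L * length(categories)),
      c(paste0("pre_", categories), paste0("post_", categories))))
  }
  data.frame(patient_id = cohort$patient_id, out, row.names = NULL,
             stringsAsFactors = FALSE)
}
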