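# Synthetic longitudinal claims generator with known latent-group structure.
#
# Dose dynamics are generated on the transformed scale log(1 + MME): each
# patient draws a latent trajectory group; the monthly target mean daily MME
# is the inverse transform of (group polynomial in window index +
# group covariate effect x cumulative stimulant count + Gaussian noise),
# floored at 0.  Opioid fills are emitted so the dispensed total in each
# 30-day window matches the target up to the quantization of the drug
# catalog.

COMORBIDITY_CATEGORIES <- c(
  "depression", "anxiety", "bipolar", "schizophrenia_psychoses",
  "chronic_acute_pain", "ADHD", "opioid_overdose", "OUD", "TUD", "AUD",
  "CUD", "other_SUD")

EXCLUSION_REASONS <- c("minor", "cancer", "prior_buprenorphine",
                       "short_pre_enrollment", "short_post_enrollment",
                       "single_fill")

#' Default synthetic drug catalog
#'
#' A small catalog of synthetic drugs covering the classes and routes that
#' the eligibility and dosing rules must discriminate: oral opioids with MME
#' conversion factors, a transdermal and an injectable opioid (excluded by
#' the oral-route rule), buprenorphine, stimulants, and a non-analgesic
#' filler drug.  Strengths are mg per unit; `mme_factor` is the published
#' oral-morphine conversion factor and is defined for opioids only.
#'
#' @return A data frame with columns `drug_id`, `drug_class`, `route`,
#'   `strength_mg`, `mme_factor`.
#' @export
default_drug_catalog <- function() {
  data.frame(
    drug_id = c("hydrocodone_5", "oxycodone_5", "morphine_15",
                "fentanyl_td_12", "morphine_inj_10", "buprenorphine_2",
                "methylphenidate_10", "amphetamine_5", "gabapentin_300"),
    drug_class = c("opioid", "opioid", "opioid", "opioid", "opioid",
                   "buprenorphine", "stimulant", "stimulant", "other"),
    route = c("oral", "oral", "oral", "patch", "injection", "oral",
              "oral", "oral", "oral"),
    strength_mg = c(5, 5, 15, 12, 10, 2, 10, 5, 300),
    mme_factor = c(1, 1.5, 1, 2.4, 3, NA, NA, NA, NA),
    stringsAsFactors = FALSE)
}

default_comorbidity_prevalence <- function() {
  # pre-index (1-year baseline) and post-index marginal probabilities
  m <- rbind(
    depression              = c(0.097, 0.204),
    anxiety                 = c(0.122, 0.304),
    bipolar                 = c(0.019, 0.049),
    schizophrenia_psychoses = c(0.003, 0.007),
    chronic_acute_pain      = c(0.577, 0.803),
    ADHD                    = c(0.026, 0.047),
    opioid_overdose         = c(0.0003, 0.002),
    OUD                     = c(0.002, 0.011),
    TUD                     = c(0.062, 0.129),
    AUD                     = c(0.012, 0.031),
    CUD                     = c(0.003, 0.012),
    other_SUD               = c(0.004, 0.015))
  colnames(m) <- c("pre", "post")
  m
}

default_poly_coeffs <- function() {
  # per raw 30-day window unit, on the log(1 + MME) scale; intercepts anchor
  # the five canonical dose groups (very low, low decreasing, low increasing,
  # moderate increasing, high sustained).  The two low groups decline through
  # the zero-censor bound, which is how discontinuation (and hence sparse
  # dispensing) arises in this model family.
  m <- rbind(
    very_low            = c(2.00, -0.550,  0.00400),
    low_decreasing      = c(2.70, -0.300,  0.00150),
    low_increasing      = c(2.45,  0.025, -0.00012),
    moderate_increasing = c(3.55,  0.020, -0.00010),
    high_sustained      = c(4.69,  0.002, -0.00002))
  colnames(m) <- c("intercept", "linear", "quadratic")
  m
}

#' Configuration for the synthetic-claims generator
#'
#' Defaults emulate the structure of a large commercial-claims opioid
#' new-user population: five latent dose-trajectory groups with heavily
#' skewed mixture proportions, group trajectories specified as quadratic
#' polynomials of the 30-day window index on the log(1 + MME) scale, and
#' group-dependent stimulant prescribing so that stimulant exposure is about
#' twice as prevalent in the increasing / high-dose groups.
#'
#' @param n_patients Number of patients to generate.
#' @param seed Integer RNG seed.  Each patient uses a stream keyed by
#'   `(seed, patient index)`, so patient-level output does not depend on
#'   `n_patients`.
#' @param mixture_proportions Strictly positive probabilities of the latent
#'   groups (normalised to sum to 1); its length sets the number of groups.
#' @param poly_coeffs Numeric matrix, one row per group, columns
#'   (intercept, linear, quadratic), on the transformed-dose scale per
#'   30-day window unit.
#' @param covariate_effect Per-group slope on the cumulative stimulant count
#'   (transformed-dose units per prescription).
#' @param sigma Residual SD of the monthly transformed dose (> 0).
#' @param stimulant_rate Per-group expected stimulant fills per 30-day
#'   window (applies to the pre-index year as well).
#' @param exclusion_fractions Named probabilities for injecting
#'   exclusion-triggering patients; names must be among
#'   `minor`, `cancer`, `prior_buprenorphine`, `short_pre_enrollment`,
#'   `short_post_enrollment`, `single_fill`.  Injections are independent
#'   across reasons.
#' @param max_months Maximum number of 30-day follow-up windows (<= 108).
#' @param follow_up_range Integer range (months) from which each patient's
#'   generated follow-up length is drawn uniformly.
#' @param drug_catalog Drug catalog data frame (see
#'   [default_drug_catalog()]); must contain at least one oral opioid.
#' @param region_probs,sex_probs Named category probabilities.
#' @param age_mean,age_sd,age_range Age-at-index distribution (normal,
#'   truncated to `age_range`).
#' @param comorbidity_prevalence Matrix with rows per category and columns
#'   `pre`, `post` of diagnosis probabilities.
#' @param pre_index_stimulant_months Number of 30-day pre-index windows in
#'   which stimulant fills are generated (12 = the 1-year baseline).
#' @param nonoral_opioid_rate Probability of one additional non-oral opioid
#'   fill per patient (exercises the route filter downstream).
#'
#' @return A validated `sim_config` object (a list).
#' @export
sim_config <- function(n_patients,
                       seed = 1L,
                       mixture_proportions = c(0.775, 0.102, 0.085, 0.024, 0.014),
                       poly_coeffs = NULL,
                       covariate_effect = NULL,
                       sigma = 0.5,
                       stimulant_rate = NULL,
                       exclusion_fractions = NULL,
                       max_months = 108L,
                       follow_up_range = c(6L, 84L),
                       drug_catalog = default_drug_catalog(),
                       region_probs = c(Northeast = 0.128, `North Central` = 0.202,
                                        South = 0.497, West = 0.162),
                       sex_probs = c(female = 0.57, male = 0.43),
                       age_mean = 43.9, age_sd = 13, age_range = c(18, 85),
                       comorbidity_prevalence = default_comorbidity_prevalence(),
                       pre_index_stimulant_months = 12L,
                       nonoral_opioid_rate = 0.02) {
  n_patients <- check_count(n_patients, "n_patients")
  seed <- check_count(seed, "seed", min = 0L)
  if (!is.numeric(mixture_proportions) || length(mixture_proportions) < 1L ||
      any(mixture_proportions <= 0))
    stop_config("mixture_proportions", "must be strictly positive")
  mixture_proportions <- mixture_proportions / sum(mixture_proportions)
  K <- length(mixture_proportions)

  if (is.null(poly_coeffs)) {
    poly_coeffs <- default_poly_coeffs()
    if (K != nrow(poly_coeffs))
      stop_config("poly_coeffs", "must be supplied when mixture_proportions is not length 5")
  }
  poly_coeffs <- as.matrix(poly_coeffs)
  if (nrow(poly_coeffs) != K || ncol(poly_coeffs) != 3L ||
      !is.numeric(poly_coeffs) || anyNA(poly_coeffs))
    stop_config("poly_coeffs", sprintf("must be a numeric %d x 3 matrix", K))

  covariate_effect <- covariate_effect %||%
    (if (K == 5L) c(0, 0, 0.3, 0.2, 0.1) else rep(0, K))
  if (length(covariate_effect) != K || anyNA(covariate_effect))
    stop_config("covariate_effect", sprintf("must have length %d", K))

  if (!is.numeric(sigma) || length(sigma) != 1L || is.na(sigma) || sigma <= 0)
    stop_config("sigma", "must be a single positive number")

  stimulant_rate <- stimulant_rate %||%
    (if (K == 5L) c(0.002, 0.002, 0.004, 0.004, 0.004) else rep(0.0015, K))
  if (length(stimulant_rate) != K || any(stimulant_rate < 0) ||
      anyNA(stimulant_rate))
    stop_config("stimulant_rate", sprintf("must be %d non-negative rates", K))

  ef <- stats::setNames(rep(0, length(EXCLUSION_REASONS)), EXCLUSION_REASONS)
  if (!is.null(exclusion_fractions)) {
    if (is.null(names(exclusion_fractions)) ||
        !all(names(exclusion_fractions) %in% EXCLUSION_REASONS))
      stop_config("exclusion_fractions",
                  paste("names must be among:",
                        paste(EXCLUSION_REASONS, collapse = ", ")))
    check_prob(exclusion_fractions, "exclusion_fractions")
    ef[names(exclusion_fractions)] <- exclusion_fractions
  }

  max_months <- check_count(max_months, "max_months", min = 1L)
  if (max_months > 108L) stop_config("max_months", "must be <= 108")
  if (length(follow_up_range) != 2L || any(follow_up_range < 3L) ||
      follow_up_range[1] > follow_up_range[2])
    stop_config("follow_up_range", "must be an increasing pair of months >= 3")
  follow_up_range <- pmin(as.integer(follow_up_range), max_months)

  req <- c("drug_id", "drug_class", "route", "strength_mg", "mme_factor")
  if (!is.data.frame(drug_catalog) || !all(req %in% names(drug_catalog)))
    stop_config("drug_catalog",
                paste("must be a data frame with columns:",
                      paste(req, collapse = ", ")))
  oral_op <- drug_catalog$drug_class == "opioid" & drug_catalog$route == "oral"
  if (!any(oral_op))
    stop_config("drug_catalog", "must contain at least one oral opioid")
  if (any(oral_op & (is.na(drug_catalog$mme_factor) |
                     drug_catalog$mme_factor <= 0)))
    stop_config("drug_catalog", "oral opioids need a positive mme_factor")

  check_prob(region_probs, "region_probs")
  check_prob(sex_probs, "sex_probs")
  cp <- as.matrix(comorbidity_prevalence)
  check_prob(cp, "comorbidity_prevalence")

  structure(list(
    n_patients = n_patients, seed = seed,
    n_groups = K,
    mixture_proportions = mixture_proportions,
    poly_coeffs = poly_coeffs,
    covariate_effect = covariate_effect,
    sigma = sigma,
    stimulant_rate = stimulant_rate,
    exclusion_fractions = ef,
    max_months = max_months,
    follow_up_range = follow_up_range,
    drug_catalog = drug_catalog,
    region_probs = region_probs / sum(region_probs),
    sex_probs = sex_probs / sum(sex_probs),
    age_mean = age_mean, age_sd = age_sd, age_range = age_range,
    comorbidity_prevalence = cp,
    pre_index_stimulant_months = as.integer(pre_index_stimulant_months),
    nonoral_opioid_rate = nonoral_opioid_rate
  ), class = "sim_config")
}

patients_cols <- c(patient_id = "character", birth_offset_days = "integer",
                   sex = "character", region = "character")
enrollment_cols <- c(patient_id = "character", start_day = "integer",
                     end_day = "integer")
prescriptions_cols <- c(patient_id = "character", day = "integer",
                        drug_id = "character", drug_class = "character",
                        route = "character", strength_mg = "double",
                        quantity = "double", days_supply = "integer")
diagnoses_cols <- c(patient_id = "character", day = "integer",
                    code = "character", category = "character")

#' Generate a synthetic claims population
#'
#' Draws a latent trajectory group per patient, simulates enrollment spans,
#' demographics, stimulant and opioid fills, and categorised diagnoses, and
#' injects exclusion-triggering defects at the configured fractions.  The
#' returned dataset carries the generating truth (group labels and model
#' parameters) and the per-patient injected exclusion reasons, so downstream
#' stages can be validated exactly.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `claims_dataset`: a list with data frames
#'   `patients`, `enrollment`, `prescriptions`, `diagnoses`,
#'   `exclusion_injections` (columns `patient_id`, `reason`), and a
#'   `ground_truth` list (`n_groups`, `mixture_proportions`, `poly_coeffs`,
#'   `covariate_effect`, `sigma`, `stimulant_rate`, `labels`).
#' @export
generate_population <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  n <- config$n_patients
  K <- config$n_groups
  cat_ <- config$drug_catalog
  oral_idx <- which(cat_$drug_class == "opioid" & cat_$route == "oral")
  nonoral_idx <- which(cat_$drug_class == "opioid" & cat_$route != "oral")
  bup_idx <- which(cat_$drug_class == "buprenorphine")
  stim_idx <- which(cat_$drug_class == "stimulant")
  regions <- names(config$region_probs)
  sexes <- names(config$sex_probs)
  comorb <- config$comorbidity_prevalence
  comorb_cats <- rownames(comorb)

  pat <- vector("list", n); enr <- vector("list", n)
  rx <- vector("list", n); dx <- vector("list", n)
  grp <- integer(n); inj <- vector("list", n)

  for (i in seq_len(n)) {
    res <- withr::with_seed(patient_seed(config$seed, i),
                            simulate_patient(i, config, oral_idx, nonoral_idx,
                                             bup_idx, stim_idx, regions, sexes,
                                             comorb, comorb_cats))
    pat[[i]] <- res$patient; enr[[i]] <- res$enrollment
    rx[[i]] <- res$rx; dx[[i]] <- res$dx
    grp[i] <- res$group; inj[[i]] <- res$injected
  }

  bind_cols_list <- function(lst, spec) {
    if (n == 0L || all(vapply(lst, is.null, TRUE))) return(empty_df(spec))
    out <- lapply(names(spec), function(cn)
      unlist(lapply(lst, function(x) x[[cn]]), use.names = FALSE))
    names(out) <- names(spec)
    as.data.frame(out, stringsAsFactors = FALSE)
  }

  ids <- if (n > 0L) sprintf("P%06d", seq_len(n)) else character(0)
  injections <- if (n == 0L) {
    empty_df(c(patient_id = "character", reason = "character"))
  } else {
    nr <- vapply(inj, length, 1L)
    data.frame(patient_id = rep(ids, nr),
               reason = unlist(inj, use.names = FALSE) %||% character(0),
               stringsAsFactors = FALSE)
  }

  structure(list(
    patients = bind_cols_list(pat, patients_cols),
    enrollment = bind_cols_list(enr, enrollment_cols),
    prescriptions = bind_cols_list(rx, prescriptions_cols),
    diagnoses = bind_cols_list(dx, diagnoses_cols),
    exclusion_injections = injections,
    ground_truth = list(
      n_groups = K,
      mixture_proportions = config$mixture_proportions,
      poly_coeffs = config$poly_coeffs,
      covariate_effect = config$covariate_effect,
      sigma = config$sigma,
      stimulant_rate = config$stimulant_rate,
      labels = data.frame(patient_id = ids, group = grp,
                          stringsAsFactors = FALSE)),
    drug_catalog = cat_
  ), class = "claims_dataset")
}

# one patient's records; runs inside a per-patient RNG stream
simulate_patient <- function(i, config, oral_idx, nonoral_idx, bup_idx,
                             stim_idx, regions, sexes, comorb, comorb_cats) {
  cat_ <- config$drug_catalog
  pid <- sprintf("P%06d", i)
  g <- sample.int(config$n_groups, 1L, prob = config$mixture_proportions)

  sex <- sample(sexes, 1L, prob = config$sex_probs)
  region <- sample(regions, 1L, prob = config$region_probs)
  age <- round(stats::rnorm(1L, config$age_mean, config$age_sd))
  age <- min(max(age, config$age_range[1]), config$age_range[2])

  fr <- config$follow_up_range
  m <- if (fr[1] == fr[2]) fr[1] else sample(seq(fr[1], fr[2]), 1L)
  enroll_start <- sample(0:364, 1L)
  index_day <- enroll_start + 365L + sample(0:365, 1L)
  enroll_end <- index_day + m * 30L + sample(0:29, 1L)

  injected <- EXCLUSION_REASONS[
    stats::runif(length(EXCLUSION_REASONS)) < config$exclusion_fractions]

  if ("minor" %in% injected) age <- sample(12:17, 1L)
  if ("short_pre_enrollment" %in% injected)
    enroll_start <- index_day - sample(30:300, 1L)
  if ("short_post_enrollment" %in% injected)
    enroll_end <- index_day + sample(31:59, 1L)
  single_fill <- "single_fill" %in% injected

  # stimulant fills: pre-index baseline windows and follow-up windows
  rate <- config$stimulant_rate[g]
  stim_days <- integer(0)
  if (rate > 0) {
    for (p in seq_len(config$pre_index_stimulant_months)) {
      cnt <- stats::rpois(1L, rate)
      if (cnt > 0)
        stim_days <- c(stim_days, index_day - 30L * p +
                         sample(0:29, min(cnt, 30L)))
    }
    for (w in seq_len(m) - 1L) {
      cnt <- stats::rpois(1L, rate)
      if (cnt > 0)
        stim_days <- c(stim_days, index_day + 30L * w +
                         sample(0:29, min(cnt, 30L)))
    }
  }
  stim_days <- sort(stim_days)

  # cumulative stimulant count at each follow-up window (from 1y pre-index)
  wins <- seq_len(m) - 1L
  cum_stim <- vapply(wins, function(w)
    sum(stim_days >= index_day - 365L & stim_days < index_day + 30L * (w + 1L)),
    1L)

  # monthly transformed-dose targets and opioid fill emission
  co <- config$poly_coeffs[g, ]
  z <- co[1] + co[2] * wins + co[3] * wins^2 +
    config$covariate_effect[g] * cum_stim +
    stats::rnorm(m, 0, config$sigma)
  target <- ifelse(z > 0, expm1(z), 0)

  drug_pick <- if (length(oral_idx) == 1L) rep(oral_idx, m) else
    sample(oral_idx, m, replace = TRUE)
  strength <- cat_$strength_mg[drug_pick]
  factor_ <- cat_$mme_factor[drug_pick]
  qty <- round(target * 30 / (strength * factor_))
  qty[wins <= 1L & qty < 1] <- 1        # guarantee >= 2 distinct fill dates
  if (single_fill) qty[wins > 0L] <- 0

  keep <- qty >= 1
  fill_day <- index_day + 30L * wins
  keep <- keep & fill_day >= enroll_start & fill_day <= enroll_end
  rx_day <- fill_day[keep]
  rx_drug <- drug_pick[keep]
  rx_qty <- qty[keep]

  rx <- list(day = rx_day, drug = rx_drug, qty = rx_qty, ds = rep(30L, sum(keep)))

  # stimulant fills (clamped into the enrollment span)
  sk <- stim_days >= enroll_start & stim_days <= enroll_end
  if (any(sk)) {
    sd_ <- stim_days[sk]
    sdrug <- if (length(stim_idx) == 1L) rep(stim_idx, length(sd_)) else
      sample(stim_idx, length(sd_), replace = TRUE)
    rx$day <- c(rx$day, sd_); rx$drug <- c(rx$drug, sdrug)
    rx$qty <- c(rx$qty, rep(30, length(sd_)))
    rx$ds <- c(rx$ds, rep(30L, length(sd_)))
  }

  if ("prior_buprenorphine" %in% injected && length(bup_idx) > 0) {
    bd <- max(index_day - sample(10:200, 1L), enroll_start)
    rx$day <- c(rx$day, bd); rx$drug <- c(rx$drug, bup_idx[1])
    rx$qty <- c(rx$qty, 30); rx$ds <- c(rx$ds, 30L)
  }

  if (length(nonoral_idx) > 0 &&
      stats::runif(1L) < config$nonoral_opioid_rate) {
    nd <- index_day + sample(0:min(enroll_end - index_day, 30L), 1L)
    rx$day <- c(rx$day, nd)
    rx$drug <- c(rx$drug, nonoral_idx[sample.int(length(nonoral_idx), 1L)])
    rx$qty <- c(rx$qty, 10); rx$ds <- c(rx$ds, 30L)
  }

  # diagnoses
  dx_day <- integer(0); dx_cat <- character(0)
  for (ci in seq_along(comorb_cats)) {
    if (stats::runif(1L) < comorb[ci, "pre"]) {
      d <- index_day - sample(1:365, 1L)
      if (d >= enroll_start) { dx_day <- c(dx_day, d); dx_cat <- c(dx_cat, comorb_cats[ci]) }
    }
    if (stats::runif(1L) < comorb[ci, "post"]) {
      d <- index_day + sample(0:max(enroll_end - index_day, 0L), 1L)
      dx_day <- c(dx_day, d); dx_cat <- c(dx_cat, comorb_cats[ci])
    }
  }
  if ("cancer" %in% injected) {
    d <- max(index_day - sample(30:300, 1L), enroll_start)
    dx_day <- c(dx_day, d); dx_cat <- c(dx_cat, "cancer")
  }

  ord <- order(rx$day)
  list(
    patient = list(patient_id = pid,
                   birth_offset_days =
                     index_day - (floor(age * 365.25) + 1L + sample(0:363, 1L)),
                   sex = sex, region = region),
    enrollment = list(patient_id = pid, start_day = as.integer(enroll_start),
                      end_day = as.integer(enroll_end)),
    rx = list(patient_id = rep(pid, length(rx$day)),
              day = as.integer(rx$day[ord]),
              drug_id = cat_$drug_id[rx$drug[ord]],
              drug_class = cat_$drug_class[rx$drug[ord]],
              route = cat_$route[rx$drug[ord]],
              strength_mg = cat_$strength_mg[rx$drug[ord]],
              quantity = as.double(rx$qty[ord]),
              days_supply = as.integer(rx$ds[ord])),
    dx = {
      o <- order(dx_day)
      list(patient_id = rep(pid, length(dx_day)),
           day = as.integer(dx_day[o]),
           code = paste0("SYN_", toupper(dx_cat[o]), recycle0 = TRUE),
           category = dx_cat[o])
    },
    group = g,
    injected = injected)
}

#' Write a synthetic dataset to delimited files
#'
#' Writes the four claims tables as headered CSV plus a ground-truth sidecar
#' (`ground_truth.yaml`, key-value parameters with the per-patient label
#' column and injected exclusion reasons).  The layout round-trips losslessly
#' through [read_dataset()].
#'
#' @param dataset A `claims_dataset`.
#' @param directory Output directory (created if needed).
#' @return Invisibly, a manifest data frame (`file`, `rows`).
#' @export
write_dataset <- function(dataset, directory) {
  stopifnot(inherits(dataset, "claims_dataset"))
  if (!dir.exists(directory))
    dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory))
    stop(sprintf("cannot create directory '%s'", directory))
  tabs <- c("patients", "enrollment", "prescriptions", "diagnoses")
  files <- file.path(directory, paste0(tabs, ".csv"))
  for (k in seq_along(tabs))
    utils::write.csv(dataset[[tabs[k]]], files[k], row.names = FALSE)
  gt <- dataset$ground_truth
  side <- file.path(directory, "ground_truth.yaml")
  yaml::write_yaml(list(
    n_groups = gt$n_groups,
    mixture_proportions = as.numeric(gt$mixture_proportions),
    poly_coeffs = apply(gt$poly_coeffs, 1L, as.numeric, simplify = FALSE),
    covariate_effect = as.numeric(gt$covariate_effect),
    sigma = gt$sigma,
    stimulant_rate = as.numeric(gt$stimulant_rate),
    labels = list(patient_id = gt$labels$patient_id,
                  group = gt$labels$group),
    exclusion_injections = list(
      patient_id = dataset$exclusion_injections$patient_id,
      reason = dataset$exclusion_injections$reason)
  ), side)
  manifest <- data.frame(
    file = basename(c(files, side)),
    rows = c(vapply(tabs, function(t) nrow(dataset[[t]]), 1L),
             nrow(gt$labels)),
    stringsAsFactors = FALSE)
  invisible(manifest)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param directory Directory containing the four CSV tables and the
#'   ground-truth sidecar.
#' @param drug_catalog Drug catalog to attach (the catalog travels with the
#'   pipeline configuration, not the data files).
#' @return A `claims_dataset`.
#' @export
read_dataset <- function(directory, drug_catalog = default_drug_catalog()) {
  rd <- function(name, spec) {
    f <- file.path(directory, paste0(name, ".csv"))
    if (!file.exists(f)) stop(sprintf("missing table file '%s'", f))
    df <- utils::read.csv(f, stringsAsFactors = FALSE,
                          colClasses = unname(spec))
    df[names(spec)]
  }
  patients <- rd("patients", patients_cols)
  enrollment <- rd("enrollment", enrollment_cols)
  prescriptions <- rd("prescriptions", prescriptions_cols)
  diagnoses <- rd("diagnoses", diagnoses_cols)
  side <- yaml::read_yaml(file.path(directory, "ground_truth.yaml"))
  lab <- data.frame(
    patient_id = as.character(side$labels$patient_id %||% character(0)),
    group = as.integer(side$labels$group %||% integer(0)),
    stringsAsFactors = FALSE)
  inj <- data.frame(
    patient_id = as.character(side$exclusion_injections$patient_id %||% character(0)),
    reason = as.character(side$exclusion_injections$reason %||% character(0)),
    stringsAsFactors = FALSE)
  pc <- do.call(rbind, side$poly_coeffs)
  structure(list(
    patients = patients, enrollment = enrollment,
    prescriptions = prescriptions, diagnoses = diagnoses,
    exclusion_injections = inj,
    ground_truth = list(
      n_groups = side$n_groups,
      mixture_proportions = as.numeric(side$mixture_proportions),
      poly_coeffs = pc,
      covariate_effect = as.numeric(side$covariate_effect),
      sigma = side$sigma,
      stimulant_rate = as.numeric(side$stimulant_rate),
      labels = lab),
    drug_catalog = drug_catalog
  ), class = "claims_dataset")
}

#' @export
print.claims_dataset <- function(x, ...) {
  cat(sprintf(
    "Synthetic claims dataset: %d patients, %d fills, %d diagnoses, %d latent groups\n",
    nrow(x$patients), nrow(x$prescriptions), nrow(x$diagnoses),
    x$ground_truth$n_groups))
  invisible(x)
}
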