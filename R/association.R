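# Post-assignment statistics: trajectory-membership logistic regression,
# rank-based subgroup comparisons, and descriptive tables.

#' Trajectory-membership logistic regression
#'
#' Binary logistic regression (maximum likelihood via iteratively
#' reweighted least squares) restricted to patients assigned to the
#' reference or target trajectory group; the outcome is membership in the
#' target group.  Reports per-predictor odds ratios with Wald 95%
#' confidence intervals `exp(beta +/- z * SE)`.
#'
#' @param predictors Data frame of patient-level predictors, one row per
#'   patient, plus a `patient_id` column.  Factors are expanded to dummy
#'   columns by the usual treatment contrasts.
#' @param assignments Assignment table from [posterior_assign()]
#'   (`patient_id`, `modal_group`).
#' @param reference_group,target_group Group indices; patients in the
#'   reference group are the 0 outcome, the target group the 1 outcome.
#' @param conf_level Confidence level of the Wald interval.
#' @return Data frame: `predictor`, `estimate` (log-odds), `se`,
#'   `odds_ratio`, `ci_lower`, `ci_upper`, `p_value`.
#' @export
membership_regression <- function(predictors, assignments, reference_group,
                                  target_group, conf_level = 0.95) {
  m <- merge(predictors, assignments[, c("patient_id", "modal_group")],
             by = "patient_id")
  m <- m[m$modal_group %in% c(reference_group, target_group), , drop = FALSE]
  if (sum(m$modal_group == reference_group) == 0L ||
      sum(m$modal_group == target_group) == 0L)
    stop("both the reference and the target group must be nonempty")
  y <- as.integer(m$modal_group == target_group)
  xdf <- m[, setdiff(names(m), c("patient_id", "modal_group")), drop = FALSE]
  mm <- stats::model.matrix(~ ., data = xdf)

  qr_ <- qr(mm)
  if (qr_$rank < ncol(mm)) {
    dep <- colnames(mm)[qr_$pivot[(qr_$rank + 1L):ncol(mm)]]
    stop(sprintf("collinear predictors: %s", paste(dep, collapse = ", ")))
  }

  fit <- suppressWarnings(
    stats::glm.fit(mm, y, family = stats::binomial()))
  coefs <- fit$coefficients
  if (!fit$converged || any(abs(coefs[-1L]) > 15))
    stop(sprintf(
      "separation detected (no finite ML optimum); predictor: %s",
      names(coefs[-1L])[which.max(abs(coefs[-1L]))]))
  # Wald covariance from the final IRLS weights
  V <- solve(crossprod(mm * sqrt(fit$weights)))
  se <- sqrt(diag(V))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  keep <- setdiff(names(coefs), "(Intercept)")
  data.frame(
    predictor = keep,
    estimate = unname(coefs[keep]),
    se = unname(se[keep]),
    odds_ratio = unname(exp(coefs[keep])),
    ci_lower = unname(exp(coefs[keep] - z * se[keep])),
    ci_upper = unname(exp(coefs[keep] + z * se[keep])),
    p_value = unname(2 * stats::pnorm(-abs(coefs[keep] / se[keep]))),
    stringsAsFactors = FALSE)
}

#' Rank-based comparison of patient subgroups
#'
#' Mann-Whitney U for two groups, Kruskal-Wallis for more; two-sided,
#' midranks for ties, significance at P < 0.05 (no multiplicity
#' adjustment).
#'
#' @param data Data frame with the grouping column and the measures.
#' @param grouping Name of the grouping column.
#' @param measures Character vector of numeric measure columns.
#' @param alpha Significance threshold.
#' @return Data frame: `measure`, `groups`, `test`, `statistic`,
#'   `p_value`, `significant`.
#' @export
subgroup_compare <- function(data, grouping, measures, alpha = 0.05) {
  g <- factor(data[[grouping]])
  sizes <- table(g)
  if (length(sizes) < 2L) stop("need at least two groups")
  if (any(sizes == 0L))
    stop(sprintf("group '%s' has zero observations",
                 names(sizes)[which(sizes == 0L)[1L]]))
  rows <- lapply(measures, function(ms) {
    x <- data[[ms]]
    if (nlevels(g) == 2L) {
      tst <- stats::wilcox.test(x[g == levels(g)[1L]],
                                x[g == levels(g)[2L]],
                                exact = FALSE, correct = TRUE)
      test <- "mann_whitney_u"
    } else {
      tst <- stats::kruskal.test(x, g)
      test <- "kruskal_wallis"
    }
    data.frame(measure = ms,
               groups = paste(levels(g), collapse = " vs "),
               test = test,
               statistic = unname(tst$statistic),
               p_value = tst$p.value,
               significant = tst$p.value < alpha,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Descriptive table by stratum
#'
#' For numeric measures reports n, mean (SD), median (IQR) per stratum;
#' for categorical measures reports n (%) per level.  A stratum of one
#' patient reports SD 0 and is flagged degenerate.
#'
#' @param data Data frame with the stratifier and the measures.
#' @param stratifier Name of the stratifying column (must be defined for
#'   every row).
#' @param measures Character vector of measure columns (numeric or
#'   categorical).
#' @return Long data frame: `stratum`, `measure`, `level` (categorical
#'   rows only), `n`, `pct`, `mean`, `sd`, `median`, `q1`, `q3`,
#'   `degenerate`.
#' @export
descriptive_table <- function(data, stratifier, measures) {
  if (anyNA(data[[stratifier]]))
    stop("stratifier must be defined for every row")
  strata <- split(data, data[[stratifier]])
  rows <- list()
  for (sname in names(strata)) {
    sd_ <- strata[[sname]]
    for (ms in measures) {
      x <- sd_[[ms]]
      if (is.numeric(x)) {
        q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
        rows[[length(rows) + 1L]] <- data.frame(
          stratum = sname, measure = ms, level = NA_character_,
          n = length(x), pct = NA_real_,
          mean = mean(x), sd = if (length(x) > 1L) stats::sd(x) else 0,
          median = q[2L], q1 = q[1L], q3 = q[3L],
          degenerate = length(x) < 2L, stringsAsFactors = FALSE)
      } else {
        tb <- table(factor(x))
        for (lv in names(tb)) {
          rows[[length(rows) + 1L]] <- data.frame(
            stratum = sname, measure = ms, level = lv,
            n = as.integer(tb[[lv]]), pct = 100 * tb[[lv]] / length(x),
            mean = NA_real_, sd = NA_real_, median = NA_real_,
            q1 = NA_real_, q3 = NA_real_,
            degenerate = length(x) < 2L, stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Assemble the patient-level predictor table
#'
#' Joins demographics, pre-index comorbidity flags, and stimulant-exposure
#' summaries into the predictor layout used by
#' [membership_regression()]: age at index (years, linear), a male
#' indicator, region dummies against a configurable reference, pre-index
#' comorbidity indicators, the pre-index stimulant count, the cumulative
#' stimulant count at the end of follow-up, and its binary form.
#'
#' @param cohort Cohort table.
#' @param stim_counts `counts` element of [covariate_table()].
#' @param comorbidities Wide table from [comorbidity_table()].
#' @param region_reference Reference region for the dummies.
#' @param comorbidity_categories Pre-index categories to include.
#' @return Data frame with `patient_id` and numeric predictor columns.
#' @export
build_predictor_table <- function(cohort, stim_counts, comorbidities,
                                  region_reference = "South",
                                  comorbidity_categories =
                                    COMORBIDITY_CATEGORIES) {
  out <- data.frame(patient_id = cohort$patient_id,
                    age_at_index = cohort$age_at_index,
                    sex_male = as.integer(cohort$sex == "male"),
                    stringsAsFactors = FALSE)
  for (rg in setdiff(unique(cohort$region), region_reference))
    out[[paste0("region_", gsub("[^A-Za-z]", "_", rg))]] <-
      as.integer(cohort$region == rg)
  cm <- comorbidities[match(cohort$patient_id, comorbidities$patient_id), ,
                      drop = FALSE]
  for (cg in comorbidity_categories) {
    col <- paste0("pre_", cg)
    if (col %in% names(cm)) out[[col]] <- as.integer(cm[[col]])
  }
  sc <- stim_counts[match(cohort$patient_id, stim_counts$patient_id), ,
                    drop = FALSE]
  out$stim_count_pre_index <- sc$stim_count_pre_index
  out$stim_tv_summary <- sc$stim_count_end
  out$stim_tv_binary <- as.integer(sc$stim_count_end > 0)
  out
}
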