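#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Configuration error naming the offending field
#' @noRd
stop_config <- function(field, msg) {
  stop(structure(
    class = c("rxtraj_config_error", "error", "condition"),
    list(message = sprintf("invalid configuration field '%s': %s", field, msg),
         call = sys.call(-1), field = field)
  ))
}

#' Data-quality error carrying the patient id
#' @noRd
stop_data_quality <- function(patient_id, msg) {
  stop(structure(
    class = c("rxtraj_data_error", "error", "condition"),
    list(message = sprintf("data-quality error for patient '%s': %s",
                           patient_id, msg),
         call = sys.call(-1), patient_id = patient_id)
  ))
}

check_prob <- function(x, field) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1))
    stop_config(field, "must be probabilities in [0, 1]")
  invisible(x)
}

check_count <- function(x, field, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != floor(x))
    stop_config(field, sprintf("must be a single integer >= %d", min))
  invisible(as.integer(x))
}

#' Row-wise log-sum-exp of a matrix
#' @noRd
row_logsumexp <- function(m) {
  mx <- do.call(pmax, c(as.data.frame(m), na.rm = FALSE))
  mx + log(rowSums(exp(m - mx)))
}

#' Deterministic per-patient RNG seed so patient-level output is invariant
#' to the total number of patients generated.
#' @noRd
patient_seed <- function(seed, i) {
  as.integer((as.double(seed) * 1000003 + as.double(i) * 7919) %% 2147483629L) + 1L
}

#' Stable inverse Mills ratio phi(z)/Phi(z)
#' @noRd
inv_mills <- function(z) {
  exp(stats::dnorm(z, log = TRUE) - stats::pnorm(z, log.p = TRUE))
}

empty_df <- function(spec) {
  # spec: named character vector column -> type
  cols <- lapply(spec, function(tp) vector(tp, 0L))
  as.data.frame(cols, stringsAsFactors = FALSE)
}
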