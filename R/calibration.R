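#' Calibration configuration
#'
#' Thresholds governing feasibility screening and settling-value estimation of
#' short impedance transients.
#'
#' @param valid_range Length-2 numeric, ohms: a series whose final sample lies
#'   outside this range is flagged for re-measurement. Default `c(500, 2000)`,
#'   the empirically valid window for upper-body dry-electrode readings.
#' @param settle_threshold Ohms. If the last two samples differ by no more than
#'   this the reading is considered already settled and the final sample is
#'   reported directly. Default 5.
#' @param ratio_band Length-2 numeric, dimensionless. If every delta ratio lies
#'   inside this band the transient is indistinguishable from linear drift
#'   (no resolvable exponential) and the final sample is reported. Default
#'   `c(0.95, 1.05)`.
#'
#' @return An object of class `calibration_config`.
#' @export
calibration_config <- function(valid_range = c(500, 2000),
                               settle_threshold = 5,
                               ratio_band = c(0.95, 1.05)) {
  stopifnot(length(valid_range) == 2, valid_range[1] < valid_range[2],
            length(ratio_band) == 2, ratio_band[1] < ratio_band[2],
            is.numeric(settle_threshold), settle_threshold > 0)
  structure(list(valid_range = as.numeric(valid_range),
                 settle_threshold = as.numeric(settle_threshold),
                 ratio_band = as.numeric(ratio_band)),
            class = "calibration_config")
}

#' Screen a raw impedance series for measurement validity
#'
#' Applies the two feasibility conditions for a dry-electrode contact event:
#'
#' * `CONDITION_1_INCREASING` — the reading increases at every consecutive
#'   step, i.e. the measurement never began to converge (typically poor or
#'   deteriorating contact);
#' * `CONDITION_2_RANGE` — the final reading falls outside the valid
#'   impedance range (default 500-2000 ohms).
#'
#' Subjects whose series violate either condition receive a re-measurement
#' flag.
#'
#' @param series An [impedance_series].
#' @param config A [calibration_config].
#' @return A list of class `feasibility_result` with `valid` (logical),
#'   `violations` (character vector, possibly empty) and `final_value` (ohms).
#'
#' @examples
#' check_feasibility(impedance_series(c(850, 840, 835, 833, 832)))
#' @export
check_feasibility <- function(series, config = calibration_config()) {
  stopifnot(inherits(series, "impedance_series"),
            inherits(config, "calibration_config"))
  v <- series$values
  violations <- character(0)
  if (all(diff(v) > 0)) {
    violations <- c(violations, "CONDITION_1_INCREASING")
  }
  final <- v[length(v)]
  if (final < config$valid_range[1] || final > config$valid_range[2]) {
    violations <- c(violations, "CONDITION_2_RANGE")
  }
  structure(list(valid = length(violations) == 0L,
                 violations = violations,
                 final_value = final),
            class = "feasibility_result")
}

#' @export
print.feasibility_result <- function(x, ...) {
  cat("<feasibility_result> valid =", x$valid)
  if (length(x$violations)) cat(" [", paste(x$violations, collapse = ", "), "]")
  cat(", final =", x$final_value, "ohms\n")
  invisible(x)
}

#' Estimate the settled impedance value from an initial transient
#'
#' The skin-electrode interface of a small dry electrode behaves as a lumped
#' parasitic RC, so the reading follows a first-order transient
#' `y(t) = b + c * exp(-a * t)` and can take far longer than the acquisition
#' window to stabilise. This estimator extrapolates the asymptote `b` from the
#' first few samples instead of waiting.
#'
#' Decision cascade:
#' 1. If the last two samples differ by at most `settle_threshold`, the series
#'    is already settled: return the final sample (`ALREADY_SETTLED`).
#' 2. If any delta is zero or the deltas change sign, no clean exponential is
#'    present: return the final sample (`FALLBACK_LAST`).
#' 3. If every delta ratio lies inside `ratio_band`, the transient is
#'    indistinguishable from linear drift: return the final sample
#'    (`RATIO_IN_BAND`).
#' 4. Otherwise fit the log-linear model: ordinary least squares of
#'    `log(|delta_i|)` on `t_i` yields slope `-a_hat` and intercept
#'    `log(|c_hat| * (1 - exp(-a_hat * delta_s)))`; the settled value is the
#'    mean of `values_i - c_hat * exp(-a_hat * t_i)` (`EXTRAPOLATED`).
#'    On a noise-free exponential this recovers `b` and `a` exactly.
#'
#' If the log-linear slope implies a non-positive decay rate (the transient is
#' growing in magnitude), the estimator falls back to the final sample rather
#' than report a non-decaying "extrapolation".
#'
#' @param series An [impedance_series] that passed [check_feasibility()].
#' @param config A [calibration_config].
#' @return An object of class `settling_estimate` with fields `settled_ohms`,
#'   `decay_rate` (1/s, `NA` unless extrapolated), `amplitude` (signed ohms,
#'   `NA` unless extrapolated), `deltas`, `delta_ratios` (possibly `NULL` when
#'   degenerate), and `method` (one of `"EXTRAPOLATED"`, `"ALREADY_SETTLED"`,
#'   `"RATIO_IN_BAND"`, `"FALLBACK_LAST"`).
#'
#' @examples
#' s <- simulate_transient(transient_params(baseline_ohms = 1000,
#'                                          amplitude = 200, decay_rate = 0.5,
#'                                          noise_sd = 0))
#' estimate_settled_value(s)
#' @export
estimate_settled_value <- function(series, config = calibration_config()) {
  stopifnot(inherits(series, "impedance_series"),
            inherits(config, "calibration_config"))
  v <- series$values
  t <- series$times
  n <- length(v)
  deltas <- compute_deltas(series)

  res <- function(settled, method, rate = NA_real_, amp = NA_real_,
                  ratios = NULL) {
    structure(list(settled_ohms = settled, decay_rate = rate, amplitude = amp,
                   deltas = deltas, delta_ratios = ratios, method = method,
                   subject_id = series$subject_id),
              class = "settling_estimate")
  }

  # (1) already settled: last inter-sample gap within threshold
  if (abs(v[n] - v[n - 1]) <= config$settle_threshold) {
    return(res(v[n], "ALREADY_SETTLED"))
  }
  # (2) zero or sign-changing deltas: no single-exponential transient
  if (any(deltas == 0) || length(unique(sign(deltas))) > 1) {
    return(res(v[n], "FALLBACK_LAST"))
  }
  ratios <- compute_delta_ratios(deltas)
  # (3) ratios in band: indistinguishable from drift
  if (all(ratios >= config$ratio_band[1] & ratios <= config$ratio_band[2])) {
    return(res(v[n], "RATIO_IN_BAND", ratios = ratios))
  }
  # (4) log-linear extrapolation
  if (length(deltas) < 3) {
    stop(structure(
      class = c("biafit_insufficient_samples", "error", "condition"),
      list(message = "estimate_settled_value: fewer than 3 usable deltas for extrapolation (INSUFFICIENT_SAMPLES)",
           call = sys.call(-1))
    ))
  }
  td <- t[-n]                       # delta_i spans [t_i, t_i + delta_s]
  fit <- stats::lm.fit(cbind(1, td), log(abs(deltas)))
  a_hat <- -fit$coefficients[[2]]
  if (!is.finite(a_hat) || a_hat <= 0) {
    return(res(v[n], "FALLBACK_LAST", ratios = ratios))
  }
  c_mag <- exp(fit$coefficients[[1]]) / (1 - exp(-a_hat * series$delta_s))
  c_hat <- sign(deltas[1]) * c_mag
  b_hat <- mean(v - c_hat * exp(-a_hat * t))
  res(b_hat, "EXTRAPOLATED", rate = a_hat, amp = c_hat, ratios = ratios)
}

#' @export
print.settling_estimate <- function(x, ...) {
  cat(sprintf("<settling_estimate> %s: settled = %.3f ohms",
              x$method, x$settled_ohms))
  if (is.finite(x$decay_rate)) {
    cat(sprintf(" (a = %.4f /s, c = %.2f ohms)", x$decay_rate, x$amplitude))
  }
  cat("\n")
  invisible(x)
}

#' Calibrate a batch of impedance series
#'
#' Runs [check_feasibility()] and, for feasible series,
#' [estimate_settled_value()] over a named list of series.
#'
#' @param series_list List of [impedance_series] objects.
#' @param config A [calibration_config].
#' @return A data.frame with one row per series: `subject_id`, `valid`,
#'   `violations` (comma-joined, `""` when none), and for valid series
#'   `settled_ohms`, `decay_rate`, `amplitude`, `method` (`NA` otherwise).
#' @export
calibrate_series <- function(series_list, config = calibration_config()) {
  rows <- lapply(series_list, function(s) {
    feas <- check_feasibility(s, config)
    if (feas$valid) {
      est <- estimate_settled_value(s, config)
      data.frame(subject_id = as.character(s$subject_id),
                 valid = TRUE, violations = "",
                 settled_ohms = est$settled_ohms,
                 decay_rate = est$decay_rate,
                 amplitude = est$amplitude,
                 method = est$method,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(subject_id = as.character(s$subject_id),
                 valid = FALSE,
                 violations = paste(feas$violations, collapse = ","),
                 settled_ohms = NA_real_, decay_rate = NA_real_,
                 amplitude = NA_real_, method = NA_character_,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
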