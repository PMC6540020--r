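#' Timed impedance series from one contact event
#'
#' Container for a short sequence of impedance readings taken at a uniform
#' sampling interval after electrode contact, e.g. the five one-second samples
#' a wearable dry-electrode device records while the skin-electrode interface
#' settles.
#'
#' @param values Numeric vector of impedance readings in ohms; all finite and
#'   strictly positive; at least 3 samples.
#' @param delta_s Sampling interval in seconds (default 1). Sample `i` is taken
#'   at time `i * delta_s` after contact.
#' @param times Optional explicit sample times in seconds; must be strictly
#'   increasing with uniform spacing `delta_s`. Defaults to
#'   `delta_s * seq_along(values)`.
#' @param subject_id Opaque subject label (default `NA`).
#'
#' @return An object of class `impedance_series`: a list with elements
#'   `times`, `values`, `delta_s`, `subject_id`.
#'
#' @examples
#' s <- impedance_series(c(1121.3, 1073.6, 1044.6, 1027.1, 1016.4))
#' compute_deltas(s)
#' @export
impedance_series <- function(values, delta_s = 1, times = NULL,
                             subject_id = NA_character_) {
  values <- as.numeric(values)
  if (length(values) < 3) {
    stop("impedance_series: need at least 3 samples, got ", length(values),
         call. = FALSE)
  }
  if (!all(is.finite(values)) || any(values <= 0)) {
    stop("impedance_series: all impedance values must be finite and > 0",
         call. = FALSE)
  }
  if (!is.numeric(delta_s) || length(delta_s) != 1 || delta_s <= 0) {
    stop("impedance_series: delta_s must be a single positive number",
         call. = FALSE)
  }
  if (is.null(times)) {
    times <- delta_s * seq_along(values)
  } else {
    times <- as.numeric(times)
    if (length(times) != length(values)) {
      stop("impedance_series: times and values lengths differ", call. = FALSE)
    }
    gaps <- diff(times)
    if (any(gaps <= 0) || any(abs(gaps - delta_s) > 1e-9)) {
      stop("impedance_series: times must increase uniformly by delta_s",
           call. = FALSE)
    }
  }
  structure(
    list(times = times, values = values, delta_s = delta_s,
         subject_id = subject_id),
    class = "impedance_series"
  )
}

#' @export
print.impedance_series <- function(x, ...) {
  cat("<impedance_series>", if (!is.na(x$subject_id)) x$subject_id else "",
      "\n")
  cat(sprintf("  %d samples, delta_s = %g s\n", length(x$values), x$delta_s))
  cat("  ohms:", paste(format(x$values, digits = 7), collapse = ", "), "\n")
  invisible(x)
}

#' Consecutive sample differences of an impedance transient
#'
#' Computes the inter-sample differences with the earlier-minus-later sign
#' convention, so a transient decaying from above yields positive deltas.
#' For a pure exponential `b + c * exp(-a * t)` sampled every `delta_s`
#' seconds, `deltas[i] = c * exp(-a * t_i) * (1 - exp(-a * delta_s))`.
#'
#' @param series An [impedance_series].
#' @return Numeric vector of length `n - 1`, in ohms.
#' @export
compute_deltas <- function(series) {
  stopifnot(inherits(series, "impedance_series"))
  -diff(series$values)
}

#' Ratios of consecutive deltas
#'
#' The delta ratio of a first-order transient is amplitude- and
#' baseline-invariant: on a noise-free exponential with decay rate `a` every
#' ratio equals `exp(a * delta_s)`, which is what makes the decay rate
#' recoverable from a handful of samples.
#'
#' @param deltas Numeric vector of consecutive differences (length >= 2).
#' @return Numeric vector `deltas[i] / deltas[i + 1]` of length
#'   `length(deltas) - 1`.
#'
#' Signals a condition of class `biafit_degenerate_delta` if any denominator
#' delta is exactly zero: the caller must take the settled/fallback path
#' rather than divide.
#' @export
compute_delta_ratios <- function(deltas) {
  deltas <- as.numeric(deltas)
  if (length(deltas) < 2) {
    stop("compute_delta_ratios: need at least 2 deltas", call. = FALSE)
  }
  denom <- deltas[-1]
  if (any(denom == 0)) {
    stop(structure(
      class = c("biafit_degenerate_delta", "error", "condition"),
      list(message = "compute_delta_ratios: zero delta in denominator (DEGENERATE_DELTA)",
           call = sys.call(-1))
    ))
  }
  deltas[-length(deltas)] / denom
}
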