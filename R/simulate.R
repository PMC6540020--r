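#' Parameters of a first-order impedance transient
#'
#' A dry-electrode reading settles as `y(t) = b + c * exp(-a * t)` where `b`
#' is the true settled impedance, `c` the (signed) contact-transient
#' amplitude and `a = 1/RC` the lumped parasitic decay rate.
#'
#' @param baseline_ohms True settled value `b`, ohms.
#' @param amplitude Transient amplitude `c`, ohms (signed; positive decays
#'   from above).
#' @param decay_rate Decay rate `a`, 1/seconds; must be > 0.
#' @param noise_sd Additive Gaussian measurement noise SD, ohms (>= 0).
#' @param n_samples Number of samples (default 5).
#' @param delta_s Sampling interval, seconds (default 1).
#' @param seed Optional integer seed for the noise draws.
#' @return An object of class `transient_params`.
#' @export
transient_params <- function(baseline_ohms, amplitude, decay_rate,
                             noise_sd = 0, n_samples = 5, delta_s = 1,
                             seed = NULL) {
  stopifnot(decay_rate > 0, noise_sd >= 0, n_samples >= 3, delta_s > 0)
  structure(list(baseline_ohms = baseline_ohms, amplitude = amplitude,
                 decay_rate = decay_rate, noise_sd = noise_sd,
                 n_samples = as.integer(n_samples), delta_s = delta_s,
                 seed = seed),
            class = "transient_params")
}

#' Simulate a timed impedance series
#'
#' Evaluates `baseline + amplitude * exp(-decay_rate * t)` at
#' `t = delta_s, 2 delta_s, ...` and adds i.i.d. Gaussian noise. Identical
#' parameters and seed give an identical series.
#'
#' @param params A [transient_params].
#' @param subject_id Optional label carried on the series.
#' @return An [impedance_series].
#' @examples
#' simulate_transient(transient_params(1000, 200, 0.5))
#' @export
simulate_transient <- function(params, subject_id = NA_character_) {
  stopifnot(inherits(params, "transient_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  t <- params$delta_s * seq_len(params$n_samples)
  v <- params$baseline_ohms + params$amplitude * exp(-params$decay_rate * t)
  if (params$noise_sd > 0) {
    v <- v + stats::rnorm(length(v), 0, params$noise_sd)
  }
  impedance_series(v, delta_s = params$delta_s, subject_id = subject_id)
}

# Published per-group anthropometric statistics (mean, sd) for the athlete
# cohort: 6 male and 6 female sport/activity groups. Units: height cm, age
# years, weight kg, waist cm, hip cm, body fat percent.
group_stats_table <- function() {
  g <- function(label, gender, n, h, a, w, wa, hi, bf) {
    data.frame(label = label, gender = gender, n_weight = n,
               height_mean = h[1], height_sd = h[2],
               age_mean = a[1], age_sd = a[2],
               weight_mean = w[1], weight_sd = w[2],
               waist_mean = wa[1], waist_sd = wa[2],
               hip_mean = hi[1], hip_sd = hi[2],
               pbf_mean = bf[1], pbf_sd = bf[2],
               stringsAsFactors = FALSE)
  }
  rbind(
    g("Basketball",   "male",    9, c(190.0, 7.2), c(20.3, 1.6), c(84.6, 10.6), c(79.0,  3.6), c( 97.8, 8.6), c(10.0, 2.7)),
    g("Kendo",        "male",   13, c(172.0, 7.7), c(19.1, 0.6), c(70.5,  8.3), c(78.5,  5.2), c( 94.6, 4.5), c(15.3, 3.7)),
    g("Ice Hockey",   "male",   10, c(176.9, 3.7), c(20.1, 1.1), c(81.7,  4.8), c(83.1,  4.0), c(102.8, 1.8), c(18.1, 2.9)),
    g("Baseball",     "male",   22, c(176.4, 4.7), c(21.0, 3.1), c(79.4, 10.4), c(82.2,  7.7), c( 99.4, 5.2), c(17.3, 4.2)),
    g("Rugby",        "male",   32, c(179.6, 6.4), c(20.1, 1.4), c(93.1, 15.0), c(86.2, 14.0), c(104.4, 6.8), c(21.6, 6.8)),
    g("General",      "male",   16, c(174.5, 5.7), c(26.2, 3.0), c(78.7,  9.8), c(81.4,  6.7), c( 99.2, 5.0), c(18.3, 5.1)),
    g("Basketball",   "female",  8, c(167.0, 4.6), c(20.9, 1.7), c(66.2,  9.5), c(73.3,  6.5), c(100.0, 5.9), c(26.8, 7.6)),
    g("Kendo",        "female",  4, c(166.0, 3.0), c(20.0, 1.4), c(62.6,  3.1), c(71.8,  3.5), c( 95.0, 2.5), c(21.4, 4.2)),
    g("Taekwondo",    "female", 14, c(167.3, 5.1), c(19.1, 1.2), c(61.1,  9.4), c(70.4,  6.9), c( 96.8, 5.4), c(23.2, 5.4)),
    g("Judo",         "female", 23, c(163.8, 8.0), c(20.0, 1.4), c(72.0, 17.7), c(77.9, 10.0), c( 99.8, 7.9), c(26.8, 6.7)),
    g("Table Tennis", "female",  6, c(161.6, 3.5), c(20.2, 1.3), c(55.8,  6.0), c(73.6,  5.9), c( 92.9, 5.0), c(25.8, 4.8)),
    g("General",      "female",  6, c(166.9, 4.2), c(24.6, 6.1), c(62.4,  4.6), c(73.7, 13.2), c( 95.4, 3.3), c(23.5, 4.5))
  )
}

#' Default synthetic-cohort configuration
#'
#' Returns the default generator settings for a synthetic athlete cohort:
#' per-group anthropometric means/SDs of the 12 published sport/gender groups
#' (102 male + 61 female subjects at their published group sizes), the
#' measured index-finger contact impedance distribution (585.06 +/- 102.67
#' ohms), and the invented-but-named plumbing constants that tie
#' anthropometrics to impedance.
#'
#' @param finger_mean_ohms,finger_sd_ohms Index-finger impedance offset
#'   distribution, ohms.
#' @param wholebody_k Cylinder-model scale constant (ohm kg / cm^2) mapping
#'   fat-free mass to whole-body 50 kHz impedance via
#'   `R50 = k * height^2 / FFM`; default 1.167 puts a 175 cm subject with
#'   65 kg fat-free mass at ~550 ohms, inside the valid measurement range.
#' @param upper_fraction Upper-body impedance as a fraction of whole-body
#'   (default 1.10).
#' @param meas_noise_sd Per-sample impedance measurement noise SD, ohms
#'   (default 2).
#' @param pbf_noise_sd Residual SD of the generative percent-body-fat rule,
#'   percentage points (default 1.5).
#' @param r50_noise_sd Relative SD of the whole-body reference impedance about
#'   the cylinder relation (default 0.03).
#' @param nonlinearity_strength Scale of the cubic waist/hip term in the
#'   generative body-fat rule (default 40; 0 makes the rule affine in the
#'   anthropometric features up to BMI curvature).
#' @param seed Default seed for [simulate_cohort()].
#' @param groups Data frame of per-group statistics; defaults to the published
#'   table.
#' @return An object of class `cohort_config`.
#' @export
default_cohort_config <- function(finger_mean_ohms = 585.06,
                                  finger_sd_ohms = 102.67,
                                  wholebody_k = 1.167,
                                  upper_fraction = 1.10,
                                  meas_noise_sd = 2,
                                  pbf_noise_sd = 1.5,
                                  r50_noise_sd = 0.03,
                                  nonlinearity_strength = 40,
                                  seed = 1L,
                                  groups = group_stats_table()) {
  stopifnot(finger_sd_ohms >= 0, upper_fraction > 0, meas_noise_sd >= 0,
            pbf_noise_sd >= 0, r50_noise_sd >= 0, wholebody_k > 0)
  stopifnot(all(c("label", "gender", "n_weight", "height_mean", "pbf_mean")
                %in% names(groups)))
  structure(list(groups = groups,
                 finger_mean_ohms = finger_mean_ohms,
                 finger_sd_ohms = finger_sd_ohms,
                 wholebody_k = wholebody_k,
                 upper_fraction = upper_fraction,
                 meas_noise_sd = meas_noise_sd,
                 pbf_noise_sd = pbf_noise_sd,
                 r50_noise_sd = r50_noise_sd,
                 nonlinearity_strength = nonlinearity_strength,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# one truncated-normal draw: reject outside mean +/- 3 sd and [lo, hi]
rtruncn <- function(mean, sd, lo = -Inf, hi = Inf) {
  if (sd == 0) return(mean)
  lo <- max(lo, mean - 3 * sd); hi <- min(hi, mean + 3 * sd)
  repeat {
    x <- stats::rnorm(1, mean, sd)
    if (x >= lo && x <= hi) return(x)
  }
}

# correlated (weight, waist, hip) triple via a shared latent factor giving
# pairwise correlation `rho`; rejected and redrawn as a triple when any
# component leaves its truncation box
rtriple <- function(means, sds, rho = 0.6, lo, hi) {
  if (all(sds == 0)) return(means)
  repeat {
    z0 <- stats::rnorm(1)
    z <- stats::rnorm(3)
    x <- means + sds * (sqrt(rho) * z0 + sqrt(1 - rho) * z)
    ok <- all(x >= pmax(lo, means - 3 * sds) & x <= pmin(hi, means + 3 * sds))
    if (ok) return(x)
  }
}

#' Simulate a synthetic athlete cohort with impedance transients
#'
#' Draws per-group anthropometrics from truncated normals (+/- 3 SD and
#' physiologic bounds), with weight, waist and hip sharing a latent factor
#' (pairwise correlation 0.6). Ground-truth percent body fat follows a stated
#' nonlinear rule:
#' `pbf = clip(pbf_mean_g + 0.8 (BMI - 24) + s * 25 * (waist/hip - r_g)^3 + e, 3, 50)`
#' with `r_g` the group mean waist/hip ratio, `s` the configured
#' nonlinearity strength and `e ~ N(0, pbf_noise_sd^2)`. Whole-body 50 kHz
#' impedance follows the cylinder relation
#' `R50 = k * height^2 / FFM * (1 + eta)`, `eta ~ N(0, r50_noise_sd^2)`, with
#' `FFM = weight (1 - pbf/100)`. Each subject's upper-body contact transient
#' has baseline `upper_fraction * R50 + finger + N(0, meas_noise_sd^2)`,
#' decay rate `a ~ U[0.2, 1.2]`, amplitude `c ~ U[50, 400]` and per-sample
#' noise `meas_noise_sd`.
#'
#' @param config A [default_cohort_config()].
#' @param n_per_group Subjects per group; `NULL` (default) uses each group's
#'   published size, giving the study's 163-subject layout.
#' @param seed Integer seed; defaults to `config$seed`. Identical
#'   `(config, n_per_group, seed)` give an identical cohort.
#' @return An object of class `bia_cohort`: list with `subjects` (data.frame,
#'   one row per subject: `id`, `group`, `gender` (female = 1, male = 0),
#'   `height_cm`, `age_yr`, `weight_kg`, `waist_cm`, `hip_cm`, `true_pbf_pct`,
#'   `ref_wholebody_r50_ohms`, `ref_h2r`, `finger_ohms`) and `series` (named
#'   list of [impedance_series], keyed by `id`).
#' @examples
#' coh <- simulate_cohort(default_cohort_config(), seed = 7)
#' nrow(coh$subjects)
#' @export
simulate_cohort <- function(config = default_cohort_config(),
                            n_per_group = NULL, seed = config$seed) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is.null(n_per_group) && n_per_group < 1) {
    stop("simulate_cohort: n_per_group must be >= 1", call. = FALSE)
  }
  set.seed(as.integer(seed))
  groups <- config$groups
  subj_rows <- list()
  series <- list()
  idx <- 0L
  for (gi in seq_len(nrow(groups))) {
    gr <- groups[gi, ]
    n <- if (is.null(n_per_group)) gr$n_weight else n_per_group
    r_g <- gr$waist_mean / gr$hip_mean
    for (k in seq_len(n)) {
      idx <- idx + 1L
      id <- sprintf("S%04d", idx)
      height <- rtruncn(gr$height_mean, gr$height_sd, 140, 210)
      age <- rtruncn(gr$age_mean, gr$age_sd, 16, 80)
      tri <- rtriple(c(gr$weight_mean, gr$waist_mean, gr$hip_mean),
                     c(gr$weight_sd, gr$waist_sd, gr$hip_sd),
                     rho = 0.6, lo = c(35, 50, 70), hi = c(160, 140, 140))
      weight <- tri[1]; waist <- tri[2]; hip <- tri[3]
      bmi <- weight / (height / 100)^2
      pbf <- gr$pbf_mean + 0.8 * (bmi - 24) +
        config$nonlinearity_strength * 25 * (waist / hip - r_g)^3 +
        stats::rnorm(1, 0, config$pbf_noise_sd)
      pbf <- min(max(pbf, 3), 50)
      ffm <- weight * (1 - pbf / 100)
      r50 <- config$wholebody_k * height^2 / ffm *
        (1 + stats::rnorm(1, 0, config$r50_noise_sd))
      finger <- rtruncn(config$finger_mean_ohms, config$finger_sd_ohms, 0, Inf)
      baseline <- config$upper_fraction * r50 + finger +
        stats::rnorm(1, 0, config$meas_noise_sd)
      a <- stats::runif(1, 0.2, 1.2)
      cc <- stats::runif(1, 50, 400)
      tp <- transient_params(baseline_ohms = baseline, amplitude = cc,
                             decay_rate = a,
                             noise_sd = config$meas_noise_sd)
      series[[id]] <- simulate_transient(tp, subject_id = id)
      subj_rows[[idx]] <- data.frame(
        id = id, group = gr$label,
        gender = if (gr$gender == "female") 1L else 0L,
        height_cm = height, age_yr = age, weight_kg = weight,
        waist_cm = waist, hip_cm = hip, true_pbf_pct = pbf,
        ref_wholebody_r50_ohms = r50, ref_h2r = height^2 / r50,
        finger_ohms = finger, upper_baseline_ohms = baseline,
        transient_decay_rate = a, transient_amplitude = cc,
        stringsAsFactors = FALSE)
    }
  }
  subjects <- do.call(rbind, subj_rows)
  rownames(subjects) <- NULL
  structure(list(subjects = subjects, series = series, config = config),
            class = "bia_cohort")
}

#' @export
print.bia_cohort <- function(x, ...) {
  s <- x$subjects
  cat(sprintf("<bia_cohort> %d subjects (%d male, %d female) in %d groups\n",
              nrow(s), sum(s$gender == 0), sum(s$gender == 1),
              length(unique(paste(s$group, s$gender)))))
  invisible(x)
}

#' Long-format measurement table of a cohort
#'
#' @param cohort A [simulate_cohort()] result.
#' @return data.frame with columns `subject_id`, `t_s`, `ohms`, one row per
#'   sample, in acquisition order.
#' @export
cohort_measurements <- function(cohort) {
  stopifnot(inherits(cohort, "bia_cohort"))
  do.call(rbind, lapply(cohort$series, function(s) {
    data.frame(subject_id = s$subject_id, t_s = s$times, ohms = s$values,
               stringsAsFactors = FALSE)
  })) -> out
  rownames(out) <- NULL
  out
}
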