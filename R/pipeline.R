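#' Fit a whole-body impedance-index estimator
#'
#' Fits a model mapping upper-body inputs (calibrated settled impedance plus
#' anthropometrics) to the whole-body cylinder index H^2/R50. Variants:
#' `REGRESSION` is an ordinary least-squares fit on the five base features;
#' `MODEL_I`-`MODEL_III` are the 128-node three-hidden-layer network on 5, 6
#' and 7 input features respectively (`MODEL_II` adds height^2/impedance,
#' `MODEL_III` adds waist/hip).
#'
#' @param subjects Training subjects (data.frame with anthropometric columns
#'   and `ref_h2r` targets).
#' @param settled_ohms Calibrated settled upper-body impedance per subject,
#'   ohms.
#' @param variant One of `"REGRESSION"`, `"MODEL_I"`, `"MODEL_II"`,
#'   `"MODEL_III"`.
#' @param seed Training seed (network variants).
#' @param targets Target H^2/R50 values; defaults to `subjects$ref_h2r`.
#' @param spec Optional [mlp_spec()] override for the network variants.
#' @return Object of class `h2r_fit`.
#' @export
fit_h2r <- function(subjects, settled_ohms, variant = c("MODEL_III",
                    "REGRESSION", "MODEL_I", "MODEL_II"),
                    seed = 1L, targets = subjects$ref_h2r, spec = NULL) {
  variant <- match.arg(variant)
  if (is.null(targets)) {
    stop("fit_h2r: no ref_h2r targets available", call. = FALSE)
  }
  set <- switch(variant, REGRESSION = "NET1_M1", MODEL_I = "NET1_M1",
                MODEL_II = "NET1_M2", MODEL_III = "NET1_M3")
  X <- build_features(subjects, set, settled_ohms = settled_ohms)
  model <- if (variant == "REGRESSION") {
    fit_ols(X, targets)
  } else {
    spec <- if (is.null(spec)) network1_spec(input_dim = ncol(X), seed = seed)
            else respec_dim(spec, ncol(X))
    train_mlp(spec, X, targets)
  }
  structure(list(variant = variant, set = set, model = model),
            class = "h2r_fit")
}

#' Estimate whole-body H^2/R50 from upper-body inputs
#'
#' @param fit An [fit_h2r()] result.
#' @param subjects Subjects to predict for.
#' @param settled_ohms Their calibrated settled impedances, ohms.
#' @return Numeric vector of estimated H^2/R50 (cm^2/ohm).
#' @export
estimate_h2r <- function(fit, subjects, settled_ohms) {
  stopifnot(inherits(fit, "h2r_fit"))
  X <- build_features(subjects, fit$set, settled_ohms = settled_ohms)
  if (inherits(fit$model, "linear_model")) {
    predict_linear(fit$model, X)
  } else {
    predict_mlp(fit$model, X)
  }
}

# reuse a spec as an architecture template at a different input width
respec_dim <- function(spec, input_dim) {
  if (spec$input_dim == input_dim) return(spec)
  spec$input_dim <- as.integer(input_dim)
  spec
}

#' Fit a percent-body-fat estimator for one regime
#'
#' Regimes follow the study's comparison design: `L_CONV` / `L_PROP` are
#' linear regressions on the conventional 5-feature and proposed 8-feature
#' sets; `DNN_CONV` / `DNN_PROP` are the 256-node three-hidden-layer network
#' on the same two feature sets, consuming the network-estimated whole-body
#' index.
#'
#' @param subjects Training subjects with `true_pbf_pct` targets.
#' @param h2r_values The H^2/R50 feature value per subject (estimated index
#'   for the DNN regimes, calibrated `height^2/settled` for the linear
#'   regimes).
#' @param regime One of `"L_CONV"`, `"L_PROP"`, `"DNN_CONV"`, `"DNN_PROP"`.
#' @param seed Training seed (DNN regimes).
#' @param targets Percent-body-fat targets; defaults to
#'   `subjects$true_pbf_pct`.
#' @param spec Optional [mlp_spec()] override.
#' @return Object of class `pbf_fit`.
#' @export
fit_pbf <- function(subjects, h2r_values, regime = c("L_CONV", "L_PROP",
                    "DNN_CONV", "DNN_PROP"),
                    seed = 1L, targets = subjects$true_pbf_pct, spec = NULL) {
  regime <- match.arg(regime)
  if (is.null(targets)) {
    stop("fit_pbf: no true_pbf_pct targets available", call. = FALSE)
  }
  set <- switch(regime, L_CONV = "CONV5", L_PROP = "PROP8",
                DNN_CONV = "NET2_CONV", DNN_PROP = "NET2_PROP")
  X <- build_features(subjects, set, h2r_values = h2r_values)
  model <- if (regime %in% c("L_CONV", "L_PROP")) {
    fit_ols(X, targets)
  } else {
    spec <- if (is.null(spec)) network2_spec(input_dim = ncol(X), seed = seed)
            else respec_dim(spec, ncol(X))
    train_mlp(spec, X, targets)
  }
  structure(list(regime = regime, set = set, model = model),
            class = "pbf_fit")
}

#' Predict percent body fat
#'
#' Predictions are clipped to the physiologic 0-60 percent range.
#'
#' @param fit A [fit_pbf()] result.
#' @param subjects Subjects to predict for.
#' @param h2r_values Their H^2/R50 feature values (same source as at fit
#'   time).
#' @return Numeric vector of percent body fat.
#' @export
estimate_pbf <- function(fit, subjects, h2r_values) {
  stopifnot(inherits(fit, "pbf_fit"))
  X <- build_features(subjects, fit$set, h2r_values = h2r_values)
  p <- if (inherits(fit$model, "linear_model")) {
    predict_linear(fit$model, X)
  } else {
    predict_mlp(fit$model, X)
  }
  pmin(pmax(p, 0), 60)
}

#' Run the end-to-end estimation experiment
#'
#' Full pipeline for each requested regime on one cohort: feasibility
#' screening and settling-value calibration of every impedance series,
#' gender-balanced train/test split, whole-body-index estimation (network
#' variant `MODEL_III`) for the DNN regimes, percent-body-fat model fitting
#' on the training set and metric evaluation (Pearson r, r^2, SEE) on the
#' held-out test set. All regimes consume the identical split and calibrated
#' impedances. Subjects whose series fail feasibility are flagged for
#' re-measurement and excluded before the split.
#'
#' @param cohort A [simulate_cohort()] result, or a list with `subjects` and
#'   `series` in the same layout.
#' @param regimes Subset of `c("L_CONV", "L_PROP", "DNN_CONV", "DNN_PROP")`.
#' @param split A [split_spec()]; its seed defaults to `seed`.
#' @param seed Master seed for split and model training.
#' @param config A [calibration_config()].
#' @param net1_spec,net2_spec Optional [mlp_spec()] overrides for the two
#'   networks.
#' @return List with `reports` (data.frame via [reports_to_df()]),
#'   `predictions` (per-regime list of test-set id/reference/predicted),
#'   `n_rejected` (feasibility failures) and `split` sizes.
#' @export
run_experiment <- function(cohort,
                           regimes = c("L_CONV", "L_PROP", "DNN_CONV",
                                       "DNN_PROP"),
                           split = NULL, seed = 1L,
                           config = calibration_config(),
                           net1_spec = NULL, net2_spec = NULL) {
  regimes <- match.arg(regimes, several.ok = TRUE)
  subjects <- cohort$subjects
  series <- cohort$series

  cal <- calibrate_series(series[subjects$id], config)
  keep <- cal$valid
  n_rejected <- sum(!keep)
  subjects <- subjects[keep, , drop = FALSE]
  settled <- stats::setNames(cal$settled_ohms[keep], cal$subject_id[keep])

  if (is.null(split)) split <- split_spec(seed = seed)
  sp <- split_cohort(subjects, split)
  tr <- sp$train; te <- sp$test
  settled_tr <- settled[tr$id]; settled_te <- settled[te$id]

  # H^2/R50 feature per regime family
  h2r_lin_tr <- tr$height_cm^2 / settled_tr
  h2r_lin_te <- te$height_cm^2 / settled_te
  if (any(c("DNN_CONV", "DNN_PROP") %in% regimes)) {
    h2r_model <- fit_h2r(tr, settled_tr, "MODEL_III", seed = seed,
                         spec = net1_spec)
    h2r_hat_tr <- estimate_h2r(h2r_model, tr, settled_tr)
    h2r_hat_te <- estimate_h2r(h2r_model, te, settled_te)
  }

  reports <- list(); predictions <- list()
  for (rg in regimes) {
    if (rg %in% c("L_CONV", "L_PROP")) {
      h2r_tr <- h2r_lin_tr; h2r_te <- h2r_lin_te
    } else {
      h2r_tr <- h2r_hat_tr; h2r_te <- h2r_hat_te
    }
    fit <- fit_pbf(tr, h2r_tr, rg, seed = seed, spec = net2_spec)
    pred <- estimate_pbf(fit, te, h2r_te)
    reports[[rg]] <- evaluation_report(rg, te$true_pbf_pct, pred,
                                       n_train = nrow(tr))
    predictions[[rg]] <- data.frame(id = te$id, ref_pbf = te$true_pbf_pct,
                                    pred_pbf = pred,
                                    stringsAsFactors = FALSE)
  }
  list(reports = reports_to_df(reports), predictions = predictions,
       n_rejected = n_rejected,
       n_train = nrow(tr), n_test = nrow(te))
}
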