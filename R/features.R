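#' Named feature sets for impedance/anthropometric models
#'
#' Returns the ordered feature names of each model input configuration used
#' in the pipeline:
#'
#' * `CONV5` — `height, age, gender, weight, h2_r50`: the classical
#'   cylinder-model regression inputs (H, A, G, W, H^2/R50).
#' * `PROP8` — `CONV5` plus `hip, waist, waist_hip`: adds lower-body
#'   circumference information.
#' * `NET1_M1` — `height, age, gender, weight, r50_prop`: whole-body-index
#'   estimation from the calibrated upper-body impedance.
#' * `NET1_M2` — adds `h2_imp` (height^2 / calibrated impedance).
#' * `NET1_M3` — adds `waist_hip` (7 features).
#' * `NET2_CONV` — `CONV5` feature names with `h2_r50` supplied as the
#'   network-estimated whole-body index.
#' * `NET2_PROP` — likewise for `PROP8`.
#'
#' Units: height cm, age years, gender coded female = 1 / male = 0, weight
#' kg, impedances ohms, `h2_r50`/`h2_imp` cm^2/ohm, circumferences cm,
#' `waist_hip` dimensionless.
#'
#' @param name One of the set names above.
#' @return Character vector of ordered feature names.
#' @export
feature_set <- function(name = c("CONV5", "PROP8", "NET1_M1", "NET1_M2",
                                 "NET1_M3", "NET2_CONV", "NET2_PROP")) {
  name <- match.arg(name)
  conv5 <- c("height", "age", "gender", "weight", "h2_r50")
  net1 <- c("height", "age", "gender", "weight", "r50_prop")
  switch(name,
         CONV5 = conv5,
         PROP8 = c(conv5, "hip", "waist", "waist_hip"),
         NET1_M1 = net1,
         NET1_M2 = c(net1, "h2_imp"),
         NET1_M3 = c(net1, "h2_imp", "waist_hip"),
         NET2_CONV = conv5,
         NET2_PROP = c(conv5, "hip", "waist", "waist_hip"))
}

#' Build a model feature matrix from subject records
#'
#' Assembles the ordered numeric features of a [feature_set()] for one or
#' more subjects. `r50_prop` is the calibrated settled impedance;
#' `h2_imp` is `height_cm^2 / settled_ohms`; `h2_r50` is taken from
#' `h2r_values` (either the reference/estimated whole-body index or, for the
#' calibrated-impedance regimes, `height_cm^2 / settled_ohms`);
#' `waist_hip` is `waist_cm / hip_cm`.
#'
#' @param subjects Data frame with columns `height_cm`, `age_yr`, `gender`,
#'   `weight_kg` and, where the set needs them, `waist_cm`, `hip_cm`.
#' @param set Feature-set name (see [feature_set()]).
#' @param settled_ohms Numeric vector of calibrated settled impedances
#'   (required by the `NET1_*` sets), ohms.
#' @param h2r_values Numeric vector of H^2/R50 values (required by `CONV5`,
#'   `PROP8`, `NET2_*` sets), cm^2/ohm.
#' @return Numeric matrix, one row per subject, columns named and ordered per
#'   the set.
#' @examples
#' subj <- data.frame(height_cm = 178, age_yr = 21, gender = 0,
#'                    weight_kg = 83.6, waist_cm = 83.5, hip_cm = 100.7)
#' build_features(subj, "NET1_M3", settled_ohms = 600)
#' @export
build_features <- function(subjects, set, settled_ohms = NULL,
                           h2r_values = NULL) {
  setname <- set
  feats <- feature_set(setname)
  need <- function(col) {
    if (is.null(subjects[[col]])) {
      stop(sprintf("build_features: missing subject field '%s' for set %s",
                   col, setname), call. = FALSE)
    }
    subjects[[col]]
  }
  n <- nrow(subjects)
  if (any(c("r50_prop", "h2_imp") %in% feats)) {
    if (is.null(settled_ohms)) {
      stop("build_features: settled_ohms required for set ", setname,
           call. = FALSE)
    }
    if (any(!is.finite(settled_ohms)) || any(settled_ohms <= 0)) {
      stop("build_features: settled_ohms must be finite and > 0",
           call. = FALSE)
    }
  }
  if ("h2_r50" %in% feats && is.null(h2r_values)) {
    stop("build_features: h2r_values required for set ", setname,
         call. = FALSE)
  }
  cols <- lapply(feats, function(f) {
    switch(f,
           height = need("height_cm"),
           age = need("age_yr"),
           gender = need("gender"),
           weight = need("weight_kg"),
           hip = need("hip_cm"),
           waist = need("waist_cm"),
           waist_hip = need("waist_cm") / need("hip_cm"),
           r50_prop = rep_len(settled_ohms, n),
           h2_imp = need("height_cm")^2 / rep_len(settled_ohms, n),
           h2_r50 = rep_len(h2r_values, n))
  })
  m <- do.call(cbind, cols)
  colnames(m) <- feats
  if (!all(is.finite(m))) {
    stop("build_features: non-finite feature values", call. = FALSE)
  }
  m
}
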