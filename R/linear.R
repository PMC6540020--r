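#' Fit an ordinary-least-squares body-composition model
#'
#' Thin wrapper around [stats::lm()] producing coefficient estimates,
#' standard errors and two-sided t-test p-values (n - p - 1 residual degrees
#' of freedom), the classical presentation of BIA regression equations.
#'
#' @param features Numeric matrix (rows = subjects) with column names.
#' @param targets Numeric response vector.
#' @return Object of class `linear_model`: `feature_names`, `intercept`,
#'   `coefficients` (named), `se`, `p_values` (named, including
#'   `(Intercept)`), `n_fit`.
#' @examples
#' x <- cbind(x1 = 1:10)
#' fit_ols(x, 2 * (1:10) + 1)
#' @export
fit_ols <- function(features, targets) {
  features <- as.matrix(features)
  targets <- as.numeric(targets)
  if (is.null(colnames(features))) {
    colnames(features) <- paste0("x", seq_len(ncol(features)))
  }
  if (nrow(features) != length(targets)) {
    stop("fit_ols: features and targets lengths differ", call. = FALSE)
  }
  if (nrow(features) <= ncol(features) + 1) {
    stop("fit_ols: need more rows than columns + 1", call. = FALSE)
  }
  X <- cbind(`(Intercept)` = 1, features)
  if (qr(X)$rank < ncol(X)) {
    stop("fit_ols: singular design (rank-deficient feature matrix)",
         call. = FALSE)
  }
  df <- as.data.frame(features)
  df$.y <- targets
  fit <- stats::lm(.y ~ ., data = df)
  sm <- summary(fit)$coefficients
  coefs <- sm[, "Estimate"]
  structure(list(feature_names = colnames(features),
                 intercept = unname(coefs["(Intercept)"]),
                 coefficients = coefs[colnames(features)],
                 se = sm[, "Std. Error"],
                 p_values = sm[, "Pr(>|t|)"],
                 n_fit = length(targets)),
            class = "linear_model")
}

#' Construct a linear model from published coefficients
#'
#' @param feature_names Ordered feature names.
#' @param intercept Intercept value.
#' @param coefficients Numeric vector, one per feature, in order.
#' @param p_values Optional named p-values (including `(Intercept)`).
#' @return A `linear_model` (no standard errors).
#' @export
linear_model <- function(feature_names, intercept, coefficients,
                         p_values = NULL) {
  stopifnot(length(coefficients) == length(feature_names))
  coefficients <- stats::setNames(as.numeric(coefficients), feature_names)
  structure(list(feature_names = feature_names, intercept = intercept,
                 coefficients = coefficients, se = NULL,
                 p_values = p_values, n_fit = NA_integer_),
            class = "linear_model")
}

#' @export
print.linear_model <- function(x, ...) {
  cat("<linear_model>", length(x$feature_names), "features")
  if (!is.na(x$n_fit)) cat(", fitted on n =", x$n_fit)
  cat("\n")
  tab <- data.frame(coefficient = c(x$intercept, unname(x$coefficients)),
                    row.names = c("(Intercept)", x$feature_names))
  if (!is.null(x$p_values)) tab$p_value <- unname(x$p_values)
  print(tab)
  invisible(x)
}

#' Evaluate a linear model
#'
#' `intercept + <coefficients, features>`; exactly affine in the features.
#'
#' @param model A `linear_model`.
#' @param features Numeric vector (one subject, in the model's feature order)
#'   or matrix with matching columns.
#' @return Numeric prediction(s).
#' @export
predict_linear <- function(model, features) {
  stopifnot(inherits(model, "linear_model"))
  if (is.matrix(features) || is.data.frame(features)) {
    features <- as.matrix(features)
    if (ncol(features) != length(model$feature_names)) {
      stop("predict_linear: feature count mismatch", call. = FALSE)
    }
    if (!is.null(colnames(features)) &&
        !identical(colnames(features), model$feature_names)) {
      if (!setequal(colnames(features), model$feature_names)) {
        stop("predict_linear: feature names do not match model", call. = FALSE)
      }
      features <- features[, model$feature_names, drop = FALSE]
    }
    return(as.numeric(model$intercept + features %*% model$coefficients))
  }
  if (length(features) != length(model$feature_names)) {
    stop("predict_linear: feature length mismatch", call. = FALSE)
  }
  model$intercept + sum(model$coefficients * as.numeric(features))
}

#' Published percent-body-fat regression coefficients
#'
#' The reference linear regression equations relating percent body fat to
#' anthropometrics and the impedance index, as printed for the 163-subject
#' athlete study: a conventional five-feature equation (age, gender, height,
#' weight, H^2/R50) and a proposed eight-feature equation adding waist, hip
#' and waist/hip. Feature order follows the printed table. These published
#' coefficients can be evaluated on new feature vectors with
#' [predict_linear()]; they are not re-fit by this package.
#'
#' @param which `"conventional"` or `"proposed"`.
#' @return A `linear_model` with published coefficients and p-values
#'   (p-values below the table's reporting limit are stored as 1e-4).
#' @examples
#' m <- published_pbf_model("conventional")
#' predict_linear(m, c(age = 20, gender = 1, height = 170, weight = 60,
#'                     h2_r50 = 50))
#' @export
published_pbf_model <- function(which = c("conventional", "proposed")) {
  which <- match.arg(which)
  if (which == "conventional") {
    linear_model(
      feature_names = c("age", "gender", "height", "weight", "h2_r50"),
      intercept = 59.6240,
      coefficients = c(-0.0992, 7.4604, -0.4174, 0.4673, -0.4217),
      p_values = c(`(Intercept)` = 1e-4, age = 0.2170, gender = 1e-4,
                   height = 1e-4, weight = 1e-4, h2_r50 = 1e-4))
  } else {
    linear_model(
      feature_names = c("age", "gender", "height", "weight", "h2_r50",
                        "waist", "hip", "waist_hip"),
      intercept = -16.2929,
      coefficients = c(-0.1302, 7.5189, -0.4005, 0.3763, -0.4021,
                       -0.6804, 0.7177, 78.5731),
      p_values = c(`(Intercept)` = 0.6774, age = 0.1059, gender = 1e-4,
                   height = 1e-4, weight = 1e-4, h2_r50 = 1e-4,
                   waist = 0.1224, hip = 0.0674, waist_hip = 0.0837))
  }
}
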