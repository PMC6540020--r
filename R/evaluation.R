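#' Pearson product-moment correlation
#'
#' @param x,y Numeric vectors of equal length (>= 3), each with nonzero
#'   variance.
#' @return Correlation coefficient in `[-1, 1]`.
#' @examples
#' pearson_r(c(1, 2, 3, 4), c(1.1, 1.9, 3.2, 3.8))
#' @export
pearson_r <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) {
    stop("pearson_r: vectors differ in length", call. = FALSE)
  }
  if (length(x) < 3) stop("pearson_r: need at least 3 points", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("pearson_r: zero variance, correlation undefined", call. = FALSE)
  }
  stats::cor(x, y)
}

#' Standard error of estimate (SEE)
#'
#' Residual spread of predictions about reference values, the standard
#' validation statistic of body-composition regression equations:
#' `sqrt(sum((ref - pred)^2) / (n - 2))`. The two-parameter denominator is
#' the convention of the BIA validation literature; pass `n_params` for an
#' `n - p - 1` denominator instead.
#'
#' @param ref Reference values (e.g. percent body fat from the reference
#'   device).
#' @param pred Predicted values, same length.
#' @param n_params Optional number of model parameters `p` for an
#'   `n - p - 1` denominator.
#' @return SEE, in the units of `ref` (percentage points for PBF).
#' @examples
#' see(c(1, 2, 3, 4), c(1.1, 1.9, 3.2, 3.8))
#' @export
see <- function(ref, pred, n_params = NULL) {
  ref <- as.numeric(ref); pred <- as.numeric(pred)
  if (length(ref) != length(pred)) {
    stop("see: vectors differ in length", call. = FALSE)
  }
  n <- length(ref)
  dof <- if (is.null(n_params)) n - 2 else n - n_params - 1
  if (dof <= 0) {
    stop("see: non-positive residual degrees of freedom", call. = FALSE)
  }
  sqrt(sum((ref - pred)^2) / dof)
}

#' Gender-balanced train/test split specification
#'
#' @param n_test Total test-set size (default 20).
#' @param n_test_male,n_test_female Test subjects per gender (default 10/10);
#'   must sum to `n_test`.
#' @param seed Integer seed for the shuffle.
#' @return Object of class `split_spec`.
#' @export
split_spec <- function(n_test = 20, n_test_male = 10, n_test_female = 10,
                       seed = 1L) {
  stopifnot(n_test_male + n_test_female == n_test, n_test >= 2)
  structure(list(n_test = as.integer(n_test),
                 n_test_male = as.integer(n_test_male),
                 n_test_female = as.integer(n_test_female),
                 seed = as.integer(seed)),
            class = "split_spec")
}

#' Split a cohort into training and gender-balanced test sets
#'
#' Draws the requested number of male and female subjects into the test set
#' by a seeded shuffle; all remaining subjects form the training set. The
#' two sets are disjoint and exhaustive.
#'
#' @param subjects Data frame with `id` and `gender` (female = 1, male = 0)
#'   columns, or a `bia_cohort`.
#' @param spec A [split_spec()].
#' @return List with `train` and `test` data frames.
#' @export
split_cohort <- function(subjects, spec = split_spec()) {
  if (inherits(subjects, "bia_cohort")) subjects <- subjects$subjects
  stopifnot(inherits(spec, "split_spec"))
  if (spec$n_test >= nrow(subjects)) {
    stop("split_cohort: n_test must be smaller than the cohort", call. = FALSE)
  }
  males <- subjects$id[subjects$gender == 0]
  females <- subjects$id[subjects$gender == 1]
  if (length(males) < spec$n_test_male) {
    stop("split_cohort: not enough male subjects for the requested balance",
         call. = FALSE)
  }
  if (length(females) < spec$n_test_female) {
    stop("split_cohort: not enough female subjects for the requested balance",
         call. = FALSE)
  }
  set.seed(spec$seed)
  test_ids <- c(sample(males, spec$n_test_male),
                sample(females, spec$n_test_female))
  list(train = subjects[!subjects$id %in% test_ids, , drop = FALSE],
       test = subjects[subjects$id %in% test_ids, , drop = FALSE])
}

#' One model/regime evaluation report
#'
#' @param regime Regime label.
#' @param ref Test-set reference values.
#' @param pred Test-set predictions.
#' @param n_train Training-set size.
#' @return Object of class `evaluation_report`: `regime`, `n_train`,
#'   `n_test`, `pearson_r`, `r_squared`, `see`.
#' @export
evaluation_report <- function(regime, ref, pred, n_train = NA_integer_) {
  r <- pearson_r(ref, pred)
  structure(list(regime = regime, n_train = n_train, n_test = length(ref),
                 pearson_r = r, r_squared = r^2, see = see(ref, pred)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %s: n_test = %d, r = %.4f, r2 = %.4f, SEE = %.3f\n",
              x$regime, x$n_test, x$pearson_r, x$r_squared, x$see))
  invisible(x)
}

#' Collect evaluation reports into a data frame
#'
#' @param reports List of `evaluation_report` objects.
#' @return data.frame with one row per regime.
#' @export
reports_to_df <- function(reports) {
  out <- do.call(rbind, lapply(reports, function(r) {
    data.frame(regime = r$regime, n_train = r$n_train, n_test = r$n_test,
               pearson_r = r$pearson_r, r_squared = r$r_squared, see = r$see,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
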