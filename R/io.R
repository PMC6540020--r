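#' Read a long-format measurement CSV
#'
#' Expects header `subject_id,t_s,ohms`, one row per timed sample, UTF-8,
#' dot decimal separator. Rows are grouped by subject and sorted by time;
#' uniform sampling spacing is validated per subject.
#'
#' @param path CSV file path.
#' @return Named list of [impedance_series], keyed by subject id.
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) {
    stop("read_measurements: file not found: ", path, call. = FALSE)
  }
  header <- strsplit(readLines(path, n = 1), ",")[[1]]
  if (!identical(trimws(header), c("subject_id", "t_s", "ohms"))) {
    stop("read_measurements: expected header 'subject_id,t_s,ohms' in ",
         path, call. = FALSE)
  }
  raw <- utils::read.csv(path, colClasses = c("character", "character",
                                              "character"),
                         check.names = FALSE)
  t_s <- suppressWarnings(as.numeric(raw$t_s))
  ohms <- suppressWarnings(as.numeric(raw$ohms))
  bad <- which(is.na(t_s) | is.na(ohms))
  if (length(bad)) {
    stop(sprintf("read_measurements: non-numeric value at line %d of %s",
                 bad[1] + 1L, path), call. = FALSE)  # +1 for header line
  }
  out <- list()
  for (id in unique(raw$subject_id)) {
    rows <- raw$subject_id == id
    ord <- order(t_s[rows])
    tt <- t_s[rows][ord]
    vv <- ohms[rows][ord]
    gaps <- diff(tt)
    if (length(gaps) && (any(gaps <= 0) ||
                         any(abs(gaps - gaps[1]) > 1e-9))) {
      stop(sprintf("read_measurements: non-uniform sampling for subject %s (first rows at lines %s)",
                   id, paste(which(rows)[1] + 1L)), call. = FALSE)
    }
    out[[id]] <- impedance_series(vv, delta_s = gaps[1], times = tt,
                                  subject_id = id)
  }
  out
}

#' Write a long-format measurement CSV
#'
#' @param series_list Named list of [impedance_series] (or a `bia_cohort`).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(series_list, path) {
  if (inherits(series_list, "bia_cohort")) {
    df <- cohort_measurements(series_list)
  } else {
    df <- do.call(rbind, lapply(series_list, function(s) {
      data.frame(subject_id = s$subject_id, t_s = s$times, ohms = s$values,
                 stringsAsFactors = FALSE)
    }))
  }
  utils::write.csv(format_num_df(df), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# fixed-precision numeric formatting so that written CSVs are byte-stable
# across runs and round-trip well below measurement resolution
format_num_df <- function(df, digits = 15) {
  for (nm in names(df)) {
    if (is.numeric(df[[nm]])) {
      df[[nm]] <- formatC(df[[nm]], digits = digits, format = "g")
    }
  }
  df
}

#' Write a cohort table CSV
#'
#' @param cohort A `bia_cohort`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "bia_cohort"))
  cols <- c("id", "group", "gender", "height_cm", "age_yr", "weight_kg",
            "waist_cm", "hip_cm", "true_pbf_pct", "ref_wholebody_r50_ohms",
            "finger_ohms")
  utils::write.csv(format_num_df(cohort$subjects[, cols]), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cohort table CSV
#'
#' @param path CSV written by [write_cohort()].
#' @return data.frame of subjects (with `ref_h2r` recomputed when the
#'   reference impedance column is present).
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(df$ref_wholebody_r50_ohms)) {
    df$ref_h2r <- df$height_cm^2 / df$ref_wholebody_r50_ohms
  }
  df
}

#' Serialise a linear model to JSON
#'
#' @param model A `linear_model`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_linear_model <- function(model, path) {
  stopifnot(inherits(model, "linear_model"))
  obj <- list(type = "linear_model",
              feature_names = model$feature_names,
              intercept = model$intercept,
              coefficients = unname(model$coefficients),
              p_values = if (!is.null(model$p_values))
                unname(model$p_values),
              n_fit = model$n_fit)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a linear model from JSON
#' @param path JSON written by [write_linear_model()].
#' @return A `linear_model`.
#' @export
read_linear_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- linear_model(obj$feature_names, obj$intercept, obj$coefficients)
  if (!is.null(obj$p_values)) {
    m$p_values <- stats::setNames(obj$p_values,
                                  c("(Intercept)", obj$feature_names))
  }
  if (!is.null(obj$n_fit)) m$n_fit <- obj$n_fit
  m
}

#' Serialise a trained network to JSON
#'
#' Weights are written at full precision so a model round-trips exactly.
#'
#' @param model An `mlp_model`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_mlp_model <- function(model, path) {
  stopifnot(inherits(model, "mlp_model"))
  obj <- list(type = "mlp_model",
              spec = unclass(model$spec),
              weights = lapply(model$weights, function(w)
                list(dim = dim(w), data = as.numeric(w))),
              biases = model$biases,
              x_center = model$x_center, x_scale = model$x_scale,
              y_center = model$y_center, y_scale = model$y_scale,
              feature_names = model$feature_names,
              stopped_epoch = model$stopped_epoch,
              best_epoch = model$best_epoch)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a trained network from JSON
#' @param path JSON written by [write_mlp_model()].
#' @return An `mlp_model` (without training history).
#' @export
read_mlp_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- do.call(mlp_spec, obj$spec[c("input_dim", "hidden_nodes",
                                       "learning_rate", "beta1", "beta2",
                                       "epsilon", "batch_size", "max_epochs",
                                       "patience", "val_fraction",
                                       "standardize", "seed")])
  weights <- lapply(seq_along(obj$weights$dim), function(i) {
    matrix(obj$weights$data[[i]], obj$weights$dim[[i]][1],
           obj$weights$dim[[i]][2])
  })
  structure(list(spec = spec, weights = weights,
                 biases = lapply(obj$biases, as.numeric),
                 x_center = obj$x_center, x_scale = obj$x_scale,
                 y_center = obj$y_center, y_scale = obj$y_scale,
                 feature_names = obj$feature_names,
                 history = NULL,
                 stopped_epoch = obj$stopped_epoch,
                 best_epoch = obj$best_epoch),
            class = "mlp_model")
}

#' Write the per-subject calibration table
#'
#' One row per feasible subject (`subject_id, settled_ohms, decay_rate,
#' amplitude, method, valid, violations`); rejected subjects keep their
#' violation labels but no settled value.
#'
#' @param calibration data.frame from [calibrate_series()].
#' @param path Output CSV path.
#' @param include_rejected Keep rejected rows in the file (default `FALSE`:
#'   rejected subjects are absent, as they require re-measurement).
#' @return `path`, invisibly.
#' @export
write_settled <- function(calibration, path, include_rejected = FALSE) {
  df <- calibration[, c("subject_id", "settled_ohms", "decay_rate",
                        "amplitude", "method", "valid", "violations")]
  if (!include_rejected) df <- df[df$valid, , drop = FALSE]
  utils::write.csv(format_num_df(df), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
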