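## Exclusion rules and feature scaling for the clustering layers.

#' Variables informing the clustering algorithm
#' @return Character vector of the 15 clustering columns.
#' @export
clustering_variables <- function() {
  c("glucose_0", "glucose_30", "glucose_120",
    "cpeptide_0", "cpeptide_30", "cpeptide_120",
    "insulin_0", "insulin_30", "insulin_120",
    "ffa_0", "ffa_30", "ffa_120",
    "age", "bmi", "waist")
}

#' Apply inclusion/exclusion rules
#'
#' Subjects under anti-diabetes medication are removed first; then subjects
#' with a missing value on any variable informing the clustering algorithm
#' (or missing sex, needed for gender-wise scaling).  A subject that is
#' both medicated and incomplete is counted once, under medication.
#' Outliers are deliberately retained.
#'
#' @param cohort A `cohort_table`.
#' @return A list with elements `cohort` (the retained subjects) and
#'   `report` (`list(n_input, medicated, missing, n_retained)`).
#' @export
apply_exclusions <- function(cohort) {
  stopifnot(nrow(cohort) > 0)
  med <- !is.na(cohort$on_medication) & cohort$on_medication
  vars <- clustering_variables()
  incomplete <- !stats::complete.cases(cohort[, vars]) | is.na(cohort$sex)
  missing_only <- incomplete & !med
  keep <- !med & !incomplete
  out <- cohort[keep, , drop = FALSE]
  class(out) <- c("cohort_table", "data.frame")
  list(
    cohort = out,
    report = list(n_input = nrow(cohort), medicated = sum(med),
                  missing = sum(missing_only), n_retained = sum(keep))
  )
}

#' Scale the clustering variables into five feature layers
#'
#' BMI and waist circumference are min-max scaled within gender; every
#' other clustering variable (the twelve OGTT measurements and age) is
#' z-standardized over the whole fit sample.  The raw OGTT analytes span
#' orders of magnitude (insulin in the hundreds of pmol/L versus FFA below
#' 1 mmol/L), so without standardization a Euclidean map would be driven by
#' insulin alone; the per-layer distance normalization applied at map
#' training time (see [train_som()]) then balances the five layers against
#' each other.
#'
#' Scaling parameters are stored in the result and can be reapplied to new
#' data (e.g. bootstrap resamples refit their own parameters; a holdout can
#' reuse the fit ones).
#'
#' @param cohort Post-exclusion cohort (no missing clustering variables).
#' @param params Optional parameters from a previous fit, to reapply.
#' @return An object of class `"feature_layers"`: list with `x` (n x 15
#'   numeric matrix), `layers` (named list of column indices: glucose,
#'   cpeptide, insulin, ffa, anthropometric), `scaling` (fit parameters),
#'   `ids`, `sex`.
#' @export
scale_features <- function(cohort, params = NULL) {
  vars <- clustering_variables()
  if (any(!stats::complete.cases(cohort[, vars])) || anyNA(cohort$sex))
    stop("cohort has missing clustering variables; run apply_exclusions() first")
  x <- as.matrix(cohort[, vars])
  sex <- cohort$sex
  zvars <- setdiff(vars, c("bmi", "waist"))
  if (is.null(params)) {
    mu <- colMeans(x[, zvars, drop = FALSE])
    sdev <- apply(x[, zvars, drop = FALSE], 2, stats::sd)
    if (any(sdev == 0))
      stop("constant clustering variable(s): ",
           paste(zvars[sdev == 0], collapse = ", "))
    minmax <- list()
    for (s in unique(sex)) {
      rows <- sex == s
      rng <- apply(x[rows, c("bmi", "waist"), drop = FALSE], 2, range)
      if (any(rng[2, ] - rng[1, ] == 0))
        stop("zero bmi/waist range in gender group '", s,
             "' (single subject or constant values)")
      minmax[[s]] <- rng
    }
    params <- list(mu = mu, sd = sdev, minmax = minmax)
  }
  out <- x
  out[, zvars] <- sweep(sweep(x[, zvars, drop = FALSE], 2, params$mu),
                        2, params$sd, "/")
  for (s in unique(sex)) {
    if (is.null(params$minmax[[s]]))
      stop("no stored scaling for gender group '", s, "'")
    rng <- params$minmax[[s]]
    rows <- sex == s
    for (v in c("bmi", "waist"))
      out[rows, v] <- (x[rows, v] - rng[1, v]) / (rng[2, v] - rng[1, v])
  }
  structure(
    list(
      x = out,
      layers = list(glucose = 1:3, cpeptide = 4:6, insulin = 7:9,
                    ffa = 10:12, anthropometric = 13:15),
      scaling = params,
      ids = cohort$id,
      sex = sex
    ),
    class = "feature_layers"
  )
}

#' Invert the feature scaling (round-trip check / interpretation)
#'
#' @param features A `feature_layers` object.
#' @return Matrix of the original-scale clustering variables.
#' @export
inverse_features <- function(features) {
  x <- features$x
  params <- features$scaling
  vars <- colnames(x)
  zvars <- setdiff(vars, c("bmi", "waist"))
  out <- x
  out[, zvars] <- sweep(sweep(x[, zvars, drop = FALSE], 2, params$sd, "*"),
                        2, params$mu, "+")
  for (s in unique(features$sex)) {
    rng <- params$minmax[[s]]
    rows <- features$sex == s
    for (v in c("bmi", "waist"))
      out[rows, v] <- x[rows, v] * (rng[2, v] - rng[1, v]) + rng[1, v]
  }
  out
}

#' @export
print.feature_layers <- function(x, ...) {
  cat("<feature_layers>", nrow(x$x), "subjects x", ncol(x$x),
      "features in", length(x$layers), "layers\n")
  invisible(x)
}
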