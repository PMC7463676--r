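## Metabolic archetypes: the parametric "phenotypes" the synthetic cohort
## generator mixes.  Concentration variables are log-normal (positive,
## right-skewed); anthropometrics are truncated normal.  The location
## parameter of every variable is its *median* (log-normal marginals are
## parameterised by meanlog = log(median)), matching the way population
## tables report central values.

# Variables drawn as correlated log-normal triples (one block per analyte).
.ogtt_vars <- c(
  "glucose_0", "glucose_30", "glucose_120",
  "cpeptide_0", "cpeptide_30", "cpeptide_120",
  "insulin_0", "insulin_30", "insulin_120",
  "ffa_0", "ffa_30", "ffa_120"
)
# Independent log-normal scalars.
.lognorm_vars <- c("hba1c", "tg", "hdl", "creatinine")
# Truncated-normal scalars with plausibility bounds.
.truncnorm_vars <- c("age", "bmi", "waist", "fat_mass_pct", "sbp", "dbp")
.trunc_bounds <- list(
  age = c(18, 95), bmi = c(15, 55), waist = c(55, 170),
  fat_mass_pct = c(5, 60), sbp = c(85, 230), dbp = c(45, 135)
)

.archetype_vars <- c(.ogtt_vars, .lognorm_vars, .truncnorm_vars)

#' Construct a metabolic archetype
#'
#' An archetype is a parametric phenotype used by [generate_cohort()]:
#' per-variable central values (medians) and coefficients of variation, a
#' mixture prevalence, and the serial correlation linking the three OGTT
#' time points of each analyte (AR(1)-like, `rho` between adjacent points,
#' `rho^2` between 0 and 120 min).
#'
#' @param name Archetype label, stored in the `true_archetype` column.
#' @param prevalence Mixture fraction in `[0, 1]`.
#' @param medians Named numeric vector of per-variable medians.  Must cover
#'   the twelve OGTT variables (`glucose_0/30/120`, `cpeptide_*`,
#'   `insulin_*` in pmol/L, `ffa_*`), `hba1c` (%), `tg`, `hdl`,
#'   `creatinine` (mg/dL), `age` (years), `bmi` (kg/m2), `waist` (cm),
#'   `fat_mass_pct` (%), `sbp`/`dbp` (mmHg).
#' @param cv Named numeric vector of coefficients of variation (same names).
#' @param ogtt_rho Within-subject correlation between adjacent OGTT time
#'   points, in `(-1, 1)`.
#' @return An object of class `"archetype"`.
#' @export
archetype <- function(name, prevalence, medians, cv, ogtt_rho = 0.6) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  stopifnot(is.numeric(prevalence), length(prevalence) == 1L,
            prevalence >= 0, prevalence <= 1)
  missing_m <- setdiff(.archetype_vars, names(medians))
  if (length(missing_m))
    stop("archetype '", name, "' is missing medians for: ",
         paste(missing_m, collapse = ", "))
  missing_c <- setdiff(.archetype_vars, names(cv))
  if (length(missing_c))
    stop("archetype '", name, "' is missing cv for: ",
         paste(missing_c, collapse = ", "))
  if (any(medians[.archetype_vars] <= 0))
    stop("archetype '", name, "' has non-positive medians")
  if (any(cv[.archetype_vars] < 0))
    stop("archetype '", name, "' has negative cv")
  if (abs(ogtt_rho) >= 1)
    stop("ogtt_rho must be in (-1, 1)")
  # AR(1) correlation across the three time points; chol() certifies PD.
  R <- .ogtt_corr(ogtt_rho)
  tryCatch(chol(R), error = function(e)
    stop("OGTT correlation structure is not positive definite"))
  structure(
    list(name = name, prevalence = prevalence,
         medians = medians[.archetype_vars], cv = cv[.archetype_vars],
         ogtt_rho = ogtt_rho),
    class = "archetype"
  )
}

.ogtt_corr <- function(rho) {
  matrix(c(1, rho, rho^2,
           rho, 1, rho,
           rho^2, rho, 1), 3, 3)
}

#' @export
print.archetype <- function(x, ...) {
  cat("<archetype>", x$name, sprintf("(prevalence %.3f, rho %.2f)\n",
                                     x$prevalence, x$ogtt_rho))
  invisible(x)
}

.default_cv <- c(
  glucose_0 = 0.10, glucose_30 = 0.14, glucose_120 = 0.18,
  cpeptide_0 = 0.30, cpeptide_30 = 0.28, cpeptide_120 = 0.30,
  insulin_0 = 0.35, insulin_30 = 0.35, insulin_120 = 0.40,
  ffa_0 = 0.35, ffa_30 = 0.38, ffa_120 = 0.45,
  hba1c = 0.05, tg = 0.35, hdl = 0.20, creatinine = 0.15,
  age = 0.16, bmi = 0.12, waist = 0.08, fat_mass_pct = 0.20,
  sbp = 0.10, dbp = 0.10
)

#' Default metabolic archetypes
#'
#' Four archetypes spanning the phenotypes a population OGTT survey is
#' expected to contain.  The normometabolic archetype is centred on the
#' published population medians of a Portuguese screening cohort (fasting
#' glucose 5.46 mmol/L, fasting insulin 43.1 pmol/L, fasting C-peptide
#' 0.68 nmol/L, fasting FFA 0.48 mmol/L, age 62 y, BMI 27 kg/m2, waist
#' 96 cm, HbA1c 5.5 %).  The other three plant the canonical departures:
#' insulin-resistant hyperinsulinemia (with obesity and a fatty-liver
#' milieu), insulin deficiency with high insulin clearance, and
#' hyperinsulinemia driven by low insulin clearance.
#'
#' @return A list of [archetype()] objects whose prevalences sum to 1.
#' @export
default_archetypes <- function() {
  normo <- c(
    glucose_0 = 5.46, glucose_30 = 9.16, glucose_120 = 6.58,
    cpeptide_0 = 0.68, cpeptide_30 = 2.09, cpeptide_120 = 2.59,
    insulin_0 = 43.1, insulin_30 = 318, insulin_120 = 238,
    ffa_0 = 0.48, ffa_30 = 0.33, ffa_120 = 0.12,
    hba1c = 5.5, tg = 105, hdl = 55, creatinine = 0.80,
    age = 62, bmi = 27, waist = 96, fat_mass_pct = 30,
    sbp = 125, dbp = 76
  )
  ir <- c(
    glucose_0 = 6.2, glucose_30 = 11.2, glucose_120 = 8.9,
    cpeptide_0 = 1.10, cpeptide_30 = 2.90, cpeptide_120 = 3.70,
    insulin_0 = 130, insulin_30 = 620, insulin_120 = 560,
    ffa_0 = 0.62, ffa_30 = 0.46, ffa_120 = 0.20,
    hba1c = 5.9, tg = 170, hdl = 42, creatinine = 0.85,
    age = 63, bmi = 32, waist = 108, fat_mass_pct = 38,
    sbp = 135, dbp = 82
  )
  deficient <- c(
    glucose_0 = 6.1, glucose_30 = 11.0, glucose_120 = 8.6,
    cpeptide_0 = 0.62, cpeptide_30 = 1.40, cpeptide_120 = 1.55,
    insulin_0 = 28, insulin_30 = 130, insulin_120 = 100,
    ffa_0 = 0.50, ffa_30 = 0.36, ffa_120 = 0.14,
    hba1c = 5.8, tg = 110, hdl = 54, creatinine = 0.82,
    age = 64, bmi = 25.5, waist = 92, fat_mass_pct = 27,
    sbp = 128, dbp = 78
  )
  lowclear <- c(
    glucose_0 = 5.7, glucose_30 = 9.8, glucose_120 = 7.4,
    cpeptide_0 = 0.70, cpeptide_30 = 2.10, cpeptide_120 = 2.70,
    insulin_0 = 110, insulin_30 = 560, insulin_120 = 450,
    ffa_0 = 0.50, ffa_30 = 0.34, ffa_120 = 0.13,
    hba1c = 5.6, tg = 130, hdl = 48, creatinine = 0.80,
    age = 60, bmi = 29, waist = 100, fat_mass_pct = 33,
    sbp = 130, dbp = 80
  )
  list(
    archetype("normometabolic", 0.55, normo, .default_cv),
    archetype("insulin_resistant", 0.20, ir, .default_cv),
    archetype("insulin_deficient_high_clearance", 0.15, deficient, .default_cv),
    archetype("hyperinsulinemic_low_clearance", 0.10, lowclear, .default_cv)
  )
}

#' Two-archetype configuration with a prescribed separation
#'
#' Builds a generator configuration mixing the normometabolic and
#' insulin-resistant default archetypes in equal proportion, with the
#' insulin-resistant mean vector moved along the line joining the two
#' archetype centres so that the fasting-insulin means are separated by
#' exactly `separation` pooled standard deviations (SD taken as
#' `cv * median` on the raw scale).  This is the planted two-cluster world
#' used for recovery and stability checks.
#'
#' @param n_subjects Cohort size.
#' @param seed Integer seed.
#' @param separation Pooled-SD separation of the fasting insulin means.
#' @param missing_rate,medicated_rate,female_fraction See
#'   [generator_config()].
#' @return A `generator_config` object.
#' @export
two_archetype_config <- function(n_subjects = 1000, seed = 1, separation = 3,
                                 missing_rate = 0.057, medicated_rate = 0.053,
                                 female_fraction = 0.6) {
  base <- default_archetypes()
  normo <- base[[1]]; ir <- base[[2]]
  m0 <- normo$medians; m1 <- ir$medians
  cvi <- .default_cv[["insulin_0"]]
  i0 <- m0[["insulin_0"]]
  # Find the scale s such that the moved insulin_0 median m(s) = i0 +
  # s*(i1 - i0) sits `separation` pooled SDs above i0.
  gap <- function(s) {
    mi <- i0 + s * (m1[["insulin_0"]] - i0)
    pooled <- sqrt(((cvi * i0)^2 + (cvi * mi)^2) / 2)
    (mi - i0) / pooled - separation
  }
  s <- stats::uniroot(gap, c(1e-6, 50), tol = 1e-10)$root
  moved <- m0 + s * (m1 - m0)
  if (any(moved <= 0))
    stop("separation ", separation,
         " pushes archetype medians non-positive; use a smaller value")
  sep_arch <- archetype("insulin_resistant", 0.5, moved, .default_cv)
  normo$prevalence <- 0.5
  generator_config(
    n_subjects = n_subjects,
    archetypes = list(normo, sep_arch),
    female_fraction = female_fraction,
    missing_rate = missing_rate,
    medicated_rate = medicated_rate,
    seed = seed
  )
}

#' Generator configuration
#'
#' @param n_subjects Non-negative integer number of subjects.
#' @param archetypes List of [archetype()] objects; prevalences must sum to
#'   1 within 1e-9.
#' @param female_fraction Fraction of women (default 0.6, the composition
#'   of the reference survey).
#' @param missing_rate Fraction of subjects given at least one missing
#'   clustering variable (default 0.057, the observed exclusion fraction).
#' @param medicated_rate Fraction flagged as under anti-diabetes medication
#'   (default 0.053).
#' @param seed Integer seed; identical config + seed gives identical output.
#' @return An object of class `"generator_config"`.
#' @export
generator_config <- function(n_subjects = 1088,
                             archetypes = default_archetypes(),
                             female_fraction = 0.6,
                             missing_rate = 0.057,
                             medicated_rate = 0.053,
                             seed = 1) {
  if (!is.numeric(n_subjects) || length(n_subjects) != 1L ||
      n_subjects < 0 || n_subjects != floor(n_subjects))
    stop("n_subjects must be a non-negative integer")
  if (!length(archetypes) || !all(vapply(archetypes, inherits, TRUE, "archetype")))
    stop("archetypes must be a non-empty list of archetype objects")
  prev <- vapply(archetypes, function(a) a$prevalence, 0)
  if (abs(sum(prev) - 1) > 1e-9)
    stop("archetype prevalences must sum to 1 (got ", sum(prev), ")")
  for (p in c(female_fraction, missing_rate, medicated_rate))
    if (!is.numeric(p) || p < 0 || p > 1)
      stop("female_fraction, missing_rate and medicated_rate must lie in [0, 1]")
  structure(
    list(n_subjects = as.integer(n_subjects), archetypes = archetypes,
         female_fraction = female_fraction, missing_rate = missing_rate,
         medicated_rate = medicated_rate, seed = as.integer(seed)),
    class = "generator_config"
  )
}

#' @export
print.generator_config <- function(x, ...) {
  cat("<generator_config>", x$n_subjects, "subjects,",
      length(x$archetypes), "archetypes, seed", x$seed, "\n")
  invisible(x)
}
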