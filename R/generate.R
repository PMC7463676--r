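## Synthetic cohort generation.  All randomness flows through the single
## seed in the config; the draw order is fixed by the code path, so an
## identical config reproduces the table exactly.

# Columns of a cohort table, in file order.
cohort_columns <- function() {
  c("id", "sex", "age", "weight", "height", "bmi", "waist",
    "glucose_0", "glucose_30", "glucose_120",
    "insulin_0", "insulin_30", "insulin_120",
    "cpeptide_0", "cpeptide_30", "cpeptide_120",
    "ffa_0", "ffa_30", "ffa_120",
    "hba1c", "tg", "hdl", "creatinine",
    "fat_mass_pct", "sbp", "dbp", "on_medication", "true_archetype")
}

# Inverse-CDF truncated normal: exact, vectorised, no rejection loop.
.rtruncnorm <- function(n, mean, sd, lo, hi) {
  plo <- pnorm((lo - mean) / sd)
  phi <- pnorm((hi - mean) / sd)
  mean + sd * qnorm(runif(n, plo, phi))
}

# Correlated log-normal OGTT triple with medians m3, cv cv3 and AR(1)
# correlation R (on the log scale).
.r_ogtt_triple <- function(n, m3, cv3, R) {
  sdlog <- sqrt(log(1 + cv3^2))
  Z <- matrix(rnorm(n * 3L), n, 3L) %*% chol(R)
  sweep(exp(sweep(Z, 2L, sdlog, "*")), 2L, m3, "*")
}

#' Generate a synthetic OGTT cohort
#'
#' Draws `n_subjects` subjects from the mixture of archetypes in `config`.
#' Concentrations (OGTT analytes, HbA1c, TG, HDL-c, creatinine) are
#' log-normal with the archetype's median and coefficient of variation; the
#' three OGTT time points of each analyte share an AR(1)-like within-subject
#' correlation on the log scale.  Anthropometrics are truncated normal, with
#' BMI and waist correlated (r = 0.8); height is drawn by sex and weight is
#' derived as `bmi * height^2`, so BMI is exactly consistent.  Missingness
#' (one randomly chosen clustering variable blanked) and anti-diabetes
#' medication flags are injected at the configured per-subject rates.
#'
#' @param config A [generator_config()].
#' @return A `data.frame` of class `"cohort_table"`, one row per subject,
#'   columns as in `cohort_columns()`.  `true_archetype` is the planted
#'   label; the analysis pipeline never reads it.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_subjects
  cols <- cohort_columns()
  if (n == 0L) {
    empty <- stats::setNames(
      as.data.frame(c(list(character(0), character(0)),
                      rep(list(numeric(0)), 24L),
                      list(logical(0), character(0)))), cols)
    class(empty) <- c("cohort_table", "data.frame")
    return(empty)
  }
  set.seed(config$seed)
  arch_names <- vapply(config$archetypes, function(a) a$name, "")
  prev <- vapply(config$archetypes, function(a) a$prevalence, 0)
  label <- sample(arch_names, n, replace = TRUE, prob = prev)
  sex <- ifelse(runif(n) < config$female_fraction, "female", "male")

  out <- as.data.frame(stats::setNames(rep(list(rep(NA_real_, n)), length(cols)), cols))
  out$id <- sprintf("S%05d", seq_len(n))
  out$sex <- sex
  out$true_archetype <- label

  for (a in config$archetypes) {
    idx <- which(label == a$name)
    g <- length(idx)
    if (!g) next
    m <- a$medians; cv <- a$cv
    R <- .ogtt_corr(a$ogtt_rho)
    for (analyte in c("glucose", "cpeptide", "insulin", "ffa")) {
      v3 <- paste0(analyte, c("_0", "_30", "_120"))
      out[idx, v3] <- .r_ogtt_triple(g, m[v3], cv[v3], R)
    }
    for (v in .lognorm_vars)
      out[idx, v] <- m[[v]] * exp(sqrt(log(1 + cv[[v]]^2)) * rnorm(g))
    # BMI and waist: correlated truncated bivariate normal (r = 0.8),
    # waist drawn from its exact conditional given BMI.
    bb <- .trunc_bounds$bmi; wb <- .trunc_bounds$waist
    mb <- m[["bmi"]]; sb <- cv[["bmi"]] * mb
    mw <- m[["waist"]]; sw <- cv[["waist"]] * mw
    bmi <- .rtruncnorm(g, mb, sb, bb[1], bb[2])
    rho_bw <- 0.8
    mu_c <- mw + sw * rho_bw * (bmi - mb) / sb
    sd_c <- sw * sqrt(1 - rho_bw^2)
    out[idx, "waist"] <- .rtruncnorm(g, mu_c, sd_c, wb[1], wb[2])
    out[idx, "bmi"] <- bmi
    for (v in c("age", "fat_mass_pct", "sbp", "dbp")) {
      b <- .trunc_bounds[[v]]
      out[idx, v] <- .rtruncnorm(g, m[[v]], cv[[v]] * m[[v]], b[1], b[2])
    }
  }
  # Height by sex, truncated to a plausible adult range; weight closes the
  # BMI identity exactly.
  hm <- ifelse(sex == "female", 1.60, 1.72)
  hs <- ifelse(sex == "female", 0.065, 0.07)
  out$height <- .rtruncnorm(n, hm, hs, 1.2, 2.2)
  out$weight <- out$bmi * out$height^2
  out$age <- round(out$age)

  out$on_medication <- runif(n) < config$medicated_rate
  miss <- runif(n) < config$missing_rate
  if (any(miss)) {
    # One clustering variable per affected subject is blanked (waist or an
    # OGTT measurement; BMI/age are assumed always recorded in a survey).
    candidates <- c(.ogtt_vars, "waist")
    pick <- sample(candidates, sum(miss), replace = TRUE)
    for (j in seq_along(pick)) out[which(miss)[j], pick[j]] <- NA_real_
  }
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Write / read a cohort table
#'
#' UTF-8 comma-delimited text, one row per subject, header as in
#' `cohort_columns()`, empty cell = missing.
#'
#' @param cohort A cohort table.
#' @param path File path.
#' @return `read_cohort` returns a `cohort_table`; `write_cohort` returns
#'   `path` invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "",
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                       fileEncoding = "UTF-8")
  required <- setdiff(cohort_columns(), c("true_archetype", "fat_mass_pct",
                                          "sbp", "dbp"))
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols))
    stop("cohort file is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (is.character(x$on_medication))
    x$on_medication <- toupper(x$on_medication) %in% c("TRUE", "1", "YES")
  class(x) <- c("cohort_table", "data.frame")
  x
}
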