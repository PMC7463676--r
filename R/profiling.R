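## Percentile-bin cluster profiling, dysglycemia composition, the radar
## "footprint" coordinates, and the gender comparison utility.

.bin_labels <- c("<p10", "p10-p25", "p25-p75", "p75-p90", ">p90")

#' Population percentiles of the profiling variables
#'
#' 10th/25th/75th/90th percentiles of every numeric profiling variable over
#' all included subjects (missing values skipped), by linear interpolation
#' between order statistics (quantile type 7).
#'
#' @param vars data.frame of profiling variables (rows = subjects).
#' @param min_n Minimum non-missing values per variable (default 10).
#' @return data.frame with columns `variable`, `p10`, `p25`, `p75`, `p90`.
#' @export
population_percentiles <- function(vars, min_n = 10) {
  num <- vars[vapply(vars, is.numeric, TRUE)]
  if (!ncol(num)) stop("no numeric profiling variables")
  res <- lapply(names(num), function(v) {
    x <- num[[v]][!is.na(num[[v]])]
    if (!length(x)) stop("variable '", v, "' is entirely missing")
    if (length(x) < min_n)
      stop("variable '", v, "' has fewer than ", min_n, " non-missing values")
    q <- stats::quantile(x, c(0.10, 0.25, 0.75, 0.90), type = 7, names = FALSE)
    data.frame(variable = v, p10 = q[1], p25 = q[2], p75 = q[3], p90 = q[4])
  })
  do.call(rbind, res)
}

# Ordinal bin of a median given the four population percentiles.
# Boundaries are inclusive towards the middle bin: < p10 | [p10, p25) |
# [p25, p75] | (p75, p90] | > p90.
.percentile_bin <- function(m, q) {
  ifelse(is.na(m), NA_integer_,
         ifelse(m < q$p10, 1L,
                ifelse(m < q$p25, 2L,
                       ifelse(m <= q$p75, 3L,
                              ifelse(m <= q$p90, 4L, 5L)))))
}

#' Profile clusters against population percentiles
#'
#' For every cluster and every profiling variable, the cluster median is
#' computed (missing values skipped) and assigned to one of five ordinal
#' bins relative to the population percentiles: `<p10`, `p10-p25`,
#' `p25-p75`, `p75-p90`, `>p90`.  A median exactly on a boundary resolves
#' towards the middle bin.
#'
#' @param assignment Named vector (subject id -> cluster).
#' @param vars data.frame of profiling variables with an `id` column or
#'   rownames matching the assignment names.
#' @param percentiles Output of [population_percentiles()] (computed on the
#'   whole included population, not per stratum).
#' @param stratum Label recorded in the result (`"all"`, `"male"`,
#'   `"female"`).
#' @return An object of class `"profile_matrix"`: list with `bins`
#'   (variables x clusters integer matrix, 1..5), `bin_labels`, `medians`
#'   (same shape), `percentiles`, `n` (subjects per cluster), `stratum`.
#' @export
profile_clusters <- function(assignment, vars, percentiles, stratum = "all") {
  ids <- if ("id" %in% names(vars)) vars$id else rownames(vars)
  if (is.null(ids)) stop("vars needs an 'id' column or rownames")
  keep <- ids %in% names(assignment)
  vars <- vars[keep, , drop = FALSE]
  ids <- ids[keep]
  cl <- assignment[ids]
  clusters <- sort(unique(cl))
  if (!length(clusters)) stop("assignment covers no subjects in vars")
  pvars <- percentiles$variable
  med <- matrix(NA_real_, length(pvars), length(clusters),
                dimnames = list(pvars, paste0("cluster_", clusters)))
  for (ci in seq_along(clusters)) {
    rows <- cl == clusters[ci]
    if (!any(rows)) stop("empty cluster: ", clusters[ci])
    for (v in pvars)
      med[v, ci] <- stats::median(vars[[v]][rows], na.rm = TRUE)
  }
  bins <- med
  for (v in pvars) {
    q <- percentiles[percentiles$variable == v, ]
    bins[v, ] <- .percentile_bin(med[v, ], q)
  }
  storage.mode(bins) <- "integer"
  structure(
    list(bins = bins, bin_labels = .bin_labels, medians = med,
         percentiles = percentiles,
         n = table(factor(cl, levels = clusters)), stratum = stratum),
    class = "profile_matrix"
  )
}

#' Dysglycemia composition per cluster
#'
#' @param assignment Named vector (subject id -> cluster).
#' @param glycemia_class Named character vector (subject id -> class in
#'   `{NG, IFG, IGT, IFG+IGT, DM}`).
#' @return list with `counts` (cluster x class matrix) and `fractions`
#'   (rows summing to 1).
#' @export
dysglycemia_composition <- function(assignment, glycemia_class) {
  ids <- intersect(names(assignment), names(glycemia_class))
  lev <- c("NG", "IFG", "IGT", "IFG+IGT", "DM")
  counts <- table(cluster = assignment[ids],
                  class = factor(glycemia_class[ids], levels = lev))
  counts <- unclass(counts)
  fractions <- counts / pmax(rowSums(counts), 1)
  list(counts = counts, fractions = fractions)
}

#' Default adverse-direction flags
#'
#' Variables for which a *low* value is the adverse direction (reversed in
#' the footprint radius): insulin sensitivity (Matsuda, ISI-FFA),
#' beta-cell function and secretion (HOMA-B, IGI, the secretion ratios,
#' DI), insulin clearance levels, renal function (eGFR), and HDL-c.
#' Everything else profiles adverse-high.  The same table ships as an
#' editable template in `extdata/adverse_low.csv`; [footprint()] accepts
#' any user-supplied replacement.
#'
#' @return Character vector of variable names.
#' @export
default_adverse_low <- function() {
  c("matsuda", "isi_ffa", "di", "egfr", "ic_fast", "ic_120",
    "homa_b", "igi", "delta_cpep_glu_030",
    "ratio_cpep_glu_030", "ratio_ins_glu_030", "hdl")
}

#' Default footprint variable grouping
#'
#' Milieu: what the subject is exposed to (raw OGTT analytes, their AUCs,
#' HbA1c, anthropometry).  Mechanisms: secretion, resistance and clearance
#' indexes.  Pathology: fatty-liver scores and renal function.  The same
#' table ships as an editable template in `extdata/footprint_groups.csv`.
#'
#' @return data.frame with columns `variable` and `group`.
#' @export
default_footprint_groups <- function() {
  milieu <- c("glucose_0", "glucose_30", "glucose_120",
              "insulin_0", "insulin_30", "insulin_120",
              "cpeptide_0", "cpeptide_30", "cpeptide_120",
              "ffa_0", "ffa_30", "ffa_120",
              "auc_glucose", "auc_insulin", "auc_cpeptide", "auc_ffa",
              "hba1c", "age", "bmi", "waist", "tg", "hdl")
  mechanisms <- c("homa_b", "homa_ir", "ratio_cpep_glu_030",
                  "ratio_ins_glu_030", "igi", "delta_cpep_glu_030", "di",
                  "matsuda", "liver_ir", "hepatic_ir", "adipo_ir",
                  "isi_ffa", "ic_fast", "ic_delta_030", "ic_120")
  pathology <- c("nafld_fls", "fli", "egfr")
  data.frame(
    variable = c(milieu, mechanisms, pathology),
    group = rep(c("milieu", "mechanisms", "pathology"),
                c(length(milieu), length(mechanisms), length(pathology))),
    stringsAsFactors = FALSE
  )
}

#' Radar-plot footprint coordinates
#'
#' Maps each variable's ordinal percentile bin to a radial coordinate in
#' `{0, 0.25, 0.5, 0.75, 1}`; variables whose adverse direction is low
#' (see `adverse_low`) are reversed so that a larger radius always means
#' more adverse.  Variables are grouped into milieu / mechanisms /
#' pathology by the declarative `grouping` table.
#'
#' @param profile A `profile_matrix`.
#' @param grouping data.frame with columns `variable`, `group` (default
#'   [default_footprint_groups()]).
#' @param adverse_low Character vector of adverse-low variables (default
#'   [default_adverse_low()]).
#' @return data.frame of class `"footprint"` with columns `cluster`,
#'   `variable`, `group`, `bin`, `radius`.
#' @export
footprint <- function(profile, grouping = default_footprint_groups(),
                      adverse_low = default_adverse_low()) {
  stopifnot(inherits(profile, "profile_matrix"))
  vars <- rownames(profile$bins)
  ungrouped <- setdiff(vars, grouping$variable)
  if (length(ungrouped))
    stop("ungrouped profiling variable(s): ", paste(ungrouped, collapse = ", "))
  group <- grouping$group[match(vars, grouping$variable)]
  out <- do.call(rbind, lapply(seq_len(ncol(profile$bins)), function(ci) {
    bin <- profile$bins[, ci]
    radius <- (bin - 1) / 4
    rev <- vars %in% adverse_low
    radius[rev] <- 1 - radius[rev]
    data.frame(cluster = colnames(profile$bins)[ci], variable = vars,
               group = group, bin = as.integer(bin), radius = radius,
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  class(out) <- c("footprint", "data.frame")
  out
}

#' Gender comparison of cohort and panel variables
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum, normal approximation) tests
#' for continuous variables and chi-square tests for categorical ones;
#' p-values are reported unadjusted.
#'
#' @param cohort Cohort table (supplies `sex` and the raw variables).
#' @param panel Optional `index_panel` aligned by `id` (its numeric columns
#'   and `glycemia_class` are tested too).
#' @return data.frame with columns `variable`, `test`, `statistic`,
#'   `p_value`.
#' @export
gender_compare <- function(cohort, panel = NULL) {
  sex <- cohort$sex
  if (length(unique(stats::na.omit(sex))) < 2)
    stop("both genders must be present")
  vars <- cohort[, setdiff(names(cohort),
                           c("id", "sex", "true_archetype")), drop = FALSE]
  if (!is.null(panel)) {
    p <- panel[match(cohort$id, panel$id),
               setdiff(names(panel), c("id")), drop = FALSE]
    vars <- cbind(vars, p)
  }
  rows <- lapply(names(vars), function(v) {
    x <- vars[[v]]
    if (is.numeric(x)) {
      ok <- !is.na(x) & !is.na(sex)
      if (length(unique(x[ok])) < 2) return(NULL)
      t <- stats::wilcox.test(x[ok] ~ sex[ok], exact = FALSE)
      data.frame(variable = v, test = "mann_whitney",
                 statistic = unname(t$statistic), p_value = t$p.value)
    } else {
      tab <- table(sex, as.character(x))
      if (any(dim(tab) < 2)) return(NULL)
      t <- suppressWarnings(stats::chisq.test(tab))
      data.frame(variable = v, test = "chi_square",
                 statistic = unname(t$statistic), p_value = t$p.value)
    }
  })
  do.call(rbind, rows)
}
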