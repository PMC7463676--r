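## Per-subject index panel: one call aggregating every metabolic index.

#' Compute the full metabolic index panel for a cohort
#'
#' One panel row per subject.  Every index is computed from the cohort's
#' raw measurements or flagged missing when a required input is missing
#' (or a formula is undefined for the input).  Insulin columns may be
#' supplied in mIU/L instead of the package's pmol/L convention via
#' `insulin_unit`; they are converted (x 6.0) before anything else, so all
#' indexes are invariant to the declared unit.
#'
#' @param cohort A `cohort_table` (see [generate_cohort()]).
#' @param insulin_unit Unit of the `insulin_*` columns, `"pmol_per_L"`
#'   (default) or `"mIU_per_L"`.
#' @param homa_backend Optional replacement backend for [homa_indexes()].
#' @return A data.frame of class `"index_panel"` with columns `id`,
#'   `auc_glucose`, `auc_insulin`, `auc_cpeptide`, `auc_ffa`, `homa_b`,
#'   `homa_ir`, `ratio_cpep_glu_030`, `ratio_ins_glu_030`, `igi`,
#'   `delta_cpep_glu_030`, `di`, `matsuda`, `liver_ir`, `hepatic_ir`,
#'   `adipo_ir`, `isi_ffa`, `ic_fast`, `ic_delta_030`, `ic_120`,
#'   `nafld_fls`, `fli`, `egfr`, `mets`, `t2d`, `glycemia_class`.
#' @export
compute_panel <- function(cohort, insulin_unit = c("pmol_per_L", "mIU_per_L"),
                          homa_backend = NULL) {
  insulin_unit <- match.arg(insulin_unit)
  if (!nrow(cohort)) stop("cohort is empty")
  x <- as.data.frame(cohort)
  if (insulin_unit == "mIU_per_L")
    for (v in c("insulin_0", "insulin_30", "insulin_120"))
      x[[v]] <- x[[v]] * 6.0
  tt <- c(0, 30, 120)
  gm <- as.matrix(x[, c("glucose_0", "glucose_30", "glucose_120")])
  im <- as.matrix(x[, c("insulin_0", "insulin_30", "insulin_120")])
  cm <- as.matrix(x[, c("cpeptide_0", "cpeptide_30", "cpeptide_120")])
  fm <- as.matrix(x[, c("ffa_0", "ffa_30", "ffa_120")])

  out <- data.frame(id = x$id)
  out$auc_glucose <- auc_trapezoid(tt, gm)
  out$auc_insulin <- auc_trapezoid(tt, im)
  out$auc_cpeptide <- auc_trapezoid(tt, cm)
  out$auc_ffa <- auc_trapezoid(tt, fm)

  out <- cbind(out, homa_indexes(gm[, 1], im[, 1], cm[, 1],
                                 backend = homa_backend))
  out <- cbind(out, beta_cell_indexes(gm[, 1], gm[, 2], im[, 1], im[, 2],
                                      cm[, 1], cm[, 2]))
  out$matsuda <- matsuda(gm, im)

  auc_g_030 <- auc_trapezoid(c(0, 30), gm[, 1:2])
  auc_i_030 <- auc_trapezoid(c(0, 30), im[, 1:2])
  fat <- if ("fat_mass_pct" %in% names(x)) x$fat_mass_pct else NA_real_
  out <- cbind(out, tissue_ir(
    auc_insulin_0_120 = out$auc_insulin,
    auc_glucose_030 = auc_g_030, auc_insulin_030 = auc_i_030,
    fat_mass_pct = fat, hdl = x$hdl, bmi = x$bmi,
    ffa0 = fm[, 1], i0 = im[, 1],
    auc_insulin = out$auc_insulin, auc_ffa = out$auc_ffa
  ))
  out <- cbind(out, insulin_clearance(cm[, 1], cm[, 2], cm[, 3],
                                      im[, 1], im[, 2], im[, 3]))

  out$glycemia_class <- classify_glycemia(gm[, 1], gm[, 3])
  out$t2d <- !is.na(out$glycemia_class) & out$glycemia_class == "DM"
  out$t2d[is.na(out$glycemia_class)] <- NA
  sbp <- if ("sbp" %in% names(x)) x$sbp else NA_real_
  dbp <- if ("dbp" %in% names(x)) x$dbp else NA_real_
  out$mets <- idf_metabolic_syndrome(x$waist, x$sex, x$tg, x$hdl,
                                     sbp, dbp, gm[, 1])
  out <- cbind(out, fatty_liver_scores(out$mets, out$t2d, im[, 1],
                                       x$tg, x$bmi, x$waist))
  out$egfr <- egfr_ckd_epi(x$creatinine, x$age, x$sex)
  class(out) <- c("index_panel", "data.frame")
  out
}

#' Units manifest for the index panel
#'
#' @return A data.frame documenting the unit of every panel column.
#' @export
units_manifest <- function() {
  data.frame(
    column = c("auc_glucose", "auc_insulin", "auc_cpeptide", "auc_ffa",
               "homa_b", "homa_ir", "ratio_cpep_glu_030",
               "ratio_ins_glu_030", "igi", "delta_cpep_glu_030", "di",
               "matsuda", "liver_ir", "hepatic_ir", "adipo_ir", "isi_ffa",
               "ic_fast", "ic_delta_030", "ic_120", "nafld_fls", "fli",
               "egfr", "glycemia_class"),
    unit = c("mmol/L.min", "pmol/L.min", "nmol/L.min", "mmol/L.min",
             "%", "dimensionless", "nmol/mmol", "pmol/mmol",
             "pmol/L per mmol/L", "nmol/L per mmol/L", "1/mmol",
             "dimensionless", "dimensionless", "pmol.mmol/L^2.min^2",
             "mmol.pmol/L^2", "dimensionless", "nmol/pmol",
             "nmol/pmol per min", "nmol/pmol", "score", "score (0-100)",
             "mL/min/1.73m2", "class"),
    stringsAsFactors = FALSE
  )
}

#' Write an index panel with its units manifest
#'
#' @param panel An `index_panel`.
#' @param path CSV path for the panel; the manifest is written next to it
#'   with suffix `"_units.csv"`.
#' @export
write_panel <- function(panel, path) {
  utils::write.csv(panel, path, row.names = FALSE, na = "", quote = FALSE)
  utils::write.csv(units_manifest(),
                   sub("\\.csv$", "_units.csv", path),
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
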