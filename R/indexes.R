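## OGTT-derived metabolic and functional indexes.  All functions are
## vectorised over subjects and propagate NA: an index is missing exactly
## when one of its required inputs is missing (or the formula is undefined
## for the input, e.g. a zero glucose excursion in a difference quotient).
##
## Unit conventions, fixed across the package:
##   glucose  mmol/L     insulin  pmol/L      C-peptide  nmol/L
##   FFA      mmol/L     TG/HDL/creatinine  mg/dL        HbA1c  %
## Conversions used where a formula demands other units:
##   glucose mmol/L -> mg/dL : * 18.016
##   insulin pmol/L -> mIU/L : / 6.0

GLUCOSE_MMOL_TO_MGDL <- 18.016
INSULIN_PMOL_TO_MIU <- 1 / 6.0

#' Trapezoidal area under the curve
#'
#' @param times Strictly increasing numeric vector of sampling times
#'   (minutes); at least two points.
#' @param values Concentrations at `times` (a vector), or a matrix with one
#'   row per subject and one column per time point.
#' @return The trapezoidal AUC in analyte-unit x min (vector of one value
#'   per subject when `values` is a matrix).  `NA` where any value is
#'   missing.
#' @examples
#' auc_trapezoid(c(0, 30, 120), c(5.46, 9.16, 6.58))  # 927.6
#' @export
auc_trapezoid <- function(times, values) {
  if (length(times) < 2L) stop("need at least 2 time points")
  if (any(is.na(times)) || any(diff(times) <= 0))
    stop("times must be strictly increasing and non-missing")
  if (is.matrix(values) || is.data.frame(values)) {
    values <- as.matrix(values)
    if (ncol(values) != length(times))
      stop("values must have one column per time point")
    dt <- diff(times)
    mid <- (values[, -ncol(values), drop = FALSE] +
              values[, -1L, drop = FALSE]) / 2
    as.numeric(mid %*% dt)
  } else {
    if (length(values) != length(times))
      stop("times and values must have equal length")
    sum(diff(times) * (values[-length(values)] + values[-1L]) / 2)
  }
}

#' Beta-cell function indexes over the early OGTT
#'
#' Absorptive secretion ratios, insulinogenic index (IGI), the C-peptide
#' difference quotient, and the disposition index (DI = IGI / fasting
#' insulin).  When the 0-30 min glucose excursion is zero the difference
#' quotients are undefined and returned as `NA`.
#'
#' @param g0,g30 Glucose (mmol/L) at 0 and 30 min.
#' @param i0,i30 Insulin (pmol/L) at 0 and 30 min.
#' @param c0,c30 C-peptide (nmol/L) at 0 and 30 min.
#' @return A data.frame with columns `ratio_cpep_glu_030`,
#'   `ratio_ins_glu_030`, `igi`, `delta_cpep_glu_030`, `di`.
#' @export
beta_cell_indexes <- function(g0, g30, i0, i30, c0, c30) {
  dg <- g30 - g0
  undef <- !is.na(dg) & dg == 0
  igi <- (i30 - i0) / dg
  dcg <- (c30 - c0) / dg
  igi[undef] <- NA_real_
  dcg[undef] <- NA_real_
  data.frame(
    ratio_cpep_glu_030 = (c0 + c30) / (g0 + g30),
    ratio_ins_glu_030 = (i0 + i30) / (g0 + g30),
    igi = igi,
    delta_cpep_glu_030 = dcg,
    di = igi / i0
  )
}

#' Homeostatic model (HOMA) indexes, closed-form approximation
#'
#' The reference computer model behind the second-generation HOMA indexes
#' is a closed-source iterative calculator; this function provides the
#' classic closed-form first-generation approximation and is clearly
#' labelled as such.  The resistance index uses fasting insulin,
#' `HOMA-IR = G0[mmol/L] * I0[mIU/L] / 22.5`.  The beta-cell index uses
#' fasting C-peptide in place of insulin (C-peptide is the stated input of
#' the reference calculation), converted to an insulin-equivalent via a
#' documented fasting molar equivalence (`cpep_scale`, default 10.6 mIU/L
#' per nmol/L): `HOMA-B = 20 * I_eq / (G0 - 3.5)`, undefined (NA) when
#' `G0 <= 3.5` mmol/L.
#'
#' A user-supplied `backend` (e.g. precomputed reference-calculator values)
#' is accepted unchanged: it must be a `function(g0, i0, c0)` returning a
#' list or data.frame with elements `homa_b` and `homa_ir`.
#'
#' @param g0 Fasting glucose, mmol/L.
#' @param i0 Fasting insulin, pmol/L.
#' @param c0 Fasting C-peptide, nmol/L.
#' @param cpep_scale Fasting insulin-equivalent of 1 nmol/L C-peptide, mIU/L.
#' @param backend Optional replacement backend (see Details).
#' @return data.frame with columns `homa_b` (%) and `homa_ir`.
#' @export
homa_indexes <- function(g0, i0, c0, cpep_scale = 10.6, backend = NULL) {
  if (!is.null(backend)) {
    out <- backend(g0, i0, c0)
    return(data.frame(homa_b = out$homa_b, homa_ir = out$homa_ir))
  }
  homa_ir <- g0 * (i0 * INSULIN_PMOL_TO_MIU) / 22.5
  homa_b <- 20 * (c0 * cpep_scale) / (g0 - 3.5)
  homa_b[!is.na(g0) & g0 <= 3.5] <- NA_real_
  homa_b[!is.na(homa_b) & (is.na(c0) | c0 <= 0)] <- NA_real_
  data.frame(homa_b = homa_b, homa_ir = homa_ir)
}

#' Matsuda whole-body insulin sensitivity index
#'
#' Composite index over the three available OGTT time points:
#' `10000 / sqrt(G0 * I0 * Gmean * Imean)` with glucose in mg/dL and
#' insulin in uU/mL, where the means are taken over 0/30/120 min.
#'
#' @param g Glucose matrix (subjects x 3) or length-3 vector, mmol/L.
#' @param i Insulin matrix (subjects x 3) or length-3 vector, pmol/L.
#' @return Numeric vector; `NA` when any input is missing or non-positive.
#' @export
matsuda <- function(g, i) {
  g <- rbind(g); i <- rbind(i)
  if (ncol(g) != 3L || ncol(i) != 3L)
    stop("matsuda needs the three OGTT time points of glucose and insulin")
  gm <- g * GLUCOSE_MMOL_TO_MGDL
  im <- i * INSULIN_PMOL_TO_MIU
  bad <- rowSums(is.na(gm) | is.na(im) | gm <= 0 | im <= 0) > 0
  out <- 10000 / sqrt(gm[, 1] * im[, 1] * rowMeans(gm) * rowMeans(im))
  out[bad] <- NA_real_
  unname(out)
}

#' Tissue-specific insulin resistance composites
#'
#' * `liver_ir  = -0.091 + 0.400 log(AUC(0-120)Insulin) + 0.346 log(fat%)
#'                - 0.408 log(HDL) + 0.435 log(BMI)` (log base 10)
#' * `hepatic_ir = AUC(0-30)Insulin * AUC(0-30)Glucose` (native units)
#' * `adipo_ir   = FFA0 * Insulin0`
#' * `isi_ffa    = 2 / (AUC(0-30-120)Insulin' * AUC(0-30-120)FFA' + 1)`
#'
#' The ISI-FFA product is scale-sensitive and the source formula carries no
#' units; the package scales the insulin AUC by `1/insulin_auc_scale`
#' (default 1e4, pmol/L x min) and the FFA AUC by `1/ffa_auc_scale`
#' (default 30, mmol/L x min) so the product is O(1) and the index spans
#' (0, 2].  Non-positive arguments to a logarithm flag `liver_ir` as NA.
#'
#' @param auc_insulin_0_120 Three-point insulin AUC over 0-120 min.
#' @param auc_glucose_030,auc_insulin_030 0-30 min trapezoids.
#' @param fat_mass_pct Fat mass, %.
#' @param hdl HDL-c, mg/dL.
#' @param bmi kg/m2.
#' @param ffa0 Fasting FFA, mmol/L.
#' @param i0 Fasting insulin, pmol/L.
#' @param auc_insulin,auc_ffa Three-point AUCs for ISI-FFA.
#' @param log_base Base of the logarithms in Liver-IR (default 10).
#' @param insulin_auc_scale,ffa_auc_scale ISI-FFA scale constants.
#' @return data.frame with columns `liver_ir`, `hepatic_ir`, `adipo_ir`,
#'   `isi_ffa`.
#' @export
tissue_ir <- function(auc_insulin_0_120, auc_glucose_030, auc_insulin_030,
                      fat_mass_pct, hdl, bmi, ffa0, i0,
                      auc_insulin, auc_ffa,
                      log_base = 10,
                      insulin_auc_scale = 1e4, ffa_auc_scale = 30) {
  lg <- function(x) {
    out <- log(x, base = log_base)
    out[!is.na(x) & x <= 0] <- NA_real_
    out
  }
  liver_ir <- -0.091 + 0.400 * lg(auc_insulin_0_120) +
    0.346 * lg(fat_mass_pct) - 0.408 * lg(hdl) + 0.435 * lg(bmi)
  data.frame(
    liver_ir = liver_ir,
    hepatic_ir = auc_insulin_030 * auc_glucose_030,
    adipo_ir = ffa0 * i0,
    isi_ffa = 2 / ((auc_insulin / insulin_auc_scale) *
                     (auc_ffa / ffa_auc_scale) + 1)
  )
}

#' Insulin clearance from C-peptide / insulin ratios
#'
#' * `ic_fast = C0 / I0`
#' * `ic_30   = (C0 + C30) / (I0 + I30)` (0-30 min AUC ratio; the trapezoid
#'   factors cancel on a single interval)
#' * `ic_120  = (C30 + C120) / (I30 + I120)` (30-120 min AUC ratio)
#' * `ic_delta_030 = (ic_fast - ic_30) / 30`, the per-minute suppression of
#'   clearance over the early OGTT (positive when clearance falls, as it
#'   typically does after the glucose load).
#'
#' @param c0,c30,c120 C-peptide, nmol/L.
#' @param i0,i30,i120 Insulin, pmol/L; must be positive.
#' @return data.frame with columns `ic_fast`, `ic_delta_030`, `ic_120`
#'   (nmol/pmol; the suppression slope is per minute).
#' @export
insulin_clearance <- function(c0, c30, c120, i0, i30, i120) {
  bad0 <- !is.na(i0) & i0 <= 0
  ic_fast <- c0 / i0
  ic_30 <- (c0 + c30) / (i0 + i30)
  ic_120 <- (c30 + c120) / (i30 + i120)
  ic_fast[bad0] <- NA_real_
  data.frame(
    ic_fast = ic_fast,
    ic_delta_030 = (ic_fast - ic_30) / 30,
    ic_120 = ic_120
  )
}

#' Fatty-liver surrogate scores
#'
#' * `nafld_fls = -2.889 + 1.179 * MetS + 0.454 * T2D(yes = 2) +
#'   0.145 * Insulin0[mIU/L]` where MetS is the metabolic-syndrome flag
#'   (1/0) and T2D contributes 2 when present.
#' * `fli = 100 * logistic(0.953 ln TG + 0.139 BMI + 0.053 waist - 15.745)`
#'   with TG in mg/dL.
#'
#' @param mets Logical metabolic-syndrome flag.
#' @param t2d Logical type 2 diabetes flag.
#' @param i0 Fasting insulin, pmol/L.
#' @param tg Triglycerides, mg/dL (must be positive).
#' @param bmi kg/m2.
#' @param waist cm.
#' @return data.frame with columns `nafld_fls` and `fli` (in `[0, 100]`).
#' @export
fatty_liver_scores <- function(mets, t2d, i0, tg, bmi, waist) {
  nafld_fls <- -2.889 + 1.179 * as.numeric(mets) + 0.454 * 2 * as.numeric(t2d) +
    0.145 * i0 * INSULIN_PMOL_TO_MIU
  lp <- 0.953 * log(tg) + 0.139 * bmi + 0.053 * waist - 15.745
  lp[!is.na(tg) & tg <= 0] <- NA_real_
  data.frame(nafld_fls = nafld_fls, fli = 100 * stats::plogis(lp))
}

#' Estimated glomerular filtration rate (CKD-EPI 2009, creatinine)
#'
#' Sex-specific knots kappa (0.7 female / 0.9 male) and exponents alpha
#' (-0.329 / -0.411); the race coefficient is omitted (single-origin
#' cohort, no race variable):
#' `eGFR = 141 * min(Scr/k, 1)^a * max(Scr/k, 1)^-1.209 * 0.993^age *
#' 1.018[female]`.
#'
#' @param creatinine Serum creatinine, mg/dL (positive).
#' @param age Years (positive).
#' @param sex `"male"`/`"female"` character vector.
#' @return eGFR in mL/min/1.73 m2.
#' @export
egfr_ckd_epi <- function(creatinine, age, sex) {
  female <- sex == "female"
  kappa <- ifelse(female, 0.7, 0.9)
  alpha <- ifelse(female, -0.329, -0.411)
  scr_k <- creatinine / kappa
  out <- 141 * pmin(scr_k, 1)^alpha * pmax(scr_k, 1)^-1.209 *
    0.993^age * ifelse(female, 1.018, 1)
  out[(!is.na(creatinine) & creatinine <= 0) | (!is.na(age) & age <= 0)] <- NA_real_
  out
}

#' WHO 1999 / IDF dysglycemia classification
#'
#' Diabetes when fasting glucose >= 7.0 mmol/L or 2 h glucose >= 11.1;
#' impaired fasting glucose (IFG) when 6.1 <= G0 < 7.0; impaired glucose
#' tolerance (IGT) when 7.8 <= G120 < 11.1; `IFG+IGT` when both bands hold;
#' else normoglycemia (NG).  A missing 2 h value leaves IGT undeterminable
#' (the fasting bands still apply); a missing fasting value gives `NA`.
#'
#' @param g0 Fasting glucose, mmol/L.
#' @param g120 2 h glucose, mmol/L (may be missing).
#' @return Character vector in `{"NG","IFG","IGT","IFG+IGT","DM", NA}`.
#' @export
classify_glycemia <- function(g0, g120) {
  n <- max(length(g0), length(g120))
  g0 <- rep_len(g0, n); g120 <- rep_len(g120, n)
  out <- rep(NA_character_, n)
  known0 <- !is.na(g0)
  dm <- known0 & (g0 >= 7.0 | (!is.na(g120) & g120 >= 11.1))
  ifg <- known0 & g0 >= 6.1 & g0 < 7.0
  igt <- !is.na(g120) & g120 >= 7.8 & g120 < 11.1
  out[known0] <- "NG"
  out[known0 & igt] <- "IGT"
  out[ifg] <- "IFG"
  out[ifg & igt] <- "IFG+IGT"
  out[dm] <- "DM"
  out
}

#' Body mass index
#' @param weight kg.
#' @param height m.
#' @return kg/m2; `NA` for non-positive height.
#' @export
bmi <- function(weight, height) {
  out <- weight / height^2
  out[!is.na(height) & height <= 0] <- NA_real_
  out
}

#' IDF metabolic syndrome flag
#'
#' Central obesity (waist >= 94 cm men / >= 80 cm women) plus at least two
#' of: TG >= 150 mg/dL; HDL-c < 40 (men) / < 50 (women) mg/dL; blood
#' pressure >= 130/85 mmHg (missing BP counts as not met); fasting glucose
#' >= 5.6 mmol/L.
#'
#' @param waist cm.
#' @param sex "male"/"female".
#' @param tg,hdl mg/dL.
#' @param sbp,dbp mmHg (may be missing).
#' @param g0 mmol/L.
#' @return Logical vector.
#' @export
idf_metabolic_syndrome <- function(waist, sex, tg, hdl, sbp, dbp, g0) {
  female <- sex == "female"
  central <- waist >= ifelse(female, 80, 94)
  comp <- cbind(
    tg >= 150,
    hdl < ifelse(female, 50, 40),
    (!is.na(sbp) & sbp >= 130) | (!is.na(dbp) & dbp >= 85),
    g0 >= 5.6
  )
  comp[is.na(comp)] <- FALSE
  central & rowSums(comp) >= 2
}
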