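# Frozen expected values below were computed by straight-line arithmetic on
# the published population medians (fasting glucose 5.46 mmol/L, 30 min
# 9.16, 120 min 6.58; insulin 43.1/318/238 pmol/L; C-peptide
# 0.68/2.09/2.59 nmol/L; FFA 0.48/0.33/0.12 mmol/L) before implementation.

g3 <- c(5.46, 9.16, 6.58)
i3 <- c(43.1, 318, 238)
c3 <- c(0.68, 2.09, 2.59)
f3 <- c(0.48, 0.33, 0.12)
tt <- c(0, 30, 120)

test_that("trapezoidal AUC matches hand evaluation and is linear", {
  expect_equal(auc_trapezoid(tt, g3), 927.6)
  expect_equal(round(auc_trapezoid(tt, g3)), 928)
  expect_equal(auc_trapezoid(tt, f3), 32.4)
  expect_equal(auc_trapezoid(tt, rep(3.7, 3)), 120 * 3.7)

  expect_error(auc_trapezoid(0, 5), "at least 2")
  expect_error(auc_trapezoid(c(0, 30, 20), c(1, 2, 3)), "increasing")
  expect_true(is.na(auc_trapezoid(tt, rbind(c(1, NA, 2)))))

  # linearity: auc(a v + b w) = a auc(v) + b auc(w), on random curves
  set.seed(4)
  for (rep in 1:20) {
    v <- runif(3, 1, 10); w <- runif(3, 1, 10); ab <- runif(2, -2, 2)
    expect_equal(auc_trapezoid(tt, ab[1] * v + ab[2] * w),
                 ab[1] * auc_trapezoid(tt, v) + ab[2] * auc_trapezoid(tt, w),
                 tolerance = 1e-12)
  }
  # matrix form agrees with row-wise vector form
  m <- matrix(runif(12, 1, 5), 4, 3)
  expect_equal(auc_trapezoid(tt, m),
               apply(m, 1, function(r) auc_trapezoid(tt, r)))
})

test_that("beta-cell indexes reproduce the median worked example", {
  b <- beta_cell_indexes(g3[1], g3[2], i3[1], i3[2], c3[1], c3[2])
  expect_equal(b$igi, 74.2972972973, tolerance = 1e-10)
  expect_equal(b$di, 1.72383520411, tolerance = 1e-10)
  expect_equal(b$ratio_cpep_glu_030, (0.68 + 2.09) / (5.46 + 9.16))
  expect_equal(b$ratio_ins_glu_030, (43.1 + 318) / (5.46 + 9.16))
  # zero numerator and undefined excursion
  expect_equal(beta_cell_indexes(5, 6, 50, 50, 0.7, 1.5)$igi, 0)
  flat <- beta_cell_indexes(5.5, 5.5, 40, 300, 0.7, 2)
  expect_true(is.na(flat$igi) && is.na(flat$delta_cpep_glu_030) &&
                is.na(flat$di))
  expect_false(is.na(flat$ratio_ins_glu_030))
})

test_that("HOMA closed forms, undefined band and backend pass-through", {
  h <- homa_indexes(5.46, 43.1, 0.68)
  expect_equal(h$homa_ir, 1.74315555556, tolerance = 1e-10)
  expect_equal(homa_indexes(5.46, 2 * 43.1, 0.68)$homa_ir, 2 * h$homa_ir)
  expect_true(is.na(homa_indexes(3.4, 43.1, 0.68)$homa_b))
  expect_false(is.na(homa_indexes(3.4, 43.1, 0.68)$homa_ir))
  # user backend values must pass through unchanged
  be <- function(g0, i0, c0) list(homa_b = rep(123, length(g0)),
                                  homa_ir = rep(0.81, length(g0)))
  hb <- homa_indexes(5.46, 43.1, 0.68, backend = be)
  expect_identical(hb$homa_b, 123)
  expect_identical(hb$homa_ir, 0.81)
})

test_that("Matsuda index: worked value, homogeneity, degenerate case", {
  expect_equal(matsuda(g3, i3), 5.77911830752, tolerance = 1e-10)
  # two insulin factors under the square root: scaling insulin by c
  # scales the index by 1/c
  expect_equal(matsuda(g3, 4 * i3), matsuda(g3, i3) / 4, tolerance = 1e-12)
  # constant profiles collapse to 10000 / (G0_mgdl * I0_uU)
  expect_equal(matsuda(rep(5, 3), rep(60, 3)),
               10000 / ((5 * 18.016) * (60 / 6)), tolerance = 1e-12)
  expect_true(is.na(matsuda(c(5, NA, 6), i3)))
  expect_true(is.na(matsuda(c(5, -1, 6), i3)))
})

test_that("tissue-specific IR composites match hand evaluation", {
  auc_i <- auc_trapezoid(tt, i3)
  auc_f <- auc_trapezoid(tt, f3)
  auc_i030 <- 30 * (i3[1] + i3[2]) / 2
  auc_g030 <- 30 * (g3[1] + g3[2]) / 2
  t <- tissue_ir(auc_insulin_0_120 = auc_i, auc_glucose_030 = auc_g030,
                 auc_insulin_030 = auc_i030, fat_mass_pct = 30, hdl = 55,
                 bmi = 27, ffa0 = f3[1], i0 = i3[1],
                 auc_insulin = auc_i, auc_ffa = auc_f)
  expect_equal(t$adipo_ir, 20.688, tolerance = 1e-10)
  expect_equal(t$hepatic_ir, 1187838.45, tolerance = 1e-8)
  expect_equal(t$liver_ir,
               -0.091 + 0.4 * log10(auc_i) + 0.346 * log10(30) -
                 0.408 * log10(55) + 0.435 * log10(27),
               tolerance = 1e-12)
  # isi_ffa fixed point: scaled product 1 -> 2/(1+1) = 1
  fp <- tissue_ir(auc_i, auc_g030, auc_i030, 30, 55, 27, f3[1], i3[1],
                  auc_insulin = 1e4, auc_ffa = 30)
  expect_equal(fp$isi_ffa, 1)
  # log of a non-positive argument flags liver_ir undefined only
  ng <- tissue_ir(auc_i, auc_g030, auc_i030, fat_mass_pct = 0, hdl = 55,
                  bmi = 27, ffa0 = f3[1], i0 = i3[1],
                  auc_insulin = auc_i, auc_ffa = auc_f)
  expect_true(is.na(ng$liver_ir))
  expect_false(is.na(ng$adipo_ir))
})

test_that("insulin clearance ratios and suppression slope", {
  ic <- insulin_clearance(c3[1], c3[2], c3[3], i3[1], i3[2], i3[3])
  expect_equal(ic$ic_fast, 0.015777262181, tolerance = 1e-10)
  expect_equal(ic$ic_120, 0.00841726618705, tolerance = 1e-10)
  # clearance falls over the early OGTT at the median profile: positive
  # suppression, magnitude matching the published 10^-4 scale
  expect_equal(ic$ic_delta_030, 0.000270208563976, tolerance = 1e-10)
  flat <- insulin_clearance(0.7, 0.7, 0.7, 50, 50, 50)
  expect_equal(flat$ic_delta_030, 0)
  expect_true(is.na(insulin_clearance(0.7, 2, 2.5, 0, 300, 200)$ic_fast))
})

test_that("fatty-liver scores: worked values and bounds", {
  fl <- fatty_liver_scores(FALSE, FALSE, 43.1, tg = 100, bmi = 27,
                           waist = 96)
  expect_equal(fl$nafld_fls, -1.84741666667, tolerance = 1e-10)
  expect_equal(fl$fli, 7.47944106889, tolerance = 1e-8)
  # logistic midpoint: choose tg so the linear predictor is zero
  tg0 <- exp((15.745 - 0.139 * 27 - 0.053 * 96) / 0.953)
  expect_equal(fatty_liver_scores(FALSE, FALSE, 43.1, tg0, 27, 96)$fli, 50,
               tolerance = 1e-9)
  # flags enter with weights 1.179 and 0.454 * 2
  both <- fatty_liver_scores(TRUE, TRUE, 43.1, 100, 27, 96)
  expect_equal(both$nafld_fls - fl$nafld_fls, 1.179 + 0.908,
               tolerance = 1e-12)
  expect_true(is.na(fatty_liver_scores(FALSE, FALSE, 43.1, 0, 27, 96)$fli))
})

test_that("CKD-EPI eGFR at the sex-specific knots and monotonicity", {
  expect_equal(egfr_ckd_epi(0.7, 62, "female"), 92.8582078029,
               tolerance = 1e-8)
  expect_equal(egfr_ckd_epi(0.9, 62, "male"), 91.2163141482,
               tolerance = 1e-8)
  cr <- seq(0.4, 3, by = 0.1)
  expect_true(all(diff(egfr_ckd_epi(cr, 62, rep("male", length(cr)))) < 0))
  expect_true(is.na(egfr_ckd_epi(-1, 62, "male")))
})

test_that("dysglycemia classification bands partition correctly", {
  expect_identical(classify_glycemia(5.46, 6.58), "NG")
  expect_identical(classify_glycemia(7.0, 5.0), "DM")   # boundary inclusive
  expect_identical(classify_glycemia(6.5, 8.0), "IFG+IGT")
  expect_identical(classify_glycemia(6.1, 5.0), "IFG")
  expect_identical(classify_glycemia(5.0, 7.8), "IGT")
  expect_identical(classify_glycemia(5.0, 11.1), "DM")
  expect_identical(classify_glycemia(6.5, NA), "IFG")
  expect_true(is.na(classify_glycemia(NA, 8)))
  # partition: every complete pair lands in exactly one class
  set.seed(9)
  g0 <- runif(500, 3, 12); g120 <- runif(500, 3, 15)
  cls <- classify_glycemia(g0, g120)
  expect_true(all(cls %in% c("NG", "IFG", "IGT", "IFG+IGT", "DM")))
})

test_that("BMI direct evaluation and linearity", {
  expect_equal(bmi(70, 1.75), 70 / 1.75^2)
  expect_equal(bmi(140, 1.75), 2 * bmi(70, 1.75))
  expect_equal(round(bmi(81, 1.732), 1), 27.0)
  expect_true(is.na(bmi(70, 0)))
})
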