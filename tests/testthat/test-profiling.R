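test_that("population percentiles use linear interpolation", {
  v <- data.frame(x = 1:100)
  q <- population_percentiles(v)
  expect_equal(unlist(q[, c("p10", "p25", "p75", "p90")]),
               c(p10 = 10.9, p25 = 25.75, p75 = 75.25, p90 = 90.1))
  # constant variable, permutation invariance, missing handling
  qc <- population_percentiles(data.frame(x = rep(3, 20)))
  expect_true(all(unlist(qc[, -1]) == 3))
  set.seed(2)
  shuffled <- data.frame(x = sample(1:100))
  expect_equal(population_percentiles(shuffled), q)
  expect_error(population_percentiles(data.frame(x = rep(NA_real_, 20))),
               "entirely missing")
  expect_error(population_percentiles(data.frame(x = c(1:5, rep(NA, 15)))),
               "fewer than")
})

test_that("bin assignment: boundaries resolve toward the middle bin", {
  pop <- data.frame(id = sprintf("s%d", 1:100), x = as.numeric(1:100))
  q <- population_percentiles(pop["x"])
  mkassign <- function(vals) {
    # one singleton cluster per value, so the cluster median is the value
    ids <- sprintf("c%d", seq_along(vals))
    vars <- data.frame(id = ids, x = vals)
    assign <- stats::setNames(seq_along(vals), ids)
    profile_clusters(assign, vars, q)$bins["x", ]
  }
  bins <- mkassign(c(5, q$p10, 15, q$p25, 50, q$p75, 80, q$p90, 99))
  expect_equal(unname(bins), c(1, 2, 2, 3, 3, 3, 4, 4, 5))
  # monotone: increasing the median never lowers the bin
  set.seed(3)
  vals <- sort(runif(50, 0, 110))
  expect_true(all(diff(mkassign(vals)) >= 0))
})

test_that("whole cohort as one cluster sits in the middle bin everywhere", {
  co <- tiny_cohort(80)
  panel <- compute_panel(co)
  vars <- cbind(co[, c("id", clustering_variables())],
                panel[, c("matsuda", "fli", "egfr")])
  q <- population_percentiles(vars[, -1])
  assign <- stats::setNames(rep(1, nrow(co)), co$id)
  pr <- profile_clusters(assign, vars, q)
  expect_true(all(pr$bins == 3))
})

test_that("a top-decile cluster lands in the top bin", {
  co <- tiny_cohort(200)
  vars <- co[, c("id", "insulin_0", "insulin_30", "insulin_120")]
  q <- population_percentiles(vars[, -1])
  top <- co$id[rank(co$insulin_0) > 180]
  assign <- stats::setNames(ifelse(co$id %in% top, 2, 1), co$id)
  pr <- profile_clusters(assign, vars, q)
  expect_equal(unname(pr$bins["insulin_0", "cluster_2"]), 5L)
  expect_s3_class(pr, "profile_matrix")
  expect_error(profile_clusters(assign, vars[0, ], q), "covers no subjects")
})

test_that("profiles at K=2 are reproducible from K=11 memberships", {
  set.seed(11)
  cfg <- two_archetype_config(300, seed = 11, missing_rate = 0,
                              medicated_rate = 0)
  co <- generate_cohort(cfg)
  f <- scale_features(co)
  m <- restart_best(f, n_restarts = 2, iterations = 80, seed = 3)
  tr <- ward_tree(m)
  a <- map_subjects(m, f)
  parts <- cut_partitions(tr, c(2, 11), a)
  vars <- co[, c("id", clustering_variables())]
  q <- population_percentiles(vars[, -1])
  direct <- profile_clusters(parts$K2$subject_clusters, vars, q)
  # coarsen K=11 memberships through the unit partition and recompute
  u2 <- parts$K2$unit_clusters
  u11 <- parts$K11$unit_clusters
  map_11_to_2 <- tapply(u2, u11, function(v) unique(v)[1])
  coarse <- stats::setNames(
    unname(map_11_to_2[as.character(parts$K11$subject_clusters)]),
    names(parts$K11$subject_clusters))
  rebuilt <- profile_clusters(coarse, vars, q)
  expect_equal(rebuilt$medians, direct$medians, tolerance = 1e-12)
  expect_equal(rebuilt$bins, direct$bins)
})

test_that("dysglycemia composition counts and conserves", {
  cls <- stats::setNames(c("NG", "NG", "DM", "IFG", "NG", "IGT"),
                         sprintf("s%d", 1:6))
  assign <- stats::setNames(c(1, 1, 1, 2, 2, 2), sprintf("s%d", 1:6))
  d <- dysglycemia_composition(assign, cls)
  expect_equal(sum(d$counts), 6)
  expect_equal(colSums(d$counts)[["NG"]], 3)
  expect_equal(unname(rowSums(d$fractions)), c(1, 1))
  # all-NG cohort
  allng <- dysglycemia_composition(assign, stats::setNames(rep("NG", 6),
                                                           names(cls)))
  expect_true(all(allng$fractions[, "NG"] == 1))
})

test_that("dysglycemia concentrates in the hyperglycemic archetype cluster", {
  cfg <- two_archetype_config(400, seed = 21, separation = 3,
                              missing_rate = 0, medicated_rate = 0)
  co <- generate_cohort(cfg)
  panel <- compute_panel(co)
  truth <- stats::setNames(ifelse(co$true_archetype == "normometabolic",
                                  1, 2), co$id)
  d <- dysglycemia_composition(truth, stats::setNames(panel$glycemia_class,
                                                      panel$id))
  dys <- c("IFG", "IGT", "IFG+IGT", "DM")
  expect_gt(sum(d$fractions[2, dys]), sum(d$fractions[1, dys]))
})

test_that("footprint radii follow bins, reversal, grouping", {
  co <- tiny_cohort(80)
  panel <- compute_panel(co)
  vars <- cbind(co[, c("id", clustering_variables(), "hba1c", "tg", "hdl")],
                panel[, setdiff(names(panel),
                                c("id", "glycemia_class", "mets", "t2d"))])
  q <- population_percentiles(vars[, -1])
  one <- stats::setNames(rep(1, nrow(co)), co$id)
  pr <- profile_clusters(one, vars, q)
  fp <- footprint(pr)
  # whole-cohort cluster: every bin is middle, radius uniformly 0.5
  expect_true(all(fp$radius == 0.5))
  expect_true(all(fp$radius >= 0 & fp$radius <= 1))
  expect_setequal(unique(fp$group), c("milieu", "mechanisms", "pathology"))
  # every profiled variable belongs to exactly one group
  expect_equal(anyDuplicated(fp$variable[fp$cluster == fp$cluster[1]]), 0)

  # an adverse-low variable below p10 reverses to radius 1
  pr2 <- pr
  pr2$bins["egfr", 1] <- 1L
  pr2$bins["glucose_0", 1] <- 1L
  fp2 <- footprint(pr2)
  expect_equal(fp2$radius[fp2$variable == "egfr"], 1)
  expect_equal(fp2$radius[fp2$variable == "glucose_0"], 0)

  # ungrouped variable errors
  pr3 <- pr
  rownames(pr3$bins)[1] <- "mystery"
  expect_error(footprint(pr3), "ungrouped")
})

test_that("gender comparison: null calibration, power, degenerate table", {
  # identical distributions -> p approximately uniform: at n = 500 per
  # group, p > 0.01 in at least 95% of 100 seeds
  pvals <- vapply(1:100, function(s) {
    set.seed(s)
    co <- data.frame(id = as.character(1:1000),
                     sex = rep(c("male", "female"), each = 500),
                     x = rnorm(1000))
    gender_compare(co)$p_value
  }, 0)
  expect_gte(mean(pvals > 0.01), 0.95)

  # and the wrapper detects a 1 SD shift at n = 500 per group
  set.seed(1)
  co <- tiny_cohort(1000)
  co$sex <- rep(c("male", "female"), each = 500)
  co$tg <- rnorm(1000, 100, 10) + ifelse(co$sex == "female", 10, 0)
  res <- gender_compare(co)
  expect_lt(res$p_value[res$variable == "tg"], 0.001)
  expect_true(all(c("mann_whitney") %in% res$test))

  # chi-square statistic is 0 for identical row profiles
  tab <- rbind(c(10, 20, 30), c(10, 20, 30))
  expect_equal(unname(suppressWarnings(stats::chisq.test(tab))$statistic), 0)
  solo <- tiny_cohort(20); solo$sex <- "male"
  expect_error(gender_compare(solo), "both genders")
})
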