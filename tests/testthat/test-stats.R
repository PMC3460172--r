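test_that("audit 2x2 tables give the published operating points", {
  op6 <- operating_point_from_counts(tp = 10, fn = 15, fp = 135, tn = 616)
  expect_equal(percent_round(op6$sensitivity), 40)
  expect_equal(percent_round(op6$specificity), 82)

  op7 <- operating_point_from_counts(tp = 9, fn = 10, fp = 78, tn = 739)
  expect_equal(percent_round(op7$sensitivity), 47)
  expect_equal(percent_round(op7$specificity), 90)
  expect_equal(percent_round(100 * 9 / (9 + 78), 1), 10.3)
})

test_that("operating points from calls partition the cohort and survive a file round-trip", {
  co <- generate_cohort(cohort_sim_config(n_cancer = 80, n_control = 120,
                                          seed = 44))
  panel <- panel_definition("p7", panel7_antigens,
                            true_cutoffs(cohort_sim_config())[panel7_antigens])
  calls <- call_panel(co, panel)
  truth <- truth_table(co)
  op <- operating_point(calls, truth)
  expect_equal(op$tp + op$fn + op$fp + op$tn, 200)
  expect_true(op$sensitivity_ci[["lower"]] <= op$sensitivity &&
                op$sensitivity <= op$sensitivity_ci[["upper"]])

  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(calls, path, row.names = FALSE)
  back <- utils::read.csv(path, colClasses = c(subject_id = "character"))
  op2 <- operating_point(back, truth)
  expect_identical(c(op2$tp, op2$fn, op2$fp, op2$tn),
                   c(op$tp, op$fn, op$fp, op$tn))

  expect_error(operating_point(calls, truth[-1, ]), "without truth")

  all_neg <- calls; all_neg$panel_positive <- FALSE
  opn <- operating_point(all_neg, truth)
  expect_equal(opn$sensitivity, 0)
  expect_equal(opn$specificity, 100)
})

test_that("exact binomial intervals reproduce published bounds and a CDF-inversion oracle", {
  expect_equal(unname(percent_round(binomial_ci(9, 53))), c(8, 30))
  expect_equal(unname(percent_round(binomial_ci(31, 235))), c(9, 18))
  expect_equal(binomial_ci(0, 10)[["lower"]], 0)
  expect_equal(binomial_ci(10, 10)[["upper"]], 100)

  # independent oracle: invert the binomial tails numerically
  cdf_ci <- function(k, n, a = 0.025) {
    lo <- if (k == 0) 0 else
      stats::uniroot(function(p) 1 - stats::pbinom(k - 1, n, p) - a,
                     c(1e-12, 1 - 1e-12), tol = 1e-12)$root
    hi <- if (k == n) 1 else
      stats::uniroot(function(p) stats::pbinom(k, n, p) - a,
                     c(1e-12, 1 - 1e-12), tol = 1e-12)$root
    100 * c(lo, hi)
  }
  for (case in list(c(31, 235), c(9, 53), c(1, 7), c(19, 20))) {
    expect_equal(unname(binomial_ci(case[1], case[2])),
                 cdf_ci(case[1], case[2]), tolerance = 1e-6)
  }
  # and against the stock exact test
  ci <- binomial_ci(13, 99)
  expect_equal(unname(ci), 100 * as.numeric(binom.test(13, 99)$conf.int),
               tolerance = 1e-9)
  expect_error(binomial_ci(5, 4), "0 <= k <= n")
})

test_that("interval covers the point estimate and narrows with n", {
  for (k in c(0, 3, 17, 40)) {
    ci <- binomial_ci(k, 40)
    expect_lte(ci[["lower"]], 100 * k / 40)
    expect_gte(ci[["upper"]], 100 * k / 40)
  }
  widths <- vapply(c(1, 2, 4, 8, 16), function(mult) {
    ci <- binomial_ci(10 * mult, 50 * mult)
    ci[["upper"]] - ci[["lower"]]
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("PPV and accuracy reproduce the prevalence-scenario arithmetic", {
  expect_equal(percent_round(ppv(0.41, 0.93, 0.024)), 13)
  expect_equal(one_in_n(ppv(0.41, 0.93, 0.024)), 8L)
  expect_equal(percent_round(ppv(0.41, 0.93, 0.013)), 7)
  expect_equal(one_in_n(ppv(0.41, 0.93, 0.013)), 14L)
  expect_equal(percent_round(ppv(0.39, 0.90, 0.024)), 9)
  expect_equal(one_in_n(ppv(0.39, 0.90, 0.024)), 11L)
  expect_equal(one_in_n(ppv(0.40, 0.82, 0.031)), 15L)
  expect_equal(one_in_n(ppv(0.47, 0.90, 0.024)), 10L)
  expect_equal(ppv(1, 1, 0.1), 100)

  expect_equal(percent_round(accuracy(0.41, 0.93, 0.024)), 92)
  expect_equal(percent_round(accuracy(0.39, 0.90, 0.024)), 89)
  expect_equal(accuracy(1, 1, 0.3), 100)

  expect_error(ppv(41, 0.93, 0.024), "fractions")
  expect_error(one_in_n(0), "undefined")
})

test_that("PPV is strictly increasing in each argument", {
  base <- c(s = 0.4, sp = 0.9, pi = 0.02)
  for (arg in names(base)) {
    grid <- seq(0.1, 0.9, by = 0.2)
    vals <- vapply(grid, function(v) {
      x <- base; x[arg] <- v
      ppv(x[["s"]], x[["sp"]], x[["pi"]])
    }, numeric(1))
    expect_true(all(diff(vals) > 0), info = arg)
  }
})

test_that("two-proportion chi-squared matches the published comparisons and a hand-rolled oracle", {
  expect_lt(compare_proportions(135, 751, 78, 817)$p, 1e-4)
  expect_equal(compare_proportions(10, 25, 9, 19)$p, 0.63, tolerance = 0.01)

  same <- compare_proportions(7, 20, 7, 20)
  expect_equal(same$chi2, 0, tolerance = 1e-12)
  expect_equal(same$p, 1)

  pearson <- function(k1, n1, k2, n2) {
    o <- matrix(c(k1, n1 - k1, k2, n2 - k2), 2, byrow = TRUE)
    e <- outer(rowSums(o), colSums(o)) / sum(o)
    chi2 <- sum((o - e)^2 / e)
    list(chi2 = chi2, p = stats::pchisq(chi2, 1, lower.tail = FALSE))
  }
  set.seed(10)
  for (i in 1:20) {
    n1 <- sample(10:200, 1); n2 <- sample(10:200, 1)
    k1 <- sample(1:(n1 - 1), 1); k2 <- sample(1:(n2 - 1), 1)
    mine <- compare_proportions(k1, n1, k2, n2)
    ref <- pearson(k1, n1, k2, n2)
    expect_equal(mine$chi2, ref$chi2, tolerance = 1e-10)
    expect_equal(mine$p, ref$p, tolerance = 1e-10)
  }
  expect_error(compare_proportions(0, 10, 0, 20), "margin")
})

test_that("false-positive reduction arithmetic", {
  expect_equal(reduction_in_false_positives(90, 93), 30)
  expect_equal(percent_round(reduction_in_false_positives(82, 90)), 44)
  expect_equal(reduction_in_false_positives(85, 85), 0)
  expect_lt(reduction_in_false_positives(90, 85), 0)
  expect_error(reduction_in_false_positives(100, 90), "undefined")
})

test_that("subgroup tables are compositionally consistent forest-plot data", {
  co <- generate_cohort(cohort_sim_config(n_cancer = 160, n_control = 100,
                                          occult_rate = 0, seed = 61))
  panel <- panel_definition("p7", panel7_antigens,
                            true_cutoffs(cohort_sim_config())[panel7_antigens])
  calls <- call_panel(co, panel)
  truth <- truth_table(co)
  s <- co$subjects

  # single group equals the overall operating point
  g1 <- stats::setNames(rep("all", nrow(s)), s$subject_id)
  tab1 <- subgroup_table(calls, truth, g1)
  op <- operating_point(calls, truth)
  expect_equal(tab1$sensitivity[tab1$group == "overall"], op$sensitivity)
  expect_equal(tab1$sensitivity[tab1$group == "all"], op$sensitivity)

  # each row matches binomial_ci(k, n) on its own counts
  g <- stats::setNames(s$subtype, s$subject_id)
  tab <- subgroup_table(calls, truth, g)
  for (i in seq_len(nrow(tab))) {
    if (tab$n[i] == 0) next
    ci <- binomial_ci(tab$k[i], tab$n[i])
    expect_equal(tab$lower[i], ci[["lower"]])
    expect_equal(tab$upper[i], ci[["upper"]])
  }

  # stage groups share the generator signal: sensitivities within each
  # other's intervals
  gs <- stats::setNames(s$stage_group[s$cohort == "cancer"],
                        s$subject_id[s$cohort == "cancer"])
  ts <- subgroup_table(calls, truth, gs)
  early <- ts[ts$group == "early", ]
  late <- ts[ts$group == "late", ]
  expect_true(early$sensitivity >= late$lower &&
                early$sensitivity <= late$upper)
  expect_true(late$sensitivity >= early$lower &&
                late$sensitivity <= early$upper)

  # empty subgroup flagged without a CI
  g0 <- stats::setNames(rep("none_seen", 3), s$subject_id[s$cohort == "control"][1:3])
  t0 <- subgroup_table(calls, truth, g0)
  expect_equal(t0$n[t0$group == "none_seen"], 0)
  expect_true(is.na(t0$sensitivity[t0$group == "none_seen"]))
})
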