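test_that("occult adjustment follows the expected-count deflation formula", {
  # no occult risk: adjustment is the identity
  expect_equal(adjusted_specificity(24, 266, 0, 0.41),
               100 * (1 - 24 / 266))

  # uniform 2.7% risk over 266 controls, sensitivity 41%
  E <- 266 * 0.027
  expect_equal(adjusted_specificity(24, 266, 0.027, 0.41),
               100 * (1 - (24 - 0.41 * E) / (266 - E)), tolerance = 1e-12)
  expect_equal(adjusted_specificity(24, 266, 0.027, 0.41), 91.86,
               tolerance = 1e-3)

  # a test that misses occult cancers (sensitivity 0) can only lose
  # specificity from the shrunken denominator
  expect_lte(adjusted_specificity(24, 266, 0.027, 0),
             100 * (1 - 24 / 266))

  # strictly increasing in sensitivity while FP exceeds sens*E
  s <- seq(0, 0.9, by = 0.1)
  vals <- vapply(s, function(x) adjusted_specificity(24, 266, 0.027, x),
                 numeric(1))
  expect_true(all(diff(vals) > 0))

  # floor at zero adjusted false positives
  expect_equal(adjusted_specificity(1, 100, 0.5, 1), 100)
  expect_error(adjusted_specificity(5, 10, 1, 0.5), "control group size")
  expect_error(adjusted_specificity(5, 10, 2, 0.5), "risks")
})

test_that("one antigen at fixed specificity reduces to the control quantile", {
  set.seed(2)
  n_ctrl <- 100
  ctrl_ru <- sort(stats::runif(n_ctrl, 1, 100))        # distinct values
  case_ru <- stats::runif(50, 20, 300)
  ru <- matrix(c(case_ru, ctrl_ru), ncol = 1,
               dimnames = list(NULL, "p53"))
  co <- cohort_from_ru(ru, c(rep("cancer", 50), rep("control", n_ctrl)))
  fit <- mc_search(co, "p53",
                   search_config(mode = "fix_specificity", target = 90,
                                 tolerance = 0.5, n_candidates = 2000,
                                 seed = 5))
  expect_equal(unname(coef(fit)),
               unname(stats::quantile(ctrl_ru, 0.9, type = 1)))
  expect_equal(fit$achieved$specificity, 90)
})

test_that("the Monte-Carlo search matches exhaustive enumeration on a small grid", {
  co <- generate_cohort(cohort_sim_config(n_cancer = 60, n_control = 80,
                                          seed = 17))
  antigens <- c("p53", "MAGEA4", "HuD")
  cm <- serodx:::cohort_call_matrices(co, antigens)
  grids <- lapply(antigens, function(a)
    unname(stats::quantile(cm$ru_ref[co$subjects$cohort == "control", a],
                           c(0.80, 0.85, 0.90, 0.95, 0.99), type = 1)))
  names(grids) <- antigens

  oracle <- exhaustive_search(co, antigens, grids, "fix_specificity",
                              target = 90, tolerance = 5)
  fit <- mc_search(co, antigens,
                   search_config(mode = "fix_specificity", target = 90,
                                 tolerance = 5, n_candidates = 10000,
                                 candidate_grid = grids, seed = 23))
  expect_equal(coef(fit), oracle$cutoffs)
  expect_equal(fit$achieved$sensitivity, oracle$sens)
  expect_equal(fit$achieved$specificity, oracle$spec)

  # same cohort, same seed: identical result
  fit2 <- mc_search(co, antigens,
                    search_config(mode = "fix_specificity", target = 90,
                                  tolerance = 5, n_candidates = 10000,
                                  candidate_grid = grids, seed = 23))
  expect_identical(coef(fit2), coef(fit))
  expect_identical(fit2$n_feasible, fit$n_feasible)
  expect_identical(fit2$achieved$tp, fit$achieved$tp)
})

test_that("fitted operating points are recomputable and honest about infeasibility", {
  co <- generate_cohort(cohort_sim_config(n_cancer = 150, n_control = 200,
                                          seed = 19))
  fit <- mc_search(co, panel7_antigens,
                   search_config(mode = "fix_specificity", target = 90,
                                 tolerance = 1, n_candidates = 1000,
                                 seed = 4))
  # re-evaluating the fitted panel on the search cohort gives bit-identical
  # counts
  op <- validate_cutoffs(co, fit$panel)
  expect_identical(c(op$tp, op$fn, op$fp, op$tn),
                   c(fit$achieved$tp, fit$achieved$fn, fit$achieved$fp,
                     fit$achieved$tn))

  # predict() applies the fitted panel
  calls <- predict(fit, co)
  expect_s3_class(calls, "aab_calls")
  expect_equal(sum(calls$panel_positive[co$subjects$cohort == "cancer"]),
               fit$achieved$tp)

  # unreachable constraint: error reports the nearest miss
  expect_error(mc_search(co, panel7_antigens,
                         search_config(mode = "fix_specificity", target = 20,
                                       tolerance = 0.5, n_candidates = 200,
                                       seed = 4)),
               "nearest miss")
})

test_that("a panel with unreachable cutoffs is all-negative", {
  co <- generate_cohort(cohort_sim_config(n_cancer = 50, n_control = 50,
                                          seed = 6))
  panel <- panel_definition("inf", panel7_antigens,
                            stats::setNames(rep(Inf, 7), panel7_antigens))
  op <- validate_cutoffs(co, panel)
  expect_equal(op$sensitivity, 0)
  expect_equal(op$specificity, 100)
})

test_that("occult adjustment inside the search uses the control risk burden", {
  co <- generate_cohort(cohort_sim_config(n_cancer = 150, n_control = 250,
                                          seed = 29))
  fit <- mc_search(co, panel7_antigens,
                   search_config(mode = "fix_specificity", target = 92,
                                 tolerance = 2, n_candidates = 1000,
                                 adjust_occult = TRUE, seed = 9))
  risks <- cohort_risks(co, risk_model_config(),
                        subset = co$subjects$subject_id[co$subjects$cohort == "control"])
  expect_equal(fit$achieved$adjusted_specificity,
               adjusted_specificity(fit$achieved$fp,
                                    fit$achieved$fp + fit$achieved$tn,
                                    risks, fit$achieved$sensitivity / 100))
  expect_gte(fit$achieved$adjusted_specificity, fit$achieved$specificity)
})
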