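# Cohort in which a single indicator (DCIS) varies: the logistic MLE of a
# saturated 2x2 design equals the cross-product odds ratio.
cohort_2x2 <- function(exp_cases = 30, unexp_cases = 10,
                       exp_controls = 100, unexp_controls = 300) {
  mk <- function(n, dcis, status, prefix) {
    if (n == 0) return(NULL)
    out <- blank_cohort(n, prefix = prefix)
    out$dcis <- dcis
    out$brca1_status <- status
    out
  }
  dplyr::bind_rows(
    mk(exp_cases, TRUE, "pathogenic", "A"),
    mk(unexp_cases, FALSE, "pathogenic", "B"),
    mk(exp_controls, TRUE, "none", "C"),
    mk(unexp_controls, FALSE, "none", "D")
  )
}

test_that("saturated 2x2 fit reproduces the cross-product odds ratio exactly", {
  fit <- fit_carrier_model(cohort_2x2(), "BRCA1", "european_mixed")
  # OR = (30*300)/(10*100) = 9
  expect_equal(unname(exp(fit$coefficients[["dcis"]])), 9, tolerance = 1e-6)
  # r0 is the case fraction, exact rational arithmetic
  expect_identical(fit$r0, 40 / 440)
  # the other 28 indicators are never exposed -> dropped and flagged
  expect_equal(nrow(fit$dropped), 28L)
  expect_true(all(fit$dropped$reason == "no_exposure"))
})

test_that("the null carrier probability is the case fraction", {
  expect_equal(round(null_carrier_prob(1706, 108602), 3), 0.015)
  expect_error(null_carrier_prob(0, 100))
})

test_that("fitting requires both cases and controls", {
  coh <- blank_cohort(50)
  expect_error(fit_carrier_model(coh, "BRCA1", "european_mixed"),
               class = "vuslr_fit_error")
})

test_that("prediction is the logistic of the linear predictor, monotone in exposure", {
  fit <- fit_carrier_model(cohort_2x2(), "BRCA1", "european_mixed")
  b0 <- fit$coefficients[["(Intercept)"]]

  none <- blank_proband("P0")
  with_dcis <- blank_proband("P1", dcis = TRUE)
  r_none <- predict_carrier(fit, none)$r_k
  r_dcis <- predict_carrier(fit, with_dcis)$r_k

  # zero design vector -> logistic(intercept); exposure multiplies odds by 9
  expect_equal(r_none, plogis(b0), tolerance = 1e-12)
  expect_equal(r_dcis / (1 - r_dcis) / (r_none / (1 - r_none)), 9,
               tolerance = 1e-6)
  expect_gt(r_dcis, r_none)

  # dropped indicators contribute nothing
  exotic <- blank_proband("P2", fam_mbc = 3L)
  expect_equal(predict_carrier(fit, exotic)$r_k, r_none, tolerance = 1e-12)
})

test_that("tidy/glance expose estimates, drop flags and model bookkeeping", {
  fit <- fit_carrier_model(cohort_2x2(), "BRCA1", "european_mixed")
  td <- tidy(fit, exponentiate = TRUE)
  expect_equal(nrow(td), 30L) # intercept + 29 indicators
  expect_equal(td$estimate[td$term == "dcis"], 9, tolerance = 1e-6)
  expect_equal(sum(!is.na(td$dropped_reason)), 28L)
  gl <- glance(fit)
  expect_equal(gl$n_cases, 40L)
  expect_true(gl$converged)
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("rank-based AUC behaves at the extremes and matches pROC", {
  # perfect separation
  perfect <- vuslr:::auc_hanley_mcneil(c(1, 2, 3, 10, 11, 12),
                                       c(0, 0, 0, 1, 1, 1))
  expect_equal(perfect$auc, 1)

  # labels independent of scores: AUC within 3 SE of 0.5
  set.seed(42)
  n <- 10000
  score <- stats::rnorm(n)
  label <- rbinom(n, 1, 0.3)
  a <- vuslr:::auc_hanley_mcneil(score, label)
  expect_lt(abs(a$auc - 0.5), 3 * a$se)

  # independent implementation agrees
  skip_if_not_installed("pROC")
  proc_auc <- as.numeric(pROC::auc(pROC::roc(label[1:2000], score[1:2000],
                                             quiet = TRUE, direction = "<")))
  a2 <- vuslr:::auc_hanley_mcneil(score[1:2000], label[1:2000])
  expect_equal(a2$auc, proc_auc, tolerance = 1e-12)

  # single-class input errors
  expect_error(vuslr:::auc_hanley_mcneil(score, rep(1, n)),
               class = "vuslr_auc_error")
})

test_that("fitting recovers generative coefficients on simulated data", {
  # single-replicate recovery at moderate n; the replicated coverage study
  # lives in the acceptance suite
  cfg <- sim_config(
    n_probands = 50000,
    race_mix = c(european_mixed = 1, african_american = 0, asian = 0, hispanic = 0),
    seed = 21
  )
  coh <- simulate_cohort(cfg)
  fit <- fit_carrier_model(apply_exclusions(coh, "BRCA1"), "BRCA1", "european_mixed")
  td <- tidy(fit, exponentiate = TRUE)
  ci <- td[td$term == "tn_pos_lt50", ]
  expect_true(ci$conf.low < 15.9 && 15.9 < ci$conf.high)

  # cases score higher than controls on average whenever AUC > 0.5
  auc <- carrier_auc(fit, coh)
  expect_gt(auc$auc, 0.5)
  rk <- predict_carrier(fit, coh)$r_k
  is_case <- coh$brca1_status == "pathogenic"
  expect_gt(mean(rk[is_case]), mean(rk[!is_case]))
})
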