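test_that("the admixture log-likelihood matches closed forms at the corners", {
  lrs <- c(2, 5)
  expect_equal(admixture_loglik(0, lrs), 0)
  expect_equal(admixture_loglik(1, lrs), log(10), tolerance = 1e-12)
  expect_equal(admixture_loglik(0.37, rep(1, 10)), 0, tolerance = 1e-12)
  # continuity / stability with extreme log10 LRs
  expect_equal(admixture_loglik(0.5, log10_lrs = c(500, -500)),
               log(0.5) + 500 * log(10) + log(0.5), tolerance = 1e-9)
  expect_error(admixture_loglik(0.5, c(1, -2)), class = "vuslr_domain_error")
})

test_that("Brent's alpha-hat matches the 10,001-point grid oracle", {
  lrs <- c(10, 10, 10, rep(0.01, 7))
  est <- estimate_alpha(lrs)
  expect_lt(abs(est$alpha_hat - grid_alpha_oracle(log10(lrs))), 1e-4)
  expect_equal(est$boundary_flag, "interior")

  set.seed(77)
  for (i in 1:10) {
    l10 <- stats::rnorm(sample(3:20, 1), sd = runif(1, 0.5, 2))
    est_i <- estimate_alpha(log10_lrs = l10)
    expect_lt(abs(est_i$alpha_hat - grid_alpha_oracle(l10)), 1e-4)
  }
})

test_that("boundary and flat likelihoods are detected and flagged", {
  up <- estimate_alpha(rep(1000, 5))
  expect_equal(up$alpha_hat, 1)
  expect_equal(up$boundary_flag, "at_one")

  down <- estimate_alpha(rep(0.001, 5))
  expect_equal(down$alpha_hat, 0)
  expect_equal(down$boundary_flag, "at_zero")

  expect_warning(flat <- estimate_alpha(rep(1, 8)), "unidentifiable")
  expect_equal(flat$alpha_hat, 0)
  expect_equal(flat$boundary_flag, "flat")
  ci <- profile_ci(rep(1, 8), alpha_hat = flat$alpha_hat,
                   loglik_max = flat$loglik_max)
  expect_equal(unname(ci), c(0, 1))
})

test_that("alpha-hat is invariant to permutation of the LR list", {
  set.seed(101)
  l10 <- stats::rnorm(50)
  a <- estimate_alpha(log10_lrs = l10)$alpha_hat
  b <- estimate_alpha(log10_lrs = rev(l10))$alpha_hat
  c_ <- estimate_alpha(log10_lrs = sample(l10))$alpha_hat
  expect_equal(a, b, tolerance = 1e-8)
  expect_equal(a, c_, tolerance = 1e-8)
})

test_that("profile CI endpoints satisfy the 3.84 drop and cover sharp truth", {
  set.seed(55)
  l10 <- gen_class_log10_lrs(2000, alpha = 0.5, sigma = 3)
  est <- estimate_alpha(log10_lrs = l10)
  ci <- profile_ci(log10_lrs = l10, alpha_hat = est$alpha_hat,
                   loglik_max = est$loglik_max)
  expect_lt(ci[["upper"]] - ci[["lower"]], 0.1)
  expect_true(ci[["lower"]] < 0.5 && 0.5 < ci[["upper"]])
  for (end in ci) {
    drop_attained <- 2 * (est$loglik_max - admixture_loglik(end, log10_lrs = l10))
    expect_equal(drop_attained, 3.84, tolerance = 1e-6)
  }
})

test_that("the partition LRT separates unequal classes and is sane when nested", {
  set.seed(61)
  strong <- list(
    lo = 10^gen_class_log10_lrs(200, alpha = 0, sigma = 2),
    hi = 10^gen_class_log10_lrs(200, alpha = 0.8, sigma = 2)
  )
  pt <- partition_test(strong)
  expect_lt(pt$p_value, 0.05)
  expect_equal(pt$df, 1L)

  # one homogeneous sample split in halves: chi2 >= 0 and small
  set.seed(62)
  one <- 10^gen_class_log10_lrs(400, alpha = 0.3, sigma = 2)
  pt2 <- partition_test(list(a = one[1:200], b = one[201:400]))
  expect_gte(pt2$chi2, 0)
  expect_lt(pt2$chi2, stats::qchisq(0.999, 1))

  # empty classes are dropped with a warning and df adjusted
  expect_warning(
    pt3 <- partition_test(list(a = one[1:200], b = one[201:400], c = numeric(0))),
    "empty"
  )
  expect_equal(pt3$df, 1L)
  expect_error(partition_test(list(a = one)), "at least two")
})

test_that("class_table recovers the ordering of class-specific alphas", {
  set.seed(71)
  mk <- function(class, alpha, n) {
    tibble::tibble(
      variant_id = paste0(class, "_", seq_len(n)), gene = "BRCA1",
      n_probands = 1L,
      sum_log10_lr = gen_class_log10_lrs(n, alpha, sigma = 2),
      combined_lr = NA_real_, lab_class = "vus", bioinfo_class = class,
      prior_prob = 0.5, multi_vus_proband = FALSE
    )
  }
  ev <- dplyr::bind_rows(
    mk("not_in_key_domain", 0.0, 300),
    mk("C15_C25", 0.4, 300),
    mk("C65", 0.8, 300)
  )
  ev$combined_lr <- 10^ev$sum_log10_lr
  tab <- class_table(ev)
  a <- setNames(tab$alpha_hat, tab$bioinfo_class)
  expect_lt(a[["not_in_key_domain"]], a[["C15_C25"]])
  expect_lt(a[["C15_C25"]], a[["C65"]])
  expect_true(all(tab$ci_lower <= tab$alpha_hat & tab$alpha_hat <= tab$ci_upper))

  # no laboratory-pathogenic variants -> both modes identical
  tab2 <- class_table(ev, include_pathogenic = FALSE)
  expect_equal(tab$alpha_hat, tab2$alpha_hat)

  # lab-pathogenic variants are removed in the VLP+VUS mode
  ev2 <- ev
  ev2$lab_class[ev2$bioinfo_class == "C65"][1:100] <- "pathogenic"
  tab3 <- class_table(ev2, include_pathogenic = FALSE)
  expect_equal(tab3$n_variants[tab3$bioinfo_class == "C65"], 200L)

  # a single-variant class is nearly uninformative
  single <- mk("C0", 1, 1)
  single$sum_log10_lr <- log10(3)
  single$combined_lr <- 3
  tab4 <- class_table(dplyr::bind_rows(ev, single))
  row <- tab4[tab4$bioinfo_class == "C0", ]
  expect_lt(row$ci_lower, 0.05)
  expect_equal(row$ci_upper, 1)
  expect_s3_class(autoplot(tab4), "ggplot")
})
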