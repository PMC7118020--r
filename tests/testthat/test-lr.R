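test_that("the individual LR formula matches hand arithmetic", {
  # r_k = r0 -> no evidence
  expect_equal(individual_lr(0.015, 0.015)$lr, 1, tolerance = 1e-12)
  # 0.5 against r0 = 0.015: (0.5 * 0.985) / (0.5 * 0.015) = 65.666...
  expect_equal(individual_lr(0.5, 0.015)$lr, 0.985 / 0.015, tolerance = 1e-12)
  # 0.99 against 0.5: 0.99*0.5 / (0.01*0.5) = 99
  expect_equal(individual_lr(0.99, 0.5)$lr, 99, tolerance = 1e-9)
  expect_equal(individual_lr(0.99, 0.5)$log10_lr, log10(99), tolerance = 1e-12)

  expect_error(individual_lr(0, 0.5), class = "vuslr_domain_error")
  expect_error(individual_lr(0.5, 1), class = "vuslr_domain_error")
})

test_that("per-variant combination multiplies LRs in log space", {
  expect_equal(combine_lr(log10(c(2, 5)))$combined_lr, 10, tolerance = 1e-9)
  expect_equal(combine_lr(log10(884))$combined_lr, 884, tolerance = 1e-9)
  expect_equal(combine_lr(log10(c(10, 0.1)))$combined_lr, 1, tolerance = 1e-12)
  expect_error(combine_lr(numeric(0)))

  # order invariance
  set.seed(8)
  l <- stats::rnorm(40)
  expect_equal(combine_lr(l)$sum_log10_lr,
               combine_lr(sample(l))$sum_log10_lr, tolerance = 1e-9)

  # extreme evidence is clamped, not overflowed
  huge <- combine_lr(rep(200, 4))
  expect_equal(huge$sum_log10_lr, 800)
  expect_true(is.finite(huge$combined_lr))
})

test_that("combined LR equals a brute-force product of the formula", {
  set.seed(12)
  for (i in 1:25) {
    k <- sample(1:5, 1)
    r_k <- runif(k, 0.001, 0.999)
    r0 <- runif(1, 0.005, 0.2)
    expected <- brute_force_combined_lr(r_k, r0)
    got <- combine_lr(individual_lr(r_k, r0)$log10_lr)$combined_lr
    expect_equal(got, expected, tolerance = 1e-9)
  }
})

test_that("score_cohort aggregates per variant with per-stratum r0", {
  pip <- run_small_pipeline()
  ev <- pip$evidence
  per <- attr(ev, "per_proband")

  # per-variant sums reproduce from the per-proband table
  chk <- per |>
    dplyr::group_by(variant_id) |>
    dplyr::summarise(s = sum(log10_lr), n = dplyr::n())
  m <- match(ev$variant_id, chk$variant_id)
  expect_equal(ev$sum_log10_lr, chk$s[m], tolerance = 1e-9)
  expect_equal(ev$n_probands, chk$n[m])

  # excluded probands never contribute
  kept1 <- apply_exclusions(pip$cohort, "BRCA1")$proband_id
  expect_true(all(per$proband_id[per$gene == "BRCA1"] %in% kept1))

  # sorted by gene then variant id
  expect_equal(ev$variant_id, ev[order(ev$gene, ev$variant_id), ]$variant_id)

  # a missing stratum fit is a configuration error naming the stratum
  expect_error(
    score_cohort(pip$cohort, pip$observations,
                 pip$fits["BRCA1.european_mixed"]),
    "BRCA2.european_mixed", class = "vuslr_config_error"
  )
})

test_that("a variant seen in two race groups multiplies the group-specific LRs", {
  cfg <- sim_config(
    n_probands = 30000,
    race_mix = c(european_mixed = 0.5, african_american = 0.5, asian = 0, hispanic = 0),
    seed = 23
  )
  coh <- simulate_cohort(cfg)
  fits <- list(
    BRCA1.european_mixed = fit_carrier_model(apply_exclusions(coh, "BRCA1"),
                                             "BRCA1", "european_mixed"),
    BRCA1.african_american = fit_carrier_model(apply_exclusions(coh, "BRCA1"),
                                               "BRCA1", "african_american")
  )
  clean <- apply_exclusions(coh, "BRCA1")
  p_eu <- clean[clean$race_group == "european_mixed" & clean$brca1_status == "none", ][1, ]
  p_aa <- clean[clean$race_group == "african_american" & clean$brca1_status == "none", ][1, ]
  two <- dplyr::bind_rows(p_eu, p_aa)
  obs <- tibble::tibble(
    proband_id = two$proband_id, gene = "BRCA1", variant_id = "shared.v1",
    lab_class = "vus", bioinfo_class = "C65", prior_prob = 0.81
  )
  ev <- score_cohort(coh, obs, fits)

  lr_eu <- individual_lr(predict_carrier(fits$BRCA1.european_mixed, p_eu)$r_k,
                         fits$BRCA1.european_mixed$r0)$lr
  lr_aa <- individual_lr(predict_carrier(fits$BRCA1.african_american, p_aa)$r_k,
                         fits$BRCA1.african_american$r0)$lr
  expect_equal(ev$combined_lr, lr_eu * lr_aa, tolerance = 1e-9)
  expect_equal(ev$n_probands, 2L)
})

test_that("pathogenic-latent variants score higher than benign-latent", {
  pip <- run_small_pipeline(small_pipeline_config(n = 15000, n_vus = 200, seed = 29))
  truth <- pip$truth
  ev <- dplyr::inner_join(pip$evidence,
                          truth[, c("variant_id", "latent_pathogenic")],
                          by = "variant_id")
  med_p <- stats::median(ev$sum_log10_lr[ev$latent_pathogenic])
  med_b <- stats::median(ev$sum_log10_lr[!ev$latent_pathogenic])
  expect_gt(med_p, med_b)
})
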