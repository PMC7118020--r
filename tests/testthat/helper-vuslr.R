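# Shared fixtures and independent oracles, built in code.

# A blank unaffected female proband row; override fields as needed.
blank_proband <- function(id, ...) {
  row <- tibble::tibble(
    proband_id = id,
    race_group = "european_mixed",
    sex = "female",
    brca1_status = "none", brca2_status = "none",
    other_gene_plp = FALSE, history_sufficient = TRUE,
    dcis = FALSE,
    bc = FALSE, bc_age_dx = NA_real_, bc_tn_status = NA_character_,
    bc_bilateral = FALSE,
    oc = FALSE, oc_age_dx = NA_real_,
    pancreatic = FALSE,
    prostate = FALSE, prostate_age_dx = NA_real_,
    fam_bc_lt50 = 0L, fam_bc_ge50 = 0L,
    fam_oc_lt60 = 0L, fam_oc_ge60 = 0L,
    fam_pancreatic = 0L, fam_mbc = 0L, fam_prostate = 0L,
    race_folded = FALSE, prev_brca_tested_negative = FALSE
  )
  mods <- list(...)
  for (nm in names(mods)) row[[nm]] <- mods[[nm]]
  row
}

blank_cohort <- function(n, prefix = "B") {
  dplyr::bind_rows(lapply(seq_len(n), function(i) {
    blank_proband(sprintf("%s%05d", prefix, i))
  }))
}

# Independent grid-search oracle for the admixture MLE.
grid_alpha_oracle <- function(log10_lrs, n_grid = 10001L) {
  grid <- seq(0, 1, length.out = n_grid)
  ll <- vapply(grid, function(a) admixture_loglik(a, log10_lrs = log10_lrs), 0)
  grid[which.max(ll)]
}

# Draw per-variant log10 LRs from a calibrated likelihood-ratio pair:
# benign ln LR ~ N(-sigma^2/2, sigma^2), pathogenic ln LR ~ N(+sigma^2/2,
# sigma^2). This pair satisfies f_path(LR)/f_benign(LR) = LR exactly, so
# the admixture model is correctly specified.
gen_class_log10_lrs <- function(n, alpha, sigma = 2) {
  path <- runif(n) < alpha
  mu <- ifelse(path, sigma^2 / 2, -sigma^2 / 2)
  (mu + sigma * stats::rnorm(n)) / log(10)
}

# Brute-force per-variant LR product for <= 5 probands (independent of the
# log-space path in combine_lr).
brute_force_combined_lr <- function(r_k, r0) {
  stopifnot(length(r_k) <= 5)
  prod((r_k * (1 - r0)) / ((1 - r_k) * r0))
}

# Small simulated pipeline shared by several tests: single stratum so every
# observation is scorable at modest n.
small_pipeline_config <- function(n = 12000, n_vus = 150, seed = 7) {
  sim_config(
    n_probands = n,
    race_mix = c(european_mixed = 1, african_american = 0, asian = 0, hispanic = 0),
    n_vus_variants = n_vus,
    seed = seed
  )
}

run_small_pipeline <- function(cfg = small_pipeline_config()) {
  coh <- simulate_cohort(cfg)
  sv <- simulate_vus_assignments(coh, cfg)
  coh <- sv$cohort
  fits <- list()
  for (g in genes) {
    el <- apply_exclusions(coh, g)
    fits[[paste(g, "european_mixed", sep = ".")]] <-
      fit_carrier_model(el, g, "european_mixed")
  }
  ev <- score_cohort(coh, sv$observations, fits)
  list(cohort = coh, observations = sv$observations, truth = sv$truth,
       fits = fits, evidence = ev)
}
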