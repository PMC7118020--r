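# Synthetic-cohort generator. Phenotypes are drawn from baseline category
# frequencies; carrier status from the logistic carrier model itself, with
# the intercept calibrated so the realized carrier prevalence matches the
# target. VUS carriers are then drawn by odds-weighted rejection from the
# same model, so the carrier- and non-carrier-conditional clinical-history
# distributions differ exactly as the inference assumes — no pedigree
# machinery is simulated.

#' Generative log-odds helpers
#'
#' `default_true_log_odds()` seeds every gene-by-race stratum from the
#' published odds ratios ([default_log_odds()]), with non-estimable cells
#' set to a null effect. `null_true_log_odds()` sets every coefficient to
#' zero (phenotypes carry no information about carrier status).
#'
#' @return Named list (`"BRCA1.european_mixed"`, ...) of 29-element
#'   log-odds vectors.
#' @export
default_true_log_odds <- function() {
  strata <- as.vector(outer(genes, race_groups, paste, sep = "."))
  out <- lapply(strata, function(s) {
    gr <- strsplit(s, ".", fixed = TRUE)[[1]]
    b <- default_log_odds(gr[1], gr[2])
    b[is.na(b)] <- 0
    b
  })
  setNames(out, strata)
}

#' @rdname default_true_log_odds
#' @export
null_true_log_odds <- function() {
  strata <- as.vector(outer(genes, race_groups, paste, sep = "."))
  setNames(
    rep(list(setNames(numeric(29), design_terms())), length(strata)),
    strata
  )
}

#' Baseline phenotype frequencies for the generator
#'
#' Marginal frequencies of the clinical-history blocks in the tested (not
#' general) population; hereditary-cancer testing cohorts are strongly
#' enriched for personal and family history of breast cancer. Blocks are
#' drawn independently — a stated simplification of the generator.
#'
#' @return Named list of baseline probabilities and Poisson means.
#' @export
default_phenotype_freqs <- function() {
  list(
    p_female = 0.96,
    p_bc_female = 0.42, p_bc_male = 0.05,
    p_bc_lt50 = 0.50,
    p_tn = c(tn_pos = 0.12, tn_neg = 0.55, tn_unknown = 0.33),
    p_bilateral = 0.05,
    p_dcis = 0.08,
    p_oc = 0.05, p_oc_lt60 = 0.60,
    p_pancreatic = 0.01,
    p_prostate = 0.10, p_prostate_lt60 = 0.30,
    lambda_fam = c(
      fam_bc_lt50 = 0.35, fam_bc_ge50 = 0.50,
      fam_oc_lt60 = 0.08, fam_oc_ge60 = 0.06,
      fam_pancreatic = 0.08, fam_mbc = 0.01, fam_prostate = 0.15
    )
  )
}

#' Default pathogenic proportion and abundance per bioinformatic class
#'
#' `default_alpha_by_class()` gives the generator's per-class mixture
#' proportion of truly pathogenic VUS; `default_class_mix()` the relative
#' abundance of the classes among simulated variants. Both mirror the
#' structure of large clinical VUS collections: most variants fall outside
#' key functional domains and are benign, Align-GVGD grade and splice-site
#' damage track pathogenicity, de novo donor predictions largely do not.
#'
#' @return Named numeric vector over [bioinfo_classes].
#' @export
default_alpha_by_class <- function() {
  c(
    not_in_key_domain = 0.02, C0 = 0.23, C15_C25 = 0.42, C35_C55 = 0.51,
    C65 = 0.76, splice_high_damage = 0.91, splice_moderate_damage = 0.79,
    denovo_donor_increased = 0.14, denovo_donor_moderate = 0.15, other = 0.10
  )
}

#' @rdname default_alpha_by_class
#' @export
default_class_mix <- function() {
  w <- c(
    not_in_key_domain = 1507, C0 = 277, C15_C25 = 73, C35_C55 = 48,
    C65 = 127, splice_high_damage = 108, splice_moderate_damage = 49,
    denovo_donor_increased = 26, denovo_donor_moderate = 48, other = 0
  )
  w / sum(w)
}

#' Simulation configuration
#'
#' @param n_probands Number of tested probands to simulate.
#' @param carrier_prevalence Per-gene probability that a tested proband
#'   carries a pathogenic variant (default 0.015 in each stratum).
#' @param race_mix Probabilities over the four race/ethnicity strata
#'   (default mirrors the composition of a large US testing cohort:
#'   84% European/mixed/unknown, 6% African American, 4% Asian,
#'   6% Hispanic).
#' @param true_log_odds Named list of generative 29-element log-odds
#'   vectors per `gene.race_group` stratum; see [default_true_log_odds()].
#' @param phenotype_freqs Baseline phenotype frequencies; see
#'   [default_phenotype_freqs()].
#' @param p_insufficient_history,p_other_gene_plp Fractions of probands
#'   flagged for the two non-genetic exclusions.
#' @param n_vus_variants Number of distinct VUS to simulate.
#' @param gene_mix Probability a simulated VUS is in BRCA1 vs BRCA2
#'   (clinical VUS collections skew toward the larger BRCA2).
#' @param singleton_prob Success probability of the geometric
#'   probands-per-variant law; 0.65 reproduces the ~65% singleton share.
#' @param alpha_by_class,class_mix Per-class pathogenic proportion and
#'   class abundances; see [default_alpha_by_class()].
#' @param p_lab_pathogenic,p_lab_vlp Probability that a truly pathogenic
#'   simulated variant already carries a laboratory classification of
#'   pathogenic / likely pathogenic (exercises the with/without-pathogenic
#'   analysis modes).
#' @param seed Integer seed; fully determines the output.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_probands = 20000,
                       carrier_prevalence = c(BRCA1 = 0.015, BRCA2 = 0.015),
                       race_mix = c(european_mixed = 0.838, african_american = 0.064,
                                    asian = 0.040, hispanic = 0.058),
                       true_log_odds = default_true_log_odds(),
                       phenotype_freqs = default_phenotype_freqs(),
                       p_insufficient_history = 0.068,
                       p_other_gene_plp = 0.040,
                       n_vus_variants = 500,
                       gene_mix = c(BRCA1 = 0.33, BRCA2 = 0.67),
                       singleton_prob = 0.65,
                       alpha_by_class = default_alpha_by_class(),
                       class_mix = default_class_mix(),
                       p_lab_pathogenic = 0.25,
                       p_lab_vlp = 0.10,
                       seed = 1L) {
  stopifnot(
    n_probands >= 1,
    all(carrier_prevalence > 0 & carrier_prevalence < 1),
    abs(sum(race_mix) - 1) < 1e-9,
    all(race_mix >= 0 & race_mix <= 1),
    all(alpha_by_class >= 0 & alpha_by_class <= 1),
    singleton_prob > 0 && singleton_prob <= 1
  )
  structure(
    list(
      n_probands = as.integer(n_probands),
      carrier_prevalence = carrier_prevalence,
      race_mix = race_mix,
      true_log_odds = true_log_odds,
      phenotype_freqs = phenotype_freqs,
      p_insufficient_history = p_insufficient_history,
      p_other_gene_plp = p_other_gene_plp,
      n_vus_variants = as.integer(n_vus_variants),
      gene_mix = gene_mix,
      singleton_prob = singleton_prob,
      alpha_by_class = alpha_by_class,
      class_mix = class_mix,
      p_lab_pathogenic = p_lab_pathogenic,
      p_lab_vlp = p_lab_vlp,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# intercept b0 such that mean(plogis(b0 + eta)) == target over the realized
# design; bisection via uniroot on a wide bracket
calibrate_intercept <- function(eta, target) {
  f <- function(b0) mean(plogis(b0 + eta)) - target
  if (f(-30) > 0 || f(30) < 0) {
    abort(sprintf("requested prevalence %.4g is not achievable", target),
          class = "vuslr_calibration_error")
  }
  uniroot(f, c(-30, 30), tol = 1e-12)$root
}

#' Simulate a tested cohort
#'
#' Draws phenotypes from the configured baseline frequencies, then assigns
#' pathogenic-carrier status per gene from the logistic model
#' `logit(p) = b0 + x'beta`, where `x` is the proband's 29-indicator
#' clinical-history vector, `beta` the configured generative log-odds for
#' the proband's stratum, and `b0` calibrated by bisection within each
#' gene-by-race stratum so the expected prevalence matches the target.
#'
#' @param config A [sim_config()].
#' @return Validated cohort tibble; the calibrated generative model is
#'   attached as attribute `"true_model"` (per-stratum intercept + beta).
#' @export
simulate_cohort <- function(config = sim_config()) {
  set.seed(config$seed)
  n <- config$n_probands
  fq <- config$phenotype_freqs

  race <- sample(names(config$race_mix), n, replace = TRUE, prob = config$race_mix)
  sex <- ifelse(runif(n) < fq$p_female, "female", "male")
  female <- sex == "female"

  bc <- runif(n) < ifelse(female, fq$p_bc_female, fq$p_bc_male)
  bc_lt50 <- bc & runif(n) < fq$p_bc_lt50
  bc_age <- ifelse(bc, ifelse(bc_lt50, sample(27:49, n, TRUE), sample(50:75, n, TRUE)), NA_real_)
  tn <- ifelse(bc, sample(names(fq$p_tn), n, TRUE, prob = fq$p_tn), NA_character_)
  bilat <- bc & runif(n) < fq$p_bilateral
  dcis <- runif(n) < fq$p_dcis
  oc <- female & runif(n) < fq$p_oc
  oc_lt60 <- oc & runif(n) < fq$p_oc_lt60
  oc_age <- ifelse(oc, ifelse(oc_lt60, sample(35:59, n, TRUE), sample(60:80, n, TRUE)), NA_real_)
  panc <- runif(n) < fq$p_pancreatic
  pros <- !female & runif(n) < fq$p_prostate
  pros_lt60 <- pros & runif(n) < fq$p_prostate_lt60
  pros_age <- ifelse(pros, ifelse(pros_lt60, sample(45:59, n, TRUE), sample(60:85, n, TRUE)), NA_real_)

  lam <- fq$lambda_fam
  cohort <- tibble::tibble(
    proband_id = sprintf("P%07d", seq_len(n)),
    race_group = race,
    sex = sex,
    brca1_status = "none",
    brca2_status = "none",
    other_gene_plp = runif(n) < config$p_other_gene_plp,
    history_sufficient = runif(n) >= config$p_insufficient_history,
    dcis = dcis,
    bc = bc, bc_age_dx = bc_age, bc_tn_status = tn, bc_bilateral = bilat,
    oc = oc, oc_age_dx = oc_age,
    pancreatic = panc,
    prostate = pros, prostate_age_dx = pros_age,
    fam_bc_lt50 = rpois(n, lam[["fam_bc_lt50"]]),
    fam_bc_ge50 = rpois(n, lam[["fam_bc_ge50"]]),
    fam_oc_lt60 = rpois(n, lam[["fam_oc_lt60"]]),
    fam_oc_ge60 = rpois(n, lam[["fam_oc_ge60"]]),
    fam_pancreatic = rpois(n, lam[["fam_pancreatic"]]),
    fam_mbc = rpois(n, lam[["fam_mbc"]]),
    fam_prostate = rpois(n, lam[["fam_prostate"]]),
    race_folded = FALSE,
    prev_brca_tested_negative = FALSE
  )

  X <- as.matrix(build_design(cohort)[, design_terms()])
  true_model <- list()
  for (g in genes) {
    status_col <- paste0(tolower(g), "_status")
    for (rg in race_groups) {
      idx <- which(race == rg)
      if (length(idx) == 0) next
      beta <- config$true_log_odds[[paste(g, rg, sep = ".")]]
      eta <- drop(X[idx, , drop = FALSE] %*% beta)
      b0 <- calibrate_intercept(eta, config$carrier_prevalence[[g]])
      carrier <- runif(length(idx)) < plogis(b0 + eta)
      cohort[[status_col]][idx[carrier]] <- "pathogenic"
      true_model[[paste(g, rg, sep = ".")]] <- list(intercept = b0, beta = beta)
    }
  }

  out <- validate_cohort(cohort)
  attr(out, "true_model") <- true_model
  out
}

#' Simulate VUS observations with a latent pathogenic/benign truth
#'
#' Each simulated variant draws a bioinformatic class, is latently
#' pathogenic with that class's configured mixture proportion, and is
#' observed in a geometric number of probands. Carrier probands for a
#' pathogenic-latent variant are sampled from the cohort's MGPT-negative
#' pool with weights proportional to the generative carrier odds of their
#' clinical history (rejection from the logistic model); benign-latent
#' variants sample uniformly. The latent truth table is returned separately
#' and must never feed back into inference.
#'
#' @param cohort Cohort from [simulate_cohort()] (carries the calibrated
#'   generative model as an attribute).
#' @param config The same [sim_config()].
#' @return List with `observations` (variant-observation tibble), `truth`
#'   (`variant_id`, `gene`, `bioinfo_class`, `latent_pathogenic`), and
#'   `cohort` (input cohort with sampled probands' gene status set to
#'   `"vus"`).
#' @export
simulate_vus_assignments <- function(cohort, config = sim_config()) {
  true_model <- attr(cohort, "true_model")
  if (is.null(true_model)) {
    abort("cohort lacks the generative model attribute; use simulate_cohort()")
  }
  set.seed(config$seed + 1L)

  nv <- config$n_vus_variants
  v_gene <- sample(names(config$gene_mix), nv, replace = TRUE, prob = config$gene_mix)
  v_class <- sample(names(config$class_mix), nv, replace = TRUE, prob = config$class_mix)
  v_path <- runif(nv) < config$alpha_by_class[v_class]
  v_size <- rgeom(nv, config$singleton_prob) + 1L

  lab <- rep("vus", nv)
  u <- runif(nv)
  lab[v_path & u < config$p_lab_pathogenic] <- "pathogenic"
  lab[v_path & u >= config$p_lab_pathogenic &
        u < config$p_lab_pathogenic + config$p_lab_vlp] <- "vlp"

  X <- as.matrix(build_design(cohort)[, design_terms()])
  priors <- default_priors()

  obs <- vector("list", nv)
  for (g in genes) {
    vi <- which(v_gene == g)
    if (length(vi) == 0) next
    eligible <- cohort$brca1_status == "none" & cohort$brca2_status == "none"
    pool <- which(eligible)
    if (sum(v_size[vi]) > length(pool)) {
      abort("more VUS observations requested than eligible probands available",
            class = "vuslr_sizing_error")
    }
    # generative carrier odds per proband, by stratum
    odds <- numeric(nrow(cohort))
    for (rg in race_groups) {
      m <- true_model[[paste(g, rg, sep = ".")]]
      if (is.null(m)) next
      idx <- which(cohort$race_group == rg)
      odds[idx] <- exp(m$intercept + drop(X[idx, , drop = FALSE] %*% m$beta))
    }
    available <- rep(TRUE, length(pool))
    for (i in vi) {
      k <- v_size[i]
      cand <- pool[available]
      w <- if (v_path[i]) odds[cand] else rep(1, length(cand))
      pick <- cand[sample.int(length(cand), k, prob = w)]
      available[match(pick, pool)] <- FALSE
      obs[[i]] <- tibble::tibble(
        proband_id = cohort$proband_id[pick],
        gene = g,
        variant_id = sprintf("%s.v%04d", g, i),
        lab_class = lab[i],
        bioinfo_class = v_class[i],
        prior_prob = priors$prior_prob[match(v_class[i], priors$bioinfo_class)]
      )
    }
  }
  observations <- dplyr::bind_rows(obs)

  truth <- tibble::tibble(
    variant_id = sprintf("%s.v%04d", v_gene, seq_len(nv)),
    gene = v_gene,
    bioinfo_class = v_class,
    latent_pathogenic = v_path,
    n_probands = v_size
  )

  # mark sampled probands as VUS carriers in the relevant gene
  for (g in genes) {
    ids <- unique(observations$proband_id[observations$gene == g])
    col <- paste0(tolower(g), "_status")
    cohort[[col]][cohort$proband_id %in% ids] <- "vus"
  }

  list(observations = observations, truth = truth, cohort = cohort)
}
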