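# Posterior probability of pathogenicity from prior x likelihood ratio,
# qualitative evidence labels at 10:1 odds thresholds, and the end-to-end
# pipeline driver.

#' Posterior probability of pathogenicity
#'
#' Bayes on the odds scale: posterior odds = prior odds x LR, i.e.
#' `posterior = prior * LR / (prior * LR + 1 - prior)`, computed stably in
#' log space so extreme LRs do not overflow.
#'
#' @param prior Prior probability(ies) of pathogenicity, in \[0, 1\].
#' @param lr Positive combined likelihood ratio(s); alternatively supply
#'   `log10_lr`.
#' @param log10_lr Optional log10 LR (preferred for extreme evidence).
#' @return Posterior probability(ies).
#' @export
#' @examples
#' posterior_prob(0.34, 884) # ~0.998
posterior_prob <- function(prior, lr = NULL, log10_lr = NULL) {
  stopifnot(all(prior >= 0 & prior <= 1))
  if (is.null(log10_lr)) {
    stopifnot(all(lr > 0))
    log10_lr <- log10(lr)
  }
  # posterior = plogis(logit(prior) + ln LR), with exact 0/1 priors fixed
  out <- plogis(qlogis(prior) + log10_lr * log(10))
  out[prior == 0] <- 0
  out[prior == 1] <- 1
  out
}

#' Qualitative evidence label from the combined LR
#'
#' `supports_pathogenic` when the odds in favor of pathogenicity exceed
#' `lr_pathogenic` : 1 (default 10:1), `supports_benign` when the odds
#' against exceed 1 : `lr_benign` (default 10:1, i.e. LR < 0.1), otherwise
#' `indeterminate`.
#'
#' @param lr Combined likelihood ratio(s).
#' @param lr_pathogenic,lr_benign Odds thresholds.
#' @return Character vector of labels.
#' @export
label_evidence <- function(lr, lr_pathogenic = 10, lr_benign = 0.1) {
  dplyr::case_when(
    lr > lr_pathogenic ~ "supports_pathogenic",
    lr < lr_benign ~ "supports_benign",
    TRUE ~ "indeterminate"
  )
}

#' Classify scored variants
#'
#' Combines each variant's prior probability with its combined clinical-
#' history LR into a posterior probability of pathogenicity, attaches the
#' 10:1-odds evidence label, and flags variants whose evidence rests on at
#' least `min_families` probands (the "five or more informative families"
#' strength rule).
#'
#' @param evidence Per-variant evidence from [score_cohort()].
#' @param priors Optional tibble `bioinfo_class`, `prior_prob` overriding
#'   the priors carried in `evidence` (see [default_priors()]).
#' @param lr_pathogenic,lr_benign Odds thresholds for the labels.
#' @param min_families Proband count for `meets_family_count_rule`.
#' @return Tibble: evidence columns plus `posterior`, `evidence_label`,
#'   `meets_family_count_rule`.
#' @export
classify_variants <- function(evidence, priors = NULL,
                              lr_pathogenic = 10, lr_benign = 0.1,
                              min_families = 5L) {
  ev <- evidence
  if (!is.null(priors)) {
    ev <- ev |>
      dplyr::select(-"prior_prob") |>
      dplyr::left_join(priors, by = "bioinfo_class")
    if (anyNA(ev$prior_prob)) {
      abort("priors table lacks a prior for some bioinfo_class in the evidence")
    }
  }
  ev |>
    dplyr::mutate(
      posterior = posterior_prob(.data$prior_prob, log10_lr = .data$sum_log10_lr),
      evidence_label = label_evidence(.data$combined_lr, lr_pathogenic, lr_benign),
      meets_family_count_rule = .data$n_probands >= min_families
    )
}

#' Run the full multifactorial pipeline
#'
#' Deterministic composition of all stages: read + validate, per-gene
#' exclusions, per-stratum carrier-model fits, per-variant LR scoring,
#' per-class admixture tables (both analysis modes), and posterior
#' classification. Writes `evidence.tsv`, `class_table.tsv`,
#' `classifications.tsv`, `model_summaries.tsv` and a JSON run manifest
#' into `outdir`.
#'
#' Sensitivity modes rerun the analysis on a restricted cohort:
#' `"exclude_unknown"` drops probands whose race/ethnicity was folded into
#' the European/mixed stratum; `"exclude_prev_tested"` drops
#' previously-tested-negative probands from the reference group.
#'
#' @param cohort_path,variants_path,priors_path Input file paths
#'   (`priors_path = NULL` uses [default_priors()]).
#' @param outdir Output directory (created if needed).
#' @param config A [cohort_config()].
#' @param sensitivity `"none"`, `"exclude_unknown"`, or
#'   `"exclude_prev_tested"`.
#' @param min_cases Strata with fewer pathogenic carriers than this are
#'   skipped (their observations cannot be scored and are dropped with a
#'   warning).
#' @return (Invisibly) a list with `evidence`, `class_tables`,
#'   `classifications`, `fits`, and the manifest.
#' @export
run_pipeline <- function(cohort_path, variants_path, priors_path = NULL,
                         outdir, config = cohort_config(),
                         sensitivity = c("none", "exclude_unknown", "exclude_prev_tested"),
                         min_cases = 10L) {
  sensitivity <- match.arg(sensitivity)
  t0 <- Sys.time()

  cohort <- read_cohort(cohort_path, config)
  variants <- read_variants(variants_path, config)
  priors <- if (is.null(priors_path)) default_priors() else read_priors(priors_path, config)

  if (sensitivity == "exclude_unknown") {
    cohort <- cohort[!(cohort$race_folded %in% TRUE), , drop = FALSE]
  } else if (sensitivity == "exclude_prev_tested") {
    drop <- cohort$prev_brca_tested_negative %in% TRUE &
      cohort$brca1_status == "none" & cohort$brca2_status == "none"
    cohort <- cohort[!drop, , drop = FALSE]
  }

  fits <- list()
  for (g in genes) {
    eligible <- apply_exclusions(cohort, g)
    status <- eligible[[paste0(tolower(g), "_status")]]
    for (rg in unique(eligible$race_group)) {
      in_rg <- eligible$race_group == rg
      n_cases <- sum(in_rg & status == "pathogenic")
      if (n_cases < min_cases || sum(in_rg & status == "none") == 0) {
        warn(sprintf("skipping stratum %s.%s (%d cases)", g, rg, n_cases))
        next
      }
      fits[[paste(g, rg, sep = ".")]] <-
        fit_carrier_model(eligible, g, rg, config)
    }
  }
  if (length(fits) == 0) abort("no stratum had enough cases to fit", class = "vuslr_fit_error")

  # drop observations in strata without a fitted model
  key <- paste(variants$gene,
               cohort$race_group[match(variants$proband_id, cohort$proband_id)],
               sep = ".")
  unscorable <- !(key %in% names(fits))
  if (any(unscorable)) {
    warn(sprintf("dropping %d observation(s) in unfitted strata", sum(unscorable)))
    variants <- variants[!unscorable, , drop = FALSE]
  }

  evidence <- score_cohort(cohort, variants, fits, config)
  tables <- dplyr::bind_rows(
    class_table(evidence, include_pathogenic = TRUE),
    class_table(evidence, include_pathogenic = FALSE)
  )
  classifications <- classify_variants(evidence, priors = priors)

  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(evidence, file.path(outdir, "evidence.tsv"))
  readr::write_tsv(tables, file.path(outdir, "class_table.tsv"))
  readr::write_tsv(classifications, file.path(outdir, "classifications.tsv"))
  readr::write_tsv(dplyr::bind_rows(lapply(fits, glance)),
                   file.path(outdir, "model_summaries.tsv"))

  manifest <- list(
    package = "vuslr",
    version = as.character(utils::packageVersion("vuslr")),
    inputs = list(cohort = cohort_path, variants = variants_path,
                  priors = priors_path %||% "default"),
    sensitivity = sensitivity,
    strata_fitted = names(fits),
    n_probands = nrow(cohort),
    n_variants = nrow(evidence),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(evidence = evidence, class_tables = tables,
                 classifications = classifications, fits = fits,
                 manifest = manifest))
}
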