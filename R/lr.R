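# Per-individual likelihood ratios of pathogenicity from predicted carrier
# probabilities, and their per-variant aggregation. All accumulation is in
# log10 space; the linear-scale LR is materialized only on output and
# clamped with an explicit overflow sentinel beyond 10^+-300.

LOG10_LR_CLAMP <- 300

#' Per-individual likelihood ratio of pathogenicity
#'
#' For a proband with predicted carrier probability `r_k` in a stratum
#' with null carrier probability `r0`, the ratio of the probability of the
#' observed clinical history given the variant is pathogenic versus
#' benign is the odds ratio
#' `LR = r_k (1 - r0) / ((1 - r_k) r0)`,
#' computed in log space.
#'
#' @param r_k Predicted carrier probability(ies), strictly in (0, 1).
#' @param r0 Null carrier probability(ies), strictly in (0, 1).
#' @return Tibble with `r_k`, `r0`, `lr`, `log10_lr`.
#' @export
#' @examples
#' individual_lr(0.5, 0.015) # LR ~ 65.7
individual_lr <- function(r_k, r0) {
  if (any(r_k <= 0 | r_k >= 1) || any(r0 <= 0 | r0 >= 1)) {
    abort("r_k and r0 must be strictly inside (0, 1)", class = "vuslr_domain_error")
  }
  log10_lr <- (qlogis(r_k) - qlogis(r0)) / log(10)
  tibble::tibble(r_k = r_k, r0 = r0, lr = 10^log10_lr, log10_lr = log10_lr)
}

# log10 sum -> clamped linear value
lr_from_log10 <- function(s) 10^pmin(pmax(s, -LOG10_LR_CLAMP), LOG10_LR_CLAMP)

#' Combine per-individual LRs into per-variant evidence
#'
#' Likelihood ratios are multiplied over every proband carrying the
#' variant (probands from different race/ethnicity strata each contribute
#' their own stratum's r_k and r0), i.e. log10 LRs are summed.
#'
#' @param log10_lrs Numeric vector of per-proband log10 LRs, length >= 1.
#' @return List with `n_probands`, `sum_log10_lr`, `combined_lr` (clamped
#'   at 10^+-300).
#' @export
combine_lr <- function(log10_lrs) {
  if (length(log10_lrs) == 0) {
    abort("cannot combine an empty set of likelihood ratios")
  }
  s <- sum(log10_lrs)
  list(n_probands = length(log10_lrs), sum_log10_lr = s, combined_lr = lr_from_log10(s))
}

#' Score every observed variant in a cohort
#'
#' Computes each proband's predicted carrier probability under their
#' stratum's fitted model, converts it to a likelihood ratio against the
#' stratum's null carrier probability, and multiplies LRs within each
#' variant. Probands removed by [apply_exclusions()] for a gene never
#' contribute to that gene's variants. Probands carrying two distinct VUS
#' in the same gene contribute their LR to both (flagged in
#' `multi_vus_proband`).
#'
#' @param cohort Validated cohort tibble (pre-exclusion; exclusions are
#'   applied internally per gene).
#' @param variants Variant-observation tibble ([read_variants()] /
#'   [simulate_vus_assignments()]).
#' @param fits Named list of `"carrier_fit"` objects keyed
#'   `"<gene>.<race_group>"`; every stratum present among scored
#'   observations must have one.
#' @param config A [cohort_config()].
#' @return Tibble of per-variant evidence sorted by gene then variant id:
#'   `variant_id`, `gene`, `n_probands`, `sum_log10_lr`, `combined_lr`,
#'   `lab_class`, `bioinfo_class`, `prior_prob`, `multi_vus_proband`.
#'   Attribute `"per_proband"` holds the per-observation LR table.
#' @export
score_cohort <- function(cohort, variants, fits, config = cohort_config()) {
  variants <- validate_variants(variants)

  per_gene <- lapply(genes, function(g) {
    obs <- variants[variants$gene == g & variants$lab_class %in% c("vus", "vlp", "pathogenic"), ]
    if (nrow(obs) == 0) return(NULL)
    eligible <- apply_exclusions(cohort, g)
    obs <- obs[obs$proband_id %in% eligible$proband_id, ]
    if (nrow(obs) == 0) return(NULL)

    sub <- eligible[match(unique(obs$proband_id), eligible$proband_id), , drop = FALSE]
    rk <- numeric(nrow(sub))
    for (rg in unique(sub$race_group)) {
      key <- paste(g, rg, sep = ".")
      fit <- fits[[key]]
      if (is.null(fit)) {
        abort(sprintf("no coefficient set for stratum %s", key),
              class = "vuslr_config_error")
      }
      idx <- which(sub$race_group == rg)
      rk[idx] <- predict_carrier(fit, sub[idx, , drop = FALSE], config)$r_k
    }
    r0 <- vapply(sub$race_group, function(rg) fits[[paste(g, rg, sep = ".")]]$r0, 0)

    i <- match(obs$proband_id, sub$proband_id)
    dplyr::bind_cols(
      obs,
      individual_lr(rk[i], unname(r0[i])),
      race_group = sub$race_group[i]
    )
  })
  per_proband <- dplyr::bind_rows(per_gene)
  if (nrow(per_proband) == 0) {
    abort("no scorable variant observations after exclusions")
  }

  multi <- per_proband |>
    dplyr::count(.data$gene, .data$proband_id) |>
    dplyr::filter(.data$n > 1)

  evidence <- per_proband |>
    dplyr::group_by(.data$gene, .data$variant_id) |>
    dplyr::summarise(
      n_probands = dplyr::n(),
      sum_log10_lr = sum(.data$log10_lr),
      lab_class = .data$lab_class[1],
      bioinfo_class = .data$bioinfo_class[1],
      prior_prob = .data$prior_prob[1],
      multi_vus_proband = any(.data$proband_id %in%
                                multi$proband_id[multi$gene == .data$gene[1]]),
      .groups = "drop"
    ) |>
    dplyr::mutate(combined_lr = lr_from_log10(.data$sum_log10_lr)) |>
    dplyr::arrange(.data$gene, .data$variant_id) |>
    dplyr::select(
      "variant_id", "gene", "n_probands", "sum_log10_lr", "combined_lr",
      "lab_class", "bioinfo_class", "prior_prob", "multi_vus_proband"
    )
  attr(evidence, "per_proband") <- per_proband
  evidence
}
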