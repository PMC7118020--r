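#' Minimal deterministic example cohort
#'
#' Three hand-written probands exercising the main design-matrix paths:
#' a triple-negative early-onset breast cancer with heavy family history,
#' an unaffected proband with no family history, and a male breast cancer
#' case. Used in examples and as a fixture seed; not representative of any
#' real cohort.
#'
#' @return Validated cohort tibble of 3 probands.
#' @export
toy_cohort <- function() {
  validate_cohort(tibble::tibble(
    proband_id = c("T001", "T002", "T003"),
    race_group = c("european_mixed", "african_american", "european_mixed"),
    sex = c("female", "female", "male"),
    brca1_status = c("pathogenic", "none", "none"),
    brca2_status = c("none", "none", "vus"),
    other_gene_plp = FALSE,
    history_sufficient = TRUE,
    dcis = c(FALSE, FALSE, FALSE),
    bc = c(TRUE, FALSE, TRUE),
    bc_age_dx = c(45, NA, 60),
    bc_tn_status = c("tn_pos", NA, "tn_neg"),
    bc_bilateral = c(FALSE, FALSE, FALSE),
    oc = FALSE, oc_age_dx = NA_real_,
    pancreatic = FALSE,
    prostate = FALSE, prostate_age_dx = NA_real_,
    fam_bc_lt50 = c(5L, 0L, 0L),
    fam_bc_ge50 = c(0L, 0L, 1L),
    fam_oc_lt60 = 0L, fam_oc_ge60 = 0L,
    fam_pancreatic = 0L, fam_mbc = 0L, fam_prostate = 0L,
    race_folded = FALSE,
    prev_brca_tested_negative = FALSE
  ))
}
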