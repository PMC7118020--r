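# 29 clinical-history indicators: 14 personal + 15 family. Order is the
# canonical column order of every design matrix and coefficient table.

design_terms_personal <- c(
  "dcis",
  "tn_pos_lt50", "tn_pos_ge50",
  "tn_neg_lt50", "tn_neg_ge50",
  "tn_unk_lt50", "tn_unk_ge50",
  "bilateral_bc",
  "ov_lt60", "ov_ge60",
  "pancreatic",
  "male_bc",
  "prostate_lt60", "prostate_ge60"
)

design_terms_family <- c(
  "fam_bc_lt50_1", "fam_bc_lt50_2", "fam_bc_lt50_3p",
  "fam_bc_ge50_1", "fam_bc_ge50_2", "fam_bc_ge50_3p",
  "fam_oc_lt60_1", "fam_oc_lt60_2p",
  "fam_oc_ge60_1", "fam_oc_ge60_2p",
  "fam_panc_1", "fam_panc_2p",
  "fam_mbc",
  "fam_prostate_1", "fam_prostate_2p"
)

#' Names of the 29 clinical-history indicators
#'
#' 14 personal-history indicators (DCIS; invasive breast cancer split by
#' triple-negative status -- positive / negative / unknown -- crossed with
#' diagnosis before/after age 50; bilateral breast cancer; ovarian cancer
#' before/after 60; pancreatic cancer; male breast cancer; prostate cancer
#' before/after 60) followed by 15 family-history indicators (counts of
#' affected first/second-degree relatives, capped at 3+ for breast cancer
#' and 2+ for the other cancers).
#'
#' @return Character vector of length 29 in canonical order.
#' @export
design_terms <- function() c(design_terms_personal, design_terms_family)

# Capped count -> indicator columns, e.g. counts 0,1,2,5 with cap 3 become
# the three dummies (x==1), (x==2), (x>=3).
count_dummies <- function(x, cap) {
  ind <- lapply(seq_len(cap), function(k) {
    if (k < cap) as.integer(x == k) else as.integer(x >= k)
  })
  names(ind) <- c(as.character(seq_len(cap - 1L)), paste0(cap, "p"))[seq_len(cap)]
  ind
}

#' Build the clinical-history design matrix
#'
#' Maps each validated proband row to the 29 binary indicators. Family
#' counts are capped into categories (0/1/2/3+ for breast cancer, 0/1/2+
#' otherwise); an invasive breast cancer fills exactly one of the six
#' TN-by-age cells; male breast cancer sets `male_bc` and (by default) also
#' the TN-by-age cell; DCIS and bilateral disease are additional indicators
#' on top of the invasive-cancer cell.
#'
#' @param cohort Cohort tibble as returned by [read_cohort()] or
#'   [simulate_cohort()].
#' @param config A [cohort_config()].
#'
#' @return Tibble with `proband_id` plus the 29 indicator columns
#'   (0/1 integers), rows aligned with `cohort`.
#' @export
#' @examples
#' ph <- toy_cohort()
#' build_design(ph)
build_design <- function(cohort, config = cohort_config()) {
  stopifnot(is.data.frame(cohort))
  n <- nrow(cohort)
  zero <- integer(n)

  bc <- cohort$bc %in% TRUE
  bc_lt <- bc & !is.na(cohort$bc_age_dx) & cohort$bc_age_dx < config$age_cut_bc
  bc_ge <- bc & !bc_lt
  tn <- ifelse(bc, as.character(cohort$bc_tn_status), NA_character_)

  cell <- function(status, young) as.integer(bc & tn %in% status & (if (young) bc_lt else bc_ge))
  male_bc <- as.integer(bc & cohort$sex == "male")
  if (!config$male_bc_fills_tn_cell) {
    # exclusive variant: male breast cancers only set male_bc
    drop_male <- male_bc == 1L
    bc_lt <- bc_lt & !drop_male
    bc_ge <- bc_ge & !drop_male
  }

  oc <- cohort$oc %in% TRUE
  oc_lt <- oc & !is.na(cohort$oc_age_dx) & cohort$oc_age_dx < config$age_cut_ov_pr
  pr <- cohort$prostate %in% TRUE
  pr_lt <- pr & !is.na(cohort$prostate_age_dx) & cohort$prostate_age_dx < config$age_cut_ov_pr

  personal <- list(
    dcis = as.integer(cohort$dcis %in% TRUE),
    tn_pos_lt50 = cell("tn_pos", TRUE), tn_pos_ge50 = cell("tn_pos", FALSE),
    tn_neg_lt50 = cell("tn_neg", TRUE), tn_neg_ge50 = cell("tn_neg", FALSE),
    tn_unk_lt50 = cell("tn_unknown", TRUE), tn_unk_ge50 = cell("tn_unknown", FALSE),
    bilateral_bc = as.integer(bc & cohort$bc_bilateral %in% TRUE),
    ov_lt60 = as.integer(oc_lt), ov_ge60 = as.integer(oc & !oc_lt),
    pancreatic = as.integer(cohort$pancreatic %in% TRUE),
    male_bc = male_bc,
    prostate_lt60 = as.integer(pr_lt), prostate_ge60 = as.integer(pr & !pr_lt)
  )

  fam <- c(
    setNames(count_dummies(cohort$fam_bc_lt50, 3L), paste0("fam_bc_lt50_", c("1", "2", "3p"))),
    setNames(count_dummies(cohort$fam_bc_ge50, 3L), paste0("fam_bc_ge50_", c("1", "2", "3p"))),
    setNames(count_dummies(cohort$fam_oc_lt60, 2L), paste0("fam_oc_lt60_", c("1", "2p"))),
    setNames(count_dummies(cohort$fam_oc_ge60, 2L), paste0("fam_oc_ge60_", c("1", "2p"))),
    setNames(count_dummies(cohort$fam_pancreatic, 2L), paste0("fam_panc_", c("1", "2p"))),
    list(fam_mbc = as.integer(cohort$fam_mbc >= 1L)),
    setNames(count_dummies(cohort$fam_prostate, 2L), paste0("fam_prostate_", c("1", "2p")))
  )

  out <- tibble::as_tibble(c(list(proband_id = cohort$proband_id), personal, fam))
  out[, c("proband_id", design_terms())]
}
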