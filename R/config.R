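# Controlled vocabularies shared across the package. Values are lower-case
# snake_case tokens as they appear in the delimited input files.

#' @rdname cohort_config
#' @format NULL
#' @export
race_groups <- c("european_mixed", "african_american", "asian", "hispanic")

#' @rdname cohort_config
#' @format NULL
#' @export
gene_statuses <- c("pathogenic", "vlp", "vus", "none")

#' @rdname cohort_config
#' @format NULL
#' @export
genes <- c("BRCA1", "BRCA2")

#' @rdname cohort_config
#' @format NULL
#' @export
bioinfo_classes <- c(
  "not_in_key_domain", "C0", "C15_C25", "C35_C55", "C65",
  "splice_high_damage", "splice_moderate_damage",
  "denovo_donor_increased", "denovo_donor_moderate", "other"
)

tn_statuses <- c("tn_pos", "tn_neg", "tn_unknown")

#' Cohort configuration
#'
#' Bundles the file-format and category-definition settings used by the
#' readers and the design-matrix builder. Age cuts follow the carrier-model
#' convention: breast cancer is dichotomised at diagnosis before/after 50
#' years; ovarian and prostate cancer at 60 years. Key functional domains
#' (BRCA1 RING + BRCT regions, BRCA2 DNA-binding domain) are carried as
#' nucleotide ranges for documentation of the bioinformatic classes; the
#' class labels themselves are inputs, never computed here.
#'
#' @param delimiter Field delimiter of the cohort / variant files.
#' @param missing_token String encoding missing values.
#' @param age_cut_bc Age cut (years) for breast cancer diagnosis categories.
#' @param age_cut_ov_pr Age cut (years) for ovarian and prostate cancer.
#' @param key_domains Named list of per-gene nucleotide range matrices.
#' @param male_bc_fills_tn_cell Should a male breast cancer also fill the
#'   appropriate TN-by-age indicator (in addition to `male_bc`)? Default
#'   `TRUE`; the two predictors are treated as parallel, not exclusive.
#'
#' @return A list of class `"cohort_config"`.
#' @export
cohort_config <- function(delimiter = "\t",
                          missing_token = "NA",
                          age_cut_bc = 50,
                          age_cut_ov_pr = 60,
                          key_domains = list(
                            BRCA1 = rbind(c(1L, 294L), c(4987L, 5577L)),
                            BRCA2 = rbind(c(7669L, 9558L))
                          ),
                          male_bc_fills_tn_cell = TRUE) {
  stopifnot(nchar(delimiter) == 1L, age_cut_bc > 0, age_cut_ov_pr > 0)
  structure(
    list(
      delimiter = delimiter,
      missing_token = missing_token,
      age_cut_bc = age_cut_bc,
      age_cut_ov_pr = age_cut_ov_pr,
      key_domains = key_domains,
      male_bc_fills_tn_cell = male_bc_fills_tn_cell
    ),
    class = "cohort_config"
  )
}
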