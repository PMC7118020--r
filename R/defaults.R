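# Published odds-ratio structure of the carrier-prediction models, used to
# seed the synthetic-cohort generator, and the external prior-probability
# calibration for the bioinformatic classes.

# Rows follow design_terms(); one column per (gene, race group). NA marks
# cells that were not estimable in the source models ("-" cells); the
# generator treats them as a null effect (OR = 1).
default_or_table <- function() {
  term <- design_terms()
  or <- cbind(
    # BRCA1: european_mixed, african_american, asian, hispanic
    BRCA1.european_mixed = c(
      1.0, 15.9, 5.1, 1.7, 0.5, 3.8, 1.1, 1.6, 10.7, 4.2, 1.3, 1.1, 1.1, 1.9,
      2.2, 3.7, 5.3, 0.9, 0.7, 0.7, 3.2, 5.4, 1.7, 1.6, 1.1, 0.7, 1.0, 0.9, 0.7
    ),
    BRCA1.african_american = c(
      0.2, 15.7, 2.8, 2.5, 0.5, 5.4, 1.2, 1.8, 8.6, 1.1, 2.3, NA, NA, NA,
      3.1, 5.1, 12.0, 0.7, 0.5, 0.7, 1.7, 0.4, 2.3, 2.7, 0.9, 2.0, 0.9, 0.4, 0.5
    ),
    BRCA1.asian = c(
      0.8, 23.5, 9.0, 3.1, 1.3, 4.2, 2.0, 1.7, 17.2, 12.0, NA, NA, NA, NA,
      2.8, 3.0, 8.3, 1.5, 0.6, 2.0, 3.4, 4.8, 1.8, 5.6, 0.7, 1.3, NA, 0.9, 0.5
    ),
    BRCA1.hispanic = c(
      0.6, 25.9, 4.6, 2.9, 0.7, 4.8, NA, 2.2, 17.5, 14.1, NA, NA, NA, NA,
      2.7, 5.0, 9.1, 1.1, 0.7, 0.9, 1.9, 3.0, 1.9, 2.0, 1.2, 2.6, 0.4, 0.8, 0.4
    ),
    BRCA2.european_mixed = c(
      1.3, 3.1, 2.9, 2.5, 1.5, 2.4, 1.4, 1.2, 4.0, 4.9, 3.9, 6.3, 1.4, 2.4,
      1.5, 2.0, 3.2, 1.1, 0.9, 0.7, 1.4, 1.4, 1.6, 1.9, 1.3, 1.7, 2.5, 1.3, 1.5
    ),
    BRCA2.african_american = c(
      0.9, 3.4, 1.5, 2.4, 1.4, 3.2, 1.4, 2.0, 3.0, 4.3, 2.4, 4.0, 3.2, 9.7,
      1.3, 1.4, 1.8, 0.8, 0.8, 1.4, 2.1, 0.6, 0.7, 1.0, 1.6, 1.1, 5.4, 1.2, 0.9
    ),
    BRCA2.asian = c(
      0.5, 1.5, 1.9, 1.0, 0.9, 0.9, 1.2, 0.8, 1.4, 4.7, 5.1, 1.8, NA, 5.1,
      1.3, 1.5, 3.1, 2.4, 1.4, 3.0, 1.5, 1.0, 1.2, NA, 1.7, 0.6, NA, 1.8, 1.9
    ),
    BRCA2.hispanic = c(
      1.6, 2.1, 0.9, 2.0, 1.8, 1.8, 1.2, 1.1, 3.9, 2.6, 6.3, 5.6, 10.3, 16.3,
      1.5, 1.3, 3.4, 1.3, 0.9, 0.4, 1.4, 1.0, 1.5, 1.6, 2.1, 0.4, 3.1, 1.3, 2.1
    )
  )
  rownames(or) <- term
  or
}

#' Default log-odds coefficients for the generative carrier model
#'
#' Published per-gene, per-race-group odds ratios of the 29 clinical-history
#' indicators, on the log scale, used to seed the synthetic-cohort
#' generator. Cells not estimable in the source models are returned as
#' `NA`; the generator treats them as a null effect.
#'
#' @param gene `"BRCA1"` or `"BRCA2"`.
#' @param race_group One of [race_groups].
#' @return Named numeric vector of 29 log-odds ratios.
#' @export
default_log_odds <- function(gene = "BRCA1", race_group = "european_mixed") {
  gene <- match.arg(gene, genes)
  race_group <- match.arg(race_group, race_groups)
  log(default_or_table()[, paste(gene, race_group, sep = ".")])
}

#' Default prior probabilities of pathogenicity per bioinformatic class
#'
#' External calibration values from earlier multifactorial studies, as
#' commonly assumed when combining clinical-history likelihood ratios into
#' posteriors: missense variants outside the key functional domains 0.02;
#' within key domains by Align-GVGD grade C0 0.03, C15--C25 0.29,
#' C35--C55 0.66, C65 0.81; splice variants with high / moderate predicted
#' damage to the wild-type site 0.97 / 0.34; increased / moderate
#' probability of a de novo donor 0.64 / 0.30. The catch-all `other` class
#' gets an uninformative 0.5. These are inputs to classification, not
#' estimates produced by this package.
#'
#' @return Tibble with columns `bioinfo_class`, `prior_prob`.
#' @export
default_priors <- function() {
  tibble::tibble(
    bioinfo_class = bioinfo_classes,
    prior_prob = c(0.02, 0.03, 0.29, 0.66, 0.81, 0.97, 0.34, 0.64, 0.30, 0.50)
  )
}
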