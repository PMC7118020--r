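# Delimited-text readers/writers for the three input tables (cohort,
# variant observations, class priors) plus validation and the exclusion
# filter. All readers are strict: schema problems name the column, row
# problems name the rows.

cohort_required_cols <- c(
  "proband_id", "race_group", "sex", "brca1_status", "brca2_status",
  "other_gene_plp", "history_sufficient",
  "dcis", "bc", "bc_age_dx", "bc_tn_status", "bc_bilateral",
  "oc", "oc_age_dx", "pancreatic", "prostate", "prostate_age_dx",
  "fam_bc_lt50", "fam_bc_ge50", "fam_oc_lt60", "fam_oc_ge60",
  "fam_pancreatic", "fam_mbc", "fam_prostate"
)

cohort_optional_cols <- c("race_folded", "prev_brca_tested_negative")

variant_required_cols <- c(
  "proband_id", "gene", "variant_id", "lab_class", "bioinfo_class", "prior_prob"
)

check_schema <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ), class = "vuslr_schema_error")
  }
  invisible(df)
}

bad_rows <- function(cond, msg, problems) {
  rows <- which(cond)
  if (length(rows) > 0) {
    problems[[length(problems) + 1L]] <- sprintf(
      "%s (rows: %s)", msg,
      paste(head(rows, 20L), collapse = ", ")
    )
  }
  problems
}

#' Validate a cohort table
#'
#' Checks the proband-level schema and row-level invariants: unique ids,
#' known factor levels, ages present whenever the corresponding cancer is
#' reported, triple-negative status defined exactly when an invasive breast
#' cancer is present, male breast cancer only in males, non-negative family
#' counts.
#'
#' @param cohort A data frame of probands.
#' @return The validated cohort as a tibble (invisibly unchanged), or an
#'   error of class `vuslr_validation_error` listing offending rows.
#' @export
validate_cohort <- function(cohort) {
  check_schema(cohort, cohort_required_cols, "cohort")
  x <- tibble::as_tibble(cohort)

  if (anyDuplicated(x$proband_id) > 0) {
    dup <- unique(x$proband_id[duplicated(x$proband_id)])
    abort(sprintf(
      "duplicate proband_id: %s", paste(head(dup, 10L), collapse = ", ")
    ), class = "vuslr_integrity_error")
  }

  p <- list()
  p <- bad_rows(!(x$race_group %in% race_groups), "unknown race_group", p)
  p <- bad_rows(!(x$sex %in% c("female", "male")), "unknown sex", p)
  p <- bad_rows(!(x$brca1_status %in% gene_statuses), "unknown brca1_status", p)
  p <- bad_rows(!(x$brca2_status %in% gene_statuses), "unknown brca2_status", p)
  p <- bad_rows(x$bc %in% TRUE & is.na(x$bc_age_dx),
                "breast cancer reported without age at diagnosis", p)
  p <- bad_rows(x$bc %in% TRUE & !(x$bc_tn_status %in% tn_statuses),
                "breast cancer reported without valid tn_status", p)
  p <- bad_rows(!(x$bc %in% TRUE) & !is.na(x$bc_tn_status),
                "tn_status present without breast cancer", p)
  p <- bad_rows(x$oc %in% TRUE & is.na(x$oc_age_dx),
                "ovarian cancer reported without age at diagnosis", p)
  p <- bad_rows(x$prostate %in% TRUE & is.na(x$prostate_age_dx),
                "prostate cancer reported without age at diagnosis", p)
  p <- bad_rows(x$sex == "female" & (x$prostate %in% TRUE),
                "prostate cancer reported for female proband", p)
  for (cc in c("fam_bc_lt50", "fam_bc_ge50", "fam_oc_lt60", "fam_oc_ge60",
               "fam_pancreatic", "fam_mbc", "fam_prostate")) {
    p <- bad_rows(is.na(x[[cc]]) | x[[cc]] < 0, paste(cc, "must be a count >= 0"), p)
  }

  if (length(p) > 0) {
    abort(paste0("cohort validation failed:\n", paste("-", unlist(p), collapse = "\n")),
          class = "vuslr_validation_error")
  }
  invisible(x)
}

#' Read / write a proband cohort table
#'
#' `read_cohort()` reads a delimited text file with one row per tested
#' proband, validates it, and folds the reported race/ethnicity into the
#' four analysis strata: `european` and `mixed_unknown` inputs are merged
#' into `european_mixed` (recorded in the logical `race_folded` column so a
#' sensitivity rerun can drop the folded probands).
#'
#' @param path File path.
#' @param config A [cohort_config()] (delimiter, missing-value token).
#' @param cohort Validated cohort tibble (for `write_cohort`).
#' @return A validated cohort tibble.
#' @export
read_cohort <- function(path, config = cohort_config()) {
  header <- strsplit(readr::read_lines(path, n_max = 1L), config$delimiter,
                     fixed = TRUE)[[1]]
  spec <- list(
    proband_id = readr::col_character(),
    race_group = readr::col_character(),
    sex = readr::col_character(),
    brca1_status = readr::col_character(),
    brca2_status = readr::col_character(),
    bc_tn_status = readr::col_character(),
    other_gene_plp = readr::col_logical(),
    history_sufficient = readr::col_logical(),
    dcis = readr::col_logical(),
    bc = readr::col_logical(),
    bc_bilateral = readr::col_logical(),
    oc = readr::col_logical(),
    pancreatic = readr::col_logical(),
    prostate = readr::col_logical(),
    bc_age_dx = readr::col_double(),
    oc_age_dx = readr::col_double(),
    prostate_age_dx = readr::col_double(),
    race_folded = readr::col_logical(),
    prev_brca_tested_negative = readr::col_logical()
  )
  spec <- spec[intersect(names(spec), header)]
  df <- readr::read_delim(
    path,
    delim = config$delimiter, na = config$missing_token,
    col_types = do.call(readr::cols,
                        c(spec, list(.default = readr::col_integer()))),
    progress = FALSE, show_col_types = FALSE
  )
  check_schema(df, cohort_required_cols, "cohort")

  # fold reported race into the four analysis strata
  if (!"race_folded" %in% names(df)) {
    df$race_folded <- df$race_group %in% "mixed_unknown"
  }
  df$race_group[df$race_group %in% c("european", "mixed_unknown")] <- "european_mixed"
  if (!"prev_brca_tested_negative" %in% names(df)) {
    df$prev_brca_tested_negative <- FALSE
  }
  validate_cohort(df)
}

#' @rdname read_cohort
#' @export
write_cohort <- function(cohort, path, config = cohort_config()) {
  readr::write_delim(cohort, path, delim = config$delimiter, na = config$missing_token)
  invisible(path)
}

#' Read a variant-observation table
#'
#' One row per proband-by-variant observation: gene, opaque HGVS label,
#' laboratory classification (`pathogenic`/`vlp`/`vus`), bioinformatic
#' class and its prior probability of pathogenicity.
#'
#' @inheritParams read_cohort
#' @return Tibble of observations; `(proband_id, gene, variant_id)` unique.
#' @export
read_variants <- function(path, config = cohort_config()) {
  df <- readr::read_delim(
    path,
    delim = config$delimiter, na = config$missing_token,
    col_types = readr::cols(
      prior_prob = readr::col_double(),
      .default = readr::col_character()
    ),
    progress = FALSE, show_col_types = FALSE
  )
  check_schema(df, variant_required_cols, "variant table")
  validate_variants(df)
}

#' @rdname read_variants
#' @param variants A data frame of variant observations.
#' @export
validate_variants <- function(variants) {
  check_schema(variants, variant_required_cols, "variant table")
  x <- tibble::as_tibble(variants)
  key <- paste(x$proband_id, x$gene, x$variant_id, sep = "\r")
  if (anyDuplicated(key) > 0) {
    abort("duplicate (proband_id, gene, variant_id) rows in variant table",
          class = "vuslr_integrity_error")
  }
  p <- list()
  p <- bad_rows(!(x$gene %in% genes), "unknown gene", p)
  p <- bad_rows(!(x$lab_class %in% c("pathogenic", "vlp", "vus")), "unknown lab_class", p)
  p <- bad_rows(!(x$bioinfo_class %in% bioinfo_classes), "unknown bioinfo_class", p)
  p <- bad_rows(is.na(x$prior_prob) | x$prior_prob < 0 | x$prior_prob > 1,
                "prior_prob outside [0, 1]", p)
  if (length(p) > 0) {
    abort(paste0("variant validation failed:\n", paste("-", unlist(p), collapse = "\n")),
          class = "vuslr_validation_error")
  }
  x
}

#' Read a prior-probability table
#'
#' Two columns: `bioinfo_class`, `prior_prob`. See [default_priors()] for
#' the packaged external calibration values.
#'
#' @inheritParams read_cohort
#' @export
read_priors <- function(path, config = cohort_config()) {
  df <- readr::read_delim(
    path,
    delim = config$delimiter, na = config$missing_token,
    col_types = readr::cols(
      bioinfo_class = readr::col_character(),
      prior_prob = readr::col_double()
    ),
    progress = FALSE, show_col_types = FALSE
  )
  check_schema(df, c("bioinfo_class", "prior_prob"), "prior table")
  stopifnot(all(df$prior_prob >= 0 & df$prior_prob <= 1))
  tibble::as_tibble(df)
}

#' Apply the per-gene analysis exclusions
#'
#' Removes, in fixed order: (a) probands with insufficient personal/family
#' history information, (b) carriers of a pathogenic or likely pathogenic
#' variant in another susceptibility gene, and (c) carriers of a
#' pathogenic/VLP/VUS variant in the *opposite* BRCA gene. A proband
#' failing several rules is counted once, under the first rule that
#' removes it.
#'
#' @param cohort Validated cohort tibble.
#' @param gene `"BRCA1"` or `"BRCA2"` — the gene under analysis.
#' @return The retained cohort, with an `"exclusion_report"` attribute: a
#'   tibble of the three rules and the number removed by each.
#' @export
apply_exclusions <- function(cohort, gene) {
  gene <- match.arg(gene, genes)
  opp <- if (gene == "BRCA1") "brca2_status" else "brca1_status"

  r_a <- !(cohort$history_sufficient %in% TRUE)
  r_b <- !r_a & cohort$other_gene_plp %in% TRUE
  r_c <- !r_a & !r_b & cohort[[opp]] %in% c("pathogenic", "vlp", "vus")

  report <- tibble::tibble(
    rule = c("insufficient_history", "other_gene_plp", "opposite_gene_variant"),
    n_removed = c(sum(r_a), sum(r_b), sum(r_c))
  )
  out <- cohort[!(r_a | r_b | r_c), , drop = FALSE]
  attr(out, "exclusion_report") <- report
  out
}

#' @rdname apply_exclusions
#' @export
exclusion_report <- function(cohort) attr(cohort, "exclusion_report")
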