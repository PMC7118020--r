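# Per-gene, per-race-group logistic regression of pathogenic-carrier
# status on the 29 clinical-history indicators, plus prediction, the null
# carrier probability r0, and rank-based AUC with a Hanley-McNeil CI.

#' Null carrier probability
#'
#' The probability that a tested proband in the stratum carries a
#' pathogenic variant, estimated as the case fraction among probands with
#' a definitive result: `n_cases / (n_cases + n_controls)`. This is the
#' reference probability r0 against which predicted probabilities are
#' converted to likelihood ratios.
#'
#' @param n_cases,n_controls Counts of pathogenic carriers and
#'   variant-negative probands.
#' @return Probability in (0, 1).
#' @export
#' @examples
#' null_carrier_prob(1706, 108602) # ~0.015
null_carrier_prob <- function(n_cases, n_controls) {
  stopifnot(n_cases > 0, n_controls > 0)
  n_cases / (n_cases + n_controls)
}

#' Fit the carrier-prediction logistic regression
#'
#' Compares the clinical histories of known pathogenic-variant carriers
#' (cases) against probands with no reportable variant in the gene
#' (controls) within one race/ethnicity stratum. Carriers of VUS or likely
#' pathogenic variants are never used for fitting — they are the probands
#' to be scored. Indicators with no exposed probands, or exposed only
#' among cases or only among controls (the non-estimable cells of sparse
#' strata), are dropped from the fit and flagged.
#'
#' @param cohort Cohort tibble that has already passed [apply_exclusions()]
#'   for `gene`.
#' @param gene `"BRCA1"` or `"BRCA2"`.
#' @param race_group One of [race_groups].
#' @param config A [cohort_config()].
#' @param epsilon,maxit IRLS convergence tolerance and iteration cap.
#' @return Object of class `"carrier_fit"`: coefficients (log-odds),
#'   covariance, dropped-term flags, r0, case/control counts, in-sample
#'   AUC, convergence diagnostics. Supports [tidy()], [glance()],
#'   [autoplot()].
#' @export
fit_carrier_model <- function(cohort, gene, race_group,
                              config = cohort_config(),
                              epsilon = 1e-8, maxit = 100L) {
  gene <- match.arg(gene, genes)
  race_group <- match.arg(race_group, race_groups)
  status <- cohort[[paste0(tolower(gene), "_status")]]
  keep <- cohort$race_group == race_group & status %in% c("pathogenic", "none")
  sub <- cohort[keep, , drop = FALSE]
  y <- as.integer(status[keep] == "pathogenic")

  n_cases <- sum(y)
  n_controls <- sum(1L - y)
  if (n_cases == 0 || n_controls == 0) {
    abort(sprintf("cannot fit %s / %s: %d cases, %d controls",
                  gene, race_group, n_cases, n_controls),
          class = "vuslr_fit_error")
  }

  X <- as.matrix(build_design(sub, config)[, design_terms()])
  exp_cases <- colSums(X[y == 1L, , drop = FALSE])
  exp_controls <- colSums(X[y == 0L, , drop = FALSE])
  reason <- dplyr::case_when(
    exp_cases + exp_controls == 0 ~ "no_exposure",
    exp_cases == 0 ~ "no_exposed_cases",
    exp_controls == 0 ~ "no_exposed_controls",
    TRUE ~ NA_character_
  )
  dropped <- tibble::tibble(term = design_terms(), reason = reason) |>
    dplyr::filter(!is.na(.data$reason))
  kept <- setdiff(design_terms(), dropped$term)

  Xk <- cbind(`(Intercept)` = 1, X[, kept, drop = FALSE])
  fit <- suppressWarnings(
    stats::glm.fit(Xk, y, family = binomial(),
                   control = list(epsilon = epsilon, maxit = as.integer(maxit)))
  )
  beta <- fit$coefficients

  sep <- names(beta)[!is.na(beta) & abs(beta) > 15 & names(beta) != "(Intercept)"]
  if (length(sep) > 0) {
    abort(sprintf("separation detected for indicator(s): %s",
                  paste(sep, collapse = ", ")),
          class = "vuslr_separation_error")
  }

  R <- qr.R(fit$qr)
  vcov <- tryCatch(chol2inv(R), error = function(e) matrix(NA_real_, ncol(Xk), ncol(Xk)))
  dimnames(vcov) <- list(names(beta), names(beta))

  eta <- drop(Xk %*% beta)
  auc <- auc_hanley_mcneil(eta, y)

  structure(
    list(
      gene = gene, race_group = race_group,
      coefficients = beta, vcov = vcov,
      dropped = dropped,
      r0 = null_carrier_prob(n_cases, n_controls),
      n_cases = n_cases, n_controls = n_controls,
      loglik = -fit$deviance / 2,
      converged = fit$converged, iterations = fit$iter,
      auc = auc
    ),
    class = "carrier_fit"
  )
}

#' Predict carrier probabilities
#'
#' Applies a fitted (or externally supplied) coefficient set to a cohort,
#' returning the predicted probability r_k that each proband carries a
#' pathogenic variant given their clinical history. Dropped indicators
#' contribute zero to the linear predictor.
#'
#' @param fit A `"carrier_fit"`.
#' @param cohort Cohort tibble (any probands, any gene status).
#' @param config A [cohort_config()].
#' @return Tibble with `proband_id`, `r_k`.
#' @export
predict_carrier <- function(fit, cohort, config = cohort_config()) {
  stopifnot(inherits(fit, "carrier_fit"))
  X <- as.matrix(build_design(cohort, config)[, design_terms()])
  beta <- setNames(numeric(length(design_terms())), design_terms())
  est <- fit$coefficients[names(fit$coefficients) != "(Intercept)"]
  beta[names(est)] <- est
  eta <- fit$coefficients[["(Intercept)"]] + drop(X %*% beta)
  tibble::tibble(proband_id = cohort$proband_id, r_k = plogis(eta))
}

# Rank-based (Mann-Whitney) AUC with midrank tie correction and the
# Hanley-McNeil closed-form variance.
auc_hanley_mcneil <- function(score, label, conf_level = 0.95) {
  y <- as.integer(label)
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  if (n1 == 0 || n0 == 0) {
    abort("AUC requires both cases and controls", class = "vuslr_auc_error")
  }
  r <- rank(score)
  a <- (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  q1 <- a / (2 - a)
  q2 <- 2 * a^2 / (1 + a)
  v <- (a * (1 - a) + (n1 - 1) * (q1 - a^2) + (n0 - 1) * (q2 - a^2)) / (n1 * n0)
  se <- sqrt(max(v, 0))
  z <- qnorm(1 - (1 - conf_level) / 2)
  tibble::tibble(
    auc = a, se = se,
    ci_lower = max(0, a - z * se), ci_upper = min(1, a + z * se),
    n_cases = n1, n_controls = n0, method = "hanley_mcneil"
  )
}

#' Rank-based AUC of a fitted carrier model on a labeled cohort
#'
#' Mann-Whitney AUC (with midrank tie correction) of the model's linear
#' predictor for discriminating pathogenic carriers from variant-negative
#' probands, with a Hanley-McNeil closed-form confidence interval.
#'
#' @inheritParams predict_carrier
#' @param conf_level Confidence level for the interval.
#' @return One-row tibble: `auc`, `se`, `ci_lower`, `ci_upper`, counts.
#' @export
carrier_auc <- function(fit, cohort, config = cohort_config(), conf_level = 0.95) {
  status <- cohort[[paste0(tolower(fit$gene), "_status")]]
  keep <- cohort$race_group == fit$race_group & status %in% c("pathogenic", "none")
  sub <- cohort[keep, , drop = FALSE]
  scores <- predict_carrier(fit, sub, config)$r_k
  auc_hanley_mcneil(scores, as.integer(status[keep] == "pathogenic"), conf_level)
}

#' @export
print.carrier_fit <- function(x, ...) {
  cat(sprintf(
    "<carrier_fit> %s / %s: %d cases, %d controls (r0 = %.4f)\n",
    x$gene, x$race_group, x$n_cases, x$n_controls, x$r0
  ))
  cat(sprintf("  AUC %.3f (%.3f-%.3f); %d indicator(s) dropped; converged: %s\n",
              x$auc$auc, x$auc$ci_lower, x$auc$ci_upper,
              nrow(x$dropped), x$converged))
  invisible(x)
}

#' Tidy a fitted carrier model
#'
#' @param x A `"carrier_fit"`.
#' @param exponentiate Report odds ratios instead of log-odds.
#' @param conf_level Confidence level for Wald intervals.
#' @param ... Unused.
#' @return Tibble with one row per term (intercept, 29 indicators);
#'   dropped indicators carry `NA` estimates and the drop reason.
#' @method tidy carrier_fit
#' @export
tidy.carrier_fit <- function(x, exponentiate = FALSE, conf_level = 0.95, ...) {
  z <- qnorm(1 - (1 - conf_level) / 2)
  est <- x$coefficients
  se <- sqrt(diag(x$vcov))
  out <- tibble::tibble(
    term = c("(Intercept)", design_terms()),
    estimate = NA_real_, std.error = NA_real_,
    statistic = NA_real_, p.value = NA_real_,
    conf.low = NA_real_, conf.high = NA_real_,
    dropped_reason = NA_character_
  )
  i <- match(names(est), out$term)
  out$estimate[i] <- est
  out$std.error[i] <- se
  out$statistic[i] <- est / se
  out$p.value[i] <- 2 * stats::pnorm(-abs(est / se))
  out$conf.low[i] <- est - z * se
  out$conf.high[i] <- est + z * se
  j <- match(x$dropped$term, out$term)
  out$dropped_reason[j] <- x$dropped$reason
  if (exponentiate) {
    out <- dplyr::mutate(out, dplyr::across(
      c("estimate", "conf.low", "conf.high"), exp
    ))
  }
  out
}

#' Model-level summary of a fitted carrier model
#'
#' @param x A `"carrier_fit"`.
#' @param ... Unused.
#' @return One-row tibble: stratum, counts, r0, AUC with CI, log-likelihood,
#'   number of dropped indicators, convergence.
#' @method glance carrier_fit
#' @export
glance.carrier_fit <- function(x, ...) {
  tibble::tibble(
    gene = x$gene, race_group = x$race_group,
    n_cases = x$n_cases, n_controls = x$n_controls,
    r0 = x$r0,
    auc = x$auc$auc, auc_ci_lower = x$auc$ci_lower, auc_ci_upper = x$auc$ci_upper,
    logLik = x$loglik, n_dropped = nrow(x$dropped),
    converged = x$converged
  )
}

#' Forest plot of estimated odds ratios
#'
#' @param object A `"carrier_fit"`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot carrier_fit
#' @export
autoplot.carrier_fit <- function(object, ...) {
  d <- tidy.carrier_fit(object, exponentiate = TRUE) |>
    dplyr::filter(.data$term != "(Intercept)", !is.na(.data$estimate)) |>
    dplyr::mutate(term = factor(.data$term, levels = rev(design_terms())))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low, xmax = .data$conf.high)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "odds ratio (log scale)", y = NULL,
      title = sprintf("Carrier-status predictors: %s, %s", object$gene, object$race_group)
    ) +
    ggplot2::theme_minimal()
}
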