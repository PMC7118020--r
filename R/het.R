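# Admixture (heterogeneity) analysis: within a class of N variants with
# per-variant combined likelihood ratios LR_i, the likelihood of the
# pathogenic proportion alpha is prod_i [alpha LR_i + (1 - alpha)]. The
# log-likelihood is maximized over [0, 1]; approximate 95% profile CIs are
# the alpha values where 2 ln L drops 3.84 below the maximum; partitions
# of the variant space are compared by likelihood-ratio tests.

CHISQ1_95 <- 3.84

#' Admixture log-likelihood
#'
#' `sum_i ln(alpha * LR_i + 1 - alpha)` over the variants of a class,
#' where `LR_i` is the combined likelihood ratio of the i-th variant.
#' Computed stably in log space, so extreme LRs (supplied as `log10_lrs`)
#' do not overflow.
#'
#' @param alpha Pathogenic proportion, in \[0, 1\].
#' @param lrs Positive per-variant combined LRs, or
#' @param log10_lrs their log10 (preferred for extreme values).
#' @return Log-likelihood (natural log) at `alpha`.
#' @export
admixture_loglik <- function(alpha, lrs = NULL, log10_lrs = NULL) {
  stopifnot(length(alpha) == 1, alpha >= 0, alpha <= 1)
  if (is.null(log10_lrs)) {
    if (any(lrs <= 0)) {
      abort("all LRs must be strictly positive", class = "vuslr_domain_error")
    }
    log10_lrs <- log10(lrs)
  }
  l <- log10_lrs * log(10)
  m <- pmax(l, 0)
  sum(m + log(alpha * exp(l - m) + (1 - alpha) * exp(-m)))
}

#' Maximum-likelihood estimate of the pathogenic proportion
#'
#' Maximizes the admixture log-likelihood over alpha in \[0, 1\] by
#' Brent's method, with explicit endpoint comparison so boundary maxima
#' (all evidence pointing one way) are detected and flagged. A fully flat
#' likelihood (every LR equal to 1) is unidentifiable: by convention
#' alpha-hat is 0 with a warning, and the profile CI spans \[0, 1\].
#'
#' @inheritParams admixture_loglik
#' @param tol Brent tolerance.
#' @return List: `alpha_hat`, `loglik_max`, `boundary_flag` (`"interior"`,
#'   `"at_zero"`, `"at_one"`, `"flat"`), `n_variants`.
#' @export
estimate_alpha <- function(lrs = NULL, log10_lrs = NULL, tol = 1e-8) {
  if (is.null(log10_lrs)) {
    if (any(lrs <= 0)) {
      abort("all LRs must be strictly positive", class = "vuslr_domain_error")
    }
    log10_lrs <- log10(lrs)
  }
  stopifnot(length(log10_lrs) >= 1)
  f <- function(a) admixture_loglik(a, log10_lrs = log10_lrs)

  if (all(abs(log10_lrs) < 1e-12)) {
    warn("all LRs equal 1: alpha is unidentifiable; returning alpha_hat = 0")
    return(list(alpha_hat = 0, loglik_max = 0, boundary_flag = "flat",
                n_variants = length(log10_lrs)))
  }

  opt <- optimize(f, c(0, 1), maximum = TRUE, tol = tol)
  cand <- c(opt$maximum, 0, 1)
  vals <- c(opt$objective, f(0), f(1))
  best <- which.max(vals)
  alpha_hat <- cand[best]
  # snap near-boundary optimizer output onto the boundary when it is not
  # a genuine interior maximum
  if (alpha_hat < tol && f(0) >= f(alpha_hat) - 1e-12) alpha_hat <- 0
  if (alpha_hat > 1 - tol && f(1) >= f(alpha_hat) - 1e-12) alpha_hat <- 1
  flag <- if (alpha_hat == 0) "at_zero" else if (alpha_hat == 1) "at_one" else "interior"
  list(alpha_hat = alpha_hat, loglik_max = f(alpha_hat),
       boundary_flag = flag, n_variants = length(log10_lrs))
}

#' Profile-likelihood confidence interval for alpha
#'
#' Finds, by bisection on each side of the maximum, the alpha values where
#' `2 * [loglik(alpha_hat) - loglik(alpha)]` equals the chi-square drop
#' (3.84 for an approximate 95% interval), truncated at \[0, 1\]. At a
#' boundary estimate the interval is one-sided.
#'
#' @inheritParams admixture_loglik
#' @param alpha_hat,loglik_max Output of [estimate_alpha()].
#' @param drop Chi-square(1) critical drop of 2 ln L (default 3.84).
#' @return Numeric `c(lower, upper)`.
#' @export
profile_ci <- function(lrs = NULL, log10_lrs = NULL, alpha_hat, loglik_max,
                       drop = CHISQ1_95) {
  if (is.null(log10_lrs)) log10_lrs <- log10(lrs)
  g <- function(a) 2 * (loglik_max - admixture_loglik(a, log10_lrs = log10_lrs)) - drop

  lower <- if (alpha_hat <= 0 || g(0) <= 0) 0 else {
    uniroot(g, c(0, alpha_hat), tol = 1e-12)$root
  }
  upper <- if (alpha_hat >= 1 || g(1) <= 0) 1 else {
    uniroot(g, c(alpha_hat, 1), tol = 1e-12)$root
  }
  c(lower = lower, upper = upper)
}

#' Likelihood-ratio test for heterogeneity of alpha across a partition
#'
#' Compares the pooled admixture fit (one alpha for all classes) against
#' class-specific alphas: `chi2 = 2 * [sum of class maxima - pooled
#' maximum]` on `#classes - 1` degrees of freedom. When any class estimate
#' sits on a boundary of \[0, 1\] the chi-square reference is conservative
#' (the mixture-boundary correction is noted, not applied).
#'
#' @param lrs_by_class Named list: class label -> vector of per-variant
#'   combined LRs (or set `log10 = TRUE` and pass log10 LRs). Empty
#'   classes are dropped with a warning.
#' @param log10 Are the supplied values log10 LRs?
#' @return List of class `"partition_test"`: `chi2`, `df`, `p_value`,
#'   `pooled` and `parts` summaries, `boundary_involved`.
#' @export
partition_test <- function(lrs_by_class, log10 = FALSE) {
  empty <- vapply(lrs_by_class, length, 0L) == 0
  if (any(empty)) {
    warn(sprintf("dropping empty class(es): %s",
                 paste(names(lrs_by_class)[empty], collapse = ", ")))
    lrs_by_class <- lrs_by_class[!empty]
  }
  if (length(lrs_by_class) < 2) {
    abort("partition test needs at least two non-empty classes")
  }
  as_l10 <- function(x) if (log10) x else log10(x)

  parts <- purrr::imap(lrs_by_class, function(x, nm) {
    est <- estimate_alpha(log10_lrs = as_l10(x))
    tibble::tibble(class_label = nm, n_variants = est$n_variants,
                   alpha_hat = est$alpha_hat, loglik_max = est$loglik_max,
                   boundary_flag = est$boundary_flag)
  }) |> dplyr::bind_rows()

  pooled_lrs <- unlist(lapply(lrs_by_class, as_l10), use.names = FALSE)
  pooled <- estimate_alpha(log10_lrs = pooled_lrs)

  chi2 <- max(0, 2 * (sum(parts$loglik_max) - pooled$loglik_max))
  df <- nrow(parts) - 1L
  structure(
    list(
      chi2 = chi2, df = df,
      p_value = pchisq(chi2, df, lower.tail = FALSE),
      pooled = pooled, parts = parts,
      boundary_involved = any(parts$boundary_flag != "interior") ||
        pooled$boundary_flag != "interior"
    ),
    class = "partition_test"
  )
}

#' @export
print.partition_test <- function(x, ...) {
  cat(sprintf("<partition_test> chi2 = %.3f on %d df, p = %.4g\n",
              x$chi2, x$df, x$p_value))
  if (x$boundary_involved) {
    cat("  note: boundary estimate involved; chi-square reference is conservative\n")
  }
  print(x$parts)
  invisible(x)
}

#' Per-class admixture summary table
#'
#' Groups scored per-variant evidence by bioinformatic class and estimates
#' the pathogenic proportion alpha with a profile-likelihood CI in each.
#' Two analysis modes: `include_pathogenic = TRUE` keeps all variants
#' meeting the class definition regardless of laboratory classification;
#' `FALSE` removes variants a laboratory already classified as pathogenic,
#' so the estimate reflects the unresolved (VLP + VUS) variants only.
#'
#' @param evidence Per-variant evidence from [score_cohort()].
#' @param include_pathogenic Keep laboratory-pathogenic variants?
#' @param drop Profile-CI chi-square drop (default 3.84).
#' @return Tibble of class `"vuslr_class_table"`: `bioinfo_class`,
#'   `n_variants`, `alpha_hat`, `ci_lower`, `ci_upper`, `boundary_flag`,
#'   `loglik_max`, `mode`.
#' @export
class_table <- function(evidence, include_pathogenic = TRUE, drop = CHISQ1_95) {
  keep <- if (include_pathogenic) c("pathogenic", "vlp", "vus") else c("vlp", "vus")
  ev <- evidence[evidence$lab_class %in% keep, , drop = FALSE]

  out <- ev |>
    dplyr::group_by(.data$bioinfo_class) |>
    dplyr::group_modify(function(d, key) {
      est <- estimate_alpha(log10_lrs = d$sum_log10_lr)
      ci <- profile_ci(log10_lrs = d$sum_log10_lr,
                       alpha_hat = est$alpha_hat, loglik_max = est$loglik_max,
                       drop = drop)
      tibble::tibble(
        n_variants = est$n_variants, alpha_hat = est$alpha_hat,
        ci_lower = ci[["lower"]], ci_upper = ci[["upper"]],
        boundary_flag = est$boundary_flag, loglik_max = est$loglik_max
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(mode = if (include_pathogenic) "with_pathogenic" else "vus_vlp_only")
  class(out) <- c("vuslr_class_table", class(out))
  out
}

#' Plot per-class pathogenic-proportion estimates
#'
#' @param object A `"vuslr_class_table"`.
#' @param ... Unused.
#' @return A ggplot of alpha-hat with profile CIs by class.
#' @method autoplot vuslr_class_table
#' @export
autoplot.vuslr_class_table <- function(object, ...) {
  d <- dplyr::mutate(object, bioinfo_class = factor(
    .data$bioinfo_class, levels = rev(bioinfo_classes)
  ))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$alpha_hat, y = .data$bioinfo_class)) +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_lower, xmax = .data$ci_upper)) +
    ggplot2::xlim(0, 1) +
    ggplot2::labs(
      x = "estimated proportion of pathogenic variants (alpha)",
      y = NULL, title = "Admixture estimates by bioinformatic class"
    ) +
    ggplot2::theme_minimal()
}
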