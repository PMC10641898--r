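#' Half-width of the normal-approximation binomial confidence interval
#'
#' \eqn{1.96 \sqrt{P (1 - P) / n}}, reported on the percent scale, as used for
#' error bars on proportions of modulated cells and correlated pairs.
#'
#' @param p Proportion in [0, 1].
#' @param n Number of samples (>= 1).
#' @return Half-width in percent.
#' @examples
#' binomial_ci_halfwidth(0.301, 2530) # ~1.8 percent
#' @export
binomial_ci_halfwidth <- function(p, n) {
  stopifnot(p >= 0, p <= 1, n >= 1)
  1.96 * sqrt(p * (1 - p) / n) * 100
}

#' Two-sided Fisher's exact test for a 2 x 2 table
#'
#' Sums hypergeometric probabilities no larger than that of the observed
#' table (the standard two-sided convention).
#'
#' @param tab 2 x 2 matrix of non-negative integer counts.
#' @return Two-sided p value.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2L, 2L)), all(tab >= 0))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("fisher_exact_2x2: zero margin")
  }
  stats::fisher.test(tab)$p.value
}

#' Wilcoxon rank-sum test (two independent groups)
#'
#' @param x,y Numeric samples.
#' @return Two-sided p value.
#' @export
rank_sum_test <- function(x, y) {
  stats::wilcox.test(x, y, exact = FALSE)$p.value
}

#' Wilcoxon signed-rank test of a zero median
#'
#' @param x Numeric sample.
#' @return Two-sided p value.
#' @export
signed_rank_test <- function(x) {
  stats::wilcox.test(x, mu = 0, exact = FALSE)$p.value
}

#' Linear model with interaction, deviance gate and post-hoc sub-models
#'
#' Fits the Gaussian linear model
#' `y ~ 1 + f1 + f2 + f1:f2` by least squares (which coincides with maximum
#' likelihood), compares it against the intercept-only model with a
#' likelihood-ratio (deviance) test, and reports per-coefficient p values.
#' When the interaction coefficient is significant at `alpha`, separate
#' post-hoc models `y ~ 1 + f2` are fitted within each level of `f1`. Because
#' every factor has two levels, no further post-hoc comparisons are needed
#' when the interaction is not significant.
#'
#' @param data Data frame containing the response and the two factors.
#' @param response,f1,f2 Column names: dependent variable, first factor (e.g.
#'   genotype or cell group) and second factor (e.g. behavioral condition).
#' @param alpha Significance threshold (default 0.05).
#' @param posthoc `"gated"` (only when the interaction is significant),
#'   `"always"`, or `"never"`.
#' @return A `ca1net_lm` list: `fit`, `coefficients` (estimate, p),
#'   `p_deviance`, `interaction_p`, `posthoc` (named list of per-level `f2` p
#'   values, or `NULL`).
#' @export
fit_interaction_lm <- function(data, response = "y", f1 = "genotype",
                               f2 = "behavior", alpha = 0.05,
                               posthoc = c("gated", "always", "never")) {
  posthoc <- match.arg(posthoc)
  stopifnot(all(c(response, f1, f2) %in% names(data)))
  d <- data.frame(
    y = data[[response]],
    a = factor(data[[f1]]),
    b = factor(data[[f2]])
  )
  if (nlevels(d$a) != 2L || nlevels(d$b) != 2L) {
    stop("fit_interaction_lm: both factors must have exactly two levels")
  }
  fit <- stats::lm(y ~ a * b, data = d)
  fit0 <- stats::lm(y ~ 1, data = d)
  n <- stats::nobs(fit)
  # ML deviance (likelihood-ratio) test against the intercept-only model
  lr <- n * log(sum(stats::resid(fit0)^2) / sum(stats::resid(fit)^2))
  df_lr <- length(stats::coef(fit)) - 1L
  p_dev <- stats::pchisq(lr, df_lr, lower.tail = FALSE)
  sm <- summary(fit)$coefficients
  coefs <- data.frame(
    term = rownames(sm), estimate = sm[, 1], p = sm[, 4],
    row.names = NULL
  )
  int_p <- sm[nrow(sm), 4]
  ph <- NULL
  if (posthoc == "always" || (posthoc == "gated" && is.finite(int_p) && int_p < alpha)) {
    ph <- lapply(levels(d$a), function(lv) {
      sub <- d[d$a == lv, , drop = FALSE]
      f <- stats::lm(y ~ b, data = sub)
      summary(f)$coefficients[2, 4]
    })
    names(ph) <- levels(d$a)
  }
  out <- list(fit = fit, coefficients = coefs, p_deviance = p_dev,
              interaction_p = int_p, posthoc = ph, alpha = alpha)
  class(out) <- "ca1net_lm"
  out
}

#' @export
print.ca1net_lm <- function(x, ...) {
  cat(sprintf("Linear model with interaction (deviance test p = %.3g)\n",
              x$p_deviance))
  print(x$coefficients, digits = 3)
  if (!is.null(x$posthoc)) {
    cat("Post-hoc per-level models (p for the second factor):\n")
    for (nm in names(x$posthoc)) cat(sprintf("  %s: p = %.3g\n", nm, x$posthoc[[nm]]))
  }
  invisible(x)
}

#' Simple linear regression with a slope t-test
#'
#' @param x,y Numeric vectors (n >= 3).
#' @return List with `slope`, `intercept`, `p` (two-sided t-test on the
#'   slope).
#' @export
simple_regression <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (stats::sd(x) == 0) stop("simple_regression: `x` is constant")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)$coefficients
  list(slope = unname(sm[2, 1]), intercept = unname(sm[1, 1]),
       p = unname(sm[2, 4]))
}

#' Assemble a structured session/group report
#'
#' Collects per-session pipeline results (as returned by [run_pipeline()])
#' into one JSON-serializable report: bout kinematics, event rates by state,
#' modulated fractions with binomial confidence intervals, correlated-pair
#' fractions and mean correlations by scope, and rest-minus-run network
#' closeness differences, together with the sample sizes used. No
#' multiple-testing correction is applied anywhere in the pipeline; the report
#' records this explicitly.
#'
#' @param sessions List of `ca1net_session` results (possibly empty).
#' @return A `ca1net_report` list.
#' @export
build_report <- function(sessions = list()) {
  per_session <- lapply(sessions, function(s) {
    list(
      kinematics = s$kinematics,
      qc = s$qc,
      event_rate = s$event_rates,
      modulated_fraction = s$modulated_fraction,
      n_cells = s$n_cells,
      correlated_fraction = s$correlated_fraction,
      mean_r = s$mean_r,
      centrality = list(
        rest = if (!is.null(s$centrality$rest)) s$centrality$rest$network_mean,
        run = if (!is.null(s$centrality$run)) s$centrality$run$network_mean,
        difference = s$centrality_difference
      )
    )
  })
  n_cells_total <- sum(vapply(sessions, function(s) s$n_cells, numeric(1)))
  n_mod_total <- sum(vapply(sessions, function(s) {
    s$modulated_fraction * s$n_cells
  }, numeric(1)))
  mod_frac <- if (n_cells_total > 0) n_mod_total / n_cells_total else NA_real_
  out <- list(
    n_sessions = length(sessions),
    sessions = per_session,
    pooled = list(
      n_cells = n_cells_total,
      modulated_fraction = mod_frac,
      modulated_ci_halfwidth_pct = if (n_cells_total > 0) {
        binomial_ci_halfwidth(mod_frac, n_cells_total)
      } else NA_real_,
      mean_centrality_difference = if (length(sessions)) {
        mean(vapply(sessions, function(s) s$centrality_difference, numeric(1)),
             na.rm = TRUE)
      } else NA_real_
    ),
    multiple_testing_correction = "none"
  )
  class(out) <- "ca1net_report"
  out
}

#' @export
print.ca1net_report <- function(x, ...) {
  cat(sprintf("CA1 pipeline report: %d session(s)\n", x$n_sessions))
  if (x$n_sessions > 0) {
    cat(sprintf("  pooled cells: %d; modulated: %.1f%% (+/- %.2f%%)\n",
                x$pooled$n_cells, 100 * x$pooled$modulated_fraction,
                x$pooled$modulated_ci_halfwidth_pct))
    cat(sprintf("  mean rest-run closeness difference: %.4f\n",
                x$pooled$mean_centrality_difference))
  }
  invisible(x)
}

#' Write a report as JSON
#'
#' @param report A `ca1net_report`.
#' @param path Output path.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
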