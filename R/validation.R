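# Model validation: leave-one-out cross-validation over the fit set, and
# Pearson correlation between in silico and in vitro conjugation capacity
# with the t-based two-sided p-value.

#' Pearson product-moment correlation
#'
#' @param x,y Numeric vectors of equal length (>= 3) with nonzero variance.
#' @return The correlation coefficient.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance: correlation undefined", call. = FALSE)
  }
  stats::cor(x, y)
}

#' Two-sided p-value of a Pearson correlation
#'
#' Uses the exact t transform `t = r * sqrt(n - 2) / sqrt(1 - r^2)` against
#' the t distribution with `n - 2` degrees of freedom. Defined from `(r, n)`
#' directly so printed coefficients can be checked without raw data.
#'
#' @param r Correlation coefficient.
#' @param n Sample size (>= 3).
#' @return Two-sided p-value. For `|r| = 1` the smallest representable
#'   positive double is returned with a warning.
#' @export
pearson_p <- function(r, n) {
  stopifnot(n >= 3, abs(r) <= 1)
  if (abs(r) == 1) {
    warning("|r| = 1: p-value below machine precision", call. = FALSE)
    return(.Machine$double.xmin)
  }
  t_stat <- r * sqrt(n - 2) / sqrt(1 - r^2)
  2 * stats::pt(-abs(t_stat), df = n - 2)
}

#' Correlation summary with regression line
#'
#' Pearson r, its two-sided p-value, and the ordinary-least-squares line of
#' the observed (in vitro) on the predicted (in silico) capacity, for
#' scatter-plot style reporting.
#'
#' @param predicted,observed Numeric vectors (in silico and in vitro
#'   capacities, same scale).
#' @return List of class `correlation_result`: `r`, `n`, `p`, `slope`,
#'   `intercept`.
#' @export
correlation_result <- function(predicted, observed) {
  r <- pearson_r(predicted, observed)
  n <- length(predicted)
  coefs <- stats::coef(stats::lm(observed ~ predicted))
  structure(list(r = r, n = n, p = pearson_p(r, n),
                 slope = unname(coefs[2]), intercept = unname(coefs[1])),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation> r = %.4f, n = %d, p = %.3g\n", x$r, x$n, x$p))
  invisible(x)
}

#' Leave-one-out cross-validation of the capacity model
#'
#' One fold per member of the fit set M: the constants are re-estimated on
#' M minus that member and the excluded variant's relative capacity is
#' predicted from the refitted model. Members outside M (not-detected
#' capacity, or no correct coenzyme binding) cannot be held out of a fit
#' they are not part of; when `include_excluded = TRUE` (default) they are
#' appended to the correlation with observed ND entered as 0 and predictions
#' from the full-panel fit, flagged in the fold table.
#'
#' @param panel A `capacity_panel`.
#' @param control A [fit_control()]; the same seed is used in every fold, so
#'   identical panel + seed gives identical folds.
#' @param include_excluded Append non-fit-set members to the correlation.
#' @return List of class `loo_result`: `folds` (data frame with `variant`,
#'   `predicted_pct`, `observed_pct`, `in_fit_set`, and the per-fold fitted
#'   constants) and `correlation` (a `correlation_result` over all pairs).
#' @export
loo_cross_validate <- function(panel, control = fit_control(),
                               include_excluded = TRUE) {
  m <- fit_set(panel, include_nd = control$include_nd)
  if (nrow(m) < 4L) {
    stop("fit set too small for leave-one-out cross-validation", call. = FALSE)
  }
  observed_pct <- function(v) {
    if (is.null(panel$wild_capacity) || is.na(panel$wild_capacity)) v
    else 100 * v / panel$wild_capacity
  }

  folds <- vector("list", nrow(m))
  for (i in seq_len(nrow(m))) {
    v_name <- m$variant[i]
    reduced <- drop_member(panel, v_name)
    fit <- tryCatch(fit_parameters(reduced, control), error = function(e) {
      stop(sprintf("fold '%s' not fittable: %s", v_name, conditionMessage(e)),
           call. = FALSE)
    })
    s <- docking_summary(v_name, panel$ligand, m$S_DT[i], m$S_DH[i],
                         m$udpga_correct_count[i])
    pred <- predict_relative(s, m$genotype[i], fit$params,
                             panel$wild_summary, control$kappa_mode)
    folds[[i]] <- data.frame(
      variant = v_name, predicted_pct = as.numeric(pred),
      observed_pct = observed_pct(m$V_c[i]), in_fit_set = TRUE,
      sigma = fit$params$sigma, gamma = fit$params$gamma,
      mu = fit$params$mu, epsilon = fit$params$epsilon
    )
  }
  folds <- do.call(rbind, folds)

  if (include_excluded) {
    rest <- panel$members[!panel$members$variant %in% m$variant, , drop = FALSE]
    if (nrow(rest) > 0L) {
      full_fit <- fit_parameters(panel, control)
      extra <- lapply(seq_len(nrow(rest)), function(j) {
        s <- docking_summary(rest$variant[j], panel$ligand, rest$S_DT[j],
                             rest$S_DH[j], rest$udpga_correct_count[j])
        pred <- predict_relative(s, rest$genotype[j], full_fit$params,
                                 panel$wild_summary, control$kappa_mode)
        obs <- if (rest$nd[j] || is.na(rest$V_c[j])) 0 else
          observed_pct(rest$V_c[j])
        data.frame(variant = rest$variant[j], predicted_pct = as.numeric(pred),
                   observed_pct = obs, in_fit_set = FALSE,
                   sigma = full_fit$params$sigma, gamma = full_fit$params$gamma,
                   mu = full_fit$params$mu, epsilon = full_fit$params$epsilon)
      })
      folds <- rbind(folds, do.call(rbind, extra))
    }
  }
  rownames(folds) <- NULL
  structure(list(
    folds = folds,
    correlation = correlation_result(folds$predicted_pct, folds$observed_pct)
  ), class = "loo_result")
}

#' @export
print.loo_result <- function(x, ...) {
  cat(sprintf("<loo_result> %d folds (%d in fit set)\n",
              nrow(x$folds), sum(x$folds$in_fit_set)))
  print(x$correlation)
  invisible(x)
}

#' Scatter plot of cross-validated predictions
#'
#' In silico (predicted) against in vitro (observed) capacity with the OLS
#' regression line and an r/p annotation. Requires ggplot2.
#'
#' @param loo A `loo_result`.
#' @return A ggplot object.
#' @export
plot_cv <- function(loo) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_cv requires the ggplot2 package", call. = FALSE)
  }
  df <- loo$folds
  corr <- loo$correlation
  label <- sprintf("r = %.3f, p = %.2g, n = %d", corr$r, corr$p, corr$n)
  ggplot2::ggplot(df, ggplot2::aes(x = predicted_pct, y = observed_pct)) +
    ggplot2::geom_abline(slope = corr$slope, intercept = corr$intercept,
                         linetype = "dashed", color = "grey40") +
    ggplot2::geom_point(ggplot2::aes(shape = in_fit_set), size = 2) +
    ggplot2::annotate("text", x = -Inf, y = Inf, hjust = -0.1, vjust = 1.5,
                      label = label) +
    ggplot2::labs(x = "In silico conjugation capacity (% of wild-type)",
                  y = "In vitro conjugation capacity (% of wild-type)",
                  shape = "In fit set") +
    ggplot2::theme_minimal()
}
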