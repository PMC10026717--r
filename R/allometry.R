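#' Fit the length-weight power law
#'
#' Ordinary least squares of log10 wet mass on log10 total length,
#' `log10(W) = b * log10(TL) + log10(a)`, the standard allometric model for
#' fish condition and mass prediction. Only records with a measured
#' (non-imputed) mass enter the fit; imputed masses are excluded to avoid
#' circularity with [impute_missing_mass()].
#'
#' @param data A fish capture tibble; the `"TL_W"` subset is taken
#'   internally via [select_subset()].
#' @param conf_level Confidence level for the parameter intervals
#'   (t-quantile, df = n - 2). Default 0.95.
#' @return An object of class `allometry_fit` with elements `b`, `log10_a`,
#'   `a`, `se_b`, `se_log10_a`, `ci_b`, `ci_log10_a`, `r2_adj`, `sigma`,
#'   `n`, and the underlying `lm` fit.
#' @examples
#' fish <- simulate_population(synthetic_config(n = 200, seed = 3))
#' fit <- fit_length_weight(fish)
#' tidy(fit)
#' @export
fit_length_weight <- function(data, conf_level = 0.95) {
  d <- select_subset(data, "TL_W")
  n <- nrow(d)
  if (n < 3) {
    abort("Need at least 3 records with measured TL and W.",
          class = "sizeage_insufficient_data")
  }
  if (sd(d$TL) == 0) {
    abort("Zero variance in TL: length-weight design is degenerate.",
          class = "sizeage_degenerate_design")
  }
  fit <- lm(log10(W) ~ log10(TL), data = d)
  est <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  crit <- qt(1 - (1 - conf_level) / 2, df = n - 2)
  structure(
    list(
      b = unname(est[2]), log10_a = unname(est[1]), a = 10^unname(est[1]),
      se_b = unname(se[2]), se_log10_a = unname(se[1]),
      ci_b = unname(est[2] + c(-1, 1) * crit * se[2]),
      ci_log10_a = unname(est[1] + c(-1, 1) * crit * se[1]),
      r2_adj = summary(fit)$adj.r.squared,
      sigma = summary(fit)$sigma,
      n = n, conf_level = conf_level, lm = fit
    ),
    class = "allometry_fit"
  )
}

#' Predict wet mass from total length
#'
#' Back-transformed power law `W = 10^(b * log10(TL) + log10(a))`. No
#' lognormal bias correction is applied: the raw inverse is the convention
#' used when the regression serves to impute individual masses for biomass
#' totals.
#'
#' @param fit An [fit_length_weight()] result (or any list with `b` and
#'   `log10_a`).
#' @param TL Total lengths in cm, all > 0.
#' @return Predicted masses in g.
#' @examples
#' predict_mass(list(b = 3.055, log10_a = -2.100), 22.5)
#' @export
predict_mass <- function(fit, TL) {
  if (any(is.na(TL) | TL <= 0)) {
    abort("`TL` must be positive.", class = "sizeage_domain_error")
  }
  10^(fit$b * log10(TL) + fit$log10_a)
}

#' Impute missing masses from the length-weight fit
#'
#' Records lacking a mass get `W = predict_mass(fit, TL)` and are flagged
#' `W_imputed = TRUE`; measured masses are untouched. Flagged records are
#' excluded from any later refit of the allometry (see [select_subset()]).
#'
#' @inheritParams validate_fish_table
#' @param fit An [fit_length_weight()] result.
#' @return The tibble with masses complete.
#' @export
impute_missing_mass <- function(data, fit) {
  missing <- is.na(data$W)
  if (!any(missing)) return(data)
  data$W[missing] <- predict_mass(fit, data$TL[missing])
  data$W_imputed[missing] <- TRUE
  data
}

#' @export
print.allometry_fit <- function(x, ...) {
  cat("Length-weight allometry (log10 OLS), n =", x$n, "\n")
  cat(sprintf("  log10(W) = %.3f * log10(TL) + (%.3f)\n", x$b, x$log10_a))
  cat(sprintf("  a = %.3g g cm^-b, adj. r^2 = %.3f\n", x$a, x$r2_adj))
  invisible(x)
}

#' @rdname fit_length_weight
#' @param x,object An `allometry_fit`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.allometry_fit <- function(x, ...) {
  tibble(
    term = c("log10_a", "b"),
    estimate = c(x$log10_a, x$b),
    std.error = c(x$se_log10_a, x$se_b),
    conf.low = c(x$ci_log10_a[1], x$ci_b[1]),
    conf.high = c(x$ci_log10_a[2], x$ci_b[2])
  )
}

#' @rdname fit_length_weight
#' @exportS3Method generics::glance
glance.allometry_fit <- function(x, ...) {
  tibble(r2_adj = x$r2_adj, sigma = x$sigma, n = x$n)
}

#' @rdname fit_length_weight
#' @exportS3Method ggplot2::autoplot
autoplot.allometry_fit <- function(object, ...) {
  d <- object$lm$model
  names(d) <- c("log10W", "log10TL")
  ggplot2::ggplot(d, ggplot2::aes(.data$log10TL, .data$log10W)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_abline(intercept = object$log10_a, slope = object$b,
                         colour = "grey30") +
    ggplot2::labs(x = "log10 TL (cm)", y = "log10 W (g)",
                  title = sprintf("log10(W) = %.3f log10(TL) %+.3f",
                                  object$b, object$log10_a)) +
    ggplot2::theme_minimal()
}
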