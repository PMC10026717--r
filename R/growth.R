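#' Length-at-age growth curves
#'
#' Mean total length at age under the three classical three-parameter
#' trajectories:
#' * von Bertalanffy: `TL_inf * (1 - exp(-K (t - t0)))`, `t0` the
#'   theoretical age at zero length;
#' * Gompertz: `TL_inf * exp(-exp(-G (t - t0)))`, sigmoid with inflection
#'   at `t0`, where the length equals `TL_inf / e`;
#' * logistic: `TL_inf / (1 + exp(-G' (t - t0)))`, sigmoid with midpoint
#'   `TL_inf / 2` at `t0`.
#'
#' @param family `"von_bertalanffy"`, `"gompertz"` or `"logistic"`.
#' @param params Named vector or list with `TL_inf` (cm), `rate` (per
#'   year: K, G or G'), `t0` (years).
#' @param t Ages in years.
#' @return Mean lengths in cm.
#' @examples
#' predict_length("gompertz", c(TL_inf = 105, rate = 0.216, t0 = 3.99), 3.99)
#' @export
predict_length <- function(family, params, t) {
  family <- arg_match(family, growth_families())
  p <- as.list(params)
  switch(family,
    von_bertalanffy = p$TL_inf * (1 - exp(-p$rate * (t - p$t0))),
    gompertz        = gompertz_length(t, p$TL_inf, p$rate, p$t0),
    logistic        = p$TL_inf / (1 + exp(-p$rate * (t - p$t0)))
  )
}

#' @rdname predict_length
#' @export
growth_families <- function() c("von_bertalanffy", "gompertz", "logistic")

gompertz_length <- function(t, TL_inf, G, t0) TL_inf * exp(-exp(-G * (t - t0)))

# data-driven starting values: asymptote just above the largest fish,
# inflection at the median age, rate from a log-linearisation of the family
growth_start <- function(family, TL, age) {
  TL_inf0 <- 1.1 * max(TL)
  t0_0 <- median(age)
  y <- switch(family,
    von_bertalanffy = log(1 - TL / TL_inf0),
    gompertz        = log(-log(TL / TL_inf0)),
    logistic        = log(TL_inf0 / TL - 1)
  )
  ok <- is.finite(y)
  slope <- if (sum(ok) >= 2) unname(coef(lm(y[ok] ~ age[ok]))[2]) else NA_real_
  rate0 <- if (is.finite(slope) && slope < 0) -slope else 0.3
  c(TL_inf = TL_inf0, rate = rate0, t0 = t0_0)
}

#' Fit a growth trajectory to length-at-age data
#'
#' Nonlinear least squares (Levenberg-Marquardt, via
#' [minpack.lm::nlsLM()]) of total length on age under one of the
#' [predict_length()] families. Standard errors come from the Jacobian at
#' the optimum; the level-`conf_level` parameter intervals are
#' `estimate ± t * s.e.` with df = n - 3 (three mean-function parameters).
#'
#' A warning is raised when the fitted asymptote exceeds
#' `max_plausible_TL_inf`, the default being the species-record scale of
#' very large river salmonids (139 cm); such fits are reported, not
#' suppressed.
#'
#' @param data Fish capture tibble; the `"TL_Age"` subset is used.
#' @param family One of [growth_families()].
#' @param start Optional named starting values `c(TL_inf, rate, t0)`;
#'   data-driven defaults otherwise.
#' @param conf_level Confidence level, default 0.95.
#' @param max_plausible_TL_inf Plausibility bound for the asymptote, cm.
#' @return An object of class `growth_fit`: `family`, `estimates` (named
#'   `TL_inf`, `rate`, `t0`), `se`, `ci` (2 x 3 matrix), `RSS`,
#'   `sigma_hat`, `n`, `logLik`, `AICc`, `converged`.
#' @examples
#' fish <- simulate_population(synthetic_config(n = 200, seed = 3))
#' fit <- fit_growth_model(fish, "gompertz")
#' glance(fit)
#' @export
fit_growth_model <- function(data, family = c("gompertz", "von_bertalanffy", "logistic"),
                             start = NULL, conf_level = 0.95,
                             max_plausible_TL_inf = 140) {
  family <- arg_match(family, growth_families())
  d <- select_subset(data, "TL_Age")
  n <- nrow(d)
  if (n < 5) {
    abort("Need at least 5 records with TL and age.",
          class = "sizeage_insufficient_data")
  }
  if (is.null(start)) start <- growth_start(family, d$TL, d$age)
  fml <- switch(family,
    von_bertalanffy = TL ~ TL_inf * (1 - exp(-rate * (age - t0))),
    gompertz        = TL ~ TL_inf * exp(-exp(-rate * (age - t0))),
    logistic        = TL ~ TL_inf / (1 + exp(-rate * (age - t0)))
  )
  nls_fit <- tryCatch(
    minpack.lm::nlsLM(
      fml, data = d, start = as.list(start),
      lower = c(TL_inf = 1e-8, rate = 1e-8, t0 = -Inf),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-10,
                                           ptol = 1e-10)
    ),
    error = function(e) e
  )
  if (inherits(nls_fit, "error")) {
    return(structure(
      list(family = family, estimates = setNames(rep(NA_real_, 3),
                                                 c("TL_inf", "rate", "t0")),
           se = NULL, ci = NULL, RSS = NA_real_, sigma_hat = NA_real_,
           n = n, logLik = NA_real_, AICc = NA_real_, converged = FALSE,
           message = conditionMessage(nls_fit)),
      class = "growth_fit"
    ))
  }
  est <- coef(nls_fit)
  se <- sqrt(diag(vcov(nls_fit)))
  crit <- qt(1 - (1 - conf_level) / 2, df = n - 3)
  ci <- rbind(lower = est - crit * se, upper = est + crit * se)
  RSS <- sum(resid(nls_fit)^2)
  k <- 4 # three curve parameters + error variance
  LL <- -n / 2 * (log(2 * pi * RSS / n) + 1)
  AICc <- -2 * LL + 2 * k + 2 * k * (k + 1) / (n - k - 1)
  if (est[["TL_inf"]] > max_plausible_TL_inf) {
    warn(sprintf(
      "Fitted TL_inf (%.1f cm) exceeds the plausibility bound of %.0f cm.",
      est[["TL_inf"]], max_plausible_TL_inf), class = "sizeage_implausible_TL_inf")
  }
  structure(
    list(family = family, estimates = est, se = se, ci = ci, RSS = RSS,
         sigma_hat = sqrt(RSS / (n - 3)), n = n, logLik = LL, AICc = AICc,
         converged = TRUE, conf_level = conf_level, data = d),
    class = "growth_fit"
  )
}

#' Compare growth fits by small-sample corrected AIC
#'
#' Ranks fits of the same length-at-age data by
#' `AICc = -2 logLik + 2k + 2k(k+1)/(n-k-1)` with k = 4 (three curve
#' parameters plus the Gaussian error variance), and computes Akaike
#' deltas, weights `w_i = exp(-delta_i/2) / sum_j exp(-delta_j/2)` and
#' cumulative weights.
#'
#' @param fits A list of [fit_growth_model()] results on the same data.
#' @return A tibble of class `growth_model_comparison`, sorted by AICc,
#'   with columns `family`, `k`, `logLik`, `AICc`, `delta_AICc`, `weight`,
#'   `cum_weight`; attribute `"best"` names the lowest-AICc family.
#' @export
compare_models_aicc <- function(fits) {
  stopifnot(length(fits) >= 1, all(vapply(fits, inherits, TRUE, "growth_fit")))
  ns <- vapply(fits, function(f) f$n, numeric(1))
  if (length(unique(ns)) != 1) {
    abort("All fits must be on the same data (mismatched n).",
          class = "sizeage_data_error")
  }
  out <- purrr::map_dfr(fits, function(f) {
    tibble(family = f$family, k = 4L, logLik = f$logLik, AICc = f$AICc,
           converged = f$converged)
  })
  out <- arrange(out, .data$AICc)
  out$delta_AICc <- out$AICc - min(out$AICc, na.rm = TRUE)
  rel <- exp(-out$delta_AICc / 2)
  out$weight <- rel / sum(rel, na.rm = TRUE)
  out$cum_weight <- cumsum(out$weight)
  structure(out, class = c("growth_model_comparison", class(tibble())),
            best = out$family[which.min(out$AICc)])
}

#' Akaike weights from raw AICc values
#'
#' @param aicc Numeric AICc values.
#' @return Weights summing to 1 (invariant to adding a constant).
#' @export
aicc_weights <- function(aicc) {
  rel <- exp(-(aicc - min(aicc)) / 2)
  rel / sum(rel)
}

#' Absolute maximum growth rate of a Gompertz fit
#'
#' The slope of the Gompertz curve at its inflection point `t0`, where
#' growth is fastest: `AMGR = G * TL_inf / e`, in cm per year.
#'
#' @param fit A [fit_growth_model()] result with `family = "gompertz"`.
#' @return AMGR in cm per year.
#' @export
amgr <- function(fit) {
  if (!inherits(fit, "growth_fit") || fit$family != "gompertz") {
    abort("AMGR is defined for Gompertz fits only.", class = "sizeage_domain_error")
  }
  unname(fit$estimates[["rate"]] * fit$estimates[["TL_inf"]] / exp(1))
}

#' Sensitivity of the asymptote to the largest fish
#'
#' Refits the same growth family after removing the `drop_k` longest fish
#' and reports the relative change in the asymptotic length. Gappy or
#' sparse upper age classes can leave the asymptote leaning on a handful
#' of large individuals; the conventional robustness call is a relative
#' change no larger than `threshold` (default 10%).
#'
#' @param data Fish capture tibble (TL_Age subset is used).
#' @param fit The reference [fit_growth_model()] result.
#' @param drop_k Number of longest fish to drop.
#' @param threshold Pass/fail bound on `|delta TL_inf| / TL_inf`.
#' @return A list: `fit` (the refit), `relative_change`, `pass`.
#' @export
sensitivity_refit <- function(data, fit, drop_k = 3L, threshold = 0.10) {
  stopifnot(inherits(fit, "growth_fit"))
  d <- select_subset(data, "TL_Age")
  if (drop_k >= nrow(d)) abort("`drop_k` must be smaller than n.")
  if (drop_k > 0) d <- d[order(-d$TL), ][-seq_len(drop_k), ]
  refit <- fit_growth_model(d, fit$family, start = fit$estimates,
                            conf_level = fit$conf_level)
  rel <- abs(refit$estimates[["TL_inf"]] - fit$estimates[["TL_inf"]]) /
    fit$estimates[["TL_inf"]]
  list(fit = refit, relative_change = unname(rel), pass = unname(rel <= threshold))
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("%s growth fit, n = %d, converged: %s\n", x$family, x$n,
              x$converged))
  if (x$converged) {
    cat(sprintf("  TL_inf = %.1f cm, rate = %.3f /yr, t0 = %.2f yr\n",
                x$estimates[["TL_inf"]], x$estimates[["rate"]],
                x$estimates[["t0"]]))
    cat(sprintf("  RSS = %.1f, AICc = %.1f\n", x$RSS, x$AICc))
  }
  invisible(x)
}

#' @rdname fit_growth_model
#' @param x,object A `growth_fit`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.growth_fit <- function(x, ...) {
  tibble(
    term = names(x$estimates),
    estimate = unname(x$estimates),
    std.error = if (is.null(x$se)) NA_real_ else unname(x$se),
    conf.low = if (is.null(x$ci)) NA_real_ else unname(x$ci["lower", ]),
    conf.high = if (is.null(x$ci)) NA_real_ else unname(x$ci["upper", ])
  )
}

#' @rdname fit_growth_model
#' @exportS3Method generics::glance
glance.growth_fit <- function(x, ...) {
  tibble(family = x$family, n = x$n, RSS = x$RSS, sigma_hat = x$sigma_hat,
         logLik = x$logLik, AICc = x$AICc, converged = x$converged)
}

#' @rdname fit_growth_model
#' @exportS3Method ggplot2::autoplot
autoplot.growth_fit <- function(object, ...) {
  d <- object$data
  grid <- tibble(age = seq(min(d$age), max(d$age), length.out = 200))
  grid$TL <- predict_length(object$family, object$estimates, grid$age)
  ggplot2::ggplot(d, ggplot2::aes(.data$age, .data$TL)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_line(data = grid, colour = "grey30") +
    ggplot2::labs(x = "age (yr)", y = "TL (cm)",
                  title = sprintf("%s growth trajectory", object$family)) +
    ggplot2::theme_minimal()
}
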