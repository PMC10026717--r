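#' Empirical length relations
#'
#' Cross-species log-linear relations predicting a length-based reference
#' point from the asymptotic length:
#' `log10(TL_x) = slope * log10(TL_inf) + intercept`. The bundled
#' constructors carry the published coefficients and residual standard
#' errors for the mean length at first maturity
#' (`log10(TL_m) = 0.8979 log10(TL_inf) - 0.0782`, s.e. 0.127) and the
#' optimum harvest length
#' (`log10(TL_opt) = 1.0421 log10(TL_inf) - 0.2742`, s.e. 0.073).
#'
#' @param slope,intercept Coefficients on the log10 scale.
#' @param se Residual standard error of the source regression (log10
#'   scale), used for prediction intervals.
#' @param df Degrees of freedom for the t-quantile of the prediction
#'   interval; the default `Inf` gives the normal quantile 1.96, the
#'   appropriate choice when the source regression's sample size is
#'   unknown but large.
#' @return A list of class `empirical_relation`.
#' @export
empirical_relation <- function(slope, intercept, se = 0, df = Inf) {
  if (se < 0) abort("`se` must be non-negative.")
  structure(list(slope = slope, intercept = intercept, se = se, df = df),
            class = "empirical_relation")
}

#' @rdname empirical_relation
#' @export
maturity_relation <- function(se = 0.127, df = Inf) {
  empirical_relation(0.8979, -0.0782, se, df)
}

#' @rdname empirical_relation
#' @export
optimum_relation <- function(se = 0.073, df = Inf) {
  empirical_relation(1.0421, -0.2742, se, df)
}

eval_relation <- function(rel, TL_inf) {
  if (any(is.na(TL_inf) | TL_inf <= 0)) {
    abort("`TL_inf` must be positive.", class = "sizeage_domain_error")
  }
  10^(rel$slope * log10(TL_inf) + rel$intercept)
}

#' Mean length at first maturity
#'
#' Back-transformed evaluation of the empirical maturity relation at the
#' asymptotic length.
#'
#' @param TL_inf Asymptotic length(s) in cm, > 0.
#' @return TL_m in cm.
#' @examples
#' length_at_maturity(105.0)
#' @export
length_at_maturity <- function(TL_inf) eval_relation(maturity_relation(), TL_inf)

#' Optimum harvest length
#'
#' Back-transformed evaluation of the empirical optimum-length (maximum
#' yield per recruit) relation at the asymptotic length.
#'
#' @inheritParams length_at_maturity
#' @return TL_opt in cm.
#' @examples
#' optimum_length(105.0)
#' @export
optimum_length <- function(TL_inf) eval_relation(optimum_relation(), TL_inf)

#' Prediction interval of an empirical length relation
#'
#' The level-`level` interval `10^(log10(point) ± c * se)` with `c` the
#' upper quantile of the t-distribution at `rel$df` (normal when `Inf`).
#' The interval is multiplicatively symmetric about the point estimate.
#'
#' @param point The back-transformed point estimate in cm.
#' @param rel The [empirical_relation()] the point was computed from.
#' @param level Interval level, default 0.95.
#' @return Numeric `c(lower, upper)` in cm.
#' @export
prediction_interval <- function(point, rel, level = 0.95) {
  crit <- qt(1 - (1 - level) / 2, df = rel$df)
  10^(log10(point) + c(-1, 1) * crit * rel$se)
}

#' Optimum harvest slot
#'
#' The length window `TL_opt ± 10%` within which the whole catch should
#' fall to avoid recruitment overfishing (harvesting fish before first
#' reproduction), growth overfishing (before the yield optimum) and the
#' removal of megaspawners.
#'
#' @param TL_opt Optimum length in cm, > 0.
#' @return Numeric `c(lower, upper) = (0.9, 1.1) * TL_opt`.
#' @export
optimum_slot <- function(TL_opt) {
  stopifnot_scalar_pos(TL_opt, "TL_opt")
  c(lower = 0.9 * TL_opt, upper = 1.1 * TL_opt)
}

#' Length-based reference points
#'
#' Computes the full set of length-based reference points from an
#' asymptotic length: mean length at first maturity and optimum length
#' (with prediction intervals), the optimum harvest slot, and the
#' megaspawner threshold (the slot's upper bound; larger fish contribute
#' disproportionately to recruitment).
#'
#' @inheritParams length_at_maturity
#' @param maturity,optimum The two [empirical_relation()]s; override to
#'   change s.e. or df.
#' @param level Prediction-interval level.
#' @return A list of class `reference_points`: `TL_inf`, `TL_m`, `pi_m`,
#'   `TL_opt`, `pi_opt`, `slot`, `megaspawner_threshold`.
#' @examples
#' reference_points(105.0)
#' @export
reference_points <- function(TL_inf, maturity = maturity_relation(),
                             optimum = optimum_relation(), level = 0.95) {
  TL_m <- eval_relation(maturity, TL_inf)
  TL_opt <- eval_relation(optimum, TL_inf)
  slot <- optimum_slot(TL_opt)
  structure(
    list(TL_inf = TL_inf,
         TL_m = TL_m, pi_m = prediction_interval(TL_m, maturity, level),
         TL_opt = TL_opt, pi_opt = prediction_interval(TL_opt, optimum, level),
         slot = slot, megaspawner_threshold = unname(slot["upper"]),
         level = level),
    class = "reference_points"
  )
}

#' @export
print.reference_points <- function(x, ...) {
  cat(sprintf("Reference points from TL_inf = %.1f cm\n", x$TL_inf))
  cat(sprintf("  TL_m   = %.3f cm (PI %.1f, %.1f)\n", x$TL_m, x$pi_m[1], x$pi_m[2]))
  cat(sprintf("  TL_opt = %.3f cm (PI %.1f, %.1f)\n", x$TL_opt, x$pi_opt[1], x$pi_opt[2]))
  cat(sprintf("  slot   = %.1f-%.1f cm, megaspawners > %.1f cm\n",
              x$slot[1], x$slot[2], x$megaspawner_threshold))
  invisible(x)
}

#' @rdname reference_points
#' @param x A `reference_points` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.reference_points <- function(x, ...) {
  tibble(
    term = c("TL_m", "TL_opt", "slot_lower", "slot_upper",
             "megaspawner_threshold"),
    estimate = c(x$TL_m, x$TL_opt, unname(x$slot), x$megaspawner_threshold),
    conf.low = c(x$pi_m[1], x$pi_opt[1], NA, NA, NA),
    conf.high = c(x$pi_m[2], x$pi_opt[2], NA, NA, NA)
  )
}
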