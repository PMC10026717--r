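#' Harvest policies
#'
#' Constructors for the two regulation types evaluated against a catch:
#' a minimum-length limit (`mll_policy`; a fish may be retained when
#' `TL >= mll`) and a harvest-slot length limit (`slot_policy`; retention
#' only within `[lower, upper]`, bounds inclusive).
#'
#' @param mll Minimum length limit in cm, > 0.
#' @param lower,upper Slot bounds in cm, `0 < lower < upper`.
#' @param label Optional label used in summaries.
#' @return A list of class `harvest_policy`.
#' @examples
#' mll_policy(40)
#' slot_policy(60, 70)
#' @export
mll_policy <- function(mll, label = sprintf("MLL %g cm", mll)) {
  stopifnot_scalar_pos(mll, "mll", strict = FALSE)
  structure(list(kind = "minimum_length", mll = mll, label = label),
            class = "harvest_policy")
}

#' @rdname mll_policy
#' @export
slot_policy <- function(lower, upper, label = sprintf("HS %g-%g cm", lower, upper)) {
  stopifnot_scalar_pos(lower, "lower")
  if (upper <= lower) abort("`upper` must exceed `lower`.")
  structure(list(kind = "slot", lower = lower, upper = upper, label = label),
            class = "harvest_policy")
}

is_retainable <- function(TL, policy) {
  switch(policy$kind,
    minimum_length = TL >= policy$mll,
    slot           = TL >= policy$lower & TL <= policy$upper
  )
}

#' Classify a catch under a harvest policy
#'
#' Labels every fish as retainable or not under the policy and, for
#' retainable fish, sub-labels it against the reference points:
#' `immature` (below the length at first maturity — retaining it is a
#' recruitment-overfishing risk), `within_slot` (inside the optimum
#' slot), or `mature_outside_slot`. The `megaspawner` flag (above the
#' megaspawner threshold) overlaps `mature_outside_slot` and is reported
#' separately.
#'
#' @param lengths Total lengths of the catch in cm (non-empty).
#' @param policy A [mll_policy()] or [slot_policy()].
#' @param rp A [reference_points()] object.
#' @return A tibble with columns `TL`, `retained`, `category` (factor,
#'   `NA` for non-retained fish) and logical `megaspawner`.
#' @examples
#' rp <- reference_points(105.0)
#' classify_catch(c(30, 45, 68, 85), mll_policy(40), rp)
#' @export
classify_catch <- function(lengths, policy, rp) {
  if (length(lengths) == 0) abort("Empty catch.", class = "sizeage_data_error")
  stopifnot(inherits(policy, "harvest_policy"), inherits(rp, "reference_points"))
  retained <- is_retainable(lengths, policy)
  category <- dplyr::case_when(
    !retained ~ NA_character_,
    lengths < rp$TL_m ~ "immature",
    lengths >= rp$slot["lower"] & lengths <= rp$slot["upper"] ~ "within_slot",
    TRUE ~ "mature_outside_slot"
  )
  tibble(
    TL = lengths, retained = retained,
    category = factor(category,
                      levels = c("immature", "within_slot", "mature_outside_slot")),
    megaspawner = retained & lengths > rp$megaspawner_threshold
  )
}

#' Summarise a classified catch
#'
#' Aggregates a [classify_catch()] result into counts and fractions. The
#' three categories partition the retained catch; fractions of retained
#' use the retained count as denominator and are defined as 0 (with the
#' `empty_retained` flag) when nothing is retainable.
#'
#' @param classified A [classify_catch()] tibble.
#' @param label Optional policy label carried into the row.
#' @return A one-row tibble of class `harvest_summary`: `label`,
#'   `n_catch`, `n_retained`, `frac_retained`, `n_immature`,
#'   `frac_immature`, `n_within_slot`, `frac_within_slot`,
#'   `n_mature_outside_slot`, `frac_mature_outside_slot`,
#'   `n_megaspawner`, `frac_megaspawner`, `empty_retained`.
#' @export
summarize_catch <- function(classified, label = NA_character_) {
  n_catch <- nrow(classified)
  n_ret <- sum(classified$retained)
  frac_of_ret <- function(k) if (n_ret == 0) 0 else k / n_ret
  n_imm <- sum(classified$category %in% "immature")
  n_slot <- sum(classified$category %in% "within_slot")
  n_mat <- sum(classified$category %in% "mature_outside_slot")
  n_mega <- sum(classified$megaspawner)
  out <- tibble(
    label = label, n_catch = n_catch, n_retained = n_ret,
    frac_retained = n_ret / n_catch,
    n_immature = n_imm, frac_immature = frac_of_ret(n_imm),
    n_within_slot = n_slot, frac_within_slot = frac_of_ret(n_slot),
    n_mature_outside_slot = n_mat,
    frac_mature_outside_slot = frac_of_ret(n_mat),
    n_megaspawner = n_mega, frac_megaspawner = frac_of_ret(n_mega),
    empty_retained = n_ret == 0
  )
  class(out) <- c("harvest_summary", class(out))
  out
}

#' Compare harvest policies on the same catch
#'
#' One [summarize_catch()] row per policy, plus `retained_ratio`, the
#' retained-catch contraction of each policy relative to the first — the
#' quantity of interest when a minimum-length limit is replaced by a
#' harvest slot.
#'
#' @param lengths Total lengths of the catch in cm.
#' @param policies A list of [mll_policy()] / [slot_policy()] objects.
#' @param rp A [reference_points()] object.
#' @return A tibble with one row per policy.
#' @examples
#' rp <- reference_points(105.0)
#' compare_policies(c(30, 45, 68, 85),
#'                  list(mll_policy(40), slot_policy(61.1, 74.7)), rp)
#' @export
compare_policies <- function(lengths, policies, rp) {
  if (length(policies) < 1) abort("Need at least one policy.")
  out <- purrr::map_dfr(policies, function(p) {
    summarize_catch(classify_catch(lengths, p, rp), label = p$label)
  })
  ref <- out$n_retained[1]
  out$retained_ratio <- if (ref == 0) NA_real_ else out$n_retained / ref
  out
}

#' Length-frequency table
#'
#' Counts per 1-cm (or `binwidth`-cm) length class with left-closed bins
#' `[k, k + binwidth)`, the convention of length-frequency harvest plots.
#'
#' @param lengths Total lengths in cm.
#' @param binwidth Bin width in cm, default 1.
#' @return A tibble `bin_lower`, `n` covering the observed range.
#' @export
length_frequency <- function(lengths, binwidth = 1) {
  lo <- floor(min(lengths) / binwidth) * binwidth
  hi <- floor(max(lengths) / binwidth) * binwidth
  bins <- seq(lo, hi, by = binwidth)
  cls <- floor(lengths / binwidth) * binwidth
  tibble(bin_lower = bins,
         n = vapply(bins, function(b) sum(cls == b), integer(1)))
}

#' Length-frequency plot with policy and reference-point overlays
#'
#' @param lengths Total lengths in cm.
#' @param rp Optional [reference_points()] to draw TL_m and the slot.
#' @param policy Optional [mll_policy()] to draw the MLL.
#' @param binwidth Bin width in cm.
#' @return A ggplot.
#' @export
plot_length_frequency <- function(lengths, rp = NULL, policy = NULL,
                                  binwidth = 1) {
  lf <- length_frequency(lengths, binwidth)
  p <- ggplot2::ggplot(lf, ggplot2::aes(.data$bin_lower, .data$n)) +
    ggplot2::geom_col(width = binwidth, fill = "grey55", just = 0) +
    ggplot2::labs(x = "TL (cm)", y = "catch (n)") +
    ggplot2::theme_minimal()
  if (!is.null(rp)) {
    p <- p +
      ggplot2::geom_vline(xintercept = rp$TL_m, linetype = "dashed") +
      ggplot2::annotate("rect", xmin = rp$slot[1], xmax = rp$slot[2],
                        ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "steelblue")
  }
  if (!is.null(policy) && policy$kind == "minimum_length") {
    p <- p + ggplot2::geom_vline(xintercept = policy$mll, colour = "firebrick")
  }
  p
}
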