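#' Sampled water volume of an electrofishing transect
#'
#' The effective field of a backpack/banked electrofishing sweep covers
#' about 2 m^3 per surveyed metre, so the sampled volume of a transect of
#' length `L` metres is `2 * L` m^3.
#'
#' @param L Transect lengths in metres, >= 0.
#' @return Volumes in m^3.
#' @export
sampling_volume <- function(L) {
  if (any(is.na(L) | L < 0)) {
    abort("`L` must be non-negative.", class = "sizeage_domain_error")
  }
  2 * L
}

#' Numerical and biomass density per transect
#'
#' Joins the density subset of a capture table (electrofishing records
#' with a transect id; see [select_subset()]) to a transect register and
#' computes, per transect, the catch per sampled volume and the biomass
#' per sampled volume. Masses must be complete — run
#' [impute_missing_mass()] first; the number of imputed masses entering
#' each biomass total is reported.
#'
#' @param data Fish capture tibble with complete masses on the DENS subset.
#' @param transects Tibble with columns `transect_id`, `tract`, `year`,
#'   `length_m` (> 0).
#' @return A tibble, one row per transect: `transect_id`, `tract`, `year`,
#'   `length_m`, `volume_m3`, `n_fish`, `n_imputed`, `biomass_g`,
#'   `numerical_density` (ind m^-3), `biomass_density` (g m^-3).
#'   Transects with no fish get zero densities.
#' @export
density_per_transect <- function(data, transects) {
  stopifnot(all(c("transect_id", "length_m") %in% names(transects)))
  if (any(is.na(transects$length_m) | transects$length_m <= 0)) {
    abort("All transects need a positive length (zero sampled volume).",
          class = "sizeage_domain_error")
  }
  d <- select_subset(data, "DENS")
  d <- filter(d, .data$transect_id %in% transects$transect_id)
  if (any(is.na(d$W))) {
    abort("Missing masses on the density subset; impute them first.",
          class = "sizeage_data_error")
  }
  per_fish <- d %>%
    group_by(.data$transect_id) %>%
    summarise(n_fish = dplyr::n(), biomass_g = sum(.data$W),
              n_imputed = sum(.data$W_imputed), .groups = "drop")
  transects %>%
    left_join(per_fish, by = "transect_id") %>%
    mutate(
      n_fish = dplyr::coalesce(.data$n_fish, 0L),
      biomass_g = dplyr::coalesce(.data$biomass_g, 0),
      n_imputed = dplyr::coalesce(.data$n_imputed, 0L),
      volume_m3 = sampling_volume(.data$length_m),
      numerical_density = .data$n_fish / .data$volume_m3,
      biomass_density = .data$biomass_g / .data$volume_m3
    ) %>%
    select("transect_id", "tract", "year", "length_m", "volume_m3",
           "n_fish", "n_imputed", "biomass_g",
           "numerical_density", "biomass_density")
}

#' Rank-based comparison of a variable across groups
#'
#' Kruskal-Wallis omnibus test across groups, followed by pairwise
#' Wilcoxon rank-sum tests with Bonferroni correction (each p multiplied
#' by the number of pairs, capped at 1). Midranks handle ties; the exact
#' null distribution is used when every group has fewer than 20
#' observations and there are no ties, the normal approximation
#' otherwise. Applies to lengths, ages, or densities grouped by river
#' tract (or any grouping).
#'
#' @param data A data frame.
#' @param value Column with the variable to compare (tidy-eval).
#' @param group Column with the grouping factor (tidy-eval).
#' @return A list of class `group_comparison`: `omnibus` (one-row tibble
#'   with `statistic`, `df`, `p.value`), `pairwise` (tibble `group1`,
#'   `group2`, `p.value` Bonferroni-adjusted), `n_groups`.
#' @examples
#' fish <- simulate_population(synthetic_config(n = 200, seed = 5))
#' compare_groups(fish, TL, tract)
#' @export
compare_groups <- function(data, value, group) {
  v <- dplyr::pull(data, {{ value }})
  g <- factor(dplyr::pull(data, {{ group }}))
  keep <- !is.na(v) & !is.na(g)
  v <- v[keep]; g <- droplevels(g[keep])
  sizes <- table(g)
  if (length(sizes) < 2 || any(sizes < 1)) {
    abort("Need at least 2 non-empty groups.", class = "sizeage_data_error")
  }
  kw <- kruskal.test(v, g)
  exact <- max(sizes) < 20 && !any(duplicated(v))
  pw <- suppressWarnings(
    pairwise.wilcox.test(v, g, p.adjust.method = "bonferroni", exact = exact)
  )
  pm <- as.data.frame(as.table(pw$p.value))
  names(pm) <- c("group1", "group2", "p.value")
  pm <- filter(pm, !is.na(.data$p.value))
  structure(
    list(
      omnibus = tibble(statistic = unname(kw$statistic),
                       df = unname(kw$parameter), p.value = kw$p.value),
      pairwise = as_tibble(pm), n_groups = length(sizes)
    ),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis chi^2 = %.3f, df = %d, p = %.3g (%d groups)\n",
              x$omnibus$statistic, x$omnibus$df, x$omnibus$p.value, x$n_groups))
  cat("Pairwise Wilcoxon (Bonferroni):\n")
  print(as.data.frame(x$pairwise), row.names = FALSE)
  invisible(x)
}
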