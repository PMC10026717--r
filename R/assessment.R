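#' Run the full size-age assessment
#'
#' One call executing the whole chain on a capture table (or a freshly
#' simulated population): recapture deduplication, length-weight
#' allometry and mass imputation, the three growth fits with AICc
#' selection and the leave-out-largest sensitivity refit, the
#' Chapman-Robson mortality chain, length-based reference points from the
#' selected asymptote, harvest-policy evaluation on the angling
#' length-frequency, and (when a transect register is supplied) per-
#' transect densities with between-tract comparisons.
#'
#' @param data A fish capture tibble ([read_fish_table()] /
#'   [simulate_population()] shape). Exactly one of `data` and `config`.
#' @param config A [synthetic_config()]; the population (and transect
#'   register, unless given) is simulated from it.
#' @param transects Optional transect register for the density stage.
#' @param t_max Maximum recorded age for natural mortality (years).
#' @param policies Harvest policies to evaluate; defaults to the historic
#'   and current minimum-length limits (35, 40 cm) and a 60-70 cm slot.
#' @param limb_mode,max_class Passed to [select_descending_limb()].
#' @param drop_k Largest fish removed in the sensitivity refit.
#' @param family Force a growth family instead of AICc selection.
#' @return A list of class `assessment_report` with elements `allometry`,
#'   `growth_fits`, `model_comparison`, `growth` (selected fit),
#'   `sensitivity`, `mortality`, `reference_points`, `harvest`, `density`,
#'   `group_tests`, `warnings`, `provenance`.
#' @examples
#' rep <- run_full_assessment(config = synthetic_config(n = 300, seed = 9))
#' rep$reference_points
#' @export
run_full_assessment <- function(data = NULL, config = NULL, transects = NULL,
                                t_max = 11,
                                policies = list(mll_policy(35), mll_policy(40),
                                                slot_policy(60, 70)),
                                limb_mode = c("exclude_peak", "include_peak"),
                                max_class = NULL, drop_k = 3L, family = NULL) {
  if (is.null(data) == is.null(config)) {
    abort("Supply exactly one of `data` or `config`.",
          class = "sizeage_config_error")
  }
  if (!is.null(config)) {
    data <- simulate_population(config)
    if (is.null(transects)) transects <- simulate_transects(config)
  }
  notes <- character(0)
  note_handler <- function(w) {
    notes <<- c(notes, conditionMessage(w))
    invokeRestart("muffleWarning")
  }

  data <- deduplicate_recaptures(validate_fish_table(data))
  allo <- fit_length_weight(data)
  data <- impute_missing_mass(data, allo)

  fits <- withCallingHandlers(
    purrr::map(set_names(growth_families()),
               ~ fit_growth_model(data, .x)),
    warning = note_handler
  )
  cmp <- compare_models_aicc(unname(fits))
  selected <- family %||% attr(cmp, "best")
  growth <- fits[[selected]]
  sens <- withCallingHandlers(sensitivity_refit(data, growth, drop_k = drop_k),
                              warning = note_handler)

  mort <- withCallingHandlers(
    estimate_mortality(data, t_max = t_max, mode = limb_mode,
                       max_class = max_class),
    warning = note_handler
  )
  rp <- reference_points(growth$estimates[["TL_inf"]])

  angling <- filter(data, .data$gear %in% "angling")
  catch_lengths <- if (nrow(angling) > 0) angling$TL else data$TL
  harvest <- compare_policies(catch_lengths, policies, rp)

  dens <- group_tests <- NULL
  if (!is.null(transects)) {
    dens <- density_per_transect(data, transects)
    if (length(unique(dens$tract)) >= 2) {
      group_tests <- list(
        numerical = compare_groups(dens, .data$numerical_density, .data$tract),
        biomass = compare_groups(dens, .data$biomass_density, .data$tract)
      )
    }
  }

  structure(
    list(allometry = allo, growth_fits = fits, model_comparison = cmp,
         growth = growth, sensitivity = sens, mortality = mort,
         reference_points = rp, harvest = harvest, density = dens,
         group_tests = group_tests, warnings = notes,
         provenance = list(
           n_records = nrow(data),
           input_hash = rlang::hash(data),
           seed = if (!is.null(config)) config$seed else NA_integer_,
           package_version = as.character(utils::packageVersion("sizeage"))
         )),
    class = "assessment_report"
  )
}

# flat, serialisable view of a report (full precision)
report_values <- function(report) {
  g <- report$growth
  m <- report$mortality
  rp <- report$reference_points
  list(
    allometry = list(b = report$allometry$b, log10_a = report$allometry$log10_a,
                     r2_adj = report$allometry$r2_adj, n = report$allometry$n),
    growth = list(family = g$family, TL_inf = unname(g$estimates[["TL_inf"]]),
                  rate = unname(g$estimates[["rate"]]),
                  t0 = unname(g$estimates[["t0"]]), n = g$n, AICc = g$AICc,
                  AMGR = if (g$family == "gompertz") amgr(g) else NULL),
    sensitivity = list(TL_inf = unname(report$sensitivity$fit$estimates[["TL_inf"]]),
                       relative_change = report$sensitivity$relative_change,
                       pass = report$sensitivity$pass),
    mortality = list(S = m$S_hat, Z = m$Z, ci_Z = unname(m$ci_Z), A_Z = m$A_Z,
                     M = m$M, A_M = m$A_M, F = m$F_, A_F = m$A_F, E = m$E,
                     t_max = m$t_max),
    reference_points = list(TL_m = rp$TL_m, pi_m = unname(rp$pi_m),
                            TL_opt = rp$TL_opt, pi_opt = unname(rp$pi_opt),
                            slot = unname(rp$slot),
                            megaspawner_threshold = rp$megaspawner_threshold),
    harvest = lapply(seq_len(nrow(report$harvest)), function(i)
      as.list(report$harvest[i, ])),
    warnings = report$warnings,
    provenance = report$provenance
  )
}

#' Render an assessment report
#'
#' Deterministic serialisation of an [run_full_assessment()] result.
#' Human formats (`"text"`, `"delimited"`) round to 3 decimals (half-up);
#' the machine format (`"json"`) keeps full precision and parses back to
#' the same values. Two renders of one report are byte-identical.
#'
#' @param report An `assessment_report`.
#' @param format `"text"`, `"json"` or `"delimited"`.
#' @return A single string (invisibly printable document).
#' @export
render_report <- function(report, format = c("text", "json", "delimited")) {
  format <- arg_match(format)
  vals <- report_values(report)
  if (format == "json") {
    return(as.character(jsonlite::toJSON(vals, auto_unbox = TRUE, digits = NA,
                                         null = "null", pretty = TRUE)))
  }
  r3 <- function(x) format(round_half_up(x, 3), nsmall = 3, trim = TRUE)
  if (format == "delimited") {
    flat <- unlist(vals[c("allometry", "growth", "sensitivity", "mortality",
                          "reference_points")])
    num <- suppressWarnings(as.numeric(flat))
    val <- ifelse(is.na(num), as.character(flat), r3(num))
    return(paste(paste(names(flat), val, sep = "\t"), collapse = "\n"))
  }
  m <- vals$mortality
  rp <- vals$reference_points
  lines <- c(
    "Size-age population assessment",
    sprintf("records: %d", vals$provenance$n_records),
    "",
    sprintf("Length-weight: log10(W) = %s log10(TL) %s (adj r2 %s, n %d)",
            r3(vals$allometry$b), r3(vals$allometry$log10_a),
            r3(vals$allometry$r2_adj), vals$allometry$n),
    sprintf("Growth [%s]: TL_inf %s cm, rate %s /yr, t0 %s yr (n %d)",
            vals$growth$family, r3(vals$growth$TL_inf), r3(vals$growth$rate),
            r3(vals$growth$t0), vals$growth$n),
    sprintf("Sensitivity (-%d largest): TL_inf %s cm, change %s%%, %s",
            3L, r3(vals$sensitivity$TL_inf),
            r3(100 * vals$sensitivity$relative_change),
            if (vals$sensitivity$pass) "pass" else "FAIL"),
    sprintf("Mortality: S %s  Z %s (CI %s, %s)  A_Z %s", r3(m$S), r3(m$Z),
            r3(m$ci_Z[1]), r3(m$ci_Z[2]), r3(m$A_Z)),
    sprintf("           M %s  A_M %s  F %s  A_F %s  E %s", r3(m$M), r3(m$A_M),
            r3(m$F), r3(m$A_F), r3(m$E)),
    sprintf("Reference:  TL_m %s cm (PI %s, %s)", r3(rp$TL_m), r3(rp$pi_m[1]),
            r3(rp$pi_m[2])),
    sprintf("            TL_opt %s cm (PI %s, %s), slot %s-%s cm",
            r3(rp$TL_opt), r3(rp$pi_opt[1]), r3(rp$pi_opt[2]),
            r3(rp$slot[1]), r3(rp$slot[2])),
    "Harvest policies:",
    vapply(vals$harvest, function(h)
      sprintf("  %s: retained %d/%d (%s), immature %s of retained",
              h$label, h$n_retained, h$n_catch, r3(h$frac_retained),
              r3(h$frac_immature)), character(1))
  )
  if (length(vals$warnings) > 0) {
    lines <- c(lines, "Warnings:", paste0("  ", vals$warnings))
  }
  paste(lines, collapse = "\n")
}

#' @export
print.assessment_report <- function(x, ...) {
  cat(render_report(x, "text"), "\n")
  invisible(x)
}
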