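#' Read a fish capture table
#'
#' Reads a delimited text file (or literal text) of individual fish capture
#' records into a tibble, one row per capture. The only mandatory column is
#' the total length; all other columns are optional and missing cells become
#' `NA`. Unknown columns are carried through untouched.
#'
#' Recognised columns (either bare or unit-suffixed names):
#' `id`, `year`, `tract`, `gear`, `TL` / `TL_cm` (total length, cm),
#' `W` / `W_g` (wet mass, g), `age` / `age_yr` (fractional age, years),
#' `transect_id`, `recapture_of` (id of the earlier capture of the same
#' individual) and `W_imputed` (logical; whether `W` was filled in by the
#' length-weight model rather than weighed).
#'
#' @param file Path to a delimited file, or a literal string containing the
#'   table (anything `readr::read_delim()` accepts).
#' @param delim Field delimiter, default comma.
#' @return A tibble with columns `id`, `year`, `tract`, `gear`, `TL`, `W`,
#'   `age`, `transect_id`, `recapture_of`, `W_imputed` (plus any extra input
#'   columns). Row order of the input is preserved.
#' @examples
#' fish <- read_fish_table(I("id,TL_cm,W_g,age_yr\nf1,22.5,105,2.3\nf2,31.0,,3.1\n"))
#' fish$W  # second record has no mass
#' @export
read_fish_table <- function(file, delim = ",") {
  raw <- readr::read_delim(file, delim = delim, col_types = readr::cols(.default = "c"),
                           na = c("", "NA", "na"), trim_ws = TRUE,
                           show_col_types = FALSE, progress = FALSE)
  names(raw) <- sub("^TL_cm$", "TL", names(raw))
  names(raw) <- sub("^W_g$", "W", names(raw))
  names(raw) <- sub("^age_yr$", "age", names(raw))
  if (!"TL" %in% names(raw)) {
    abort("Input is missing the mandatory total-length column (`TL` or `TL_cm`).",
          class = "sizeage_format_error")
  }

  parse_num <- function(col) {
    x <- raw[[col]]
    if (is.null(x)) return(NULL)
    val <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(val))
    if (length(bad) > 0) {
      abort(sprintf("Non-numeric `%s` values in rows: %s.", col,
                    paste(bad, collapse = ", ")),
            class = "sizeage_row_error")
    }
    val
  }

  out <- raw
  for (col in intersect(c("TL", "W", "age"), names(out))) out[[col]] <- parse_num(col)
  if ("year" %in% names(out)) out$year <- suppressWarnings(as.integer(out$year))
  if (!"id" %in% names(out)) out$id <- sprintf("row%04d", seq_len(nrow(out)))
  if ("W_imputed" %in% names(out)) {
    out$W_imputed <- tolower(as.character(out$W_imputed)) %in% c("true", "t", "1", "yes")
  } else {
    out$W_imputed <- FALSE
  }
  for (col in c("year", "tract", "gear", "W", "age", "transect_id", "recapture_of")) {
    if (!col %in% names(out)) out[[col]] <- NA
  }
  out <- select(out, "id", "year", "tract", "gear", "TL", "W", "age",
                "transect_id", "recapture_of", "W_imputed",
                dplyr::everything())
  validate_fish_table(out)
}

#' Validate fish record invariants
#'
#' Checks `TL > 0`, `W` absent or positive, `age` absent or in (0, 12],
#' and that `W_imputed` only flags records that carry a mass.
#'
#' @param data A fish capture tibble (see [read_fish_table()]).
#' @return `data`, invisibly usable in a pipe (returned visibly).
#' @export
validate_fish_table <- function(data) {
  if (any(is.na(data$TL) | data$TL <= 0)) {
    abort("All records must have a positive total length `TL`.",
          class = "sizeage_data_error")
  }
  if (any(!is.na(data$W) & data$W <= 0)) {
    abort("`W` must be positive where present.", class = "sizeage_data_error")
  }
  if (any(!is.na(data$age) & (data$age <= 0 | data$age > 12))) {
    abort("`age` must lie in (0, 12] years where present.",
          class = "sizeage_data_error")
  }
  if (any(data$W_imputed & is.na(data$W))) {
    abort("`W_imputed` set on records with no mass.", class = "sizeage_data_error")
  }
  data
}

#' Write a fish capture table
#'
#' Inverse of [read_fish_table()]: writes the record tibble as delimited
#' text, including the `W_imputed` flag column.
#'
#' @inheritParams validate_fish_table
#' @param file Output path.
#' @param delim Field delimiter, default comma.
#' @return `file`, invisibly.
#' @export
write_fish_table <- function(data, file, delim = ",") {
  readr::write_delim(data, file, delim = delim, na = "")
  invisible(file)
}

#' Assign integer age classes
#'
#' Age classes are one-year intervals that exclude their lower limit:
#' class k covers ages in (k, k + 1]. A fish aged exactly 1.0 year is still
#' in class 0; a fish aged 2.3 years is in class 2.
#'
#' @param age Fractional ages in years, all > 0.
#' @return Integer vector of class indices, `ceiling(age) - 1`.
#' @examples
#' assign_age_class(c(0.3, 1.0, 2.3))  # 0 0 2
#' @export
assign_age_class <- function(age) {
  if (any(is.na(age) | age <= 0)) {
    abort("`age` must be positive.", class = "sizeage_domain_error")
  }
  as.integer(ceiling(age) - 1)
}

#' Collapse recaptured individuals to a single record
#'
#' Individually tagged fish caught more than once appear as several rows
#' linked by `recapture_of`, each later capture pointing at an earlier one.
#' Only the earliest capture of each chain is retained, so no individual is
#' counted twice in any analysis. The earliest record is kept because it is
#' the least growth-confounded measurement.
#'
#' @inheritParams validate_fish_table
#' @return The tibble with all later captures removed; ids are unique.
#' @export
deduplicate_recaptures <- function(data) {
  links <- data$recapture_of
  if (all(is.na(links))) return(data)
  ids <- data$id
  dangling <- setdiff(links[!is.na(links)], ids)
  if (length(dangling) > 0) {
    abort(sprintf("`recapture_of` refers to unknown ids: %s.",
                  paste(unique(dangling), collapse = ", ")),
          class = "sizeage_data_error")
  }
  parent <- setNames(links, ids)
  # follow every chain to its root; a chain longer than the table is a cycle
  root_of <- function(id) {
    seen <- character(0)
    while (!is.na(parent[[id]])) {
      if (id %in% seen) {
        abort("Circular `recapture_of` links detected.",
              class = "sizeage_data_error")
      }
      seen <- c(seen, id)
      id <- parent[[id]]
    }
    id
  }
  roots <- vapply(ids, root_of, character(1))
  out <- data[is.na(links), , drop = FALSE]
  if (anyDuplicated(out$id) > 0) {
    abort("Duplicate ids remain after deduplication.", class = "sizeage_data_error")
  }
  out
}

#' Select the analysis subset of a capture table
#'
#' The three analysis subsets mirror standard practice for this kind of
#' survey: `"TL_W"` (length-weight regression) keeps records with a length
#' and a *measured* (non-imputed) mass; `"TL_Age"` (growth, age structure,
#' mortality) keeps records with a length and a determined age; `"DENS"`
#' (density) keeps electrofishing records assigned to a transect, since
#' only those have a known sampled water volume.
#'
#' @inheritParams validate_fish_table
#' @param purpose One of `"TL_W"`, `"DENS"`, `"TL_Age"`.
#' @return The filtered tibble (possibly empty).
#' @export
select_subset <- function(data, purpose = c("TL_W", "DENS", "TL_Age")) {
  purpose <- arg_match(purpose)
  switch(purpose,
    TL_W   = filter(data, !is.na(.data$TL), !is.na(.data$W), !.data$W_imputed),
    TL_Age = filter(data, !is.na(.data$TL), !is.na(.data$age)),
    DENS   = filter(data, .data$gear %in% "electrofishing", !is.na(.data$transect_id))
  )
}
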