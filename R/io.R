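#' Read per-sample total element concentrations
#'
#' Reads a long-format CSV of total (aqua regia digest) concentrations, one
#' row per sample and element, and validates it: concentrations must be
#' non-negative, element symbols must belong to `element_set` (matched
#' case-insensitively), and each (sample_id, element) pair must be unique.
#'
#' @param path Path to a CSV file with columns `sample_id`, `river`, `site`,
#'   `element`, `concentration` (mg/kg dry weight).
#' @param element_set Allowed element symbols; defaults to [pte_elements()].
#' @return A tibble with one validated row per sample-element measurement.
#' @export
read_totals <- function(path, element_set = pte_elements()) {
  df <- read_csv_strict(path)
  validate_totals(df, element_set, what = basename(path))
}

#' @rdname read_totals
#' @param totals A data frame to validate in place of a file.
#' @param what Label used in error messages.
#' @export
validate_totals <- function(totals, element_set = pte_elements(),
                            what = "totals table") {
  require_columns(totals, c("sample_id", "river", "site", "element", "concentration"), what)
  totals <- as_tibble(totals)
  totals$sample_id <- as.character(totals$sample_id)
  totals$concentration <- as.double(totals$concentration)
  totals$element <- canonical_element(as.character(totals$element), element_set)
  check_nonnegative(totals, what)
  dup <- duplicated(totals[c("sample_id", "element")])
  if (any(dup)) {
    d <- totals[dup, ]
    stop_validation(
      "%s: duplicated (sample_id, element) key(s): %s.",
      what,
      paste(sprintf("(%s, %s)", d$sample_id, d$element), collapse = "; ")
    )
  }
  totals
}

check_nonnegative <- function(df, what) {
  bad <- !is.finite(df$concentration) | df$concentration < 0
  if (any(bad)) {
    b <- df[bad, ]
    key <- if ("fraction" %in% names(df)) {
      sprintf("(%s, %s, F%s)", b$sample_id, b$element, b$fraction)
    } else {
      sprintf("(%s, %s)", b$sample_id, b$element)
    }
    stop_validation(
      "%s: negative or non-finite concentration at %s.",
      what, paste(key, collapse = "; ")
    )
  }
  invisible(df)
}

#' Read five-step sequential-extraction concentrations
#'
#' Reads a long-format CSV with one row per sample, element and extraction
#' step. Fraction codes may be written `1`..`5` or `F1`..`F5` and are
#' normalised to integers. Missing steps for a (sample, element) pair are
#' permitted at read time but reported via [fraction_completeness()]; a
#' warning is raised if the file is empty or incomplete.
#'
#' @param path Path to a CSV with columns `sample_id`, `element`, `fraction`,
#'   `concentration`.
#' @param element_set Allowed element symbols.
#' @return A tibble of validated fraction records; the completeness summary is
#'   attached as attribute `"completeness"`.
#' @export
read_fractions <- function(path, element_set = pte_elements()) {
  df <- read_csv_strict(path)
  validate_fractions(df, element_set, what = basename(path))
}

#' @rdname read_fractions
#' @param fractions A data frame to validate in place of a file.
#' @param what Label used in error messages.
#' @export
validate_fractions <- function(fractions, element_set = pte_elements(),
                               what = "fractions table") {
  require_columns(fractions, c("sample_id", "element", "fraction", "concentration"), what)
  fractions <- as_tibble(fractions)
  fractions$sample_id <- as.character(fractions$sample_id)
  fractions$concentration <- as.double(fractions$concentration)
  if (nrow(fractions) > 0) {
    fractions$element <- canonical_element(as.character(fractions$element), element_set)
    fractions$fraction <- normalize_fraction_code(fractions$fraction, what)
    check_nonnegative(fractions, what)
    dup <- duplicated(fractions[c("sample_id", "element", "fraction")])
    if (any(dup)) {
      d <- fractions[dup, ]
      stop_validation(
        "%s: duplicated (sample_id, element, fraction) key(s): %s.",
        what,
        paste(sprintf("(%s, %s, F%d)", d$sample_id, d$element, d$fraction),
              collapse = "; ")
      )
    }
  } else {
    fractions$element <- as.character(fractions$element)
    fractions$fraction <- as.integer(fractions$fraction)
  }
  comp <- fraction_completeness(fractions)
  if (nrow(fractions) == 0) {
    warn(sprintf("%s: no fraction records read.", what))
  } else if (any(comp$n_steps < 5L)) {
    warn(sprintf(
      "%s: %d (sample, element) pair(s) have fewer than 5 extraction steps.",
      what, sum(comp$n_steps < 5L)
    ))
  }
  attr(fractions, "completeness") <- comp
  fractions
}

normalize_fraction_code <- function(x, what) {
  x_chr <- toupper(trimws(as.character(x)))
  x_chr <- sub("^F", "", x_chr)
  suppressWarnings(code <- as.integer(x_chr))
  bad <- is.na(code) | code < 1L | code > 5L
  if (any(bad)) {
    stop_validation(
      "%s: fraction code(s) outside F1-F5: %s.",
      what, paste(unique(as.character(x)[bad]), collapse = ", ")
    )
  }
  code
}

#' Summarise which extraction steps are present per sample and element
#'
#' @param fractions A validated fractions tibble.
#' @return A tibble with columns `sample_id`, `element`, `n_steps`,
#'   `missing_steps` (comma-separated labels, `""` when complete).
#' @export
fraction_completeness <- function(fractions) {
  if (nrow(fractions) == 0) {
    return(tibble(
      sample_id = character(), element = character(),
      n_steps = integer(), missing_steps = character()
    ))
  }
  fractions |>
    dplyr::group_by(.data$sample_id, .data$element) |>
    dplyr::summarise(
      n_steps = dplyr::n_distinct(.data$fraction),
      missing_steps = paste0("F", setdiff(1:5, .data$fraction), collapse = ","),
      .groups = "drop"
    )
}

# reference table ----------------------------------------------------------

#' Read a per-element reference table (backgrounds, toxic responses, guidelines)
#'
#' The reference config is a YAML file mapping element symbols to entries with
#' fields `background` (mg/kg), `toxic_response` (dimensionless), `guideline`
#' (mg/kg) and optionally `min`/`max`/`mean` summary statistics of the study's
#' total concentrations. Absent values must be written as explicit nulls
#' (`~`); they are returned as `NA` and propagate downstream as "element
#' excluded", never as zero.
#'
#' With no arguments this returns the packaged reference table for the eleven
#' elements of the Serbian river-sediment survey, whose backgrounds are the
#' study minima.
#'
#' @param path Path to a YAML config; `NULL` for the packaged default.
#' @return A tibble with columns `element`, `background`, `toxic_response`,
#'   `guideline`, `min`, `max`, `mean`.
#' @export
#' @examples
#' read_reference()
read_reference <- function(path = NULL) {
  if (is.null(path)) path <- default_reference_path()
  if (!file.exists(path)) stop_format("Reference config not found: %s.", path)
  cfg <- yaml::read_yaml(path)
  entries <- cfg[["elements"]]
  if (is.null(entries)) stop_format("Reference config %s has no `elements` mapping.", basename(path))
  if (anyDuplicated(names(entries))) {
    stop_validation(
      "Reference config: duplicated element entr(ies): %s.",
      paste(unique(names(entries)[duplicated(names(entries))]), collapse = ", ")
    )
  }
  num_or_na <- function(entry, field) {
    v <- entry[[field]]
    if (is.null(v)) NA_real_ else as.double(v)
  }
  ref <- purrr::imap(entries, function(entry, el) {
    tibble(
      element = el,
      background = num_or_na(entry, "background"),
      toxic_response = num_or_na(entry, "toxic_response"),
      guideline = num_or_na(entry, "guideline"),
      min = num_or_na(entry, "min"),
      max = num_or_na(entry, "max"),
      mean = num_or_na(entry, "mean")
    )
  }) |>
    purrr::list_rbind()
  validate_reference(ref)
}

#' @rdname read_reference
#' @param reference A data frame to validate in place of a file.
#' @export
validate_reference <- function(reference) {
  require_columns(reference, c("element", "background", "toxic_response"), "reference table")
  reference <- as_tibble(reference)
  for (col in c("guideline", "min", "max", "mean")) {
    if (!col %in% names(reference)) reference[[col]] <- NA_real_
  }
  if (anyDuplicated(reference$element)) {
    stop_validation(
      "Reference table: duplicated element(s): %s.",
      paste(unique(reference$element[duplicated(reference$element)]), collapse = ", ")
    )
  }
  bad_bg <- !is.na(reference$background) & reference$background <= 0
  if (any(bad_bg)) {
    stop_validation(
      "Reference table: background must be > 0 (got %s for %s).",
      paste(reference$background[bad_bg], collapse = ", "),
      paste(reference$element[bad_bg], collapse = ", ")
    )
  }
  bad_tr <- !is.na(reference$toxic_response) & reference$toxic_response < 0
  if (any(bad_tr)) {
    stop_validation(
      "Reference table: toxic_response must be >= 0 (element %s).",
      paste(reference$element[bad_tr], collapse = ", ")
    )
  }
  reference[c("element", "background", "toxic_response", "guideline", "min", "max", "mean")]
}

default_reference_path <- function() {
  system.file("extdata", "serbia_reference.yaml", package = "sedrisk", mustWork = TRUE)
}

#' Study-wide concentration summaries (min/max/mean) from a reference table
#'
#' Convenience accessor for the summary-statistic columns of a reference
#' table, the inputs to [fit_from_summary()].
#'
#' @param reference A reference tibble; defaults to the packaged table.
#' @return A tibble with columns `element`, `min`, `max`, `mean`, dropping
#'   elements whose summaries are absent.
#' @export
concentration_summaries <- function(reference = read_reference()) {
  reference |>
    dplyr::select("element", "min", "max", "mean") |>
    dplyr::filter(!is.na(.data$min), !is.na(.data$max), !is.na(.data$mean))
}

# writing ------------------------------------------------------------------

#' Write study tables back to disk
#'
#' CSV writers that round-trip with the readers to full stored precision
#' (doubles are written in their shortest round-trippable decimal form), plus
#' a YAML writer for
#' reference tables using explicit nulls for absent values.
#'
#' @param totals,fractions,reference Validated study tibbles.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_totals <- function(totals, path) {
  readr::write_csv(totals, path)
  invisible(path)
}

#' @rdname write_totals
#' @export
write_fractions <- function(fractions, path) {
  df <- fractions
  attr(df, "completeness") <- NULL
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname write_totals
#' @export
write_reference <- function(reference, path) {
  entries <- purrr::map(seq_len(nrow(reference)), function(i) {
    row <- reference[i, ]
    purrr::map(
      list(
        background = row$background, toxic_response = row$toxic_response,
        guideline = row$guideline, min = row$min, max = row$max, mean = row$mean
      ),
      function(v) if (is.na(v)) NULL else v
    )
  })
  names(entries) <- reference$element
  yaml::write_yaml(list(elements = entries), path)
  invisible(path)
}

read_csv_strict <- function(path) {
  if (!file.exists(path)) stop_format("File not found: %s.", path)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Convert a wide totals table (one column per element) to long format
#'
#' @param wide A data frame with columns `sample_id`, `river`, `site` and one
#'   numeric column per element symbol.
#' @param element_set Allowed element symbols.
#' @return A long tibble suitable for [validate_totals()].
#' @export
totals_longer <- function(wide, element_set = pte_elements()) {
  require_columns(wide, c("sample_id", "river", "site"), "wide totals table")
  el_cols <- setdiff(names(wide), c("sample_id", "river", "site"))
  if (length(el_cols) == 0) stop_format("Wide totals table has no element columns.")
  long <- tidyr::pivot_longer(
    wide,
    cols = dplyr::all_of(el_cols),
    names_to = "element", values_to = "concentration"
  )
  validate_totals(long, element_set, what = "wide totals table")
}
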