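#' Fraction percentage profiles from sequential-extraction data
#'
#' Converts five-step extraction concentrations into percentage profiles: for
#' each sample and element, step k's percentage is 100 * c_k / sum(c), i.e.
#' relative to the total *extracted* content (the independent total digest is
#' used only for recovery QC, see [recovery_qc()]).
#'
#' @param fractions A fractions tibble (columns `sample_id`, `element`,
#'   `fraction`, `concentration`), e.g. from [read_fractions()]. All five
#'   steps must be present for each (sample, element) pair.
#' @return A tibble `sample_id`, `element`, `fraction`, `concentration`,
#'   `percentage`; percentages sum to 100 within each (sample, element).
#' @export
#' @examples
#' f <- tibble::tibble(
#'   sample_id = "S1", element = "Cd", fraction = 1:5,
#'   concentration = c(2, 3, 5, 10, 20)
#' )
#' fraction_percentages(f)
fraction_percentages <- function(fractions) {
  check_profile_input(fractions)
  out <- fractions |>
    dplyr::group_by(.data$sample_id, .data$element) |>
    dplyr::mutate(percentage = 100 * .data$concentration / sum(.data$concentration)) |>
    dplyr::ungroup()
  if (anyNA(out$percentage)) {
    bad <- out |>
      dplyr::filter(is.na(.data$percentage)) |>
      dplyr::distinct(.data$sample_id, .data$element)
    stop_validation(
      "Degenerate profile (all five steps zero) for %s.",
      paste(sprintf("(%s, %s)", bad$sample_id, bad$element), collapse = "; ")
    )
  }
  out
}

check_profile_input <- function(fractions) {
  require_columns(fractions, c("sample_id", "element", "fraction", "concentration"),
                  "fractions table")
  if (nrow(fractions) == 0) stop_usage("Empty fractions table.")
  if (any(fractions$concentration < 0)) {
    stop_validation("Fraction concentrations must be non-negative.")
  }
  counts <- fraction_completeness(as_tibble(fractions))
  if (any(counts$n_steps < 5L)) {
    bad <- counts[counts$n_steps < 5L, ]
    stop_validation(
      "Incomplete five-step profile for %s.",
      paste(sprintf("(%s, %s)", bad$sample_id, bad$element), collapse = "; ")
    )
  }
  invisible(fractions)
}

#' Study-mean fraction profile per element
#'
#' Averages per-sample percentage profiles arithmetically across samples and
#' renormalises so each element's mean profile again sums to exactly 100.
#'
#' @param profiles Output of [fraction_percentages()].
#' @return A tibble `element`, `fraction`, `percentage` (study means).
#' @export
study_mean_profile <- function(profiles) {
  require_columns(profiles, c("element", "fraction", "percentage"), "profiles table")
  if (nrow(profiles) == 0) stop_usage("Empty profiles table.")
  profiles |>
    dplyr::group_by(.data$element, .data$fraction) |>
    dplyr::summarise(percentage = mean(.data$percentage), .groups = "drop_last") |>
    dplyr::mutate(percentage = 100 * .data$percentage / sum(.data$percentage)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$element, .data$fraction)
}

#' Mobility ordering of extraction fractions
#'
#' Orders the five fractions by descending percentage and joins neighbours
#' whose percentages differ by less than `tie_threshold` percentage points
#' with an approximate-equality mark, producing orderings such as
#' `"F5 > F2 > F1 > F4 > F3"` or `"F5 ≈ F3 > F4 ≈ F2 > F1"`.
#'
#' With `tie_threshold = 0` the ordering is the strict descending sort;
#' raising the threshold can only merge neighbours, never reorder them.
#'
#' @param profiles A tibble with columns `element`, `fraction`, `percentage`
#'   (per-sample profiles may additionally carry `sample_id`, in which case
#'   one ordering per sample is returned).
#' @param tie_threshold Tie width in percentage points (default 2).
#' @return A tibble with one row per profile: grouping columns plus
#'   `ordering` (display string) and `groups` (list column of character
#'   vectors, the tie groups in descending order).
#' @export
mobility_order <- function(profiles, tie_threshold = 2) {
  require_columns(profiles, c("element", "fraction", "percentage"), "profiles table")
  stopifnot(is_scalar_number(tie_threshold), tie_threshold >= 0)
  keys <- intersect(c("sample_id", "element"), names(profiles))
  profiles |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::group_modify(function(df, key) {
      if (nrow(df) != 5L || anyDuplicated(df$fraction)) {
        stop_validation("Each profile must contain the five fractions exactly once.")
      }
      ord <- order(-df$percentage, df$fraction)
      p <- df$percentage[ord]
      lab <- paste0("F", df$fraction[ord])
      # neighbours closer than the threshold share a tie group
      gaps <- -diff(p)
      grp <- cumsum(c(1, gaps >= tie_threshold))
      groups <- split(lab, grp)
      tibble(
        ordering = paste(
          vapply(groups, paste, "", collapse = " ≈ "),
          collapse = " > "
        ),
        groups = list(unname(groups))
      )
    }) |>
    dplyr::ungroup()
}

#' Compare two mobility orderings treating tie groups as sets
#'
#' @param a,b Ordering strings as produced by [mobility_order()] (or written
#'   by hand with `>` and the approximate-equality mark `≈` / `~`).
#' @return `TRUE` if both orderings have the same sequence of tie groups,
#'   compared as sets.
#' @export
#' @examples
#' ordering_equal("F5 ≈ F3 > F1", "F3 ≈ F5 > F1")
ordering_equal <- function(a, b) {
  parse_groups <- function(s) {
    lapply(strsplit(s, ">", fixed = TRUE)[[1]], function(g) {
      sort(trimws(strsplit(g, "≈|~")[[1]]))
    })
  }
  identical(parse_groups(a), parse_groups(b))
}

#' Retention-based contamination factor
#'
#' The ratio of an element's content in the mobile phases (steps F1-F4) to
#' its residual-phase content (F5): `Cf = (c1 + c2 + c3 + c4) / c5`. Lower
#' values mean stronger retention in the sediment; higher values mean the
#' element is more readily released. A zero residual step is an error rather
#' than infinity, so that downstream statistics never mix finite and infinite
#' factors.
#'
#' This is the retention-time contamination factor of sequential-extraction
#' work, distinct from the Hakanson contamination factor [hakanson_cf()]
#' (concentration over background).
#'
#' @param fractions A fractions tibble with all five steps per
#'   (sample, element).
#' @return A tibble `sample_id`, `element`, `retention_cf`.
#' @export
#' @examples
#' f <- tibble::tibble(
#'   sample_id = "S1", element = "Pb", fraction = 1:5,
#'   concentration = c(2, 3, 5, 10, 5)
#' )
#' retention_cf(f) # Cf = 4
retention_cf <- function(fractions) {
  check_profile_input(fractions)
  out <- fractions |>
    dplyr::group_by(.data$sample_id, .data$element) |>
    dplyr::summarise(
      mobile = sum(.data$concentration[.data$fraction != 5L]),
      residual = .data$concentration[.data$fraction == 5L],
      .groups = "drop"
    )
  if (any(out$residual <= 0)) {
    bad <- out[out$residual <= 0, ]
    stop_validation(
      "Retention Cf undefined: residual step (F5) is zero for %s.",
      paste(sprintf("(%s, %s)", bad$sample_id, bad$element), collapse = "; ")
    )
  }
  out |>
    dplyr::mutate(retention_cf = .data$mobile / .data$residual) |>
    dplyr::select("sample_id", "element", "retention_cf")
}

#' Mean retention contamination factor per element
#'
#' @param cf_table Output of [retention_cf()].
#' @return A tibble `element`, `retention_cf` (arithmetic mean over samples).
#' @export
retention_cf_mean <- function(cf_table) {
  require_columns(cf_table, c("element", "retention_cf"), "Cf table")
  cf_table |>
    dplyr::group_by(.data$element) |>
    dplyr::summarise(retention_cf = mean(.data$retention_cf), .groups = "drop")
}

#' Extraction recovery quality control
#'
#' Recovery is the summed five-step extracted content as a percentage of the
#' independent total digest, `100 * sum(fractions) / total`. Samples outside
#' the acceptance band are flagged, not dropped.
#'
#' @param fractions A fractions tibble with all five steps per pair.
#' @param totals A totals tibble ([read_totals()]).
#' @param band Acceptance band in percent, default `c(80, 120)`.
#' @return A tibble `sample_id`, `element`, `fraction_sum`, `total`,
#'   `recovery`, `in_band`.
#' @export
recovery_qc <- function(fractions, totals, band = c(80, 120)) {
  check_profile_input(fractions)
  require_columns(totals, c("sample_id", "element", "concentration"), "totals table")
  stopifnot(length(band) == 2, band[1] < band[2])
  sums <- fractions |>
    dplyr::group_by(.data$sample_id, .data$element) |>
    dplyr::summarise(fraction_sum = sum(.data$concentration), .groups = "drop")
  out <- dplyr::inner_join(
    sums,
    dplyr::select(totals, "sample_id", "element", total = "concentration"),
    by = c("sample_id", "element")
  )
  if (any(out$total <= 0)) {
    bad <- out[out$total <= 0, ]
    stop_validation(
      "Recovery undefined: total digest <= 0 for %s.",
      paste(sprintf("(%s, %s)", bad$sample_id, bad$element), collapse = "; ")
    )
  }
  out |>
    dplyr::mutate(
      recovery = 100 * .data$fraction_sum / .data$total,
      in_band = .data$recovery >= band[1] & .data$recovery <= band[2]
    )
}
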