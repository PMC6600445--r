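#' Risk classification scheme for Er and RI
#'
#' The standard Hakanson class boundaries: single-factor ecological risk Er
#' is classed at 40 / 80 / 160 / 320 (Low, Lower, Median, High, Extremely
#' high) and the total risk index RI at 150 / 300 / 600 (Low, Lower, Median,
#' High). Intervals are half-open on the right, `[lower, upper)`: a value
#' exactly at a threshold belongs to the upper class (Er = 40 is "Lower").
#'
#' @param er_thresholds Strictly increasing Er class boundaries.
#' @param er_labels One more label than `er_thresholds`, lowest class first.
#' @param ri_thresholds Strictly increasing RI class boundaries.
#' @param ri_labels One more label than `ri_thresholds`.
#' @return An object of class `risk_scheme`.
#' @export
#' @examples
#' risk_scheme()
risk_scheme <- function(er_thresholds = c(40, 80, 160, 320),
                        er_labels = c("Low", "Lower", "Median", "High", "Extremely high"),
                        ri_thresholds = c(150, 300, 600),
                        ri_labels = c("Low", "Lower", "Median", "High")) {
  check_scale <- function(thresholds, labels, what) {
    if (any(diff(thresholds) <= 0)) {
      stop_validation("%s thresholds must be strictly increasing.", what)
    }
    if (length(labels) != length(thresholds) + 1) {
      stop_validation(
        "%s needs one more label than thresholds (%d thresholds, %d labels).",
        what, length(thresholds), length(labels)
      )
    }
  }
  check_scale(er_thresholds, er_labels, "Er")
  check_scale(ri_thresholds, ri_labels, "RI")
  structure(
    list(
      er_thresholds = as.double(er_thresholds), er_labels = er_labels,
      ri_thresholds = as.double(ri_thresholds), ri_labels = ri_labels
    ),
    class = "risk_scheme"
  )
}

#' @export
print.risk_scheme <- function(x, ...) {
  cat("<risk_scheme>\n")
  cat("  Er:", paste(x$er_labels, collapse = " | "),
      "at", paste(x$er_thresholds, collapse = "/"), "\n")
  cat("  RI:", paste(x$ri_labels, collapse = " | "),
      "at", paste(x$ri_thresholds, collapse = "/"), "\n")
  invisible(x)
}

classify_on <- function(x, thresholds, labels) {
  stopifnot(all(is.finite(x)), all(x >= 0))
  cut(x,
    breaks = c(-Inf, thresholds, Inf), labels = labels,
    right = FALSE, ordered_result = TRUE
  )
}

#' Classify single-factor risk values
#'
#' @param er,ri Non-negative numeric vectors of index values.
#' @param scheme A [risk_scheme()].
#' @return An ordered factor of class labels.
#' @export
#' @examples
#' classify_er(c(39.99, 40, 320))
classify_er <- function(er, scheme = risk_scheme()) {
  classify_on(er, scheme$er_thresholds, scheme$er_labels)
}

#' @rdname classify_er
#' @export
classify_ri <- function(ri, scheme = risk_scheme()) {
  classify_on(ri, scheme$ri_thresholds, scheme$ri_labels)
}

#' Hakanson contamination factor, single-factor risk and total risk index
#'
#' The Hakanson contamination factor is the measured concentration over the
#' background reference concentration, `Cf = C / C_n`. The single-factor
#' ecological risk weights it by the element's toxic response factor,
#' `Er = T_r * C / C_n`, and the total risk index is the sum of Er over the
#' assessed elements, `RI = sum(Er)`.
#'
#' @param concentration Measured concentration(s), mg/kg, non-negative.
#' @param background Background concentration C_n, mg/kg, > 0.
#' @param toxic_response Toxic response factor T_r, dimensionless, >= 0.
#' @param element Optional element label for error messages.
#' @return Numeric vector (dimensionless factor / index values).
#' @export
#' @examples
#' hakanson_cf(4.82, 1.28)
#' hakanson_er(4.82, 1.28, 30)
hakanson_cf <- function(concentration, background, element = NULL) {
  if (anyNA(background) || any(background <= 0)) {
    stop_validation(
      "Background must be present and > 0%s.",
      if (is.null(element)) "" else sprintf(" (element %s)", paste(unique(element), collapse = ", "))
    )
  }
  if (any(concentration < 0)) stop_validation("Concentration must be non-negative.")
  concentration / background
}

#' @rdname hakanson_cf
#' @export
hakanson_er <- function(concentration, background, toxic_response, element = NULL) {
  if (anyNA(toxic_response) || any(toxic_response < 0)) {
    stop_validation(
      "Toxic response factor must be present and >= 0%s; elements without one are excluded, not zeroed.",
      if (is.null(element)) "" else sprintf(" (element %s)", paste(unique(element), collapse = ", "))
    )
  }
  toxic_response * hakanson_cf(concentration, background, element)
}

#' @rdname hakanson_cf
#' @param er_values Numeric vector of per-element Er values; the empty sum
#'   is 0.
#' @export
hakanson_ri <- function(er_values) {
  if (length(er_values) == 0) return(0)
  stopifnot(is.numeric(er_values))
  sum(er_values)
}

#' Deterministic ecological risk assessment per site
#'
#' Applies the Hakanson indices to every sample: per eligible element the
#' contamination factor `Cf = C / C_n` and risk `Er = T_r * Cf`, and per site
#' the total `RI = sum(Er)`. An element is eligible when its reference entry
#' has both a background and a toxic response factor; all other elements are
#' listed in the exclusion report with the missing field(s), never silently
#' zero-filled.
#'
#' @param totals A validated totals tibble ([read_totals()]).
#' @param reference A reference tibble ([read_reference()]).
#' @param scheme A [risk_scheme()].
#' @return An object of class `sed_risk` with components
#'   \describe{
#'     \item{elements}{tibble: `sample_id`, `element`, `concentration`,
#'       `background`, `toxic_response`, `cf`, `er`, `er_class`}
#'     \item{sites}{tibble: `sample_id`, `river`, `site`, `m` (number of
#'       elements summed), `ri`, `ri_class`}
#'     \item{excluded}{tibble: `element`, `reason`}
#'     \item{scheme}{the scheme used}
#'   }
#'   `tidy()` returns the per-element table, `glance()` a one-row summary and
#'   `autoplot()` a per-site RI bar chart.
#' @export
assess_sites <- function(totals, reference = read_reference(), scheme = risk_scheme()) {
  require_columns(totals, c("sample_id", "element", "concentration"), "totals table")
  reference <- validate_reference(reference)
  elements_present <- unique(totals$element)
  missing_ref <- setdiff(elements_present, reference$element)
  if (length(missing_ref) > 0) {
    stop_validation(
      "No reference entry for element(s): %s.",
      paste(missing_ref, collapse = ", ")
    )
  }
  ref <- reference |>
    dplyr::filter(.data$element %in% elements_present) |>
    dplyr::mutate(
      eligible = !is.na(.data$background) & !is.na(.data$toxic_response),
      reason = dplyr::case_when(
        is.na(.data$background) & is.na(.data$toxic_response) ~ "missing background and toxic_response",
        is.na(.data$background) ~ "missing background",
        is.na(.data$toxic_response) ~ "missing toxic_response",
        .default = NA_character_
      )
    )
  excluded <- ref |>
    dplyr::filter(!.data$eligible) |>
    dplyr::select("element", "reason")
  eligible_ref <- dplyr::filter(ref, .data$eligible)
  if (nrow(eligible_ref) == 0) {
    stop_validation("No element has both a background and a toxic response factor; nothing to assess.")
  }
  per_element <- totals |>
    dplyr::inner_join(
      dplyr::select(eligible_ref, "element", "background", "toxic_response"),
      by = "element"
    ) |>
    dplyr::mutate(
      cf = hakanson_cf(.data$concentration, .data$background, .data$element),
      er = .data$toxic_response * .data$cf,
      er_class = classify_er(.data$er, scheme)
    ) |>
    dplyr::select(dplyr::any_of(c(
      "sample_id", "element", "concentration", "background",
      "toxic_response", "cf", "er", "er_class"
    )))
  site_cols <- intersect(c("river", "site"), names(totals))
  sites <- totals |>
    dplyr::distinct(dplyr::across(dplyr::all_of(c("sample_id", site_cols)))) |>
    dplyr::left_join(
      per_element |>
        dplyr::group_by(.data$sample_id) |>
        dplyr::summarise(m = dplyr::n(), ri = sum(.data$er), .groups = "drop"),
      by = "sample_id"
    ) |>
    dplyr::mutate(ri_class = classify_ri(.data$ri, scheme))
  structure(
    list(elements = per_element, sites = sites, excluded = excluded, scheme = scheme),
    class = "sed_risk"
  )
}

#' @export
print.sed_risk <- function(x, ...) {
  cat(sprintf(
    "<sed_risk> %d site(s), %d element(s) assessed, %d excluded\n",
    nrow(x$sites), dplyr::n_distinct(x$elements$element), nrow(x$excluded)
  ))
  if (nrow(x$excluded) > 0) {
    cat("  excluded:", paste(x$excluded$element, collapse = ", "), "\n")
  }
  cat(sprintf(
    "  RI range %.3g-%.3g; classes: %s\n",
    min(x$sites$ri), max(x$sites$ri),
    paste(sprintf("%s %d", levels(x$sites$ri_class), table(x$sites$ri_class)), collapse = ", ")
  ))
  invisible(x)
}

#' @export
tidy.sed_risk <- function(x, type = c("elements", "sites"), ...) {
  type <- match.arg(type)
  x[[type]]
}

#' @export
glance.sed_risk <- function(x, ...) {
  tibble(
    n_sites = nrow(x$sites),
    n_elements = dplyr::n_distinct(x$elements$element),
    n_excluded = nrow(x$excluded),
    mean_ri = mean(x$sites$ri),
    max_ri = max(x$sites$ri),
    max_ri_class = as.character(x$sites$ri_class[which.max(x$sites$ri)])
  )
}
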