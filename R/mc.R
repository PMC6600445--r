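#' Monte Carlo configuration
#'
#' @param iterations Number of draws (default 100,000).
#' @param seed Integer master seed.
#' @param rounding Decimal places for *reported* probabilities (default 2).
#'   Internal arithmetic is never rounded; rounding is applied half-even at
#'   the reporting layer only.
#' @return An object of class `mc_config`.
#' @export
mc_config <- function(iterations = 100000L, seed = 1L, rounding = 2L) {
  stopifnot(is_scalar_number(iterations), iterations >= 1,
            is_scalar_number(seed), is_scalar_number(rounding), rounding >= 0)
  structure(
    list(iterations = as.integer(iterations), seed = as.integer(seed),
         rounding = as.integer(rounding)),
    class = "mc_config"
  )
}

class_probabilities <- function(x, thresholds, labels) {
  cls <- classify_on(x, thresholds, labels)
  counts <- table(cls)
  tibble(
    class = factor(labels, levels = labels, ordered = TRUE),
    probability = 100 * as.double(counts[labels]) / length(x)
  )
}

#' Monte Carlo simulation of the single-factor ecological risk Er
#'
#' Draws exposure concentrations from an element's distribution spec,
#' converts each draw to `Er = T_r * C / C_n`, and tabulates the percentage
#' of draws in each risk class.
#'
#' @param spec A one-row spec tibble for the element.
#' @param reference A reference tibble containing that element with both
#'   `background` and `toxic_response` present.
#' @param config An [mc_config()].
#' @param scheme A [risk_scheme()].
#' @return A list with `element`, `er` (the draws), `class_probs` (tibble
#'   `class`, `probability` in %, unrounded), `summary` (tibble of draw
#'   count, mean, quantiles) and `config`.
#' @export
simulate_element_risk <- function(spec, reference = read_reference(),
                                  config = mc_config(), scheme = risk_scheme()) {
  spec <- validate_specs(spec)
  stopifnot(nrow(spec) == 1)
  ref <- reference[reference$element == spec$element, ]
  if (nrow(ref) != 1 || is.na(ref$background) || is.na(ref$toxic_response)) {
    stop_validation(
      "Element %s lacks a background and/or toxic response factor and is excluded from risk simulation.",
      spec$element
    )
  }
  draws <- draw_concentrations(spec, n = config$iterations, seed = config$seed)
  er <- ref$toxic_response * draws$concentration / ref$background
  list(
    element = spec$element,
    er = er,
    class_probs = class_probabilities(er, scheme$er_thresholds, scheme$er_labels),
    summary = draw_summary(er),
    config = config
  )
}

draw_summary <- function(x) {
  qs <- quantile(x, c(0.05, 0.25, 0.5, 0.75, 0.95), names = FALSE)
  tibble(
    n = length(x), mean = mean(x), sd = sd(x),
    q05 = qs[1], q25 = qs[2], median = qs[3], q75 = qs[4], q95 = qs[5]
  )
}

#' Monte Carlo simulation of the total risk index RI
#'
#' Runs [simulate_element_risk()] for every eligible element (one
#' independent, seed-derived substream each), sums the per-element Er draws
#' iteration-wise into `RI_j = sum_i Er_ij`, and tabulates class
#' probabilities on both scales plus exceedance curves. Elements whose
#' reference entry lacks a background or toxic response factor are excluded
#' and reported, exactly as in [assess_sites()].
#'
#' @param specs A spec tibble, one row per element.
#' @param reference A reference tibble.
#' @param config An [mc_config()].
#' @param scheme A [risk_scheme()].
#' @return An object of class `mc_risk` with components `er` (tibble
#'   `element`, `.draw`, `er`), `ri` (numeric draws), `er_class_probs`
#'   (tibble `element`, `class`, `probability`), `ri_class_probs`,
#'   `er_summary`, `ri_summary`, `excluded`, `config`, `scheme`. `tidy()`
#'   returns the class-probability table, `glance()` a one-row summary,
#'   `autoplot()` the RI exceedance curve; [class_prob_table()] reshapes to
#'   the classes-by-elements report.
#' @export
simulate_total_risk <- function(specs, reference = read_reference(),
                                config = mc_config(), scheme = risk_scheme()) {
  specs <- validate_specs(specs)
  reference <- validate_reference(reference)
  missing_ref <- setdiff(specs$element, reference$element)
  if (length(missing_ref) > 0) {
    stop_validation("No reference entry for element(s): %s.",
                    paste(missing_ref, collapse = ", "))
  }
  ref <- reference[match(specs$element, reference$element), ]
  eligible <- !is.na(ref$background) & !is.na(ref$toxic_response)
  excluded <- tibble(
    element = specs$element[!eligible],
    reason = dplyr::case_when(
      is.na(ref$background[!eligible]) & is.na(ref$toxic_response[!eligible]) ~
        "missing background and toxic_response",
      is.na(ref$background[!eligible]) ~ "missing background",
      .default = "missing toxic_response"
    )
  )
  if (!any(eligible)) {
    stop_validation("No element has both a background and a toxic response factor.")
  }
  sims <- purrr::map(which(eligible), function(i) {
    simulate_element_risk(specs[i, ], reference, config, scheme)
  })
  er_long <- purrr::map(sims, function(s) {
    tibble(element = s$element, .draw = seq_along(s$er), er = s$er)
  }) |>
    purrr::list_rbind()
  ri <- rowSums(vapply(sims, function(s) s$er, double(config$iterations)))
  structure(
    list(
      er = er_long,
      ri = ri,
      er_class_probs = purrr::map(sims, function(s) {
        dplyr::mutate(s$class_probs, element = s$element, .before = 1)
      }) |> purrr::list_rbind(),
      ri_class_probs = class_probabilities(ri, scheme$ri_thresholds, scheme$ri_labels),
      er_summary = purrr::map(sims, function(s) {
        dplyr::mutate(s$summary, element = s$element, .before = 1)
      }) |> purrr::list_rbind(),
      ri_summary = draw_summary(ri),
      excluded = excluded,
      config = config,
      scheme = scheme
    ),
    class = "mc_risk"
  )
}

#' Risk-class probability table in report shape
#'
#' Reshapes an `mc_risk` result into the conventional report layout: one row
#' per risk class (with its defining interval), one column per element, cells
#' holding the probability (%) rounded half-even to `digits` decimals. With
#' `scale = "ri"` the single-column total-risk table is returned.
#'
#' @param x An `mc_risk` object.
#' @param scale `"er"` (per element) or `"ri"` (total).
#' @param digits Decimals to round to; defaults to the run's configured
#'   reporting precision.
#' @return A tibble with columns `interval`, `class`, then one per element
#'   (or `probability`).
#' @export
class_prob_table <- function(x, scale = c("er", "ri"), digits = NULL) {
  stopifnot(inherits(x, "mc_risk"))
  scale <- match.arg(scale)
  if (is.null(digits)) digits <- x$config$rounding
  thresholds <- if (scale == "er") x$scheme$er_thresholds else x$scheme$ri_thresholds
  labels <- if (scale == "er") x$scheme$er_labels else x$scheme$ri_labels
  bounds <- c(-Inf, thresholds, Inf)
  interval <- vapply(seq_along(labels), function(k) {
    lo <- bounds[k]
    hi <- bounds[k + 1]
    if (!is.finite(lo)) sprintf("< %g", hi)
    else if (!is.finite(hi)) sprintf(">= %g", lo)
    else sprintf("[%g, %g)", lo, hi)
  }, "")
  base <- tibble(interval = interval,
                 class = factor(labels, levels = labels, ordered = TRUE))
  if (scale == "ri") {
    return(dplyr::mutate(
      base,
      probability = round(x$ri_class_probs$probability, digits)
    ))
  }
  wide <- x$er_class_probs |>
    dplyr::mutate(probability = round(.data$probability, digits)) |>
    tidyr::pivot_wider(names_from = "element", values_from = "probability")
  dplyr::left_join(base, wide, by = "class") |>
    dplyr::relocate("interval", "class")
}

#' Exceedance probability curve
#'
#' For each distinct draw value v, the probability that the simulated index
#' is at least v: `P(X >= v) = #\{draws >= v\} / n`. The curve starts at
#' probability 1 (at the minimum) and is nonincreasing.
#'
#' @param draws Non-empty numeric vector of simulated index values.
#' @return A tibble `value`, `exceedance`, ordered by increasing value.
#' @export
#' @examples
#' exceedance_curve(c(1, 2, 3, 4))
exceedance_curve <- function(draws) {
  if (length(draws) == 0) stop_usage("Cannot build an exceedance curve from no draws.")
  stopifnot(is.numeric(draws), all(is.finite(draws)))
  v <- sort(unique(draws))
  counts <- tabulate(match(draws, v), nbins = length(v))
  below <- c(0, cumsum(counts))[seq_along(v)]  # draws strictly below each v
  tibble(value = v, exceedance = (length(draws) - below) / length(draws))
}

#' @export
print.mc_risk <- function(x, ...) {
  cat(sprintf(
    "<mc_risk> %s iterations, seed %d, %d element(s), %d excluded\n",
    format(x$config$iterations, big.mark = ","), x$config$seed,
    dplyr::n_distinct(x$er$element), nrow(x$excluded)
  ))
  print(class_prob_table(x), ...)
  cat("RI classes (%):\n")
  print(class_prob_table(x, "ri"), ...)
  invisible(x)
}

#' @export
tidy.mc_risk <- function(x, scale = c("er", "ri"), ...) {
  scale <- match.arg(scale)
  if (scale == "er") x$er_class_probs else x$ri_class_probs
}

#' @export
glance.mc_risk <- function(x, ...) {
  tibble(
    iterations = x$config$iterations,
    seed = x$config$seed,
    n_elements = dplyr::n_distinct(x$er$element),
    n_excluded = nrow(x$excluded),
    ri_mean = mean(x$ri),
    ri_q95 = unname(quantile(x$ri, 0.95)),
    p_ri_low = x$ri_class_probs$probability[1]
  )
}
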