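#' The potentially toxic elements covered by the packaged reference table
#'
#' Eleven elements routinely assessed in river-sediment surveys: Cd, Co, Cr,
#' Cu, Fe, Mn, Ni, Pb, V, Zn and As.
#'
#' @return Character vector of IUPAC element symbols.
#' @export
#' @examples
#' pte_elements()
pte_elements <- function() {
  c("Cd", "Co", "Cr", "Cu", "Fe", "Mn", "Ni", "Pb", "V", "Zn", "As")
}

#' Canonicalise element symbols
#'
#' Matches symbols case-insensitively against a declared element set and
#' returns the canonical IUPAC spelling ("cd", "CD" and "Cd" all map to "Cd").
#'
#' @param x Character vector of element symbols.
#' @param element_set Character vector of allowed canonical symbols.
#' @return Character vector of canonical symbols, same length as `x`.
#' @export
#' @examples
#' canonical_element(c("cd", "ZN"))
canonical_element <- function(x, element_set = pte_elements()) {
  idx <- match(tolower(x), tolower(element_set))
  if (anyNA(idx)) {
    bad <- unique(x[is.na(idx)])
    abort(
      sprintf(
        "Unknown element symbol(s): %s. Allowed: %s.",
        paste(bad, collapse = ", "), paste(element_set, collapse = ", ")
      ),
      class = "sedrisk_error_validation"
    )
  }
  element_set[idx]
}

# error helpers -----------------------------------------------------------

stop_validation <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "sedrisk_error_validation")
}

stop_format <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "sedrisk_error_format")
}

stop_usage <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "sedrisk_error_usage")
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop_format(
      "%s is missing required column(s): %s.",
      what, paste(missing, collapse = ", ")
    )
  }
  invisible(df)
}
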