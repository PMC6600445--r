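# Small in-code fixtures shared across the suite.

make_totals <- function(sample_id = c("S1", "S2", "S3"),
                        element = c("Cd", "Zn", "Pb"),
                        concentration = c(4.82, 353, 132)) {
  tibble::tibble(
    sample_id = sample_id, river = "R", site = "R 1",
    element = element, concentration = concentration
  )
}

make_fractions <- function(sample_id = "S1", element = "Cd",
                           concentration = c(2, 3, 5, 10, 20)) {
  tibble::tibble(
    sample_id = sample_id, element = element,
    fraction = 1:5, concentration = concentration
  )
}

write_temp_csv <- function(df) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  readr::write_csv(df, path)
  path
}

# the published study-mean mobility orderings, tie groups marked with ~
expected_orderings <- c(
  Cd = "F5 > F2 > F1 > F4 > F3",
  Cr = "F5 > F4 > F3 > F2 > F1",
  Co = "F5 > F2 > F3 > F4 > F1",
  Cu = "F5 ~ F3 > F4 ~ F2 > F1",
  Fe = "F5 > F3 > F4 > F2 > F1",
  Mn = "F2 > F1 > F5 > F4 > F3",
  Ni = "F5 > F4 ~ F2 ~ F3 > F1",
  Pb = "F2 > F4 > F3 ~ F5 ~ F1",
  Zn = "F2 > F5 > F4 > F3 > F1",
  V  = "F5 > F3 > F2 > F4 > F1",
  As = "F5 > F3 > F2 > F4 > F1"
)
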