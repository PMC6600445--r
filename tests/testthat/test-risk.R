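# Frozen oracle values, computed by independent hand/spreadsheet arithmetic
# from the published per-element means and backgrounds:
#   Cd: 30 * 4.82 / 1.28  = 112.96875
#   Cr:  2 * 113  / 62.1  = 3.6392914654...
#   Cu:  5 * 78.5 / 11.5  = 34.1304347826...
#   Pb:  5 * 132  / 57.8  = 11.4186851211...
#   Zn:  1 * 353  / 66.6  = 5.3003003003...
#   sum                   = 167.4574616694...
er_means_oracle <- c(
  Cd = 112.96875, Cr = 3.6392914653784306, Cu = 34.130434782608695,
  Pb = 11.418685121107266, Zn = 5.3003003003003
)
ri_oracle <- 167.45746166939283

test_that("Hakanson contamination factor is concentration over background", {
  expect_equal(hakanson_cf(1.28, 1.28), 1)
  expect_equal(hakanson_cf(0, 57.8), 0)
  expect_equal(hakanson_cf(4.82, 1.28), 3.765625)
  expect_error(hakanson_cf(1, 0, element = "Cd"),
               class = "sedrisk_error_validation", regexp = "Cd")
  expect_error(hakanson_cf(1, NA_real_), class = "sedrisk_error_validation")
})

test_that("single-factor risk Er weights the contamination factor by Tr", {
  expect_equal(hakanson_er(1.28, 1.28, 30), 30) # C = C_n gives Er = Tr
  expect_equal(hakanson_er(0, 1.28, 30), 0)
  expect_equal(hakanson_er(4.82, 1.28, 30), 112.96875)
  # a missing toxic response excludes the element, it is never zeroed
  expect_error(hakanson_er(1, 1, NA_real_, element = "Co"),
               class = "sedrisk_error_validation", regexp = "Co")
})

test_that("Er is linear in concentration and monotone in its arguments", {
  withr::with_seed(11, {
    for (i in 1:100) {
      C <- stats::rlnorm(1, 3, 2)
      Cn <- stats::rlnorm(1, 2, 1)
      Tr <- stats::runif(1, 0, 40)
      lambda <- stats::rlnorm(1, 0, 1)
      expect_equal(hakanson_er(lambda * C, Cn, Tr),
                   lambda * hakanson_er(C, Cn, Tr), tolerance = 1e-12)
      expect_gte(hakanson_er(C * 1.1, Cn, Tr), hakanson_er(C, Cn, Tr))
      expect_gte(hakanson_er(C, Cn, Tr * 1.1), hakanson_er(C, Cn, Tr))
      expect_lte(hakanson_er(C, Cn * 1.1, Tr), hakanson_er(C, Cn, Tr))
    }
  })
})

test_that("RI is the plain sum of Er values, empty sum zero, order-invariant", {
  expect_equal(hakanson_ri(numeric(0)), 0)
  expect_equal(hakanson_ri(42), 42)
  expect_equal(hakanson_ri(unname(er_means_oracle)), ri_oracle)
  withr::with_seed(12, {
    er <- stats::rlnorm(7, 2, 1)
    expect_identical(hakanson_ri(er), hakanson_ri(rev(er)))
    expect_identical(hakanson_ri(er), hakanson_ri(sample(er)))
  })
})

test_that("risk classes use half-open intervals with thresholds in the upper class", {
  expect_equal(as.character(classify_er(c(0, 39.999, 40, 112.97, 160, 320, 1000))),
               c("Low", "Low", "Lower", "Median", "High",
                 "Extremely high", "Extremely high"))
  expect_equal(as.character(classify_ri(c(0, 149.99, 150, 300, 599.9, 600))),
               c("Low", "Low", "Lower", "Median", "Median", "High"))
})

test_that("classification agrees with a brute-force linear interval scan", {
  scheme <- risk_scheme()
  brute <- function(x, thresholds, labels) {
    vapply(x, function(v) {
      k <- 1
      for (t in thresholds) if (v >= t) k <- k + 1 else break
      labels[k]
    }, "")
  }
  withr::with_seed(13, {
    x <- c(scheme$er_thresholds, scheme$ri_thresholds,
           stats::runif(10000, 0, 700))
  })
  expect_equal(as.character(classify_er(x, scheme)),
               brute(x, scheme$er_thresholds, scheme$er_labels))
  expect_equal(as.character(classify_ri(x, scheme)),
               brute(x, scheme$ri_thresholds, scheme$ri_labels))
})

test_that("risk_scheme validates thresholds and label counts", {
  expect_error(risk_scheme(er_thresholds = c(40, 40, 160, 320)),
               class = "sedrisk_error_validation", regexp = "increasing")
  expect_error(risk_scheme(er_labels = c("a", "b")),
               class = "sedrisk_error_validation", regexp = "label")
})

test_that("assess_sites computes per-element Er, sums RI and reports exclusions", {
  # one site at exactly the published mean concentrations
  totals <- tibble::tibble(
    sample_id = "S1", river = "R", site = "R 1",
    element = pte_elements(),
    concentration = c(4.82, 22.0, 113, 78.5, 44177, 1399, 77.8, 132, 111, 353, 14.7)
  )
  a <- assess_sites(totals)
  el <- tidy(a)
  expect_setequal(el$element, names(er_means_oracle))
  expect_equal(setNames(el$er, el$element)[names(er_means_oracle)],
               er_means_oracle)
  expect_equal(a$sites$ri, ri_oracle)
  expect_equal(a$sites$m, 5L)
  expect_equal(as.character(a$sites$ri_class), "Lower")
  # Tr missing for Co/Fe/Mn/V, background missing for Ni/As
  expect_setequal(a$excluded$element, c("Co", "Fe", "Mn", "Ni", "V", "As"))
  expect_equal(sort(a$excluded$element[a$excluded$reason == "missing toxic_response"]),
               c("Co", "Fe", "Mn", "V"))
  expect_equal(sort(a$excluded$element[a$excluded$reason == "missing background"]),
               c("As", "Ni"))
})

test_that("a site at background concentrations has RI = sum of Tr", {
  ref <- read_reference()
  eligible <- ref[!is.na(ref$background) & !is.na(ref$toxic_response), ]
  totals <- tibble::tibble(
    sample_id = "S1", river = "R", site = "R 1",
    element = eligible$element, concentration = eligible$background
  )
  a <- assess_sites(totals)
  expect_equal(tidy(a)$cf, rep(1, nrow(eligible)))
  expect_equal(a$sites$ri, sum(eligible$toxic_response))
})

test_that("assess_sites handles degenerate references", {
  totals <- make_totals()
  ref_none <- tibble::tibble(
    element = c("Cd", "Zn", "Pb"), background = NA_real_, toxic_response = 1
  )
  expect_error(assess_sites(totals, ref_none),
               class = "sedrisk_error_validation", regexp = "No element")

  one <- tibble::tibble(element = c("Cd", "Zn", "Pb"),
                        background = c(1.28, NA, NA),
                        toxic_response = c(30, NA, NA))
  a <- assess_sites(totals[totals$element == "Cd", ], one)
  expect_equal(a$sites$ri, tidy(a)$er) # single eligible element: RI = Er
})

test_that("RI over a study is invariant to element order in the input", {
  study <- generate_study(synth_config(n_sites = 5), seed = 21)
  a1 <- assess_sites(study$totals)
  shuffled <- withr::with_seed(22, study$totals[sample(nrow(study$totals)), ])
  a2 <- assess_sites(shuffled)
  s1 <- dplyr::arrange(a1$sites, sample_id)
  s2 <- dplyr::arrange(a2$sites, sample_id)
  expect_equal(s2$ri, s1$ri)
})

test_that("sed_risk tidy and glance expose the assessment tables", {
  a <- assess_sites(make_totals())
  expect_s3_class(tidy(a), "tbl_df")
  expect_s3_class(tidy(a, "sites"), "tbl_df")
  g <- glance(a)
  expect_equal(nrow(g), 1)
  expect_equal(g$n_sites, 3)
})
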