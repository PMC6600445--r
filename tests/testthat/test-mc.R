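test_that("a point-mass concentration gives a one-class probability table", {
  # Er(C) = 1 * 333 / 66.6 = 5 < 40: all mass in the lowest class
  spec <- dist_spec("Zn", "point_mass", location = 333)
  sim <- simulate_element_risk(spec, config = mc_config(iterations = 1000, seed = 1))
  expect_equal(sim$class_probs$probability, c(100, 0, 0, 0, 0))
  expect_equal(unique(sim$er), 5)
})

test_that("elements without complete reference data are refused, not zeroed", {
  spec <- dist_spec("Ni", "point_mass", location = 50) # Ni background absent
  expect_error(simulate_element_risk(spec),
               class = "sedrisk_error_validation", regexp = "Ni")
})

test_that("MC class probabilities match the closed-form CDF within 3 binomial SEs", {
  n <- 100000
  scheme <- risk_scheme()
  ref <- read_reference()

  check_against_oracle <- function(spec, analytic_cdf) {
    r <- ref[ref$element == spec$element, ]
    sim <- simulate_element_risk(spec, ref, mc_config(iterations = n, seed = 17), scheme)
    # class k covers Er in [t_k, t_{k+1}); convert to concentration bounds
    bounds <- c(0, scheme$er_thresholds, Inf) * r$background / r$toxic_response
    p_oracle <- diff(analytic_cdf(bounds))
    for (k in seq_along(p_oracle)) {
      se <- sqrt(p_oracle[k] * (1 - p_oracle[k]) / n)
      expect_lt(abs(sim$class_probs$probability[k] / 100 - p_oracle[k]),
                3 * se + 1e-12)
    }
  }

  # truncated normal: Cd-like law straddling several class boundaries
  cd <- fit_from_summary(min = 1.28, max = 10.5, mean = 4.82, element = "Cd")
  check_against_oracle(cd, function(q) {
    pa <- pnorm(1.28, 4.82, 2.305)
    pb <- pnorm(10.5, 4.82, 2.305)
    pmin(pmax((pnorm(pmin(pmax(q, 1.28), 10.5), 4.82, 2.305) - pa) / (pb - pa), 0), 1)
  })

  # plain normal with negative-rejection: renormalised on [0, Inf)
  cu <- dist_spec("Cu", "normal", location = 78.5, scale = 100)
  check_against_oracle(cu, function(q) {
    p0 <- pnorm(0, 78.5, 100)
    pmin(pmax((pnorm(pmax(q, 0), 78.5, 100) - p0) / (1 - p0), 0), 1)
  })
})

test_that("class probabilities sum to 100 before and after reporting rounding", {
  specs <- fit_from_summary(concentration_summaries())
  specs <- specs[specs$element %in% c("Cd", "Cu", "Zn"), ]
  mc <- simulate_total_risk(specs, config = mc_config(iterations = 20000, seed = 23))
  sums <- mc$er_class_probs |>
    dplyr::summarise(s = sum(probability), .by = element)
  expect_equal(sums$s, rep(100, 3), tolerance = 1e-9)
  expect_equal(sum(mc$ri_class_probs$probability), 100, tolerance = 1e-9)
  tab <- class_prob_table(mc)
  for (el in c("Cd", "Cu", "Zn")) {
    expect_lt(abs(sum(tab[[el]]) - 100), 0.05)
  }
})

test_that("point-mass specs collapse the MC pipeline onto the deterministic index", {
  ref <- read_reference()
  eligible <- ref[!is.na(ref$background) & !is.na(ref$toxic_response), ]
  conc <- setNames(c(4.82, 113, 78.5, 132, 353), c("Cd", "Cr", "Cu", "Pb", "Zn"))
  specs <- purrr::list_rbind(purrr::imap(
    conc, function(v, el) dist_spec(el, "point_mass", location = v)
  ))
  mc <- simulate_total_risk(specs, ref, mc_config(iterations = 100, seed = 3))

  totals <- tibble::tibble(
    sample_id = "S1", river = "R", site = "R 1",
    element = names(conc), concentration = unname(conc)
  )
  det <- assess_sites(totals, ref)

  expect_equal(unique(mc$ri), det$sites$ri)
  det_el <- tidy(det)
  for (el in names(conc)) {
    expect_equal(unique(mc$er$er[mc$er$element == el]),
                 det_el$er[det_el$element == el])
    # the MC class table puts all mass on the deterministic class
    probs <- mc$er_class_probs[mc$er_class_probs$element == el, ]
    expect_equal(as.character(probs$class[probs$probability == 100]),
                 as.character(det_el$er_class[det_el$element == el]))
  }
  expect_equal(
    as.character(mc$ri_class_probs$class[mc$ri_class_probs$probability == 100]),
    as.character(det$sites$ri_class)
  )
})

test_that("RI draws are the iteration-wise sum with the expected mean", {
  # two independent normal laws: E[RI] = sum of analytic Er means
  ref <- tibble::tibble(
    element = c("Cd", "Zn"), background = c(1, 10),
    toxic_response = c(2, 1), guideline = NA_real_,
    min = NA_real_, max = NA_real_, mean = NA_real_
  )
  specs <- dplyr::bind_rows(
    dist_spec("Cd", "normal", location = 50, scale = 5),
    dist_spec("Zn", "normal", location = 200, scale = 20)
  )
  n <- 50000
  mc <- simulate_total_risk(specs, ref, mc_config(iterations = n, seed = 29))
  # negative-rejection is immaterial here (P(X<0) ~ 1e-23)
  mean_oracle <- 2 * 50 / 1 + 1 * 200 / 10
  sd_ri <- sqrt((2 * 5 / 1)^2 + (1 * 20 / 10)^2)
  expect_lt(abs(mean(mc$ri) - mean_oracle), 3 * sd_ri / sqrt(n))
  # RI is exactly the sum of the per-element draws
  er_wide <- tidyr::pivot_wider(mc$er, names_from = element, values_from = er)
  expect_equal(mc$ri, er_wide$Cd + er_wide$Zn)
})

test_that("identical config reproduces an identical MCResult", {
  specs <- fit_from_summary(concentration_summaries())
  specs <- specs[specs$element %in% c("Cd", "Zn"), ]
  m1 <- simulate_total_risk(specs, config = mc_config(iterations = 5000, seed = 41))
  m2 <- simulate_total_risk(specs, config = mc_config(iterations = 5000, seed = 41))
  expect_identical(m1$er, m2$er)
  expect_identical(m1$ri, m2$ri)
  expect_identical(m1$er_class_probs, m2$er_class_probs)
})

test_that("doubling the iterations moves class probabilities only within MC error", {
  specs <- fit_from_summary(min = 1.28, max = 10.5, mean = 4.82, element = "Cd")
  n <- 20000
  p1 <- simulate_element_risk(specs, config = mc_config(iterations = n, seed = 43))
  p2 <- simulate_element_risk(specs, config = mc_config(iterations = 2 * n, seed = 44))
  bound <- 3 * sqrt(0.25 / n) * 100
  expect_true(all(abs(p1$class_probs$probability - p2$class_probs$probability) <= bound))
})

test_that("exceedance curves count draws at or above each value", {
  expect_equal(exceedance_curve(7), tibble::tibble(value = 7, exceedance = 1))
  out <- exceedance_curve(c(1, 2, 3, 4))
  expect_equal(out$value, 1:4)
  expect_equal(out$exceedance, c(1, 0.75, 0.5, 0.25))
  expect_error(exceedance_curve(numeric(0)), class = "sedrisk_error_usage")

  withr::with_seed(47, {
    for (i in 1:20) {
      draws <- stats::rlnorm(200, 2, 1)
      curve <- exceedance_curve(draws)
      expect_equal(curve$exceedance[1], 1)
      expect_true(all(diff(curve$exceedance) < 0))
      expect_false(is.unsorted(curve$value))
      # spot-check one interior point against direct counting
      v <- curve$value[97]
      expect_equal(curve$exceedance[97], mean(draws >= v))
    }
  })
})

test_that("excluded elements are reported by simulate_total_risk", {
  specs <- fit_from_summary(concentration_summaries())
  mc <- simulate_total_risk(specs, config = mc_config(iterations = 100, seed = 53))
  expect_setequal(mc$excluded$element, c("Co", "Fe", "Mn", "Ni", "V", "As"))
  expect_setequal(unique(mc$er$element), c("Cd", "Cr", "Cu", "Pb", "Zn"))
})

test_that("mc_risk tidy, glance and the report table are consistent", {
  specs <- fit_from_summary(concentration_summaries())
  specs <- specs[specs$element %in% c("Zn", "Pb"), ]
  mc <- simulate_total_risk(specs, config = mc_config(iterations = 2000, seed = 59))
  expect_s3_class(tidy(mc), "tbl_df")
  expect_equal(glance(mc)$iterations, 2000)
  tab <- class_prob_table(mc)
  expect_equal(tab$interval[1], "< 40")
  expect_equal(tab$interval[2], "[40, 80)")
  expect_equal(names(tab), c("interval", "class", "Pb", "Zn"))
})
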