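#' Concentration distribution specifications
#'
#' A distribution spec describes the sampling law of one element's exposure
#' concentration. Specs are plain tibble rows so that a set of them (one per
#' element) is itself a tidy table. Supported families:
#' \describe{
#'   \item{normal}{mean `location`, sd `scale`; negatives are rejected and
#'     redrawn at sampling time.}
#'   \item{truncated_normal}{normal(location, scale) truncated to
#'     `[lower, upper]`; sampled by inverse CDF, so draws lie inside the
#'     support exactly.}
#'   \item{lognormal}{mean `location`, sd `scale` on the concentration scale
#'     (converted to log-scale parameters internally); optional truncation.}
#'   \item{point_mass}{degenerate at `location`.}
#'   \item{empirical}{bootstrap resampling of stored `values`.}
#' }
#'
#' @param element Element symbol.
#' @param family One of `"normal"`, `"truncated_normal"`, `"lognormal"`,
#'   `"point_mass"`, `"empirical"`.
#' @param location,scale Centre and spread in mg/kg (`scale` ignored for
#'   point_mass, both ignored for empirical).
#' @param lower,upper Optional support bounds in mg/kg.
#' @param values Numeric vector of stored values (empirical family only).
#' @param provenance How the spec arose: `"fit_from_samples"`,
#'   `"fit_from_summary"` or `"user"`.
#' @return A one-row spec tibble with columns `element`, `family`,
#'   `location`, `scale`, `lower`, `upper`, `provenance`, `values`
#'   (list column).
#' @export
#' @examples
#' dist_spec("Zn", "truncated_normal", 353, 257.1, lower = 66.6, upper = 1095)
dist_spec <- function(element, family, location = NA_real_, scale = NA_real_,
                      lower = NA_real_, upper = NA_real_, values = NULL,
                      provenance = "user") {
  spec <- tibble(
    element = element, family = family,
    location = as.double(location), scale = as.double(scale),
    lower = as.double(lower), upper = as.double(upper),
    provenance = provenance,
    values = list(values)
  )
  validate_specs(spec)
}

dist_families <- function() {
  c("normal", "truncated_normal", "lognormal", "point_mass", "empirical")
}

#' Validate a table of distribution specs
#'
#' @param specs A spec tibble (one row per element).
#' @return The validated tibble, invisibly usable in pipes.
#' @export
validate_specs <- function(specs) {
  require_columns(specs, c("element", "family", "location", "scale"), "spec table")
  specs <- as_tibble(specs)
  if (!"lower" %in% names(specs)) specs$lower <- NA_real_
  if (!"upper" %in% names(specs)) specs$upper <- NA_real_
  if (!"provenance" %in% names(specs)) specs$provenance <- "user"
  if (!"values" %in% names(specs)) specs$values <- vector("list", nrow(specs))
  for (i in seq_len(nrow(specs))) {
    s <- specs[i, ]
    el <- s$element
    if (!s$family %in% dist_families()) {
      stop_validation("Unknown distribution family '%s' (element %s).", s$family, el)
    }
    if (s$family == "empirical") {
      v <- s$values[[1]]
      if (is.null(v) || length(v) == 0) {
        stop_validation("Empirical spec for %s has no stored values.", el)
      }
      if (any(v < 0)) stop_validation("Empirical spec for %s contains negative values.", el)
      next
    }
    if (!is.finite(s$location)) stop_validation("Spec for %s has no location.", el)
    if (s$family != "point_mass" && (!is.finite(s$scale) || s$scale <= 0)) {
      stop_validation("Spec for %s needs scale > 0 (got %s).", el, format(s$scale))
    }
    has_support <- is.finite(s$lower) || is.finite(s$upper)
    if (has_support) {
      lo <- if (is.finite(s$lower)) s$lower else -Inf
      hi <- if (is.finite(s$upper)) s$upper else Inf
      if (lo >= hi) stop_validation("Spec for %s has support lower >= upper.", el)
      if (hi <= 0) stop_validation("Spec for %s is infeasible: support upper <= 0.", el)
      if (s$family == "truncated_normal") {
        if (!is.finite(s$lower) || !is.finite(s$upper)) {
          stop_validation("truncated_normal spec for %s needs finite lower and upper.", el)
        }
        if (s$lower < 0) {
          stop_validation("truncated_normal spec for %s needs support lower >= 0 (concentrations).", el)
        }
        if (s$location < s$lower || s$location > s$upper) {
          stop_validation("truncated_normal spec for %s needs location inside [lower, upper].", el)
        }
      }
      if (s$family == "lognormal" && is.finite(s$lower) && s$lower < 0) {
        stop_validation("lognormal spec for %s needs support lower >= 0.", el)
      }
    }
    if (s$family == "lognormal" && s$location <= 0) {
      stop_validation("lognormal spec for %s needs location > 0.", el)
    }
  }
  specs
}

# truncated normal machinery ----------------------------------------------
# standardised bounds alpha = (a - mu)/sigma, beta = (b - mu)/sigma

tnorm_z <- function(alpha, beta) pnorm(beta) - pnorm(alpha)

#' Moments and CDF of the truncated normal distribution
#'
#' Closed-form mean, standard deviation and CDF of a normal(mean, sd)
#' truncated to `[lower, upper]`, used for moment matching and as the
#' analytic reference for Monte Carlo class probabilities.
#'
#' @param mean,sd Parameters of the parent normal.
#' @param lower,upper Truncation bounds.
#' @param q Quantile(s) at which to evaluate the CDF.
#' @return `tnorm_mean()`/`tnorm_sd()` a scalar; `ptnorm()` vector of
#'   probabilities.
#' @export
tnorm_mean <- function(mean, sd, lower, upper) {
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  mean + sd * (dnorm(a) - dnorm(b)) / tnorm_z(a, b)
}

#' @rdname tnorm_mean
#' @export
tnorm_sd <- function(mean, sd, lower, upper) {
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  z <- tnorm_z(a, b)
  m1 <- (dnorm(a) - dnorm(b)) / z
  v <- 1 + (a * dnorm(a) - b * dnorm(b)) / z - m1^2
  # v can dip below 0 by rounding (or be NaN when z underflows) for extreme
  # parameters probed during optimisation
  if (!is.finite(v)) return(NaN)
  sd * sqrt(max(v, 0))
}

#' @rdname tnorm_mean
#' @export
ptnorm <- function(q, mean, sd, lower, upper) {
  pa <- pnorm(lower, mean, sd)
  pb <- pnorm(upper, mean, sd)
  p <- (pnorm(q, mean, sd) - pa) / (pb - pa)
  pmin(pmax(p, 0), 1)
}

rtnorm <- function(n, mean, sd, lower, upper) {
  pa <- pnorm(lower, mean, sd)
  pb <- pnorm(upper, mean, sd)
  qnorm(pa + runif(n) * (pb - pa), mean, sd)
}

# match a truncated normal's mean/sd on [lower, upper] to target moments
tnorm_moment_match <- function(target_mean, target_sd, lower, upper) {
  objective <- function(par) {
    mu <- par[1]
    sigma <- exp(par[2])
    val <- ((tnorm_mean(mu, sigma, lower, upper) - target_mean) / target_sd)^2 +
      ((tnorm_sd(mu, sigma, lower, upper) - target_sd) / target_sd)^2
    if (!is.finite(val)) 1e10 else val
  }
  fit <- optim(c(target_mean, log(target_sd)), objective,
               control = list(reltol = 1e-14, maxit = 2000))
  list(location = fit$par[1], scale = exp(fit$par[2]), value = fit$value)
}

# fitting ------------------------------------------------------------------

#' Fit concentration distributions from raw samples
#'
#' Method-of-moments fits per element. For `normal` and `lognormal` the
#' sample mean and sd are matched directly; for `truncated_normal` the
#' support is the sample range and the parent normal's (location, scale) are
#' solved so the *truncated* distribution's mean and sd match the sample
#' moments (a naive location = sample-mean fit is badly biased when the
#' truncation is asymmetric). A constant sample degenerates to a point mass;
#' `empirical` stores the values for bootstrap resampling.
#'
#' @param x Either a numeric vector of concentrations for one element, or a
#'   totals tibble with columns `element` and `concentration` (fit per
#'   element).
#' @param family Distribution family to fit (see [dist_spec()]).
#' @param element Element label when `x` is a numeric vector.
#' @return A spec tibble, one row per element, `provenance =
#'   "fit_from_samples"`.
#' @export
fit_from_samples <- function(x, family = "truncated_normal", element = "X") {
  if (is.data.frame(x)) {
    require_columns(x, c("element", "concentration"), "totals table")
    return(
      x |>
        dplyr::group_by(.data$element) |>
        dplyr::group_modify(function(df, key) {
          fit_from_samples(df$concentration, family = family, element = key$element) |>
            dplyr::select(-"element")
        }) |>
        dplyr::ungroup()
    )
  }
  values <- as.double(x)
  if (length(values) < 2) {
    stop_validation("Need at least 2 values to estimate a scale for %s.", element)
  }
  if (any(values < 0)) {
    stop_validation("Negative concentrations in sample for %s.", element)
  }
  if (length(unique(values)) < 2) {
    return(dist_spec(element, "point_mass", location = values[1],
                     provenance = "fit_from_samples"))
  }
  m <- mean(values)
  s <- sd(values)
  spec <- switch(family,
    normal = dist_spec(element, "normal", m, s, provenance = "fit_from_samples"),
    lognormal = dist_spec(element, "lognormal", m, s, provenance = "fit_from_samples"),
    truncated_normal = {
      lo <- min(values)
      hi <- max(values)
      mm <- tnorm_moment_match(m, s, lo, hi)
      loc <- min(max(mm$location, lo), hi)
      dist_spec(element, "truncated_normal", loc, mm$scale,
                lower = lo, upper = hi, provenance = "fit_from_samples")
    },
    empirical = dist_spec(element, "empirical", values = values,
                          provenance = "fit_from_samples"),
    point_mass = stop_validation(
      "point_mass cannot be fitted from a non-constant sample (%s).", element
    ),
    stop_validation("Unknown distribution family '%s'.", family)
  )
  spec
}

#' Fit concentration distributions from printed summary statistics
#'
#' Builds a sampling law from (min, max, mean) alone, the situation when only
#' a summary table is published. The location is the mean; the scale comes
#' from an `sd_rule` heuristic, by default the range rule `(max - min) / 4`;
#' `truncated_normal` (the default) uses `[min, max]` as support so draws
#' respect the observed range. A degenerate summary (min = max = mean)
#' becomes a point mass.
#'
#' @param x Either a summary tibble with columns `element`, `min`, `max`,
#'   `mean` (e.g. [concentration_summaries()]), or a single element's
#'   `min`/`max`/`mean` given as scalars.
#' @param min,max,mean Scalar summaries when `x` is not given.
#' @param family Distribution family (default `"truncated_normal"`).
#' @param sd_rule Either the string `"range4"` or a function
#'   `f(min, max, mean)` returning the scale.
#' @param element Element label for the scalar form.
#' @return A spec tibble, `provenance = "fit_from_summary"`.
#' @export
#' @examples
#' fit_from_summary(min = 66.6, max = 1095, mean = 353, element = "Zn")
fit_from_summary <- function(x = NULL, min = NULL, max = NULL, mean = NULL,
                             family = "truncated_normal", sd_rule = "range4",
                             element = "X") {
  if (is.data.frame(x)) {
    require_columns(x, c("element", "min", "max", "mean"), "summary table")
    specs <- purrr::pmap(
      x[c("element", "min", "max", "mean")],
      function(element, min, max, mean) {
        fit_from_summary(
          min = min, max = max, mean = mean,
          family = family, sd_rule = sd_rule, element = element
        )
      }
    )
    return(purrr::list_rbind(specs))
  }
  stopifnot(is_scalar_number(min), is_scalar_number(max), is_scalar_number(mean))
  if (mean < min || mean > max) {
    stop_validation("Summary for %s has mean %g outside [min, max] = [%g, %g].",
                    element, mean, min, max)
  }
  if (min == max) {
    return(dist_spec(element, "point_mass", location = mean,
                     provenance = "fit_from_summary"))
  }
  scale <- if (is.function(sd_rule)) {
    sd_rule(min, max, mean)
  } else if (identical(sd_rule, "range4")) {
    (max - min) / 4
  } else {
    stop_usage("Unknown sd_rule '%s'; use \"range4\" or a function.", sd_rule)
  }
  spec <- switch(family,
    truncated_normal = dist_spec(element, "truncated_normal", mean, scale,
                                 lower = min, upper = max,
                                 provenance = "fit_from_summary"),
    normal = dist_spec(element, "normal", mean, scale,
                       provenance = "fit_from_summary"),
    lognormal = dist_spec(element, "lognormal", mean, scale,
                          provenance = "fit_from_summary"),
    stop_validation("Family '%s' cannot be fitted from summaries.", family)
  )
  spec
}

# sampling -----------------------------------------------------------------

# draw n values from one validated spec row; assumes RNG state already set
draw_spec <- function(s, n) {
  switch(s$family,
    point_mass = rep(s$location, n),
    empirical = sample(s$values[[1]], n, replace = TRUE),
    truncated_normal = rtnorm(n, s$location, s$scale, s$lower, s$upper),
    lognormal = draw_lognormal(s, n),
    normal = draw_normal_rejected(s, n)
  )
}

draw_lognormal <- function(s, n) {
  sdlog <- sqrt(log(1 + (s$scale / s$location)^2))
  meanlog <- log(s$location) - sdlog^2 / 2
  lo <- if (is.finite(s$lower)) s$lower else 0
  hi <- if (is.finite(s$upper)) s$upper else Inf
  if (lo > 0 || is.finite(hi)) {
    pa <- stats::plnorm(lo, meanlog, sdlog)
    pb <- stats::plnorm(hi, meanlog, sdlog)
    stats::qlnorm(pa + runif(n) * (pb - pa), meanlog, sdlog)
  } else {
    stats::rlnorm(n, meanlog, sdlog)
  }
}

draw_normal_rejected <- function(s, n) {
  accept <- 1 - pnorm(0, s$location, s$scale)
  if (accept < 0.01) {
    stop_validation(
      "Infeasible spec for %s: P(concentration >= 0) = %.2g (rejection rate > 99%%).",
      s$element, accept
    )
  }
  out <- double(0)
  while (length(out) < n) {
    batch <- rnorm(ceiling((n - length(out)) / accept) + 16, s$location, s$scale)
    out <- c(out, batch[batch >= 0])
  }
  out[seq_len(n)]
}

#' Draw concentrations from distribution specs
#'
#' Seeded, reproducible sampling: the master `seed` spawns one substream per
#' element, so identical `(specs, n, seed)` give bitwise-identical draws and
#' adding an element to the spec table never perturbs another element's
#' stream.
#'
#' @param specs A spec tibble ([dist_spec()], [fit_from_samples()],
#'   [fit_from_summary()]).
#' @param n Number of draws per element.
#' @param seed Integer master seed.
#' @return A tibble `element`, `.draw` (1..n), `concentration`.
#' @export
#' @examples
#' spec <- dist_spec("Zn", "point_mass", location = 5)
#' draw_concentrations(spec, n = 3, seed = 1)
draw_concentrations <- function(specs, n, seed) {
  specs <- validate_specs(specs)
  stopifnot(is_scalar_number(n), n >= 1)
  draws <- purrr::map(seq_len(nrow(specs)), function(i) {
    s <- specs[i, ]
    tibble(
      element = s$element,
      .draw = seq_len(n),
      concentration = with_substream(seed, s$element, draw_spec(s, n))
    )
  })
  purrr::list_rbind(draws)
}
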