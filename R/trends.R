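#' Ordinary least-squares trend fit
#'
#' Fits `y ~ x` and reports slope, intercept, Pearson r, r squared and the
#' two-sided p-value of the slope, the workhorse of the distance-from-Africa
#' trend analyses.
#'
#' @param x,y numeric vectors; incomplete cases are dropped.
#' @return object of class `trend_fit`: list with `coefficients` (data.table:
#'   term, estimate, se, p), `r`, `r2`, `n`, `p`, `flag`.
#' @export
fit_trend <- function(x, y) {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 3L) {
    return(trend_fit_flagged("fewer than 3 complete cases", n))
  }
  if (stats::var(x) == 0) {
    return(trend_fit_flagged("zero variance in x", n))
  }
  m <- stats::lm(y ~ x)
  s <- summary(m)
  co <- data.table::data.table(term = rownames(s$coefficients),
                               estimate = s$coefficients[, 1L],
                               se = s$coefficients[, 2L],
                               p = s$coefficients[, 4L])
  r <- stats::cor(x, y)
  structure(list(model = "y ~ x", coefficients = co, r = r, r2 = r^2, n = n,
                 p = co$p[co$term == "x"], flag = NA_character_,
                 residuals = summary(stats::residuals(m)), fit = m),
            class = "trend_fit")
}

trend_fit_flagged <- function(why, n) {
  structure(list(model = NA_character_, coefficients = NULL, r = NA_real_,
                 r2 = NA_real_, n = n, p = NA_real_, flag = why,
                 residuals = NULL, fit = NULL),
            class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  if (!is.na(x$flag)) {
    cat(sprintf("Flagged fit (%s), n = %d\n", x$flag, x$n))
    return(invisible(x))
  }
  cat(sprintf("%s: r = %.3f, r2 = %.3f, n = %d\n", x$model, x$r, x$r2, x$n))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Joint model of the two archaic signals and distance
#'
#' Multiple regression `nd_NEA ~ nd_DEN + distance + nd_DEN:distance`,
#' reporting the per-term p-values (the interaction term tests whether the
#' relationship between the two archaic signals itself changes with distance
#' from Africa).
#'
#' @param nd_nea,nd_den,distance numeric vectors (complete cases used).
#' @return a `trend_fit` with the three-term coefficient table.
#' @export
fit_interaction_model <- function(nd_nea, nd_den, distance) {
  keep <- stats::complete.cases(nd_nea, nd_den, distance)
  d <- data.frame(nd_nea = nd_nea[keep], nd_den = nd_den[keep],
                  distance = distance[keep])
  if (nrow(d) < 5L) return(trend_fit_flagged("fewer than 5 complete cases",
                                             nrow(d)))
  if (stats::var(d$distance) == 0 || stats::var(d$nd_den) == 0) {
    return(trend_fit_flagged("degenerate predictor (zero variance)", nrow(d)))
  }
  m <- stats::lm(nd_nea ~ nd_den * distance, data = d)
  if (any(is.na(stats::coef(m)))) {
    return(trend_fit_flagged("collinear predictors", nrow(d)))
  }
  s <- summary(m)
  co <- data.table::data.table(term = rownames(s$coefficients),
                               estimate = s$coefficients[, 1L],
                               se = s$coefficients[, 2L],
                               p = s$coefficients[, 4L])
  structure(list(model = "nd_NEA ~ nd_DEN * distance", coefficients = co,
                 r = sqrt(s$r.squared) * sign(co$estimate[co$term == "nd_den"]),
                 r2 = s$r.squared, n = nrow(d),
                 p = co$p[co$term == "nd_den:distance"], flag = NA_character_,
                 residuals = summary(stats::residuals(m)), fit = m),
            class = "trend_fit")
}

#' Region-stratified trend with a common-slope test
#'
#' Fits `value ~ distance * region` and tests the distance-by-region
#' interaction (an F-test comparing against the parallel-slopes model): a
#' non-significant interaction means all regions share a common slope.
#' Regions with fewer than `min_per_region` points are excluded (counted);
#' with a single usable region the model degenerates to [fit_trend()] with a
#' warning.
#'
#' @param value response (e.g. f4 values).
#' @param distance covariate.
#' @param region factor/character of region labels.
#' @param min_per_region minimum points per region.
#' @return a `trend_fit` whose `p_interaction` element carries the
#'   common-slope test; `excluded_regions` counts dropped groups.
#' @export
fit_region_glm <- function(value, distance, region, min_per_region = 3L) {
  keep <- stats::complete.cases(value, distance, region)
  d <- data.frame(value = value[keep], distance = distance[keep],
                  region = as.character(region[keep]))
  tab <- table(d$region)
  small <- names(tab)[tab < min_per_region]
  d <- d[!d$region %in% small, , drop = FALSE]
  if (length(unique(d$region)) < 2L) {
    warning("fewer than 2 usable regions; falling back to a single trend")
    ft <- fit_trend(d$distance, d$value)
    ft$p_interaction <- NA_real_
    ft$excluded_regions <- length(small)
    return(ft)
  }
  d$region <- factor(d$region)
  m1 <- stats::lm(value ~ distance + region, data = d)
  m2 <- stats::lm(value ~ distance * region, data = d)
  a <- stats::anova(m1, m2)
  s <- summary(m2)
  co <- data.table::data.table(term = rownames(s$coefficients),
                               estimate = s$coefficients[, 1L],
                               se = s$coefficients[, 2L],
                               p = s$coefficients[, 4L])
  structure(list(model = "value ~ distance * region", coefficients = co,
                 r = NA_real_, r2 = s$r.squared, n = nrow(d),
                 p = co$p[co$term == "distance"],
                 p_interaction = a$`Pr(>F)`[2L],
                 excluded_regions = length(small), flag = NA_character_,
                 residuals = summary(stats::residuals(m2)), fit = m2),
            class = "trend_fit")
}
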