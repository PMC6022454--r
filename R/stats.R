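# The significance procedures used in claims-based prevalence studies:
# two-sample z for a difference of proportions (pooled variance, no
# continuity correction), one-sample z for a proportion, and the t test for
# a Pearson correlation coefficient. All tests are two-sided. These closed
# forms are authored here; prop.test()/cor.test() serve only as independent
# cross-checks in the test suite.

new_test_result <- function(method, statistic, p_value, estimate, n,
                            note = NULL) {
  structure(list(method = method, statistic = statistic, p_value = p_value,
                 estimate = estimate, n = n, sided = "two", note = note),
            class = "painclaims_test")
}

#' @export
print.painclaims_test <- function(x, ...) {
  cat(sprintf("%s\n  statistic = %.4f, two-sided p = %.4g\n",
              x$method, x$statistic, x$p_value))
  est <- paste(sprintf("%s = %.4f", names(x$estimate), x$estimate),
               collapse = ", ")
  cat(sprintf("  %s; n = %s\n", est, paste(x$n, collapse = ", ")))
  if (!is.null(x$note)) cat(sprintf("  note: %s\n", x$note))
  invisible(x)
}

#' @export
tidy.painclaims_test <- function(x, ...) {
  out <- tibble(statistic = x$statistic, p.value = x$p_value,
                method = x$method)
  for (nm in names(x$estimate)) out[[nm]] <- x$estimate[[nm]]
  for (nm in names(x$n)) out[[paste0("n_", nm)]] <- x$n[[nm]]
  out
}

#' @export
glance.painclaims_test <- function(x, ...) {
  tibble(statistic = x$statistic, p.value = x$p_value,
         n = sum(unlist(x$n)), method = x$method)
}

#' Two-sample z test for a difference of proportions
#'
#' Pooled-proportion z statistic without continuity correction:
#' `z = (p1 - p2) / sqrt(p(1-p)(1/n1 + 1/n2))` with `p` the pooled
#' proportion; two-sided p from the standard normal.
#'
#' @param x1,n1 successes and trials in sample 1.
#' @param x2,n2 successes and trials in sample 2.
#' @return a `painclaims_test` (supports [tidy()]/[glance()]).
#' @examples
#' two_sample_z(60, 100, 40, 100)
#' @export
two_sample_z <- function(x1, n1, x2, n2) {
  if (n1 < 1 || n2 < 1) abort("two_sample_z: both sample sizes must be >= 1")
  if (x1 < 0 || x1 > n1 || x2 < 0 || x2 > n2) {
    abort("two_sample_z: successes must satisfy 0 <= x <= n")
  }
  p1 <- x1 / n1; p2 <- x2 / n2
  pooled <- (x1 + x2) / (n1 + n2)
  note <- NULL
  if (pooled %in% c(0, 1)) {
    warn("two_sample_z: pooled proportion is degenerate (0 or 1); no variance")
    z <- 0; p <- 1
    note <- "degenerate pooled proportion"
  } else {
    z <- (p1 - p2) / sqrt(pooled * (1 - pooled) * (1 / n1 + 1 / n2))
    p <- 2 * pnorm(-abs(z))
  }
  new_test_result("two-sample z test for difference of proportions",
                  z, p, c(p1 = p1, p2 = p2, diff = p1 - p2),
                  c(n1 = n1, n2 = n2), note)
}

#' One-sample z test for a proportion
#'
#' `z = (x/n - p0) / sqrt(p0 (1 - p0) / n)`; two-sided p from the standard
#' normal.
#'
#' @param x,n successes and trials.
#' @param p0 null proportion, strictly inside (0, 1).
#' @return a `painclaims_test`.
#' @examples
#' one_sample_z(60, 100, 0.5)
#' @export
one_sample_z <- function(x, n, p0) {
  if (n < 1) abort("one_sample_z: n must be >= 1")
  if (x < 0 || x > n) abort("one_sample_z: 0 <= x <= n required")
  if (!(p0 > 0 && p0 < 1)) abort("one_sample_z: p0 must lie strictly in (0, 1)")
  phat <- x / n
  z <- (phat - p0) / sqrt(p0 * (1 - p0) / n)
  new_test_result("one-sample z test for a proportion",
                  z, 2 * pnorm(-abs(z)),
                  c(p = phat, p0 = p0), c(n = n))
}

#' t test for a Pearson correlation coefficient
#'
#' Computes Pearson's r and `t = r sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2`
#' degrees of freedom, two-sided.
#'
#' @param x,y numeric vectors of equal length (>= 3), each non-constant.
#'   Alternatively pass a two-column data frame/matrix of pairs as `x`.
#' @return a `painclaims_test` with estimate `r`.
#' @examples
#' corr_t_test(1:10, c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9))
#' @export
corr_t_test <- function(x, y = NULL) {
  if (is.null(y)) {
    x <- as.data.frame(x)
    if (ncol(x) < 2) abort("corr_t_test: need pairs (x, y)")
    y <- x[[2]]; x <- x[[1]]
  }
  if (length(x) != length(y)) abort("corr_t_test: x and y lengths differ")
  n <- length(x)
  if (n < 3) abort("corr_t_test: need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort("corr_t_test: constant series have no defined correlation")
  }
  r <- cor(x, y)
  if (abs(r) >= 1 - 1e-15) {
    warn("corr_t_test: |r| = 1; correlation is exactly linear")
    return(new_test_result("t test for a correlation coefficient",
                           statistic = sign(r) * Inf, p_value = 0,
                           c(r = r), c(n = n), "perfect correlation"))
  }
  t <- r * sqrt(n - 2) / sqrt(1 - r^2)
  new_test_result("t test for a correlation coefficient",
                  t, 2 * pt(-abs(t), df = n - 2), c(r = r), c(n = n))
}

#' County-level correlations between an outcome and socioeconomic covariates
#'
#' For each of the three county covariates (median income, % below poverty,
#' % bachelor's degree or higher), tests the Pearson correlation with the
#' chosen county-level outcome via [corr_t_test()]. Correlations are
#' computed on raw values, so "positively correlated with *lower* income"
#' appears here as a negative r between income and the public-insurance
#' share.
#'
#' @param table tibble with one row per county: `county`, the outcome
#'   column, `median_income`, `pct_poverty`, `pct_bachelors`.
#' @param outcome name of the outcome column, e.g. `"prevalence_pct"`,
#'   `"public_pct"` or `"private_pct"`.
#' @return tibble with one row per covariate: `covariate`, `outcome`, `r`,
#'   `statistic`, `p_value`, `n`.
#' @export
county_correlations <- function(table, outcome) {
  covars <- c("median_income", "pct_poverty", "pct_bachelors")
  need <- c("county", outcome, covars)
  missing_cols <- setdiff(need, names(table))
  if (length(missing_cols) > 0) {
    abort(sprintf("county_correlations: missing column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  if (nrow(table) < 3) abort("county_correlations: need at least 3 counties")
  for (cv in covars) {
    bad <- is.na(table[[cv]])
    if (any(bad)) {
      abort(sprintf("county_correlations: covariate %s missing for county %s",
                    cv, table$county[bad][1]))
    }
  }
  purrr::map_dfr(covars, function(cv) {
    res <- corr_t_test(table[[cv]], table[[outcome]])
    tibble(covariate = cv, outcome = outcome, r = unname(res$estimate["r"]),
           statistic = res$statistic, p_value = res$p_value,
           n = unname(res$n["n"]))
  })
}
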