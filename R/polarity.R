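# ON/OFF polarity scoring of markers (first sprout, Golgi, N-cadherin
# crescent, axon) against the flat/pillar interface, with binomial
# uncertainty and chi-square goodness-of-fit.

#' Construct an ON/OFF polarity count
#'
#' @param n_on,n_off,n_unclassified non-negative counts.
#' @param null_p expected ON fraction under random positioning (0.5 for a
#'   two-sided interface, 0.25 for the quadrant test).
#' @return a `polarity_count`.
#' @export
polarity_count <- function(n_on, n_off, n_unclassified = 0, null_p = 0.5) {
  stopifnot(n_on >= 0, n_off >= 0, n_unclassified >= 0,
            null_p > 0, null_p < 1)
  structure(list(n_on = as.integer(n_on), n_off = as.integer(n_off),
                 n_unclassified = as.integer(n_unclassified),
                 null_p = null_p),
            class = "polarity_count")
}

#' @export
print.polarity_count <- function(x, ...) {
  cat(sprintf("polarity_count: %d ON / %d OFF (%d unclassified), null %g\n",
              x$n_on, x$n_off, x$n_unclassified, x$null_p))
  invisible(x)
}

#' Score marker positions ON/OFF against the interface
#'
#' A cell's marker is ON when its centroid lies on the pillar side (larger
#' x) of the line through the soma centroid parallel to the interface, by
#' more than `tie_epsilon_um`; OFF when on the flat side by more; otherwise
#' the cell is unclassified (mirroring cells not yet sufficiently polarized
#' to score).
#'
#' @param cells data.frame with columns `soma_x`, `soma_y`, `marker_x`,
#'   `marker_y` (micrometres; pillars at larger x).
#' @param tie_epsilon_um dead zone half-width around the line (default
#'   0.1 um).
#' @param null_p null ON fraction recorded with the count (default 0.5).
#' @return a [polarity_count()].
#' @export
score_onoff <- function(cells, tie_epsilon_um = 0.1, null_p = 0.5) {
  stopifnot(all(c("soma_x", "marker_x") %in% names(cells)),
            tie_epsilon_um >= 0)
  dx <- cells$marker_x - cells$soma_x
  stopifnot(all(is.finite(dx)))
  polarity_count(n_on = sum(dx > tie_epsilon_um),
                 n_off = sum(dx < -tie_epsilon_um),
                 n_unclassified = sum(abs(dx) <= tie_epsilon_um),
                 null_p = null_p)
}

#' ON proportion with binomial standard error
#'
#' Unclassified cells are excluded. Reported in percent:
#' `p_hat = n_on / (n_on + n_off)` and `sem = sqrt(p_hat (1 - p_hat) / n)`.
#'
#' @param count a [polarity_count()] with at least one classified cell.
#' @return list with `p_hat_pct`, `sem_pct`, `n_classified`.
#' @export
proportion_sem <- function(count) {
  n <- count$n_on + count$n_off
  if (n < 1L) stop("no classified cells")
  p <- count$n_on / n
  list(p_hat_pct = 100 * p,
       sem_pct = 100 * sqrt(p * (1 - p) / n),
       n_classified = n)
}

#' Chi-square goodness-of-fit of an ON/OFF count against its null
#'
#' One-degree-of-freedom chi-square over the ON/OFF table with expected
#' counts from `null_p`, without continuity correction.
#'
#' @param count a [polarity_count()].
#' @return list with `chi2`, `df` (= 1) and `p`.
#' @export
chisq_gof <- function(count) {
  n <- count$n_on + count$n_off
  if (n < 1L) stop("no classified cells")
  e_on <- n * count$null_p
  e_off <- n * (1 - count$null_p)
  if (e_on <= 0 || e_off <= 0) stop("expected count is zero")
  chi2 <- (count$n_on - e_on)^2 / e_on + (count$n_off - e_off)^2 / e_off
  list(chi2 = chi2, df = 1L,
       p = stats::pchisq(chi2, df = 1L, lower.tail = FALSE))
}

#' Pooled ON proportion over several cohorts
#'
#' @param counts non-empty list of [polarity_count()] objects.
#' @return pooled ON percentage, `sum(n_on) / sum(classified) * 100`.
#' @export
pooled_proportion <- function(counts) {
  stopifnot(length(counts) >= 1L)
  on <- sum(vapply(counts, `[[`, integer(1), "n_on"))
  n <- on + sum(vapply(counts, `[[`, integer(1), "n_off"))
  if (n < 1L) stop("no classified cells in any cohort")
  100 * on / n
}

#' Quadrant test for Golgi position at the axon base
#'
#' The cell disc is divided into four quadrants about the soma centroid, one
#' centred on the axon direction; the Golgi is ON when its centroid falls in
#' that axon-base quadrant (within 45 degrees of the axon vector). Under
#' random positioning the ON fraction is 25%, so the returned count carries
#' `null_p = 0.25`. Cells without an axis (or with the Golgi on the soma
#' centroid) are unclassified.
#'
#' @param cells data.frame with `soma_x`, `soma_y`, `marker_x`, `marker_y`,
#'   `axon_dx`, `axon_dy`.
#' @return a [polarity_count()] with `null_p = 0.25`.
#' @export
quadrant_golgi_test <- function(cells) {
  stopifnot(all(c("soma_x", "soma_y", "marker_x", "marker_y",
                  "axon_dx", "axon_dy") %in% names(cells)))
  gx <- cells$marker_x - cells$soma_x
  gy <- cells$marker_y - cells$soma_y
  ax <- cells$axon_dx; ay <- cells$axon_dy
  g_len <- sqrt(gx^2 + gy^2)
  a_len <- sqrt(ax^2 + ay^2)
  ok <- is.finite(a_len) & a_len > 0 & g_len > 0
  ang <- rep(NA_real_, nrow(cells))
  cosang <- (gx * ax + gy * ay) / (g_len * a_len)
  ang[ok] <- acos(pmin(1, pmax(-1, cosang[ok])))
  on <- ok & ang <= pi / 4 + 1e-12
  polarity_count(n_on = sum(on, na.rm = TRUE),
                 n_off = sum(ok & !on, na.rm = TRUE),
                 n_unclassified = sum(!ok),
                 null_p = 0.25)
}

#' Two-sample comparison of growth-cone areas
#'
#' Equal-variance two-sided Student's t-test between two groups of
#' growth-cone areas, with group means and SEMs.
#'
#' @param areas_a,areas_b numeric vectors of areas (um2), each of length >= 2.
#' @return list with `t`, `df`, `p`, `mean_a`, `sem_a`, `mean_b`, `sem_b`.
#' @export
growthcone_area_test <- function(areas_a, areas_b) {
  stopifnot(length(areas_a) >= 2L, length(areas_b) >= 2L)
  if (stats::sd(areas_a) == 0 && stats::sd(areas_b) == 0 &&
      mean(areas_a) == mean(areas_b)) {
    tt <- list(statistic = c(t = 0), parameter = c(df = length(areas_a) +
                                                     length(areas_b) - 2L),
               p.value = 1)
  } else if (stats::sd(areas_a) == 0 && stats::sd(areas_b) == 0) {
    stop("degenerate (zero) variance in both groups")
  } else {
    tt <- stats::t.test(areas_a, areas_b, var.equal = TRUE)
  }
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       mean_a = mean(areas_a),
       sem_a = stats::sd(areas_a) / sqrt(length(areas_a)),
       mean_b = mean(areas_b),
       sem_b = stats::sd(areas_b) / sqrt(length(areas_b)))
}

#' Published polarity cohort summaries bundled with the package
#'
#' Cohort sizes and printed ON-percentages (with their published +/- values
#' and significance calls) for the first-sprout, Golgi and N-cadherin
#' scoring of hippocampal neurons at micropillar interfaces, grouped by
#' pillar-spacing bin (dense 0.6-1 um, intermediate 1.2-2 um, sparse 2.4-7
#' um). Used by the worked examples and the acceptance script to check that
#' the package's binomial SEM and chi-square machinery reproduces the
#' published values from `n` and the ON-percentage alone. Note: the
#' first-sprout "+/-" values equal `100 - p_hat`, not a binomial SEM; the
#' package reports binomial SEMs and flags that discrepancy rather than
#' replicating it.
#'
#' @return data.frame with columns `cohort_id`, `marker`, `soma_contact`,
#'   `spacing_bin`, `n`, `pct_on`, `pm_printed_pct`, `unclassified_pct`,
#'   `null_p`, `sig_printed`.
#' @export
polarity_cohorts <- function() {
  path <- system.file("extdata", "polarity_cohorts.csv",
                      package = "pillarpatch", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Reconstruct ON/OFF counts from a cohort summary row
#'
#' The ON count is recovered as `round(pct_on / 100 * n)`; the remainder of
#' the classified cells is OFF.
#'
#' @param n classified cohort size.
#' @param pct_on printed ON percentage.
#' @param null_p null ON fraction.
#' @return a [polarity_count()].
#' @export
count_from_summary <- function(n, pct_on, null_p = 0.5) {
  stopifnot(n >= 1, pct_on >= 0, pct_on <= 100)
  n_on <- round(pct_on / 100 * n)
  polarity_count(n_on = n_on, n_off = n - n_on, null_p = null_p)
}
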