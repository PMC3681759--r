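# Nearest point-to-event distance statistics under the masked ("patched")
# complete-spatial-randomness null: Monte Carlo simulation on the neurite
# mask, per-image 95% envelopes and rank p-values, cross-image aggregation.

#' Empirical CDF of a distance sample
#'
#' @param distances non-negative distances (um), at least one.
#' @return list with `cdf` (right-continuous step function), `d50` (smallest
#'   distance at which the CDF reaches 0.5), `mean_um` and `n`.
#' @export
empirical_cdf <- function(distances) {
  if (length(distances) == 0L) stop("empty distance sample")
  stopifnot(all(distances >= 0))
  s <- sort(distances)
  n <- length(s)
  list(cdf = stats::ecdf(s),
       d50 = s[ceiling(n / 2)],
       mean_um = mean(s),
       n = n)
}

#' @rdname empirical_cdf
#' @export
distance_d50 <- function(distances) empirical_cdf(distances)$d50

#' Closed-form nearest-distance CDF under unbounded CSR
#'
#' For a homogeneous Poisson process of intensity `lambda` (events per um2)
#' in the plane, the distance from a fixed point to the nearest event has CDF
#' `G(r) = 1 - exp(-lambda * pi * r^2)`.
#'
#' @param r distances (um), non-negative.
#' @param lambda intensity in events per um2 (>= 0).
#' @return probabilities.
#' @export
csr_closed_form <- function(r, lambda) {
  if (any(r < 0)) stop("r must be non-negative")
  stopifnot(lambda >= 0)
  1 - exp(-lambda * pi * r^2)
}

#' Exact CDF of the distance from a uniform point to the nearest lattice centre
#'
#' Analytic oracle for the uniform-event / fixed-lattice case: the CDF equals
#' the area of the union of radius-`r` disks intersected with one unit cell,
#' over the cell area, computed by circle-segment geometry. For a square
#' lattice the cell is the pitch-sized square (apothem `p/2`, circumradius
#' `p/sqrt(2)`); for a hexagonal lattice the Voronoi hexagon (apothem `p/2`,
#' circumradius `p/sqrt(3)`, area `sqrt(3)/2 p^2`).
#'
#' @param r distances (um).
#' @param geometry `"square"` or `"hexagonal"`.
#' @param pitch_um centre-to-centre distance.
#' @return probabilities, 1 for `r` at or beyond the cell circumradius.
#' @export
lattice_distance_cdf <- function(r, geometry = c("hexagonal", "square"),
                                 pitch_um) {
  geometry <- match.arg(geometry)
  stopifnot(pitch_um > 0, all(r >= 0))
  p <- pitch_um
  d <- p / 2                                  # apothem: distance to cell edge
  if (geometry == "square") {
    n_edge <- 4L; R <- p / sqrt(2); cell <- p^2
  } else {
    n_edge <- 6L; R <- p / sqrt(3); cell <- sqrt(3) / 2 * p^2
  }
  out <- numeric(length(r))
  lo <- r <= d
  mid <- r > d & r < R
  out[lo] <- pi * r[lo]^2 / cell
  if (any(mid)) {
    rm <- r[mid]
    seg <- rm^2 * acos(d / rm) - d * sqrt(rm^2 - d^2)  # one protruding segment
    out[mid] <- (pi * rm^2 - n_edge * seg) / cell
  }
  out[r >= R] <- 1
  pmin(1, pmax(0, out))
}

#' Simulate patched-CSR replicates on a neurite mask
#'
#' Realizes the null model of the analysis: in each replicate, `n_patches`
#' disk centres are placed uniformly at random on the mask (a mask pixel is
#' drawn, then jittered uniformly within it, so placement is
#' continuous-uniform over the mask region) and the exact distance from each
#' centre to the nearest pillar centre is recorded. Replicates are
#' independent and the whole simulation is a pure function of `seed`.
#'
#' @param mask a `neurite_mask` (non-empty).
#' @param n_patches events per replicate (must not exceed the mask pixel
#'   count).
#' @param lattice a `pillar_lattice`.
#' @param n_reps number of replicates (>= 19).
#' @param seed integer seed.
#' @param jitter jitter centres within their pixel (default `TRUE`); turn off
#'   to pin events to pixel centres.
#' @return list of `n_reps` sorted numeric distance vectors.
#' @export
simulate_pcsr <- function(mask, n_patches, lattice, n_reps = 999L, seed = 1,
                          jitter = TRUE) {
  stopifnot(inherits(mask, "neurite_mask"), n_patches >= 1L, n_reps >= 19L)
  idx <- which(mask$mask)
  if (length(idx) == 0L) stop("mask is empty")
  if (n_patches > length(idx))
    stop("n_patches exceeds the mask pixel count")
  px <- mask$pixel_size_um
  set.seed(check_seed(seed))
  total <- n_patches * n_reps
  pick <- idx[sample.int(length(idx), total, replace = TRUE)]
  ii <- ((pick - 1L) %% nrow(mask$mask)) + 1L
  jj <- ((pick - 1L) %/% nrow(mask$mask)) + 1L
  x <- px_centers_um(jj, px)
  y <- px_centers_um(ii, px)
  if (jitter) {
    x <- x + stats::runif(total, -px / 2, px / 2)
    y <- y + stats::runif(total, -px / 2, px / 2)
  }
  d <- nearest_pillar_distances(x, y, lattice)
  lapply(split(d, rep(seq_len(n_reps), each = n_patches)), sort)
}

#' Monte Carlo envelope of the replicate statistic
#'
#' @param replicate_stats numeric vector of per-replicate summary statistics
#'   (e.g. each replicate's d50), length >= 19.
#' @param level envelope coverage in (0.5, 1); default 0.95 gives the 2.5th
#'   and 97.5th percentiles (linear-interpolation percentiles).
#' @return named numeric `c(lower_um, upper_um)`.
#' @export
envelope <- function(replicate_stats, level = 0.95) {
  m <- length(replicate_stats)
  if (m < 19L) stop("need at least 19 replicates for an envelope")
  stopifnot(level > 0.5, level < 1)
  if (m < 2 / (1 - level))
    stop(sprintf("need at least %d replicates for a %.0f%% envelope",
                 ceiling(2 / (1 - level)), 100 * level))
  alpha <- (1 - level) / 2
  q <- stats::quantile(replicate_stats, c(alpha, 1 - alpha),
                       type = 7, names = FALSE)
  c(lower_um = q[1], upper_um = q[2])
}

#' Monte Carlo rank p-value
#'
#' One-sided rank test against the simulated null: for `side = "attraction"`
#' (observed unusually small), `p = (1 + #{replicates <= observed}) /
#' (m + 1)`; for `"repulsion"`, with `>=`. Ties count as exceedances
#' (conservative).
#'
#' @param observed observed summary statistic.
#' @param replicate_stats per-replicate statistics (>= 19).
#' @param side `"attraction"` or `"repulsion"`.
#' @return p-value in (0, 1].
#' @export
mc_pvalue <- function(observed, replicate_stats,
                      side = c("attraction", "repulsion")) {
  side <- match.arg(side)
  m <- length(replicate_stats)
  if (m < 19L) stop("need at least 19 replicates")
  k <- if (side == "attraction") sum(replicate_stats <= observed)
       else sum(replicate_stats >= observed)
  (1 + k) / (m + 1)
}

#' Per-image nearest point-to-event analysis
#'
#' The full per-image inference: observed patch-to-pillar distances and their
#' CDF summary, a patched-CSR simulation with the observed patch count on the
#' observed mask, the 95% envelope of the replicate statistic and both
#' one-sided rank p-values. The summary statistic is the distance at the 50%
#' level of the CDF by default; `statistic = "mean"` switches to the mean
#' distance (both are always reported).
#'
#' @param patches a `patch_set` with at least one patch.
#' @param mask a `neurite_mask`.
#' @param lattice a `pillar_lattice`.
#' @param n_reps Monte Carlo replicates (default 999).
#' @param seed integer seed.
#' @param level envelope coverage (default 0.95).
#' @param statistic `"d50"` (default) or `"mean"`.
#' @return an `envelope_result`: list with `observed_d50`, `observed_mean`,
#'   `lower_um`, `upper_um`, `p_attraction`, `p_repulsion`, `n_reps`,
#'   `n_patches`, `statistic`, and the replicate statistics.
#' @export
analyze_image <- function(patches, mask, lattice, n_reps = 999L, seed = 1,
                          level = 0.95, statistic = c("d50", "mean")) {
  statistic <- match.arg(statistic)
  if (nrow(patches) == 0L) stop("no observed patches")
  obs_d <- nearest_pillar_distances(patches$x_um, patches$y_um, lattice)
  obs <- empirical_cdf(obs_d)
  reps <- simulate_pcsr(mask, n_patches = nrow(patches), lattice = lattice,
                        n_reps = n_reps, seed = seed)
  rep_d50 <- vapply(reps, function(d) d[ceiling(length(d) / 2)], numeric(1))
  rep_mean <- vapply(reps, mean, numeric(1))
  rep_stat <- if (statistic == "d50") rep_d50 else rep_mean
  obs_stat <- if (statistic == "d50") obs$d50 else obs$mean_um
  env <- envelope(rep_stat, level = level)
  structure(
    list(observed_d50 = obs$d50, observed_mean = obs$mean_um,
         observed_stat = obs_stat,
         lower_um = unname(env[1]), upper_um = unname(env[2]),
         p_attraction = mc_pvalue(obs_stat, rep_stat, "attraction"),
         p_repulsion = mc_pvalue(obs_stat, rep_stat, "repulsion"),
         n_reps = length(reps), n_patches = nrow(patches),
         statistic = statistic, level = level,
         replicate_d50 = rep_d50, replicate_mean = rep_mean),
    class = "envelope_result")
}

#' @export
print.envelope_result <- function(x, ...) {
  cat(sprintf(paste0("envelope_result (%s): observed %.4f um, ",
                     "envelope [%.4f, %.4f] um, p_attr %.4g, p_rep %.4g ",
                     "(%d patches, %d reps)\n"),
              x$statistic, x$observed_stat, x$lower_um, x$upper_um,
              x$p_attraction, x$p_repulsion, x$n_patches, x$n_reps))
  invisible(x)
}

#' Aggregate per-image envelope results into a condition-level verdict
#'
#' Envelope borders are random variables; averaging them over the images of
#' one spacing condition estimates their population values. The condition is
#' called "attraction" when the mean observed statistic falls below the mean
#' lower border, "repulsion" when above the mean upper border, and "neutral"
#' otherwise.
#'
#' @param results non-empty list of `envelope_result` objects.
#' @return an `aggregate_result`: `mean_observed_um`, `mean_lower_um`,
#'   `mean_upper_um`, `verdict`, `n_images`, `statistic`.
#' @export
aggregate_condition <- function(results) {
  if (length(results) == 0L) stop("no per-image results to aggregate")
  stopifnot(all(vapply(results, inherits, logical(1), "envelope_result")))
  obs <- mean(vapply(results, `[[`, numeric(1), "observed_stat"))
  lo <- mean(vapply(results, `[[`, numeric(1), "lower_um"))
  hi <- mean(vapply(results, `[[`, numeric(1), "upper_um"))
  verdict <- if (obs < lo) "attraction" else if (obs > hi) "repulsion"
             else "neutral"
  structure(list(mean_observed_um = obs, mean_lower_um = lo,
                 mean_upper_um = hi, verdict = verdict,
                 n_images = length(results),
                 statistic = results[[1]]$statistic),
            class = "aggregate_result")
}

#' @export
print.aggregate_result <- function(x, ...) {
  cat(sprintf("aggregate_result (%d images, %s): observed %.4f um vs [%.4f, %.4f] -> %s\n",
              x$n_images, x$statistic, x$mean_observed_um,
              x$mean_lower_um, x$mean_upper_um, x$verdict))
  invisible(x)
}
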