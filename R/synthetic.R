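# Synthetic-scene generator: neurite masks, punctate patches and polarity
# cohorts with known ground truth, emulating the statistical structure the
# downstream analysis assumes (not the optics of a microscope).

#' Generate a synthetic soma + neurite mask
#'
#' Draws `n_cells` cells, each a disk-shaped soma with a few smooth
#' random-walk neurites (thin tubes) emanating from it, rasterized at
#' `pixel_size_um`. The soma region is kept as a separate raster so it can be
#' excluded from patch statistics, as cell bodies are in the real analysis.
#'
#' @param extent_um field size (height, width) in micrometres.
#' @param n_cells number of cells; 0 yields an empty mask.
#' @param tube_width_um neurite tube width (>= 2 pixels). Default 2 um, a
#'   typical hippocampal neurite calibre at this magnification.
#' @param pixel_size_um micrometres per pixel (default 0.1).
#' @param seed integer seed; the generator is a pure function of it.
#' @param n_neurites_range neurites per cell, sampled uniformly in this range.
#' @param neurite_length_um mean neurite length (exponential lengths are
#'   truncated to at least half this value).
#' @param soma_radius_um soma radius.
#' @param turn_sd_rad std. dev. of the per-step heading change of the walk.
#' @return a `neurite_mask`: list with `mask` (logical, soma excluded),
#'   `soma` (logical), `cell_mask` (soma + neurites), `pixel_size_um`,
#'   `area_um2` (neurite-only area), `soma_centers_um` (data.frame).
#' @export
generate_neurite_mask <- function(extent_um, n_cells, tube_width_um = 2,
                                  pixel_size_um = 0.1, seed = 1,
                                  n_neurites_range = c(2L, 4L),
                                  neurite_length_um = 25,
                                  soma_radius_um = 5,
                                  turn_sd_rad = 0.15) {
  stopifnot(length(extent_um) == 2L, all(extent_um > 0), n_cells >= 0)
  if (tube_width_um < 2 * pixel_size_um)
    stop("tube_width_um must be at least two pixels")
  dim <- c(round(extent_um[1] / pixel_size_um),
           round(extent_um[2] / pixel_size_um))
  set.seed(check_seed(seed))
  soma <- matrix(FALSE, dim[1], dim[2])
  tubes <- matrix(FALSE, dim[1], dim[2])
  soma_xy <- data.frame(x_um = numeric(0), y_um = numeric(0))
  step <- pixel_size_um  # walk step; dense enough to leave no gaps
  path_x <- path_y <- list()
  for (cell in seq_len(n_cells)) {
    sx <- stats::runif(1, soma_radius_um, extent_um[2] - soma_radius_um)
    sy <- stats::runif(1, soma_radius_um, extent_um[1] - soma_radius_um)
    soma_xy <- rbind(soma_xy, data.frame(x_um = sx, y_um = sy))
    n_neur <- sample(n_neurites_range[1]:n_neurites_range[2], 1L)
    for (k in seq_len(n_neur)) {
      len <- max(neurite_length_um / 2, stats::rexp(1, 1 / neurite_length_um))
      n_steps <- max(2L, round(len / step))
      heading <- stats::runif(1, 0, 2 * pi)
      dh <- stats::rnorm(n_steps, 0, turn_sd_rad)
      hs <- heading + cumsum(dh)
      # start at the soma boundary so the tube emanates from the disk edge
      x <- sx + soma_radius_um * cos(heading) + c(0, cumsum(cos(hs) * step))
      y <- sy + soma_radius_um * sin(heading) + c(0, cumsum(sin(hs) * step))
      keep <- x > 0 & x < extent_um[2] & y > 0 & y < extent_um[1]
      if (!any(keep)) next
      path_x[[length(path_x) + 1L]] <- x[keep]
      path_y[[length(path_y) + 1L]] <- y[keep]
    }
  }
  if (n_cells > 0 && length(path_x) > 0) {
    # raster of path points, then dilate to tube width via distance transform
    pj <- pmin(dim[2], pmax(1L, round(um_to_px(unlist(path_x), pixel_size_um))))
    pi_ <- pmin(dim[1], pmax(1L, round(um_to_px(unlist(path_y), pixel_size_um))))
    pts <- matrix(TRUE, dim[1], dim[2])
    pts[cbind(pi_, pj)] <- FALSE           # paths become background ...
    dist_px <- EBImage::distmap(as_image(pts))  # ... so distmap = distance to path
    tubes <- as.matrix(dist_px) <= (tube_width_um / 2) / pixel_size_um
  }
  if (n_cells > 0) {
    soma <- rasterize_disks(dim, soma_xy$x_um, soma_xy$y_um,
                            soma_radius_um, pixel_size_um)
  }
  neurites <- tubes & !soma
  if (n_cells > 0 && !any(neurites))
    stop("generated mask has zero neurite area")
  structure(
    list(mask = neurites, soma = soma, cell_mask = tubes | soma,
         pixel_size_um = pixel_size_um,
         area_um2 = sum(neurites) * pixel_size_um^2,
         soma_centers_um = soma_xy),
    class = "neurite_mask")
}

#' @export
print.neurite_mask <- function(x, ...) {
  cat(sprintf("neurite_mask: %d x %d px at %.3g um/px, neurite area %.1f um2, %d soma(ta)\n",
              nrow(x$mask), ncol(x$mask), x$pixel_size_um, x$area_um2,
              nrow(x$soma_centers_um)))
  invisible(x)
}

#' Describe how synthetic patches are placed on the neurite mask
#'
#' `mode = "pcsr"` is the null model of the analysis: patch centres uniform
#' over the neurite mask (CSR restricted to the mask, "patched CSR"). `mode =
#' "attraction"` is the alternative generator: a fraction `alpha` of centres
#' is drawn with Gaussian weights `exp(-d^2 / (2 sigma^2))` in the
#' nearest-pillar-centre distance `d`, restricted to the mask; the remainder
#' is uniform.
#'
#' @param mode `"pcsr"` or `"attraction"`.
#' @param alpha fraction of biased patches in `[0, 1]`; must be 0 for pcsr.
#' @param sigma_um spread of the bias around pillar centres.
#' @param mean_patch_area_um2 mean patch area; default 0.331 um2, the
#'   typical phosphotyrosine patch size at this magnification.
#' @param density_target target total-patch-area / neurite-area fraction;
#'   default 0.15 (observed densities run ~13-18%).
#' @return a `patch_model` list.
#' @export
patch_model <- function(mode = c("pcsr", "attraction"), alpha = 0,
                        sigma_um = 0.3, mean_patch_area_um2 = 0.331,
                        density_target = 0.15) {
  mode <- match.arg(mode)
  stopifnot(alpha >= 0, alpha <= 1, mean_patch_area_um2 > 0,
            sigma_um > 0, density_target > 0)
  if (mode == "pcsr" && alpha != 0)
    stop("pcsr mode requires alpha = 0")
  if (density_target > 1) stop("density target cannot exceed 1")
  structure(list(mode = mode, alpha = alpha, sigma_um = sigma_um,
                 mean_patch_area_um2 = mean_patch_area_um2,
                 density_target = density_target),
            class = "patch_model")
}

#' Place synthetic punctate patches on a neurite mask
#'
#' Patch count is chosen so that total patch area over neurite area matches
#' the model's density target; individual areas are Gamma-distributed around
#' the model mean (shape 4, mildly right-skewed like observed patch-area
#' histograms). Centres are restricted to mask pixels (with sub-pixel
#' jitter); disks may overhang the mask edge, as observed patches abut
#' neurite boundaries.
#'
#' @param mask a `neurite_mask`.
#' @param lattice a `pillar_lattice` (used only in attraction mode).
#' @param model a [patch_model()].
#' @param seed integer seed.
#' @return a `patch_set` data.frame with columns `x_um`, `y_um`, `area_um2`
#'   and attribute `source = "simulated"`.
#' @export
place_patches <- function(mask, lattice, model, seed = 1) {
  stopifnot(inherits(mask, "neurite_mask"), inherits(model, "patch_model"))
  idx <- which(mask$mask)
  if (length(idx) == 0L) stop("mask is empty")
  px <- mask$pixel_size_um
  n_patches <- max(1L, round(model$density_target * mask$area_um2 /
                               model$mean_patch_area_um2))
  set.seed(check_seed(seed))
  ii <- ((idx - 1L) %% nrow(mask$mask)) + 1L
  jj <- ((idx - 1L) %/% nrow(mask$mask)) + 1L
  n_bias <- round(model$alpha * n_patches)
  n_unif <- n_patches - n_bias
  pick_unif <- sample.int(length(idx), n_unif, replace = TRUE)
  pick <- pick_unif
  if (n_bias > 0) {
    d <- nearest_pillar_distances(px_centers_um(jj, px), px_centers_um(ii, px),
                                  lattice)
    w <- exp(-d^2 / (2 * model$sigma_um^2))
    if (sum(w) <= 0) w <- rep(1, length(w))
    pick <- c(pick, sample.int(length(idx), n_bias, replace = TRUE, prob = w))
  }
  x <- px_centers_um(jj[pick], px) + stats::runif(n_patches, -px / 2, px / 2)
  y <- px_centers_um(ii[pick], px) + stats::runif(n_patches, -px / 2, px / 2)
  areas <- stats::rgamma(n_patches, shape = 4,
                         scale = model$mean_patch_area_um2 / 4)
  patches <- data.frame(x_um = x, y_um = y, area_um2 = areas)
  attr(patches, "source") <- "simulated"
  class(patches) <- c("patch_set", "data.frame")
  patches
}

#' Sample a synthetic ON/OFF polarity cohort
#'
#' Emulates a scored cohort of cells at the flat/pillar interface: a fraction
#' is not yet sufficiently polarized to classify; among the classified, ON
#' counts are Binomial with true ON probability `p_true`.
#'
#' @param n cohort size (> 0).
#' @param p_true true ON probability among classified cells.
#' @param unclassified_fraction expected fraction of unclassifiable cells.
#' @param seed integer seed.
#' @param null_p null ON fraction recorded with the cohort (default 0.5).
#' @return a [polarity_count()].
#' @export
sample_polarity_cohort <- function(n, p_true, unclassified_fraction = 0,
                                   seed = 1, null_p = 0.5) {
  stopifnot(n >= 1, p_true >= 0, p_true <= 1,
            unclassified_fraction >= 0, unclassified_fraction < 1)
  set.seed(check_seed(seed))
  n_uncl <- stats::rbinom(1, n, unclassified_fraction)
  n_class <- n - n_uncl
  n_on <- stats::rbinom(1, n_class, p_true)
  polarity_count(n_on = n_on, n_off = n_class - n_on,
                 n_unclassified = n_uncl, null_p = null_p)
}
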