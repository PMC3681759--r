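# Segmentation of the tubulin (neurite) and punctate-patch channels, soma
# exclusion and patch summary statistics.

#' Build a neurite mask directly from a logical matrix
#'
#' Low-level constructor used when a mask comes from somewhere other than
#' [exclude_somata()] (e.g. a full-frame window for validating the Monte
#' Carlo engine against the closed-form lattice CDF).
#'
#' @param mask logical matrix (the soma-free neurite domain).
#' @param pixel_size_um micrometres per pixel.
#' @param soma optional logical soma matrix (default: none).
#' @return a `neurite_mask`.
#' @export
neurite_mask_from_matrix <- function(mask, pixel_size_um, soma = NULL) {
  stopifnot(is.logical(mask), pixel_size_um > 0)
  if (is.null(soma)) soma <- matrix(FALSE, nrow(mask), ncol(mask))
  stopifnot(identical(dim(soma), dim(mask)))
  structure(list(mask = mask & !soma, soma = soma, cell_mask = mask | soma,
                 pixel_size_um = pixel_size_um,
                 area_um2 = sum(mask & !soma) * pixel_size_um^2,
                 soma_centers_um = data.frame(x_um = numeric(0),
                                              y_um = numeric(0))),
            class = "neurite_mask")
}

#' Segment neurites from the tubulin channel
#'
#' Thresholds the channel and removes specks below `min_object_px` pixels
#' (8-connectivity). An all-background image yields an empty mask, which is
#' valid.
#'
#' @param tubulin numeric image matrix.
#' @param threshold_method `"otsu"` (default) or `"fixed"`.
#' @param fixed_threshold threshold when `threshold_method = "fixed"`.
#' @param min_object_px minimum object size in pixels (default 10).
#' @return logical mask matrix.
#' @export
segment_neurites <- function(tubulin, threshold_method = c("otsu", "fixed"),
                             fixed_threshold = 0.5, min_object_px = 10L) {
  threshold_method <- match.arg(threshold_method)
  stopifnot(length(dim(tubulin)) == 2L, all(dim(tubulin) > 0))
  fg <- tubulin > auto_threshold(tubulin, threshold_method, fixed_threshold)
  if (!any(fg)) return(fg)
  lab <- as.matrix(EBImage::bwlabel(as_image(fg)))
  sz <- tabulate(lab[lab > 0L])
  small <- which(sz < min_object_px)
  if (length(small)) fg[lab %in% small] <- FALSE
  fg
}

#' Exclude cell bodies from a segmented mask
#'
#' Cell bodies bias the patch statistics, so they are cut out before any
#' spatial analysis. A region counts as a soma when its local half-width (the
#' distance-transform maximum) exceeds half of `max_neurite_width_um` and the
#' resulting wide core is larger than `min_soma_area_um2`. The soma is taken
#' to be the wide core dilated back to the cell outline (morphological
#' reconstruction by distance), so the thin neurites attached to it survive.
#'
#' @param mask logical matrix from [segment_neurites()].
#' @param pixel_size_um micrometres per pixel.
#' @param max_neurite_width_um widest structure still considered a neurite
#'   (default 3 um).
#' @param min_soma_area_um2 minimum area of an excluded region (default 20
#'   um2).
#' @return a `neurite_mask` with the somata removed and recorded.
#' @export
exclude_somata <- function(mask, pixel_size_um, max_neurite_width_um = 3,
                           min_soma_area_um2 = 20) {
  stopifnot(is.logical(mask))
  if (!any(mask)) {
    return(structure(list(mask = mask, soma = mask, cell_mask = mask,
                          pixel_size_um = pixel_size_um, area_um2 = 0,
                          soma_centers_um = data.frame(x_um = numeric(0),
                                                       y_um = numeric(0))),
                     class = "neurite_mask"))
  }
  dt_px <- as.matrix(EBImage::distmap(as_image(mask)))
  half_w_px <- (max_neurite_width_um / 2) / pixel_size_um
  core <- dt_px > half_w_px
  soma <- matrix(FALSE, nrow(mask), ncol(mask))
  soma_xy <- data.frame(x_um = numeric(0), y_um = numeric(0))
  if (any(core)) {
    lab <- as.matrix(EBImage::bwlabel(as_image(core)))
    for (l in seq_len(max(lab))) {
      core_px <- which(lab == l)
      # grow the core back out by its own radius to cover the soma disk
      ii <- ((core_px - 1L) %% nrow(mask)) + 1L
      jj <- ((core_px - 1L) %/% nrow(mask)) + 1L
      grow <- rasterize_disks(dim(mask), px_centers_um(jj, pixel_size_um),
                              px_centers_um(ii, pixel_size_um),
                              dt_px[core_px] * pixel_size_um, pixel_size_um)
      region <- grow & mask
      if (sum(region) * pixel_size_um^2 >= min_soma_area_um2) {
        soma <- soma | region
        soma_xy <- rbind(soma_xy,
                         data.frame(x_um = px_centers_um(mean(jj), pixel_size_um),
                                    y_um = px_centers_um(mean(ii), pixel_size_um)))
      }
    }
  }
  neurites <- mask & !soma
  structure(list(mask = neurites, soma = soma, cell_mask = mask,
                 pixel_size_um = pixel_size_um,
                 area_um2 = sum(neurites) * pixel_size_um^2,
                 soma_centers_um = soma_xy),
            class = "neurite_mask")
}

#' Segment punctate patches from the patch channel
#'
#' Connected components above threshold (8-connectivity) with area at least
#' `min_area_um2` are reduced to centroid + area. Touching puncta merged by
#' thresholding become one patch whose area is the sum.
#'
#' @param py_channel numeric image matrix (punctate signal).
#' @param pixel_size_um micrometres per pixel.
#' @param threshold_method `"otsu"` (default) or `"fixed"`.
#' @param fixed_threshold threshold when `threshold_method = "fixed"`.
#' @param min_area_um2 minimum patch area; default two pixels' worth, to
#'   suppress shot noise.
#' @return a `patch_set` data.frame (`x_um`, `y_um`, `area_um2`), attribute
#'   `source = "observed"`; 0 rows for a blank image.
#' @export
segment_patches <- function(py_channel, pixel_size_um,
                            threshold_method = c("otsu", "fixed"),
                            fixed_threshold = 0.5, min_area_um2 = NULL) {
  threshold_method <- match.arg(threshold_method)
  stopifnot(length(dim(py_channel)) == 2L, all(dim(py_channel) > 0))
  if (is.null(min_area_um2)) min_area_um2 <- 2 * pixel_size_um^2
  empty <- data.frame(x_um = numeric(0), y_um = numeric(0),
                      area_um2 = numeric(0))
  attr(empty, "source") <- "observed"
  class(empty) <- c("patch_set", "data.frame")
  fg <- py_channel > auto_threshold(py_channel, threshold_method,
                                    fixed_threshold)
  if (!any(fg)) return(empty)
  lab <- as.matrix(EBImage::bwlabel(as_image(fg)))
  idx <- which(lab > 0L)
  labels <- lab[idx]
  ii <- ((idx - 1L) %% nrow(lab)) + 1L
  jj <- ((idx - 1L) %/% nrow(lab)) + 1L
  npx <- tapply(rep(1L, length(idx)), labels, sum)
  cx <- tapply(jj, labels, mean)
  cy <- tapply(ii, labels, mean)
  area <- as.numeric(npx) * pixel_size_um^2
  keep <- area >= min_area_um2
  out <- data.frame(x_um = px_centers_um(as.numeric(cx), pixel_size_um)[keep],
                    y_um = px_centers_um(as.numeric(cy), pixel_size_um)[keep],
                    area_um2 = area[keep])
  attr(out, "source") <- "observed"
  class(out) <- c("patch_set", "data.frame")
  out
}

#' Mean, SEM and histogram of patch areas
#'
#' @param patches a `patch_set` with at least one patch.
#' @param breaks histogram breaks (um2); default fixed bins of 0.05 um2 up to
#'   the maximum area.
#' @return list with `mean_um2`, `sem_um2` (sd/sqrt(n); 0 for a single
#'   patch), `n` and `histogram` (a [hist()] object, not plotted).
#' @export
patch_area_stats <- function(patches, breaks = NULL) {
  n <- nrow(patches)
  if (is.null(n) || n == 0L) stop("patch set is empty")
  a <- patches$area_um2
  if (is.null(breaks))
    breaks <- seq(0, max(a) + 0.05, by = 0.05)
  list(mean_um2 = mean(a),
       sem_um2 = if (n > 1L) stats::sd(a) / sqrt(n) else 0,
       n = n,
       histogram = graphics::hist(a, breaks = breaks, plot = FALSE))
}

#' Fraction of neurite area covered by patches
#'
#' Patch disks are clipped to the mask before summing, so the result is
#' always in `[0, 1]` even when disks overhang the mask edge.
#'
#' @param patches a `patch_set` (areas are converted to equivalent disks).
#' @param mask a `neurite_mask` with positive area.
#' @return covered fraction in `[0, 1]`.
#' @export
patch_density <- function(patches, mask) {
  stopifnot(inherits(mask, "neurite_mask"))
  if (mask$area_um2 <= 0) stop("mask area must be positive")
  if (nrow(patches) == 0L) return(0)
  px <- mask$pixel_size_um
  clip <- disk_pixels_in_mask(mask$mask, patches$x_um, patches$y_um,
                              sqrt(patches$area_um2 / pi), px)
  # scale each disk's nominal area by its in-mask pixel fraction
  frac <- ifelse(clip$total > 0, clip$inside / clip$total, 0)
  covered <- sum(patches$area_um2 * frac)
  min(1, covered / mask$area_um2)
}
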