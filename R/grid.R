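# Recovering the pillar grid from the substrate-reflectance channel.

#' Detect pillar centres in a reflectance image
#'
#' Thresholds the reflectance channel, labels connected bright components
#' (8-connectivity) and reduces each to its intensity-weighted centroid in
#' micrometres. Components smaller than a fraction of the nominal pillar area
#' are discarded as noise; partially visible edge pillars above that fraction
#' are kept.
#'
#' @param reflectance numeric image matrix.
#' @param pixel_size_um micrometres per pixel.
#' @param threshold_method `"otsu"` (default) or `"fixed"`.
#' @param fixed_threshold threshold value when `threshold_method = "fixed"`.
#' @param nominal_width_um expected pillar diameter; when given, components
#'   with fewer pixels than `min_area_fraction` of the nominal disk area are
#'   dropped.
#' @param min_area_fraction fraction of nominal pillar area below which a
#'   component is treated as noise (default 0.25).
#' @return data.frame with columns `x_um`, `y_um` (possibly 0 rows; a blank
#'   image is not an error).
#' @export
detect_pillars <- function(reflectance, pixel_size_um,
                           threshold_method = c("otsu", "fixed"),
                           fixed_threshold = 0.5,
                           nominal_width_um = NULL,
                           min_area_fraction = 0.25) {
  threshold_method <- match.arg(threshold_method)
  stopifnot(length(dim(reflectance)) == 2L, all(dim(reflectance) > 0))
  th <- auto_threshold(reflectance, threshold_method, fixed_threshold)
  fg <- reflectance > th
  if (!any(fg)) return(data.frame(x_um = numeric(0), y_um = numeric(0)))
  lab <- as.matrix(EBImage::bwlabel(as_image(fg)))
  idx <- which(lab > 0L)
  labels <- lab[idx]
  ii <- ((idx - 1L) %% nrow(lab)) + 1L
  jj <- ((idx - 1L) %/% nrow(lab)) + 1L
  w <- pmax(reflectance[idx], 0)
  w[w == 0] <- .Machine$double.eps
  sz <- tapply(rep(1L, length(idx)), labels, sum)
  cx <- tapply(w * jj, labels, sum) / tapply(w, labels, sum)
  cy <- tapply(w * ii, labels, sum) / tapply(w, labels, sum)
  keep <- rep(TRUE, length(sz))
  if (!is.null(nominal_width_um)) {
    nominal_px <- pi * (nominal_width_um / 2)^2 / pixel_size_um^2
    keep <- sz >= min_area_fraction * nominal_px
  }
  data.frame(x_um = px_centers_um(as.numeric(cx[keep]), pixel_size_um),
             y_um = px_centers_um(as.numeric(cy[keep]), pixel_size_um))
}

#' Fit lattice parameters to detected pillar centres
#'
#' Pitch is the mean nearest-neighbour centre distance. Geometry is
#' classified from the neighbour structure: centres whose neighbours (within
#' 1.3 x pitch) typically number six with 60-degree angular steps are called
#' hexagonal, four with 90-degree steps square; anything else (or fewer than
#' 3 centres) is `"unknown"`. The lattice rotation is the circular median of
#' neighbour angles folded to the lattice's angular period.
#'
#' @param centers data.frame with `x_um`, `y_um` (>= 1 row).
#' @param pixel_size_um carried into the result for downstream stages.
#' @return a `pillar_lattice` with estimated `pitch_um`, `geometry` and
#'   `rotation_deg`.
#' @export
fit_lattice <- function(centers, pixel_size_um = NA_real_) {
  stopifnot(is.data.frame(centers), nrow(centers) >= 1L,
            all(is.finite(centers$x_um)), all(is.finite(centers$y_um)))
  n <- nrow(centers)
  if (n == 1L) {
    return(structure(list(centers = centers, pitch_um = NA_real_,
                          geometry = "unknown", rotation_deg = NA_real_,
                          pixel_size_um = pixel_size_um),
                     class = "pillar_lattice"))
  }
  d <- as.matrix(stats::dist(centers[, c("x_um", "y_um")]))
  diag(d) <- Inf
  nn <- apply(d, 1L, min)
  pitch <- mean(nn)
  geometry <- "unknown"
  rotation <- NA_real_
  if (n >= 3L) {
    counts <- integer(n)
    angles <- list()
    for (i in seq_len(n)) {
      nb <- which(d[i, ] <= 1.3 * pitch)
      counts[i] <- length(nb)
      if (length(nb)) {
        a <- atan2(centers$y_um[nb] - centers$y_um[i],
                   centers$x_um[nb] - centers$x_um[i])
        angles[[length(angles) + 1L]] <- a
      }
    }
    typical <- stats::median(counts)
    if (typical >= 5) geometry <- "hexagonal"
    else if (typical >= 3) geometry <- "square"
    else {
      # sparse view: fall back on the angular step between neighbour bonds
      a <- sort(unique(round(unlist(angles) * 180 / pi) %% 180))
      if (length(a) >= 2) {
        steps <- diff(a)
        geometry <- if (min(abs(steps - 60)) < min(abs(steps - 90)))
          "hexagonal" else "square"
      }
    }
    if (geometry != "unknown") {
      period <- if (geometry == "hexagonal") 60 else 90
      folded <- (unlist(angles) * 180 / pi) %% period
      folded[folded > period / 2] <- folded[folded > period / 2] - period
      rotation <- stats::median(folded)
    }
  }
  structure(list(centers = centers, pitch_um = pitch, geometry = geometry,
                 rotation_deg = rotation, pixel_size_um = pixel_size_um),
            class = "pillar_lattice")
}
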