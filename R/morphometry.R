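# Skeleton-based neurite morphometry: a documented substitute for
# proprietary semi-automated tracing. Lengths are geodesic distances along
# the morphological skeleton, with diagonal steps counting sqrt(2) pixels.

#' @keywords internal
shift_mat <- function(m, di, dj) {
  out <- matrix(FALSE, nrow(m), ncol(m))
  si <- seq_len(nrow(m)) - di
  sj <- seq_len(ncol(m)) - dj
  ok_i <- si >= 1 & si <= nrow(m)
  ok_j <- sj >= 1 & sj <= ncol(m)
  out[ok_i, ok_j] <- m[si[ok_i], sj[ok_j]]
  out
}

#' Morphological thinning (Zhang-Suen) of a binary mask
#'
#' Iteratively peels the mask down to a one-pixel-wide, topology-preserving
#' skeleton.
#'
#' @param mask logical matrix.
#' @return logical skeleton matrix.
#' @export
thin_mask <- function(mask) {
  stopifnot(is.logical(mask))
  m <- mask
  # neighbour order P2..P9: N, NE, E, SE, S, SW, W, NW (rows grow downward)
  offs <- list(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
               c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  repeat {
    changed <- FALSE
    for (phase in 1:2) {
      nb <- lapply(offs, function(o) shift_mat(m, o[1], o[2]))
      B <- Reduce(`+`, nb)
      ring <- c(nb, nb[1])
      A <- Reduce(`+`, lapply(1:8, function(k) !ring[[k]] & ring[[k + 1]]))
      if (phase == 1) {
        c1 <- !(nb[[1]] & nb[[3]] & nb[[5]])   # P2 P4 P6
        c2 <- !(nb[[3]] & nb[[5]] & nb[[7]])   # P4 P6 P8
      } else {
        c1 <- !(nb[[1]] & nb[[3]] & nb[[7]])   # P2 P4 P8
        c2 <- !(nb[[1]] & nb[[5]] & nb[[7]])   # P2 P6 P8
      }
      del <- m & B >= 2 & B <= 6 & A == 1 & c1 & c2
      if (any(del)) {
        m[del] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

#' @keywords internal
skeleton_graph <- function(skel, pixel_size_um) {
  idx <- which(skel)
  if (length(idx) == 0L)
    return(list(g = NULL, idx = integer(0)))
  nr <- nrow(skel)
  pos <- match(idx, idx)  # identity; node k corresponds to pixel idx[k]
  lookup <- integer(length(skel))
  lookup[idx] <- seq_along(idx)
  edges <- integer(0)
  weights <- numeric(0)
  offs <- list(c(1L, 0L, 1), c(0L, 1L, 1), c(1L, 1L, sqrt(2)),
               c(-1L, 1L, sqrt(2)))  # forward half of the 8-neighbourhood
  ii <- ((idx - 1L) %% nr) + 1L
  jj <- ((idx - 1L) %/% nr) + 1L
  for (o in offs) {
    ni <- ii + o[1]; nj <- jj + o[2]
    ok <- ni >= 1 & ni <= nr & nj >= 1 & nj <= ncol(skel)
    nidx <- (nj - 1L) * nr + ni
    ok[ok] <- skel[nidx[ok]]
    if (any(ok)) {
      edges <- c(edges, rbind(lookup[idx[ok]], lookup[nidx[ok]]))
      weights <- c(weights, rep(o[3] * pixel_size_um, sum(ok)))
    }
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges))
    g <- igraph::add_edges(g, edges, weight = weights)
  list(g = g, idx = idx)
}

#' Measure neurite process lengths of segmented cells
#'
#' Each labeled cell region is skeletonized; process lengths are geodesic
#' distances along the skeleton from the soma region (multi-source start at
#' the skeleton pixels inside the soma) to each skeleton tip, so a process's
#' length is measured from the soma boundary to its tip. The longest process
#' corresponds to the axon; the mean is over all root-to-tip paths. A
#' soma-only cell has zero lengths.
#'
#' @param mask logical cell mask (somata included) or a `neurite_mask`.
#' @param soma logical soma mask (ignored when `mask` is a `neurite_mask`).
#' @param pixel_size_um micrometres per pixel (ignored for a
#'   `neurite_mask`).
#' @param min_process_um tips closer than this to the soma are not counted
#'   as processes (default 1 um; suppresses skeletonization whiskers).
#' @return data.frame with one row per soma-bearing cell: `cell_id`,
#'   `longest_um`, `mean_um`, `n_processes`. Mask components without a soma
#'   (detached fragments) are skipped; a mask with no soma at all is an
#'   error.
#' @export
measure_processes <- function(mask, soma = NULL, pixel_size_um = NULL,
                              min_process_um = 1) {
  if (inherits(mask, "neurite_mask")) {
    soma <- mask$soma
    pixel_size_um <- mask$pixel_size_um
    mask <- mask$cell_mask
  }
  stopifnot(is.logical(mask), is.logical(soma), !is.null(pixel_size_um))
  if (!any(mask)) stop("mask is empty")
  if (!any(soma & mask)) stop("mask contains no soma region")
  lab <- as.matrix(EBImage::bwlabel(as_image(mask)))
  out <- data.frame(cell_id = integer(0), longest_um = numeric(0),
                    mean_um = numeric(0), n_processes = integer(0))
  dt_um <- as.matrix(EBImage::distmap(as_image(mask))) * pixel_size_um
  for (l in seq_len(max(lab))) {
    cell <- lab == l
    cell_soma <- cell & soma
    # detached neurite fragments carry no soma; they are debris, not cells
    if (!any(cell_soma)) next
    skel <- thin_mask(cell)
    sg <- skeleton_graph(skel, pixel_size_um)
    lengths <- numeric(0)
    if (!is.null(sg$g) && length(sg$idx) > 1L) {
      in_soma <- cell_soma[sg$idx]
      deg <- igraph::degree(sg$g)
      tips <- which(deg <= 1L & !in_soma)
      sources <- which(in_soma)
      if (length(sources) && length(tips)) {
        dmat <- igraph::distances(sg$g, v = sources, to = tips)
        lengths <- apply(dmat, 2L, min)
        # thinning erodes blunt process ends by about the local half-width;
        # add the distance-transform radius at each tip to compensate
        lengths <- lengths + dt_um[sg$idx[tips]]
        lengths <- lengths[is.finite(lengths) & lengths >= min_process_um]
      }
    }
    out <- rbind(out, data.frame(
      cell_id = l,
      longest_um = if (length(lengths)) max(lengths) else 0,
      mean_um = if (length(lengths)) mean(lengths) else 0,
      n_processes = length(lengths)))
  }
  out
}

#' Growth-cone area from a thresholded tip ROI
#'
#' @param roi numeric image matrix of the growth-cone region of interest.
#' @param pixel_size_um micrometres per pixel.
#' @param threshold_method `"otsu"` (default) or `"fixed"`.
#' @param fixed_threshold threshold when `threshold_method = "fixed"`.
#' @return foreground area in um2; an ROI with no foreground is an error.
#' @export
growthcone_area <- function(roi, pixel_size_um,
                            threshold_method = c("otsu", "fixed"),
                            fixed_threshold = 0.5) {
  threshold_method <- match.arg(threshold_method)
  stopifnot(length(dim(roi)) == 2L, all(dim(roi) > 0))
  fg <- roi > auto_threshold(roi, threshold_method, fixed_threshold)
  if (!any(fg)) stop("ROI contains no foreground")
  sum(fg) * pixel_size_um^2
}
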