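# Internal helpers shared across modules. Raster convention: matrices are
# indexed [row, col] with row -> y and col -> x; the centre of pixel
# [i, j] (1-based) sits at ((j - 0.5) * px, (i - 0.5) * px) in micrometres,
# i.e. 0-based pixel centres at (i + 0.5, j + 0.5) * px.

#' @keywords internal
px_centers_um <- function(idx, pixel_size_um) (idx - 0.5) * pixel_size_um

#' @keywords internal
um_to_px <- function(um, pixel_size_um) um / pixel_size_um + 0.5

#' Rasterize a union of disks onto a logical matrix
#'
#' @param dim integer (nrow, ncol)
#' @param x_um,y_um disk centres in micrometres
#' @param r_um disk radii (recycled)
#' @param pixel_size_um micrometres per pixel
#' @keywords internal
rasterize_disks <- function(dim, x_um, y_um, r_um, pixel_size_um) {
  out <- matrix(FALSE, dim[1], dim[2])
  if (length(x_um) == 0L) return(out)
  r_um <- rep_len(r_um, length(x_um))
  for (k in seq_along(x_um)) {
    r_px <- r_um[k] / pixel_size_um
    ci <- um_to_px(y_um[k], pixel_size_um)  # fractional row
    cj <- um_to_px(x_um[k], pixel_size_um)  # fractional col
    i0 <- max(1L, floor(ci - r_px)); i1 <- min(dim[1], ceiling(ci + r_px))
    j0 <- max(1L, floor(cj - r_px)); j1 <- min(dim[2], ceiling(cj + r_px))
    if (i0 > i1 || j0 > j1) next
    ii <- i0:i1; jj <- j0:j1
    d2 <- outer((ii - ci)^2, (jj - cj)^2, "+")
    out[ii, jj] <- out[ii, jj] | (d2 <= r_px^2)
  }
  out
}

# Count, per disk, how many of its pixels fall inside `mask` and how many it
# has in total (clipping support for patch_density()).
#' @keywords internal
disk_pixels_in_mask <- function(mask, x_um, y_um, r_um, pixel_size_um) {
  dim <- dim(mask)
  r_um <- rep_len(r_um, length(x_um))
  inside <- total <- integer(length(x_um))
  for (k in seq_along(x_um)) {
    r_px <- r_um[k] / pixel_size_um
    ci <- um_to_px(y_um[k], pixel_size_um)
    cj <- um_to_px(x_um[k], pixel_size_um)
    i0 <- max(1L, floor(ci - r_px)); i1 <- min(dim[1], ceiling(ci + r_px))
    j0 <- max(1L, floor(cj - r_px)); j1 <- min(dim[2], ceiling(cj + r_px))
    if (i0 > i1 || j0 > j1) next
    ii <- i0:i1; jj <- j0:j1
    in_disk <- outer((ii - ci)^2, (jj - cj)^2, "+") <= r_px^2
    total[k] <- sum(in_disk)
    inside[k] <- sum(in_disk & mask[ii, jj])
  }
  list(inside = inside, total = total)
}

# Row-wise minimum Euclidean distance from points to a fixed set of sites,
# computed exactly in blocks to bound memory.
#' @keywords internal
min_dist_exact <- function(px, py, sx, sy, block = 2048L) {
  n <- length(px)
  if (n == 0L) return(numeric(0))
  stopifnot(length(sx) >= 1L)
  out <- numeric(n)
  s2 <- sx^2 + sy^2
  for (start in seq(1L, n, by = block)) {
    idx <- start:min(n, start + block - 1L)
    # squared distance matrix |p|^2 - 2 p.s + |s|^2
    d2 <- outer(px[idx]^2 + py[idx]^2, s2, "+") -
      2 * (cbind(px[idx], py[idx]) %*% rbind(sx, sy))
    best <- max.col(-d2, ties.method = "first")
    out[idx] <- sqrt(pmax(0, d2[cbind(seq_along(idx), best)]))
  }
  out
}

#' @keywords internal
as_image <- function(x) {
  if (inherits(x, "Image")) x else EBImage::Image(x)
}

# Otsu threshold that tolerates images outside [0,1] and flat images.
#' @keywords internal
auto_threshold <- function(img, method = c("otsu", "fixed"), fixed = 0.5) {
  method <- match.arg(method)
  if (method == "fixed") return(fixed)
  rng <- range(img, finite = TRUE)
  if (diff(rng) <= 0) return(rng[1])  # flat image: nothing above threshold
  scaled <- (img - rng[1]) / diff(rng)
  th <- EBImage::otsu(as_image(scaled), range = c(0, 1), levels = 256L)
  rng[1] + th * diff(rng)
}

#' @keywords internal
check_seed <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer(seed)
}
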