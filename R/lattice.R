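#' Specify a micropillar lattice
#'
#' Describes the geometry of a microfabricated pillar array: pillar diameter
#' (`width_um`), edge-to-edge gap (`spacing_um`), lattice type, field extent
#' and the x-position of the flat/pillar interface. The centre-to-centre
#' pitch is `width_um + spacing_um`. Fabricated arrays in this line of
#' experiments have widths of roughly 1-5.6 um and spacings of 0.6-15 um;
#' pillars occupy the half-plane `x > border_x_um`, the flat substrate the
#' other half.
#'
#' @param geometry `"hexagonal"` (default) or `"square"`.
#' @param width_um pillar diameter in micrometres (> 0).
#' @param spacing_um edge-to-edge gap in micrometres (> 0).
#' @param extent_um numeric length-2, field size as (height, width) in
#'   micrometres.
#' @param pixel_size_um micrometres per pixel of the associated raster.
#' @param border_x_um x-coordinate of the flat/pillar interface; pillar
#'   centres are generated only at `x > border_x_um`. Use a large negative
#'   value for a field fully covered by pillars.
#' @param rotation_deg rotation of the lattice about the field centre.
#' @return an object of class `lattice_spec`.
#' @export
lattice_spec <- function(geometry = c("hexagonal", "square"),
                         width_um, spacing_um,
                         extent_um, pixel_size_um = 0.1,
                         border_x_um = 0, rotation_deg = 0) {
  geometry <- match.arg(geometry)
  stopifnot(
    is.numeric(width_um), width_um > 0,
    is.numeric(spacing_um), spacing_um > 0,
    length(extent_um) == 2L, all(extent_um > 0),
    pixel_size_um > 0
  )
  pitch <- width_um + spacing_um
  if (pitch < 2 * pixel_size_um)
    stop("pitch (width + spacing) must be at least two pixels")
  structure(
    list(geometry = geometry, width_um = width_um, spacing_um = spacing_um,
         pitch_um = pitch, extent_um = as.numeric(extent_um),
         pixel_size_um = pixel_size_um, border_x_um = border_x_um,
         rotation_deg = rotation_deg),
    class = "lattice_spec")
}

#' Construct the pillar-centre lattice from a specification
#'
#' Generates all pillar centres of the specified lattice that fall inside the
#' field and on the pillar side of the interface (`x > border_x_um`). For a
#' square lattice, centres sit on a grid of pitch `width + spacing`; for a
#' hexagonal lattice, rows are `pitch * sqrt(3)/2` apart with alternate rows
#' offset by half a pitch, so every interior centre has six equidistant
#' neighbours. The first centre is placed half a pitch from the interface and
#' from the field edge.
#'
#' @param spec a [lattice_spec()].
#' @param margin_um optional margin: centres are also generated up to this
#'   distance outside the field (useful when points near the field edge must
#'   see their true nearest centre of the infinite lattice). Default 0.
#' @return a `pillar_lattice`: list with `centers` (data.frame `x_um`,
#'   `y_um`), `pitch_um`, `geometry`, `width_um`, `spacing_um`,
#'   `pixel_size_um`, `border_x_um`, `extent_um`.
#' @export
make_lattice <- function(spec, margin_um = 0) {
  stopifnot(inherits(spec, "lattice_spec"))
  p <- spec$pitch_um
  H <- spec$extent_um[1]; W <- spec$extent_um[2]
  m <- margin_um
  # generous index ranges; rotation handled by rotating candidates about the
  # field centre, then cropping
  span <- max(H, W) + 2 * m + 2 * p
  n_idx <- ceiling(span / p) + 2L
  # x-columns are phased off the interface (first column half a pitch past
  # it) but the index range is anchored to the field, so a far-away border
  # still yields the columns that actually cross the field
  x0 <- spec$border_x_um + p / 2
  k0 <- max(0L, floor((-m - p - x0) / p))
  kk <- k0:(k0 + n_idx)
  if (spec$geometry == "square") {
    cand <- expand.grid(x = x0 + p * kk, y = p / 2 + p * ((-n_idx):n_idx))
  } else {
    h <- p * sqrt(3) / 2
    rows <- (-n_idx):n_idx
    cand <- do.call(rbind, lapply(rows, function(j) {
      off <- if (j %% 2 == 0) 0 else p / 2
      data.frame(x = x0 + off + p * kk, y = p / 2 + h * j)
    }))
  }
  if (spec$rotation_deg != 0) {
    th <- spec$rotation_deg * pi / 180
    cx <- W / 2; cy <- H / 2
    x0 <- cand$x - cx; y0 <- cand$y - cy
    cand$x <- cx + cos(th) * x0 - sin(th) * y0
    cand$y <- cy + sin(th) * x0 + cos(th) * y0
  }
  keep <- cand$x > spec$border_x_um &
    cand$x >= -m & cand$x <= W + m &
    cand$y >= -m & cand$y <= H + m
  centers <- cand[keep, , drop = FALSE]
  if (nrow(centers) == 0L)
    stop("no pillar fits within the extent: empty lattice")
  centers <- centers[order(centers$y, centers$x), , drop = FALSE]
  structure(
    list(centers = data.frame(x_um = centers$x, y_um = centers$y),
         pitch_um = p, geometry = spec$geometry,
         width_um = spec$width_um, spacing_um = spec$spacing_um,
         pixel_size_um = spec$pixel_size_um,
         border_x_um = spec$border_x_um, extent_um = spec$extent_um),
    class = "pillar_lattice")
}

#' @export
print.pillar_lattice <- function(x, ...) {
  cat(sprintf("pillar_lattice: %d centers, %s, pitch %.3g um (W %.3g + S %.3g)\n",
              nrow(x$centers), x$geometry, x$pitch_um,
              x$width_um %||% NA, x$spacing_um %||% NA))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Exact nearest pillar-centre distance for a set of points
#'
#' For each point, the Euclidean distance (in micrometres) to the nearest
#' pillar centre. The search is exact, not approximate: every centre is
#' considered.
#'
#' @param x_um,y_um point coordinates in micrometres.
#' @param lattice a `pillar_lattice` (or any list with a `centers`
#'   data.frame).
#' @return numeric vector of distances, one per point; `numeric(0)` for an
#'   empty point set.
#' @export
nearest_pillar_distances <- function(x_um, y_um, lattice) {
  stopifnot(length(x_um) == length(y_um))
  ctr <- lattice$centers
  if (is.null(ctr) || nrow(ctr) == 0L) stop("lattice has no centers")
  min_dist_exact(x_um, y_um, ctr$x_um, ctr$y_um)
}
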