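# Shared fixture builders: everything is generated in code at test time.

PX <- 0.1  # default pixel size, um/px

fixture_lattice <- function(geometry = "hexagonal", width = 1.6,
                            spacing = 1.2, extent = c(28, 28),
                            px = PX, border = 0, margin = 0) {
  make_lattice(lattice_spec(geometry, width, spacing, extent, px,
                            border_x_um = border), margin_um = margin)
}

full_frame_mask <- function(nrow, ncol, px = PX)
  neurite_mask_from_matrix(matrix(TRUE, nrow, ncol), px)

# one synthetic "image" for the spatial statistics: truth mask + patches
fixture_spatial_image <- function(seed, spacing = 2, width = 1.6,
                                  extent = c(40, 40), alpha = 0,
                                  sigma = 0.3, density = 0.15,
                                  lattice = NULL) {
  if (is.null(lattice))
    lattice <- fixture_lattice(width = width, spacing = spacing,
                               extent = extent)
  mask <- generate_neurite_mask(extent, n_cells = 2, seed = seed)
  model <- if (alpha > 0)
    patch_model("attraction", alpha = alpha, sigma_um = sigma,
                density_target = density)
  else patch_model("pcsr", density_target = density)
  patches <- place_patches(mask, lattice, model, seed = seed + 500000L)
  list(lattice = lattice, mask = mask, patches = patches)
}

# soma disk + straight horizontal tube of given length beyond the soma edge
fixture_straight_cell <- function(length_um = 50, tube_width_um = 1,
                                  soma_radius_um = 3, px = PX) {
  sx <- 10; sy <- 15
  h <- ceiling((sy + soma_radius_um + 5) / px)
  w <- ceiling((sx + soma_radius_um + length_um + 5) / px)
  soma <- pillarpatch:::rasterize_disks(c(h, w), sx, sy, soma_radius_um, px)
  tube <- matrix(FALSE, h, w)
  rows <- which(abs((seq_len(h) - 0.5) * px - sy) <= tube_width_um / 2)
  cols <- which((seq_len(w) - 0.5) * px >= sx &
                  (seq_len(w) - 0.5) * px <= sx + soma_radius_um + length_um)
  tube[rows, cols] <- TRUE
  list(mask = soma | tube, soma = soma, px = px)
}

# soma at a corner with two perpendicular arms of equal length beyond the edge
fixture_y_cell <- function(arm_um = 30, tube_width_um = 1,
                           soma_radius_um = 3, px = PX) {
  s <- 15
  n <- ceiling((s + soma_radius_um + arm_um + 5) / px)
  soma <- pillarpatch:::rasterize_disks(c(n, n), s, s, soma_radius_um, px)
  horiz <- matrix(FALSE, n, n)
  rows <- which(abs((seq_len(n) - 0.5) * px - s) <= tube_width_um / 2)
  cols <- which((seq_len(n) - 0.5) * px >= s &
                  (seq_len(n) - 0.5) * px <= s + soma_radius_um + arm_um)
  horiz[rows, cols] <- TRUE
  vert <- matrix(FALSE, n, n)
  vert[cols, rows] <- TRUE  # same geometry rotated 90 degrees
  list(mask = soma | horiz | vert, soma = soma, px = px)
}
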