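# Rendering synthetic three-channel scenes (substrate reflectance / tubulin /
# punctate patch channel) and their TIFF + JSON ground-truth round trip.

#' Render a synthetic three-channel scene
#'
#' Produces the image triplet the real pipeline consumes: a reflectance
#' channel with bright disks at pillar centres, a tubulin channel equal to
#' the cell mask (soma + neurites), and a patch channel with disks at the
#' patch centroids. Optional additive Gaussian noise; signal amplitude is 1,
#' so `noise_sd = 0.1` corresponds to SNR 10.
#'
#' @param lattice a `pillar_lattice`.
#' @param mask a `neurite_mask`.
#' @param patches a `patch_set`.
#' @param noise_sd additive Gaussian noise SD (0 = noiseless).
#' @param seed integer seed for the noise.
#' @return a `scene_bundle`: list of `reflectance`, `tubulin`, `patch`
#'   matrices plus a `truth` list (`lattice`, `mask`, `patches`, `seed`,
#'   `noise_sd`, `pixel_size_um`).
#' @export
render_scene <- function(lattice, mask, patches, noise_sd = 0, seed = 1) {
  stopifnot(inherits(mask, "neurite_mask"))
  dim <- dim(mask$mask)
  px <- mask$pixel_size_um
  refl <- rasterize_disks(dim, lattice$centers$x_um, lattice$centers$y_um,
                          lattice$width_um / 2, px) * 1.0
  tub <- mask$cell_mask * 1.0
  pat <- rasterize_disks(dim, patches$x_um, patches$y_um,
                         sqrt(patches$area_um2 / pi), px) * 1.0
  if (noise_sd > 0) {
    set.seed(check_seed(seed))
    refl <- refl + stats::rnorm(length(refl), 0, noise_sd)
    tub <- tub + stats::rnorm(length(tub), 0, noise_sd)
    pat <- pat + stats::rnorm(length(pat), 0, noise_sd)
  }
  structure(
    list(reflectance = refl, tubulin = tub, patch = pat,
         truth = list(lattice = lattice, mask = mask, patches = patches,
                      seed = seed, noise_sd = noise_sd, pixel_size_um = px)),
    class = "scene_bundle")
}

#' Write a scene bundle to disk
#'
#' Channels go to a multi-page TIFF (pages: reflectance, tubulin, patch;
#' 16-bit, values clamped to `[0, 1]`); the ground truth to a JSON sidecar
#' (lattice centres and parameters, patch table, seed) and the truth masks to
#' a second two-page TIFF (cell mask, soma mask).
#'
#' @param scene a `scene_bundle`.
#' @param path path of the scene TIFF; the sidecars take the same stem with
#'   `_truth.json` / `_truthmask.tif` suffixes.
#' @return invisibly, the paths written.
#' @export
write_scene <- function(scene, path) {
  stopifnot(inherits(scene, "scene_bundle"))
  clamp <- function(m) { m[] <- pmin(1, pmax(0, m)); m }  # keep dims
  tiff::writeTIFF(lapply(scene[c("reflectance", "tubulin", "patch")], clamp),
                  path, bits.per.sample = 16L)
  stem <- sub("\\.tiff?$", "", path)
  truth_json <- paste0(stem, "_truth.json")
  truth_mask <- paste0(stem, "_truthmask.tif")
  lat <- scene$truth$lattice
  jsonlite::write_json(
    list(pixel_size_um = scene$truth$pixel_size_um,
         noise_sd = scene$truth$noise_sd, seed = scene$truth$seed,
         lattice = list(geometry = lat$geometry, pitch_um = lat$pitch_um,
                        width_um = lat$width_um, spacing_um = lat$spacing_um,
                        border_x_um = lat$border_x_um,
                        centers = lat$centers),
         patches = as.data.frame(scene$truth$patches)),
    truth_json, auto_unbox = TRUE, digits = NA)
  m <- scene$truth$mask
  tiff::writeTIFF(list(m$cell_mask * 1.0, m$soma * 1.0), truth_mask,
                  bits.per.sample = 8L)
  invisible(c(scene = path, truth = truth_json, truth_mask = truth_mask))
}

#' Read a scene TIFF (and, if present, its truth sidecar)
#'
#' @param path path of a scene TIFF written by [write_scene()] or any
#'   three-page TIFF in the same channel order.
#' @param pixel_size_um micrometres per pixel; taken from the sidecar when
#'   one is found next to the TIFF.
#' @return a list with `reflectance`, `tubulin`, `patch`, `pixel_size_um`
#'   and, when available, `truth` (parsed sidecar JSON).
#' @export
read_scene <- function(path, pixel_size_um = NULL) {
  if (!file.exists(path)) stop("cannot read scene TIFF: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) < 3L)
    stop("scene TIFF must have 3 pages (reflectance, tubulin, patch): ", path)
  out <- list(reflectance = pages[[1]], tubulin = pages[[2]],
              patch = pages[[3]])
  stem <- sub("\\.tiff?$", "", path)
  truth_json <- paste0(stem, "_truth.json")
  if (file.exists(truth_json)) {
    out$truth <- jsonlite::read_json(truth_json, simplifyVector = TRUE)
    pixel_size_um <- pixel_size_um %||% out$truth$pixel_size_um
  }
  if (is.null(pixel_size_um))
    stop("pixel_size_um must be given when no truth sidecar exists")
  out$pixel_size_um <- pixel_size_um
  out
}
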