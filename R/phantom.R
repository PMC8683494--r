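#' Specification of the synthetic gyrified phantom
#'
#' The phantom is a two-hemisphere "brain" slab: a white-matter core topped
#' by a gray-matter ribbon of fixed cortical thickness whose upper surface
#' undulates sinusoidally along y (gyri and sulci), a CSF layer above the
#' ribbon, and a CSF-filled interhemispheric fissure splitting left from
#' right at x = 0. Deep gray structures (hippocampus, amygdala, subcortical
#' nuclei, cerebellar gray) are axis-aligned blocks embedded in the white
#' matter. Partial volume at every tissue interface is modeled as a logistic
#' function of signed distance to the interface with width `softness_mm`, so
#' voxels near boundaries carry fractional probabilities as a probabilistic
#' segmentation would produce.
#'
#' @param extent_mm length-3 physical extent (mm) in x (left-right),
#'   y (anterior-posterior), z (inferior-superior).
#' @param voxel_mm isotropic voxel size (mm).
#' @param thickness_mm cortical (gray-matter ribbon) thickness.
#' @param wavelength_mm gyral wavelength of the sinusoidal folding along y.
#' @param amplitude_mm gyral amplitude; 0 gives a flat slab.
#' @param csf_mm thickness of the CSF layer above the cortical surface.
#' @param gap_mm width of the interhemispheric fissure (0 disables it).
#' @param softness_mm logistic partial-volume width on signed distance to
#'   each interface; 0 gives hard binary boundaries.
#' @param surface_z_mm mean height (mm) of the gray/CSF interface.
#' @param edge_margin_mm background margin stripped from each lateral x
#'   edge; 0 lets tissue span the full x extent.
#' @param deep_structures embed the deep gray blocks (hippocampus,
#'   amygdala, subcortical nuclei, cerebellar gray) in the white matter;
#'   FALSE gives the pure ribbon geometry with closed-form tissue volumes.
#' @param seed integer recorded with the spec (the phantom itself is
#'   deterministic; the seed seeds layout jitter in [generate_cohort()]).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(extent_mm = c(100, 100, 80),
                         voxel_mm = 2,
                         thickness_mm = 3,
                         wavelength_mm = 20,
                         amplitude_mm = 6,
                         csf_mm = 6,
                         gap_mm = 4,
                         softness_mm = 1,
                         surface_z_mm = 55,
                         edge_margin_mm = 5,
                         deep_structures = TRUE,
                         seed = 1L) {
  if (thickness_mm <= 0) stop("invalid phantom spec: `thickness_mm` must be > 0")
  if (csf_mm <= 0) stop("invalid phantom spec: `csf_mm` must be > 0")
  if (voxel_mm <= 0) stop("invalid phantom spec: `voxel_mm` must be > 0")
  if (softness_mm < 0) stop("invalid phantom spec: `softness_mm` must be >= 0")
  if (amplitude_mm < 0 || gap_mm < 0 || edge_margin_mm < 0)
    stop("invalid phantom spec: negative geometry parameter")
  if (wavelength_mm <= 0) stop("invalid phantom spec: `wavelength_mm` must be > 0")
  if (surface_z_mm + csf_mm + amplitude_mm >= extent_mm[3])
    stop("invalid phantom spec: surface + CSF exceeds the z extent")
  structure(list(extent_mm = as.numeric(extent_mm), voxel_mm = voxel_mm,
                 thickness_mm = thickness_mm, wavelength_mm = wavelength_mm,
                 amplitude_mm = amplitude_mm, csf_mm = csf_mm,
                 gap_mm = gap_mm, softness_mm = softness_mm,
                 surface_z_mm = surface_z_mm,
                 edge_margin_mm = edge_margin_mm,
                 deep_structures = isTRUE(deep_structures),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Tissue probability volumes
#'
#' Per-voxel probabilities of gray matter, white matter and CSF on a shared
#' grid. Probabilities are each in `[0, 1]` and sum to at most 1 per voxel
#' (the remainder is background).
#'
#' @param grid a [volume_grid()].
#' @param p_gm,p_wm,p_csf 3D probability arrays on `grid`.
#' @return An object of class `tissue_probs`.
#' @export
tissue_probs <- function(grid, p_gm, p_wm, p_csf) {
  for (p in list(p_gm, p_wm, p_csf)) {
    if (!all(dim(p) == grid$dim)) stop("probability map does not match grid")
    if (min(p) < -1e-9 || max(p) > 1 + 1e-9)
      stop("probabilities must lie in [0, 1]")
  }
  s <- p_gm + p_wm + p_csf
  if (max(s) > 1 + 1e-6) stop("tissue probabilities sum to > 1 at some voxel")
  structure(list(grid = grid, p_gm = p_gm, p_wm = p_wm, p_csf = p_csf),
            class = "tissue_probs")
}

#' Atlas label volume with a lookup table
#'
#' @param grid a [volume_grid()].
#' @param label integer 3D array of region ids (0 = unlabeled).
#' @param lut data frame with columns `id`, `name`, `class`; `class` is one
#'   of `"cortical-analysis"`, `"subcortical-excluded"`,
#'   `"cerebellum-excluded"`.
#' @return An object of class `atlas_labels`.
#' @export
atlas_labels <- function(grid, label, lut) {
  if (!all(dim(label) == grid$dim)) stop("label map does not match grid")
  ids <- setdiff(unique(as.integer(label)), 0L)
  if (!all(ids %in% lut$id))
    stop("label map contains region ids missing from the lookup table")
  ok <- lut$class %in% c("cortical-analysis", "subcortical-excluded",
                         "cerebellum-excluded")
  if (!all(ok)) stop("every region must have an exclusion class")
  structure(list(grid = grid, label = label, lut = lut),
            class = "atlas_labels")
}

#' Region ids carrying a given atlas class
#' @param atlas an [atlas_labels()] object.
#' @param classes character vector of region classes to select.
#' @return Integer vector of region ids.
#' @export
atlas_region_ids <- function(atlas, classes = "cortical-analysis") {
  atlas$lut$id[atlas$lut$class %in% classes]
}

#' Exclusion mask (subcortical + cerebellar parcels) of an atlas
#' @param atlas an [atlas_labels()] object (or NULL for no exclusion).
#' @return Logical array, TRUE where coverage must not be counted.
#' @export
atlas_exclusion_mask <- function(atlas) {
  if (is.null(atlas)) return(NULL)
  ids <- atlas_region_ids(atlas, c("subcortical-excluded",
                                   "cerebellum-excluded"))
  array(atlas$label %in% ids, dim = atlas$grid$dim)
}

logistic_step <- function(u, w) {
  if (w == 0) as.numeric(u >= 0) else stats::plogis(u / w)
}

phantom_lut <- function() {
  data.frame(
    id = 1:8,
    name = c("frontal", "temporal", "hippocampus", "amygdala",
             "insula", "cingulate", "subcortical", "cerebellum"),
    class = c(rep("cortical-analysis", 6),
              "subcortical-excluded", "cerebellum-excluded"),
    stringsAsFactors = FALSE)
}

# Deep-structure boxes as fractions of the phantom extent; mirrored across
# the midline. Each row: name, |x| lo/hi, y lo/hi, z lo/hi (fractions).
phantom_deep_boxes <- function() {
  data.frame(
    name = c("hippocampus", "amygdala", "subcortical", "cerebellum"),
    x0 = c(0.14, 0.14, 0.04, 0.05), x1 = c(0.26, 0.26, 0.12, 0.45),
    y0 = c(0.42, 0.28, 0.35, 0.80), y1 = c(0.60, 0.42, 0.65, 0.98),
    z0 = c(0.325, 0.325, 0.30, 0.05), z1 = c(0.475, 0.475, 0.55, 0.30),
    stringsAsFactors = FALSE)
}

#' Height of the gray/CSF interface of a phantom at given y
#' @param spec a [phantom_spec()].
#' @param y numeric vector of y coordinates (mm).
#' @return Interface height z (mm).
#' @export
phantom_surface_z <- function(spec, y) {
  spec$surface_z_mm + spec$amplitude_mm * sin(2 * pi * y / spec$wavelength_mm)
}

#' Crown height (gyral tops) of a phantom
#' @param spec a [phantom_spec()].
#' @return z (mm) of the gyral crowns, where the smoothed surface sits.
#' @export
phantom_crown_z <- function(spec) spec$surface_z_mm + spec$amplitude_mm

#' Generate the gyrified phantom
#'
#' Builds tissue probability volumes, atlas labels and hemisphere masks on a
#' shared grid from a [phantom_spec()]. The construction is deterministic.
#'
#' @param spec a [phantom_spec()].
#' @return List of class `ieeg_phantom` with elements `tissue`
#'   ([tissue_probs()]), `atlas` ([atlas_labels()]), `hemispheres`
#'   (see [split_hemispheres()]) and `spec`.
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) stop("`spec` must be a phantom_spec")
  ext <- spec$extent_mm
  v <- spec$voxel_mm
  dim <- as.integer(round(ext / v))
  grid <- volume_grid(dim, rep(v, 3),
                      c(-ext[1] / 2 + v / 2, v / 2, v / 2))
  ax <- grid_axes(grid)
  x <- ax[[1]]; y <- ax[[2]]; z <- ax[[3]]
  w <- spec$softness_mm

  s_y <- phantom_surface_z(spec, y)           # gray/CSF interface height
  # Interface logistic steps along z, broadcast over (x, y, z)
  Z <- array(rep(z, each = dim[1] * dim[2]), dim)
  S <- array(rep(rep(s_y, each = dim[1]), dim[3]), dim)
  above_wm <- logistic_step(Z - (S - spec$thickness_mm), w)
  above_gm <- logistic_step(Z - S, w)
  above_csf <- logistic_step(Z - (S + spec$csf_mm), w)
  p_wm <- 1 - above_wm
  p_gm <- above_wm - above_gm
  p_csf <- above_gm - above_csf

  # lateral membership: inside the slab but outside the fissure
  X <- array(rep(x, dim[2] * dim[3]), dim)
  xmax <- ext[1] / 2 - spec$edge_margin_mm
  inside_edge <- logistic_step(xmax - abs(X), w)
  in_hemi <- if (spec$gap_mm > 0) {
    logistic_step(abs(X) - spec$gap_mm / 2, w)
  } else array(1, dim)
  # fissure converts brain tissue to CSF; edge margin converts it to
  # background
  p_csf <- (p_csf + (1 - in_hemi) * (p_gm + p_wm)) * inside_edge
  p_gm <- p_gm * in_hemi * inside_edge
  p_wm <- p_wm * in_hemi * inside_edge

  # deep gray blocks: convert white matter to gray matter inside each box
  Y <- array(rep(rep(y, each = dim[1]), dim[3]), dim)
  boxes <- if (spec$deep_structures) phantom_deep_boxes() else
    phantom_deep_boxes()[0, ]
  lut <- phantom_lut()
  label <- array(0L, dim)
  deep_any <- array(FALSE, dim)
  for (b in seq_len(nrow(boxes))) {
    bx <- boxes[b, ]
    inbox <- abs(X) >= bx$x0 * ext[1] & abs(X) <= bx$x1 * ext[1] &
      Y >= bx$y0 * ext[2] & Y <= bx$y1 * ext[2] &
      Z >= bx$z0 * ext[3] & Z <= bx$z1 * ext[3]
    p_gm[inbox] <- p_gm[inbox] + p_wm[inbox]
    p_wm[inbox] <- 0
    id <- lut$id[match(bx$name, lut$name)]
    label[inbox] <- id
    deep_any <- deep_any | inbox
  }

  # cortical parcels: y bands over every remaining tissue voxel
  bands <- c(frontal = 0.30, temporal = 0.55, insula = 0.70, cingulate = 1.01)
  band_id <- c(1L, 2L, 5L, 6L)
  yfrac <- Y / ext[2]
  cortical <- (p_gm + p_wm) > 0.01 & !deep_any
  bidx <- findInterval(yfrac, c(0, bands[-length(bands)]), left.open = FALSE)
  label[cortical] <- band_id[bidx[cortical]]

  tissue <- tissue_probs(grid, pmin(p_gm, 1), pmin(p_wm, 1), pmin(p_csf, 1))
  atlas <- atlas_labels(grid, label, lut)
  hemis <- split_hemispheres(tissue$p_gm, grid, plane_x = 0)
  structure(list(tissue = tissue, atlas = atlas, hemispheres = hemis,
                 spec = spec),
            class = "ieeg_phantom")
}

#' Write phantom volumes to NIfTI files
#'
#' One file per probability map plus the label map, written into `dir` as
#' `<prefix>_gm.nii.gz`, `_wm`, `_csf`, `_atlas`, with the generating seed
#' recorded in `<prefix>_meta.json`.
#'
#' @param phantom an `ieeg_phantom` from [generate_phantom()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return Character vector of the written paths, invisibly.
#' @export
write_phantom <- function(phantom, dir, prefix = "phantom") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- phantom$tissue$grid
  paths <- c(
    gm = file.path(dir, paste0(prefix, "_gm.nii.gz")),
    wm = file.path(dir, paste0(prefix, "_wm.nii.gz")),
    csf = file.path(dir, paste0(prefix, "_csf.nii.gz")),
    atlas = file.path(dir, paste0(prefix, "_atlas.nii.gz")))
  write_volume_nifti(phantom$tissue$p_gm, g, paths["gm"])
  write_volume_nifti(phantom$tissue$p_wm, g, paths["wm"])
  write_volume_nifti(phantom$tissue$p_csf, g, paths["csf"])
  write_volume_nifti(phantom$atlas$label, g, paths["atlas"])
  meta <- file.path(dir, paste0(prefix, "_meta.json"))
  jsonlite::write_json(c(unclass(phantom$spec), list(lut = phantom$atlas$lut)),
                       meta, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, meta = meta))
}
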