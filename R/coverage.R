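#' Radius-of-influence sweep configuration
#'
#' @param radii_mm strictly increasing positive radii (default 1 to 15 mm
#'   in 0.5 mm steps).
#' @param named_mm radii highlighted in summaries and group comparisons
#'   (default 2.5, 5, 10, 15 mm).
#' @return An object of class `roi_sweep_config`.
#' @export
roi_sweep_config <- function(radii_mm = seq(1, 15, by = 0.5),
                             named_mm = c(2.5, 5, 10, 15)) {
  if (any(radii_mm <= 0) || any(diff(radii_mm) <= 0))
    stop("`radii_mm` must be strictly increasing and positive")
  structure(list(radii_mm = radii_mm, named_mm = named_mm),
            class = "roi_sweep_config")
}

#' Spherical RoI mask around a point
#'
#' A voxel belongs to the mask iff its center lies within Euclidean
#' distance `r_mm` of `center`.
#'
#' @param center world position (mm), length 3.
#' @param r_mm sphere radius (mm, > 0).
#' @param grid a [volume_grid()].
#' @return Logical 3D array.
#' @export
sphere_mask <- function(center, r_mm, grid) {
  if (r_mm <= 0) stop("`r_mm` must be > 0")
  d <- .contact_distance_field_cpp(grid$dim, grid$spacing, grid$origin,
                                   matrix(as.numeric(center), 1), r_mm)
  m <- array(d <= r_mm, dim = grid$dim)
  if (!any(m)) warning("sphere lies entirely outside the grid: empty mask")
  m
}

#' Union of boolean volumes on a shared grid
#' @param masks list of logical arrays with identical dimensions.
#' @return Logical array, the voxelwise OR.
#' @export
union_mask <- function(masks) {
  if (!length(masks)) stop("no masks supplied")
  d <- dim(masks[[1]])
  for (m in masks)
    if (!identical(dim(m), d)) stop("masks are not on the same grid")
  Reduce(`|`, masks)
}

#' Probability-weighted tissue volume inside a mask
#'
#' The volume per voxel is multiplied by the probability that the voxel is
#' the tissue of interest and summed over the mask, minus any exclusion
#' region (subcortical/cerebellar parcels are excluded from total
#' gray/white quantification).
#'
#' @param mask logical array.
#' @param prob_map probability array in `[0, 1]` on the same grid.
#' @param grid a [volume_grid()].
#' @param exclusion optional logical array of voxels to discard.
#' @return Weighted volume in mm^3.
#' @export
weighted_volume <- function(mask, prob_map, grid, exclusion = NULL) {
  if (!identical(dim(mask), dim(prob_map)))
    stop("mask and probability map are not on the same grid")
  if (min(prob_map) < -1e-9 || max(prob_map) > 1 + 1e-9)
    stop("probabilities must lie in [0, 1]")
  if (!is.null(exclusion)) mask <- mask & !exclusion
  sum(prob_map[mask]) * voxel_volume(grid)
}

# Effective distance-to-nearest-contact field honoring hemisphere
# restriction of interhemispheric contacts. Returns a numeric array whose
# <= r level sets are exactly the per-radius union RoI masks, so one field
# serves the whole radius sweep.
contact_union_field <- function(electrodes, grid, rmax, hemispheres = NULL) {
  pos <- contact_positions(electrodes)
  inter <- electrodes$interhemispheric
  if (any(inter) && is.null(hemispheres)) {
    warning("interhemispheric contacts present but no hemisphere masks; ",
            "treating them as unrestricted")
    inter <- rep(FALSE, length(inter))
  }
  dfield <- function(centers) {
    if (!nrow(centers)) return(NULL)
    array(.contact_distance_field_cpp(grid$dim, grid$spacing, grid$origin,
                                      centers, rmax), dim = grid$dim)
  }
  d <- dfield(pos[!inter, , drop = FALSE])
  if (is.null(d)) d <- array(Inf, grid$dim)
  if (any(inter)) {
    side <- vapply(which(inter), function(i)
      contact_side(electrodes$x_mm[i], hemispheres), character(1))
    for (s in c("left", "right")) {
      sel <- which(inter)[side == s]
      ds <- dfield(pos[sel, , drop = FALSE])
      if (is.null(ds)) next
      ds[!hemispheres[[s]]] <- Inf
      d <- pmin(d, ds)
    }
  }
  d
}

#' Sweep gray/white matter coverage across RoI radii
#'
#' For each radius the per-patient recording volume is the union of contact
#' spheres (each voxel counted once, however many spheres cover it), with
#' interhemispheric contacts restricted to their hemisphere. Gray and white
#' matter coverage is the probability-weighted volume of that union with
#' subcortical and cerebellar parcels excluded; per-contact coverage is the
#' total divided by the number of contacts.
#'
#' @param electrodes an [electrode_set()] (subdural contacts should already
#'   be projected).
#' @param tissue a [tissue_probs()] object.
#' @param atlas optional [atlas_labels()] supplying the exclusion parcels.
#' @param hemispheres optional hemisphere masks from [split_hemispheres()].
#' @param config a [roi_sweep_config()].
#' @return A `coverage_curve` tibble with columns `patient_id`,
#'   `implant_class`, `radius_mm`, `tissue`, `total_mm3`,
#'   `per_contact_mm3`, `n_contacts`.
#' @export
coverage_sweep <- function(electrodes, tissue, atlas = NULL,
                           hemispheres = NULL,
                           config = roi_sweep_config()) {
  n <- nrow(electrodes)
  if (n == 0) stop("electrode set has zero contacts")
  grid <- tissue$grid
  radii <- config$radii_mm
  d <- contact_union_field(electrodes, grid, max(radii), hemispheres)
  excl <- atlas_exclusion_mask(atlas)
  keep <- if (is.null(excl)) TRUE else !excl
  gm <- tissue$p_gm
  wm <- tissue$p_wm
  vv <- voxel_volume(grid)
  gm_tot <- wm_tot <- numeric(length(radii))
  for (i in seq_along(radii)) {
    m <- (d <= radii[i]) & keep
    gm_tot[i] <- sum(gm[m]) * vv
    wm_tot[i] <- sum(wm[m]) * vv
  }
  out <- tibble(
    patient_id = electrodes$patient_id[1],
    implant_class = implant_class(electrodes),
    radius_mm = rep(radii, 2),
    tissue = rep(c("gm", "wm"), each = length(radii)),
    total_mm3 = c(gm_tot, wm_tot),
    per_contact_mm3 = c(gm_tot, wm_tot) / n,
    n_contacts = n)
  class(out) <- c("coverage_curve", class(out))
  out
}

#' Atlas-region gray-matter coverage at one radius
#'
#' Gray-matter-weighted volume of the union RoI intersected with each
#' analysis parcel (frontal, temporal, hippocampus, amygdala, insula,
#' cingulate on the bundled phantom atlas).
#'
#' @param electrodes an [electrode_set()].
#' @param atlas an [atlas_labels()].
#' @param tissue a [tissue_probs()].
#' @param radius_mm RoI radius (mm, > 0).
#' @param hemispheres optional hemisphere masks.
#' @return Tibble with `patient_id`, `implant_class`, `region_id`,
#'   `region`, `radius_mm`, `gm_mm3`.
#' @export
region_coverage <- function(electrodes, atlas, tissue, radius_mm = 5,
                            hemispheres = NULL) {
  if (radius_mm <= 0) stop("`radius_mm` must be > 0")
  stop_if_grid_mismatch(atlas$grid, tissue$grid)
  d <- contact_union_field(electrodes, tissue$grid, radius_mm, hemispheres)
  m <- d <= radius_mm
  vv <- voxel_volume(tissue$grid)
  ids <- atlas_region_ids(atlas, "cortical-analysis")
  gm <- vapply(ids, function(id)
    sum(tissue$p_gm[m & atlas$label == id]) * vv, numeric(1))
  tibble(patient_id = electrodes$patient_id[1],
         implant_class = implant_class(electrodes),
         region_id = ids,
         region = atlas$lut$name[match(ids, atlas$lut$id)],
         radius_mm = radius_mm,
         gm_mm3 = gm)
}

#' Regional inclusion rule
#'
#' A patient counts as having coverage in a region only when the
#' gray-matter coverage there (at the 5 mm reference radius) exceeds the
#' inclusion threshold; patients without coverage are excluded from that
#' region's group comparison.
#'
#' @param regions output of [region_coverage()] (conventionally at 5 mm).
#' @param threshold_mm3 inclusion threshold (default 0 mm^3: any nonzero
#'   coverage counts).
#' @return The input tibble with a logical `included` column.
#' @export
regional_inclusion <- function(regions, threshold_mm3 = 0) {
  regions$included <- regions$gm_mm3 > threshold_mm3
  regions
}

#' Write coverage curves to a tidy long-format CSV
#'
#' One row per patient x radius x tissue x scope, with columns
#' `patient_id, implant_class, radius_mm, tissue, scope, volume_mm3,
#' n_contacts`.
#'
#' @param curves a `coverage_curve` tibble (rows from one or more patients).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_coverage_csv <- function(curves, path) {
  df <- as.data.frame(curves)
  long <- rbind(
    data.frame(df[c("patient_id", "implant_class", "radius_mm", "tissue")],
               scope = "total", volume_mm3 = df$total_mm3,
               n_contacts = df$n_contacts),
    data.frame(df[c("patient_id", "implant_class", "radius_mm", "tissue")],
               scope = "per_contact", volume_mm3 = df$per_contact_mm3,
               n_contacts = df$n_contacts))
  long <- long[order(long$patient_id, long$tissue, long$scope,
                     long$radius_mm), ]
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' Read a coverage CSV back into a `coverage_curve` tibble
#' @param path CSV written by [write_coverage_csv()].
#' @return A `coverage_curve` tibble (wide total/per-contact columns).
#' @export
read_coverage_csv <- function(path) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  tot <- long[long$scope == "total", ]
  per <- long[long$scope == "per_contact", ]
  key <- function(d) paste(d$patient_id, d$tissue, d$radius_mm)
  per <- per[match(key(tot), key(per)), ]
  out <- tibble(patient_id = tot$patient_id,
                implant_class = tot$implant_class,
                radius_mm = tot$radius_mm, tissue = tot$tissue,
                total_mm3 = tot$volume_mm3,
                per_contact_mm3 = per$volume_mm3,
                n_contacts = tot$n_contacts)
  class(out) <- c("coverage_curve", class(out))
  out
}
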