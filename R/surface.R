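#' Triangular surface mesh in world millimetres
#'
#' @param vertices n x 3 numeric matrix of vertex positions (mm).
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(faces), ncol = 3)
  if (ncol(vertices) != 3) stop("`vertices` must be n x 3")
  if (nrow(faces) && (min(faces) < 1 || max(faces) > nrow(vertices)))
    stop("face indices out of range")
  structure(list(vertices = vertices, faces = faces), class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Check that a mesh is watertight
#'
#' Every undirected edge must be shared by exactly two faces and no face may
#' be degenerate.
#'
#' @param mesh a [surface_mesh()].
#' @return TRUE/FALSE.
#' @export
is_watertight <- function(mesh) {
  f <- mesh$faces
  if (!nrow(f)) return(FALSE)
  if (any(f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3]))
    return(FALSE)
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2L)
}

#' Enclosed volume of a watertight mesh (mm^3)
#' @param mesh a [surface_mesh()] with outward-oriented faces.
#' @return Scalar volume in mm^3 (divergence theorem over signed tetrahedra).
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  det6 <- a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
          a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
          a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
  abs(sum(det6)) / 6
}

#' Extract the smoothed gray-matter surface
#'
#' Thresholds the gray-matter probability map, morphologically closes the
#' binary mask with a spherical structuring element (diameter `kernel_mm`)
#' so that sulci and holes narrower than the kernel are bridged, then
#' extracts the zero level set of the signed distance field with marching
#' tetrahedra. The result is a closed (watertight) mesh suitable for
#' brain-shift projection of subdural contacts.
#'
#' @param p_gm gray-matter probability array.
#' @param grid a [volume_grid()].
#' @param threshold binary threshold on `p_gm`, in (0, 1).
#' @param kernel_mm closing kernel diameter (mm); 0 skips the closing and
#'   iso-surfaces the raw thresholded mask.
#' @return A [surface_mesh()].
#' @export
extract_smooth_surface <- function(p_gm, grid, threshold = 0.5,
                                   kernel_mm = 24) {
  if (threshold <= 0 || threshold >= 1) stop("`threshold` must be in (0, 1)")
  if (kernel_mm < 0) stop("`kernel_mm` must be >= 0")
  mask <- p_gm >= threshold
  if (!any(mask)) stop("no voxels above threshold: empty surface")
  closed <- close_binary(mask, grid, kernel_mm)
  # pad one background layer so the level set closes at the array border
  pdim <- grid$dim + 2L
  pm <- array(FALSE, pdim)
  pm[2:(pdim[1] - 1), 2:(pdim[2] - 1), 2:(pdim[3] - 1)] <- closed
  pgrid <- volume_grid(pdim, grid$spacing, grid$origin - grid$spacing)
  signed <- distance_transform(pm, pgrid) - distance_transform(!pm, pgrid)
  mt <- .marching_tets_cpp(as.numeric(signed), pgrid$dim, pgrid$spacing,
                           pgrid$origin, 0)
  surface_mesh(mt$vertices, mt$faces)
}

#' Hemisphere masks split at a sagittal plane
#'
#' Splits the volume at `plane_x`, hole-fills each side, and (optionally)
#' mean-filters the side indicator with a Gaussian kernel before
#' re-thresholding at 0.5. The default 0.1 mm kernel is far below typical
#' voxel sizes and therefore acts as the identity; it is exposed so the
#' smoothing strength can be raised if needed.
#'
#' @param p_gm gray-matter probability array (defines the grid extent the
#'   masks must cover).
#' @param grid a [volume_grid()].
#' @param plane_x x coordinate (mm) of the midsagittal plane.
#' @param sigma_mm Gaussian kernel width (mm) for mean filtering.
#' @param tie_break hemisphere assigned to voxels exactly on the plane.
#' @return An object of class `hemisphere_masks`: logical arrays `left`,
#'   `right`, plus `grid` and `plane_x`.
#' @export
split_hemispheres <- function(p_gm, grid, plane_x = 0, sigma_mm = 0.1,
                              tie_break = c("left", "right")) {
  tie_break <- match.arg(tie_break)
  ax <- grid_axes(grid)
  xr <- range(ax[[1]])
  if (plane_x < xr[1] || plane_x > xr[2])
    stop("midline plane does not intersect the volume")
  X <- array(rep(ax[[1]], grid$dim[2] * grid$dim[3]), grid$dim)
  left <- X < plane_x | (X == plane_x & tie_break == "left")
  if (sigma_mm > 0) {
    sm <- gaussian_smooth(left * 1, grid, sigma_mm)
    left <- sm > 0.5 | (sm == 0.5 & left)
  }
  left <- fill_holes(left)
  right <- fill_holes(!left)
  right <- right & !left
  structure(list(left = left, right = right, grid = grid, plane_x = plane_x,
                 tie_break = tie_break),
            class = "hemisphere_masks")
}

#' Separable Gaussian smoothing of a 3D volume
#'
#' @param arr numeric 3D array.
#' @param grid a [volume_grid()].
#' @param sigma_mm kernel standard deviation (mm). Kernels narrower than
#'   half a voxel reduce to the identity.
#' @return Smoothed array.
#' @export
gaussian_smooth <- function(arr, grid, sigma_mm) {
  out <- arr
  for (a in 1:3) {
    h <- grid$spacing[a]
    rad <- ceiling(3 * sigma_mm / h)
    if (rad < 1) next
    k <- stats::dnorm(seq(-rad, rad) * h, sd = sigma_mm)
    k <- k / sum(k)
    out <- apply_filter_1d(out, k, a)
  }
  out
}

apply_filter_1d <- function(arr, k, axis) {
  d <- dim(arr)
  rad <- (length(k) - 1) / 2
  out <- array(0, d)
  for (m in seq_along(k)) {
    off <- m - 1 - rad
    src <- pmin(pmax(seq_len(d[axis]) + off, 1), d[axis])  # replicate edges
    idx <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    idx[[axis]] <- src
    out <- out + k[m] * arr[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  }
  out
}

#' Project subdural contacts onto the smoothed gray-matter surface
#'
#' Corrects brain shift by moving every strip/grid contact onto the closed
#' gray-matter surface. The projection direction is the normal of a local
#' plane fitted (principal axes) to the contact and its nearest same-lead
#' neighbors (up to 4 for grids, 2 for strips); where the neighborhood is
#' collinear or too small to define a plane, the contact is moved to the
#' nearest point on the mesh instead. Contacts farther than
#' `max_distance_mm` from the surface are flagged (`projected = FALSE`) and
#' left in place with a warning. Depth contacts are never moved, and the
#' operation is idempotent: a contact already on the surface stays put.
#'
#' @param electrodes an [electrode_set()] containing at least one
#'   strip/grid contact.
#' @param surface a watertight [surface_mesh()].
#' @param max_distance_mm maximum allowed projection distance (default 25).
#' @return The projected [electrode_set()] with original coordinates kept
#'   in `x_orig_mm`, `y_orig_mm`, `z_orig_mm` and a logical `projected`
#'   column.
#' @export
project_surface_contacts <- function(electrodes, surface,
                                     max_distance_mm = 25) {
  sel <- which(electrodes$modality %in% SUBDURAL)
  if (!length(sel)) stop("electrode set contains no strip/grid contacts")
  pos <- contact_positions(electrodes)
  out <- electrodes
  out$x_orig_mm <- pos[, 1]
  out$y_orig_mm <- pos[, 2]
  out$z_orig_mm <- pos[, 3]
  out$projected <- FALSE
  n_flagged <- 0L
  for (i in sel) {
    p <- pos[i, ]
    nb <- lead_neighbors(electrodes, i)
    normal <- local_plane_normal(rbind(p, pos[nb, , drop = FALSE]))
    target <- NULL
    if (!is.null(normal)) {
      hit <- .mesh_line_hit_cpp(p, normal, surface$vertices, surface$faces)
      if (isTRUE(hit$hit) && abs(hit$t) <= max_distance_mm)
        target <- as.numeric(hit$point)
    }
    if (is.null(target)) {
      np <- .mesh_nearest_cpp(matrix(p, 1), surface$vertices, surface$faces)
      if (np$distance[1] <= max_distance_mm) target <- as.numeric(np$points)
    }
    if (is.null(target)) {
      n_flagged <- n_flagged + 1L
    } else {
      out$x_mm[i] <- target[1]
      out$y_mm[i] <- target[2]
      out$z_mm[i] <- target[3]
      out$projected[i] <- TRUE
    }
  }
  if (n_flagged > 0)
    warning(n_flagged, " contact(s) farther than ", max_distance_mm,
            " mm from the surface were flagged and not projected")
  out
}

# indices of the k nearest same-lead contacts (k = 4 for grids, 2 otherwise)
lead_neighbors <- function(electrodes, i) {
  same <- which(electrodes$lead_id == electrodes$lead_id[i])
  same <- setdiff(same, i)
  if (!length(same)) return(integer(0))
  pos <- contact_positions(electrodes)
  d <- sqrt(rowSums(sweep(pos[same, , drop = FALSE], 2, pos[i, ])^2))
  k <- if (electrodes$modality[i] == "grid") 4L else 2L
  same[order(d)][seq_len(min(k, length(same)))]
}

# Normal of the best-fit plane through a point cloud, or NULL when the
# cloud is too small or collinear for the normal to be well defined.
local_plane_normal <- function(pts) {
  if (nrow(pts) < 3) return(NULL)
  cen <- sweep(pts, 2, colMeans(pts))
  ev <- eigen(crossprod(cen), symmetric = TRUE)
  lam <- ev$values
  if (lam[2] < 1e-8 * max(lam[1], 1e-12)) return(NULL)  # collinear
  unit_vec(ev$vectors[, 3])
}

#' Restrict an RoI mask to a contact's hemisphere
#'
#' For interhemispheric subdural contacts, tissue sampling is limited to the
#' hemisphere the contact records from, so the spherical volume cannot pick
#' up tissue across the fissure. Non-interhemispheric contacts pass
#' through unchanged.
#'
#' @param roi_mask logical array on the hemisphere grid.
#' @param contact a single-row [electrode_set()] (or a list with
#'   `interhemispheric` and `x_mm`).
#' @param hemispheres a `hemisphere_masks` object from
#'   [split_hemispheres()].
#' @return The (possibly restricted) logical mask.
#' @export
restrict_hemisphere <- function(roi_mask, contact, hemispheres) {
  if (!isTRUE(contact$interhemispheric[1])) return(roi_mask)
  side <- contact_side(contact$x_mm[1], hemispheres)
  roi_mask & hemispheres[[side]]
}

contact_side <- function(x, hemispheres) {
  if (x < hemispheres$plane_x) return("left")
  if (x > hemispheres$plane_x) return("right")
  message("contact centroid lies exactly on the midline plane; ",
          "assigned to the ", hemispheres$tie_break, " hemisphere")
  hemispheres$tie_break
}

#' Distance from points to a surface mesh
#'
#' @param pts n x 3 matrix of world coordinates (mm).
#' @param mesh a [surface_mesh()].
#' @return Numeric vector of unsigned distances (mm) to the nearest point
#'   on the mesh.
#' @export
mesh_distance <- function(pts, mesh) {
  .mesh_nearest_cpp(matrix(pts, ncol = 3), mesh$vertices,
                    mesh$faces)$distance
}

#' Write a surface mesh as ASCII PLY
#' @param mesh a [surface_mesh()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nrow(mesh$vertices)),
               "property float x", "property float y", "property float z",
               paste("element face", nrow(mesh$faces)),
               "property list uchar int vertex_indices", "end_header"), con)
  utils::write.table(format(mesh$vertices, trim = TRUE, digits = 9), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  utils::write.table(cbind(3L, mesh$faces - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an ASCII PLY surface mesh
#' @param path PLY file path.
#' @return A [surface_mesh()].
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  end <- match("end_header", lines)
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex", lines, value = TRUE)[1]))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face", lines, value = TRUE)[1]))
  vtx <- utils::read.table(text = lines[(end + 1):(end + nv)])
  fc <- utils::read.table(text = lines[(end + nv + 1):(end + nv + nf)])
  surface_mesh(unname(as.matrix(vtx[, 1:3])),
               unname(as.matrix(fc[, 2:4])) + 1L)
}
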