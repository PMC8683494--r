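#' Regular volume grid in world millimetres
#'
#' A `volume_grid` maps 1-based voxel indices to world coordinates of voxel
#' centers: `world = origin + (index - 1) * spacing`, one axis order
#' (x = left/right, y = anterior/posterior, z = inferior/superior)
#' throughout the package. Grids are axis-aligned; the affine is therefore
#' diagonal and always invertible for positive spacings.
#'
#' @param dim integer length-3 voxel counts.
#' @param spacing numeric length-3 voxel size in mm (all > 0).
#' @param origin numeric length-3 world position (mm) of the center of voxel
#'   `(1, 1, 1)`.
#' @return An object of class `volume_grid`.
#' @export
volume_grid <- function(dim, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  dim <- as.integer(dim)
  spacing <- rep_len(as.numeric(spacing), 3L)
  origin <- rep_len(as.numeric(origin), 3L)
  if (length(dim) != 3L || any(dim < 1L))
    stop("`dim` must be three positive integers")
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be positive, got ", paste(spacing, collapse = ", "))
  structure(list(dim = dim, spacing = spacing, origin = origin),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("<volume_grid> %d x %d x %d voxels, %.3g x %.3g x %.3g mm\n",
              x$dim[1], x$dim[2], x$dim[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' Voxel volume of a grid in mm^3
#' @param grid a [volume_grid()].
#' @return Scalar voxel volume (mm^3).
#' @export
voxel_volume <- function(grid) prod(grid$spacing)

#' Voxel-center world coordinates along each axis
#' @param grid a [volume_grid()].
#' @return List of three numeric vectors (x, y, z centers in mm).
#' @export
grid_axes <- function(grid) {
  lapply(1:3, function(a)
    grid$origin[a] + (seq_len(grid$dim[a]) - 1) * grid$spacing[a])
}

#' 4x4 voxel-index (1-based) to world affine of a grid
#' @param grid a [volume_grid()].
#' @return A 4x4 affine matrix.
#' @export
grid_affine <- function(grid) {
  A <- diag(4)
  diag(A)[1:3] <- grid$spacing
  A[1:3, 4] <- grid$origin - grid$spacing
  A
}

world_to_index <- function(grid, xyz) {
  xyz <- matrix(xyz, ncol = 3)
  sweep(sweep(xyz, 2, grid$origin, "-"), 2, grid$spacing, "/") + 1
}

index_to_world <- function(grid, ijk) {
  ijk <- matrix(ijk, ncol = 3)
  sweep(sweep(ijk - 1, 2, grid$spacing, "*"), 2, grid$origin, "+")
}

grid_equal <- function(a, b, tol = 1e-9) {
  all(a$dim == b$dim) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

stop_if_grid_mismatch <- function(a, b) {
  if (!grid_equal(a, b)) stop("volumes are not on the same grid")
}

#' Trilinear interpolation of a volume at world points
#'
#' Values outside the grid are `NA`. If `na_zero` is TRUE, `NA` array
#' entries are treated as 0 (useful for probability maps padded by
#' background).
#'
#' @param arr 3D numeric array on `grid`.
#' @param grid a [volume_grid()].
#' @param pts n x 3 matrix of world coordinates (mm).
#' @param na_zero replace `NA` array values by 0 before interpolating.
#' @return Numeric vector of length n.
#' @export
interp_trilinear <- function(arr, grid, pts, na_zero = FALSE) {
  pts <- matrix(pts, ncol = 3)
  if (na_zero) arr[is.na(arr)] <- 0
  idx <- world_to_index(grid, pts)
  n <- nrow(pts)
  out <- rep(NA_real_, n)
  i0 <- floor(idx)
  fr <- idx - i0
  ok <- idx[, 1] >= 1 & idx[, 1] <= grid$dim[1] &
        idx[, 2] >= 1 & idx[, 2] <= grid$dim[2] &
        idx[, 3] >= 1 & idx[, 3] <= grid$dim[3]
  if (!any(ok)) return(out)
  i0 <- pmin(pmax(i0, 1), matrix(rep(grid$dim - 1L, each = n), ncol = 3))
  fr <- idx - i0
  acc <- numeric(sum(ok))
  i0k <- i0[ok, , drop = FALSE]
  frk <- fr[ok, , drop = FALSE]
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    w <- (if (dx) frk[, 1] else 1 - frk[, 1]) *
         (if (dy) frk[, 2] else 1 - frk[, 2]) *
         (if (dz) frk[, 3] else 1 - frk[, 3])
    acc <- acc + w * arr[cbind(i0k[, 1] + dx, i0k[, 2] + dy, i0k[, 3] + dz)]
  }
  out[ok] <- acc
  out
}

#' Write a volume to NIfTI
#'
#' @param arr 3D array on `grid`.
#' @param grid a [volume_grid()].
#' @param path output file path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume_nifti <- function(arr, grid, path) {
  img <- RNifti::asNifti(arr * 1)
  RNifti::pixdim(img) <- grid$spacing
  # RNifti xforms map 0-based voxel indices to world mm
  aff0 <- grid_affine(grid)
  aff0[1:3, 4] <- grid$origin
  RNifti::qform(img) <- structure(aff0, code = 2L)
  RNifti::sform(img) <- structure(aff0, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume written by this package
#'
#' @param path NIfTI file path.
#' @return List with `arr` (3D array) and `grid` ([volume_grid()]).
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  sp <- abs(diag(aff)[1:3])
  org <- aff[1:3, 4]
  list(arr = array(as.numeric(img), dim = dim(img)),
       grid = volume_grid(dim(img), sp, org))
}

#' Euclidean distance transform of a binary volume
#'
#' Distance (mm) from each voxel center to the nearest TRUE voxel center,
#' honoring anisotropic voxel sizes.
#'
#' @param mask logical 3D array.
#' @param grid a [volume_grid()].
#' @return Numeric array of distances (mm); `Inf` where the mask is empty.
#' @export
distance_transform <- function(mask, grid) {
  d2 <- .edt_squared_cpp(as.logical(mask), grid$dim, grid$spacing)
  sqrt(array(d2, dim = grid$dim))
}

#' Morphological closing of a binary volume with a spherical element
#'
#' Dilation then erosion with a ball of the given diameter, computed from
#' two distance transforms. The volume is padded internally so the closing
#' is not clipped at the array border.
#'
#' @param mask logical 3D array.
#' @param grid a [volume_grid()].
#' @param kernel_mm diameter (mm) of the spherical structuring element;
#'   0 returns the mask unchanged.
#' @return Logical array, a superset of `mask` (closing is extensive).
#' @export
close_binary <- function(mask, grid, kernel_mm) {
  if (kernel_mm < 0) stop("`kernel_mm` must be >= 0")
  if (kernel_mm == 0) return(mask)
  r <- kernel_mm / 2
  pad <- ceiling(r / grid$spacing) + 1L
  pdim <- grid$dim + 2L * pad
  pm <- array(FALSE, pdim)
  ix <- lapply(1:3, function(a) seq.int(pad[a] + 1L, pad[a] + grid$dim[a]))
  pm[ix[[1]], ix[[2]], ix[[3]]] <- mask
  pgrid <- volume_grid(pdim, grid$spacing, grid$origin - pad * grid$spacing)
  dil <- distance_transform(pm, pgrid) <= r
  ero <- distance_transform(!dil, pgrid) > r
  closed <- ero | pm  # guarantee extensivity against voxel-center rounding
  closed[ix[[1]], ix[[2]], ix[[3]]]
}

#' Fill interior holes of a binary volume
#'
#' Background voxels not connected (6-connectivity) to the array border
#' become foreground.
#'
#' @param mask logical 3D array.
#' @return Logical array with interior cavities filled.
#' @export
fill_holes <- function(mask) {
  d <- dim(mask)
  array(.fill_holes_cpp(as.logical(mask), as.integer(d)), dim = d)
}
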