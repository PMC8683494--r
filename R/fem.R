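#' Tissue conductivities for the head model (S/m)
#'
#' Defaults: CSF 1.79, gray matter 0.33, white matter 0.142.
#'
#' @param csf,gm,wm conductivities in S/m, all > 0.
#' @return Named numeric vector of class `conductivity_table`.
#' @export
conductivity_table <- function(csf = 1.79, gm = 0.33, wm = 0.142) {
  v <- c(csf = csf, gm = gm, wm = wm)
  if (any(v <= 0)) stop("conductivities must be > 0")
  structure(v, class = "conductivity_table")
}

#' FEM source configuration
#'
#' @param current_mA injected current (mA, nonzero; default 1 mA).
#' @param ground_fraction fraction of the outer boundary area, taken from
#'   the top (superior, +z), used as the grounded current return
#'   (default 0.05).
#' @param n_sphere_samples points used to sample the reference sphere when
#'   thresholding FEM recording volumes (default 500).
#' @param use_abs average `|V|` (TRUE, default) rather than signed `V` on
#'   the reference sphere.
#' @return An object of class `fem_source_config`.
#' @export
fem_source_config <- function(current_mA = 1, ground_fraction = 0.05,
                              n_sphere_samples = 500, use_abs = TRUE) {
  if (current_mA == 0) stop("`current_mA` must be nonzero")
  if (ground_fraction <= 0 || ground_fraction >= 1)
    stop("`ground_fraction` must be in (0, 1)")
  structure(list(current_mA = current_mA, ground_fraction = ground_fraction,
                 n_sphere_samples = n_sphere_samples, use_abs = use_abs),
            class = "fem_source_config")
}

# Kuhn 6-tet split of a lattice cell; corner bits: 1 = +x, 2 = +y, 4 = +z.
KUHN_TETS <- rbind(c(0, 1, 3, 7), c(0, 2, 3, 7), c(0, 2, 6, 7),
                   c(0, 4, 6, 7), c(0, 4, 5, 7), c(0, 1, 5, 7))

corner_offset <- function(corner) {
  cbind(bitwAnd(corner, 1L),
        bitwAnd(corner, 2L) %/% 2L,
        bitwAnd(corner, 4L) %/% 4L)
}

# P1 stiffness matrix (unit conductivity) and volume of one tet with
# vertex coordinates X (4 x 3).
tet_stiffness <- function(X) {
  M <- cbind(1, X)
  vol <- abs(det(M)) / 6
  G <- solve(M)[2:4, , drop = FALSE]   # rows: d(lambda_j)/d(x,y,z)
  list(K = vol * crossprod(G), vol = vol)
}

#' Build a labeled tetrahedral mesh from tissue probability volumes
#'
#' Nodes form a regular lattice of spacing `edge_mm` over the volume; each
#' lattice cell is split into six tetrahedra (Kuhn subdivision, conforming
#' across cells). Each element is labeled with the majority tissue (CSF,
#' gray, white) at its centroid, interpolated from the probability maps;
#' elements whose centroid is mostly background are dropped, so the mesh
#' boundary follows the outer CSF envelope.
#'
#' @param tissue a [tissue_probs()] object.
#' @param edge_mm target lattice edge length (mm, default 1.5).
#' @return An object of class `tet_mesh` with nodes (mm), 4-column `tets`,
#'   per-element `label` (`csf`/`gm`/`wm`) and lattice bookkeeping used for
#'   interpolation of nodal fields.
#' @export
build_tet_mesh <- function(tissue, edge_mm = 1.5) {
  grid <- tissue$grid
  span <- (grid$dim - 1) * grid$spacing
  nn <- pmax(as.integer(floor(span / edge_mm)) + 1L, 2L)
  h <- edge_mm
  org <- grid$origin
  nx <- nn[1]; ny <- nn[2]; nz <- nn[3]
  nc <- c(nx, ny, nz) - 1L
  cells <- as.matrix(expand.grid(i = 0:(nc[1] - 1), j = 0:(nc[2] - 1),
                                 k = 0:(nc[3] - 1)))
  lin0 <- function(i, j, k) i + j * nx + k * nx * ny  # 0-based lattice index

  tiss_names <- c("csf", "gm", "wm")
  tets_list <- vector("list", 6)
  lab_list <- vector("list", 6)
  type_list <- vector("list", 6)
  Ke <- vector("list", 6)
  for (t in 1:6) {
    off <- corner_offset(KUHN_TETS[t, ])
    X <- off * h
    st <- tet_stiffness(X)
    Ke[[t]] <- st$K
    cen <- org + rep(1, nrow(cells)) %o% (colMeans(off) * h) +
      cells * h
    p <- cbind(
      csf = interp_trilinear(tissue$p_csf, grid, cen, na_zero = TRUE),
      gm = interp_trilinear(tissue$p_gm, grid, cen, na_zero = TRUE),
      wm = interp_trilinear(tissue$p_wm, grid, cen, na_zero = TRUE))
    p[is.na(p)] <- 0
    bg <- pmax(0, 1 - rowSums(p))
    lab <- max.col(cbind(p, bg), ties.method = "first")
    keep <- lab != 4L
    if (!any(keep)) next
    nodes4 <- sapply(1:4, function(m) {
      o <- corner_offset(KUHN_TETS[t, m])
      lin0(cells[, 1] + o[1], cells[, 2] + o[2], cells[, 3] + o[3]) + 1L
    })
    tets_list[[t]] <- nodes4[keep, , drop = FALSE]
    lab_list[[t]] <- tiss_names[lab[keep]]
    type_list[[t]] <- rep(t, sum(keep))
  }
  tets <- do.call(rbind, tets_list)
  if (is.null(tets) || !nrow(tets))
    stop("meshing error: no elements inside the head")
  label <- do.call(c, lab_list)
  type <- do.call(c, type_list)

  used <- sort(unique(as.vector(tets)))
  remap <- rep(NA_integer_, nx * ny * nz)
  remap[used] <- seq_along(used)
  tets <- matrix(remap[tets], ncol = 4)
  id0 <- used - 1L
  nodes <- cbind(org[1] + (id0 %% nx) * h,
                 org[2] + ((id0 %/% nx) %% ny) * h,
                 org[3] + (id0 %/% (nx * ny)) * h)
  structure(list(nodes = nodes, tets = tets, label = label,
                 tet_type = type, Ke = Ke, edge_mm = h, nn = nn,
                 origin = org, node_map = remap),
            class = "tet_mesh")
}

#' @export
print.tet_mesh <- function(x, ...) {
  cat(sprintf("<tet_mesh> %d nodes, %d tets (h = %.2f mm): %s\n",
              nrow(x$nodes), nrow(x$tets), x$edge_mm,
              paste(names(table(x$label)), table(x$label),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' Total and per-tissue mesh volume (mm^3)
#' @param mesh a [build_tet_mesh()] result.
#' @return Named numeric vector of per-tissue volumes plus `total`.
#' @export
tet_mesh_volumes <- function(mesh) {
  vol1 <- abs(det(cbind(1, corner_offset(KUHN_TETS[1, ]) * mesh$edge_mm))) / 6
  v <- tapply(rep(vol1, nrow(mesh$tets)), mesh$label, sum)
  out <- as.numeric(v)
  names(out) <- names(v)
  c(out, total = vol1 * nrow(mesh$tets))
}

mesh_boundary_facets <- function(mesh) {
  t4 <- mesh$tets
  faces <- rbind(t4[, c(1, 2, 3)], t4[, c(1, 2, 4)],
                 t4[, c(1, 3, 4)], t4[, c(2, 3, 4)])
  lo <- pmin(faces[, 1], faces[, 2], faces[, 3])
  hi <- pmax(faces[, 1], faces[, 2], faces[, 3])
  mid <- faces[, 1] + faces[, 2] + faces[, 3] - lo - hi
  key <- paste(lo, mid, hi)
  dup <- key %in% key[duplicated(key)]
  faces[!dup, , drop = FALSE]
}

facet_area_centroid <- function(mesh, facets) {
  a <- mesh$nodes[facets[, 1], , drop = FALSE]
  b <- mesh$nodes[facets[, 2], , drop = FALSE]
  c_ <- mesh$nodes[facets[, 3], , drop = FALSE]
  u <- b - a
  v <- c_ - a
  cr <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
              u[, 3] * v[, 1] - u[, 1] * v[, 3],
              u[, 1] * v[, 2] - u[, 2] * v[, 1])
  list(area = sqrt(rowSums(cr^2)) / 2, cz = (a[, 3] + b[, 3] + c_[, 3]) / 3)
}

#' Solve the quasi-static potential for one contact
#'
#' Solves the conduction equation div(sigma grad V) = 0 with the injected
#' current distributed over the mesh nodes inside the contact's geometric
#' footprint (disc or cylinder approximated by its bounding ball, never
#' smaller than three quarters of an element edge) and V = 0 on the ground
#' region. By default the ground is the top `ground_fraction` of the outer
#' boundary by facet-area quantile along +z, mimicking scalp screws at the
#' vertex; `ground = "boundary_values"` instead fixes every boundary node
#' at values given by `boundary_potential` (used to emulate an infinite
#' medium when validating against the analytic point-source solution).
#'
#' @param mesh a [build_tet_mesh()] result.
#' @param conductivities a [conductivity_table()].
#' @param source a [fem_source_config()].
#' @param contact single-row [electrode_set()] (or list with `x_mm`,
#'   `y_mm`, `z_mm`, `geom_diameter_mm`, `geom_height_mm`, `contact_id`).
#' @param ground `"top"` or `"boundary_values"`.
#' @param boundary_potential function taking an n x 3 coordinate matrix and
#'   returning boundary voltages (required for `"boundary_values"`).
#' @return An object of class `potential_field`: nodal voltages `v` (V),
#'   the lattice array `v_lattice` for interpolation, the ground flux check
#'   and solve metadata.
#' @export
solve_potential <- function(mesh, conductivities = conductivity_table(),
                            source = fem_source_config(), contact,
                            ground = c("top", "boundary_values"),
                            boundary_potential = NULL) {
  ground <- match.arg(ground)
  nN <- nrow(mesh$nodes)
  # mesh lengths are mm: conductivities (S/m) become S/mm so nodal
  # voltages come out in volts
  sigma <- unclass(conductivities)[mesh$label] * 1e-3

  ii <- jj <- xx <- vector("list", 6)
  for (t in 1:6) {
    sel <- which(mesh$tet_type == t)
    if (!length(sel)) next
    t4 <- mesh$tets[sel, , drop = FALSE]
    K <- mesh$Ke[[t]]
    s <- sigma[sel]
    rows <- cols <- vals <- vector("list", 16)
    m <- 1
    for (a in 1:4) for (b in 1:4) {
      rows[[m]] <- t4[, a]
      cols[[m]] <- t4[, b]
      vals[[m]] <- s * K[a, b]
      m <- m + 1
    }
    ii[[t]] <- unlist(rows)
    jj[[t]] <- unlist(cols)
    xx[[t]] <- unlist(vals)
  }
  K <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(nN, nN))

  # Source load: the injected current is distributed over the nodes inside
  # a small ball spanning the contact footprint, with hat (center-peaked)
  # weights. A spherically symmetric source leaves the exterior field of a
  # monopole unchanged while avoiding the anisotropic near-field of a
  # single-node point load on the tetrahedral lattice.
  pos <- c(contact$x_mm[1], contact$y_mm[1], contact$z_mm[1])
  geom_r <- max(contact$geom_diameter_mm[1] / 2,
                if (!is.null(contact$geom_height_mm) &&
                    is.finite(contact$geom_height_mm[1]))
                  contact$geom_height_mm[1] / 2 else 0)
  r_src <- max(geom_r, 1.05 * mesh$edge_mm)
  dn <- sqrt(rowSums(sweep(mesh$nodes, 2, pos)^2))
  src <- which(dn <= r_src)
  if (!length(src)) src <- which.min(dn)
  if (min(dn) > 2 * mesh$edge_mm)
    stop("contact lies outside the mesh")
  I <- source$current_mA * 1e-3
  w <- pmax(1 - dn[src] / (r_src + mesh$edge_mm / 2), 0.05)
  w <- w / sum(w)
  f <- numeric(nN)
  f[src] <- I * w

  # ground (Dirichlet) nodes
  bf <- mesh_boundary_facets(mesh)
  if (ground == "top") {
    fa <- facet_area_centroid(mesh, bf)
    o <- order(fa$cz, decreasing = TRUE)
    n_take <- max(1L, which(cumsum(fa$area[o]) >=
                              source$ground_fraction * sum(fa$area))[1])
    gnodes <- sort(unique(as.vector(bf[o[seq_len(n_take)], ])))
    gvals <- numeric(length(gnodes))
  } else {
    if (is.null(boundary_potential))
      stop("`boundary_potential` required for ground = 'boundary_values'")
    gnodes <- sort(unique(as.vector(bf)))
    gvals <- boundary_potential(mesh$nodes[gnodes, , drop = FALSE])
  }
  if (!length(gnodes)) stop("singular system: empty ground region")

  free <- setdiff(seq_len(nN), gnodes)
  v <- numeric(nN)
  v[gnodes] <- gvals
  rhs <- f[free] - as.numeric(K[free, gnodes, drop = FALSE] %*% gvals)
  Kff <- Matrix::forceSymmetric(K[free, free])
  ch <- Matrix::Cholesky(Kff, LDL = FALSE, super = TRUE)
  v[free] <- as.numeric(Matrix::solve(ch, rhs))

  reaction <- as.numeric(K %*% v - f)
  ground_flux <- sum(reaction[gnodes])

  v_lat <- rep(NA_real_, prod(mesh$nn))
  ok <- !is.na(mesh$node_map)
  v_lat[ok] <- v[mesh$node_map[ok]]
  structure(list(v = v, v_lattice = array(v_lat, mesh$nn), mesh = mesh,
                 contact_id = contact$contact_id[1], current_A = I,
                 ground_nodes = gnodes, ground_flux = ground_flux,
                 source_nodes = src),
            class = "potential_field")
}

#' Interpolate a potential field at world points
#' @param field a [solve_potential()] result.
#' @param pts n x 3 world coordinates (mm).
#' @return Voltages (V); `NA` outside the meshed head.
#' @export
interp_potential <- function(field, pts) {
  m <- field$mesh
  g <- volume_grid(m$nn, rep(m$edge_mm, 3), m$origin)
  interp_trilinear(field$v_lattice, g, pts)
}

fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' FEM-based recording volume at a nominal radius
#'
#' The voltage threshold is the mean of `|V|` (or signed `V`) sampled over
#' the radius-`r_mm` sphere around the contact center; the recording volume
#' is every voxel whose interpolated `|V|` reaches that threshold. In a
#' homogeneous medium the equipotentials are spheres and this reproduces
#' the spherical RoI; conductivity contrasts (notably CSF) deform it.
#'
#' @param field a [solve_potential()] result.
#' @param center contact center (mm).
#' @param r_mm nominal radius (mm, > 0).
#' @param grid sampling [volume_grid()] for the voxelized volume.
#' @param n_samples sphere sample count (default 500).
#' @param use_abs threshold on `|V|` (default TRUE).
#' @return An object of class `fem_volume`: logical `mask` on `grid`,
#'   `threshold_v`, `r_mm`.
#' @export
fem_volume <- function(field, center, r_mm, grid,
                       n_samples = 500, use_abs = TRUE) {
  if (r_mm <= 0) stop("`r_mm` must be > 0")
  dirs <- fibonacci_sphere(n_samples)
  pts <- sweep(dirs * r_mm, 2, as.numeric(center), "+")
  vs <- interp_potential(field, pts)
  dropped <- mean(is.na(vs))
  if (dropped > 0.2)
    warning(sprintf("%.0f%% of sphere samples fall outside the mesh",
                    100 * dropped))
  vs <- vs[!is.na(vs)]
  if (!length(vs)) stop("reference sphere lies entirely outside the mesh")
  if (use_abs) vs <- abs(vs)
  thr <- mean(vs)
  ax <- grid_axes(grid)
  cen <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))
  vv <- interp_potential(field, cen)
  if (use_abs) vv <- abs(vv)
  mask <- array(!is.na(vv) & vv >= thr, dim = grid$dim)
  structure(list(mask = mask, threshold_v = thr, r_mm = r_mm, grid = grid),
            class = "fem_volume")
}

#' Dice volumetric overlap coefficient
#'
#' `2|A intersect B| / (|A| + |B|)`, in `[0, 1]`.
#'
#' @param a,b logical arrays on the same grid (or `fem_volume` objects).
#' @return Dice coefficient.
#' @export
dice <- function(a, b) {
  if (inherits(a, "fem_volume")) a <- a$mask
  if (inherits(b, "fem_volume")) b <- b$mask
  if (!identical(dim(a), dim(b))) stop("masks are not on the same grid")
  sa <- sum(a)
  sb <- sum(b)
  if (sa + sb == 0) stop("Dice undefined: both masks are empty")
  2 * sum(a & b) / (sa + sb)
}

#' Compare spherical and FEM recording volumes contact by contact
#'
#' For each contact and nominal radius, computes gray-matter coverage under
#' the spherical RoI and under the FEM-based volume, plus their Dice
#' overlap.
#'
#' @param electrodes an [electrode_set()].
#' @param tissue a [tissue_probs()].
#' @param fields named list of [solve_potential()] results keyed by
#'   `contact_id` (one per contact).
#' @param radii_mm nominal radii (default 2.5, 5, 10, 15 mm).
#' @param atlas optional [atlas_labels()] for the exclusion parcels.
#' @return Tibble with `contact_id`, `modality`, `radius_mm`,
#'   `sphere_gm_mm3`, `fem_gm_mm3`, `dice`, `threshold_v`.
#' @export
fem_coverage_compare <- function(electrodes, tissue, fields,
                                 radii_mm = c(2.5, 5, 10, 15),
                                 atlas = NULL) {
  grid <- tissue$grid
  excl <- atlas_exclusion_mask(atlas)
  rows <- list()
  for (i in seq_len(nrow(electrodes))) {
    cid <- electrodes$contact_id[i]
    field <- fields[[cid]]
    if (is.null(field)) stop("missing potential field for contact ", cid)
    cen <- as.numeric(electrodes[i, c("x_mm", "y_mm", "z_mm")])
    for (r in radii_mm) {
      sph <- sphere_mask(cen, r, grid)
      fv <- fem_volume(field, cen, r, grid)
      rows[[length(rows) + 1]] <- tibble(
        contact_id = cid, modality = electrodes$modality[i], radius_mm = r,
        sphere_gm_mm3 = weighted_volume(sph, tissue$p_gm, grid, excl),
        fem_gm_mm3 = weighted_volume(fv$mask, tissue$p_gm, grid, excl),
        dice = dice(sph, fv$mask),
        threshold_v = fv$threshold_v)
    }
  }
  dplyr::bind_rows(rows)
}

#' Uniform single-tissue cube, mainly for model validation
#'
#' @param size_mm cube edge length (mm).
#' @param voxel_mm voxel size (mm).
#' @param tissue which tissue fills the cube (`"gm"`, `"wm"` or `"csf"`).
#' @param centered center the cube on the origin (default TRUE).
#' @return A [tissue_probs()] object.
#' @export
uniform_tissue_cube <- function(size_mm, voxel_mm = 1, tissue = "gm",
                                centered = TRUE) {
  n <- as.integer(round(size_mm / voxel_mm))
  org <- if (centered) rep(-size_mm / 2 + voxel_mm / 2, 3) else rep(voxel_mm / 2, 3)
  g <- volume_grid(rep(n, 3), rep(voxel_mm, 3), org)
  one <- array(1, g$dim)
  zero <- array(0, g$dim)
  tissue_probs(g,
               p_gm = if (tissue == "gm") one else zero,
               p_wm = if (tissue == "wm") one else zero,
               p_csf = if (tissue == "csf") one else zero)
}
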