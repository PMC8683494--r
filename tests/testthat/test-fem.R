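# The FEM checks share one homogeneous solve: a 40 mm gray-matter cube at
# 1.5 mm edges with the analytic monopole potential imposed on the outer
# boundary, which emulates an infinite medium so the interior solution can
# be compared against V = I / (4 pi sigma r).
SIGMA_GM <- 0.33
I_A <- 1e-3
monopole <- function(p)
  I_A / (4 * pi * SIGMA_GM * pmax(sqrt(rowSums(p^2)), 1e-9) * 1e-3)

center_contact <- function(z = 0, modality = "depth") {
  electrode_set(data.frame(contact_id = "c1", lead_id = "l1",
                           modality = modality, x_mm = 0, y_mm = 0,
                           z_mm = z), "pt")
}

hom_cache <- new.env()
hom_solve <- function() {
  if (is.null(hom_cache$field)) {
    tis <- uniform_tissue_cube(40, voxel_mm = 2, tissue = "gm")
    mesh <- build_tet_mesh(tis, edge_mm = 1.5)
    hom_cache$field <- solve_potential(
      mesh, contact = center_contact()[1, ], ground = "boundary_values",
      boundary_potential = monopole)
  }
  hom_cache$field
}

test_that("tet mesh volume and refinement behave as expected", {
  tis <- uniform_tissue_cube(24, voxel_mm = 2, tissue = "gm")
  mesh <- build_tet_mesh(tis, edge_mm = 2)
  vols <- tet_mesh_volumes(mesh)
  # lattice spans the voxel-center bounding box of the 24 mm cube
  expect_equal(unname(vols["total"]), 22^3, tolerance = 0.01)
  expect_true(all(mesh$label == "gm"))
  finer <- build_tet_mesh(tis, edge_mm = 1)
  expect_gt(nrow(finer$tets), nrow(mesh$tets))
})

test_that("three-layer slab meshes with per-tissue volumes within 5%", {
  g <- volume_grid(c(21, 21, 21), c(1.5, 1.5, 1.5), c(0, 0, 0))
  ax <- grid_axes(g)
  Z <- array(rep(ax[[3]], each = 21 * 21), g$dim)
  tis <- tissue_probs(g, p_gm = (Z > 9 & Z <= 21) * 1,
                      p_wm = (Z <= 9) * 1, p_csf = (Z > 21) * 1)
  mesh <- build_tet_mesh(tis, edge_mm = 1.5)
  vols <- tet_mesh_volumes(mesh)
  span <- 30  # node lattice spans 0..30 mm in each axis
  expect_equal(unname(vols["wm"]) / (span^2 * 9.75), 1, tolerance = 0.05)
  expect_equal(unname(vols["gm"]) / (span^2 * 12), 1, tolerance = 0.05)
  expect_equal(unname(vols["csf"]) / (span^2 * 8.25), 1, tolerance = 0.05)
})

test_that("homogeneous solve matches the analytic monopole within 10%", {
  f <- hom_solve()
  for (r in c(2.5, 5, 10)) {
    pts <- rbind(c(r, 0, 0), c(-r, 0, 0), c(0, r, 0), c(0, -r, 0),
                 c(0, 0, r), c(0, 0, -r))
    v <- mean(interp_potential(f, pts))
    # r in mm converts to meters; at 5 mm this is the familiar 48.2 mV
    expect_equal(v, I_A / (4 * pi * SIGMA_GM * r * 1e-3), tolerance = 0.10)
  }
})

test_that("the discrete solution conserves the injected current", {
  f <- hom_solve()
  expect_equal(f$ground_flux, -f$current_A, tolerance = 1e-9)
})

test_that("the potential is linear in the injected current", {
  tis <- uniform_tissue_cube(24, voxel_mm = 2, tissue = "gm")
  mesh <- build_tet_mesh(tis, edge_mm = 2)
  f1 <- solve_potential(mesh, contact = center_contact()[1, ],
                        source = fem_source_config(current_mA = 1))
  f2 <- solve_potential(mesh, contact = center_contact()[1, ],
                        source = fem_source_config(current_mA = 2))
  expect_equal(f2$v, 2 * f1$v, tolerance = 1e-9)
})

test_that("refining the mesh changes probe potentials by less than 5%", {
  tis <- uniform_tissue_cube(30, voxel_mm = 1.5, tissue = "gm")
  coarse <- build_tet_mesh(tis, edge_mm = 3)
  fine <- build_tet_mesh(tis, edge_mm = 1.5)
  fc <- solve_potential(coarse, contact = center_contact()[1, ],
                        ground = "boundary_values",
                        boundary_potential = monopole)
  ff <- solve_potential(fine, contact = center_contact()[1, ],
                        ground = "boundary_values",
                        boundary_potential = monopole)
  probes <- rbind(c(6, 0, 0), c(0, 6, 0), c(0, 0, -6), c(-4.5, 4.5, 0))
  vc <- interp_potential(fc, probes)
  vf <- interp_potential(ff, probes)
  expect_true(all(abs(vc - vf) / abs(vf) < 0.05))
})

test_that("FEM volumes nest, shrink their threshold, and match spheres", {
  f <- hom_solve()
  g <- volume_grid(c(33, 33, 33), c(1, 1, 1), c(-16, -16, -16))
  fv <- lapply(c(2.5, 5, 10), function(r)
    fem_volume(f, c(0, 0, 0), r, g))
  thr <- vapply(fv, `[[`, numeric(1), "threshold_v")
  expect_true(all(diff(thr) < 0))            # threshold decays with radius
  expect_true(all(fv[[3]]$mask[fv[[1]]$mask]))  # nesting
  for (i in seq_along(fv)) {
    s <- sphere_mask(c(0, 0, 0), fv[[i]]$r_mm, g)
    expect_gte(dice(fv[[i]]$mask, s), 0.9)
  }
})

test_that("Dice obeys identity, range, symmetry and translation", {
  g <- volume_grid(c(20, 20, 20), c(1, 1, 1))
  a <- sphere_mask(c(8, 8, 8), 4, g)
  b <- sphere_mask(c(12, 10, 9), 4, g)
  expect_equal(dice(a, a), 1)
  expect_equal(dice(a, b), dice(b, a))
  disjoint <- sphere_mask(c(16, 16, 16), 2, g)
  expect_equal(dice(a, disjoint), 0)
  # A inside B with |B| = 2|A| gives 2/3 (use synthetic index masks)
  A <- array(FALSE, c(10, 10, 10)); A[1:100] <- TRUE
  B <- array(FALSE, c(10, 10, 10)); B[1:200] <- TRUE
  expect_equal(dice(A, B), 2 / 3)
  # translating both masks together leaves Dice unchanged
  g2 <- volume_grid(c(20, 20, 20), c(1, 1, 1), c(3, -2, 5))
  a2 <- sphere_mask(c(8, 8, 8) + c(3, -2, 5), 4, g2)
  b2 <- sphere_mask(c(12, 10, 9) + c(3, -2, 5), 4, g2)
  expect_equal(dice(a2, b2), dice(a, b))
  expect_error(dice(A & FALSE, B & FALSE), "empty")
})

test_that("a conductive CSF layer deforms the recording volume", {
  mk_layer <- function() {
    g <- volume_grid(c(29, 29, 29), c(1.5, 1.5, 1.5), c(-21, -21, -21))
    ax <- grid_axes(g)
    Z <- array(rep(ax[[3]], each = 29 * 29), g$dim)
    tissue_probs(g, p_gm = (Z <= 7 & Z > -14) * 1, p_wm = (Z <= -14) * 1,
                 p_csf = (Z > 7) * 1)
  }
  tis <- mk_layer()
  mesh <- build_tet_mesh(tis, 1.5)
  ct <- center_contact(z = 5.5, modality = "strip")
  f_het <- solve_potential(mesh, contact = ct[1, ])
  tis_h <- uniform_tissue_cube(42, 1.5, "gm")
  mesh_h <- build_tet_mesh(tis_h, 1.5)
  f_hom <- solve_potential(mesh_h, contact = ct[1, ])
  g <- volume_grid(c(31, 31, 31), c(1, 1, 1), c(-15, -15, -9.5))
  s <- sphere_mask(c(0, 0, 5.5), 5, g)
  d_het <- dice(fem_volume(f_het, c(0, 0, 5.5), 5, g)$mask, s)
  d_hom <- dice(fem_volume(f_hom, c(0, 0, 5.5), 5, g)$mask, s)
  expect_lt(d_het, d_hom)
})

test_that("fem_coverage_compare pairs spherical and FEM coverage", {
  tis <- uniform_tissue_cube(40, voxel_mm = 2, tissue = "gm")
  mesh <- build_tet_mesh(tis, edge_mm = 2)
  es <- center_contact()
  fields <- list(c1 = solve_potential(mesh, contact = es[1, ],
                                      ground = "boundary_values",
                                      boundary_potential = monopole))
  cmp <- fem_coverage_compare(es, tis, fields, radii_mm = c(2.5, 5))
  expect_equal(nrow(cmp), 2)
  expect_true(all(cmp$dice >= 0 & cmp$dice <= 1))
  # homogeneous medium: FEM and spherical coverage agree within 10%
  expect_true(all(abs(cmp$fem_gm_mm3 / cmp$sphere_gm_mm3 - 1) <= 0.10))
  expect_error(fem_coverage_compare(es, tis, list(), c(5)), "missing")
})
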