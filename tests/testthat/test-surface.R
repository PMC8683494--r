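test_that("smoothed surface of a slab is watertight and encloses it", {
  sp <- phantom_spec(extent_mm = c(40, 40, 30), voxel_mm = 1,
                     amplitude_mm = 0, softness_mm = 0, gap_mm = 0,
                     edge_margin_mm = 0, surface_z_mm = 18, csf_mm = 4,
                     deep_structures = FALSE)
  ph <- generate_phantom(sp)
  surf <- extract_smooth_surface(ph$tissue$p_gm, ph$tissue$grid,
                                 kernel_mm = 24)
  expect_true(is_watertight(surf))
  slab_vol <- sum(ph$tissue$p_gm >= 0.5)  # mm^3 at 1 mm voxels
  # closing is extensive: the enclosed volume matches the slab up to the
  # sub-voxel rounding of its corners and edges by the level set
  expect_gte(mesh_volume(surf), 0.98 * slab_vol)
  expect_error(extract_smooth_surface(array(0, c(4, 4, 4)),
                                      volume_grid(c(4, 4, 4))),
               "empty surface")
})

test_that("kernel 0 surfaces the raw thresholded mask", {
  sp <- phantom_spec(extent_mm = c(30, 30, 24), voxel_mm = 1,
                     amplitude_mm = 0, softness_mm = 0, gap_mm = 0,
                     edge_margin_mm = 0, surface_z_mm = 14, csf_mm = 4,
                     deep_structures = FALSE)
  ph <- generate_phantom(sp)
  s0 <- extract_smooth_surface(ph$tissue$p_gm, ph$tissue$grid, kernel_mm = 0)
  expect_true(is_watertight(s0))
  # GM slab is 30 x 30 x 3 mm; the level set traces its geometric boundary
  # (midway between inside and outside voxel centers), rounding corners by
  # less than a voxel
  expect_equal(mesh_volume(s0), 30 * 30 * 3, tolerance = 0.02)
})

test_that("closing with a 24 mm kernel bridges sulcal slits", {
  g <- volume_grid(c(40, 30, 20), c(1, 1, 1))
  mask <- array(FALSE, g$dim)
  mask[4:37, 4:27, 4:12] <- TRUE
  mask[16:25, , 7:20] <- FALSE   # 10 mm-wide slit cut into the top
  closed <- close_binary(mask, g, 24)
  # the slit is recovered everywhere below its mouth; the closing ball
  # sags into the opening by r - sqrt(r^2 - (w/2)^2) ~ 1.1 mm, so only the
  # top layers can stay open
  expect_true(all(closed[mask]))
  expect_true(all(closed[16:25, 8:23, 7:10]))  # away from the slab edges
  # a slit much narrower than the kernel is bridged to within one voxel
  # (0.5 mm voxels keep the geometric sag below the voxel size)
  g2 <- volume_grid(c(80, 48, 40), c(0.5, 0.5, 0.5))
  mask6 <- array(FALSE, g2$dim)
  mask6[7:74, 7:42, 7:24] <- TRUE  # slab, top boundary at z = 11.75 mm
  mask6[34:45, , 13:40] <- FALSE   # 6 mm-wide slit
  surf <- extract_smooth_surface(array(as.numeric(mask6), g2$dim) * 0.9, g2,
                                 threshold = 0.5, kernel_mm = 24)
  in_slit <- surf$vertices[, 1] > 17 & surf$vertices[, 1] < 21.5 &
    surf$vertices[, 2] > 5 & surf$vertices[, 2] < 18 &
    surf$vertices[, 3] > 8
  expect_true(any(in_slit))  # the bridged roof spans the slit
  expect_gte(min(surf$vertices[in_slit, 3]), 11.75 - 0.51)
})

test_that("hemisphere masks are disjoint, covering, and hole-filled", {
  ph <- generate_phantom(small_gyrified_spec())
  h <- split_hemispheres(ph$tissue$p_gm, ph$tissue$grid, plane_x = 0)
  expect_s3_class(h, "hemisphere_masks")
  expect_false(any(h$left & h$right))
  expect_true(all((h$left | h$right)[ph$tissue$p_gm > 0.5]))
  expect_error(split_hemispheres(ph$tissue$p_gm, ph$tissue$grid,
                                 plane_x = 500), "plane")
})

test_that("planar projection is the exact foot of the perpendicular", {
  # analytic plane z = 10 as a two-triangle square, closed by a mirrored
  # bottom so ray casting has a well-defined target
  v <- rbind(c(-50, -50, 10), c(50, -50, 10), c(50, 50, 10), c(-50, 50, 10),
             c(-50, -50, -90), c(50, -50, -90), c(50, 50, -90),
             c(-50, 50, -90))
  f <- rbind(c(1, 2, 3), c(1, 3, 4), c(5, 7, 6), c(5, 8, 7),
             c(1, 6, 2), c(1, 5, 6), c(2, 7, 3), c(2, 6, 7),
             c(3, 8, 4), c(3, 7, 8), c(4, 5, 1), c(4, 8, 5))
  plane <- surface_mesh(v, f)
  es <- generate_strip(3, 10, anchor = c(-10, 0, 5), direction = c(1, 0, 0),
                       lead_id = "s1")
  proj <- project_surface_contacts(es, plane)
  expect_equal(proj$z_mm, rep(10, 3), tolerance = 1e-6)
  expect_equal(proj$x_mm, es$x_mm, tolerance = 1e-6)
  expect_equal(proj$y_mm, es$y_mm, tolerance = 1e-6)
  # idempotence: projecting the projected set changes nothing
  again <- project_surface_contacts(proj, plane)
  expect_equal(again$x_mm, proj$x_mm, tolerance = 1e-9)
  expect_equal(again$z_mm, proj$z_mm, tolerance = 1e-9)
})

test_that("spherical projection is radial to analytic tolerance", {
  sph <- icosphere(radius = 50, subdiv = 4)
  es <- electrode_set(data.frame(
    contact_id = "c1", lead_id = "s1", modality = "strip",
    x_mm = 40 / sqrt(3), y_mm = 40 / sqrt(3), z_mm = 40 / sqrt(3)), "pt")
  proj <- project_surface_contacts(es, sph)
  r_out <- sqrt(proj$x_mm^2 + proj$y_mm^2 + proj$z_mm^2)
  # icosphere subdiv 4 chords deviate < 0.1 mm from the true sphere
  expect_equal(r_out, 50, tolerance = 0.002)
  u <- c(proj$x_mm, proj$y_mm, proj$z_mm) / r_out
  expect_equal(u, rep(1 / sqrt(3), 3), tolerance = 1e-3)
})

test_that("projection never touches depth contacts and flags outliers", {
  sph <- icosphere(radius = 30, subdiv = 3)
  es <- combine_electrodes(
    generate_strip(2, 10, c(0, 0, 20), c(1, 0, 0), lead_id = "s1"),
    generate_depth(3, 5, entry = c(0, 0, 15), target = c(0, 0, 5),
                   lead_id = "d1"),
    patient_id = "pt")
  proj <- project_surface_contacts(es, sph)
  dsel <- proj$modality == "depth"
  expect_identical(proj$x_mm[dsel], es$x_mm[dsel])
  expect_identical(proj$z_mm[dsel], es$z_mm[dsel])
  # a contact 70 mm outside a radius-30 sphere exceeds the 25 mm default
  far <- electrode_set(data.frame(contact_id = "far", lead_id = "s2",
                                  modality = "strip", x_mm = 100, y_mm = 0,
                                  z_mm = 0), "pt")
  expect_warning(pf <- project_surface_contacts(far, sph), "flagged")
  expect_false(pf$projected[1])
  expect_equal(pf$x_mm[1], 100)
})

test_that("projection corrects a 10 mm synthetic brain shift on the phantom", {
  ph <- generate_phantom(small_gyrified_spec())
  g <- ph$tissue$grid
  surf <- extract_smooth_surface(ph$tissue$p_gm, g, kernel_mm = 24)
  crown <- phantom_crown_z(ph$spec)
  es <- generate_strip(5, 10, anchor = c(-18, 8, crown),
                       direction = c(0, 1, 0), lead_id = "s1")
  es_on <- project_surface_contacts(es, surf)     # seat on the surface
  shifted <- apply_brain_shift(es_on, 10)
  proj <- project_surface_contacts(shifted, surf)
  d <- mesh_distance(as.matrix(proj[, c("x_mm", "y_mm", "z_mm")]), surf)
  expect_true(all(d <= 0.5 * max(g$spacing)))
  expect_true(all(proj$projected))
})

test_that("hemisphere restriction masks the opposite bank", {
  ph <- generate_phantom(small_gyrified_spec())
  g <- ph$tissue$grid
  h <- ph$hemispheres
  contact <- electrode_set(data.frame(
    contact_id = "ih1", lead_id = "s1", modality = "strip",
    x_mm = -1, y_mm = 30, z_mm = 30, interhemispheric = TRUE), "pt")
  roi <- sphere_mask(c(-1, 30, 30), 8, g)
  restricted <- restrict_hemisphere(roi, contact[1, ], h)
  expect_true(all(restricted[roi & h$right] == FALSE))
  expect_true(all(restricted <= roi))
  # non-interhemispheric contacts pass through untouched
  contact$interhemispheric <- FALSE
  expect_identical(restrict_hemisphere(roi, contact[1, ], h), roi)
})

test_that("midline-sphere coverage halves under hemisphere restriction", {
  tis <- unit_gm_cube(40, 1)
  g <- tis$grid
  h <- split_hemispheres(tis$p_gm, g, plane_x = 0)
  roi <- sphere_mask(c(0, 0, 0), 10, g)
  contact <- electrode_set(data.frame(
    contact_id = "c", lead_id = "s", modality = "strip",
    x_mm = -0.2, y_mm = 0, z_mm = 0, interhemispheric = TRUE), "pt")
  restricted <- restrict_hemisphere(roi, contact[1, ], h)
  expect_equal(sum(restricted), sum(roi) / 2, tolerance = 0.01)
})

test_that("PLY round trip preserves the mesh", {
  sph <- icosphere(radius = 10, subdiv = 1)
  path <- tempfile(fileext = ".ply")
  write_ply(sph, path)
  back <- read_ply(path)
  expect_equal(back$vertices, unname(sph$vertices), tolerance = 1e-6)
  expect_identical(back$faces, sph$faces)
  expect_true(is_watertight(back))
  unlink(path)
})
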