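test_that("sphere mask follows the voxel-center membership rule", {
  g <- volume_grid(c(21, 21, 21), c(1, 1, 1), c(-10, -10, -10))
  m <- sphere_mask(c(0, 0, 0), 1, g)
  expect_equal(sum(m), 7)  # center + 6 face neighbors at unit distance
  # nesting across the sweep
  radii <- seq(1, 8, 0.5)
  masks <- lapply(radii, function(r) sphere_mask(c(0.3, -0.2, 0.1), r, g))
  for (i in seq_len(length(masks) - 1))
    expect_true(all(masks[[i + 1]][masks[[i]]]))
  expect_warning(sphere_mask(c(100, 100, 100), 2, g), "outside")
  expect_error(sphere_mask(c(0, 0, 0), 0, g), "> 0")
})

test_that("averaged sphere volumes match the analytic value within 2%", {
  for (r in c(2.5, 5, 10)) {
    n <- 2 * ceiling(r) + 9
    g <- volume_grid(rep(n, 3), c(1, 1, 1), rep(-(n - 1) / 2, 3))
    v <- mean_mask_volume(function(off) sphere_mask(off, r, g), n = 200)
    expect_equal(v, sphere_volume(r), tolerance = 0.02)
  }
})

test_that("union of masks matches the closed-form lens formula", {
  g <- volume_grid(c(31, 31, 31), c(1, 1, 1), c(-15, -15, -15))
  v2 <- mean_mask_volume(function(off) {
    union_mask(list(sphere_mask(off + c(-2.5, 0, 0), 5, g),
                    sphere_mask(off + c(2.5, 0, 0), 5, g)))
  }, n = 200)
  expect_equal(v2, 2 * sphere_volume(5) - lens_volume(5, 5),
               tolerance = 0.02)
  # identical masks collapse to one; disjoint masks add
  m <- sphere_mask(c(0, 0, 0), 4, g)
  expect_identical(union_mask(list(m, m)), m)
  m2 <- sphere_mask(c(10, 0, 0), 4, g)
  expect_equal(sum(union_mask(list(m, m2))), sum(m) + sum(m2))
  expect_error(union_mask(list(m, m[1:10, , ])), "same grid")
})

test_that("weighted volume multiplies voxel volume by tissue probability", {
  g <- volume_grid(c(10, 10, 10), c(1, 1, 1))
  mask <- array(FALSE, g$dim)
  mask[1:10] <- TRUE
  p <- array(0.5, g$dim)
  expect_equal(weighted_volume(mask, p, g), 5)
  p1 <- array(1, g$dim)
  m <- sphere_mask(c(4.5, 4.5, 4.5), 3, g)
  expect_equal(weighted_volume(m, p1, g), sum(m))
  expect_error(weighted_volume(mask, p * 3, g), "0, 1")
})

test_that("masks inside excluded parcels contribute zero coverage", {
  ph <- generate_phantom(phantom_spec())
  g <- ph$tissue$grid
  lut <- ph$atlas$lut
  cer <- which(ph$atlas$label == lut$id[lut$name == "cerebellum"],
               arr.ind = TRUE)
  center <- (colMeans(cer) - 1) * g$spacing + g$origin
  excl <- atlas_exclusion_mask(ph$atlas)
  m <- sphere_mask(center, 4, g)
  expect_gt(weighted_volume(m, ph$tissue$p_gm, g), 0)
  expect_equal(weighted_volume(m, ph$tissue$p_gm, g, exclusion = excl), 0)
})

test_that("coverage sweep reproduces the single-sphere oracle", {
  tis <- unit_gm_cube(40, 1)
  es <- generate_depth(1, 5, entry = c(0, 0, 10), target = c(0.21, 0.4, 0.13),
                       lead_id = "d1")
  cv <- coverage_sweep(es, tis, config = roi_sweep_config(radii_mm = c(5, 10)))
  gm10 <- cv$total_mm3[cv$tissue == "gm" & cv$radius_mm == 10]
  expect_equal(gm10, sphere_volume(10), tolerance = 0.02)
  expect_equal(cv$per_contact_mm3, cv$total_mm3 / cv$n_contacts)
})

test_that("5 mm lead spacing creates coverage redundancy at r = 5", {
  tis <- unit_gm_cube(94, 1)
  sweep_at <- function(off) {
    lead <- generate_depth(8, 5, entry = off + c(0, 0, 37.5),
                           target = off + c(0, 0, -17.5), lead_id = "d1")
    coverage_sweep(lead, tis, config = roi_sweep_config(radii_mm = 5))
  }
  cv <- sweep_at(c(0, 0, 0))
  per <- cv$per_contact_mm3[cv$tissue == "gm"]
  expect_lt(per, sphere_volume(5))
  # closed-form union of 8 collinear spheres: 8 V - 7 lens overlaps;
  # voxelization bias averaged out over random sub-voxel lead offsets
  union8 <- 8 * sphere_volume(5) - 7 * lens_volume(5, 5)
  tot <- withr::with_seed(3, mean(replicate(40, {
    x <- sweep_at(stats::runif(3, -0.5, 0.5))
    x$total_mm3[x$tissue == "gm"]
  })))
  expect_equal(tot, union8, tolerance = 0.02)
  # a 10 mm-spaced lead of equal length has no overlap: higher per-contact
  lead10 <- generate_depth(8, 10, entry = c(0, 0, 40), target = c(0, 0, -35),
                           lead_id = "d2")
  cv10 <- coverage_sweep(lead10, tis, config = roi_sweep_config(radii_mm = 5))
  expect_gt(cv10$per_contact_mm3[cv10$tissue == "gm"], per)
})

test_that("coverage curves are non-decreasing in radius", {
  ph <- generate_phantom(small_gyrified_spec())
  es <- combine_electrodes(
    generate_strip(4, 10, c(-18, 8, phantom_crown_z(ph$spec)), c(0, 1, 0),
                   lead_id = "s1"),
    generate_depth(6, 5, entry = c(15, 10, 37), target = c(8, 30, 15),
                   lead_id = "d1"),
    patient_id = "pt")
  cv <- coverage_sweep(es, ph$tissue, ph$atlas, ph$hemispheres)
  for (tis in c("gm", "wm")) {
    tot <- cv$total_mm3[cv$tissue == tis][order(cv$radius_mm[cv$tissue == tis])]
    expect_true(all(diff(tot) >= 0))
  }
  expect_error(coverage_sweep(es[0, ], ph$tissue), "zero contacts")
})

test_that("region coverage partitions the sphere across parcels", {
  tis <- unit_gm_cube(40, 1)
  g <- tis$grid
  ax <- grid_axes(g)
  X <- array(rep(ax[[1]], prod(g$dim[2:3])), g$dim)
  label <- array(1L, g$dim)
  label[X >= 0] <- 2L
  lut <- data.frame(id = 1:2, name = c("A", "B"),
                    class = "cortical-analysis")
  atlas <- atlas_labels(g, label, lut)
  es <- generate_depth(1, 5, entry = c(0, 0, 10), target = c(0.1, 0, 0),
                       lead_id = "d1")
  rc <- region_coverage(es, atlas, tis, radius_mm = 5)
  whole <- weighted_volume(sphere_mask(c(0.1, 0, 0), 5, g), tis$p_gm, g)
  expect_equal(sum(rc$gm_mm3), whole, tolerance = 1e-9)
  expect_true(all(rc$gm_mm3 > 0))
  # a sphere wholly inside parcel A contributes nothing to parcel B
  es_a <- generate_depth(1, 5, entry = c(-10, 0, 10), target = c(-10, 0, 0),
                         lead_id = "d2")
  rc_a <- region_coverage(es_a, atlas, tis, radius_mm = 4)
  expect_equal(rc_a$gm_mm3[rc_a$region == "B"], 0)
  expect_gt(rc_a$gm_mm3[rc_a$region == "A"], 0)
})

test_that("regional sum never exceeds total gray matter coverage", {
  ph <- generate_phantom(phantom_spec())
  es <- generate_depth(8, 5, entry = c(35, 30, 63), target = c(20, 51, 32),
                       lead_id = "d1")
  rc <- region_coverage(es, ph$atlas, ph$tissue, radius_mm = 5)
  cv <- coverage_sweep(es, ph$tissue, ph$atlas,
                       config = roi_sweep_config(radii_mm = 5))
  expect_lte(sum(rc$gm_mm3),
             cv$total_mm3[cv$tissue == "gm"] + 1e-6)
})

test_that("coverage curves round-trip through the tidy long CSV", {
  tis <- unit_gm_cube(30, 1)
  es <- generate_depth(4, 5, entry = c(0, 0, 12), target = c(0, 0, -3),
                       lead_id = "d1")
  cv <- coverage_sweep(es, tis, config = roi_sweep_config(radii_mm = c(2, 5)))
  path <- tempfile(fileext = ".csv")
  write_coverage_csv(cv, path)
  long <- utils::read.csv(path)
  expect_setequal(names(long),
                  c("patient_id", "implant_class", "radius_mm", "tissue",
                    "scope", "volume_mm3", "n_contacts"))
  back <- read_coverage_csv(path)
  key <- function(d) paste(d$radius_mm, d$tissue)
  back <- back[match(key(cv), key(back)), ]
  expect_equal(back$total_mm3, cv$total_mm3)
  expect_equal(back$per_contact_mm3, cv$per_contact_mm3)
  unlink(path)
})

test_that("regional inclusion rule applies the configured threshold", {
  rc <- tibble::tibble(patient_id = "pt", implant_class = "D",
                       region_id = 1:3,
                       region = c("a", "b", "c"), radius_mm = 5,
                       gm_mm3 = c(0, 0.3, 5))
  inc0 <- regional_inclusion(rc)
  expect_equal(inc0$included, c(FALSE, TRUE, TRUE))
  inc1 <- regional_inclusion(rc, threshold_mm3 = 1)
  expect_equal(inc1$included, c(FALSE, FALSE, TRUE))
})
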