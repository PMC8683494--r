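# Closed-form and brute-force oracles shared across tests. These stay
# independent of the implementation paths they check.

# volume of the lens-shaped intersection of two equal spheres of radius r
# whose centers are d apart (0 <= d <= 2r)
lens_volume <- function(r, d) pi * (4 * r + d) * (2 * r - d)^2 / 12

sphere_volume <- function(r) 4 / 3 * pi * r^3

# average voxel count of a mask builder over randomly offset centers;
# the expectation over uniform sub-voxel offsets equals the true volume
mean_mask_volume <- function(build, n = 200, seed = 42) {
  withr::with_seed(seed, {
    mean(replicate(n, sum(build(stats::runif(3, -0.5, 0.5)))))
  })
}

# analytic triangulated sphere: subdivided icosahedron scaled to `radius`
icosphere <- function(radius = 1, center = c(0, 0, 0), subdiv = 3) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
    c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
    c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    nv <- nrow(v)
    mid_cache <- new.env()
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      if (!is.null(mid_cache[[key]])) return(mid_cache[[key]])
      v <<- rbind(v, (v[a, ] + v[b, ]) / 2)
      mid_cache[[key]] <- nrow(v)
      nrow(v)
    }
    nf <- list()
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; c_ <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c_); ca <- midpoint(c_, a)
      nf[[length(nf) + 1]] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                    c(c_, ca, bc), c(ab, bc, ca))
    }
    f <- do.call(rbind, nf)
  }
  v <- v / sqrt(rowSums(v^2)) * radius
  v <- sweep(v, 2, center, "+")
  surface_mesh(v, f)
}

# brute-force morphological closing with a spherical element (diameter k)
# on a small logical volume with unit voxels
brute_close <- function(mask, k) {
  r <- k / 2
  # pad with background so the morphology sees the world outside the array
  pad <- ceiling(r) + 1L
  d0 <- dim(mask)
  d <- d0 + 2L * pad
  pm <- array(FALSE, d)
  pm[pad + seq_len(d0[1]), pad + seq_len(d0[2]), pad + seq_len(d0[3])] <- mask
  mask <- pm
  all_idx <- which(array(TRUE, d), arr.ind = TRUE)
  min_dist <- function(pts, seeds) {
    # squared distances via |p - s|^2 = |p|^2 + |s|^2 - 2 p.s, chunked to
    # keep the distance matrix small
    s2 <- rowSums(seeds^2)
    out <- numeric(nrow(pts))
    for (i0 in seq(1, nrow(pts), by = 1000)) {
      idx <- i0:min(i0 + 999, nrow(pts))
      p <- pts[idx, , drop = FALSE]
      d2 <- outer(rowSums(p^2), s2, "+") - 2 * tcrossprod(p, seeds)
      out[idx] <- sqrt(pmax(matrixStats_rowMins(d2), 0))
    }
    out
  }
  dil <- min_dist(all_idx, which(mask, arr.ind = TRUE)) <= r
  dil <- array(dil, d)
  ero <- if (!any(!dil)) array(TRUE, d) else
    array(min_dist(all_idx, which(!dil, arr.ind = TRUE)) > r, d)
  out <- ero | mask
  out[pad + seq_len(d0[1]), pad + seq_len(d0[2]), pad + seq_len(d0[3])]
}

matrixStats_rowMins <- function(m) apply(m, 1, min)

# small uniform gray-matter cube helper for coverage tests
unit_gm_cube <- function(size_mm = 40, voxel_mm = 1) {
  uniform_tissue_cube(size_mm, voxel_mm, tissue = "gm")
}

# compact gyrified phantom for surface/projection tests (1 mm voxels)
small_gyrified_spec <- function(...) {
  phantom_spec(extent_mm = c(60, 60, 50), voxel_mm = 1, thickness_mm = 3,
               wavelength_mm = 20, amplitude_mm = 5, csf_mm = 5,
               gap_mm = 4, softness_mm = 0.5, surface_z_mm = 32,
               edge_margin_mm = 4, ...)
}
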