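#' Cohort generation configuration
#'
#' Defines how many synthetic patients to draw per implant class, on which
#' phantom, with how much layout jitter and how much simulated brain shift.
#' Electrode geometries follow the clinical conventions the package models:
#' depth leads with 5 mm inter-contact spacing, subdural strips/grids with
#' 10 mm spacing.
#'
#' @param n_per_class named integer vector of patient counts for classes
#'   `S`, `S+G`, `S+G+D`, `D` (missing classes default to 0).
#' @param spec a [phantom_spec()] shared by all patients.
#' @param jitter_mm standard deviation (mm) of Gaussian jitter on lead
#'   anchor positions.
#' @param shift_mm inward brain-shift displacement (mm) applied to subdural
#'   contacts of the observed electrode tables.
#' @param strip_n_mean mean contact count per strip lead (counts are drawn
#'   around this mean, clamped to 4-10).
#' @param depth_spacing_mm,subdural_spacing_mm inter-contact spacings.
#' @param seed RNG seed making the cohort reproducible.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_per_class = c("S" = 2, "S+G" = 2,
                                          "S+G+D" = 2, "D" = 2),
                          spec = phantom_spec(),
                          jitter_mm = 2, shift_mm = 5,
                          strip_n_mean = 8,
                          depth_spacing_mm = 5, subdural_spacing_mm = 10,
                          seed = 1L) {
  full <- c("S" = 0L, "S+G" = 0L, "S+G+D" = 0L, "D" = 0L)
  bad <- setdiff(names(n_per_class), names(full))
  if (length(bad)) stop("unknown implant class: ", paste(bad, collapse = ", "))
  full[names(n_per_class)] <- as.integer(n_per_class)
  if (any(full < 0)) stop("patient counts must be >= 0")
  structure(list(n_per_class = full, spec = spec, jitter_mm = jitter_mm,
                 shift_mm = shift_mm, strip_n_mean = strip_n_mean,
                 depth_spacing_mm = depth_spacing_mm,
                 subdural_spacing_mm = subdural_spacing_mm,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

jit <- function(sd) if (sd > 0) stats::rnorm(1, 0, sd) else 0

# Strip along +y on the crown plane of the phantom.
cohort_strip <- function(spec, cfg, x0, y0, lead_id, patient_id) {
  n <- max(4L, min(10L, round(stats::rnorm(1, cfg$strip_n_mean, 1))))
  crown <- phantom_crown_z(spec)
  ylim <- spec$extent_mm[2] * 0.78
  anchor <- c(x0 + jit(cfg$jitter_mm),
              min(max(y0 + jit(cfg$jitter_mm), 4),
                  ylim - (n - 1) * cfg$subdural_spacing_mm),
              crown)
  generate_strip(n, cfg$subdural_spacing_mm, anchor, c(0, 1, 0),
                 lead_id = lead_id, patient_id = patient_id)
}

# 5 x 8 grid covering one hemisphere on the crown plane.
cohort_grid <- function(spec, cfg, side, lead_id, patient_id) {
  ext <- spec$extent_mm
  crown <- phantom_crown_z(spec)
  sp <- cfg$subdural_spacing_mm
  rows <- max(2L, min(5L, floor((ext[1] / 2 - spec$edge_margin_mm -
                                   spec$gap_mm / 2 - 4) / sp) + 1L))
  cols <- max(2L, min(8L, floor((ext[2] * 0.78 - 8) / sp) + 1L))
  x0 <- if (side < 0) -(spec$gap_mm / 2 + 2 + (rows - 1) * sp) else
    spec$gap_mm / 2 + 2
  anchor <- c(x0 + jit(cfg$jitter_mm / 2), 8 + jit(cfg$jitter_mm), crown)
  generate_grid(rows, cols, sp, anchor, dir_row = c(1, 0, 0),
                dir_col = c(0, 1, 0), lead_id = lead_id,
                patient_id = patient_id)
}

# Depth lead aimed at a deep target or crossing cortical folds obliquely.
cohort_depth <- function(spec, cfg, kind, side, y0, lead_id, patient_id) {
  ext <- spec$extent_mm
  crown <- phantom_crown_z(spec)
  jx <- jit(cfg$jitter_mm); jy <- jit(cfg$jitter_mm)
  if (kind == "hippocampus") {
    target <- c(side * 0.20 * ext[1] + jx, 0.51 * ext[2] + jy, 0.40 * ext[3])
    entry <- c(side * 0.35 * ext[1], 0.30 * ext[2], crown + 2)
  } else if (kind == "amygdala") {
    target <- c(side * 0.20 * ext[1] + jx, 0.35 * ext[2] + jy, 0.40 * ext[3])
    entry <- c(side * 0.35 * ext[1], 0.16 * ext[2], crown + 2)
  } else if (kind == "vertical") {
    # straight insertion through the ribbon into deep white matter
    x0 <- side * 0.28 * ext[1] + jx
    entry <- c(x0, y0 + jy, crown + 1)
    target <- c(x0, y0 + jy, max(crown - 36, 4))
  } else {  # near-tangential mediolateral trajectory through the ribbon:
    # runs along x with a shallow descent so several contacts traverse the
    # cortical gray while the deepest reach white matter, the way SEEG
    # trajectories are planned to maximize traversed gray matter
    yl <- y0 + jy
    z0 <- phantom_surface_z(spec, yl) - spec$thickness_mm / 2
    entry <- c(side * 0.44 * ext[1] + jx, yl, z0 + 4)
    target <- c(side * 0.10 * ext[1] + jx, yl, z0 - 4)
  }
  generate_depth(8, cfg$depth_spacing_mm, entry = entry, target = target,
                 lead_id = lead_id, patient_id = patient_id)
}

cohort_patient <- function(class, spec, cfg, patient_id) {
  ext <- spec$extent_mm
  sx <- ext[1] / 100
  sy <- ext[2] / 100
  leads <- list()
  add <- function(es) leads[[length(leads) + 1]] <<- es
  strip_x <- c(-40, -30, -20, 20, 30, 40) * sx
  y_front <- 8 * sy
  if (class == "S") {
    for (i in 1:6)
      add(cohort_strip(spec, cfg, strip_x[i], y_front,
                       sprintf("strip%d", i), patient_id))
  } else if (class == "S+G") {
    add(cohort_grid(spec, cfg, -1, "grid1", patient_id))
    for (i in 1:3)
      add(cohort_strip(spec, cfg, strip_x[3 + i], y_front,
                       sprintf("strip%d", i), patient_id))
  } else if (class == "S+G+D") {
    add(cohort_grid(spec, cfg, -1, "grid1", patient_id))
    for (i in 1:2)
      add(cohort_strip(spec, cfg, strip_x[4 + i], y_front,
                       sprintf("strip%d", i), patient_id))
    add(cohort_depth(spec, cfg, "hippocampus", 1, NA, "depth1", patient_id))
    add(cohort_depth(spec, cfg, "amygdala", 1, NA, "depth2", patient_id))
  } else {  # D
    k <- 0
    for (side in c(-1, 1)) {
      for (kind in c("hippocampus", "amygdala")) {
        k <- k + 1
        add(cohort_depth(spec, cfg, kind, side, NA, sprintf("depth%d", k),
                         patient_id))
      }
      for (y0 in c(8, 28, 48) * sy) {
        k <- k + 1
        add(cohort_depth(spec, cfg, "oblique", side, y0,
                         sprintf("depth%d", k), patient_id))
      }
      k <- k + 1
      add(cohort_depth(spec, cfg, "vertical", side, 64 * sy,
                       sprintf("depth%d", k), patient_id))
    }
  }
  es <- do.call(combine_electrodes, c(leads, list(patient_id = patient_id)))
  es
}

#' Generate a synthetic patient cohort
#'
#' Draws the configured number of patients per implant class on a shared
#' gyrified phantom. Subdural leads sit on the gyral-crown plane (where the
#' smoothed gray-matter surface runs); depth leads either target deep gray
#' structures (hippocampus, amygdala) or cross the folded cortical ribbon
#' obliquely. The observed electrode tables additionally carry the
#' configured inward brain shift on strip/grid contacts; the pre-shift
#' truth is kept alongside for validation.
#'
#' @param config a [cohort_config()].
#' @return An object of class `ieeg_cohort`: the shared `phantom`, a list
#'   of `patients` (each with `electrodes` = observed/shifted table and
#'   `electrodes_true` = pre-shift table), and the `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  phantom <- generate_phantom(config$spec)
  patients <- with_seed(config$seed, {
    out <- list()
    idx <- 0
    for (class in names(config$n_per_class)) {
      nc <- config$n_per_class[[class]]
      if (nc == 0) next
      for (p in seq_len(nc)) {
        idx <- idx + 1
        pid <- sprintf("pt%02d", idx)
        es_true <- cohort_patient(class, config$spec, config, pid)
        es_obs <- apply_brain_shift(es_true, config$shift_mm)
        out[[pid]] <- list(patient_id = pid, implant_class = class,
                           electrodes = es_obs, electrodes_true = es_true)
      }
    }
    out
  })
  if (!length(patients)) stop("empty cohort: all class counts are zero")
  structure(list(phantom = phantom, patients = patients, config = config),
            class = "ieeg_cohort")
}

#' @export
print.ieeg_cohort <- function(x, ...) {
  cls <- vapply(x$patients, `[[`, "", "implant_class")
  cat(sprintf("<ieeg_cohort> %d patients (%s) on a %s phantom\n",
              length(x$patients),
              paste(names(table(cls)), table(cls), sep = "=", collapse = ", "),
              paste(x$phantom$tissue$grid$dim, collapse = "x")))
  invisible(x)
}
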