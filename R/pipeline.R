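#' Pipeline run configuration
#'
#' @param sweep a [roi_sweep_config()].
#' @param fem run the finite-element stage (default FALSE; it is by far the
#'   most expensive stage).
#' @param fem_edge_mm tet-mesh lattice edge (default 1.5 mm).
#' @param fem_radii_mm nominal radii for FEM volumes (default
#'   2.5, 5, 10, 15 mm).
#' @param fem_max_contacts cap on the number of contacts solved per patient
#'   (`Inf` for all); contacts are subsampled evenly when capped.
#' @param inclusion_radius_mm reference radius for the regional inclusion
#'   rule (default 5 mm).
#' @param max_projection_mm maximum brain-shift projection distance.
#' @param surface_kernel_mm closing kernel for the smoothed gray-matter
#'   surface (default 24 mm).
#' @param out_dir optional output directory for stage artifacts
#'   (NIfTI/CSV/PLY); NULL keeps everything in memory.
#' @return An object of class `run_config`.
#' @export
run_config <- function(sweep = roi_sweep_config(), fem = FALSE,
                       fem_edge_mm = 1.5, fem_radii_mm = c(2.5, 5, 10, 15),
                       fem_max_contacts = Inf,
                       inclusion_radius_mm = 5, max_projection_mm = 25,
                       surface_kernel_mm = 24, out_dir = NULL) {
  structure(list(sweep = sweep, fem = fem, fem_edge_mm = fem_edge_mm,
                 fem_radii_mm = fem_radii_mm,
                 fem_max_contacts = fem_max_contacts,
                 inclusion_radius_mm = inclusion_radius_mm,
                 max_projection_mm = max_projection_mm,
                 surface_kernel_mm = surface_kernel_mm, out_dir = out_dir),
            class = "run_config")
}

#' Run the coverage pipeline for one patient
#'
#' Stages, in order: brain-shift projection of subdural contacts onto the
#' smoothed gray-matter surface (skipped for depth-only patients),
#' hemisphere-restricted coverage sweep, region coverage with the inclusion
#' rule, and optionally the FEM comparison. Stage failures abort with a
#' stage-tagged error.
#'
#' @param phantom an `ieeg_phantom` (or any list with `tissue`, `atlas`,
#'   `hemispheres`).
#' @param electrodes the observed [electrode_set()].
#' @param config a [run_config()].
#' @param surface optional precomputed [surface_mesh()] (computed on demand
#'   when subdural contacts are present).
#' @param mesh optional precomputed [build_tet_mesh()] result for the FEM
#'   stage.
#' @return A patient record: list with `patient_id`, `implant_class`,
#'   `n_contacts`, `electrodes` (projected), `curve`, `regions`, `dice`
#'   (NULL when FEM is off), `n_flagged`.
#' @export
run_patient <- function(phantom, electrodes, config = run_config(),
                        surface = NULL, mesh = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  tissue <- phantom$tissue
  n_flagged <- 0L
  proj <- electrodes
  if (any(electrodes$modality %in% SUBDURAL)) {
    proj <- stage("projection", {
      if (is.null(surface))
        surface <- extract_smooth_surface(tissue$p_gm, tissue$grid,
                                          kernel_mm = config$surface_kernel_mm)
      withCallingHandlers(
        project_surface_contacts(electrodes, surface,
                                 config$max_projection_mm),
        warning = function(w) {
          n_flagged <<- n_flagged + 1L
          invokeRestart("muffleWarning")
        })
    })
  }
  curve <- stage("coverage",
                 coverage_sweep(proj, tissue, phantom$atlas,
                                phantom$hemispheres, config$sweep))
  regions <- stage("regions", {
    rc <- region_coverage(proj, phantom$atlas, tissue,
                          config$inclusion_radius_mm, phantom$hemispheres)
    regional_inclusion(rc)
  })
  dice_tbl <- NULL
  if (isTRUE(config$fem)) {
    dice_tbl <- stage("fem", {
      if (is.null(mesh)) mesh <- build_tet_mesh(tissue, config$fem_edge_mm)
      idx <- seq_len(nrow(proj))
      if (is.finite(config$fem_max_contacts) &&
          nrow(proj) > config$fem_max_contacts)
        idx <- unique(round(seq(1, nrow(proj),
                                length.out = config$fem_max_contacts)))
      sub <- proj[idx, ]
      fields <- lapply(seq_len(nrow(sub)), function(i)
        solve_potential(mesh, contact = sub[i, ]))
      names(fields) <- sub$contact_id
      fem_coverage_compare(sub, tissue, fields, config$fem_radii_mm,
                           phantom$atlas)
    })
  }
  rec <- list(patient_id = electrodes$patient_id[1],
              implant_class = implant_class(electrodes),
              n_contacts = nrow(electrodes), electrodes = proj,
              curve = curve, regions = regions, dice = dice_tbl,
              n_flagged = n_flagged)
  if (!is.null(config$out_dir)) write_patient_record(rec, config$out_dir)
  rec
}

write_patient_record <- function(rec, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pid <- rec$patient_id
  write_electrodes_csv(rec$electrodes,
                       file.path(out_dir, paste0(pid, "_electrodes.csv")))
  write_coverage_csv(rec$curve,
                     file.path(out_dir, paste0(pid, "_coverage.csv")))
  utils::write.csv(as.data.frame(rec$regions),
                   file.path(out_dir, paste0(pid, "_regions.csv")),
                   row.names = FALSE)
  if (!is.null(rec$dice))
    utils::write.csv(as.data.frame(rec$dice),
                     file.path(out_dir, paste0(pid, "_fem.csv")),
                     row.names = FALSE)
  invisible(NULL)
}

#' Run the full pipeline over a cohort
#'
#' Shares the smoothed surface (and, with FEM on, the tet mesh) across
#' patients on the common phantom, runs [run_patient()] for each patient
#' (failures are recorded and the cohort continues), then computes cohort
#' summaries, pairwise modality comparisons at the named radii, and the
#' depth-vs-surface crossover radius. When `config$out_dir` is set, tidy
#' CSVs and a provenance file (config echo, seed, package version, output
#' checksums) are written.
#'
#' @param cohort an `ieeg_cohort` from [generate_cohort()].
#' @param config a [run_config()].
#' @return List with `records`, `failed` (named error messages),
#'   `summary` (see [summarize_cohort()]), `comparisons`, `crossover_mm`,
#'   and `provenance`.
#' @export
run_cohort <- function(cohort, config = run_config()) {
  if (!length(cohort$patients)) stop("empty cohort")
  tissue <- cohort$phantom$tissue
  any_subdural <- any(vapply(cohort$patients, function(p)
    any(p$electrodes$modality %in% SUBDURAL), TRUE))
  surface <- if (any_subdural)
    extract_smooth_surface(tissue$p_gm, tissue$grid,
                           kernel_mm = config$surface_kernel_mm)
  mesh <- if (isTRUE(config$fem)) build_tet_mesh(tissue, config$fem_edge_mm)
  records <- list()
  failed <- character(0)
  for (p in cohort$patients) {
    rec <- tryCatch(
      run_patient(cohort$phantom, p$electrodes, config, surface, mesh),
      error = function(e) e)
    if (inherits(rec, "error")) {
      failed[p$patient_id] <- conditionMessage(rec)
    } else {
      records[[p$patient_id]] <- rec
    }
  }
  if (!length(records)) stop("every patient failed: ",
                             paste(failed, collapse = "; "))
  summary <- summarize_cohort(records)
  comparisons <- cohort_comparisons(summary$curves, config$sweep$named_mm)
  cross <- tryCatch(
    crossover_radius(summary$curves, "D", surface_class(summary$curves),
                     from_radius_mm = min(config$sweep$named_mm)),
    error = function(e) NA_real_)
  prov <- list(seed = cohort$config$seed,
               n_patients = length(records),
               n_failed = length(failed),
               package_version = as.character(utils::packageVersion("ieegcover")),
               config = config_fingerprint(cohort$config, config))
  out <- list(records = records, failed = failed, summary = summary,
              comparisons = comparisons, crossover_mm = cross,
              provenance = prov)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_coverage_csv(summary$curves,
                       file.path(config$out_dir, "cohort_coverage.csv"))
    utils::write.csv(as.data.frame(summary$regions),
                     file.path(config$out_dir, "cohort_regions.csv"),
                     row.names = FALSE)
    if (!is.null(comparisons))
      utils::write.csv(as.data.frame(comparisons),
                       file.path(config$out_dir, "cohort_stats.csv"),
                       row.names = FALSE)
    prov$outputs <- as.list(tools::md5sum(
      list.files(config$out_dir, pattern = "\\.csv$", full.names = TRUE)))
    names(prov$outputs) <- basename(names(prov$outputs))
    jsonlite::write_json(prov, file.path(config$out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA)
    out$provenance <- prov
  }
  out
}

# the surface class with the most patients, preferring S then S+G
surface_class <- function(curves) {
  cls <- unique(curves$implant_class)
  for (c in c("S", "S+G", "S+G+D")) if (c %in% cls) return(c)
  stop("no surface-electrode class in the cohort")
}

cohort_comparisons <- function(curves, named_mm) {
  res <- list()
  for (r in named_mm) for (tis in c("gm", "wm")) {
    cmp <- tryCatch(suppressMessages(compare_modalities(curves, r, tis)),
                    error = function(e) NULL)
    if (!is.null(cmp)) res[[length(res) + 1]] <- cmp
  }
  if (!length(res)) return(NULL)
  dplyr::bind_rows(res)
}

config_fingerprint <- function(cohort_cfg, run_cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(list(utils::capture.output(utils::str(cohort_cfg)),
               utils::capture.output(utils::str(run_cfg))), tmp)
  list(md5 = unname(tools::md5sum(tmp)),
       cohort = unclass(cohort_cfg)[c("n_per_class", "jitter_mm", "shift_mm",
                                      "strip_n_mean", "depth_spacing_mm",
                                      "subdural_spacing_mm", "seed")],
       phantom = unclass(cohort_cfg$spec))
}
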