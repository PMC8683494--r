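#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr bind_rows
NULL

MODALITIES <- c("strip", "grid", "depth")
SUBDURAL <- c("strip", "grid")

# Default contact geometry by modality: subdural contacts are discs of
# 2.3 mm diameter; depth contacts are cylinders 2.29 mm high, 0.86 mm in
# diameter.
default_geometry <- function(modality) {
  disc <- modality %in% SUBDURAL
  tibble(geom_type = ifelse(disc, "disc", "cylinder"),
         geom_diameter_mm = ifelse(disc, 2.3, 0.86),
         geom_height_mm = ifelse(disc, NA_real_, 2.29))
}

#' Construct an electrode set
#'
#' An `electrode_set` is a tibble of contacts with one row per contact and
#' columns `patient_id`, `contact_id`, `lead_id`, `modality` (`strip`,
#' `grid` or `depth`), world coordinates `x_mm`, `y_mm`, `z_mm`,
#' `interhemispheric`, and the contact geometry (`geom_type`,
#' `geom_diameter_mm`, `geom_height_mm`). The implant class (`S`, `S+G`,
#' `S+G+D` or `D`) is derived from the modalities present.
#'
#' @param contacts data frame with at least `contact_id`, `lead_id`,
#'   `modality`, `x_mm`, `y_mm`, `z_mm`. Missing geometry columns get the
#'   modality defaults; a missing `interhemispheric` column defaults FALSE.
#' @param patient_id patient identifier.
#' @return An `electrode_set` tibble.
#' @export
electrode_set <- function(contacts, patient_id = "pt") {
  df <- as_tibble(contacts)
  need <- c("contact_id", "lead_id", "modality", "x_mm", "y_mm", "z_mm")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing contact columns: ", paste(miss, collapse = ", "))
  if (!all(df$modality %in% MODALITIES))
    stop("modality must be one of ", paste(MODALITIES, collapse = ", "))
  if (!"interhemispheric" %in% names(df)) df$interhemispheric <- FALSE
  if (!"geom_type" %in% names(df)) {
    df <- cbind(df, default_geometry(df$modality))
    df <- as_tibble(df)
  }
  bad <- (df$modality %in% SUBDURAL & df$geom_type != "disc") |
    (df$modality == "depth" & df$geom_type != "cylinder")
  if (any(bad)) stop("contact geometry type does not match modality")
  if (!"patient_id" %in% names(df)) df$patient_id <- patient_id
  df <- df[, union(c("patient_id", "contact_id", "lead_id", "modality",
                     "x_mm", "y_mm", "z_mm", "interhemispheric"),
                   names(df))]
  class(df) <- c("electrode_set", class(df))
  df
}

#' Implant class of an electrode set
#' @param electrodes an [electrode_set()].
#' @return One of `"S"`, `"S+G"`, `"S+G+D"`, `"D"`.
#' @export
implant_class <- function(electrodes) {
  m <- unique(electrodes$modality)
  has_d <- "depth" %in% m
  has_surf <- any(SUBDURAL %in% m)
  if (has_d && has_surf) return("S+G+D")
  if (has_d) return("D")
  if ("grid" %in% m) return("S+G")
  "S"
}

contact_positions <- function(electrodes) {
  as.matrix(electrodes[, c("x_mm", "y_mm", "z_mm")])
}

unit_vec <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop("direction vector has zero length")
  v / n
}

check_in_grid <- function(pos, grid, what) {
  if (is.null(grid)) return(invisible(TRUE))
  lo <- grid$origin - grid$spacing / 2
  hi <- grid$origin + (grid$dim - 1 / 2) * grid$spacing
  out <- sweep(pos, 2, lo, "<") | sweep(pos, 2, hi, ">")
  if (any(out)) stop(what, " extends outside the volume grid")
  invisible(TRUE)
}

lead_frame <- function(patient_id, lead_id, modality, pos, interhemispheric) {
  n <- nrow(pos)
  electrode_set(tibble(
    contact_id = sprintf("%s_c%02d", lead_id, seq_len(n)),
    lead_id = lead_id, modality = modality,
    x_mm = pos[, 1], y_mm = pos[, 2], z_mm = pos[, 3],
    interhemispheric = interhemispheric), patient_id = patient_id)
}

#' Generate a subdural strip lead
#'
#' Contacts are laid on a straight line from `anchor` along `direction` at
#' exact world-coordinate spacing.
#'
#' @param n number of contacts (>= 1).
#' @param spacing_mm inter-contact spacing (default 10 mm).
#' @param anchor world position (mm) of the first contact.
#' @param direction length-3 direction vector (normalized internally).
#' @param lead_id,patient_id identifiers.
#' @param interhemispheric flag applied to every contact.
#' @param grid optional [volume_grid()]; an error is raised if the lead
#'   leaves it.
#' @return An [electrode_set()].
#' @export
generate_strip <- function(n, spacing_mm = 10, anchor, direction,
                           lead_id = "strip1", patient_id = "pt",
                           interhemispheric = FALSE, grid = NULL) {
  if (n < 1) stop("`n` must be >= 1")
  if (spacing_mm <= 0) stop("`spacing_mm` must be > 0")
  u <- unit_vec(direction)
  pos <- matrix(rep(anchor, each = n), ncol = 3) +
    outer((seq_len(n) - 1) * spacing_mm, u)
  check_in_grid(pos, grid, "strip lead")
  lead_frame(patient_id, lead_id, "strip", pos, interhemispheric)
}

#' Generate a subdural grid array
#'
#' A planar `rows x cols` array with exact spacing along two orthogonalized
#' in-plane directions.
#'
#' @param rows,cols array dimensions (>= 1).
#' @param spacing_mm inter-contact spacing (default 10 mm).
#' @param anchor world position (mm) of the corner contact.
#' @param dir_row,dir_col in-plane directions; `dir_col` is orthogonalized
#'   against `dir_row`.
#' @inheritParams generate_strip
#' @return An [electrode_set()].
#' @export
generate_grid <- function(rows, cols, spacing_mm = 10, anchor,
                          dir_row = c(1, 0, 0), dir_col = c(0, 1, 0),
                          lead_id = "grid1", patient_id = "pt",
                          interhemispheric = FALSE, grid = NULL) {
  if (rows < 1 || cols < 1) stop("`rows` and `cols` must be >= 1")
  if (spacing_mm <= 0) stop("`spacing_mm` must be > 0")
  u <- unit_vec(dir_row)
  v <- dir_col - sum(dir_col * u) * u
  v <- unit_vec(v)
  ij <- expand.grid(i = seq_len(rows) - 1, j = seq_len(cols) - 1)
  pos <- matrix(rep(anchor, each = nrow(ij)), ncol = 3) +
    outer(ij$i * spacing_mm, u) + outer(ij$j * spacing_mm, v)
  check_in_grid(pos, grid, "grid array")
  lead_frame(patient_id, lead_id, "grid", pos, interhemispheric)
}

#' Generate a depth (SEEG) lead
#'
#' Contacts are collinear on the target-to-entry segment, the first contact
#' at `target`, spaced exactly `spacing_mm` apart (5 mm default).
#'
#' @param n number of contacts (>= 1).
#' @param spacing_mm inter-contact spacing (default 5 mm).
#' @param entry,target world positions (mm); contacts run from `target`
#'   toward `entry`.
#' @inheritParams generate_strip
#' @return An [electrode_set()].
#' @export
generate_depth <- function(n, spacing_mm = 5, entry, target,
                           lead_id = "depth1", patient_id = "pt",
                           grid = NULL) {
  if (n < 1) stop("`n` must be >= 1")
  if (spacing_mm <= 0) stop("`spacing_mm` must be > 0")
  u <- unit_vec(entry - target)
  pos <- matrix(rep(target, each = n), ncol = 3) +
    outer((seq_len(n) - 1) * spacing_mm, u)
  check_in_grid(pos, grid, "depth lead")
  lead_frame(patient_id, lead_id, "depth", pos, interhemispheric = FALSE)
}

#' Combine electrode sets for one patient
#' @param ... [electrode_set()] objects.
#' @param patient_id patient identifier applied to all contacts.
#' @return A combined [electrode_set()].
#' @export
combine_electrodes <- function(..., patient_id = NULL) {
  df <- bind_rows(lapply(list(...), as_tibble))
  if (!is.null(patient_id)) df$patient_id <- patient_id
  if (anyDuplicated(df$contact_id))
    df$contact_id <- make.unique(df$contact_id, sep = "_")
  electrode_set(df, patient_id = df$patient_id[1])
}

#' Apply a rigid brain-shift displacement to subdural contacts
#'
#' Translates every strip/grid contact by `displacement_mm` along
#' `direction`; depth contacts are untouched. This emulates the
#' intraoperative inward settling of the cortical surface that mislocalizes
#' subdural contacts relative to preoperative imaging.
#'
#' @param electrodes an [electrode_set()].
#' @param displacement_mm displacement magnitude (mm, >= 0).
#' @param direction displacement direction (default inferior, i.e. inward
#'   for a superiorly exposed surface).
#' @return The displaced [electrode_set()].
#' @export
apply_brain_shift <- function(electrodes, displacement_mm,
                              direction = c(0, 0, -1)) {
  if (displacement_mm < 0) stop("`displacement_mm` must be >= 0")
  if (displacement_mm == 0) return(electrodes)
  u <- unit_vec(direction) * displacement_mm
  sel <- electrodes$modality %in% SUBDURAL
  electrodes$x_mm[sel] <- electrodes$x_mm[sel] + u[1]
  electrodes$y_mm[sel] <- electrodes$y_mm[sel] + u[2]
  electrodes$z_mm[sel] <- electrodes$z_mm[sel] + u[3]
  electrodes
}

#' Write an electrode table to CSV
#'
#' Columns: `patient_id, contact_id, lead_id, modality, x_mm, y_mm, z_mm,
#' interhemispheric`, plus original coordinates (`x_orig_mm`, ...) when the
#' set has been projected.
#'
#' @param electrodes an [electrode_set()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_electrodes_csv <- function(electrodes, path) {
  utils::write.csv(as.data.frame(electrodes), path, row.names = FALSE)
  invisible(path)
}

#' Read an electrode table from CSV
#' @param path CSV path written by [write_electrodes_csv()] (or matching its
#'   column contract).
#' @return An [electrode_set()].
#' @export
read_electrodes_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  electrode_set(df, patient_id = df$patient_id[1])
}
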