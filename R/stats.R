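#' Kruskal-Wallis rank test across groups
#'
#' Nonparametric H test with tie correction and the chi-squared
#' approximation on k - 1 degrees of freedom. By documented convention a
#' fully degenerate input (every value identical across all groups) returns
#' H = 0, p = 1 rather than an error.
#'
#' @param groups list of (nonempty) numeric vectors, one per group.
#' @return List with `H`, `p_value`, `df`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2) stop("need at least two groups")
  if (any(!vapply(groups, length, 1L))) stop("every group must be nonempty")
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  if (length(unique(x)) == 1L)
    return(list(H = 0, p_value = 1, df = length(groups) - 1L))
  kt <- stats::kruskal.test(x, g)
  list(H = unname(kt$statistic), p_value = kt$p.value,
       df = unname(kt$parameter))
}

#' Bonferroni adjustment with an explicit comparison count
#'
#' @param p raw p values.
#' @param m number of comparisons in the family (default `length(p)`).
#' @return Adjusted p values `min(1, p * m)`.
#' @export
bonferroni <- function(p, m = length(p)) {
  if (m < 1) stop("`m` must be >= 1")
  pmin(1, p * m)
}

#' Pearson chi-squared statistic on a contingency table
#'
#' Plain Pearson statistic (no continuity correction),
#' df = (rows - 1)(cols - 1).
#'
#' @param tab integer matrix of counts.
#' @return List with `statistic`, `p_value`, `df`.
#' @export
pearson_chisq <- function(tab) {
  tab <- as.matrix(tab)
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), p_value = ct$p.value,
       df = unname(ct$parameter))
}

#' Pairwise modality comparisons of coverage at one radius
#'
#' Kruskal-Wallis tests on per-patient coverage between every pair of
#' implant classes, Bonferroni-corrected over the number of pairs tested
#' (the family is all pairwise contrasts at one radius and tissue). Classes
#' with fewer than two patients are excluded with a message.
#'
#' @param curves `coverage_curve` rows for a cohort (one patient per
#'   `patient_id`).
#' @param radius_mm radius at which to compare.
#' @param tissue `"gm"` or `"wm"`.
#' @param scope `"per_contact"` (default) or `"total"`.
#' @param alpha significance level after correction (default 0.05).
#' @return Tibble with one row per class pair: group sizes, `H`, `p`,
#'   `p_adj`, `significant`.
#' @export
compare_modalities <- function(curves, radius_mm, tissue = "gm",
                               scope = c("per_contact", "total"),
                               alpha = 0.05) {
  scope <- match.arg(scope)
  col <- if (scope == "per_contact") "per_contact_mm3" else "total_mm3"
  sub <- curves[abs(curves$radius_mm - radius_mm) < 1e-9 &
                  curves$tissue == tissue, ]
  if (!nrow(sub)) stop("no rows at the requested radius/tissue")
  vals <- split(sub[[col]], sub$implant_class)
  sizes <- vapply(vals, length, 1L)
  small <- names(sizes)[sizes < 2]
  if (length(small))
    message("excluding class(es) with < 2 patients: ",
            paste(small, collapse = ", "))
  vals <- vals[sizes >= 2]
  if (length(vals) < 2) stop("need at least two classes with >= 2 patients")
  pairs <- utils::combn(names(vals), 2)
  res <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    kw <- kruskal_wallis(list(vals[[a]], vals[[b]]))
    tibble(radius_mm = radius_mm, tissue = tissue, scope = scope,
           group_a = a, group_b = b,
           n_a = length(vals[[a]]), n_b = length(vals[[b]]),
           H = kw$H, p = kw$p_value)
  })
  out <- dplyr::bind_rows(res)
  out$p_adj <- bonferroni(out$p, m = nrow(out))
  out$significant <- out$p_adj < alpha
  out
}

#' Group test on Dice coefficient distributions
#'
#' Default reading: Pearson chi-squared on a contingency table of binned
#' Dice values (pooled decile bins with expected counts of at least 5 per
#' cell); a Kruskal-Wallis alternative on the raw values is available
#' behind `method = "kruskal"`.
#'
#' @param dice_values named list of numeric Dice vectors, one per group.
#' @param method `"chisq"` (default) or `"kruskal"`.
#' @param bins initial number of quantile bins (default 10).
#' @return List with `statistic`, `p_value`, `df`, `method` (and the pooled
#'   contingency `table` for the chi-squared route).
#' @export
dice_group_test <- function(dice_values, method = c("chisq", "kruskal"),
                            bins = 10) {
  method <- match.arg(method)
  if (length(dice_values) < 2) stop("need at least two groups")
  if (method == "kruskal") {
    kw <- kruskal_wallis(dice_values)
    return(list(statistic = kw$H, p_value = kw$p_value, df = kw$df,
                method = "kruskal"))
  }
  pooled <- unlist(dice_values, use.names = FALSE)
  br <- unique(stats::quantile(pooled, probs = seq(0, 1, length.out = bins + 1)))
  if (length(br) < 3) stop("insufficient spread in Dice values to bin")
  br[1] <- -Inf; br[length(br)] <- Inf
  tab <- t(vapply(dice_values,
                  function(v) table(cut(v, br)),
                  integer(length(br) - 1)))
  # pool adjacent bins until every expected count is >= 5
  expected <- function(tb) outer(rowSums(tb), colSums(tb)) / sum(tb)
  while (ncol(tab) > 2 && any(expected(tab) < 5)) {
    cs <- colSums(tab)
    k <- which.min(cs)
    j <- if (k == 1) 2 else k - 1
    tab[, j] <- tab[, j] + tab[, k]
    tab <- tab[, -k, drop = FALSE]
  }
  if (any(expected(tab) < 5))
    stop("insufficient counts for the chi-squared test after pooling")
  ct <- pearson_chisq(tab)
  list(statistic = ct$statistic, p_value = ct$p_value, df = ct$df,
       method = "chisq", table = tab)
}

#' Radius at which two classes' coverage curves cross
#'
#' Scans the sweep for the smallest radius where the sign of
#' `mean(class A) - mean(class B)` (per-contact coverage) flips relative to
#' its sign at the reference radius (the smallest swept radius by default).
#' Returns `NA` when the curves never cross; swapping the classes returns
#' the same radius. On coarse grids, radii below the voxel size carry
#' mostly quantization noise; `from_radius_mm` lets callers anchor the
#' reference sign at the first radius they consider reliable.
#'
#' @param curves cohort `coverage_curve` rows.
#' @param class_a,class_b implant classes to compare.
#' @param tissue `"gm"` (default) or `"wm"`.
#' @param scope `"per_contact"` (default) or `"total"`.
#' @param from_radius_mm radii below this are ignored when fixing the
#'   reference sign and scanning for the flip (default 0: use the full
#'   sweep).
#' @return Crossover radius (mm) or `NA_real_`.
#' @export
crossover_radius <- function(curves, class_a, class_b, tissue = "gm",
                             scope = c("per_contact", "total"),
                             from_radius_mm = 0) {
  scope <- match.arg(scope)
  col <- if (scope == "per_contact") "per_contact_mm3" else "total_mm3"
  sub <- curves[curves$tissue == tissue &
                  curves$implant_class %in% c(class_a, class_b), ]
  if (!all(c(class_a, class_b) %in% sub$implant_class))
    stop("both classes must be present in the curves")
  agg <- stats::aggregate(sub[[col]],
                          list(radius_mm = sub$radius_mm,
                               implant_class = sub$implant_class), mean)
  wide <- stats::reshape(agg, idvar = "radius_mm",
                         timevar = "implant_class", direction = "wide")
  wide <- wide[order(wide$radius_mm), ]
  wide <- wide[wide$radius_mm >= from_radius_mm, , drop = FALSE]
  if (!nrow(wide)) return(NA_real_)
  diff <- wide[[paste0("x.", class_a)]] - wide[[paste0("x.", class_b)]]
  s <- sign(diff)
  nz <- which(s != 0)
  if (!length(nz)) return(NA_real_)
  first <- s[nz[1]]
  flip <- nz[s[nz] != first]
  if (!length(flip)) return(NA_real_)
  wide$radius_mm[flip[1]]
}

#' Cohort summary tables
#'
#' Tidy long-format summaries: coverage curves per implant class (median
#' and IQR of total and per-contact coverage), region coverage with
#' inclusion counts, and Dice summaries when FEM results are present.
#'
#' @param records list of patient records from [run_patient()].
#' @return List of tibbles `curves`, `curve_summary`, `regions`,
#'   `region_summary`, and `dice_summary` (NULL without FEM results).
#' @export
summarize_cohort <- function(records) {
  if (!length(records)) stop("no patient records")
  curves <- dplyr::bind_rows(lapply(records, `[[`, "curve"))
  curve_summary <- curves |>
    dplyr::group_by(.data$implant_class, .data$radius_mm, .data$tissue) |>
    dplyr::summarise(
      n_patients = dplyr::n_distinct(.data$patient_id),
      per_contact_median = stats::median(.data$per_contact_mm3),
      per_contact_q25 = stats::quantile(.data$per_contact_mm3, 0.25),
      per_contact_q75 = stats::quantile(.data$per_contact_mm3, 0.75),
      total_median = stats::median(.data$total_mm3),
      total_q25 = stats::quantile(.data$total_mm3, 0.25),
      total_q75 = stats::quantile(.data$total_mm3, 0.75),
      .groups = "drop")
  regions <- dplyr::bind_rows(lapply(records, `[[`, "regions"))
  region_summary <- NULL
  if (nrow(regions)) {
    region_summary <- regions |>
      dplyr::group_by(.data$implant_class, .data$region) |>
      dplyr::summarise(
        n_included = sum(.data$included),
        n_patients = dplyr::n(),
        gm_median_mm3 = if (any(.data$included))
          stats::median(.data$gm_mm3[.data$included]) else NA_real_,
        .groups = "drop")
  }
  dices <- dplyr::bind_rows(lapply(records, function(r) {
    if (is.null(r$dice) || !nrow(r$dice)) return(NULL)
    d <- r$dice
    d$patient_id <- r$patient_id
    d$implant_class <- r$implant_class
    d
  }))
  dice_summary <- NULL
  if (!is.null(dices) && nrow(dices)) {
    dice_summary <- dices |>
      dplyr::group_by(.data$implant_class, .data$radius_mm) |>
      dplyr::summarise(dice_median = stats::median(.data$dice),
                       dice_q25 = stats::quantile(.data$dice, 0.25),
                       dice_q75 = stats::quantile(.data$dice, 0.75),
                       n_contacts = dplyr::n(), .groups = "drop")
  }
  list(curves = curves, curve_summary = curve_summary, regions = regions,
       region_summary = region_summary, dice_summary = dice_summary)
}
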