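#' Plot coverage curves across the radius sweep
#'
#' Median per-contact (or total) coverage per implant class with an IQR
#' ribbon, faceted by tissue.
#'
#' @param curve_summary the `curve_summary` tibble from
#'   [summarize_cohort()].
#' @param scope `"per_contact"` or `"total"`.
#' @return A ggplot object.
#' @export
plot_coverage_curves <- function(curve_summary,
                                 scope = c("per_contact", "total")) {
  scope <- match.arg(scope)
  pre <- if (scope == "per_contact") "per_contact" else "total"
  df <- curve_summary
  df$mid <- df[[paste0(pre, "_median")]]
  df$lo <- df[[paste0(pre, "_q25")]]
  df$hi <- df[[paste0(pre, "_q75")]]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$radius_mm, y = .data$mid,
                                   color = .data$implant_class,
                                   fill = .data$implant_class)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.2, color = NA) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~tissue, scales = "free_y",
                        labeller = ggplot2::as_labeller(
                          c(gm = "gray matter", wm = "white matter"))) +
    ggplot2::labs(x = "radius of influence (mm)",
                  y = sprintf("%s coverage (mm³, median ± IQR)",
                              sub("_", "-", scope)),
                  color = "implant class", fill = "implant class") +
    ggplot2::theme_minimal()
}

#' Plot region-specific gray-matter coverage
#'
#' One panel per region; patients excluded by the inclusion rule are
#' dropped and the number of included patients is appended to the class
#' label.
#'
#' @param regions the `regions` tibble from [summarize_cohort()] (with the
#'   `included` column from [regional_inclusion()]).
#' @return A ggplot object.
#' @export
plot_region_coverage <- function(regions) {
  df <- regions[regions$included, , drop = FALSE]
  cnt <- stats::aggregate(included ~ implant_class + region, regions, sum)
  df$label <- paste0(df$implant_class, " (",
                     cnt$included[match(paste(df$implant_class, df$region),
                                        paste(cnt$implant_class, cnt$region))],
                     ")")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$label, y = .data$gm_mm3)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.6, size = 1) +
    ggplot2::facet_wrap(~region, scales = "free") +
    ggplot2::labs(x = "implant class (n included)",
                  y = "gray matter coverage (mm³)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
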