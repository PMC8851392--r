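LOBE_COLORS <- c(frontal = "#4477AA", temporal = "#EE6677",
                 parietal = "#228833", occipital = "#CCBB44",
                 PCG = "#AA3377")

#' Plot the multiregion classifier matrix
#'
#' Patients by regions grid: fill encodes amyloid status (red positive,
#' green negative), an x marks cSS-positive regions.
#'
#' @param object a `region_status_matrix` from [assemble_matrix()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.region_status_matrix <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$region <- factor(df$region_id, levels = sort(unique(df$region_id)))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$region, y = .data$patient_id)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$ab_pos), colour = "grey80") +
    ggplot2::scale_fill_manual(
      values = c(`TRUE` = "#CC3311", `FALSE` = "#117733"),
      labels = c(`TRUE` = "amyloid+", `FALSE` = "amyloid-"),
      name = NULL
    ) +
    ggplot2::geom_point(
      data = df[df$css_pos, , drop = FALSE],
      shape = 4, size = 1.5, colour = "black"
    ) +
    ggplot2::labs(x = "atlas region", y = NULL,
                  subtitle = "x = cSS-positive region") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, size = 5))
  p
}

#' Frequency scatter of regional positivity
#'
#' Per-region frequency of cSS-positive patients against the frequency of
#' amyloid-positive patients, coloured by lobe, with the rank correlation in
#' the subtitle. Coincident points are jittered horizontally.
#'
#' @param matrix a `region_status_matrix`.
#' @param exclude_lobes optional lobes to drop before plotting/correlating.
#' @param jitter_width horizontal jitter applied to coincident points.
#' @return a ggplot.
#' @export
plot_frequency_scatter <- function(matrix, exclude_lobes = NULL,
                                   jitter_width = 0.15) {
  freq <- region_frequencies(matrix, exclude_lobes = exclude_lobes)
  rs <- spearman_frequency_correlation(matrix, exclude_lobes = exclude_lobes)
  sub <- if (isTRUE(rs$undefined)) {
    "rank correlation undefined (constant frequencies)"
  } else {
    sprintf("Spearman rs = %.3f, p = %.3f (n = %d regions)",
            rs$rs, rs$p, rs$n_regions)
  }
  ggplot2::ggplot(freq, ggplot2::aes(x = .data$freq_css, y = .data$freq_ab,
                                     colour = .data$lobe)) +
    ggplot2::geom_jitter(width = jitter_width, height = 0, size = 2) +
    ggplot2::scale_colour_manual(values = LOBE_COLORS, name = "lobe") +
    ggplot2::labs(x = "patients cSS-positive (n)",
                  y = "patients amyloid-positive (n)", subtitle = sub) +
    ggplot2::theme_minimal()
}

#' Stratum SUVr boxplots per lobe family
#'
#' Distribution of SUVr in the whole cSS-positive region, its direct and
#' surrounding siderosis strata, and the contralateral control regions,
#' pooled over (patient, region) units of one lobe family.
#'
#' @param suvr combined SUVr tibble (as in a `petcoloc_run`).
#' @param lobe one of `"composite"`, `"frontal"`, `"temporal"`,
#'   `"parietal"`, `"PCG"`.
#' @return a ggplot.
#' @export
plot_lobe_suvr <- function(suvr, lobe = "composite") {
  lobes <- LOBE_FAMILIES[[match.arg(lobe, names(LOBE_FAMILIES))]]
  sub <- suvr[suvr$css_pos %in% TRUE & suvr$lobe %in% lobes, ]
  long <- tidyr::pivot_longer(
    sub,
    cols = c("suvr_voi", "suvr_css1", "suvr_css0", "suvr_control"),
    names_to = "stratum", values_to = "suvr"
  )
  long$stratum <- factor(
    long$stratum,
    levels = c("suvr_voi", "suvr_css1", "suvr_css0", "suvr_control"),
    labels = c("cSS+", "cSS+1", "cSS+0", "contralateral")
  )
  ggplot2::ggplot(long[!is.na(long$suvr), ],
                  ggplot2::aes(x = .data$stratum, y = .data$suvr)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(ggplot2::aes(colour = .data$patient_id),
                         width = 0.15, size = 1, alpha = 0.7) +
    ggplot2::labs(x = NULL, y = "SUVr (cerebellar reference)",
                  subtitle = paste0(lobe, " lobe family")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}
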