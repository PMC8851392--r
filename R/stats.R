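#' Per-region positivity frequencies
#'
#' For each region, the number of patients classified amyloid-positive and
#' cSS-positive.
#'
#' @param matrix a `region_status_matrix` from [assemble_matrix()].
#' @param exclude_lobes optional character vector of lobes to drop (the
#'   temporal-exclusion sensitivity analysis uses `"temporal"`).
#' @return tibble with `region_id`, (`lobe` if present), `freq_ab`,
#'   `freq_css`.
#' @export
region_frequencies <- function(matrix, exclude_lobes = NULL) {
  tbl <- matrix
  if (!is.null(exclude_lobes)) {
    if (!"lobe" %in% names(tbl)) abort("matrix has no lobe column")
    tbl <- tbl[!tbl$lobe %in% exclude_lobes, ]
  }
  tbl |>
    dplyr::group_by(dplyr::across(dplyr::any_of(c("region_id", "lobe")))) |>
    dplyr::summarise(freq_ab = sum(.data$ab_pos),
                     freq_css = sum(.data$css_pos), .groups = "drop")
}

#' Spearman correlation of regional positivity frequencies
#'
#' Rank correlation (average ranks for ties) between the per-region number
#' of amyloid-positive patients and the per-region number of cSS-positive
#' patients, with a two-sided p-value from the t approximation. When either
#' frequency vector is constant the correlation is undefined and flagged.
#'
#' @inheritParams region_frequencies
#' @return one-row tibble: `rs`, `p`, `n_regions`, `undefined`.
#' @export
spearman_frequency_correlation <- function(matrix, exclude_lobes = NULL) {
  freq <- region_frequencies(matrix, exclude_lobes = exclude_lobes)
  if (sd(freq$freq_ab) == 0 || sd(freq$freq_css) == 0) {
    return(tibble::tibble(rs = NA_real_, p = NA_real_,
                          n_regions = nrow(freq), undefined = TRUE))
  }
  ct <- suppressWarnings(
    cor.test(freq$freq_css, freq$freq_ab, method = "spearman", exact = FALSE)
  )
  tibble::tibble(rs = unname(ct$estimate), p = ct$p.value,
                 n_regions = nrow(freq), undefined = FALSE)
}

#' Concordance of regional amyloid and siderosis positivity
#'
#' Cross-tabulates all (patient, region) cells into the 2x2 table
#' (cSS+/abeta+, cSS+/abeta-, cSS-/abeta+, cSS-/abeta-) and reports the
#' margins and the number of doubly-positive regions expected under
#' independence, `expected_a = (cSS+ total) x (abeta+ total) / N`.
#'
#' @param matrix a `region_status_matrix` from [assemble_matrix()].
#' @return a `coloc_concordance` object.
#' @export
concordance_analysis <- function(matrix) {
  concordance_from_counts(
    a = sum(matrix$css_pos & matrix$ab_pos),
    b = sum(matrix$css_pos & !matrix$ab_pos),
    c = sum(!matrix$css_pos & matrix$ab_pos),
    d = sum(!matrix$css_pos & !matrix$ab_pos)
  )
}

#' @rdname concordance_analysis
#' @param a,b,c,d cell counts: (cSS+, abeta+), (cSS+, abeta-),
#'   (cSS-, abeta+), (cSS-, abeta-).
#' @export
concordance_from_counts <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(counts < 0)) abort("counts must be nonnegative")
  N <- sum(counts)
  if (N == 0) abort("empty table")
  structure(
    list(
      a = a, b = b, c = c, d = d, N = N,
      expected_a = (a + b) * (a + c) / N,
      pct_ab_pos = 100 * (a + c) / N,
      pct_css_pos = 100 * (a + b) / N,
      pct_concordant = 100 * a / N
    ),
    class = "coloc_concordance"
  )
}

#' @export
print.coloc_concordance <- function(x, ...) {
  cat("<coloc_concordance> regional amyloid x siderosis 2x2\n")
  cat(sprintf("            abeta+  abeta-   total\n"))
  cat(sprintf("  cSS+    %7d %7d %7d\n", x$a, x$b, x$a + x$b))
  cat(sprintf("  cSS-    %7d %7d %7d\n", x$c, x$d, x$c + x$d))
  cat(sprintf("  total   %7d %7d %7d\n", x$a + x$c, x$b + x$d, x$N))
  cat(sprintf(
    "  abeta+ %.1f%%; cSS+ %.1f%%; concordant %.1f%%; expected under independence %.1f\n",
    x$pct_ab_pos, x$pct_css_pos, x$pct_concordant, x$expected_a
  ))
  invisible(x)
}

#' @rdname concordance_analysis
#' @param x a `coloc_concordance`.
#' @param ... unused.
#' @export
tidy.coloc_concordance <- function(x, ...) {
  tibble::tibble(
    css = c(TRUE, TRUE, FALSE, FALSE),
    ab = c(TRUE, FALSE, TRUE, FALSE),
    n = c(x$a, x$b, x$c, x$d)
  )
}

#' @rdname concordance_analysis
#' @export
glance.coloc_concordance <- function(x, ...) {
  tibble::tibble(
    n = x$N, observed_a = x$a, expected_a = x$expected_a,
    pct_ab_pos = x$pct_ab_pos, pct_css_pos = x$pct_css_pos,
    pct_concordant = x$pct_concordant
  )
}

#' Paired (dependent-samples) t-test
#'
#' One-sample t on the pairwise differences with df = n - 1 and a two-sided
#' p-value. When all differences are equal (zero variance, including the
#' all-zero case) the statistic is undefined and the result is flagged
#' degenerate, with the direction of the constant shift reported.
#'
#' @param x,y paired numeric vectors of equal length (n >= 2).
#' @return one-row tibble: `n`, `mean_diff`, `t`, `df`, `p`, `degenerate`,
#'   `direction` (-1, 0, 1 for degenerate results, NA otherwise).
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) abort("paired samples must have equal length")
  n <- length(x)
  if (n < 2) abort("need at least 2 pairs")
  d <- x - y
  # constant differences (including a constant nonzero shift) carry no
  # within-pair information: flagged rather than tested
  if (sd(d) <= max(abs(mean(d)), .Machine$double.eps) * 1e-10) {
    return(tibble::tibble(
      n = n, mean_diff = mean(d), t = NA_real_, df = n - 1,
      p = NA_real_, degenerate = TRUE, direction = sign(mean(d))
    ))
  }
  tt <- t.test(x, y, paired = TRUE)
  tibble::tibble(
    n = n, mean_diff = unname(tt$estimate), t = unname(tt$statistic),
    df = unname(tt$parameter), p = tt$p.value,
    degenerate = FALSE, direction = NA_real_
  )
}

#' Two-sample t-test (Welch by default)
#'
#' Welch's unequal-variance form with Welch-Satterthwaite degrees of
#' freedom; the pooled equal-variance form is available via `var_equal`.
#' Degenerate inputs (zero variance in both groups and equal means) are
#' flagged rather than erroring.
#'
#' @param x,y numeric samples (n >= 2 each).
#' @param var_equal use the pooled-variance form.
#' @return one-row tibble: `mean_x`, `mean_y`, `t`, `df`, `p`, `degenerate`.
#' @export
welch_t <- function(x, y, var_equal = FALSE) {
  if (length(x) < 2 || length(y) < 2) abort("need n >= 2 per group")
  if (sd(x) == 0 && sd(y) == 0) {
    if (mean(x) == mean(y)) {
      return(tibble::tibble(mean_x = mean(x), mean_y = mean(y),
                            t = NA_real_, df = NA_real_, p = NA_real_,
                            degenerate = TRUE))
    }
    abort("zero variance in both groups with unequal means")
  }
  tt <- t.test(x, y, var.equal = var_equal)
  tibble::tibble(
    mean_x = mean(x), mean_y = mean(y),
    t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
    degenerate = FALSE
  )
}

#' Pearson chi-square test on a 2x2 table
#'
#' Without continuity correction by default (`correct = TRUE` applies
#' Yates' correction). All four margins must be positive.
#'
#' @param a,b,c,d cell counts, rows = groups, columns = categories.
#' @param correct apply Yates' continuity correction.
#' @return one-row tibble: `chi2`, `df`, `p`.
#' @export
chi_square_2x2 <- function(a, b, c, d, correct = FALSE) {
  m <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    abort("all margins of the 2x2 table must be > 0")
  }
  ct <- suppressWarnings(chisq.test(m, correct = correct))
  tibble::tibble(chi2 = unname(ct$statistic), df = unname(ct$parameter),
                 p = ct$p.value)
}

#' Hierarchical p-value adjustment: FDR within a lobe, Bonferroni across lobes
#'
#' The four contrasts of one lobe form a family; Benjamini-Hochberg step-up
#' is applied within the family, every adjusted value is then multiplied by
#' the number of lobes analysed (5) and capped at 1.
#'
#' @param p numeric vector of raw p-values (one lobe family; NAs allowed).
#' @param n_lobes Bonferroni factor across lobe analyses (default 5).
#' @return adjusted p-values in \[0, 1\].
#' @export
adjust_lobe_p <- function(p, n_lobes = 5) {
  pmin(1, p.adjust(p, method = "BH") * n_lobes)
}

LOBE_FAMILIES <- list(
  composite = c("frontal", "temporal", "parietal", "PCG"),
  frontal = "frontal",
  temporal = "temporal",
  parietal = "parietal",
  PCG = "PCG"
)

CONTRAST_SPECS <- tibble::tibble(
  contrast = c("css_vs_css1", "css_vs_css0", "css1_vs_css0", "css0_vs_control"),
  col_a = c("suvr_voi", "suvr_voi", "suvr_css1", "suvr_css0"),
  col_b = c("suvr_css1", "suvr_css0", "suvr_css0", "suvr_control")
)

#' Lobe-wise paired SUVr comparisons
#'
#' For each lobe family (composite = frontal + temporal + parietal + PCG,
#' then each of these four lobes separately; occipital regions are not an
#' amyloid target region and are excluded), all cSS-positive
#' (patient, region) units are pooled and four dependent-samples contrasts
#' are run: whole region vs direct-siderosis stratum, whole region vs
#' surrounding stratum, direct vs surrounding stratum, and surrounding
#' stratum vs contralateral control (restricted to regions with an assigned
#' control). The four raw p-values of each lobe are adjusted with
#' [adjust_lobe_p()]. Lobes without eligible regions report NA throughout.
#'
#' @param suvr combined per-(patient, region) SUVr tibble with columns
#'   `patient_id`, `lobe`, `css_pos`, `suvr_voi`, `suvr_css1`, `suvr_css0`,
#'   `suvr_control`.
#' @param n_lobes Bonferroni factor (default 5).
#' @return tibble: `lobe`, `contrast`, `n`, `mean_a`, `sd_a`, `mean_b`,
#'   `sd_b`, `t`, `df`, `p_raw`, `p_adj`.
#' @export
lobe_comparisons <- function(suvr, n_lobes = 5) {
  pos <- suvr[suvr$css_pos %in% TRUE, ]
  purrr::imap_dfr(LOBE_FAMILIES, function(lobes, fam) {
    sub <- pos[pos$lobe %in% lobes, ]
    rows <- purrr::pmap_dfr(CONTRAST_SPECS, function(contrast, col_a, col_b) {
      dat <- sub[!is.na(sub[[col_a]]) & !is.na(sub[[col_b]]), ]
      if (nrow(dat) < 2) {
        return(tibble::tibble(
          contrast = contrast, n = nrow(dat),
          mean_a = NA_real_, sd_a = NA_real_,
          mean_b = NA_real_, sd_b = NA_real_,
          t = NA_real_, df = NA_real_, p_raw = NA_real_
        ))
      }
      a <- dat[[col_a]]; b <- dat[[col_b]]
      tt <- paired_t(a, b)
      tibble::tibble(
        contrast = contrast, n = nrow(dat),
        mean_a = mean(a), sd_a = sd(a), mean_b = mean(b), sd_b = sd(b),
        t = tt$t, df = tt$df, p_raw = tt$p
      )
    })
    rows$p_adj <- adjust_lobe_p(rows$p_raw, n_lobes = n_lobes)
    dplyr::bind_cols(tibble::tibble(lobe = fam), rows)
  })
}

#' Demographic group comparisons
#'
#' Reproduces the cohort-description statistics: patients vs controls
#' compared on age and injected dose (two-tailed t-test, Welch form by
#' default) and on sex (chi-square without continuity correction), plus the
#' within-patient subgroup comparison splitting patients at 70%
#' amyloid/siderosis overlap.
#'
#' @param subjects a subject tibble as returned by [study_subjects()] /
#'   [load_subject_table()].
#' @param welch use the unequal-variance t (default); `FALSE` pools.
#' @param yates apply continuity correction to the chi-square tests.
#' @return list with `groups` (per-group descriptives), `tests` (tibble of
#'   comparisons: `comparison`, `test`, `statistic`, `p`) and `subgroups`
#'   (descriptives of the overlap split).
#' @export
demographics_analysis <- function(subjects, welch = TRUE, yates = FALSE) {
  caa <- subjects[subjects$group == "CAA", ]
  hc <- subjects[subjects$group == "HC", ]
  groups <- subjects |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_male = sum(.data$sex == "M"), n_female = sum(.data$sex == "F"),
      mean_age = mean(.data$age), sd_age = sd(.data$age),
      mean_dose = mean(.data$injected_dose, na.rm = TRUE),
      sd_dose = sd(.data$injected_dose, na.rm = TRUE),
      mean_mmse = mean(.data$mmse, na.rm = TRUE),
      sd_mmse = sd(.data$mmse, na.rm = TRUE),
      mean_overlap_pct = mean(.data$overlap_pct, na.rm = TRUE),
      sd_overlap_pct = sd(.data$overlap_pct, na.rm = TRUE),
      .groups = "drop"
    )
  age_t <- welch_t(caa$age, hc$age, var_equal = !welch)
  sex_chi <- chi_square_2x2(sum(caa$sex == "M"), sum(caa$sex == "F"),
                            sum(hc$sex == "M"), sum(hc$sex == "F"),
                            correct = yates)
  tests <- tibble::tibble(
    comparison = c("age_caa_vs_hc", "sex_caa_vs_hc"),
    test = c(if (welch) "welch_t" else "pooled_t", "chi_square"),
    statistic = c(age_t$t, sex_chi$chi2),
    p = c(age_t$p, sex_chi$p)
  )
  if (all(is.finite(hc$injected_dose)) || any(is.finite(hc$injected_dose))) {
    dose_t <- welch_t(caa$injected_dose[is.finite(caa$injected_dose)],
                      hc$injected_dose[is.finite(hc$injected_dose)],
                      var_equal = !welch)
    tests <- dplyr::bind_rows(tests, tibble::tibble(
      comparison = "dose_caa_vs_hc",
      test = if (welch) "welch_t" else "pooled_t",
      statistic = dose_t$t, p = dose_t$p
    ))
  }
  subgroups <- NULL
  if ("overlap_pct" %in% names(caa) && any(is.finite(caa$overlap_pct))) {
    hi <- caa[!is.na(caa$overlap_pct) & caa$overlap_pct > 70, ]
    lo <- caa[!is.na(caa$overlap_pct) & caa$overlap_pct <= 70, ]
    if (nrow(hi) >= 2 && nrow(lo) >= 2) {
      subgroups <- dplyr::bind_rows(
        dplyr::mutate(lo, subgroup = "overlap_le_70"),
        dplyr::mutate(hi, subgroup = "overlap_gt_70")
      ) |>
        dplyr::group_by(.data$subgroup) |>
        dplyr::summarise(
          n = dplyr::n(),
          mean_age = mean(.data$age), sd_age = sd(.data$age),
          mean_dose = mean(.data$injected_dose, na.rm = TRUE),
          mean_mmse = mean(.data$mmse, na.rm = TRUE),
          .groups = "drop"
        )
      sub_tests <- tibble::tibble(
        comparison = c("age_subgroups", "dose_subgroups", "mmse_subgroups"),
        test = if (welch) "welch_t" else "pooled_t",
        statistic = c(
          welch_t(lo$age, hi$age, var_equal = !welch)$t,
          welch_t(lo$injected_dose, hi$injected_dose, var_equal = !welch)$t,
          welch_t(lo$mmse, hi$mmse, var_equal = !welch)$t
        ),
        p = c(
          welch_t(lo$age, hi$age, var_equal = !welch)$p,
          welch_t(lo$injected_dose, hi$injected_dose, var_equal = !welch)$p,
          welch_t(lo$mmse, hi$mmse, var_equal = !welch)$p
        )
      )
      tests <- dplyr::bind_rows(tests, sub_tests)
    }
  }
  list(groups = groups, tests = tests, subgroups = subgroups)
}
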