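#' Build the healthy-control SUVr reference
#'
#' Controls are screened a priori with a single leave-one-out pass: control
#' h is excluded when, in at least one region, its SUVr exceeds the mean of
#' the other controls by more than `k_excl` of their standard deviations
#' (one-sided, high values only — the screen removes controls at early
#' stages of amyloid buildup). Per-region mean (MV) and sample SD are then
#' computed over the retained controls.
#'
#' @param hc_suvr long tibble with columns `subject_id`, `region_id`, `suvr`
#'   (one row per control and region).
#' @param k_excl SD multiplier of the exclusion screen (default 2.5).
#' @return an `hc_reference` object: per-region `mv`, `sd`, `n_retained`,
#'   plus `excluded_ids`.
#' @export
build_hc_reference <- function(hc_suvr, k_excl = 2.5) {
  required <- c("subject_id", "region_id", "suvr")
  if (!all(required %in% names(hc_suvr))) {
    abort("hc_suvr needs columns subject_id, region_id, suvr")
  }
  subjects <- unique(hc_suvr$subject_id)
  if (length(subjects) < 3) abort("need >= 3 healthy controls")
  wide <- tidyr::pivot_wider(hc_suvr, id_cols = "subject_id",
                             names_from = "region_id", values_from = "suvr")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$subject_id
  n <- nrow(m)
  excluded <- purrr::map_lgl(seq_len(n), function(h) {
    others <- m[-h, , drop = FALSE]
    mv <- colMeans(others)
    sdv <- apply(others, 2, sd)
    any(m[h, ] > mv + k_excl * sdv)
  })
  retained <- m[!excluded, , drop = FALSE]
  if (nrow(retained) < 2) abort("fewer than 2 retained controls")
  regions <- tibble::tibble(
    region_id = as.integer(colnames(m)),
    mv = unname(colMeans(retained)),
    sd = unname(apply(retained, 2, sd)),
    n_retained = nrow(retained)
  )
  structure(
    list(regions = regions,
         excluded_ids = rownames(m)[excluded],
         k_excl = k_excl, n_input = n),
    class = "hc_reference"
  )
}

#' @export
print.hc_reference <- function(x, ...) {
  cat(sprintf(
    "<hc_reference> %d regions; %d/%d controls retained (k_excl = %g)\n",
    nrow(x$regions), x$n_input - length(x$excluded_ids), x$n_input, x$k_excl
  ))
  if (length(x$excluded_ids) > 0) {
    cat("  excluded:", paste(x$excluded_ids, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @rdname build_hc_reference
#' @param x an `hc_reference`.
#' @param ... unused.
#' @export
tidy.hc_reference <- function(x, ...) x$regions

#' @rdname build_hc_reference
#' @export
glance.hc_reference <- function(x, ...) {
  tibble::tibble(
    n_input = x$n_input,
    n_retained = x$n_input - length(x$excluded_ids),
    n_excluded = length(x$excluded_ids),
    k_excl = x$k_excl
  )
}

#' Classify regions as amyloid-positive
#'
#' A region is amyloid-positive when its whole-VOI SUVr reaches the
#' control-derived threshold MV + `k_pos` SD (inclusive).
#'
#' @param suvr a per-region SUVr tibble (needs `region_id` and `suvr_voi`).
#' @param ref an [build_hc_reference()] object covering all regions.
#' @param k_pos SD multiplier of the positivity threshold (default 2.5; the
#'   2.0 variant is accepted as well).
#' @return `suvr` with columns `ab_threshold` and `ab_pos` added.
#' @export
classify_ab <- function(suvr, ref, k_pos = 2.5) {
  missing <- setdiff(suvr$region_id, ref$regions$region_id)
  if (length(missing) > 0) {
    abort(paste0("regions absent from HC reference: ",
                 paste(missing, collapse = ", ")))
  }
  suvr <- dplyr::select(suvr, -dplyr::any_of(c("ab_threshold", "ab_pos")))
  suvr |>
    dplyr::left_join(
      dplyr::mutate(ref$regions, ab_threshold = .data$mv + k_pos * .data$sd) |>
        dplyr::select("region_id", "ab_threshold"),
      by = "region_id"
    ) |>
    dplyr::mutate(ab_pos = .data$suvr_voi >= .data$ab_threshold)
}

#' Assemble the multiregion classifier matrix
#'
#' Joins the amyloid and siderosis classifications on the common
#' (patient, region) grid and computes the per-patient summary: number of
#' amyloid- and cSS-positive regions, and the percentage of cSS-positive
#' regions that are also amyloid-positive (`overlap_pct`, missing when the
#' patient has no cSS-positive region). `overlap_pct` is kept at full
#' precision; round for Table-style reports.
#'
#' @param ab long tibble: `patient_id`, `region_id`, `ab_pos`.
#' @param css long tibble: `patient_id`, `region_id`, `css_pos`.
#' @return a `region_status_matrix` (a tibble with a `patients` attribute).
#' @export
assemble_matrix <- function(ab, css) {
  key_ab <- dplyr::arrange(ab[c("patient_id", "region_id")],
                           .data$patient_id, .data$region_id)
  key_css <- dplyr::arrange(css[c("patient_id", "region_id")],
                            .data$patient_id, .data$region_id)
  if (!identical(key_ab, key_css)) {
    abort("ab and css classifications cover different (patient, region) grids")
  }
  cell <- dplyr::inner_join(
    dplyr::select(ab, "patient_id", "region_id",
                  dplyr::any_of(c("lobe", "hemisphere")), "ab_pos"),
    dplyr::select(css, "patient_id", "region_id", "css_pos"),
    by = c("patient_id", "region_id")
  )
  patients <- cell |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      n_ab_pos = sum(.data$ab_pos),
      n_css_pos = sum(.data$css_pos),
      overlap_pct = ifelse(.data$n_css_pos > 0,
                           100 * sum(.data$ab_pos & .data$css_pos) / .data$n_css_pos,
                           NA_real_),
      .groups = "drop"
    )
  structure(cell, patients = patients,
            class = c("region_status_matrix", class(cell)))
}

#' @export
summary.region_status_matrix <- function(object, ...) {
  attr(object, "patients")
}

#' @rdname assemble_matrix
#' @param x a `region_status_matrix`.
#' @param ... unused.
#' @export
glance.region_status_matrix <- function(x, ...) {
  pats <- attr(x, "patients")
  tibble::tibble(
    n_patients = nrow(pats),
    n_regions = length(unique(x$region_id)),
    n_ab_pos = sum(x$ab_pos),
    n_css_pos = sum(x$css_pos),
    mean_overlap_pct = mean(pats$overlap_pct, na.rm = TRUE)
  )
}
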