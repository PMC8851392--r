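CORTICAL_LOBES <- c("frontal", "temporal", "parietal", "occipital", "PCG")
PAPER_LOBE_COUNTS <- c(frontal = 26L, temporal = 20L, parietal = 6L,
                       occipital = 6L, PCG = 2L)

#' Validate a region table
#'
#' A region table defines the atlas volumes of interest (VOIs): one row per
#' region with its id, name, hemisphere, lobe and contralateral homolog.
#' The standard reduced cortical set has 60 regions (30 per hemisphere:
#' 26 frontal, 20 temporal, 6 parietal, 6 occipital, 2 posterior cingulate)
#' plus left and right cerebellum used as the SUVr reference.
#'
#' @param table a data frame with columns `region_id`, `name`, `hemisphere`
#'   (`L`, `R` or `midline`), `lobe` (`frontal`, `temporal`, `parietal`,
#'   `occipital`, `PCG`, `cerebellum` or `excluded`) and `homolog_id`
#'   (region id or `NA`).
#' @param paper_standard if `TRUE`, additionally require the standard lobe
#'   composition (26/20/6/6/2 cortical, 2 cerebellar).
#' @return the validated table as a tibble, invisibly usable downstream.
#' @export
validate_region_table <- function(table, paper_standard = FALSE) {
  required <- c("region_id", "name", "hemisphere", "lobe", "homolog_id")
  missing <- setdiff(required, names(table))
  if (length(missing) > 0) {
    abort(paste0("region table missing columns: ", paste(missing, collapse = ", ")))
  }
  tbl <- tibble::as_tibble(table)
  tbl$region_id <- as.integer(tbl$region_id)
  tbl$homolog_id <- suppressWarnings(as.integer(tbl$homolog_id))
  if (anyNA(tbl$region_id) || any(tbl$region_id <= 0)) {
    abort("region_id must be positive integers")
  }
  if (anyDuplicated(tbl$region_id)) abort("duplicate region_id")
  bad_hemi <- setdiff(unique(tbl$hemisphere), c("L", "R", "midline"))
  if (length(bad_hemi) > 0) {
    abort(paste0("invalid hemisphere value: ", paste(bad_hemi, collapse = ", ")))
  }
  bad_lobe <- setdiff(unique(tbl$lobe), c(CORTICAL_LOBES, "cerebellum", "excluded"))
  if (length(bad_lobe) > 0) {
    abort(paste0("invalid lobe value: ", paste(bad_lobe, collapse = ", ")))
  }
  # homolog relation must be symmetric: homolog(homolog(i)) == i
  has_h <- !is.na(tbl$homolog_id)
  if (any(!tbl$homolog_id[has_h] %in% tbl$region_id)) {
    abort("homolog_id refers to unknown region_id")
  }
  idx <- match(tbl$homolog_id[has_h], tbl$region_id)
  back <- tbl$homolog_id[idx]
  if (anyNA(back) || any(back != tbl$region_id[has_h])) {
    abort("homolog mapping is not symmetric")
  }
  if (paper_standard) {
    cortical <- tbl[tbl$lobe %in% CORTICAL_LOBES, ]
    counts <- table(factor(cortical$lobe, levels = names(PAPER_LOBE_COUNTS)))
    if (nrow(cortical) != 60L || any(counts != PAPER_LOBE_COUNTS)) {
      abort(sprintf(
        paste0(
          "paper-standard region table requires 26/20/6/6/2 cortical regions ",
          "(got %s = %d total)"
        ),
        paste(counts, collapse = "/"), nrow(cortical)
      ))
    }
    cere <- tbl[tbl$lobe == "cerebellum", ]
    if (nrow(cere) != 2L || !setequal(cere$hemisphere, c("L", "R"))) {
      abort("paper-standard region table requires exactly 2 cerebellar rows (L, R)")
    }
    if (any(cortical$hemisphere == "midline")) {
      abort("paper-standard region table has no midline regions (30 per hemisphere)")
    }
  }
  tbl
}

#' Load a region table from delimited text
#'
#' @param path CSV or TSV file with the columns described in
#'   [validate_region_table()].
#' @inheritParams validate_region_table
#' @return a validated tibble.
#' @export
load_region_table <- function(path, paper_standard = FALSE) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  delim <- if (grepl("\\.tsv$", path)) "\t" else ","
  tbl <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE, na = c("", "NA", "n.a."))
  validate_region_table(tbl, paper_standard = paper_standard)
}

#' The packaged standard region table
#'
#' The reduced 62-region table used throughout the package: 60 cortical VOIs
#' (26 frontal, 20 temporal, 6 parietal, 6 occipital, 2 posterior cingulate;
#' 30 per hemisphere with mirror-image homologs) plus left/right cerebellum.
#' Region names are the synthetic block labels of [make_atlas()].
#'
#' @return a validated region-table tibble with 62 rows.
#' @export
standard_region_table <- function() {
  path <- system.file("extdata", "region_table_standard.csv",
                      package = "petcoloc", mustWork = TRUE)
  load_region_table(path, paper_standard = TRUE)
}

#' Load a subject metadata table
#'
#' One row per subject: `subject_id`, `group` (`CAA` or `HC`), `sex`
#' (`M`/`F`), `age` (years), and for patients `mmse`, `injected_dose` (MBq),
#' `caa_status` (`possible`/`probable`), `css_pattern`
#' (`focal`/`disseminated`) and `overlap_pct`. Missing values are encoded
#' explicitly as `n.a.`/`NA`, never as 0. Healthy controls must carry no
#' CAA status or cSS pattern.
#'
#' @param path CSV or TSV file.
#' @return a tibble.
#' @export
load_subject_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  delim <- if (grepl("\\.tsv$", path)) "\t" else ","
  tbl <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE, na = c("", "NA", "n.a."))
  required <- c("subject_id", "group", "sex", "age")
  missing <- setdiff(required, names(tbl))
  if (length(missing) > 0) {
    abort(paste0("subject table missing columns: ", paste(missing, collapse = ", ")))
  }
  if (!all(tbl$group %in% c("CAA", "HC"))) abort("group must be CAA or HC")
  hc <- tbl[tbl$group == "HC", ]
  for (col in intersect(c("caa_status", "css_pattern"), names(tbl))) {
    if (any(!is.na(hc[[col]]))) {
      abort(sprintf("healthy controls must have %s = n.a.", col))
    }
  }
  tibble::as_tibble(tbl)
}

#' The packaged study demographics table
#'
#' Demographic and clinical data of the 10 CAA patients and 14 healthy
#' controls (sex, age at PET, injected florbetaben dose, MMSE, CAA status,
#' cSS pattern, and the per-patient percentage of cSS-positive regions that
#' were also amyloid-positive).
#'
#' @return a tibble with 24 rows.
#' @export
study_subjects <- function() {
  path <- system.file("extdata", "study_subjects.csv",
                      package = "petcoloc", mustWork = TRUE)
  load_subject_table(path)
}
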