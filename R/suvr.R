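#' Mean activity over a voxel set
#'
#' @param pet an [image3d()] activity image.
#' @param voxel_set integer vector of linear voxel indices.
#' @return arithmetic mean of the activity over the set.
#' @export
voi_mean <- function(pet, voxel_set) {
  if (length(voxel_set) == 0) abort("empty stratum")
  mean(pet$voxels[voxel_set])
}

#' Cerebellar reference activity
#'
#' The left and right cerebellar VOI means are averaged (unweighted, the
#' default) to form the SUVr reference. For unequal VOI sizes a pooled-voxel
#' mean is available as an alternative.
#'
#' @param pet an [image3d()] activity image.
#' @param atlas a [label_atlas()] containing cerebellar L and R regions.
#' @param method `"voi_mean"` (default, mean of the two VOI means) or
#'   `"pooled"` (mean over the union of voxels).
#' @return reference activity (scalar).
#' @export
cerebellar_reference <- function(pet, atlas, method = c("voi_mean", "pooled")) {
  method <- match.arg(method)
  cere <- atlas$table[atlas$table$lobe == "cerebellum", ]
  if (nrow(cere) != 2L) abort("atlas must contain exactly 2 cerebellar regions")
  idx <- purrr::map(cere$region_id, ~ region_voxels(atlas, .x))
  if (any(lengths(idx) == 0)) abort("missing cerebellar label in atlas volume")
  if (method == "voi_mean") {
    mean(purrr::map_dbl(idx, ~ voi_mean(pet, .x)))
  } else {
    voi_mean(pet, unlist(idx))
  }
}

#' Cerebellum-referenced SUVr per region and cSS stratum
#'
#' For every cortical VOI the whole-region SUVr is computed as the VOI mean
#' activity divided by the cerebellar reference. For cSS-positive VOIs the
#' direct-siderosis (cSS+1) and surrounding (cSS+0) strata get their own
#' SUVr, and regions with an assigned contralateral control also report the
#' control region's SUVr. Injected dose and body weight cancel in the ratio
#' and are not required.
#'
#' @param pet an [image3d()] activity image.
#' @param statuses per-patient status tibble from [classify_css_regions()]
#'   (after [assign_contralateral_controls()] if control SUVr is wanted).
#' @param atlas a [label_atlas()] on the same grid as `pet`.
#' @param reference `"voi_mean"` or `"pooled"`, see [cerebellar_reference()].
#' @return a tibble with one row per cortical region: `region_id`, `name`,
#'   `hemisphere`, `lobe`, `css_pos`, `suvr_voi`, `suvr_css1`, `suvr_css0`,
#'   `suvr_control`, `control_region_id`, `n_css1`, `n_css0`, `n_voxels`.
#' @export
compute_suvr <- function(pet, statuses, atlas,
                         reference = c("voi_mean", "pooled")) {
  assert_same_grid(pet, atlas$labels)
  means <- region_mean_vector(pet, atlas)
  cere <- atlas$table$region_id[atlas$table$lobe == "cerebellum"]
  ref <- if (match.arg(reference) == "voi_mean") {
    mean(means[as.character(cere)])
  } else {
    cnt <- atlas$counts[as.character(cere)]
    sum(means[as.character(cere)] * cnt) / sum(cnt)
  }
  if (!is.finite(ref) || ref <= 0) abort("nonpositive cerebellar reference")
  has_control <- "control_region_id" %in% names(statuses)
  n <- nrow(statuses)
  suvr_voi <- unname(means[as.character(statuses$region_id)]) / ref
  s1 <- rep(NA_real_, n); s0 <- rep(NA_real_, n); ctrl <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (isTRUE(statuses$css_pos[i])) {
      s1[i] <- voi_mean(pet, statuses$css1_idx[[i]]) / ref
      s0[i] <- if (length(statuses$css0_idx[[i]]) > 0) {
        voi_mean(pet, statuses$css0_idx[[i]]) / ref
      } else {
        NA_real_
      }
    }
    if (has_control && !is.na(statuses$control_region_id[i])) {
      ctrl[i] <- means[as.character(statuses$control_region_id[i])] / ref
    }
  }
  rows <- tibble::tibble(region_id = statuses$region_id, suvr_voi = suvr_voi,
                         suvr_css1 = s1, suvr_css0 = s0, suvr_control = ctrl)
  keep <- intersect(
    c("region_id", "name", "hemisphere", "lobe", "homolog_id", "css_pos",
      "control_region_id", "n_css1", "n_css0", "n_voxels"),
    names(statuses)
  )
  dplyr::left_join(dplyr::select(statuses, dplyr::all_of(keep)), rows,
                   by = "region_id")
}
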