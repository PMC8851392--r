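gaussian_kernel_1d <- function(sigma_vox) {
  r <- max(1L, ceiling(4 * sigma_vox))
  w <- exp(-((-r:r)^2) / (2 * sigma_vox^2))
  w / sum(w)
}

# banded convolution matrix for one axis, zero padding at the edges
conv_band_matrix <- function(n, w) {
  r <- (length(w) - 1L) / 2L
  K <- matrix(0, n, n)
  for (off in -r:r) {
    i <- seq_len(n)
    j <- i + off
    ok <- j >= 1L & j <= n
    K[cbind(i[ok], j[ok])] <- w[off + r + 1L]
  }
  K
}

#' Smooth a binary segmentation into a probability map
#'
#' Separable Gaussian smoothing of a binary cSS segmentation, emulating the
#' effective PET resolution. The width is given as full-width-at-half-maximum
#' in mm (the PET-resolution convention), so sigma = fwhm / (2 sqrt(2 ln 2))
#' per axis, converted to voxels via the image spacing. The kernel is
#' truncated at 4 sigma and normalized; edges are zero-padded and the output
#' clipped to \[0, 1\], so a fully interior solid mask keeps value 1.
#'
#' @param mask an [image3d()] with values exactly in \{0, 1\}.
#' @param fwhm_mm smoothing width in mm (default 5).
#' @param interpretation `"fwhm"` (default) treats `fwhm_mm` as FWHM;
#'   `"sigma"` treats it directly as the Gaussian sigma in mm.
#' @return a `smoothed_css_map`: list with `map` (an [image3d()] bounded in
#'   \[0,1\]) and `fwhm_mm`.
#' @export
smooth_mask <- function(mask, fwhm_mm = 5, interpretation = c("fwhm", "sigma")) {
  interpretation <- match.arg(interpretation)
  if (!inherits(mask, "image3d")) abort("mask must be an image3d")
  if (!is_binary_mask(mask)) abort("mask must be binary (values in {0, 1})")
  if (fwhm_mm <= 0) abort("fwhm_mm must be > 0")
  sigma_mm <- if (interpretation == "fwhm") {
    fwhm_mm / (2 * sqrt(2 * log(2)))
  } else {
    fwhm_mm
  }
  v <- mask$voxels
  d <- dim(v)
  # axis 1
  K <- conv_band_matrix(d[1], gaussian_kernel_1d(sigma_mm / mask$spacing[1]))
  v <- array(K %*% matrix(v, d[1], d[2] * d[3]), dim = d)
  # axis 2, slice by slice
  K <- conv_band_matrix(d[2], gaussian_kernel_1d(sigma_mm / mask$spacing[2]))
  tK <- t(K)
  for (k in seq_len(d[3])) v[, , k] <- v[, , k] %*% tK
  # axis 3
  K <- conv_band_matrix(d[3], gaussian_kernel_1d(sigma_mm / mask$spacing[3]))
  v <- array(matrix(v, d[1] * d[2], d[3]) %*% t(K), dim = d)
  v[v < 0] <- 0
  v[v > 1] <- 1
  structure(
    list(map = image3d(v, spacing = mask$spacing, origin = mask$origin),
         fwhm_mm = fwhm_mm),
    class = "smoothed_css_map"
  )
}

#' Classify atlas regions as cSS-positive and partition their voxels
#'
#' A cortical VOI is cSS-positive when the smoothed segmentation reaches the
#' probability threshold inside it (default rule: maximum smoothed value
#' >= `prob_threshold`; the alternative `"fraction"` rule requires at least
#' `1 - prob_threshold` of the VOI volume at or above `voxel_tau`). Within
#' every cSS-positive VOI, voxels with smoothed value >= `voxel_tau` form
#' the direct-siderosis stratum (cSS+1) and the remainder the surrounding
#' stratum (cSS+0); together they partition the VOI exactly. Negative VOIs
#' carry no partition. Cerebellar and non-cortical regions are never
#' classified.
#'
#' @param smap a `smoothed_css_map` from [smooth_mask()].
#' @param atlas a [label_atlas()] on the same grid.
#' @param prob_threshold region-level positivity threshold (default 0.90).
#' @param voxel_tau voxel-level stratum threshold (default 0.1).
#' @param rule `"max"` (default) or `"fraction"`, see Details.
#' @return a tibble with one row per cortical region: `region_id`, `name`,
#'   `hemisphere`, `lobe`, `css_pos`, `n_voxels`, `n_css1`, `n_css0`, and
#'   list-columns `css1_idx` / `css0_idx` of linear voxel indices (NULL for
#'   negative regions).
#' @export
classify_css_regions <- function(smap, atlas, prob_threshold = 0.90,
                                 voxel_tau = 0.1, rule = c("max", "fraction")) {
  rule <- match.arg(rule)
  assert_same_grid(smap$map, atlas$labels)
  if (prob_threshold <= 0 || prob_threshold > 1) {
    abort("prob_threshold must be in (0, 1]")
  }
  if (voxel_tau <= 0 || voxel_tau > 1) abort("voxel_tau must be in (0, 1]")
  v <- smap$map$voxels
  tbl <- atlas$table[atlas$table$lobe %in% CORTICAL_LOBES, ]
  nreg <- nrow(tbl)
  css_pos <- logical(nreg)
  n_voxels <- integer(nreg)
  n_css1 <- rep(NA_integer_, nreg)
  n_css0 <- rep(NA_integer_, nreg)
  css1_idx <- vector("list", nreg)
  css0_idx <- vector("list", nreg)
  for (i in seq_len(nreg)) {
    idx <- region_voxels(atlas, tbl$region_id[i])
    vals <- v[idx]
    n_voxels[i] <- length(idx)
    pos <- if (rule == "max") {
      max(vals) >= prob_threshold
    } else {
      mean(vals >= voxel_tau) >= (1 - prob_threshold)
    }
    css_pos[i] <- pos
    if (pos) {
      in1 <- vals >= voxel_tau
      n_css1[i] <- sum(in1)
      n_css0[i] <- sum(!in1)
      css1_idx[[i]] <- idx[in1]
      css0_idx[[i]] <- idx[!in1]
    }
  }
  dplyr::bind_cols(
    dplyr::select(tbl, "region_id", "name", "hemisphere", "lobe", "homolog_id"),
    tibble::tibble(css_pos = css_pos, n_voxels = n_voxels,
                   n_css1 = n_css1, n_css0 = n_css0,
                   css1_idx = css1_idx, css0_idx = css0_idx)
  )
}

#' Assign contralateral control regions
#'
#' Each cSS-positive VOI receives its contralateral homolog as control
#' region if and only if that homolog is itself cSS-negative; otherwise no
#' control is assigned.
#'
#' @param statuses output of [classify_css_regions()].
#' @return `statuses` with a `control_region_id` column added.
#' @export
assign_contralateral_controls <- function(statuses) {
  status_of <- setNames(statuses$css_pos, statuses$region_id)
  statuses |>
    dplyr::mutate(
      control_region_id = dplyr::if_else(
        .data$css_pos & !is.na(.data$homolog_id) &
          !dplyr::coalesce(status_of[as.character(.data$homolog_id)], TRUE),
        .data$homolog_id, NA_integer_
      )
    )
}

#' Classify a patient's siderosis pattern
#'
#' Region-count proxy for the sulcus-based clinical rule: at most 3
#' cSS-positive regions is `focal`, more is `disseminated`.
#'
#' @param statuses a per-patient status tibble from [classify_css_regions()].
#' @return `"focal"` or `"disseminated"`.
#' @export
classify_dissemination <- function(statuses) {
  if (sum(statuses$css_pos) <= 3L) "focal" else "disseminated"
}

#' Unilateral vs bilateral siderosis bookkeeping
#'
#' Counts, over a set of per-patient status tibbles, how many cSS-positive
#' regions have a cSS-positive contralateral homolog (bilateral) versus not
#' (unilateral).
#'
#' @param status_list list of per-patient tibbles from
#'   [classify_css_regions()].
#' @return tibble with `n_css_pos`, `n_unilateral`, `n_bilateral`.
#' @export
laterality_summary <- function(status_list) {
  counts <- purrr::map_dfr(status_list, function(st) {
    status_of <- setNames(st$css_pos, st$region_id)
    pos <- st[st$css_pos, ]
    bilateral <- sum(status_of[as.character(pos$homolog_id)], na.rm = TRUE)
    tibble::tibble(n_pos = nrow(pos), n_bi = bilateral)
  })
  tibble::tibble(
    n_css_pos = sum(counts$n_pos),
    n_unilateral = sum(counts$n_pos) - sum(counts$n_bi),
    n_bilateral = sum(counts$n_bi)
  )
}
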