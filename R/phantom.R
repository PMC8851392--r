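#' Phantom cohort configuration
#'
#' Defines the synthetic study conditions: a 10-patient / 14-control cohort
#' on a 64 x 64 x 48 voxel grid at 2 mm spacing, with 60 cortical VOIs and
#' 2 cerebellar reference VOIs. Healthy-control SUVr per region is
#' approximately N(1.3, 0.1), composed of a per-subject global uptake effect
#' (shared across cortical regions, mimicking the strong inter-regional
#' correlation of amyloid PET), an independent per-region effect, and voxel
#' noise; the cerebellar activity is fixed at `ref_level` so true SUVr is
#' known. Siderosis is planted as 6-mm-thick crossing line segments confined
#' to the listed regions, and amyloid-positive regions are drawn with a
#' tunable coupling `coloc_rho` to the siderosis regions.
#'
#' @param grid integer length-3 voxel grid shape.
#' @param spacing numeric length-3 voxel size in mm.
#' @param n_hc number of healthy controls (>= 2).
#' @param n_patients number of patients.
#' @param hc_mean cortical activity mean, in units of `ref_level` (so the
#'   true baseline SUVr equals `hc_mean / ref_level`).
#' @param hc_region_sd total across-subject SD of a region's activity
#'   (marginal; each region's mean activity is Normal(`hc_mean`,
#'   `hc_region_sd`)).
#' @param subject_rho fraction of `hc_region_sd^2` carried by the
#'   per-subject global uptake effect shared across cortical regions. Real
#'   amyloid-PET regional SUVr are strongly correlated across regions within
#'   a subject; the default 0.9 reproduces that structure and keeps the
#'   a-priori control screen selective for genuinely high-uptake subjects.
#' @param noise_sd SD of iid voxel noise.
#' @param ref_level cerebellar (reference) activity level.
#' @param p_ab baseline probability that a cortical region carries a planted
#'   amyloid elevation.
#' @param ab_effect multiplicative activity elevation of planted
#'   amyloid-positive regions.
#' @param coloc_rho probability in \[0,1\] that a siderosis region is
#'   additionally forced amyloid-positive: P(abeta+ | cSS region) =
#'   `p_ab + coloc_rho * (1 - p_ab)`, so 0 gives exact independence and 1
#'   full nesting.
#' @param css_counts integer vector (recycled to `n_patients`): number of
#'   siderosis regions per patient. The default mirrors a cohort of 4 focal
#'   (<= 3 regions) and 6 disseminated patients totalling 170 regions.
#' @param css_regions optional list of explicit cortical region-id vectors,
#'   one per patient; overrides `css_counts`.
#' @param css_line_thickness_mm thickness of the planted siderosis lines.
#' @param css1_deficit planted SUVr deficit applied to voxels of the
#'   direct-siderosis stratum (smoothed map >= 0.1); 0 disables.
#' @param fwhm_mm smoothing width used when planting `css1_deficit`.
#' @param seed master seed; one RNG stream per subject is derived from
#'   (seed, subject index) so cohorts are reproducible under subsetting.
#' @return a validated `phantom_config` list.
#' @export
phantom_config <- function(grid = c(64, 64, 48),
                           spacing = c(2, 2, 2),
                           n_hc = 14,
                           n_patients = 10,
                           hc_mean = 1.3,
                           hc_region_sd = 0.095,
                           subject_rho = 0.9,
                           noise_sd = 0.05,
                           ref_level = 1.0,
                           p_ab = 0.6,
                           ab_effect = 1.4,
                           coloc_rho = 0,
                           css_counts = c(1, 2, 2, 3, 13, 20, 25, 30, 35, 39),
                           css_regions = NULL,
                           css_line_thickness_mm = 6,
                           css1_deficit = 0,
                           fwhm_mm = 5,
                           seed = 1L) {
  cfg <- list(
    grid = as.integer(grid), spacing = as.numeric(spacing),
    n_hc = as.integer(n_hc), n_patients = as.integer(n_patients),
    hc_mean = hc_mean, hc_region_sd = hc_region_sd, subject_rho = subject_rho,
    noise_sd = noise_sd, ref_level = ref_level,
    p_ab = p_ab, ab_effect = ab_effect, coloc_rho = coloc_rho,
    css_counts = as.integer(rep_len(css_counts, n_patients)),
    css_regions = css_regions,
    css_line_thickness_mm = css_line_thickness_mm,
    css1_deficit = css1_deficit, fwhm_mm = fwhm_mm,
    seed = as.integer(seed)
  )
  if (cfg$coloc_rho < 0 || cfg$coloc_rho > 1) abort("coloc_rho must be in [0, 1]")
  if (cfg$p_ab < 0 || cfg$p_ab > 1) abort("p_ab must be in [0, 1]")
  if (cfg$n_hc < 2) abort("n_hc must be >= 2")
  sds <- c(cfg$hc_region_sd, cfg$noise_sd)
  if (any(sds < 0)) abort("all SDs must be >= 0")
  if (cfg$subject_rho < 0 || cfg$subject_rho > 1) {
    abort("subject_rho must be in [0, 1]")
  }
  if (cfg$ref_level <= 0) abort("ref_level must be > 0")
  if (cfg$ab_effect <= 0) abort("ab_effect must be > 0")
  structure(cfg, class = "phantom_config")
}

# deterministic per-subject stream: small integer, below 2^31
derive_seed <- function(master, role, index) {
  offset <- switch(role, hc = 1000L, patient = 2000L, cohort = 3000L,
                   abort("unknown seed role"))
  as.integer((as.double(master) * 48611 + offset * 7919 + index * 104729) %%
               2147483647)
}

#' Build a label atlas
#'
#' Binds an integer label volume to its region table, validates that every
#' nonzero label is described and every cortical region is nonempty, and
#' caches the per-region voxel index sets used by all VOI statistics.
#'
#' @param labels an [image3d()] with integer voxel labels (0 = background).
#' @param table a region table (see [validate_region_table()]).
#' @return a `label_atlas` object.
#' @export
label_atlas <- function(labels, table) {
  table <- validate_region_table(table)
  lab <- as.integer(labels$voxels)
  present <- sort(unique(lab[lab != 0L]))
  unknown <- setdiff(present, table$region_id)
  if (length(unknown) > 0) {
    abort(paste0("labels not in region table: ", paste(unknown, collapse = ", ")))
  }
  cortical <- table$region_id[table$lobe %in% CORTICAL_LOBES]
  empty <- setdiff(cortical, present)
  if (length(empty) > 0) {
    abort(paste0("cortical regions with no voxels: ", paste(empty, collapse = ", ")))
  }
  idx <- split(seq_along(lab), lab)
  idx[["0"]] <- NULL
  nz <- which(lab != 0L)
  counts <- lengths(idx)
  structure(
    list(labels = labels, table = table, index = idx,
         nz = nz, nz_lab = lab[nz], counts = counts),
    class = "label_atlas"
  )
}

# mean activity of every labeled region in one pass (named by region id)
region_mean_vector <- function(pet, atlas) {
  s <- rowsum(pet$voxels[atlas$nz], atlas$nz_lab, reorder = TRUE)
  means <- s[, 1] / atlas$counts[rownames(s)]
  means
}

#' @export
print.label_atlas <- function(x, ...) {
  cat(sprintf(
    "<label_atlas> %d regions on a %s grid\n",
    nrow(x$table), paste(dim(x$labels$voxels), collapse = " x ")
  ))
  print(dplyr::count(x$table, .data$lobe))
  invisible(x)
}

region_voxels <- function(atlas, region_id) {
  idx <- atlas$index[[as.character(region_id)]]
  if (is.null(idx)) integer(0) else idx
}

cortical_ids <- function(atlas) {
  atlas$table$region_id[atlas$table$lobe %in% CORTICAL_LOBES]
}

# lobe assignment for the 6 (y) x 5 (z) block grid of one hemisphere;
# yields 13 frontal, 10 temporal, 3 parietal, 3 occipital, 1 PCG
block_lobe <- function(yi, zi) {
  if (yi >= 5) return("frontal")
  if (yi == 4 && zi >= 3) return("frontal")
  if (zi <= 2) return("temporal")
  if (yi <= 1) return("occipital")
  if (yi == 2 && zi == 3) return("temporal")
  if (yi == 3 && zi == 3) return("temporal")
  if (yi == 2 && zi == 4) return("PCG")
  "parietal"
}

split_range <- function(from, to, k) {
  n <- to - from + 1L
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ends <- cumsum(sizes) + from - 1L
  starts <- ends - sizes + 1L
  purrr::map2(starts, ends, ~ seq.int(.x, .y))
}

#' Construct the phantom atlas
#'
#' Builds a left/right mirror-symmetric parcellation: each hemisphere is a
#' lateral cortical plate partitioned into 30 cuboid blocks arranged on a
#' 6 (anterior-posterior) by 5 (inferior-superior) grid, with lobes assigned
#' to match the standard composition (13 frontal, 10 temporal, 3 parietal,
#' 3 occipital, 1 posterior cingulate per hemisphere). Left and right
#' cerebellar VOIs occupy an inferior slab. Homolog pairs are exact mirror
#' images, hence equal in voxel count. Region ids: left 1-30, right 31-60
#' (homolog = id + 30), cerebellum 61 (L) and 62 (R).
#'
#' @param config a [phantom_config()] (grid and spacing are used).
#' @return a [label_atlas()] with 62 regions.
#' @export
make_atlas <- function(config = phantom_config()) {
  n <- config$grid
  n1 <- n[1]; n2 <- n[2]; n3 <- n[3]

  pxw <- max(3L, round(n1 * 0.16))           # plate thickness (x)
  px0 <- max(2L, round(n1 * 0.09))
  lx <- seq.int(px0, px0 + pxw - 1L)
  y0 <- max(2L, round(n2 * 0.12)); y1 <- n2 + 1L - y0
  cz_lo <- max(2L, round(n3 * 0.04))
  cz_hi <- cz_lo + max(3L, round(n3 * 0.12)) - 1L
  z0 <- cz_hi + 3L
  z1 <- n3 - max(2L, round(n3 * 0.06))

  if (max(lx) >= floor(n1 / 2) || y1 - y0 + 1L < 18L || z1 - z0 + 1L < 15L ||
      cz_hi >= n3) {
    abort("grid too small")
  }
  yb <- split_range(y0, y1, 6L)
  zb <- split_range(z0, z1, 5L)
  if (any(lengths(yb) < 3L) || any(lengths(zb) < 3L)) abort("grid too small")

  lab <- array(0L, dim = n)
  rows <- list()
  lobe_counter <- c(frontal = 0L, temporal = 0L, parietal = 0L,
                    occipital = 0L, PCG = 0L)
  rid <- 0L
  for (yi in 1:6) {
    for (zi in 1:5) {
      rid <- rid + 1L
      lobe <- block_lobe(yi, zi)
      lobe_counter[lobe] <- lobe_counter[lobe] + 1L
      lab[lx, yb[[yi]], zb[[zi]]] <- rid                 # left
      lab[n1 + 1L - lx, yb[[yi]], zb[[zi]]] <- rid + 30L # mirrored right
      nm <- sprintf("%s_%02d", lobe, lobe_counter[lobe])
      rows[[length(rows) + 1L]] <- tibble::tibble(
        region_id = c(rid, rid + 30L),
        name = paste0(nm, c("_L", "_R")),
        hemisphere = c("L", "R"),
        lobe = lobe,
        homolog_id = c(rid + 30L, rid)
      )
    }
  }
  # cerebellum: inferior slab, mirrored halves
  cx <- seq.int(px0, floor(n1 / 2) - 2L)
  cy <- seq.int(round(n2 * 0.3), round(n2 * 0.7))
  cz <- seq.int(cz_lo, cz_hi)
  lab[cx, cy, cz] <- 61L
  lab[n1 + 1L - cx, cy, cz] <- 62L
  rows[[length(rows) + 1L]] <- tibble::tibble(
    region_id = c(61L, 62L),
    name = c("cerebellum_L", "cerebellum_R"),
    hemisphere = c("L", "R"),
    lobe = "cerebellum",
    homolog_id = c(62L, 61L)
  )
  table <- dplyr::bind_rows(rows) |> dplyr::arrange(.data$region_id)

  counts <- tabulate(lab[lab > 0L], nbins = 62L)
  if (any(counts < 27L)) abort("grid too small")

  label_atlas(image3d(lab, spacing = config$spacing), table)
}

# region activity means for one subject: cortical regions share a global
# uptake effect; cerebellum is pinned to ref_level so true SUVr is known
draw_region_means <- function(config, atlas) {
  tbl <- atlas$table
  cortical <- tbl$lobe %in% CORTICAL_LOBES
  s_global <- config$hc_region_sd * sqrt(config$subject_rho)
  s_region <- config$hc_region_sd * sqrt(1 - config$subject_rho)
  global <- rnorm(1, 0, s_global)
  means <- ifelse(cortical,
                  config$hc_mean + global + rnorm(nrow(tbl), 0, s_region),
                  config$ref_level)
  setNames(means, tbl$region_id)
}

fill_regions <- function(config, atlas, means) {
  vox <- array(0, dim = config$grid)
  by_label <- numeric(max(atlas$nz_lab))
  by_label[as.integer(names(means))] <- means
  vox[atlas$nz] <- by_label[atlas$nz_lab]
  vox
}

render_image <- function(config, atlas, means) {
  vox <- fill_regions(config, atlas, means)
  if (config$noise_sd > 0) {
    vox <- vox + rnorm(length(vox), 0, config$noise_sd)
  }
  image3d(vox, spacing = config$spacing)
}

#' Simulate the healthy-control arm
#'
#' One image per control: per-region activity drawn from the HC model of
#' [phantom_config()] plus voxel noise. Deterministic given the master seed;
#' each subject uses its own derived RNG stream.
#'
#' @param atlas a [label_atlas()] from [make_atlas()].
#' @param config a [phantom_config()].
#' @return list with `images` (list of [image3d()]) and `subjects` (tibble).
#' @export
simulate_hc_images <- function(atlas, config) {
  images <- vector("list", config$n_hc)
  ages <- integer(config$n_hc)
  for (i in seq_len(config$n_hc)) {
    set.seed(derive_seed(config$seed, "hc", i))
    means <- draw_region_means(config, atlas)
    images[[i]] <- render_image(config, atlas, means)
    ages[i] <- as.integer(round(rnorm(1, 65.9, 5.7)))
  }
  subjects <- tibble::tibble(
    subject_id = sprintf("HC%02d", seq_len(config$n_hc)),
    group = "HC",
    sex = rep_len(c("M", "F"), config$n_hc),
    age = ages,
    mmse = NA_integer_, injected_dose = NA_real_,
    caa_status = NA_character_, css_pattern = NA_character_
  )
  list(images = images, subjects = subjects)
}

# two crossing slabs (thickness in y resp. z) through the region centroid,
# clipped to the region: siderosis tracing the two banks of a sulcus
make_css_mask_voxels <- function(atlas, config, regions) {
  d <- config$grid
  mask <- array(0, dim = d)
  half <- config$css_line_thickness_mm / 2
  for (rid in regions) {
    idx <- region_voxels(atlas, rid)
    coord <- arrayInd(idx, d)
    cy <- round(mean(coord[, 2])); cz <- round(mean(coord[, 3]))
    in_y <- abs(coord[, 2] - cy) * config$spacing[2] <= half
    in_z <- abs(coord[, 3] - cz) * config$spacing[3] <= half
    mask[idx[in_y | in_z]] <- 1
  }
  mask
}

#' Simulate one patient
#'
#' Draws the patient's true siderosis and amyloid region sets (with coupling
#' `coloc_rho`), renders the PET image with multiplicative amyloid elevation
#' in planted regions and an optional direct-siderosis SUVr deficit, and
#' rasterizes the binary siderosis mask.
#'
#' @inheritParams simulate_hc_images
#' @param patient_idx patient index (1-based), used to derive the RNG stream.
#' @return list with `pet`, `css_mask` (both [image3d()]) and `truth`
#'   (list with `css_regions`, `ab_regions`).
#' @export
simulate_patient <- function(atlas, config, patient_idx) {
  set.seed(derive_seed(config$seed, "patient", patient_idx))
  cort <- cortical_ids(atlas)

  if (!is.null(config$css_regions)) {
    css <- as.integer(config$css_regions[[patient_idx]])
    bad <- setdiff(css, cort)
    if (length(bad) > 0) {
      abort(paste0("css_regions contains non-cortical ids: ",
                   paste(bad, collapse = ", ")))
    }
  } else {
    k <- min(config$css_counts[patient_idx], length(cort))
    css <- sample(cort, k)
  }
  p <- rep(config$p_ab, length(cort))
  p[cort %in% css] <- config$p_ab + config$coloc_rho * (1 - config$p_ab)
  ab <- cort[runif(length(cort)) < p]

  means <- draw_region_means(config, atlas)
  means[as.character(ab)] <- means[as.character(ab)] * config$ab_effect

  mask <- make_css_mask_voxels(atlas, config, css)

  vox <- fill_regions(config, atlas, means)
  if (config$css1_deficit > 0 && any(mask > 0)) {
    smap <- smooth_mask(image3d(mask, spacing = config$spacing),
                        fwhm_mm = config$fwhm_mm)
    direct <- smap$map$voxels >= 0.1
    vox[direct] <- vox[direct] - config$css1_deficit * config$ref_level
  }
  if (config$noise_sd > 0) vox <- vox + rnorm(length(vox), 0, config$noise_sd)

  list(
    pet = image3d(vox, spacing = config$spacing),
    css_mask = image3d(mask, spacing = config$spacing),
    truth = list(css_regions = sort(css), ab_regions = sort(ab))
  )
}

#' Simulate a complete phantom cohort in memory
#'
#' @inheritParams simulate_hc_images
#' @param atlas optionally a prebuilt atlas (rebuilt from `config` if NULL).
#' @return list with `atlas`, `hc` (see [simulate_hc_images()]), `patients`
#'   (list of [simulate_patient()] results), `subjects` (combined tibble)
#'   and `truth` (long tibble: patient_id, region_id, css, ab).
#' @export
simulate_cohort <- function(config = phantom_config(), atlas = NULL) {
  if (is.null(atlas)) atlas <- make_atlas(config)
  hc <- simulate_hc_images(atlas, config)
  patients <- purrr::map(seq_len(config$n_patients),
                         ~ simulate_patient(atlas, config, .x))
  pat_ids <- sprintf("CAA%02d", seq_len(config$n_patients))
  cort <- cortical_ids(atlas)
  truth <- purrr::map2_dfr(patients, pat_ids, function(p, id) {
    tibble::tibble(
      patient_id = id, region_id = cort,
      css = cort %in% p$truth$css_regions,
      ab = cort %in% p$truth$ab_regions
    )
  })
  set.seed(derive_seed(config$seed, "cohort", 0L))
  pat_subjects <- tibble::tibble(
    subject_id = pat_ids, group = "CAA",
    sex = rep_len(c("M", "F"), config$n_patients),
    age = as.integer(round(rnorm(config$n_patients, 73.3, 10.9))),
    mmse = as.integer(pmin(30, pmax(0, round(rnorm(config$n_patients, 22.6, 7.5))))),
    injected_dose = round(rnorm(config$n_patients, 294.8, 7.1), 2),
    caa_status = sample(c("possible", "probable"), config$n_patients,
                        replace = TRUE, prob = c(0.3, 0.7)),
    css_pattern = ifelse(lengths(purrr::map(patients, ~ .x$truth$css_regions)) <= 3,
                         "focal", "disseminated")
  )
  list(
    atlas = atlas, hc = hc, patients = patients,
    subjects = dplyr::bind_rows(pat_subjects, hc$subjects),
    truth = truth
  )
}

#' Write a phantom cohort to disk
#'
#' Writes every volume (NIfTI), the region/subject/ground-truth tables
#' (CSV), the fully-resolved configuration (YAML, including the seed), and
#' a manifest listing each file with its MD5 checksum.
#'
#' @inheritParams simulate_cohort
#' @param out_dir writable output directory (created if needed).
#' @return path of the manifest file, invisibly.
#' @export
write_cohort <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  co <- simulate_cohort(config)
  files <- character(0)
  wv <- function(img, name) {
    p <- file.path(out_dir, name)
    write_volume(img, p)
    files <<- c(files, name)
  }
  wt <- function(tbl, name) {
    p <- file.path(out_dir, name)
    readr::write_csv(tbl, p, progress = FALSE)
    files <<- c(files, name)
  }
  wv(co$atlas$labels, "atlas_labels.nii.gz")
  for (i in seq_len(config$n_hc)) {
    wv(co$hc$images[[i]], sprintf("hc_%02d_pet.nii.gz", i))
  }
  for (i in seq_len(config$n_patients)) {
    wv(co$patients[[i]]$pet, sprintf("pat_%02d_pet.nii.gz", i))
    wv(co$patients[[i]]$css_mask, sprintf("pat_%02d_css.nii.gz", i))
  }
  wt(co$atlas$table, "region_table.csv")
  wt(co$subjects, "subjects.csv")
  wt(co$truth, "ground_truth.csv")
  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(unclass(config), cfg_path)
  files <- c(files, "config.yaml")
  manifest <- tibble::tibble(
    file = files,
    md5 = unname(tools::md5sum(file.path(out_dir, files)))
  )
  mpath <- file.path(out_dir, "manifest.csv")
  readr::write_csv(manifest, mpath, progress = FALSE)
  invisible(mpath)
}

#' Verify a cohort manifest
#'
#' Recomputes MD5 checksums of every file listed in `manifest.csv` and
#' errors on any mismatch or missing file.
#'
#' @param dir cohort directory written by [write_cohort()].
#' @return `TRUE` invisibly.
#' @export
verify_manifest <- function(dir) {
  mpath <- file.path(dir, "manifest.csv")
  if (!file.exists(mpath)) abort("manifest.csv not found")
  manifest <- readr::read_csv(mpath, show_col_types = FALSE, progress = FALSE)
  paths <- file.path(dir, manifest$file)
  missing <- manifest$file[!file.exists(paths)]
  if (length(missing) > 0) {
    abort(paste0("manifest verification failed, missing: ",
                 paste(missing, collapse = ", ")))
  }
  md5 <- unname(tools::md5sum(paths))
  bad <- manifest$file[md5 != manifest$md5]
  if (length(bad) > 0) {
    abort(paste0("manifest verification failed, checksum mismatch: ",
                 paste(bad, collapse = ", ")))
  }
  invisible(TRUE)
}
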