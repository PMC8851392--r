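test_that("leave-one-out screening excludes exactly the high outlier, one-sided", {
  base <- c(1.25, 1.27, 1.29, 1.31, 1.33, 1.35, 1.28, 1.30, 1.32)
  mk <- function(extra) {
    vals <- c(base, extra)
    tibble::tibble(
      subject_id = sprintf("HC%02d", seq_along(vals)),
      region_id = 1L, suvr = vals
    )
  }
  # closed-form check that the outlier exceeds the others' MV + 2.5 SD
  hi <- mean(base) + 10 * sd(base)
  expect_gt(hi, mean(base) + 2.5 * sd(base))

  ref_hi <- build_hc_reference(mk(hi))
  expect_equal(ref_hi$excluded_ids, "HC10")
  expect_equal(ref_hi$regions$n_retained, 9)
  expect_equal(ref_hi$regions$mv, mean(base))
  expect_equal(ref_hi$regions$sd, sd(base))

  # a low outlier is retained: the screen targets early amyloid buildup only
  lo <- mean(base) - 10 * sd(base)
  ref_lo <- build_hc_reference(mk(lo))
  expect_length(ref_lo$excluded_ids, 0)

  # identical controls: nobody can exceed the others' mean
  same <- tibble::tibble(subject_id = sprintf("HC%02d", 1:5),
                         region_id = 1L, suvr = 1.3)
  expect_length(build_hc_reference(same)$excluded_ids, 0)

  expect_error(build_hc_reference(mk(hi)[1:2, ]), ">= 3")
})

test_that("amyloid positivity threshold is inclusive at MV + k SD", {
  ref <- structure(
    list(regions = tibble::tibble(region_id = 1:2, mv = c(1.3, 1.4),
                                  sd = c(0.1, 0.2), n_retained = 14),
         excluded_ids = character(0), k_excl = 2.5, n_input = 14),
    class = "hc_reference"
  )
  suvr <- tibble::tibble(region_id = c(1L, 1L, 1L, 2L),
                         suvr_voi = c(1.3, 1.55, 1.5499999, 1.4))
  out <- classify_ab(suvr, ref, k_pos = 2.5)
  expect_equal(out$ab_pos, c(FALSE, TRUE, FALSE, FALSE))

  expect_error(
    classify_ab(tibble::tibble(region_id = 3L, suvr_voi = 1), ref),
    "absent from HC reference"
  )
})

test_that("raising k_pos never increases the amyloid-positive count", {
  cfg <- tiny_config(phantom = list(seed = 5))
  run <- cohort_analysis(cfg)
  counts <- vapply(c(1.5, 2, 2.5, 3, 3.5), function(k) {
    sum(classify_ab(run$suvr[names(run$suvr) != "ab_pos"],
                    run$hc_reference, k_pos = k)$ab_pos)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("per-region positivity of control-like subjects matches the normal tail", {
  # large control pool so the reference MV/SD are near the true parameters
  set.seed(77)
  n_hc <- 2000; n_new <- 25000
  hc <- tibble::tibble(
    subject_id = rep(sprintf("H%04d", 1:n_hc), each = 2),
    region_id = rep(1:2, n_hc),
    suvr = rnorm(2 * n_hc, 1.3, 0.095)
  )
  ref <- build_hc_reference(hc, k_excl = 10)  # no screening: isolate the rule
  new <- tibble::tibble(region_id = rep(1:2, n_new),
                        suvr_voi = rnorm(2 * n_new, 1.3, 0.095))
  rate <- mean(classify_ab(new, ref, k_pos = 2.5)$ab_pos)
  expect_lt(abs(rate - pnorm(-2.5)), 0.004)
})

test_that("retained controls self-classify below 5% positivity", {
  cfg <- validate_config(config = list(seed = 3))
  atlas <- make_atlas(cfg$phantom)
  hc <- simulate_hc_images(atlas, cfg$phantom)
  hc_suvr <- purrr::imap_dfr(hc$images, function(img, i) {
    dplyr::mutate(petcoloc:::region_suvr_table(img, atlas),
                  subject_id = hc$subjects$subject_id[i])
  })
  ref <- build_hc_reference(hc_suvr, k_excl = 2.5)
  retained <- hc_suvr[!hc_suvr$subject_id %in% ref$excluded_ids, ]
  out <- classify_ab(dplyr::rename(retained, suvr_voi = "suvr"), ref)
  expect_lte(mean(out$ab_pos), 0.05)
})

test_that("classifier recovers planted effects with few false positives", {
  # isolate classification from reference-estimation error: iid region model,
  # large control pool, 5-SD planted elevation, small voxel noise
  set.seed(41)
  sd_r <- 0.05
  hc <- tibble::tibble(
    subject_id = rep(sprintf("H%03d", 1:500), each = 60),
    region_id = rep(1:60, 500),
    suvr = rnorm(60 * 500, 1.3, sd_r)
  )
  ref <- build_hc_reference(hc, k_excl = 2.5)
  cfg <- tiny_phantom(subject_rho = 0, hc_region_sd = sd_r, noise_sd = 0.01,
                      ab_effect = 1.2, p_ab = 0.5, n_patients = 40,
                      css_counts = 0, seed = 41)
  atlas <- make_atlas(cfg)
  res <- purrr::map_dfr(seq_len(cfg$n_patients), function(i) {
    p <- simulate_patient(atlas, cfg, i)
    suvr <- dplyr::rename(petcoloc:::region_suvr_table(p$pet, atlas),
                          suvr_voi = "suvr")
    dplyr::mutate(classify_ab(suvr, ref),
                  planted = region_id %in% p$truth$ab_regions)
  })
  sens <- with(res, sum(ab_pos & planted) / sum(planted))
  fp <- with(res, sum(ab_pos & !planted) / sum(!planted))
  expect_gte(sens, 0.95)
  expect_lte(fp, 0.02)
})

test_that("the classifier matrix summarises per-patient overlap", {
  ab <- matrix(c(1, 1, 1, 0,
                 0, 0, 1, 1,
                 0, 0, 0, 0), nrow = 3, byrow = TRUE)
  css <- matrix(c(1, 1, 0, 0,
                  1, 1, 0, 0,
                  0, 0, 0, 0), nrow = 3, byrow = TRUE)
  m <- fake_matrix(ab, css)
  pats <- summary(m)
  expect_equal(pats$overlap_pct, c(100, 0, NA))
  expect_equal(pats$n_ab_pos, c(3, 2, 0))
  g <- glance(m)
  expect_equal(g$n_css_pos, 4)
  expect_equal(g$mean_overlap_pct, 50)

  # mismatched grids are rejected
  ab_t <- tibble::tibble(patient_id = "P1", region_id = 1:2,
                         ab_pos = c(TRUE, FALSE))
  css_t <- tibble::tibble(patient_id = "P1", region_id = 2:3,
                          css_pos = c(TRUE, FALSE))
  expect_error(assemble_matrix(ab_t, css_t), "different")
})
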