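no_noise_config <- function(shape = c(24L, 20L, 20L), fwhm = 0) {
  simulation_config(class_counts = c(AD = 2, CN = 2), raw_shape = shape,
                    noise_sd = 0, smoothing_fwhm = fwhm, site_shift_sd = 0,
                    seed = 5)
}

test_that("a noise-free CN volume is the (smoothed) baseline template", {
  cfg <- no_noise_config()
  atlas <- scale_atlas(default_atlas(), cfg$raw_shape)
  eff <- default_class_effects()
  v <- generate_volume("CN", atlas, eff, cfg)
  expect_identical(v, baseline_template(cfg$raw_shape))

  cfg2 <- no_noise_config(fwhm = 2)
  v2 <- generate_volume("CN", atlas, eff, cfg2)
  expect_false(identical(v2, baseline_template(cfg2$raw_shape)))
  expect_equal(dim(v2), cfg2$raw_shape)
})

test_that("regional deltas reduce masked means by exactly the stated factor", {
  cfg <- no_noise_config()
  atlas <- scale_atlas(default_atlas(), cfg$raw_shape)
  eff <- tibble::tibble(class = c("AD", "MCI"),
                        region = "posterior_cingulate",
                        delta = c(0.3, 0.15))
  base <- baseline_template(cfg$raw_shape)
  mask <- region_mask(atlas, "posterior_cingulate", cfg$raw_shape)

  ad <- generate_volume("AD", atlas, eff, cfg)
  expect_equal(mean(ad[mask]), 0.7 * mean(base[mask]), tolerance = 1e-12)
  expect_equal(ad[!mask], base[!mask])

  # MCI at lambda = 0.5: exactly half the AD reduction
  mci <- generate_volume("MCI", atlas, eff, cfg)
  red_ad <- mean(base[mask]) - mean(ad[mask])
  red_mci <- mean(base[mask]) - mean(mci[mask])
  expect_equal(red_mci, red_ad / 2, tolerance = 1e-12)
})

test_that("increasing a delta strictly decreases the masked mean", {
  cfg <- no_noise_config()
  atlas <- scale_atlas(default_atlas(), cfg$raw_shape)
  mask <- region_mask(atlas, "posterior_cingulate", cfg$raw_shape)
  means <- vapply(c(0, 0.2, 0.4, 0.8), function(d) {
    eff <- tibble::tibble(class = "AD", region = "posterior_cingulate",
                          delta = d)
    mean(generate_volume("AD", atlas, eff, cfg)[mask])
  }, numeric(1))
  expect_true(all(diff(means) < 0))
})

test_that("unknown class labels are rejected by name", {
  cfg <- no_noise_config()
  atlas <- scale_atlas(default_atlas(), cfg$raw_shape)
  expect_error(generate_volume("PSP", atlas, default_class_effects(), cfg),
               "PSP")
})

test_that("cohort generation is deterministic and order-independent", {
  cfg <- simulation_config(class_counts = c(AD = 3, CN = 4),
                           raw_shape = c(16L, 14L, 20L), smoothing_fwhm = 1,
                           seed = 42)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$manifest, b$manifest)
  expect_identical(a$volumes, b$volumes)

  # per-subject streams are hash-derived: a subject's voxels do not depend on
  # who else is in the cohort
  solo <- generate_cohort(simulation_config(class_counts = c(AD = 3),
                                            raw_shape = c(16L, 14L, 20L),
                                            smoothing_fwhm = 1, seed = 42))
  expect_identical(solo$volumes[["AD_002"]], a$volumes[["AD_002"]])
})

test_that("cohort manifest respects counts, uniqueness and demographics", {
  cfg <- simulation_config(class_counts = c(AD = 1),
                           raw_shape = c(16L, 14L, 20L), seed = 1)
  one <- generate_cohort(cfg, generate_volumes = FALSE)
  expect_equal(nrow(one$manifest), 1)

  m <- generate_cohort(scaled_config(seed = 2),
                       generate_volumes = FALSE)$manifest
  expect_false(anyDuplicated(m$subject_id) > 0)
  expect_equal(unname(table(m$class)[c("AD", "MCI", "DLB", "CN")]),
               c(40L, 40L, 32L, 40L), ignore_attr = TRUE)
  expect_true(all(m$age >= 40 & m$age <= 100))
  expect_true(all(m$sex %in% c("M", "F")))
  expect_true(all(m$site %in% c("A", "B")))
  # DLB comes from the second source only
  expect_true(all(m$site[m$class == "DLB"] == "B"))
  expect_error(generate_cohort(simulation_config(class_counts = c(AD = 0))),
               "zero total")
})

test_that("external FTLD cases are always flagged external", {
  cfg <- simulation_config(class_counts = c(AD = 2), n_external = 8,
                           raw_shape = c(16L, 14L, 20L), seed = 3)
  ext <- generate_external_ftld(cfg)
  expect_equal(nrow(ext$manifest), 8)
  expect_true(all(ext$manifest$split == "external"))
  expect_length(ext$volumes, 8)

  cfg0 <- simulation_config(class_counts = c(AD = 2), n_external = 0,
                            raw_shape = c(16L, 14L, 20L), seed = 3)
  ext0 <- generate_external_ftld(cfg0)
  expect_equal(nrow(ext0$manifest), 0)
})

test_that("cohorts round-trip through NIfTI + CSV on disk", {
  dir <- withr::local_tempdir()
  cfg <- simulation_config(class_counts = c(AD = 2, CN = 1),
                           raw_shape = c(16L, 14L, 20L), seed = 9)
  coh <- generate_cohort(cfg)
  write_cohort(coh, dir)
  back <- read_cohort(dir)
  expect_identical(back$manifest$subject_id, coh$manifest$subject_id)
  expect_equal(back$volumes[["AD_001"]], coh$volumes[["AD_001"]],
               tolerance = 1e-6)
})
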