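#' Simulation configuration for a synthetic PET-like cohort
#'
#' Defaults reproduce the study conditions of the reference cohort: 757
#' non-external cases (AD 200, MCI 200, DLB 157, CN 200), eight external FTLD
#' cases, raw template-space volumes of 95 x 79 x 79 voxels (so that trimming
#' the first 10 and last 9 axial slices leaves 60), additive Gaussian voxel
#' noise, isotropic Gaussian smoothing, and a per-site multiplicative
#' intensity scale mimicking two acquisition sources.
#'
#' @param class_counts Named integer vector of non-external class sizes.
#' @param n_external Number of external FTLD cases (default 8).
#' @param raw_shape Integer length-3 raw volume shape; the axial (third) axis
#'   must have at least 20 slices so that trimming is possible.
#' @param noise_sd Additive Gaussian noise sd (intensity units; baseline peaks
#'   at 1).
#' @param smoothing_fwhm Full width at half maximum of the Gaussian smoothing
#'   kernel, voxels. 0 disables smoothing.
#' @param site_shift_sd Sd of the per-site multiplicative intensity factor
#'   `N(1, site_shift_sd)`.
#' @param seed Master seed; every per-subject stream is derived from it by a
#'   stable hash of the subject id.
#' @return A list of class `pet_sim_config`.
#' @export
simulation_config <- function(class_counts = c(AD = 200, MCI = 200,
                                               DLB = 157, CN = 200),
                              n_external = 8,
                              raw_shape = c(95L, 79L, 79L),
                              noise_sd = 0.05,
                              smoothing_fwhm = 2,
                              site_shift_sd = 0.05,
                              seed = 1L) {
  if (is.null(names(class_counts)) || any(!nzchar(names(class_counts))))
    stop("`class_counts` must be a named vector", call. = FALSE)
  if (any(class_counts < 0)) stop("class counts must be >= 0", call. = FALSE)
  stopifnot_scalar_number(noise_sd, "noise_sd", lower = 0)
  stopifnot_scalar_number(site_shift_sd, "site_shift_sd", lower = 0)
  stopifnot_scalar_number(smoothing_fwhm, "smoothing_fwhm", lower = 0)
  raw_shape <- as.integer(raw_shape)
  stopifnot(length(raw_shape) == 3)
  if (raw_shape[3] < 20)
    stop("raw_shape third axis must be >= 20 so trimming is possible",
         call. = FALSE)
  structure(list(class_counts = class_counts, n_external = as.integer(n_external),
                 raw_shape = raw_shape, noise_sd = noise_sd,
                 smoothing_fwhm = smoothing_fwhm,
                 site_shift_sd = site_shift_sd, seed = as.integer(seed)),
            class = "pet_sim_config")
}

#' Desk-scale simulation configuration
#'
#' A reduced configuration used throughout the examples, tests and reports:
#' 32 x 28 x 24 voxel volumes (trim 2 + 2 axial slices to 20, mosaic grid
#' 4 x 5), class counts at one fifth of the full cohort (AD 40, MCI 40,
#' DLB 32, CN 40) and the default noise/site model. Same generator, smaller
#' problem sizes.
#'
#' @inheritParams simulation_config
#' @return A `pet_sim_config`.
#' @export
scaled_config <- function(seed = 1L,
                          class_counts = c(AD = 40, MCI = 40, DLB = 32, CN = 40),
                          noise_sd = 0.05) {
  simulation_config(class_counts = class_counts, n_external = 8,
                    raw_shape = c(32L, 28L, 24L), noise_sd = noise_sd,
                    smoothing_fwhm = 1, site_shift_sd = 0.05, seed = seed)
}

#' Procedural baseline "brain" intensity field
#'
#' A smooth ellipsoidal foreground on a zero background: a sigmoid shell
#' profile times a radial falloff, peaking at 1 in the centre. This is the
#' noise-free CN template every synthetic scan starts from.
#'
#' @param shape Integer length-3 grid shape.
#' @return Numeric 3D array with values in `[0, 1]`.
#' @export
baseline_template <- function(shape) {
  shape <- as.integer(shape)
  ctr <- (shape + 1) / 2
  semi <- 0.42 * shape
  dx2 <- ((seq_len(shape[1]) - ctr[1]) / semi[1])^2
  dy2 <- ((seq_len(shape[2]) - ctr[2]) / semi[2])^2
  dz2 <- ((seq_len(shape[3]) - ctr[3]) / semi[3])^2
  r <- sqrt(outer(outer(dx2, dy2, `+`), dz2, `+`))
  shell <- 1 / (1 + exp((r - 1) / 0.08))
  radial <- pmax(0, 0.4 + 0.6 * (1 - r^2))
  v <- shell * radial
  array(v, dim = shape)
}

brain_mask_template <- function(shape) baseline_template(shape) > 0.1

fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

#' Generate one synthetic scan
#'
#' The voxel model is
#' `smooth( baseline * prod(1 - delta_region * mask_region) * site_factor + noise )`,
#' with Gaussian noise of sd `config$noise_sd` and isotropic Gaussian
#' smoothing of FWHM `config$smoothing_fwhm`. With the same seed the output is
#' bit-identical.
#'
#' @param class_label Class with a profile in `effects` ("CN" is always valid
#'   and applies no reduction).
#' @param atlas Atlas tibble, already referenced to `config$raw_shape` (see
#'   [scale_atlas()]).
#' @param effects Effects tibble from [default_class_effects()].
#' @param config A `pet_sim_config`.
#' @param seed RNG seed for this scan's noise.
#' @param site_factor Multiplicative global intensity factor of the scan's
#'   acquisition site.
#' @return Numeric 3D array of dim `config$raw_shape`.
#' @export
generate_volume <- function(class_label, atlas, effects, config,
                            seed = config$seed, site_factor = 1) {
  known <- unique(c("CN", effects$class))
  if (!class_label %in% known)
    stop(sprintf("unknown class label '%s' (no effect profile)", class_label),
         call. = FALSE)
  shape <- config$raw_shape
  v <- baseline_template(shape)
  deltas <- class_deltas(effects, class_label)
  for (region in names(deltas)) {
    m <- region_mask(atlas, region, shape)
    v[m] <- v[m] * (1 - deltas[[region]])
  }
  v <- v * site_factor
  if (config$noise_sd > 0)
    v <- v + with_seed(seed, array(rnorm(prod(shape), 0, config$noise_sd),
                                   dim = shape))
  if (config$smoothing_fwhm > 0)
    v <- array(gauss_smooth3d(as.numeric(v), dim(v),
                              fwhm_to_sigma(config$smoothing_fwhm)),
               dim = shape)
  v
}

# Age model: per class and sex, normal with the reference cohort's
# demographics, truncated to [40, 100]. Only used for manifest realism.
age_params <- list(
  AD       = list(M = c(76.7, 8.2), F = c(74.0, 7.8), p_female = 0.360),
  MCI      = list(M = c(75.6, 7.5), F = c(73.2, 8.2), p_female = 0.380),
  CN_A     = list(M = c(77.5, 5.4), F = c(78.3, 5.0), p_female = 0.397),
  DLB      = list(M = c(73.3, 7.2), F = c(74.8, 6.4), p_female = 0.375),
  CN_B     = list(M = c(70.1, 10.3), F = c(67.5, 9.2), p_female = 0.500),
  FTLD     = list(M = c(65.0, 8.0), F = c(65.0, 8.0), p_female = 0.400)
)

draw_demographics <- function(key, seed) {
  p <- age_params[[key]] %||% age_params[["CN_A"]]
  with_seed(seed, {
    sex <- if (runif(1) < p$p_female) "F" else "M"
    mu <- p[[sex]][1]; s <- p[[sex]][2]
    age <- min(100, max(40, rnorm(1, mu, s)))
    list(sex = sex, age = round(age, 1))
  })
}

# Site assignment mirrors the two-source composition of the reference cohort:
# AD/MCI from site A, DLB from site B, CN split 156:44 between A and B.
subject_site <- function(class_label, index, n_class) {
  if (class_label %in% c("AD", "MCI")) return("A")
  if (class_label %in% c("DLB", "FTLD")) return("B")
  n_a <- round(n_class * 156 / 200)
  if (index <= n_a) "A" else "B"
}

site_factors <- function(config) {
  with_seed(subject_seed(config$seed, "site-factors"),
            c(A = rnorm(1, 1, config$site_shift_sd),
              B = rnorm(1, 1, config$site_shift_sd)))
}

cohort_manifest <- function(config, classes = names(config$class_counts),
                            external = FALSE) {
  rows <- purrr::map_dfr(classes, function(cls) {
    n <- if (external) config$n_external else config$class_counts[[cls]]
    if (n == 0) return(NULL)
    idx <- seq_len(n)
    ids <- sprintf("%s_%03d", cls, idx)
    demo <- purrr::map2(ids, cls, function(id, c)
      draw_demographics(demo_key(c, id, config), subject_seed(config$seed, id)))
    tibble::tibble(
      subject_id = ids,
      class = cls,
      site = purrr::map_chr(idx, ~ subject_site(cls, .x, n)),
      age = purrr::map_dbl(demo, "age"),
      sex = purrr::map_chr(demo, "sex"),
      split = if (external) "external" else "train"
    )
  })
  rows
}

demo_key <- function(class_label, subject_id, config) {
  if (class_label != "CN") return(class_label)
  n <- config$class_counts[["CN"]]
  idx <- as.integer(sub(".*_", "", subject_id))
  if (subject_site("CN", idx, n) == "A") "CN_A" else "CN_B"
}

#' Generate a synthetic cohort
#'
#' Builds the cohort manifest (subject id, class, site, age, sex, split) and,
#' unless `generate_volumes = FALSE`, one raw volume per row. Each subject's
#' noise stream is seeded by a stable hash of its id combined with the master
#' seed, so cohorts are bit-reproducible and independent of generation order.
#'
#' @param config A `pet_sim_config`.
#' @param atlas Atlas tibble (rescaled automatically to `config$raw_shape`).
#' @param effects Effects tibble.
#' @param generate_volumes If `FALSE`, return the manifest with an empty
#'   volume list (fast path for split/count checks).
#' @return A list of class `pet_cohort` with elements `manifest` (tibble) and
#'   `volumes` (named list of 3D arrays).
#' @examples
#' coh <- generate_cohort(scaled_config(seed = 7))
#' dplyr::count(coh$manifest, class)
#' @export
generate_cohort <- function(config = simulation_config(),
                            atlas = default_atlas(),
                            effects = default_class_effects(),
                            generate_volumes = TRUE) {
  if (sum(config$class_counts) == 0)
    stop("cohort has zero total count", call. = FALSE)
  atlas <- scale_atlas(atlas, config$raw_shape)
  manifest <- cohort_manifest(config)
  volumes <- list()
  if (generate_volumes) {
    sf <- site_factors(config)
    volumes <- purrr::map2(manifest$subject_id, seq_len(nrow(manifest)),
      function(id, i) {
        generate_volume(manifest$class[i], atlas, effects, config,
                        seed = subject_seed(config$seed, id),
                        site_factor = sf[[manifest$site[i]]])
      })
    names(volumes) <- manifest$subject_id
  }
  structure(list(manifest = manifest, volumes = volumes,
                 config = config, atlas = atlas, effects = effects),
            class = "pet_cohort")
}

#' Generate external FTLD cases
#'
#' External frontotemporal cases are never part of any training fold: every
#' row carries `split = "external"`. Their effect profile (frontal plus
#' temporal reduction) comes from `effects`.
#'
#' @inheritParams generate_cohort
#' @return A `pet_cohort` whose manifest rows all have `split = "external"`.
#' @export
generate_external_ftld <- function(config = simulation_config(),
                                   atlas = default_atlas(),
                                   effects = default_class_effects(),
                                   generate_volumes = TRUE) {
  atlas <- scale_atlas(atlas, config$raw_shape)
  manifest <- cohort_manifest(config, classes = "FTLD", external = TRUE)
  volumes <- list()
  if (config$n_external > 0 && generate_volumes) {
    sf <- site_factors(config)
    volumes <- purrr::map(seq_len(nrow(manifest)), function(i) {
      generate_volume("FTLD", atlas, effects, config,
                      seed = subject_seed(config$seed, manifest$subject_id[i]),
                      site_factor = sf[[manifest$site[i]]])
    })
    names(volumes) <- manifest$subject_id
  }
  structure(list(manifest = manifest, volumes = volumes,
                 config = config, atlas = atlas, effects = effects),
            class = "pet_cohort")
}

#' Write a cohort to disk (NIfTI volumes + CSV manifest)
#'
#' Volumes are written one `.nii.gz` per subject with an identity orientation
#' and 2 mm isotropic voxels; the manifest as
#' `subject_id,class,site,age,sex,split`.
#'
#' @param cohort A `pet_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  for (id in names(cohort$volumes)) {
    img <- RNifti::asNifti(cohort$volumes[[id]], pixdim = c(2, 2, 2))
    RNifti::writeNifti(img, file.path(dir, paste0(id, ".nii.gz")))
  }
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing `manifest.csv` and per-subject NIfTI files.
#' @return A `pet_cohort` (without simulation metadata).
#' @export
read_cohort <- function(dir) {
  manifest <- tibble::as_tibble(utils::read.csv(file.path(dir, "manifest.csv"),
                                                stringsAsFactors = FALSE))
  volumes <- lapply(manifest$subject_id, function(id) {
    arr <- RNifti::readNifti(file.path(dir, paste0(id, ".nii.gz")))
    array(as.numeric(arr), dim = dim(arr))
  })
  names(volumes) <- manifest$subject_id
  structure(list(manifest = manifest, volumes = volumes),
            class = "pet_cohort")
}

#' @export
print.pet_cohort <- function(x, ...) {
  cat(sprintf("<pet_cohort> %d subjects (%d with volumes)\n",
              nrow(x$manifest), length(x$volumes)))
  print(dplyr::count(x$manifest, .data$class, .data$split))
  invisible(x)
}
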