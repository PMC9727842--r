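#' Ellipsoidal region atlas for synthetic volumes
#'
#' The package plants class-specific signal reductions inside named ellipsoidal
#' regions of the template grid. The default atlas places seven proxy regions
#' (posterior cingulate, occipital, frontal, temporal, parietal, left striatum,
#' pons/thalamus) at fixed coordinates of the 95 x 79 x 79 grid; the geometry
#' is a reproducible stand-in at plausible template locations, not an
#' anatomical segmentation.
#'
#' @return A tibble with one row per region and columns `name`, `cx`, `cy`,
#'   `cz` (1-based ellipsoid centre) and `rx`, `ry`, `rz` (semi-axes, voxels),
#'   carrying the reference grid shape as attribute `reference_shape`.
#' @examples
#' default_atlas()
#' @export
default_atlas <- function() {
  path <- system.file("extdata", "atlas_default.yaml", package = "neuropet")
  read_atlas(path)
}

#' Read a region atlas from YAML
#'
#' @param path YAML file with fields `reference_shape` and `regions`
#'   (each region: `name`, `center`, `radii`).
#' @return Atlas tibble, see [default_atlas()].
#' @export
read_atlas <- function(path) {
  spec <- yaml::read_yaml(path)
  atlas <- purrr::map_dfr(spec$regions, function(r) {
    tibble::tibble(
      name = r$name,
      cx = r$center[[1]], cy = r$center[[2]], cz = r$center[[3]],
      rx = r$radii[[1]], ry = r$radii[[2]], rz = r$radii[[3]]
    )
  })
  attr(atlas, "reference_shape") <- as.integer(unlist(spec$reference_shape))
  validate_atlas(atlas)
  atlas
}

validate_atlas <- function(atlas) {
  shape <- attr(atlas, "reference_shape")
  stopifnot(length(shape) == 3, all(shape >= 1))
  lo <- cbind(atlas$cx - atlas$rx, atlas$cy - atlas$ry, atlas$cz - atlas$rz)
  hi <- cbind(atlas$cx + atlas$rx, atlas$cy + atlas$ry, atlas$cz + atlas$rz)
  if (any(lo < 1) || any(t(hi) > shape))
    stop("atlas region(s) extend outside the reference grid", call. = FALSE)
  if (anyDuplicated(atlas$name))
    stop("atlas region names must be unique", call. = FALSE)
  invisible(atlas)
}

#' Rescale an atlas to a different grid shape
#'
#' Centres and semi-axes are scaled per axis by the ratio of the target to the
#' reference shape, so scaled-down cohorts keep the same relative geometry.
#'
#' @param atlas Atlas tibble from [default_atlas()] or [read_atlas()].
#' @param shape Integer length-3 target grid shape.
#' @return Atlas tibble referenced to `shape`.
#' @export
scale_atlas <- function(atlas, shape) {
  ref <- attr(atlas, "reference_shape")
  shape <- as.integer(shape)
  f <- shape / ref
  out <- dplyr::mutate(atlas,
    cx = pmax(1, .data$cx * f[1]), cy = pmax(1, .data$cy * f[2]),
    cz = pmax(1, .data$cz * f[3]),
    rx = pmax(1, .data$rx * f[1]), ry = pmax(1, .data$ry * f[2]),
    rz = pmax(1, .data$rz * f[3])
  )
  attr(out, "reference_shape") <- shape
  out
}

#' Voxel membership mask of one atlas region
#'
#' Membership is the exact ellipsoid inequality
#' \eqn{((x-c_x)/r_x)^2 + ((y-c_y)/r_y)^2 + ((z-c_z)/r_z)^2 \le 1},
#' evaluated at 1-based voxel centres, hence deterministic given the region row.
#'
#' @param atlas Atlas tibble.
#' @param name Region name.
#' @param shape Grid shape; defaults to the atlas reference shape.
#' @return Logical 3D array.
#' @export
region_mask <- function(atlas, name, shape = attr(atlas, "reference_shape")) {
  r <- atlas[atlas$name == name, ]
  if (nrow(r) != 1)
    stop(sprintf("region '%s' not found in atlas", name), call. = FALSE)
  dx2 <- ((seq_len(shape[1]) - r$cx) / r$rx)^2
  dy2 <- ((seq_len(shape[2]) - r$cy) / r$ry)^2
  dz2 <- ((seq_len(shape[3]) - r$cz) / r$rz)^2
  q <- outer(outer(dx2, dy2, `+`), dz2, `+`)
  q <= 1
}

#' Class-specific regional effect profiles
#'
#' Fractional intensity reductions per (class, region). CN carries no
#' reductions; the MCI profile is `mci_lambda` times the AD profile, encoding
#' an intermediate phenotype on the CN to AD axis. The default profiles put
#' the AD/MCI/DLB signal in the posterior cingulate, an additional occipital
#' deficit in DLB, and frontal plus temporal deficits in the external FTLD
#' class.
#'
#' @return A tibble with columns `class`, `region`, `delta` (in `[0, 1]`),
#'   with the interpolation factor as attribute `mci_lambda`.
#' @examples
#' default_class_effects()
#' @export
default_class_effects <- function() {
  path <- system.file("extdata", "class_effects_default.yaml",
                      package = "neuropet")
  read_class_effects(path)
}

#' Read class effect profiles from YAML
#'
#' @param path YAML file with fields `mci_lambda` and `effects`
#'   (class -> region -> delta). An MCI profile is derived from AD unless one
#'   is given explicitly.
#' @return Effects tibble, see [default_class_effects()].
#' @export
read_class_effects <- function(path) {
  spec <- yaml::read_yaml(path)
  lambda <- spec$mci_lambda %||% 0.5
  eff <- purrr::imap_dfr(spec$effects, function(regions, cls) {
    tibble::tibble(class = cls, region = names(regions),
                   delta = as.numeric(unlist(regions)))
  })
  if (!"MCI" %in% eff$class && "AD" %in% eff$class) {
    mci <- dplyr::mutate(eff[eff$class == "AD", ],
                         class = "MCI", delta = .data$delta * lambda)
    eff <- dplyr::bind_rows(eff, mci)
  }
  attr(eff, "mci_lambda") <- lambda
  validate_class_effects(eff)
  eff
}

validate_class_effects <- function(effects) {
  if (any(effects$delta < 0 | effects$delta > 1))
    stop("effect deltas must lie in [0, 1]", call. = FALSE)
  cn <- effects[effects$class == "CN", ]
  if (nrow(cn) > 0 && any(cn$delta != 0))
    stop("CN must carry no intensity reduction", call. = FALSE)
  invisible(effects)
}

#' Scale all effect deltas by a common factor
#'
#' Used to sweep separability from the default ("strong effects") profile down
#' to zero effect, where all classes coincide and accuracy must fall to chance.
#'
#' @param effects Effects tibble.
#' @param factor Scalar in `[0, 1]` (values above 1 are allowed as long as no
#'   delta exceeds 1).
#' @return Effects tibble with `delta` multiplied by `factor`.
#' @export
scale_effects <- function(effects, factor) {
  stopifnot_scalar_number(factor, "factor", lower = 0)
  out <- dplyr::mutate(effects, delta = .data$delta * factor)
  validate_class_effects(out)
  attr(out, "mci_lambda") <- attr(effects, "mci_lambda")
  out
}

class_deltas <- function(effects, class_label) {
  rows <- effects[effects$class == class_label, ]
  stats::setNames(rows$delta, rows$region)
}
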