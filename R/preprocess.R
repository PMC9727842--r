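#' Preprocessing configuration
#'
#' Controls axial slice trimming and the 3D-to-2D mosaic layout. With the
#' full-size defaults a 95 x 79 x 79 raw volume is trimmed (first 10 and last
#' 9 slices dropped) to 95 x 79 x 60 and tiled into a 6 x 10 mosaic of
#' 570 x 790 pixels.
#'
#' @param drop_head,drop_tail Axial slices removed from the start / end.
#' @param epsilon Guard on the per-feature standard deviation: features whose
#'   sd is `<= epsilon` are set to 0 instead of divided.
#' @param grid_rows,grid_cols Mosaic tiling; their product must equal the
#'   retained slice count when a mosaic is built.
#' @return A list of class `pet_prep_config`.
#' @export
preprocess_config <- function(drop_head = 10L, drop_tail = 9L, epsilon = 1e-8,
                              grid_rows = 6L, grid_cols = 10L) {
  stopifnot(drop_head >= 0, drop_tail >= 0, epsilon >= 0,
            grid_rows >= 1, grid_cols >= 1)
  structure(list(drop_head = as.integer(drop_head),
                 drop_tail = as.integer(drop_tail), epsilon = epsilon,
                 grid_rows = as.integer(grid_rows),
                 grid_cols = as.integer(grid_cols)),
            class = "pet_prep_config")
}

#' Desk-scale preprocessing configuration
#'
#' Companion of [scaled_config()]: trims 2 + 2 of the 24 raw axial slices to
#' 20 and tiles them as a 4 x 5 mosaic.
#'
#' @return A `pet_prep_config`.
#' @export
scaled_preprocess_config <- function() {
  preprocess_config(drop_head = 2L, drop_tail = 2L,
                    grid_rows = 4L, grid_cols = 5L)
}

#' Trim axial slices
#'
#' Drops the first `drop_head` and last `drop_tail` axial slices (third array
#' axis), preserving order — the ends of the field of view contain very little
#' brain.
#'
#' @param volume Numeric 3D array.
#' @param config A `pet_prep_config`.
#' @return The trimmed 3D array.
#' @export
trim_slices <- function(volume, config = preprocess_config()) {
  nz <- dim(volume)[3]
  keep <- config$drop_head + config$drop_tail
  if (nz <= keep)
    stop(sprintf("cannot trim %d + %d slices from a %d-slice volume",
                 config$drop_head, config$drop_tail, nz), call. = FALSE)
  volume[, , (config$drop_head + 1):(nz - config$drop_tail), drop = FALSE]
}

#' Per-scan feature-wise standardisation
#'
#' Treats each axial slice of one scan as a sample and each in-plane pixel
#' position (x, y) as a feature: every feature is centred by its mean over
#' slices and divided by its (population) standard deviation over slices,
#' within this single scan. Features whose sd is `<= epsilon` (constant along
#' the slice axis, e.g. background) are set to 0. No statistics are shared
#' across scans, so site-level intensity scaling cancels per scan.
#'
#' @inheritParams trim_slices
#' @return Standardised 3D array of the same shape.
#' @export
standardize_scan <- function(volume, config = preprocess_config()) {
  mu <- rowMeans(volume, dims = 2)
  centred <- volume - as.vector(mu)
  s <- sqrt(rowMeans(centred^2, dims = 2))
  keep <- s > config$epsilon
  s[!keep] <- 1
  out <- centred / as.vector(s)
  out <- out * as.vector(keep)
  out
}

#' Min-max rescale a scan to [0, 1]
#'
#' Per-scan: the volume's minimum maps to 0 and its maximum to 1. A constant
#' volume maps to all zeros.
#'
#' @param volume Numeric 3D array (finite values).
#' @return Rescaled array.
#' @export
rescale_01 <- function(volume) {
  lo <- min(volume); hi <- max(volume)
  if (hi - lo == 0) return(array(0, dim = dim(volume)))
  (volume - lo) / (hi - lo)
}

#' Tile the axial slices of a volume into a 2D mosaic
#'
#' Slice `k` (1-based) occupies tile `(floor((k-1)/grid_cols),
#' (k-1) mod grid_cols)` in row-major order; voxel `(x, y)` of that slice maps
#' to pixel `(tile_row * X + x, tile_col * Y + y)`. The rearrangement is
#' lossless.
#'
#' @inheritParams trim_slices
#' @return Numeric matrix of dim `(grid_rows * X, grid_cols * Y)`.
#' @export
volume_to_mosaic <- function(volume, config = preprocess_config()) {
  d <- dim(volume)
  gr <- config$grid_rows; gc <- config$grid_cols
  if (d[3] != gr * gc)
    stop(sprintf("volume has %d slices but the mosaic grid is %d x %d = %d",
                 d[3], gr, gc, gr * gc), call. = FALSE)
  m <- matrix(0, nrow = gr * d[1], ncol = gc * d[2])
  for (k in seq_len(d[3])) {
    tr <- (k - 1) %/% gc
    tc <- (k - 1) %% gc
    m[tr * d[1] + seq_len(d[1]), tc * d[2] + seq_len(d[2])] <- volume[, , k]
  }
  m
}

#' Invert [volume_to_mosaic()]
#'
#' @param image Mosaic matrix.
#' @param tile_dim Length-2 in-plane slice shape `(X, Y)`.
#' @return Numeric 3D array with `grid_rows * grid_cols` axial slices;
#'   bit-exact inverse of the forward tiling.
#' @export
mosaic_to_volume <- function(image, tile_dim) {
  d <- dim(image)
  if (d[1] %% tile_dim[1] != 0 || d[2] %% tile_dim[2] != 0)
    stop(sprintf("mosaic %d x %d is not divisible by tile %d x %d",
                 d[1], d[2], tile_dim[1], tile_dim[2]), call. = FALSE)
  gr <- d[1] %/% tile_dim[1]
  gc <- d[2] %/% tile_dim[2]
  v <- array(0, dim = c(tile_dim[1], tile_dim[2], gr * gc))
  for (k in seq_len(gr * gc)) {
    tr <- (k - 1) %/% gc
    tc <- (k - 1) %% gc
    v[, , k] <- image[tr * tile_dim[1] + seq_len(tile_dim[1]),
                      tc * tile_dim[2] + seq_len(tile_dim[2])]
  }
  v
}

#' Replicate a single-channel image across RGB channels
#'
#' 2D backbones expect three input channels; grey-scale mosaics are replicated
#' identically into each.
#'
#' @param image Numeric matrix.
#' @return Numeric array of dim `(nrow, ncol, 3)` with identical channels.
#' @export
replicate_rgb <- function(image) {
  array(rep(as.numeric(image), 3), dim = c(dim(image), 3))
}

#' Full per-scan preprocessing chain
#'
#' `trim_slices()` then [standardize_scan()] then [rescale_01()] — the
#' model-ready 3D representation.
#'
#' @inheritParams trim_slices
#' @return Preprocessed 3D array with values in `[0, 1]`.
#' @export
preprocess_volume <- function(volume, config = preprocess_config()) {
  rescale_01(standardize_scan(trim_slices(volume, config), config))
}

#' Preprocess every volume of a cohort
#'
#' @param cohort A `pet_cohort`.
#' @param config A `pet_prep_config`.
#' @return The cohort with each volume replaced by its preprocessed version.
#' @export
preprocess_cohort <- function(cohort, config = preprocess_config()) {
  cohort$volumes <- lapply(cohort$volumes, preprocess_volume, config = config)
  cohort$prep_config <- config
  cohort
}

#' Mosaic images for every volume of a cohort
#'
#' @param cohort A preprocessed `pet_cohort`.
#' @param config A `pet_prep_config` (tiling grid).
#' @param rgb Replicate each mosaic across three channels.
#' @return Named list of matrices (or HxWx3 arrays if `rgb = TRUE`).
#' @export
cohort_mosaics <- function(cohort, config = preprocess_config(), rgb = FALSE) {
  out <- lapply(cohort$volumes, function(v) {
    m <- volume_to_mosaic(v, config)
    if (rgb) replicate_rgb(m) else m
  })
  out
}

#' Write a mosaic as an 8-bit PNG preview
#'
#' Values are min-max scaled to the 8-bit range; intended for quick visual
#' inspection, not analysis (use the matrix form for that).
#'
#' @param image Mosaic matrix.
#' @param path Output `.png` path.
#' @return `path`, invisibly.
#' @export
write_mosaic_png <- function(image, path) {
  rng <- range(image)
  scaled <- if (diff(rng) > 0) (image - rng[1]) / diff(rng) else image * 0
  png::writePNG(scaled, path)
  invisible(path)
}
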