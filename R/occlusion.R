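# Occlusion-sensitivity explainability: cross-entropy response maps over a
# strided occlusion-window grid, per-class averaging, voxel accumulation and
# mosaic projection over the average brain.

#' Occlusion experiment configuration
#'
#' A 2D window of `window[1] x window[2]` pixels is zeroed out of one axial
#' slice at a time, on a grid with the given stride, so the same number of
#' pixels is hidden for 2D and 3D models. With the full-size defaults a
#' 95 x 79 slice yields 45 x 38 = 1710 window positions. The projection range
#' takes 49 axial slices (1-based slices 6..54) into a 7 x 7 mosaic — the
#' range is sized to fill the grid exactly (a nominal "slices 5 to 54" span
#' would hold 50 slices, one too many, so the 49-slice reading is used).
#'
#' @param window Occlusion window (height, width), pixels (default 6 x 5).
#' @param stride Grid stride in pixels (default 2).
#' @param fill_value Scalar written into the window (default 0, the
#'   background level after `[0,1]` rescaling), or a reference volume of the
#'   input's shape whose values replace the occluded voxels (e.g. the
#'   [average_brain()], which erases subject-specific evidence instead of
#'   darkening the region).
#' @param depth Number of consecutive axial slices occluded per position
#'   (default 1, matching the 2D-window protocol; larger values give
#'   volumetric occlusion for 3D models).
#' @param projection_slices Inclusive 1-based axial range projected into the
#'   summary mosaic.
#' @param projection_grid Mosaic grid (rows, cols); its product must equal the
#'   number of projected slices.
#' @return A list of class `pet_occlusion_config`.
#' @export
occlusion_config <- function(window = c(6L, 5L), stride = 2L, fill_value = 0,
                             projection_slices = c(6L, 54L),
                             projection_grid = c(7L, 7L), depth = 1L) {
  stopifnot(all(window >= 1), stride >= 1, depth >= 1,
            projection_slices[1] >= 1,
            projection_slices[2] >= projection_slices[1])
  n_proj <- projection_slices[2] - projection_slices[1] + 1
  if (prod(projection_grid) != n_proj)
    stop(sprintf("projection grid %d x %d does not hold %d slices",
                 projection_grid[1], projection_grid[2], n_proj),
         call. = FALSE)
  structure(list(window = as.integer(window), stride = as.integer(stride),
                 fill_value = fill_value,
                 projection_slices = as.integer(projection_slices),
                 projection_grid = as.integer(projection_grid),
                 depth = as.integer(depth)),
            class = "pet_occlusion_config")
}

#' Occlusion-window positions on one slice
#'
#' Start offsets (1-based) of every window position: `floor((H - h) / s) + 1`
#' rows by `floor((W - w) / s) + 1` columns.
#'
#' @param slice_dim In-plane slice shape `(H, W)`.
#' @param config A `pet_occlusion_config`.
#' @return List with integer vectors `rows` and `cols`.
#' @export
occlusion_positions <- function(slice_dim, config = occlusion_config()) {
  h <- config$window[1]; w <- config$window[2]; s <- config$stride
  if (h > slice_dim[1] || w > slice_dim[2])
    stop(sprintf("window %d x %d exceeds slice %d x %d", h, w,
                 slice_dim[1], slice_dim[2]), call. = FALSE)
  list(rows = seq(1L, slice_dim[1] - h + 1L, by = s),
       cols = seq(1L, slice_dim[2] - w + 1L, by = s))
}

#' Occlude one window of one (or several consecutive) axial slices
#'
#' Sets the `h x w` window starting at (1-based) `(row, col)` of slices
#' `slice_idx .. slice_idx + depth - 1` to `fill_value`; every other voxel is
#' untouched. The default depth of 1 occludes a single slice.
#'
#' @param volume Numeric 3D array.
#' @param slice_idx First occluded axial slice (1-based).
#' @param row,col Window start (1-based).
#' @param config A `pet_occlusion_config`.
#' @return The occluded copy.
#' @export
occlude <- function(volume, slice_idx, row, col, config = occlusion_config()) {
  d <- dim(volume)
  h <- config$window[1]; w <- config$window[2]; dp <- config$depth
  if (slice_idx < 1 || slice_idx + dp - 1 > d[3] || row < 1 || col < 1 ||
      row + h - 1 > d[1] || col + w - 1 > d[2])
    stop(sprintf("occlusion window [%d:%d, %d:%d] of slice(s) %d:%d out of bounds for %s",
                 row, row + h - 1, col, col + w - 1, slice_idx,
                 slice_idx + dp - 1, paste(d, collapse = "x")), call. = FALSE)
  rows <- row:(row + h - 1); cols <- col:(col + w - 1)
  slices <- slice_idx:(slice_idx + dp - 1)
  fill <- config$fill_value
  volume[rows, cols, slices] <- if (is.array(fill)) fill[rows, cols, slices]
                                else fill
  volume
}

resolve_class_index <- function(model, true_class, p = NULL) {
  cl <- model$classes %||% colnames(p)
  if (is.character(true_class)) {
    i <- match(true_class, cl)
    if (is.na(i)) stop(sprintf("unknown class '%s'", true_class),
                       call. = FALSE)
    i
  } else as.integer(true_class)
}

#' Cross-entropy response of a model on one input
#'
#' `-log p(true class)`, with the probability clipped to `[1e-12, 1]`; always
#' nonnegative, and high when a region needed for the correct classification
#' has been occluded.
#'
#' @param model Trained model (anything with a [predict_proba()] method).
#' @param x One input volume (or feature row, matching the model).
#' @param true_class Class label (character) or index.
#' @return Nonnegative scalar.
#' @export
response <- function(model, x, true_class) {
  xs <- if (is.matrix(x)) x else list(x)
  p <- predict_proba(model, xs)
  i <- resolve_class_index(model, true_class, p)
  -log(min(1, max(p[1, i], 1e-12)))
}

#' Occlusion-sensitivity map of one input volume
#'
#' Computes the cross-entropy response for every occlusion position on every
#' axial slice. Deterministic: the response grid follows the configured window
#' and stride exactly.
#'
#' @param model Trained model operating on volumes (e.g. the 3D CNN or a
#'   [probe_model()]).
#' @param volume Preprocessed 3D array.
#' @param true_class Class label or index.
#' @param config A `pet_occlusion_config`.
#' @param predict_fun Optional replacement predictor
#'   `function(list_of_volumes) -> probability matrix` (used to push occluded
#'   volumes through a mosaic + backbone + head pipeline).
#' @param subject_id Carried into the result for bookkeeping.
#' @return A `pet_occlusion_map`: `responses` array indexed (slice, row
#'   position, col position), start offsets, `vol_dim`, `true_class`, config.
#' @export
occlusion_map <- function(model, volume, true_class,
                          config = occlusion_config(), predict_fun = NULL,
                          subject_id = NULL) {
  d <- dim(volume)
  pos <- occlusion_positions(d[1:2], config)
  if (is.null(predict_fun))
    predict_fun <- function(vols) predict_proba(model, vols)
  ci <- resolve_class_index(model, true_class,
                            predict_fun(list(volume)))
  nr <- length(pos$rows); nc <- length(pos$cols)
  nz <- d[3] - config$depth + 1L
  responses <- array(0, dim = c(nz, nr, nc))
  for (z in seq_len(nz)) {
    occluded <- vector("list", nr * nc)
    k <- 1
    for (ri in seq_len(nr)) for (cj in seq_len(nc)) {
      occluded[[k]] <- occlude(volume, z, pos$rows[ri], pos$cols[cj], config)
      k <- k + 1
    }
    p <- predict_fun(occluded)
    r <- -log(pmin(1, pmax(p[, ci], 1e-12)))
    responses[z, , ] <- matrix(r, nr, nc, byrow = TRUE)
  }
  structure(list(responses = responses, rows = pos$rows, cols = pos$cols,
                 vol_dim = d, true_class = true_class, config = config,
                 subject_id = subject_id),
            class = "pet_occlusion_map")
}

#' Average occlusion maps of one class
#'
#' Element-wise mean of maps sharing shape and true class — the per-class
#' attention map, computed over all included subjects of that class.
#'
#' @param maps List of `pet_occlusion_map`s with equal shape and true class.
#' @param class_label Expected `true_class` of every map.
#' @return A `pet_occlusion_map` with averaged responses.
#' @export
class_average <- function(maps, class_label) {
  if (length(maps) == 0) stop("no occlusion maps to average", call. = FALSE)
  ok <- vapply(maps, function(m) identical(m$true_class, class_label),
               logical(1))
  if (!all(ok)) stop("all maps must share true_class = class_label",
                     call. = FALSE)
  shp <- dim(maps[[1]]$responses)
  if (!all(vapply(maps, function(m) identical(dim(m$responses), shp),
                  logical(1))))
    stop("occlusion maps differ in shape", call. = FALSE)
  out <- maps[[1]]
  out$responses <- Reduce(`+`, lapply(maps, `[[`, "responses")) / length(maps)
  out$subject_id <- NULL
  out
}

#' Project an occlusion map onto the voxel grid
#'
#' Each position's response is added to every voxel its window covers (all
#' `depth` occluded slices); each voxel is then divided by the number of
#' windows covering it. Voxels never covered stay 0.
#'
#' @param map A `pet_occlusion_map`.
#' @return Numeric 3D array of dim `map$vol_dim`.
#' @export
to_voxel_map <- function(map) {
  d <- map$vol_dim
  h <- map$config$window[1]; w <- map$config$window[2]
  dp <- map$config$depth
  cover2d <- matrix(0, d[1], d[2])
  for (r in map$rows) for (cc in map$cols)
    cover2d[r:(r + h - 1), cc:(cc + w - 1)] <-
      cover2d[r:(r + h - 1), cc:(cc + w - 1)] + 1
  nz <- dim(map$responses)[1]
  acc <- array(0, dim = d)
  zcover <- integer(d[3])
  for (z in seq_len(nz)) {
    a2 <- matrix(0, d[1], d[2])
    for (ri in seq_along(map$rows)) for (cj in seq_along(map$cols)) {
      r <- map$rows[ri]; cc <- map$cols[cj]
      a2[r:(r + h - 1), cc:(cc + w - 1)] <-
        a2[r:(r + h - 1), cc:(cc + w - 1)] + map$responses[z, ri, cj]
    }
    for (dz in 0:(dp - 1)) {
      acc[, , z + dz] <- acc[, , z + dz] + a2
      zcover[z + dz] <- zcover[z + dz] + 1L
    }
  }
  out <- array(0, dim = d)
  nonzero <- cover2d > 0
  for (s in seq_len(d[3])) {
    if (zcover[s] == 0) next
    sl <- acc[, , s]
    sl[nonzero] <- sl[nonzero] / (cover2d[nonzero] * zcover[s])
    sl[!nonzero] <- 0
    out[, , s] <- sl
  }
  out
}

#' Voxel-wise mean volume ("average brain")
#'
#' @param volumes List of equally shaped 3D arrays (typically the preprocessed
#'   training volumes).
#' @return Numeric 3D array.
#' @export
average_brain <- function(volumes) {
  Reduce(`+`, volumes) / length(volumes)
}

#' Mosaic projection of a voxel response map over the average brain
#'
#' The configured axial slice range is tiled row-major into the projection
#' grid; the response mosaic is alpha-blended over the average-brain mosaic.
#'
#' @param voxel_map 3D response array from [to_voxel_map()].
#' @param avg_brain 3D array of the same shape ([average_brain()]).
#' @param config A `pet_occlusion_config` (projection range and grid).
#' @param alpha Blend weight of the heatmap (default 0.6).
#' @return A `pet_class_heatmap`: matrices `heat`, `brain`, `overlay` plus the
#'   grid layout.
#' @export
project_mosaic <- function(voxel_map, avg_brain,
                           config = occlusion_config(), alpha = 0.6) {
  d <- dim(voxel_map)
  rng <- config$projection_slices
  if (rng[2] > d[3])
    stop(sprintf("projection range %d..%d exceeds %d slices", rng[1], rng[2],
                 d[3]), call. = FALSE)
  sl <- rng[1]:rng[2]
  grid <- config$projection_grid
  pc <- preprocess_config(grid_rows = grid[1], grid_cols = grid[2])
  heat <- volume_to_mosaic(voxel_map[, , sl, drop = FALSE], pc)
  brain <- volume_to_mosaic(avg_brain[, , sl, drop = FALSE], pc)
  norm01 <- function(m) if (max(m) > min(m)) (m - min(m)) / (max(m) - min(m))
                        else m * 0
  overlay <- (1 - alpha) * norm01(brain) + alpha * norm01(heat)
  structure(list(heat = heat, brain = brain, overlay = overlay, grid = grid,
                 slices = sl),
            class = "pet_class_heatmap")
}

#' Fraction of top response mass inside a planted region
#'
#' Takes the top 5% (by default) most-responsive voxels of the map and
#' returns the fraction of their response mass that falls inside the given
#' mask — a quantitative check that the attention map recovers the planted
#' discriminative region.
#'
#' @param voxel_map 3D response array.
#' @param mask Logical 3D array of the same shape.
#' @param top_fraction Fraction of voxels considered "most responsive".
#' @return Scalar in `[0, 1]`; 0 (with a warning) for an all-zero map.
#' @export
region_recovery_score <- function(voxel_map, mask, top_fraction = 0.05) {
  stopifnot(identical(dim(voxel_map), dim(mask)))
  v <- as.numeric(voxel_map)
  if (all(v == 0)) {
    warning("all-zero response map; recovery score undefined, returning 0",
            call. = FALSE)
    return(0)
  }
  n_top <- max(1L, ceiling(top_fraction * length(v)))
  ord <- order(v, decreasing = TRUE)[seq_len(n_top)]
  top_mass <- sum(v[ord])
  if (top_mass <= 0) return(0)
  sum(v[ord][mask[ord]]) / top_mass
}

#' Linear probe model with a planted dependence
#'
#' A minimal classifier whose "correct class" probability depends only on the
#' mean intensity of one planted window on one axial slice:
#' `p = plogis(gain * (mean(window) - bias))`, shared evenly over the other
#' classes. Occluding exactly the planted window produces the largest
#' cross-entropy response, which makes this the ground-truth fixture for
#' occlusion-map localisation checks.
#'
#' @param slice_idx,row,col 1-based planted window position.
#' @param window Window shape (height, width).
#' @param n_classes Number of classes (class 1 is the planted "true" class).
#' @param gain,bias Logistic scale and offset.
#' @return An object of class `pet_probe_model` usable with
#'   [predict_proba()], [response()] and [occlusion_map()].
#' @export
probe_model <- function(slice_idx, row, col, window = c(6L, 5L),
                        n_classes = 2L, gain = 8, bias = 0) {
  structure(list(slice_idx = slice_idx, row = row, col = col,
                 window = as.integer(window), n_classes = as.integer(n_classes),
                 gain = gain, bias = bias,
                 classes = paste0("class", seq_len(n_classes)),
                 spec = list(n_classes = as.integer(n_classes))),
            class = "pet_probe_model")
}

#' @export
predict_proba.pet_probe_model <- function(model, x) {
  if (!is.list(x)) x <- list(x)
  p <- t(vapply(x, function(v) {
    win <- v[model$row:(model$row + model$window[1] - 1),
             model$col:(model$col + model$window[2] - 1),
             model$slice_idx]
    p1 <- stats::plogis(model$gain * (mean(win) - model$bias))
    c(p1, rep((1 - p1) / (model$n_classes - 1), model$n_classes - 1))
  }, numeric(model$n_classes)))
  colnames(p) <- model$classes
  p
}
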