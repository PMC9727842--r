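test_that("position-grid cardinality matches the closed-form stride count", {
  set.seed(1)
  for (i in 1:20) {
    H <- sample(10:60, 1); W <- sample(10:60, 1)
    h <- sample(2:6, 1); w <- sample(2:6, 1); s <- sample(1:4, 1)
    cfg <- occlusion_config(window = c(h, w), stride = s,
                            projection_slices = c(1, 4),
                            projection_grid = c(2, 2))
    pos <- occlusion_positions(c(H, W), cfg)
    expect_length(pos$rows, (H - h) %/% s + 1)
    expect_length(pos$cols, (W - w) %/% s + 1)
    # brute force: every start offset whose window fits, on the stride lattice
    expect_identical(pos$rows,
                     seq(1L, H, by = s)[seq(1L, H, by = s) + h - 1 <= H])
  }
  expect_error(occlusion_positions(c(5, 5), occlusion_config()),
               "exceeds")
})

test_that("occlusion touches exactly one window and commutes when disjoint", {
  v <- tiny_volume(2, c(12, 10, 6)) + 1   # strictly positive
  cfg <- occlusion_config(window = c(3, 2), projection_slices = c(1, 4),
                          projection_grid = c(2, 2))
  o <- occlude(v, 4, 5, 6, cfg)
  expect_equal(sum(o != v), 3 * 2)
  expect_true(all(o[5:7, 6:7, 4] == 0))

  # occluding an already-zero region changes nothing
  vz <- v; vz[1:3, 1:2, 2] <- 0
  expect_identical(occlude(vz, 2, 1, 1, cfg), vz)

  # disjoint occlusions commute
  a <- occlude(occlude(v, 1, 1, 1, cfg), 1, 8, 8, cfg)
  b <- occlude(occlude(v, 1, 8, 8, cfg), 1, 1, 1, cfg)
  expect_identical(a, b)
  expect_error(occlude(v, 1, 11, 1, cfg), "out of bounds")
})

test_that("cross-entropy response matches its closed form", {
  pm <- probe_model(slice_idx = 2, row = 3, col = 3, window = c(3, 2),
                    gain = 4, bias = 0.2)
  v <- tiny_volume(3, c(10, 8, 4))
  win_mean <- mean(v[3:5, 3:4, 2])
  p_true <- plogis(4 * (win_mean - 0.2))
  expect_equal(response(pm, v, "class1"), -log(p_true), tolerance = 1e-12)
  expect_equal(response(pm, v, 1), -log(p_true), tolerance = 1e-12)
  expect_gte(response(pm, v, 2), 0)
  # p_true = 1 => response 0 (up to the clip)
  sat <- probe_model(2, 3, 3, window = c(3, 2), gain = 1e9, bias = -10)
  expect_equal(response(sat, v, 1), 0, tolerance = 1e-6)
})

test_that("occlusion maps localise a planted window exactly", {
  # probe depends on one grid-aligned window; the argmax of the averaged map
  # must be that exact position
  cfg <- occlusion_config(window = c(6, 5), stride = 2,
                          projection_slices = c(1, 4),
                          projection_grid = c(2, 2))
  pm <- probe_model(slice_idx = 3, row = 7, col = 9, window = c(6, 5),
                    gain = 10)
  maps <- lapply(1:3, function(i) {
    v <- tiny_volume(10 + i, c(20, 19, 5)) * 0.5 + 0.5
    occlusion_map(pm, v, "class1", cfg)
  })
  avg <- class_average(maps, "class1")
  expect_equal(dim(avg$responses),
               c(5, (20 - 6) %/% 2 + 1, (19 - 5) %/% 2 + 1))
  expect_true(all(avg$responses >= 0))
  idx <- arrayInd(which.max(avg$responses), dim(avg$responses))
  expect_equal(idx[1], 3)                 # planted slice
  expect_equal(avg$rows[idx[2]], 7)       # planted row
  expect_equal(avg$cols[idx[3]], 9)       # planted col

  # constant-output model: all responses equal
  flat <- probe_model(3, 7, 9, window = c(6, 5), gain = 0)
  m0 <- occlusion_map(flat, tiny_volume(20, c(20, 19, 5)), "class1", cfg)
  expect_equal(max(m0$responses) - min(m0$responses), 0)
})

test_that("class_average rejects mismatched maps and averages element-wise", {
  cfg <- occlusion_config(window = c(3, 3), stride = 3,
                          projection_slices = c(1, 4),
                          projection_grid = c(2, 2))
  pm <- probe_model(1, 1, 1, window = c(3, 3), gain = 2)
  v1 <- tiny_volume(5, c(9, 9, 4)); v2 <- tiny_volume(6, c(9, 9, 4))
  m1 <- occlusion_map(pm, v1, "class1", cfg)
  m2 <- occlusion_map(pm, v2, "class1", cfg)
  avg <- class_average(list(m1, m2), "class1")
  expect_equal(avg$responses, (m1$responses + m2$responses) / 2)
  expect_equal(class_average(list(m1), "class1")$responses, m1$responses)
  expect_error(class_average(list(), "class1"), "no occlusion maps")
  m2$true_class <- "class2"
  expect_error(class_average(list(m1, m2), "class1"), "share true_class")
})

test_that("voxel accumulation is coverage-weighted and matches brute force", {
  cfg <- occlusion_config(window = c(3, 2), stride = 2,
                          projection_slices = c(1, 4),
                          projection_grid = c(2, 2))
  pm <- probe_model(1, 1, 1, window = c(3, 2), gain = 0)   # constant model
  v <- tiny_volume(7, c(9, 8, 3))
  m <- occlusion_map(pm, v, "class1", cfg)
  vm <- to_voxel_map(m)
  r0 <- m$responses[1, 1, 1]
  covered <- vm != 0
  expect_true(all(abs(vm[covered] - r0) < 1e-12))

  # brute-force coverage counting
  cover <- array(0L, dim = dim(v)[1:2])
  for (r in m$rows) for (cc in m$cols)
    cover[r:(r + 2), cc:(cc + 1)] <- cover[r:(r + 2), cc:(cc + 1)] + 1L
  expect_identical(unname(vm[, , 2] != 0), unname(cover > 0))

  # a single nonzero position contributes to exactly h x w voxels of its slice
  m1 <- m
  m1$responses[] <- 0
  m1$responses[2, 3, 4] <- 5
  vm1 <- to_voxel_map(m1)
  expect_equal(sum(vm1[, , 2] != 0), 3 * 2)
  expect_equal(sum(vm1[, , c(1, 3)] != 0), 0)
})

test_that("mosaic projection tiles the configured slices over the brain", {
  cfg <- occlusion_config(window = c(3, 2), stride = 2,
                          projection_slices = c(2, 7),
                          projection_grid = c(2, 3))
  vm <- tiny_volume(8, c(6, 5, 8))
  brain <- tiny_volume(9, c(6, 5, 8))
  hm <- project_mosaic(vm, brain, cfg)
  expect_equal(dim(hm$heat), c(12, 15))
  # tile (i div 3, i mod 3) holds slice 2 + i
  for (i in 0:5) {
    tr <- i %/% 3; tc <- i %% 3
    tile <- hm$heat[tr * 6 + 1:6, tc * 5 + 1:5]
    expect_identical(tile, vm[, , 2 + i])
  }
  # zero heatmap: overlay reduces to the (scaled) average brain
  hm0 <- project_mosaic(vm * 0, brain, cfg)
  bn <- (hm0$brain - min(hm0$brain)) / diff(range(hm0$brain))
  expect_equal(hm0$overlay, 0.4 * bn, tolerance = 1e-12)
  expect_error(project_mosaic(vm[, , 1:3], brain[, , 1:3], cfg), "exceeds")
  expect_s3_class(autoplot(hm), "ggplot")
})

test_that("region recovery scores behave at the extremes", {
  vm <- tiny_volume(10, c(10, 10, 10))
  all_mask <- array(TRUE, dim = dim(vm))
  expect_equal(region_recovery_score(vm, all_mask), 1)
  expect_warning(z <- region_recovery_score(vm * 0, all_mask), "all-zero")
  expect_equal(z, 0)

  # uniform response mass: expected score ~ mask fraction of the top set
  set.seed(11)
  u <- array(runif(8000, 0.99, 1.01), dim = c(20, 20, 20))
  mask <- array(FALSE, dim = dim(u))
  mask[1:10, , ] <- TRUE                  # half the voxels
  sc <- region_recovery_score(u, mask)
  expect_lt(abs(sc - 0.5), 0.12)
})
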