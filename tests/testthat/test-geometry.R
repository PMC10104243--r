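test_that("resampling hits exact arc-length targets on straight filaments", {
  f <- filaments(straight_filament("a", c(0, 0, 0), c(60, 0, 0)))
  r <- resample_filaments(f, 4)
  expect_equal(nrow(r), 16)
  expect_equal(r$x, seq(0, 60, by = 4))
  expect_equal(r$y, rep(0, 16))
})

test_that("resampling an L-shaped filament matches the dense-walk oracle", {
  nodes <- rbind(c(0, 0, 0), c(30, 0, 0), c(30, 40, 0))
  f <- filaments(tibble(filament_id = "L", kind = "actin", node_index = 1:3,
                        x = nodes[, 1], y = nodes[, 2], z = nodes[, 3]))
  r <- resample_filaments(f, 4)
  expect_equal(nrow(r), 19)  # arc lengths 0,4,...,68 plus terminal at 70
  expect_equal(unlist(r[19, c("x", "y", "z")], use.names = FALSE), c(30, 40, 0))
  oracle <- oracle_resample(nodes, 4)
  expect_equal(as.matrix(r[, c("x", "y", "z")]), oracle,
               ignore_attr = TRUE, tolerance = 0.02)
})

test_that("resampled point counts and spacing obey the construction", {
  set.seed(99)
  for (i in 1:10) {
    f <- filaments(random_filament_set(1, seed = i))
    L <- filament_lengths(f)$arc_length
    r <- resample_filaments(f, 4)
    expect_true(nrow(r) %in% c(floor(L / 4) + 1, floor(L / 4) + 2))
    steps <- sqrt(diff(r$x)^2 + diff(r$y)^2 + diff(r$z)^2)
    if (length(steps) > 1) {
      expect_equal(steps[-length(steps)], rep(4, length(steps) - 1),
                   tolerance = 1e-6)
    }
    # length coverage within one interval
    expect_lt(abs(sum(steps) - L), 4 + 1e-9)
  }
})

test_that("interval larger than the filament degrades to both end nodes", {
  f <- filaments(straight_filament("a", c(0, 0, 0), c(10, 0, 0)))
  expect_warning(r <- resample_filaments(f, 50), "interval")
  expect_equal(nrow(r), 2)
  expect_equal(r$x, c(0, 10))
})

test_that("chord angles follow closed forms and symmetry", {
  expect_equal(angle_between_chords(c(1, 0, 0), c(0, 1, 0)), 90)
  expect_equal(angle_between_chords(c(1, 0, 0), c(-1, 0, 0)), 0)
  expect_equal(angle_between_chords(c(1, 0, 0), c(-1, 0, 0), "directed"), 180)
  expect_equal(angle_between_chords(c(1, 1, 0) / sqrt(2), c(1, 0, 0)), 45)
  expect_error(angle_between_chords(c(0, 0, 0), c(1, 0, 0)), "zero")
  set.seed(3)
  for (i in 1:20) {
    a <- rnorm(3); a <- a / sqrt(sum(a^2))
    b <- rnorm(3); b <- b / sqrt(sum(b^2))
    expect_equal(angle_between_chords(a, b), angle_between_chords(b, a))
    d <- angle_between_chords(a, b, "directed")
    expect_equal(angle_between_chords(a, b), min(d, 180 - d))
  }
})

test_that("plane elevation spans parallel to orthogonal", {
  expect_equal(angle_to_reference_plane(c(1, 0, 0)), 0)
  expect_equal(angle_to_reference_plane(c(0, 0, 1)), 90)
  expect_equal(angle_to_reference_plane(c(1, 0, 1) / sqrt(2)), 45)
})

test_that("accelerated nearest-neighbor equals brute force on random scenes", {
  for (seed in 1:6) {
    fil <- filaments(random_filament_set(sample(3:8, 1), seed = seed))
    pts <- resample_filaments(fil, 4)
    fast <- nearest_foreign_points(pts)
    slow <- oracle_nearest_foreign(pts)
    expect_identical(fast$nn_distance, slow$nn_distance)
    expect_identical(fast$nn_filament_id, slow$nn_filament_id)
    expect_identical(fast$nn_point_index, slow$nn_point_index)
  }
})

test_that("parallel filaments at fixed offset yield that exact distance", {
  fil <- filaments(bind_rows(
    straight_filament("a", c(0, 0, 0), c(100, 0, 0)),
    straight_filament("b", c(0, 12.5, 0), c(100, 12.5, 0))
  ))
  nn <- nearest_foreign_points(resample_filaments(fil, 4))
  expect_true(all(nn$nn_distance == 12.5))
})

test_that("self-identical reference points are excluded by filament id", {
  fil <- filaments(bind_rows(
    straight_filament("a", c(0, 0, 0), c(100, 0, 0)),
    straight_filament("b", c(0, 10, 0), c(100, 10, 0)),
    straight_filament("c", c(0, 40, 0), c(100, 40, 0))
  ))
  pts <- resample_filaments(fil, 4)
  nn <- nearest_foreign_points(pts)
  expect_true(all(nn$nn_filament_id != nn$filament_id))
  b_rows <- nn$filament_id == "b"
  expect_true(all(nn$nn_distance[b_rows] == 10))
  expect_true(all(nn$nn_filament_id[b_rows] == "a"))
})

test_that("mask surface distances match sphere geometry and the oracle", {
  vs <- 5
  m <- sphere_mask(c(300, 200, 200), 150, extent = c(500, 400, 400), voxel_size = vs)
  pts <- rbind(c(50, 200, 200), c(300, 200, 200), c(300, 10, 200))
  d_edt <- distance_to_mask_surface(pts, m)
  expect_equal(d_edt$distance[1], 100, tolerance = vs * sqrt(3))
  expect_equal(d_edt$distance[2], 0)  # center is inside
  expect_equal(d_edt$distance[3], 40, tolerance = vs * sqrt(3))
  d_ex <- distance_to_mask_surface(pts, m, method = "exact")
  oracle <- oracle_mask_distance(pts, m)
  expect_equal(d_ex$distance, oracle, tolerance = 1e-9)
  expect_equal(d_edt$distance, oracle, tolerance = vs * sqrt(3))
})

test_that("EDT distances track the exhaustive boundary search on random blobs", {
  set.seed(17)
  g <- array(0L, c(20, 20, 20))
  seedpts <- cbind(sample(5:15, 3), sample(5:15, 3), sample(5:15, 3))
  for (r in 1:3) {
    g[max(1, seedpts[r, 1] - 2):min(20, seedpts[r, 1] + 2),
      max(1, seedpts[r, 2] - 2):min(20, seedpts[r, 2] + 2),
      max(1, seedpts[r, 3] - 2):min(20, seedpts[r, 3] + 2)] <- 1L
  }
  m <- volume_mask(g, voxel_size = 3, role = "isg")
  pts <- cbind(runif(100, 0, 60), runif(100, 0, 60), runif(100, 0, 60))
  fast <- distance_to_mask_surface(pts, m)$distance
  slow <- oracle_mask_distance(pts, m)
  expect_true(all(abs(fast - slow) <= 3 * sqrt(3) + 1e-9))
  exact <- distance_to_mask_surface(pts, m, method = "exact")$distance
  expect_equal(exact, slow, tolerance = 1e-12)
})

test_that("points outside the grid are clamped and flagged", {
  m <- sphere_mask(c(50, 50, 50), 20, extent = c(100, 100, 100), voxel_size = 5)
  expect_warning(d <- distance_to_mask_surface(rbind(c(-40, 50, 50)), m), "outside")
  expect_true(d$clamped[1])
  expect_gt(d$distance[1], 0)
})

test_that("angles and pair distances are invariant under rigid motion", {
  fil <- filaments(random_filament_set(5, seed = 8))
  R <- rotation_matrix(0.4, -0.8, 1.2)
  tr <- c(40, -40, 90)
  fil2 <- filaments(apply_rigid(fil, R, tr))
  nn1 <- nearest_foreign_points(resample_filaments(fil, 4))
  nn2 <- nearest_foreign_points(resample_filaments(fil2, 4))
  expect_equal(nn1$nn_distance, nn2$nn_distance, tolerance = 1e-6)
  c1 <- filament_chords(fil)
  c2 <- filament_chords(fil2)
  a1 <- angle_between_chords(as.matrix(c1[1, c("ux", "uy", "uz")]),
                             as.matrix(c1[2, c("ux", "uy", "uz")]))
  a2 <- angle_between_chords(as.matrix(c2[1, c("ux", "uy", "uz")]),
                             as.matrix(c2[2, c("ux", "uy", "uz")]))
  expect_equal(a1, a2, tolerance = 1e-6)
})
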