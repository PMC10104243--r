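isg_scene <- function(fil, mask, extent = c(500, 400, 400)) {
  scene_bundle(filaments(fil), list(isg = mask), condition = "synthetic",
               scene_id = "prox", extent = extent)
}

test_that("granule distances follow sphere geometry, zero at contact", {
  vs <- 5
  m <- sphere_mask(c(300, 200, 200), 150, extent = c(500, 400, 400), voxel_size = vs)
  # line passing at closest approach 300 nm from center -> 150 from surface
  fil <- straight_filament("a", c(0, 380, 200), c(480, 380, 200), n_nodes = 3)
  rec <- filament_isg_distances(isg_scene(fil, m))
  expect_equal(min(rec$distance), 150, tolerance = vs * sqrt(3))
  # a point on the surface measures (near) zero
  fil2 <- straight_filament("b", c(150, 200, 200), c(30, 200, 200))
  rec2 <- filament_isg_distances(isg_scene(fil2, m))
  expect_lte(min(rec2$distance), vs * sqrt(3))
  expect_equal(min(rec2$distance), 0, tolerance = vs * sqrt(3))
})

test_that("the 200 nm cutoff trims histograms but not raw records", {
  rec <- tibble(distance = c(50, 120, 250, 400))
  h <- distance_histogram(rec, cutoff = 200, bin_width = 75)
  expect_equal(sum(h$n), 2)            # 250 and 400 excluded from the histogram
  expect_equal(sum(h$probability), 1)
  expect_equal(nrow(rec), 4)           # raw records untouched
  h_all <- distance_histogram(rec, cutoff = NULL, bin_width = 75)
  expect_equal(sum(h_all$n), 4)
  # cutoff consistency: included mass equals the raw fraction under cutoff
  expect_equal(attr(h, "provenance")$n_included / nrow(rec),
               mean(rec$distance <= 200))
})

test_that("dilating a spherical granule shifts outside distances by delta", {
  vs <- 4
  base <- sphere_mask(c(200, 200, 200), 100, extent = c(400, 400, 400), voxel_size = vs)
  dilated <- sphere_mask(c(200, 200, 200), 120, extent = c(400, 400, 400), voxel_size = vs)
  pts <- rbind(c(200, 200, 370), c(30, 200, 200), c(200, 40, 200))
  d0 <- distance_to_mask_surface(pts, base, method = "exact")$distance
  d1 <- distance_to_mask_surface(pts, dilated, method = "exact")$distance
  expect_equal(d0 - d1, rep(20, 3), tolerance = vs * sqrt(3))
})

test_that("actin-MT distances match the oracle and per-filament minima", {
  fil <- bind_rows(
    random_filament_set(4, seed = 77),
    random_filament_set(2, seed = 78, kind = "mt")
  )
  sc <- scene_bundle(filaments(fil), list(), condition = "synthetic",
                     scene_id = "amt", extent = c(300, 300, 300))
  res <- actin_mt_distances(sc)
  apts <- resample_filaments(filaments(filter(fil, kind == "actin")), 4)
  mpts <- resample_filaments(filaments(filter(fil, kind == "mt")), 4)
  oracle <- oracle_nearest_foreign(apts, mpts)
  expect_identical(res$points$distance, oracle$nn_distance)
  # per-filament minimum really is the minimum over that filament's points
  per <- res$points %>% group_by(filament_id) %>%
    summarise(m = min(distance), .groups = "drop")
  expect_equal(
    res$filaments$shortest_mt_distance[order(res$filaments$filament_id)],
    per$m[order(per$filament_id)])
  expect_true(all(res$filaments$shortest_mt_distance <= tapply(
    res$points$distance, res$points$filament_id, min) + 1e-12))
})

test_that("parallel and crossing actin-MT fixtures give exact distances", {
  fil <- bind_rows(
    straight_filament("a1", c(50, 100, 100), c(250, 100, 100)),
    straight_filament("m1", c(50, 150, 100), c(250, 150, 100), kind = "mt")
  )
  sc <- scene_bundle(filaments(fil), list(), condition = "synthetic",
                     scene_id = "par", extent = c(300, 300, 300))
  res <- actin_mt_distances(sc)
  expect_true(all(res$points$distance == 50))
  expect_equal(res$filaments$shortest_mt_distance, 50)

  cross <- bind_rows(
    straight_filament("a1", c(50, 150, 120), c(250, 150, 120)),
    straight_filament("m1", c(150, 50, 100), c(150, 250, 100), kind = "mt")
  )
  sc2 <- scene_bundle(filaments(cross), list(), condition = "synthetic",
                      scene_id = "crs", extent = c(300, 300, 300))
  res2 <- actin_mt_distances(sc2)
  expect_equal(res2$filaments$shortest_mt_distance, 20)
})

test_that("missing granules or microtubules degrade gracefully", {
  fil <- straight_filament("a", c(10, 10, 10), c(100, 10, 10))
  sc <- scene_bundle(filaments(fil), list(), condition = "synthetic",
                     scene_id = "none", extent = c(200, 200, 200))
  expect_warning(rec <- filament_isg_distances(sc), "ISG")
  expect_equal(nrow(rec), 0)
  expect_warning(res <- actin_mt_distances(sc), "MT")
  expect_equal(nrow(res$points), 0)
})
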