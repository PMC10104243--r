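anchor_scene <- function(fil, extent = c(200, 200, 300), voxel_size = 5,
                         z_centers = c(20, 280)) {
  scene_bundle(filaments(fil),
               list(pm = slab_pm_mask(extent, voxel_size, z_centers)),
               condition = "synthetic", scene_id = "anch", extent = extent)
}

test_that("PM component labeling counts slabs and matches flood fill", {
  one <- slab_pm_mask(z_centers = 100)
  expect_equal(label_pm_components(one)$n_components, 1)
  two <- slab_pm_mask(z_centers = c(20, 220))
  expect_equal(label_pm_components(two)$n_components, 2)

  set.seed(12)
  g <- array(as.integer(runif(15^3) < 0.2), c(15, 15, 15))
  if (!any(g != 0L)) g[1] <- 1L
  m <- volume_mask(g, 4, role = "pm")
  expect_equal(label_pm_components(m)$n_components, oracle_component_count(g))
})

test_that("anchoring respects the 60 nm end-point threshold exactly", {
  vs <- 5
  # lower slab spans z in [15, 25]; top boundary voxel centers at z = 22.5
  z_surface <- 22.5
  # xy positions on voxel-center columns so distances are pure z offsets
  fil <- bind_rows(
    straight_filament("near", c(102.5, 102.5, z_surface + 50), c(102.5, 102.5, z_surface + 170)),
    straight_filament("far", c(152.5, 152.5, z_surface + 61), c(152.5, 152.5, z_surface + 170)),
    straight_filament("at", c(52.5, 52.5, z_surface + 60), c(52.5, 52.5, z_surface + 170))
  )
  anc <- find_anchored(anchor_scene(fil, voxel_size = vs))
  a <- setNames(anc$anchored, anc$filament_id)
  expect_true(a[["near"]])
  expect_false(a[["far"]])
  expect_true(a[["at"]])  # boundary case: within means <=
  expect_equal(anc$end_pm_distance[anc$filament_id == "near"], 50)
})

test_that("near and far ends order by PM distance; vector points away", {
  fil <- straight_filament("f", c(100, 100, 130), c(100, 100, 40))
  # node order starts at the far end: near end must still be detected at z=40
  anc <- find_anchored(anchor_scene(fil))
  expect_true(anc$anchored)
  expect_equal(anc$near_z, 40)
  expect_equal(anc$far_z, 130)
  expect_gt(anc$vz, 0)  # away from the lower PM
})

test_that("neighbor relation obeys separation, component and symmetry rules", {
  fil <- bind_rows(
    straight_filament("a", c(50, 50, 50), c(50, 50, 170)),
    straight_filament("b", c(150, 50, 50), c(150, 50, 170)),   # 100 nm from a
    straight_filament("c", c(50, 185, 50), c(50, 185, 170))    # 135 nm from a
  )
  anc <- find_anchored(anchor_scene(fil))
  expect_true(all(anc$anchored))
  nb <- neighbor_angles(anc)
  pairs <- paste(nb$filament_id_a, nb$filament_id_b)
  expect_true(all(c("a b", "b a") %in% pairs))
  expect_false(any(grepl("c", pairs)))  # 135 nm > 120 nm separation
  expect_equal(nb$directed_angle, rep(0, nrow(nb)))
  # ordered pairs come in equal-angle mirror pairs
  ab <- nb$directed_angle[pairs == "a b"]
  ba <- nb$directed_angle[pairs == "b a"]
  expect_equal(ab, ba)
})

test_that("antiparallel anchored vectors give a 180 degree directed angle", {
  # near-horizontal filaments running in opposite directions, both with
  # their near end at the lower PM; near-end separation 110.5 nm < 120
  fil <- bind_rows(
    straight_filament("east", c(60, 100, 50), c(170, 100, 52)),
    straight_filament("west", c(170, 110, 50), c(60, 110, 52))
  )
  anc <- find_anchored(anchor_scene(fil))
  expect_true(all(anc$anchored))
  nb <- neighbor_angles(anc)
  expect_equal(nrow(nb), 2)
  expect_true(all(nb$directed_angle > 175))
  # undirected projection folds the same pair to [0, 90]
  und <- angle_between_chords(as.matrix(anc[1, c("vx", "vy", "vz")]),
                              as.matrix(anc[2, c("vx", "vy", "vz")]),
                              mode = "undirected")
  expect_lt(und, 3)  # two ~1 degree tilts away from horizontal
})

test_that("netlike and blooming generator scenes separate in the histograms", {
  net <- generate_scene(scene_spec(seed = 41, n_actin = 80, n_isg = 0,
                                   voxel_size = 10,
                                   quasi_orthogonal_fraction = 0.3,
                                   architecture = "netlike"))
  nb_net <- neighbor_angles(find_anchored(net$scene))
  h_net <- anchored_angle_histograms(nb_net)
  qo <- filter(h_net, host_orientation_class == "quasi_orthogonal")
  expect_equal(sum(qo$probability), 1)
  mode_bin <- qo$bin_lo[which.max(qo$probability)]
  expect_true(mode_bin >= 60 && mode_bin < 90)

  bloom <- generate_scene(scene_spec(seed = 41, n_actin = 80, n_isg = 0,
                                     voxel_size = 10,
                                     quasi_orthogonal_fraction = 0.3,
                                     architecture = "blooming"))
  nb_bloom <- neighbor_angles(find_anchored(bloom$scene))
  h_bloom <- anchored_angle_histograms(nb_bloom)
  qo_b <- filter(h_bloom, host_orientation_class == "quasi_orthogonal")
  expect_lt(qo_b$bin_lo[which.max(qo_b$probability)], 30)

  # identical vectors pile all mass into the first bin
  same <- tibble(directed_angle = rep(2, 8), host_orientation_class = "parallel")
  h_same <- anchored_angle_histograms(same)
  expect_equal(h_same$probability[h_same$bin_lo == 0], 1)
})

test_that("anchored summary percentages stay within bounds", {
  g <- generate_scene(scene_spec(seed = 4, n_actin = 60, n_isg = 0,
                                 voxel_size = 10, anchored_fraction = 0.75))
  anc <- find_anchored(g$scene)
  s <- attr(anc, "summary")
  expect_lte(s$anchored_count, s$n_filaments)
  expect_gte(s$anchored_percentage, 0)
  expect_lte(s$anchored_percentage, 100)
  expect_equal(s$anchored_count, sum(g$truth$filaments$anchored_true))
})

test_that("periphery height reads slab separation, tilted or not", {
  sc <- anchor_scene(straight_filament("f", c(50, 50, 60), c(50, 50, 160)),
                     z_centers = c(20, 220))
  expect_equal(as.numeric(periphery_height(sc)), 200, tolerance = 5)

  # tilted parallel slabs: mean-z separation is gap / cos(tilt)
  vs <- 4
  extent <- c(200, 200, 400)
  dims <- round(extent / vs)
  g <- array(0L, dims)
  tilt <- 10 * pi / 180
  yc <- (seq_len(dims[2]) - 0.5) * vs
  zc <- (seq_len(dims[3]) - 0.5) * vs
  for (j in seq_len(dims[2])) {
    plane_lo <- 60 + tan(tilt) * (yc[j] - 100)
    plane_hi <- plane_lo + 200 / cos(tilt)
    g[, j, abs(zc - plane_lo) <= vs] <- 1L
    g[, j, abs(zc - plane_hi) <= vs] <- 1L
  }
  m <- volume_mask(g, vs, role = "pm")
  fil <- filaments(straight_filament("f", c(50, 100, 150), c(150, 100, 150)))
  sc2 <- scene_bundle(fil, list(pm = m), condition = "synthetic",
                      scene_id = "tilt", extent = extent)
  expect_equal(as.numeric(periphery_height(sc2)), 200 / cos(tilt),
               tolerance = 2 * vs)

  # generator ground truth: height recovered within a voxel
  gsc <- generate_scene(scene_spec(seed = 2, n_actin = 30, n_isg = 0,
                                   voxel_size = 5, periphery_height = 250,
                                   extent = c(600, 600, 320)))
  expect_equal(as.numeric(periphery_height(gsc$scene)), 250, tolerance = 5)

  # single component cannot define the z-based height
  one <- anchor_scene(straight_filament("f", c(50, 50, 60), c(50, 50, 160)),
                      z_centers = 20)
  expect_error(periphery_height(one), "single component")
})
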