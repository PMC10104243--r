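make_scene <- function(fil, extent = c(1000, 1000, 1000), masks = list(),
                       scene_id = "s1") {
  scene_bundle(filaments(fil), masks, condition = "synthetic",
               scene_id = scene_id, extent = extent)
}

test_that("orientation fractions mirror a constructed 97/3 split", {
  in_plane <- bind_rows(lapply(1:97, function(i) {
    ang <- i * 3.6
    straight_filament(sprintf("p%02d", i), c(500, 500, 100),
                      c(500 + 100 * cos(ang), 500 + 100 * sin(ang), 100))
  }))
  vertical <- bind_rows(lapply(1:3, function(i) {
    straight_filament(sprintf("v%02d", i), c(100 * i, 100 * i, 100),
                      c(100 * i, 100 * i, 250))
  }))
  sc <- make_scene(bind_rows(in_plane, vertical))
  o <- orientation_distribution(sc)
  expect_equal(o$fractions$parallel_fraction, 0.97)
  expect_equal(o$fractions$quasi_orthogonal_fraction, 0.03)
  expect_equal(sum(o$histogram$fraction), 1)
})

test_that("exactly 45 degrees classifies as quasi-orthogonal", {
  f <- straight_filament("edge", c(0, 0, 0), c(100, 0, 100))
  rec <- orientation_records(filaments(f))
  expect_equal(rec$angle_to_pm, 45)
  expect_equal(rec$orientation_class, "quasi_orthogonal")
})

test_that("orientation fractions sum to one over any partition", {
  sc <- generate_scene(scene_spec(seed = 21, n_actin = 50, n_isg = 0,
                                  voxel_size = 10))$scene
  o <- orientation_distribution(sc, bin_width = 7)
  expect_equal(sum(o$histogram$fraction), 1)
  expect_equal(o$fractions$parallel_fraction +
                 o$fractions$quasi_orthogonal_fraction, 1)
})

test_that("volume ratio matches the cylinder closed form", {
  f <- straight_filament("a", c(100, 100, 100), c(700, 100, 100))  # 600 nm
  sc <- make_scene(f)
  expect_equal(volume_ratio(sc, "actin"), pi * 16 * 600 / 1e9)
  # empty scene of the other kind
  expect_equal(volume_ratio(sc, "mt"), 0)
})

test_that("volume ratio is additive over filaments and rigid-motion invariant", {
  fil <- random_filament_set(50, seed = 5)
  sc <- make_scene(fil, extent = c(400, 400, 400))
  per_fil <- filament_lengths(filaments(fil))
  closed <- sum(per_fil$arc_length) * pi * 16 / 400^3
  expect_equal(volume_ratio(sc, "actin"), closed, tolerance = 1e-12)
  R <- rotation_matrix(0.2, 0.1, -0.4)
  sc2 <- make_scene(apply_rigid(fil, R, c(600, 600, 600)),
                    extent = c(400, 400, 400) * 3)
  expect_equal(volume_ratio(sc2, "actin") * 27, volume_ratio(sc, "actin"),
               tolerance = 1e-9)
})

test_that("pair records capture bundle and crossing geometry", {
  bundle <- bind_rows(
    straight_filament("a", c(100, 100, 100), c(300, 100, 100)),
    straight_filament("b", c(100, 112.5, 100), c(300, 112.5, 100))
  )
  rec <- pair_distance_angle(make_scene(bundle))
  expect_true(all(rec$nn_distance == 12.5))
  expect_true(all(rec$pair_angle < 1e-6))

  crossing <- bind_rows(
    straight_filament("a", c(100, 300, 100), c(500, 300, 100)),
    straight_filament("b", c(300, 100, 120), c(300, 500, 120))
  )
  rec2 <- pair_distance_angle(make_scene(crossing))
  expect_equal(min(rec2$nn_distance), 20)
  at_min <- rec2[which.min(rec2$nn_distance), ]
  expect_equal(unname(at_min$pair_angle), 90)
})

test_that("pair records equal the exhaustive oracle on random scenes", {
  for (seed in c(2, 9)) {
    fil <- random_filament_set(5, seed = seed)
    sc <- make_scene(fil, extent = c(300, 300, 300))
    rec <- pair_distance_angle(sc)
    pts <- resample_filaments(filaments(fil), 4)
    oracle <- oracle_nearest_foreign(pts)
    expect_identical(rec$nn_distance, oracle$nn_distance)
    expect_identical(rec$nn_filament_id, oracle$nn_filament_id)
  }
})

test_that("single filament yields an empty pair table with a warning", {
  sc <- make_scene(straight_filament("solo", c(0, 0, 0), c(100, 0, 0)))
  expect_warning(rec <- pair_distance_angle(sc), "fewer than two")
  expect_equal(nrow(rec), 0)
})

test_that("class-split distance histograms normalize per class", {
  rec <- tibble(
    nn_distance = c(rep(12.5, 10), runif(50, 0, 100)),
    host_orientation_class = c(rep("parallel", 10), rep("quasi_orthogonal", 50))
  )
  h <- distance_histograms_by_class(rec, bin_width = 10)
  par <- filter(h, host_orientation_class == "parallel")
  expect_equal(sum(par$probability), 1)
  expect_equal(par$probability[par$bin_lo == 10], 1)  # all mass in [10,20)
  qo <- filter(h, host_orientation_class == "quasi_orthogonal")
  expect_equal(sum(qo$probability), 1)

  # empty class: only the present histogram is emitted
  expect_message(h2 <- distance_histograms_by_class(
    filter(rec, host_orientation_class == "parallel")), "omitted")
  expect_equal(unique(h2$host_orientation_class), "parallel")
})

test_that("near-uniform distances fill 10 nm bins uniformly", {
  set.seed(14)
  rec <- tibble(nn_distance = runif(20000, 0, 100),
                host_orientation_class = "parallel")
  h <- distance_histograms_by_class(rec, bin_width = 10, max_distance = 100)
  chi <- sum((h$n - 2000)^2 / 2000)
  expect_gt(stats::pchisq(chi, df = 9, lower.tail = FALSE), 0.01)
})

test_that("bundle flags operationalize the angle-distance box", {
  par_rec <- tibble(nn_distance = rep(12.5, 5), pair_angle = rep(0, 5))
  expect_equal(bundle_flags(par_rec)$fraction, 1)
  orth_rec <- tibble(nn_distance = rep(12.5, 5), pair_angle = rep(90, 5))
  expect_equal(bundle_flags(orth_rec)$fraction, 0)
  expect_error(bundle_flags(par_rec, dist_range = c(17, 8)), "increasing")
})

test_that("a constructed 70/30 bundled mixture is recovered within its CI", {
  set.seed(31)
  n_b <- 70; n_d <- 30
  rec <- tibble(
    nn_distance = c(rnorm(n_b, 12.5, 0.5), runif(n_d, 30, 90)),
    pair_angle = c(abs(rnorm(n_b, 0, 3)), runif(n_d, 20, 90))
  )
  fr <- bundle_flags(rec)$fraction
  ci <- stats::binom.test(n_b, n_b + n_d)$conf.int
  expect_gte(fr, ci[1])
  expect_lte(fr, ci[2])
})
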