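test_that("binarization thresholds two-level and bimodal images correctly", {
  img <- matrix(0, 20, 20)
  img[5:10, 5:15] <- 255
  b <- binarize(img)
  expect_equal(unname(b), unname(img == 255), ignore_attr = TRUE)

  set.seed(8)
  px <- c(rnorm(3000, 40, 8), rnorm(1000, 200, 12))
  img2 <- matrix(sample(px), 40, 100)
  b2 <- binarize(img2)
  thr <- attr(b2, "threshold")
  expect_gt(thr, 60)
  expect_lt(thr, 180)
  truth <- matrix(sample(px), 1)  # same values: misclassification on values
  mis <- mean((img2 > thr) != (img2 > 120))
  expect_lt(mis, 0.01)

  expect_error(binarize(matrix(5, 4, 4)), "constant")
})

test_that("a straight line skeleton measures n-1 steps and no junctions", {
  m <- matrix(FALSE, 5, 14)
  m[3, 3:12] <- TRUE
  st <- skeletonize_and_measure(m, pixel_size = 31.3)
  expect_equal(st$n_branches, 1)
  expect_equal(st$n_junctions, 0)
  expect_equal(st$total_length, 9 * 31.3)
})

test_that("a plus sign yields one junction and four branches", {
  m <- matrix(FALSE, 15, 15)
  m[8, 3:13] <- TRUE
  m[3:13, 8] <- TRUE
  st <- skeletonize_and_measure(m, pixel_size = 31.3)
  expect_equal(st$n_junctions, 1)
  expect_equal(st$n_branches, 4)
  expect_equal(st$total_length, 2 * 10 * 31.3)
})

test_that("the one-pixel filter removes isolated pixels", {
  m <- matrix(FALSE, 9, 9)
  m[5, 5] <- TRUE
  st <- skeletonize_and_measure(m, pixel_size = 31.3)
  expect_equal(st$total_length, 0)
  expect_equal(st$n_branches, 0)
  # isolated speckles alongside a real line disappear, the line stays
  m2 <- matrix(FALSE, 12, 20)
  m2[6, 3:17] <- TRUE
  m2[2, 2] <- TRUE
  m2[10, 18] <- TRUE
  st2 <- skeletonize_and_measure(m2, pixel_size = 1)
  expect_equal(st2$n_branches, 1)
  expect_equal(st2$total_length, 14)
})

test_that("skeleton metrics are invariant to rotation and mirroring", {
  g <- generate_meshwork(1200, 6, pixel_size = 1, seed = 5)
  bin <- binarize(g$image)
  s0 <- skeletonize_and_measure(bin, pixel_size = 1)
  for (tr in list(function(m) t(m)[ncol(m):1, ],         # 90 degree rotation
                  function(m) m[nrow(m):1, ],            # vertical mirror
                  function(m) m[, ncol(m):1])) {         # horizontal mirror
    st <- skeletonize_and_measure(tr(bin), pixel_size = 1)
    expect_equal(st$total_length, s0$total_length)
    expect_equal(st$n_junctions, s0$n_junctions)
  }
})

test_that("pixel size scales lengths linearly and leaves counts alone", {
  g <- generate_meshwork(900, 4, pixel_size = 1, seed = 3)
  bin <- binarize(g$image)
  s1 <- skeletonize_and_measure(bin, pixel_size = 10)
  s2 <- skeletonize_and_measure(bin, pixel_size = 30)
  expect_equal(s2$total_length, 3 * s1$total_length)
  expect_equal(s2$n_junctions, s1$n_junctions)
})

test_that("grid meshworks recover the m-by-n closed form", {
  for (mn in list(c(2, 3), c(3, 3), c(2, 5))) {
    S <- 80
    img <- matrix(FALSE, S, S)
    rows <- round(seq(15, S - 15, length.out = mn[1]))
    cols <- round(seq(12, S - 12, length.out = mn[2]))
    for (r in rows) img[r, ] <- TRUE
    for (cc in cols) img[, cc] <- TRUE
    st <- skeletonize_and_measure(img, pixel_size = 1)
    expect_equal(st$n_junctions, mn[1] * mn[2])
    analytic <- (mn[1] + mn[2]) * (S - 1)
    expect_lt(abs(st$total_length - analytic), mn[1] * mn[2] + 2)
  }
})

test_that("grayscale images read back with their calibration", {
  g <- generate_meshwork(1000, 4, seed = 9)
  tf <- withr::local_tempfile(fileext = ".png")
  png::writePNG(g$image$pixels / 255, tf)
  img <- read_meshwork_image(tf, pixel_size = 31.3)
  expect_s3_class(img, "meshwork_image")
  expect_equal(dim(img$pixels), dim(g$image$pixels))
  st_a <- skeletonize_and_measure(binarize(img), img$pixel_size)
  st_b <- skeletonize_and_measure(binarize(g$image), g$image$pixel_size)
  expect_equal(st_a$total_length, st_b$total_length)
  expect_identical(st_a$n_junctions, st_b$n_junctions)
  expect_error(read_meshwork_image("nope.png"), "no such file")
})

test_that("subsection reports aggregate with SEMs and flag empty images", {
  g <- generate_meshwork(1400, 6, seed = 10)
  imgs <- list(g$image, g$image, g$image, g$image)
  rep4 <- subsection_report(imgs, conditions = rep("basal", 4))
  expect_equal(nrow(rep4), 4)
  expect_equal(dplyr::n_distinct(rep4$total_length), 1)
  s <- attr(rep4, "summary")
  expect_equal(s$sem_length, 0)

  blank <- meshwork_image(matrix(10, 30, 30))
  rep5 <- subsection_report(c(imgs, list(blank)))
  expect_equal(nrow(rep5), 5)
  expect_true(rep5$empty[5])
  expect_equal(rep5$total_length[5], 0)
})

test_that("synthetic meshwork batches center on their generated scale", {
  set.seed(77)
  reports <- purrr::map(1:12, function(i) {
    g <- generate_meshwork(1400 + rnorm(1, 0, 100), 6, seed = 100 + i)
    st <- skeletonize_and_measure(binarize(g$image), g$image$pixel_size)
    tibble(measured = st$total_length, truth = g$truth$total_length)
  }) %>% bind_rows()
  expect_true(all(abs(reports$measured - reports$truth) / reports$truth < 0.05))
})
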