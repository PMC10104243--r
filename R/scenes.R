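#' Specify a synthetic cytoskeleton scene
#'
#' Parameters of the synthetic tomogram-equivalent scene: filament counts
#' and orientation mix, bundle geometry, anchored-architecture mode,
#' periphery geometry, and granule population. Defaults emulate a basal
#' beta-cell periphery: a predominantly PM-parallel network (3 percent
#' quasi-orthogonal), most filaments anchored, crossing anchored neighbors
#' ("netlike"), bundles at 12.5 nm lateral spacing, and a 200 nm-high
#' periphery between two membrane slabs. Granule radii (mean 150 nm,
#' sd 25 nm) are a plausible secretory-granule scale, not a measured
#' value.
#'
#' @param seed integer seed; mandatory. Every random stream (filaments,
#'   granules, microtubules, noise) derives its own sub-seed from it, so
#'   e.g. adding granules does not perturb the filament layout.
#' @param n_actin,n_mt filament counts.
#' @param quasi_orthogonal_fraction fraction of actin filaments with
#'   elevation at or above 45 degrees (exact count by rounding).
#' @param bundle_fraction fraction of the unanchored parallel filaments
#'   laid out in parallel bundles.
#' @param bundle_spacing,bundle_jitter_sd lateral bundle spacing and its
#'   jitter, nm.
#' @param architecture `"netlike"` (anchored neighbors cross at directed
#'   angles of 60-90 degrees), `"blooming"` (radial near-parallel
#'   projections, mutual angles below 30 degrees), or `"mixed"`.
#' @param anchored_fraction fraction of actin filaments anchored to the
#'   lower PM slab.
#' @param periphery_height center-to-center separation of the two PM
#'   slabs, nm.
#' @param n_isg,isg_radius_mean,isg_radius_sd granule count and radius
#'   distribution (nm).
#' @param extent scene box, nm. @param voxel_size mask voxel size, nm.
#' @return a `scene_spec` list.
#' @export
scene_spec <- function(seed,
                       n_actin = 120, n_mt = 8,
                       quasi_orthogonal_fraction = 0.03,
                       bundle_fraction = 0.7,
                       bundle_spacing = 12.5, bundle_jitter_sd = 0.5,
                       architecture = c("netlike", "blooming", "mixed"),
                       anchored_fraction = 0.9,
                       periphery_height = 200,
                       n_isg = 4, isg_radius_mean = 150, isg_radius_sd = 25,
                       extent = c(1000, 1000, 250), voxel_size = 2.5) {
  if (missing(seed) || !is.numeric(seed)) abort("seed is mandatory")
  architecture <- match.arg(architecture)
  fr <- c(quasi_orthogonal_fraction, bundle_fraction, anchored_fraction)
  if (any(fr < 0 | fr > 1)) abort("fractions must lie in [0, 1]")
  if (n_actin < 0 || n_mt < 0 || n_isg < 0) abort("counts must be >= 0")
  if (any(extent <= 0) || voxel_size <= 0) abort("extent and voxel_size must be positive")
  structure(list(
    seed = as.integer(seed), n_actin = as.integer(n_actin),
    n_mt = as.integer(n_mt),
    quasi_orthogonal_fraction = quasi_orthogonal_fraction,
    bundle_fraction = bundle_fraction,
    bundle_spacing = bundle_spacing, bundle_jitter_sd = bundle_jitter_sd,
    architecture = architecture, anchored_fraction = anchored_fraction,
    periphery_height = periphery_height,
    n_isg = as.integer(n_isg), isg_radius_mean = isg_radius_mean,
    isg_radius_sd = isg_radius_sd,
    extent = as.double(extent), voxel_size = voxel_size
  ), class = "scene_spec")
}

seed_for <- function(seed, component) {
  as.integer((as.double(seed) * 1009 + component * 9176) %% 2147483647)
}

sph_unit <- function(elev_deg, azim_deg) {
  c(cos(rad(elev_deg)) * cos(rad(azim_deg)),
    cos(rad(elev_deg)) * sin(rad(azim_deg)),
    sin(rad(elev_deg)))
}

elev_of <- function(v) deg(asin(pmin(abs(v[3]), 1)))

# unit vector at exactly `theta` degrees from u, rejection-sampled until
# it points upward and its elevation lies in [band1, band2]
vector_at_angle <- function(u, theta, band, min_z = 0.05, tries = 400) {
  for (i in seq_len(tries)) {
    r <- rnorm(3)
    w <- r - sum(r * u) * u
    nw <- sqrt(sum(w^2))
    if (nw < 1e-9) next
    w <- w / nw
    v <- cos(rad(theta)) * u + sin(rad(theta)) * w
    if (v[3] >= min_z && elev_of(v) >= band[1] && elev_of(v) <= band[2]) return(v)
  }
  NULL
}

elev_band <- function(class) if (class == "par") c(3, 43) else c(47, 85)

# longest step from p along v staying inside [lo, hi] per axis
max_reach <- function(p, v, lo, hi) {
  t <- Inf
  for (a in 1:3) {
    if (v[a] > 1e-12) t <- min(t, (hi[a] - p[a]) / v[a])
    if (v[a] < -1e-12) t <- min(t, (lo[a] - p[a]) / v[a])
  }
  max(t, 0)
}

#' Generate a synthetic scene with ground truth
#'
#' Deterministically (given the spec seed) lays out the scene described by
#' a [scene_spec()]: two parallel PM voxel slabs separated by the
#' periphery height, anchored filament clusters whose mutual directed
#' angles follow the architecture mode, parallel bundles at the requested
#' spacing, dispersed and reoriented filaments, gently curved
#' microtubules, and spherical granules rasterized into a labeled mask.
#'
#' @param spec a [scene_spec()].
#' @param scene_id identifier for the emitted scene.
#' @return list with `scene` (a [scene_bundle()]) and `truth` (per-filament
#'   true classes, architecture label, true height, granule table).
#' @export
generate_scene <- function(spec, scene_id = paste0("synthetic_", spec$seed)) {
  if (!inherits(spec, "scene_spec")) abort("spec must be a scene_spec")
  if (exists(".Random.seed", globalenv())) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  }
  ext <- spec$extent
  vs <- spec$voxel_size
  slab_t <- max(2 * vs, 5)
  zc_b <- 20
  zc_t <- zc_b + spec$periphery_height
  if (zc_t + slab_t / 2 + vs > ext[3]) {
    abort("periphery_height does not fit the extent along z")
  }
  # filaments live between the slabs; anchored ends reach the lower slab
  z_lo <- zc_b + slab_t / 2 + 2
  z_hi <- zc_t - slab_t / 2 - 65
  if (z_hi - z_lo < 40) abort("periphery too thin for filament placement")
  box_lo <- c(5, 5, z_lo)
  box_hi <- c(ext[1] - 5, ext[2] - 5, z_hi)

  n_qo <- round(spec$quasi_orthogonal_fraction * spec$n_actin)
  n_par <- spec$n_actin - n_qo
  n_anch <- round(spec$anchored_fraction * spec$n_actin)
  qo_anch <- min(n_qo, round(spec$quasi_orthogonal_fraction * n_anch))
  par_anch <- min(n_par, n_anch - qo_anch)
  qo_anch <- n_anch - par_anch
  if (qo_anch > n_qo) abort("infeasible class split for anchored filaments")

  csize <- if (spec$architecture == "blooming") 3L else 2L
  # clusters are class-homogeneous so orientation counts stay exact
  cluster_sizes <- function(n) if (n == 0) integer(0) else {
    s <- rep(csize, n %/% csize)
    if (n %% csize > 0) s <- c(s, n %% csize)
    s
  }
  clusters <- c(
    lapply(cluster_sizes(qo_anch), function(s) list(class = "qo", size = s)),
    lapply(cluster_sizes(par_anch), function(s) list(class = "par", size = s))
  )
  n_clusters <- length(clusters)

  usable <- (ext[1] - 160) * (ext[2] - 160)
  if (n_clusters > 0 && n_clusters * 60 * 60 > usable) {
    abort(sprintf(
      "infeasible packing: %d anchor clusters will not fit a %.0f x %.0f nm face",
      n_clusters, ext[1], ext[2]))
  }

  set.seed(seed_for(spec$seed, 1))
  # anchor sites: soft Poisson-disk (best effort, 40 tries per site)
  sites <- matrix(0, n_clusters, 2)
  if (n_clusters > 0) {
    for (ci in seq_len(n_clusters)) {
      cand <- c(runif(1, 80, ext[1] - 80), runif(1, 80, ext[2] - 80))
      if (ci > 1) {
        for (t in seq_len(40)) {
          d <- sqrt(rowSums(sweep(sites[seq_len(ci - 1), , drop = FALSE], 2, cand)^2))
          if (min(d) >= 120) break
          cand <- c(runif(1, 80, ext[1] - 80), runif(1, 80, ext[2] - 80))
        }
      }
      sites[ci, ] <- cand
    }
  }

  node_xyz <- list()
  node_id <- character(0)
  node_kind <- character(0)
  node_n <- integer(0)
  truth_rows <- list()
  fid <- 0
  add_filament <- function(p0, v, class, true_class, cluster_id = NA_integer_,
                           length_draw = NULL) {
    fid <<- fid + 1
    id <- sprintf("actin_%04d", fid)
    reach <- max_reach(p0, v, box_lo, box_hi)
    L <- length_draw %||% runif(1, 120, 600)
    L <- min(L, reach * 0.98)
    L <- max(L, min(40, reach * 0.9))
    if (L < 10) L <- 10
    p1 <- p0 + L * v
    mid <- (p0 + p1) / 2 + rnorm(3, 0, 0.5) * c(1, 1, 0)
    node_xyz[[length(node_xyz) + 1]] <<- rbind(p0, mid, p1)
    node_id <<- c(node_id, id)
    node_kind <<- c(node_kind, "actin")
    node_n <<- c(node_n, 3L)
    truth_rows[[length(truth_rows) + 1]] <<- list(
      filament_id = id, true_class = true_class,
      orientation_true = if (class == "qo") "quasi_orthogonal" else "parallel",
      reoriented_true = class == "qo",
      anchored_true = true_class == "anchored",
      bundled_true = true_class == "bundled",
      cluster_id = cluster_id
    )
    id
  }

  # --- anchored clusters ---------------------------------------------------
  if (n_anch > 0) {
    for (cl in seq_len(n_clusters)) {
      cls <- clusters[[cl]]$class
      members <- seq_len(clusters[[cl]]$size)
      band <- elev_band(cls)
      mode <- spec$architecture
      if (mode == "mixed") mode <- if (cl %% 2 == 1) "netlike" else "blooming"
      base_elev <- if (cls == "par") {
        if (mode == "blooming") runif(1, 5, 35) else runif(1, 5, 40)
      } else {
        if (mode == "netlike") runif(1, 47, 58) else runif(1, 50, 80)
      }
      u <- sph_unit(base_elev, runif(1, 0, 360))
      dirs <- list(u)
      for (m in seq_along(members)[-1]) {
        if (mode == "netlike") {
          cap <- if (cls == "qo") max(2 * (90 - base_elev) - 2, 61) else 88
          theta <- runif(1, 60, max(cap, 61))
        } else {
          theta <- runif(1, 3, 13)
        }
        v <- vector_at_angle(u, theta, band)
        if (is.null(v)) {
          # degenerate cone/band intersection: fall back to an independent
          # in-band direction (breaks the mutual-angle control for this one)
          v <- sph_unit(runif(1, band[1], band[2]), runif(1, 0, 360))
        }
        dirs[[m]] <- v
      }
      for (m in seq_along(members)) {
        off <- runif(1, 0, 30)
        ang <- runif(1, 0, 2 * pi)
        p0 <- c(
          min(max(sites[cl, 1] + off * cos(ang), box_lo[1]), box_hi[1]),
          min(max(sites[cl, 2] + off * sin(ang), box_lo[2]), box_hi[2]),
          zc_b + slab_t / 2 + runif(1, 2, 45)
        )
        add_filament(p0, dirs[[m]], cls, "anchored", cluster_id = cl)
      }
    }
  }

  # --- unanchored filaments ------------------------------------------------
  qo_free <- n_qo - qo_anch
  par_free <- n_par - par_anch
  n_bund <- round(spec$bundle_fraction * par_free)
  n_disp <- par_free - n_bund
  free_lo <- c(box_lo[1], box_lo[2], zc_b + slab_t / 2 + 65)
  free_hi <- box_hi
  if (free_hi[3] - free_lo[3] < 20) {
    free_lo[3] <- box_lo[3] + (box_hi[3] - box_lo[3]) * 0.6
  }
  runif_box <- function(lo, hi) c(runif(1, lo[1], hi[1]), runif(1, lo[2], hi[2]),
                                  runif(1, lo[3], hi[3]))
  # bundles: groups of up to 5 parallel filaments offset laterally
  remaining <- n_bund
  bundle_id <- 0
  while (remaining > 0) {
    bundle_id <- bundle_id + 1
    k <- min(5L, remaining)
    v <- sph_unit(runif(1, 2, 20), runif(1, 0, 360))
    h <- c(-v[2], v[1], 0)
    h <- h / sqrt(sum(h^2))
    base <- runif_box(free_lo + c(60, 60, 5), free_hi - c(60, 60, 5))
    reach_f <- max_reach(base, v, free_lo, free_hi)
    reach_b <- max_reach(base, -v, free_lo, free_hi)
    L <- min(runif(1, 200, 600), (reach_f + reach_b) * 0.9)
    start <- base - v * min(L / 2, reach_b * 0.95)
    for (m in seq_len(k)) {
      offset <- (m - 1) * spec$bundle_spacing + rnorm(1, 0, spec$bundle_jitter_sd)
      p0 <- start + offset * h
      for (a in 1:2) p0[a] <- min(max(p0[a], free_lo[a]), free_hi[a])
      add_filament(p0, v, "par", "bundled", length_draw = L)
    }
    remaining <- remaining - k
  }
  for (i in seq_len(n_disp)) {
    v <- sph_unit(runif(1, 3, 40), runif(1, 0, 360))
    if (runif(1) < 0.5) v <- -v * c(1, 1, -1)  # vary azimuth sense, keep z >= 0
    add_filament(runif_box(free_lo, free_hi), v, "par", "dispersed")
  }
  for (i in seq_len(qo_free)) {
    v <- sph_unit(runif(1, 47, 85), runif(1, 0, 360))
    p0 <- runif_box(free_lo, c(free_hi[1], free_hi[2],
                               free_lo[3] + (free_hi[3] - free_lo[3]) * 0.3))
    add_filament(p0, v, "qo", "reoriented")
  }

  # --- microtubules --------------------------------------------------------
  set.seed(seed_for(spec$seed, 4))
  for (i in seq_len(spec$n_mt)) {
    id <- sprintf("mt_%04d", i)
    p <- runif_box(free_lo, free_hi)
    azim <- runif(1, 0, 360)
    elev <- runif(1, 0, 8)
    pts <- list(p)
    n_steps <- sample(8:20, 1)
    for (s in seq_len(n_steps)) {
      azim <- azim + rnorm(1, 0, 3)
      v <- sph_unit(elev, azim)
      if (max_reach(p, v, free_lo, free_hi) < 50) break
      p <- p + 50 * v
      pts[[length(pts) + 1]] <- p
    }
    if (length(pts) < 2) next
    m <- do.call(rbind, pts)
    node_xyz[[length(node_xyz) + 1]] <- m
    node_id <- c(node_id, id)
    node_kind <- c(node_kind, "mt")
    node_n <- c(node_n, nrow(m))
  }

  # --- masks ---------------------------------------------------------------
  dims <- pmax(round(ext / vs), 1)
  zc <- (seq_len(dims[3]) - 0.5) * vs
  pm_grid <- array(0L, dim = dims)
  in_slab <- function(zc, center) abs(zc - center) <= slab_t / 2
  pm_grid[, , which(in_slab(zc, zc_b))] <- 1L
  pm_grid[, , which(in_slab(zc, zc_t))] <- 1L
  masks <- list(pm = volume_mask(pm_grid, vs, role = "pm"))

  set.seed(seed_for(spec$seed, 2))
  granules <- tibble(granule_id = integer(), cx = double(), cy = double(),
                     cz = double(), radius = double())
  if (spec$n_isg > 0) {
    isg_grid <- array(0L, dim = dims)
    centers <- matrix(0, 0, 3)
    radii <- numeric(0)
    guard <- 0
    while (nrow(centers) < spec$n_isg && guard < 400 * spec$n_isg) {
      guard <- guard + 1
      rr <- min(max(rnorm(1, spec$isg_radius_mean, spec$isg_radius_sd), 60), 250)
      cc <- c(runif(1, 80, ext[1] - 80), runif(1, 80, ext[2] - 80),
              runif(1, z_lo + 10, zc_t - slab_t / 2 - 10))
      if (nrow(centers) > 0) {
        d <- sqrt(rowSums(sweep(centers, 2, cc)^2))
        if (any(d < radii + rr + 10)) next
      }
      centers <- rbind(centers, cc)
      radii <- c(radii, rr)
    }
    for (gi in seq_len(nrow(centers))) {
      cc <- centers[gi, ]; rr <- radii[gi]
      rng <- lapply(1:3, function(a) {
        lo <- max(floor((cc[a] - rr) / vs), 0)
        hi <- min(ceiling((cc[a] + rr) / vs), dims[a] - 1)
        if (lo > hi) integer(0) else lo:hi
      })
      if (any(lengths(rng) == 0)) next
      cx <- (rng[[1]] + 0.5) * vs - cc[1]
      cy <- (rng[[2]] + 0.5) * vs - cc[2]
      cz2 <- (rng[[3]] + 0.5) * vs - cc[3]
      d2 <- outer(outer(cx^2, cy^2, "+"), cz2^2, "+")
      sel <- which(d2 <= rr^2, arr.ind = TRUE)
      if (nrow(sel) > 0) {
        lin <- cbind(rng[[1]][sel[, 1]] + 1, rng[[2]][sel[, 2]] + 1,
                     rng[[3]][sel[, 3]] + 1)
        isg_grid[lin] <- gi
      }
    }
    granules <- tibble(granule_id = seq_len(nrow(centers)),
                       cx = centers[, 1], cy = centers[, 2], cz = centers[, 3],
                       radius = radii)
    if (any(isg_grid != 0L)) {
      masks$isg <- volume_mask(isg_grid, vs, role = "isg")
    }
  }

  xyz <- do.call(rbind, node_xyz)
  fil <- filaments(tibble(
    filament_id = rep(node_id, times = node_n),
    kind = rep(node_kind, times = node_n),
    node_index = unlist(lapply(node_n, seq_len)),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]
  ))
  scene <- scene_bundle(fil, masks, condition = "synthetic",
                        scene_id = scene_id, extent = ext)
  truth_tbl <- if (length(truth_rows) > 0) {
    bind_rows(lapply(truth_rows, as_tibble))
  } else tibble()
  list(
    scene = scene,
    truth = list(
      filaments = truth_tbl,
      architecture = spec$architecture,
      height = spec$periphery_height,
      granules = granules,
      spec = spec
    )
  )
}

#' Generate a synthetic 2D meshwork image with known skeleton metrics
#'
#' Draws a grid-like planar line network (full-span horizontal and
#' vertical lines at random, well-separated positions) whose exact
#' skeleton length and junction count follow from the generating segments:
#' m horizontal and n vertical lines give m*n junctions and
#' `(m*(W-1) + n*(H-1)) * pixel_size` nm of skeleton. Lines are rendered
#' 3 pixels wide with optional additive Gaussian noise.
#'
#' @param length_target target total skeleton length, nm.
#' @param junction_target target junction count (the generator factors it
#'   into a lines grid; the achieved exact values are in the ground
#'   truth).
#' @param pixel_size nm per pixel.
#' @param seed integer seed.
#' @param noise_sd additive Gaussian noise sd (grayscale units, image in
#'   0-255); 0 for a noiseless render.
#' @return list with `image` (a [meshwork_image()]) and `truth`
#'   (`total_length` nm, `n_junctions`, `n_horizontal`, `n_vertical`).
#' @export
generate_meshwork <- function(length_target, junction_target, pixel_size = 31.3,
                              seed = 1, noise_sd = 0) {
  if (length_target <= 0 || junction_target <= 0) abort("targets must be positive")
  divs <- which(junction_target %% seq_len(floor(sqrt(junction_target))) == 0)
  m <- max(divs)                       # rows of the junction grid
  n <- junction_target / m             # columns
  L_px <- length_target / pixel_size
  S <- round(L_px / (m + n)) + 1
  S <- max(S, 8 * (max(m, n) + 1))
  if (S > 4096) abort("length target infeasible for a renderable image")
  set.seed(seed_for(seed, 3))
  sep_positions <- function(k, S) {
    # k distinct positions with >= 6 px separation, 4 px margins
    stopifnot(k * 6 + 8 < S)
    p <- sort(sample(seq(5, S - 4), k))
    while (k > 1 && min(diff(p)) < 6) p <- sort(sample(seq(5, S - 4), k))
    p
  }
  rows <- sep_positions(m, S)
  cols <- sep_positions(n, S)
  img <- matrix(30, S, S)
  # 3 px body with 1 px tapered tips (blunt wide ends erode under thinning)
  for (r in rows) {
    img[(r - 1):(r + 1), 3:(S - 2)] <- 220
    img[r, c(1, 2, S - 1, S)] <- 220
  }
  for (cc in cols) {
    img[3:(S - 2), (cc - 1):(cc + 1)] <- 220
    img[c(1, 2, S - 1, S), cc] <- 220
  }
  if (noise_sd > 0) img <- img + matrix(rnorm(S * S, 0, noise_sd), S, S)
  truth <- list(
    total_length = (m * (S - 1) + n * (S - 1)) * pixel_size,
    n_junctions = as.integer(m * n),
    n_horizontal = as.integer(m), n_vertical = as.integer(n),
    image_size = as.integer(S)
  )
  list(image = meshwork_image(img, pixel_size = pixel_size), truth = truth)
}

#' Write a scene to a directory
#'
#' Emits the same formats [read_scene()] (and the segmentation readers)
#' consume: `filaments.tsv`, one MRC per mask (`pm.mrc`, `isg.mrc`), and a
#' `scene.yaml` with condition, extent, and scene id.
#'
#' @param scene a [scene_bundle()].
#' @param dir output directory (created if needed).
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_records(record_table(scene$filaments, "filament_nodes",
                             list(scene_id = scene$scene_id)),
                file.path(dir, "filaments.tsv"))
  for (role in names(scene$masks)) {
    write_mask(scene$masks[[role]], file.path(dir, paste0(role, ".mrc")))
  }
  yaml::write_yaml(list(
    scene_id = scene$scene_id, condition = scene$condition,
    extent = as.list(scene$extent),
    masks = as.list(names(scene$masks))
  ), file.path(dir, "scene.yaml"))
  invisible(dir)
}

#' Read a scene directory written by [write_scene()]
#'
#' @param dir scene directory.
#' @return a [scene_bundle()].
#' @export
read_scene <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "scene.yaml"))
  fil <- read_filaments(file.path(dir, "filaments.tsv"))
  masks <- list()
  for (role in unlist(meta$masks)) {
    p <- file.path(dir, paste0(role, ".mrc"))
    if (file.exists(p)) {
      masks[[role]] <- suppressMessages(read_mask(p, role = role))
    }
  }
  scene_bundle(fil, masks, condition = meta$condition,
               scene_id = meta$scene_id, extent = unlist(meta$extent))
}
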