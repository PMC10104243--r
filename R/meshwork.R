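#' Construct a 2D meshwork image
#'
#' Grayscale fluorescence subsection with its physical pixel size
#' (default 31.3 nm, the SIM lateral resolution) and, as metadata, the
#' subsection area in square micrometres.
#'
#' @param pixels numeric matrix of grayscale values.
#' @param pixel_size nm per pixel.
#' @param subsection_area subsection area in um^2 (metadata only).
#' @return object of class `meshwork_image`.
#' @export
meshwork_image <- function(pixels, pixel_size = 31.3, subsection_area = 0.97) {
  if (!is.matrix(pixels) || length(pixels) == 0) abort("pixels must be a nonempty matrix")
  if (pixel_size <= 0) abort("pixel_size must be > 0 (nm)")
  structure(list(pixels = pixels, pixel_size = pixel_size,
                 subsection_area = subsection_area),
            class = "meshwork_image")
}

#' Read a grayscale image as a meshwork image
#'
#' Reads TIFF or PNG (by extension). Multi-channel images are averaged to
#' grayscale.
#'
#' @param path image path.
#' @inheritParams meshwork_image
#' @export
read_meshwork_image <- function(path, pixel_size = 31.3, subsection_area = 0.97) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    "tif" = , "tiff" = tiff::readTIFF(path),
    "png" = png::readPNG(path),
    abort(paste0("unsupported image format: .", ext))
  )
  if (length(dim(arr)) == 3) arr <- apply(arr, c(1, 2), mean)
  meshwork_image(arr, pixel_size = pixel_size, subsection_area = subsection_area)
}

#' Binarize a meshwork image
#'
#' The default method is the IsoData (iterative intermeans) algorithm --
#' the "Default" auto-threshold of common image-analysis tools: starting
#' from the mid-range, the threshold is updated to the mean of the
#' below-threshold and above-threshold class means until it stabilizes.
#' Foreground is everything strictly above the threshold.
#'
#' @param image a [meshwork_image()] or a numeric matrix.
#' @param method `"isodata"` (default) or `"otsu"`.
#' @return logical matrix with attribute `"threshold"`.
#' @export
binarize <- function(image, method = c("isodata", "otsu")) {
  method <- match.arg(method)
  px <- if (inherits(image, "meshwork_image")) image$pixels else image
  if (!all(is.finite(px))) abort("image contains non-finite values")
  if (diff(range(px)) == 0) abort("constant image: no threshold exists")
  thr <- switch(method, isodata = isodata_threshold(px), otsu = otsu_threshold(px))
  out <- px > thr
  attr(out, "threshold") <- thr
  out
}

isodata_threshold <- function(px, max_iter = 200) {
  t <- mean(range(px))
  for (i in seq_len(max_iter)) {
    lo <- px[px <= t]
    hi <- px[px > t]
    if (length(lo) == 0 || length(hi) == 0) break
    t_new <- (mean(lo) + mean(hi)) / 2
    if (abs(t_new - t) < 1e-9 * diff(range(px))) {
      t <- t_new
      break
    }
    t <- t_new
  }
  t
}

otsu_threshold <- function(px, n_bins = 256) {
  breaks <- seq(min(px), max(px), length.out = n_bins + 1)
  h <- tabulate(findInterval(px, breaks, rightmost.closed = TRUE), nbins = n_bins)
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  w <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  between <- (mu_t * w - mu)^2 / (w * (1 - w))
  between[!is.finite(between)] <- 0
  mids[which.max(between)]
}

#' Skeletonize a binary meshwork and measure its graph
#'
#' Thins the foreground to a 1-pixel skeleton, decomposes it into branches
#' running between endpoints and junctions, and measures branch lengths as
#' inter-pixel steps (1 pixel for orthogonal moves, sqrt(2) for diagonal),
#' scaled by the pixel size. Junctions are clusters of skeleton pixels
#' with at least three 8-connected skeleton neighbors; adjacent junction
#' pixels are merged into one junction. Branches whose length does not
#' exceed `min_branch_px` pixels (after including their attachment steps to
#' junctions) are discarded, which removes isolated-pixel artifacts under
#' the default filter of one pixel.
#'
#' @param binary logical matrix (or output of [binarize()]).
#' @param pixel_size nm per pixel.
#' @param min_branch_px branch-length filter in pixels; branches with
#'   length <= this are dropped.
#' @return object of class `skeleton_stats`: `total_length` (nm),
#'   `n_junctions`, `n_branches`, `branch_lengths` (nm), and the skeleton
#'   matrix.
#' @export
skeletonize_and_measure <- function(binary, pixel_size = 31.3, min_branch_px = 1) {
  if (!is.matrix(binary)) abort("binary must be a matrix")
  bin <- binary
  storage.mode(bin) <- "logical"
  empty <- structure(list(total_length = 0, n_junctions = 0L, n_branches = 0L,
                          branch_lengths = numeric(0), junction_length = 0,
                          skeleton = matrix(FALSE, nrow(bin), ncol(bin)),
                          pixel_size = pixel_size),
                     class = "skeleton_stats")
  if (!any(bin)) return(empty)
  skel <- cpp_thin2d(bin)
  if (!any(skel)) return(empty)
  nb <- neighbor_count8(skel)
  junction_px <- skel & nb >= 3
  jl <- label2d8(junction_px)
  branch_px <- skel & !junction_px
  bl <- label2d8(branch_px)
  n_br <- max(bl, 0)
  lengths_px <- numeric(n_br)
  coords <- which(branch_px, arr.ind = TRUE)
  labs <- bl[branch_px]
  for (b in seq_len(n_br)) {
    pix <- coords[labs == b, , drop = FALSE]
    lengths_px[b] <- branch_path_length(pix) + junction_attachment(pix, junction_px, jl)
  }
  keep <- lengths_px > min_branch_px
  n_junc <- max(jl, 0)
  # multi-pixel junction clusters contribute their internal spanning steps
  jcoords <- which(junction_px, arr.ind = TRUE)
  jlabs <- jl[junction_px]
  junction_span <- 0
  for (jcl in seq_len(n_junc)) {
    jp <- jcoords[jlabs == jcl, , drop = FALSE]
    if (nrow(jp) > 1) junction_span <- junction_span + cluster_mst_length(jp)
  }
  structure(list(
    total_length = (sum(lengths_px[keep]) + junction_span) * pixel_size,
    n_junctions = as.integer(n_junc),
    n_branches = as.integer(sum(keep)),
    branch_lengths = lengths_px[keep] * pixel_size,
    junction_length = junction_span * pixel_size,
    skeleton = skel, pixel_size = pixel_size
  ), class = "skeleton_stats")
}

#' @export
print.skeleton_stats <- function(x, ...) {
  cat(sprintf("<skeleton_stats: total length %.1f nm, %d junction(s), %d branch(es)>\n",
              x$total_length, x$n_junctions, x$n_branches))
  invisible(x)
}

# 8-neighbor counts of a logical matrix
neighbor_count8 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(0L, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- m
  out <- matrix(0L, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    out <- out + pad[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
  }
  out
}

# 8-connected labeling of a 2D logical matrix via the 3D labeler
label2d8 <- function(m) {
  lab <- cpp_label3d(as.vector(m), c(nrow(m), ncol(m), 1L))
  matrix(as.integer(lab), nrow(m), ncol(m))
}

# walk a 1-px-wide branch component, summing step weights
branch_path_length <- function(pix) {
  n <- nrow(pix)
  if (n <= 1) return(0)
  key <- paste(pix[, 1], pix[, 2])
  index <- setNames(seq_len(n), key)
  adj <- function(i) {
    r <- pix[i, 1]; c <- pix[i, 2]
    hits <- integer(0)
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      j <- index[paste(r + dr, c + dc)]
      if (!is.na(j)) hits <- c(hits, j)
    }
    hits
  }
  degs <- vapply(seq_len(n), function(i) length(adj(i)), integer(1))
  start <- which(degs <= 1)[1]
  if (is.na(start)) start <- 1L  # cycle: start anywhere
  visited <- rep(FALSE, n)
  total <- 0
  cur <- start
  visited[cur] <- TRUE
  repeat {
    nxt <- adj(cur)
    nxt <- nxt[!visited[nxt]]
    if (length(nxt) == 0) break
    # prefer orthogonal over diagonal steps to follow the path faithfully
    w <- sqrt((pix[nxt, 1] - pix[cur, 1])^2 + (pix[nxt, 2] - pix[cur, 2])^2)
    pick <- nxt[which.min(w)]
    total <- total + min(w)
    visited[pick] <- TRUE
    cur <- pick
  }
  # close a cycle if the walk returned next to its start
  if (all(visited) && sum(degs <= 1) == 0 && n > 2) {
    d <- sqrt(sum((pix[cur, ] - pix[start, ])^2))
    if (d < 1.5) total <- total + d
  }
  total
}

# minimum spanning length over a (small) junction pixel cluster, 8-adjacency
cluster_mst_length <- function(pix) {
  n <- nrow(pix)
  in_tree <- c(TRUE, rep(FALSE, n - 1))
  dist_to <- sqrt((pix[, 1] - pix[1, 1])^2 + (pix[, 2] - pix[1, 2])^2)
  total <- 0
  for (step in seq_len(n - 1)) {
    cand <- which(!in_tree)
    pick <- cand[which.min(dist_to[cand])]
    total <- total + dist_to[pick]
    in_tree[pick] <- TRUE
    d_new <- sqrt((pix[, 1] - pix[pick, 1])^2 + (pix[, 2] - pix[pick, 2])^2)
    dist_to <- pmin(dist_to, d_new)
  }
  total
}

# steps connecting a branch's terminal pixels to adjacent junction clusters
junction_attachment <- function(pix, junction_px, jl) {
  n <- nrow(pix)
  total <- 0
  nr <- nrow(junction_px); nc <- ncol(junction_px)
  for (i in seq_len(n)) {
    r <- pix[i, 1]; c <- pix[i, 2]
    best <- list()
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; cc <- c + dc
      if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
      if (junction_px[rr, cc]) {
        cl <- as.character(jl[rr, cc])
        w <- sqrt(dr^2 + dc^2)
        if (is.null(best[[cl]]) || w < best[[cl]]) best[[cl]] <- w
      }
    }
    total <- total + sum(unlist(best))
  }
  total
}

#' Measure a batch of meshwork subsections
#'
#' Thresholds, skeletonizes, and measures each subsection image, returning
#' one row per subsection plus per-condition summaries (mean and standard
#' error of the mean) as attribute `"summary"`. Empty images yield
#' zero-measure rows flagged in `empty`.
#'
#' @param images list of [meshwork_image()] objects.
#' @param conditions optional character vector of condition labels.
#' @param min_branch_px branch filter, see [skeletonize_and_measure()].
#' @return record tibble: `subsection`, `condition`, `total_length` (nm),
#'   `n_junctions`, `n_branches`, `empty`.
#' @export
subsection_report <- function(images, conditions = NULL, min_branch_px = 1) {
  if (length(images) == 0) abort("need at least one image")
  conditions <- conditions %||% rep(NA_character_, length(images))
  rows <- imap(images, function(img, i) {
    stats <- tryCatch({
      bin <- binarize(img)
      skeletonize_and_measure(bin, pixel_size = img$pixel_size,
                              min_branch_px = min_branch_px)
    }, error = function(e) NULL)
    if (is.null(stats)) {
      tibble(subsection = as.integer(i), condition = conditions[[i]],
             total_length = 0, n_junctions = 0L, n_branches = 0L, empty = TRUE)
    } else {
      tibble(subsection = as.integer(i), condition = conditions[[i]],
             total_length = stats$total_length,
             n_junctions = stats$n_junctions,
             n_branches = stats$n_branches,
             empty = stats$n_branches == 0L)
    }
  })
  out <- bind_rows(rows)
  summ <- out %>%
    group_by(.data$condition) %>%
    summarise(
      n = n(),
      mean_length = mean(.data$total_length),
      sem_length = sd(.data$total_length) / sqrt(n()),
      mean_junctions = mean(.data$n_junctions),
      sem_junctions = sd(.data$n_junctions) / sqrt(n()),
      .groups = "drop"
    )
  res <- record_table(out, "meshwork_subsections",
                      list(min_branch_px = min_branch_px))
  attr(res, "summary") <- summ
  res
}
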