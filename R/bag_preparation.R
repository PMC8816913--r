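#' Tissue mask by colour thresholding
#'
#' Marks a pixel as tissue when its luminance (0.299 R + 0.587 G + 0.114 B)
#' falls below `threshold`: stained tissue is darker than the bright slide
#' background. `threshold = 1` accepts every pixel (loosening the threshold
#' never shrinks the mask).
#'
#' @param image height x width x 3 array in `[0, 1]` (a height x width
#'   matrix is treated as grayscale).
#' @param threshold Luminance cut-off in `[0, 1]` (default 0.8).
#' @return Logical height x width matrix.
#' @export
tissue_mask <- function(image, threshold = 0.8) {
  if (length(image) == 0) stop("empty image")
  lum <- if (length(dim(image)) == 3)
    0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
  else as.matrix(image)
  lum < threshold
}

#' Tile an image into non-overlapping square patches over tissue
#'
#' Row-major grid of `patch_size` squares anchored at the top-left corner
#' (0-based origins, half-open intervals); incomplete border tiles are
#' dropped. A patch is kept when its tissue-mask coverage is at least
#' `coverage_min`.
#'
#' @param mask Logical tissue mask (height x width).
#' @param patch_size Patch side length in pixels (<= both image dimensions).
#' @param coverage_min Minimum mask coverage in `[0, 1]` (default 0.5).
#' @return Data frame of patches: `x`, `y` (0-based origin), `size`,
#'   `coverage`, `cluster` (NA until clustered).
#' @export
grid_patches <- function(mask, patch_size, coverage_min = 0.5) {
  h <- nrow(mask); w <- ncol(mask)
  if (patch_size > h || patch_size > w)
    stop("patch_size exceeds the image dimensions")
  ys <- seq(0L, h - patch_size, by = patch_size)
  xs <- seq(0L, w - patch_size, by = patch_size)
  out <- do.call(rbind, lapply(ys, function(y) do.call(rbind, lapply(xs, function(x) {
    cov <- mean(mask[(y + 1):(y + patch_size), (x + 1):(x + patch_size)])
    data.frame(x = x, y = y, size = patch_size, coverage = cov)
  }))))
  out <- out[out$coverage >= coverage_min, , drop = FALSE]
  rownames(out) <- NULL
  out$cluster <- rep(NA_integer_, nrow(out))
  out
}

patch_pixels <- function(image, patch) {
  rows <- (patch$y + 1):(patch$y + patch$size)
  cols <- (patch$x + 1):(patch$x + patch$size)
  if (length(dim(image)) == 3) image[rows, cols, , drop = FALSE]
  else image[rows, cols, drop = FALSE]
}

#' Per-patch clustering features: mean colour plus intensity histogram
#'
#' @param image Source image.
#' @param patches Data frame from [grid_patches()].
#' @param n_bins Number of luminance histogram bins (default 8).
#' @return Numeric matrix, one row per patch.
#' @export
patch_cluster_features <- function(image, patches, n_bins = 8L) {
  t(vapply(seq_len(nrow(patches)), function(i) {
    px <- patch_pixels(image, patches[i, ])
    if (length(dim(px)) == 3) {
      means <- apply(px, 3, mean)
      lum <- 0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
    } else {
      means <- rep(mean(px), 3)
      lum <- px
    }
    hist <- tabulate(pmin(floor(lum * n_bins) + 1L, n_bins), n_bins) / length(lum)
    c(means, hist)
  }, numeric(3 + n_bins)))
}

#' Cluster tissue patches into a preset number of groups
#'
#' k-means on the patch features, deterministic under the seed. When there
#' are fewer patches than requested clusters, the cluster count is reduced
#' to the patch count with a warning.
#'
#' @param features Numeric matrix (rows = patches).
#' @param n_clusters Requested number of clusters.
#' @param seed Integer seed.
#' @return Integer cluster labels (one of `1:n_clusters` per patch).
#' @export
cluster_patches <- function(features, n_clusters, seed = 1L) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (n_clusters < 1) stop("need at least one cluster")
  if (n < n_clusters) {
    warning(sprintf("only %d patches; reducing clusters from %d", n, n_clusters))
    n_clusters <- n
  }
  if (n_clusters == 1) return(rep(1L, n))
  if (n_clusters == n) return(seq_len(n))   # every patch its own cluster
  # jitter breaks exact duplicates, which kmeans rejects as centres
  with_seed(seed, {
    km <- stats::kmeans(features + matrix(stats::rnorm(length(features), sd = 1e-9),
                                          nrow(features)),
                        centers = n_clusters, nstart = 10, iter.max = 100)
    as.integer(km$cluster)
  })
}

#' Sample a mosaic: a fixed portion of every cluster
#'
#' From each cluster, `ceiling(fraction * cluster size)` patches are drawn
#' without replacement (ceiling, so no non-empty cluster is dropped). The
#' mosaic is returned ordered by cluster and original patch index, which
#' makes repeated runs with one seed identical.
#'
#' @param patches Data frame with a filled `cluster` column.
#' @param fraction Selection fraction in (0, 1] (default 0.10).
#' @param seed Integer seed.
#' @return The sampled subset of `patches`.
#' @export
select_mosaic <- function(patches, fraction = 0.10, seed = 1L) {
  if (fraction <= 0 || fraction > 1) stop("fraction must lie in (0, 1]")
  if (any(is.na(patches$cluster))) stop("patches must be clustered first")
  keep <- integer(0)
  for (cl in sort(unique(patches$cluster))) {
    idx <- which(patches$cluster == cl)
    k <- ceiling(fraction * length(idx))
    sel <- with_seed(substream_seed(seed, paste0("cluster-", cl)),
                     sample.int(length(idx), k))
    keep <- c(keep, sort(idx[sel]))
  }
  out <- patches[keep[order(patches$cluster[keep], keep)], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Deterministic stand-in patch feature extractor
#'
#' Returns an extractor function mapping a patch's pixels to a
#' `feature_dim`-dimensional vector: per-channel intensity histograms plus
#' channel means and standard deviations, passed through a fixed-seed random
#' projection. It is a deterministic, architecture-free drop-in for the
#' pluggable extractor slot (a pre-trained network in the real pipeline).
#'
#' @param feature_dim Output dimension f.
#' @param n_bins Histogram bins per channel (default 16).
#' @param seed Seed of the fixed projection.
#' @return Function `(pixels) -> numeric(feature_dim)`.
#' @export
default_patch_extractor <- function(feature_dim = 16L, n_bins = 16L, seed = 1L) {
  in_dim <- 3L * n_bins + 6L
  proj <- with_seed(seed,
    matrix(stats::rnorm(in_dim * feature_dim, sd = 1 / sqrt(in_dim)),
           in_dim, feature_dim))
  function(px) {
    if (length(dim(px)) != 3) px <- array(rep(px, 3), c(dim(px), 3))
    hists <- unlist(lapply(1:3, function(ch) {
      v <- px[, , ch]
      tabulate(pmin(floor(v * n_bins) + 1L, n_bins), n_bins) / length(v)
    }))
    moments <- c(apply(px, 3, mean), apply(px, 3, stats::sd))
    drop(c(hists, moments) %*% proj)
  }
}

#' Extract a feature bag from a mosaic
#'
#' One feature vector per mosaic patch, in mosaic order.
#'
#' @param image Source image.
#' @param mosaic Data frame of selected patches.
#' @param extractor Feature extractor function (see
#'   [default_patch_extractor()]).
#' @param label Optional bag label.
#' @param bag_id Bag identifier.
#' @return A `feature_bag`.
#' @export
extract_features <- function(image, mosaic, extractor = default_patch_extractor(),
                             label = NA, bag_id = "bag") {
  if (is.null(mosaic) || nrow(mosaic) == 0)
    stop("cannot extract features from an empty mosaic")
  x <- t(vapply(seq_len(nrow(mosaic)),
                function(i) extractor(patch_pixels(image, mosaic[i, ])),
                numeric(length(extractor(patch_pixels(image, mosaic[1, ]))))))
  feature_bag(x, label = label, bag_id = bag_id)
}

#' Full mosaic bag-preparation pipeline for one image
#'
#' Threshold, tile, cluster, sample a mosaic, extract features: image to
#' `feature_bag` in one call, bit-reproducible under the seed.
#'
#' @param image height x width x 3 array.
#' @param patch_size Patch side in pixels (default 16 for fixture-sized
#'   images; the real pipeline uses 1000 px tiles).
#' @param threshold Tissue luminance threshold.
#' @param coverage_min Minimum tissue coverage per patch.
#' @param n_clusters Number of patch clusters.
#' @param fraction Per-cluster mosaic selection fraction.
#' @param extractor Patch feature extractor.
#' @param seed Integer seed.
#' @param label,bag_id Bag metadata.
#' @return List with `bag`, `mosaic`, `patches`, `mask`.
#' @export
prepare_bag <- function(image, patch_size = 16L, threshold = 0.8,
                        coverage_min = 0.5, n_clusters = 4L, fraction = 0.10,
                        extractor = default_patch_extractor(), seed = 1L,
                        label = NA, bag_id = "bag") {
  mask <- tissue_mask(image, threshold)
  patches <- grid_patches(mask, patch_size, coverage_min)
  if (nrow(patches) == 0) stop("no tissue-bearing patches found")
  feats <- patch_cluster_features(image, patches)
  patches$cluster <- cluster_patches(feats, n_clusters,
                                     substream_seed(seed, "cluster"))
  mosaic <- select_mosaic(patches, fraction, substream_seed(seed, "mosaic"))
  bag <- extract_features(image, mosaic, extractor, label, bag_id)
  list(bag = bag, mosaic = mosaic, patches = patches, mask = mask)
}

#' Write a mosaic as CSV (x, y, size, cluster)
#' @param mosaic Data frame of selected patches.
#' @param path Output path.
#' @export
write_mosaic_csv <- function(mosaic, path) {
  utils::write.csv(mosaic[, c("x", "y", "size", "cluster")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Write an image array as PNG
#' @param image height x width (x 3) array in `[0, 1]`.
#' @param path Output path.
#' @export
write_image_png <- function(image, path) {
  png::writePNG(image, path)
  invisible(path)
}

#' Read a PNG image as a height x width x 3 array
#' @param path PNG path.
#' @export
read_image_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3 && dim(img)[3] > 3) img <- img[, , 1:3]
  img
}
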