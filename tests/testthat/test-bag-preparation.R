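test_that("tissue masking thresholds luminance as specified", {
  img <- array(1, c(20, 20, 3))            # all-bright background
  expect_equal(sum(tissue_mask(img)), 0)
  expect_true(all(tissue_mask(img, threshold = 1.01)))   # accept everything
  expect_error(tissue_mask(array(0, c(0, 0, 3))), "empty")

  fix <- make_tissue_image(96, 96, 6, seed = 2, target_fraction = 0.3)
  got <- tissue_mask(fix$image, 0.8)
  jaccard <- sum(got & fix$mask) / sum(got | fix$mask)
  expect_gte(jaccard, 0.8)
})

test_that("grid tiling matches a brute-force coverage count", {
  full <- matrix(TRUE, 100, 100)
  p <- grid_patches(full, 50)
  expect_equal(nrow(p), 4)
  expect_equal(p$x, c(0, 50, 0, 50))       # row-major order
  expect_equal(p$y, c(0, 0, 50, 50))
  expect_equal(nrow(grid_patches(matrix(FALSE, 100, 100), 50)), 0)
  expect_error(grid_patches(full, 101), "exceeds")

  # half-covered image: compare against an explicit per-patch loop
  mask <- matrix(FALSE, 64, 64); mask[, 1:32] <- TRUE
  set.seed(4); mask[sample(64 * 64, 500)] <- TRUE
  got <- nrow(grid_patches(mask, 16, coverage_min = 0.5))
  brute <- 0
  for (y in seq(0, 48, 16)) for (x in seq(0, 48, 16)) {
    if (mean(mask[(y + 1):(y + 16), (x + 1):(x + 16)]) >= 0.5) brute <- brute + 1
  }
  expect_equal(got, brute)
})

test_that("loosening the tissue threshold never drops patches", {
  fix <- make_tissue_image(96, 96, 5, seed = 9, target_fraction = 0.25)
  counts <- vapply(c(0.5, 0.7, 0.8, 0.95, 1.0), function(th)
    nrow(grid_patches(tissue_mask(fix$image, th), 16, 0.4)), numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("patch clustering recovers separable groups deterministically", {
  skip_if_not_installed("mclust")
  set.seed(6)
  feats <- rbind(matrix(rnorm(40, 0), 20, 2), matrix(rnorm(40, 8), 20, 2))
  truth <- rep(1:2, each = 20)
  lab <- cluster_patches(feats, 2, seed = 3)
  expect_equal(mclust::adjustedRandIndex(lab, truth), 1.0)
  expect_identical(lab, cluster_patches(feats, 2, seed = 3))
  expect_true(all(cluster_patches(feats, 1) == 1L))
  expect_warning(lab2 <- cluster_patches(feats[1:3, ], 5, seed = 1), "reducing")
  expect_lte(max(lab2), 3)
})

test_that("mosaic selection samples the ceiling of each cluster", {
  patches <- data.frame(x = 0:29 * 10, y = 0, size = 10,
                        coverage = 1, cluster = rep(c(1, 2), c(10, 20)))
  mosaic <- select_mosaic(patches, 0.10, seed = 2)
  expect_equal(as.vector(table(mosaic$cluster)), c(1, 2))
  expect_identical(select_mosaic(patches, 0.10, seed = 2), mosaic)
  expect_equal(nrow(select_mosaic(patches, 1.0, seed = 2)), 30)
  expect_error(select_mosaic(patches, 0), "fraction")

  # size bound: |mosaic| <= ceil(fraction * N) + n_clusters, >= n_clusters
  for (fr in c(0.1, 0.3, 0.7)) {
    ms <- select_mosaic(patches, fr, seed = 5)
    expect_lte(nrow(ms), ceiling(fr * 30) + 2)
    expect_gte(nrow(ms), 2)
  }
})

test_that("the default extractor is deterministic with fixed dimension", {
  ex <- default_patch_extractor(feature_dim = 12, seed = 3)
  px <- make_tissue_image(32, 32, 2, seed = 1, target_fraction = 0.4)$image
  v1 <- ex(px); v2 <- ex(px)
  expect_identical(v1, v2)
  expect_length(v1, 12)
  # dimension independent of patch size
  expect_length(ex(px[1:8, 1:8, , drop = FALSE]), 12)
})

test_that("the image-to-bag pipeline is reproducible end to end", {
  fix <- make_tissue_image(96, 96, 6, seed = 12, target_fraction = 0.35)
  r1 <- prepare_bag(fix$image, patch_size = 16, n_clusters = 3,
                    fraction = 0.5, seed = 21, label = 1, bag_id = "img1")
  r2 <- prepare_bag(fix$image, patch_size = 16, n_clusters = 3,
                    fraction = 0.5, seed = 21, label = 1, bag_id = "img1")
  expect_identical(r1$bag$x, r2$bag$x)
  expect_equal(ncol(r1$bag$x), 16)
  expect_equal(nrow(r1$bag$x), nrow(r1$mosaic))
  expect_equal(r1$bag$label, 1)
  # identical patches produce identical feature vectors
  ex <- default_patch_extractor(8, seed = 1)
  same <- extract_features(fix$image,
                           rbind(r1$mosaic[1, ], r1$mosaic[1, ]), ex)
  expect_identical(same$x[1, ], same$x[2, ])
  expect_error(extract_features(fix$image, r1$mosaic[0, ], ex), "empty mosaic")
})

test_that("mosaics and images serialize to disk formats", {
  fix <- make_tissue_image(64, 64, 4, seed = 3, target_fraction = 0.3)
  r <- prepare_bag(fix$image, patch_size = 16, n_clusters = 2,
                   fraction = 0.5, seed = 2)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_mosaic_csv(r$mosaic, csv)
  back <- read.csv(csv)
  expect_equal(names(back), c("x", "y", "size", "cluster"))
  expect_equal(nrow(back), nrow(r$mosaic))

  pngf <- withr::local_tempfile(fileext = ".png")
  write_image_png(fix$image, pngf)
  img <- read_image_png(pngf)
  expect_equal(dim(img), dim(fix$image))
  expect_lt(max(abs(img - fix$image)), 1 / 255)
})
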