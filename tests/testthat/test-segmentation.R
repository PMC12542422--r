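disk_image <- function(n, centers, radii, value = 1, bg = 0.02) {
  m <- matrix(bg, n, n)
  for (i in seq_len(nrow(centers)))
    m <- rbscreen:::paint_disk(m, centers[i, 1], centers[i, 2], radii[i],
                               value, 1)
  m
}

test_that("blank and constant images segment to zero objects", {
  g <- segment_nuclei(matrix(0, 64, 64))
  expect_equal(max(g$labels), 0)
  g2 <- segment_nuclei(matrix(0.7, 64, 64))
  expect_equal(max(g2$labels), 0)
})

test_that("disjoint noise-free nuclei are recovered one label each", {
  opt <- site_optics()
  opt$noise$enabled <- FALSE
  opt$vignette$enabled <- FALSE
  p <- c(0, 0, 1, 0, 0, 0, 0, 0)  # plain interphase nuclei
  cells <- sample_well_cells(p, 20, seed = 8)
  site <- render_site(cells, opt, seed = 8)
  g <- segment_nuclei(site$hoechst)
  expect_equal(max(g$labels), 20)
  m <- match_labels(g$labels, site$labels)
  expect_equal(nrow(m$pairs), 20)
  expect_gt(min(m$pairs$iou), 0.9)
})

test_that("watershed splits two disks overlapping by ~20%", {
  # centres 1.6 r apart -> substantial overlap, still two nuclei
  img <- disk_image(96, rbind(c(40, 48), c(56, 48)), c(10, 10), value = 1)
  g <- segment_nuclei(img, pixel_size_um = 0.65)
  expect_equal(max(g$labels), 2)
})

test_that("ring radius conversion follows round(width / pixel size)", {
  expect_equal(ring_width_px(6.5, 0.65), 10L)
  expect_equal(ring_width_px(6.5, 1.3), 5L)
  expect_equal(ring_width_px(6.5, 0.6), 11L)
  for (ps in c(0.3, 0.5, 0.65, 1, 1.6))
    expect_equal(ring_width_px(6.5, ps), as.integer(round(6.5 / ps)))
  expect_error(cytoplasm_rings(label_grid(matrix(0L, 4, 4), 0.65), 0),
               "positive")
})

test_that("rings are disjoint from nuclei and split at equidistance", {
  lab <- matrix(0L, 64, 64)
  lab[30:34, 20:24] <- 1L  # two square nuclei 8 px apart (edge to edge)
  lab[30:34, 33:37] <- 2L
  grid <- label_grid(lab, 0.65)
  rings <- cytoplasm_rings(grid, width_um = 6.5)  # 10 px dilation
  expect_true(all(rings$labels[lab > 0] == 0))
  # brute-force nearest-nucleus oracle over explicit pixel coordinates
  px1 <- which(lab == 1L, arr.ind = TRUE)
  px2 <- which(lab == 2L, arr.ind = TRUE)
  ring_px <- which(rings$labels > 0, arr.ind = TRUE)
  for (k in seq_len(nrow(ring_px))) {
    d1 <- sqrt(min((px1[, 1] - ring_px[k, 1])^2 +
                     (px1[, 2] - ring_px[k, 2])^2))
    d2 <- sqrt(min((px2[, 1] - ring_px[k, 1])^2 +
                     (px2[, 2] - ring_px[k, 2])^2))
    want <- if (d1 < d2) 1L else if (d2 < d1) 2L else 1L  # ties: lower label
    expect_lte(min(d1, d2), 10)
    expect_equal(rings$labels[ring_px[k, 1], ring_px[k, 2]], want)
  }
  # empty nucleus grid -> empty ring grid
  empty <- cytoplasm_rings(label_grid(matrix(0L, 16, 16), 0.65), 6.5)
  expect_true(all(empty$labels == 0))
})

test_that("feature extraction matches a per-pixel oracle on a toy grid", {
  set.seed(21)
  lab <- matrix(0L, 48, 48)
  lab[5:14, 5:14] <- 1L
  lab[30:41, 28:35] <- 2L
  grid <- label_grid(lab, 0.5)
  rings <- cytoplasm_rings(grid, width_um = 2)
  dna <- matrix(runif(48 * 48), 48, 48)
  rep_ <- matrix(runif(48 * 48, 0.1, 1), 48, 48)
  fx <- extract_features(grid, rings, dna, rep_)
  expect_equal(nrow(fx), 2)
  expect_identical(names(fx)[2:16], feature_names())
  for (l in 1:2) {
    px <- lab == l
    expect_equal(fx$area_um2[l], sum(px) * 0.25)
    expect_equal(fx$dna_mean[l], mean(dna[px]))
    expect_equal(fx$dna_integrated[l], sum(dna[px]))
    expect_equal(fx$dna_sd[l], sd(dna[px]))
    expect_equal(fx$rep_mean[l], mean(rep_[px]))
    rpx <- rings$labels == l
    expect_equal(fx$ring_rep_mean[l], mean(rep_[rpx]))
    expect_equal(fx$ring_rep_integrated[l], sum(rep_[rpx]))
    v <- sort(rep_[px], decreasing = TRUE)
    td <- mean(v[seq_len(ceiling(sum(px) / 10))])
    expect_equal(fx$rep_topdecile_mean[l], td)
    expect_equal(fx$rep_topdecile_ratio[l], td / median(rep_[px]))
    expect_equal(fx$nuc_ring_ratio[l], mean(rep_[px]) / mean(rep_[rpx]))
  }
})

test_that("uniform and degenerate intensity cases behave as closed forms", {
  lab <- matrix(0L, 32, 32)
  lab[10:19, 10:19] <- 1L
  grid <- label_grid(lab, 1)
  rings <- cytoplasm_rings(grid, width_um = 3)
  flat <- matrix(0.6, 32, 32)
  fx <- extract_features(grid, rings, flat, flat)
  expect_equal(fx$rep_topdecile_ratio, 1)
  expect_equal(fx$dna_sd, 0)
  expect_equal(fx$rep_integrated, 0.6 * 100)  # v * A for a constant object
  expect_equal(fx$rep_spot_count, 0)
  # ring absent (denominator guard): all-zero reporter
  zero <- matrix(0, 32, 32)
  fz <- extract_features(grid, rings, flat, zero)
  expect_true(fz$ratio_flag)
  expect_equal(fz$nuc_ring_ratio, 0)
  # empty label grid -> empty table
  fe <- extract_features(label_grid(matrix(0L, 16, 16), 1),
                         label_grid(matrix(0L, 16, 16), 1),
                         matrix(0, 16, 16), matrix(0, 16, 16))
  expect_equal(nrow(fe), 0)
})

test_that("rendered nucleolar cells show nucleolar-proxy contrast", {
  opt <- site_optics()
  opt$noise$enabled <- FALSE
  opt$vignette$enabled <- FALSE
  cells <- sample_well_cells(c(1, 0, 0, 0, 0, 0, 0, 0), 6, seed = 12)
  site <- render_site(cells, opt, seed = 12)
  nuc <- segment_nuclei(site$hoechst)
  rings <- cytoplasm_rings(nuc)
  fx <- extract_features(nuc, rings, site$hoechst, site$reporter)
  expect_gt(nrow(fx), 0)
  expect_true(all(fx$rep_topdecile_ratio > 1.5))
  expect_true(all(fx$rep_spot_count >= 1))
})

test_that("border-touching nuclei carry the border flag", {
  lab <- matrix(0L, 32, 32)
  lab[1:6, 10:15] <- 1L   # touches row 1
  lab[15:20, 15:20] <- 2L
  grid <- label_grid(lab, 1)
  rings <- cytoplasm_rings(grid, width_um = 2)
  fx <- extract_features(grid, rings, matrix(1, 32, 32), matrix(1, 32, 32))
  expect_equal(fx$border, c(TRUE, FALSE))
  expect_equal(border_labels(grid), 1L)
})
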