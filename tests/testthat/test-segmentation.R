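test_that("CN segmentation: empty, disjoint disks, merged overlaps", {
  expect_warning(lab0 <- segment_cn(matrix(0, 32, 32)), "constant")
  expect_equal(sum(lab0), 0)
  # five disjoint bright disks on a dark background
  img <- matrix(5, 96, 96)
  centers <- cbind(c(15, 15, 48, 80, 80), c(15, 80, 48, 15, 80))
  for (i in 1:5) img <- add_disk(img, centers[i, 1], centers[i, 2], 6, 200)
  lab <- segment_cn(img, min_area_px = 10)
  expect_equal(max(lab), 5)
  expect_equal(igraph_component_count(lab > 0), 5)
  # two overlapping disks form one 8-connected component
  img2 <- matrix(5, 64, 64)
  img2 <- add_disk(img2, 30, 28, 8, 200)
  img2 <- add_disk(img2, 30, 38, 8, 200)
  lab2 <- segment_cn(img2, min_area_px = 10)
  expect_equal(max(lab2), 1)
  expect_equal(igraph_component_count(lab2 > 0), 1)
})

test_that("size filter drops small components; labels stay disjoint/exhaustive", {
  img <- matrix(0, 48, 48)
  img <- add_disk(img, 12, 12, 5, 100)   # area ~ 81 px
  img <- add_disk(img, 36, 36, 1.2, 100) # area ~ 5 px
  lab_all <- segment_cn(img, min_area_px = 1)
  expect_equal(max(lab_all), 2)
  lab <- segment_cn(img, min_area_px = 20)
  expect_equal(max(lab), 1)
  # every foreground pixel above threshold belongs to exactly one label
  expect_true(all(lab[lab > 0] == 1))
})

test_that("ratio-based bacterial segmentation thresholds at killed median + 3 SD", {
  vals <- matrix(0.00368, 48, 48)
  killed <- c(0.00368, 0.00002)
  rimg <- structure(list(values = vals, valid_mask = matrix(TRUE, 48, 48),
                         min_denominator_counts = 1), class = "ratio_image")
  expect_equal(max(segment_bacteria_by_ratio(rimg, killed, 5)), 0)
  # one 20-ish px patch at median + 10 SD
  vals2 <- vals
  vals2[20:23, 20:24] <- killed[1] + 10 * killed[2]
  rimg2 <- structure(list(values = vals2, valid_mask = matrix(TRUE, 48, 48),
                          min_denominator_counts = 1), class = "ratio_image")
  lab <- segment_bacteria_by_ratio(rimg2, killed, min_area_px = 5)
  expect_equal(max(lab), 1)
  expect_equal(sum(lab > 0), 20)
  # below the size filter -> nothing
  expect_equal(max(segment_bacteria_by_ratio(rimg2, killed,
                                             min_area_px = 30)), 0)
  expect_error(segment_bacteria_by_ratio(rimg2, c(0.003, -1), 5), ">= 0")
})

test_that("area gate is inclusive and attachment matches a brute-force oracle", {
  # one algal-sized blob, one bacterium touching it, one far away
  lab <- matrix(0L, 64, 64)
  lab[10:19, 10:17] <- 1L          # 80 px exactly -> algal (inclusive)
  lab[10:13, 19:20] <- 2L          # 8 px, 1 px gap from col 17.. wait cols 19:20
  lab[50:53, 50:52] <- 3L          # 12 px, far
  rois <- classify_and_flag(lab, algal_min_area_px = 80, adjacency_px = 2)
  tab <- rois$table
  expect_equal(tab$kind[tab$roi_id == 1], "algal")
  expect_equal(tab$area_px[tab$roi_id == 1], 80)
  expect_false(tab$attached[tab$roi_id == 1])  # algal never flagged
  # oracle distances
  px1 <- which(rois$labels == 1, arr.ind = TRUE)
  for (id in 2:3) {
    pxb <- which(rois$labels == id, arr.ind = TRUE)
    want <- min_chebyshev(pxb, px1) <= 2
    expect_equal(tab$attached[tab$roi_id == id], want)
  }
  expect_true(tab$attached[tab$roi_id == 2])
  expect_false(tab$attached[tab$roi_id == 3])
  # no algal ROIs -> nothing attached
  lab2 <- matrix(0L, 32, 32); lab2[4:6, 4:6] <- 1L; lab2[20:22, 20:22] <- 2L
  rois2 <- classify_and_flag(lab2, algal_min_area_px = 80, adjacency_px = 2)
  expect_true(all(!rois2$table$attached))
  expect_true(all(rois2$table$kind == "bacterial"))
  expect_error(classify_and_flag(lab2, adjacency_px = -1), ">= 0")
})

test_that("attached-bacteria pixels are subtracted from algal ROIs", {
  lab <- matrix(0L, 32, 32)
  lab[10:20, 10:20] <- 1L   # algal blob (121 px)
  lab[14:16, 21:23] <- 2L   # bacterium flush against its right edge
  rois <- classify_and_flag(lab, algal_min_area_px = 100, adjacency_px = 2)
  tab <- rois$table
  # algal ROI lost the 1-px-dilated bacterial border column
  expect_lt(tab$area_px[tab$kind == "algal"], 121)
  expect_true(tab$attached[tab$kind == "bacterial"])
  # ROIs remain disjoint
  expect_equal(sum(rois$labels == 1) + sum(rois$labels == 2),
               sum(rois$labels > 0))
})

test_that("planted cells are recovered with centroids within 2 px", {
  cfg <- small_config(seed = 81, cycles = 6, pixels = 96)
  cells <- place_cells(cfg, n_bacteria = 6, n_algal = 1, seed = 9)
  sim <- render_ion_stacks(cells, cfg)
  summed <- lapply(sim$stacks, accumulate_cycles)
  # at 96 px / 20 um a 0.35 um bacterium covers ~9 px
  rois <- segment_field(summed, raster_um = cfg$raster_um, min_area_px = 4)
  expect_equal(nrow(rois$table), nrow(cells))
  expect_equal(sum(rois$table$kind == "algal"), 1)
  for (i in seq_len(nrow(cells))) {
    same <- rois$table[rois$table$kind == cells$kind[i], ]
    d <- sqrt((same$centroid_row - cells$row[i])^2 +
                (same$centroid_col - cells$col[i])^2)
    expect_lt(min(d), 2)
  }
  # area_um2 scales with the raster
  expect_equal(rois$table$area_um2,
               rois$table$area_px * (cfg$raster_um / cfg$pixels)^2)
})
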