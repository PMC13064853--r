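test_that("mask_iou counts pixels and rejects two empty masks", {
  a <- matrix(FALSE, 4, 4); a[1:2, 1:2] <- TRUE
  expect_identical(mask_iou(a, a), 1)
  b <- matrix(FALSE, 4, 4); b[3:4, 3:4] <- TRUE
  expect_identical(mask_iou(a, b), 0)
  shifted <- matrix(FALSE, 4, 4); shifted[1:2, 2:3] <- TRUE
  expect_equal(mask_iou(a, shifted), 2 / 6)
  expect_error(mask_iou(matrix(FALSE, 2, 2), matrix(FALSE, 2, 2)), "empty")
})

test_that("mask_iou is symmetric and matches per-pixel counting on random masks", {
  set.seed(19)
  for (rep in 1:20) {
    a <- matrix(runif(36) < 0.4, 6, 6)
    b <- matrix(runif(36) < 0.4, 6, 6)
    if (!any(a | b)) next
    brute <- sum(a & b) / sum(a | b)
    expect_identical(mask_iou(a, b), brute)
    expect_identical(mask_iou(a, b), mask_iou(b, a))
  }
})

test_that("relabel_global offsets ids and leaves background untouched", {
  alloc <- id_allocator()
  first <- matrix(c(0L, 1L, 2L, 3L, 4L, 5L), 2, 3)
  relabel_global(first, 1L, alloc) # consumes ids 1..5
  chunk <- matrix(c(0L, 1L, 2L, 0L), 2, 2)
  out <- relabel_global(chunk, 2L, alloc)
  expect_identical(sort(unique(as.vector(out))), c(0L, 6L, 7L))
  blank <- matrix(0L, 3, 3)
  expect_identical(relabel_global(blank, 3L, alloc), blank)
  expect_identical(alloc$next_id, 8L) # blank chunk consumed nothing
  two_more <- relabel_global(matrix(c(1L, 2L, 3L, 0L), 2, 2), 4L, alloc)
  all_ids <- c(unique(as.vector(out)), unique(as.vector(two_more)))
  expect_length(setdiff(unique(all_ids), 0L), 5L) # globally distinct
})

test_that("relabel_global detects id overflow of the 32-bit width", {
  alloc <- id_allocator()
  alloc$next_id <- .Machine$integer.max - 1L
  expect_error(relabel_global(matrix(c(1L, 2L, 3L, 4L), 2, 2), 1L, alloc),
               "32-bit")
})

test_that("reference segmentation finds, filters and splits objects", {
  blank <- array(0, c(1, 16, 16))
  expect_identical(max(reference_segmentation(blank, threshold = 0.5)), 0L)

  # one bright 6 x 10 blob of exactly 60 px
  raster <- array(0, c(1, 20, 20))
  raster[1, 3:8, 5:14] <- 5
  lab <- reference_segmentation(raster, threshold = 1, min_size = 10)
  expect_identical(max(lab), 1L)
  expect_identical(sum(lab == 1L), 60L)

  # 5 px object is removed at min_size 10
  small <- array(0, c(1, 16, 16))
  small[1, 4, 4:8] <- 5
  expect_identical(max(reference_segmentation(small, threshold = 1, min_size = 10)), 0L)

  # two touching squares with distinct nuclear seeds are split in two
  touching <- array(0, c(2, 12, 20))
  touching[1, 4:9, 3:8] <- 1   # body A (channel sum above threshold)
  touching[1, 4:9, 9:14] <- 1  # body B, 4-adjacent to A
  touching[2, 6:7, 5:6] <- 9   # seed A
  touching[2, 6:7, 11:12] <- 9 # seed B
  lab2 <- reference_segmentation(touching, threshold = 0.5, min_size = 5,
                                 nuclear_channel = 2, nuclear_threshold = 5)
  expect_identical(max(lab2), 2L)
  expect_true(all(lab2[5, 3:8] == lab2[5, 3]))  # body A kept whole
  expect_true(lab2[5, 8] != lab2[5, 9])         # split at the interface
})

test_that("label_components uses 8-connectivity", {
  m <- matrix(0, 5, 5)
  m[1, 1] <- 1; m[2, 2] <- 1 # diagonal pair
  m[5, 5] <- 1
  lab <- label_components(m)
  expect_identical(lab[1, 1], lab[2, 2])
  expect_false(lab[5, 5] == lab[1, 1])
  expect_identical(max(lab), 2L)
})

test_that("merge strategies behave on constructed border scenes", {
  # one disk fully inside a single core: all strategies return it unchanged
  sc <- generate_scene(scene_spec(image_shape = c(64, 64), n_cells = 1,
                                  radius_range = c(6, 6), seed = 2))
  plan <- plan_chunks(c(64, 64), chunk_size = 32, overlap = 16)
  for (strategy in c("iou_merge", "no_merge", "touch_merge")) {
    lab <- segment_chunked(sc$image, scene_segmenter(), plan,
                           merge_config(2, 0.7, strategy))
    expect_identical(max(lab), 1L)
    expect_gt(aggregated_jaccard_index(lab, sc$labels), 0.9)
  }
})

test_that("a cell straddling a border merges to exactly one object", {
  # disk centered on the core boundary of a 2-chunk plan
  img <- array(0, c(2, 40, 80))
  cy <- 19; cx <- 39 # 0-based center sits on the x = 40 boundary
  for (y in 1:40) for (x in 1:80) {
    d <- sqrt((y - 1 - cy)^2 + (x - 1 - cx)^2)
    if (d <= 8) img[1, y, x] <- 5
    if (d <= 3) img[2, y, x] <- 9
  }
  image <- multiplex_image(img, channel_names = c("body", "nuclear"))
  plan <- plan_chunks(c(40, 80), chunk_size = 40, overlap = 12)
  seg <- reference_segmenter(threshold = 1, min_size = 10,
                             nuclear_channel = 2, nuclear_threshold = 5)
  merged <- segment_chunked(image, seg, plan, merge_config(2, 0.7, "iou_merge"))
  expect_identical(max(merged), 1L)
  fragmented <- segment_chunked(image, seg, plan, merge_config(2, 0.7, "no_merge"))
  expect_identical(max(fragmented), 2L)
})

test_that("touching distinct disks across a border: iou_merge keeps 2, touch_merge gives 1", {
  img <- array(0, c(2, 40, 80))
  centers <- rbind(c(19, 32), c(19, 47)) # tangent pair straddling x = 40
  for (i in 1:2) for (y in 1:40) for (x in 1:80) {
    d <- sqrt((y - 1 - centers[i, 1])^2 + (x - 1 - centers[i, 2])^2)
    if (d <= 8) img[1, y, x] <- 5
    if (d <= 3) img[2, y, x] <- max(img[2, y, x], 9)
  }
  image <- multiplex_image(img, channel_names = c("body", "nuclear"))
  plan <- plan_chunks(c(40, 80), chunk_size = 40, overlap = 12)
  seg <- reference_segmenter(threshold = 1, min_size = 10,
                             nuclear_channel = 2, nuclear_threshold = 5)
  whole <- segment_chunked(image, seg, whole_plan(c(40, 80)))
  expect_identical(max(whole), 2L)
  kept <- segment_chunked(image, seg, plan, merge_config(2, 0.7, "iou_merge"))
  expect_identical(max(kept), 2L)
  expect_equal(aggregated_jaccard_index(kept, whole), 1)
  over <- segment_chunked(image, seg, plan, merge_config(2, 0.7, "touch_merge"))
  expect_identical(max(over), 1L)
})

test_that("merge output is invariant to chunk processing order", {
  sc <- generate_scene(scene_spec(n_cells = 50, allow_touching = TRUE, seed = 21))
  plan <- plan_chunks(c(256, 256), chunk_size = 96, overlap = 40)
  seg <- scene_segmenter()
  alloc <- id_allocator()
  chunks <- lapply(seq_along(plan$specs), function(k) {
    raster <- extract_chunk(sc$image, plan$specs[[k]])
    relabel_global(seg$fn(raster), k, alloc)
  })
  ref <- merge_across_borders(chunks, plan, merge_config())
  # relabeling the chunks as if visited in reverse order must not change
  # the stitched masks (ids are renumbered consecutively either way)
  alloc2 <- id_allocator()
  rev_order <- rev(seq_along(chunks))
  relab <- vector("list", length(chunks))
  for (k in rev_order) {
    relab[[k]] <- relabel_global(chunks[[k]], k, alloc2)
  }
  out2 <- merge_across_borders(relab, plan, merge_config())
  # same partition of pixels into objects
  expect_identical(max(ref), max(out2))
  key <- paste(as.vector(ref), as.vector(out2))
  expect_identical(length(unique(key[as.vector(ref) > 0])), as.integer(max(ref)))
  expect_true(all((ref > 0) == (out2 > 0)))
})

test_that("edge_band larger than the overlap is rejected for multi-chunk plans", {
  sc <- generate_scene(scene_spec(image_shape = c(64, 64), n_cells = 3, seed = 5))
  plan <- plan_chunks(c(64, 64), chunk_size = 32, overlap = 4)
  expect_error(
    segment_chunked(sc$image, scene_segmenter(), plan, merge_config(edge_band = 6)),
    "edge_band")
  # single-chunk plans have no borders; the default edge_band must pass
  lab <- segment_chunked(sc$image, scene_segmenter(),
                         plan_chunks(c(64, 64), 64, 0), merge_config())
  expect_identical(max(lab), 3L)
})

test_that("a segmenter returning the wrong shape names the offending chunk", {
  sc <- generate_scene(scene_spec(image_shape = c(64, 64), n_cells = 2, seed = 9))
  bad <- segmenter(function(raster) matrix(0L, 3, 3))
  expect_error(segment_chunked(sc$image, bad, plan_chunks(c(64, 64), 32, 8)),
               "contract violation at chunk \\(1, 1\\)")
})

test_that("unknown segmenter channels are rejected", {
  sc <- generate_scene(scene_spec(image_shape = c(64, 64), n_cells = 2, seed = 9))
  seg <- reference_segmenter(1, channels = c("nuclear", "CD3"))
  expect_error(segment_chunked(sc$image, seg, plan_chunks(c(64, 64), 64, 0)),
               "CD3")
})

test_that("overlap sufficiency implements the equivalent-radius rule", {
  res <- check_overlap_sufficiency(3044, 50)
  expect_identical(res$equivalent_radius_px, 31L)
  expect_true(res$sufficient)
  expect_warning(res2 <- check_overlap_sufficiency(pi, 1), "not larger")
  expect_identical(res2$equivalent_radius_px, 1L)
  expect_false(res2$sufficient)
  expect_warning(res3 <- check_overlap_sufficiency(10000 * pi, 50), "not larger")
  expect_identical(res3$equivalent_radius_px, 100L)
  expect_false(res3$sufficient)
  expect_error(check_overlap_sufficiency(0, 50), "positive")
})
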