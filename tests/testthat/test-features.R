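test_that("accumulate_chunk sums labels, intensities and coordinates", {
  labels <- matrix(0L, 3, 3)
  labels[1, 1] <- 1L; labels[2, 1] <- 1L
  img <- array(0, c(1, 3, 3))
  img[1, 1, 1] <- 2; img[1, 2, 1] <- 4
  st <- accumulate_chunk(labels, img)
  expect_identical(st$ids, 1L)
  expect_equal(unname(st$n), 2)
  expect_equal(unname(st$sums[1, 1]), 6)

  empty <- accumulate_chunk(matrix(0L, 3, 3), img)
  expect_length(empty$ids, 0L)
})

test_that("accumulate_chunk matches a per-pixel loop on a random core", {
  set.seed(4)
  labels <- matrix(sample(0:5, 32 * 32, replace = TRUE), 32, 32)
  img <- array(runif(2 * 32 * 32), c(2, 32, 32))
  st <- accumulate_chunk(labels, img, origin = c(10L, 20L))
  for (id in st$ids) {
    idx <- which(labels == id)
    expect_equal(unname(st$n[as.character(id) == as.character(st$ids)]),
                 length(idx))
    ys <- 10 + (idx - 1) %% 32
    xs <- 20 + (idx - 1) %/% 32
    pos <- match(id, st$ids)
    expect_equal(unname(st$sy[pos]), sum(ys))
    expect_equal(unname(st$sx[pos]), sum(xs))
    for (k in 1:2) {
      v <- sum(vapply(idx, function(i) {
        img[k, (i - 1) %% 32 + 1, (i - 1) %/% 32 + 1]
      }, numeric(1)))
      expect_equal(unname(st$sums[pos, k]), v)
    }
  }
})

test_that("combine_stats is commutative with an identity element", {
  set.seed(8)
  la <- matrix(sample(0:3, 64, replace = TRUE), 8, 8)
  lb <- matrix(sample(0:3, 64, replace = TRUE), 8, 8)
  ia <- array(runif(64), c(1, 8, 8)); ib <- array(runif(64), c(1, 8, 8))
  a <- accumulate_chunk(la, ia)
  b <- accumulate_chunk(lb, ib, origin = c(8L, 0L))
  empty <- accumulate_chunk(matrix(0L, 2, 2), array(0, c(1, 2, 2)))
  expect_equal(combine_stats(list(a, empty)), a)
  expect_equal(combine_stats(list(a, b)), combine_stats(list(b, a)))
})

test_that("a label split across chunks accumulates its whole-image count", {
  labels <- matrix(1L, 9, 9) # one cell over the whole frame
  img <- array(1, c(1, 9, 9))
  plan <- plan_chunks(c(9, 9), chunk_size = 3, overlap = 0)
  parts <- lapply(plan$specs, function(s) {
    rows <- (s$core_y[1] + 1):s$core_y[2]
    cols <- (s$core_x[1] + 1):s$core_x[2]
    accumulate_chunk(labels[rows, cols, drop = FALSE],
                     img[, rows, cols, drop = FALSE],
                     origin = c(s$core_y[1], s$core_x[1]))
  })
  st <- combine_stats(parts)
  expect_equal(unname(st$n), 81)
  expect_equal(unname(st$sy), sum(0:8) * 9)
})

test_that("finalize_features computes means, area and centroid", {
  labels <- matrix(0L, 8, 8)
  labels[3, 4] <- 1L; labels[3, 5] <- 1L
  img <- array(0, c(1, 8, 8)); img[1, 3, 4] <- 2; img[1, 3, 5] <- 4
  tab <- finalize_features(accumulate_chunk(labels, img), sample_id = "s1")
  expect_equal(tab$channel_0, 3)
  expect_equal(tab$area_px2, 2)
  expect_equal(tab$centroid_y, 2)   # 0-based pixel-center coordinates
  expect_equal(tab$centroid_x, 3.5)

  single <- matrix(0L, 10, 10); single[6, 8] <- 1L
  tab2 <- finalize_features(accumulate_chunk(single, array(1, c(1, 10, 10))))
  expect_equal(tab2$centroid_y, 5)
  expect_equal(tab2$centroid_x, 7)
})

test_that("extract_features matches the per-pixel oracle row for row", {
  sc <- generate_scene(scene_spec(image_shape = c(96, 96), n_cells = 12, seed = 6))
  tab <- extract_features(sc$image, sc$labels)
  ora <- oracle_features(sc$image, sc$labels)
  expect_identical(tab$cell_id, ora$cell_id)
  expect_equal(tab$area_px2, ora$area_px2)
  expect_equal(tab$centroid_y, ora$centroid_y)
  expect_equal(tab$centroid_x, ora$centroid_x)
  for (ch in sc$image$channel_names) expect_equal(tab[[ch]], ora[[ch]])
})

test_that("feature extraction is invariant to the chunking", {
  sc <- generate_scene(scene_spec(n_cells = 30, allow_touching = TRUE, seed = 13))
  ref <- extract_features(sc$image, sc$labels)
  for (cs in c(64, 97, 128)) {
    tab <- extract_features(sc$image, sc$labels, plan_chunks(c(256, 256), cs, 0))
    expect_identical(tab$cell_id, ref$cell_id)
    num_ref <- as.matrix(ref[, -1])
    num_tab <- as.matrix(tab[, -1])
    expect_lt(max(abs(num_tab - num_ref) / pmax(abs(num_ref), 1e-12)), 1e-9)
  }
})

test_that("areas conserve the pixel count and every label appears once", {
  sc <- generate_scene(scene_spec(n_cells = 25, seed = 17))
  tab <- extract_features(sc$image, sc$labels)
  expect_identical(sort(tab$cell_id), sort(unique(sc$labels[sc$labels > 0])))
  expect_identical(anyDuplicated(tab$cell_id), 0L)
  expect_equal(sum(tab$area_px2) + sum(sc$labels == 0L), 256 * 256)
  # centroids lie inside the image bounds
  expect_true(all(tab$centroid_y >= 0 & tab$centroid_y <= 255))
  expect_true(all(tab$centroid_x >= 0 & tab$centroid_x <= 255))
})

test_that("an all-zero image yields zero means with unchanged areas", {
  labels <- matrix(0L, 10, 10); labels[2:4, 2:4] <- 1L
  img <- multiplex_image(array(0, c(2, 10, 10)))
  tab <- extract_features(img, labels)
  expect_equal(tab$channel_0, 0)
  expect_equal(tab$channel_1, 0)
  expect_equal(tab$area_px2, 9)
})

test_that("shape mismatches are invalid arguments", {
  img <- multiplex_image(array(1, c(1, 10, 10)))
  expect_error(extract_features(img, matrix(0L, 5, 5)), "shape")
  expect_error(accumulate_chunk(matrix(0L, 4, 4), array(1, c(1, 5, 5))),
               "same core region")
})
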