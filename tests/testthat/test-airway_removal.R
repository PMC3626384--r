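test_that("seed specs validate their own geometry", {
  expect_s3_class(seed_spec(3, c(10, 10), c(5, 5, 20, 20)), "seed_spec")
  expect_error(seed_spec(1, c(5, 5), c(5, 5, 20, 20)), "strictly inside")
  expect_error(seed_spec(1, c(10, 10), c(20, 5, 5, 20)), "row_min")
})

test_that("seed specs round-trip through the JSON sidecar", {
  specs <- list(seed_spec(4, c(20, 128), c(5, 110, 110, 146)),
                seed_spec(5, c(22, 130), c(6, 112, 112, 148)))
  f <- withr::local_tempfile(fileext = ".json")
  write_seed_specs(specs, f)
  back <- read_seed_specs(f)
  expect_identical(back, specs)
})

test_that("region growing fills a uniform box and stays inside the bbox", {
  slice <- matrix(100, 30, 30)
  spec <- seed_spec(1, c(15, 15), c(6, 6, 25, 25))
  grown <- region_grow(slice, spec, stop_delta = 5)
  expect_equal(sum(grown), 20 * 20)
  expect_true(all(which(grown == 1L, arr.ind = TRUE)[, 1] %in% 6:25))

  # stop_delta = 0 admits only pixels exactly at the running mean
  noisy <- slice + matrix(seq_len(900) %% 2, 30, 30)  # alternating 100/101
  g0 <- region_grow(noisy, spec, stop_delta = 0)
  expect_true(g0[15, 15] == 1L)
  expect_true(all(noisy[g0 == 1L] == noisy[15, 15]))
})

test_that("region growing extracts a homogeneous tube exactly", {
  fx <- make_tube_fixture()
  spec <- seed_spec(1, c(20, 40), c(2, 30, 45, 50))
  grown <- region_grow(fx$slice, spec, stop_delta = 50)
  expected <- oracle_bright_component(fx$slice, c(20, 40), spec$bbox, 50)
  expect_identical(grown, expected)
  expect_identical(grown, fx$tube_mask)  # the bbox covers the whole tube
})

test_that("grown regions are connected, contain the seed, and are deterministic", {
  set.seed(64)
  for (i in 1:5) {
    slice <- matrix(round(runif(40 * 40, 0, 60)), 40, 40)
    spec <- seed_spec(1, c(20, 20), c(8, 8, 33, 33))
    g1 <- region_grow(slice, spec, stop_delta = 15)
    g2 <- region_grow(slice, spec, stop_delta = 15)
    expect_identical(g1, g2)
    expect_equal(g1[20, 20], 1L)
    lab <- oracle_components(g1, 4)
    expect_equal(max(lab), 1)
    rc <- which(g1 == 1L, arr.ind = TRUE)
    expect_true(all(rc[, 1] >= 8 & rc[, 1] <= 33 & rc[, 2] >= 8 & rc[, 2] <= 33))
  }
})

test_that("component labelling matches flood fill and the connectivity definitions", {
  m <- matrix(0L, 10, 10)
  m[2:4, 2:4] <- 1L
  m[7:9, 7:9] <- 1L
  expect_equal(max(label_components(m, 8)), 2)

  diagonal <- matrix(0L, 5, 5)
  diagonal[2, 2] <- 1L
  diagonal[3, 3] <- 1L
  expect_equal(max(label_components(diagonal, 8)), 1)
  expect_equal(max(label_components(diagonal, 4)), 2)

  expect_equal(max(label_components(matrix(0L, 6, 6), 8)), 0)

  set.seed(5)
  rnd <- matrix(as.integer(runif(64 * 64) < 0.4), 64, 64)
  for (conn in c(4, 8)) {
    mine <- label_components(rnd, conn)
    ref <- oracle_components(rnd, conn)
    # same partition (labels may be numbered differently only if scan orders
    # differ; both use row-major first-occurrence, so they agree exactly)
    expect_identical(mine, ref)
  }
})

test_that("labelling agrees with EBImage on 4-connectivity", {
  skip_if_not_installed("EBImage")
  set.seed(6)
  rnd <- matrix(as.integer(runif(48 * 48) < 0.35), 48, 48)
  mine <- label_components(rnd, 4)
  ref <- EBImage::bwlabel(rnd)
  # identical partitions up to label numbering
  expect_equal(max(mine), max(ref))
  expect_true(all(tapply(ref[rnd == 1], mine[rnd == 1],
                         function(v) length(unique(v))) == 1))
})

test_that("area filter keeps components of at least min_area pixels", {
  m <- matrix(0L, 40, 80)
  m[2:8, 2:8] <- 1L          # 49 px
  m[12:18, 12:18] <- 1L
  m[12, 19] <- 1L            # 50 px
  m[22:28, 22:28] <- 1L
  m[22, 29:30] <- 1L         # 51 px
  out <- area_filter(m, min_area = 50)
  expect_equal(sum(out), 50 + 51)
  expect_equal(sum(out[2:8, 2:8]), 0)
  expect_identical(area_filter(out, 50), out)  # idempotent
  expect_equal(sum(area_filter(matrix(0L, 10, 10), 50)), 0)

  set.seed(77)
  rnd <- matrix(as.integer(runif(64 * 64) < 0.45), 64, 64)
  lab <- oracle_components(rnd, 8)
  sizes <- table(lab[lab > 0])
  keep <- as.integer(names(sizes)[sizes >= 50])
  expect_identical(area_filter(rnd, 50), matrix(as.integer(lab %in% keep), 64, 64))
})

test_that("binary subtraction removes exactly the airway pixels", {
  m <- matrix(as.integer(runif(400) < 0.5), 20, 20)
  a <- matrix(0L, 20, 20)
  a[5:10, 5:10] <- 1L
  out <- subtract_airway(m, a)
  expect_true(all(out[5:10, 5:10] == 0L))
  expect_identical(out, subtract_airway(out, a))  # idempotent
  expect_identical(subtract_airway(m, matrix(0L, 20, 20)), m)
  expect_equal(sum(subtract_airway(m, m)), 0)
  expect_true(all(subtract_airway(m, 1L - m) <= m))
  expect_error(subtract_airway(m, matrix(0L, 10, 10)), "shapes differ")
})

test_that("morphology matches the literal set-shift oracle on small rasters", {
  set.seed(13)
  for (radius in 1:3) {
    se <- disk_element(radius)
    for (i in 1:4) {
      m <- matrix(as.integer(runif(32 * 32) < 0.5), 32, 32)
      expect_identical(binary_dilate(m, se), oracle_dilate(m, se$offsets))
      expect_identical(binary_erode(m, se), oracle_erode(m, se$offsets))
      # duality: erosion of A = complement of dilation of complement
      # (holds away from the raster border, where the complement of the
      # out-of-raster background would be needed)
      interior <- (radius + 1):(32 - radius)
      expect_identical(binary_erode(m, se)[interior, interior],
                       (1L - binary_dilate(1L - m, se))[interior, interior])
      # anti-extensivity / extensivity
      expect_true(all(binary_erode(m, se) <= m))
      expect_true(all(m <= binary_dilate(m, se)))
    }
  }
})

test_that("template box follows the W/4, H/2 centroid rule", {
  m <- matrix(0L, 256, 256)
  m[79:178, 79:178] <- 1L  # centred 100x100 square, centroid (128.5, 128.5)
  expect_equal(compute_template(m), c(79L, 104L, 178L, 153L))

  single <- matrix(0L, 20, 20)
  single[7, 9] <- 1L
  expect_equal(compute_template(single), c(7L, 9L, 7L, 9L))

  edge <- matrix(0L, 30, 30)
  edge[1:20, 1:10] <- 1L
  tpl <- compute_template(edge)
  expect_true(all(tpl >= 1) && tpl[3] <= 30 && tpl[4] <= 30)

  expect_error(compute_template(matrix(0L, 5, 5)), "empty")
})

test_that("morphological cleanup removes stubs but preserves lung bodies", {
  # two 'lungs' joined by a 1-px bridge carrying a small airway stub
  m <- matrix(0L, 60, 90)
  m[15:45, 10:35] <- 1L
  m[15:45, 55:80] <- 1L
  m[30, 36:54] <- 1L            # 1-px bridge
  m[10:14, 44:47] <- 1L         # 20-px stub attached near the midline
  m[14, 43] <- 1L
  m[15, 36:54] <- 1L
  out <- morphological_cleanup(m, disk_element(2), min_area = 50)
  expect_equal(sum(out[10:14, 44:47]), 0)            # stub gone
  expect_true(sum(out[20:40, 12:33]) > 0.9 * sum(m[20:40, 12:33]))
  expect_true(all(out <= binary_dilate(m, disk_element(2))))

  # a solid region far outside the template passes through unchanged
  far <- matrix(0L, 80, 200)
  far[10:70, 10:60] <- 1L       # main body defines the template
  far[35:45, 180:195] <- 1L     # far structure outside the box
  tpl <- compute_template(far)
  expect_lt(tpl[4], 180)
  out2 <- morphological_cleanup(far, disk_element(2), min_area = 50)
  expect_identical(out2[35:45, 180:195], far[35:45, 180:195])

  expect_equal(sum(morphological_cleanup(matrix(0L, 10, 10))), 0)
})

test_that("remove_airways deletes the tube, keeps the lungs, and passes through without specs", {
  fx <- make_tube_fixture()
  stack <- image_stack(fx$slice)
  refined <- apply_threshold(stack, 40)
  spec <- seed_spec(1, c(20, 40), c(2, 30, 45, 50))
  out <- remove_airways(stack, refined, list(spec), stop_delta = 30)
  expect_equal(sum(out$mask$slices[[1]] * fx$tube_mask), 0)
  lab <- label_components(out$mask$slices[[1]], 8)
  expect_equal(max(lab), 2)  # two lungs survive
  expect_true(all(out$mask$slices[[1]] <= refined$slices[[1]]))

  # slice with no spec: morphological cleanup only
  out2 <- remove_airways(stack, refined, list())
  expect_identical(out2$mask$slices[[1]],
                   morphological_cleanup(refined$slices[[1]], disk_element(2), 50))

  # a background seed grows over background only and removes nothing
  bg_spec <- seed_spec(1, c(50, 40), c(46, 30, 59, 50))
  out3 <- remove_airways(stack, refined, list(bg_spec), stop_delta = 30)
  expect_identical(out3$mask$slices[[1]], out2$mask$slices[[1]])

  expect_error(remove_airways(stack, refined, list(seed_spec(9, c(20, 40),
                                                            c(2, 30, 45, 50)))),
               "nonexistent slice")
})

test_that("airway removal is idempotent in effect and never increases volume", {
  fx <- make_tube_fixture()
  stack <- image_stack(fx$slice)
  refined <- apply_threshold(stack, 40)
  spec <- seed_spec(1, c(20, 40), c(2, 30, 45, 50))
  once <- remove_airways(stack, refined, list(spec), stop_delta = 30)
  expect_lte(compute_vlv(once$mask)$total_l, compute_vlv(refined)$total_l)
  twice <- remove_airways(stack, once$mask, list(spec), stop_delta = 30)
  expect_lte(compute_vlv(twice$mask)$total_l, compute_vlv(once$mask)$total_l)
})
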