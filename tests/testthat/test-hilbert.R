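test_that("Hilbert curves are bijective with unit-step adjacency (orders 1-8)", {
  for (ord in 1:8) {
    p <- hilbert_curve(ord)
    n <- 2^ord
    expect_equal(nrow(p$coords), n^2)
    # bijection onto the grid
    key <- p$coords[, "x"] * n + p$coords[, "y"]
    expect_equal(sort(key), 0:(n^2 - 1))
    # consecutive cells are 4-neighbours
    steps <- abs(diff(p$coords[, "x"])) + abs(diff(p$coords[, "y"]))
    expect_true(all(steps == 1L))
  }
  expect_error(hilbert_curve(0), "order")
  expect_error(hilbert_curve(16), "order")
})

test_that("restriction keeps exactly H*W coordinates in curve order", {
  p <- restrict_path(hilbert_curve(2), 4, 4)
  expect_equal(nrow(p$valid_coords), 16)
  expect_equal(p$valid_coords, p$coords)

  p <- restrict_path(hilbert_curve(2), 3, 3)
  expect_equal(nrow(p$valid_coords), 9)

  # brute-force filter oracle on the enumerated order-3 curve
  full <- hilbert_curve(3)
  keep <- full$coords[, "x"] < 7 & full$coords[, "y"] < 5
  oracle <- full$coords[keep, ]
  p <- restrict_path(hilbert_curve(3), 5, 7)
  expect_equal(p$valid_coords, oracle)
  expect_equal(nrow(p$valid_coords), 35)

  expect_error(restrict_path(hilbert_curve(2), 5, 5), "order >= 3")
})

test_that("segmentation follows the frame-count formula with near-equal sizes", {
  expect_equal(n_time_frames(sonification_timing(1, 16000, 500)), 32L)
  expect_equal(n_time_frames(sonification_timing(2, 16000, 500)), 64L)

  # N_p = 10 into T = 3 frames -> sizes 4, 3, 3
  path <- restrict_path(hilbert_curve(3), 5, 2)
  tm <- sonification_timing(3, 1, 1)
  seg <- segment_path(path, tm)
  expect_equal(seg$sizes, c(4L, 3L, 3L))
  expect_lte(max(seg$sizes) - min(seg$sizes), 1L)
  # ordered union of segments reconstructs the path
  expect_equal(seg$coords, path$valid_coords)
  expect_equal(rep(seq_len(seg$n_frames), seg$sizes), seg$segment_id)

  expect_error(segment_path(path, sonification_timing(100, 1, 1)), "larger image")
})

test_that("segment averaging conserves the per-channel pixel sum", {
  set.seed(4)
  H <- 13; W <- 21
  maps <- array(runif(H * W * 4), dim = c(H, W, 4))
  seg <- segment_path(hilbert_path_for_image(H, W), sonification_timing(1, 64, 2))
  ts <- path_to_timeseries(maps, seg)
  expect_equal(dim(ts$values), c(4L, 32L))
  for (ch in 1:4) {
    # direct pixel-sum oracle: weighted frame means must total the map sum
    expect_equal(sum(seg$sizes * ts$values[ch, ]), sum(maps[, , ch]),
                 tolerance = 1e-10)
  }
  # constant map -> constant series
  maps[, , 2] <- 0.37
  ts <- path_to_timeseries(maps, seg)
  expect_equal(unname(ts$values[2, ]), rep(0.37, 32))
})

test_that("restrict->segment->average is deterministic", {
  set.seed(9)
  maps <- array(runif(20 * 20 * 2), dim = c(20, 20, 2))
  run <- function() {
    seg <- segment_path(hilbert_path_for_image(20, 20),
                        sonification_timing(1, 64, 4))
    path_to_timeseries(maps, seg)$values
  }
  expect_identical(run(), run())
})

test_that("raster path is row-major and orders match the stated examples", {
  p <- raster_path(2, 3)
  expect_equal(p$valid_coords[, "x"], c(0L, 1L, 2L, 0L, 1L, 2L))
  expect_equal(p$valid_coords[, "y"], c(0L, 0L, 0L, 1L, 1L, 1L))
  p1 <- raster_path(3, 1)
  expect_equal(p1$valid_coords[, "y"], 0:2)
})

test_that("Hilbert beats raster on typical neighbour locality and segment compactness", {
  tm <- sonification_timing(2, 16000, 500)
  for (n in c(16, 32, 64, 128)) {
    hp <- restrict_path(hilbert_curve(as.integer(log2(n))), n, n)
    rp <- raster_path(n, n)
    expect_lt(locality_score(hp), locality_score(rp))
    if (n >= 64) {   # enough pixels for the 64 default frames
      expect_lt(segment_compactness(hp, tm), segment_compactness(rp, tm))
    }
  }
  # the Hilbert median separation is exactly 1: half of all neighbour pairs
  # are consecutive on the curve
  expect_equal(locality_score(restrict_path(hilbert_curve(6), 64, 64)), 1)
})
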