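empty_mask_like <- function(vol) binary_mask(array(FALSE, dim(vol$data)),
                                             vol$spacing)

cfg_no_close <- function(...) affinity_config(closing_radius = 0, ...)

test_that("affinity follows the intensity-difference formula", {
  expect_equal(affinity(0.4, 0.4, 0.2), 1)      # identical intensities
  expect_equal(affinity(0.7, 0.5, 0.2), 0)      # |dI| == a
  expect_equal(affinity(0.9, 0.8, 0.4), 0.75)
  expect_lt(affinity(0.9, 0.1, 0.2), 0)         # may go negative
  expect_error(affinity(0.5, 0.5, 0), class = "irisseg_value_error")
})

test_that("smart click grows exactly the affinity-connected block", {
  I <- matrix(0.1, 7, 7); I[3:5, 3:5] <- 0.9
  vol <- slice_volume(I)
  out <- smart_click(vol, empty_mask_like(vol), c(1, 4, 4),
                     cfg_no_close(sensitivity_a = 0.3))
  expect_identical(out$data[1, , ], I == 0.9)  # border step 0.8 > a/2 blocks
})

test_that("a seed with no compatible neighbors stays a single voxel", {
  I <- matrix(0.1, 5, 5); I[3, 3] <- 0.9
  vol <- slice_volume(I)
  out <- smart_click(vol, empty_mask_like(vol), c(1, 3, 3), cfg_no_close())
  expect_equal(sum(out$data), 1)
  expect_true(out$data[1, 3, 3])
})

test_that("closing inside smart click fills an interior hole", {
  I <- matrix(0.1, 9, 9)
  I[3:7, 3:7] <- 0.9
  I[5, 5] <- 0.1                      # hole within the lesion
  vol <- slice_volume(I)
  grown <- smart_click(vol, empty_mask_like(vol), c(1, 3, 3),
                       cfg_no_close(sensitivity_a = 0.3))
  expect_false(grown$data[1, 5, 5])   # growth alone cannot enter the hole
  closed <- smart_click(vol, empty_mask_like(vol), c(1, 3, 3),
                        affinity_config(sensitivity_a = 0.3,
                                        closing_radius = 1))
  expect_true(closed$data[1, 5, 5])
  # matches the morphology oracle applied to the grown region
  expect_identical(closed$data[1, , ], oracle_closing(grown$data[1, , ], 1))
})

test_that("seed-comparison growth matches the brute-force oracle", {
  set.seed(101)
  for (rep in 1:20) {
    I <- random_image(16, 16)
    seed <- c(sample(16, 1), sample(16, 1))
    a <- runif(1, 0.1, 0.6)
    conn <- sample(c(4, 8), 1)
    vol <- slice_volume(I)
    out <- smart_click(vol, empty_mask_like(vol), c(1, seed),
                       cfg_no_close(sensitivity_a = a, connectivity = conn,
                                    comparison_mode = "seed"))
    expect_identical(out$data[1, , ],
                     oracle_region_seed(I, seed, a, 0.5, conn))
  }
})

test_that("chain growth is frontier-order invariant and matches the oracle", {
  set.seed(202)
  for (rep in 1:20) {
    I <- random_image(16, 16)
    seed <- c(sample(16, 1), sample(16, 1))
    a <- runif(1, 0.1, 0.6)
    bfs <- oracle_region_chain(I, seed, a, 0.5, 4, "bfs")
    dfs <- oracle_region_chain(I, seed, a, 0.5, 4, "dfs")
    expect_identical(bfs, dfs)
    vol <- slice_volume(I)
    out <- smart_click(vol, empty_mask_like(vol), c(1, seed),
                       cfg_no_close(sensitivity_a = a))
    expect_identical(out$data[1, , ], bfs)
  }
})

test_that("removal erases only the clicked component", {
  # bright tube plus bright sphere, both already segmented (vessel-inclusion
  # error); one click into the tube must leave the sphere intact
  I <- matrix(0.35, 32, 32)
  tube <- row(I) %in% 20:24 & col(I) %in% 4:30
  dd <- sqrt((row(I) - 10)^2 + (col(I) - 10)^2)
  sphere <- dd <= 5
  I[tube] <- 0.85; I[sphere] <- 0.9
  vol <- slice_volume(I)
  mask <- slice_mask(tube | sphere)
  out <- anti_smart_click(vol, mask, c(1, 22, 15), cfg_no_close())
  expect_identical(out$data[1, , ], sphere)
})

test_that("removal at a background voxel is a warning no-op", {
  I <- matrix(0.5, 6, 6)
  vol <- slice_volume(I)
  mask <- slice_mask(matrix(c(TRUE, FALSE), 6, 6))
  expect_warning(out <- anti_smart_click(vol, mask, c(1, 2, 2)),
                 class = "irisseg_noop_warning")
  expect_identical(out$data, mask$data)
})

test_that("removal immediately undoes a click on an empty mask", {
  set.seed(303)
  for (rep in 1:8) {
    rb <- random_blob_volume()
    seed <- rb$center
    for (mode in c("chain", "seed")) {
      cfg <- cfg_no_close(comparison_mode = mode,
                          scope = sample(c("2d", "3d"), 1))
      m0 <- empty_mask_like(rb$volume)
      m1 <- smart_click(rb$volume, m0, seed, cfg)
      expect_gt(sum(m1$data), 1)
      m2 <- anti_smart_click(rb$volume, m1, seed, cfg)
      expect_identical(m2$data, m0$data)
    }
  }
})

test_that("3D scope crosses slices, 2D scope does not", {
  arr <- array(0.1, c(3, 5, 5)); arr[, 3, 3] <- 0.9
  vol <- image_volume(arr)
  m2d <- smart_click(vol, empty_mask_like(vol), c(2, 3, 3),
                     cfg_no_close(scope = "2d"))
  expect_equal(sum(m2d$data), 1)
  m3d <- smart_click(vol, empty_mask_like(vol), c(2, 3, 3),
                     cfg_no_close(scope = "3d"))
  expect_equal(sum(m3d$data), 3)
})

test_that("paintbrush edits exactly the clicked disk", {
  m0 <- binary_mask(array(FALSE, c(2, 9, 9)))
  one <- paint(m0, c(1, 5, 5), 0, "add")
  expect_equal(sum(one$data), 1)
  five <- paint(m0, c(1, 5, 5), 1, "add")
  expect_equal(sum(five$data), 5)                 # radius-1 Euclidean disk
  expect_true(all(which(five$data, arr.ind = TRUE)[, 1] == 1))
  back <- paint(five, c(1, 5, 5), 1, "remove")
  expect_identical(back$data, m0$data)            # involution on the disk
  clipped <- paint(m0, c(2, 1, 1), 2, "add")      # disk clipped at border
  expect_equal(sum(clipped$data), 6)
  expect_error(paint(m0, c(3, 5, 5), 1, "add"), class = "irisseg_usage_error")
})

test_that("closing is extensive, idempotent, and matches the oracle", {
  m <- matrix(FALSE, 9, 9); m[3:5, 3:5] <- TRUE; m[4, 4] <- FALSE
  closed <- closing(slice_mask(m), 1)
  expect_true(closed$data[1, 4, 4])
  expect_identical(closed$data[1, , ], oracle_closing(m, 1))

  expect_identical(closing(slice_mask(m), 0)$data[1, , ], m)  # identity

  set.seed(404)
  for (rep in 1:10) {
    r <- sample(1:2, 1)
    mm <- matrix(runif(15 * 15) < 0.3, 15, 15)
    mm[1, 1] <- TRUE  # exercise the array border
    c1 <- closing(slice_mask(mm), r)
    expect_true(all(mm <= c1$data[1, , ]))                  # extensive
    expect_identical(closing(c1, r)$data, c1$data)          # idempotent
    expect_identical(c1$data[1, , ], oracle_closing(mm, r))
  }
})

test_that("click with closing is a superset of click without", {
  set.seed(505)
  for (rep in 1:5) {
    I <- random_image(20, 20)
    vol <- slice_volume(I)
    seed <- c(1, sample(20, 1), sample(20, 1))
    a <- runif(1, 0.2, 0.5)
    plain <- smart_click(vol, empty_mask_like(vol), seed,
                         cfg_no_close(sensitivity_a = a))
    closed <- smart_click(vol, empty_mask_like(vol), seed,
                          affinity_config(sensitivity_a = a,
                                          closing_radius = 1))
    expect_true(all(plain$data <= closed$data))
  }
})

test_that("growth never shrinks and removal never grows a mask", {
  set.seed(606)
  for (rep in 1:5) {
    rb <- random_blob_volume()
    m0 <- binary_mask(array(runif(prod(dim(rb$volume$data))) < 0.2,
                            dim(rb$volume$data)))
    added <- smart_click(rb$volume, m0, rb$center, affinity_config())
    expect_true(all(m0$data <= added$data))
    if (m0$data[rb$center[1], rb$center[2], rb$center[3]]) {
      removed <- anti_smart_click(rb$volume, m0, rb$center, affinity_config())
      expect_true(all(removed$data <= m0$data))
    }
  }
})
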