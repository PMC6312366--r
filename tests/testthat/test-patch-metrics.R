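test_that("a square block is one patch with textbook area, perimeter and shape", {
  cover <- matrix(0L, 20, 20)
  cover[6:15, 6:15] <- 1L                      # 10 x 10 cells of 10 m
  ps <- label_patches(landscape_grid(cover), connectivity = 8)
  expect_equal(nrow(ps$patches), 1L)
  expect_equal(ps$patches$area_m2, 1e4)        # 1 ha
  expect_equal(ps$patches$perimeter_m, 400)
  expect_equal(unname(shape_metrics(ps)), c(1, 1))
  a <- area_metrics(ps)
  expect_equal(unname(a), c(1, 1))             # ha
})

test_that("diagonal adjacency merges patches under 8- but not 4-connectivity", {
  g <- grid_from_rows(c(1L, 0L), c(0L, 1L))
  expect_equal(nrow(label_patches(g, 8)$patches), 1L)
  expect_equal(nrow(label_patches(g, 4)$patches), 2L)
})

test_that("union-find labelling matches a flood-fill oracle on random grids", {
  withr::with_seed(99, {
    for (trial in 1:100) {
      conn <- if (trial %% 2 == 0) 8 else 4
      cover <- matrix(rbinom(900, 1, runif(1, 0.2, 0.7)), 30, 30)
      ps <- label_patches(landscape_grid(cover), connectivity = conn)
      oracle <- flood_fill_oracle(cover, connectivity = conn)
      # same partition: labels must be a relabelling of each other
      expect_identical(ps$labels > 0, oracle > 0)
      key <- paste(ps$labels[ps$labels > 0], oracle[oracle > 0])
      expect_equal(length(unique(key)), max(oracle))
      expect_equal(max(ps$labels), max(oracle))
    }
  })
})

test_that("patch areas tally exactly with PLAND", {
  withr::with_seed(5, {
    cover <- matrix(rbinom(2500, 1, 0.45), 50, 50)
  })
  g <- landscape_grid(cover)
  ps <- label_patches(g)
  expect_equal(sum(ps$patches$area_m2),
               pland(g) / 100 * 50 * 50 * 100)
})

test_that("area metrics follow the weighted-mean formulas", {
  # synthetic patches: 1 ha (100 cells) and 3 ha (300 cells), far apart
  cover <- matrix(0L, 100, 100)
  cover[1:10, 1:10] <- 1L
  cover[50:59, 31:60] <- 1L
  ps <- label_patches(landscape_grid(cover))
  a <- area_metrics(ps)
  expect_equal(unname(a["area_mn"]), 2)
  expect_equal(unname(a["area_am"]), (1 + 9) / 4)   # sum(a^2)/sum(a)

  # equal-sized patches: weighted and unweighted means agree
  cover2 <- matrix(0L, 20, 20)
  cover2[1:5, 1:5] <- 1L
  cover2[10:14, 10:14] <- 1L
  a2 <- area_metrics(label_patches(landscape_grid(cover2)))
  expect_equal(unname(a2["area_mn"]), unname(a2["area_am"]))
})

test_that("shape index is 1 for squares and single cells, larger for strips", {
  strip <- matrix(0L, 10, 10)
  strip[3, 2:5] <- 1L                           # 1 x 4 cells
  s <- shape_metrics(label_patches(landscape_grid(strip)))
  expect_equal(unname(s["shape_mn"]), 0.25 * 100 / sqrt(400))  # 1.25

  single <- blank_grid(5, 5, forest_cells = 13)
  s1 <- shape_metrics(label_patches(single))
  expect_equal(unname(s1["shape_mn"]), 1)
})

test_that("every raster patch scores shape index >= 1", {
  withr::with_seed(21, {
    for (trial in 1:20) {
      cover <- matrix(rbinom(900, 1, 0.4), 30, 30)
      ps <- label_patches(landscape_grid(cover))
      p <- ps$patches
      if (nrow(p) > 0) {
        expect_true(all(0.25 * p$perimeter_m / sqrt(p$area_m2) >= 1 - 1e-12))
      }
    }
  })
})

test_that("connectance index counts patch pairs within the threshold", {
  # single patch
  one <- blank_grid(10, 10, forest_cells = 1:10)
  expect_equal(connect_index(label_patches(one)), 0)

  # two patches 3 cells apart (30 m, centre to centre) -> connected at 50 m
  two <- matrix(0L, 10, 10)
  two[5, 2] <- 1L
  two[5, 5] <- 1L
  expect_equal(connect_index(label_patches(landscape_grid(two))), 100)

  # three patches, exactly one pair within 50 m
  three <- matrix(0L, 20, 20)
  three[2, 2] <- 1L
  three[2, 5] <- 1L      # 30 m from first
  three[18, 18] <- 1L    # far from both
  expect_equal(connect_index(label_patches(landscape_grid(three))),
               100 / 3, tolerance = 1e-12)
})

test_that("connect distances agree with the exhaustive cell-pair oracle", {
  withr::with_seed(31, {
    cover <- matrix(rbinom(400, 1, 0.25), 20, 20)
  })
  ps <- label_patches(landscape_grid(cover))
  n <- nrow(ps$patches)
  expect_gte(n, 2)
  for (threshold in c(20, 50, 100)) {
    hits <- 0L
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        d <- pairwise_min_dist_oracle(ps$labels, i, j, 10)
        if (d <= threshold) hits <- hits + 1L
      }
    }
    expect_equal(connect_index(ps, threshold = threshold),
                 100 * hits / (n * (n - 1) / 2))
  }
})

test_that("connectance index is monotone in the threshold", {
  withr::with_seed(41, {
    cover <- matrix(rbinom(900, 1, 0.2), 30, 30)
  })
  ps <- label_patches(landscape_grid(cover))
  vals <- vapply(c(10, 30, 50, 80, 120), function(th) {
    connect_index(ps, threshold = th)
  }, numeric(1))
  expect_true(all(diff(vals) >= 0))
})

test_that("an empty landscape yields zero metrics throughout", {
  g <- blank_grid(10, 10)
  m <- landscape_metrics(g)
  expect_equal(unlist(m[, c("pland", "area_mn", "area_am", "shape_mn",
                            "shape_am", "connect")]),
               c(pland = 0, area_mn = 0, area_am = 0, shape_mn = 0,
                 shape_am = 0, connect = 0))
})
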