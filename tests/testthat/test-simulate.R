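half_grid <- function(seed = 5) {
  habitat_gradient(fractal_surface(seed = seed), levels = 0.5)$grids[[1]]
}

test_that("flower placement respects guilds, uniqueness and totals", {
  g <- half_grid()
  flowers <- flower_profiles()
  fl <- withr::with_seed(1, place_flowers(g, flowers))
  placed <- which(fl > 0)
  expect_equal(length(placed), 400)            # 20 species x 20 cells
  expect_equal(anyDuplicated(placed), 0L)
  cover_vec <- as.vector(g$cover)
  for (i in seq_len(nrow(flowers))) {
    cells <- which(fl == flowers$flower_id[i])
    expect_equal(length(cells), 20)
    expected <- if (flowers$guild[i] == "forest") 1L else 0L
    expect_true(all(cover_vec[cells] == expected))
  }
  fl2 <- withr::with_seed(1, place_flowers(g, flowers))
  expect_identical(fl, fl2)
})

test_that("flower placement degrades gracefully without eligible habitat", {
  allforest <- landscape_grid(matrix(1L, 50, 50))
  expect_warning(
    fl <- withr::with_seed(2, place_flowers(allforest, flower_profiles())),
    "insufficient"
  )
  flowers <- flower_profiles()
  open_ids <- flowers$flower_id[flowers$guild == "open"]
  forest_ids <- flowers$flower_id[flowers$guild == "forest"]
  expect_equal(sum(fl %in% open_ids), 0)
  expect_true(all(table(fl[fl %in% forest_ids]) == 20))
})

test_that("a partial shortfall is shared evenly across a guild's species", {
  # 30 forest cells for 10 forest species wanting 20 each
  g <- blank_grid(20, 20, forest_cells = 1:30)
  expect_warning(
    fl <- withr::with_seed(3, place_flowers(g, flower_profiles())),
    "insufficient"
  )
  forest_counts <- table(factor(fl[fl %in% 1:10], levels = 1:10))
  expect_equal(sum(forest_counts), 30)
  expect_lte(max(forest_counts) - min(forest_counts), 1)
})

test_that("nest placement honours habitat constraints", {
  bees <- bee_profiles()
  allopen <- landscape_grid(matrix(0L, 30, 30))
  nests <- suppressMessages(withr::with_seed(4, place_nests(allopen, bees)))
  expect_equal(sum(nests$absent), 9)          # all specialists
  expect_true(all(nests$absent == (bees$nest_habitat == "forest_only")))

  g <- half_grid()
  cover_vec <- as.vector(g$cover)
  for (s in 1:50) {
    nests <- withr::with_seed(s, place_nests(g, bees))
    expect_false(any(nests$absent))
    spec <- nests$cell[bees$nest_habitat == "forest_only"]
    expect_true(all(cover_vec[spec] == 1L))
  }
})

test_that("diet allocation matches group breadths and the configured pools", {
  bees <- bee_profiles()
  flowers <- flower_profiles()
  diet <- allocate_diets(bees, flowers, seed = 1)
  expect_equal(sort(unname(rowSums(diet))), sort(bees$diet_size))
  expect_equal(sum(bees$diet_size), 9 * 1 + 8 * 4 + 3 * 8)  # max 65 links

  # default: specialist diets come from the forest guild
  spec_rows <- which(bees$group == "specialist")
  forest_cols <- which(flowers$guild == "forest")
  expect_true(all(which(colSums(diet[spec_rows, , drop = FALSE]) > 0)
                  %in% forest_cols))

  # "all" pool can reach open flowers eventually
  hits_open <- vapply(1:30, function(s) {
    d <- allocate_diets(bees, flowers, seed = s, specialist_pool = "all")
    any(colSums(d[spec_rows, , drop = FALSE]) > 0 &
          flowers$guild == "open")
  }, logical(1))
  expect_true(any(hits_open))

  expect_false(identical(diet, allocate_diets(bees, flowers, seed = 2)))
  tiny <- flower_profiles(n_forest = 2L, n_open = 2L)
  expect_error(allocate_diets(bees, tiny, seed = 1), "diet size")
})

test_that("one step moves, reflects, spends energy and can kill", {
  g <- landscape_grid(matrix(0L, 10, 10))
  diet <- matrix(TRUE, 1, 1)
  flower_none <- integer(100)

  agent <- list(x = 5, y = 5, heading = 0, energy = 0.5, species_id = 1L)
  out <- withr::with_seed(1, step_agent(agent, g, flower_none, diet))
  expect_false(out$agent$alive)                 # drawn step ~2 >> 0.5
  expect_lt(out$agent$energy, 0)
  expect_gt(out$agent$energy, -10)              # one step's overshoot at most

  # agent aimed at the wall reflects back inside
  edge <- list(x = 9.9, y = 5, heading = 0, energy = 100, species_id = 1L)
  out <- withr::with_seed(2, step_agent(edge, g, flower_none, diet))
  expect_true(out$agent$x >= 0 && out$agent$x <= 10)
  expect_true(out$agent$y >= 0 && out$agent$y <= 10)
})

test_that("landing on a diet flower emits a visit; off-diet flowers do not", {
  g <- landscape_grid(matrix(0L, 10, 10))
  flower_at <- integer(100)
  flower_at[] <- 2L                              # flower species 2 everywhere
  diet_yes <- matrix(c(FALSE, TRUE), 1, 2)
  diet_no <- matrix(c(TRUE, FALSE), 1, 2)
  agent <- list(x = 5, y = 5, heading = 1, energy = 100, species_id = 1L)
  out1 <- withr::with_seed(3, step_agent(agent, g, flower_at, diet_yes))
  expect_identical(out1$visit, 2L)
  out2 <- withr::with_seed(3, step_agent(agent, g, flower_at, diet_no))
  expect_true(is.na(out2$visit))
})

test_that("simulations are reproducible and respect diet closure", {
  g <- half_grid()
  cm <- community_config()
  m1 <- run_simulation(g, cm, seed = 7)
  m2 <- run_simulation(g, cm, seed = 7)
  expect_identical(unclass(m1)[, ], unclass(m2)[, ])
  expect_false(identical(unclass(m1)[, ], unclass(run_simulation(g, cm, seed = 8))[, ]))
  # visits only where diets allow
  expect_true(all(m1[!cm$diet] == 0L))
  expect_gt(sum(m1), 0)
})

test_that("energy accounting bounds every agent's flight", {
  g <- half_grid()
  cm <- community_config()
  m <- run_simulation(g, cm, seed = 11)
  fe <- attr(m, "final_energy")
  dt <- attr(m, "death_tick")
  expect_true(all(!is.na(dt)))                   # all flights completed
  expect_true(all(fe <= 0))                      # dead means exhausted
  expect_true(all(fe > -10))                     # overshoot < one extreme step
  expect_lte(attr(m, "last_tick"), 150)
})

test_that("a landscape without flowers yields an all-zero network", {
  allopen <- landscape_grid(matrix(0L, 30, 30))
  bees <- bee_profiles(group_sizes = c(specialist = 0L, generalist = 2L,
                                       super_generalist = 1L),
                       diet_sizes = c(specialist = 1L, generalist = 2L,
                                      super_generalist = 4L))
  flowers <- flower_profiles(n_forest = 4L, n_open = 0L)  # forest-only guild
  cm <- community_config(bees, flowers,
                         allocate_diets(bees, flowers, seed = 1,
                                        specialist_pool = "all"))
  m <- suppressWarnings(run_simulation(allopen, cm, seed = 5))
  expect_true(all(m == 0L))
})

test_that("specialist lifetimes match a truncated-step Monte Carlo oracle", {
  # one generalist-like species with specialist energy, alone on open land
  bees <- bee_profiles(n_individuals = 400,
                       group_sizes = c(specialist = 0L, generalist = 1L,
                                       super_generalist = 0L),
                       diet_sizes = c(specialist = 1L, generalist = 1L,
                                      super_generalist = 1L))
  bees$energy <- 50
  flowers <- flower_profiles(n_forest = 0L, n_open = 1L)
  cm <- community_config(bees, flowers,
                         allocate_diets(bees, flowers, seed = 1,
                                        specialist_pool = "all"))
  g <- landscape_grid(matrix(0L, 100, 100))
  m <- suppressWarnings(run_simulation(g, cm, seed = 13))
  dt <- attr(m, "death_tick")

  oracle <- withr::with_seed(99, {
    vapply(1:4000, function(i) {
      steps <- pmax(rnorm(60, 2, 0.5), 0.1)
      which(cumsum(steps) >= 50)[1]
    }, numeric(1))
  })
  se <- sd(oracle) * sqrt(1 / length(dt) + 1 / length(oracle))
  expect_lt(abs(mean(dt) - mean(oracle)), 3 * se)
})

test_that("more individuals mean stochastically more recorded visits", {
  g <- half_grid()
  bees1 <- bee_profiles(n_individuals = 5)
  bees2 <- bee_profiles(n_individuals = 10)
  flowers <- flower_profiles()
  totals <- vapply(1:30, function(s) {
    d <- allocate_diets(bees1, flowers, seed = 1)
    c(sum(run_simulation(g, community_config(bees1, flowers, d), seed = s)),
      sum(run_simulation(g, community_config(bees2, flowers, d), seed = s)))
  }, numeric(2))
  expect_gt(mean(totals[2, ]), mean(totals[1, ]))
})
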