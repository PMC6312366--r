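small_design <- function(base_seed = 3) {
  experiment_design(cover_levels = c(0.3, 0.7), n_replicates = 2,
                    base_seed = base_seed)
}

test_that("the experiment table has one deterministic row per run", {
  res <- run_experiment(small_design())
  expect_equal(nrow(res), 4)
  expect_equal(res$level, c(30, 30, 70, 70))
  expect_equal(res$replicate, c(1, 2, 1, 2))
  expect_false(any(is.na(res$pland)))
  expect_true(all(res$h2 >= 0 & res$h2 <= 1, na.rm = TRUE))

  res2 <- run_experiment(small_design())
  expect_equal(res, res2)
  res3 <- run_experiment(small_design(base_seed = 4))
  expect_false(isTRUE(all.equal(res$n_visits, res3$n_visits)))
})

test_that("landscape metrics are a pure function of the grid", {
  d <- small_design()
  surf <- fractal_surface(d$hurst, seed = pollinet:::derive_seed(3, 1, 0))
  grid <- habitat_gradient(surf, d$cover_levels)$grids[[1]]
  before <- landscape_metrics(grid)
  invisible(run_simulation(grid, d$community, d$movement, seed = 1))
  expect_identical(landscape_metrics(grid), before)
})

test_that("per-level summaries compute mean and standard error", {
  toy <- tibble::tibble(level = c(0, 0, 50, 50),
                        pland = c(5, 5, 1, 3))
  s <- summarize_by_level(toy)
  expect_equal(s$se[s$level == 0], 0)
  expect_equal(s$mean[s$level == 50], 2)
  expect_equal(s$se[s$level == 50], 1)
  expect_equal(s$n, c(2, 2))
})

test_that("diet reallocation changes networks but not landscapes", {
  d <- experiment_design(cover_levels = c(0.4, 0.8), n_replicates = 1,
                         base_seed = 9)
  sens <- run_sensitivity(d, n_reallocations = 2)
  expect_equal(unique(sens$allocation), c(1, 2))
  a1 <- sens[sens$allocation == 1, ]
  a2 <- sens[sens$allocation == 2, ]
  landcols <- c("pland", "area_mn", "area_am", "shape_mn", "shape_am",
                "connect")
  expect_equal(a1[landcols], a2[landcols])
  expect_false(isTRUE(all.equal(a1$n_visits, a2$n_visits)))

  empty <- run_sensitivity(d, n_reallocations = 0)
  expect_equal(nrow(empty), 0)
})

test_that("empty configurations resolve to the default study values", {
  cfg <- validate_config(NULL, quiet = TRUE)
  expect_equal(cfg$community$n_bee_species, 20L)
  expect_equal(unlist(cfg$community$group_sizes),
               c(specialist = 9L, generalist = 8L, super_generalist = 3L))
  expect_equal(unlist(cfg$community$energies),
               c(specialist = 50, generalist = 100, super_generalist = 200))
  expect_equal(unlist(cfg$community$diet_sizes),
               c(specialist = 1L, generalist = 4L, super_generalist = 8L))
  expect_equal(cfg$movement$step_mean, 2)
  expect_equal(cfg$movement$max_ticks, 150L)
  expect_equal(cfg$experiment$hurst, 0.9)
  expect_equal(length(cfg$experiment$cover_levels), 11)

  design <- design_from_config(cfg)
  expect_equal(nrow(design$community$bees), 20)
  expect_equal(nrow(design$community$flowers), 20)
})

test_that("inconsistent configurations fail with named schema errors", {
  expect_error(
    validate_config(list(community = list(
      group_sizes = list(specialist = 10, generalist = 10,
                         super_generalist = 10)))),
    "sum to 30"
  )
  expect_error(
    validate_config(list(community = list(flowers_forest = 3))),
    "n_flower_species"
  )
  expect_error(validate_config(list(community = list(nonsense = 1))),
               "unknown config key")
  expect_error(
    validate_config(list(community = list(
      diet_sizes = list(specialist = 1, generalist = 4,
                        super_generalist = 30)))),
    "diet size"
  )
})

test_that("overrides are honoured, echoed, and readable from YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("movement:", "  step_mean: 3", "experiment:",
               "  n_replicates: 2"), path)
  expect_message(cfg <- validate_config(path), "step_mean")
  expect_equal(cfg$movement$step_mean, 3)
  expect_equal(cfg$experiment$n_replicates, 2)
  design <- design_from_config(cfg)
  expect_equal(design$movement$step_mean, 3)
  expect_equal(design$n_replicates, 2L)
})
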