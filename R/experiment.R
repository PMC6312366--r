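#' Define a deforestation experiment
#'
#' The default design mirrors the in-silico study: 11 forest-cover levels
#' (0%, 10%, ..., 100%) cut as a nested gradient from one fractal surface
#' (Hurst exponent 0.9) per replicate, 10 replicates, so 110 runs in total.
#' One diet allocation (derived from `base_seed`) is shared by every run;
#' each replicate's surface and each run's simulation get their own derived
#' seeds, so the whole experiment is a pure function of `base_seed`.
#'
#' @param cover_levels Forest-cover fractions (default `seq(0, 1, 0.1)`).
#' @param n_replicates Gradient replicates (default 10).
#' @param hurst Hurst exponent for the fractal surfaces (default 0.9).
#' @param base_seed Master seed.
#' @param n_rows,n_cols,cell_size World geometry (default 100 x 100 cells of
#'   10 m).
#' @param community A [community_config()]; by default built from
#'   [bee_profiles()] and [flower_profiles()] with diets allocated from
#'   `base_seed`.
#' @param movement A [movement_config()].
#' @param connectivity,connect_threshold Passed to [landscape_metrics()].
#' @return An object of class `experiment_design`.
#' @export
experiment_design <- function(cover_levels = seq(0, 1, by = 0.1),
                              n_replicates = 10L,
                              hurst = 0.9,
                              base_seed = 1L,
                              n_rows = 100L, n_cols = 100L, cell_size = 10,
                              community = NULL,
                              movement = movement_config(),
                              connectivity = 8, connect_threshold = 50) {
  if (n_replicates < 1L) stop("`n_replicates` must be >= 1", call. = FALSE)
  if (is.null(community)) {
    bees <- bee_profiles()
    flowers <- flower_profiles()
    community <- community_config(
      bees, flowers,
      diet = allocate_diets(bees, flowers, seed = derive_seed(base_seed))
    )
  }
  structure(
    list(cover_levels = sort(cover_levels),
         n_replicates = as.integer(n_replicates),
         hurst = hurst, base_seed = as.integer(base_seed),
         n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         cell_size = cell_size,
         community = community, movement = movement,
         connectivity = connectivity, connect_threshold = connect_threshold),
    class = "experiment_design"
  )
}

#' Run a full deforestation experiment
#'
#' For each replicate, generates one fractal surface and its nested
#' habitat-loss gradient, then for each cover level computes the six class
#' metrics and runs one foraging simulation, appending the five network
#' descriptors. Rows are sorted by (level, replicate). Deterministic given
#' the design's `base_seed`.
#'
#' @param design An [experiment_design()].
#' @param quiet Suppress per-run placement warnings for degenerate covers
#'   (0%/100%, where one flower guild has no habitat); default `TRUE`.
#' @param progress Print one line per replicate; default `FALSE`.
#' @param artifact_dir If non-`NULL`, write each run's landscape
#'   (`maps/*.asc`) and visitation matrix (`visits/*.csv`) under this
#'   directory.
#' @return Tibble with one row per run: `level` (percent cover),
#'   `replicate`, `surface_seed`, `sim_seed`, the landscape metric columns of
#'   [landscape_metrics()], the network metric columns of
#'   [network_metrics()], plus `n_visits` and `last_tick`.
#' @examples
#' \donttest{
#' res <- run_experiment(experiment_design(cover_levels = c(0.3, 0.7),
#'                                         n_replicates = 2))
#' }
#' @export
run_experiment <- function(design, quiet = TRUE, progress = FALSE,
                           artifact_dir = NULL) {
  stopifnot(inherits(design, "experiment_design"))
  if (!is.null(artifact_dir)) {
    dir.create(file.path(artifact_dir, "maps"), recursive = TRUE,
               showWarnings = FALSE)
    dir.create(file.path(artifact_dir, "visits"), recursive = TRUE,
               showWarnings = FALSE)
  }
  rows <- vector("list", design$n_replicates * length(design$cover_levels))
  k <- 0L
  for (rep_i in seq_len(design$n_replicates)) {
    surface_seed <- derive_seed(design$base_seed, rep_i, 0L)
    surface <- fractal_surface(design$hurst, seed = surface_seed,
                               n_rows = design$n_rows, n_cols = design$n_cols)
    grad <- habitat_gradient(surface, design$cover_levels,
                             cell_size = design$cell_size)
    for (lev_i in seq_along(design$cover_levels)) {
      grid <- grad$grids[[lev_i]]
      lm <- landscape_metrics(grid, connectivity = design$connectivity,
                              threshold = design$connect_threshold)
      sim_seed <- derive_seed(design$base_seed, rep_i, lev_i)
      vm <- tryCatch({
        sim_call <- function() run_simulation(grid, design$community,
                                              design$movement, seed = sim_seed)
        if (quiet) suppressWarnings(suppressMessages(sim_call())) else sim_call()
      }, error = function(e) {
        stop(sprintf("run failed at level %g%%, replicate %d, seed %d: %s",
                     100 * design$cover_levels[lev_i], rep_i, sim_seed,
                     conditionMessage(e)), call. = FALSE)
      })
      nm <- if (quiet) suppressWarnings(network_metrics(vm)) else
        network_metrics(vm)
      if (!is.null(artifact_dir)) {
        tag <- sprintf("rep%02d_cover%03d", rep_i,
                       round(100 * design$cover_levels[lev_i]))
        write_ascii_grid(grid, file.path(artifact_dir, "maps",
                                         paste0(tag, ".asc")))
        write_visit_matrix(vm, file.path(artifact_dir, "visits",
                                         paste0(tag, ".csv")))
      }
      k <- k + 1L
      rows[[k]] <- dplyr::bind_cols(
        tibble::tibble(level = 100 * design$cover_levels[lev_i],
                       replicate = rep_i,
                       surface_seed = surface_seed, sim_seed = sim_seed),
        lm, nm,
        tibble::tibble(n_visits = sum(vm),
                       last_tick = attr(vm, "last_tick"))
      )
    }
    if (progress) {
      message(sprintf("replicate %d/%d done", rep_i, design$n_replicates))
    }
  }
  out <- dplyr::bind_rows(rows)
  dplyr::arrange(out, .data$level, .data$replicate)
}

#' Per-level mean and standard error of every metric
#'
#' @param results A [run_experiment()] table.
#' @return Tibble with one row per (level, metric): `level`, `metric`,
#'   `mean`, `se`, `n`.
#' @export
summarize_by_level <- function(results) {
  metric_cols <- intersect(
    c("pland", "area_mn", "area_am", "shape_mn", "shape_am", "connect",
      "n_patches", "connectance", "nestedness", "h2", "size", "asymmetry",
      "n_links", "n_visits"),
    names(results)
  )
  results |>
    tidyr::pivot_longer(dplyr::all_of(metric_cols), names_to = "metric",
                        values_to = "value") |>
    dplyr::group_by(.data$level, .data$metric) |>
    dplyr::summarise(
      mean = mean(.data$value, na.rm = TRUE),
      se = stats::sd(.data$value, na.rm = TRUE) /
        sqrt(sum(!is.na(.data$value))),
      n = sum(!is.na(.data$value)),
      .groups = "drop"
    )
}

#' Diet-allocation sensitivity analysis
#'
#' Re-runs the full design under freshly seeded random diet allocations.
#' Landscapes (and hence landscape metrics) are identical across
#' allocations because they derive from the same `base_seed`; only the
#' network side changes.
#'
#' @param design An [experiment_design()].
#' @param n_reallocations Number of alternative allocations (0 gives an
#'   empty table).
#' @param quiet,progress Passed to [run_experiment()].
#' @return Tibble of stacked [run_experiment()] tables with an extra leading
#'   `allocation` column (1..n).
#' @export
run_sensitivity <- function(design, n_reallocations = 3L, quiet = TRUE,
                            progress = FALSE) {
  stopifnot(inherits(design, "experiment_design"))
  if (n_reallocations < 1L) {
    return(tibble::tibble(allocation = integer(0)))
  }
  out <- lapply(seq_len(n_reallocations), function(a) {
    diet <- allocate_diets(design$community$bees, design$community$flowers,
                           seed = derive_seed(design$base_seed, 0L, a))
    d2 <- design
    d2$community <- community_config(design$community$bees,
                                     design$community$flowers, diet)
    res <- run_experiment(d2, quiet = quiet, progress = progress)
    dplyr::bind_cols(tibble::tibble(allocation = a), res)
  })
  dplyr::bind_rows(out)
}

#' Plot per-level means of the network metrics
#'
#' Mean with standard-error bars of connectance, nestedness, H2' and network
#' size against percentage forest cover.
#'
#' @param results A [run_experiment()] table.
#' @return A ggplot object.
#' @export
plot_level_summary <- function(results) {
  smry <- summarize_by_level(results)
  smry <- dplyr::filter(smry, .data$metric %in%
                          c("connectance", "nestedness", "h2", "size"))
  ggplot2::ggplot(smry, ggplot2::aes(x = .data$level, y = .data$mean)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$se,
                   ymax = .data$mean + .data$se),
      width = 2) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "Forest cover (%)", y = "Mean ± SE") +
    ggplot2::theme_minimal()
}
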