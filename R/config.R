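default_config <- function() {
  list(
    community = list(
      n_bee_species = 20L,
      group_sizes = list(specialist = 9L, generalist = 8L,
                         super_generalist = 3L),
      energies = list(specialist = 50, generalist = 100,
                      super_generalist = 200),
      diet_sizes = list(specialist = 1L, generalist = 4L,
                        super_generalist = 8L),
      n_individuals = 10L,
      n_flower_species = 20L,
      flowers_forest = 10L,
      flowers_open = 10L,
      flower_cells = 20L
    ),
    movement = list(
      step_mean = 2, step_sd = 0.5, step_min = 0.1,
      turn_sd_deg = 40, max_ticks = 150L
    ),
    experiment = list(
      cover_levels = seq(0, 1, by = 0.1),
      n_replicates = 10L,
      hurst = 0.9,
      base_seed = 1L,
      connectivity = 8L,
      connect_threshold = 50,
      n_rows = 100L, n_cols = 100L, cell_size = 10
    )
  )
}

merge_section <- function(defaults, user, section, quiet) {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0L) {
    stop(sprintf("unknown config key(s) in '%s': %s", section,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.list(user[[k]]) &&
        length(user[[k]]) > 1 && !is.null(names(user[[k]]))) {
      user[[k]] <- as.list(user[[k]])
    }
    if (is.list(defaults[[k]])) {
      user[[k]] <- merge_section(defaults[[k]], as.list(user[[k]]),
                                 paste(section, k, sep = "."), quiet)
    } else if (!is.numeric(user[[k]])) {
      stop(sprintf("config key '%s.%s' must be numeric", section, k),
           call. = FALSE)
    }
    if (!quiet && !identical(unname(unlist(user[[k]])),
                             unname(unlist(defaults[[k]])))) {
      message(sprintf("config: %s.%s overridden (default %s -> %s)",
                      section, k,
                      paste(unlist(defaults[[k]]), collapse = ","),
                      paste(unlist(user[[k]]), collapse = ",")))
    }
    defaults[[k]] <- user[[k]]
  }
  defaults
}

#' Validate and resolve a study configuration
#'
#' Reads a YAML or JSON configuration file (or takes a list), fills every
#' missing key with the default study values (20 bee species in groups
#' 9/8/3 with energies 50/100/200 and diets 1/4/8, 10 individuals each; 20
#' flower species, 10 per guild, 20 cells each; mean step 2 cells, 150
#' ticks; 11 cover levels x 10 replicates at Hurst 0.9), and checks the
#' schema: unknown keys, non-numeric values, group sizes that do not sum to
#' the species count, guild splits that do not sum to the flower count, or
#' diet sizes exceeding the number of flower species are all named errors.
#' Every departure from the defaults is echoed as a message.
#'
#' @param config Path to a `.yaml`/`.yml`/`.json` file, a list, or `NULL`
#'   for pure defaults.
#' @param quiet Suppress override messages.
#' @return The fully resolved configuration list (class `pollinet_config`).
#' @export
validate_config <- function(config = NULL, quiet = FALSE) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  if (is.null(config)) config <- list()
  if (!is.list(config)) {
    stop("config must be a file path, a list, or NULL", call. = FALSE)
  }
  resolved <- merge_section(default_config(), config, "config", quiet)

  cm <- resolved$community
  gs <- unlist(cm$group_sizes)
  if (sum(gs) != cm$n_bee_species) {
    stop(sprintf("group sizes sum to %d but n_bee_species is %d",
                 sum(gs), cm$n_bee_species), call. = FALSE)
  }
  if (cm$flowers_forest + cm$flowers_open != cm$n_flower_species) {
    stop(sprintf("guild sizes sum to %d but n_flower_species is %d",
                 cm$flowers_forest + cm$flowers_open, cm$n_flower_species),
         call. = FALSE)
  }
  if (any(unlist(cm$diet_sizes) > cm$n_flower_species)) {
    stop("a diet size exceeds the number of flower species", call. = FALSE)
  }
  if (resolved$movement$step_min <= 0) {
    stop("movement.step_min must be positive", call. = FALSE)
  }
  structure(resolved, class = "pollinet_config")
}

#' Build an experiment design from a resolved configuration
#'
#' @param config A [validate_config()] result (or anything it accepts).
#' @param base_seed Optional override of the configured master seed.
#' @return An [experiment_design()].
#' @export
design_from_config <- function(config = NULL, base_seed = NULL) {
  cfg <- if (inherits(config, "pollinet_config")) config else
    validate_config(config, quiet = TRUE)
  cm <- cfg$community
  ex <- cfg$experiment
  if (!is.null(base_seed)) ex$base_seed <- as.integer(base_seed)
  bees <- bee_profiles(
    n_individuals = cm$n_individuals,
    group_sizes = unlist(cm$group_sizes),
    energies = unlist(cm$energies),
    diet_sizes = unlist(cm$diet_sizes)
  )
  flowers <- flower_profiles(
    n_cells = cm$flower_cells,
    n_forest = cm$flowers_forest,
    n_open = cm$flowers_open
  )
  community <- community_config(
    bees, flowers,
    diet = allocate_diets(bees, flowers, seed = derive_seed(ex$base_seed))
  )
  mv <- cfg$movement
  experiment_design(
    cover_levels = ex$cover_levels,
    n_replicates = ex$n_replicates,
    hurst = ex$hurst,
    base_seed = ex$base_seed,
    n_rows = ex$n_rows, n_cols = ex$n_cols, cell_size = ex$cell_size,
    community = community,
    movement = movement_config(step_mean = mv$step_mean,
                               step_sd = mv$step_sd,
                               step_min = mv$step_min,
                               turn_sd_deg = mv$turn_sd_deg,
                               max_ticks = mv$max_ticks),
    connectivity = ex$connectivity,
    connect_threshold = ex$connect_threshold
  )
}
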