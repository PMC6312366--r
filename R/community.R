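#' Default bee community profiles
#'
#' The default community holds 20 bee species in three functional groups:
#' 9 specialists (flight energy 50, diet of 1 flower species, nesting in
#' forest only), 8 generalists (energy 100, diet of 4, nesting anywhere) and
#' 3 super-generalists (energy 200, diet of 8, nesting anywhere). Energy is
#' measured in cell-lengths of flight (1 unit = 10 m at the default cell
#' size). Each species is represented by 10 individuals.
#'
#' @param n_individuals Individuals per bee species (default 10).
#' @param group_sizes Named integer vector with entries `specialist`,
#'   `generalist`, `super_generalist` (default 9/8/3).
#' @param energies,diet_sizes Named vectors (same names) overriding the
#'   per-group flight energies and diet breadths.
#' @return Tibble with columns `species_id`, `group`, `energy`, `diet_size`,
#'   `nest_habitat`, `n_individuals`.
#' @export
bee_profiles <- function(n_individuals = 10,
                         group_sizes = c(specialist = 9L, generalist = 8L,
                                         super_generalist = 3L),
                         energies = c(specialist = 50, generalist = 100,
                                      super_generalist = 200),
                         diet_sizes = c(specialist = 1L, generalist = 4L,
                                        super_generalist = 8L)) {
  req <- c("specialist", "generalist", "super_generalist")
  for (arg in list(group_sizes, energies, diet_sizes)) {
    if (!all(req %in% names(arg))) {
      stop("group parameters must name specialist, generalist and super_generalist",
           call. = FALSE)
    }
  }
  group <- rep(req, times = group_sizes[req])
  nests <- c(specialist = "forest_only", generalist = "any",
             super_generalist = "any")
  tibble::tibble(
    species_id = seq_along(group),
    group = group,
    energy = unname(energies[group]),
    diet_size = as.integer(unname(diet_sizes[group])),
    nest_habitat = unname(nests[group]),
    n_individuals = as.integer(n_individuals)
  )
}

#' Default flower community profiles
#'
#' 20 flower species split evenly between habitat guilds: 10 restricted to
#' forest and 10 to open vegetation. Each species occupies `n_cells` grid
#' cells (flower individuals) when placed.
#'
#' @param n_cells Grid cells (individuals) per flower species (default 20).
#' @param n_forest,n_open Number of species per guild (default 10 and 10).
#' @return Tibble with columns `flower_id`, `guild`, `n_cells`.
#' @export
flower_profiles <- function(n_cells = 20, n_forest = 10L, n_open = 10L) {
  tibble::tibble(
    flower_id = seq_len(n_forest + n_open),
    guild = rep(c("forest", "open"), times = c(n_forest, n_open)),
    n_cells = as.integer(n_cells)
  )
}

#' Randomly allocate flower species to bee diets
#'
#' Generalists and super-generalists draw their diets uniformly at random,
#' without replacement within each draw, from the full flower community (4
#' and 8 flower species respectively by default). Specialists — forest
#' species that nest in forest only and embody the specialized interactions
#' of intact forest — draw their single diet plant from the forest guild by
#' default; set `specialist_pool = "all"` to sample them from the whole
#' community instead. Re-allocating under a new seed is the basis of the
#' diet sensitivity analysis.
#'
#' @param bees A [bee_profiles()] tibble.
#' @param flowers A [flower_profiles()] tibble.
#' @param seed Integer seed.
#' @param specialist_pool `"forest"` (default) restricts specialist diets to
#'   forest-guild flowers; `"all"` samples them like the other groups.
#' @return Logical matrix `diet` (bee species x flower species): `TRUE`
#'   where the flower is in the bee's diet.
#' @export
allocate_diets <- function(bees, flowers, seed = 1L,
                           specialist_pool = c("forest", "all")) {
  specialist_pool <- match.arg(specialist_pool)
  n_f <- nrow(flowers)
  if (any(bees$diet_size > n_f)) {
    stop("diet size exceeds the number of flower species", call. = FALSE)
  }
  spec_pool <- if (specialist_pool == "forest" &&
                   any(flowers$guild == "forest")) {
    which(flowers$guild == "forest")
  } else {
    seq_len(n_f)
  }
  withr::with_seed(as.integer(seed), {
    diet <- matrix(FALSE, nrow = nrow(bees), ncol = n_f,
                   dimnames = list(bee = paste0("bee_", bees$species_id),
                                   flower = paste0("flower_", flowers$flower_id)))
    for (i in seq_len(nrow(bees))) {
      pool <- if (bees$group[i] == "specialist") spec_pool else seq_len(n_f)
      if (bees$diet_size[i] > length(pool)) {
        stop("diet size exceeds the specialist flower pool", call. = FALSE)
      }
      diet[i, pool[sample.int(length(pool), bees$diet_size[i])]] <- TRUE
    }
    diet
  })
}

#' Assemble a community configuration
#'
#' Bundles bee profiles, flower profiles and a diet allocation, checking
#' mutual consistency (diet matrix dimensions, diet sizes per functional
#' group, guild split).
#'
#' @param bees A [bee_profiles()] tibble.
#' @param flowers A [flower_profiles()] tibble.
#' @param diet Logical bee x flower matrix, e.g. from [allocate_diets()].
#' @return An object of class `bee_community`.
#' @export
community_config <- function(bees = bee_profiles(),
                             flowers = flower_profiles(),
                             diet = allocate_diets(bees, flowers, seed = 1L)) {
  if (!is.matrix(diet) || nrow(diet) != nrow(bees) ||
      ncol(diet) != nrow(flowers)) {
    stop("`diet` must be a bee x flower matrix matching the profiles",
         call. = FALSE)
  }
  got <- rowSums(diet)
  if (!all(got == bees$diet_size)) {
    bad <- which(got != bees$diet_size)[1]
    stop(sprintf("bee species %d has %d diet items, expected %d",
                 bees$species_id[bad], got[bad], bees$diet_size[bad]),
         call. = FALSE)
  }
  structure(
    list(bees = bees, flowers = flowers, diet = diet),
    class = "bee_community"
  )
}

#' @export
print.bee_community <- function(x, ...) {
  cat(sprintf(
    "<bee_community> %d bee species (%s), %d flower species (%d forest / %d open)\n",
    nrow(x$bees),
    paste(sprintf("%d %s", table(factor(x$bees$group,
      levels = c("specialist", "generalist", "super_generalist"))),
      c("specialist", "generalist", "super-generalist")), collapse = ", "),
    nrow(x$flowers), sum(x$flowers$guild == "forest"),
    sum(x$flowers$guild == "open")))
  invisible(x)
}

#' Movement configuration for the correlated random walk
#'
#' Each tick a bee turns by an angle drawn from a wrapped-normal
#' distribution centred on zero and moves forward by a step drawn from a
#' normal distribution truncated below, paying one unit of energy per
#' cell-length flown. Defaults: mean step 2 cells (20 m), step SD 0.5,
#' minimum step 0.1, turning-angle SD 40 degrees, and a 150-tick cap (all
#' default foraging flights finish well before it).
#'
#' @param step_mean,step_sd,step_min Step-length distribution in cell units.
#' @param turn_sd_deg SD of the turning-angle distribution, degrees.
#' @param max_ticks Maximum number of ticks per simulation.
#' @return An object of class `movement_config`.
#' @export
movement_config <- function(step_mean = 2, step_sd = 0.5, step_min = 0.1,
                            turn_sd_deg = 40, max_ticks = 150L) {
  if (step_min <= 0) stop("`step_min` must be positive", call. = FALSE)
  if (max_ticks < 1L) stop("`max_ticks` must be at least 1", call. = FALSE)
  structure(
    list(step_mean = step_mean, step_sd = step_sd, step_min = step_min,
         turn_sd_deg = turn_sd_deg, max_ticks = as.integer(max_ticks),
         boundary = "reflect"),
    class = "movement_config"
  )
}
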