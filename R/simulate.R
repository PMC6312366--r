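#' Place flower resources on a landscape
#'
#' Each flower species occupies `n_cells` distinct grid cells drawn uniformly
#' at random from the cells matching its habitat guild (forest species on
#' forest cells, open species on open cells), without replacement across all
#' species, so no cell hosts more than one flower. When a guild has fewer
#' eligible cells than demanded (e.g. at 0% or 100% forest cover), the
#' available cells are dealt round-robin across the guild's species so the
#' shortfall is shared evenly, and a warning reports it.
#'
#' Draws from the current RNG state; wrap in [withr::with_seed()] (as
#' [run_simulation()] does) for reproducible placements.
#'
#' @param grid A [landscape_grid()].
#' @param flowers A [flower_profiles()] tibble.
#' @return Integer vector of length `n_rows * n_cols` (column-major cell
#'   order): 0 where no flower grows, otherwise the occupying `flower_id`.
#' @export
place_flowers <- function(grid, flowers) {
  stopifnot(inherits(grid, "landscape_grid"))
  n <- grid$n_rows * grid$n_cols
  placement <- integer(n)
  eligible <- list(
    forest = which(as.vector(grid$cover) == 1L),
    open = which(as.vector(grid$cover) == 0L)
  )
  shortfall <- 0L
  for (guild in unique(flowers$guild)) {
    species <- which(flowers$guild == guild)
    demand <- flowers$n_cells[species]
    pool <- eligible[[guild]]
    if (length(pool) >= sum(demand)) {
      chosen <- pool[sample.int(length(pool), sum(demand))]
      placement[chosen] <- rep(flowers$flower_id[species], times = demand)
    } else if (length(pool) > 0L) {
      # shortfall: deal the available cells round-robin across species
      shortfall <- shortfall + sum(demand) - length(pool)
      chosen <- pool[sample.int(length(pool), length(pool))]
      deal <- unlist(lapply(seq_len(max(demand)), function(k) {
        flowers$flower_id[species[demand >= k]]
      }))
      placement[chosen] <- deal[seq_along(chosen)]
    } else {
      shortfall <- shortfall + sum(demand)
    }
  }
  if (shortfall > 0L) {
    warning(sprintf(
      "insufficient eligible habitat: %d flower cells could not be placed",
      shortfall), call. = FALSE)
  }
  placement
}

#' Place one nest per bee species
#'
#' Specialist species nest uniformly at random on forest cells only; if the
#' landscape has no forest the species is marked absent for the run.
#' Generalists and super-generalists nest uniformly anywhere. All individuals
#' of a species start their foraging flights from the species' nest cell.
#'
#' Draws from the current RNG state (see [place_flowers()]).
#'
#' @param grid A [landscape_grid()].
#' @param bees A [bee_profiles()] tibble.
#' @return Tibble with `species_id`, `cell` (column-major index, NA when
#'   absent), `absent`.
#' @export
place_nests <- function(grid, bees) {
  stopifnot(inherits(grid, "landscape_grid"))
  n <- grid$n_rows * grid$n_cols
  forest_cells <- which(as.vector(grid$cover) == 1L)
  cell <- integer(nrow(bees))
  absent <- logical(nrow(bees))
  for (i in seq_len(nrow(bees))) {
    if (bees$nest_habitat[i] == "forest_only") {
      if (length(forest_cells) == 0L) {
        cell[i] <- NA_integer_
        absent[i] <- TRUE
      } else {
        cell[i] <- forest_cells[sample.int(length(forest_cells), 1L)]
      }
    } else {
      cell[i] <- sample.int(n, 1L)
    }
  }
  if (any(absent)) {
    message(sprintf("%d forest-nesting species absent (no forest cells)",
                    sum(absent)))
  }
  tibble::tibble(species_id = bees$species_id, cell = cell, absent = absent)
}

# Fold a coordinate into [0, limit] by specular reflection and report
# whether the direction of travel along that axis ended up reversed.
reflect_fold <- function(z, limit) {
  pos <- limit - abs((z %% (2 * limit)) - limit)
  flip <- (floor(z / limit) %% 2) != 0
  list(pos = pos, flip = flip)
}

# One correlated-random-walk tick for all live agents (vectorised).
# state: list(x, y, heading, energy, alive, species_idx, death_tick)
# Returns updated state plus the tick's visit events (species_idx, flower_id).
advance_tick <- function(state, n_rows, n_cols, flower_at, diet, cfg, tick) {
  ia <- which(state$alive)
  m <- length(ia)
  if (m == 0L) {
    return(list(state = state, events = NULL))
  }
  turn <- rnorm(m, 0, cfg$turn_sd_deg * pi / 180)
  heading <- (state$heading[ia] + turn) %% (2 * pi)
  step <- pmax(rnorm(m, cfg$step_mean, cfg$step_sd), cfg$step_min)
  zx <- state$x[ia] + step * cos(heading)
  zy <- state$y[ia] + step * sin(heading)
  fx <- reflect_fold(zx, n_cols)
  fy <- reflect_fold(zy, n_rows)
  heading[fx$flip] <- pi - heading[fx$flip]
  heading[fy$flip] <- -heading[fy$flip]
  state$x[ia] <- fx$pos
  state$y[ia] <- fy$pos
  state$heading[ia] <- heading %% (2 * pi)
  state$energy[ia] <- state$energy[ia] - step

  # cell occupancy: 0-based (row, col) = (floor(y), floor(x)), the upper
  # boundary belonging to the last cell
  crow <- pmin(floor(state$y[ia]), n_rows - 1)
  ccol <- pmin(floor(state$x[ia]), n_cols - 1)
  cell <- as.integer(crow + ccol * n_rows + 1)
  fid <- flower_at[cell]
  sp <- state$species_idx[ia]
  hit <- fid > 0L
  hit[hit] <- diet[cbind(sp[hit], fid[hit])]

  dead <- state$energy[ia] <= 0
  state$alive[ia[dead]] <- FALSE
  state$death_tick[ia[dead]] <- tick

  events <- if (any(hit)) {
    list(species_idx = sp[hit], flower_id = fid[hit])
  }
  list(state = state, events = events)
}

#' Advance a single bee agent by one tick
#'
#' One step of the correlated random walk: the heading is perturbed by a
#' wrapped-normal turning angle, a truncated-normal step is taken (reflecting
#' specularly off world boundaries), energy falls by the distance flown, and
#' a visit is recorded if the agent lands in a cell hosting a flower in its
#' diet. An agent whose energy reaches zero or below after the move dies; it
#' still completes the move, so flight paths are not truncated at death.
#'
#' @param agent List with `x`, `y` (cell units), `heading` (radians),
#'   `energy` (cell-lengths), `species_id`.
#' @param grid A [landscape_grid()].
#' @param flower_at Placement vector from [place_flowers()].
#' @param diet Logical bee x flower matrix.
#' @param movement A [movement_config()].
#' @return List with the updated `agent` (plus `alive`) and `visit` (the
#'   flower id visited this tick, or `NA`).
#' @export
step_agent <- function(agent, grid, flower_at, diet,
                       movement = movement_config()) {
  state <- list(
    x = agent$x, y = agent$y, heading = agent$heading, energy = agent$energy,
    alive = TRUE, species_idx = agent$species_id, death_tick = NA_integer_
  )
  out <- advance_tick(state, grid$n_rows, grid$n_cols, flower_at, diet,
                      movement, tick = 1L)
  s <- out$state
  list(
    agent = list(x = s$x, y = s$y, heading = s$heading, energy = s$energy,
                 species_id = agent$species_id, alive = s$alive),
    visit = if (is.null(out$events)) NA_integer_ else out$events$flower_id
  )
}

#' Run one foraging simulation
#'
#' Places flowers and nests, releases all bee individuals from their species'
#' nests with independent uniform headings, and advances every living agent
#' each tick by the correlated random walk until all flight energy is
#' exhausted or `max_ticks` is reached. Flower visits (agent coincident with
#' a flower cell of its diet after a move) are summed into a bee-species by
#' flower-species visitation matrix — the raw pollination network. The run
#' is a pure function of `(grid, community, movement, seed)`.
#'
#' @param grid A [landscape_grid()].
#' @param community A [community_config()].
#' @param movement A [movement_config()].
#' @param seed Integer seed for all randomness in the run.
#' @param trajectories If `TRUE`, also record per-tick agent positions
#'   (useful for debugging; off by default).
#' @return An integer visitation matrix (bee species x flower species) of
#'   class `visit_matrix`, with attributes `seed`, `death_tick` and
#'   `final_energy` (per agent), `last_tick` (first tick by which every
#'   agent was dead, or `max_ticks` if any survived), `absent_species`, and
#'   optionally `trajectories`.
#' @examples
#' g <- habitat_gradient(fractal_surface(seed = 5), levels = 0.5)$grids[[1]]
#' m <- run_simulation(g, community_config(), seed = 42)
#' sum(m)  # total recorded visits
#' @export
run_simulation <- function(grid, community, movement = movement_config(),
                           seed = 1L, trajectories = FALSE) {
  stopifnot(inherits(grid, "landscape_grid"),
            inherits(community, "bee_community"),
            inherits(movement, "movement_config"))
  bees <- community$bees
  flowers <- community$flowers
  diet <- community$diet
  if (ncol(diet) != nrow(flowers)) {
    stop("diet matrix does not match the flower community", call. = FALSE)
  }
  n_rows <- grid$n_rows
  n_cols <- grid$n_cols

  res <- withr::with_seed(as.integer(seed), {
    flower_at <- place_flowers(grid, flowers)
    nests <- place_nests(grid, bees)
    present <- !nests$absent
    idx <- rep(which(present), times = bees$n_individuals[present])
    n_agents <- length(idx)
    nest_cell <- nests$cell[idx]
    nrow0 <- (nest_cell - 1L) %% n_rows       # 0-based
    ncol0 <- (nest_cell - 1L) %/% n_rows
    state <- list(
      x = ncol0 + 0.5,
      y = nrow0 + 0.5,
      heading = runif(n_agents, 0, 2 * pi),
      energy = bees$energy[idx],
      alive = rep(TRUE, n_agents),
      species_idx = idx,
      death_tick = rep(NA_integer_, n_agents)
    )
    visits <- matrix(0L, nrow = nrow(bees), ncol = nrow(flowers),
                     dimnames = dimnames(diet))
    traj <- if (trajectories) vector("list", movement$max_ticks)
    last_tick <- 0L
    for (tick in seq_len(movement$max_ticks)) {
      if (!any(state$alive)) break
      out <- advance_tick(state, n_rows, n_cols, flower_at, diet,
                          movement, tick)
      state <- out$state
      if (!is.null(out$events)) {
        lin <- out$events$species_idx + (out$events$flower_id - 1L) * nrow(bees)
        tab <- tabulate(lin, nbins = length(visits))
        visits <- visits + tab
      }
      if (trajectories) {
        traj[[tick]] <- tibble::tibble(
          tick = tick, agent = seq_len(n_agents),
          species_id = bees$species_id[idx],
          x = state$x, y = state$y, energy = state$energy,
          alive = state$alive
        )
      }
      last_tick <- tick
    }
    list(visits = visits, state = state, nests = nests, traj = traj,
         last_tick = last_tick, n_agents = n_agents)
  })

  visits <- res$visits
  class(visits) <- c("visit_matrix", class(visits))
  attr(visits, "seed") <- as.integer(seed)
  attr(visits, "death_tick") <- res$state$death_tick
  attr(visits, "final_energy") <- res$state$energy
  attr(visits, "last_tick") <-
    if (any(res$state$alive)) movement$max_ticks else max(res$state$death_tick, 0L)
  attr(visits, "absent_species") <-
    res$nests$species_id[res$nests$absent]
  attr(visits, "n_agents") <- res$n_agents
  if (trajectories) {
    attr(visits, "trajectories") <- dplyr::bind_rows(res$traj)
  }
  visits
}

#' @export
print.visit_matrix <- function(x, ...) {
  cat(sprintf(
    "<visit_matrix> %d bee x %d flower species, %d visits over %d links (seed %d)\n",
    nrow(x), ncol(x), sum(x), sum(x > 0), attr(x, "seed")))
  invisible(x)
}

#' Write / read a visitation matrix as labelled CSV
#'
#' Rows are bee species, columns flower species; the first column holds the
#' bee species labels.
#'
#' @param m A visit matrix (any integer matrix with dimnames).
#' @param path File path.
#' @return `read_visit_matrix()` returns an integer matrix;
#'   `write_visit_matrix()` returns `path` invisibly.
#' @export
write_visit_matrix <- function(m, path) {
  df <- data.frame(species = rownames(m), m, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_visit_matrix
#' @export
read_visit_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df[[1]]
  m
}
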