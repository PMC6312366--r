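#' Delineate forest patches in a binary landscape
#'
#' Partitions forest cells into maximal connected components using a two-pass
#' union-find labelling. Patch ids are assigned in order of each patch's first
#' cell in row-major order, so labelling is deterministic.
#'
#' @param grid A [landscape_grid()].
#' @param connectivity Neighbourhood rule, 4 (rook) or 8 (queen, the
#'   FRAGSTATS default).
#' @return An object of class `patch_set`: list with `labels` (integer matrix,
#'   0 = open), `patches` (tibble with `id`, `n_cells`, `area_m2`,
#'   `perimeter_m`), `cell_size`, `connectivity`. Zero forest cells give an
#'   empty patch table.
#' @export
label_patches <- function(grid, connectivity = 8) {
  stopifnot(inherits(grid, "landscape_grid"))
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(4L, 8L)) {
    stop("`connectivity` must be 4 or 8", call. = FALSE)
  }
  cover <- grid$cover
  nr <- grid$n_rows
  nc <- grid$n_cols

  lbl <- matrix(0L, nr, nc)
  parent <- integer(0)
  find_root <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }

  n_lab <- 0L
  for (r in seq_len(nr)) {
    for (cl in seq_len(nc)) {
      if (cover[r, cl] != 1L) next
      nbr <- integer(0)
      if (cl > 1L && lbl[r, cl - 1L] > 0L) nbr <- c(nbr, lbl[r, cl - 1L])
      if (r > 1L) {
        if (lbl[r - 1L, cl] > 0L) nbr <- c(nbr, lbl[r - 1L, cl])
        if (connectivity == 8L) {
          if (cl > 1L && lbl[r - 1L, cl - 1L] > 0L) {
            nbr <- c(nbr, lbl[r - 1L, cl - 1L])
          }
          if (cl < nc && lbl[r - 1L, cl + 1L] > 0L) {
            nbr <- c(nbr, lbl[r - 1L, cl + 1L])
          }
        }
      }
      if (length(nbr) == 0L) {
        n_lab <- n_lab + 1L
        parent[n_lab] <- n_lab
        lbl[r, cl] <- n_lab
      } else {
        roots <- vapply(unique(nbr), find_root, integer(1))
        keep <- min(roots)
        lbl[r, cl] <- keep
        for (rt in roots) parent[rt] <- keep
      }
    }
  }

  if (n_lab > 0L) {
    # resolve unions, then renumber by first row-major occurrence
    root_of <- vapply(seq_len(n_lab), find_root, integer(1))
    lt <- t(lbl)  # row-major traversal
    idx <- which(lt > 0L)
    roots_seq <- root_of[lt[idx]]
    new_id <- integer(n_lab)
    first_seen <- !duplicated(roots_seq)
    new_id[roots_seq[first_seen]] <- seq_len(sum(first_seen))
    lt[idx] <- new_id[roots_seq]
    lbl <- t(lt)
  }

  patches <- patch_table(lbl, grid$cell_size)
  structure(
    list(labels = lbl, patches = patches, cell_size = grid$cell_size,
         n_rows = nr, n_cols = nc, connectivity = connectivity),
    class = "patch_set"
  )
}

# Per-patch cell counts and raster perimeters (4-neighbour edge rule:
# an edge contributes when the adjacent cell is open or off-grid).
patch_table <- function(lbl, cell_size) {
  ids <- sort(unique(lbl[lbl > 0L]))
  if (length(ids) == 0L) {
    return(tibble::tibble(id = integer(0), n_cells = integer(0),
                          area_m2 = numeric(0), perimeter_m = numeric(0)))
  }
  nr <- nrow(lbl)
  nc <- ncol(lbl)
  pad <- matrix(0L, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- lbl
  core <- pad[2:(nr + 1L), 2:(nc + 1L)]
  forest <- core > 0L
  open_edges <-
    (pad[1:nr, 2:(nc + 1L)] == 0L) +
    (pad[3:(nr + 2L), 2:(nc + 1L)] == 0L) +
    (pad[2:(nr + 1L), 1:nc] == 0L) +
    (pad[2:(nr + 1L), 3:(nc + 2L)] == 0L)
  n_cells <- tabulate(core[forest], nbins = max(ids))
  perim_cells <- vapply(
    ids, function(i) sum(open_edges[core == i]), numeric(1)
  )
  tibble::tibble(
    id = ids,
    n_cells = n_cells[ids],
    area_m2 = n_cells[ids] * cell_size^2,
    perimeter_m = perim_cells * cell_size
  )
}

#' Percentage of landscape covered by forest (PLAND)
#'
#' @param grid A [landscape_grid()].
#' @return Percentage in \[0, 100\].
#' @export
pland <- function(grid) {
  stopifnot(inherits(grid, "landscape_grid"))
  100 * mean(grid$cover == 1L)
}

#' Patch area metrics (AREA_MN, AREA_AM)
#'
#' Mean patch area and area-weighted mean patch area, in hectares. The
#' area-weighted mean weights each patch by its proportional contribution to
#' total forest area, so AREA_AM = sum(a_i^2) / sum(a_i).
#'
#' @param patches A [label_patches()] result.
#' @return Named numeric vector `c(area_mn, area_am)` in ha; both 0 when
#'   there are no patches.
#' @export
area_metrics <- function(patches) {
  stopifnot(inherits(patches, "patch_set"))
  a <- patches$patches$area_m2 / 1e4
  if (length(a) == 0L) {
    return(c(area_mn = 0, area_am = 0))
  }
  c(area_mn = mean(a), area_am = sum(a^2) / sum(a))
}

#' Patch shape metrics (SHAPE_MN, SHAPE_AM)
#'
#' Per-patch shape index \eqn{0.25 p / \sqrt{a}} (perimeter in m, area in
#' m^2); the 0.25 constant makes a square patch score exactly 1, and larger
#' values indicate more irregular shapes. `shape_mn` is the unweighted mean,
#' `shape_am` the area-weighted mean.
#'
#' @param patches A [label_patches()] result.
#' @return Named numeric vector `c(shape_mn, shape_am)`; both 0 when there
#'   are no patches.
#' @export
shape_metrics <- function(patches) {
  stopifnot(inherits(patches, "patch_set"))
  p <- patches$patches
  if (nrow(p) == 0L) {
    return(c(shape_mn = 0, shape_am = 0))
  }
  shp <- 0.25 * p$perimeter_m / sqrt(p$area_m2)
  w <- p$area_m2 / sum(p$area_m2)
  c(shape_mn = mean(shp), shape_am = sum(w * shp))
}

#' Landscape connectance index (CONNECT)
#'
#' Percentage of patch pairs whose minimum Euclidean distance between cell
#' centres is within a functional threshold (default 50 m, an assumed bee
#' gap-crossing ability), relative to all n(n-1)/2 possible pairs. Returns 0
#' when there are fewer than two patches.
#'
#' @param patches A [label_patches()] result.
#' @param threshold Functional distance threshold in metres (default 50);
#'   pairs at exactly the threshold count as connected.
#' @return Percentage in \[0, 100\].
#' @export
connect_index <- function(patches, threshold = 50) {
  stopifnot(inherits(patches, "patch_set"))
  n <- nrow(patches$patches)
  if (n <= 1L) {
    return(0)
  }
  cs <- patches$cell_size
  lbl <- patches$labels
  nr <- nrow(lbl)
  nc <- ncol(lbl)

  # only patch boundary cells can realise the minimum separation
  pad <- matrix(0L, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- lbl
  core <- pad[2:(nr + 1L), 2:(nc + 1L)]
  is_boundary <- core > 0L & (
    pad[1:nr, 2:(nc + 1L)] != core |
    pad[3:(nr + 2L), 2:(nc + 1L)] != core |
    pad[2:(nr + 1L), 1:nc] != core |
    pad[2:(nr + 1L), 3:(nc + 2L)] != core
  )
  idx <- which(is_boundary)
  brow <- (idx - 1L) %% nr + 1L
  bcol <- (idx - 1L) %/% nr + 1L
  blab <- core[idx]
  bx <- (bcol - 0.5) * cs
  by <- (brow - 0.5) * cs

  cells <- split(data.frame(x = bx, y = by), blab)
  bbox <- lapply(cells, function(d) {
    c(xmin = min(d$x), xmax = max(d$x), ymin = min(d$y), ymax = max(d$y))
  })

  ids <- names(cells)
  connected <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      bi <- bbox[[i]]
      bj <- bbox[[j]]
      gx <- max(0, max(bi["xmin"], bj["xmin"]) - min(bi["xmax"], bj["xmax"]))
      gy <- max(0, max(bi["ymin"], bj["ymin"]) - min(bi["ymax"], bj["ymax"]))
      if (sqrt(gx^2 + gy^2) > threshold) next
      di <- cells[[i]]
      dj <- cells[[j]]
      d2 <- outer(di$x, dj$x, `-`)^2 + outer(di$y, dj$y, `-`)^2
      if (min(d2) <= threshold^2) connected <- connected + 1L
    }
  }
  100 * connected / (n * (n - 1L) / 2)
}

#' All six class metrics for one landscape
#'
#' Convenience wrapper computing PLAND, AREA_MN, AREA_AM, SHAPE_MN, SHAPE_AM
#' and CONNECT in one pass.
#'
#' @inheritParams label_patches
#' @inheritParams connect_index
#' @return One-row tibble with columns `pland`, `area_mn`, `area_am`,
#'   `shape_mn`, `shape_am`, `connect`, `n_patches`.
#' @examples
#' g <- habitat_gradient(fractal_surface(seed = 5), levels = 0.5)$grids[[1]]
#' landscape_metrics(g)
#' @export
landscape_metrics <- function(grid, connectivity = 8, threshold = 50) {
  ps <- label_patches(grid, connectivity = connectivity)
  a <- area_metrics(ps)
  s <- shape_metrics(ps)
  tibble::tibble(
    pland = pland(grid),
    area_mn = a[["area_mn"]],
    area_am = a[["area_am"]],
    shape_mn = s[["shape_mn"]],
    shape_am = s[["shape_am"]],
    connect = connect_index(ps, threshold = threshold),
    n_patches = nrow(ps$patches)
  )
}
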