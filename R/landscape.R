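#' Generate a fractal random surface
#'
#' Builds a spatially autocorrelated real-valued surface by 2-D spectral
#' synthesis: independent complex Gaussian Fourier coefficients are scaled so
#' that spectral power falls off as \eqn{f^{-(2H+2)}} with radial frequency
#' \eqn{f}, giving a fractional-Brownian-like field whose smoothness is
#' controlled by the Hurst exponent \eqn{H}. High \eqn{H} (e.g. 0.9, the
#' default used throughout the simulation experiments) produces large, smooth,
#' clumped structure; low \eqn{H} produces rough, fine-grained structure.
#'
#' The surface is the continuous template from which binary forest/open
#' landscapes are cut by thresholding (see [habitat_gradient()]).
#'
#' @param hurst Hurst exponent in (0, 1]. Default 0.9.
#' @param seed Integer seed; the surface is a pure function of
#'   `(hurst, seed, n_rows, n_cols)`.
#' @param n_rows,n_cols Grid dimensions (default 100 x 100).
#' @return An object of class `fractal_surface`: a list with `values`
#'   (numeric `n_rows` x `n_cols` matrix), `hurst`, `seed` and `method`.
#' @examples
#' s <- fractal_surface(hurst = 0.9, seed = 5)
#' range(s$values)
#' @export
fractal_surface <- function(hurst = 0.9, seed = 1L, n_rows = 100L, n_cols = 100L) {
  if (!is.numeric(hurst) || length(hurst) != 1L || is.na(hurst) ||
      hurst <= 0 || hurst > 1) {
    stop("`hurst` must be a single value in (0, 1]", call. = FALSE)
  }
  if (n_rows < 2L || n_cols < 2L) {
    stop("grid dimensions must be at least 2 x 2", call. = FALSE)
  }
  n_rows <- as.integer(n_rows)
  n_cols <- as.integer(n_cols)

  fr <- fft_frequencies(n_rows)
  fc <- fft_frequencies(n_cols)
  f2 <- outer(fr^2, fc^2, `+`)
  # amplitude ~ f^-(H+1)  <=>  power ~ f^-(2H+2); DC component suppressed
  amp <- f2^(-(hurst + 1) / 2)
  amp[1L, 1L] <- 0

  vals <- withr::with_seed(as.integer(seed), {
    n <- n_rows * n_cols
    coefs <- matrix(complex(real = rnorm(n), imaginary = rnorm(n)),
                    nrow = n_rows, ncol = n_cols)
    Re(fft(amp * coefs, inverse = TRUE)) / n
  })

  structure(
    list(values = vals, hurst = hurst, seed = as.integer(seed),
         method = "spectral_synthesis"),
    class = "fractal_surface"
  )
}

fft_frequencies <- function(n) {
  k <- 0:(n - 1L)
  k[k > n / 2] <- k[k > n / 2] - n
  k / n
}

#' Construct a binary land-cover grid
#'
#' A `landscape_grid` is the world the bee agents move over: a binary raster
#' with categories forest (1) and open (0), by default 100 x 100 cells of
#' 10 m, i.e. a 1 km^2 landscape. The world does not wrap in either direction.
#'
#' @param cover Integer matrix of 0 (open) and 1 (forest).
#' @param cell_size Cell edge length in metres (default 10).
#' @return An object of class `landscape_grid`.
#' @export
landscape_grid <- function(cover, cell_size = 10) {
  cover <- as.matrix(cover)
  if (!all(cover %in% c(0L, 1L))) {
    stop("`cover` must contain only 0 (open) and 1 (forest)", call. = FALSE)
  }
  if (nrow(cover) < 1L || ncol(cover) < 1L || cell_size <= 0) {
    stop("grid dimensions and cell size must be positive", call. = FALSE)
  }
  storage.mode(cover) <- "integer"
  structure(
    list(cover = cover, n_rows = nrow(cover), n_cols = ncol(cover),
         cell_size = cell_size, wrap = FALSE),
    class = "landscape_grid"
  )
}

#' @export
print.landscape_grid <- function(x, ...) {
  cat(sprintf("<landscape_grid> %d x %d cells of %g m, forest cover %.1f%%\n",
              x$n_rows, x$n_cols, x$cell_size,
              100 * mean(x$cover == 1L)))
  invisible(x)
}

#' Cut a nested habitat-loss gradient from a fractal surface
#'
#' Thresholds one fixed surface at a series of target forest-cover fractions.
#' A cell is forest at level \eqn{c} iff its surface value ranks within the
#' top \eqn{\lfloor c N \rfloor} of all \eqn{N} cells (descending; ties broken
#' by row-major cell order). Because every level thresholds the same ranking,
#' the forest cell set at a lower cover is always a subset of the set at any
#' higher cover — the gradient is sequential habitat loss over the same base
#' landscape. Under a high Hurst exponent high-ranked cells cluster, so
#' habitat is lost from patch edges inward and patch shape is approximately
#' preserved along the gradient.
#'
#' @param surface A [fractal_surface()].
#' @param levels Numeric vector of target forest-cover fractions in \[0, 1\].
#' @param cell_size Cell edge length in metres for the produced grids.
#' @param min_cover Floor applied to every level (default 0). Some landscape
#'   generators leave a residue of habitat in their nominal 0% treatment;
#'   setting e.g. `min_cover = 0.0079` emulates that behaviour instead of
#'   producing a truly forest-free map.
#' @return An object of class `habitat_gradient`: list with `surface`,
#'   `levels` (sorted increasing, after applying `min_cover`), and `grids`
#'   (one [landscape_grid()] per level, named by percentage cover).
#' @examples
#' g <- habitat_gradient(fractal_surface(seed = 5), levels = c(0.3, 0.7))
#' mean(g$grids[[1]]$cover)  # ~0.3
#' @export
habitat_gradient <- function(surface, levels, cell_size = 10,
                             min_cover = 0) {
  stopifnot(inherits(surface, "fractal_surface"))
  if (length(levels) == 0L) {
    stop("`levels` must contain at least one cover fraction", call. = FALSE)
  }
  if (any(!is.finite(levels)) || any(levels < 0) || any(levels > 1)) {
    stop("`levels` must lie in [0, 1]", call. = FALSE)
  }
  if (anyDuplicated(levels)) {
    stop("`levels` must be distinct", call. = FALSE)
  }
  levels <- sort(unique(pmin(pmax(levels, min_cover), 1)))

  v <- surface$values
  nr <- nrow(v)
  nc <- ncol(v)
  n <- nr * nc
  # row-major index of each column-major position, for deterministic ties
  pos <- seq_len(n) - 1L
  r <- pos %% nr
  cc <- pos %/% nr
  row_major <- r * nc + cc
  rk <- integer(n)
  rk[order(-as.vector(v), row_major)] <- seq_len(n)

  grids <- lapply(levels, function(lv) {
    k <- floor(lv * n)
    cover <- matrix(as.integer(rk <= k), nrow = nr, ncol = nc)
    landscape_grid(cover, cell_size = cell_size)
  })
  names(grids) <- sprintf("%g%%", 100 * levels)

  structure(
    list(surface = surface, levels = levels, grids = grids),
    class = "habitat_gradient"
  )
}

#' Read and write Esri ASCII grid rasters
#'
#' `write_ascii_grid()` writes a [landscape_grid()] as a plain-text Esri
#' ASCII grid (header `ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`,
#' `NODATA_value`, then row-major data with the top row first). Forest is
#' coded 1 and open 0. `read_ascii_grid()` is its inverse on cover,
#' dimensions and cell size.
#'
#' @param path File path.
#' @param grid A [landscape_grid()].
#' @return `read_ascii_grid()` returns a [landscape_grid()];
#'   `write_ascii_grid()` returns `path` invisibly.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 6L) {
    stop("ASCII grid too short: need a 6-line header plus data", call. = FALSE)
  }
  header <- list()
  keys <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  for (i in 1:6) {
    parts <- strsplit(trimws(lines[[i]]), "\\s+")[[1]]
    if (length(parts) != 2L || !tolower(parts[1]) %in% keys ||
        is.na(suppressWarnings(as.numeric(parts[2])))) {
      stop(sprintf("malformed ASCII grid header at line %d: '%s'",
                   i, lines[[i]]), call. = FALSE)
    }
    header[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  for (k in c("ncols", "nrows", "cellsize")) {
    if (is.null(header[[k]])) {
      stop(sprintf("ASCII grid header missing '%s'", k), call. = FALSE)
    }
  }
  nc <- as.integer(header$ncols)
  nr <- as.integer(header$nrows)
  data_lines <- lines[-(1:6)]
  data_lines <- data_lines[nzchar(trimws(data_lines))]
  if (length(data_lines) != nr) {
    stop(sprintf("ASCII grid declares %d rows but provides %d data lines",
                 nr, length(data_lines)), call. = FALSE)
  }
  cover <- matrix(0L, nrow = nr, ncol = nc)
  for (i in seq_len(nr)) {
    vals <- suppressWarnings(
      as.numeric(strsplit(trimws(data_lines[[i]]), "\\s+")[[1]])
    )
    line_no <- 6L + i
    if (length(vals) != nc) {
      stop(sprintf(
        "ASCII grid line %d: %d columns declared but %d values provided",
        line_no, nc, length(vals)), call. = FALSE)
    }
    if (any(is.na(vals)) || !all(vals %in% c(0, 1))) {
      stop(sprintf("ASCII grid line %d: values must be binary 0/1", line_no),
           call. = FALSE)
    }
    cover[i, ] <- as.integer(vals)
  }
  landscape_grid(cover, cell_size = header$cellsize)
}

#' @rdname read_ascii_grid
#' @export
write_ascii_grid <- function(grid, path) {
  stopifnot(inherits(grid, "landscape_grid"))
  header <- c(
    sprintf("ncols %d", grid$n_cols),
    sprintf("nrows %d", grid$n_rows),
    "xllcorner 0",
    "yllcorner 0",
    sprintf("cellsize %g", grid$cell_size),
    "NODATA_value -9999"
  )
  rows <- apply(grid$cover, 1L, paste, collapse = " ")
  writeLines(c(header, rows), path)
  invisible(path)
}
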