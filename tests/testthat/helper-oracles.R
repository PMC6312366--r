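# Independent oracles used across the suite. Each is deliberately naive and
# shares no code with the implementation it checks.

# Connected-component labelling by breadth-first flood fill.
flood_fill_oracle <- function(cover, connectivity = 8) {
  nr <- nrow(cover)
  nc <- ncol(cover)
  lbl <- matrix(0L, nr, nc)
  nbrs <- if (connectivity == 8) {
    cbind(rep(-1:1, 3), rep(-1:1, each = 3))[-5, , drop = FALSE]
  } else {
    rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  }
  nxt <- 0L
  for (r0 in seq_len(nr)) {
    for (c0 in seq_len(nc)) {
      if (cover[r0, c0] != 1L || lbl[r0, c0] != 0L) next
      nxt <- nxt + 1L
      queue <- matrix(c(r0, c0), ncol = 2)
      lbl[r0, c0] <- nxt
      while (nrow(queue) > 0) {
        cur <- queue[1, ]
        queue <- queue[-1, , drop = FALSE]
        for (k in seq_len(nrow(nbrs))) {
          rr <- cur[1] + nbrs[k, 1]
          cc <- cur[2] + nbrs[k, 2]
          if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc &&
              cover[rr, cc] == 1L && lbl[rr, cc] == 0L) {
            lbl[rr, cc] <- nxt
            queue <- rbind(queue, c(rr, cc))
          }
        }
      }
    }
  }
  lbl
}

# Minimum distance between cell centres of two patches, by exhaustive
# comparison of every cell pair.
pairwise_min_dist_oracle <- function(lbl, id_a, id_b, cell_size) {
  a <- which(lbl == id_a, arr.ind = TRUE)
  b <- which(lbl == id_b, arr.ind = TRUE)
  best <- Inf
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      d <- cell_size * sqrt(sum((a[i, ] - b[j, ])^2))
      best <- min(best, d)
    }
  }
  best
}

# Moran's I with rook (4-neighbour) weights, computed directly from values.
morans_i <- function(v) {
  z <- v - mean(v)
  nr <- nrow(v)
  nc <- ncol(v)
  num <- sum(z[-nr, ] * z[-1, ]) + sum(z[, -nc] * z[, -1])
  w <- (nr - 1) * nc + nr * (nc - 1)          # each edge counted once
  (length(v) / (2 * w)) * (2 * num / sum(z^2))
}

# Shannon entropy of interaction frequencies (duplicated on purpose).
entropy_oracle <- function(m) {
  p <- m[m > 0] / sum(m)
  -sum(p * log(p))
}

# All compositions of `total` into `k` non-negative parts.
compositions <- function(total, k) {
  if (k == 1) return(matrix(total, ncol = 1))
  out <- lapply(0:total, function(first) {
    cbind(first, compositions(total - first, k - 1), deparse.level = 0)
  })
  do.call(rbind, out)
}

# Exhaustive entropy extremes over all non-negative integer matrices with
# fixed marginals, by enumerating every matrix with total <= max_total and
# grouping by marginal signature. Returns a lookup environment.
enumerate_entropy_extremes <- function(nr, nc, max_total) {
  out <- new.env(parent = emptyenv())
  for (total in 1:max_total) {
    grids <- compositions(total, nr * nc)
    for (k in seq_len(nrow(grids))) {
      m <- matrix(grids[k, ], nr, nc)
      key <- paste(c(rowSums(m), colSums(m)), collapse = ",")
      h <- entropy_oracle(m)
      cur <- out[[key]]
      if (is.null(cur)) {
        out[[key]] <- c(min = h, max = h)
      } else {
        out[[key]] <- c(min = min(cur["min"], h), max = max(cur["max"], h))
      }
    }
  }
  out
}

# A random binary matrix guaranteed to have no empty rows or columns.
random_filled_binary <- function(nr, nc, p = 0.4) {
  repeat {
    m <- matrix(rbinom(nr * nc, 1, p), nr, nc)
    if (all(rowSums(m) > 0) && all(colSums(m) > 0)) return(m)
  }
}

# Small landscape helpers.
grid_from_rows <- function(...) {
  landscape_grid(do.call(rbind, list(...)), cell_size = 10)
}

blank_grid <- function(nr, nc, forest_cells = NULL) {
  cover <- matrix(0L, nr, nc)
  if (!is.null(forest_cells)) cover[forest_cells] <- 1L
  landscape_grid(cover, cell_size = 10)
}
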