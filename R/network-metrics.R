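#' Network connectance
#'
#' The realised fraction of possible bee-flower links: number of nonzero
#' cells divided by the number of cells of the matrix. With
#' `convention = "full"` the denominator uses the full configured matrix
#' (including species that recorded no interaction); with
#' `convention = "active"` the matrix is first pruned to species with at
#' least one interaction, which is how the bipartite-network tradition
#' computes it on observed webs.
#'
#' @param m Non-negative integer matrix (bee species x flower species).
#' @param convention `"full"` (default) or `"active"`.
#' @return Fraction in \[0, 1\]; 0 (with a warning) for an all-zero matrix.
#' @export
connectance <- function(m, convention = c("full", "active")) {
  convention <- match.arg(convention)
  links <- sum(m > 0)
  if (links == 0L) {
    warning("empty interaction matrix; connectance is 0", call. = FALSE)
    return(0)
  }
  if (convention == "full") {
    links / length(m)
  } else {
    links / (sum(rowSums(m) > 0) * sum(colSums(m) > 0))
  }
}

# Drop species (rows/columns) with no interactions.
prune_active <- function(m) {
  m[rowSums(m) > 0, colSums(m) > 0, drop = FALSE]
}

#' Nestedness of an interaction matrix
#'
#' Default metric is NODF (nestedness based on overlap and decreasing fill):
#' rows and columns are ordered by decreasing marginal degree; every pair of
#' rows (and of columns) contributes 0 when the lower-degree member does not
#' have strictly fewer links, and otherwise the percentage of its links
#' shared with the higher-degree member. NODF is the mean over all pairs,
#' ranging 0 (no nested structure) to 100 (perfectly nested). Matrix
#' temperature (0 = perfectly nested, 100 = random) is available as an
#' alternative via \pkg{vegan}.
#'
#' The matrix is pruned to species with at least one interaction first;
#' fewer than two active rows or columns gives `NA`.
#'
#' @param m Non-negative matrix; only the binary structure is used.
#' @param method `"nodf"` (default) or `"temperature"`.
#' @return Metric value with attribute `method`.
#' @export
nestedness <- function(m, method = c("nodf", "temperature")) {
  method <- match.arg(method)
  b <- prune_active(as.matrix(m)) > 0
  if (nrow(b) < 2L || ncol(b) < 2L) {
    return(structure(NA_real_, method = method))
  }
  val <- if (method == "nodf") {
    nodf_value(b)
  } else {
    if (!requireNamespace("vegan", quietly = TRUE)) {
      stop("method 'temperature' requires the vegan package", call. = FALSE)
    }
    unname(vegan::nestedtemp(b * 1)$statistic)
  }
  structure(val, method = method)
}

# NODF on a binary matrix with no empty rows/columns.
nodf_value <- function(b) {
  b <- b[order(-rowSums(b)), order(-colSums(b)), drop = FALSE]
  pair_sum <- function(x) {      # x: binary matrix, pairs over rows
    k <- rowSums(x)
    n <- nrow(x)
    s <- 0
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if (k[j] < k[i]) {
          s <- s + 100 * sum(x[i, ] & x[j, ]) / k[j]
        }
      }
    }
    s
  }
  nr <- nrow(b)
  nc <- ncol(b)
  (pair_sum(b) + pair_sum(t(b))) /
    (nr * (nr - 1) / 2 + nc * (nc - 1) / 2)
}

# Shannon entropy of a count matrix's interaction frequencies.
interaction_entropy <- function(m) {
  p <- m[m > 0] / sum(m)
  -sum(p * log(p))
}

# Integer matrix with the given marginal totals whose interaction entropy is
# (approximately) extreme. Greedy construction plus a best-improvement pass
# over marginal-preserving unit swaps.
entropy_extreme_matrix <- function(r, cs, which = c("max", "min")) {
  which <- match.arg(which)
  nr <- length(r)
  nc <- length(cs)
  tot <- sum(r)
  stopifnot(tot == sum(cs))
  m <- matrix(0, nr, nc)
  if (tot == 0) return(m)

  if (which == "min") {
    # concentrate: repeatedly exhaust the largest remaining row/column
    rr <- r
    cc <- cs
    while (sum(rr) > 0) {
      i <- which.max(rr)
      j <- which.max(cc)
      a <- min(rr[i], cc[j])
      m[i, j] <- m[i, j] + a
      rr[i] <- rr[i] - a
      cc[j] <- cc[j] - a
    }
  } else {
    # spread: round the independence expectation, then repair marginals
    e <- outer(r, cs) / tot
    m <- floor(e)
    rd <- r - rowSums(m)
    cd <- cs - colSums(m)
    frac <- e - m
    ord <- order(-frac)
    for (k in ord) {
      if (sum(rd) == 0) break
      i <- (k - 1) %% nr + 1
      j <- (k - 1) %/% nr + 1
      if (rd[i] > 0 && cd[j] > 0) {
        m[i, j] <- m[i, j] + 1
        rd[i] <- rd[i] - 1
        cd[j] <- cd[j] - 1
      }
    }
    while (sum(rd) > 0) {          # mop up any remaining deficits
      i <- which(rd > 0)[1]
      j <- which(cd > 0)[1]
      a <- min(rd[i], cd[j])
      m[i, j] <- m[i, j] + a
      rd[i] <- rd[i] - a
      cd[j] <- cd[j] - a
    }
  }
  swap_improve(m, maximize = which == "max")
}

# Hill-climb over unit swaps m[i1,j1]--, m[i2,j2]--, m[i1,j2]++, m[i2,j1]++
# (which preserve both marginals), taking the best improving swap each sweep.
swap_improve <- function(m, maximize, max_sweeps = 500L) {
  tot <- sum(m)
  h <- function(a) ifelse(a > 0, -(a / tot) * log(a / tot), 0)
  for (sweep in seq_len(max_sweeps)) {
    nz <- which(m > 0, arr.ind = TRUE)
    if (nrow(nz) < 2L) break
    k <- nrow(nz)
    g <- expand.grid(p = seq_len(k), q = seq_len(k))
    g <- g[nz[g$p, 1] != nz[g$q, 1] & nz[g$p, 2] != nz[g$q, 2], , drop = FALSE]
    if (nrow(g) == 0L) break
    i1 <- nz[g$p, 1]; j1 <- nz[g$p, 2]
    i2 <- nz[g$q, 1]; j2 <- nz[g$q, 2]
    a <- m[cbind(i1, j1)]
    b <- m[cbind(i2, j2)]
    cc <- m[cbind(i1, j2)]
    d <- m[cbind(i2, j1)]
    delta <- h(a - 1) + h(b - 1) + h(cc + 1) + h(d + 1) -
      (h(a) + h(b) + h(cc) + h(d))
    if (!maximize) delta <- -delta
    best <- which.max(delta)
    if (delta[best] <= 1e-12) break
    m[i1[best], j1[best]] <- a[best] - 1
    m[i2[best], j2[best]] <- b[best] - 1
    m[i1[best], j2[best]] <- cc[best] + 1
    m[i2[best], j1[best]] <- d[best] + 1
  }
  m
}

#' H2': complementary specialization of an interaction network
#'
#' The network-level standardized two-dimensional Shannon entropy of the
#' interaction frequencies: \eqn{H_2' = (H_{2max} - H_2) / (H_{2max} -
#' H_{2min})}, where \eqn{H_2 = -\sum p_{ij} \ln p_{ij}} and the extremes
#' are taken over integer interaction matrices with the observed marginal
#' totals. 0 means interactions are as generalized as the marginals allow;
#' 1 means perfectly complementary (reciprocal) specialization. The extremes
#' are found by a greedy construction with a swap-improvement pass.
#'
#' @param m Non-negative integer matrix of interaction counts.
#' @return Value in \[0, 1\]; `NA` for an all-zero matrix; 0 when the
#'   marginals fully determine the matrix (e.g. a single active species on
#'   either side).
#' @export
h2prime <- function(m) {
  m <- as.matrix(m)
  if (any(m < 0) || any(abs(m - round(m)) > 1e-8)) {
    stop("`m` must contain non-negative integer counts", call. = FALSE)
  }
  m <- round(m)
  if (sum(m) == 0) {
    warning("empty interaction matrix; H2' undefined", call. = FALSE)
    return(NA_real_)
  }
  m <- prune_active(m)
  h2 <- interaction_entropy(m)
  r <- rowSums(m)
  cs <- colSums(m)
  h2max <- interaction_entropy(entropy_extreme_matrix(r, cs, "max"))
  h2min <- interaction_entropy(entropy_extreme_matrix(r, cs, "min"))
  if (h2max - h2min < 1e-12) {
    return(0)
  }
  min(max((h2max - h2) / (h2max - h2min), 0), 1)
}

#' Network size and web asymmetry
#'
#' Size is the number of species with at least one interaction (bees +
#' plants). Asymmetry is (plants - bees) / (plants + bees): positive when
#' plant species outnumber bee species in the realised network.
#'
#' @param m Non-negative matrix (rows = bee species, columns = plants).
#' @return List with `size` (integer) and `asymmetry` (0 when size is 0).
#' @export
network_size_asymmetry <- function(m) {
  bees <- sum(rowSums(m) > 0)
  plants <- sum(colSums(m) > 0)
  size <- bees + plants
  list(
    size = as.integer(size),
    asymmetry = if (size == 0) 0 else (plants - bees) / size
  )
}

#' All five network descriptors for one visitation matrix
#'
#' Computes connectance, nestedness (NODF), H2', network size and asymmetry.
#' Connectance here uses the active (pruned) matrix convention, matching how
#' the bipartite-network tooling computes indices on observed webs; use
#' [connectance()] directly for the full-matrix convention.
#'
#' @param m Visit matrix (bee species x flower species counts).
#' @param nestedness_method Passed to [nestedness()].
#' @return One-row tibble: `connectance`, `nestedness`, `h2`, `size`,
#'   `asymmetry`, `n_links`, `nestedness_method`.
#' @examples
#' m <- matrix(c(4, 0, 1, 3), 2, 2)
#' network_metrics(m)
#' @export
network_metrics <- function(m, nestedness_method = "nodf") {
  nest <- nestedness(m, method = nestedness_method)
  sa <- network_size_asymmetry(m)
  conn <- if (sum(m > 0) == 0) 0 else connectance(m, convention = "active")
  tibble::tibble(
    connectance = conn,
    nestedness = as.numeric(nest),
    h2 = if (sum(m) == 0) NA_real_ else h2prime(m),
    size = sa$size,
    asymmetry = sa$asymmetry,
    n_links = sum(m > 0),
    nestedness_method = attr(nest, "method")
  )
}
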