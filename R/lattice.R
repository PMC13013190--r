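# 3D lattice geometry and occupancy bookkeeping.
#
# Conventions (fixed for the whole package):
#   * sites are 0-based integer (x, y, z) triples; extents are exclusive upper bounds
#   * boundaries are clipped (non-periodic): the tumour sits inside the grid and
#     oxygen enters from the periphery, which periodic wrapping would break
#   * neighbour ordering is lexicographic in the offset (dx, dy, dz) so that RNG
#     consumption is reproducible for a fixed seed

# 26 Moore offsets in lexicographic (dx, dy, dz) order.
.moore_offsets <- local({
  g <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  g <- g[, c("dx", "dy", "dz")]
  g <- g[!(g[, 1] == 0 & g[, 2] == 0 & g[, 3] == 0), , drop = FALSE]
  storage.mode(g) <- "integer"
  dimnames(g) <- NULL
  g
})

# linear (1-based) index of 0-based sites; sites is an n x 3 matrix
.site_lin <- function(sites, extents) {
  1L + sites[, 1] + extents[1] * (sites[, 2] + extents[2] * sites[, 3])
}

# inverse of .site_lin: n x 3 matrix of 0-based coordinates
.lin_site <- function(lin, extents) {
  i <- lin - 1L
  x <- i %% extents[1]
  i <- i %/% extents[1]
  cbind(x, i %% extents[2], i %/% extents[2])
}

.as_site <- function(site) {
  site <- as.integer(site)
  if (length(site) != 3L || anyNA(site)) stop("a site is an integer (x, y, z) triple")
  site
}

.in_bounds <- function(sites, extents) {
  sites[, 1] >= 0L & sites[, 1] < extents[1] &
    sites[, 2] >= 0L & sites[, 2] < extents[2] &
    sites[, 3] >= 0L & sites[, 3] < extents[3]
}

#' Create an empty 3D lattice
#'
#' The lattice holds at most one agent per site. Occupancy is stored as an
#' integer array: `0` marks an empty site, positive entries index cancer
#' agents and negative entries index immune agents (an internal convention of
#' the simulation engine; [lattice_place()] accepts any nonzero id).
#'
#' @param extents three positive integers, the grid dimensions. Coordinates are
#'   0-based, so valid x coordinates are `0:(extents[1] - 1)` etc.
#' @return an environment of class `tme_lattice` with fields `extents` and
#'   `occ` (the occupancy array). Environments give reference semantics, which
#'   the simulation state relies on.
#' @examples
#' lat <- tme_lattice(c(10, 10, 10))
#' nrow(lattice_neighbors(lat, c(5, 5, 5)))  # 26
#' @export
tme_lattice <- function(extents) {
  extents <- as.integer(extents)
  if (length(extents) != 3L || any(is.na(extents)) || any(extents < 1L))
    stop("extents must be three positive integers")
  lat <- new.env(parent = emptyenv())
  lat$extents <- extents
  lat$occ <- array(0L, dim = extents)
  class(lat) <- "tme_lattice"
  lat
}

# lazily built prod(extents) x 26 matrix of neighbour linear indices
# (0 marks out-of-bounds); cached on the lattice for the engine's hot paths
.neighbor_matrix <- function(lat) {
  if (!is.null(lat$nbmat)) return(lat$nbmat)
  ext <- lat$extents
  n <- prod(ext)
  sites <- .lin_site(seq_len(n), ext)
  nb <- matrix(0L, n, nrow(.moore_offsets))
  for (k in seq_len(nrow(.moore_offsets))) {
    cand <- sweep(sites, 2L, .moore_offsets[k, ], "+")
    ok <- .in_bounds(cand, ext)
    v <- integer(n)
    v[ok] <- .site_lin(cand[ok, , drop = FALSE], ext)
    nb[, k] <- v
  }
  lat$nbmat <- nb
  nb
}

#' Moore neighbourhood of a lattice site
#'
#' All sites differing by at most 1 in each coordinate, excluding the site
#' itself and out-of-bounds sites: 26 sites in the interior, 17 on a face,
#' 11 on an edge and 7 in a corner. Order is deterministic (lexicographic by
#' offset).
#'
#' @param lattice a [tme_lattice()]
#' @param site integer (x, y, z), 0-based
#' @return integer matrix with one row per neighbour
#' @export
lattice_neighbors <- function(lattice, site) {
  site <- .as_site(site)
  if (!all(site >= 0L & site < lattice$extents)) stop("site out of bounds")
  nb <- sweep(.moore_offsets, 2L, site, "+")
  nb[.in_bounds(nb, lattice$extents), , drop = FALSE]
}

#' Unoccupied Moore neighbours of a site
#'
#' @inheritParams lattice_neighbors
#' @return integer matrix of empty neighbouring sites (possibly zero rows when
#'   the site is fully surrounded)
#' @export
lattice_free_neighbors <- function(lattice, site) {
  nb <- lattice_neighbors(lattice, site)
  occv <- lattice$occ[.site_lin(nb, lattice$extents)]
  nb[which(occv == 0L), , drop = FALSE]
}

# distance from each row of `sites` to its nearest row of `targets`
# (vectorised; euclidean uses a max.col trick on squared distances)
.nearest_dists <- function(sites, targets, metric = "euclidean") {
  n <- nrow(sites)
  if (metric == "euclidean") {
    d2 <- outer(sites[, 1], targets[, 1], "-")^2 +
      outer(sites[, 2], targets[, 2], "-")^2 +
      outer(sites[, 3], targets[, 3], "-")^2
    sqrt(d2[cbind(seq_len(n), max.col(-d2, ties.method = "first"))])
  } else {
    vapply(seq_len(n), function(i)
      distance_to_nearest(sites[i, ], targets, metric), numeric(1))
  }
}

#' Distance from a site to the nearest of a set of target sites
#'
#' Used for the chemotaxis bias of immune-cell movement: effectors drift
#' towards cancer cells, suppressors towards effectors. Euclidean distance on
#' lattice indices is the default metric.
#'
#' @param site integer (x, y, z)
#' @param targets integer matrix of target sites (one per row); must be
#'   nonempty
#' @param metric one of `"euclidean"`, `"manhattan"`, `"chebyshev"`
#' @return the minimum distance (nonnegative scalar)
#' @export
distance_to_nearest <- function(site, targets, metric = c("euclidean", "manhattan", "chebyshev")) {
  metric <- match.arg(metric)
  site <- .as_site(site)
  if (is.null(dim(targets))) targets <- matrix(as.integer(targets), ncol = 3L)
  if (nrow(targets) == 0L) stop("targets must be nonempty")
  d <- abs(sweep(targets, 2L, site, "-"))
  min(switch(metric,
    euclidean = sqrt(rowSums(d^2)),
    manhattan = rowSums(d),
    chebyshev = apply(d, 1L, max)
  ))
}

#' Place or remove an agent on the lattice
#'
#' Occupancy bookkeeping: at most one agent per site, and every registered
#' agent occupies exactly one site.
#'
#' @inheritParams lattice_neighbors
#' @param id nonzero integer agent identifier
#' @return the lattice, invisibly
#' @export
lattice_place <- function(lattice, site, id) {
  site <- .as_site(site)
  if (!all(site >= 0L & site < lattice$extents)) stop("site out of bounds")
  lin <- .site_lin(matrix(site, ncol = 3L), lattice$extents)
  if (lattice$occ[lin] != 0L) stop("site already occupied")
  if (id == 0L) stop("id must be nonzero")
  lattice$occ[lin] <- as.integer(id)
  invisible(lattice)
}

#' @rdname lattice_place
#' @export
lattice_remove <- function(lattice, site) {
  site <- .as_site(site)
  if (!all(site >= 0L & site < lattice$extents)) stop("site out of bounds")
  lin <- .site_lin(matrix(site, ncol = 3L), lattice$extents)
  if (lattice$occ[lin] == 0L) stop("site is empty")
  lattice$occ[lin] <- 0L
  invisible(lattice)
}

#' Number of occupied sites
#' @inheritParams lattice_neighbors
#' @export
lattice_n_agents <- function(lattice) sum(lattice$occ != 0L)

#' Sample one free neighbour uniformly at random
#'
#' Daughter placement after division: the newborn agent goes to one of the
#' free positions next to the mother, each with equal probability.
#'
#' @inheritParams lattice_neighbors
#' @return an integer site, or `NULL` when the site is fully surrounded (a
#'   valid outcome, not an error)
#' @export
sample_free_neighbor <- function(lattice, site) {
  fr <- lattice_free_neighbors(lattice, site)
  if (nrow(fr) == 0L) return(NULL)
  fr[sample.int(nrow(fr), 1L), ]
}

#' One chemotactic step of an immune cell
#'
#' The destination is sampled from the free Moore neighbours with weight
#' `exp(-bias * distance_to_nearest(neighbour, targets))`, normalised. With
#' `bias = 0`, or when `targets` is empty, the walk is an unbiased uniform
#' choice among free neighbours.
#'
#' @inheritParams distance_to_nearest
#' @param lattice a [tme_lattice()]
#' @param bias nonnegative weight parameter; larger values concentrate the
#'   step on the neighbour closest to a target
#' @return the chosen site, or `NULL` when there is no free neighbour
#' @export
biased_step <- function(lattice, site, targets, bias = 1,
                        metric = c("euclidean", "manhattan", "chebyshev")) {
  metric <- match.arg(metric)
  fr <- lattice_free_neighbors(lattice, site)
  if (nrow(fr) == 0L) return(NULL)
  if (is.null(dim(targets))) {
    targets <- if (length(targets)) matrix(as.integer(targets), ncol = 3L)
               else matrix(integer(0), ncol = 3L)
  }
  if (bias <= 0 || nrow(targets) == 0L) {
    return(fr[sample.int(nrow(fr), 1L), ])
  }
  d <- .nearest_dists(fr, targets, metric)
  w <- exp(-bias * (d - min(d)))  # shift for numerical safety; normalisation absorbs it
  fr[sample.int(nrow(fr), 1L, prob = w), ]
}
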