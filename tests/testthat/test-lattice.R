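# Lattice geometry, neighbourhoods and occupancy bookkeeping.

# brute-force neighbourhood oracle: enumerate the full 3x3x3 block and clip
oracle_neighbors <- function(site, extents) {
  out <- list()
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    p <- site + c(dx, dy, dz)
    if (all(p >= 0) && all(p < extents)) out[[length(out) + 1L]] <- p
  }
  do.call(rbind, out)
}

sort_rows <- function(m) m[order(m[, 1], m[, 2], m[, 3]), , drop = FALSE]

test_that("Moore neighbourhood sizes follow the boundary geometry", {
  lat <- tme_lattice(c(10, 10, 10))
  expect_equal(nrow(lattice_neighbors(lat, c(5, 5, 5))), 26L)
  expect_equal(nrow(lattice_neighbors(lat, c(0, 0, 0))), 7L)
  # face-centre site: one coordinate on a boundary plane
  face <- lattice_neighbors(lat, c(0, 5, 5))
  expect_equal(nrow(face), 17L)
  expect_equal(sort_rows(face), sort_rows(oracle_neighbors(c(0L, 5L, 5L), c(10, 10, 10))))
  # |neighbors| in {7, 11, 17, 26} exactly by number of boundary coordinates
  set.seed(1)
  for (k in 1:40) {
    site <- sapply(1:3, function(i) sample(0:9, 1))
    n_bound <- sum(site == 0 | site == 9)
    expected <- c(26L, 17L, 11L, 7L)[n_bound + 1L]
    nb <- lattice_neighbors(lat, site)
    expect_equal(nrow(nb), expected)
    expect_equal(sort_rows(nb), sort_rows(oracle_neighbors(site, c(10, 10, 10))))
  }
  expect_error(lattice_neighbors(lat, c(10, 5, 5)), "bounds")
})

test_that("neighbourhood relation is symmetric and deterministically ordered", {
  lat <- tme_lattice(c(6, 7, 8))
  set.seed(2)
  for (k in 1:30) {
    a <- c(sample(0:5, 1), sample(0:6, 1), sample(0:7, 1))
    nbs <- lattice_neighbors(lat, a)
    for (r in seq_len(nrow(nbs))) {
      b <- nbs[r, ]
      back <- lattice_neighbors(lat, b)
      expect_true(any(back[, 1] == a[1] & back[, 2] == a[2] & back[, 3] == a[3]))
    }
    expect_identical(nbs, lattice_neighbors(lat, a))  # fixed ordering
  }
})

test_that("free neighbours are the set difference against occupied sites", {
  lat <- tme_lattice(c(10, 10, 10))
  ctr <- c(5L, 5L, 5L)
  expect_equal(nrow(lattice_free_neighbors(lat, ctr)), 26L)
  nb <- lattice_neighbors(lat, ctr)
  set.seed(3)
  occ_rows <- sample(26, 5)
  for (i in seq_along(occ_rows)) lattice_place(lat, nb[occ_rows[i], ], i)
  fr <- lattice_free_neighbors(lat, ctr)
  expect_equal(nrow(fr), 21L)
  expect_equal(sort_rows(fr), sort_rows(nb[-occ_rows, , drop = FALSE]))
  for (r in seq_len(26)) {
    if (lat$occ[tmesim:::.site_lin(nb[r, , drop = FALSE], lat$extents)] == 0L)
      lattice_place(lat, nb[r, ], 100L + r)
  }
  expect_equal(nrow(lattice_free_neighbors(lat, ctr)), 0L)
  expect_null(sample_free_neighbor(lat, ctr))
})

test_that("distance_to_nearest matches an exhaustive pairwise scan", {
  expect_equal(distance_to_nearest(c(1, 2, 3), rbind(c(1, 2, 3))), 0)
  expect_equal(distance_to_nearest(c(0, 0, 0), rbind(c(3, 4, 0))), 5)
  expect_error(distance_to_nearest(c(0, 0, 0), matrix(integer(0), ncol = 3)),
               "nonempty")
  set.seed(4)
  targets <- cbind(sample(0:20, 50, TRUE), sample(0:20, 50, TRUE),
                   sample(0:20, 50, TRUE))
  site <- c(7L, 3L, 11L)
  oracle <- min(apply(targets, 1, function(t) sqrt(sum((t - site)^2))))
  expect_equal(distance_to_nearest(site, targets), oracle)
  # other metrics agree with their definitions
  oracle_man <- min(apply(targets, 1, function(t) sum(abs(t - site))))
  expect_equal(distance_to_nearest(site, targets, "manhattan"), oracle_man)
})

test_that("occupancy is conserved under place/remove sequences", {
  lat <- tme_lattice(c(8, 8, 8))
  set.seed(5)
  placed <- list()
  n_placed <- 0L
  for (step in 1:200) {
    if (length(placed) == 0L || stats::runif(1) < 0.6) {
      site <- c(sample(0:7, 1), sample(0:7, 1), sample(0:7, 1))
      lin <- tmesim:::.site_lin(matrix(as.integer(site), ncol = 3), lat$extents)
      if (lat$occ[lin] == 0L) {
        lattice_place(lat, site, step)
        placed[[length(placed) + 1L]] <- site
        n_placed <- n_placed + 1L
      } else {
        expect_error(lattice_place(lat, site, step), "occupied")
      }
    } else {
      k <- sample(length(placed), 1)
      lattice_remove(lat, placed[[k]])
      placed[[k]] <- NULL
      n_placed <- n_placed - 1L
    }
    expect_equal(lattice_n_agents(lat), n_placed)
  }
})

test_that("daughter placement is uniform over the free neighbourhood", {
  lat <- tme_lattice(c(9, 9, 9))
  ctr <- c(4L, 4L, 4L)
  set.seed(6)
  n <- 10000
  draws <- matrix(NA_integer_, n, 3)
  for (i in seq_len(n)) draws[i, ] <- sample_free_neighbor(lat, ctr)
  key <- paste(draws[, 1], draws[, 2], draws[, 3])
  counts <- table(key)
  expect_equal(length(counts), 26L)
  chi <- stats::chisq.test(as.vector(counts))
  expect_gt(chi$p.value, 1e-4)
  # each frequency within 3 binomial sigmas of 1/26
  p <- 1 / 26
  expect_true(all(abs(as.vector(counts) / n - p) < 3 * sqrt(p * (1 - p) / n)))
})

test_that("biased steps are uniform at bias zero and modal towards targets", {
  lat <- tme_lattice(c(9, 9, 9))
  ctr <- c(4L, 4L, 4L)
  set.seed(7)
  n <- 10000
  # unbiased limit
  key <- character(n)
  for (i in seq_len(n)) {
    d <- biased_step(lat, ctr, rbind(c(8L, 8L, 8L)), bias = 0)
    key[i] <- paste(d, collapse = ",")
  }
  counts <- table(key)
  p <- 1 / 26
  expect_true(all(abs(as.vector(counts) / n - p) < 3 * sqrt(p * (1 - p) / n)))
  # strong bias: modal destination minimises distance to the single target
  target <- rbind(c(7L, 4L, 4L))
  d <- replicate(2000, paste(biased_step(lat, ctr, target, bias = 8), collapse = ","))
  expect_equal(names(which.max(table(d))), "5,4,4")
})
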