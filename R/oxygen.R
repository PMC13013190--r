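# Oxygen reaction-diffusion field on the lattice.
#
# dC/dt = D * laplacian(C) - k_o * chi_cycling - q_c * k_o * chi_quiescent
#
# discretised with the 7-point face-neighbour Laplacian on unit grid spacing
# and explicit Euler in time (stability bound dt <= 1/(6 D)). Oxygen enters
# from the periphery: the boundary faces hold a fixed value (default 1,
# concentrations are relative to it), or, when vessel sites are configured,
# the fixed value is imposed there and the outer faces become no-flux.

# cached interior-site indices and their 6 face neighbours, keyed by extents
.oxy_cache <- new.env(parent = emptyenv())

.oxy_stencil <- function(d) {
  key <- paste(d, collapse = "x")
  if (!is.null(.oxy_cache[[key]])) return(.oxy_cache[[key]])
  sites <- .lin_site(seq_len(prod(d)), d)
  interior <- which(sites[, 1] > 0L & sites[, 1] < d[1] - 1L &
                      sites[, 2] > 0L & sites[, 2] < d[2] - 1L &
                      sites[, 3] > 0L & sites[, 3] < d[3] - 1L)
  si <- sites[interior, , drop = FALSE]
  off <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
               c(0, 0, 1), c(0, 0, -1))
  storage.mode(off) <- "integer"
  nb <- vapply(seq_len(6), function(k)
    .site_lin(sweep(si, 2L, off[k, ], "+"), d), integer(length(interior)))
  st <- list(interior = interior, nb = nb)
  .oxy_cache[[key]] <- st
  st
}

.laplacian7 <- function(C) {
  d <- dim(C)
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  # edge-duplicated shifts: gives zero-flux at faces, which is overwritten
  # wherever Dirichlet values are re-imposed after the step
  C[c(2:nx, nx), , ] + C[c(1, 1:(nx - 1)), , ] +
    C[, c(2:ny, ny), ] + C[, c(1, 1:(ny - 1)), ] +
    C[, , c(2:nz, nz)] + C[, , c(1, 1:(nz - 1))] - 6 * C
}

.face_indices <- function(d) {
  key <- paste("faces", paste(d, collapse = "x"))
  if (!is.null(.oxy_cache[[key]])) return(.oxy_cache[[key]])
  sites <- .lin_site(seq_len(prod(d)), d)
  idx <- which(sites[, 1] == 0L | sites[, 1] == d[1] - 1L |
                 sites[, 2] == 0L | sites[, 2] == d[2] - 1L |
                 sites[, 3] == 0L | sites[, 3] == d[3] - 1L)
  .oxy_cache[[key]] <- idx
  idx
}

.impose_boundary <- function(C, params) {
  if (is.null(params$vessel_sites)) {
    C[.face_indices(dim(C))] <- params$boundary
  } else {
    vs <- params$vessel_sites
    if (is.null(dim(vs))) vs <- matrix(as.integer(vs), ncol = 3L)
    C[.site_lin(vs, dim(C))] <- params$boundary
  }
  C
}

#' One explicit finite-difference step of the oxygen field
#'
#' Advances the reaction-diffusion equation by a single explicit Euler step.
#' Cycling cancer cells consume oxygen at rate `k_o` at their site; quiescent
#' cells consume `q_c * k_o`. Values are clipped at 0 and the boundary value
#' is re-imposed after the step. The step size must satisfy the explicit
#' stability bound `dt <= 1/(6 D)`; the simulation loop sub-steps
#' automatically, this low-level function refuses an unstable `dt`.
#'
#' @param field 3D numeric array of relative oxygen concentrations
#' @param cycling integer linear indices (1-based) of sites holding cycling
#'   cancer cells
#' @param quiescent linear indices of sites holding quiescent (G0) cells
#' @param params oxygen parameter block (see [tme_config()]): `D`, `k_o`,
#'   `q_c`, `boundary`, optional `vessel_sites`
#' @param dt step in hours
#' @return the updated field
#' @export
step_oxygen <- function(field, cycling = integer(0), quiescent = integer(0),
                        params = tme_config()$oxygen, dt) {
  if (dt <= 0) stop("dt must be positive")
  if (dt > 1 / (6 * params$D) + 1e-12)
    stop("unstable oxygen step: dt must satisfy dt <= 1/(6 D)")
  if (is.null(params$vessel_sites)) {
    # Dirichlet faces: only interior sites evolve, so the boundary value
    # never needs re-imposing (fast path used by the simulation loop)
    st <- .oxy_stencil(dim(field))
    field <- .impose_boundary(field, params)
    ci <- field[st$interior]
    lap <- field[st$nb[, 1]] + field[st$nb[, 2]] + field[st$nb[, 3]] +
      field[st$nb[, 4]] + field[st$nb[, 5]] + field[st$nb[, 6]] - 6 * ci
    new_int <- ci + dt * params$D * lap
    out <- field
    out[st$interior] <- new_int
  } else {
    # vessel boundary: fixed value at vessel sites, no-flux outer faces
    out <- field + dt * params$D * .laplacian7(field)
  }
  if (length(cycling)) out[cycling] <- out[cycling] - dt * params$k_o
  if (length(quiescent)) out[quiescent] <- out[quiescent] - dt * params$q_c * params$k_o
  out[out < 0] <- 0
  .impose_boundary(out, params)
}

# advance by a macro step, sub-stepping to stay within the stability bound
.advance_oxygen <- function(field, cycling, quiescent, params, dt_macro) {
  bound <- params$safety / (6 * params$D)
  nsub <- max(1L, ceiling(dt_macro / bound))
  sub <- dt_macro / nsub
  for (k in seq_len(nsub))
    field <- step_oxygen(field, cycling, quiescent, params, sub)
  field
}

#' Classify an oxygen level into proliferative / quiescent / necrotic
#'
#' Thresholds are strict-lower half-open: a cell is necrotic iff
#' `level < threshold_necrosis`, quiescent iff
#' `threshold_necrosis <= level < threshold_quiescence`, proliferative
#' otherwise (so a level exactly at the quiescence threshold is
#' proliferative).
#'
#' @param level relative oxygen level(s) in `[0, 1]`
#' @param params oxygen parameter block with the two thresholds
#' @return character vector of `"proliferative"`, `"quiescent"`, `"necrotic"`
#' @export
classify_oxygen <- function(level, params = tme_config()$oxygen) {
  if (params$threshold_necrosis >= params$threshold_quiescence)
    stop("necrosis threshold must lie below the quiescence threshold")
  if (any(level < 0 | level > 1)) stop("oxygen level must lie in [0, 1]")
  out <- rep("proliferative", length(level))
  out[level < params$threshold_quiescence] <- "quiescent"
  out[level < params$threshold_necrosis] <- "necrotic"
  out
}
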