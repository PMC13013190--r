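# Gillespie event engine: propensity assembly from population counts and
# cumulative-kill counters, exact event/waiting-time sampling, and event
# dispatch to the agent operations.
#
# Dependency structure of the propensities (all linear in the named
# quantities, with per-dependency coefficients in the rates block):
#   cancer division          ~ division rate x N_cancer
#   cancer natural death     ~ death rate x N_cancer
#   PDL1 expression          ~ base x N_PDL1- + coef x cumulative kills
#                              (by effectors, chemo, RT, DDRi)
#   effector kill            ~ kill rate x N_active_effectors
#   effector infiltration    ~ a1 x N_cancer + a2 x N_active_effectors
#                              + a3 x cumulative effector kills
#                              + post-RT infiltration boost
#   suppressor infiltration  ~ coef x cumulative effector kills
#   immune division          ~ rate x N_division-eligible immune cells
#   immune move              ~ rate x N_active immune cells
#   effector exhaustion      ~ (c_s x N_suppressors + c_p x N_PDL1+)
#                              x (1 - receptor occupancy)
#
# Events with spatial preconditions (kill, exhaustion, division placement)
# select a uniformly random eligible agent or pair and become logged no-ops
# when none is eligible.

#' Gillespie propensities of the current state
#'
#' @param state a simulation state (see [tme_initialize()])
#' @param config a [tme_config()]
#' @return named nonnegative numeric vector of per-hour propensities, one
#'   entry per event type
#' @export
tme_propensities <- function(state, config) {
  r <- config$rates
  ct <- .counts(state)
  cnt <- state$cnt
  if (ct$n_cancer < 0) stop("negative cancer count")
  kills_elim <- cnt[["kills_eff"]] + cnt[["kills_chemo"]] +
    cnt[["kills_rt"]] + cnt[["kills_ddri"]]
  ie <- r$infiltration_effector
  ex <- r$exhaustion
  boost <- rt_infiltration_boost(state$time, .rt_history(state), config$radio)
  imm <- state$imm
  ii <- seq_len(imm$n)
  elig_div <- sum(imm$alive[ii] & !imm$exhausted[ii] &
                    imm$tdiv[ii] >= config$immune$time_to_division &
                    imm$divcount[ii] < config$immune$max_divisions)
  n_active_imm <- sum(imm$alive[ii] & !imm$exhausted[ii])
  c(
    cancer_division = r$division * ct$n_cancer,
    cancer_death = r$death * ct$n_cancer,
    pdl1_expression = if (ct$n_pdl1neg > 0)
      r$pdl1_base * ct$n_pdl1neg + r$pdl1_per_kill * kills_elim else 0,
    effector_kill = r$kill * ct$n_eff_active,
    effector_infiltration = if (ct$n_cancer > 0 || ct$n_eff_active > 0 || boost > 0)
      ie[["per_cancer"]] * ct$n_cancer + ie[["per_effector"]] * ct$n_eff_active +
        ie[["per_kill"]] * cnt[["kills_eff"]] + boost else 0,
    suppressor_infiltration = r$infiltration_suppressor_per_kill * cnt[["kills_eff"]],
    immune_division = r$immune_division * elig_div,
    immune_move = r$immune_move * n_active_imm,
    effector_exhaustion = if (ct$n_eff_active > 0)
      (ex[["per_suppressor"]] * ct$n_sup + ex[["per_pdl1"]] * ct$n_pdl1pos) *
        (1 - state$ro) else 0
  )
}

#' Sample the next Gillespie event and waiting time
#'
#' Waiting time is exponential with rate `sum(p)`; the event type `k` is
#' chosen with probability `p[k] / sum(p)`. The waiting time is drawn before
#' the event type (documented RNG order, relevant for reproducibility).
#'
#' @param p a propensity vector from [tme_propensities()]
#' @return `NULL` when the total propensity is zero (no stochastic event;
#'   the caller advances to the next deterministic event), otherwise a list
#'   with `type` and `wait` (hours)
#' @export
sample_event <- function(p) {
  if (any(p < 0)) stop("propensities must be nonnegative")
  total <- sum(p)
  if (total <= 0) return(NULL)
  wait <- stats::rexp(1, total)
  k <- sample.int(length(p), 1L, prob = p)
  list(type = names(p)[k], wait = wait)
}

# --- eligibility scans -------------------------------------------------------

# adjacent (effector, cancer) pairs; matrix with cols eff, can. Pair order is
# deterministic (column-major over the neighbour-id matrix).
.kill_pairs <- function(s) {
  imm <- s$imm
  ii <- which(imm$alive[seq_len(imm$n)] & imm$role[seq_len(imm$n)] == 1L &
                !imm$exhausted[seq_len(imm$n)])
  if (!length(ii)) return(matrix(integer(0), ncol = 2L))
  ids <- .neighbor_ids(s, imm$pos[ii])
  hit <- which(ids > 0L, arr.ind = TRUE)
  if (!nrow(hit)) return(matrix(integer(0), ncol = 2L))
  cbind(ii[hit[, 1]], ids[hit])
}

# active effectors adjacent to a PDL1+ cancer cell or a suppressor
.exhaustion_eligible <- function(s) {
  imm <- s$imm
  can <- s$can
  ii <- which(imm$alive[seq_len(imm$n)] & imm$role[seq_len(imm$n)] == 1L &
                !imm$exhausted[seq_len(imm$n)])
  if (!length(ii)) return(integer(0))
  ids <- .neighbor_ids(s, imm$pos[ii])
  pdl1_adj <- matrix(ids > 0L & can$pdl1[pmax(ids, 1L)], nrow = nrow(ids))
  sup_adj <- matrix(ids < 0L & imm$role[pmax(-ids, 1L)] == 2L, nrow = nrow(ids))
  ii[rowSums(pdl1_adj | sup_adj) > 0L]
}

# --- event execution ---------------------------------------------------------

#' Execute a sampled event on the simulation state
#'
#' Dispatches to the corresponding agent operation. Events whose spatial
#' precondition fails (no division-ready cell with a free neighbour, no
#' effector adjacent to a cancer cell, ...) are executed as logged no-ops.
#' Counters feeding the propensities (cumulative kills by cause) are updated
#' and every event is appended to the event log.
#'
#' @param state a simulation state
#' @param type an event type name as returned by [sample_event()]
#' @param config a [tme_config()]
#' @return `TRUE` if the event had an effect, `FALSE` for a vacuous no-op
#' @export
execute_event <- function(state, type, config) {
  switch(type,
    cancer_division = .ev_cancer_division(state, config),
    cancer_death = .ev_cancer_death(state),
    pdl1_expression = .ev_pdl1(state),
    effector_kill = .ev_kill(state),
    effector_infiltration = .ev_infiltrate(state, config, role = 1L),
    suppressor_infiltration = .ev_infiltrate(state, config, role = 2L),
    immune_division = .ev_immune_division(state, config),
    immune_move = .ev_immune_move(state, config),
    effector_exhaustion = .ev_exhaust(state),
    stop("unknown event type: ", type)
  )
}

.ev_cancer_division <- function(s, cfg) {
  can <- s$can
  ci <- seq_len(can$n)
  pool <- if (cfg$cycle$gating) {
    which(can$alive[ci] & can$ready[ci] & can$phase[ci] != 5L)
  } else {
    which(can$alive[ci] & can$phase[ci] != 5L)
  }
  if (!length(pool)) {
    .log_event(s, "cancer_division", vacuous = TRUE)
    return(FALSE)
  }
  mother <- pool[sample.int(length(pool), 1L)]
  free <- .free_neighbor_lins(s$lat, can$pos[mother])
  if (!length(free)) {
    .log_event(s, "cancer_division", a = mother, vacuous = TRUE)
    return(FALSE)
  }
  lin <- free[sample.int(length(free), 1L)]
  # both cells restart the cycle in G1; the daughter inherits the mother's
  # PDL1 status (spatial interferon-gamma adaptive-resistance surrogate)
  can$phase[mother] <- 1L
  can$clock[mother] <- 0
  can$ready[mother] <- FALSE
  d <- .add_cancer(s, lin, phase = 1L, clock = 0, pdl1 = can$pdl1[mother])
  .log_event(s, "cancer_division", a = mother, b = d, site = lin)
  TRUE
}

.ev_cancer_death <- function(s) {
  can <- s$can
  pool <- which(can$alive[seq_len(can$n)])
  if (!length(pool)) {
    .log_event(s, "cancer_death", vacuous = TRUE)
    return(FALSE)
  }
  i <- pool[sample.int(length(pool), 1L)]
  .log_event(s, "cancer_death", a = i, site = can$pos[i], phase = can$phase[i])
  s$cnt["deaths_nat"] <- s$cnt["deaths_nat"] + 1
  .remove_cancer(s, i)
  TRUE
}

.ev_pdl1 <- function(s) {
  can <- s$can
  pool <- which(can$alive[seq_len(can$n)] & !can$pdl1[seq_len(can$n)])
  if (!length(pool)) {
    .log_event(s, "pdl1_expression", vacuous = TRUE)
    return(FALSE)
  }
  i <- pool[sample.int(length(pool), 1L)]
  can$pdl1[i] <- TRUE
  .log_event(s, "pdl1_expression", a = i, site = can$pos[i])
  TRUE
}

.ev_kill <- function(s) {
  pairs <- .kill_pairs(s)
  if (!nrow(pairs)) {
    .log_event(s, "effector_kill", vacuous = TRUE)
    return(FALSE)
  }
  pick <- pairs[sample.int(nrow(pairs), 1L), ]
  i <- pick[2]
  .log_event(s, "effector_kill", a = pick[1], b = i, site = s$can$pos[i],
             phase = s$can$phase[i])
  s$cnt["kills_eff"] <- s$cnt["kills_eff"] + 1
  .remove_cancer(s, i)
  TRUE
}

.ev_infiltrate <- function(s, cfg, role) {
  free <- which(s$lat$occ == 0L)
  type <- if (role == 1L) "effector_infiltration" else "suppressor_infiltration"
  if (!length(free)) {
    .log_event(s, type, vacuous = TRUE)
    return(FALSE)
  }
  lin <- free[sample.int(length(free), 1L)]
  lifespan <- cfg$immune$lifespan[[if (role == 1L) "effector" else "suppressor"]]
  j <- .add_immune(s, lin, role = role, lifespan = lifespan)
  .log_event(s, type, a = j, site = lin)
  TRUE
}

.ev_immune_division <- function(s, cfg) {
  imm <- s$imm
  ii <- seq_len(imm$n)
  pool <- which(imm$alive[ii] & !imm$exhausted[ii] &
                  imm$tdiv[ii] >= cfg$immune$time_to_division &
                  imm$divcount[ii] < cfg$immune$max_divisions)
  if (!length(pool)) {
    .log_event(s, "immune_division", vacuous = TRUE)
    return(FALSE)
  }
  mother <- pool[sample.int(length(pool), 1L)]
  free <- .free_neighbor_lins(s$lat, imm$pos[mother])
  if (!length(free)) {
    .log_event(s, "immune_division", a = mother, vacuous = TRUE)
    return(FALSE)
  }
  lin <- free[sample.int(length(free), 1L)]
  imm$divcount[mother] <- imm$divcount[mother] + 1L
  imm$tdiv[mother] <- 0
  # daughter inherits the (updated) division count; her clocks start at 0
  d <- .add_immune(s, lin, role = imm$role[mother],
                   divcount = imm$divcount[mother],
                   lifespan = imm$lifespan[mother])
  .log_event(s, "immune_division", a = mother, b = d, site = lin)
  TRUE
}

.ev_immune_move <- function(s, cfg) {
  imm <- s$imm
  can <- s$can
  ii <- seq_len(imm$n)
  pool <- which(imm$alive[ii] & !imm$exhausted[ii])
  if (!length(pool)) {
    .log_event(s, "immune_move", vacuous = TRUE)
    return(FALSE)
  }
  j <- pool[sample.int(length(pool), 1L)]
  ext <- s$lat$extents
  free <- .free_neighbor_lins(s$lat, imm$pos[j])
  if (!length(free)) {
    .log_event(s, "immune_move", a = j, vacuous = TRUE)
    return(FALSE)
  }
  # effectors chase cancer cells; suppressors chase active effectors
  tgt_lins <- if (imm$role[j] == 1L) {
    can$pos[which(can$alive[seq_len(can$n)])]
  } else {
    imm$pos[which(imm$alive[ii] & imm$role[ii] == 1L & !imm$exhausted[ii] &
                    seq_len(imm$n) != j)]
  }
  lin <- if (length(tgt_lins)) {
    fr <- .lin_site(free, ext)
    targets <- .lin_site(tgt_lins, ext)
    d <- .nearest_dists(fr, targets, cfg$immune$metric)
    w <- exp(-cfg$immune$bias * (d - min(d)))
    free[sample.int(length(free), 1L, prob = w)]
  } else {
    free[sample.int(length(free), 1L)]
  }
  s$lat$occ[imm$pos[j]] <- 0L
  s$lat$occ[lin] <- -j
  imm$pos[j] <- lin
  .log_event(s, "immune_move", a = j, site = lin)
  TRUE
}

.ev_exhaust <- function(s) {
  elig <- .exhaustion_eligible(s)
  if (!length(elig)) {
    .log_event(s, "effector_exhaustion", vacuous = TRUE)
    return(FALSE)
  }
  j <- elig[sample.int(length(elig), 1L)]
  # the exhausted effector becomes inactive (no move/kill/divide) but keeps
  # occupying its site until its lifespan is reached
  s$imm$exhausted[j] <- TRUE
  .log_event(s, "effector_exhaustion", a = j, site = s$imm$pos[j])
  TRUE
}

# exact SSA within one macro-step: propensities are recomputed after every
# executed event (they depend only on scalar counts, so this is cheap and
# avoids the O(rate x dt) bias of freezing them at step start)
.gillespie_step <- function(s, cfg, t_end) {
  repeat {
    p <- tme_propensities(s, cfg)
    ev <- sample_event(p)
    if (is.null(ev)) break
    if (s$time + ev$wait > t_end) break
    s$time <- s$time + ev$wait
    execute_event(s, ev$type, cfg)
  }
  s$time <- t_end
  invisible(s)
}
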