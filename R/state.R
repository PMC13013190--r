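# Simulation state: agent registries (struct-of-arrays in environments for
# in-place mutation), occupancy encoding, counters, radiation history and the
# event log.
#
# Occupancy convention: occ == 0 empty, occ == +i row i of the cancer
# registry, occ == -j row j of the immune registry. Rows are never recycled
# within a run (dead rows keep alive = FALSE), so row indices are stable and
# the event log can reference them.

.EVENT_TYPES <- c(
  "cancer_division", "cancer_death", "pdl1_expression", "effector_kill",
  "effector_infiltration", "suppressor_infiltration", "immune_division",
  "immune_move", "effector_exhaustion",
  # deterministic / treatment records
  "rt_fraction", "rt_death_cancer", "rt_death_immune",
  "chemo_death_cancer", "chemo_death_immune", "ddri_death_cancer",
  "necrosis", "quiescence_enter", "quiescence_exit", "immune_clearance"
)
.N_GILLESPIE <- 9L

.new_state <- function(cfg) {
  s <- new.env(parent = emptyenv())
  s$cfg_dt <- cfg$run$dt
  s$time <- 0
  s$lat <- tme_lattice(cfg$lattice$extents)
  s$oxy <- array(cfg$oxygen$boundary, dim = cfg$lattice$extents)

  can <- new.env(parent = emptyenv())
  can$n <- 0L
  for (f in c("pos", "phase")) can[[f]] <- integer(0)
  for (f in c("clock", "sclock", "delay")) can[[f]] <- numeric(0)
  can$sphase <- integer(0)
  for (f in c("pdl1", "ready", "sready", "alive")) can[[f]] <- logical(0)
  s$can <- can

  imm <- new.env(parent = emptyenv())
  imm$n <- 0L
  for (f in c("pos", "role", "divcount")) imm[[f]] <- integer(0)
  for (f in c("age", "tdiv", "lifespan")) imm[[f]] <- numeric(0)
  for (f in c("exhausted", "alive")) imm[[f]] <- logical(0)
  s$imm <- imm

  s$cnt <- c(kills_eff = 0, kills_chemo = 0, kills_rt = 0, kills_ddri = 0,
             deaths_nat = 0, necrosis = 0, imm_deaths_rt = 0,
             imm_deaths_chemo = 0, imm_cleared = 0)
  s$rt_times <- numeric(0)
  s$rt_doses <- numeric(0)
  s$rt_kills <- numeric(0)
  s$ro <- 0

  log <- new.env(parent = emptyenv())
  log$n <- 0L
  log$cap <- 1024L
  log$time <- numeric(1024L)
  log$type <- integer(1024L)
  log$a <- integer(1024L)
  log$b <- integer(1024L)
  log$site <- integer(1024L)
  log$phase <- integer(1024L)
  log$vacuous <- logical(1024L)
  s$log <- log
  s
}

.grow_registry <- function(reg, need) {
  cap <- length(reg$pos)
  if (need <= cap) return(invisible(reg))
  newcap <- max(need, 2L * max(cap, 16L))
  for (f in ls(reg)) {
    if (f == "n") next
    v <- reg[[f]]
    length(v) <- newcap
    reg[[f]] <- v
  }
  invisible(reg)
}

.add_cancer <- function(s, lin, phase, clock, pdl1, ready = FALSE) {
  can <- s$can
  i <- can$n + 1L
  .grow_registry(can, i)
  can$n <- i
  can$pos[i] <- lin
  can$phase[i] <- phase
  can$clock[i] <- clock
  can$sphase[i] <- NA_integer_
  can$sclock[i] <- NA_real_
  can$sready[i] <- FALSE
  can$pdl1[i] <- pdl1
  can$delay[i] <- 0
  can$ready[i] <- ready
  can$alive[i] <- TRUE
  if (s$lat$occ[lin] != 0L) stop("internal: placing cancer agent on occupied site")
  s$lat$occ[lin] <- i
  i
}

.remove_cancer <- function(s, i, debris = FALSE) {
  can <- s$can
  # NA marks persistent necrotic debris: the site stays blocked but holds no
  # live agent
  s$lat$occ[can$pos[i]] <- if (debris) NA_integer_ else 0L
  can$alive[i] <- FALSE
  can$pos[i] <- NA_integer_
  invisible(s)
}

.add_immune <- function(s, lin, role, divcount = 0L, lifespan) {
  imm <- s$imm
  j <- imm$n + 1L
  .grow_registry(imm, j)
  imm$n <- j
  imm$pos[j] <- lin
  imm$role[j] <- role  # 1 = effector, 2 = suppressor
  imm$age[j] <- 0
  imm$tdiv[j] <- 0
  imm$divcount[j] <- divcount
  imm$lifespan[j] <- lifespan
  imm$exhausted[j] <- FALSE
  imm$alive[j] <- TRUE
  if (s$lat$occ[lin] != 0L) stop("internal: placing immune agent on occupied site")
  s$lat$occ[lin] <- -j
  j
}

.remove_immune <- function(s, j) {
  imm <- s$imm
  s$lat$occ[imm$pos[j]] <- 0L
  imm$alive[j] <- FALSE
  imm$pos[j] <- NA_integer_
  invisible(s)
}

.log_event <- function(s, type, a = NA_integer_, b = NA_integer_,
                       site = NA_integer_, phase = NA_integer_,
                       vacuous = FALSE) {
  log <- s$log
  n <- log$n + 1L
  if (n > log$cap) {
    newcap <- 2L * log$cap
    for (f in c("time", "type", "a", "b", "site", "phase", "vacuous")) {
      v <- log[[f]]
      length(v) <- newcap
      log[[f]] <- v
    }
    log$cap <- newcap
  }
  log$n <- n
  log$time[n] <- s$time
  log$type[n] <- match(type, .EVENT_TYPES)
  log$a[n] <- a
  log$b[n] <- b
  log$site[n] <- site
  log$phase[n] <- phase
  log$vacuous[n] <- vacuous
  invisible(s)
}

.event_log_df <- function(s) {
  log <- s$log
  idx <- seq_len(log$n)
  data.frame(
    time = log$time[idx],
    type = .EVENT_TYPES[log$type[idx]],
    agent_a = log$a[idx],
    agent_b = log$b[idx],
    site = log$site[idx],
    phase = ifelse(is.na(log$phase[idx]), NA_character_,
                   .phase_names[log$phase[idx]]),
    vacuous = log$vacuous[idx],
    stringsAsFactors = FALSE
  )
}

# scalar population counts used by the propensities and the census
.counts <- function(s) {
  can <- s$can
  imm <- s$imm
  ci <- seq_len(can$n)
  ii <- seq_len(imm$n)
  calive <- can$alive[ci]
  ialive <- imm$alive[ii]
  eff <- ialive & imm$role[ii] == 1L
  list(
    n_cancer = sum(calive),
    n_pdl1pos = sum(calive & can$pdl1[ci]),
    n_pdl1neg = sum(calive & !can$pdl1[ci]),
    n_eff = sum(eff),
    n_eff_active = sum(eff & !imm$exhausted[ii]),
    n_exhausted = sum(eff & imm$exhausted[ii]),
    n_sup = sum(ialive & imm$role[ii] == 2L),
    n_imm = sum(ialive)
  )
}

# number of free Moore neighbours for each given linear position, via the
# cached neighbour-index matrix
.free_neighbor_counts <- function(s, lins) {
  nb <- .neighbor_matrix(s$lat)[lins, , drop = FALSE]
  occv <- matrix(s$lat$occ[pmax(nb, 1L)], nrow = nrow(nb))
  rowSums(nb > 0L & !is.na(occv) & occv == 0L)
}

# free-neighbour linear indices of a single site (engine hot path)
.free_neighbor_lins <- function(lat, lin) {
  nb <- .neighbor_matrix(lat)[lin, ]
  nb <- nb[nb > 0L]
  occv <- lat$occ[nb]
  nb[!is.na(occv) & occv == 0L]
}

# occupancy ids (0 = empty/out-of-bounds) of the 26 neighbours of each given
# position; rows align with `lins`
.neighbor_ids <- function(s, lins) {
  nb <- .neighbor_matrix(s$lat)[lins, , drop = FALSE]
  occv <- matrix(s$lat$occ[pmax(nb, 1L)], nrow = nrow(nb))
  occv[nb == 0L | is.na(occv)] <- 0L
  occv
}

.rt_history <- function(s) {
  list(times = s$rt_times, doses = s$rt_doses, kills = s$rt_kills)
}
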