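# Orchestrator: initial state from config, the hybrid loop (deterministic
# PK/oxygen/clock layers on a fixed macro-step, exact Gillespie within each
# step, scheduled doses), and the census / snapshot outputs.
#
# Macro-step order, repeated until the horizon, extinction or the lethal
# agent ceiling:
#   1. apply dose events due in the step (PK boluses are handled by the
#      precomputed trajectories; radiation fractions hit the agents here)
#   2. advance the oxygen PDE by dt and read the PK outputs at the step end
#   3. advance clocks (phase progression with delay consumption, immune
#      ageing and lifespan clearance) and apply oxygen-threshold transitions
#      (necrosis, quiescence entry/exit)
#   4. apply per-step treatment death draws (chemo on G2/M cells and immune
#      cells, DDRi on S-phase cells, both at oxygen-scaled local levels)
#   5. run the Gillespie events within the step
#   6. record census / snapshot if due

#' Build the initial simulation state
#'
#' Cancer agents are seeded as a compact sphere around the lattice centre
#' (or scattered uniformly, per config), all PDL1-negative, with cycle
#' positions drawn uniformly over the 24 h cycle (or synchronised in G1).
#' Immune agents are seeded at the configured immune:cancer ratio (default
#' 1:100) on uniformly random free sites. The oxygen field starts at the
#' boundary value everywhere.
#'
#' @param config a [tme_config()]
#' @return a simulation state environment of class `tme_state`
#' @export
tme_initialize <- function(config) {
  .validate_config(config)
  s <- .new_state(config)
  ext <- config$lattice$extents
  n0 <- config$init$n_cancer
  if (n0 > 0) {
    lins <- if (identical(config$init$geometry, "sphere")) {
      ctr <- (ext - 1) / 2
      all_sites <- .lin_site(seq_len(prod(ext)), ext)
      d2 <- (all_sites[, 1] - ctr[1])^2 + (all_sites[, 2] - ctr[2])^2 +
        (all_sites[, 3] - ctr[3])^2
      order(d2)[seq_len(n0)]  # densest packing around the centre; ties by index
    } else {
      sample.int(prod(ext), n0)
    }
    dur <- unname(config$cycle$durations)
    cum <- cumsum(dur)
    for (lin in lins) {
      if (identical(config$init$phases, "uniform")) {
        u <- stats::runif(1, 0, cum[4])
        ph <- findInterval(u, cum) + 1L
        clk <- u - c(0, cum)[ph]
      } else {
        ph <- 1L
        clk <- 0
      }
      .add_cancer(s, lin, phase = ph, clock = clk, pdl1 = FALSE)
    }
  }
  n_imm <- round(n0 * config$init$immune_ratio)
  if (n_imm > 0) {
    n_sup <- round(n_imm * config$init$suppressor_fraction)
    free <- which(s$lat$occ == 0L)
    picks <- free[sample.int(length(free), n_imm)]
    for (k in seq_len(n_imm)) {
      role <- if (k <= n_sup) 2L else 1L
      lifespan <- config$immune$lifespan[[if (role == 1L) "effector" else "suppressor"]]
      .add_immune(s, picks[k], role = role, lifespan = lifespan)
    }
  }
  class(s) <- c("tme_state", class(s))
  s
}

#' Census of a simulation state
#'
#' Exact integer counts per category; cancer phase counts sum to the alive
#' cancer count and PDL1+ plus PDL1- partition it.
#'
#' @param state a simulation state
#' @return one-row data.frame of counts and cumulative counters
#' @export
census <- function(state) {
  can <- state$can
  ci <- which(can$alive[seq_len(can$n)])
  ph <- tabulate(can$phase[ci], nbins = 5L)
  ct <- .counts(state)
  data.frame(
    time = state$time,
    cancer = ct$n_cancer,
    G1 = ph[1], S = ph[2], G2 = ph[3], M = ph[4], G0 = ph[5],
    pdl1_pos = ct$n_pdl1pos, pdl1_neg = ct$n_pdl1neg,
    eff_active = ct$n_eff_active, eff_exhausted = ct$n_exhausted,
    suppressors = ct$n_sup, immune = ct$n_imm,
    kills_effector = unname(state$cnt["kills_eff"]),
    kills_rt = unname(state$cnt["kills_rt"]),
    kills_chemo = unname(state$cnt["kills_chemo"]),
    kills_ddri = unname(state$cnt["kills_ddri"]),
    deaths_natural = unname(state$cnt["deaths_nat"]),
    necrosis = unname(state$cnt["necrosis"])
  )
}

.snapshot <- function(state) {
  can <- state$can
  imm <- state$imm
  ci <- which(can$alive[seq_len(can$n)])
  ii <- which(imm$alive[seq_len(imm$n)])
  ext <- state$lat$extents
  cs <- .lin_site(can$pos[ci], ext)
  is <- .lin_site(imm$pos[ii], ext)
  agents <- rbind(
    if (length(ci)) data.frame(type = "cancer", x = cs[, 1], y = cs[, 2], z = cs[, 3],
                               phase = .phase_names[can$phase[ci]],
                               pdl1 = can$pdl1[ci], exhausted = NA),
    if (length(ii)) data.frame(type = ifelse(imm$role[ii] == 1L, "effector", "suppressor"),
                               x = is[, 1], y = is[, 2], z = is[, 3],
                               phase = NA_character_, pdl1 = NA,
                               exhausted = imm$exhausted[ii])
  )
  list(time = state$time, agents = agents, oxygen = as.vector(state$oxy),
       extents = ext)
}

# deterministic clock layer: phase progression, immune ageing / clearance
.advance_clocks <- function(s, cfg, dt) {
  if (cfg$cycle$enabled) {
    can <- s$can
    ci <- which(can$alive[seq_len(can$n)] & can$phase[seq_len(can$n)] != 5L)
    if (length(ci)) {
      out <- .advance_cycle_core(can$phase[ci], can$clock[ci], can$delay[ci],
                                 can$ready[ci], dt, unname(cfg$cycle$durations))
      can$phase[ci] <- out$phase
      can$clock[ci] <- out$clock
      can$delay[ci] <- out$delay
      can$ready[ci] <- out$ready
    }
    imm <- s$imm
    ii <- which(imm$alive[seq_len(imm$n)])
    if (length(ii)) {
      imm$age[ii] <- imm$age[ii] + dt
      imm$tdiv[ii] <- imm$tdiv[ii] + dt
      gone <- ii[imm$age[ii] > imm$lifespan[ii]]
      for (j in gone) {
        .log_event(s, "immune_clearance", a = j, site = imm$pos[j])
        s$cnt["imm_cleared"] <- s$cnt["imm_cleared"] + 1
        .remove_immune(s, j)
      }
    }
  }
  invisible(s)
}

# oxygen-threshold transitions: necrosis, quiescence entry, reactivation
.apply_oxygen_classification <- function(s, cfg) {
  can <- s$can
  ci <- which(can$alive[seq_len(can$n)])
  if (!length(ci)) return(invisible(s))
  ox <- cfg$oxygen
  o <- s$oxy[can$pos[ci]]
  necro <- ci[o < ox$threshold_necrosis]
  for (i in necro) {
    .log_event(s, "necrosis", a = i, site = can$pos[i], phase = can$phase[i])
    s$cnt["necrosis"] <- s$cnt["necrosis"] + 1
    .remove_cancer(s, i, debris = ox$necrotic_debris)
  }
  ci <- which(can$alive[seq_len(can$n)])
  if (!length(ci)) return(invisible(s))
  o <- s$oxy[can$pos[ci]]
  nfree <- .free_neighbor_counts(s, can$pos[ci])
  trig <- quiescence_trigger(pmin(o, 1), nfree, ox$threshold_quiescence)
  cyc <- can$phase[ci] != 5L
  # entry: store the exact cycle position
  enter <- ci[cyc & trig]
  if (length(enter)) {
    can$sphase[enter] <- can$phase[enter]
    can$sclock[enter] <- can$clock[enter]
    can$sready[enter] <- can$ready[enter]
    can$phase[enter] <- 5L
    can$ready[enter] <- FALSE
    for (i in enter) .log_event(s, "quiescence_enter", a = i, site = can$pos[i])
  }
  # exit: restore it bit-exactly
  leave <- ci[!cyc & !trig]
  if (length(leave)) {
    can$phase[leave] <- can$sphase[leave]
    can$clock[leave] <- can$sclock[leave]
    can$ready[leave] <- can$sready[leave]
    can$sphase[leave] <- NA_integer_
    can$sclock[leave] <- NA_real_
    can$sready[leave] <- FALSE
    for (i in leave) .log_event(s, "quiescence_exit", a = i, site = can$pos[i])
  }
  invisible(s)
}

# per-step chemotherapy and DDRi death draws; K_sys and ddr_conc are the
# systemic step-start values, scaled to local levels by the oxygen gradient.
# Probabilities treat the dimensionless quantity as a per-hour hazard:
# p = 1 - exp(-h * dt), so halving dt halves the per-step probability.
.apply_drug_draws <- function(s, cfg, K_sys, ddr_conc, dt) {
  can <- s$can
  if (K_sys > 0) {
    elig <- which(can$alive[seq_len(can$n)] & can$phase[seq_len(can$n)] %in% c(3L, 4L))
    if (length(elig)) {
      o <- if (cfg$oxygen$enabled) s$oxy[can$pos[elig]] else rep(1, length(elig))
      K_loc <- local_concentration(K_sys, pmin(o, 1), cfg$drug_scaling)
      h <- chemo_death_probability(pmin(K_loc, cfg$chemo$k_max), cfg$chemo$k_max)
      p <- 1 - exp(-h * dt)
      dead <- elig[stats::runif(length(elig)) < p]
      for (i in dead) {
        .log_event(s, "chemo_death_cancer", a = i, site = can$pos[i],
                   phase = can$phase[i])
        s$cnt["kills_chemo"] <- s$cnt["kills_chemo"] + 1
        .remove_cancer(s, i)
      }
    }
    if (cfg$chemo$affects_immune) {
      imm <- s$imm
      ii <- which(imm$alive[seq_len(imm$n)])
      if (length(ii)) {
        o <- if (cfg$oxygen$enabled) s$oxy[imm$pos[ii]] else rep(1, length(ii))
        K_loc <- local_concentration(K_sys, pmin(o, 1), cfg$drug_scaling)
        h <- pmin(K_loc, cfg$chemo$k_max) / cfg$chemo$k_max
        p <- 1 - exp(-h * dt)
        dead <- ii[stats::runif(length(ii)) < p]
        for (j in dead) {
          .log_event(s, "chemo_death_immune", a = j, site = imm$pos[j])
          s$cnt["imm_deaths_chemo"] <- s$cnt["imm_deaths_chemo"] + 1
          .remove_immune(s, j)
        }
      }
    }
  }
  if (ddr_conc > 0) {
    elig <- which(can$alive[seq_len(can$n)] & can$phase[seq_len(can$n)] == 2L)
    if (length(elig)) {
      o <- if (cfg$oxygen$enabled) s$oxy[can$pos[elig]] else rep(1, length(elig))
      c_loc <- local_concentration(ddr_conc, pmin(o, 1), cfg$drug_scaling)
      eff <- ddr_effect(c_loc, cfg$ddri)
      p <- 1 - exp(-eff * dt)
      dead <- elig[stats::runif(length(elig)) < p]
      for (i in dead) {
        .log_event(s, "ddri_death_cancer", a = i, site = can$pos[i],
                   phase = can$phase[i])
        s$cnt["kills_ddri"] <- s$cnt["kills_ddri"] + 1
        .remove_cancer(s, i)
      }
    }
  }
  invisible(s)
}

# precompute the deterministic pharmacology on the macro grid
.precompute_pk <- function(cfg, grid) {
  sched <- .compile_schedule(cfg$treatments)
  out <- list(schedule = sched,
              ro = rep(0, length(grid)),
              chemo_K = rep(0, length(grid)),
              ddr_conc = rep(0, length(grid)),
              pd1 = NULL, chemo = NULL, ddri = NULL)
  pd1_doses <- sched[sched$modality == "pd1_antibody", , drop = FALSE]
  if (nrow(pd1_doses)) {
    spec <- cfg$pd1$model %||% default_pd1_model()
    doses <- data.frame(time = pd1_doses$time,
                        amount = pd1_doses$amount * cfg$pd1$weight_kg)  # mg/kg -> mg
    traj <- integrate_pk(spec, doses, grid)
    out$pd1 <- traj
    out$ro <- receptor_occupancy(traj[, spec$binding$complex],
                                 spec$binding$r_tot)
  }
  chemo_doses <- sched[sched$modality == "docetaxel", , drop = FALSE]
  if (nrow(chemo_doses)) {
    spec <- .one_compartment_spec(cfg$chemo$k_elim)
    doses <- data.frame(time = chemo_doses$time,
                        amount = chemo_doses$amount * 1000)  # g -> mg
    traj <- integrate_pk(spec, doses, grid)
    out$chemo <- traj
    t0 <- min(chemo_doses$time)
    amt <- traj[, "central"]
    out$chemo_K <- ifelse(grid >= t0,
                          chemo_kill_rate(pmax(grid - t0, 0), amt, cfg$chemo), 0)
  }
  ddri_doses <- sched[sched$modality == "ddri", , drop = FALSE]
  if (nrow(ddri_doses)) {
    spec <- .one_compartment_spec(cfg$ddri$k_elim)
    doses <- data.frame(time = ddri_doses$time,
                        amount = ddri_doses$amount * cfg$ddri$bsa)  # mg/m^2 -> mg
    traj <- integrate_pk(spec, doses, grid)
    out$ddri <- traj
    out$ddr_conc <- traj[, "central"]
  }
  out
}

#' Run the hybrid simulation
#'
#' Advances the coupled system (agents + oxygen field + pharmacology) from
#' the configured initial state to the horizon, recording a census at the
#' configured cadence. Stops early at cancer extinction or when the total
#' agent count reaches the lethal ceiling. All randomness is drawn from R's
#' RNG seeded with `config$run$seed`, so identical configs give bit-identical
#' outputs.
#'
#' @param config a [tme_config()]
#' @return an object of class `tme_run`: list with `config`, `time_series`
#'   (census data.frame, one row per output interval, with current
#'   propensities and PK outputs appended), `event_log`, `snapshots`,
#'   `pk` (precomputed trajectories), `stopped` (reason) and `final_state`
#' @examples
#' \donttest{
#' cfg <- tme_config(init = list(n_cancer = 30),
#'                   lattice = list(extents = c(14, 14, 14)),
#'                   run = list(horizon_days = 5, seed = 42))
#' run <- tme_run(cfg)
#' summary(run)
#' }
#' @export
tme_run <- function(config) {
  .validate_config(config)
  set.seed(config$run$seed)
  dt <- config$run$dt
  horizon <- config$run$horizon_days * 24
  nsteps <- ceiling(horizon / dt)
  grid <- seq(0, by = dt, length.out = nsteps + 1L)
  pk <- .precompute_pk(config, grid)
  rad <- pk$schedule[pk$schedule$modality == "radiation", , drop = FALSE]

  s <- tme_initialize(config)
  ts_rows <- vector("list", nsteps + 1L)
  snaps <- list()
  snap_times <- config$run$snapshot_days * 24
  record <- function(k) {
    row <- census(s)
    p <- tme_propensities(s, config)
    names(p) <- paste0("prop_", names(p))
    cbind(row, as.data.frame(as.list(p)),
          ro = pk$ro[k], chemo_kill_rate = pk$chemo_K[k],
          ddr_conc = pk$ddr_conc[k])
  }
  ts_rows[[1]] <- record(1L)
  out_every <- max(1L, round(config$run$output_interval / dt))
  stopped <- "horizon"

  for (istep in seq_len(nsteps)) {
    t0 <- grid[istep]
    t1 <- grid[istep + 1L]
    # (1) radiation fractions due in [t0, t1)
    due <- rad$time >= t0 & rad$time < t1
    if (any(due)) for (d in rad$amount[due]) apply_fraction(s, d, config)
    # (2) deterministic fields
    if (config$oxygen$enabled) {
      can <- s$can
      ci <- which(can$alive[seq_len(can$n)])
      cyc <- ci[can$phase[ci] != 5L]
      qui <- ci[can$phase[ci] == 5L]
      s$oxy <- .advance_oxygen(s$oxy, can$pos[cyc], can$pos[qui],
                               config$oxygen, dt)
    }
    s$ro <- pk$ro[istep]
    # (3) clocks and oxygen-threshold transitions
    .advance_clocks(s, config, dt)
    if (config$oxygen$enabled) .apply_oxygen_classification(s, config)
    # (4) treatment death draws at step-start systemic levels
    .apply_drug_draws(s, config, pk$chemo_K[istep], pk$ddr_conc[istep], dt)
    # (5) stochastic events
    .gillespie_step(s, config, t1)
    # (6) outputs and stop conditions
    if (istep %% out_every == 0L || istep == nsteps)
      ts_rows[[istep + 1L]] <- record(istep + 1L)
    if (length(snap_times) && any(abs(snap_times - t1) < dt / 2))
      snaps[[length(snaps) + 1L]] <- .snapshot(s)
    ct <- .counts(s)
    if (config$run$stop_at_extinction && ct$n_cancer == 0L) {
      if (is.null(ts_rows[[istep + 1L]])) ts_rows[[istep + 1L]] <- record(istep + 1L)
      stopped <- "extinction"
      break
    }
    if (ct$n_cancer + ct$n_imm >= config$run$lethal_agents) {
      if (is.null(ts_rows[[istep + 1L]])) ts_rows[[istep + 1L]] <- record(istep + 1L)
      stopped <- "lethal_size"
      break
    }
  }

  ts <- do.call(rbind, ts_rows[!vapply(ts_rows, is.null, logical(1))])
  rownames(ts) <- NULL
  ts$day <- ts$time / 24
  structure(list(config = config, time_series = ts,
                 event_log = .event_log_df(s), snapshots = snaps,
                 pk = pk, stopped = stopped, final_state = s),
            class = "tme_run")
}

#' @export
print.tme_run <- function(x, ...) {
  ts <- x$time_series
  last <- ts[nrow(ts), ]
  cat("<tme_run>", nrow(ts), "census records over", round(last$day, 1),
      "days; stopped:", x$stopped, "\n")
  cat("  final counts: cancer", last$cancer,
      sprintf("(G1 %d / S %d / G2 %d / M %d / G0 %d, PDL1+ %d)",
              last$G1, last$S, last$G2, last$M, last$G0, last$pdl1_pos), "\n")
  cat("  immune:", last$eff_active, "active +", last$eff_exhausted,
      "exhausted effectors,", last$suppressors, "suppressors\n")
  cat("  events logged:", nrow(x$event_log), "\n")
  invisible(x)
}

#' @export
summary.tme_run <- function(object, ...) {
  ts <- object$time_series
  last <- ts[nrow(ts), ]
  out <- list(
    days = last$day, stopped = object$stopped,
    cancer_initial = ts$cancer[1], cancer_final = last$cancer,
    growth_fold = if (ts$cancer[1] > 0) last$cancer / ts$cancer[1] else NA,
    pdl1_fraction_final = if (last$cancer > 0) last$pdl1_pos / last$cancer else NA,
    kills = c(effector = last$kills_effector, rt = last$kills_rt,
              chemo = last$kills_chemo, ddri = last$kills_ddri),
    exhausted_final = last$eff_exhausted,
    n_events = nrow(object$event_log)
  )
  class(out) <- "summary.tme_run"
  out
}

#' @export
print.summary.tme_run <- function(x, ...) {
  cat("Hybrid tumour-immune simulation:", round(x$days, 1), "days (",
      x$stopped, ")\n")
  cat("  cancer agents:", x$cancer_initial, "->", x$cancer_final,
      sprintf("(x%.2f)", x$growth_fold), "\n")
  cat("  final PDL1+ fraction:", round(x$pdl1_fraction_final, 3), "\n")
  cat("  cumulative kills:", paste(names(x$kills), x$kills, collapse = ", "),
      "\n")
  cat("  exhausted effectors at end:", x$exhausted_final, "\n")
  invisible(x)
}

#' Plot a simulation run
#'
#' Two base-graphics panels: population counts over time and the cancer
#' cell-cycle phase census.
#'
#' @param x a `tme_run`
#' @param ... ignored
#' @export
plot.tme_run <- function(x, ...) {
  ts <- x$time_series
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::matplot(ts$day, cbind(ts$cancer, ts$eff_active, ts$eff_exhausted,
                                  ts$suppressors, ts$pdl1_pos),
                    type = "l", lty = 1, lwd = 2,
                    col = c("firebrick", "steelblue", "grey50", "darkorange",
                            "purple"),
                    xlab = "day", ylab = "agents", main = "cell counts")
  graphics::legend("topleft", bty = "n", lwd = 2,
                   col = c("firebrick", "steelblue", "grey50", "darkorange",
                           "purple"),
                   legend = c("cancer", "effector", "exhausted", "suppressor",
                              "PDL1+"))
  graphics::matplot(ts$day, cbind(ts$G1, ts$S, ts$G2, ts$M, ts$G0),
                    type = "l", lty = 1, lwd = 2,
                    col = c("black", "forestgreen", "royalblue", "red",
                            "grey60"),
                    xlab = "day", ylab = "cancer agents",
                    main = "cell-cycle phases")
  graphics::legend("topleft", bty = "n", lwd = 2,
                   col = c("black", "forestgreen", "royalblue", "red",
                           "grey60"),
                   legend = c("G1", "S", "G2", "M", "G0"))
  invisible(x)
}
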