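# Per-fraction radiation effects: modified linear-quadratic survival with an
# oxygen modification factor and phase-dependent sensitivity, uniform G1/G2
# cycle delay, PDL1-linked kill counting, and the deterministic delayed
# immune-infiltration response to irradiation.

#' Oxygen modification factor
#'
#' Hypoxic cells are less radiosensitive: the effective dose is the physical
#' dose multiplied by a saturating factor of the local relative oxygen level,
#' normalised to 1 at full oxygenation and bounded below by
#' `(1 + k_m) / (oer + k_m)` (~ 1/OER for small `k_m`) at zero oxygen. The
#' functional form is a documented stand-in; its constants live in the radio
#' config block.
#'
#' @param oxygen relative oxygen level(s) in `[0, 1]`
#' @param params radio parameter block: `oer` (oxygen enhancement ratio),
#'   `k_m` (half-saturation constant)
#' @return factor in `(0, 1]`, nondecreasing in oxygen
#' @export
oxygen_modification_factor <- function(oxygen, params = tme_config()$radio) {
  if (any(oxygen < 0 | oxygen > 1)) stop("oxygen must lie in [0, 1]")
  f <- function(o) (params$oer * o + params$k_m) / (o + params$k_m)
  f(oxygen) / f(1)
}

#' Linear-quadratic survival probability after a radiation fraction
#'
#' `S = exp(-s_phase * (alpha * d_eff + beta * d_eff^2))` with
#' `d_eff = OMF(oxygen) * dose`. G1 (and G0) carry a lower sensitivity
#' multiplier than S/G2/M, reflecting the lower radiosensitivity of cells
#' outside G2-M. A cell survives the fraction iff a uniform draw falls below
#' `S`.
#'
#' @param dose physical dose in Gy (>= 0)
#' @param phase one of `"G1" "S" "G2" "M" "G0"`
#' @param oxygen local relative oxygen in `[0, 1]`
#' @param params radio parameter block (`alpha`, `beta`, `sens`, `oer`, `k_m`)
#' @return survival probability in `(0, 1]`
#' @export
lq_survival <- function(dose, phase, oxygen = 1, params = tme_config()$radio) {
  if (any(dose < 0)) stop("dose must be nonnegative")
  s <- params$sens[phase]
  if (anyNA(s)) stop("unknown phase: ", paste(phase[is.na(s)], collapse = ", "))
  d_eff <- oxygen_modification_factor(oxygen, params) * dose
  unname(exp(-s * (params$alpha * d_eff + params$beta * d_eff^2)))
}

#' Sample radiation-induced cycle delays
#'
#' Surviving cancer cells in G1 or G2 acquire a cell-cycle delay drawn from a
#' uniform distribution between 1 and 9 hours (bounds configurable); the
#' delay is consumed before the remaining phase duration, prolonging
#' residence in the current phase. Cells in S, M or G0 receive no delay.
#'
#' @param n number of draws
#' @param params radio parameter block with `delay_bounds`
#' @return `n` delays in hours
#' @export
sample_cycle_delay <- function(n, params = tme_config()$radio) {
  stats::runif(n, params$delay_bounds[1], params$delay_bounds[2])
}

#' Deterministic post-radiation immune infiltration boost
#'
#' Radiation-induced cancer-cell death produces immunogenic debris that
#' attracts effector cells after an initial immune suppression. The boost is
#' an additional effector-infiltration rate: each administered fraction
#' contributes `amplitude * kills_i * k(t - t_i)` with the delayed
#' double-exponential kernel
#' `k(tau) = (tau > lag) * (1 - exp(-(tau - lag)/rise)) * exp(-(tau - lag)/decay)`,
#' which is zero within the lag (the initial suppression window), rises over
#' `rise` hours and decays over `decay` hours. The functional form is a
#' documented stand-in; all constants are config entries.
#'
#' @param t simulation time in hours (>= 0)
#' @param history radiation history: list with `times`, `doses`, `kills`
#'   vectors (one entry per administered fraction)
#' @param params radio parameter block with the `infiltration` constants
#' @return additional effector-infiltration rate (per hour), zero before the
#'   first fraction
#' @export
rt_infiltration_boost <- function(t, history, params = tme_config()$radio) {
  t <- unname(t)
  if (any(t < 0)) stop("t must be nonnegative")
  if (!length(history$times)) return(0 * t)
  p <- params$infiltration
  vapply(t, function(tt) {
    tau <- tt - history$times
    k <- ifelse(tau > p["lag"],
                (1 - exp(-(tau - p["lag"]) / p["rise"])) *
                  exp(-(tau - p["lag"]) / p["decay"]),
                0)
    unname(p["amplitude"] * sum(history$kills * k))
  }, numeric(1))
}

#' Apply one radiation fraction to the simulation state
#'
#' Every cancer and immune cell draws survival from [lq_survival()] at its
#' local oxygen level (immune cells use the configured `immune_sens`
#' multiplier; exhausted effectors are included unless configured
#' otherwise). Killed cells are removed; surviving cycling cancer cells in
#' G1 or G2 acquire a sampled cycle delay; radiation kills feed the
#' cumulative counters that raise the PDL1-expression propensity and the
#' radiation history that drives [rt_infiltration_boost()].
#'
#' @param state a simulation state (see [tme_initialize()])
#' @param dose fraction dose in Gy
#' @param config a [tme_config()]
#' @return the state, invisibly
#' @export
apply_fraction <- function(state, dose, config) {
  if (dose < 0) stop("dose must be nonnegative")
  rp <- config$radio
  can <- state$can
  ci <- which(can$alive[seq_len(can$n)])
  n_kill_cancer <- 0L
  if (length(ci)) {
    o <- state$oxy[can$pos[ci]]
    ph <- .phase_names[can$phase[ci]]
    surv <- lq_survival(dose, ph, o, rp)
    u <- stats::runif(length(ci))
    dead <- ci[u >= surv]
    n_kill_cancer <- length(dead)
    for (i in dead) {
      .log_event(state, "rt_death_cancer", a = i, site = can$pos[i],
                 phase = can$phase[i])
      .remove_cancer(state, i)
    }
    surv_idx <- setdiff(ci, dead)
    elig <- if (dose > 0) surv_idx[can$phase[surv_idx] %in% c(1L, 3L)] else integer(0)
    if (length(elig))
      can$delay[elig] <- can$delay[elig] + sample_cycle_delay(length(elig), rp)
  }
  imm <- state$imm
  ii <- which(imm$alive[seq_len(imm$n)])
  if (!rp$include_exhausted) ii <- ii[!imm$exhausted[ii]]
  if (length(ii)) {
    o <- state$oxy[imm$pos[ii]]
    d_eff <- oxygen_modification_factor(o, rp) * dose
    surv <- exp(-rp$immune_sens * (rp$alpha * d_eff + rp$beta * d_eff^2))
    u <- stats::runif(length(ii))
    dead <- ii[u >= surv]
    state$cnt["imm_deaths_rt"] <- state$cnt["imm_deaths_rt"] + length(dead)
    for (j in dead) {
      .log_event(state, "rt_death_immune", a = j, site = imm$pos[j])
      .remove_immune(state, j)
    }
  }
  state$cnt["kills_rt"] <- state$cnt["kills_rt"] + n_kill_cancer
  state$rt_times <- c(state$rt_times, state$time)
  state$rt_doses <- c(state$rt_doses, dose)
  state$rt_kills <- c(state$rt_kills, n_kill_cancer)
  .log_event(state, "rt_fraction", a = n_kill_cancer)
  invisible(state)
}
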