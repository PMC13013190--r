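# Agent state machines: the cancer cell cycle (G1 -> S -> G2 -> M, with
# quiescence G0 and radiation-induced delay) and the quiescence trigger.
#
# Phases are encoded as integers 1..5 = G1, S, G2, M, G0 internally; the
# public cell-level API uses the phase names. A cell that completes M is
# flagged division-ready and waits there until a Gillespie division event
# selects it; both cells restart in G1 with clock 0 after division.

.phase_id <- function(phase) {
  id <- match(phase, .phase_names)
  if (anyNA(id)) stop("unknown phase: ", paste(phase[is.na(id)], collapse = ", "))
  id
}

# Vectorised clock advance for cycling (non-G0, non-ready) cells.
# Pending radiation delay is consumed before the remaining phase duration,
# i.e. the delay prolongs residence in the current phase. Cells completing M
# become division-ready and stop ageing until they divide.
.advance_cycle_core <- function(phase, clock, delay, ready, dt, dur) {
  rem <- rep(dt, length(phase))
  eps <- 1e-9
  repeat {
    act <- which(rem > eps & !ready & phase <= 4L)
    if (!length(act)) break
    used <- pmin(delay[act], rem[act])
    delay[act] <- delay[act] - used
    rem[act] <- rem[act] - used
    act <- act[rem[act] > eps]
    if (!length(act)) break
    adv <- pmin(dur[phase[act]] - clock[act], rem[act])
    clock[act] <- clock[act] + adv
    rem[act] <- rem[act] - adv
    done <- act[clock[act] >= dur[phase[act]] - eps]
    if (!length(done)) break
    is_m <- phase[done] == 4L
    if (any(is_m)) {
      ready[done[is_m]] <- TRUE
      rem[done[is_m]] <- 0
    }
    nxt <- done[!is_m]
    if (length(nxt)) {
      phase[nxt] <- phase[nxt] + 1L
      clock[nxt] <- 0
    }
  }
  list(phase = phase, clock = clock, delay = delay, ready = ready)
}

#' Advance a cancer cell's cycle clock
#'
#' Ages a cycling cell by `dt` hours. Any pending radiation-induced delay is
#' consumed first (the delay prolongs residence in the current phase); the
#' cell then transitions G1 -> S -> G2 -> M as phase durations are completed.
#' A cell completing the 1 h M phase is flagged `ready` for division and
#' stops ageing until a division event fires.
#'
#' @param cell a list with `phase` (one of `"G1" "S" "G2" "M"`), `phase_clock`
#'   (hours in the current phase), and optionally `pending_delay` (hours) and
#'   `ready`
#' @param dt positive time step in hours
#' @param durations named phase durations in hours (defaults G1 = 11, S = 8,
#'   G2 = 4, M = 1)
#' @return the updated cell list
#' @examples
#' cell <- list(phase = "G1", phase_clock = 0)
#' advance_cycle(cell, 11)$phase  # "S"
#' @export
advance_cycle <- function(cell, dt, durations = tme_config()$cycle$durations) {
  if (dt <= 0) stop("dt must be positive")
  if (identical(cell$phase, "G0")) stop("cannot advance a quiescent (G0) cell")
  out <- .advance_cycle_core(.phase_id(cell$phase), cell$phase_clock,
                             cell$pending_delay %||% 0, isTRUE(cell$ready),
                             dt, unname(durations))
  cell$phase <- .phase_names[out$phase]
  cell$phase_clock <- out$clock
  cell$pending_delay <- out$delay
  cell$ready <- out$ready
  cell
}

#' Quiescence entry and exit
#'
#' A cell entering G0 stores its exact cycle position (phase, clock and
#' division-readiness); on reactivation it resumes from that position
#' bit-exactly, so enter-then-reactivate is the identity.
#'
#' @param cell a cell list as for [advance_cycle()]
#' @return the updated cell
#' @export
enter_quiescence <- function(cell) {
  if (identical(cell$phase, "G0")) stop("cell is already quiescent")
  cell$stored_phase <- cell$phase
  cell$stored_clock <- cell$phase_clock
  cell$stored_ready <- isTRUE(cell$ready)
  cell$phase <- "G0"
  cell$ready <- FALSE
  cell
}

#' @rdname enter_quiescence
#' @export
reactivate <- function(cell) {
  if (!identical(cell$phase, "G0")) stop("cannot reactivate a cell that is not in G0")
  cell$phase <- cell$stored_phase
  cell$phase_clock <- cell$stored_clock
  cell$ready <- isTRUE(cell$stored_ready)
  cell$stored_phase <- NULL
  cell$stored_clock <- NULL
  cell$stored_ready <- NULL
  cell
}

#' Quiescence trigger
#'
#' A cancer cell becomes quiescent when the local oxygen level falls below
#' the quiescence threshold, or when it has no free neighbouring site for
#' division. Vectorised over cells.
#'
#' @param oxygen relative oxygen level(s) in `[0, 1]`
#' @param n_free number of free Moore neighbours
#' @param threshold quiescence oxygen threshold (strictly-below comparison)
#' @return logical
#' @export
quiescence_trigger <- function(oxygen, n_free, threshold) {
  if (any(oxygen < 0 | oxygen > 1)) stop("oxygen must lie in [0, 1]")
  oxygen < threshold | n_free == 0L
}
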