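# Run configuration: defaults, recursive merging, YAML loading, validation.
#
# Many constants below are documented placeholders: the biological source
# material states the rule ("consumption rate k_o", "the parameters are
# assumed and can be changed") without printing the constant, so every such
# value is an explicit, named config entry chosen at a physiologically
# plausible order of magnitude. See the methods vignette for the reasoning
# behind each default.

.phase_names <- c("G1", "S", "G2", "M", "G0")

#' Build a simulation configuration
#'
#' Returns the full default configuration, recursively merged with any
#' overrides supplied as named arguments. Each argument must be a named list
#' matching (part of) the corresponding block; atomic vectors replace their
#' default wholesale.
#'
#' Blocks:
#' \describe{
#' \item{lattice}{`extents`: three grid dimensions (sites).}
#' \item{scaling}{`cells_per_agent` (default 1e6 biological cells per agent)
#'   and `cell_density` (cells per cm^3, default 1e9), so a 0.1 cm^3 tumour is
#'   100 agents and the 1000 cm^3 lethal size is 1e6 agents.}
#' \item{init}{`n_cancer` starting cancer agents; `immune_ratio` immune:cancer
#'   seeding ratio (default 0.01, i.e. 1:100); `suppressor_fraction` of the
#'   seeded immune cells; `geometry` `"sphere"` (compact nodule at the lattice
#'   centre) or `"scatter"`; `phases` `"uniform"` (uniform position within the
#'   24 h cycle) or `"g1"` (synchronised).}
#' \item{cycle}{`durations` in hours (G1 = 11, S = 8, G2 = 4, M = 1);
#'   `enabled` advances phase clocks (off = frozen-clock validation mode);
#'   `gating` requires an M-complete, division-ready cell for a division event
#'   (off = rate-only division, the pure birth/death validation mode).}
#' \item{rates}{Gillespie base rates, all per hour: `division` and `death` per
#'   cancer cell; `pdl1_base` per PDL1-negative cell plus `pdl1_per_kill` per
#'   cumulative eliminated cell; `kill` per active effector;
#'   `infiltration_effector` coefficients (per cancer cell, per active
#'   effector, per cumulative effector kill); `infiltration_suppressor_per_kill`;
#'   `immune_division` per division-eligible immune cell; `immune_move` per
#'   active immune cell; `exhaustion` coefficients (per suppressor, per PDL1+
#'   cancer cell), multiplied by `1 - receptor occupancy`.}
#' \item{immune}{lifespans (hours), `max_divisions`, `time_to_division`
#'   (hours), chemotaxis `bias` and `metric`.}
#' \item{oxygen}{`enabled`; diffusion coefficient `D` (lattice^2/h);
#'   consumption `k_o` (per hour at a cycling cell's site); quiescent
#'   reduction factor `q_c`; classification thresholds (relative units,
#'   necrosis < quiescence); fixed `boundary` value (default 1) imposed at the
#'   periphery, or at `vessel_sites` (n x 3 matrix, 0-based) when supplied;
#'   `necrotic_debris` keeps necrotic cells on the lattice; `safety` fraction
#'   of the explicit-scheme stability bound used for sub-stepping.}
#' \item{pd1}{antibody PKPD: `weight_kg` converts mg/kg doses, `model` a PK
#'   spec as for [integrate_pk()] (`NULL` = [default_pd1_model()]).}
#' \item{chemo}{K/PD docetaxel: `epsilon` efficacy (per hour per mg), `lambda`
#'   resistance decay (per hour), `k_max` maximum kill rate (per hour),
#'   `k_elim` elimination (per hour), `affects_immune`.}
#' \item{ddri}{DNA-damage-response inhibitor: `emax`, `ec50` (amount units),
#'   `k_elim`, `bsa` (m^2) for mg/m^2 dosing.}
#' \item{radio}{LQ coefficients `alpha` (per Gy), `beta` (per Gy^2); phase
#'   sensitivity multipliers `sens` (G1 and G0 less sensitive than S/G2/M);
#'   `immune_sens`; OMF constants `oer`, `k_m`; `delay_bounds` of the uniform
#'   G1/G2 cycle delay (hours); post-RT infiltration kernel
#'   (`amplitude`, `lag`, `rise`, `decay`); `include_exhausted` exposes
#'   exhausted effectors to radiation kill.}
#' \item{drug_scaling}{`"oxygen_linear"` multiplies systemic drug levels by
#'   the local relative oxygen (core < edge), `"none"` disables it.}
#' \item{treatments}{list of regimen specs for [build_schedule()].}
#' \item{run}{`horizon_days`, macro-step `dt` (hours), `seed`,
#'   `output_interval` (hours between census records), `snapshot_days`,
#'   `stop_at_extinction`, `lethal_agents` ceiling.}
#' }
#'
#' @param ... named blocks of overrides
#' @return a list of class `tme_config`
#' @examples
#' cfg <- tme_config(init = list(n_cancer = 50), run = list(horizon_days = 10))
#' cfg$init$n_cancer
#' @export
tme_config <- function(...) {
  base <- list(
    lattice = list(extents = c(24L, 24L, 24L)),
    scaling = list(cells_per_agent = 1e6, cell_density = 1e9),
    init = list(n_cancer = 100L, immune_ratio = 0.01, suppressor_fraction = 0,
                geometry = "sphere", phases = "uniform"),
    cycle = list(durations = c(G1 = 11, S = 8, G2 = 4, M = 1),
                 enabled = TRUE, gating = TRUE),
    rates = list(
      division = 3e-3, death = 1e-4,
      pdl1_base = 1e-5, pdl1_per_kill = 2e-3,
      kill = 0.02,
      infiltration_effector = c(per_cancer = 5e-5, per_effector = 5e-5,
                                per_kill = 2e-4),
      infiltration_suppressor_per_kill = 1e-3,
      immune_division = 0.02, immune_move = 0.2,
      exhaustion = c(per_suppressor = 2e-3, per_pdl1 = 2e-3)
    ),
    immune = list(lifespan = c(effector = 2000, suppressor = 2000),
                  max_divisions = 4L, time_to_division = 24,
                  bias = 1, metric = "euclidean"),
    oxygen = list(enabled = TRUE, D = 0.5, k_o = 0.01, q_c = 0.5,
                  threshold_quiescence = 0.3, threshold_necrosis = 0.1,
                  boundary = 1, vessel_sites = NULL, necrotic_debris = FALSE,
                  safety = 0.9),
    pd1 = list(weight_kg = 70, model = NULL),
    chemo = list(epsilon = 4e-4, lambda = 5e-4, k_max = 1, k_elim = 0.063,
                 affects_immune = TRUE),
    ddri = list(emax = 0.3, ec50 = 50, k_elim = 0.06, bsa = 1.75),
    radio = list(alpha = 0.3, beta = 0.03,
                 sens = c(G1 = 0.5, S = 1, G2 = 1, M = 1, G0 = 0.5),
                 immune_sens = 1, oer = 3, k_m = 0.5,
                 delay_bounds = c(1, 9),
                 infiltration = c(amplitude = 1e-3, lag = 48, rise = 24,
                                  decay = 240),
                 include_exhausted = TRUE),
    drug_scaling = "oxygen_linear",
    treatments = list(),
    run = list(horizon_days = 40, dt = 0.5, seed = 1L,
               output_interval = 24, snapshot_days = numeric(0),
               stop_at_extinction = TRUE, lethal_agents = 1e6)
  )
  cfg <- .merge_config(base, list(...))
  class(cfg) <- "tme_config"
  cfg
}

# recursive merge; atomic overrides replace, lists merge by name. A list
# override of an atomic default (as produced by YAML) is unlisted.
.merge_config <- function(base, override) {
  if (is.null(override)) return(base)
  for (nm in names(override)) {
    ov <- override[[nm]]
    if (nm == "treatments" || nm == "vessel_sites" || nm == "model") {
      base[[nm]] <- ov
    } else if (is.list(ov) && is.list(base[[nm]])) {
      base[[nm]] <- .merge_config(base[[nm]], ov)
    } else if (is.list(ov) && is.atomic(base[[nm]]) && !is.null(base[[nm]])) {
      v <- unlist(ov)
      if (is.null(names(ov)) || any(names(ov) == "")) names(v) <- names(base[[nm]])
      base[[nm]] <- v
    } else {
      base[[nm]] <- ov
    }
  }
  base
}

#' Load a configuration from a YAML file
#'
#' The file holds overrides in the block structure of [tme_config()]; missing
#' entries keep their defaults.
#'
#' @param path YAML file path
#' @param ... further overrides applied on top of the file
#' @return a `tme_config`
#' @export
tme_config_from_yaml <- function(path, ...) {
  ov <- yaml::read_yaml(path)
  cfg <- .merge_config(tme_config(), ov)
  cfg <- .merge_config(cfg, list(...))
  class(cfg) <- "tme_config"
  cfg
}

.validate_config <- function(cfg) {
  stopifnot(
    length(cfg$lattice$extents) == 3L, all(cfg$lattice$extents >= 3),
    cfg$scaling$cells_per_agent > 0, cfg$scaling$cell_density > 0,
    cfg$init$n_cancer >= 0, cfg$init$immune_ratio >= 0,
    all(cfg$cycle$durations > 0), length(cfg$cycle$durations) == 4L,
    cfg$run$horizon_days > 0, cfg$run$dt > 0,
    cfg$oxygen$D > 0, cfg$oxygen$k_o >= 0,
    cfg$oxygen$q_c >= 0, cfg$oxygen$q_c <= 1,
    cfg$immune$max_divisions >= 0, cfg$immune$time_to_division > 0,
    cfg$radio$alpha >= 0, cfg$radio$beta >= 0,
    cfg$radio$delay_bounds[1] <= cfg$radio$delay_bounds[2],
    cfg$chemo$k_max > 0, cfg$ddri$ec50 > 0, cfg$ddri$emax >= 0
  )
  rates <- cfg$rates
  if (any(unlist(rates) < 0)) stop("all base rates must be nonnegative")
  if (cfg$oxygen$threshold_necrosis >= cfg$oxygen$threshold_quiescence)
    stop("necrosis threshold must lie below the quiescence threshold")
  capacity <- prod(cfg$lattice$extents)
  n0 <- cfg$init$n_cancer + round(cfg$init$n_cancer * cfg$init$immune_ratio)
  if (n0 > capacity) stop("initial agents exceed lattice capacity")
  invisible(cfg)
}

#' Tumour scaling helpers
#'
#' One simulated agent stands for `cells_per_agent` biological cells (default
#' 1e6) at a tissue density of `cell_density` cells per cm^3 (default 1e9), so
#' a 0.1 cm^3 tumour maps to 100 agents, 1 cm^3 to 1000 agents, and the
#' 1000 cm^3 lethal size to 1e6 agents.
#'
#' @param volume_cm3 tumour volume in cm^3
#' @param scaling a list with `cells_per_agent` and `cell_density`
#' @return number of simulated agents
#' @export
agents_for_volume <- function(volume_cm3,
                              scaling = tme_config()$scaling) {
  if (any(volume_cm3 < 0)) stop("volume must be nonnegative")
  volume_cm3 * scaling$cell_density / scaling$cells_per_agent
}

#' @export
print.tme_config <- function(x, ...) {
  cat("<tme_config>\n")
  cat("  lattice  :", paste(x$lattice$extents, collapse = " x "), "sites\n")
  cat("  init     :", x$init$n_cancer, "cancer agents, immune ratio",
      x$init$immune_ratio, "\n")
  cat("  horizon  :", x$run$horizon_days, "days, dt =", x$run$dt, "h, seed =",
      x$run$seed, "\n")
  if (length(x$treatments)) {
    for (tr in x$treatments)
      cat("  regimen  :", tr$modality, tr$amount, "|", tr$pattern,
          "from day", tr$start_day %||% 0, "\n")
  } else cat("  regimen  : none (untreated)\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
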