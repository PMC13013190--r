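# Shared helpers: fixture loading (memoised so shape and reproducibility
# checks reuse the same runs) and small config builders.

fixture_path <- function(name) {
  p <- system.file("extdata", "configs", paste0(name, ".yaml"), package = "tmesim")
  stopifnot(nzchar(p))
  p
}

fixture_names <- c("untreated", "pd1_antibody", "radiotherapy", "chemotherapy",
                   "ddri", "combo_pd1_rt", "combo_ddri_rt", "combo_chemo_rt")

.fixture_cache <- new.env(parent = emptyenv())

run_fixture <- function(name) {
  if (is.null(.fixture_cache[[name]])) {
    cfg <- tme_config_from_yaml(fixture_path(name))
    .fixture_cache[[name]] <- tme_run(cfg)
  }
  .fixture_cache[[name]]
}

# a minimal, fast configuration: no oxygen dynamics, no immune seeding
tiny_cfg <- function(...) {
  tme_config(
    lattice = list(extents = c(12L, 12L, 12L)),
    init = list(n_cancer = 10L, immune_ratio = 0),
    oxygen = list(enabled = FALSE),
    run = list(horizon_days = 2, seed = 7L),
    ...
  )
}

# pure birth/death validation mode: rate-only division, frozen clocks,
# scattered seeding on a large lattice so spatial blocking is negligible
birth_death_cfg <- function(n0, division, death, horizon_h, seed,
                            extents = c(30L, 30L, 30L), lethal = 1e6) {
  tme_config(
    lattice = list(extents = extents),
    init = list(n_cancer = n0, immune_ratio = 0, geometry = "scatter"),
    cycle = list(enabled = FALSE, gating = FALSE),
    oxygen = list(enabled = FALSE),
    rates = list(division = division, death = death,
                 pdl1_base = 0, pdl1_per_kill = 0, kill = 0,
                 infiltration_effector = c(per_cancer = 0, per_effector = 0,
                                           per_kill = 0),
                 infiltration_suppressor_per_kill = 0,
                 immune_division = 0, immune_move = 0,
                 exhaustion = c(per_suppressor = 0, per_pdl1 = 0)),
    run = list(horizon_days = horizon_h / 24, seed = seed,
               output_interval = horizon_h, lethal_agents = lethal)
  )
}

final_cancer <- function(run) {
  ts <- run$time_series
  ts$cancer[nrow(ts)]
}
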