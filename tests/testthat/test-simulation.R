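# Orchestrator: initialisation, census partitions, frozen-system behaviour,
# determinism, accounting, output round trips and absorbing extinction.

test_that("initialisation follows the tumour scaling and seeding rules", {
  # 0.1 cm^3 at default scaling = 100 agents; 1:100 immune seeding
  n <- agents_for_volume(0.1)
  cfg <- tme_config(init = list(n_cancer = n))
  set.seed(51)
  s <- tme_initialize(cfg)
  cen <- census(s)
  expect_equal(cen$cancer, 100)
  expect_equal(cen$immune, 1)  # round(100 * 0.01)
  expect_equal(cen$pdl1_pos, 0)  # all PDL1-negative at start
  expect_equal(cen$G1 + cen$S + cen$G2 + cen$M + cen$G0, cen$cancer)

  # compact sphere: all cancer agents within a tight radius of the centre
  ci <- which(s$can$alive[1:s$can$n])
  sites <- tmesim:::.lin_site(s$can$pos[ci], cfg$lattice$extents)
  ctr <- (cfg$lattice$extents - 1) / 2
  r <- sqrt(rowSums(sweep(sites, 2, ctr)^2))
  expect_lt(max(r), (3 * 100 / (4 * pi))^(1 / 3) + 1.5)

  # zero initial immune cells is a valid state
  s0 <- tme_initialize(tme_config(init = list(n_cancer = 50L, immune_ratio = 0)))
  expect_equal(census(s0)$immune, 0)

  expect_error(tme_initialize(tme_config(lattice = list(extents = c(4L, 4L, 4L)),
                                         init = list(n_cancer = 100L))),
               "capacity")
})

test_that("census partitions are exact on a live run", {
  run <- run_fixture("untreated")
  ts <- run$time_series
  expect_true(all(ts$G1 + ts$S + ts$G2 + ts$M + ts$G0 == ts$cancer))
  expect_true(all(ts$pdl1_pos + ts$pdl1_neg == ts$cancer))
  expect_true(all(ts$eff_active + ts$eff_exhausted + ts$suppressors == ts$immune))
  expect_true(all(diff(ts$time) > 0))
})

test_that("a frozen system keeps every census constant", {
  cfg <- tme_config(
    lattice = list(extents = c(12L, 12L, 12L)),
    init = list(n_cancer = 40L, immune_ratio = 0.1),
    cycle = list(enabled = FALSE),
    oxygen = list(enabled = FALSE),
    rates = list(division = 0, death = 0, pdl1_base = 0, pdl1_per_kill = 0,
                 kill = 0,
                 infiltration_effector = c(per_cancer = 0, per_effector = 0,
                                           per_kill = 0),
                 infiltration_suppressor_per_kill = 0, immune_division = 0,
                 immune_move = 0, exhaustion = c(per_suppressor = 0, per_pdl1 = 0)),
    run = list(horizon_days = 4, seed = 52)
  )
  r <- tme_run(cfg)
  ts <- r$time_series
  for (col in c("cancer", "G1", "S", "G2", "M", "G0", "pdl1_pos", "eff_active",
                "eff_exhausted", "suppressors"))
    expect_equal(length(unique(ts[[col]])), 1L, info = col)
})

test_that("population accounting balances births against deaths", {
  run <- run_fixture("chemotherapy")
  ts <- run$time_series
  log <- run$event_log
  births <- sum(log$type == "cancer_division" & !log$vacuous)
  deaths <- sum(log$type %in% c("cancer_death", "effector_kill",
                                "rt_death_cancer", "chemo_death_cancer",
                                "ddri_death_cancer", "necrosis") & !log$vacuous)
  expect_equal(ts$cancer[nrow(ts)] - ts$cancer[1], births - deaths)
})

test_that("identical config and seed reproduce outputs byte-for-byte", {
  cfg <- tme_config_from_yaml(fixture_path("untreated"),
                              run = list(horizon_days = 6))
  r1 <- tme_run(cfg)
  r2 <- tme_run(cfg)
  expect_identical(r1$time_series, r2$time_series)
  expect_identical(r1$event_log, r2$event_log)
})

test_that("written outputs round-trip and the config echo reproduces the run", {
  cfg <- tme_config(lattice = list(extents = c(12L, 12L, 12L)),
                    init = list(n_cancer = 25L, immune_ratio = 0.08),
                    run = list(horizon_days = 5, seed = 53, snapshot_days = 5))
  r <- tme_run(cfg)
  dir <- withr::local_tempdir()
  paths <- write_tme_outputs(r, dir)
  ts <- utils::read.csv(paths["time_series"])
  expect_equal(ts$cancer, r$time_series$cancer)
  expect_equal(ts$time, r$time_series$time, tolerance = 1e-12)

  cfg2 <- read_tme_config(paths["config"])
  r2 <- tme_run(cfg2)
  expect_identical(r2$event_log, r$event_log)

  # snapshot agent totals agree with the census at the same time
  snap <- r$snapshots[[1]]
  cen <- r$time_series[r$time_series$time == snap$time, ]
  expect_equal(nrow(snap$agents), cen$cancer + cen$immune)
  expect_equal(sum(snap$agents$type == "cancer"), cen$cancer)
})

test_that("extinction is absorbing", {
  cfg <- birth_death_cfg(n0 = 5, division = 0, death = 0.5, horizon_h = 72,
                         seed = 54)
  cfg$run$stop_at_extinction <- FALSE
  cfg$run$output_interval <- 12
  r <- tme_run(cfg)
  ts <- r$time_series
  first_zero <- which(ts$cancer == 0)[1]
  expect_false(is.na(first_zero))
  expect_true(all(ts$cancer[first_zero:nrow(ts)] == 0))
})

test_that("division-only dynamics are invariant to the macro-step size", {
  # the stochastic layer is an exact SSA within each step, so halving dt
  # leaves the birth process distribution unchanged; compare mean growth
  mean_final <- function(dt) {
    out <- numeric(30)
    for (i in seq_along(out)) {
      cfg <- birth_death_cfg(n0 = 10, division = 0.1, death = 0,
                             horizon_h = 12, seed = 5400 + i)
      cfg$run$dt <- dt
      out[i] <- final_cancer(tme_run(cfg))
    }
    out
  }
  a <- mean_final(1)
  b <- mean_final(0.5)
  se <- sqrt(stats::var(a) / 30 + stats::var(b) / 30)
  expect_lt(abs(mean(a) - mean(b)), 3 * se + 1e-9)
})

test_that("run objects print and summarise without error", {
  run <- run_fixture("untreated")
  expect_output(print(run), "tme_run")
  expect_output(print(summary(run)), "cancer agents")
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(run))
})
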