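# Cancer-cell cycle state machine, quiescence round trips, division
# inheritance and effector exhaustion contracts.

test_that("phase clock transitions follow the configured durations", {
  newborn <- list(phase = "G1", phase_clock = 0)
  expect_equal(advance_cycle(newborn, 11)$phase, "S")
  expect_equal(advance_cycle(newborn, 11)$phase_clock, 0)

  s_cell <- list(phase = "S", phase_clock = 0)
  out <- advance_cycle(s_cell, 0.5)
  expect_equal(out$phase, "S")
  expect_equal(out$phase_clock, 0.5)

  # pending delay is consumed before the remaining phase duration:
  # G2 (4 h) with 3 h delay needs 7 h to reach M
  g2 <- list(phase = "G2", phase_clock = 0, pending_delay = 3)
  out <- advance_cycle(g2, 7)
  expect_equal(out$phase, "M")
  expect_equal(out$phase_clock, 0)
  expect_equal(out$pending_delay, 0)
  out_partial <- advance_cycle(g2, 6.5)
  expect_equal(out_partial$phase, "G2")
  expect_equal(out_partial$phase_clock, 3.5)

  # a full 24 h cycle ends division-ready in M
  out <- advance_cycle(newborn, 24)
  expect_equal(out$phase, "M")
  expect_true(out$ready)
  # ready cells stop ageing until a division event fires
  expect_true(advance_cycle(out, 10)$ready)

  expect_error(advance_cycle(newborn, 0), "positive")
  expect_error(advance_cycle(list(phase = "G0", phase_clock = 0), 1), "G0")
})

test_that("quiescence stores and restores the exact cycle position", {
  cell <- list(phase = "S", phase_clock = 3.2, pending_delay = 0)
  q <- enter_quiescence(cell)
  expect_equal(q$phase, "G0")
  back <- reactivate(q)
  expect_identical(back$phase, "S")
  expect_identical(back$phase_clock, 3.2)  # bit-exact round trip
  expect_error(reactivate(cell), "G0")
  expect_error(enter_quiescence(q), "quiescent")

  # reactivated G2 cell needs (4 - stored clock) further hours to reach M
  g2 <- reactivate(enter_quiescence(list(phase = "G2", phase_clock = 1.5)))
  out <- advance_cycle(g2, 4 - 1.5)
  expect_equal(out$phase, "M")
})

test_that("quiescence triggers on hypoxia or crowding", {
  thr <- 0.3
  expect_false(quiescence_trigger(0.8, 5, thr))
  expect_true(quiescence_trigger(0.8, 0, thr))
  expect_true(quiescence_trigger(0.1, 26, thr))
  expect_true(quiescence_trigger(0.1, 0, thr))
  expect_error(quiescence_trigger(1.5, 3, thr), "\\[0, 1\\]")
})

test_that("daughters inherit PDL1 status and division is blocked when surrounded", {
  cfg <- tiny_cfg()
  s <- tme_initialize(tme_config(lattice = list(extents = c(9L, 9L, 9L)),
                                 init = list(n_cancer = 0L, immune_ratio = 0),
                                 oxygen = list(enabled = FALSE)))
  ctr_lin <- tmesim:::.site_lin(matrix(c(4L, 4L, 4L), ncol = 3), s$lat$extents)
  mother <- tmesim:::.add_cancer(s, ctr_lin, phase = 4L, clock = 1, pdl1 = TRUE,
                                 ready = TRUE)
  set.seed(11)
  expect_true(execute_event(s, "cancer_division", cfg))
  expect_equal(sum(s$can$alive[1:s$can$n]), 2L)
  expect_true(all(s$can$pdl1[1:2]))
  expect_true(all(s$can$phase[1:2] == 1L))  # both restart in G1

  # fully surrounded mother: division event is a logged no-op
  s2 <- tme_initialize(tme_config(lattice = list(extents = c(9L, 9L, 9L)),
                                  init = list(n_cancer = 0L, immune_ratio = 0),
                                  oxygen = list(enabled = FALSE)))
  m2 <- tmesim:::.add_cancer(s2, ctr_lin, phase = 4L, clock = 1, pdl1 = FALSE,
                             ready = TRUE)
  nb <- lattice_neighbors(s2$lat, c(4L, 4L, 4L))
  for (r in seq_len(nrow(nb)))
    tmesim:::.add_cancer(s2, tmesim:::.site_lin(nb[r, , drop = FALSE], s2$lat$extents),
                         phase = 1L, clock = 0, pdl1 = FALSE)
  before <- sum(s2$can$alive[1:s2$can$n])
  expect_false(execute_event(s2, "cancer_division", tme_config(cycle = list(gating = TRUE))))
  log <- tmesim:::.event_log_df(s2)
  expect_true(log$vacuous[nrow(log)])
  expect_equal(sum(s2$can$alive[1:s2$can$n]), before)
})

test_that("exhausted effectors become inert but keep their site until cleared", {
  cfg <- tme_config(lattice = list(extents = c(9L, 9L, 9L)),
                    init = list(n_cancer = 0L, immune_ratio = 0),
                    oxygen = list(enabled = FALSE))
  s <- tme_initialize(cfg)
  ext <- s$lat$extents
  eff <- tmesim:::.add_immune(s, tmesim:::.site_lin(matrix(c(4L, 4L, 4L), ncol = 3), ext),
                              role = 1L, lifespan = 10)
  sup <- tmesim:::.add_immune(s, tmesim:::.site_lin(matrix(c(5L, 4L, 4L), ncol = 3), ext),
                              role = 2L, lifespan = 1000)
  set.seed(12)
  expect_true(execute_event(s, "effector_exhaustion", cfg))
  expect_true(s$imm$exhausted[eff])
  expect_equal(s$lat$occ[s$imm$pos[eff]], -eff)  # still occupies its site
  # inactivity contract: no kill pairs, no movers, zero exhaustion propensity
  expect_equal(nrow(tmesim:::.kill_pairs(s)), 0L)
  p <- tme_propensities(s, cfg)
  # only the (active) suppressor still counts as a mover; the exhausted
  # effector contributes nothing to any channel
  expect_equal(unname(p["immune_move"]), cfg$rates$immune_move * 1)
  expect_equal(unname(p["effector_kill"]), 0)
  # move events never select the exhausted effector
  pos_before <- s$imm$pos[eff]
  for (k in 1:10) execute_event(s, "immune_move", cfg)
  expect_equal(s$imm$pos[eff], pos_before)

  # clearance at lifespan: age past 10 h
  tmesim:::.advance_clocks(s, cfg, 11)
  expect_false(s$imm$alive[eff])
  expect_true(s$imm$alive[sup])
})

test_that("suppressors cannot be exhausted", {
  cfg <- tme_config(lattice = list(extents = c(9L, 9L, 9L)),
                    init = list(n_cancer = 0L, immune_ratio = 0),
                    oxygen = list(enabled = FALSE))
  s <- tme_initialize(cfg)
  ext <- s$lat$extents
  tmesim:::.add_immune(s, tmesim:::.site_lin(matrix(c(4L, 4L, 4L), ncol = 3), ext),
                       role = 2L, lifespan = 1000)
  tmesim:::.add_immune(s, tmesim:::.site_lin(matrix(c(5L, 4L, 4L), ncol = 3), ext),
                       role = 2L, lifespan = 1000)
  # only suppressors present: no eligible effector, event is vacuous
  expect_false(execute_event(s, "effector_exhaustion", cfg))
  expect_false(any(s$imm$exhausted[1:s$imm$n]))
})

test_that("immune division bookkeeping respects the division cap", {
  cfg <- tme_config(lattice = list(extents = c(9L, 9L, 9L)),
                    init = list(n_cancer = 0L, immune_ratio = 0),
                    oxygen = list(enabled = FALSE),
                    immune = list(max_divisions = 2L, time_to_division = 24))
  s <- tme_initialize(cfg)
  ext <- s$lat$extents
  j <- tmesim:::.add_immune(s, tmesim:::.site_lin(matrix(c(4L, 4L, 4L), ncol = 3), ext),
                            role = 1L, lifespan = 1e4)
  set.seed(13)
  for (k in 1:10) {
    s$imm$tdiv[1:s$imm$n] <- 48  # force division-eligible clocks
    execute_event(s, "immune_division", cfg)
  }
  n <- s$imm$n
  expect_true(all(s$imm$divcount[1:n] <= 2L))
  # daughter inherits the mother's updated division count
  log <- tmesim:::.event_log_df(s)
  div <- log[log$type == "immune_division" & !log$vacuous, ]
  expect_gt(nrow(div), 0)
  for (r in seq_len(nrow(div)))
    expect_equal(s$imm$divcount[div$agent_b[r]] >= 1L, TRUE)
})
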