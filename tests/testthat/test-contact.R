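test_that("contact pulls hold an otherwise immobile group together", {
  # no directional movement at all (LDD and FDD always draw none), but both
  # roles always respond to contact: the group stays clustered
  none <- directional_distribution(c(none = 1))
  p <- contact_params(ldd = none, fdd = none, lmc = 1, fmc = 1,
                      ppc = 1, frp = 0, lrp = 0, fmp = 1, lmp = 1,
                      mdi = 50, mpi = 50)
  rec <- run_simulation(p, seed = 2, max_steps = 50, cumulative = TRUE,
                        return_state = TRUE)
  a <- rec$state$agents
  expect_lte(diff(range(a$x)), 9)
  expect_lte(diff(range(a$y)), 6)
})

test_that("without contact responses, protrusion dynamics do not affect movement", {
  # FMC-true = LMC-true = 0: trajectories must be statistically independent
  # of the protrusion machinery, here toggled at opposite extremes
  base <- list(lmc = 0, fmc = 0, sid = TRUE, mdi = 50)
  p_slow <- do.call(contact_params, c(base, list(mpi = 50)))
  p_fast <- do.call(contact_params, c(base, list(mpi = 0)))
  x_slow <- run_replicates(p_slow, n = 300, seed = 5)$runs$persistence
  x_fast <- run_replicates(p_fast, n = 300, seed = 6)$runs$persistence
  ks <- suppressWarnings(stats::ks.test(x_slow, x_fast))
  expect_gt(ks$p.value, 0.001)
})

test_that("matrix resistance does not impede the pure contact model", {
  # fully distally-polarized followers and leaders walk straight through
  # closed matrix: no track exists, yet the chain reaches the target
  p <- contact_params(ldd = 1, fdd = 1, lmc = 0, fmc = 0, sid = TRUE,
                      mdi = 50, mpi = 50)
  rec <- run_simulation(p, seed = 4, cumulative = TRUE, return_state = TRUE)
  expect_equal(rec$termination_reason, "target_reached")
  expect_true(all(rec$state$agents$y == 22))
})

test_that("protrusion lengths never exceed the three-site clamp", {
  for (seed in 1:5) {
    rec <- run_simulation(contact_params(fmp = 1, lmp = 1, mpi = 2),
                          seed = seed, max_steps = 30, cumulative = TRUE,
                          return_state = TRUE)
    pl <- rec$state$protrusion_len
    expect_true(all(pl >= 0 & pl <= 3))
    # followers use at most 2 rays, leaders at most 8
    rays <- rowSums(pl > 0)
    fol <- rec$state$agents$role == "follower"
    expect_true(all(rays[fol] <= 2))
    expect_true(all(rays[!fol] <= 8))
  }
})

test_that("synchronized distal polarity with slow clocks sustains migration", {
  # SID with MDI = 50 rarely re-randomizes follower polarity: chains persist
  # far longer than the unsynchronized default
  p_sync <- contact_params(ldd = 1, sid = TRUE, mdi = 50, fmc = 0, mpi = 5)
  p_def <- contact_params()
  m_sync <- run_replicates(p_sync, n = 200, seed = 31)$mean_persistence
  m_def <- run_replicates(p_def, n = 200, seed = 32)$mean_persistence
  expect_gt(m_sync, 5 * m_def)
})

test_that("compiled and reference Contact engines agree in distribution", {
  p <- contact_params()
  compiled <- run_replicates(p, n = 400, seed = 41)
  ref <- vapply(1:150, function(s) {
    run_simulation(p, seed = 9000 + s, engine = "reference")$persistence
  }, numeric(1))
  se <- sqrt(var(ref) / 150 + compiled$sem^2)
  expect_lt(abs(mean(ref) - compiled$mean_persistence), 4 * se)
})
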