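test_that("all-none distributions leave the chain intact but stationary", {
  p <- ecm_params(
    ldd = directional_distribution(c(none = 1)),
    fdd = directional_distribution(c(none = 1)),
    pos = 0.5, ats = 0.5, track = TRUE
  )
  for (seed in 1:5) {
    rec <- run_simulation(p, seed = seed)
    # structure holds but the velocity checkpoint at t = 10 fails
    expect_equal(rec$persistence, 9)
    expect_equal(rec$steps, 10)
    expect_equal(rec$termination_reason, "chain_broken")
    expect_equal(rec$final_centroid_x, 4.5)
  }
})

test_that("with full forging bias the chain marches to the target", {
  # LDD = FDD = distal 100%, always willing to forge (POS-true = 0)
  p <- ecm_params(ldd = 1, fdd = 1, pos = 0, ats = 0, track = FALSE)
  rec <- run_simulation(p, seed = 3, cumulative = TRUE, return_state = TRUE)
  expect_equal(rec$termination_reason, "target_reached")
  a <- rec$state$agents
  expect_true(all(a$y == 22))              # nobody ever leaves the row
  expect_equal(max(a$x), 149)
  # leaders entered the run distal-most and stay ahead of the rear
  expect_gt(min(a$x[a$role == "leader"]), min(a$x[a$role == "follower"]))
})

test_that("agents refusing to forge are confined to the existing open area", {
  # POS-true = 1 and no track: nothing can leave the initial footprint, so
  # the chain stalls and the t = 10 velocity checkpoint kills the run
  p <- ecm_params(ldd = 1, fdd = 1, pos = 1, ats = 0, track = FALSE)
  for (seed in 1:3) {
    rec <- run_simulation(p, seed = seed, return_state = TRUE)
    expect_equal(rec$persistence, 9)
    expect_equal(rec$steps, 10)
    expect_true(all(rec$state$agents$x <= 8))
    # the only non-closed sites are the 8 initial agent sites' footprint
    expect_equal(sum(rec$state$grid$states != SITE_CLOSED), 8)
  }
})

test_that("a single-file chain on a track advances without leaving the row", {
  p <- ecm_params(ldd = 1, fdd = 1, pos = 1, ats = 0, track = TRUE)
  rec <- run_simulation(p, seed = 9, cumulative = TRUE, return_state = TRUE)
  a <- rec$state$agents
  expect_true(all(a$y == 22))
  expect_equal(rec$termination_reason, "target_reached")
  # single file: distinct x, order preserved
  expect_equal(anyDuplicated(a$x), 0L)
})

test_that("the ATS double step speeds a lone agent down an open track", {
  base <- ecm_params(ldd = 1, fdd = 1, pos = 1, ats = 0, track = TRUE)
  fast <- ecm_params(ldd = 1, fdd = 1, pos = 1, ats = 1, track = TRUE)
  steps_base <- steps_fast <- numeric(6)
  for (s in 1:6) {
    steps_base[s] <- run_simulation(base, seed = s, cumulative = TRUE,
                                    n_leaders = 1, n_followers = 0)$steps
    steps_fast[s] <- run_simulation(fast, seed = s, cumulative = TRUE,
                                    n_leaders = 1, n_followers = 0)$steps
  }
  # ~149 single steps vs ~75 double steps
  expect_true(all(steps_fast < steps_base * 0.75))
})

test_that("an agent moves at most two sites per step", {
  # speed bound: centroid displacement can never exceed 2 sites/step
  for (seed in 1:10) {
    rec <- run_simulation(ecm_params(ldd = 1, fdd = 1, pos = 0, ats = 1),
                          seed = seed, cumulative = TRUE)
    expect_lte(rec$final_centroid_x - 4.5, 2 * rec$steps)
  }
})

test_that("compiled and reference ECM engines agree in distribution", {
  p <- ecm_params()  # default baseline with track
  compiled <- run_replicates(p, n = 400, seed = 21)$mean_persistence
  ref <- vapply(1:200, function(s) {
    run_simulation(p, seed = 7000 + s, engine = "reference")$persistence
  }, numeric(1))
  # same rules, independent implementations: means agree within joint noise
  se <- sqrt(var(ref) / 200 + 0.12^2)
  expect_lt(abs(mean(ref) - compiled), 4 * se)
})
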