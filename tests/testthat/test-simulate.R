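test_that("identical seeds replay identical runs", {
  p <- ecm_params()
  a <- run_replicates(p, n = 50, seed = 123)
  b <- run_replicates(p, n = 50, seed = 123)
  expect_identical(a$runs, b$runs)
  expect_identical(a$mean_persistence, b$mean_persistence)
  c <- run_replicates(p, n = 50, seed = 124)
  expect_false(identical(a$runs$persistence, c$runs$persistence))
})

test_that("replicate summaries are coherent", {
  r <- run_replicates(contact_params(), n = 80, seed = 9)
  expect_equal(r$n, 80)
  expect_equal(r$mean_persistence, mean(r$runs$persistence))
  expect_equal(r$sem, sd(r$runs$persistence) / sqrt(80))
  expect_lte(r$min, r$mean_persistence)
  expect_gte(r$max, r$mean_persistence)
  expect_true(all(r$runs$persistence <= r$runs$steps))
  expect_true(all(r$runs$termination %in%
                    c("max_steps", "chain_broken", "target_reached")))
  df <- as.data.frame(r)
  expect_equal(df$mean_persistence, r$mean_persistence)
})

test_that("persistence never exceeds steps and respects max_steps", {
  for (seed in 1:5) {
    rec <- run_simulation(ecm_params(ldd = 0.8, fdd = 0.8, pos = 1),
                          seed = seed, max_steps = 37)
    expect_lte(rec$persistence, rec$steps)
    expect_lte(rec$steps, 37)
  }
})

test_that("cumulative counting never terminates on a broken chain", {
  rec <- run_simulation(ecm_params(), seed = 2, max_steps = 120,
                        cumulative = TRUE)
  expect_true(rec$termination_reason %in% c("max_steps", "target_reached"))
  nonc <- run_simulation(ecm_params(), seed = 2, max_steps = 120)
  expect_lte(nonc$persistence, rec$persistence + 1)
})

test_that("sweeps are reproducible and summarize every set", {
  sets <- enumerate_ecm_grid(list(
    ldd = c(1 / 9, 1), fdd = c(1), pos = c(0, 1), ats = c(0)
  ), expected_n = 4)
  sw1 <- run_sweep(sets, "ecm", reps = 30, seed = 50, track = TRUE)
  sw2 <- run_sweep(sets, "ecm", reps = 30, seed = 50, track = TRUE)
  expect_identical(sw1, sw2)
  expect_equal(nrow(sw1), 4)
  # each set's summary reproduces an isolated run_replicates call
  p3 <- ecm_params(ldd = sets$ldd_distal[3], fdd = sets$fdd_distal[3],
                   pos = sets$pos_true[3], ats = sets$ats_true[3])
  iso <- run_replicates(p3, n = 30, seed = sweep_set_seed(50, 3))
  expect_equal(sw1$mean_persistence[3], iso$mean_persistence)
})

test_that("grid enumeration and random sampling validate their inputs", {
  expect_equal(nrow(enumerate_ecm_grid()), 6400)
  expect_error(enumerate_ecm_grid(list(ldd = c(0.5, 0.5), fdd = 1, pos = 1,
                                       ats = 1), expected_n = NULL),
               "duplicate")
  expect_warning(enumerate_ecm_grid(list(ldd = c(0.5), fdd = 1, pos = 1,
                                         ats = 1)), "expected")
  one <- enumerate_ecm_grid(list(ldd = 1, fdd = 1, pos = 1, ats = 1),
                            expected_n = 1)
  expect_equal(nrow(one), 1)

  sets <- sample_contact_sets(5000, seed = 99)
  expect_equal(nrow(sets), 5000)
  expect_true(all(sets$mdi %in% c(0, 5, 10, 20, 35, 50)))
  # marginal frequency of SID = TRUE ~ Binomial(n, 1/2)
  expect_lt(abs(sum(sets$sid) - 2500), 3 * sqrt(5000 * 0.25))
  expect_error(sample_contact_sets(0), ">= 1")
})
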