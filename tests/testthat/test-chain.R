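test_that("sequential_pair implements the spacing rule", {
  expect_true(sequential_pair(c(10, 20), c(11, 20)))
  expect_true(sequential_pair(c(10, 20), c(14, 21)))   # 3 empty x sites
  expect_false(sequential_pair(c(10, 20), c(15, 20)))  # 4 empty x sites
  expect_false(sequential_pair(c(10, 20), c(11, 22)))  # 1 empty y site
  expect_true(sequential_pair(c(5, 5), c(5, 5)))
})

test_that("chain detection on canonical configurations", {
  row8 <- cbind(1:8, rep(22, 8))
  ch <- detect_chain(row8)
  expect_true(ch$is_chain)
  expect_equal(ch$members, 1:8)

  # two groups of four split by five empty x sites
  split <- cbind(c(1:4, 10:13), rep(22, 8))
  expect_false(detect_chain(split)$is_chain)

  # five agents can never make a chain
  expect_false(detect_chain(cbind(1:5, rep(0, 5)))$is_chain)

  # six agents spaced at the maximum sequential gap (3 empty sites) qualify
  spaced <- cbind(seq(0, 20, by = 4), rep(3, 6))
  expect_true(detect_chain(spaced)$is_chain)
  # one more empty site anywhere breaks it
  expect_false(detect_chain(cbind(c(0, 4, 8, 12, 16, 21), rep(3, 6)))$is_chain)
})

test_that("chain detection is invariant under translation and y reflection", {
  set.seed(11)
  for (i in 1:200) {
    pos <- random_placement()
    base <- detect_chain(pos)$length
    shift <- sweep(pos, 2, c(sample(-20:20, 1), sample(-10:10, 1)), "+")
    expect_equal(detect_chain(shift)$length, base)
    refl <- cbind(pos[, 1], -pos[, 2])
    expect_equal(detect_chain(refl)$length, base)
  }
})

test_that("adding an agent never destroys an existing chain", {
  set.seed(12)
  for (i in 1:200) {
    pos <- random_placement()
    before <- detect_chain(pos)
    extra <- random_placement(n = 1, xmax = 20, ymax = 10)
    if (any(pos[, 1] == extra[1] & pos[, 2] == extra[2])) next
    after <- detect_chain(rbind(pos, extra))
    expect_gte(after$length, before$length)
  }
})

test_that("chain detector agrees exactly with the exhaustive search oracle", {
  set.seed(13)
  n_cases <- 1000
  for (i in seq_len(n_cases)) {
    # alternate between tight boxes (dense, tie-heavy) and looser ones
    pos <- if (i %% 2 == 0) {
      random_placement(8, xmax = 6, ymax = 3)
    } else {
      random_placement(8, xmax = 14, ymax = 6)
    }
    got <- detect_chain(pos)$length
    want <- oracle_chain_length(pos[, 1], pos[, 2])
    if (got != want) {
      fail(sprintf(
        "mismatch (%d vs oracle %d) at case %d: %s", got, want, i,
        paste(apply(pos, 1, paste, collapse = ","), collapse = " ")
      ))
    }
  }
  succeed()
})

test_that("velocity verdicts follow the checkpoint semantics", {
  # exactly one site per ten steps passes at every checkpoint
  adv <- seq(0, 5, by = 0.1)
  expect_true(velocity_ok(adv, 10))
  expect_true(velocity_ok(adv, 50))
  expect_true(velocity_ok(adv, 15))  # between checkpoints: carry the verdict

  stat <- rep(4.5, 51)
  expect_true(velocity_ok(stat, 9))   # before the first checkpoint
  expect_false(velocity_ok(stat, 10))
  expect_false(velocity_ok(stat, 19))

  slow <- seq(0, 5, by = 0.09)  # 0.9 sites per window
  expect_false(velocity_ok(slow, 10))
  expect_error(velocity_ok(stat, 60), "too short")
})
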