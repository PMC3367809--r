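test_that("tukey_kramer matches stats::TukeyHSD on a fixed fixture", {
  set.seed(71)
  groups <- list(
    base = rnorm(20, 5, 1),
    mid = rnorm(15, 6, 1),
    far = rnorm(25, 9, 1)
  )
  got <- tukey_kramer(groups, baseline = "base")

  values <- unlist(groups)
  fac <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  hsd <- stats::TukeyHSD(stats::aov(values ~ fac))$fac
  expect_equal(got$diff[got$group == "mid"], hsd["mid-base", "diff"])
  expect_equal(got$p_value[got$group == "mid"], hsd["mid-base", "p adj"],
               tolerance = 1e-8)
  expect_equal(got$p_value[got$group == "far"], hsd["far-base", "p adj"],
               tolerance = 1e-8)
  expect_equal(got$significant, got$p_value < 0.05)
})

test_that("tukey_kramer separates what should be separated", {
  set.seed(72)
  same <- list(a = rnorm(400, 5, 3), b = rnorm(400, 5, 3))
  expect_false(tukey_kramer(same, "a")$significant)

  apart <- list(a = rnorm(50, 5, 1), b = rnorm(50, 50, 1))
  expect_true(tukey_kramer(apart, "a")$significant)
})

test_that("tukey_kramer rejects degenerate inputs", {
  expect_error(tukey_kramer(list(a = 1:5)), "at least two groups")
  expect_error(tukey_kramer(list(a = 1:5, b = 3)), "two observations")
  expect_error(tukey_kramer(list(a = rep(1, 5), b = rep(2, 5))), "degenerate")
  expect_error(tukey_kramer(list(a = 1:5, b = 1:5), baseline = "c"),
               "baseline")
})

test_that("subgroup analysis splits, summarizes and correlates correctly", {
  # hand-built fixture: 10 parameter sets, 4 in the high group
  sets <- data.frame(
    p1 = c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0),
    p2 = c(10, 20, 30, 40, 5, 5, 5, 5, 5, 5),
    flag = c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE)
  )
  means <- c(25, 30, 21, 40, 3, 1, 0, 5, 2, 4)
  rep <- subgroup_analysis(means, sets, threshold = 20)
  expect_equal(rep$n_high, 4)
  expect_equal(rep$n_low, 6)
  expect_equal(rep$n_high + rep$n_low, nrow(sets))  # a true partition
  expect_false(rep$empty_high)

  pt <- rep$parameters
  expect_equal(pt$mean_high[pt$parameter == "p1"], 1)
  expect_equal(pt$mean_low[pt$parameter == "p1"], 0)
  expect_equal(pt$mean_high[pt$parameter == "p2"], 25)
  expect_equal(pt$sem_high[pt$parameter == "p2"],
               sd(c(10, 20, 30, 40)) / 2)
  # Boolean parameter coded 0/1
  expect_equal(pt$mean_high[pt$parameter == "flag"], 0.75)

  # p2 and the persistence-linked p1 are constant/varying as constructed;
  # correlation matrix is symmetric with unit diagonal, in [-1, 1]
  expect_equal(rep$correlation, t(rep$correlation))
  expect_true(all(diag(rep$correlation) == 1))
  expect_true(all(abs(rep$correlation) <= 1, na.rm = TRUE))
  expect_equal(sum(rep$frequencies$p2), 4)
})

test_that("a perfectly coupled parameter pair has correlation one", {
  sets <- data.frame(a = c(1, 2, 3, 4, 0, 0), b = c(2, 4, 6, 8, 1, 7))
  means <- c(30, 30, 30, 30, 1, 1)
  rep <- subgroup_analysis(means, sets, threshold = 20)
  expect_equal(rep$correlation["a", "b"], 1)
})

test_that("an empty high group is flagged explicitly", {
  sets <- data.frame(a = 1:5)
  rep <- subgroup_analysis(rep(1, 5), sets, threshold = 20)
  expect_true(rep$empty_high)
  expect_equal(rep$n_high, 0)
  expect_null(rep$frequencies)
  expect_null(rep$correlation)
  expect_error(subgroup_analysis(1:3, sets), "not aligned")
})
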