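test_that("direction algebra: nine values, unique unit offsets, none has no offset", {
  d <- directions()
  expect_equal(nrow(d), 9)
  moves <- d[d$direction != "none", ]
  offs <- paste(moves$dx, moves$dy)
  expect_equal(anyDuplicated(offs), 0L)
  expect_true(all(moves$dx %in% -1:1 & moves$dy %in% -1:1))
  expect_false(any(moves$dx == 0 & moves$dy == 0))
  expect_error(direction_offset("none"), "offset")
  expect_error(direction_offset("sideways"), "unknown")
})

test_that("neighbor_site respects the non-cyclic boundary", {
  expect_equal(neighbor_site(c(10, 10), "distal"), c(11, 10))
  expect_equal(neighbor_site(c(10, 10), "proximal_anterior"), c(9, 9))
  expect_null(neighbor_site(c(149, 10), "distal"))
  expect_null(neighbor_site(c(0, 0), "proximal_anterior"))
  expect_null(neighbor_site(c(5, 44), "posterior"))
})

test_that("track initialization opens exactly the sites ahead of the chain", {
  g <- init_track(new_grid(), chain_row = 22, front_x = 8)
  expect_equal(sum(g$states == SITE_OPEN), 141)  # width - 1 - front_x
  expect_true(all(g$states[10:150, 23] == SITE_OPEN))
  expect_equal(sum(g$states == SITE_CLOSED), 150 * 45 - 141)

  g2 <- init_track(new_grid(), chain_row = 0, front_x = 148)
  expect_equal(sum(g2$states == SITE_OPEN), 1)
  expect_error(init_track(new_grid(), 22, 149), "degenerate")
  # no-track variant: a fresh grid has no open sites at all
  expect_equal(sum(new_grid()$states == SITE_OPEN), 0)
})

test_that("apply_move leaves an open wake and conserves occupancy", {
  g <- new_grid()
  g$states[6, 23] <- SITE_OCCUPIED  # agent at (5, 22)
  g2 <- apply_move(g, c(5, 22), c(6, 22))
  expect_equal(g2$states[6, 23], SITE_OPEN)
  expect_equal(g2$states[7, 23], SITE_OCCUPIED)
  expect_equal(sum(g2$states == SITE_OCCUPIED), sum(g$states == SITE_OCCUPIED))

  # re-entry into the now-open wake is legal (Open -> Occupied)
  g2$states[5, 23] <- SITE_OCCUPIED
  g3 <- apply_move(g2, c(4, 22), c(5, 22))
  expect_equal(g3$states[6, 23], SITE_OCCUPIED)

  expect_error(apply_move(g2, c(6, 22), c(6, 22)), "occupied")
  expect_error(apply_move(g2, c(6, 22), c(9, 22)), "not reachable")
  g$states[1, 1] <- SITE_OCCUPIED
  expect_error(apply_move(g, c(0, 0), c(-1, 0)), "off the grid")
})

test_that("two-step moves require an open channel", {
  g <- new_grid()
  g$states[6, 23] <- SITE_OCCUPIED
  g$states[7, 23] <- SITE_OPEN
  g$states[8, 23] <- SITE_OPEN
  g2 <- apply_move(g, c(5, 22), c(7, 22))  # straight double step
  expect_equal(g2$states[8, 23], SITE_OCCUPIED)
  g$states[7, 23] <- SITE_CLOSED
  expect_error(apply_move(g, c(5, 22), c(7, 22)), "non-open")
})

test_that("grid rasters round-trip", {
  g <- init_track(new_grid(30, 9), chain_row = 4, front_x = 8)
  g$states[3, 5] <- SITE_OCCUPIED
  lines <- write_grid_raster(g)
  g2 <- read_grid_raster(lines)
  expect_identical(g2$states, g$states)
  path <- tempfile(fileext = ".txt")
  write_grid_raster(g, path)
  expect_identical(read_grid_raster(path)$states, g$states)
})

test_that("site states only ever move forward (closed -> occupied <-> open)", {
  # per-step state histories from the reference engine: legal transitions
  # only, (open + occupied) never decreases, occupancy conserved, no overlap
  for (params in list(ecm_params(ats = 0.8), ecm_params(track = FALSE),
                      contact_params(), hybrid_params())) {
    set.seed(42)
    rec <- chainABM:::.run_simulation_reference(
      params, seed = 42, max_steps = 30, cumulative = TRUE,
      nL = 3, nF = 5, W = 150, H = 45, return_state = FALSE,
      record_states = TRUE
    )
    h <- rec$history
    expect_gte(length(h), 2)
    for (i in seq_len(length(h) - 1)) {
      a <- h[[i]]$states
      b <- h[[i + 1]]$states
      # a site never returns to Closed
      expect_false(any(a != SITE_CLOSED & b == SITE_CLOSED))
      expect_gte(sum(b != SITE_CLOSED), sum(a != SITE_CLOSED))
      expect_equal(sum(b == SITE_OCCUPIED), 8)
      expect_equal(anyDuplicated(cbind(h[[i + 1]]$x, h[[i + 1]]$y)), 0L)
    }
  }
})
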