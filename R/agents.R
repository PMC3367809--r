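## Agent initialization and the stochastic clocks.

#' Initialize the standard chain of agents
#'
#' Places `n_followers + n_leaders` agents in a contiguous single file at the
#' grid's mid-height row, rear Follower at x = 1 and Leaders distal-most,
#' and marks their sites Occupied. For the Contact/Hybrid models the agents
#' also receive polarized directions, clock values and extended protrusions:
#' with `sid` every Follower starts polarized distally with a common
#' direction-clock value, otherwise polarity is drawn from `fdd` and clocks
#' independently from `{0, ..., mdi}`; with `sip` all agents share one
#' initial protrusion-clock value.
#'
#' @param n_leaders,n_followers Positive agent counts (3 and 5 by default).
#' @param grid A fresh [new_grid()]; agent sites are marked Occupied on it.
#' @param model `"ecm"` agents carry no polarity or clocks; `"contact"` and
#'   `"hybrid"` agents do.
#' @param sid,sip Synchronize initial directions / protrusion clocks.
#' @param mdi,mpi Maximum clock intervals, integers in `[0, 50]`.
#' @param fdd Follower directionality distribution used to draw initial
#'   polarity when `sid` is `FALSE`.
#' @return List with `agents` (a data frame: `id`, `role`, `x`, `y`,
#'   `polarized`, `direction_clock`, `protrusion_clock`, `extended`) and the
#'   updated `grid`.
#' @examples
#' set.seed(1)
#' init_agents()$agents
#' @export
init_agents <- function(n_leaders = 3, n_followers = 5, grid = new_grid(),
                        model = c("ecm", "contact", "hybrid"),
                        sid = FALSE, sip = FALSE, mdi = 5, mpi = 5,
                        fdd = uniform_directional()) {
  model <- match.arg(model)
  if (n_leaders < 0 || n_followers < 0 || n_leaders + n_followers < 1) {
    stop("agent counts must be non-negative and total at least 1")
  }
  n <- n_leaders + n_followers
  if (n + 1 >= grid$width) stop("grid too narrow for the chain")
  row <- grid$height %/% 2L
  agents <- data.frame(
    id = seq_len(n),
    role = c(rep("follower", n_followers), rep("leader", n_leaders)),
    x = seq_len(n),
    y = rep(row, n),
    polarized = NA_character_,
    direction_clock = NA_integer_,
    protrusion_clock = NA_integer_,
    extended = FALSE
  )
  for (i in seq_len(n)) {
    grid <- .grid_set(grid, c(agents$x[i], agents$y[i]), SITE_OCCUPIED)
  }
  if (model != "ecm") {
    mdi <- .check_interval(mdi, "mdi")
    mpi <- .check_interval(mpi, "mpi")
    followers <- agents$role == "follower"
    if (isTRUE(sid)) {
      agents$polarized[followers] <- "distal"
      agents$direction_clock[followers] <- mdi  # in phase, full interval
    } else {
      agents$polarized[followers] <-
        sample_distribution(fdd, sum(followers))
      agents$direction_clock[followers] <-
        sample.int(mdi + 1L, sum(followers), replace = TRUE) - 1L
    }
    agents$protrusion_clock <- if (isTRUE(sip)) {
      rep(mpi, n)
    } else {
      sample.int(mpi + 1L, n, replace = TRUE) - 1L
    }
    agents$extended <- TRUE  # all protrusions start extended
  }
  list(agents = agents, grid = grid)
}

#' Tick an agent's stochastic clocks
#'
#' Clocks are counters decremented once per global time step. When a
#' Follower's direction-change clock reaches 0 it draws a new polarized
#' direction from `fdd` and the clock resets uniformly on `{0, ..., mdi}`;
#' when any agent's protrusion-change clock reaches 0 its protrusion state
#' toggles and the clock resets uniformly on `{0, ..., mpi}`. With a maximum
#' interval of 0 the associated event fires every step.
#'
#' (In the full Contact model a retraction that would sever a live
#' filopodial contact can be suppressed by the PPC parameter; that gating
#' lives in the simulation engines, which know the contact state.)
#'
#' @param agents Agent data frame as built by [init_agents()].
#' @param fdd Follower directionality distribution.
#' @param mdi,mpi Maximum clock intervals.
#' @return The updated agent data frame.
#' @export
tick_clocks <- function(agents, fdd = uniform_directional(), mdi = 5, mpi = 5) {
  for (i in seq_len(nrow(agents))) {
    if (agents$role[i] == "follower") {
      cl <- agents$direction_clock[i]
      cl <- max(cl - 1L, 0L)
      if (cl == 0L) {
        agents$polarized[i] <- sample_distribution(fdd, 1)
        cl <- sample.int(mdi + 1L, 1L) - 1L
      }
      agents$direction_clock[i] <- cl
    }
    cl <- agents$protrusion_clock[i]
    cl <- max(cl - 1L, 0L)
    if (cl == 0L) {
      agents$extended[i] <- !agents$extended[i]
      cl <- sample.int(mpi + 1L, 1L) - 1L
    }
    agents$protrusion_clock[i] <- cl
  }
  agents
}
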