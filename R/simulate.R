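## Single-simulation driver and replicate batches.

.termination_levels <- c("max_steps", "chain_broken", "target_reached")

#' Run one chain-migration simulation
#'
#' Simulates the configured model from the standard initial configuration (a
#' single-file chain at mid-height, Leaders distal-most) and returns its
#' chain persistence: the number of time steps on which at least six
#' sequential agents travelled towards the target at the minimum velocity.
#' The run ends when the chain criterion first fails (`chain_broken`; this
#' covers both a structural break and a failed velocity checkpoint), when an
#' agent reaches the distal edge (`target_reached`), or at `max_steps`.
#'
#' Each time step, every agent's clocks tick once (Contact/Hybrid), and then
#' as many update attempts are made as there are agents, each on a uniformly
#' selected agent (asynchronous updating with replacement, so an agent may
#' act twice or not at all in a step).
#'
#' @param params An [ecm_params()], [contact_params()] or [hybrid_params()]
#'   object.
#' @param seed Master seed (non-negative integer); the same seed always
#'   reproduces the same run.
#' @param max_steps Step budget; the default comfortably exceeds the ~150
#'   steps a fast chain needs to traverse the grid.
#' @param cumulative Count every qualifying step over the full `max_steps`
#'   instead of stopping at the first failure of the chain criterion.
#' @param n_leaders,n_followers Chain composition (default 3 + 5).
#' @param width,height Grid dimensions.
#' @param engine `"compiled"` (the C++ core) or `"reference"` (the plain-R
#'   implementation of the same rules; identical in distribution, much
#'   slower -- used for cross-validation).
#' @param return_state Also return the final grid and agent table.
#' @return A `persistence_record`: list with `persistence`,
#'   `termination_reason`, `final_centroid_x`, `steps`, `seed`, `model`, and
#'   (if requested) `state`.
#' @examples
#' run_simulation(ecm_params(), seed = 1)
#' @export
run_simulation <- function(params, seed, max_steps = 1000, cumulative = FALSE,
                           n_leaders = 3, n_followers = 5,
                           width = 150, height = 45,
                           engine = c("compiled", "reference"),
                           return_state = FALSE) {
  engine <- match.arg(engine)
  stopifnot(inherits(params, "chain_params"))
  model <- .model_code(params)
  if (engine == "reference") {
    rec <- .run_simulation_reference(params, seed, max_steps, cumulative,
                                     n_leaders, n_followers, width, height,
                                     return_state)
  } else {
    res <- cpp_run_one(model, .engine_params(params), seed, max_steps,
                       cumulative, width, height, n_leaders, n_followers)
    rec <- list(
      persistence = res$persistence,
      termination_reason = .termination_levels[res$termination + 1L],
      final_centroid_x = res$final_centroid_x,
      steps = res$steps,
      seed = seed,
      model = class(params)[1]
    )
    if (return_state) {
      grid <- new_grid(width, height)
      grid$states <- res$grid
      rec$state <- list(
        grid = grid,
        agents = data.frame(
          id = seq_along(res$x),
          role = ifelse(res$leader, "leader", "follower"),
          x = res$x, y = res$y,
          polarized = .direction_names[res$polarized + 1L],
          extended = res$extended
        ),
        protrusion_len = res$protrusion_len
      )
    }
  }
  class(rec) <- "persistence_record"
  rec
}

#' @export
print.persistence_record <- function(x, ...) {
  cat(sprintf(
    "<persistence_record> persistence = %d steps (%s after %d steps, centroid x = %.1f)\n",
    x$persistence, x$termination_reason, x$steps, x$final_centroid_x
  ))
  invisible(x)
}

#' Run replicate simulations and summarize chain persistence
#'
#' Repeats [run_simulation()] `n` times with independent random streams
#' derived from the master seed and reports the replicate-level mean,
#' standard error of the mean, minimum and maximum -- the summary reported
#' for every parameter set in the sensitivity analyses (400 replicates by
#' convention).
#'
#' @inheritParams run_simulation
#' @param n Number of replicates.
#' @param ... Passed on to the simulation (e.g. `max_steps`, `n_leaders`).
#' @return A `replicate_summary`: list with `n`, `mean_persistence`, `sem`,
#'   `min`, `max`, the per-run data frame `runs` (replicate index,
#'   persistence, termination reason, final centroid, steps), `seed` and
#'   `model`.
#' @examples
#' run_replicates(ecm_params(), n = 25, seed = 1)
#' @export
run_replicates <- function(params, n = 400, seed, max_steps = 1000,
                           cumulative = FALSE, n_leaders = 3, n_followers = 5,
                           width = 150, height = 45) {
  stopifnot(inherits(params, "chain_params"))
  if (n < 1) stop("n must be >= 1")
  res <- cpp_run_batch(.model_code(params), .engine_params(params), n, seed,
                       max_steps, cumulative, width, height,
                       n_leaders, n_followers)
  per <- res$persistence
  structure(
    list(
      n = n,
      mean_persistence = mean(per),
      sem = stats::sd(per) / sqrt(n),
      min = min(per),
      max = max(per),
      runs = data.frame(
        rep = seq_len(n),
        persistence = per,
        termination = .termination_levels[res$termination + 1L],
        final_centroid_x = res$final_centroid_x,
        steps = res$steps
      ),
      seed = seed,
      model = class(params)[1],
      params = params
    ),
    class = "replicate_summary"
  )
}

#' @export
print.replicate_summary <- function(x, ...) {
  cat(sprintf(
    "<replicate_summary> %s, n = %d: mean persistence %.2f +- %.2f s.e.m. (min %d, max %d)\n",
    sub("_params$", "", x$model), x$n, x$mean_persistence, x$sem, x$min, x$max
  ))
  invisible(x)
}

#' @rdname run_replicates
#' @param x A `replicate_summary`.
#' @param ... Unused.
#' @export
as.data.frame.replicate_summary <- function(x, ...) {
  data.frame(
    model = sub("_params$", "", x$model),
    n = x$n,
    mean_persistence = x$mean_persistence,
    sem = x$sem,
    min = x$min,
    max = x$max,
    seed = x$seed
  )
}
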