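## Parameter-space exploration: the exhaustive ECM grid and random Contact
## sampling, plus the replicate-batch sweep driver.

#' Default ECM sweep grid
#'
#' Discretization of the four ECM parameters used for the exhaustive sweep:
#' 10 directional distal-bias levels evenly spaced from 1/9 (uniform, about
#' 11 per cent) to 100 per cent for LDD and FDD, and 8 Boolean `p_true`
#' levels evenly spaced from 0 to 100 per cent for POS and ATS, giving
#' 10 x 10 x 8 x 8 = 6400 parameter sets.
#'
#' @return Named list of numeric level vectors (`ldd`, `fdd`, `pos`, `ats`).
#' @export
default_ecm_grid <- function() {
  list(
    ldd = seq(1 / 9, 1, length.out = 10),
    fdd = seq(1 / 9, 1, length.out = 10),
    pos = seq(0, 1, length.out = 8),
    ats = seq(0, 1, length.out = 8)
  )
}

#' Enumerate the exhaustive ECM parameter grid
#'
#' Cartesian product of the level lists. Directional levels are distal-bias
#' values: probability `p` on `distal`, the remaining `1 - p` spread equally
#' over the other seven directions and `none` (see
#' [distal_biased_distribution()]).
#'
#' @param grid Level lists as from [default_ecm_grid()].
#' @param expected_n If the product of level counts differs from this a
#'   warning is issued (the default grid is expected to yield 6400 sets).
#' @return Data frame with one parameter set per row: columns `ldd_distal`,
#'   `fdd_distal`, `pos_true`, `ats_true`.
#' @export
enumerate_ecm_grid <- function(grid = default_ecm_grid(), expected_n = 6400) {
  for (nm in c("ldd", "fdd", "pos", "ats")) {
    lv <- grid[[nm]]
    if (is.null(lv) || !length(lv)) stop("missing levels for ", nm)
    if (anyDuplicated(lv)) stop("duplicate levels for ", nm)
    if (any(lv < 0 | lv > 1)) stop("levels for ", nm, " must be probabilities")
  }
  sets <- expand.grid(
    ldd_distal = grid$ldd, fdd_distal = grid$fdd,
    pos_true = grid$pos, ats_true = grid$ats,
    KEEP.OUT.ATTRS = FALSE
  )
  if (!is.null(expected_n) && nrow(sets) != expected_n) {
    warning("grid yields ", nrow(sets), " parameter sets, expected ", expected_n)
  }
  sets
}

#' Default Contact sweep grid
#'
#' Value lists for random sampling of the 13 Contact parameters: the same 10
#' directional distal-bias levels as the ECM grid, Boolean `p_true` levels
#' from 0 to 100 per cent in 6 steps, clock maxima from
#' `{0, 5, 10, 20, 35, 50}`, and both values of the SID/SIP switches. The
#' full product is astronomically large (order 10^9), which is why the
#' Contact space is explored by uniform random sampling rather than
#' exhaustively.
#'
#' @return Named list of level vectors.
#' @export
default_contact_grid <- function() {
  bool6 <- seq(0, 1, length.out = 6)
  list(
    ldd = seq(1 / 9, 1, length.out = 10),
    fdd = seq(1 / 9, 1, length.out = 10),
    lmc = bool6, fmc = bool6, ppc = bool6, frp = bool6, lrp = bool6,
    fmp = bool6, lmp = bool6,
    mdi = c(0L, 5L, 10L, 20L, 35L, 50L),
    mpi = c(0L, 5L, 10L, 20L, 35L, 50L),
    sid = c(FALSE, TRUE), sip = c(FALSE, TRUE)
  )
}

#' Randomly sample Contact model parameter sets
#'
#' Each parameter is drawn independently and uniformly from its value list.
#'
#' @param n Number of parameter sets.
#' @param grid Level lists as from [default_contact_grid()].
#' @param seed Seed for the draw.
#' @return Data frame with one parameter set per row: columns `ldd_distal`,
#'   `fdd_distal`, `lmc_true` ... `lmp_true`, `mdi`, `mpi`, `sid`, `sip`.
#' @export
sample_contact_sets <- function(n, grid = default_contact_grid(), seed = NULL) {
  if (n < 1) stop("n must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  draw <- function(lv) lv[sample.int(length(lv), n, replace = TRUE)]
  data.frame(
    ldd_distal = draw(grid$ldd), fdd_distal = draw(grid$fdd),
    lmc_true = draw(grid$lmc), fmc_true = draw(grid$fmc),
    ppc_true = draw(grid$ppc), frp_true = draw(grid$frp),
    lrp_true = draw(grid$lrp), fmp_true = draw(grid$fmp),
    lmp_true = draw(grid$lmp),
    mdi = draw(grid$mdi), mpi = draw(grid$mpi),
    sid = draw(grid$sid), sip = draw(grid$sip)
  )
}

.params_from_row <- function(row, model, track) {
  switch(model,
    ecm = ecm_params(
      ldd = row$ldd_distal, fdd = row$fdd_distal,
      pos = row$pos_true, ats = row$ats_true, track = track
    ),
    contact = contact_params(
      ldd = row$ldd_distal, fdd = row$fdd_distal,
      lmc = row$lmc_true, fmc = row$fmc_true, ppc = row$ppc_true,
      frp = row$frp_true, lrp = row$lrp_true, fmp = row$fmp_true,
      lmp = row$lmp_true, sid = row$sid, sip = row$sip,
      mdi = row$mdi, mpi = row$mpi
    ),
    hybrid = hybrid_params(
      ldd = row$ldd_distal, fdd = row$fdd_distal,
      pos = row$pos_true, ats = row$ats_true,
      lmc = row$lmc_true, fmc = row$fmc_true, ppc = row$ppc_true,
      frp = row$frp_true, lrp = row$lrp_true, fmp = row$fmp_true,
      lmp = row$lmp_true, sid = row$sid, sip = row$sip,
      mdi = row$mdi, mpi = row$mpi, track = track
    ),
    stop("unknown model: ", model)
  )
}

#' Run a replicate batch for every parameter set of a sweep
#'
#' For each row of `sets`, runs `reps` independent simulations and records
#' the mean chain persistence with its s.e.m., minimum and maximum. Each
#' parameter set gets its own deterministic seed stream derived from the
#' master seed, so a sweep is exactly reproducible and individual sets can
#' be re-run in isolation (`run_replicates(params, n, seed = sweep_set_seed(seed, i))`).
#'
#' @param sets Parameter-set data frame from [enumerate_ecm_grid()] or
#'   [sample_contact_sets()].
#' @param model `"ecm"`, `"contact"` or `"hybrid"`.
#' @param reps Replicates per parameter set.
#' @param seed Master seed for the whole sweep.
#' @param track Track flag (ECM / Hybrid models).
#' @param max_steps Per-simulation step budget.
#' @param progress Print a progress line every 500 sets.
#' @return Data frame: `set` (row index into `sets`), `mean_persistence`,
#'   `sem`, `min`, `max`, `n`.
#' @export
run_sweep <- function(sets, model = c("ecm", "contact", "hybrid"), reps = 100,
                      seed = 1, track = TRUE, max_steps = 1000,
                      progress = FALSE) {
  model <- match.arg(model)
  n_sets <- nrow(sets)
  mcode <- switch(model, ecm = 0L, contact = 1L, hybrid = 2L)
  out <- data.frame(
    set = seq_len(n_sets), mean_persistence = NA_real_, sem = NA_real_,
    min = NA_integer_, max = NA_integer_, n = reps
  )
  for (i in seq_len(n_sets)) {
    params <- .params_from_row(sets[i, , drop = FALSE], model, track)
    res <- cpp_run_batch(mcode, .engine_params(params), reps,
                         sweep_set_seed(seed, i), max_steps)
    per <- res$persistence
    out$mean_persistence[i] <- mean(per)
    out$sem[i] <- stats::sd(per) / sqrt(reps)
    out$min[i] <- min(per)
    out$max[i] <- max(per)
    if (progress && i %% 500L == 0L) {
      message(sprintf("sweep: %d / %d parameter sets", i, n_sets))
    }
  }
  out
}

#' @rdname run_sweep
#' @param i Parameter-set row index.
#' @export
sweep_set_seed <- function(seed, i) seed + i * 1000003
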