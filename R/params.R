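## Parameter sets for the three rule systems. Directional parameters accept
## either a directional_distribution or a single distal-bias scalar (the
## sweep parameterization); Boolean parameters accept a boolean_distribution
## or a bare p_true.

.as_dir <- function(x, what) {
  if (inherits(x, "directional_distribution")) return(x)
  if (is.numeric(x) && length(x) == 1) return(distal_biased_distribution(x))
  if (is.numeric(x) && !is.null(names(x))) return(directional_distribution(x))
  stop(what, " must be a directional_distribution or a distal-bias scalar")
}

.as_bool <- function(x, what) {
  if (inherits(x, "boolean_distribution")) return(x)
  if (is.numeric(x) && length(x) == 1) return(boolean_distribution(x))
  stop(what, " must be a boolean_distribution or a p_true scalar")
}

.check_interval <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x != round(x) ||
      x < 0 || x > 50) {
    stop(what, " must be an integer in [0, 50]")
  }
  as.integer(x)
}

#' ECM (path-of-least-resistance) model parameters
#'
#' The four ECM model parameters. Each update an agent draws a direction
#' from LDD (Leaders) or FDD (Followers); `"none"` means it stays put.
#' Otherwise the adjacent site in that direction decides the outcome:
#' Occupied or off-grid blocks the move; Closed matrix is forged into only
#' if *false* is drawn from POS ("Prefer an Open Site"); an Open site is
#' entered, and when the next site in the same direction is also Open, a
#' *true* draw from ATS ("Advance Two Sites") grants a second step.
#'
#' @param ldd,fdd Leader / Follower directionality distribution: a
#'   [directional_distribution()] or a distal-bias scalar.
#' @param pos,ats Boolean distributions (or `p_true` scalars).
#' @param track Whether a pre-existing track of Open sites (presumed forged
#'   by preceding cells) runs from the chain to the distal edge.
#' @return An object of class `c("ecm_params", "chain_params")`.
#' @examples
#' # the default baseline: everything maximally uninformative
#' ecm_params()
#' @export
ecm_params <- function(ldd = uniform_directional(), fdd = uniform_directional(),
                       pos = 0.5, ats = 0.5, track = TRUE) {
  structure(
    list(
      ldd = .as_dir(ldd, "ldd"), fdd = .as_dir(fdd, "fdd"),
      pos = .as_bool(pos, "pos"), ats = .as_bool(ats, "ats"),
      track = isTRUE(track)
    ),
    class = c("ecm_params", "chain_params")
  )
}

#' Contact (filopodial guidance) model parameters
#'
#' The thirteen Contact model parameters. Before moving, an agent checks for
#' filopodial contact (its rays touching another agent's body, or another
#' agent's rays touching it). In contact, a *true* draw from LMC/FMC makes
#' the Leader/Follower attempt one step towards the contact (retracting its
#' filopodia afterwards on a *true* LRP/FRP draw); otherwise Leaders draw
#' from LDD and Followers step along their polarized direction. Follower
#' polarity and every agent's protrusion state are re-randomized by internal
#' clocks with maximum intervals MDI and MPI; FMP/LMP let a filopodium
#' stretch or shorten to maintain a contact when one of the linked cells
#' moves, and PPC lets a contact-mediating filopodium persist when its
#' retraction clock fires.
#'
#' @param ldd,fdd Directionality distributions (or distal-bias scalars).
#' @param lmc,fmc Move-towards-contact Booleans for Leaders / Followers.
#' @param ppc Persist-protrusion-contact Boolean.
#' @param frp,lrp Retract-protrusions-after-contact-move Booleans.
#' @param fmp,lmp Maintain-protrusions (filopodium length adjustment)
#'   Booleans.
#' @param sid Synchronize Initial Directions: start all Followers polarized
#'   distally with a common direction-clock value.
#' @param sip Synchronize Initial Protrusions: start all agents with a
#'   common protrusion-clock value.
#' @param mdi,mpi Maximum Direction / Protrusion Interval, integers in
#'   `[0, 50]`: a clock that fires resets uniformly on `{0, ..., max}`.
#' @return An object of class `c("contact_params", "chain_params")`.
#' @export
contact_params <- function(ldd = uniform_directional(),
                           fdd = uniform_directional(),
                           lmc = 0.5, fmc = 0.5, ppc = 0.5, frp = 0.5,
                           lrp = 0.5, fmp = 0.5, lmp = 0.5,
                           sid = FALSE, sip = FALSE, mdi = 5, mpi = 5) {
  structure(
    list(
      ldd = .as_dir(ldd, "ldd"), fdd = .as_dir(fdd, "fdd"),
      lmc = .as_bool(lmc, "lmc"), fmc = .as_bool(fmc, "fmc"),
      ppc = .as_bool(ppc, "ppc"), frp = .as_bool(frp, "frp"),
      lrp = .as_bool(lrp, "lrp"), fmp = .as_bool(fmp, "fmp"),
      lmp = .as_bool(lmp, "lmp"),
      sid = isTRUE(sid), sip = isTRUE(sip),
      mdi = .check_interval(mdi, "mdi"), mpi = .check_interval(mpi, "mpi")
    ),
    class = c("contact_params", "chain_params")
  )
}

#' Hybrid ECM-Contact model parameters
#'
#' Agents decide where to move by the Contact model rules but the move is
#' executed through the ECM site-state gate (POS forging, ATS double steps,
#' optional pre-existing track).
#'
#' @inheritParams contact_params
#' @inheritParams ecm_params
#' @return An object of class `c("hybrid_params", "chain_params")`.
#' @export
hybrid_params <- function(ldd = uniform_directional(),
                          fdd = uniform_directional(),
                          pos = 0.5, ats = 0.5,
                          lmc = 0.5, fmc = 0.5, ppc = 0.5, frp = 0.5,
                          lrp = 0.5, fmp = 0.5, lmp = 0.5,
                          sid = FALSE, sip = FALSE, mdi = 5, mpi = 5,
                          track = TRUE) {
  p <- contact_params(ldd, fdd, lmc, fmc, ppc, frp, lrp, fmp, lmp,
                      sid, sip, mdi, mpi)
  p$pos <- .as_bool(pos, "pos")
  p$ats <- .as_bool(ats, "ats")
  p$track <- isTRUE(track)
  class(p) <- c("hybrid_params", "chain_params")
  p
}

#' @export
print.chain_params <- function(x, ...) {
  model <- sub("_params$", "", class(x)[1])
  cat(sprintf("<%s model parameters>\n", model))
  for (nm in names(x)) {
    v <- x[[nm]]
    if (inherits(v, "directional_distribution")) {
      cat(sprintf("  %-5s distal = %s%%\n", toupper(nm),
                  format(round(100 * v[["distal"]], 2))))
    } else if (inherits(v, "boolean_distribution")) {
      cat(sprintf("  %-5s true = %s%%\n", toupper(nm),
                  format(round(100 * v$p_true, 2))))
    } else {
      cat(sprintf("  %-5s %s\n", toupper(nm), format(v)))
    }
  }
  invisible(x)
}

## model code used by the compiled engine
.model_code <- function(params) {
  switch(class(params)[1],
    ecm_params = 0L, contact_params = 1L, hybrid_params = 2L,
    stop("not a chain_params object")
  )
}

## flatten a chain_params object into the engine's plain list
.engine_params <- function(params) {
  out <- list(
    ldd = as.numeric(params$ldd),
    fdd = as.numeric(params$fdd)
  )
  for (nm in c("pos", "ats", "lmc", "fmc", "ppc", "frp", "lrp", "fmp", "lmp")) {
    if (!is.null(params[[nm]])) out[[nm]] <- params[[nm]]$p_true
  }
  for (nm in c("sid", "sip", "mdi", "mpi", "track")) {
    if (!is.null(params[[nm]])) out[[nm]] <- params[[nm]]
  }
  out
}
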