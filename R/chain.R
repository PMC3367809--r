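## The formal chain criterion: sequential pairs, structural chain detection,
## and the minimum-velocity rule.

#' Are two agents sequential?
#'
#' Two agents are *sequential* when there are no empty sites between them
#' along the anterior-posterior axis (|dy| <= 1) and at most three empty
#' sites along the proximal-distal axis (|dx| <= 4).
#'
#' @param a,b Integer `c(x, y)` positions (0-based). Matrices with one
#'   position per row are compared row-wise.
#' @return Logical.
#' @examples
#' sequential_pair(c(10, 20), c(11, 20))  # TRUE: adjacent
#' sequential_pair(c(10, 20), c(15, 20))  # FALSE: four empty x sites
#' @export
sequential_pair <- function(a, b) {
  a <- matrix(a, ncol = 2)
  b <- matrix(b, ncol = 2)
  abs(a[, 1] - b[, 1]) <= 4 & abs(a[, 2] - b[, 2]) <= 1
}

#' Detect a migratory chain in an agent configuration
#'
#' A chain requires at least six *sequential* agents traversed front-to-back:
#' formally, an ordering of agents with non-increasing x in which every
#' consecutive pair satisfies [sequential_pair()]. `detect_chain()` finds the
#' longest such ordered sub-sequence; the configuration is a chain when it
#' has 6 or more members.
#'
#' @param positions Integer matrix, one agent per row, columns x and y
#'   (0-based).
#' @param timestamp Optional time step recorded on the assessment.
#' @return A `chain_assessment`: list with `is_chain`, `members` (row
#'   indices of the agents on the longest front-to-back sequence), `length`,
#'   and `timestamp`.
#' @examples
#' pos <- cbind(1:8, rep(22, 8))
#' detect_chain(pos)$is_chain  # TRUE: 8 agents in single file
#' @export
detect_chain <- function(positions, timestamp = NA_integer_) {
  positions <- matrix(as.integer(positions), ncol = 2)
  if (nrow(positions) < 1) stop("need at least one agent")
  res <- cpp_detect_chain(positions)
  structure(
    list(
      is_chain = res$is_chain,
      members = sort(res$members),
      length = res$length,
      timestamp = timestamp
    ),
    class = "chain_assessment"
  )
}

#' @export
print.chain_assessment <- function(x, ...) {
  cat(sprintf(
    "<chain_assessment> %s (%d sequential agents%s)\n",
    if (x$is_chain) "chain" else "no chain", x$length,
    if (is.na(x$timestamp)) "" else sprintf(", t = %d", x$timestamp)
  ))
  invisible(x)
}

#' Minimum-velocity verdict for a chain
#'
#' Chains must show a collective displacement towards the target of at least
#' one site every 10th time step. At each checkpoint (t = 10, 20, ...) the
#' verdict is `centroid[t] - centroid[t - 10] >= 1`; between checkpoints the
#' last verdict carries over, and before the first checkpoint the verdict is
#' `TRUE`. In a simulation a failed checkpoint ends the run: the chain
#' criterion (structure and velocity) no longer holds.
#'
#' @param centroids Numeric vector of the chain centroid's x position at
#'   steps `0, 1, ..., t` (so `centroids[i]` is the value at step `i - 1`).
#' @param t Time step at which to evaluate the verdict.
#' @return Logical verdict at step `t`.
#' @examples
#' velocity_ok(seq(0, 2, by = 0.1), 10)   # 1 site per 10 steps: TRUE
#' velocity_ok(rep(5, 21), 20)            # stationary: FALSE
#' @export
velocity_ok <- function(centroids, t) {
  if (t < 0 || t + 1 > length(centroids)) stop("centroid history too short")
  checkpoint <- (t %/% 10) * 10
  if (checkpoint < 10) return(TRUE)
  centroids[checkpoint + 1] - centroids[checkpoint - 10 + 1] >= 1
}
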