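## Categorical samplers over the 8 compass directions + none, and Boolean
## probability distributions. These are the three parameter kinds varied in
## the sensitivity analyses (integers, Booleans, probability distributions).

#' Directional probability distribution
#'
#' A categorical distribution over the nine admissible direction values (8
#' compass directions plus `"none"`; drawing `"none"` means no movement
#' decision is made that step). Probabilities must be non-negative and sum
#' to 1 (within 1e-9).
#'
#' @param probs Named numeric vector of probabilities. Names must be a
#'   subset of `directions()$direction`; omitted values get probability 0.
#' @return A `directional_distribution` object (named length-9 numeric).
#' @seealso [distal_biased_distribution()], [uniform_directional()]
#' @examples
#' directional_distribution(c(distal = 1))
#' @export
directional_distribution <- function(probs) {
  if (is.null(names(probs)) || any(names(probs) == "")) {
    stop("probabilities must be named by direction")
  }
  bad <- setdiff(names(probs), .direction_names)
  if (length(bad)) stop("unknown direction value(s): ", paste(bad, collapse = ", "))
  p <- stats::setNames(numeric(9), .direction_names)
  p[names(probs)] <- probs
  if (any(p < 0)) stop("directional probabilities must be non-negative")
  if (abs(sum(p) - 1) > 1e-9) {
    stop("directional probabilities must sum to 1 (got ", format(sum(p)), ")")
  }
  structure(p, class = "directional_distribution")
}

#' Uniform directional distribution
#'
#' All nine values equally likely (probability 1/9, about 11 per cent each):
#' the unbiased default used for baseline parameter sets.
#'
#' @return A `directional_distribution`.
#' @export
uniform_directional <- function() {
  directional_distribution(stats::setNames(rep(1 / 9, 9), .direction_names))
}

#' Distal-biased directional distribution
#'
#' Assigns probability `bias` to the target direction (`distal`) and spreads
#' the remainder equally over the other seven directions and `"none"`. A
#' bias of 1/9 recovers the uniform distribution; this one-parameter family
#' is how directional parameters are discretized in the sweeps.
#'
#' @param bias Probability of drawing `distal`, in `[1/9, 1]` by convention
#'   (any value in `[0, 1]` is accepted).
#' @return A `directional_distribution`.
#' @export
distal_biased_distribution <- function(bias) {
  if (bias < 0 || bias > 1) stop("bias must be a probability")
  p <- stats::setNames(rep((1 - bias) / 8, 9), .direction_names)
  p["distal"] <- bias
  directional_distribution(p)
}

#' @export
print.directional_distribution <- function(x, ...) {
  cat("<directional_distribution>\n")
  print(round(unclass(x), 4))
  invisible(x)
}

#' Boolean probability distribution
#'
#' @param p_true Probability of drawing `TRUE`.
#' @return A `boolean_distribution` object.
#' @examples
#' boolean_distribution(0.25)  # true = 25%, false = 75%
#' @export
boolean_distribution <- function(p_true) {
  if (!is.numeric(p_true) || length(p_true) != 1 || is.na(p_true) ||
      p_true < 0 || p_true > 1) {
    stop("p_true must be a single probability in [0, 1]")
  }
  structure(list(p_true = p_true), class = "boolean_distribution")
}

#' @export
print.boolean_distribution <- function(x, ...) {
  cat(sprintf("<boolean_distribution> true = %s%%, false = %s%%\n",
              format(100 * x$p_true), format(100 * (1 - x$p_true))))
  invisible(x)
}

#' Draw from a directional or Boolean distribution
#'
#' Uses R's global random number stream (`set.seed()` controls
#' reproducibility).
#'
#' @param dist A `directional_distribution` or `boolean_distribution`.
#' @param n Number of draws.
#' @return For directional distributions, a character vector of direction
#'   values; for Boolean distributions, a logical vector.
#' @examples
#' set.seed(1)
#' sample_distribution(distal_biased_distribution(1), 3)  # always "distal"
#' @export
sample_distribution <- function(dist, n = 1) {
  if (inherits(dist, "directional_distribution")) {
    sample(.direction_names, n, replace = TRUE, prob = unclass(dist))
  } else if (inherits(dist, "boolean_distribution")) {
    stats::runif(n) < dist$p_true
  } else {
    stop("not a directional_distribution or boolean_distribution")
  }
}
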