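#' Composition counts for an identity sample
#'
#' @param counts named nonnegative integer vector (group label -> number of
#'   individuals), or a character vector of labels which is tabulated.
#' @param max_richness maximum possible number of unique identity types in a
#'   sample; defaults to the number of labels in \code{counts}.
#' @return object of class \code{composition_counts}: list with
#'   \code{counts}, \code{N} and \code{max_richness}.
#' @export
composition_counts <- function(counts, max_richness = NULL) {
  if (is.character(counts) || is.factor(counts)) {
    counts <- table(as.character(counts))
    counts <- stats::setNames(as.integer(counts), names(counts))
  }
  if (is.null(names(counts))) {
    names(counts) <- paste0("group", seq_along(counts))
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be nonnegative integers")
  }
  N <- sum(counts)
  if (N < 1) stop("composition must contain at least one individual")
  if (is.null(max_richness)) max_richness <- length(counts)
  richness <- sum(counts > 0)
  if (max_richness < richness) {
    stop(sprintf("max_richness (%d) is below the observed richness (%d)",
                 max_richness, richness))
  }
  structure(list(counts = counts, N = N,
                 max_richness = as.integer(max_richness)),
            class = "composition_counts")
}

#' Shannon entropy of an identity composition
#'
#' H = -sum_i p_i ln(p_i) with p_i = n_i / N, natural logarithm, and the
#' convention 0 * ln 0 = 0 (types with zero count contribute nothing).
#' H captures both richness (how many types occur) and evenness (how
#' balanced their proportions are).
#'
#' @param composition a \code{composition_counts}, or anything accepted by
#'   \code{\link{composition_counts}}.
#' @return the entropy H >= 0 (in nats).
#' @export
shannon_entropy <- function(composition) {
  if (!inherits(composition, "composition_counts")) {
    composition <- composition_counts(composition)
  }
  p <- composition$counts / composition$N
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Identity diversity index
#'
#' D = exp(H) / max(r): the effective number of identity types present,
#' scaled by the maximum possible richness.  D lies in (0, 1], with values
#' near 1 indicating a sample both rich and even in identities.
#'
#' @param composition a \code{composition_counts} (or coercible).
#' @param max_richness optional override of the composition's maximum
#'   richness.
#' @return the identity diversity D.
#' @export
identity_diversity <- function(composition, max_richness = NULL) {
  if (!inherits(composition, "composition_counts")) {
    composition <- composition_counts(composition, max_richness)
  } else if (!is.null(max_richness)) {
    composition <- composition_counts(composition$counts, max_richness)
  }
  exp(shannon_entropy(composition)) / composition$max_richness
}

#' Cognitive diversity of a collection
#'
#' The mean of all C(N, 2) pairwise cognitive distances: how dissimilar, on
#' average, the individuals' mental models are.
#'
#' @param dm an \code{fcm_distmat} over at least two individuals.
#' @return mean pairwise CD in [0, 1].
#' @export
cognitive_diversity <- function(dm) {
  stopifnot(inherits(dm, "fcm_distmat"))
  if (length(dm$ids) < 2L) stop("need at least two individuals")
  mean(dm$cd[upper.tri(dm$cd)])
}
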