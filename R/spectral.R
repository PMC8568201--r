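#' Symmetric normalized Laplacian
#'
#' L^sym = D^{-1/2} (D - A) D^{-1/2} for a nonnegative symmetric weighted
#' adjacency A with degree d_i = sum_j a_ij.  Rows/columns of degree-zero
#' (isolated) nodes are set to zero by convention, so padding a map with
#' isolated concepts only appends zero eigenvalues and leaves the informative
#' part of the spectrum untouched.
#'
#' @param A_w symmetric matrix with nonnegative entries (see
#'   \code{\link{symmetrized_weighted_adjacency}}).
#' @return the symmetric normalized Laplacian matrix.
#' @export
normalized_laplacian <- function(A_w) {
  A_w <- as.matrix(A_w)
  if (nrow(A_w) != ncol(A_w) || !isSymmetric(unname(A_w), tol = 1e-12)) {
    stop("A_w must be a symmetric square matrix")
  }
  if (any(A_w < 0)) stop("A_w must have nonnegative entries")
  d <- rowSums(A_w)
  s <- ifelse(d > 0, 1 / sqrt(d), 0)
  L <- -outer(s, s) * A_w
  diag(L) <- diag(L) + as.numeric(d > 0)
  dimnames(L) <- dimnames(A_w)
  L
}

#' Spectrum of a normalized Laplacian with the 90%-mass truncation index
#'
#' Eigenvalues are sorted in descending order and clipped at zero after a
#' numerical-tolerance check (an eigenvalue below -1e-9 signals an invalid
#' matrix upstream and errors).  The truncation index k is the smallest
#' number of leading eigenvalues whose sum reaches at least 90% of the total
#' spectral mass (k = 0 for an all-zero spectrum).
#'
#' @param L symmetric normalized Laplacian.
#' @param coverage spectral-mass coverage threshold (default 0.9).
#' @return an object of class \code{spectral_summary}: list with
#'   \code{eigenvalues} (descending), \code{k} and \code{total_mass}.
#' @export
spectrum_summary <- function(L, coverage = 0.9) {
  ev <- eigen(L, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-9)) {
    stop(sprintf("negative eigenvalue %g: invalid Laplacian upstream",
                 min(ev)))
  }
  ev <- pmax(ev, 0)                      # descending already
  total <- sum(ev)
  k <- if (total == 0) 0L else {
    which(cumsum(ev) >= coverage * total - 1e-12)[1L]
  }
  structure(list(eigenvalues = ev, k = as.integer(k), total_mass = total),
            class = "spectral_summary")
}

#' Jaccard distance between dichotomized adjacency matrices
#'
#' d_J = 1 - |E1 intersect E2| / |E1 union E2|, treating each binary matrix
#' as a set of directed edges.  Two empty edge sets are maximally similar by
#' convention (J = 1, d_J = 0).
#'
#' @param A1,A2 binary matrices of identical shape over a shared universe.
#' @return the Jaccard distance in [0, 1].
#' @export
jaccard_distance <- function(A1, A2) {
  if (!identical(dim(A1), dim(A2))) {
    stop("adjacency matrices must have identical shape (shared universe)")
  }
  inter <- sum(A1 != 0 & A2 != 0)
  uni <- sum(A1 != 0 | A2 != 0)
  if (uni == 0) return(0)
  1 - inter / uni
}

#' Euclidean distance between truncated Laplacian spectra
#'
#' Uses the smaller of the two maps' 90%-mass truncation indices,
#' k* = min(k1, k2), and compares the k* largest eigenvalues:
#' d_s = sqrt(sum_{i<=k*} (lambda_1i - lambda_2i)^2).  If k* = 0 (at least
#' one all-zero spectrum) the distance is 0 by convention; such degenerate
#' pairs are flagged downstream.
#'
#' @param s1,s2 \code{spectral_summary} objects computed with the same
#'   coverage threshold.
#' @return the spectral distance (>= 0).
#' @export
spectral_graph_distance <- function(s1, s2) {
  stopifnot(inherits(s1, "spectral_summary"), inherits(s2, "spectral_summary"))
  k <- min(s1$k, s2$k)
  if (k == 0L) return(0)
  sqrt(sum((s1$eigenvalues[seq_len(k)] - s2$eigenvalues[seq_len(k)])^2))
}

# per-map precomputations shared by the pairwise routines
.map_signature <- function(map, universe, mode = "sum_abs") {
  idx <- .universe_index(map, universe)
  can <- canonical_label(universe)
  edges <- if (nrow(map$edges)) {
    paste(match(canonical_label(map$edges$source), can),
          match(canonical_label(map$edges$target), can), sep = "\r")
  } else character()
  spec <- spectrum_summary(
    normalized_laplacian(symmetrized_weighted_adjacency(map, universe, mode)))
  list(edges = edges, spectrum = spec)
}

#' Raw (unstandardized) cognitive distance between two maps
#'
#' Combines the structural Jaccard distance and the spectral distance into
#' raw = d_s / (1 - d_J).  Structurally disjoint maps (d_J = 1) are
#' maximally distant: raw = +Inf by convention (standardization later maps
#' this to CD = 1).
#'
#' @param m1,m2 \code{concept_map}s homogenized to the same node universe.
#' @param mode symmetrization mode passed to
#'   \code{\link{symmetrized_weighted_adjacency}}.
#' @return list with \code{d_j}, \code{d_s} and \code{raw}.
#' @export
raw_cognitive_distance <- function(m1, m2, mode = "sum_abs") {
  stopifnot(inherits(m1, "concept_map"), inherits(m2, "concept_map"))
  if (!identical(canonical_label(m1$nodes), canonical_label(m2$nodes))) {
    stop("maps must be homogenized to a shared universe before comparison")
  }
  u <- m1$nodes
  sig1 <- .map_signature(m1, u, mode)
  sig2 <- .map_signature(m2, u, mode)
  .pair_distance(sig1, sig2)
}

.pair_distance <- function(sig1, sig2) {
  inter <- length(intersect(sig1$edges, sig2$edges))
  uni <- length(union(sig1$edges, sig2$edges))
  d_j <- if (uni == 0) 0 else 1 - inter / uni
  d_s <- spectral_graph_distance(sig1$spectrum, sig2$spectrum)
  raw <- if (d_j == 1) Inf else d_s / (1 - d_j)
  list(d_j = d_j, d_s = d_s, raw = raw)
}

#' All pairwise cognitive distances with the phi standardization
#'
#' Computes d_J, d_s and raw = d_s/(1 - d_J) for every unordered pair, then
#' standardizes: phi = 1 / max(finite raw), CD = min(raw * phi, 1), with
#' CD = 1 wherever raw = +Inf.  phi is collection-relative: CD values are
#' comparable only within one analyzed collection.
#'
#' @param collection an \code{fcm_collection} with at least 2 maps.
#' @param mode symmetrization mode for the spectral term.
#' @param phi optional externally fixed standardization coefficient (for
#'   cross-collection comparability); default \code{NULL} computes it from
#'   this collection.
#' @return an object of class \code{fcm_distmat}: list with \code{ids},
#'   matrices \code{d_j}, \code{d_s}, \code{raw}, \code{cd}, the coefficient
#'   \code{phi} and a character vector \code{degenerate} flagging
#'   empty-spectrum or disjoint pairs.
#' @export
pairwise_distance_matrix <- function(collection, mode = "sum_abs",
                                     phi = NULL) {
  stopifnot(inherits(collection, "fcm_collection"))
  n <- length(collection$maps)
  if (n < 2L) stop("need at least two maps for pairwise distances")
  ids <- names(collection$maps)
  sigs <- lapply(collection$maps, .map_signature, universe = collection$universe,
                 mode = mode)

  d_j <- d_s <- raw <- matrix(0, n, n, dimnames = list(ids, ids))
  degenerate <- character()
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      p <- .pair_distance(sigs[[i]], sigs[[j]])
      d_j[i, j] <- d_j[j, i] <- p$d_j
      d_s[i, j] <- d_s[j, i] <- p$d_s
      raw[i, j] <- raw[j, i] <- p$raw
      if (is.infinite(p$raw)) {
        degenerate <- c(degenerate,
                        sprintf("disjoint edge sets: (%s, %s)", ids[i], ids[j]))
      } else if (min(sigs[[i]]$spectrum$k, sigs[[j]]$spectrum$k) == 0L &&
                 i < j) {
        degenerate <- c(degenerate,
                        sprintf("empty spectrum in pair (%s, %s)", ids[i], ids[j]))
      }
    }
  }

  off <- raw[upper.tri(raw)]
  finite_pos <- off[is.finite(off) & off > 0]
  if (is.null(phi)) {
    if (!length(finite_pos)) {
      if (all(off == 0)) {
        stop("phi undefined: all pairwise raw distances are zero ",
             "(all maps structurally and spectrally identical)")
      }
      if (all(is.infinite(off))) {
        stop("phi undefined: all pairs have disjoint edge sets ",
             "(every raw distance is infinite)")
      }
      # mixed zeros and infinities: no finite positive raw to anchor phi
      phi <- 1
      degenerate <- c(degenerate,
                      "phi fixed at 1: no finite positive raw distance")
    } else {
      phi <- 1 / max(finite_pos)
    }
  }
  cd <- pmin(raw * phi, 1)
  cd[is.infinite(raw)] <- 1
  cd[raw == 0] <- 0
  diag(cd) <- 0

  structure(list(ids = ids, d_j = d_j, d_s = d_s, raw = raw, cd = cd,
                 phi = phi, degenerate = degenerate),
            class = "fcm_distmat")
}

#' @export
print.fcm_distmat <- function(x, ...) {
  cat(sprintf("<fcm_distmat: %d individuals, phi = %.6g, %d degenerate pair flag(s)>\n",
              length(x$ids), x$phi, length(x$degenerate)))
  invisible(x)
}

#' Export a distance matrix as a long-format data.frame
#'
#' One row per unordered pair: \code{id1, id2, d_j, d_s, raw, cd}.
#'
#' @param dm an \code{fcm_distmat}.
#' @return a data.frame.
#' @export
distances_long <- function(dm) {
  stopifnot(inherits(dm, "fcm_distmat"))
  n <- length(dm$ids)
  ut <- which(upper.tri(dm$cd), arr.ind = TRUE)
  ut <- ut[order(ut[, 1L], ut[, 2L]), , drop = FALSE]
  data.frame(id1 = dm$ids[ut[, 1L]], id2 = dm$ids[ut[, 2L]],
             d_j = dm$d_j[ut], d_s = dm$d_s[ut], raw = dm$raw[ut],
             cd = dm$cd[ut], stringsAsFactors = FALSE)
}
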