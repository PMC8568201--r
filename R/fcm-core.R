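#' Canonical form of a concept label
#'
#' Trims leading/trailing whitespace, collapses internal whitespace runs and
#' case-folds.  Canonical forms are used for matching and ordering; original
#' casing is preserved for display.
#'
#' @param x character vector of labels.
#' @return character vector of canonical labels.
#' @export
canonical_label <- function(x) {
  tolower(gsub("[[:space:]]+", " ", trimws(as.character(x))))
}

# locale-independent lexicographic order over canonical labels
.label_order <- function(x) order(canonical_label(x), method = "radix")

#' Construct a fuzzy cognitive map
#'
#' A concept map is a labeled, weighted, directed graph: one individual's
#' mental model of a system.  Edge weights lie in [-1, +1] and encode the
#' sign and strength of a perceived causal influence; a zero weight means
#' "edge absent" and is rejected.
#'
#' @param id map identifier (length-1 character).
#' @param edges a data.frame with columns \code{source}, \code{target},
#'   \code{weight}, or \code{NULL} for an edgeless map.
#' @param nodes character vector of concept labels; endpoints of edges are
#'   added automatically.
#' @return an object of class \code{concept_map} with elements \code{id},
#'   \code{nodes} (sorted lexicographically on the canonical form),
#'   \code{edges} (data.frame sorted by source then target) and
#'   \code{self_loops} (character vector of flagged self-loop edges).
#' @export
concept_map <- function(id, edges = NULL, nodes = character()) {
  stopifnot(is.character(id) || is.numeric(id), length(id) == 1L)
  id <- as.character(id)
  if (is.null(edges)) {
    edges <- data.frame(source = character(), target = character(),
                        weight = numeric(), stringsAsFactors = FALSE)
  }
  if (!all(c("source", "target", "weight") %in% names(edges))) {
    stop("edges must have columns source, target, weight")
  }
  edges <- data.frame(source = as.character(edges$source),
                      target = as.character(edges$target),
                      weight = as.numeric(edges$weight),
                      stringsAsFactors = FALSE)
  if (anyNA(edges$weight)) stop("edge weights must be numeric and non-missing")

  bad <- which(edges$weight < -1 | edges$weight > 1 | edges$weight == 0)
  if (length(bad)) {
    e <- edges[bad[1L], ]
    stop(sprintf(
      "invalid weight %g on edge (%s, %s): weights must lie in [-1, +1] and be nonzero",
      e$weight, e$source, e$target))
  }

  key <- paste(canonical_label(edges$source), canonical_label(edges$target),
               sep = "\r")
  if (anyDuplicated(key)) {
    d <- edges[duplicated(key), , drop = FALSE][1L, ]
    stop(sprintf("duplicate edge (%s, %s): at most one edge per ordered pair",
                 d$source, d$target))
  }

  nodes <- as.character(nodes)
  all_nodes <- c(nodes, edges$source, edges$target)
  all_nodes <- all_nodes[!duplicated(canonical_label(all_nodes))]
  if (anyDuplicated(canonical_label(nodes))) {
    stop("node labels must be unique after canonical normalization")
  }
  all_nodes <- all_nodes[.label_order(all_nodes)]

  edges <- edges[order(canonical_label(edges$source),
                       canonical_label(edges$target), method = "radix"), ,
                 drop = FALSE]
  rownames(edges) <- NULL

  loops <- which(canonical_label(edges$source) == canonical_label(edges$target))
  structure(
    list(id = id, nodes = all_nodes, edges = edges,
         self_loops = sprintf("%s -> %s", edges$source[loops],
                              edges$target[loops])),
    class = "concept_map")
}

#' @export
print.concept_map <- function(x, ...) {
  cat(sprintf("<concept_map '%s': %d nodes, %d edges%s>\n",
              x$id, length(x$nodes), nrow(x$edges),
              if (length(x$self_loops))
                sprintf(", %d self-loop(s)", length(x$self_loops)) else ""))
  invisible(x)
}

# index of a map's nodes inside a universe (canonical matching); errors on
# nodes outside the universe
.universe_index <- function(map, universe) {
  idx <- match(canonical_label(map$nodes), canonical_label(universe))
  if (anyNA(idx)) {
    stop(sprintf("node '%s' of map '%s' is not in the universe",
                 map$nodes[which(is.na(idx))[1L]], map$id))
  }
  idx
}

#' Dichotomized adjacency matrix
#'
#' Binary presence/absence matrix of the directed edges of a map over a node
#' universe: entry (i, j) is 1 iff the directed edge i -> j is present,
#' regardless of the sign or strength of the weight.
#'
#' @param map a \code{concept_map}.
#' @param universe character vector of concept labels; defaults to the map's
#'   own node set.  Rows are sources, columns targets.
#' @return an n x n 0/1 matrix with \code{universe} as dimnames.
#' @export
dichotomized_adjacency <- function(map, universe = map$nodes) {
  stopifnot(inherits(map, "concept_map"))
  .universe_index(map, universe)
  n <- length(universe)
  A <- matrix(0, n, n, dimnames = list(universe, universe))
  if (nrow(map$edges)) {
    i <- match(canonical_label(map$edges$source), canonical_label(universe))
    j <- match(canonical_label(map$edges$target), canonical_label(universe))
    A[cbind(i, j)] <- 1
  }
  A
}

#' Directed weighted adjacency matrix
#'
#' @param map a \code{concept_map}.
#' @param universe node universe (defaults to the map's nodes).
#' @return an n x n matrix of signed weights; 0 encodes absence.
#' @export
weighted_adjacency <- function(map, universe = map$nodes) {
  stopifnot(inherits(map, "concept_map"))
  .universe_index(map, universe)
  n <- length(universe)
  W <- matrix(0, n, n, dimnames = list(universe, universe))
  if (nrow(map$edges)) {
    i <- match(canonical_label(map$edges$source), canonical_label(universe))
    j <- match(canonical_label(map$edges$target), canonical_label(universe))
    W[cbind(i, j)] <- map$edges$weight
  }
  W
}

#' Symmetrized nonnegative weighted adjacency
#'
#' Converts the directed, signed FCM into the undirected, nonnegative
#' weighted adjacency matrix used for the normalized-Laplacian spectrum.
#' The default \code{sum_abs} sets a_ij = a_ji = |w(i->j)| + |w(j->i)|,
#' preserving the total causal intensity of a dyad; \code{max_abs} and
#' \code{mean_abs} take the elementwise max/mean of the two absolute
#' weights.  Self-loops contribute |w| on the diagonal.  Absolute values
#' guarantee nonnegative entries and hence a real, nonnegative Laplacian
#' spectrum.
#'
#' @param map a \code{concept_map}.
#' @param universe node universe.
#' @param mode one of \code{"sum_abs"}, \code{"max_abs"}, \code{"mean_abs"}.
#' @return a symmetric matrix with nonnegative entries.
#' @export
symmetrized_weighted_adjacency <- function(map, universe = map$nodes,
                                           mode = c("sum_abs", "max_abs",
                                                    "mean_abs")) {
  mode <- match.arg(mode)
  M <- abs(weighted_adjacency(map, universe))
  S <- switch(mode,
              sum_abs  = M + t(M),
              max_abs  = pmax(M, t(M)),
              # average over the directed edges actually present in the dyad
              mean_abs = (M + t(M)) / pmax((M > 0) + (t(M) > 0), 1))
  diag(S) <- diag(M)
  S
}

#' Quantitative homogenization of a set of concept maps
#'
#' Pads every map to the union concept set: the universe is the sorted union
#' of all node labels and each map gains its absent concepts as isolated
#' (degree-zero) nodes.  No edge is added, removed or reweighted.  This makes
#' all adjacency matrices the same size and hence comparable.
#'
#' @param maps list of \code{concept_map} objects with distinct ids.
#' @param identities group label for every map: either a named character
#'   vector (names = map ids) or a data.frame whose first two columns are
#'   individual id and group label.
#' @return an object of class \code{fcm_collection}: list with elements
#'   \code{universe}, \code{maps} (each padded to the universe) and
#'   \code{identities} (named character vector aligned with the maps).
#' @export
homogenize_collection <- function(maps, identities) {
  if (length(maps) < 1L) stop("need at least one map")
  stopifnot(all(vapply(maps, inherits, logical(1), "concept_map")))
  ids <- vapply(maps, function(m) m$id, character(1))
  if (anyDuplicated(ids)) stop("map ids must be unique")

  if (is.data.frame(identities)) {
    identities <- stats::setNames(as.character(identities[[2L]]),
                                  as.character(identities[[1L]]))
  }
  missing <- setdiff(ids, names(identities))
  if (length(missing)) {
    stop("missing identity label for map(s): ", paste(missing, collapse = ", "))
  }
  identities <- identities[ids]

  all_nodes <- unlist(lapply(maps, function(m) m$nodes), use.names = FALSE)
  universe <- all_nodes[!duplicated(canonical_label(all_nodes))]
  universe <- universe[.label_order(universe)]

  padded <- lapply(maps, function(m) {
    m$nodes <- universe
    m
  })
  names(padded) <- ids
  structure(list(universe = universe, maps = padded, identities = identities),
            class = "fcm_collection")
}

#' @export
print.fcm_collection <- function(x, ...) {
  cat(sprintf("<fcm_collection: %d maps over %d concepts, %d group(s)>\n",
              length(x$maps), length(x$universe),
              length(unique(x$identities))))
  invisible(x)
}

#' Apply a synonym table to a concept map (qualitative homogenization)
#'
#' Renames concepts according to a raw -> canonical synonym table.  When a
#' renaming merges two concepts, parallel edges landing on the same ordered
#' pair are combined by \code{merge_rule}; a merged weight of exactly zero
#' drops the edge (zero encodes absence).  Merges that create self-loops are
#' kept but flagged.  The synonym semantics (which terms mean the same
#' thing) are entirely the user's: the table is applied mechanically.
#'
#' @param map a \code{concept_map}.
#' @param table a \code{synonym_table} (see \code{\link{synonym_table}}).
#' @param merge_rule \code{"mean"} (default, clipped to [-1, +1]) or
#'   \code{"max_abs"} (weight of largest magnitude, ties broken toward the
#'   positive value).
#' @return the renamed/merged \code{concept_map}, with an attribute
#'   \code{"report"} listing \code{merged_nodes}, \code{dropped_edges} and
#'   \code{self_loops_created}.
#' @export
apply_synonym_table <- function(map, table, merge_rule = c("mean", "max_abs")) {
  stopifnot(inherits(map, "concept_map"), inherits(table, "synonym_table"))
  merge_rule <- match.arg(merge_rule)

  lookup <- stats::setNames(table$canonical, canonical_label(table$raw))
  rename <- function(x) {
    hit <- lookup[canonical_label(x)]
    ifelse(is.na(hit), x, hit)
  }

  new_nodes <- rename(map$nodes)
  merged <- new_nodes[duplicated(canonical_label(new_nodes))]

  ed <- map$edges
  dropped <- character()
  loops_created <- character()
  if (nrow(ed)) {
    was_loop <- canonical_label(ed$source) == canonical_label(ed$target)
    n_prior_loops <- sum(was_loop)
    ed$source <- rename(ed$source)
    ed$target <- rename(ed$target)
    key <- paste(canonical_label(ed$source), canonical_label(ed$target),
                 sep = "\r")
    comb <- lapply(split(seq_len(nrow(ed)), key), function(ix) {
      w <- ed$weight[ix]
      wm <- switch(merge_rule,
                   mean = max(-1, min(1, mean(w))),
                   max_abs = {
                     top <- w[abs(w) == max(abs(w))]
                     if (any(top > 0)) max(top) else min(top)
                   })
      data.frame(source = ed$source[ix[1L]], target = ed$target[ix[1L]],
                 weight = wm, n_merged = length(ix),
                 stringsAsFactors = FALSE)
    })
    ed <- do.call(rbind, comb)
    zero <- ed$weight == 0
    if (any(zero)) {
      dropped <- paste0(ed$source[zero], " -> ", ed$target[zero])
    }
    is_loop <- ed$weight != 0 &
      canonical_label(ed$source) == canonical_label(ed$target)
    if (sum(is_loop) > n_prior_loops) {
      loops_created <- paste0(ed$source[is_loop], " -> ", ed$target[is_loop])
    }
    ed <- ed[!zero, c("source", "target", "weight"), drop = FALSE]
  }

  out <- concept_map(map$id, edges = ed,
                     nodes = new_nodes[!duplicated(canonical_label(new_nodes))])
  attr(out, "report") <- list(merged_nodes = unique(merged),
                              dropped_edges = dropped,
                              self_loops_created = loops_created)
  out
}
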