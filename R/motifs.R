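#' The default catalog of seven causal micro-motifs
#'
#' Directed graphlets on 2-3 distinct nodes representing the elementary
#' patterns of perceived causation in a cognitive map:
#' \enumerate{
#'   \item \code{direct}: A -> B
#'   \item \code{reciprocal}: A -> B and B -> A
#'   \item \code{chain}: A -> B -> C
#'   \item \code{fork}: A -> B, A -> C (common cause)
#'   \item \code{collider}: A -> C, B -> C (common effect)
#'   \item \code{cycle3}: A -> B -> C -> A (feedback loop)
#'   \item \code{transitive}: A -> B -> C with the shortcut A -> C
#' }
#' Each pattern is a required edge set over abstract roles; occurrences are
#' counted up to role automorphism, with extra edges allowed
#' (pattern-occurrence, not induced-subgraph, semantics).  The catalog is
#' configurable: any list of such patterns (e.g. loaded from JSON via
#' \code{\link{read_motif_catalog}}) can replace the default.
#'
#' @return object of class \code{motif_catalog}: named list of character
#'   matrices (rows = required edges, columns = from/to roles).
#' @export
default_motif_catalog <- function() {
  pat <- function(...) matrix(c(...), ncol = 2L, byrow = TRUE,
                              dimnames = list(NULL, c("from", "to")))
  structure(list(
    direct     = pat("A", "B"),
    reciprocal = pat("A", "B", "B", "A"),
    chain      = pat("A", "B", "B", "C"),
    fork       = pat("A", "B", "A", "C"),
    collider   = pat("A", "C", "B", "C"),
    cycle3     = pat("A", "B", "B", "C", "C", "A"),
    transitive = pat("A", "B", "B", "C", "A", "C")
  ), class = "motif_catalog")
}

#' Load a motif catalog from JSON
#'
#' Expected shape: \code{{"name": [["A","B"], ...], ...}} mapping motif
#' names to lists of directed role edges.
#'
#' @param path JSON file path.
#' @return a \code{motif_catalog}.
#' @export
read_motif_catalog <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!length(doc)) stop("motif catalog is empty")
  cat_list <- lapply(doc, function(edges) {
    m <- do.call(rbind, lapply(edges, function(e) {
      c(as.character(e[[1L]]), as.character(e[[2L]]))
    }))
    colnames(m) <- c("from", "to")
    m
  })
  structure(cat_list, class = "motif_catalog")
}

# number of role permutations preserving a pattern's edge set
.motif_automorphisms <- function(pattern) {
  roles <- sort(unique(as.vector(pattern)))
  key <- function(p) {
    m <- matrix(p[match(pattern, roles)], ncol = 2L)
    paste(sort(paste(m[, 1L], m[, 2L])), collapse = ";")
  }
  perms <- .permutations(roles)
  ref <- key(roles)
  sum(vapply(perms, function(p) key(p) == ref, TRUE))
}

.permutations <- function(x) {
  if (length(x) == 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in .permutations(x[-i])) out <- c(out, list(c(x[i], rest)))
  }
  out
}

# generic occurrence counter: injective role assignments / |Aut|
.count_pattern <- function(A, pattern) {
  roles <- sort(unique(as.vector(pattern)))
  r <- length(roles)
  n <- nrow(A)
  if (n < r) return(0L)
  aut <- .motif_automorphisms(pattern)
  from_i <- match(pattern[, 1L], roles)
  to_i <- match(pattern[, 2L], roles)
  total <- 0L
  idx <- seq_len(n)
  if (r == 2L) {
    for (a in idx) for (b in idx) {
      if (a != b && all(A[cbind(c(a, b)[from_i], c(a, b)[to_i])] != 0)) {
        total <- total + 1L
      }
    }
  } else if (r == 3L) {
    for (a in idx) for (b in idx) for (c0 in idx) {
      if (a != b && a != c0 && b != c0 &&
          all(A[cbind(c(a, b, c0)[from_i], c(a, b, c0)[to_i])] != 0)) {
        total <- total + 1L
      }
    }
  } else {
    stop("motif patterns must span 2 or 3 roles")
  }
  total %/% aut
}

# closed-form counts for the default catalog (A binary, zero diagonal)
.count_default_motifs <- function(A) {
  M <- A * t(A)
  outd <- rowSums(A)
  ind <- colSums(A)
  A2 <- A %*% A
  c(direct     = sum(A),
    reciprocal = sum(M) / 2,
    chain      = sum(ind * outd) - sum(M),
    fork       = sum(outd * (outd - 1) / 2),
    collider   = sum(ind * (ind - 1) / 2),
    cycle3     = sum(A2 * t(A)) / 3,
    transitive = sum(A2 * A))
}

#' Count micro-motif occurrences in one map
#'
#' Counts, for each catalog motif, the number of distinct node subsets with
#' a role assignment whose required edges are all present (extra edges
#' allowed; occurrences counted once per automorphism class).  Edge weights
#' and signs are ignored, and self-loops are excluded: motifs are purely
#' structural and defined on distinct nodes.
#'
#' @param map a \code{concept_map}.
#' @param catalog a \code{motif_catalog} (default
#'   \code{\link{default_motif_catalog}}).
#' @return object of class \code{motif_profile}: list with \code{map_id},
#'   integer \code{counts}, \code{frequencies} (counts / total; all zero
#'   with \code{degenerate = TRUE} when the map has no motif occurrences).
#' @export
count_motifs <- function(map, catalog = default_motif_catalog()) {
  stopifnot(inherits(map, "concept_map"))
  if (!length(catalog)) stop("motif catalog is empty")
  A <- dichotomized_adjacency(map)
  diag(A) <- 0

  counts <- if (identical(names(catalog), names(default_motif_catalog()))) {
    .count_default_motifs(A)
  } else {
    vapply(catalog, function(p) as.numeric(.count_pattern(A, p)), 0)
  }
  counts <- stats::setNames(as.numeric(counts), names(catalog))
  total <- sum(counts)
  freq <- if (total > 0) counts / total else counts * 0
  structure(list(map_id = map$id, counts = counts, frequencies = freq,
                 degenerate = total == 0),
            class = "motif_profile")
}

#' Motif profiles for every map in a collection
#'
#' @param collection an \code{fcm_collection}.
#' @param catalog a \code{motif_catalog}.
#' @return data.frame (one row per map, ordered by map id as stored):
#'   \code{map_id}, one frequency column per motif, one \code{n_} count
#'   column per motif, and \code{degenerate}.
#' @export
motif_profiles <- function(collection, catalog = default_motif_catalog()) {
  stopifnot(inherits(collection, "fcm_collection"))
  profs <- lapply(collection$maps, count_motifs, catalog = catalog)
  freq <- do.call(rbind, lapply(profs, `[[`, "frequencies"))
  cnts <- do.call(rbind, lapply(profs, `[[`, "counts"))
  colnames(cnts) <- paste0("n_", colnames(cnts))
  out <- data.frame(map_id = vapply(profs, `[[`, "", "map_id"),
                    freq, cnts,
                    degenerate = vapply(profs, `[[`, TRUE, "degenerate"),
                    stringsAsFactors = FALSE, row.names = NULL)
  out
}

#' PCA embedding of motif-frequency profiles
#'
#' Columns are z-scored when \code{standardize} (zero-variance columns left
#' at zero), components are ordered by decreasing explained variance, and
#' each component's sign is fixed so that its largest-magnitude loading is
#' positive, making the embedding reproducible.
#'
#' @param profiles data.frame from \code{\link{motif_profiles}} or a
#'   numeric matrix of motif frequencies.
#' @param n_components number of components to retain (default 2).
#' @param standardize z-score the motif dimensions first (default FALSE:
#'   raw frequency covariance, which concentrates the between-map variance
#'   on the leading components).
#' @return list with \code{coordinates} (n x n_components score matrix,
#'   rownames = map ids), \code{variance_explained} (proportions) and
#'   \code{loadings}.
#' @export
pca_embed <- function(profiles, n_components = 2L, standardize = FALSE) {
  if (is.data.frame(profiles)) {
    freq_cols <- setdiff(names(profiles),
                         c("map_id", "degenerate",
                           grep("^n_", names(profiles), value = TRUE)))
    X <- as.matrix(profiles[, freq_cols, drop = FALSE])
    rownames(X) <- profiles$map_id
  } else {
    X <- as.matrix(profiles)
  }
  if (nrow(X) < 3L) stop("need at least 3 profiles")
  if (n_components > ncol(X)) stop("n_components exceeds motif dimensions")
  Xc <- scale(X, center = TRUE, scale = FALSE)
  if (standardize) {
    sds <- apply(X, 2L, stats::sd)
    pos <- sds > 0
    Xc[, pos] <- sweep(Xc[, pos, drop = FALSE], 2L, sds[pos], "/")
  }
  if (all(abs(Xc) < 1e-14)) stop("all profiles identical: no variance for PCA")
  pc <- stats::prcomp(Xc, center = FALSE, scale. = FALSE)
  flip <- vapply(seq_len(ncol(pc$rotation)), function(j) {
    v <- pc$rotation[, j]
    if (v[which.max(abs(v))] < 0) -1 else 1
  }, 0)
  rot <- sweep(pc$rotation, 2L, flip, "*")
  scores <- Xc %*% rot
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  k <- seq_len(n_components)
  list(coordinates = scores[, k, drop = FALSE],
       variance_explained = ve[k],
       loadings = rot[, k, drop = FALSE])
}

#' K-means clustering of embedded maps
#'
#' Best-of-restarts k-means on the PC coordinates (Euclidean distance),
#' deterministic for a fixed seed.  Cluster indices are relabeled in order
#' of first appearance so the labeling is stable.
#'
#' @param coordinates numeric matrix (rows = maps).
#' @param k number of clusters; a sensible default is the number of
#'   distinct identity labels.
#' @param rng_seed integer seed.
#' @param n_restarts random restarts (default 10).
#' @return integer vector of cluster indices named by map id.
#' @export
kmeans_assign <- function(coordinates, k, rng_seed = 1L, n_restarts = 10L) {
  coordinates <- as.matrix(coordinates)
  if (k < 1L) stop("k must be at least 1")
  if (k > nrow(coordinates)) stop("k exceeds the number of points")
  if (k == nrow(coordinates)) {          # every point its own cluster
    return(stats::setNames(seq_len(k), rownames(coordinates)))
  }
  if (!is.null(rng_seed)) set.seed(rng_seed)
  km <- stats::kmeans(coordinates, centers = k, nstart = n_restarts,
                      iter.max = 100L)
  cl <- km$cluster
  relabel <- match(cl, unique(cl))
  stats::setNames(relabel, rownames(coordinates))
}

#' Concurrency of cognitive clusters and social identities
#'
#' concurrency[c, g] is the fraction of cluster-c members carrying identity
#' g; each row sums to 1.  A cluster's dominant identity is the row
#' maximum; a dominant probability above 0.5 means the majority of a
#' cognitive cluster shares one social identity.
#'
#' @param cluster_of named integer vector (map id -> cluster index).
#' @param identities named character vector (map id -> group label).
#' @return list with \code{concurrency} (cluster x identity matrix) and
#'   \code{dominant} (data.frame \code{cluster, identity, probability}).
#' @export
concurrency_matrix <- function(cluster_of, identities) {
  miss <- setdiff(names(cluster_of), names(identities))
  if (length(miss)) stop("missing identity for map(s): ",
                         paste(miss, collapse = ", "))
  g <- as.character(identities[names(cluster_of)])
  tab <- table(cluster = cluster_of, identity = g)
  empty <- rowSums(tab) == 0
  if (any(empty)) {
    warning("empty cluster(s) omitted: ",
            paste(rownames(tab)[empty], collapse = ", "))
    tab <- tab[!empty, , drop = FALSE]
  }
  conc <- sweep(unclass(tab), 1L, rowSums(tab), "/")
  dom <- data.frame(
    cluster = rownames(conc),
    identity = colnames(conc)[apply(conc, 1L, which.max)],
    probability = apply(conc, 1L, max),
    stringsAsFactors = FALSE, row.names = NULL)
  list(concurrency = conc, dominant = dom)
}

#' Motif-based clustering pipeline for a collection
#'
#' Convenience wrapper: motif profiles -> 2-component PCA -> k-means ->
#' identity concurrency.
#'
#' @param collection an \code{fcm_collection}.
#' @param k number of clusters; default = number of distinct identities.
#' @param rng_seed integer seed for k-means.
#' @param catalog motif catalog.
#' @param standardize passed to \code{\link{pca_embed}}.
#' @return object of class \code{fcm_clustering}: list with
#'   \code{profiles}, \code{coordinates}, \code{variance_explained},
#'   \code{cluster_of}, \code{concurrency}, \code{dominant}.
#' @export
cluster_by_motifs <- function(collection, k = NULL, rng_seed = 1L,
                              catalog = default_motif_catalog(),
                              standardize = FALSE) {
  stopifnot(inherits(collection, "fcm_collection"))
  if (is.null(k)) k <- length(unique(collection$identities))
  prof <- motif_profiles(collection, catalog)
  emb <- pca_embed(prof, n_components = 2L, standardize = standardize)
  cl <- kmeans_assign(emb$coordinates, k = k, rng_seed = rng_seed)
  conc <- concurrency_matrix(cl, collection$identities)
  structure(list(profiles = prof, coordinates = emb$coordinates,
                 variance_explained = emb$variance_explained,
                 cluster_of = cl, concurrency = conc$concurrency,
                 dominant = conc$dominant),
            class = "fcm_clustering")
}

#' @export
print.fcm_clustering <- function(x, ...) {
  cat(sprintf(
    "<fcm_clustering: %d maps, %d clusters, 2 PCs explain %.1f%% of variance>\n",
    nrow(x$coordinates), nrow(x$concurrency),
    100 * sum(x$variance_explained)))
  print(x$dominant, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Scatter plot of the motif PC embedding
#'
#' Base-graphics scatter of PC1/PC2, colored by social identity (default)
#' or by cognitive cluster.
#'
#' @param x an \code{fcm_clustering}.
#' @param color_by \code{"identity"} or \code{"cluster"}.
#' @param identities named character vector, required for
#'   \code{color_by = "identity"}.
#' @param ... passed to \code{plot}.
#' @export
plot.fcm_clustering <- function(x, color_by = c("identity", "cluster"),
                                identities = NULL, ...) {
  color_by <- match.arg(color_by)
  lab <- if (color_by == "cluster") {
    factor(x$cluster_of[rownames(x$coordinates)])
  } else {
    if (is.null(identities)) stop("supply identities for color_by='identity'")
    factor(as.character(identities[rownames(x$coordinates)]))
  }
  graphics::plot(x$coordinates[, 1L], x$coordinates[, 2L],
                 col = as.integer(lab), pch = 19, cex = 0.6,
                 xlab = sprintf("PC1 (%.1f%%)", 100 * x$variance_explained[1L]),
                 ylab = sprintf("PC2 (%.1f%%)", 100 * x$variance_explained[2L]),
                 ...)
  graphics::legend("topright", legend = levels(lab),
                   col = seq_along(levels(lab)), pch = 19, cex = 0.7)
  invisible(x)
}
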