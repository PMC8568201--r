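# Independent brute-force oracles used to verify the package's optimized
# implementations.  These are deliberately naive re-derivations from first
# principles and never call the code paths they check.

# Jaccard distance by explicit elementwise double loop
oracle_jaccard <- function(A1, A2) {
  inter <- 0; uni <- 0
  for (i in seq_len(nrow(A1))) {
    for (j in seq_len(ncol(A1))) {
      p1 <- A1[i, j] != 0
      p2 <- A2[i, j] != 0
      if (p1 && p2) inter <- inter + 1
      if (p1 || p2) uni <- uni + 1
    }
  }
  if (uni == 0) return(0)
  1 - inter / uni
}

# eigenvalues as roots of the characteristic polynomial (pracma).  Root
# finding splits a multiple root symmetrically (to first order), so roots
# closer than 1e-5 are replaced by their cluster mean to recover the
# multiple root accurately.
oracle_eigenvalues <- function(M) {
  cp <- pracma::charpoly(M)
  ev <- sort(Re(polyroot(rev(cp))), decreasing = TRUE)
  cl <- cumsum(c(1, diff(ev) < -1e-5))
  unlist(lapply(split(ev, cl), function(g) rep(mean(g), length(g))),
         use.names = FALSE)
}

# truncation index by literal reading of the 90% rule
oracle_k <- function(ev, coverage = 0.9) {
  total <- sum(ev)
  if (total == 0) return(0L)
  for (k in seq_along(ev)) {
    if (sum(ev[seq_len(k)]) >= coverage * total - 1e-12) return(k)
  }
  length(ev)
}

# raw cognitive distance recomputed from scratch for a pair of maps
oracle_raw_cd <- function(m1, m2) {
  u <- m1$nodes
  d_j <- oracle_jaccard(dichotomized_adjacency(m1, u),
                        dichotomized_adjacency(m2, u))
  ev <- function(m) {
    S <- symmetrized_weighted_adjacency(m, u)
    d <- rowSums(S)
    L <- diag(ifelse(d > 0, 1, 0))
    for (i in seq_along(d)) for (j in seq_along(d)) {
      if (S[i, j] != 0) L[i, j] <- L[i, j] - S[i, j] / sqrt(d[i] * d[j])
    }
    pmax(sort(eigen(L, symmetric = TRUE, only.values = TRUE)$values,
              decreasing = TRUE), 0)
  }
  e1 <- ev(m1); e2 <- ev(m2)
  k <- min(oracle_k(e1), oracle_k(e2))
  d_s <- if (k == 0) 0 else sqrt(sum((e1[seq_len(k)] - e2[seq_len(k)])^2))
  raw <- if (d_j == 1) Inf else d_s / (1 - d_j)
  list(d_j = d_j, d_s = d_s, raw = raw)
}

# exhaustive enumeration of motif occurrences over ordered pairs/triples
oracle_motif_counts <- function(A) {
  diag(A) <- 0
  n <- nrow(A)
  cnt <- c(direct = 0, reciprocal = 0, chain = 0, fork = 0, collider = 0,
           cycle3 = 0, transitive = 0)
  for (a in seq_len(n)) for (b in seq_len(n)) {
    if (a == b) next
    if (A[a, b]) cnt["direct"] <- cnt["direct"] + 1
    if (a < b && A[a, b] && A[b, a]) cnt["reciprocal"] <- cnt["reciprocal"] + 1
  }
  if (n >= 3) {
    for (a in seq_len(n)) for (b in seq_len(n)) for (c0 in seq_len(n)) {
      if (a == b || a == c0 || b == c0) next
      if (A[a, b] && A[b, c0]) cnt["chain"] <- cnt["chain"] + 1
      if (b < c0 && A[a, b] && A[a, c0]) cnt["fork"] <- cnt["fork"] + 1
      if (a < b && A[a, c0] && A[b, c0]) cnt["collider"] <- cnt["collider"] + 1
      if (a < b && a < c0 && A[a, b] && A[b, c0] && A[c0, a]) {
        cnt["cycle3"] <- cnt["cycle3"] + 1    # one orientation per rotation class
      }
      if (A[a, b] && A[b, c0] && A[a, c0]) {
        cnt["transitive"] <- cnt["transitive"] + 1
      }
    }
  }
  cnt
}

# Welch t statistic from the closed-form definition
oracle_welch <- function(a, b) {
  se2 <- stats::var(a) / length(a) + stats::var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / (stats::var(a)^2 / (length(a)^2 * (length(a) - 1)) +
                 stats::var(b)^2 / (length(b)^2 * (length(b) - 1)))
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

# random valid concept map over given node labels
random_map <- function(id, nodes, n_edges, allow_loops = FALSE) {
  pairs <- expand.grid(source = nodes, target = nodes,
                       stringsAsFactors = FALSE)
  if (!allow_loops) pairs <- pairs[pairs$source != pairs$target, ]
  pick <- pairs[sample.int(nrow(pairs), min(n_edges, nrow(pairs))), ]
  w <- stats::runif(nrow(pick), -1, 1)
  w[w == 0] <- 0.5
  pick$weight <- w
  concept_map(id, edges = pick)
}
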