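#' Specification of a synthetic FCM population
#'
#' Describes K groups of virtual stakeholders over a shared concept
#' universe.  Each group owns an edge set of size \code{edges_per_group}: a
#' fraction \code{overlap} of it is a common core shared by all groups
#' (with identical inclusion frequencies and weight distributions), the
#' rest is private and pairwise disjoint across groups.  \code{overlap}
#' therefore acts as the between-group separation knob
#' (separation = 1 - overlap): at \code{overlap = 1} the group labels carry
#' no information, at \code{overlap = 0} the groups share no structure.
#'
#' Defaults emulate a stakeholder study at interview scale: 5 social
#' groups, 40 concepts, 40 candidate edges per group, edge inclusion
#' frequencies between 0.3 and 0.9, signed mean weights anywhere in
#' [-1, 1], and a weight noise of sigma = 0.15.
#'
#' @param n_groups number of social groups.
#' @param n_concepts size of the concept universe.
#' @param edges_per_group union-edge-set size per group.
#' @param overlap fraction in [0, 1] of each group's edges shared with the
#'   common core.
#' @param weight_mu_range range of mean edge weights (within [-1, 1]).
#' @param weight_sigma weight standard deviation (>= 0).
#' @param pi_range range of edge-inclusion frequencies (within (0, 1]).
#' @param seed integer seed.
#' @return object of class \code{population_spec}.
#' @export
population_spec <- function(n_groups = 5L, n_concepts = 40L,
                            edges_per_group = 40L, overlap = 0.3,
                            weight_mu_range = c(-1, 1), weight_sigma = 0.15,
                            pi_range = c(0.3, 0.9), seed = 1L) {
  stopifnot(n_groups >= 1L, n_concepts >= 2L,
            overlap >= 0, overlap <= 1,
            weight_mu_range[1L] <= weight_mu_range[2L],
            weight_mu_range[1L] >= -1, weight_mu_range[2L] <= 1,
            weight_sigma >= 0,
            pi_range[1L] <= pi_range[2L],
            pi_range[1L] > 0, pi_range[2L] <= 1)
  if (edges_per_group > n_concepts * (n_concepts - 1L)) {
    stop("edges_per_group exceeds the number of possible directed edges")
  }
  structure(list(n_groups = as.integer(n_groups),
                 n_concepts = as.integer(n_concepts),
                 edges_per_group = as.integer(edges_per_group),
                 overlap = overlap,
                 weight_mu_range = weight_mu_range,
                 weight_sigma = weight_sigma,
                 pi_range = pi_range, seed = as.integer(seed)),
            class = "population_spec")
}

# group-private edge placement styles: each group lays its private edges
# down in a distinctive causal topology, so groups differ not only in WHICH
# edges they hold (the Jaccard channel) but also in the micro-motif
# composition of their maps (the graphlet channel).  Uniformly random
# placement would leave all groups in the same random-graph ensemble with
# near-identical expected motif frequencies.  All styles are mixtures of
# three primitives (fork hubs = common-cause reasoning, collider hubs =
# common-effect reasoning, chains = linear causal reasoning), so the five
# group centroids lie in a two-dimensional plane of motif-frequency space
# and a 2-component PCA retains the full between-group geometry.
.style_names <- c("fork_hub", "collider_hub", "chain", "fork_collider",
                  "fork_chain")

# draw n_edges free (source, target) index pairs in the given style;
# `used` is an n x n logical matrix of already-taken pairs (diag = TRUE)
.style_edges <- function(style, n_edges, n, used) {
  out <- matrix(0L, 0L, 2L)
  free <- function(a, b) !used[a, b]
  take <- function(a, b) {
    used[a, b] <<- TRUE
    out <<- rbind(out, c(a, b))
  }
  fork_step <- function(need) {
    hub <- sample.int(n, 1L)
    for (t in sample(setdiff(seq_len(n), hub), min(6L, need))) {
      if (free(hub, t)) take(hub, t)
    }
  }
  collider_step <- function(need) {
    hub <- sample.int(n, 1L)
    for (s in sample(setdiff(seq_len(n), hub), min(6L, need))) {
      if (free(s, hub)) take(s, hub)
    }
  }
  chain_step <- function(need) {
    walk <- sample.int(n, min(8L, need + 1L))
    for (i in seq_len(length(walk) - 1L)) {
      if (free(walk[i], walk[i + 1L])) take(walk[i], walk[i + 1L])
    }
  }
  guard <- 0L
  turn <- 0L
  while (nrow(out) < n_edges && (guard <- guard + 1L) < 200L * n_edges) {
    need <- n_edges - nrow(out)
    turn <- turn + 1L
    switch(style,
      fork_hub = fork_step(need),
      collider_hub = collider_step(need),
      chain = chain_step(need),
      fork_collider = if (turn %% 2L) fork_step(need) else collider_step(need),
      fork_chain = if (turn %% 2L) fork_step(need) else chain_step(need))
  }
  if (nrow(out) < n_edges) {              # fall back to uniform free pairs
    left <- which(!used)
    extra <- if (length(left) < n_edges - nrow(out)) {
      stop("not enough distinct directed edges for disjoint private sets")
    } else sample(left, n_edges - nrow(out))
    out <- rbind(out, cbind((extra - 1L) %% n + 1L, (extra - 1L) %/% n + 1L))
  }
  list(edges = out, used = used)
}

#' Build per-group edge models from a population spec
#'
#' Draws a common core of \code{round(overlap * edges_per_group)} edges
#' shared by all groups (same pi, mu, sigma everywhere) plus disjoint
#' group-private edge sets.  Core edges are placed uniformly at random;
#' each group's private edges are placed in a group-specific causal style
#' (fork hubs, collider hubs, chains, feedback cycles, reciprocal dyads
#' with transitive triangles, cycling through the five styles), so that
#' between-group separation is expressed both in edge membership and in
#' micro-motif composition.  pi is uniform in \code{pi_range}, mu uniform
#' in \code{weight_mu_range}, sigma fixed at \code{weight_sigma}.
#'
#' @param spec a \code{population_spec}.
#' @return named list of \code{group_edge_model}s (\code{group1} ...).
#' @export
make_group_models <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  set.seed(spec$seed)
  n <- spec$n_concepts
  concepts <- sprintf("C%02d", seq_len(n))
  n_core <- round(spec$overlap * spec$edges_per_group)
  n_priv <- spec$edges_per_group - n_core
  need <- n_core + spec$n_groups * n_priv
  if (need > n * (n - 1L)) {
    stop("not enough distinct directed edges for disjoint private sets")
  }
  used <- diag(n) > 0
  core_lin <- if (n_core > 0) sample(which(!used), n_core) else integer()
  used[core_lin] <- TRUE
  to_edges <- function(pairs) {
    data.frame(source = concepts[pairs[, 1L]], target = concepts[pairs[, 2L]],
               stringsAsFactors = FALSE)
  }
  draw_params <- function(k) {
    data.frame(pi = stats::runif(k, spec$pi_range[1L], spec$pi_range[2L]),
               mu = stats::runif(k, spec$weight_mu_range[1L],
                                 spec$weight_mu_range[2L]),
               sigma = rep(spec$weight_sigma, k))
  }
  core_pairs <- cbind((core_lin - 1L) %% n + 1L, (core_lin - 1L) %/% n + 1L)
  core <- cbind(to_edges(core_pairs), draw_params(n_core))
  models <- vector("list", spec$n_groups)
  for (g in seq_len(spec$n_groups)) {
    style <- .style_names[(g - 1L) %% length(.style_names) + 1L]
    placed <- .style_edges(style, n_priv, n, used)
    used <- placed$used
    priv <- cbind(to_edges(placed$edges), draw_params(n_priv))
    edges <- rbind(core, priv)
    edges <- edges[order(edges$source, edges$target, method = "radix"), ,
                   drop = FALSE]
    rownames(edges) <- NULL
    # mu of exactly 0 would make a weight that encodes absence the modal
    # draw; nudge it off zero
    edges$mu[edges$mu == 0] <- 0.01
    nodes <- unique(c(edges$source, edges$target))
    models[[g]] <- structure(
      list(group = paste0("group", g), edges = edges,
           nodes = nodes[order(nodes, method = "radix")],
           k_members = NA_integer_),
      class = "group_edge_model")
  }
  names(models) <- vapply(models, `[[`, "", "group")
  models
}

#' Generate a labeled synthetic population of concept maps
#'
#' Builds the per-group edge models for \code{spec} and samples the
#' requested number of virtual agents from each, returning a homogenized,
#' identity-labeled collection.  Deterministic under \code{spec$seed}.
#'
#' @param spec a \code{population_spec}.
#' @param composition named integer vector or \code{composition_counts}
#'   giving the number of agents per group; names must be
#'   \code{group1 ... groupK}.  Default: 33 agents split 11/4/6/6/6 across
#'   5 groups (a typical interview-study shape) when \code{n_groups} is 5,
#'   otherwise balanced.
#' @return an \code{fcm_collection}.
#' @export
generate_population <- function(spec, composition = NULL) {
  stopifnot(inherits(spec, "population_spec"))
  models <- make_group_models(spec)      # also seeds the RNG stream
  if (is.null(composition)) {
    composition <- if (spec$n_groups == 5L) {
      c(group1 = 11L, group2 = 4L, group3 = 6L, group4 = 6L, group5 = 6L)
    } else {
      stats::setNames(rep(7L, spec$n_groups), names(models))
    }
  }
  if (!inherits(composition, "composition_counts")) {
    composition <- composition_counts(composition,
                                      max_richness = spec$n_groups)
  }
  extra <- setdiff(names(composition$counts), names(models))
  if (length(extra)) stop("composition labels not in spec groups: ",
                          paste(extra, collapse = ", "))
  assemble_virtual_sample(models, composition, rng_seed = NULL)
}
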