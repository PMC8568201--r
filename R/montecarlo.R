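#' Fit a per-group edge model from a homogenized collection
#'
#' For group g with K member maps, the model consists of the union edge set
#' of all members, the empirical inclusion frequency pi_e (fraction of
#' member maps containing e), and the mean mu_e and standard deviation
#' sigma_e of the signed weights over the member maps that contain e.  The
#' population convention (divide by the count, not count - 1) is used for
#' sigma so single-observation edges are well-defined with sigma = 0.
#'
#' @param collection an \code{fcm_collection}.
#' @param group a group label present in the collection's identities.
#' @param sigma_convention \code{"population"} (default) or \code{"sample"}
#'   (sigma = 0 when an edge occurs in a single map).
#' @return object of class \code{group_edge_model}: list with \code{group},
#'   \code{edges} (data.frame \code{source,target,pi,mu,sigma}),
#'   \code{nodes} and \code{k_members}.
#' @export
fit_group_edge_model <- function(collection, group,
                                 sigma_convention = c("population", "sample")) {
  stopifnot(inherits(collection, "fcm_collection"))
  sigma_convention <- match.arg(sigma_convention)
  member <- collection$maps[collection$identities == group]
  if (!length(member)) stop(sprintf("unknown or empty group '%s'", group))
  K <- length(member)

  ed <- do.call(rbind, lapply(member, function(m) m$edges))
  if (is.null(ed) || !nrow(ed)) {
    return(structure(list(group = group,
                          edges = data.frame(source = character(),
                                             target = character(),
                                             pi = numeric(), mu = numeric(),
                                             sigma = numeric(),
                                             stringsAsFactors = FALSE),
                          nodes = character(), k_members = K),
                     class = "group_edge_model"))
  }
  key <- paste(canonical_label(ed$source), canonical_label(ed$target),
               sep = "\r")
  sp <- split(seq_len(nrow(ed)), key)
  rows <- lapply(sp, function(ix) {
    w <- ed$weight[ix]
    s <- if (sigma_convention == "population") {
      sqrt(mean((w - mean(w))^2))
    } else if (length(w) > 1L) stats::sd(w) else 0
    data.frame(source = ed$source[ix[1L]], target = ed$target[ix[1L]],
               pi = length(ix) / K, mu = mean(w), sigma = s,
               stringsAsFactors = FALSE)
  })
  edges <- do.call(rbind, rows)
  edges <- edges[order(canonical_label(edges$source),
                       canonical_label(edges$target), method = "radix"), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  nodes <- unique(c(edges$source, edges$target))
  structure(list(group = group, edges = edges,
                 nodes = nodes[.label_order(nodes)], k_members = K),
            class = "group_edge_model")
}

#' @export
print.group_edge_model <- function(x, ...) {
  cat(sprintf("<group_edge_model '%s': %d union edges over %d concepts, K = %s>\n",
              x$group, nrow(x$edges), length(x$nodes),
              if (is.na(x$k_members)) "?" else x$k_members))
  invisible(x)
}

#' Draw one virtual agent's map from a group edge model
#'
#' Two-step generation: each union edge is included independently with
#' probability pi_e (Bernoulli), and each included edge receives a weight
#' drawn from N(mu_e, sigma_e).  Draws are clipped to [-1, +1]; because a
#' zero weight would encode absence, the magnitude is floored at 0.01,
#' preserving the sign of the draw (the sign of mu_e, or + if both are
#' zero), so Bernoulli-decided presence survives.  The node set is the set
#' of endpoints of the model's union edges.
#'
#' @param model a \code{group_edge_model}.
#' @param id identifier for the generated map.
#' @param rng_seed optional integer seed; \code{NULL} uses (and advances)
#'   the current RNG stream.
#' @return a \code{concept_map}.
#' @export
sample_virtual_map <- function(model, id = "virtual", rng_seed = NULL) {
  stopifnot(inherits(model, "group_edge_model"))
  if (!is.null(rng_seed)) set.seed(rng_seed)
  ed <- model$edges
  keep <- stats::runif(nrow(ed)) < ed$pi
  ed <- ed[keep, , drop = FALSE]
  if (nrow(ed)) {
    w <- stats::rnorm(nrow(ed), ed$mu, ed$sigma)
    w <- pmax(-1, pmin(1, w))
    small <- abs(w) < 0.01
    sgn <- sign(w)
    sgn[sgn == 0] <- sign(ed$mu)[sgn == 0]
    sgn[sgn == 0] <- 1
    w[small] <- 0.01 * sgn[small]
    ed <- data.frame(source = ed$source, target = ed$target, weight = w,
                     stringsAsFactors = FALSE)
  } else {
    ed <- NULL
  }
  concept_map(id, edges = ed, nodes = model$nodes)
}

#' Sample a random identity composition spanning low-to-high evenness
#'
#' Group proportions are drawn from a symmetric Dirichlet whose
#' concentration parameter is itself drawn log-uniformly over
#' \code{spread}, then converted to integer counts by largest-remainder
#' rounding (which preserves the total exactly).  Small concentrations give
#' lopsided compositions (low identity diversity), large ones near-uniform
#' compositions, so repeated draws cover the whole evenness axis.
#'
#' @param n sample size (>= 2).
#' @param groups character vector of group labels.
#' @param rng_seed optional integer seed.
#' @param spread concentration range: length-2 numeric (default
#'   \code{c(0.05, 20)}) or a single fixed concentration.
#' @return a \code{composition_counts} with
#'   \code{max_richness = length(groups)}.
#' @export
sample_composition <- function(n, groups, rng_seed = NULL,
                               spread = c(0.05, 20)) {
  if (n < 2L) stop("sample size must be at least 2")
  if (!length(groups)) stop("need at least one group")
  if (!is.null(rng_seed)) set.seed(rng_seed)
  k <- length(groups)
  alpha <- if (length(spread) == 1L) spread else {
    exp(stats::runif(1L, log(spread[1L]), log(spread[2L])))
  }
  g <- stats::rgamma(k, shape = alpha)
  while (sum(g) == 0) g <- stats::rgamma(k, shape = alpha)
  p <- g / sum(g)
  target <- n * p
  cnt <- floor(target)
  short <- n - sum(cnt)
  if (short > 0) {
    frac <- target - cnt
    give <- order(-frac, seq_len(k))[seq_len(short)]
    cnt[give] <- cnt[give] + 1
  }
  composition_counts(stats::setNames(as.integer(cnt), groups),
                     max_richness = k)
}

#' Assemble a virtual sample of agents from per-group edge models
#'
#' @param models list of \code{group_edge_model}s, named or carrying their
#'   group labels.
#' @param composition a \code{composition_counts}; a model must exist for
#'   every group with a positive count.
#' @param rng_seed optional integer seed.
#' @return an \code{fcm_collection} of the generated maps, homogenized over
#'   the union universe, with identity labels attached.
#' @export
assemble_virtual_sample <- function(models, composition, rng_seed = NULL) {
  if (!inherits(composition, "composition_counts")) {
    composition <- composition_counts(composition)
  }
  if (!is.null(rng_seed)) set.seed(rng_seed)
  names(models) <- vapply(models, `[[`, "", "group")
  want <- names(composition$counts)[composition$counts > 0]
  miss <- setdiff(want, names(models))
  if (length(miss)) stop("no edge model for group(s): ",
                         paste(miss, collapse = ", "))
  maps <- list()
  identities <- character()
  idx <- 0L
  for (g in want) {
    for (r in seq_len(composition$counts[[g]])) {
      idx <- idx + 1L
      id <- sprintf("v%03d_%s", idx, g)
      maps[[id]] <- sample_virtual_map(models[[g]], id = id)
      identities[id] <- g
    }
  }
  homogenize_collection(maps, identities)
}

#' Percentile bootstrap CI for the mean pairwise cognitive distance
#'
#' Individuals are resampled with replacement; for each resample the mean
#' pairwise CD is recomputed from the existing distance matrix (pairs made
#' of two copies of the same individual contribute CD = 0).
#'
#' @param dm an \code{fcm_distmat}.
#' @param n_boot number of bootstrap resamples (default 1000; fewer than
#'   100 triggers a warning).
#' @param level confidence level (default 0.95).
#' @param rng_seed optional integer seed.
#' @return numeric vector \code{c(lo, hi)}.
#' @export
bootstrap_mean_ci <- function(dm, n_boot = 1000L, level = 0.95,
                              rng_seed = NULL) {
  stopifnot(inherits(dm, "fcm_distmat"))
  n <- length(dm$ids)
  if (n < 2L) stop("need at least two individuals")
  if (n_boot < 100L) warning("fewer than 100 bootstrap resamples")
  if (!is.null(rng_seed)) set.seed(rng_seed)
  ut <- upper.tri(dm$cd)
  stat <- vapply(seq_len(n_boot), function(b) {
    ix <- sample.int(n, n, replace = TRUE)
    m <- dm$cd[ix, ix]
    mean(m[ut])
  }, 0)
  a <- (1 - level) / 2
  q <- stats::quantile(stat, c(a, 1 - a), names = FALSE, type = 7)
  c(lo = q[1L], hi = q[2L])
}

#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors of equal length >= 2, both nonconstant.
#' @return the correlation coefficient r in [-1, 1].
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L) {
    stop("x and y must have equal length >= 2")
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("correlation undefined: constant input")
  }
  stats::cor(x, y, method = "pearson")
}

#' Identity-diversity versus cognitive-diversity experiment
#'
#' Builds \code{n_replicates} virtual samples of \code{sample_size} agents.
#' For each replicate a random identity composition is drawn, agents' maps
#' are generated from the per-group edge models, the identity diversity D
#' and the mean pairwise cognitive distance are computed, and a percentile
#' bootstrap CI for the mean CD is estimated.  Finally the Pearson
#' correlation between D and mean CD over replicates is reported.
#'
#' Standardization: because the correlation compares mean CD values
#' \emph{across} replicates, the default fits one global phi from a
#' balanced reference sample drawn from the same models and applies it to
#' every replicate.  Normalizing each replicate by its own maximum raw
#' distance (\code{phi = "per-replicate"}) makes CDs comparable only
#' within a replicate and cancels most of the between-replicate signal;
#' it is provided for completeness, not recommended here.
#'
#' @param models list of \code{group_edge_model}s (>= 2 groups).
#' @param n_replicates number of virtual samples (default 100).
#' @param sample_size agents per sample (default 33).
#' @param n_boot bootstrap resamples per replicate (default 1000).
#' @param rng_seed integer seed driving the whole experiment.
#' @param spread composition-concentration range (see
#'   \code{\link{sample_composition}}).
#' @param phi \code{"global"} (default: one coefficient fitted from a
#'   balanced reference sample), \code{"per-replicate"}, or a fixed
#'   numeric coefficient.
#' @param mode symmetrization mode for the spectral term.
#' @return object of class \code{fcm_experiment}: list with
#'   \code{replicates} (data.frame: composition columns, \code{D},
#'   \code{mean_cd}, \code{ci_lo}, \code{ci_hi}), \code{pearson_r} and
#'   \code{settings}.
#' @export
run_diversity_experiment <- function(models, n_replicates = 100L,
                                     sample_size = 33L, n_boot = 1000L,
                                     rng_seed = 1L, spread = c(0.05, 20),
                                     phi = "global", mode = "sum_abs") {
  if (length(models) < 2L) stop("need at least two group models")
  if (n_replicates < 2L) stop("need at least two replicates")
  set.seed(rng_seed)
  groups <- vapply(models, `[[`, "", "group")

  phi_mode <- if (is.numeric(phi)) "fixed" else match.arg(phi, c("global",
                                                                 "per-replicate"))
  phi_val <- if (phi_mode == "fixed") phi else NULL
  if (phi_mode == "global") {
    k <- length(groups)
    base <- sample_size %/% k
    extra <- sample_size - base * k
    counts <- rep(base, k) + c(rep(1L, extra), rep(0L, k - extra))
    ref_comp <- composition_counts(stats::setNames(as.integer(counts), groups),
                                   max_richness = k)
    ref <- assemble_virtual_sample(models, ref_comp, rng_seed = NULL)
    phi_val <- pairwise_distance_matrix(ref, mode = mode)$phi
  }

  rows <- vector("list", n_replicates)
  for (rep_i in seq_len(n_replicates)) {
    comp <- sample_composition(sample_size, groups, rng_seed = NULL,
                               spread = spread)
    coll <- assemble_virtual_sample(models, comp, rng_seed = NULL)
    dm <- pairwise_distance_matrix(coll, mode = mode, phi = phi_val)
    ci <- bootstrap_mean_ci(dm, n_boot = n_boot, rng_seed = NULL)
    rows[[rep_i]] <- c(comp$counts,
                       D = identity_diversity(comp),
                       mean_cd = cognitive_diversity(dm),
                       ci_lo = unname(ci["lo"]), ci_hi = unname(ci["hi"]))
  }
  replicates <- as.data.frame(do.call(rbind, rows))
  if (stats::var(replicates$D) == 0 || stats::var(replicates$mean_cd) == 0) {
    stop("correlation undefined: zero variance across replicates ",
         sprintf("(var D = %g, var mean_cd = %g)",
                 stats::var(replicates$D), stats::var(replicates$mean_cd)))
  }
  r <- pearson_correlation(replicates$D, replicates$mean_cd)
  structure(list(replicates = replicates, pearson_r = r,
                 settings = list(n_replicates = n_replicates,
                                 sample_size = sample_size,
                                 n_boot = n_boot, seed = rng_seed,
                                 spread = spread,
                                 phi_mode = phi_mode, phi = phi_val)),
            class = "fcm_experiment")
}

#' @export
print.fcm_experiment <- function(x, ...) {
  cat(sprintf(
    "<fcm_experiment: %d replicates of N = %d, Pearson r(D, mean CD) = %.3f>\n",
    x$settings$n_replicates, x$settings$sample_size, x$pearson_r))
  invisible(x)
}
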