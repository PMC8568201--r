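#' Split pairwise cognitive distances into intra- and inter-group sets
#'
#' For a named group g, the intra set holds CD values of pairs whose two
#' members both carry label g, and the inter set holds pairs with exactly
#' one member in g.  For group \code{"ALL"}, intra pools every same-label
#' pair and inter every different-label pair, so the two sets partition all
#' C(N, 2) pairs.
#'
#' @param dm an \code{fcm_distmat}.
#' @param identities named character vector (id -> group label) covering
#'   every id in \code{dm}.
#' @param group a group label present in \code{identities}, or \code{"ALL"}.
#' @return list with \code{group}, numeric vectors \code{intra} and
#'   \code{inter}, and data.frames \code{intra_pairs}, \code{inter_pairs}.
#' @export
partition_distances <- function(dm, identities, group = "ALL") {
  stopifnot(inherits(dm, "fcm_distmat"))
  miss <- setdiff(dm$ids, names(identities))
  if (length(miss)) stop("missing identity for id(s): ",
                         paste(miss, collapse = ", "))
  lab <- as.character(identities[dm$ids])
  if (!identical(group, "ALL") && !group %in% lab) {
    stop(sprintf("unknown group label '%s'", group))
  }
  long <- distances_long(dm)
  g1 <- lab[match(long$id1, dm$ids)]
  g2 <- lab[match(long$id2, dm$ids)]
  if (identical(group, "ALL")) {
    in_intra <- g1 == g2
    in_inter <- g1 != g2
  } else {
    in_intra <- g1 == group & g2 == group
    in_inter <- xor(g1 == group, g2 == group)
  }
  list(group = group,
       intra = long$cd[in_intra], inter = long$cd[in_inter],
       intra_pairs = long[in_intra, c("id1", "id2"), drop = FALSE],
       inter_pairs = long[in_inter, c("id1", "id2"), drop = FALSE])
}

#' Independent two-sample t test (Welch or pooled)
#'
#' Welch's unequal-variance form is the default: group sizes in stakeholder
#' samples are typically unbalanced, which makes the pooled-variance form
#' fragile.
#'
#' @param a,b numeric samples (each of length >= 2).
#' @param variant \code{"welch"} (default) or \code{"pooled"}.
#' @param alternative \code{"two.sided"} (default), \code{"greater"} (mean
#'   of \code{a} exceeds mean of \code{b}) or \code{"less"}.
#' @return list with \code{t}, \code{p}, \code{df}, \code{mean_a},
#'   \code{mean_b}.
#' @export
independent_t_test <- function(a, b, variant = c("welch", "pooled"),
                               alternative = c("two.sided", "greater", "less")) {
  variant <- match.arg(variant)
  alternative <- match.arg(alternative)
  if (length(a) < 2L || length(b) < 2L) {
    stop("each sample needs at least 2 observations")
  }
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    stop("degenerate samples: zero variance in both groups")
  }
  ht <- stats::t.test(a, b, var.equal = (variant == "pooled"),
                      alternative = alternative)
  list(t = unname(ht$statistic), p = unname(ht$p.value),
       df = unname(ht$parameter), mean_a = mean(a), mean_b = mean(b))
}

# exact null distribution of U by enumerating all group-A subsets of the
# pooled sample (valid with ties); feasible for small combined n
.mwu_exact_p <- function(a, b, u_obs, alternative) {
  pooled <- c(a, b)
  n1 <- length(a)
  r <- rank(pooled)
  subsets <- utils::combn(length(pooled), n1)
  u_all <- apply(subsets, 2L, function(ix) {
    sum(r[ix]) - n1 * (n1 + 1) / 2
  })
  eps <- 1e-9
  switch(alternative,
         greater = mean(u_all >= u_obs - eps),
         less = mean(u_all <= u_obs + eps),
         two.sided = min(1, 2 * min(mean(u_all >= u_obs - eps),
                                    mean(u_all <= u_obs + eps))))
}

#' Wilcoxon-Mann-Whitney U test
#'
#' Rank-based comparison of two independent samples that does not assume
#' normality.  For combined sample sizes up to \code{exact_max} (default
#' 12), the p-value is computed by exact enumeration of all subset
#' assignments (valid under ties); otherwise a normal approximation with
#' tie correction and continuity correction is used.
#'
#' @param a,b numeric samples (nonempty).
#' @param alternative \code{"two.sided"} (default), \code{"greater"}
#'   (\code{a} stochastically larger) or \code{"less"}.
#' @param exact_max largest combined sample size for the exact-enumeration
#'   path.
#' @return list with \code{u} (U statistic of sample \code{a}), \code{p} and
#'   \code{method}.
#' @export
mann_whitney_u <- function(a, b, alternative = c("two.sided", "greater", "less"),
                           exact_max = 12L) {
  alternative <- match.arg(alternative)
  if (!length(a) || !length(b)) stop("both samples must be nonempty")
  n1 <- length(a)
  n2 <- length(b)
  r <- rank(c(a, b))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2

  if (n1 + n2 <= exact_max) {
    p <- .mwu_exact_p(a, b, u, alternative)
    return(list(u = u, p = p, method = "exact"))
  }

  mu <- n1 * n2 / 2
  ties <- table(r)
  n <- n1 + n2
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) {                      # all values tied
    p <- 1
    return(list(u = u, p = p, method = "normal_approx"))
  }
  sigma <- sqrt(sigma2)
  z <- switch(alternative,
              two.sided = (u - mu - sign(u - mu) * 0.5) / sigma,
              greater = (u - mu - 0.5) / sigma,
              less = (u - mu + 0.5) / sigma)
  p <- switch(alternative,
              two.sided = 2 * stats::pnorm(-abs(z)),
              greater = stats::pnorm(z, lower.tail = FALSE),
              less = stats::pnorm(z))
  list(u = u, p = min(1, p), method = "normal_approx")
}

#' Intra- versus inter-group comparison report
#'
#' For every group (and for the pooled \code{"ALL"} partition) compares the
#' intra-group and inter-group cognitive-distance sets with an independent
#' t test and a Wilcoxon-Mann-Whitney U test.  Groups with fewer than two
#' members have no intra pairs; their tests are skipped with a warning
#' entry.
#'
#' Pairwise distances are not statistically independent (each individual
#' appears in many pairs); the tests are reported as commonly practiced,
#' and this caveat is attached to the result and printed.
#'
#' @param dm an \code{fcm_distmat}.
#' @param identities named character vector id -> group label.
#' @param alternative test alternative, applied as inter versus intra
#'   (\code{"greater"} means inter-group distances are larger).
#' @param variant t-test variant.
#' @return data.frame of class \code{fcm_group_report} with one row per
#'   group plus \code{"ALL"}: means, test statistics, p-values and pair
#'   counts.
#' @export
compare_groups_report <- function(dm, identities,
                                  alternative = c("two.sided", "greater", "less"),
                                  variant = c("welch", "pooled")) {
  alternative <- match.arg(alternative)
  variant <- match.arg(variant)
  stopifnot(inherits(dm, "fcm_distmat"))
  lab <- as.character(identities[dm$ids])
  groups <- sort(unique(lab), method = "radix")
  if (length(groups) < 2L) stop("need at least two distinct groups")

  rows <- lapply(c(groups, "ALL"), function(g) {
    part <- partition_distances(dm, identities, g)
    n_i <- length(part$intra)
    n_e <- length(part$inter)
    row <- data.frame(group = g, n_intra = n_i, n_inter = n_e,
                      mean_intra = if (n_i) mean(part$intra) else NA_real_,
                      mean_inter = if (n_e) mean(part$inter) else NA_real_,
                      t = NA_real_, t_p = NA_real_,
                      u = NA_real_, u_p = NA_real_,
                      skipped = FALSE, stringsAsFactors = FALSE)
    if (n_i < 2L || n_e < 2L) {
      warning(sprintf("group '%s': too few pairs (intra %d, inter %d); tests skipped",
                      g, n_i, n_e))
      row$skipped <- TRUE
      return(row)
    }
    tt <- independent_t_test(part$inter, part$intra, variant = variant,
                             alternative = alternative)
    uu <- mann_whitney_u(part$inter, part$intra, alternative = alternative)
    row$t <- tt$t; row$t_p <- tt$p
    row$u <- uu$u; row$u_p <- uu$p
    row
  })
  out <- do.call(rbind, rows)
  attr(out, "alternative") <- alternative
  attr(out, "variant") <- variant
  attr(out, "caveat") <- paste(
    "pairwise distances share individuals and are therefore not independent;",
    "p-values are computed under the usual independence assumption")
  class(out) <- c("fcm_group_report", "data.frame")
  out
}

#' @export
print.fcm_group_report <- function(x, ...) {
  cat(sprintf("Intra- vs inter-group cognitive distances (%s %s test)\n",
              attr(x, "variant"), attr(x, "alternative")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  cat("note:", attr(x, "caveat"), "\n")
  invisible(x)
}
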