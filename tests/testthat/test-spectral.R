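test_that("normalized Laplacian matches hand-computed small cases", {
  # single undirected edge: L = [[1,-1],[-1,1]] for any positive weight
  for (w in c(0.2, 0.9)) {
    m <- concept_map("m", data.frame(source = "A", target = "B", weight = w))
    L <- normalized_laplacian(symmetrized_weighted_adjacency(m))
    expect_equal(unname(L), matrix(c(1, -1, -1, 1), 2))
    expect_equal(spectrum_summary(L)$eigenvalues, c(2, 0), tolerance = 1e-12)
  }

  # zero matrix (all isolated): zero Laplacian, all-zero spectrum, k = 0
  Z <- matrix(0, 3, 3)
  expect_equal(normalized_laplacian(Z), Z)
  sz <- spectrum_summary(normalized_laplacian(Z))
  expect_equal(sz$k, 0L)
  expect_equal(sz$total_mass, 0)

  # unit path A-B-C: eigenvalues {0, 1, 2}
  p3 <- concept_map("p", data.frame(source = c("A", "B"), target = c("B", "C"),
                                    weight = c(1, 1)))
  sp <- spectrum_summary(normalized_laplacian(symmetrized_weighted_adjacency(p3)))
  expect_equal(sp$eigenvalues, c(2, 1, 0), tolerance = 1e-12)

  expect_error(normalized_laplacian(matrix(c(0, 1, 0, 0), 2)), "symmetric")
  expect_error(normalized_laplacian(matrix(c(0, -1, -1, 0), 2)), "nonnegative")
})

test_that("90%-mass truncation index is minimal", {
  # spectrum [2,1,0]: k=1 gives 2/3 < 0.9; k=2 gives 1 -> k = 2
  fake <- function(ev) {
    # build a diagonal matrix with the desired spectrum (valid symmetric input)
    spectrum_summary(diag(ev))
  }
  expect_equal(fake(c(2, 1, 0))$k, 2L)
  expect_equal(fake(c(2, 0))$k, 1L)
  expect_equal(fake(c(1, 1, 1, 1, 1, 1, 1, 1, 1, 1))$k, 9L)
  expect_error(spectrum_summary(diag(c(1, -1e-6))), "negative eigenvalue")
})

test_that("Laplacian spectra match characteristic-polynomial roots (<= 4 nodes)", {
  skip_if_not_installed("pracma")
  set.seed(123)
  for (i in 1:200) {
    n <- sample(2:4, 1)
    m <- random_map("r", LETTERS[1:n], sample.int(n * (n - 1), 1))
    L <- normalized_laplacian(symmetrized_weighted_adjacency(m))
    got <- spectrum_summary(L)$eigenvalues
    want <- pmax(oracle_eigenvalues(L), 0)
    expect_equal(got, want, tolerance = 1e-8)
  }
})

test_that("Jaccard distance agrees with set arithmetic and conventions", {
  u <- c("A", "B", "C")
  m1 <- concept_map("1", data.frame(source = c("A", "B"), target = c("B", "C"),
                                    weight = c(0.5, 0.5)), nodes = u)
  m2 <- concept_map("2", data.frame(source = c("A", "A"), target = c("B", "C"),
                                    weight = c(0.5, 0.5)), nodes = u)
  A1 <- dichotomized_adjacency(m1, u); A2 <- dichotomized_adjacency(m2, u)
  expect_equal(jaccard_distance(A1, A1), 0)
  expect_equal(jaccard_distance(A1, A2), 2 / 3)   # |inter|=1, |union|=3
  # disjoint nonempty edge sets
  m3 <- concept_map("3", data.frame(source = "C", target = "A", weight = 1),
                    nodes = u)
  expect_equal(jaccard_distance(A1, dichotomized_adjacency(m3, u)), 1)
  # both empty: maximal similarity by convention
  e <- dichotomized_adjacency(concept_map("e", nodes = u), u)
  expect_equal(jaccard_distance(e, e), 0)
  expect_error(jaccard_distance(A1, matrix(0, 2, 2)), "shape")

  set.seed(5)
  for (i in 1:100) {
    n <- sample(2:4, 1)
    r1 <- random_map("a", LETTERS[1:n], sample.int(n * (n - 1), 1))
    r2 <- random_map("b", LETTERS[1:n], sample.int(n * (n - 1), 1))
    B1 <- dichotomized_adjacency(r1, LETTERS[1:n])
    B2 <- dichotomized_adjacency(r2, LETTERS[1:n])
    expect_equal(jaccard_distance(B1, B2), oracle_jaccard(B1, B2))
  }
})

test_that("spectral distance truncates at the smaller k", {
  u3 <- c("A", "B", "C")
  single <- concept_map("s", data.frame(source = "A", target = "B", weight = 1),
                        nodes = u3)
  path3 <- concept_map("p", data.frame(source = c("A", "B"),
                                       target = c("B", "C"), weight = c(1, 1)))
  ss <- spectrum_summary(normalized_laplacian(symmetrized_weighted_adjacency(single, u3)))
  sp <- spectrum_summary(normalized_laplacian(symmetrized_weighted_adjacency(path3)))
  expect_equal(ss$k, 1L)
  expect_equal(sp$k, 2L)
  # k* = 1: both lead with eigenvalue 2 -> distance 0 (truncation coarseness)
  expect_equal(spectral_graph_distance(ss, sp), 0)
  expect_equal(spectral_graph_distance(sp, sp), 0)
  # empty spectrum: k* = 0 -> 0 by convention
  empty <- spectrum_summary(matrix(0, 3, 3))
  expect_equal(spectral_graph_distance(ss, empty), 0)
})

test_that("raw cognitive distance composes d_s/(1 - d_J) with conventions", {
  u <- c("A", "B", "C")
  m <- concept_map("m", data.frame(source = c("A", "B"), target = c("B", "C"),
                                   weight = c(0.8, -0.5)), nodes = u)
  self <- raw_cognitive_distance(m, m)
  expect_equal(unlist(self), c(d_j = 0, d_s = 0, raw = 0))

  # identical edge sets, different weights: raw = d_s
  m2 <- concept_map("m2", data.frame(source = c("A", "B"), target = c("B", "C"),
                                     weight = c(0.3, 0.9)), nodes = u)
  p <- raw_cognitive_distance(m, m2)
  expect_equal(p$d_j, 0)
  expect_equal(p$raw, p$d_s)

  # disjoint edge sets: raw = +Inf
  m3 <- concept_map("m3", data.frame(source = "C", target = "A", weight = 1),
                    nodes = u)
  expect_equal(raw_cognitive_distance(m, m3)$raw, Inf)

  # different universes refuse comparison
  other <- concept_map("o", data.frame(source = "A", target = "B", weight = 1))
  expect_error(raw_cognitive_distance(m, other), "universe")
})

test_that("pairwise matrix matches an independent double-loop oracle", {
  set.seed(99)
  maps <- lapply(1:5, function(i) random_map(paste0("m", i), LETTERS[1:5],
                                             sample(3:8, 1)))
  coll <- homogenize_collection(maps, stats::setNames(rep("g", 5),
                                                      paste0("m", 1:5)))
  dm <- pairwise_distance_matrix(coll)

  raws <- matrix(0, 5, 5)
  for (i in 1:4) for (j in (i + 1):5) {
    o <- oracle_raw_cd(coll$maps[[i]], coll$maps[[j]])
    raws[i, j] <- raws[j, i] <- o$raw
    expect_equal(dm$d_j[i, j], o$d_j, tolerance = 1e-10)
    expect_equal(dm$d_s[i, j], o$d_s, tolerance = 1e-8)
  }
  finite <- raws[upper.tri(raws)]
  finite <- finite[is.finite(finite) & finite > 0]
  expect_equal(dm$phi, 1 / max(finite), tolerance = 1e-8)
  expect_equal(unname(dm$cd), unname(pmin(raws * dm$phi, 1)), tolerance = 1e-8)
  # the maximal finite pair attains CD = 1
  expect_equal(max(dm$cd[is.finite(raws)]), 1)
})

test_that("degenerate collections are rejected with clear messages", {
  u <- c("A", "B")
  same <- lapply(1:3, function(i) {
    concept_map(paste0("s", i), data.frame(source = "A", target = "B",
                                           weight = 0.5), nodes = u)
  })
  coll <- homogenize_collection(same, stats::setNames(rep("g", 3),
                                                      paste0("s", 1:3)))
  expect_error(pairwise_distance_matrix(coll), "identical")

  disjoint <- list(
    concept_map("a", data.frame(source = "A", target = "B", weight = 1),
                nodes = u),
    concept_map("b", data.frame(source = "B", target = "A", weight = 1),
                nodes = u))
  coll2 <- homogenize_collection(disjoint, c(a = "g", b = "g"))
  expect_error(pairwise_distance_matrix(coll2), "disjoint")
})

test_that("metric sanity: symmetry, range, padding and scale invariance", {
  set.seed(314)
  for (i in 1:25) {
    n <- sample(4:8, 1)
    nodes <- paste0("c", 1:n)
    m1 <- random_map("x", nodes, sample(3:12, 1))
    m2 <- random_map("y", nodes, sample(3:12, 1))
    u <- sort(unique(c(m1$nodes, m2$nodes)))
    m1$nodes <- u; m2$nodes <- u
    p <- raw_cognitive_distance(m1, m2)
    q <- raw_cognitive_distance(m2, m1)
    expect_equal(p, q)
    expect_gte(p$d_j, 0); expect_lte(p$d_j, 1); expect_gte(p$d_s, 0)

    # padding both maps with shared isolated nodes changes nothing
    pad <- c(u, paste0("pad", 1:3))
    m1p <- m1; m1p$nodes <- pad
    m2p <- m2; m2p$nodes <- pad
    pp <- raw_cognitive_distance(m1p, m2p)
    expect_equal(pp$d_j, p$d_j)
    expect_equal(pp$d_s, p$d_s, tolerance = 1e-9)

    # positive rescaling of one map's weights changes nothing
    m1s <- m1
    m1s$edges$weight <- pmax(-1, pmin(1, m1$edges$weight * 0.5))
    ps <- raw_cognitive_distance(m1s, m2)
    expect_equal(ps$d_j, p$d_j)
    expect_equal(ps$d_s, p$d_s, tolerance = 1e-9)

    # flipping a sign changes nothing (absolute-value symmetrization)
    m1f <- m1
    m1f$edges$weight[1] <- -m1f$edges$weight[1]
    pf <- raw_cognitive_distance(m1f, m2)
    expect_equal(pf$d_s, p$d_s, tolerance = 1e-12)
  }
})
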