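test_that("concept maps are constructed, ordered and validated", {
  m <- concept_map("m1", data.frame(source = c("A", "B"), target = c("B", "C"),
                                    weight = c(0.5, -0.7)))
  expect_s3_class(m, "concept_map")
  expect_equal(m$nodes, c("A", "B", "C"))
  expect_equal(nrow(m$edges), 2L)
  expect_length(m$self_loops, 0L)

  # weight range violations name the offending edge
  expect_error(concept_map("bad", data.frame(source = "A", target = "B",
                                             weight = 1.3)),
               "\\(A, B\\)")
  expect_error(concept_map("bad", data.frame(source = "A", target = "B",
                                             weight = 0)),
               "nonzero")
  # duplicate ordered pair
  expect_error(concept_map("dup", data.frame(source = c("A", "a "),
                                             target = c("B", "B"),
                                             weight = c(0.1, 0.2))),
               "duplicate")
  # self-loops permitted but flagged
  loopy <- concept_map("loop", data.frame(source = "A", target = "A",
                                          weight = 0.3))
  expect_length(loopy$self_loops, 1L)
})

test_that("label normalization collapses whitespace and case for matching", {
  expect_equal(canonical_label("  Cod   Stock "), "cod stock")
  m <- concept_map("m", data.frame(source = "Cod Stock", target = "Fishery",
                                   weight = 0.5),
                   nodes = c("Cod Stock", "Fishery"))
  # same canonical node referenced with different spacing is one node
  m2 <- concept_map("m", data.frame(source = "cod  stock", target = "Fishery",
                                    weight = 0.5),
                    nodes = c("Cod Stock", "Fishery"))
  expect_equal(length(m2$nodes), 2L)
})

test_that("dichotomized adjacency records presence only", {
  m <- concept_map("m", data.frame(source = "A", target = "B", weight = 0.9))
  u <- c("A", "B")
  expect_equal(unname(dichotomized_adjacency(m, u)),
               matrix(c(0, 0, 1, 0), 2))
  # sign and magnitude are irrelevant
  m2 <- concept_map("m", data.frame(source = "A", target = "B", weight = -0.1))
  expect_equal(dichotomized_adjacency(m, u), dichotomized_adjacency(m2, u))
  # empty map, and node outside universe
  empty <- concept_map("e", nodes = c("A", "B"))
  expect_equal(sum(dichotomized_adjacency(empty)), 0)
  expect_error(dichotomized_adjacency(m, c("A", "X")), "universe")
})

test_that("symmetrized adjacency is symmetric, nonnegative, mode-correct", {
  m <- concept_map("m", data.frame(source = c("A", "B"), target = c("B", "A"),
                                   weight = c(0.5, -0.3)))
  S <- symmetrized_weighted_adjacency(m)
  expect_equal(S["A", "B"], 0.8)
  expect_equal(S, t(S))
  expect_equal(symmetrized_weighted_adjacency(m, mode = "max_abs")["A", "B"], 0.5)
  # mean over the two present directed edges
  expect_equal(symmetrized_weighted_adjacency(m, mode = "mean_abs")["A", "B"], 0.4)

  m1 <- concept_map("m", data.frame(source = "A", target = "B", weight = -0.6))
  for (mode in c("sum_abs", "max_abs", "mean_abs")) {
    expect_equal(symmetrized_weighted_adjacency(m1, mode = mode)["A", "B"], 0.6)
  }
  expect_error(symmetrized_weighted_adjacency(m1, mode = "nope"))

  # property: symmetric nonnegative for random maps and all modes
  set.seed(42)
  for (i in 1:20) {
    rm <- random_map(paste0("r", i), LETTERS[1:6], sample(3:10, 1))
    for (mode in c("sum_abs", "max_abs", "mean_abs")) {
      S <- symmetrized_weighted_adjacency(rm, mode = mode)
      expect_true(all(S >= 0))
      expect_equal(S, t(S))
    }
  }
})

test_that("homogenization pads with isolated nodes and preserves edges", {
  m1 <- concept_map("p1", data.frame(source = "A", target = "B", weight = 0.4))
  m2 <- concept_map("p2", data.frame(source = "B", target = "C", weight = 0.6))
  coll <- homogenize_collection(list(m1, m2), c(p1 = "g1", p2 = "g2"))
  expect_equal(coll$universe, c("A", "B", "C"))
  expect_equal(coll$maps$p1$nodes, c("A", "B", "C"))
  expect_equal(coll$maps$p1$edges, m1$edges)   # edges untouched
  expect_equal(coll$maps$p2$edges, m2$edges)

  # single map: universe equals its nodes
  solo <- homogenize_collection(list(m1), c(p1 = "g1"))
  expect_equal(solo$universe, m1$nodes)

  # padding is idempotent
  again <- homogenize_collection(coll$maps, coll$identities)
  expect_equal(again$universe, coll$universe)
  expect_equal(again$maps$p1$edges, coll$maps$p1$edges)

  # disjoint singleton extras grow the universe additively
  base_nodes <- c("X", "Y")
  maps <- lapply(1:12, function(i) {
    concept_map(paste0("s", i),
                data.frame(source = "X", target = paste0("extra", i),
                           weight = 0.5),
                nodes = base_nodes)
  })
  ids <- stats::setNames(rep("g", 12), paste0("s", 1:12))
  coll2 <- homogenize_collection(maps, ids)
  expect_length(coll2$universe, length(base_nodes) + 12)

  expect_error(homogenize_collection(list(), c()), "at least one")
  expect_error(homogenize_collection(list(m1, m2), c(p1 = "g1")), "p2")
})

test_that("synonym application renames, merges and drops cancelled edges", {
  tab <- synonym_table(data.frame(raw = "Cod stock", canonical = "Cod"))
  m <- concept_map("m", data.frame(source = "Cod stock", target = "Fishery",
                                   weight = 0.5))
  out <- apply_synonym_table(m, tab)
  expect_true("Cod" %in% out$nodes)
  expect_false(any(canonical_label(out$nodes) == "cod stock"))
  expect_equal(out$edges$weight, 0.5)

  # merge two nodes: parallel edges combined by mean
  tab2 <- synonym_table(data.frame(raw = c("X", "Y"), canonical = c("Z", "Z")))
  m2 <- concept_map("m", data.frame(source = c("X", "Y"), target = c("A", "A"),
                                    weight = c(0.4, 0.8)))
  out2 <- apply_synonym_table(m2, tab2, merge_rule = "mean")
  expect_equal(out2$edges$weight, 0.6)
  expect_equal(out2$edges$source, "Z")

  # cancellation: merged weight 0 drops the edge and reports it
  m3 <- concept_map("m", data.frame(source = c("X", "Y"), target = c("A", "A"),
                                    weight = c(0.5, -0.5)))
  out3 <- apply_synonym_table(m3, tab2, merge_rule = "mean")
  expect_equal(nrow(out3$edges), 0L)
  expect_length(attr(out3, "report")$dropped_edges, 1L)

  # max_abs merge rule
  out4 <- apply_synonym_table(m3, tab2, merge_rule = "max_abs")
  expect_equal(abs(out4$edges$weight), 0.5)

  # merge creating a self-loop is kept and flagged
  m5 <- concept_map("m", data.frame(source = "X", target = "Z", weight = 0.3))
  out5 <- apply_synonym_table(m5, tab2)
  expect_length(attr(out5, "report")$self_loops_created, 1L)
  expect_equal(nrow(out5$edges), 1L)

  # chained synonym tables are rejected at load
  expect_error(synonym_table(data.frame(raw = c("A", "B"),
                                        canonical = c("B", "C"))),
               "chain")
  expect_error(synonym_table(data.frame(raw = c("A", "A"),
                                        canonical = c("B", "C"))),
               "single-valued")
})

test_that("merge by mean matches brute-force enumeration on random merges", {
  set.seed(7)
  tab <- synonym_table(data.frame(raw = c("N1", "N2"), canonical = c("M", "M")))
  for (rep in 1:10) {
    # targets drawn with replacement so renaming does merge parallel edges
    ed <- data.frame(source = c("N1", "N2", "N1", "N2"),
                     target = c(sample(c("P", "Q"), 3, replace = TRUE), "Q"),
                     weight = round(stats::runif(4, -1, 1), 3))
    ed <- ed[ed$weight != 0, ]
    ed <- ed[!duplicated(paste(ed$source, ed$target)), ]
    m <- concept_map("m", ed)
    out <- apply_synonym_table(m, tab, merge_rule = "mean")
    # brute force: group renamed edges by target, average
    expect_gt(nrow(ed), 0)
    exp_w <- c(tapply(ed$weight, ed$target, mean))
    exp_w <- exp_w[exp_w != 0]
    got <- stats::setNames(out$edges$weight, out$edges$target)
    expect_equal(sort(names(got)), sort(names(exp_w)))
    expect_equal(unname(got[sort(names(got))]),
                 unname(exp_w[sort(names(exp_w))]), tolerance = 1e-12)
  }
})
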