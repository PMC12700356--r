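test_that("reverse_cycle_surgery reproduces the worked two-graph example", {
  g1 <- fixture_joint_cycle_graph()
  g2 <- reverse_cycle_surgery(g1, list(c(1, 2, 3)))
  # reversed cycle weights are reciprocals of the originals
  expect_equal(round(g2$weights["Y1", "Y2"], 2), 0.95)    # 1/1.05
  expect_equal(round(g2$weights["Y3", "Y1"], 2), -1.05)   # -1/0.95
  expect_equal(g2$weights["Y2", "Y3"], 1)
  # out-of-cycle parent edge Y4->Y3 re-targeted to Y4->Y2
  expect_equal(g2$weights["Y2", "Y4"], -1)
  expect_equal(g2$weights["Y3", "Y4"], 0)
  # untouched row outside the cycle
  expect_equal(g2$weights["Y4", "Y1"], -0.1)
  # both computation routes agree
  ge <- reverse_cycle_surgery(g1, list(c(1, 2, 3)), method = "edges")
  expect_equal(ge$weights, g2$weights, tolerance = 1e-12)
})

test_that("surgery handles 2-cycles and rejects joint cycles", {
  B <- matrix(0, 2, 2); B[2, 1] <- 0.6; B[1, 2] <- 0.4
  g <- weighted_digraph(B)
  rev <- reverse_cycle_surgery(g, list(c(1, 2)))
  # weights (a, b) on (1->2, 2->1) become (1/b, 1/a)
  expect_equal(rev$weights[2, 1], 1 / 0.4)
  expect_equal(rev$weights[1, 2], 1 / 0.6)
  g1 <- fixture_joint_cycle_graph()
  expect_error(reverse_cycle_surgery(g1, list(c(1, 2, 3), c(1, 4, 3))),
               "disjoint")
})

test_that("enumerate_class: DAG singleton, benchmark classes, stability", {
  # any DAG has a singleton class
  B <- matrix(0, 4, 4); B[2, 1] <- 1; B[3, 2] <- -0.5; B[4, 1] <- 0.3
  expect_length(enumerate_class(weighted_digraph(B)), 1L)

  g1 <- fixture_joint_cycle_graph()
  cls <- enumerate_class(g1)
  expect_length(cls, 3L)
  stable_flags <- vapply(cls$members, `[[`, logical(1), "stable")
  expect_equal(sum(stable_flags), 2L)
  expect_length(enumerate_class(g1, stable_only = TRUE), 2L)

  # instrument-augmented graph: class of exactly 3, and the re-targeted
  # instrument edges carry the documented rounded coefficients
  aug <- augment_with_instruments(g1, fixture_instruments())
  cls_aug <- enumerate_class(aug)
  expect_length(cls_aug, 3L)
  non_base <- Filter(function(m) !is.null(m$perm), cls_aug$members)
  unstable <- Filter(function(m) !m$stable, non_base)
  expect_length(unstable, 1L)   # exactly one non-base member is unstable
  # the unstable member reverses the weak cycle: weight product ~ 1/0.095
  wu <- unstable[[1]]$graph$weights
  cyc_prod <- wu["Y3", "Y1"] * wu["Y4", "Y3"] * wu["Y1", "Y4"]
  expect_equal(abs(cyc_prod), 1 / 0.095, tolerance = 1e-6)
  g2p <- reverse_cycle_surgery(aug, list(c(1, 2, 3)))
  expect_equal(round(g2p$weights["Y3", "IY1"], 2), 0.53)  # 0.5/0.95
  expect_equal(round(g2p$weights["Y1", "IY2"], 2), -0.48) # -0.5/1.05
  expect_error(enumerate_class(aug, max_vertices = 5L), "capped")
})

test_that("surgery enumeration equals brute force; closure; disjoint case", {
  set.seed(76)
  n_checked <- 0
  while (n_checked < 20) {
    n <- sample(3:5, 1)
    g <- random_digraph(n, p_edge = 0.45,
                        target_radius = stats::runif(1, 0.3, 0.9))
    if (!length(find_cycles(g))) next
    n_checked <- n_checked + 1
    brute <- enumerate_class(g)
    surg <- enumerate_class_by_surgery(g)
    expect_identical(class_support_keys(brute), class_support_keys(surg))
    # closure: the class of any member is the same class
    other <- brute$members[[length(brute$members)]]$graph
    again <- enumerate_class(other)
    expect_identical(class_support_keys(again), class_support_keys(brute))
  }
  # the base graph is always the first member, with identity generator,
  # even when a non-identity permutation preserves the edge support
  # (a 2-cycle reversed onto itself)
  B2 <- matrix(0, 2, 2); B2[1, 2] <- 0.5; B2[2, 1] <- 0.9
  cls2 <- enumerate_class(weighted_digraph(B2))
  expect_null(cls2$members[[1]]$perm)
  expect_equal(cls2$members[[1]]$graph$weights,
               weighted_digraph(B2)$weights)
  # disjoint-cycle graph: exactly one stable member
  B <- matrix(0, 4, 4)
  B[1, 2] <- 0.9; B[2, 1] <- 0.9   # cycle 1: product 0.81
  B[3, 4] <- 0.8; B[4, 3] <- 0.7   # cycle 2: product 0.56
  g <- weighted_digraph(B)
  expect_length(enumerate_class(g, stable_only = TRUE), 1L)
})

test_that("identifiability certificates match the worked analysis", {
  g1 <- fixture_joint_cycle_graph()
  spec <- fixture_instruments()
  c1 <- certify_identifiability(g1, spec, use = "IY1")
  expect_true(c1$unique)
  expect_true(c1$sufficient)     # Y1 lies on both cycles
  expect_equal(c1$class_size, 3L)
  c2 <- certify_identifiability(g1, spec, use = "IY2")
  expect_false(c2$unique)
  expect_false(c2$sufficient)
  expect_length(c2$surviving, 2L)
  c3 <- certify_identifiability(g1, spec, use = c("IY2", "IY4"))
  expect_true(c3$unique)
  expect_true(c3$sufficient)
  # serialization carries the class information
  js <- jsonlite::fromJSON(certificate_json(c2))
  expect_false(js$unique)
  expect_equal(length(js$surviving$stable), 2L)
})

test_that("sufficient condition implies constructive uniqueness", {
  set.seed(77)
  n_checked <- 0
  while (n_checked < 10) {
    n <- sample(3:5, 1)
    g <- random_digraph(n, p_edge = 0.4,
                        target_radius = stats::runif(1, 0.3, 0.9))
    cys <- find_cycles(g)
    if (!length(cys)) next
    n_checked <- n_checked + 1
    # instrument one vertex in every cycle
    targets <- unique(vapply(cys, function(cy) g$labels[min(cy)], character(1)))
    spec <- instrument_spec(targets)
    cert <- certify_identifiability(g, spec)
    expect_true(cert$sufficient)
    expect_true(cert$unique)
  }
})

test_that("instrument declarations are validated", {
  expect_error(instrument_spec(c("Y1", "Y2"), c("I", "I")), "distinct")
  g1 <- fixture_joint_cycle_graph()
  # instrument vertex already present with a child other than the target
  expect_error(
    augment_with_instruments(g1, instrument_spec("Y1", "Y2")),
    "no edge|invalid instrument")
  expect_error(
    augment_with_instruments(g1, instrument_spec("Z9")), "not in graph")
})
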