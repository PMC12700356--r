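test_that("weighted_digraph validates its invariants", {
  expect_error(weighted_digraph(matrix(1, 2, 3)), "square")
  B <- diag(c(0.5, 0)); B[1, 2] <- 1
  expect_error(weighted_digraph(B), "diagonal")
  g <- weighted_digraph(matrix(0, 3, 3))
  expect_identical(g$labels, c("Y1", "Y2", "Y3"))
  expect_equal(nrow(edge_list(g)), 0L)
})

test_that("find_cycles reproduces the worked examples", {
  mk <- function(n, edges) {
    B <- matrix(0, n, n)
    for (e in edges) B[e[2], e[1]] <- 1
    weighted_digraph(B)
  }
  # a 3-cycle
  g <- mk(3, list(c(1, 2), c(2, 3), c(3, 1)))
  expect_identical(find_cycles(g), list(c(1L, 2L, 3L)))
  # same vertices, edge Y1->Y3 instead of Y3->Y1: no cycle
  g2 <- mk(3, list(c(1, 2), c(2, 3), c(1, 3)))
  expect_length(find_cycles(g2), 0L)
  # joint-cycle benchmark graph: two 3-cycles sharing {Y1, Y3}
  g3 <- fixture_joint_cycle_graph()
  cys <- find_cycles(g3)
  expect_length(cys, 2L)
  shared <- Reduce(intersect, cys)
  expect_setequal(shared, c(1L, 3L))
  # chord handling: adding Y1->Y3 to the 3-cycle creates a genuine 2-cycle
  # (Y1, Y3); the 3-cycle is kept by default and dropped when only
  # chordless cycles are requested
  g4 <- mk(3, list(c(1, 2), c(2, 3), c(3, 1), c(1, 3)))
  expect_identical(find_cycles(g4), list(c(1L, 3L), c(1L, 2L, 3L)))
  expect_identical(find_cycles(g4, chordless_only = TRUE), list(c(1L, 3L)))
})

test_that("find_cycles matches the brute-force oracle on random graphs", {
  set.seed(71)
  for (rep in 1:25) {
    n <- sample(2:6, 1)
    g <- random_digraph(n, p_edge = stats::runif(1, 0.2, 0.6))
    got <- find_cycles(g)
    want <- oracle_cycles(g)
    key <- function(cys) sort(vapply(cys, paste, character(1), collapse = "-"))
    expect_identical(key(got), key(want))
    for (cy in got) expect_true(validate_cycle(g, cy))
  }
})

test_that("is_stable agrees with eigen analysis and the power oracle", {
  expect_true(is_stable(matrix(0, 3, 3)))
  # benchmark instantaneous matrix: nonzero eigen modulus (0.9025)^(1/3)
  B0 <- fixture_joint_cycle_graph()$weights
  expect_true(is_stable(B0))
  expect_equal(max(Mod(eigen(B0)$values)), 0.9025^(1 / 3), tolerance = 1e-10)
  # 2-cycle with product 1.1: eigenvalues +/- sqrt(1.1)
  B <- matrix(0, 2, 2); B[1, 2] <- 1.1; B[2, 1] <- 1
  expect_false(is_stable(B))
  expect_error(is_stable(matrix(1, 2, 3)), "square")
  set.seed(72)
  for (rep in 1:200) {
    n <- sample(2:6, 1)
    B <- matrix(stats::rnorm(n * n, sd = 0.5), n, n)
    rho_oracle <- oracle_spectral_radius(B)
    if (abs(rho_oracle - 1) < 1e-6) next  # boundary: oracle resolution
    expect_identical(is_stable(B), rho_oracle < 1)
  }
})

test_that("solve_equilibrium solves Y = B0 Y + c and matches Neumann sums", {
  expect_equal(solve_equilibrium(matrix(0, 3, 3), c(1, 2, 3)), c(1, 2, 3))
  B <- matrix(0, 2, 2); B[1, 2] <- 0.5; B[2, 1] <- 0.5
  expect_equal(solve_equilibrium(B, c(1, 1)), c(2, 2))
  B0 <- fixture_joint_cycle_graph()$weights
  expect_equal(solve_equilibrium(B0, rep(0, 4)), rep(0, 4))
  unstable <- matrix(c(0, 1.2, 1.2, 0), 2, 2)
  expect_error(solve_equilibrium(unstable, c(1, 1)), "stable")
  set.seed(73)
  for (rep in 1:30) {
    n <- sample(2:6, 1)
    g <- random_digraph(n, target_radius = stats::runif(1, 0.1, 0.9))
    cc <- stats::rnorm(n)
    y <- solve_equilibrium(g$weights, cc)
    expect_lt(max(abs(y - g$weights %*% y - cc)), 1e-10)
    # truncated Neumann series
    acc <- cc; term <- cc
    for (k in 1:300) { term <- g$weights %*% term; acc <- acc + term }
    expect_equal(y, as.numeric(acc), tolerance = 1e-6)
  }
})

test_that("unmixing conversions are mutually inverse and scale invariant", {
  g0 <- weighted_digraph(matrix(0, 3, 3))
  expect_equal(unname(to_unmixing(g0)), diag(3))
  g <- fixture_joint_cycle_graph()
  W <- to_unmixing(g)
  expect_equal(W[1, ], c(Y1 = 1, Y2 = 0, Y3 = 0.95, Y4 = 0))
  expect_equal(from_unmixing(W)$weights, g$weights)
  # scaling a row leaves the normalized graph unchanged
  W2 <- W; W2[2, ] <- -2 * W2[2, ]
  expect_equal(from_unmixing(W2)$weights, g$weights)
  Wbad <- W; Wbad[1, 1] <- 0
  expect_error(from_unmixing(Wbad), "diagonal")
  set.seed(74)
  for (rep in 1:20) {
    g <- random_digraph(sample(2:6, 1))
    expect_equal(from_unmixing(to_unmixing(g))$weights, g$weights,
                 tolerance = 1e-12)
  }
})

test_that("graph export round-trips (CSV) and writes DOT/GraphML", {
  g <- fixture_joint_cycle_graph()
  tmp <- withr::local_tempdir()
  csv <- file.path(tmp, "g.csv")
  write_digraph(g, csv, format = "csv")
  expect_equal(read_digraph_csv(csv)$weights, g$weights)
  dot <- file.path(tmp, "g.dot")
  write_digraph(g, dot, format = "dot")
  txt <- readLines(dot)
  expect_true(any(grepl("\"Y3\" -> \"Y1\"", txt)))
  gml <- file.path(tmp, "g.graphml")
  write_digraph(g, gml, format = "graphml")
  expect_true(file.size(gml) > 0)
})
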