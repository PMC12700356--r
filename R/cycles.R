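#' Enumerate the simple directed cycles of a weighted digraph
#'
#' A directed cycle on vertices `(v1, ..., vM)`, `M >= 2`, consists of
#' exactly the `M` loop edges `v1 -> v2, ..., vM -> v1`; self-loops are
#' excluded.  Each cycle is reported once, in canonical rotation (the
#' sequence starts at its smallest vertex index), and the output is
#' ordered by length and then lexicographically.
#'
#' By default a chord (an extra edge among the cycle's vertices that is
#' not one of its loop edges) does not suppress the cycle: the cycle is
#' the vertex sequence together with its own loop edges, and other edges
#' of the host graph are irrelevant.  Setting `chordless_only = TRUE`
#' switches to the stricter reading in which a cycle is only reported
#' when no chord connects two of its vertices.
#'
#' @param graph a [weighted_digraph()].
#' @param chordless_only drop cycles that carry a chord (default `FALSE`).
#' @return list of integer vectors, each a cycle in canonical rotation;
#'   empty list when the graph is acyclic.
#' @export
find_cycles <- function(graph, chordless_only = FALSE) {
  if (!inherits(graph, "weighted_digraph")) {
    stop("`graph` must be a weighted_digraph", call. = FALSE)
  }
  sup <- edge_support(graph)                 # sup[q, p]: edge p -> q
  n <- nrow(sup)
  out_nbrs <- lapply(seq_len(n), function(p) which(sup[, p]))
  cycles <- list()

  # Johnson-style enumeration: for each root s in increasing order, search
  # only vertices >= s so every cycle is found exactly once, rooted at its
  # smallest vertex.  `blocked` prunes vertices that cannot reach s on the
  # current stack.
  for (s in seq_len(n)) {
    path <- integer(0)
    on_path <- rep(FALSE, n)
    dfs <- function(v) {
      path[length(path) + 1L] <<- v
      on_path[v] <<- TRUE
      for (w in out_nbrs[[v]]) {
        if (w == s && length(path) >= 2L) {
          cycles[[length(cycles) + 1L]] <<- path
        } else if (w > s && !on_path[w]) {
          dfs(w)
        }
      }
      on_path[v] <<- FALSE
      path <<- path[-length(path)]
    }
    dfs(s)
  }

  if (chordless_only && length(cycles)) {
    keep <- vapply(cycles, function(cy) {
      m <- length(cy)
      loop <- cbind(cy[c(seq_len(m)[-1L], 1L)], cy)  # (to, from) pairs
      inner <- sup[cy, cy, drop = FALSE]
      sum(inner) == m &&
        all(sup[loop])  # exactly the M loop edges among cycle vertices
    }, logical(1))
    cycles <- cycles[keep]
  }

  if (length(cycles)) {
    ord <- order(lengths(cycles),
                 vapply(cycles, function(cy) {
                   paste(formatC(cy, width = 3, flag = "0"), collapse = "")
                 }, character(1)))
    cycles <- cycles[ord]
  }
  cycles
}

#' Validate a cycle against a host graph
#'
#' Checks that the vertex sequence has length at least two, contains no
#' repeats, and that every loop edge (including the wrap-around) is
#' present in the graph.
#'
#' @param graph a [weighted_digraph()].
#' @param cycle integer vector of vertex indices.
#' @return `TRUE` invisibly; errors otherwise.
#' @export
validate_cycle <- function(graph, cycle) {
  cycle <- as.integer(cycle)
  n <- n_vertices(graph)
  if (length(cycle) < 2L) stop("a cycle has at least 2 vertices", call. = FALSE)
  if (anyDuplicated(cycle)) stop("cycle vertices must be distinct", call. = FALSE)
  if (any(cycle < 1L | cycle > n)) stop("cycle vertex out of range", call. = FALSE)
  sup <- edge_support(graph)
  to <- cycle[c(seq_along(cycle)[-1L], 1L)]
  ok <- sup[cbind(to, cycle)]
  if (!all(ok)) {
    stop("missing cycle edge(s): ",
         paste(graph$labels[cycle[!ok]], "->", graph$labels[to[!ok]],
               collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

canonical_rotation <- function(cycle) {
  k <- which.min(cycle)
  if (k == 1L) cycle else c(cycle[k:length(cycle)], cycle[seq_len(k - 1L)])
}

#' In-cycle parent of each cycle vertex
#'
#' For a cycle `v1 -> v2 -> ... -> vM -> v1` the parent of `v_k` inside
#' the cycle is `v_{k-1}` (and the parent of `v1` is `vM`); it is unique
#' by definition.
#'
#' @param cycle integer vector of vertex indices in cycle order.
#' @return named integer vector mapping each vertex to its in-cycle parent.
#' @keywords internal
cycle_parents <- function(cycle) {
  m <- length(cycle)
  stats::setNames(cycle[c(m, seq_len(m - 1L))], cycle)
}
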