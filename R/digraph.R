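#' Weighted directed graph with target-row coefficient convention
#'
#' Container for the instantaneous structure of a linear structural causal
#' model.  The coefficient matrix `B` follows the target-row convention:
#' entry `(q, p)` is the coefficient of the edge `p -> q`, i.e. the direct
#' effect of vertex `p` on vertex `q`.  Self-loops are excluded, so the
#' diagonal must be exactly zero.  An edge exists iff its coefficient
#' exceeds `zero_tol` in magnitude.
#'
#' @param weights square numeric matrix, entry `(q, p)` the effect of `p`
#'   on `q`.
#' @param labels optional character vector of vertex names; defaults to
#'   `Y1, ..., Yn` (or the matrix dimnames when present).
#' @param zero_tol magnitude below which a coefficient is treated as a
#'   structural zero.
#' @return an object of class `weighted_digraph` with elements `weights`,
#'   `labels`, `zero_tol`.
#' @examples
#' B <- matrix(0, 3, 3); B[2, 1] <- 0.8; B[1, 2] <- -0.5
#' g <- weighted_digraph(B)
#' edge_list(g)
#' @export
weighted_digraph <- function(weights, labels = NULL, zero_tol = 1e-8) {
  weights <- as.matrix(weights)
  if (nrow(weights) != ncol(weights)) {
    stop("`weights` must be a square matrix", call. = FALSE)
  }
  if (!is.numeric(weights) || anyNA(weights)) {
    stop("`weights` must be numeric without missing values", call. = FALSE)
  }
  if (any(abs(diag(weights)) > 0)) {
    stop("invalid graph: diagonal of `weights` must be exactly zero ",
         "(self-loops are excluded)", call. = FALSE)
  }
  n <- nrow(weights)
  if (is.null(labels)) {
    labels <- if (!is.null(rownames(weights))) rownames(weights)
              else paste0("Y", seq_len(n))
  }
  if (length(labels) != n || anyDuplicated(labels)) {
    stop("`labels` must be ", n, " distinct names", call. = FALSE)
  }
  dimnames(weights) <- list(labels, labels)
  structure(list(weights = weights, labels = labels, zero_tol = zero_tol),
            class = "weighted_digraph")
}

#' @export
print.weighted_digraph <- function(x, ...) {
  el <- edge_list(x)
  cat("<weighted_digraph> ", length(x$labels), " vertices, ",
      nrow(el), " edges\n", sep = "")
  if (nrow(el)) {
    apply(el, 1L, function(e) {
      cat("  ", e[["from"]], " -> ", e[["to"]],
          "  (", signif(as.numeric(e[["weight"]]), 4), ")\n", sep = "")
    })
  }
  invisible(x)
}

n_vertices <- function(graph) length(graph$labels)

#' Logical adjacency (edge support) of a weighted digraph
#'
#' @param graph a [weighted_digraph()].
#' @return logical matrix; entry `(q, p)` is `TRUE` iff edge `p -> q`
#'   exists at the graph's zero tolerance.
#' @export
edge_support <- function(graph) {
  abs(graph$weights) > graph$zero_tol
}

#' Edges of a weighted digraph as a data frame
#'
#' @param graph a [weighted_digraph()].
#' @return data frame with columns `from`, `to`, `weight`, ordered by
#'   source then target vertex index.
#' @export
edge_list <- function(graph) {
  sup <- edge_support(graph)
  idx <- which(t(sup), arr.ind = TRUE)  # transpose: rows (from, to)
  data.frame(from   = graph$labels[idx[, 1L]],
             to     = graph$labels[idx[, 2L]],
             weight = graph$weights[cbind(idx[, 2L], idx[, 1L])],
             stringsAsFactors = FALSE)
}

#' Stability of an instantaneous coefficient matrix
#'
#' A cyclic linear system `Y = B0 Y + C` has a unique equilibrium when the
#' spectral radius of `B0` is strictly below one.  Boundary cases are
#' classified unstable via a small margin.
#'
#' @param B0 square numeric matrix (or a [weighted_digraph()]).
#' @param tol stability margin; the matrix is stable iff its spectral
#'   radius is `< 1 - tol`.
#' @return `TRUE` or `FALSE`.
#' @export
is_stable <- function(B0, tol = 1e-9) {
  if (inherits(B0, "weighted_digraph")) B0 <- B0$weights
  B0 <- as.matrix(B0)
  if (nrow(B0) != ncol(B0)) stop("`B0` must be square", call. = FALSE)
  spectral_radius(B0) < 1 - tol
}

spectral_radius <- function(B) {
  max(Mod(eigen(B, only.values = TRUE)$values))
}

#' Equilibrium of the cyclic system Y = B0 Y + c
#'
#' @param B0 stable square matrix of instantaneous coefficients.
#' @param c numeric vector of non-cyclic components (intercept, lagged and
#'   covariate effects, exogenous error).
#' @param tol stability margin passed to [is_stable()].
#' @return the unique solution `y = (I - B0)^{-1} c`.
#' @export
solve_equilibrium <- function(B0, c, tol = 1e-9) {
  if (inherits(B0, "weighted_digraph")) B0 <- B0$weights
  B0 <- as.matrix(B0)
  if (!is_stable(B0, tol)) {
    stop("`B0` is not stable: spectral radius ", signif(spectral_radius(B0), 6),
         " >= 1", call. = FALSE)
  }
  as.numeric(solve(diag(nrow(B0)) - B0, c))
}

#' Convert between a coefficient graph and its unmixing matrix
#'
#' The unmixing matrix of a linear SCM `Y = B Y + E` is `W = I - B`; its
#' rows map observations to independent exogenous errors.  `from_unmixing`
#' first normalizes each row by its diagonal element (ICA determines rows
#' only up to scale) and then reads off `B = I - W`.
#'
#' @param graph a [weighted_digraph()].
#' @return `to_unmixing`: the matrix `I - B`.
#' @export
to_unmixing <- function(graph) {
  diag(n_vertices(graph)) - graph$weights
}

#' @rdname to_unmixing
#' @param W square numeric matrix with nonzero diagonal.
#' @param zero_tol zero tolerance for the resulting graph (also used to
#'   test diagonal admissibility).
#' @param labels optional vertex names.
#' @return `from_unmixing`: the [weighted_digraph()] with `B = I - W`
#'   after row normalization.
#' @export
from_unmixing <- function(W, zero_tol = 1e-8, labels = NULL) {
  W <- as.matrix(W)
  if (nrow(W) != ncol(W)) stop("`W` must be square", call. = FALSE)
  d <- diag(W)
  if (any(abs(d) <= zero_tol)) {
    stop("inadmissible unmixing matrix: zero diagonal element(s) at row(s) ",
         paste(which(abs(d) <= zero_tol), collapse = ", "), call. = FALSE)
  }
  Wn <- W / d  # divide each row by its diagonal
  B <- diag(nrow(W)) - Wn
  B[abs(B) <= zero_tol] <- 0
  diag(B) <- 0
  if (is.null(labels) && !is.null(rownames(W))) labels <- rownames(W)
  weighted_digraph(B, labels = labels, zero_tol = zero_tol)
}

# ---- export formats -------------------------------------------------------

as_igraph <- function(graph) {
  # igraph adjacency uses (from, to); ours is (to, from)
  igraph::graph_from_adjacency_matrix(t(graph$weights), mode = "directed",
                                      weighted = TRUE)
}

#' Write a weighted digraph to DOT, GraphML or adjacency CSV
#'
#' @param graph a [weighted_digraph()].
#' @param path output file path.
#' @param format one of `"dot"`, `"graphml"`, `"csv"`.
#' @param digits number of digits for DOT edge labels.
#' @return `path`, invisibly.
#' @export
write_digraph <- function(graph, path, format = c("dot", "graphml", "csv"),
                          digits = 2) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(graph$weights, path, row.names = TRUE)
  } else if (format == "graphml") {
    igraph::write_graph(as_igraph(graph), path, format = "graphml")
  } else {
    el <- edge_list(graph)
    lines <- c("digraph G {",
               paste0("  \"", graph$labels, "\";"),
               if (nrow(el)) {
                 paste0("  \"", el$from, "\" -> \"", el$to,
                        "\" [weight=", el$weight,
                        ", label=\"", round(el$weight, digits), "\"];")
               },
               "}")
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read a weighted digraph from an adjacency CSV written by [write_digraph()]
#'
#' @param path CSV file with header labels and one label column.
#' @param zero_tol zero tolerance of the resulting graph.
#' @return a [weighted_digraph()].
#' @export
read_digraph_csv <- function(path, zero_tol = 1e-8) {
  m <- as.matrix(utils::read.csv(path, row.names = 1, check.names = FALSE))
  weighted_digraph(m, labels = rownames(m), zero_tol = zero_tol)
}
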