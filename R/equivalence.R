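#' Reverse disjoint cycles of a graph within its ICA equivalence class
#'
#' Reversing a set of pairwise vertex-disjoint cycles, while re-targeting
#' every out-of-cycle parent edge of a cycle vertex to that vertex's
#' in-cycle parent, produces another member of the graph's ICA
#' equivalence class.  The operation corresponds exactly to the
#' admissible row-permutation `phi(r) = pa_O(r)` (each cycle vertex maps
#' to its in-cycle parent) applied to the unmixing matrix `W = I - B`,
#' followed by row normalization:
#'
#' * a reversed cycle edge `r -> pa(r)` carries weight `1 / B[r, pa(r)]`
#'   (the reciprocal of the original in-cycle coefficient), and
#' * an out-of-cycle parent edge `t -> r` is re-targeted to
#'   `t -> pa(r)` with weight `-B[r, t] / B[r, pa(r)]`.
#'
#' @param graph a [weighted_digraph()].
#' @param cycles list of integer vectors, pairwise vertex-disjoint cycles
#'   present in `graph` (as returned by [find_cycles()]).
#' @param method `"unmixing"` performs the row-permutation on `W` and
#'   normalizes; `"edges"` performs the combinatorial graph surgery
#'   directly.  The two routes agree up to floating point.
#' @return the resulting [weighted_digraph()].
#' @export
reverse_cycle_surgery <- function(graph, cycles,
                                  method = c("unmixing", "edges")) {
  method <- match.arg(method)
  if (!length(cycles)) return(graph)
  cycles <- lapply(cycles, as.integer)
  for (cy in cycles) validate_cycle(graph, cy)
  all_v <- unlist(cycles)
  if (anyDuplicated(all_v)) {
    stop("cycles must be pairwise vertex-disjoint: no admissible ",
         "row-permutation can reverse joint cycles", call. = FALSE)
  }

  if (method == "unmixing") {
    pa <- unlist(lapply(cycles, cycle_parents))
    dom <- as.integer(names(pa))
    phi <- row_permutation(dom, as.integer(pa))
    W <- to_unmixing(graph)
    if (!is_admissible(W, phi, graph$zero_tol)) {
      stop("cycle reversal is not admissible for this graph", call. = FALSE)
    }
    return(from_unmixing(apply_permutation(W, phi),
                         zero_tol = graph$zero_tol, labels = graph$labels))
  }

  B <- graph$weights
  Bnew <- B
  for (cy in cycles) {
    pa <- cycle_parents(cy)
    for (k in seq_along(cy)) {
      r <- cy[k]; s <- pa[[as.character(r)]]
      brs <- B[r, s]
      row <- numeric(ncol(B))
      row[r] <- 1 / brs
      others <- setdiff(which(abs(B[r, ]) > graph$zero_tol), c(r, s))
      row[others] <- -B[r, others] / brs
      Bnew[s, ] <- row
    }
  }
  weighted_digraph(Bnew, labels = graph$labels, zero_tol = graph$zero_tol)
}

support_key <- function(graph) {
  paste(which(edge_support(graph)), collapse = ",")
}

all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (p in sub) {
    for (pos in seq_len(n)) {
      k <- k + 1L
      out[[k]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

#' Enumerate the ICA equivalence class of a directed graph
#'
#' Iterates over all permutations of the full row index set of the
#' unmixing matrix `W = I - B`, keeps the admissible ones, normalizes
#' rows, and deduplicates the resulting graphs by edge support at the
#' zero tolerance.  The base graph (identity permutation) is always a
#' member.  A directed acyclic graph yields a class of size one.
#'
#' @param graph a [weighted_digraph()].
#' @param stable_only keep only members whose coefficient matrix is
#'   stable (spectral radius below one).
#' @param max_vertices guard on the factorial cost of the enumeration.
#' @return object of class `ica_equivalence_class`: list with `base` and
#'   `members`, each member a list `graph`, `stable`, `perm` (the
#'   generating [row_permutation()], `NULL` for the base).
#' @export
enumerate_class <- function(graph, stable_only = FALSE, max_vertices = 9L) {
  n <- n_vertices(graph)
  if (n > max_vertices) {
    stop("graph has ", n, " vertices; enumeration is factorial and capped ",
         "at ", max_vertices, " (raise `max_vertices` to override)",
         call. = FALSE)
  }
  W <- to_unmixing(graph)
  tol <- graph$zero_tol
  members <- list()
  seen <- character(0)
  # the base graph (identity permutation) is always the first member, so
  # that support-preserving non-identity permutations cannot claim its slot
  base_norm <- from_unmixing(W, zero_tol = tol, labels = graph$labels)
  if (!stable_only || is_stable(base_norm$weights)) {
    members[[1L]] <- list(graph = base_norm,
                          stable = is_stable(base_norm$weights), perm = NULL)
    seen <- support_key(base_norm)
  }
  for (perm in all_permutations(n)) {
    phi <- row_permutation_from_perm(perm)
    if (is.null(phi)) next  # identity already handled
    # diagonal of the permuted matrix at row perm[r] is W[r, perm[r]]
    if (any(abs(W[cbind(seq_len(n), perm)]) <= tol)) next
    W2 <- apply_permutation(W, phi)
    g2 <- from_unmixing(W2, zero_tol = tol, labels = graph$labels)
    stab <- is_stable(g2$weights)
    if (stable_only && !stab) next
    key <- support_key(g2)
    if (key %in% seen) next
    seen <- c(seen, key)
    members[[length(members) + 1L]] <-
      list(graph = g2, stable = stab, perm = phi)
  }
  # deterministic order: base first, then by support key
  is_base <- vapply(members, function(m) is.null(m$perm), logical(1))
  keys <- vapply(members, function(m) support_key(m$graph), character(1))
  members <- members[order(!is_base, keys)]
  structure(list(base = graph, members = members),
            class = "ica_equivalence_class")
}

#' @export
print.ica_equivalence_class <- function(x, ...) {
  cat("<ica_equivalence_class> ", length(x$members), " member(s); ",
      sum(vapply(x$members, `[[`, logical(1), "stable")), " stable\n",
      sep = "")
  invisible(x)
}

#' @export
length.ica_equivalence_class <- function(x) length(x$members)

class_support_keys <- function(cls) {
  sort(vapply(cls$members, function(m) support_key(m$graph), character(1)))
}

#' Enumerate the equivalence class via cycle-reversal surgery
#'
#' Generates class members by applying [reverse_cycle_surgery()] to every
#' subset of pairwise vertex-disjoint cycles of the graph (the
#' characterization of the ICA equivalence class).  Used as the
#' constructive counterpart of the brute-force [enumerate_class()].
#'
#' @inheritParams enumerate_class
#' @return an `ica_equivalence_class`.
#' @export
enumerate_class_by_surgery <- function(graph, stable_only = FALSE) {
  cycles <- find_cycles(graph)
  nc <- length(cycles)
  members <- list()
  seen <- character(0)
  add_member <- function(g2, perm) {
    stab <- is_stable(g2$weights)
    if (stable_only && !stab) return(invisible(NULL))
    key <- support_key(g2)
    if (key %in% seen) return(invisible(NULL))
    seen <<- c(seen, key)
    members[[length(members) + 1L]] <<-
      list(graph = g2, stable = stab, perm = perm)
  }
  add_member(graph, NULL)
  if (nc) {
    for (mask in seq_len(2^nc - 1L)) {
      pick <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(nc) - 1L)) != 0L)
      chosen <- cycles[pick]
      if (anyDuplicated(unlist(chosen))) next  # joint cycles: skip
      pa <- unlist(lapply(chosen, cycle_parents))
      phi <- row_permutation(as.integer(names(pa)), as.integer(pa))
      g2 <- reverse_cycle_surgery(graph, chosen)
      add_member(g2, phi)
    }
  }
  is_base <- vapply(members, function(m) is.null(m$perm), logical(1))
  keys <- vapply(members, function(m) support_key(m$graph), character(1))
  members <- members[order(!is_base, keys)]
  structure(list(base = graph, members = members),
            class = "ica_equivalence_class")
}

#' Declare instrumental variables for graph vertices
#'
#' An instrumental variable for a vertex `Y` is a variable outside the
#' instantaneous graph whose only edge into the graph is `I_Y -> Y`.  In
#' longitudinal data the natural candidates are covariates and lagged
#' copies of the outcomes.
#'
#' @param targets character vector of target vertex labels.
#' @param instruments character vector of instrument names (must be
#'   distinct; an instrument has exactly one declared child).
#' @param weights numeric vector of edge weights used when the instrument
#'   vertex has to be added to a graph (default 0.5 each).
#' @return object of class `instrument_spec`.
#' @export
instrument_spec <- function(targets, instruments = paste0("I_", targets),
                            weights = rep(0.5, length(targets))) {
  targets <- as.character(targets)
  instruments <- as.character(instruments)
  if (length(instruments) != length(targets) ||
      length(weights) != length(targets)) {
    stop("`targets`, `instruments`, `weights` must have equal length",
         call. = FALSE)
  }
  if (anyDuplicated(instruments)) {
    stop("invalid instrument: an instrumental variable has exactly one ",
         "child, so instrument names must be distinct", call. = FALSE)
  }
  if (anyDuplicated(targets)) {
    stop("each target may carry at most one declared instrument",
         call. = FALSE)
  }
  structure(list(targets = targets, instruments = instruments,
                 weights = as.numeric(weights)),
            class = "instrument_spec")
}

#' Augment a graph with its declared instrument vertices
#'
#' Instrument vertices not already present are appended with a single
#' edge to their declared target.
#'
#' @param graph a [weighted_digraph()].
#' @param spec an [instrument_spec()].
#' @return a [weighted_digraph()] over the original and instrument vertices.
#' @export
augment_with_instruments <- function(graph, spec) {
  stopifnot(inherits(spec, "instrument_spec"))
  missing_t <- setdiff(spec$targets, graph$labels)
  if (length(missing_t)) {
    stop("target(s) not in graph: ", paste(missing_t, collapse = ", "),
         call. = FALSE)
  }
  new_iv <- setdiff(spec$instruments, graph$labels)
  n0 <- n_vertices(graph)
  labels <- c(graph$labels, new_iv)
  n <- length(labels)
  B <- matrix(0, n, n, dimnames = list(labels, labels))
  B[seq_len(n0), seq_len(n0)] <- graph$weights
  for (k in seq_along(spec$targets)) {
    iv <- spec$instruments[k]; tg <- spec$targets[k]
    if (iv %in% new_iv) {
      B[tg, iv] <- spec$weights[k]
    } else if (abs(B[tg, iv]) <= graph$zero_tol) {
      stop("instrument ", iv, " is present in the graph but has no edge ",
           "to its declared target ", tg, call. = FALSE)
    }
  }
  # Definition check: each instrument's only child among graph vertices
  # must be its declared target.
  for (k in seq_along(spec$instruments)) {
    iv <- spec$instruments[k]
    children <- labels[abs(B[, iv]) > graph$zero_tol]
    children <- setdiff(children, spec$instruments)
    if (!identical(sort(children), sort(spec$targets[k]))) {
      stop("invalid instrument ", iv, ": children among graph vertices are {",
           paste(children, collapse = ", "), "}, expected only ",
           spec$targets[k], call. = FALSE)
    }
  }
  weighted_digraph(B, labels = labels, zero_tol = graph$zero_tol)
}

#' Certify unique identifiability of a graph given instruments
#'
#' Two complementary checks are performed on the instrument-augmented
#' graph.  The sufficient condition requires every directed cycle to
#' contain a vertex with its own (used) instrument.  The constructive
#' check enumerates the ICA equivalence class of the augmented graph and
#' counts the members in which every used instrument's only child among
#' the original vertices is its declared target; the graph is uniquely
#' identified iff exactly one member survives.  When the surviving
#' subclass is larger, the certificate lists it.
#'
#' @param graph a [weighted_digraph()] (instantaneous structure; may
#'   already contain the instrument vertices).
#' @param spec an [instrument_spec()]; instruments absent from `graph`
#'   are added via [augment_with_instruments()].
#' @param use character vector of instrument names actually known /
#'   used for identification (default: all declared).
#' @param stable_only restrict the surviving subclass to stable members.
#' @param max_vertices passed to [enumerate_class()].
#' @return object of class `identifiability_certificate`: list with
#'   `unique`, `sufficient`, `class_size`, `surviving` (member list),
#'   `used_instruments`.
#' @export
certify_identifiability <- function(graph, spec, use = spec$instruments,
                                    stable_only = FALSE, max_vertices = 9L) {
  stopifnot(inherits(spec, "instrument_spec"))
  keep <- spec$instruments %in% use
  if (!any(keep)) stop("`use` selects no declared instrument", call. = FALSE)
  aug <- augment_with_instruments(graph, spec)
  outcome_labels <- setdiff(graph$labels, spec$instruments)

  # sufficient condition on the unaugmented outcome graph
  gsub <- weighted_digraph(
    graph$weights[outcome_labels, outcome_labels, drop = FALSE],
    labels = outcome_labels, zero_tol = graph$zero_tol)
  cycles <- find_cycles(gsub)
  instrumented <- spec$targets[keep]
  sufficient <- all(vapply(cycles, function(cy) {
    any(outcome_labels[cy] %in% instrumented)
  }, logical(1)))

  cls <- enumerate_class(aug, stable_only = stable_only,
                         max_vertices = max_vertices)
  surviving <- Filter(function(m) {
    B <- m$graph$weights
    all(vapply(which(keep), function(k) {
      iv <- spec$instruments[k]
      children <- m$graph$labels[abs(B[, iv]) > m$graph$zero_tol]
      children <- setdiff(children, spec$instruments)
      identical(children, spec$targets[k])
    }, logical(1)))
  }, cls$members)

  structure(list(unique = length(surviving) == 1L,
                 sufficient = sufficient,
                 class_size = length(cls$members),
                 surviving = surviving,
                 used_instruments = spec$instruments[keep]),
            class = "identifiability_certificate")
}

#' @export
print.identifiability_certificate <- function(x, ...) {
  cat("<identifiability_certificate>\n",
      "  unique:          ", x$unique, "\n",
      "  sufficient cond: ", x$sufficient, "\n",
      "  class size:      ", x$class_size, "\n",
      "  surviving:       ", length(x$surviving), " member(s)\n", sep = "")
  invisible(x)
}

#' Serialize an identifiability certificate to JSON
#'
#' @param cert an `identifiability_certificate`.
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to a file).
#' @export
certificate_json <- function(cert, path = NULL) {
  payload <- list(
    unique = cert$unique,
    sufficient_condition = cert$sufficient,
    class_size = cert$class_size,
    used_instruments = cert$used_instruments,
    surviving = lapply(cert$surviving, function(m) {
      list(edges = edge_list(m$graph),
           stable = m$stable,
           permutation = if (is.null(m$perm)) NULL else
             list(domain = m$perm$domain, image = m$perm$image))
    }))
  txt <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                          null = "null")
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}
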