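#' Posterior summary and median-probability graph selection
#'
#' An edge is included exactly when its posterior inclusion probability
#' (fraction of retained draws in the slab) strictly exceeds the
#' threshold; a fraction exactly equal to the threshold is excluded.
#' Coefficients of included edges are posterior means over their slab
#' draws.
#'
#' @param fit a [fit_dcg()] result.
#' @param threshold inclusion-probability threshold (default 0.5, the
#'   median probability model).
#' @return object of class `dcg_summary` with elements `graph` (selected
#'   instantaneous [weighted_digraph()]), `B0_prob`, `B0_mean`, lagged
#'   matrices `B_lag` / `B_lag_prob`, covariate matrices `A` / `A_prob`,
#'   `mu`, `sigma2`, `edges` (combined edge table), `threshold`,
#'   `diagnostics`.
#' @export
select_graph <- function(fit, threshold = 0.5) {
  stopifnot(inherits(fit, "dcg_fit"))
  if (!fit$draws$n_kept) stop("fit contains no retained draws", call. = FALSE)
  Q <- length(fit$ylabels)
  g0 <- fit$draws$gamma0          # Q x Q x K, 1 = slab
  B0d <- fit$draws$B0
  prob0 <- apply(g0, c(1, 2), mean)
  mean0 <- slab_mean(B0d, g0)
  sel0 <- (prob0 > threshold)
  diag(sel0) <- FALSE
  B0_sel <- ifelse(sel0, mean0, 0)
  dimnames(prob0) <- dimnames(mean0) <- dimnames(B0_sel) <-
    list(fit$ylabels, fit$ylabels)
  graph <- weighted_digraph(B0_sel, labels = fit$ylabels)

  info <- fit$col_info
  thd <- fit$draws$theta; gZ <- fit$draws$gammaZ
  probZ <- apply(gZ, c(1, 2), mean)
  meanZ <- slab_mean(thd, gZ)
  mu <- apply(thd[1L, , , drop = FALSE], 2L, mean)

  B_lag <- list(); B_lag_prob <- list()
  if (fit$control$Ly > 0L) for (l in seq_len(fit$control$Ly)) {
    ks <- which(info$type == "Ylag" & info$lag == l)
    ks <- ks[order(info$src[ks])]
    m <- t(meanZ[ks, , drop = FALSE]); p <- t(probZ[ks, , drop = FALSE])
    m[p <= threshold] <- 0
    dimnames(m) <- dimnames(p) <- list(fit$ylabels, fit$ylabels)
    B_lag[[l]] <- m; B_lag_prob[[l]] <- p
  }
  A <- list(); A_prob <- list()
  if (any(info$type == "X")) for (l in 0:fit$control$Lx) {
    ks <- which(info$type == "X" & info$lag == l)
    ks <- ks[order(info$src[ks])]
    m <- t(meanZ[ks, , drop = FALSE]); p <- t(probZ[ks, , drop = FALSE])
    m[p <= threshold] <- 0
    rownames(m) <- rownames(p) <- fit$ylabels
    colnames(m) <- colnames(p) <- sub("^lag[0-9]+_", "", info$name[ks])
    A[[l + 1L]] <- m; A_prob[[l + 1L]] <- p
  }

  edges <- selected_edge_table(fit$ylabels, B0_sel, prob0, B_lag, B_lag_prob,
                               A, A_prob)
  structure(list(graph = graph, B0_prob = prob0, B0_mean = mean0,
                 B_lag = B_lag, B_lag_prob = B_lag_prob,
                 A = A, A_prob = A_prob,
                 mu = mu, sigma2 = rowMeans(fit$draws$sigma2),
                 edges = edges, threshold = threshold,
                 diagnostics = fit$diagnostics),
            class = "dcg_summary")
}

slab_mean <- function(draws, ind) {
  num <- apply(draws * ind, c(1, 2), sum)
  den <- apply(ind, c(1, 2), sum)
  out <- num / pmax(den, 1)
  out[den == 0] <- 0
  out
}

selected_edge_table <- function(ylabels, B0, P0, B_lag, B_lag_prob,
                                A, A_prob) {
  rows <- list()
  add <- function(from, to, lag, weight, prob) {
    rows[[length(rows) + 1L]] <<- data.frame(
      from = from, to = to, lag = lag, weight = weight, prob = prob,
      stringsAsFactors = FALSE)
  }
  idx <- which(B0 != 0, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    add(ylabels[idx[r, 2]], ylabels[idx[r, 1]], 0L,
        B0[idx[r, 1], idx[r, 2]], P0[idx[r, 1], idx[r, 2]])
  }
  for (l in seq_along(B_lag)) {
    idx <- which(B_lag[[l]] != 0, arr.ind = TRUE)
    for (r in seq_len(nrow(idx))) {
      add(paste0("lag", l, "_", ylabels[idx[r, 2]]), ylabels[idx[r, 1]], l,
          B_lag[[l]][idx[r, 1], idx[r, 2]],
          B_lag_prob[[l]][idx[r, 1], idx[r, 2]])
    }
  }
  for (l in seq_along(A)) {
    idx <- which(A[[l]] != 0, arr.ind = TRUE)
    for (r in seq_len(nrow(idx))) {
      nm <- colnames(A[[l]])[idx[r, 2]]
      add(if (l == 1L) nm else paste0("lag", l - 1L, "_", nm),
          ylabels[idx[r, 1]], l - 1L,
          A[[l]][idx[r, 1], idx[r, 2]], A_prob[[l]][idx[r, 1], idx[r, 2]])
    }
  }
  if (!length(rows)) {
    return(data.frame(from = character(0), to = character(0),
                      lag = integer(0), weight = numeric(0),
                      prob = numeric(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' @export
print.dcg_summary <- function(x, ...) {
  cat("<dcg_summary> selected edges (threshold ", x$threshold, "):\n",
      sep = "")
  print(x$edges, row.names = FALSE)
  invisible(x)
}

#' Support key identifying a selected graph mode
#'
#' Instantaneous plus lagged edge support (weights ignored), used to
#' count distinct selected graphs across replicates.
#'
#' @param summary a [select_graph()] result.
#' @return a character key.
#' @export
summary_support_key <- function(summary) {
  e <- summary$edges
  paste(sort(paste0(e$from, ">", e$to)), collapse = ";")
}

#' Select lag orders by the coefficient-decay rule
#'
#' Fits the model once with `L_max` outcome and covariate lags, computes
#' the largest absolute posterior-mean coefficient `m_l` per lag matrix,
#' and retains lag `l >= 1` while `m_l / m_0 > drop_ratio` (with `m_0`
#' the corresponding lag-0 magnitude).  The rule is scale-free:
#' multiplying all genuinely active lags by a common factor does not
#' change the selection.
#'
#' @param panel a `panel_data`.
#' @param L_max maximal lag fitted (at least 1).
#' @param priors a [prior_config()].
#' @param drop_ratio relative-magnitude threshold below which a lag is
#'   deemed to have decayed to zero.
#' @param ... further arguments to [fit_dcg()] (`n_iter`, `seed`, ...).
#' @return list with `Ly`, `Lx`, the per-lag magnitudes `m_B`, `m_A`,
#'   and the underlying `fit`.
#' @export
select_lags <- function(panel, L_max = 2L, priors = prior_config(),
                        drop_ratio = 0.1, ...) {
  if (L_max < 1L) stop("`L_max` must be at least 1", call. = FALSE)
  has_x <- length(panel_columns(panel)$x) > 0L
  fit <- fit_dcg(panel, Ly = L_max, Lx = if (has_x) L_max else 0L,
                 priors = priors, ...)
  summ <- select_graph(fit)
  post_mean_B <- c(list(abs_max(slab_mean_for(fit, "B0"))),
                   lapply(seq_len(L_max), function(l)
                     abs_max(slab_mean_for(fit, "Ylag", l))))
  m_B <- unlist(post_mean_B)
  Ly <- pick_lag(m_B, drop_ratio)
  if (has_x) {
    m_A <- vapply(0:L_max, function(l) abs_max(slab_mean_for(fit, "X", l)),
                  numeric(1))
    Lx <- pick_lag(m_A, drop_ratio)
  } else {
    m_A <- numeric(0); Lx <- 0L
  }
  list(Ly = Ly, Lx = Lx, m_B = m_B, m_A = m_A, fit = fit, summary = summ)
}

# raw posterior-mean magnitude of a coefficient block (zeros from spike
# draws included, so inactive lags decay toward zero)
slab_mean_for <- function(fit, type, lag = NULL) {
  if (type == "B0") {
    return(apply(fit$draws$B0, c(1, 2), mean))
  }
  info <- fit$col_info
  ks <- which(info$type == type & info$lag == lag)
  apply(fit$draws$theta[ks, , , drop = FALSE], c(1, 2), mean)
}

abs_max <- function(m) if (length(m)) max(abs(m)) else 0

pick_lag <- function(m, drop_ratio) {
  # m[1] is lag 0; retain l while m[l+1]/m[1] stays above drop_ratio
  ref <- if (m[1] > 1e-8) m[1] else max(m, 1e-8)
  active <- which(m[-1L] / ref > drop_ratio)
  if (length(active)) max(active) else 0L
}

#' Post-hoc identifiability validation of a learned graph
#'
#' Delegates to [certify_identifiability()] on the selected instantaneous
#' graph.  When the declared instruments do not certify uniqueness, the
#' certificate carries all (by default stable) members of the learned
#' graph's ICA equivalence class, which is then the honest output of the
#' structural learning.
#'
#' @param summary a [select_graph()] result (or a [weighted_digraph()]).
#' @param spec an [instrument_spec()].
#' @param stable_only restrict the reported class to stable members
#'   (default `TRUE`, matching the stability constraint of the sampler).
#' @param ... passed to [certify_identifiability()].
#' @return an `identifiability_certificate`.
#' @export
posthoc_validate <- function(summary, spec = NULL, stable_only = TRUE, ...) {
  graph <- if (inherits(summary, "weighted_digraph")) summary
           else summary$graph
  if (is.null(spec)) {
    # no instruments declared: the output is the (stable) equivalence class
    cls <- enumerate_class(graph, stable_only = stable_only)
    cycles <- find_cycles(graph)
    return(structure(list(unique = length(cls$members) == 1L,
                          sufficient = length(cycles) == 0L,
                          class_size = length(cls$members),
                          surviving = cls$members,
                          used_instruments = character(0)),
                     class = "identifiability_certificate"))
  }
  certify_identifiability(graph, spec, stable_only = stable_only, ...)
}
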