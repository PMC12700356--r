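# Independent oracles and fixture builders used across the suite.

# Brute-force simple-cycle oracle: checks every cyclic arrangement of
# every vertex subset against the edge support.  Exponential; n <= 6.
oracle_cycles <- function(graph) {
  sup <- edge_support(graph)
  n <- nrow(sup)
  found <- list()
  subsets <- function(v) {
    if (!length(v)) return(list(integer(0)))
    rest <- subsets(v[-1L])
    c(rest, lapply(rest, function(s) c(v[1L], s)))
  }
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    }
    out
  }
  for (s in subsets(seq_len(n))) {
    if (length(s) < 2L) next
    first <- min(s)
    for (p in perms(setdiff(s, first))) {
      cy <- c(first, p)
      to <- cy[c(seq_along(cy)[-1L], 1L)]
      if (all(sup[cbind(to, cy)])) found[[length(found) + 1L]] <- cy
    }
  }
  found
}

# Power-iteration spectral radius (oracle for is_stable).  The growth
# rate is measured as the geometric mean of per-step norm ratios over the
# tail, which converges even for complex-conjugate dominant pairs.
oracle_spectral_radius <- function(B, iters = 3000L, tail = 1000L) {
  n <- nrow(B)
  v <- complex(real = stats::rnorm(n), imaginary = stats::rnorm(n))
  v <- v / sqrt(sum(Mod(v)^2))
  log_acc <- 0; counted <- 0L
  for (k in seq_len(iters)) {
    w <- B %*% v
    nw <- sqrt(sum(Mod(w)^2))
    if (nw < 1e-300) return(0)
    if (k > iters - tail) {
      log_acc <- log_acc + log(nw)
      counted <- counted + 1L
    }
    v <- w / nw
  }
  exp(log_acc / counted)
}

# Random weighted digraph; optionally rescaled to a target spectral radius
random_digraph <- function(n, p_edge = 0.4, target_radius = NULL) {
  repeat {
    B <- matrix(stats::runif(n * n, -1, 1) *
                  (stats::runif(n * n) < p_edge), n, n)
    diag(B) <- 0
    if (is.null(target_radius)) break
    rho <- max(Mod(eigen(B, only.values = TRUE)$values))
    if (rho > 1e-8) {
      B <- B * (target_radius / rho)
      break
    }
  }
  weighted_digraph(B)
}

# Fixture: the four-outcome joint-cycle instantaneous graph used by the
# benchmark scenarios (two 3-cycles sharing {Y1, Y3})
fixture_joint_cycle_graph <- function() {
  B0 <- matrix(0, 4, 4)
  B0[1, 3] <- -0.95
  B0[2, 1] <- 1.05
  B0[3, 2] <- 1
  B0[3, 4] <- 1
  B0[4, 1] <- -0.1
  weighted_digraph(B0)
}

fixture_instruments <- function() {
  instrument_spec(c("Y1", "Y2", "Y4"), c("IY1", "IY2", "IY4"))
}

# Direct Laplace sampler (difference of exponentials), independent of the
# package's normal scale-mixture route
oracle_rlaplace <- function(n, b) {
  stats::rexp(n, 1 / b) - stats::rexp(n, 1 / b)
}
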