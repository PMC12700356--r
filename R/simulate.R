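#' Parameters of the longitudinal cyclic data-generating model
#'
#' The generative model for `Q` outcomes and `S` covariates is
#' \deqn{Y_j = \mu + \sum_{\ell=0}^{L_y} B_\ell Y_{j-\ell}
#'            + \sum_{\ell=0}^{L_x} A_\ell X_{j-\ell} + E_j,}
#' where `B0` holds the instantaneous (possibly cyclic) effects with zero
#' diagonal and spectral radius below one, and the exogenous errors are
#' Laplace with variance `8 * sigma2[q]` per outcome.
#'
#' @param mu intercept vector (length `Q`).
#' @param B list of `Q x Q` matrices `B0, B1, ..., BLy` (at least `B0`).
#' @param A list of `Q x S` matrices `A0, ..., ALx`, or `NULL` for `S = 0`.
#' @param sigma2 positive vector of error scale parameters (length `Q`);
#'   the marginal Laplace error variance is `8 * sigma2`.
#' @return object of class `dcg_params`.
#' @export
dcg_params <- function(mu, B, A = NULL, sigma2) {
  B <- lapply(B, as.matrix)
  Q <- length(mu)
  if (any(vapply(B, function(m) !all(dim(m) == Q), logical(1)))) {
    stop("every B matrix must be ", Q, "x", Q, call. = FALSE)
  }
  if (any(abs(diag(B[[1L]])) > 0)) {
    stop("B0 must have zero diagonal (no instantaneous self-loops)",
         call. = FALSE)
  }
  if (!is_stable(B[[1L]])) {
    stop("B0 must be stable (spectral radius < 1)", call. = FALSE)
  }
  if (is.null(A)) {
    S <- 0L
  } else {
    A <- lapply(A, as.matrix)
    S <- ncol(A[[1L]])
    if (any(vapply(A, function(m) nrow(m) != Q || ncol(m) != S, logical(1)))) {
      stop("every A matrix must be ", Q, "x", S, call. = FALSE)
    }
  }
  if (length(sigma2) == 1L) sigma2 <- rep(sigma2, Q)
  if (length(sigma2) != Q || any(sigma2 <= 0)) {
    stop("`sigma2` must be ", Q, " strictly positive values", call. = FALSE)
  }
  structure(list(Q = Q, S = S, Ly = length(B) - 1L,
                 Lx = if (is.null(A)) 0L else length(A) - 1L,
                 mu = as.numeric(mu), B = B, A = A,
                 sigma2 = as.numeric(sigma2)),
            class = "dcg_params")
}

#' Draw Laplace errors via their normal scale-mixture representation
#'
#' Draws `tau ~ Inverse-Gamma(1, 1/8)` and then
#' `e | tau ~ Normal(0, sigma2 / tau)`.  Marginally
#' `e ~ Laplace(0, 2 * sqrt(sigma2))` with variance `8 * sigma2`;
#' `sigma2 = 1/8` gives unit-variance errors.
#'
#' @param sigma2 positive scale parameter.
#' @param size number of draws.
#' @param return_tau also return the latent mixing variables.
#' @return numeric vector of draws, or a list `e`, `tau` when
#'   `return_tau = TRUE`.
#' @export
sample_laplace_mixture <- function(sigma2, size, return_tau = FALSE) {
  if (length(sigma2) != 1L || !is.finite(sigma2) || sigma2 <= 0) {
    stop("`sigma2` must be a single strictly positive value", call. = FALSE)
  }
  # tau ~ InvGamma(shape 1, scale 1/8)  <=>  1/tau ~ Exp(rate 1/8)
  tau <- 1 / stats::rgamma(size, shape = 1, rate = 1 / 8)
  e <- stats::rnorm(size, 0, sqrt(sigma2 / tau))
  if (return_tau) list(e = e, tau = tau) else e
}

#' Laplace density matching the scale-mixture parameterization
#'
#' @param x quantiles.
#' @param sigma2 scale parameter; the Laplace scale is `2 * sqrt(sigma2)`.
#' @param log return log density.
#' @return density values.
#' @export
dlaplace_mixture <- function(x, sigma2, log = FALSE) {
  b <- 2 * sqrt(sigma2)
  ld <- -log(2 * b) - abs(x) / b
  if (log) ld else exp(ld)
}

default_covariate_sampler <- function(S) {
  function(n) matrix(stats::rnorm(n * S), n, S)
}

#' Simulate a longitudinal panel from the cyclic generative model
#'
#' For each visit the non-cyclic component `C` (intercept, lagged
#' outcome and covariate terms, fresh Laplace errors) is assembled and
#' the outcome solves the equilibrium `Y = B0 Y + C`.  Initial lagged
#' values are handled by a burn-in of discarded visits (default 50) so
#' that retained visits are approximately stationary; `init = "zero"`
#' instead starts each individual from zero lags with no burn-in, which
#' is useful for exactness tests.
#'
#' @param params a [dcg_params()].
#' @param n_individuals number of individuals.
#' @param Ji visits per individual: a single count or a vector of length
#'   `n_individuals` (all at least 2).
#' @param covariate_sampler function `n -> n x S` matrix drawing one row
#'   per visit (i.i.d. across visits); default standard normal columns.
#' @param init `"burnin"` or `"zero"`.
#' @param burnin number of discarded initial visits per individual under
#'   `init = "burnin"`.
#' @return object of class `panel_data`: a long-format data frame with
#'   columns `id`, `visit`, `Y1..YQ`, `X1..XS`, plus attributes `errors`
#'   (matrix of retained exogenous errors) and `params`.
#' @export
simulate_panel <- function(params, n_individuals, Ji,
                           covariate_sampler = NULL,
                           init = c("burnin", "zero"), burnin = 50L) {
  stopifnot(inherits(params, "dcg_params"))
  init <- match.arg(init)
  if (length(Ji) == 1L) Ji <- rep(as.integer(Ji), n_individuals)
  if (length(Ji) != n_individuals || any(Ji < 2L)) {
    stop("`Ji` must give at least 2 visits for each individual", call. = FALSE)
  }
  Q <- params$Q; S <- params$S
  Ly <- params$Ly; Lx <- params$Lx
  if (S > 0L && is.null(covariate_sampler)) {
    covariate_sampler <- default_covariate_sampler(S)
  }
  pre <- if (init == "burnin") max(burnin, Ly, Lx) else max(Ly, Lx)
  rows <- vector("list", n_individuals)
  errs <- vector("list", n_individuals)
  for (i in seq_len(n_individuals)) {
    total <- pre + Ji[i]
    X <- if (S > 0L) covariate_sampler(total) else
      matrix(numeric(0), total, 0L)
    if (S > 0L && (!is.matrix(X) || nrow(X) != total || ncol(X) != S)) {
      stop("`covariate_sampler(n)` must return an n x S matrix", call. = FALSE)
    }
    E <- vapply(seq_len(Q),
                function(q) sample_laplace_mixture(params$sigma2[q], total),
                numeric(total))
    Y <- matrix(0, total, Q)
    IminusB0 <- diag(Q) - params$B[[1L]]
    for (j in seq_len(total)) {
      cvec <- params$mu + E[j, ]
      if (Ly > 0L) for (l in seq_len(Ly)) {
        if (j - l >= 1L) cvec <- cvec + params$B[[l + 1L]] %*% Y[j - l, ]
      }
      if (S > 0L) for (l in 0:Lx) {
        if (j - l >= 1L) cvec <- cvec + params$A[[l + 1L]] %*% X[j - l, ]
      }
      Y[j, ] <- solve(IminusB0, cvec)
    }
    keep <- (pre + 1L):total
    df <- data.frame(id = i, visit = seq_len(Ji[i]))
    for (q in seq_len(Q)) df[[paste0("Y", q)]] <- Y[keep, q]
    if (S > 0L) for (s in seq_len(S)) df[[paste0("X", s)]] <- X[keep, s]
    rows[[i]] <- df
    errs[[i]] <- E[keep, , drop = FALSE]
  }
  panel <- do.call(rbind, rows)
  rownames(panel) <- NULL
  structure(panel, errors = do.call(rbind, errs), params = params,
            class = c("panel_data", "data.frame"))
}

#' @export
print.panel_data <- function(x, ...) {
  cat("<panel_data> ", length(unique(x$id)), " individuals, ",
      nrow(x), " individual-visits, outcomes: ",
      paste(grep("^Y", names(x), value = TRUE), collapse = ", "), "\n",
      sep = "")
  NextMethod()
}

#' Four-outcome joint-cycle benchmark scenario
#'
#' Generates the four-variable instantaneous system with two joint
#' 3-cycles sharing `{Y1, Y3}`:
#' `Y1 = -0.95 Y3 + 0.5 I_{Y1} + e1`, `Y2 = 1.05 Y1 + e2`,
#' `Y3 = Y2 + Y4 + e3`, `Y4 = -0.1 Y1 + e4`, with `mu = 0`,
#' `sigma2 = 1/8` (unit-variance Laplace errors) and `Ji = 5` visits per
#' individual.  The instrument for `Y1` is either a standard-normal
#' covariate (`instrument = "covariate"`, giving `S = 1`, `Ly = Lx = 0`)
#' or the lag-1 copy of `Y1` (`instrument = "lag1"`, giving `S = 0`,
#' `Ly = 1`).
#'
#' @param n_individuals number of individuals (the benchmark uses 200,
#'   500 or 1000, i.e. total samples 1000, 2500, 5000; other values are
#'   allowed).
#' @param instrument `"covariate"` or `"lag1"`.
#' @return list with `panel` ([simulate_panel()] output), `truth` (the
#'   instantaneous [weighted_digraph()]), `instruments`
#'   ([instrument_spec()]), and `params`.
#' @export
scenario_one <- function(n_individuals = 1000L,
                         instrument = c("covariate", "lag1")) {
  instrument <- match.arg(instrument)
  B0 <- matrix(0, 4, 4)
  B0[1, 3] <- -0.95
  B0[2, 1] <- 1.05
  B0[3, 2] <- 1
  B0[3, 4] <- 1
  B0[4, 1] <- -0.1
  truth <- weighted_digraph(B0)
  if (instrument == "covariate") {
    A0 <- matrix(c(0.5, 0, 0, 0), 4, 1)
    params <- dcg_params(mu = rep(0, 4), B = list(B0), A = list(A0),
                         sigma2 = rep(1 / 8, 4))
    spec <- instrument_spec("Y1", "X1", 0.5)
  } else {
    B1 <- matrix(0, 4, 4)
    B1[1, 1] <- 0.5
    params <- dcg_params(mu = rep(0, 4), B = list(B0, B1),
                         sigma2 = rep(1 / 8, 4))
    spec <- instrument_spec("Y1", "lag1_Y1", 0.5)
  }
  panel <- simulate_panel(params, n_individuals, Ji = 5L)
  list(panel = panel, truth = truth, instruments = spec, params = params)
}

# Synthetic per-individual visit counts used as the default for the
# three-outcome cohort scenario: 200 counts on [3, 46] totalling 3684,
# mimicking the visit-count range and total of the motivating cohort
# (whose exact empirical distribution is not public).  Frozen from a
# right-skewed negative-binomial draw; see the methods vignette.
synthetic_visit_counts <- c(
  7, 29, 15, 27, 10, 29, 26, 7, 46, 35, 20, 27, 18, 41, 3, 5, 26, 8, 8, 4,
  11, 5, 7, 13, 22, 9, 9, 15, 20, 21, 28, 4, 32, 46, 21, 22, 5, 13, 46, 6,
  10, 16, 30, 15, 8, 26, 46, 46, 12, 6, 16, 3, 35, 20, 11, 19, 21, 5, 31, 45,
  37, 31, 28, 19, 19, 6, 9, 40, 6, 16, 6, 39, 35, 16, 9, 26, 28, 11, 19, 39,
  9, 18, 25, 5, 46, 17, 20, 23, 46, 29, 9, 34, 13, 9, 22, 8, 20, 15, 3, 14,
  17, 15, 4, 16, 5, 10, 23, 24, 14, 9, 3, 3, 12, 27, 5, 17, 9, 19, 14, 12,
  17, 30, 29, 11, 40, 46, 7, 10, 5, 11, 15, 12, 15, 22, 12, 8, 6, 25, 9, 5,
  46, 5, 4, 42, 24, 8, 37, 22, 9, 10, 17, 46, 13, 31, 10, 14, 3, 27, 4, 22,
  19, 10, 22, 11, 12, 16, 19, 13, 6, 46, 24, 5, 13, 26, 11, 16, 6, 11, 31, 7,
  11, 18, 9, 13, 45, 10, 8, 16, 7, 37, 10, 22, 24, 17, 36, 46, 23, 16, 8, 6)

#' Three-outcome cohort-like scenario with lagged and cyclic effects
#'
#' Generates `Q = 3` outcomes with one instantaneous 3-cycle
#' `Y1 -> Y3 -> Y2 -> Y1` and first-order lagged effects:
#' \preformatted{
#' Y1 = 1 + 0.5n Y2 + 0.5n lag(Y1) + 0.25n lag(Y2) + 0.75n X1 + e1
#' Y2 = -1 + 0.25n Y3 + 0.5n lag(Y2) + 0.125n lag(Y3) - 0.5n X2 + e2
#' Y3 = 0.1n Y1 + 0.5n lag(Y3) + 0.25n X3 + e3
#' }
#' with effect-size scale `n = eta`, covariates `X1 ~ Bernoulli(0.6)` and
#' `X2, X3 ~ N(0, 1)` i.i.d. across visits, and unit-variance Laplace
#' errors (`sigma2 = 1/8`).  Default visit counts are a frozen synthetic
#' distribution on `[3, 46]` totalling 3684 over 200 individuals.
#'
#' @param eta positive effect-size scale (0.5, 0.75 and 1 are the
#'   benchmark values).
#' @param n_individuals number of individuals.
#' @param Ji visit counts; defaults to the bundled synthetic counts when
#'   `n_individuals = 200`, otherwise resampled from them.
#' @return list with `panel`, `truth` (instantaneous graph), `truth_B1`,
#'   `truth_A0`, `instruments`, `params`.
#' @export
scenario_two <- function(eta = 1, n_individuals = 200L, Ji = NULL) {
  if (!is.finite(eta) || eta <= 0) {
    stop("`eta` must be strictly positive (eta = 0 is degenerate)",
         call. = FALSE)
  }
  if (is.null(Ji)) {
    Ji <- if (n_individuals == 200L) synthetic_visit_counts
          else sample(synthetic_visit_counts, n_individuals, replace = TRUE)
  }
  B0 <- matrix(0, 3, 3)
  B0[1, 2] <- 0.5 * eta
  B0[2, 3] <- 0.25 * eta
  B0[3, 1] <- 0.1 * eta
  B1 <- matrix(0, 3, 3)
  diag(B1) <- 0.5 * eta
  B1[1, 2] <- 0.25 * eta
  B1[2, 3] <- 0.125 * eta
  A0 <- diag(c(0.75, -0.5, 0.25) * eta)
  params <- dcg_params(mu = c(1, -1, 0), B = list(B0, B1), A = list(A0),
                       sigma2 = rep(1 / 8, 3))
  sampler <- function(n) {
    cbind(stats::rbinom(n, 1L, 0.6),
          stats::rnorm(n), stats::rnorm(n))
  }
  panel <- simulate_panel(params, n_individuals, Ji,
                          covariate_sampler = sampler)
  truth <- weighted_digraph(B0)
  spec <- instrument_spec(c("Y1", "Y2", "Y3"),
                          c("lag1_Y1", "X2", "X3"),
                          c(0.5 * eta, -0.5 * eta, 0.25 * eta))
  list(panel = panel, truth = truth, truth_B1 = B1, truth_A0 = A0,
       instruments = spec, params = params)
}
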