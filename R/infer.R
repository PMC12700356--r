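#' Prior configuration for spike-and-slab structural learning
#'
#' Every coefficient (instantaneous and lagged outcome effects, covariate
#' effects) carries a spike-and-slab prior: with probability `rho` the
#' coefficient is in the slab `N(0, nu)` with `nu ~ Inverse-Gamma(a_nu,
#' b_nu)`, otherwise it is in the spike and treated as zero (`nu0` is the
#' nominal spike scale used for reporting).  `rho ~ Beta(a_rho, b_rho)` is
#' shared across coefficients, intercepts are `N(0, sigma_mu2)`, and the
#' error scales follow `sigma_q^2 ~ Inverse-Gamma(a_sigma, b_sigma)`.
#'
#' @param nu0 nominal spike scale (very small).
#' @param a_nu,b_nu inverse-gamma shape/scale for the slab variance.
#' @param a_rho,b_rho beta hyper-parameters for the inclusion probability.
#' @param sigma_mu2 intercept prior variance.
#' @param a_sigma,b_sigma inverse-gamma shape/scale for the error scales.
#' @param constrained enable the hierarchical/shared-sign constrained
#'   variant: a lagged effect of `Yp` on `Yq` (`p != q`) can only be
#'   included when the instantaneous effect is, and all lags of a pair
#'   share the instantaneous sign (half-normal slab magnitudes); the same
#'   hierarchy applies to lagged covariate effects.
#' @return object of class `prior_config`.
#' @export
prior_config <- function(nu0 = 2.5e-4, a_nu = 5, b_nu = 50,
                         a_rho = 0.5, b_rho = 0.5,
                         sigma_mu2 = 100, a_sigma = 1, b_sigma = 1,
                         constrained = FALSE) {
  vals <- c(nu0 = nu0, a_nu = a_nu, b_nu = b_nu, a_rho = a_rho,
            b_rho = b_rho, sigma_mu2 = sigma_mu2, a_sigma = a_sigma,
            b_sigma = b_sigma)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all prior hyper-parameters must be strictly positive",
         call. = FALSE)
  }
  if (nu0 >= 0.1) stop("`nu0` must be much smaller than 1", call. = FALSE)
  structure(c(as.list(vals), list(constrained = isTRUE(constrained))),
            class = "prior_config")
}

#' Switch a prior configuration to the constrained variant
#'
#' @param priors a [prior_config()].
#' @return the same configuration with the constrained hierarchy enabled.
#' @export
constrained_prior_transform <- function(priors) {
  stopifnot(inherits(priors, "prior_config"))
  priors$constrained <- TRUE
  priors
}

panel_columns <- function(panel) {
  ycols <- grep("^Y[0-9]+$", names(panel), value = TRUE)
  xcols <- grep("^X[0-9]+$", names(panel), value = TRUE)
  if (!length(ycols)) stop("panel has no outcome columns Y1..YQ", call. = FALSE)
  list(y = ycols[order(as.integer(sub("Y", "", ycols)))],
       x = xcols[order(as.integer(sub("X", "", xcols)))])
}

# Assemble the regression representation: outcomes of contributing visits
# (j > max(Ly, Lx), conditioning on each individual's first visits) and
# the design of intercept, lagged outcomes, and (lagged) covariates.
build_design <- function(panel, Ly, Lx) {
  cols <- panel_columns(panel)
  Q <- length(cols$y); S <- length(cols$x)
  if (S == 0L && Lx > 0L) stop("Lx > 0 but panel has no covariates",
                               call. = FALSE)
  Lmax <- max(Ly, Lx)
  panel <- panel[order(panel$id, panel$visit), , drop = FALSE]
  ids <- unique(panel$id)
  Yl <- list(); Zl <- list()
  for (i in ids) {
    sub <- panel[panel$id == i, , drop = FALSE]
    Ji <- nrow(sub)
    if (Ji <= Lmax) next
    js <- (Lmax + 1L):Ji
    Ym <- as.matrix(sub[, cols$y, drop = FALSE])
    Xm <- if (S) as.matrix(sub[, cols$x, drop = FALSE]) else NULL
    Z <- matrix(1, length(js), 1L)
    if (Ly > 0L) for (l in seq_len(Ly)) Z <- cbind(Z, Ym[js - l, , drop = FALSE])
    if (S > 0L) for (l in 0:Lx) Z <- cbind(Z, Xm[js - l, , drop = FALSE])
    Yl[[length(Yl) + 1L]] <- Ym[js, , drop = FALSE]
    Zl[[length(Zl) + 1L]] <- Z
  }
  if (!length(Yl)) {
    stop("no individual has more than max(Ly, Lx) = ", Lmax, " visits",
         call. = FALSE)
  }
  Y <- do.call(rbind, Yl)
  Z <- do.call(rbind, Zl)
  cn <- "(Intercept)"
  col_type <- "intercept"; col_lag <- 0L; col_src <- 0L
  if (Ly > 0L) for (l in seq_len(Ly)) {
    cn <- c(cn, paste0("lag", l, "_", cols$y))
    col_type <- c(col_type, rep("Ylag", Q))
    col_lag <- c(col_lag, rep(l, Q)); col_src <- c(col_src, seq_len(Q))
  }
  if (S > 0L) for (l in 0:Lx) {
    cn <- c(cn, if (l == 0L) cols$x else paste0("lag", l, "_", cols$x))
    col_type <- c(col_type, rep("X", S))
    col_lag <- c(col_lag, rep(l, S)); col_src <- c(col_src, seq_len(S))
  }
  colnames(Z) <- cn
  list(Y = Y, Z = Z, Q = Q, S = S, Ly = Ly, Lx = Lx,
       ylabels = cols$y,
       col_info = data.frame(name = cn, type = col_type, lag = col_lag,
                             src = col_src, stringsAsFactors = FALSE))
}

#' Exact log-likelihood of the cyclic longitudinal model
#'
#' Sums, over all contributing individual-visits (those beyond each
#' individual's first `max(Ly, Lx)` visits, which are conditioned on),
#' the Laplace log-density of the structural residuals plus the
#' change-of-variables Jacobian term `log |det(I - B0)|` per visit.
#'
#' @param params a [dcg_params()].
#' @param panel a `panel_data` (or long data frame with `id`, `visit`,
#'   `Y*`, `X*` columns).
#' @return the log-likelihood value.
#' @export
log_likelihood <- function(params, panel) {
  stopifnot(inherits(params, "dcg_params"))
  d <- build_design(panel, params$Ly, params$Lx)
  if (d$Q != params$Q || d$S != params$S) {
    stop("panel dimensions do not match `params`", call. = FALSE)
  }
  n <- nrow(d$Y)
  E <- d$Y %*% t(diag(params$Q) - params$B[[1L]])
  # subtract design contributions
  mean_part <- matrix(params$mu, n, params$Q, byrow = TRUE)
  info <- d$col_info
  for (k in seq_len(ncol(d$Z))[-1L]) {
    coefs <- if (info$type[k] == "Ylag") {
      params$B[[info$lag[k] + 1L]][, info$src[k]]
    } else {
      params$A[[info$lag[k] + 1L]][, info$src[k]]
    }
    mean_part <- mean_part + outer(d$Z[, k], coefs)
  }
  E <- E - mean_part
  ld <- determinant(diag(params$Q) - params$B[[1L]], logarithm = TRUE)
  ll <- sum(vapply(seq_len(params$Q), function(q) {
    sum(dlaplace_mixture(E[, q], params$sigma2[q], log = TRUE))
  }, numeric(1)))
  ll + n * as.numeric(ld$modulus)
}

#' Fit the Bayesian cyclic structural model by MCMC
#'
#' Runs the spike-and-slab Metropolis-within-Gibbs sampler: inverse-
#' Gaussian updates for the Laplace mixing variables, collapsed
#' Gibbs updates for lagged-outcome / covariate coefficients and their
#' inclusion indicators, birth/death/random-walk Metropolis updates with
#' exact Jacobian for the instantaneous coefficients, and conjugate
#' updates for intercepts, slab variances, inclusion probability, and
#' error scales.  Every retained draw of `B0` satisfies the stability
#' condition (spectral radius below one), which is enforced by proposal
#' rejection.
#'
#' @param panel a `panel_data` or long data frame (`id`, `visit`,
#'   `Y1..YQ`, optionally `X1..XS`).
#' @param Ly,Lx numbers of outcome and covariate lags in the fitted model.
#' @param priors a [prior_config()].
#' @param n_iter,burnin,thin MCMC control (defaults: 5000 iterations,
#'   burn-in 2500, thinning 5).
#' @param seed optional integer seed (`set.seed` is called when given, so
#'   identical seeds give identical chains).
#' @param stability_margin stability rejection margin for `B0` proposals.
#' @return object of class `dcg_fit` with elements `draws` (`B0`,
#'   `gamma0`, `theta`, `gammaZ`, `sigma2`, `rho`, `logdet`), `col_info`,
#'   `ylabels`, `priors`, `control`, and `diagnostics`.
#' @export
fit_dcg <- function(panel, Ly = 0L, Lx = 0L, priors = prior_config(),
                    n_iter = 5000L, burnin = 2500L, thin = 5L,
                    seed = NULL, stability_margin = 1e-9) {
  stopifnot(inherits(priors, "prior_config"))
  if (burnin >= n_iter) stop("`burnin` must be below `n_iter`", call. = FALSE)
  d <- build_design(panel, Ly, Lx)
  sds <- apply(d$Y, 2L, stats::sd)
  if (any(!is.finite(sds) | sds < 1e-12)) {
    stop("degenerate data: outcome column(s) ",
         paste(d$ylabels[sds < 1e-12], collapse = ", "),
         " are constant", call. = FALSE)
  }
  P <- ncol(d$Z); Q <- d$Q
  lag_parent <- matrix(0L, P, Q)
  info <- d$col_info
  for (k in seq_len(P)) {
    if (info$type[k] == "Ylag") {
      p <- info$src[k]
      lag_parent[k, ] <- ifelse(seq_len(Q) == p, 0L, p)
    }
  }
  col_parent <- integer(P)
  lag0_x <- which(info$type == "X" & info$lag == 0L)
  for (k in seq_len(P)) {
    if (info$type[k] == "X" && info$lag[k] > 0L) {
      col_parent[k] <- lag0_x[info$src[k]]
    }
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  raw <- .dcg_sampler(d$Y, d$Z, lag_parent, col_parent,
                      priors[c("nu0", "a_nu", "b_nu", "a_rho", "b_rho",
                               "sigma_mu2", "a_sigma", "b_sigma")],
                      as.integer(n_iter), as.integer(burnin),
                      as.integer(thin), isTRUE(priors$constrained),
                      stability_margin)
  structure(list(draws = raw, col_info = info, ylabels = d$ylabels,
                 n_obs = nrow(d$Y), priors = priors,
                 control = list(Ly = Ly, Lx = Lx, n_iter = n_iter,
                                burnin = burnin, thin = thin, seed = seed),
                 diagnostics = list(
                   move_accept_rate = raw$move_accept_rate,
                   rw_scale = raw$rw_scale)),
            class = "dcg_fit")
}

#' @export
print.dcg_fit <- function(x, ...) {
  cat("<dcg_fit> ", x$n_obs, " observations, Q = ", length(x$ylabels),
      ", Ly = ", x$control$Ly, ", Lx = ", x$control$Lx, ", ",
      x$draws$n_kept, " retained draws\n", sep = "")
  invisible(x)
}

#' Inclusion indicator draws on the spike/slab value scale
#'
#' Indicators are returned with slab coded as 1 and spike as the nominal
#' spike scale `nu0` of the prior configuration.
#'
#' @param fit a [fit_dcg()] result.
#' @return list with arrays `gamma0` (`Q x Q x draws`) and `gammaZ`
#'   (`P x Q x draws`).
#' @export
gamma_draws <- function(fit) {
  nu0 <- fit$priors$nu0
  f <- function(a) { a[a == 0] <- nu0; a }
  list(gamma0 = f(fit$draws$gamma0), gammaZ = f(fit$draws$gammaZ))
}
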