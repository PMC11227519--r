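## Bayesian estimation of one model cell. The two-part likelihood factorises
## exactly into a logistic block (beta | zero/positive indicator) and a
## gamma block (gamma, log alpha | positive counts), so each block is
## sampled by its own Metropolis chain: a mixture kernel of independence
## proposals from the block's Laplace approximation and adaptive
## random-walk proposals, initialised near the posterior mode.

#' Prior specification
#'
#' Independent wide zero-centred normals on every regression coefficient and
#' a half-normal on the gamma shape. The shape is sampled on the log scale;
#' the Jacobian is included in the posterior density.
#'
#' @param coef_sd Prior SD for each logistic and gamma coefficient.
#' @param alpha_sd Scale of the half-normal prior on the gamma shape.
#' @return Object of class `prior_spec`.
#' @export
prior_spec <- function(coef_sd = 10, alpha_sd = 10) {
  stopifnot(coef_sd > 0, alpha_sd > 0)
  structure(list(coef_sd = coef_sd, alpha_sd = alpha_sd),
            class = "prior_spec")
}

#' Log posterior density of a model cell
#'
#' Two-part log-likelihood plus log prior, on the unconstrained
#' parameterisation `theta = c(beta, gamma, log(alpha))`.
#'
#' @param theta Parameter vector `c(beta, gamma, log_alpha)` with `beta` and
#'   `gamma` each of length `ncol(X)`.
#' @param X Design matrix.
#' @param y Non-negative counts aligned with `X` rows.
#' @param priors A [prior_spec()].
#' @return Scalar log posterior (unnormalised).
#' @export
log_posterior <- function(theta, X, y, priors = prior_spec()) {
  p <- ncol(X)
  stopifnot(length(theta) == 2L * p + 1L)
  beta <- theta[seq_len(p)]
  gam <- theta[p + seq_len(p)]
  log_alpha <- theta[2L * p + 1L]
  alpha <- exp(log_alpha)
  ll <- twopart_loglik(twopart_params(beta, gam, alpha), X, y)
  lp <- sum(dnorm(c(beta, gam), 0, priors$coef_sd, log = TRUE)) +
    dnorm(alpha, 0, priors$alpha_sd, log = TRUE) + log(2) +
    log_alpha # Jacobian of alpha = exp(log_alpha)
  ll + lp
}

# --- internal block posteriors -------------------------------------------

.logpost_logistic <- function(beta, X, z, coef_sd) {
  eta <- drop(X %*% beta)
  sum(-log1p(exp(eta[!z]))) + sum(-log1p(exp(-eta[z]))) +
    sum(dnorm(beta, 0, coef_sd, log = TRUE))
}

.logpost_gamma <- function(theta, Xp, yp, coef_sd, alpha_sd) {
  p <- ncol(Xp)
  gam <- theta[seq_len(p)]
  log_alpha <- theta[p + 1L]
  if (abs(log_alpha) > 30) return(-Inf)
  alpha <- exp(log_alpha)
  mu <- exp(drop(Xp %*% gam))
  sum(dgamma(yp, shape = alpha, rate = alpha / mu, log = TRUE)) +
    sum(dnorm(gam, 0, coef_sd, log = TRUE)) +
    dnorm(alpha, 0, alpha_sd, log = TRUE) + log(2) + log_alpha
}

# Laplace approximation of one block: mode and a proposal covariance from
# the numerically differentiated Hessian (ridge-regularised if needed).
.laplace <- function(fn, init) {
  opt <- optim(init, function(th) -fn(th), method = "BFGS",
               control = list(maxit = 500, reltol = 1e-10))
  H <- try(optimHess(opt$par, function(th) -fn(th)), silent = TRUE)
  d <- length(init)
  V <- NULL
  if (!inherits(H, "try-error")) {
    V <- try(solve((H + t(H)) / 2 + diag(1e-8, d)), silent = TRUE)
    if (inherits(V, "try-error") || any(!is.finite(V)) ||
        any(diag(V) <= 0)) V <- NULL
  }
  if (is.null(V)) V <- diag(0.1, d)
  ev <- eigen((V + t(V)) / 2, symmetric = TRUE)
  ev$values <- pmax(ev$values, 1e-10)
  S <- ev$vectors %*% (sqrt(ev$values) * t(ev$vectors)) # symmetric sqrt
  Sinv <- ev$vectors %*% (1 / sqrt(ev$values) * t(ev$vectors))
  list(mode = opt$par, S = S, Sinv = Sinv,
       logdetS = 0.5 * sum(log(ev$values)))
}

# One MCMC chain for a block: a mixture kernel alternating at random
# between independence proposals from the Laplace approximation (mode,
# inflated covariance) and adaptive random-walk proposals. The
# independence component gives near-iid draws when the Laplace fit is
# good (large cells); the random-walk component keeps the chain moving
# when it is not. The random-walk scale adapts by Robbins-Monro toward
# 0.234 acceptance during burn-in and is frozen after.
.mcmc_chain <- function(fn, init, lap, n_burn, n_keep,
                        p_indep = 0.75, indep_infl = 1.1) {
  d <- length(init)
  mode <- lap$mode
  L <- lap$S
  scale <- 2.38 / sqrt(d)
  logq <- function(th) {
    z <- drop(lap$Sinv %*% (th - mode)) / indep_infl
    -0.5 * sum(z^2) - d * log(indep_infl) - lap$logdetS
  }
  th <- init
  lp <- fn(th)
  if (!is.finite(lp)) {
    th <- mode
    lp <- fn(th)
  }
  lq <- logq(th)
  out <- matrix(NA_real_, n_keep, d)
  n_acc <- 0L
  total <- n_burn + n_keep
  use_indep <- runif(total) < p_indep
  for (i in seq_len(total)) {
    if (use_indep[i]) {
      prop <- mode + indep_infl * drop(L %*% rnorm(d))
      lp_prop <- fn(prop)
      lq_prop <- logq(prop)
      acc <- is.finite(lp_prop) &&
        log(runif(1)) < (lp_prop - lp) + (lq - lq_prop)
    } else {
      prop <- th + scale * drop(L %*% rnorm(d))
      lp_prop <- fn(prop)
      acc <- is.finite(lp_prop) && log(runif(1)) < lp_prop - lp
      if (i <= n_burn) {
        scale <- scale * exp((as.numeric(acc) - 0.234) / sqrt(i))
      }
    }
    if (acc) {
      th <- prop
      lp <- lp_prop
      lq <- logq(th)
    }
    if (i > n_burn) {
      out[i - n_burn, ] <- th
      n_acc <- n_acc + as.integer(acc)
    }
  }
  list(draws = out, accept = n_acc / n_keep)
}

#' Run MCMC for one model cell
#'
#' Multi-chain Metropolis sampling of the posterior of
#' `(beta, gamma, log alpha)`, mixing Laplace-approximation independence
#' proposals with adaptive random-walk moves. The logistic and gamma blocks
#' are sampled independently (the likelihood factorises exactly). Chains
#' start from the posterior mode jittered by the Laplace scale. A cell whose
#' counts are all zero (or all positive) only identifies one block; the
#' other block is sampled from its prior and flagged as degenerate.
#'
#' @param X Design matrix for the cell.
#' @param y Non-negative counts.
#' @param priors A [prior_spec()].
#' @param n_chains Number of chains (>= 2 for Rhat; the reference analysis
#'   used 4).
#' @param n_burn Burn-in iterations per chain (reference analysis: 5000).
#' @param n_keep Kept iterations per chain (4 x 5000 = merged posterior of
#'   20,000 in the reference analysis; scaled-down defaults are used in
#'   tests).
#' @param seed Integer seed; the fit is deterministic given it.
#' @return Object of class `posterior_draws`: an array
#'   `[chain, iteration, parameter]`, per-parameter Rhat, acceptance rates,
#'   degeneracy flags and the seed.
#' @export
run_mcmc <- function(X, y, priors = prior_spec(), n_chains = 4L,
                     n_burn = 500L, n_keep = 500L, seed = 1L) {
  stopifnot(nrow(X) == length(y), all(y >= 0), n_chains >= 1L,
            n_burn >= 1L, n_keep >= 1L)
  p <- ncol(X)
  z <- y > 0
  degenerate <- character(0)
  if (!any(z)) degenerate <- c(degenerate, "gamma_part_no_positive_counts")
  if (all(z)) degenerate <- c(degenerate, "logistic_part_all_positive")

  set.seed(seed)
  fn_b <- function(b) .logpost_logistic(b, X, z, priors$coef_sd)
  lap_b <- .laplace(fn_b, numeric(p))
  has_gamma <- any(z)
  if (has_gamma) {
    Xp <- X[z, , drop = FALSE]
    yp <- y[z]
    fn_g <- function(th) .logpost_gamma(th, Xp, yp, priors$coef_sd,
                                        priors$alpha_sd)
    init_g <- c(numeric(p), 0)
    init_g[1] <- log(mean(yp))
    lap_g <- .laplace(fn_g, init_g)
  }

  par_names <- c(paste0("beta.", colnames(X)), paste0("gamma.", colnames(X)),
                 "log_alpha")
  draws <- array(NA_real_, dim = c(n_chains, n_keep, 2L * p + 1L),
                 dimnames = list(NULL, NULL, par_names))
  accept <- matrix(NA_real_, n_chains, 2,
                   dimnames = list(NULL, c("logistic", "gamma")))
  for (m in seq_len(n_chains)) {
    init_b <- lap_b$mode + 2 * drop(lap_b$S %*% rnorm(p))
    ch_b <- .mcmc_chain(fn_b, init_b, lap_b, n_burn, n_keep)
    draws[m, , seq_len(p)] <- ch_b$draws
    accept[m, 1] <- ch_b$accept
    if (has_gamma) {
      init_g2 <- lap_g$mode + 2 * drop(lap_g$S %*% rnorm(p + 1L))
      ch_g <- .mcmc_chain(fn_g, init_g2, lap_g, n_burn, n_keep)
      draws[m, , p + seq_len(p + 1L)] <- ch_g$draws
      accept[m, 2] <- ch_g$accept
    } else {
      # no positive counts: the gamma block's posterior is its prior
      draws[m, , p + seq_len(p)] <-
        rnorm(n_keep * p, 0, priors$coef_sd)
      draws[m, , 2L * p + 1L] <-
        log(abs(rnorm(n_keep, 0, priors$alpha_sd)))
    }
  }
  rh <- apply(draws, 3, function(d) rhat(t(d)))
  structure(list(draws = draws, parameters = par_names, rhat = rh,
                 accept = accept, n_chains = n_chains, n_burn = n_burn,
                 n_keep = n_keep, seed = seed, degenerate = degenerate),
            class = "posterior_draws")
}

#' Gelman-Rubin diagnostic
#'
#' The pooled standard deviation of all draws from the `M` chains divided by
#' the average of the per-chain standard deviations. No split-chain or
#' rank-normalisation refinement is applied. Values near 1 indicate
#' convergence; below 1.01 is the usual rule of thumb.
#'
#' @param chains A matrix with one column per chain (rows are iterations),
#'   or a list of equal-length numeric vectors.
#' @return Scalar Rhat; `+Inf` with a warning when every chain is constant.
#' @export
rhat <- function(chains) {
  if (is.list(chains)) chains <- do.call(cbind, chains)
  stopifnot(is.matrix(chains), ncol(chains) >= 2L, nrow(chains) >= 2L)
  within <- mean(apply(chains, 2, sd))
  if (within == 0) {
    if (sd(as.vector(chains)) == 0) return(1) # identical constant chains
    warning("zero average within-chain SD; Rhat reported as +Inf")
    return(Inf)
  }
  sd(as.vector(chains)) / within
}

#' Posterior summary table
#'
#' Point estimate is the posterior mean; the 95% credible interval is the
#' empirical 2.5 and 97.5 percentiles with linear interpolation between
#' order statistics (R's default quantile type 7).
#'
#' @param draws A [run_mcmc()] result, a draws matrix (iterations x
#'   parameters), or a numeric vector for a single parameter.
#' @param probs Interval percentiles.
#' @return `data.frame` with columns `parameter`, `mean`, `lower`, `upper`
#'   and, for `posterior_draws` input, `rhat`.
#' @export
summarize_posterior <- function(draws, probs = c(0.025, 0.975)) {
  rh <- NULL
  if (inherits(draws, "posterior_draws")) {
    rh <- draws$rhat
    draws <- merged_draws(draws)
  }
  if (is.null(dim(draws))) draws <- matrix(draws, ncol = 1,
                                           dimnames = list(NULL, "par"))
  stopifnot(nrow(draws) >= 1L)
  qs <- apply(draws, 2, quantile, probs = probs, names = FALSE, type = 7)
  out <- data.frame(parameter = colnames(draws),
                    mean = colMeans(draws),
                    lower = qs[1, ], upper = qs[2, ],
                    row.names = NULL)
  if (!is.null(rh)) out$rhat <- unname(rh)
  out
}

#' Merge chains of a fit into one draws matrix
#'
#' @param fit A `posterior_draws` object.
#' @return Matrix `(n_chains * n_keep) x n_parameters`.
#' @export
merged_draws <- function(fit) {
  stopifnot(inherits(fit, "posterior_draws"))
  d <- fit$draws
  out <- matrix(aperm(d, c(2, 1, 3)), nrow = dim(d)[1] * dim(d)[2],
                dimnames = list(NULL, dimnames(d)[[3]]))
  out
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat(sprintf("posterior_draws: %d chains x %d kept (%d burn-in), %d parameters\n",
              x$n_chains, x$n_keep, x$n_burn, length(x$parameters)))
  cat(sprintf("max Rhat: %.4f%s\n", max(x$rhat),
              if (length(x$degenerate))
                paste0("; degenerate: ", paste(x$degenerate, collapse = ", "))
              else ""))
  invisible(x)
}
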