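# Negative-binomial log-linear model fitting by Fisher scoring.
#
# The dispersion parameterisation is var(y) = mu + phi * mu^2; phi = 0 is the
# Poisson limit. Fitting is per gene with a shared design matrix, which keeps
# the whole differential-density stage in plain matrix algebra.

nb_loglik <- function(y, mu, phi) {
  mu <- pmax(mu, 1e-300)
  if (phi <= 0) {
    sum(stats::dpois(y, mu, log = TRUE))
  } else {
    sum(stats::dnbinom(y, size = 1 / phi, mu = mu, log = TRUE))
  }
}

# IRLS for a log-link NB GLM with offset. Returns NA coefficients for
# degenerate responses (all zero) rather than failing.
nb_fit <- function(y, X, offset, phi = 0, maxit = 100L, tol = 1e-10) {
  p <- ncol(X)
  if (sum(y) == 0)
    return(list(beta = rep(NA_real_, p), mu = rep(0, length(y)),
                loglik = 0, converged = FALSE))
  mu <- pmax(y, 1 / 6) + 1e-8
  eta <- log(mu)
  beta <- rep(0, p)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(maxit)) {
    w <- mu / (1 + phi * mu)
    z <- eta - offset + (y - mu) / mu
    xw <- X * w
    fit <- tryCatch(solve(crossprod(X, xw), crossprod(xw, z)),
                    error = function(e) NULL)
    if (is.null(fit)) break
    beta_new <- drop(fit)
    eta_new <- drop(X %*% beta_new) + offset
    eta_new <- pmin(pmax(eta_new, -50), 50)
    mu_new <- exp(eta_new)
    ll <- nb_loglik(y, mu_new, phi)
    # step-halve if the likelihood went down
    step <- 1
    while (is.finite(ll_old) && ll < ll_old - 1e-12 && step > 1e-4) {
      step <- step / 2
      beta_new <- beta + step * (beta_new - beta)
      eta_new <- pmin(pmax(drop(X %*% beta_new) + offset, -50), 50)
      mu_new <- exp(eta_new)
      ll <- nb_loglik(y, mu_new, phi)
    }
    delta <- abs(ll - ll_old) / (abs(ll) + 1)
    beta <- beta_new; eta <- eta_new; mu <- mu_new
    if (is.finite(delta) && delta < tol) {
      converged <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
  }
  list(beta = beta, mu = mu, loglik = ll_old, converged = converged)
}

# Adjusted profile log-likelihood of the dispersion for one gene, holding the
# fitted means fixed: NB log-likelihood minus the Cox-Reid adjustment
# 0.5 * log det(X' W X), W = mu / (1 + phi * mu).
apl_one <- function(y, mu, X, phi) {
  w <- mu / (1 + phi * mu)
  xtwx <- crossprod(X, X * w)
  ld <- determinant(xtwx, logarithm = TRUE)$modulus
  nb_loglik(y, mu, phi) - 0.5 * as.numeric(ld)
}

# Maximise a gridded function with one quadratic-interpolation refinement.
grid_argmax <- function(log_phi, val) {
  j <- which.max(val)
  if (j == 1L || j == length(val)) return(exp(log_phi[j]))
  x <- log_phi[(j - 1L):(j + 1L)]
  y <- val[(j - 1L):(j + 1L)]
  denom <- (x[1] - x[2]) * (x[1] - x[3]) * (x[2] - x[3])
  a <- (x[3] * (y[2] - y[1]) + x[2] * (y[1] - y[3]) +
          x[1] * (y[3] - y[2])) / denom
  b <- (x[3]^2 * (y[1] - y[2]) + x[2]^2 * (y[3] - y[1]) +
          x[1]^2 * (y[2] - y[3])) / denom
  if (a >= 0) return(exp(log_phi[j]))
  exp(max(min(-b / (2 * a), log_phi[j + 1L]), log_phi[j - 1L]))
}

# Per-gene dispersion estimation with empirical-Bayes shrinkage toward the
# common value: each gene's adjusted profile likelihood is augmented with the
# across-gene average, weighted so the shared information counts for
# `prior_df` residual degrees of freedom.
estimate_dispersion <- function(Y, Mu, X, prior_df = 10,
                                phi_grid = exp(seq(log(1e-4), log(5),
                                                   length.out = 25L))) {
  G <- nrow(Y)
  resid_df <- ncol(Y) - ncol(X)
  apl <- matrix(NA_real_, G, length(phi_grid))
  for (g in seq_len(G)) {
    for (j in seq_along(phi_grid)) {
      apl[g, j] <- apl_one(Y[g, ], Mu[g, ], X, phi_grid[j])
    }
  }
  apl_bar <- colMeans(apl)
  lp <- log(phi_grid)
  common <- grid_argmax(lp, apl_bar)
  wt <- prior_df / max(resid_df, 1L)
  shrunk <- vapply(seq_len(G), function(g)
    grid_argmax(lp, apl[g, ] + wt * apl_bar), numeric(1))
  list(common = common, shrunk = shrunk, genewise_apl = apl,
       phi_grid = phi_grid)
}
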