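## Per-gene negative-binomial GLM (log link) with maximum-likelihood
## dispersion, Wald test on the condition coefficient and per-gene AIC.
## Deliberately plain: no dispersion shrinkage, no fold-change moderation.

.nb_loglik <- function(y, mu, phi) {
  if (phi < 1e-9) {
    sum(stats::dpois(y, lambda = mu, log = TRUE))
  } else {
    sum(stats::dnbinom(y, size = 1 / phi, mu = mu, log = TRUE))
  }
}

.nb_irls <- function(y, X, offset, phi, beta0 = NULL,
                     max_iter = 25L, tol = 1e-8) {
  p <- ncol(X)
  if (is.null(beta0)) {
    z0 <- log(pmax(y, 0.5)) - offset
    beta0 <- tryCatch(qr.solve(X, z0), error = function(e) rep(0, p))
  }
  beta <- beta0
  converged <- FALSE
  mu <- NULL
  xtwx <- NULL
  for (it in seq_len(max_iter)) {
    eta <- pmin(pmax(drop(X %*% beta) + offset, -30), 30)
    mu <- exp(eta)
    w <- mu / (1 + phi * mu)
    z <- (eta - offset) + (y - mu) / mu
    xtw <- t(X * w)
    xtwx <- xtw %*% X
    bnew <- tryCatch(solve(xtwx, xtw %*% z), error = function(e) NULL)
    if (is.null(bnew)) return(list(ok = FALSE))
    delta <- max(abs(bnew - beta))
    beta <- drop(bnew)
    if (!is.finite(delta)) return(list(ok = FALSE))
    if (delta < tol) { converged <- TRUE; break }
  }
  eta <- pmin(pmax(drop(X %*% beta) + offset, -30), 30)
  mu <- exp(eta)
  w <- mu / (1 + phi * mu)
  xtwx <- t(X * w) %*% X
  list(ok = TRUE, converged = converged, beta = beta, mu = mu, xtwx = xtwx)
}

.ml_phi <- function(y, mu) {
  f <- function(lphi) -.nb_loglik(y, mu, exp(lphi))
  opt <- optimize(f, interval = c(log(1e-8), log(50)))
  exp(opt$minimum)
}

#' Fit a negative-binomial GLM for one gene
#'
#' Log-link negative-binomial regression with an offset of
#' `log(size_factor)`, fitted by iteratively reweighted least squares
#' alternated with one-dimensional maximum-likelihood estimation of the
#' gene-wise dispersion (method-of-moments start).  Reports a Wald test on
#' the condition coefficient (the first design column) and the per-gene
#' AIC, `2k - 2 loglik`, counting the dispersion as one estimated
#' parameter.
#'
#' @param counts_gene Integer vector of counts across samples.
#' @param design Numeric matrix of predictors without intercept; the first
#'   column is the condition contrast, any further columns are covariates.
#'   An intercept is added internally.
#' @param size_factors Positive per-sample size factors (default all 1).
#' @return A one-row tibble: `coefficient` (condition effect on the log2
#'   scale), `se`, `wald_p`, `dispersion`, `loglik`, `aic`, `converged`.
#'   Non-converged fits report `wald_p = 1` and `NA` AIC so they cannot
#'   inflate downstream performance.
#' @export
fit_nb_glm <- function(counts_gene, design, size_factors = NULL) {
  y <- as.numeric(counts_gene)
  n <- length(y)
  design <- as.matrix(design)
  if (nrow(design) != n) abort("design rows must match the number of samples")
  if (is.null(size_factors)) size_factors <- rep(1, n)
  if (any(size_factors <= 0)) abort("size factors must be positive")
  offset <- log(size_factors)
  X <- cbind(`(Intercept)` = 1, design)
  failed <- list(coefficient = NA_real_, se = NA_real_, wald_p = 1,
                 dispersion = NA_real_, loglik = NA_real_, aic = NA_real_,
                 converged = FALSE)
  if (all(y == 0) || qr(X)$rank < ncol(X)) {
    return(tibble::as_tibble(failed))
  }
  ## stage 1: near-Poisson fit for starting values
  fit <- .nb_irls(y, X, offset, phi = 1e-4)
  if (!fit$ok) return(tibble::as_tibble(failed))
  ## method-of-moments dispersion start, then ML refinement
  p <- ncol(X)
  mu <- pmax(fit$mu, 1e-8)
  phi <- max((sum((y - mu)^2 / mu^2) - sum(1 / mu)) / max(n - p, 1), 1e-8)
  for (round in 1:2) {
    phi <- .ml_phi(y, mu)
    fit <- .nb_irls(y, X, offset, phi = phi, beta0 = fit$beta)
    if (!fit$ok) return(tibble::as_tibble(failed))
    mu <- pmax(fit$mu, 1e-8)
  }
  cov <- tryCatch(solve(fit$xtwx), error = function(e) NULL)
  if (is.null(cov) || !fit$converged || any(!is.finite(diag(cov)))) {
    return(tibble::as_tibble(failed))
  }
  se <- sqrt(diag(cov))[2]
  z <- fit$beta[2] / se
  ll <- .nb_loglik(y, mu, phi)
  k <- ncol(X) + 1
  tibble(
    coefficient = unname(fit$beta[2]) / log(2),
    se = unname(se) / log(2),
    wald_p = 2 * pnorm(-abs(z)),
    dispersion = phi,
    loglik = ll,
    aic = 2 * k - 2 * ll,
    converged = TRUE
  )
}

#' Median-of-ratios size factors
#'
#' Per-sample normalization factors computed as the median, over genes
#' expressed in every sample, of the ratio of a sample's counts to the
#' per-gene geometric mean.
#'
#' @param counts Count matrix, genes x samples.
#' @return Named numeric vector of size factors.
#' @export
size_factors_mor <- function(counts) {
  lg <- log(counts)
  ok <- rowSums(is.finite(lg)) == ncol(counts)
  if (!any(ok)) abort("no gene has nonzero counts in every sample; cannot normalize")
  geo <- rowMeans(lg[ok, , drop = FALSE])
  sf <- apply(lg[ok, , drop = FALSE], 2, function(col) exp(median(col - geo)))
  setNames(sf, colnames(counts))
}
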