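# Independent oracles used across tests. These deliberately avoid the
# package's spectral shortcut: likelihoods are evaluated by dense matrix
# algebra and maximized by grid search plus Nelder-Mead.

# Direct multivariate-normal (restricted) log-likelihood of
# y = X beta + g + e, g ~ MVN(0, va K), e ~ N(0, ve I), at the GLS beta.
dense_loglik <- function(y, X, K, va, ve, reml = TRUE) {
  n <- length(y)
  p <- ncol(X)
  V <- va * K + ve * diag(n)
  cV <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(cV)) return(-Inf)
  ldV <- 2 * sum(log(diag(cV)))
  Vi <- chol2inv(cV)
  XtViX <- t(X) %*% Vi %*% X
  beta <- solve(XtViX, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  quad <- drop(t(r) %*% Vi %*% r)
  if (reml) {
    ldXtViX <- determinant(XtViX, logarithm = TRUE)$modulus
    ldXtX <- determinant(crossprod(X), logarithm = TRUE)$modulus
    -0.5 * ((n - p) * log(2 * pi) + ldV + as.numeric(ldXtViX) -
              as.numeric(ldXtX) + quad)
  } else {
    -0.5 * (n * log(2 * pi) + ldV + quad)
  }
}

# Dense-grid maximization over (va, ve), refined by Nelder-Mead on the log
# scale. Returns the maximized log-likelihood and the GLS beta there.
dense_opt <- function(y, X, K, reml = TRUE, grid_n = 30) {
  s2 <- var(y)
  lg <- log(s2) + seq(-8, 4, length.out = grid_n)
  best <- c(-Inf, NA, NA)
  for (la in lg) for (le in lg) {
    ll <- dense_loglik(y, X, K, exp(la), exp(le), reml)
    if (ll > best[1]) best <- c(ll, la, le)
  }
  f <- function(par) -dense_loglik(y, X, K, exp(par[1]), exp(par[2]), reml)
  o <- optim(best[2:3], f, method = "Nelder-Mead",
             control = list(reltol = 1e-14, maxit = 5000))
  va <- exp(o$par[1]); ve <- exp(o$par[2])
  # boundary candidates: the interior optimizer cannot reach va = 0 / ve = 0
  o_ve <- optimize(function(l) dense_loglik(y, X, K, 0, exp(l), reml),
                   range(lg), maximum = TRUE, tol = 1e-10)
  if (o_ve$objective > -o$value) {
    va <- 0; ve <- exp(o_ve$maximum); o$value <- -o_ve$objective
  }
  o_va <- optimize(function(l) dense_loglik(y, X, K, exp(l), 0, reml),
                   range(lg), maximum = TRUE, tol = 1e-10)
  if (is.finite(o_va$objective) && o_va$objective > -o$value) {
    va <- exp(o_va$maximum); ve <- 0; o$value <- -o_va$objective
  }
  V <- va * K + ve * diag(length(y))
  Vi <- chol2inv(chol(V))
  beta <- drop(solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y))
  list(loglik = -o$value, va = va, ve = ve, beta = beta)
}

# Naive double-loop centered-IBS kinship (site loop, no matrix algebra).
naive_centered_ibs <- function(M) {
  p <- colMeans(M) / 2
  poly <- p > 0 & p < 1
  M <- M[, poly, drop = FALSE]
  p <- p[poly]
  n <- nrow(M)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    s <- 0
    for (k in seq_along(p)) s <- s + (M[i, k] - 2 * p[k]) * (M[j, k] - 2 * p[k])
    K[i, j] <- s
  }
  K / (2 * sum(p * (1 - p)))
}

# Naive double-loop standardized GRM over pre-filtered sites.
naive_grm <- function(M, maf_min = 0.01, max_missing = 0.6) {
  miss <- colMeans(is.na(M))
  p <- colMeans(M, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  keep <- which(miss <= max_missing & !is.na(maf) & maf >= maf_min)
  n <- nrow(M)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    s <- 0
    for (k in keep) {
      wi <- (M[i, k] - 2 * p[k]) / sqrt(2 * p[k] * (1 - p[k]))
      wj <- (M[j, k] - 2 * p[k]) / sqrt(2 * p[k] * (1 - p[k]))
      if (is.na(wi)) wi <- 0
      if (is.na(wj)) wj <- 0
      s <- s + wi * wj
    }
    K[i, j] <- s / length(keep)
  }
  K
}

# Weir-Cockerham-style FST estimator (theta) for complete genotype data and
# equal-sized populations; averaged over sites via ratio of sums.
wc_fst <- function(calls, pop) {
  r <- length(unique(pop))
  n_i <- tabulate(match(pop, unique(pop)))
  nbar <- mean(n_i)
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  num <- den <- 0
  for (j in seq_len(ncol(calls))) {
    g <- calls[, j]
    p_i <- tapply(g, pop, function(x) mean(x) / 2)
    h_i <- tapply(g, pop, function(x) mean(x == 1))
    pbar <- sum(n_i * p_i) / (r * nbar)
    s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n_i * h_i) / (r * nbar)
    a <- nbar / nc * (s2 - 1 / (nbar - 1) *
                        (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
    b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    num <- num + a
    den <- den + a + b + cc
  }
  num / den
}

# Random small LMM fixture with block-structured kinship.
make_lmm_fixture <- function(n, seed) {
  set.seed(seed)
  A <- matrix(rnorm(n * 2 * n), n, 2 * n)
  K <- tcrossprod(A) / (2 * n) + diag(0.05, n)
  X <- cbind(1, rnorm(n))
  va <- runif(1, 0.5, 2)
  ve <- runif(1, 0.5, 2)
  L <- t(chol(va * K + ve * diag(n)))
  y <- drop(X %*% c(1, 0.5) + L %*% rnorm(n))
  list(y = y, X = X, K = K, va = va, ve = ve)
}
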