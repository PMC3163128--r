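# Independent oracles coded from the textbook definitions, kept free of
# any package internals so they can certify the engine.

# Plain EM for a scalar/vector spherical Gaussian mixture.  Returns the
# log-likelihood evaluated at the *start* of each iteration, mirroring the
# engine's trace convention.
oracle_em_gaussian <- function(X, mu, s2, pr, iters) {
  X <- as.matrix(X)
  K <- length(s2)
  lls <- numeric(iters)
  for (it in seq_len(iters)) {
    dens <- sapply(seq_len(K), function(k) {
      q <- rowSums(sweep(X, 2L, mu[[k]])^2)
      pr[k] * (2 * pi * s2[k])^(-ncol(X) / 2) * exp(-q / (2 * s2[k]))
    })
    tot <- rowSums(dens)
    lls[it] <- sum(log(tot))
    f <- dens / tot
    for (k in seq_len(K)) {
      w <- f[, k]
      mu[[k]] <- colSums(X * w) / sum(w)
      s2[k] <- sum(w * rowSums(sweep(X, 2L, mu[[k]])^2)) / (ncol(X) * sum(w))
      pr[k] <- mean(w)
    }
  }
  list(loglik = lls, mu = mu, s2 = s2, pr = pr)
}

# Plain EM for a Bernoulli mixture with the same clamping as the package.
oracle_em_bernoulli <- function(X, P, pr, iters, eps = 1e-6) {
  X <- as.matrix(X)
  K <- nrow(P)
  lls <- numeric(iters)
  for (it in seq_len(iters)) {
    logd <- sapply(seq_len(K), function(k) {
      log(pr[k]) + colSums(t(X) * log(P[k, ]) + t(1 - X) * log(1 - P[k, ]))
    })
    mx <- apply(logd, 1L, max)
    tot <- mx + log(rowSums(exp(logd - mx)))
    lls[it] <- sum(tot)
    f <- exp(logd - tot)
    for (k in seq_len(K)) {
      w <- f[, k]
      P[k, ] <- pmin(pmax(colSums(X * w) / sum(w), eps), 1 - eps)
      pr[k] <- mean(w)
    }
  }
  list(loglik = lls, P = P, pr = pr)
}

# Exhaustive minimum over all injective assignments of prototype rows to
# fitted rows (K! enumeration; K <= 6).
oracle_match_error <- function(P, proto) {
  K <- nrow(proto)
  n_fit <- nrow(P)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  cost <- matrix(0, n_fit, K)
  for (i in seq_len(n_fit))
    cost[i, ] <- rowMeans(abs(sweep(proto, 2L, P[i, ]) * -1))
  best <- Inf
  if (n_fit >= K) {
    for (sel in utils::combn(n_fit, K, simplify = FALSE))
      for (p in perms(sel)) {
        cc <- sum(cost[cbind(p, seq_len(K))])
        best <- min(best, cc)
      }
    best / K
  } else {
    for (sel in utils::combn(K, n_fit, simplify = FALSE))
      for (p in perms(sel)) {
        cc <- sum(cost[cbind(seq_len(n_fit), p)])
        best <- min(best, cc)
      }
    (best + (K - n_fit)) / K
  }
}

# Tiny well-separated scalar 2-cluster fixture.
two_cluster_data <- function(n = 50, sep = 8, seed = 42) {
  set.seed(seed)
  matrix(c(rnorm(n / 2, -sep / 2), rnorm(n / 2, sep / 2)), ncol = 1)
}
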