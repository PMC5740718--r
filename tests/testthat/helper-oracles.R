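# Independent oracles, deliberately naive / brute-force.

# Textbook OLS via explicit normal equations + t distribution.
ols_oracle <- function(y, X) {
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  res <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  sigma2 <- sum(res^2) / df
  covb <- sigma2 * solve(XtX)
  est <- unname(beta[2, 1])
  se <- unname(sqrt(covb[2, 2]))
  tval <- est / se
  list(estimate = est, se = se, t = tval, p = 2 * pt(-abs(tval), df))
}

# Brute-force double-loop BH step-up.
bh_oracle <- function(p, n_tests = length(p)) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    best <- Inf
    for (j in i:m) {
      cand <- ps[j] * n_tests / j
      if (cand < best) best <- cand
    }
    adj[i] <- min(best, 1)
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# Exhaustive hypergeometric upper tail: draw k from 1..N, category = 1..C,
# P(overlap >= O) by enumerating every k-subset.
ora_oracle <- function(N, C, k, O) {
  if (O == 0) return(1)
  subsets <- utils::combn(N, k)
  hits <- colSums(subsets <= C)
  mean(hits >= O)
}
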