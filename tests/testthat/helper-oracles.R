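# Independent brute-force oracles used to cross-check the implementation.

# Explicit normal-equations OLS: beta = (X'X)^-1 X'y, classical SEs.
ols_oracle <- function(X, y) {
  X <- as.matrix(X)
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  res <- y - X %*% beta
  n <- nrow(X); p <- ncol(X)
  sigma2 <- sum(res^2) / (n - p)
  covb <- sigma2 * solve(XtX)
  list(coefficients = drop(beta), cov = covb, se = sqrt(diag(covb)),
       sigma = sqrt(sigma2))
}

# Double-loop mid-rank Spearman: ranks computed by pairwise counting, then
# the Pearson formula written out longhand.
spearman_oracle <- function(x, y) {
  midrank <- function(v) {
    n <- length(v)
    r <- numeric(n)
    for (i in seq_len(n)) {
      below <- 0; tied <- 0
      for (j in seq_len(n)) {
        if (v[j] < v[i]) below <- below + 1
        if (v[j] == v[i]) tied <- tied + 1
      }
      r[i] <- below + (tied + 1) / 2
    }
    r
  }
  rx <- midrank(x); ry <- midrank(y)
  n <- length(x)
  mx <- sum(rx) / n; my <- sum(ry) / n
  num <- 0; dx <- 0; dy <- 0
  for (i in seq_len(n)) {
    num <- num + (rx[i] - mx) * (ry[i] - my)
    dx <- dx + (rx[i] - mx)^2
    dy <- dy + (ry[i] - my)^2
  }
  num / sqrt(dx * dy)
}

# All permutations of 1..n, one per row (recursive construction kept
# independent of the package internals).
perm_oracle <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- perm_oracle(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    unname(cbind(k, sub + (sub >= k)))
  }))
}

# Observations drawn from a known exponential power coefficient set, two
# balanced sites, lognormal noise.
make_model_obs <- function(truth, n, noise_sd, sw_range = c(1, 25)) {
  Sw <- runif(n, sw_range[1], sw_range[2])
  site <- rep(c("dense", "clear"), length.out = n)
  S <- as.integer(site != "dense")
  mu <- ep_evaluate(truth, Sw, S)
  data.frame(T = mu * exp(rnorm(n, 0, noise_sd)), Sw = Sw, site = site)
}
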