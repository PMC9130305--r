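# Independent brute-force oracles the implementation is checked against.
# These deliberately share no code with the package internals.

# OLS by explicit normal equations.
oracle_ols <- function(X, y) {
  beta <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% beta
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  p <- ncol(X) - 1L
  n <- length(y)
  r2 <- 1 - rss / tss
  list(beta = drop(beta), RSS = rss, R2 = r2,
       R2_adj = 1 - (1 - r2) * (n - 1) / (n - p - 1))
}

oracle_aicc <- function(n, rss, k) n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)

# Adjusted R2 of y on the second-order expansion of a variable set,
# standardizing from scratch (scale() uses the n-1 sd).
oracle_set_r2adj <- function(y, climate, vars) {
  cols <- lapply(vars, function(v) {
    z <- drop(scale(climate[[v]]))
    cbind(z, drop(scale(z^2)))
  })
  X <- cbind(do.call(cbind, cols), 1)
  oracle_ols(X, y)$R2_adj
}

oracle_partition_two <- function(y, a, b, climate) {
  ra <- oracle_set_r2adj(y, climate, a)
  rb <- oracle_set_r2adj(y, climate, b)
  rab <- oracle_set_r2adj(y, climate, c(a, b))
  c(unique_A = rab - rb, unique_B = rab - ra, shared = ra + rb - rab,
    unexplained = 1 - rab)
}

# Interval-overlap oracle: does [l, u] (point allowed) occupy band [bl, bu)?
oracle_occupies <- function(l, u, bl, bu) {
  if (u > l) min(bu, u) - max(bl, l) > 0 else (bl <= l && l < bu)
}

# A small random climate-like table with independent columns (no
# elevational structure), handy when orthogonal-ish predictors are wanted.
random_climate <- function(n, seed) {
  set.seed(seed)
  data.frame(bio1 = rnorm(n, 15, 5), bio4 = rnorm(n, 500, 50),
             bio6 = rnorm(n, 0, 5), bio12 = rnorm(n, 1500, 300),
             bio14 = abs(rnorm(n, 10, 3)), bio15 = rnorm(n, 80, 10),
             area = exp(rnorm(n, 7, 0.5)))
}
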