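# Shared fixtures and independent oracles used across the test files.

# clean rendering conditions for pixel-exact checks
noiseless_params <- function(...) {
  generator_params(noise_sigma = 0, vignette_strength = 0, jitter_px = 0L, ...)
}

# independent mean-square oracle for the balanced nested design: fit the
# nested factorial with stats::aov and read the mean squares off its table
aov_nested_ms <- function(data, top, mid) {
  d <- data.frame(top = factor(data[[top]]),
                  mid = factor(data[[mid]]),
                  value = data$value)
  fit <- stats::aov(value ~ top + top:mid, data = d)
  tab <- summary(fit)[[1]]
  ms <- tab[["Mean Sq"]]
  list(MS_top = ms[1], MS_mid = ms[2], MS_error = ms[3])
}

# exhaustive signed-rank confidence interval for small n: enumerate all 2^n
# sign assignments to build the exact null distribution of W+, find the
# largest k with P(W <= k) <= alpha/2, and take the symmetric Walsh-average
# order statistics
enumerated_signrank_ci <- function(d, conf_level = 0.95) {
  d <- d[d != 0]
  n <- length(d)
  ranks <- seq_len(n)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_null <- as.vector(signs %*% ranks)
  cdf <- function(k) mean(w_null <= k)
  alpha <- 1 - conf_level
  # largest k (a value of W, counted from 0) with P(W <= k) <= alpha/2
  k <- -1
  while (cdf(k + 1) <= alpha / 2) k <- k + 1
  stopifnot(k >= 0)
  w <- sort(outer(d, d, `+`)[upper.tri(diag(n), diag = TRUE)] / 2)
  M <- n * (n + 1) / 2
  c(w[k + 1], w[M - k])
}

# polynomial OLS via explicit normal equations (independent of stats::lm)
normal_equations_fit <- function(x, y, order) {
  X <- outer(x, 0:order, `^`)
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}
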