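# Independent oracle implementations used to cross-check the package.
# These deliberately share no code with the implementation under test.

published_beta <- c(-2.754, -1.077, -0.756, 0.188, 0.025,
                    -81.08, -165.6, -1174, 0.218, 0.164)

# Term-by-term scalar evaluation of the sqrt-scale linear predictor.
oracle_mean_sqrt <- function(beta, sex, bmi, day) {
  a <- 2 * pi * (day - 1) / 365
  t <- -1 / sqrt(bmi)
  t25 <- -1 / sqrt(25)
  male <- sex == "M"
  beta[1] +
    beta[2] * sin(a) + beta[3] * cos(a) +
    beta[4] * sin(2 * a) + beta[5] * cos(2 * a) +
    beta[6] * t + beta[7] * t^2 +
    beta[8] * (if (male && bmi < 25) (t - t25)^2 else 0) +
    beta[9] * (if (!male) sin(a) else 0) +
    beta[10] * (if (!male) cos(a) else 0)
}

# Brute-force Passing-Bablok: explicit double loop, shifted median rule
# (shifted ranks that run past the ends are pinned to the extreme order
# statistics, the boundary convention the estimator documents).
oracle_pb <- function(x, y) {
  n <- length(x)
  S <- c()
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      dx <- x[j] - x[i]; dy <- y[j] - y[i]
      if (dx == 0 && dy == 0) next
      s <- if (dx == 0) sign(dy) * Inf else dy / dx
      if (s == -1) next
      S <- c(S, s)
    }
  }
  S <- sort(S)
  N <- length(S)
  K <- sum(S < -1)
  pin <- function(i) min(max(i, 1), N)
  slope <- if (N %% 2 == 1) S[pin((N + 1) / 2 + K)]
           else (S[pin(N / 2 + K)] + S[pin(N / 2 + 1 + K)]) / 2
  c(slope = slope, intercept = median(y - slope * x))
}

# Brute-force one-sample KS against U(0,1): enumerate both gap families.
oracle_ks <- function(u) {
  u <- sort(u); n <- length(u)
  gaps <- c()
  for (i in seq_len(n)) gaps <- c(gaps, i / n - u[i], u[i] - (i - 1) / n)
  max(gaps)
}

# Normal-equation OLS, independent of the package's QR path.
oracle_ols <- function(X, y) drop(solve(t(X) %*% X, t(X) %*% y))
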