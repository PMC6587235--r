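# Brute-force two-way ANOVA ICC oracle: explicit summation loops, no
# linear-algebra shortcuts, kept independent of the package's estimator.
oracle_icc <- function(Y, model = "two_way_random_absolute_single") {
  n <- nrow(Y); k <- ncol(Y)
  grand <- 0
  for (i in 1:n) for (j in 1:k) grand <- grand + Y[i, j]
  grand <- grand / (n * k)
  row_means <- numeric(n)
  for (i in 1:n) {
    s <- 0
    for (j in 1:k) s <- s + Y[i, j]
    row_means[i] <- s / k
  }
  col_means <- numeric(k)
  for (j in 1:k) {
    s <- 0
    for (i in 1:n) s <- s + Y[i, j]
    col_means[j] <- s / n
  }
  ssr <- 0
  for (i in 1:n) ssr <- ssr + k * (row_means[i] - grand)^2
  ssc <- 0
  for (j in 1:k) ssc <- ssc + n * (col_means[j] - grand)^2
  sse <- 0
  for (i in 1:n) for (j in 1:k) {
    sse <- sse + (Y[i, j] - row_means[i] - col_means[j] + grand)^2
  }
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  if (model == "two_way_random_absolute_single") {
    (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  } else {
    (msr - mse) / (msr + (k - 1) * mse)
  }
}

random_ratings_matrix <- function(n, k) {
  matrix(rnorm(n * k, mean = 12, sd = 3), n, k) +
    rnorm(n, 0, 2)            # subject effect recycled down columns
}
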