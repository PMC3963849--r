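# Random valid model generators used by the property-style tests.
# Column sums are capped well below 1 so that both dynamics contract and
# forced-dynamic convergence is fast.

random_fire_curve <- function() {
  th <- sort(stats::runif(2))
  pm <- sort(stats::runif(2))
  fire_model(theta1 = th[1], theta2 = th[2], p_max = pm[2], p_min = pm[1])
}

random_stage <- function(n, max_colsum = 0.9) {
  A <- matrix(stats::runif(n * n), n, n)
  target <- stats::runif(n, 0.1, max_colsum)
  sweep(A, 2, target / colSums(A), "*")
}

random_model <- function(n = 1L, max_colsum = 0.9) {
  tree_model(A_nf = random_stage(n, max_colsum),
             A_f = random_stage(n, max_colsum),
             a = stats::runif(1, 0.05, 0.5),
             fire = random_fire_curve())
}

random_state <- function(n) {
  x <- stats::runif(n)
  x / sum(x) * stats::runif(1)
}

# independent stationary-distribution oracle: leading left eigenvector
stationary_by_eigen <- function(T) {
  e <- eigen(t(T))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v / sum(v)
}

random_row_stochastic <- function(N) {
  T <- matrix(stats::runif(N * N) + 0.05, N, N)
  T / rowSums(T)
}
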