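# Shared fixtures and independent brute-force oracles. The oracles use
# explicit loops and share no code with the implementation they check.

tiny_config <- function(seed = 11, ...) {
  scenario_config(n_households = 60, n_communities = 6, n_reserves = 3,
                  seed = seed, ...)
}

# Post-truncation moments by numerical quadrature (independent of the
# closed-form expressions used by the calibrator).
quadrature_tn_moments <- function(mu, sigma, lower, upper) {
  dens <- function(x) stats::dnorm(x, mu, sigma)
  Z <- stats::integrate(dens, lower, upper, rel.tol = 1e-12)$value
  m <- stats::integrate(function(x) x * dens(x), lower, upper,
                        rel.tol = 1e-12)$value / Z
  v <- stats::integrate(function(x) (x - m)^2 * dens(x), lower, upper,
                        rel.tol = 1e-12)$value / Z
  list(mean = m, sd = sqrt(v))
}

# Brute-force maximum sd over two-point distributions on [lower, upper]
# with the given mean: grid over support pairs (a, b) straddling the mean.
bruteforce_max_sd <- function(mean, lower, upper, n_grid = 400) {
  grid <- seq(lower, upper, length.out = n_grid)
  best <- 0
  for (a in grid[grid <= mean]) {
    for (b in grid[grid >= mean]) {
      if (b - a < 1e-12) next
      p <- (b - mean) / (b - a)
      v <- p * (a - mean)^2 + (1 - p) * (b - mean)^2
      if (v > best) best <- v
    }
  }
  sqrt(best)
}

# Brute-force niche widths: explicit double loops over units and indexes.
bruteforce_widths <- function(scaled, W, meta) {
  dims <- unique(meta$dimension)
  n <- nrow(scaled)
  N <- matrix(0, n, length(dims), dimnames = list(NULL, dims))
  for (d in seq_along(dims)) {
    idx <- meta$index[meta$dimension == dims[d]]
    wd <- 0
    for (k in idx) wd <- wd + W[[k]]
    for (i in seq_len(n)) {
      acc <- 0
      for (k in idx) {
        tot <- 0
        for (i2 in seq_len(n)) tot <- tot + scaled[i2, k]
        acc <- acc + (W[[k]] / wd) * scaled[i, k] / tot
      }
      N[i, d] <- acc
    }
  }
  w_d <- numeric(length(dims))
  for (d in seq_along(dims)) {
    for (k in meta$index[meta$dimension == dims[d]]) w_d[d] <- w_d[d] + W[[k]]
  }
  M <- numeric(n)
  for (i in seq_len(n)) {
    for (d in seq_along(dims)) M[i] <- M[i] + N[i, d] * w_d[d]
  }
  list(N = N, M = M)
}

# Brute-force Pianka overlap with explicit normalization and loops.
bruteforce_overlap <- function(p, q) {
  sp <- 0; sq <- 0
  for (i in seq_along(p)) { sp <- sp + p[i]; sq <- sq + q[i] }
  num <- 0; d1 <- 0; d2 <- 0
  for (i in seq_along(p)) {
    a <- p[i] / sp
    b <- q[i] / sq
    num <- num + a * b
    d1 <- d1 + a^2
    d2 <- d2 + b^2
  }
  unname(num / sqrt(d1 * d2))
}

# Minimal hand-built index-matrix object for niche unit tests.
toy_index_matrix <- function(n = 3, seed = 5) {
  set.seed(seed)
  meta <- index_metadata()
  state <- matrix(runif(n * 14, 0.2, 1), n, 14,
                  dimnames = list(NULL, meta$index))
  potential <- matrix(runif(n * 14, -0.1, 0.2), n, 14,
                      dimnames = list(NULL, meta$index))
  structure(list(
    rows = data.frame(community_id = sprintf("C%02d", seq_len(n)),
                      reserve_id = "R1",
                      age_group = rep("YAG", n),
                      stringsAsFactors = FALSE),
    state = state, potential = potential, meta = meta
  ), class = "panda_index_matrix")
}
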