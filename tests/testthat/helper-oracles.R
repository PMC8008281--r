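# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: areas via Heron's formula, voxel counts via
# triple loops, BH via the sorted step-up recursion, etc.

# total surface area by Heron's formula, one face at a time
oracle_mesh_area <- function(vertices, faces) {
  tot <- 0
  for (i in seq_len(nrow(faces))) {
    p <- vertices[faces[i, ], , drop = FALSE]
    a <- sqrt(sum((p[1, ] - p[2, ])^2))
    b <- sqrt(sum((p[2, ] - p[3, ])^2))
    cc <- sqrt(sum((p[3, ] - p[1, ])^2))
    s <- (a + b + cc) / 2
    tot <- tot + sqrt(max(0, s * (s - a) * (s - b) * (s - cc)))
  }
  tot
}

# voxel count of a code set by explicit triple loop
oracle_voxel_count <- function(grid, codes) {
  d <- dim(grid)
  n <- 0L
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3]))
    if (grid[i, j, k] %in% codes) n <- n + 1L
  n
}

# BH step-up: q_(i) = min over j >= i of p_(j) * m / j, input order restored
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- ps * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) q[i] <- min(q[i], q[i + 1])
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# one-sample KS distance to N(mu, sigma) by sweeping the ECDF jumps
oracle_ks_D <- function(x, mu, sigma) {
  xs <- sort(x)
  n <- length(xs)
  Fx <- pnorm(xs, mu, sigma)
  max(abs(Fx - seq_len(n) / n), abs(Fx - (seq_len(n) - 1) / n))
}

# ICC(A,1) via stats::aov mean squares (a different decomposition route)
oracle_icc_a1 <- function(m) {
  n <- nrow(m); k <- ncol(m)
  d <- data.frame(y = as.vector(m),
                  item = factor(rep(seq_len(n), k)),
                  rater = factor(rep(seq_len(k), each = n)))
  ms <- summary(aov(y ~ item + rater, data = d))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
}

# exact two-sided rank-sum p by enumerating all splits of the pooled ranks
oracle_ranksum_exact <- function(x, y, alternative = "two.sided") {
  n1 <- length(x); n <- n1 + length(y)
  rk <- rank(c(x, y))
  obs <- sum(rk[seq_len(n1)])
  mu <- n1 * (n + 1) / 2
  sums <- apply(combn(n, n1), 2, function(ix) sum(rk[ix]))
  switch(alternative,
         less = mean(sums <= obs + 1e-9),
         greater = mean(sums >= obs - 1e-9),
         two.sided = mean(abs(sums - mu) >= abs(obs - mu) - 1e-9))
}

# a unit icosphere with one vertex dented radially inward
dented_sphere <- function(subdivisions = 3, dent = 0.3, vertex = 1L,
                          radius = 1) {
  m <- icosphere(subdivisions)
  v <- m$vertices * radius
  v[vertex, ] <- v[vertex, ] * (1 - dent)
  surface_mesh(v, m$faces)
}

# minimal single-outcome cohort configuration for association tests
one_outcome_config <- function(beta_ses, sd = 1, n_subjects = 144,
                               seed = NULL, subject_sd = 0.7) {
  es <- data.frame(outcome = "y", beta0 = 10, beta_ses = beta_ses,
                   beta_ga = 0.5, beta_sex = 0.3, sd = sd)
  cohort_config(n_subjects = n_subjects, effect_sizes = es, seed = seed,
                subject_sd = subject_sd)
}
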