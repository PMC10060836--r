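# Shared fixtures and independent oracles. Oracles are deliberately naive
# (enumeration, triple loops, grid refinement) and never call the code
# paths they check.

# Small synthetic atlas: networks given as named sizes, deterministic
# coordinates on a grid, small voxel volumes.
tiny_atlas <- function(sizes = c(NETA = 3L, NETB = 2L)) {
  n <- sum(sizes)
  data.frame(
    roi_id = seq_len(n),
    network = rep(names(sizes), sizes),
    name = paste("region", seq_len(n)),
    abbrev = sprintf("R%02d", seq_len(n)),
    label = sprintf("R%02d", seq_len(n)),
    x = seq_len(n) * 10, y = rep_len(c(0, 20, -20), n), z = rep_len(c(5, -5), n),
    volume_voxels = rep_len(c(5L, 8L, 10L), n),
    stringsAsFactors = FALSE
  )
}

# Random valid FC matrix via a random Gram matrix (always PSD, unit diag).
random_fc <- function(n, labels = sprintf("R%02d", seq_len(n))) {
  x <- matrix(rnorm(n * (n + 2)), ncol = n)
  labeled_matrix(stats::cor(x), labels, "fc")
}

random_sc_prob <- function(n, labels = sprintf("R%02d", seq_len(n))) {
  m <- matrix(runif(n * n), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  labeled_matrix(m, labels, "sc_prob")
}

# Build a voxel_count_table from a named list of integer vectors and totals.
make_counts <- function(pairs, total_leaving, labels) {
  voxel_count_table(pairs, total_leaving, labels)
}

# Exact two-sided Wilcoxon rank-sum p by exhaustive enumeration of all
# C(n1 + n2, n1) assignments of the pooled ranks to group a. Two-sided p =
# min(1, 2 * min(P(W <= w), P(W >= w))), the standard exact definition.
wilcox_enum_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  stopifnot(!anyDuplicated(pooled))
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n1)])
  sets <- utils::combn(n1 + n2, n1)
  w_all <- colSums(matrix(r[sets], nrow = n1))
  pl <- mean(w_all <= w_obs)
  pu <- mean(w_all >= w_obs)
  min(1, 2 * min(pl, pu))
}

# Brute-force second-order incorporation: literal triple loop.
second_order_brute <- function(m) {
  v <- unclass(m)
  n <- nrow(v)
  out <- v
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      best <- v[i, j]
      for (k in seq_len(n)) {
        if (k == i || k == j) next
        best <- max(best, v[i, k] * v[k, j])
      }
      out[i, j] <- best
    }
  }
  attributes(out) <- list(dim = dim(v), dimnames = dimnames(v))
  out
}

# Zero-inflated Poisson log-likelihood, written independently of fit_zip.
zip_loglik <- function(s, g, a0, a1, w) {
  mu <- exp(a0 + a1 * g)
  z <- s == 0
  sum(log(w + (1 - w) * exp(-mu[z]))) +
    sum(log(1 - w) - mu[!z] + s[!z] * log(mu[!z]) - lfactorial(s[!z]))
}

# Grid-search oracle: iteratively refined grid over (a0, a1, omega)
# maximizing zip_loglik. Returns the best log-likelihood found.
zip_grid_oracle <- function(s, g, a0_range = c(1, 3), a1_range = c(-0.05, 0.01),
                            w_range = c(0.01, 0.6), rounds = 9L, pts = 11L) {
  best <- c(mean(a0_range), mean(a1_range), mean(w_range))
  span <- c(diff(a0_range), diff(a1_range), diff(w_range)) / 2
  best_ll <- -Inf
  for (r in seq_len(rounds)) {
    a0s <- seq(best[1] - span[1], best[1] + span[1], length.out = pts)
    a1s <- seq(best[2] - span[2], best[2] + span[2], length.out = pts)
    ws <- pmin(pmax(seq(best[3] - span[3], best[3] + span[3],
                        length.out = pts), 1e-4), 1 - 1e-4)
    for (a0 in a0s) for (a1 in a1s) for (w in ws) {
      ll <- zip_loglik(s, g, a0, a1, w)
      if (is.finite(ll) && ll > best_ll) {
        best_ll <- ll
        best <- c(a0, a1, w)
      }
    }
    span <- span / 4
  }
  list(loglik = best_ll, par = best)
}

# Draw from the ZIP streamline-count model directly (generator-independent).
rzip <- function(n, a0, a1, g, omega) {
  ifelse(runif(n) < omega, 0L, rpois(n, exp(a0 + a1 * g)))
}
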