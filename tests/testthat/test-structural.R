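# structural_connectivity: percentile probabilities, ZIP distance model,
# second-order incorporation

test_that("sc_probability applies the percentile-over-total rule", {
  labs <- c("A", "B")
  # constant vector: any percentile is the constant
  vct <- make_counts(list("A->B" = rep(5L, 6), "B->A" = rep(0L, 4)),
                     c(A = 50, B = 100), labs)
  p <- sc_probability(vct)
  expect_equal(p["A", "B"], 0.1)
  expect_equal(p["B", "A"], 0)

  # interpolated type-7 quantile: h = (n-1) * 0.9 = 8.1 on 0..9 gives 8.1
  vct2 <- make_counts(list("A->B" = 0:9, "B->A" = rep(1L, 4)),
                      c(A = 100, B = 10), labs)
  expect_equal(sc_probability(vct2)["A", "B"], 0.081)

  # clipping to [0, 1]
  vct3 <- make_counts(list("A->B" = rep(10L, 3), "B->A" = rep(0L, 3)),
                      c(A = 5, B = 5), labs)
  expect_equal(sc_probability(vct3)["A", "B"], 1)

  # zero total leaving: probability 0 with a warning
  vct4 <- make_counts(list("A->B" = rep(2L, 3), "B->A" = rep(0L, 3)),
                      c(A = 0, B = 5), labs)
  expect_warning(p4 <- sc_probability(vct4), "total_leaving is 0")
  expect_equal(p4["A", "B"], 0)
})

test_that("sc_probability never exceeds 1 and is 0 for all-zero counts", {
  set.seed(5)
  labs <- sprintf("R%02d", 1:4)
  for (rep in 1:10) {
    pairs <- list()
    for (i in labs) for (j in labs) if (i != j) {
      pairs[[pair_key(i, j)]] <- as.integer(rpois(6, sample(0:8, 1)))
    }
    tot <- setNames(pmax(1, rpois(4, 10)), labs)
    p <- sc_probability(make_counts(pairs, tot, labs))
    expect_true(all(p >= 0 & p <= 1))
    zero <- vapply(labs, function(i) vapply(labs, function(j) {
      i != j && all(pairs[[pair_key(i, j)]] == 0)
    }, logical(1)), logical(4))
    # zero[j, i] flags the ordered pair i -> j
    expect_true(all(p[t(zero)] == 0))
  }
})

test_that("symmetrize_sc averages directions (or takes the max)", {
  d <- matrix(c(0, 0.2, 0.4, 0), 2, 2, byrow = TRUE,
              dimnames = list(c("A", "B"), c("A", "B")))
  m <- symmetrize_sc(d)
  expect_equal(m["A", "B"], 0.3)
  expect_equal(m["B", "A"], 0.3)
  expect_equal(diag(unclass(m)), c(A = 1, B = 1))
  expect_equal(symmetrize_sc(d, "max")["A", "B"], 0.4)
  z <- symmetrize_sc(matrix(0, 2, 2, dimnames = dimnames(d)))
  expect_equal(unclass(z)[, ], matrix(c(1, 0, 0, 1), 2, dimnames = dimnames(d)))
})

test_that("fit_zip reduces to Poisson on constant zero-free counts", {
  set.seed(1)
  g <- runif(50, 10, 120)
  s <- rep(7L, 50)
  fit <- fit_zip(s, g)
  expect_true(fit$converged)
  expect_equal(fit$alpha1, 0, tolerance = 1e-3)
  expect_equal(fit$alpha0, log(7), tolerance = 0.02)
  expect_lt(fit$omega, 0.05)
})

test_that("fit_zip recovers generating parameters at n = 1000", {
  set.seed(20)
  g <- runif(1000, 10, 120)
  s <- rzip(1000, 2.0, -0.02, g, 0.25)
  fit <- fit_zip(s, g)
  expect_true(fit$converged)
  expect_lt(abs(fit$alpha0 - 2.0), 0.1)
  expect_lt(abs(fit$alpha1 + 0.02), 0.005)
  expect_lt(abs(fit$omega - 0.25), 0.05)
  # optimizer log-likelihood matches the independent grid-search oracle
  oracle <- zip_grid_oracle(s, g)
  expect_lt(abs(fit$loglik - oracle$loglik), 1e-4)
})

test_that("fit_zip rejects degenerate inputs", {
  expect_error(fit_zip(rep(0L, 20), runif(20, 10, 100)), "degenerate")
  expect_error(fit_zip(c(1L, 2L), c(10, 20)), "fewer pairs")
  expect_error(fit_zip(c(1L, -1L, 2L, 0L, 1L, 3L), 1:6), "non-negative integers")
  expect_error(fit_zip(rep(1L, 6), c(1:5, Inf)), "finite")
})

test_that("distance_adjust removes the fitted trend at the median distance", {
  labs <- c("A", "B", "C")
  # off-diagonal distances 100, 50, 30 -> median 50
  d <- matrix(0, 3, 3, dimnames = list(labs, labs))
  d["A", "B"] <- d["B", "A"] <- 100
  d["A", "C"] <- d["C", "A"] <- 50
  d["B", "C"] <- d["C", "B"] <- 30
  dist_m <- labeled_matrix(d, labs, "distance")
  p <- matrix(0.1, 3, 3, dimnames = list(labs, labs)); diag(p) <- 1
  pi_mat <- labeled_matrix(p, labs, "sc_prob")
  fit <- structure(list(alpha0 = 2, alpha1 = -0.02, omega = 0.2,
                        converged = TRUE, loglik = 0, n_pairs = 6),
                   class = "zip_fit")
  adj <- distance_adjust(pi_mat, fit, dist_m)
  # g = 100 vs g_med = 50: factor exp(0.02 * 50) = e
  expect_equal(adj["A", "B"], 0.1 * exp(1), tolerance = 1e-12)
  # at the median distance the value is unchanged
  expect_equal(adj["A", "C"], 0.1)
  expect_equal(diag(unclass(adj)), setNames(rep(1, 3), labs))

  # clipping branch
  p2 <- p; p2["A", "B"] <- p2["B", "A"] <- 0.5
  adj2 <- distance_adjust(labeled_matrix(p2, labs, "sc_prob"), fit, dist_m)
  expect_equal(adj2["A", "B"], 1)

  # alpha1 = 0 is the identity
  fit0 <- fit; fit0$alpha1 <- 0
  adj0 <- distance_adjust(pi_mat, fit0, dist_m)
  expect_equal(unclass(adj0)[, ], unclass(pi_mat)[, ])

  # non-converged fit refuses unless forced
  bad <- fit; bad$converged <- FALSE
  expect_error(distance_adjust(pi_mat, bad, dist_m), "converge")
  expect_equal(unclass(distance_adjust(pi_mat, bad, dist_m, force = TRUE))[, ],
               unclass(adj)[, ])
})

test_that("distance adjustment boosts longer pairs for a negative slope", {
  set.seed(8)
  cohort <- generate_cohort(sim_config(seed = 8))
  s <- cohort$subjects[[1]]
  raw <- symmetrize_sc(sc_probability(s$connectome$counts))
  fit <- fit_zip(s$connectome$pair_totals, s$connectome$distances)
  adj <- distance_adjust(raw, fit, s$connectome$distances)
  off <- upper.tri(raw)
  ratio <- unclass(adj)[off] / pmax(unclass(raw)[off], 1e-12)
  g <- unclass(s$connectome$distances)[off]
  keep <- unclass(raw)[off] > 0 & ratio < 1e11
  expect_lt(fit$alpha1, 0)
  expect_gt(suppressWarnings(cor(g[keep], ratio[keep], method = "spearman")), 0.8)
  # trend removal: adjusted probabilities less distance-dependent than raw
  raw_trend <- abs(cor(g, unclass(raw)[off], method = "spearman"))
  adj_trend <- abs(cor(g, unclass(adj)[off], method = "spearman"))
  expect_lt(adj_trend, raw_trend)
})

test_that("second_order matches its formula and the brute-force oracle", {
  labs <- c("A", "B", "C")
  p <- diag(3); dimnames(p) <- list(labs, labs)
  p["A", "B"] <- p["B", "A"] <- 0.9
  p["B", "C"] <- p["C", "B"] <- 0.8
  p["A", "C"] <- p["C", "A"] <- 0.5
  out <- second_order(labeled_matrix(p, labs, "sc_prob"))
  expect_equal(out["A", "C"], 0.72)
  expect_equal(out["A", "B"], 0.9)
  expect_equal(out["B", "C"], 0.8)
  expect_true(attr(out, "indirect")["A", "C"])
  expect_false(attr(out, "indirect")["A", "B"])

  # all-zero off-diagonal unchanged
  z <- labeled_matrix(diag(3), labs, "sc_prob")
  expect_equal(unclass(second_order(z))[, ], unclass(z)[, ])

  set.seed(33)
  for (i in 1:10) {
    m <- random_sc_prob(10)
    expect_identical(unclass(second_order(m))[, ], second_order_brute(m))
  }
})

test_that("second_order is monotone, permutation-equivariant, not idempotent", {
  set.seed(44)
  m <- random_sc_prob(8)
  out <- second_order(m)
  expect_true(all(unclass(out) >= unclass(m)))

  perm <- sample(8)
  mp <- labeled_matrix(unclass(m)[perm, perm], rownames(m)[perm], "sc_prob")
  outp <- second_order(mp)
  expect_equal(unclass(outp)[, ], unclass(out)[perm, perm])

  # a 4-node chain composes further on a second application
  labs <- c("A", "B", "C", "D")
  ch <- diag(4); dimnames(ch) <- list(labs, labs)
  ch["A", "B"] <- ch["B", "A"] <- 0.9
  ch["B", "C"] <- ch["C", "B"] <- 0.9
  ch["C", "D"] <- ch["D", "C"] <- 0.9
  once <- second_order(labeled_matrix(ch, labs, "sc_prob"))
  twice <- second_order(once)
  expect_equal(once["A", "D"], 0)  # three hops: not reachable in one pass
  expect_gt(twice["A", "D"], once["A", "D"])
})

test_that("fit_zip parameter recovery: median |alpha1 error| over 20 seeds", {
  errs <- vapply(1:20, function(seed) {
    set.seed(seed)
    g <- runif(1000, 10, 120)
    s <- rzip(1000, 2.0, -0.02, g, 0.25)
    abs(fit_zip(s, g)$alpha1 + 0.02)
  }, numeric(1))
  expect_lte(median(errs), 0.003)
})
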