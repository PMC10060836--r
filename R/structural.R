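#' Directed structural connectivity probabilities from voxel counts
#'
#' For each ordered ROI pair (i, j), takes a percentile (default the 90th)
#' of the voxel-level streamline counts landing in j and divides by the
#' total number of streamlines leaving i. The quantile uses linear
#' interpolation between order statistics (type 7) by default; the
#' convention is configurable because none is canonical for tract counts.
#' Values are clipped to \[0, 1\]. A source ROI with zero streamlines
#' leaving yields probability 0 with a warning.
#'
#' @param counts a `voxel_count_table`.
#' @param percentile percentile in (0, 100\].
#' @param type quantile type passed to [stats::quantile()].
#' @return a square numeric matrix of directed probabilities (diagonal 0);
#'   ordered pairs absent from `counts` are treated as zero-count.
#' @export
sc_probability <- function(counts, percentile = 90, type = 7) {
  stopifnot(inherits(counts, "voxel_count_table"),
            percentile > 0, percentile <= 100)
  labs <- counts$labels
  n <- length(labs)
  p <- matrix(0, n, n, dimnames = list(labs, labs))
  warned <- character(0)
  for (nm in names(counts$pairs)) {
    st <- strsplit(nm, "->", fixed = TRUE)[[1L]]
    src <- st[1L]
    v <- counts$pairs[[nm]]
    if (length(v) == 0L) stop(sprintf("empty voxel-count vector for pair %s", nm))
    tot <- counts$total_leaving[[src]]
    if (is.null(tot) || is.na(tot)) {
      stop(sprintf("total_leaving missing for source ROI %s", src))
    }
    if (tot == 0) {
      if (!src %in% warned) {
        warning(sprintf("total_leaving is 0 for ROI %s; probabilities set to 0", src))
        warned <- c(warned, src)
      }
      next
    }
    q <- stats::quantile(v, probs = percentile / 100, type = type, names = FALSE)
    p[st[1L], st[2L]] <- min(1, max(0, q / tot))
  }
  diag(p) <- 0
  p
}

#' Symmetrize directed probabilities into an SC probability matrix
#'
#' The percentile rule is asymmetric (its denominator counts streamlines
#' leaving the source ROI) while the analysis is of undirected ROI pairs,
#' so the two directions are combined — by arithmetic mean by default, or
#' by the maximum. The diagonal is fixed at 1 and excluded from all
#' downstream fitting and testing.
#'
#' @param directed square matrix of directed probabilities.
#' @param method `"mean"` or `"max"`.
#' @return a `labeled_matrix` of kind `sc_prob`, symmetric with unit
#'   diagonal.
#' @export
symmetrize_sc <- function(directed, method = c("mean", "max")) {
  method <- match.arg(method)
  if (is.null(rownames(directed))) stop("directed matrix must carry ROI labels")
  if (nrow(directed) != ncol(directed)) stop("directed matrix must be square")
  m <- switch(method,
              mean = (directed + t(directed)) / 2,
              max  = pmax(directed, t(directed)))
  diag(m) <- 1
  validate_labeled_matrix(labeled_matrix(m, rownames(directed), "sc_prob"))
}

#' Fit a zero-inflated Poisson model of tract counts versus distance
#'
#' Models pair-total streamline counts S as a mixture of a point mass at
#' zero (weight omega) and a Poisson whose log mean is linear in the
#' inter-ROI distance g: log mu = alpha0 + alpha1 * g. Maximized by BFGS on
#' (alpha0, alpha1, logit omega) from method-of-moments starts (log-linear
#' fit on the positive counts; omega from the excess-zero fraction).
#' Non-convergence returns the best iterate with `converged = FALSE`
#' rather than raising.
#'
#' @param totals non-negative integer pair totals, or a `labeled_matrix`
#'   of kind `tract_count` (off-diagonal entries are used).
#' @param distances distances matching `totals` (vector or `labeled_matrix`
#'   of kind `distance`).
#' @return object of class `zip_fit`: `alpha0`, `alpha1` (per mm), `omega`
#'   in \[0, 1), `converged`, `loglik`, `n_pairs`.
#' @export
fit_zip <- function(totals, distances) {
  if (inherits(totals, "labeled_matrix")) {
    off <- row(totals) != col(totals)
    if (inherits(distances, "labeled_matrix")) {
      if (!identical(rownames(totals), rownames(distances))) {
        stop("label mismatch between totals and distances")
      }
      distances <- unclass(distances)[off]
    }
    totals <- unclass(totals)[off]
  }
  s <- as.numeric(totals)
  g <- as.numeric(distances)
  if (length(s) != length(g)) stop("totals and distances differ in length")
  if (length(s) < 6L) stop("fewer pairs than needed to fit three parameters")
  if (any(!is.finite(g)) || any(g < 0)) stop("distances must be finite and non-negative")
  if (any(s < 0) || any(s != round(s))) stop("totals must be non-negative integers")
  if (all(s == 0)) stop("degenerate data: all pair totals are zero")

  pos <- s > 0
  # method-of-moments starts
  if (sum(pos) >= 2L && stats::var(g[pos]) > 0) {
    cf <- stats::coef(stats::lm(log(s[pos]) ~ g[pos]))
    a0 <- cf[[1L]]; a1 <- cf[[2L]]
  } else {
    a0 <- log(mean(s[pos])); a1 <- 0
  }
  mu0 <- exp(pmin(a0 + a1 * g, 30))
  p0_pred <- mean(exp(-mu0))
  w0 <- (mean(s == 0) - p0_pred) / max(1 - p0_pred, 1e-8)
  w0 <- min(max(w0, 1e-3), 0.99)

  nll <- function(theta) {
    a0 <- theta[1L]; a1 <- theta[2L]; w <- stats::plogis(theta[3L])
    eta <- pmin(a0 + a1 * g, 30)
    mu <- exp(eta)
    ll <- numeric(length(s))
    z <- s == 0
    ll[z] <- log(w + (1 - w) * exp(-mu[z]))
    ll[!z] <- log1p(-w) - mu[!z] + s[!z] * eta[!z] - lfactorial(s[!z])
    if (any(!is.finite(ll))) return(1e10)
    -sum(ll)
  }
  # bounded quasi-Newton on (alpha0, alpha1, logit omega); the logit is
  # boxed so a boundary MLE (omega -> 0) terminates cleanly
  ctrl <- list(maxit = 500, factr = 1e3,
               parscale = c(1, 0.01, 1))  # alpha1 lives on a ~0.01 scale
  lower <- c(-Inf, -Inf, stats::qlogis(1e-4))
  upper <- c(Inf, Inf, stats::qlogis(1 - 1e-4))
  start <- c(a0, a1, min(max(stats::qlogis(w0), lower[3L]), upper[3L]))
  opt <- stats::optim(start, nll, method = "L-BFGS-B",
                      lower = lower, upper = upper, control = ctrl)
  flat <- FALSE
  for (restart in 1:4) {  # polish: restart until the likelihood is flat
    again <- stats::optim(opt$par, nll, method = "L-BFGS-B",
                          lower = lower, upper = upper, control = ctrl)
    if (opt$value - again$value < 1e-8) { opt <- again; flat <- TRUE; break }
    opt <- again
  }
  structure(list(alpha0 = opt$par[1L], alpha1 = opt$par[2L],
                 omega = stats::plogis(opt$par[3L]),
                 converged = opt$convergence == 0L || flat,
                 loglik = -opt$value, n_pairs = length(s)),
            class = "zip_fit")
}

#' @export
print.zip_fit <- function(x, ...) {
  cat(sprintf(paste0("Zero-inflated Poisson fit (%d pairs%s)\n",
                     "  alpha0 = %.4f   alpha1 = %.5f /mm   omega = %.4f\n",
                     "  loglik = %.3f\n"),
              x$n_pairs, if (x$converged) "" else ", NOT converged",
              x$alpha0, x$alpha1, x$omega, x$loglik))
  invisible(x)
}

#' Remove the fitted distance trend from SC probabilities
#'
#' Rescales each pair's probability by the ratio of the fitted Poisson
#' mean at the cohort-median off-diagonal distance to the fitted mean at
#' the pair's own distance, pi_adj = min(1, pi * exp(-alpha1 * (g -
#' g_med))). This removes the fitted exponential distance trend while
#' preserving scale at the typical distance; with alpha1 = 0 it is the
#' identity. The diagonal is untouched.
#'
#' @param pi_mat a `labeled_matrix` of kind `sc_prob`.
#' @param fit a `zip_fit`.
#' @param distances a `labeled_matrix` of kind `distance` with the same
#'   labels.
#' @param force apply the adjustment even if the fit did not converge.
#' @return the adjusted `sc_prob` matrix.
#' @export
distance_adjust <- function(pi_mat, fit, distances, force = FALSE) {
  stopifnot(inherits(fit, "zip_fit"))
  validate_labeled_matrix(pi_mat)
  if (!identical(rownames(pi_mat), rownames(distances))) {
    stop("label mismatch between probabilities and distances")
  }
  if (!fit$converged && !force) {
    stop("ZIP fit did not converge; pass force = TRUE to adjust anyway")
  }
  off <- row(pi_mat) != col(pi_mat)
  g_med <- stats::median(unclass(distances)[off])
  factor <- exp(-fit$alpha1 * (unclass(distances) - g_med))
  if (any(!is.finite(factor[off]))) stop("non-finite distance rescale factor")
  adj <- pmin(unclass(pi_mat) * factor, 1)
  adj[!off] <- unclass(pi_mat)[!off]
  labeled_matrix(adj, rownames(pi_mat), "sc_prob")
}

#' Incorporate second-order (indirect) structural connections
#'
#' For every ROI pair (i, j) the indirect connectivity through a single
#' intermediate m is the product pi_im * pi_mj; the pair's connectivity
#' becomes the larger of the direct value and the best indirect value,
#' pi_ij = max(pi_ij, max_m pi_im * pi_mj). A single pass over the input
#' values — no in-place propagation, so chains longer than one
#' intermediate are not composed. The result carries a logical `indirect`
#' attribute flagging pairs where an indirect route won.
#'
#' @param pi_mat a symmetric `labeled_matrix` of kind `sc_prob` with unit
#'   diagonal.
#' @return the updated `sc_prob` matrix (elementwise >= the input).
#' @export
second_order <- function(pi_mat) {
  validate_labeled_matrix(pi_mat)
  v <- unclass(pi_mat)
  n <- nrow(v)
  b <- v
  diag(b) <- 0  # zero diagonal removes m = i and m = j from the max
  best <- matrix(0, n, n)
  for (m in seq_len(n)) best <- pmax(best, outer(b[, m], b[m, ]))
  out <- pmax(v, best)
  diag(out) <- diag(v)
  res <- labeled_matrix(out, rownames(pi_mat), "sc_prob")
  attr(res, "indirect") <- best > v & row(v) != col(v)
  res
}

#' Full structural-connectivity stage for one subject
#'
#' Probabilities -> symmetrization -> distance adjustment -> second-order
#' incorporation, in that order. Stages can be ablated.
#'
#' @param counts a `voxel_count_table`.
#' @param distances `labeled_matrix` of kind `distance`.
#' @param percentile percentile for [sc_probability()].
#' @param symmetrization `"mean"` or `"max"`.
#' @param adjust `"median-distance"` or `"none"`.
#' @param second_order apply [second_order()]?
#' @param fit optional pre-computed `zip_fit` (e.g. pooled across
#'   subjects); fitted from this subject's pair totals when `NULL`.
#' @param force_adjust adjust even on a non-converged fit.
#' @return list with `sc` (the final `sc_prob` matrix) and `zip` (the fit
#'   used, or `NULL` when `adjust = "none"`).
#' @export
structural_stage <- function(counts, distances, percentile = 90,
                             symmetrization = "mean",
                             adjust = c("median-distance", "none"),
                             second_order = TRUE, fit = NULL,
                             force_adjust = FALSE) {
  adjust <- match.arg(adjust)
  pi_mat <- symmetrize_sc(sc_probability(counts, percentile), symmetrization)
  zip <- NULL
  if (adjust == "median-distance") {
    zip <- if (is.null(fit)) fit_zip(pair_totals_matrix(counts), distances) else fit
    pi_mat <- distance_adjust(pi_mat, zip, distances, force = force_adjust)
  }
  if (second_order) pi_mat <- second_order(pi_mat)
  list(sc = pi_mat, zip = zip)
}
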