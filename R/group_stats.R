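#' Two-sided Wilcoxon rank-sum test
#'
#' Exact p-value by enumeration of the rank-sum distribution when both
#' samples have at most 25 observations and there are no ties; otherwise
#' the normal approximation with tie and continuity corrections. This is
#' the standard two-sample behaviour of `wilcox.test()`, pinned down
#' explicitly so the exact/approximate switch does not depend on the
#' engine's defaults.
#'
#' @param a,b non-empty numeric samples (independent groups).
#' @return the two-sided p-value.
#' @export
wilcoxon_rank_sum <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) stop("empty sample")
  ties <- anyDuplicated(c(a, b)) > 0L
  use_exact <- !ties && max(length(a), length(b)) <= 25L
  res <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided",
                       exact = use_exact, correct = TRUE)
  )
  p <- unname(res$p.value)
  # all observations tied across both samples: the statistic is exactly at
  # its mean with zero variance; no evidence of a difference
  if (!is.finite(p)) p <- 1
  p
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Sorts the p-values ascending, multiplies the k-th by n/k, enforces
#' monotonicity from the largest down, caps at 1, and returns the adjusted
#' values in the input order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values (same length and order).
#' @export
fdr_bh <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  n <- length(p)
  ord <- order(p)
  scaled <- p[ord] * n / seq_len(n)
  adj <- rev(cummin(rev(scaled)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[ord] <- adj
  out
}

#' Cohen's d with pooled standard deviation
#'
#' d = (mean(control) - mean(adversity)) / s_pooled, with the usual
#' (n1 + n2 - 2)-weighted pooled SD and no small-sample correction. The
#' sign is positive when the control group exceeds the adversity group.
#'
#' @param control,adversity numeric samples of size >= 2.
#' @return Cohen's d.
#' @export
cohens_d <- function(control, adversity) {
  n1 <- length(control); n2 <- length(adversity)
  if (n1 < 2L || n2 < 2L) stop("each sample needs at least 2 observations")
  sp2 <- ((n1 - 1) * stats::var(control) + (n2 - 1) * stats::var(adversity)) /
    (n1 + n2 - 2)
  if (sp2 <= 0) stop("degenerate samples: zero pooled variance")
  (mean(control) - mean(adversity)) / sqrt(sp2)
}

#' Effect-size class of a Cohen's d
#'
#' Classification on |d|: below 0.2 negligible, \[0.2, 0.5) small,
#' \[0.5, 0.8) medium, at or above 0.8 large.
#'
#' @param d Cohen's d (vectorized).
#' @return character vector of labels.
#' @export
classify_effect <- function(d) {
  cut(abs(d), breaks = c(-Inf, 0.2, 0.5, 0.8, Inf), right = FALSE,
      labels = c("negligible", "small", "medium", "large")) |> as.character()
}

#' Per-pair group comparison table
#'
#' For every tested ROI pair, compares the two groups on SC, FC and awFC
#' with Wilcoxon rank-sum tests, adjusts each metric's p-values for false
#' discovery (Benjamini-Hochberg) across all tested pairs (pooled over
#' networks by default, or within each network), and reports Cohen's d on
#' awFC (positive = control above adversity) with its size label. Only
#' within-network pairs are tested by default. Rows are ordered by network
#' then pair, following atlas order.
#'
#' @param results list of `awfc_result` objects, one per subject, sharing
#'   one label order.
#' @param groups character vector parallel to `results`, each `"control"`
#'   or `"adversity"`; at least 2 subjects per group.
#' @param atlas ROI atlas giving network membership.
#' @param fdr_scope `"pooled"` (across all tested pairs, per metric) or
#'   `"per-network"`.
#' @param within_only test only within-network pairs (default).
#' @param d_metric metric on which Cohen's d is computed.
#' @return data.frame with columns `start_roi`, `end_roi`, `network`,
#'   `p_sc`, `p_fc`, `p_awfc`, `q_sc`, `q_fc`, `q_awfc`, `cohens_d`,
#'   `size_label`.
#' @export
build_results_table <- function(results, groups, atlas,
                                fdr_scope = c("pooled", "per-network"),
                                within_only = TRUE,
                                d_metric = c("awfc", "sc", "fc")) {
  fdr_scope <- match.arg(fdr_scope)
  d_metric <- match.arg(d_metric)
  groups <- as.character(groups)
  if (length(results) != length(groups)) {
    stop("results and groups differ in length")
  }
  bad <- setdiff(unique(groups), c("control", "adversity"))
  if (length(bad)) stop("unknown group label: ", paste(bad, collapse = ", "))
  if (sum(groups == "control") < 2L || sum(groups == "adversity") < 2L) {
    stop("each group needs at least 2 subjects")
  }
  labs <- results[[1L]]$labels
  for (r in results) {
    if (!identical(r$labels, labs)) stop("inconsistent pair set across subjects")
  }
  pairs <- network_pairs(atlas[atlas$label %in% labs, , drop = FALSE],
                         within_only = within_only)

  extract <- function(metric, s, e) {
    vapply(results, function(r) unclass(r[[metric]])[s, e], numeric(1))
  }
  ctrl <- groups == "control"
  rows <- lapply(seq_len(nrow(pairs)), function(k) {
    s <- pairs$start_roi[k]; e <- pairs$end_roi[k]
    vals <- lapply(c(sc = "sc", fc = "fc", awfc = "awfc"),
                   function(m) extract(m, s, e))
    p <- vapply(vals, function(v) wilcoxon_rank_sum(v[ctrl], v[!ctrl]),
                numeric(1))
    dv <- vals[[d_metric]]
    d <- tryCatch(cohens_d(dv[ctrl], dv[!ctrl]), error = function(err) 0)
    data.frame(start_roi = s, end_roi = e, network = pairs$network[k],
               p_sc = p[["sc"]], p_fc = p[["fc"]], p_awfc = p[["awfc"]],
               cohens_d = d, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  adjust <- function(p) {
    if (fdr_scope == "pooled") return(fdr_bh(p))
    q <- numeric(length(p))
    for (net in unique(tab$network)) {
      sel <- tab$network == net
      q[sel] <- fdr_bh(p[sel])
    }
    q
  }
  tab$q_sc <- adjust(tab$p_sc)
  tab$q_fc <- adjust(tab$p_fc)
  tab$q_awfc <- adjust(tab$p_awfc)
  tab$size_label <- classify_effect(tab$cohens_d)
  tab[, c("start_roi", "end_roi", "network", "p_sc", "p_fc", "p_awfc",
          "q_sc", "q_fc", "q_awfc", "cohens_d", "size_label")]
}
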