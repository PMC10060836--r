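#' Anatomically weighted functional dissimilarity
#'
#' Structural dissimilarity (1 - SC) times functional dissimilarity
#' (1 - FC). A perfect structural connection (SC = 1) annihilates the
#' dissimilarity regardless of FC; a strongly anticorrelated pair with no
#' structural support approaches the maximum of 2.
#'
#' @param sc structural connectivity probability in \[0, 1\] (vectorized).
#' @param fc functional connectivity (Pearson r) in \[-1, 1\].
#' @return (1 - sc) * (1 - fc), in \[0, 2\].
#' @export
awfd <- function(sc, fc) {
  if (any(sc < -.lm_tol | sc > 1 + .lm_tol, na.rm = TRUE)) {
    stop("validation error: sc outside [0, 1]")
  }
  if (any(abs(fc) > 1 + .lm_tol, na.rm = TRUE)) {
    stop("validation error: fc outside [-1, 1]")
  }
  (1 - sc) * (1 - fc)
}

#' awFC from awFd
#'
#' Maps the dissimilarity back onto a correlation-like scale:
#' awFC = 1 - |awFd|, in \[-1, 1\]. Values below 0 arise only from
#' negative FC (awFd > 1).
#'
#' @param awfd anatomically weighted functional dissimilarity, >= 0.
#' @return 1 - |awfd|.
#' @export
awfc_from_awfd <- function(awfd) 1 - abs(awfd)

#' Fuse one subject's SC and FC matrices
#'
#' Applies the awFd/awFC fusion elementwise over off-diagonal pairs; the
#' diagonal awFC is 1 by convention. Negative FC passes through the
#' formula verbatim unless `truncate_fc` is set, in which case FC is
#' floored at 0 before fusion.
#'
#' @param sc a `labeled_matrix` of kind `sc_prob`.
#' @param fc a `labeled_matrix` of kind `fc` with identical label order.
#' @param truncate_fc floor FC at 0 before fusing (default off).
#' @return object of class `awfc_result`: list with `labels` and the four
#'   matrices `sc`, `fc`, `awfd`, `awfc`.
#' @export
fuse_subject <- function(sc, fc, truncate_fc = FALSE) {
  validate_labeled_matrix(sc)
  validate_labeled_matrix(fc)
  if (!identical(rownames(sc), rownames(fc))) {
    differing <- union(setdiff(rownames(sc), rownames(fc)),
                       setdiff(rownames(fc), rownames(sc)))
    stop("label mismatch between SC and FC: ",
         if (length(differing)) paste(differing, collapse = ", ")
         else "same labels in different order")
  }
  fcv <- unclass(fc)
  if (truncate_fc) fcv <- pmax(fcv, 0)
  d <- awfd(unclass(sc), fcv)
  a <- awfc_from_awfd(d)
  diag(d) <- 0
  diag(a) <- 1
  structure(list(labels = rownames(sc),
                 sc = sc, fc = fc,
                 awfd = d,
                 awfc = labeled_matrix(a, rownames(sc), "awfc")),
            class = "awfc_result")
}

#' @export
print.awfc_result <- function(x, ...) {
  cat(sprintf("<awfc_result: %d ROIs, %d unordered pairs>\n",
              length(x$labels), choose(length(x$labels), 2)))
  invisible(x)
}

#' Long-format view of a fusion result
#'
#' One row per unordered off-diagonal ROI pair with the pair's SC, FC,
#' awFd and awFC values; when an atlas is supplied a `network` column is
#' added (`"cross"` for cross-network pairs).
#'
#' @param x an `awfc_result`.
#' @param atlas optional ROI atlas for network annotation.
#' @param ... unused.
#' @return data.frame with columns `start_roi`, `end_roi` (, `network`),
#'   `sc`, `fc`, `awfd`, `awfc`.
#' @export
as.data.frame.awfc_result <- function(x, atlas = NULL, ...) {
  idx <- utils::combn(length(x$labels), 2L)
  i <- idx[1L, ]; j <- idx[2L, ]
  df <- data.frame(start_roi = x$labels[i], end_roi = x$labels[j],
                   stringsAsFactors = FALSE)
  if (!is.null(atlas)) {
    ni <- atlas$network[match(df$start_roi, atlas$label)]
    nj <- atlas$network[match(df$end_roi, atlas$label)]
    df$network <- ifelse(ni == nj, ni, "cross")
  }
  pick <- cbind(i, j)
  df$sc <- unclass(x$sc)[pick]
  df$fc <- unclass(x$fc)[pick]
  df$awfd <- x$awfd[pick]
  df$awfc <- unclass(x$awfc)[pick]
  df
}
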