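#' Labeled square connectivity matrix
#'
#' The basic container shared by every stage of the pipeline: a square
#' numeric matrix whose rows and columns are indexed by ROI labels, tagged
#' with a `kind` that determines which invariants hold.
#'
#' Kinds and their invariants:
#' * `fc` — symmetric, unit diagonal, entries in \[-1, 1\] (Pearson r).
#' * `distance` — symmetric, non-negative, zero diagonal (millimetres).
#' * `tract_count` — non-negative integers (need not be symmetric:
#'   streamline counts are tallied per ordered ROI pair).
#' * `sc_prob` — entries in \[0, 1\].
#' * `awfc` — entries in \[-1, 1\].
#'
#' @param values square numeric matrix.
#' @param labels character vector of ROI labels; defaults to the row names
#'   of `values`. Must be unique and non-empty.
#' @param kind one of `"fc"`, `"tract_count"`, `"distance"`, `"sc_prob"`,
#'   `"awfc"`.
#' @return a `labeled_matrix`: a numeric matrix with dimnames set to the
#'   labels and a `kind` attribute.
#' @export
labeled_matrix <- function(values, labels = rownames(values), kind) {
  kind <- match.arg(kind, c("fc", "tract_count", "distance", "sc_prob", "awfc"))
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(labels)) stop("labeled_matrix: labels are required")
  labels <- as.character(labels)
  if (length(labels) == 0L) stop("empty matrix: no labels")
  if (anyDuplicated(labels)) stop("labeled_matrix: duplicated labels")
  if (nrow(values) != ncol(values)) {
    stop(sprintf("format error: matrix is %d x %d, not square",
                 nrow(values), ncol(values)))
  }
  if (nrow(values) != length(labels)) {
    stop("labeled_matrix: label count does not match matrix dimension")
  }
  dimnames(values) <- list(labels, labels)
  structure(values, kind = kind, class = c("labeled_matrix", "matrix", "array"))
}

#' @export
print.labeled_matrix <- function(x, ...) {
  cat(sprintf("<labeled_matrix kind=%s, %d ROIs>\n", attr(x, "kind"), nrow(x)))
  print(unclass(x)[, , drop = FALSE], ...)
  invisible(x)
}

#' @rdname labeled_matrix
#' @param m a `labeled_matrix`.
#' @export
matrix_kind <- function(m) attr(m, "kind")

# Numerical slack for symmetry / range checks on values that have been
# through floating-point arithmetic (not applied to sign constraints on
# counts, which must be exact).
.lm_tol <- 1e-8

#' Validate a labeled matrix against its kind invariants
#'
#' @param m a `labeled_matrix`.
#' @return `m`, invisibly; stops with an error naming the offending cell on
#'   the first violation found.
#' @export
validate_labeled_matrix <- function(m) {
  if (!inherits(m, "labeled_matrix")) stop("not a labeled_matrix")
  kind <- matrix_kind(m)
  labs <- rownames(m)
  v <- unclass(m)
  bad_cell <- function(mask) {
    idx <- which(mask, arr.ind = TRUE)[1L, ]
    sprintf("[%s, %s] = %g", labs[idx[1L]], labs[idx[2L]], v[idx[1L], idx[2L]])
  }
  if (any(!is.finite(v))) {
    stop(sprintf("validation error (%s): non-finite entry at %s",
                 kind, bad_cell(!is.finite(v))))
  }
  need_sym <- kind %in% c("fc", "distance")
  if (need_sym && max(abs(v - t(v))) > .lm_tol) {
    stop(sprintf("validation error (%s): matrix is not symmetric at %s",
                 kind, bad_cell(abs(v - t(v)) > .lm_tol)))
  }
  if (kind == "fc") {
    if (any(abs(v) > 1 + .lm_tol)) {
      stop(sprintf("validation error (fc): |r| > 1 at %s", bad_cell(abs(v) > 1 + .lm_tol)))
    }
    if (any(abs(diag(v) - 1) > .lm_tol)) {
      k <- which(abs(diag(v) - 1) > .lm_tol)[1L]
      stop(sprintf("validation error (fc): diagonal not 1 at [%s, %s]",
                   labs[k], labs[k]))
    }
  } else if (kind == "distance") {
    if (any(v < -.lm_tol)) {
      stop(sprintf("validation error (distance): negative distance at %s",
                   bad_cell(v < -.lm_tol)))
    }
    if (any(abs(diag(v)) > .lm_tol)) {
      k <- which(abs(diag(v)) > .lm_tol)[1L]
      stop(sprintf("validation error (distance): nonzero diagonal at [%s, %s]",
                   labs[k], labs[k]))
    }
  } else if (kind == "tract_count") {
    if (any(v < 0) || any(v != round(v))) {
      stop(sprintf("validation error (tract_count): negative or non-integer count at %s",
                   bad_cell(v < 0 | v != round(v))))
    }
  } else if (kind == "sc_prob") {
    if (any(v < -.lm_tol | v > 1 + .lm_tol)) {
      stop(sprintf("validation error (sc_prob): entry outside [0, 1] at %s",
                   bad_cell(v < -.lm_tol | v > 1 + .lm_tol)))
    }
  } else if (kind == "awfc") {
    if (any(abs(v) > 1 + .lm_tol)) {
      stop(sprintf("validation error (awfc): entry outside [-1, 1] at %s",
                   bad_cell(abs(v) > 1 + .lm_tol)))
    }
  }
  invisible(m)
}

#' Read a labeled square matrix from text
#'
#' Accepts two dialects: (a) TSV with a header row and a first column of
#' labels (what [write_labeled_matrix()] emits), and (b) FATCAT-style
#' whitespace text — `#`-prefixed comment lines, one label line, then one
#' whitespace-delimited numeric row per ROI. The dialect is detected from
#' the content: if the second non-comment line parses entirely as numbers
#' the file is FATCAT-style, otherwise TSV. Decimal parsing always uses the
#' period radix regardless of locale.
#'
#' @param path path to an existing text file.
#' @param kind the matrix kind to validate against (see [labeled_matrix()]).
#' @return a validated `labeled_matrix` with labels in file order.
#' @export
read_labeled_matrix <- function(path, kind) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines)]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop(sprintf("format error: %s has no matrix body", path))
  split_ws <- function(x) strsplit(trimws(x), "[ \t]+")[[1L]]
  second <- split_ws(lines[2L])
  all_numeric <- !anyNA(suppressWarnings(as.numeric(second)))
  if (all_numeric) {
    labels <- split_ws(lines[1L])
    rows <- lapply(lines[-1L], function(l) suppressWarnings(as.numeric(split_ws(l))))
  } else {
    header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
    labels <- header[-1L]
    body <- strsplit(lines[-1L], "\t", fixed = TRUE)
    row_labels <- vapply(body, `[`, character(1), 1L)
    if (!identical(row_labels, labels)) {
      stop(sprintf("format error: row labels do not match column labels in %s", path))
    }
    rows <- lapply(body, function(f) suppressWarnings(as.numeric(f[-1L])))
  }
  n <- length(labels)
  if (length(rows) != n || any(lengths(rows) != n)) {
    stop(sprintf("format error: non-square grid in %s (%d labels, %d rows)",
                 path, n, length(rows)))
  }
  values <- do.call(rbind, rows)
  if (anyNA(values)) stop(sprintf("format error: non-numeric cell in %s", path))
  validate_labeled_matrix(labeled_matrix(values, labels, kind))
}

#' Write a labeled matrix as TSV
#'
#' Emits the TSV dialect of [read_labeled_matrix()]: a header row
#' (`label`, then the ROI labels) and one row per ROI. Values are printed
#' with 17 significant digits so a write/read cycle reproduces the doubles
#' bitwise.
#'
#' @param m a valid `labeled_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_labeled_matrix <- function(m, path) {
  validate_labeled_matrix(m)
  labs <- rownames(m)
  body <- apply(unclass(m), 1L, function(r) {
    paste(formatC(r, digits = 17, format = "g"), collapse = "\t")
  })
  lines <- c(paste(c("label", labs), collapse = "\t"), paste(labs, body, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}
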