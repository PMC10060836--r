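#' Voxel-level streamline count table
#'
#' Holds, for each ordered ROI pair (i, j), the streamline count landing in
#' each voxel of the target ROI j, plus the total number of streamlines
#' leaving each ROI. The per-pair vector length equals the target ROI's
#' voxel volume for synthetic data; real tractography may use inflated-ROI
#' voxel counts, so only positive length is enforced.
#'
#' @param pairs named list; names are `"src->tgt"` label pairs, values are
#'   non-negative integer vectors of voxel counts.
#' @param total_leaving named non-negative numeric, one entry per ROI label.
#' @param labels ROI label order shared with the other subject matrices.
#' @return an object of class `voxel_count_table`.
#' @export
voxel_count_table <- function(pairs, total_leaving, labels) {
  stopifnot(is.list(pairs), !is.null(names(pairs)))
  if (is.null(names(total_leaving)) || !all(labels %in% names(total_leaving))) {
    stop("total_leaving must be named with every ROI label")
  }
  if (any(total_leaving < 0)) stop("total_leaving must be non-negative")
  for (nm in names(pairs)) {
    v <- pairs[[nm]]
    if (length(v) == 0L) stop(sprintf("empty voxel-count vector for pair %s", nm))
    if (any(v < 0) || any(v != round(v))) {
      stop(sprintf("negative or non-integer voxel count for pair %s", nm))
    }
  }
  structure(list(pairs = pairs, total_leaving = total_leaving[labels],
                 labels = labels),
            class = "voxel_count_table")
}

pair_key <- function(src, tgt) paste(src, tgt, sep = "->")

#' @export
print.voxel_count_table <- function(x, ...) {
  cat(sprintf("<voxel_count_table: %d ROIs, %d ordered pairs>\n",
              length(x$labels), length(x$pairs)))
  invisible(x)
}

#' Read / write voxel-count tables
#'
#' Long TSV with columns `source_roi`, `target_roi`, `voxel_index`,
#' `count`; the companion totals file has columns `roi`, `total_leaving`.
#'
#' @param counts_path path to the long-format counts TSV.
#' @param totals_path path to the totals TSV.
#' @param labels ROI label order to impose.
#' @return a `voxel_count_table`.
#' @export
read_voxel_counts <- function(counts_path, totals_path, labels) {
  long <- utils::read.delim(counts_path, stringsAsFactors = FALSE)
  need <- c("source_roi", "target_roi", "voxel_index", "count")
  miss <- setdiff(need, names(long))
  if (length(miss)) stop("counts file missing column: ", paste(miss, collapse = ", "))
  tot <- utils::read.delim(totals_path, stringsAsFactors = FALSE)
  if (!all(c("roi", "total_leaving") %in% names(tot))) {
    stop("totals file must have columns roi, total_leaving")
  }
  key <- pair_key(long$source_roi, long$target_roi)
  ord <- order(match(long$source_roi, labels), match(long$target_roi, labels),
               long$voxel_index)
  long <- long[ord, ]
  key <- key[ord]
  pairs <- split(long$count, factor(key, levels = unique(key)))
  total_leaving <- stats::setNames(tot$total_leaving, tot$roi)
  voxel_count_table(pairs, total_leaving, labels)
}

#' @rdname read_voxel_counts
#' @param vct a `voxel_count_table`.
#' @export
write_voxel_counts <- function(vct, counts_path, totals_path) {
  rows <- lapply(names(vct$pairs), function(nm) {
    st <- strsplit(nm, "->", fixed = TRUE)[[1L]]
    v <- vct$pairs[[nm]]
    data.frame(source_roi = st[1L], target_roi = st[2L],
               voxel_index = seq_along(v), count = v,
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), counts_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(roi = names(vct$total_leaving),
               total_leaving = as.numeric(vct$total_leaving)),
    totals_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(counts_path)
}

#' Composite adversity score and group assignment
#'
#' A subject is flagged for perinatal depression/anxiety when EPDS > 11, or
#' STAI > 29 together with HAM-A > 17, or MADRS > 6. One composite point is
#' assigned if that flag or the low-income indicator is present; a score of
#' at least 1 places the child in the adversity group, 0 in the control
#' group. Missing questionnaire scores cannot trigger a flag (set
#' `strict = TRUE` to make them an error instead).
#'
#' @param epds,stai,ham_a,madrs integer questionnaire scores, or `NA`.
#' @param low_income logical: parental income at or below the low-income
#'   cut-off (about $30,000).
#' @param strict error on missing scores instead of treating them as
#'   sub-threshold.
#' @return list with `score` (0 or 1) and `group` (`"adversity"` or
#'   `"control"`).
#' @export
adversity_group <- function(epds = NA, stai = NA, ham_a = NA, madrs = NA,
                            low_income = FALSE, strict = FALSE) {
  scores <- list(epds = epds, stai = stai, ham_a = ham_a, madrs = madrs)
  if (strict && anyNA(unlist(scores))) {
    stop("missing questionnaire score in strict mode: ",
         paste(names(scores)[is.na(unlist(scores))], collapse = ", "))
  }
  for (nm in names(scores)) {
    s <- scores[[nm]]
    if (!is.na(s) && s < 0) stop(sprintf("negative %s score", nm))
  }
  gt <- function(x, thr) !is.na(x) && x > thr
  mental <- gt(epds, 11) || (gt(stai, 29) && gt(ham_a, 17)) || gt(madrs, 6)
  score <- as.integer(mental || isTRUE(low_income))
  list(score = score, group = if (score >= 1L) "adversity" else "control")
}

#' Motion quality-control filter
#'
#' Excludes subjects whose mean relative volume-to-volume displacement
#' strictly exceeds the threshold (default 0.55 mm); a displacement exactly
#' at the threshold is kept.
#'
#' @param cohort list of subject records, each with a
#'   `mean_relative_displacement` field (millimetres).
#' @param threshold_mm positive exclusion threshold.
#' @return list with `kept` and `excluded` sublists; order preserved.
#' @export
qc_filter <- function(cohort, threshold_mm = 0.55) {
  stopifnot(threshold_mm > 0)
  disp <- vapply(cohort, function(s) {
    d <- s$mean_relative_displacement
    if (is.null(d) || is.na(d)) {
      stop(sprintf("missing mean_relative_displacement for subject %s",
                   if (is.null(s$subject_id)) "<unnamed>" else s$subject_id))
    }
    as.numeric(d)
  }, numeric(1))
  keep <- disp <= threshold_mm
  list(kept = cohort[keep], excluded = cohort[!keep])
}

#' Read a cohort manifest
#'
#' TSV or CSV (sniffed from the header line) with required columns
#' `subject_id` and `mean_relative_displacement`; optional questionnaire
#' columns `epds`, `stai`, `ham_a`, `madrs`, `low_income`, an optional
#' precomputed `group` override, and per-subject file references
#' `fc_path`, `counts_path`, `totals_path`, `grid_path` (relative paths are
#' resolved against the manifest's directory). Connectomes are not loaded
#' here; see [read_subject_connectome()].
#'
#' @param path manifest file.
#' @return list of subject records.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- tryCatch(
    utils::read.table(path, sep = sep, header = TRUE, stringsAsFactors = FALSE),
    error = function(e) stop("no subjects in manifest: ", conditionMessage(e))
  )
  if (nrow(df) == 0L) stop("no subjects in manifest")
  for (col in c("subject_id", "mean_relative_displacement")) {
    if (!col %in% names(df)) stop(sprintf("manifest missing required column: %s", col))
  }
  if (!("group" %in% names(df)) &&
      !any(c("epds", "stai", "ham_a", "madrs", "low_income") %in% names(df))) {
    stop("manifest missing required column: group (or adversity score columns)")
  }
  if (anyDuplicated(df$subject_id)) {
    stop("duplicate subject_id in manifest: ",
         paste(unique(df$subject_id[duplicated(df$subject_id)]), collapse = ", "))
  }
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p) || is.na(p)) return(NA_character_)
    if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(base, p)
  }
  getcol <- function(nm, default = NA) {
    if (nm %in% names(df)) df[[nm]] else rep(default, nrow(df))
  }
  lapply(seq_len(nrow(df)), function(i) {
    adv <- list(epds = getcol("epds")[i], stai = getcol("stai")[i],
                ham_a = getcol("ham_a")[i], madrs = getcol("madrs")[i],
                low_income = isTRUE(as.logical(getcol("low_income", FALSE)[i])))
    grp <- getcol("group", NA_character_)[i]
    if (is.na(grp)) grp <- do.call(adversity_group, adv)$group
    list(
      subject_id = as.character(df$subject_id[i]),
      mean_relative_displacement = as.numeric(df$mean_relative_displacement[i]),
      adversity = adv,
      group = grp,
      fc_path = resolve(getcol("fc_path", NA_character_)[i]),
      counts_path = resolve(getcol("counts_path", NA_character_)[i]),
      totals_path = resolve(getcol("totals_path", NA_character_)[i]),
      grid_path = resolve(getcol("grid_path", NA_character_)[i])
    )
  })
}

#' Load one subject's connectome from manifest file references
#'
#' Reads the FC matrix, voxel-count and totals tables, and distance grid
#' referenced by a manifest record and checks that all components share one
#' label order (a mismatch is an error, never silently reindexed; labels
#' are matched case-sensitively).
#'
#' @param record a subject record from [read_manifest()].
#' @return the record with a `connectome` field attached (`fc`, `counts`,
#'   `pair_totals`, `distances`).
#' @export
read_subject_connectome <- function(record) {
  fc <- read_labeled_matrix(record$fc_path, "fc")
  distances <- read_labeled_matrix(record$grid_path, "distance")
  if (!identical(rownames(fc), rownames(distances))) {
    stop(sprintf("label mismatch between FC and distance files for subject %s",
                 record$subject_id))
  }
  counts <- read_voxel_counts(record$counts_path, record$totals_path,
                              rownames(fc))
  pair_totals <- pair_totals_matrix(counts)
  record$connectome <- list(fc = fc, counts = counts,
                            pair_totals = pair_totals, distances = distances)
  record
}

#' Pair-total streamline counts from a voxel-count table
#'
#' @param vct a `voxel_count_table`.
#' @return a `labeled_matrix` of kind `tract_count` whose (i, j) entry is
#'   the summed voxel-level count for the ordered pair; diagonal 0.
#' @export
pair_totals_matrix <- function(vct) {
  n <- length(vct$labels)
  m <- matrix(0, n, n, dimnames = list(vct$labels, vct$labels))
  for (nm in names(vct$pairs)) {
    st <- strsplit(nm, "->", fixed = TRUE)[[1L]]
    m[st[1L], st[2L]] <- sum(vct$pairs[[nm]])
  }
  labeled_matrix(m, vct$labels, "tract_count")
}
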