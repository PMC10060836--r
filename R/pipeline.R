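#' Run the full awFC analysis
#'
#' QC filtering -> group assignment -> per-subject structural stage
#' (percentile probabilities, symmetrization, ZIP distance adjustment,
#' second-order incorporation) -> SC/FC fusion -> per-pair group
#' statistics. Input is either an in-memory cohort (from
#' [generate_cohort()]) or a manifest path; with identical inputs,
#' configuration and seed the output is identical.
#'
#' @param cohort an `awfc_cohort`, or a list of subject records with
#'   connectomes attached, or a manifest path (string).
#' @param atlas ROI atlas; defaults to the cohort's own atlas or the
#'   packaged one.
#' @param percentile percentile for the SC probability rule.
#' @param adjust `"median-distance"` or `"none"`.
#' @param symmetrization `"mean"` or `"max"`.
#' @param second_order incorporate indirect connections?
#' @param zip_pooled fit the ZIP model once on all subjects' pair totals
#'   pooled (default fits per subject).
#' @param fdr_scope `"pooled"` or `"per-network"`.
#' @param q_threshold significance threshold on adjusted p-values.
#' @param qc_threshold_mm motion exclusion threshold.
#' @param truncate_fc floor FC at 0 before fusion.
#' @param force_adjust apply the distance adjustment even when a ZIP fit
#'   did not converge.
#' @param outdir if non-`NULL`, [render_report()] is called there.
#' @param verbose print stage-tagged progress lines.
#' @return list of class `awfc_run`: `table` (the per-pair statistics),
#'   `fusions` (per-subject `awfc_result`s), `groups`, `zip_fits`,
#'   `report` (subject counts, tests performed, parameters).
#' @export
run_pipeline <- function(cohort,
                         atlas = NULL,
                         percentile = 90,
                         adjust = c("median-distance", "none"),
                         symmetrization = c("mean", "max"),
                         second_order = TRUE,
                         zip_pooled = FALSE,
                         fdr_scope = c("pooled", "per-network"),
                         q_threshold = 0.05,
                         qc_threshold_mm = 0.55,
                         truncate_fc = FALSE,
                         force_adjust = FALSE,
                         outdir = NULL,
                         verbose = FALSE) {
  adjust <- match.arg(adjust)
  symmetrization <- match.arg(symmetrization)
  fdr_scope <- match.arg(fdr_scope)
  say <- function(stage, fmt, ...) {
    if (verbose) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
  }

  if (is.character(cohort)) {
    say("io", "reading manifest %s", cohort)
    records <- read_manifest(cohort)
    records <- lapply(records, read_subject_connectome)
  } else if (inherits(cohort, "awfc_cohort")) {
    if (is.null(atlas)) atlas <- cohort$atlas
    records <- cohort$subjects
  } else {
    records <- cohort
  }
  if (is.null(atlas)) atlas <- default_atlas()

  qc <- qc_filter(records, qc_threshold_mm)
  say("qc", "%d kept, %d excluded at %.2f mm", length(qc$kept),
      length(qc$excluded), qc_threshold_mm)
  kept <- qc$kept
  if (length(kept) == 0L) stop("qc stage: no subjects left after motion exclusion")

  groups <- vapply(kept, function(s) {
    if (!is.null(s$group) && !is.na(s$group)) s$group
    else do.call(adversity_group, s$adversity)$group
  }, character(1))

  pooled_fit <- NULL
  if (adjust == "median-distance" && zip_pooled) {
    tot <- unlist(lapply(kept, function(s) {
      m <- s$connectome$pair_totals
      unclass(m)[row(m) != col(m)]
    }))
    dst <- unlist(lapply(kept, function(s) {
      m <- s$connectome$distances
      unclass(m)[row(m) != col(m)]
    }))
    pooled_fit <- fit_zip(tot, dst)
    say("sc", "pooled ZIP fit: alpha0=%.3f alpha1=%.4f omega=%.3f",
        pooled_fit$alpha0, pooled_fit$alpha1, pooled_fit$omega)
  }

  fusions <- vector("list", length(kept))
  zip_fits <- vector("list", length(kept))
  for (k in seq_along(kept)) {
    s <- kept[[k]]
    stage <- tryCatch(
      structural_stage(s$connectome$counts, s$connectome$distances,
                       percentile = percentile,
                       symmetrization = symmetrization,
                       adjust = adjust, second_order = second_order,
                       fit = pooled_fit, force_adjust = force_adjust),
      error = function(e) stop(sprintf("sc stage failed for subject %s: %s",
                                       s$subject_id, conditionMessage(e)))
    )
    zip_fits[k] <- list(stage$zip)
    fusions[[k]] <- tryCatch(
      fuse_subject(stage$sc, s$connectome$fc, truncate_fc = truncate_fc),
      error = function(e) stop(sprintf("fusion stage failed for subject %s: %s",
                                       s$subject_id, conditionMessage(e)))
    )
  }
  names(fusions) <- names(zip_fits) <-
    vapply(kept, `[[`, character(1), "subject_id")
  say("fuse", "%d subjects fused", length(fusions))

  table <- build_results_table(fusions, groups, atlas, fdr_scope = fdr_scope)
  say("stats", "%d pairs tested, %d significant at q < %g",
      nrow(table), sum(table$q_awfc < q_threshold), q_threshold)

  report <- list(
    n_input = length(records),
    n_excluded_qc = length(qc$excluded),
    excluded_ids = vapply(qc$excluded, `[[`, character(1), "subject_id"),
    n_control = sum(groups == "control"),
    n_adversity = sum(groups == "adversity"),
    n_pairs_tested = nrow(table),
    n_tests = 3L * nrow(table),
    n_significant_awfc = sum(table$q_awfc < q_threshold),
    parameters = list(percentile = percentile, adjust = adjust,
                      symmetrization = symmetrization,
                      second_order = second_order, zip_pooled = zip_pooled,
                      fdr_scope = fdr_scope, q_threshold = q_threshold,
                      qc_threshold_mm = qc_threshold_mm)
  )
  run <- structure(list(table = table, fusions = fusions, groups = groups,
                        zip_fits = zip_fits, report = report),
                   class = "awfc_run")
  if (!is.null(outdir)) render_report(run, outdir, q_threshold = q_threshold)
  run
}

#' @export
print.awfc_run <- function(x, ...) {
  r <- x$report
  cat(sprintf(paste0("awFC run: %d subjects in (%d excluded by QC), ",
                     "%d control vs %d adversity\n",
                     "%d ROI pairs tested; %d significant on awFC at q < %g\n"),
              r$n_input, r$n_excluded_qc, r$n_control, r$n_adversity,
              r$n_pairs_tested, r$n_significant_awfc,
              r$parameters$q_threshold))
  sig <- x$table[x$table$q_awfc < r$parameters$q_threshold, , drop = FALSE]
  if (nrow(sig)) {
    print(sig[, c("start_roi", "end_roi", "network", "q_awfc",
                  "cohens_d", "size_label")], row.names = FALSE)
  }
  invisible(x)
}

#' Write the results table, run summary and boxplots
#'
#' Emits `results.tsv` (one row per tested pair: raw and FDR-adjusted
#' p-values for SC, FC and awFC, Cohen's d, size label), `summary.json`
#' (the run report plus significant pairs), and one per-pair boxplot PDF
#' of awFC by group for each pair significant at `q_threshold`, annotated
#' with one star below 0.05 and two below 0.01.
#'
#' @param run an `awfc_run`.
#' @param outdir output directory (created if needed).
#' @param q_threshold significance threshold for plotting.
#' @return invisibly, the paths written.
#' @export
render_report <- function(run, outdir, q_threshold = 0.05) {
  stopifnot(inherits(run, "awfc_run"))
  if (nrow(run$table) == 0L) stop("empty results: nothing to report")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  tsv <- file.path(outdir, "results.tsv")
  utils::write.table(run$table, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  sig <- run$table[run$table$q_awfc < q_threshold, , drop = FALSE]
  summary_path <- file.path(outdir, "summary.json")
  jsonlite::write_json(
    list(report = run$report,
         significant_pairs = sig,
         note = if (nrow(sig) == 0L) "no pair significant at threshold" else NULL),
    summary_path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  plots <- character(0)
  for (k in seq_len(nrow(sig))) {
    s <- sig$start_roi[k]; e <- sig$end_roi[k]
    vals <- vapply(run$fusions, function(f) unclass(f$awfc)[s, e], numeric(1))
    fname <- file.path(outdir, sprintf("boxplot_%02d_%s.pdf", k,
                                       gsub("[^A-Za-z0-9]+", "_", paste(s, e))))
    stars <- if (sig$q_awfc[k] < 0.01) "**" else "*"
    grDevices::pdf(fname, width = 4, height = 4)
    graphics::boxplot(vals ~ factor(run$groups, c("control", "adversity")),
                      xlab = "", ylab = "awFC",
                      main = sprintf("%s - %s (%s) %s", s, e, sig$network[k], stars),
                      col = c("#5B9BD5", "#ED7D31"))
    grDevices::dev.off()
    plots <- c(plots, fname)
  }
  invisible(list(results = tsv, summary = summary_path, plots = plots))
}
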