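#' Synthetic cohort configuration
#'
#' Bundles the generator's stated world: the packaged 19-ROI atlas, group
#' sizes of 9 control and 8 adversity children, 105 retained fMRI volumes
#' (108 acquired minus 3 discarded), a block correlation structure with
#' within-network correlation 0.6 and between-network correlation 0.1, and
#' a distance-dependent zero-inflated Poisson streamline model with
#' log-mean intercept 2.0, distance slope -0.02 per mm and zero-inflation
#' weight 0.25.
#'
#' @param atlas ROI atlas (default the packaged atlas).
#' @param n_control,n_adversity group sizes.
#' @param t_volumes retained fMRI volumes per subject.
#' @param rho_within,rho_between generating correlations
#'   (`rho_within > rho_between >= 0`).
#' @param zip_alpha0,zip_alpha1,zip_omega streamline-count generator
#'   parameters (log-mean intercept, per-mm slope, zero-inflation weight).
#' @param lost_rate mean number of streamlines leaving an ROI that reach
#'   no target (adds to `total_leaving` only).
#' @param effects list of planted group effects; each element is a list
#'   with fields `pair` (two ROI labels), `metric` (`"fc"` or `"sc"`),
#'   `shift` (added to the generating correlation, or to alpha0 for that
#'   pair, in the target group) and `group` (default `"adversity"`).
#' @param seed integer seed; every random draw in the generator flows from
#'   it.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(atlas = default_atlas(),
                       n_control = 9, n_adversity = 8,
                       t_volumes = 105,
                       rho_within = 0.6, rho_between = 0.1,
                       zip_alpha0 = 2.0, zip_alpha1 = -0.02, zip_omega = 0.25,
                       lost_rate = 20,
                       effects = list(),
                       seed = 1L) {
  validate_atlas(atlas)
  stopifnot(n_control >= 1, n_adversity >= 1, t_volumes >= 4,
            rho_within > rho_between, rho_between >= 0, rho_within < 1,
            zip_omega >= 0, zip_omega <= 1, lost_rate >= 0)
  for (ef in effects) {
    if (!all(c("pair", "metric", "shift") %in% names(ef))) {
      stop("each effect needs fields pair, metric, shift")
    }
    if (!all(ef$pair %in% atlas$label)) {
      stop("effect pair not in atlas: ", paste(ef$pair, collapse = ", "))
    }
    if (!ef$metric %in% c("fc", "sc")) stop("effect metric must be fc or sc")
  }
  structure(list(atlas = atlas, n_control = n_control,
                 n_adversity = n_adversity, t_volumes = t_volumes,
                 rho_within = rho_within, rho_between = rho_between,
                 zip_alpha0 = zip_alpha0, zip_alpha1 = zip_alpha1,
                 zip_omega = zip_omega, lost_rate = lost_rate,
                 effects = effects, seed = as.integer(seed)),
            class = "sim_config")
}

# Generating correlation matrix for one group: block structure plus any
# planted FC shifts, repaired to the nearest unit-diagonal PSD matrix by
# eigenvalue flooring.
generating_sigma <- function(config, group) {
  atlas <- config$atlas
  n <- nrow(atlas)
  same <- outer(atlas$network, atlas$network, "==")
  sigma <- ifelse(same, config$rho_within, config$rho_between)
  diag(sigma) <- 1
  dimnames(sigma) <- list(atlas$label, atlas$label)
  for (ef in config$effects) {
    if (ef$metric != "fc") next
    tgt <- if (is.null(ef$group)) "adversity" else ef$group
    if (tgt != group) next
    a <- ef$pair[1L]; b <- ef$pair[2L]
    r <- sigma[a, b] + ef$shift
    if (abs(r) >= 1) stop("planted FC shift leaves (-1, 1)")
    sigma[a, b] <- sigma[b, a] <- r
  }
  ev <- eigen(sigma, symmetric = TRUE)
  if (min(ev$values) < 1e-6) {
    vals <- pmax(ev$values, 1e-6)
    sigma <- ev$vectors %*% diag(vals) %*% t(ev$vectors)
    sigma <- stats::cov2cor(sigma)
    dimnames(sigma) <- list(atlas$label, atlas$label)
  }
  sigma
}

#' Simulate one subject's FC matrix
#'
#' Draws `t_volumes` samples from a zero-mean multivariate normal whose
#' correlation matrix has `rho_within` inside each network block and
#' `rho_between` elsewhere (group-specific planted shifts applied before a
#' nearest-PSD repair), and returns the sample Pearson correlation matrix.
#' Simulating at the time-series level makes the FC sampling noise scale
#' with the number of retained volumes, as in real data.
#'
#' @param config a `sim_config`.
#' @param group `"control"` or `"adversity"` (selects planted effects).
#' @return a `labeled_matrix` of kind `fc`.
#' @export
simulate_fc <- function(config, group = "control") {
  sigma <- generating_sigma(config, group)
  n <- nrow(sigma)
  z <- matrix(stats::rnorm(config$t_volumes * n), config$t_volumes, n)
  x <- z %*% chol(sigma)
  fc <- stats::cor(x)
  fc[abs(fc) > 1] <- sign(fc[abs(fc) > 1])  # guard against rounding
  diag(fc) <- 1
  validate_labeled_matrix(labeled_matrix(fc, rownames(sigma), "fc"))
}

#' Simulate one subject's tractography summaries
#'
#' For each ordered ROI pair (i, j): with probability `zip_omega` the pair
#' total is 0; otherwise it is Poisson with mean
#' exp(alpha0 + alpha1 * g_ij) (per-pair alpha0 shifts from planted SC
#' effects applied for the target group). The total is spread over the
#' target ROI's voxels by a uniform multinomial. `total_leaving[i]` is the
#' sum of totals leaving i plus a Poisson(`lost_rate`) count of
#' streamlines that terminate outside every ROI.
#'
#' @param config a `sim_config`.
#' @param distances `labeled_matrix` of kind `distance` over the atlas
#'   labels.
#' @param group `"control"` or `"adversity"`.
#' @return list with `counts` (a `voxel_count_table`) and `pair_totals`
#'   (`labeled_matrix` of kind `tract_count`).
#' @export
simulate_tractography <- function(config, distances = euclidean_distances(config$atlas),
                                  group = "control") {
  atlas <- config$atlas
  labs <- atlas$label
  n <- length(labs)
  a0 <- matrix(config$zip_alpha0, n, n, dimnames = list(labs, labs))
  for (ef in config$effects) {
    if (ef$metric != "sc") next
    tgt <- if (is.null(ef$group)) "adversity" else ef$group
    if (tgt != group) next
    a <- ef$pair[1L]; b <- ef$pair[2L]
    a0[a, b] <- a0[a, b] + ef$shift
    a0[b, a] <- a0[b, a] + ef$shift
  }
  pairs <- list()
  totals <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      mu <- exp(a0[i, j] + config$zip_alpha1 * distances[i, j])
      tot <- if (stats::runif(1) < config$zip_omega) 0L else stats::rpois(1, mu)
      totals[i, j] <- tot
      nv <- atlas$volume_voxels[j]
      vox <- if (tot > 0) {
        as.integer(stats::rmultinom(1, tot, rep(1 / nv, nv)))
      } else {
        integer(nv)
      }
      pairs[[pair_key(labs[i], labs[j])]] <- vox
    }
  }
  lost <- stats::rpois(n, config$lost_rate)
  total_leaving <- rowSums(totals) + lost
  list(counts = voxel_count_table(pairs, stats::setNames(total_leaving, labs), labs),
       pair_totals = labeled_matrix(totals, labs, "tract_count"))
}

#' Generate a synthetic multimodal cohort
#'
#' Produces `n_control + n_adversity` subjects, each with an FC matrix,
#' voxel-level tractography counts, pair totals and a shared distance
#' matrix (Euclidean between MNI peaks), plus manifest fields: a
#' subject id, a mean relative displacement drawn uniformly below the QC
#' threshold (a displacement above 0.55 mm can be planted via
#' `qc_fail_ids`), and questionnaire scores consistent with the group
#' label. A ground-truth ledger records the generator parameters, the
#' planted effects and the generating correlations per group. Fully
#' reproducible from `config$seed`.
#'
#' @param config a `sim_config`.
#' @param qc_fail_ids subject indices (1-based) whose displacement is
#'   drawn above the exclusion threshold, for testing QC integration.
#' @return object of class `awfc_cohort`: list with `subjects`, `atlas`,
#'   `distances`, `config`, `truth`.
#' @export
generate_cohort <- function(config, qc_fail_ids = integer(0)) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  atlas <- config$atlas
  distances <- euclidean_distances(atlas)
  n_total <- config$n_control + config$n_adversity
  groups <- rep(c("control", "adversity"), c(config$n_control, config$n_adversity))
  ids <- sprintf("%s%02d", ifelse(groups == "control", "ctrl", "adv"),
                 c(seq_len(config$n_control), seq_len(config$n_adversity)))
  subjects <- vector("list", n_total)
  for (k in seq_len(n_total)) {
    fc <- simulate_fc(config, groups[k])
    tract <- simulate_tractography(config, distances, groups[k])
    disp <- if (k %in% qc_fail_ids) stats::runif(1, 0.56, 0.9)
            else stats::runif(1, 0.05, 0.50)
    adv <- if (groups[k] == "adversity") {
      # one random criterion triggers the composite point
      pick <- sample(c("epds", "stai_hama", "madrs", "income"), 1L)
      list(epds = if (pick == "epds") 12L + stats::rpois(1, 3) else stats::rpois(1, 4),
           stai = if (pick == "stai_hama") 30L + stats::rpois(1, 5) else stats::rpois(1, 10),
           ham_a = if (pick == "stai_hama") 18L + stats::rpois(1, 4) else stats::rpois(1, 5),
           madrs = if (pick == "madrs") 7L + stats::rpois(1, 3) else stats::rpois(1, 2),
           low_income = pick == "income")
    } else {
      list(epds = stats::rpois(1, 3), stai = stats::rpois(1, 8),
           ham_a = stats::rpois(1, 4), madrs = stats::rpois(1, 1),
           low_income = FALSE)
    }
    subjects[[k]] <- list(
      subject_id = ids[k],
      group = groups[k],
      mean_relative_displacement = round(disp, 3),
      adversity = adv,
      connectome = list(fc = fc, counts = tract$counts,
                        pair_totals = tract$pair_totals,
                        distances = distances)
    )
  }
  truth <- list(
    zip = list(alpha0 = config$zip_alpha0, alpha1 = config$zip_alpha1,
               omega = config$zip_omega),
    rho = list(within = config$rho_within, between = config$rho_between),
    effects = config$effects,
    sigma_control = generating_sigma(config, "control"),
    sigma_adversity = generating_sigma(config, "adversity")
  )
  structure(list(subjects = subjects, atlas = atlas, distances = distances,
                 config = config, truth = truth),
            class = "awfc_cohort")
}

#' @export
print.awfc_cohort <- function(x, ...) {
  groups <- vapply(x$subjects, `[[`, character(1), "group")
  cat(sprintf("<awfc_cohort: %d subjects (%d control, %d adversity), %d ROIs>\n",
              length(x$subjects), sum(groups == "control"),
              sum(groups == "adversity"), nrow(x$atlas)))
  invisible(x)
}

#' Write a cohort to disk in the manifest formats
#'
#' Per subject: `<id>_fc.tsv`, `<id>_counts.tsv`, `<id>_totals.tsv` and a
#' shared `grid.tsv`, referenced from `manifest.tsv`; the ground-truth
#' ledger goes to `truth.json`.
#'
#' @param cohort an `awfc_cohort`.
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_labeled_matrix(cohort$distances, file.path(dir, "grid.tsv"))
  rows <- lapply(cohort$subjects, function(s) {
    fc_f <- sprintf("%s_fc.tsv", s$subject_id)
    cn_f <- sprintf("%s_counts.tsv", s$subject_id)
    tt_f <- sprintf("%s_totals.tsv", s$subject_id)
    write_labeled_matrix(s$connectome$fc, file.path(dir, fc_f))
    write_voxel_counts(s$connectome$counts, file.path(dir, cn_f),
                       file.path(dir, tt_f))
    data.frame(subject_id = s$subject_id,
               mean_relative_displacement = s$mean_relative_displacement,
               epds = s$adversity$epds, stai = s$adversity$stai,
               ham_a = s$adversity$ham_a, madrs = s$adversity$madrs,
               low_income = s$adversity$low_income,
               group = s$group,
               fc_path = fc_f, counts_path = cn_f, totals_path = tt_f,
               grid_path = "grid.tsv", stringsAsFactors = FALSE)
  })
  manifest <- file.path(dir, "manifest.tsv")
  utils::write.table(do.call(rbind, rows), manifest, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- cohort$truth
  truth$sigma_control <- NULL
  truth$sigma_adversity <- NULL
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
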