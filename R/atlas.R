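#' Packaged 19-ROI resting-state atlas
#'
#' Nineteen group-level ROIs spanning five resting-state networks: default
#' mode (DMN), frontoparietal (FPN), limbic (LIM), ventral attention (VAN)
#' and dorsal attention (DAN). Each ROI carries its peak MNI coordinate
#' (millimetres) and cluster volume in voxels. Two abbreviations recur in
#' different networks (R-aOFG, R-pOFG), so the matrix `label` qualifies
#' those with the network name to keep labels unique.
#'
#' @return a data.frame with columns `roi_id`, `network`, `name`,
#'   `abbrev`, `label`, `x`, `y`, `z`, `volume_voxels`.
#' @export
default_atlas <- function() {
  atlas <- data.frame(
    roi_id  = 1:19,
    network = rep(c("DMN", "FPN", "LIM", "VAN", "DAN"), c(4L, 3L, 5L, 3L, 4L)),
    name = c(
      "Medial frontal gyrus", "Posterior cingulate cortex",
      "Right angular gyrus", "Left angular gyrus",
      "Left inferior frontal gyrus", "Lingual gyrus/cerebellum",
      "Right superior frontal gyrus",
      "Right posterior orbitofrontal gyrus",
      "Left posterior orbitofrontal gyrus",
      "Right superior temporal gyrus", "Left superior temporal gyrus",
      "Dorsolateral prefrontal cortex",
      "Left lingual gyrus/Cuneus-Lateral occipital cortex",
      "Right orbitofrontal gyrus", "Right cerebellum",
      "Right anterior orbitofrontal gyrus",
      "Right posterior orbitofrontal gyrus",
      "Right middle frontal gyrus", "Left inferior temporal gyrus"
    ),
    abbrev = c("MFG", "PCC", "R-AG", "L-AG",
               "L-IFG", "LG/CER", "R-SFG",
               "R-pOFG", "L-pOFG", "R-STG", "L-STG", "DLPFC",
               "L-LG/CU", "R-aOFG", "R-CER",
               "R-aOFG", "R-pOFG", "R-MFG", "L-ITG"),
    x = c(2, -2, 46, -46, -38, -6, 10, 18, -42, 46, -42, -2,
          -14, 14, 10, 14, 22, 38, -50),
    y = c(62, -62, -58, -58, 38, -74, 38, 38, 30, 14, 2, 46,
          -98, 70, -66, 58, 30, 42, -54),
    z = c(8, 24, 28, 28, 12, -12, 56, -24, -20, -44, -52, 32,
          -16, -16, 44, -20, -16, -16, -16),
    volume_voxels = c(7L, 5L, 6L, 5L, 12L, 12L, 10L, 12L, 12L, 11L, 12L,
                      12L, 20L, 5L, 20L, 9L, 14L, 14L, 14L),
    stringsAsFactors = FALSE
  )
  dup <- atlas$abbrev %in% atlas$abbrev[duplicated(atlas$abbrev)]
  atlas$label <- ifelse(dup, paste(atlas$abbrev, atlas$network, sep = "."),
                        atlas$abbrev)
  validate_atlas(atlas)
}

#' Validate an ROI atlas
#'
#' @param atlas a data.frame shaped like [default_atlas()].
#' @return the atlas, invisibly returned after checking that roi_ids are
#'   contiguous from 1, labels are unique, volumes are positive and every
#'   ROI belongs to exactly one network.
#' @export
validate_atlas <- function(atlas) {
  req <- c("roi_id", "network", "name", "abbrev", "label",
           "x", "y", "z", "volume_voxels")
  miss <- setdiff(req, names(atlas))
  if (length(miss)) stop("atlas is missing columns: ", paste(miss, collapse = ", "))
  if (!identical(as.integer(atlas$roi_id), seq_len(nrow(atlas)))) {
    stop("atlas roi_ids must be contiguous from 1")
  }
  if (anyDuplicated(atlas$label)) stop("atlas labels must be unique")
  if (any(atlas$volume_voxels < 1)) stop("atlas volumes must be positive")
  invisible(atlas)
}

#' Euclidean inter-ROI distances
#'
#' Straight-line distance between peak MNI coordinates, in millimetres — a
#' proxy for tract length when streamline-length summaries are not
#' available.
#'
#' @param atlas an ROI atlas (see [default_atlas()]).
#' @return a `labeled_matrix` of kind `distance`.
#' @export
euclidean_distances <- function(atlas) {
  validate_atlas(atlas)
  d <- as.matrix(stats::dist(as.matrix(atlas[, c("x", "y", "z")])))
  labeled_matrix(d, atlas$label, "distance")
}

#' Within-network ROI pairs
#'
#' Enumerates the unordered ROI pairs tested by the group comparison: by
#' default only pairs whose two ROIs share a network, ordered by network
#' (atlas order) then by roi_id.
#'
#' @param atlas an ROI atlas.
#' @param within_only if `FALSE`, all pairs are returned (cross-network
#'   testing is off by default in the pipeline).
#' @return data.frame with columns `start_roi`, `end_roi`, `network`
#'   (`"cross"` for cross-network pairs).
#' @export
network_pairs <- function(atlas, within_only = TRUE) {
  validate_atlas(atlas)
  idx <- utils::combn(nrow(atlas), 2L)
  df <- data.frame(
    start_roi = atlas$label[idx[1L, ]],
    end_roi   = atlas$label[idx[2L, ]],
    network   = ifelse(atlas$network[idx[1L, ]] == atlas$network[idx[2L, ]],
                       atlas$network[idx[1L, ]], "cross"),
    stringsAsFactors = FALSE
  )
  if (within_only) df <- df[df$network != "cross", , drop = FALSE]
  net_order <- match(df$network, unique(atlas$network))
  df <- df[order(net_order, match(df$start_roi, atlas$label),
                 match(df$end_roi, atlas$label)), , drop = FALSE]
  rownames(df) <- NULL
  df
}
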