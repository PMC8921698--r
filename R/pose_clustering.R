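# Common-scaffold clustering of docked poses: scaffold-atom RMSD matrix,
# agglomerative clustering at a distance cutoff, and selection of the
# cluster covering the most ligands.
#
# RMSD is computed WITHOUT superposition: docked poses share the receptor
# frame, and superposing them would erase exactly the binding-mode
# differences the clustering is meant to resolve.

#' Pose ensemble container
#'
#' @param ligand_id identifier.
#' @param poses list of `molecule3d` sharing atom count and element order.
#' @param scaffold_atoms heavy-atom indices of the common scaffold, valid
#'   for all poses.
#' @param pose_scores optional docking fitness per pose (higher is better).
#' @return a `pose_ensemble`.
#' @export
pose_ensemble <- function(ligand_id, poses, scaffold_atoms,
                          pose_scores = NULL) {
  stopifnot(length(poses) >= 1, length(scaffold_atoms) >= 1)
  els <- lapply(poses, function(p) p$atoms$element)
  if (length(unique(vapply(els, paste, "", collapse = ","))) != 1)
    stop("all poses must share atom count and element sequence")
  if (!is.null(pose_scores)) stopifnot(length(pose_scores) == length(poses))
  structure(list(ligand_id = as.character(ligand_id), poses = poses,
                 scaffold_atoms = as.integer(scaffold_atoms),
                 pose_scores = pose_scores),
            class = "pose_ensemble")
}

#' Scaffold RMSD between two poses
#'
#' `sqrt(mean || a_i - b_i ||^2)` over the scaffold atoms, in the shared
#' docking frame (no superposition). Symmetric.
#'
#' @param a,b `molecule3d` poses in the common receptor frame.
#' @param scaffold_atoms atom indices valid in both.
#' @return RMSD in Angstrom.
#' @export
scaffold_rmsd <- function(a, b, scaffold_atoms) {
  na <- nrow(a$atoms); nb <- nrow(b$atoms)
  if (any(scaffold_atoms < 1) || any(scaffold_atoms > min(na, nb)))
    stop("scaffold atom index out of range")
  A <- coords(a)[scaffold_atoms, , drop = FALSE]
  B <- coords(b)[scaffold_atoms, , drop = FALSE]
  sqrt(mean(rowSums((A - B)^2)))
}

# All-vs-all scaffold RMSD over the pooled poses of several ensembles.
pose_rmsd_matrix <- function(ensembles) {
  scaffold <- ensembles[[1]]$scaffold_atoms
  mats <- list()
  meta <- list()
  for (e in ensembles) {
    if (!identical(e$scaffold_atoms, scaffold))
      stop("all ensembles must share one scaffold_atoms definition")
    for (pi in seq_along(e$poses)) {
      mats[[length(mats) + 1L]] <-
        as.numeric(t(coords(e$poses[[pi]])[scaffold, , drop = FALSE]))
      meta[[length(meta) + 1L]] <- data.frame(ligand_id = e$ligand_id,
                                              pose = pi)
    }
  }
  P <- do.call(rbind, mats)
  # ||P_i - P_j|| over flattened coords equals sqrt(m) * RMSD
  d <- dist(P) / sqrt(length(scaffold))
  list(dist = d, meta = do.call(rbind, meta))
}

#' Agglomerative clustering of docked poses
#'
#' Builds the pairwise scaffold-RMSD matrix over all poses of all ligands
#' and merges agglomeratively until no inter-cluster linkage distance is at
#' or below `cutoff`. Deterministic (stats::hclust with documented
#' tie-breaking; labels are dense from 1 in order of first appearance).
#'
#' @param ensembles list of `pose_ensemble` sharing one scaffold map.
#' @param cutoff linkage-distance cutoff, Angstrom.
#' @param linkage "complete" (default), "average" or "single".
#' @return a `cluster_result`: labels (per pooled pose), cutoff, linkage,
#'   `members` (data.frame ligand_id, pose, cluster).
#' @export
cluster_poses <- function(ensembles, cutoff = 3.5,
                          linkage = c("complete", "average", "single")) {
  linkage <- match.arg(linkage)
  pm <- pose_rmsd_matrix(ensembles)
  n <- nrow(pm$meta)
  if (n < 2) {
    warning("fewer than 2 poses: single cluster", call. = FALSE)
    labels <- rep(1L, n)
  } else {
    hc <- hclust(pm$dist, method = linkage)
    raw <- cutree(hc, h = cutoff)
    labels <- match(raw, unique(raw))  # dense, order of first appearance
  }
  members <- cbind(pm$meta, cluster = labels)
  structure(list(labels = labels, cutoff = cutoff, linkage = linkage,
                 members = members),
            class = "cluster_result")
}

#' Select the representative (max-membership) cluster
#'
#' Chooses the cluster covering the largest number of distinct ligands
#' (ties: larger total pose count, then lowest cluster id). Within the
#' winning cluster each covered ligand contributes its highest-scoring pose
#' (its lowest pose index when scores are absent).
#'
#' @param result a `cluster_result`.
#' @param ensembles the ensembles `result` was computed over.
#' @return list(cluster, representatives (data.frame ligand_id, pose),
#'   coverage, n_ligands, covered).
#' @export
select_representative_cluster <- function(result, ensembles) {
  mem <- result$members
  stats_by_cluster <- do.call(rbind, lapply(split(mem, mem$cluster),
    function(d) data.frame(cluster = d$cluster[1],
                           n_ligands = length(unique(d$ligand_id)),
                           n_poses = nrow(d))))
  o <- order(-stats_by_cluster$n_ligands, -stats_by_cluster$n_poses,
             stats_by_cluster$cluster)
  win <- stats_by_cluster$cluster[o[1]]
  inwin <- mem[mem$cluster == win, , drop = FALSE]
  scores <- setNames(lapply(ensembles, function(e) e$pose_scores),
                     vapply(ensembles, function(e) e$ligand_id, ""))
  reps <- do.call(rbind, lapply(split(inwin, inwin$ligand_id), function(d) {
    sc <- scores[[d$ligand_id[1]]]
    pick <- if (is.null(sc)) min(d$pose) else
      d$pose[order(-sc[d$pose], d$pose)[1]]
    data.frame(ligand_id = d$ligand_id[1], pose = pick)
  }))
  rownames(reps) <- NULL
  n_total <- length(ensembles)
  list(cluster = win, representatives = reps,
       coverage = nrow(reps) / n_total, n_ligands = n_total,
       covered = nrow(reps))
}
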