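# Alignment-independent correlogram encoding of interaction fields.
#
# Fields are first discretized into a small set of energetically relevant,
# spatially spread nodes (an AMANDA-style greedy extraction), then encoded
# as maximum auto-/cross-correlograms: for every ordered probe pair and
# node-node distance bin, the descriptor value is the largest product of
# the two node energies whose distance falls in that bin. Because only
# inter-node distances enter, the encoding is exactly invariant under rigid
# motion of the molecule. Node-pair provenance is kept per nonzero entry so
# model peaks can be mapped back onto atoms (hotspot back-mapping).

BLOCK_ORDER <- c("DRY-DRY", "O-O", "N1-N1", "TIP-TIP", "DRY-O", "DRY-N1",
                 "DRY-TIP", "O-N1", "O-TIP", "N1-TIP")

#' Extract relevant field nodes (AMANDA-style)
#'
#' Candidate nodes are the lattice nodes at or below the probe's energy
#' cutoff. Selection is greedy: the first pick is the deepest minimum, and
#' every subsequent pick maximizes
#' `(1 - w) * |E| / max|E| + w * d_min(candidate, selected) / d_ref`,
#' trading field intensity against spatial coverage (`d_ref` is the grid
#' diagonal). Deterministic with lowest-index tie-breaks.
#'
#' @param mif a `mif`.
#' @param max_nodes maximum nodes retained.
#' @param coverage_weight `w` above, in `[0, 1]`.
#' @return data.frame with columns x, y, z, energy (possibly 0 rows).
#' @export
extract_nodes <- function(mif, max_nodes = 100, coverage_weight = 0.5) {
  keep <- which(mif$energies <= mif$probe$energy_cutoff)
  empty <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      energy = numeric(0))
  if (!length(keep)) return(empty)
  nodes <- grid_nodes(mif$grid)[keep, , drop = FALSE]
  e <- mif$energies[keep]
  w <- coverage_weight
  d_ref <- sqrt(sum(((mif$grid$dims - 1L) * mif$grid$spacing)^2))
  if (d_ref <= 0) d_ref <- 1
  intensity <- abs(e) / max(abs(e))

  n <- length(e)
  sel <- integer(0)
  first <- which.min(e)           # deepest; which.min takes lowest index on ties
  sel <- first
  if (n > 1 && max_nodes > 1) {
    dmin <- cross_dist(nodes, nodes[first, , drop = FALSE])[, 1]
    while (length(sel) < min(max_nodes, n)) {
      score <- (1 - w) * intensity + w * dmin / d_ref
      score[sel] <- -Inf
      pick <- which.max(score)
      sel <- c(sel, pick)
      dmin <- pmin(dmin, cross_dist(nodes, nodes[pick, , drop = FALSE])[, 1])
    }
  }
  data.frame(x = nodes[sel, 1], y = nodes[sel, 2], z = nodes[sel, 3],
             energy = e[sel])
}

#' Correlogram variable layout
#'
#' @param bin_width bin width, Angstrom.
#' @param max_dist largest encoded distance, Angstrom.
#' @return data.frame (block, bin, lo, hi, name), one row per variable,
#'   ordered block-major in the canonical block order.
#' @export
correlogram_layout <- function(bin_width = 0.4, max_dist = 30) {
  n_bins <- as.integer(ceiling(max_dist / bin_width - 1e-9))
  lo <- (seq_len(n_bins) - 1L) * bin_width
  out <- do.call(rbind, lapply(BLOCK_ORDER, function(b)
    data.frame(block = b, bin = seq_len(n_bins), lo = lo,
               hi = lo + bin_width)))
  out$name <- sprintf("%s_%.1f_%.1f", out$block, out$lo, out$hi)
  out
}

#' Encode node sets as a maximum auto/cross-correlogram
#'
#' For each probe-pair block and each distance bin `[k w, (k+1) w)`, the
#' value is the maximum over qualifying node pairs of the product of the
#' two node energies (both negative, hence the product is >= 0); bins with
#' no pair are 0. Auto-blocks use unordered distinct pairs. Provenance
#' records the argmax pair per nonzero entry.
#'
#' @param nodes_by_probe named list (DRY, O, N1, TIP) of node data.frames
#'   as returned by [extract_nodes()]; missing probes count as empty.
#' @param bin_width bin width, Angstrom (default 0.4).
#' @param max_dist largest encoded distance, Angstrom.
#' @return a `correlogram` object: `values` (named numeric, length
#'   10 x n_bins), `layout`, `provenance` (data.frame of argmax pairs).
#' @export
encode <- function(nodes_by_probe, bin_width = 0.4, max_dist = 30) {
  if (bin_width <= 0) stop("bin_width must be positive")
  layout <- correlogram_layout(bin_width, max_dist)
  n_bins <- max(layout$bin)
  values <- setNames(numeric(nrow(layout)), layout$name)
  prov <- list()
  get_nodes <- function(p) {
    nd <- nodes_by_probe[[p]]
    if (is.null(nd)) data.frame(x = numeric(0), y = numeric(0),
                                z = numeric(0), energy = numeric(0)) else nd
  }
  for (block in BLOCK_ORDER) {
    pq <- strsplit(block, "-")[[1]]
    a <- get_nodes(pq[1]); b <- get_nodes(pq[2])
    if (!nrow(a) || !nrow(b)) next
    auto <- pq[1] == pq[2]
    D <- cross_dist(a[, 1:3], b[, 1:3])
    P <- outer(a$energy, b$energy)
    if (auto) {
      if (nrow(a) < 2) next
      keep <- upper.tri(D)
    } else keep <- matrix(TRUE, nrow(a), nrow(b))
    idx <- which(keep & D < max_dist, arr.ind = TRUE)
    if (!nrow(idx)) next
    d <- D[idx]; p <- P[idx]
    bin <- pmin(floor(d / bin_width) + 1L, n_bins)
    base <- match(block, BLOCK_ORDER) - 1L
    for (bb in unique(bin)) {
      rows <- which(bin == bb)
      best <- rows[which.max(p[rows])]
      col <- base * n_bins + bb
      values[col] <- p[best]
      if (p[best] > 0) {
        i <- idx[best, 1]; j <- idx[best, 2]
        prov[[length(prov) + 1L]] <- data.frame(
          block = block, bin = bb, lo = layout$lo[col], hi = layout$hi[col],
          xi = a$x[i], yi = a$y[i], zi = a$z[i], ei = a$energy[i],
          xj = b$x[j], yj = b$y[j], zj = b$z[j], ej = b$energy[j],
          dist = d[best], value = p[best])
      }
    }
  }
  provenance <- if (length(prov)) do.call(rbind, prov) else
    data.frame(block = character(0), bin = integer(0), lo = numeric(0),
               hi = numeric(0), xi = numeric(0), yi = numeric(0),
               zi = numeric(0), ei = numeric(0), xj = numeric(0),
               yj = numeric(0), zj = numeric(0), ej = numeric(0),
               dist = numeric(0), value = numeric(0))
  structure(list(values = values, layout = layout, provenance = provenance,
                 bin_width = bin_width, max_dist = max_dist),
            class = "correlogram")
}

#' Configuration for descriptor-matrix construction
#'
#' @param spacing,margin lattice parameters, Angstrom.
#' @param max_nodes,coverage_weight node-extraction parameters.
#' @param bin_width,max_dist correlogram parameters, Angstrom.
#' @param probes list of `probe_params`.
#' @param lj_table per-element LJ parameters.
#' @param charge_source free-text record of where partial charges came
#'   from (the charge model used upstream is part of the model definition).
#' @return a config list.
#' @export
grind_config <- function(spacing = 0.5, margin = 4.0, max_nodes = 100,
                         coverage_weight = 0.5, bin_width = 0.4,
                         max_dist = 30, probes = default_probes(),
                         lj_table = default_lj_table(),
                         charge_source = "input SDF (zero-filled if absent)") {
  list(spacing = spacing, margin = margin, max_nodes = max_nodes,
       coverage_weight = coverage_weight, bin_width = bin_width,
       max_dist = max_dist, probes = probes, lj_table = lj_table,
       charge_source = charge_source)
}

#' Synthetic-scale GRIND configuration
#'
#' The toy ligands of [gen_ligand_set()] carry at most four genuine field
#' minima per probe, so node extraction is capped at 4 nodes per probe:
#' with the drug-scale default of 100 the extractor would keep every
#' lattice node of every basin, occupy nearly every distance bin for every
#' compound and drown the planted signal in bin collisions. All other
#' parameters keep their defaults.
#'
#' The lattice margin is 3 Angstrom (default 4): the toy payload wells lie
#' well inside the bounding box, and no probe can pass its cutoff further
#' than ~3 Angstrom from the outermost atom.
#'
#' @param ... overrides passed to [grind_config()].
#' @return a config list.
#' @export
synthetic_grind_config <- function(...) {
  grind_config(max_nodes = 4, margin = 3, ...)
}

#' Build the GRIND descriptor matrix for a set of compounds
#'
#' Runs flag assignment, lattice construction, the four probe fields, node
#' extraction and correlogram encoding per compound (one representative
#' pose each). Compounds whose encoding fails are skipped with a logged
#' reason; if fewer than 80 percent succeed the build aborts.
#'
#' @param mols list of `molecule3d`.
#' @param config see [grind_config()].
#' @param verbose print per-compound progress.
#' @return a `grind_matrix`: `X` (compounds x variables), `layout`,
#'   `provenance` (per-compound list), `config`, `failed` (named reasons).
#' @export
build_descriptor_matrix <- function(mols, config = grind_config(),
                                    verbose = FALSE) {
  stopifnot(length(mols) >= 1)
  layout <- correlogram_layout(config$bin_width, config$max_dist)
  ids <- vapply(mols, function(m) if (is.null(m$id)) "unknown" else m$id,
                character(1))
  X <- matrix(0, nrow = length(mols), ncol = nrow(layout),
              dimnames = list(ids, layout$name))
  provenance <- vector("list", length(mols))
  names(provenance) <- ids
  ok <- rep(TRUE, length(mols))
  failed <- character(0)
  for (k in seq_along(mols)) {
    res <- tryCatch({
      mol <- mols[[k]]
      if (!any(mol$atoms$hydrophobic | mol$atoms$hba | mol$atoms$hbd))
        mol <- assign_atom_flags(mol)
      grid <- make_grid(mol, config$spacing, config$margin)
      mifs <- compute_mif_set(mol, config$probes, grid, config$lj_table)
      nodes <- lapply(mifs, extract_nodes, max_nodes = config$max_nodes,
                      coverage_weight = config$coverage_weight)
      encode(nodes, config$bin_width, config$max_dist)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      ok[k] <- FALSE
      failed[length(failed) + 1L] <- conditionMessage(res)
      names(failed)[length(failed)] <- ids[k]
      if (verbose) message("skipped ", ids[k], ": ", conditionMessage(res))
      next
    }
    X[k, ] <- res$values
    provenance[[k]] <- res$provenance
    if (verbose) message("encoded ", ids[k])
  }
  if (any(!ok)) {
    if (sum(ok) < 0.8 * length(mols))
      stop(sprintf("descriptor build failed for %d of %d compounds",
                   sum(!ok), length(mols)))
    X <- X[ok, , drop = FALSE]
    provenance <- provenance[ok]
  }
  structure(list(X = X, layout = layout, provenance = provenance,
                 config = config, failed = failed),
            class = "grind_matrix")
}

#' Consistency trim of a GRIND descriptor matrix
#'
#' Drops variables that are nonzero in fewer than `min_support` of the
#' compounds (and constant columns). The proprietary CLACC encoding selects
#' nodes that are *consistent* across compounds; with the fixed-binning
#' encoding used here the same goal is served at the variable level:
#' a bin populated in only one or two compounds cannot express a
#' structure-activity trend, but after autoscaling it acts as a
#' per-compound dummy and destabilizes cross-validation.
#'
#' Near-constant variables are removed on a *relative* scale
#' (`min_rel_range`): a bin whose value varies by a fraction of a percent
#' across all compounds (numerical jitter from distant atoms) carries no
#' structure-activity information, but autoscaling would inflate it into a
#' per-compound dummy.
#'
#' @param gm a `grind_matrix`.
#' @param min_support minimum fraction of compounds with a nonzero entry.
#' @param min_rel_range minimum (max - min) / max value spread.
#' @return `gm` with `X` and `layout` reduced.
#' @export
trim_correlogram <- function(gm, min_support = 0.1, min_rel_range = 0.05) {
  support <- colMeans(gm$X != 0)
  rng <- apply(gm$X, 2, function(col) {
    top <- max(abs(col))
    if (top == 0) 0 else (max(col) - min(col)) / top
  })
  keep <- support >= min_support & rng >= min_rel_range
  gm$X <- gm$X[, keep, drop = FALSE]
  gm$layout <- gm$layout[keep, , drop = FALSE]
  gm
}

#' Write a descriptor matrix (and provenance) as CSV
#'
#' @param gm a `grind_matrix`.
#' @param path CSV path for the matrix; provenance goes to
#'   `<path>_provenance.csv`.
#' @export
write_grind_csv <- function(gm, path) {
  df <- data.frame(compound = rownames(gm$X), gm$X, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  prov <- do.call(rbind, lapply(names(gm$provenance), function(id) {
    p <- gm$provenance[[id]]
    if (is.null(p) || !nrow(p)) return(NULL)
    cbind(compound = id, p)
  }))
  if (!is.null(prov))
    write.csv(prov, sub("\\.csv$", "_provenance.csv", path),
              row.names = FALSE)
  invisible(path)
}
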