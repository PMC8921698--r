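# Fixture molecules (built in code) and independent brute-force oracles.

make_methane <- function() {
  d <- 1.09 / sqrt(3)
  molecule3d("methane", data.frame(
    element = c("C", "H", "H", "H", "H"),
    x = c(0, d, d, -d, -d), y = c(0, d, -d, d, -d),
    z = c(0, d, -d, -d, d), charge = 0),
    bonds = data.frame(i = 1, j = 2:5, order = 1))
}

make_benzene <- function() {
  ang <- 2 * pi * (0:5) / 6
  molecule3d("benzene", data.frame(
    element = rep(c("C", "H"), each = 6),
    x = c(1.39 * cos(ang), 2.48 * cos(ang)),
    y = c(1.39 * sin(ang), 2.48 * sin(ang)),
    z = 0, charge = 0),
    bonds = data.frame(i = c(1:6, 1:6), j = c(2:6, 1, 7:12),
                       order = c(rep(1L, 6), rep(1L, 6))))
}

make_acetone <- function() {
  molecule3d("acetone", data.frame(
    element = c("C", "O", "C", "C"),
    x = c(0, 0, -1.29, 1.29), y = c(0, 1.22, -0.75, -0.75),
    z = 0, charge = 0),
    bonds = data.frame(i = c(1, 1, 1), j = c(2, 3, 4), order = c(2, 1, 1)))
}

make_pyridine <- function() {
  ang <- 2 * pi * (0:5) / 6
  el <- c("N", rep("C", 5), rep("H", 5))
  molecule3d("pyridine", data.frame(
    element = el,
    x = c(1.39 * cos(ang), 2.48 * cos(ang[-1])),
    y = c(1.39 * sin(ang), 2.48 * sin(ang[-1])),
    z = 0, charge = 0),
    bonds = data.frame(i = c(1:6, 2:6), j = c(2:6, 1, 7:11),
                       order = 1))
}

# random flagged molecule for field oracles (no bonds: bare N/O count as
# acceptors, bare C/S as hydrophobic under the default rules)
random_toy_molecule <- function(seed, n_atoms = 6) {
  withr::with_seed(seed, {
    mol <- molecule3d(
      sprintf("toy%03d", seed),
      data.frame(element = sample(c("C", "N", "O", "S"), n_atoms,
                                  replace = TRUE),
                 x = runif(n_atoms, 0, 6), y = runif(n_atoms, 0, 6),
                 z = runif(n_atoms, 0, 6),
                 charge = round(runif(n_atoms, -0.5, 0.5), 3)),
      bonds = NULL)
    suppressWarnings(assign_atom_flags(mol))
  })
}

# --- independent oracles ---------------------------------------------------

# scalar double-loop probe energy per the stated model (no vectorization,
# no neighbor lists); mirrors the published contract, not the implementation
oracle_probe_energy <- function(node, mol, probe,
                                lj_table = default_lj_table()) {
  a <- mol$atoms
  e <- 0
  clamped <- FALSE
  for (i in seq_len(nrow(a))) {
    r <- sqrt(sum((node - c(a$x[i], a$y[i], a$z[i]))^2))
    # LJ set
    in_lj <- a$heavy[i] && (probe$senses != "hydrophobic" || a$hydrophobic[i])
    if (in_lj && r <= 8) {
      row <- match(a$element[i], lj_table$element)
      if (is.na(row)) row <- match("C", lj_table$element)
      rmin <- (lj_table$rmin[row] + probe$lj_rmin) / 2
      eps <- sqrt(lj_table$eps[row] * probe$lj_eps)
      rr <- rmin / max(r, 1e-12)
      e <- e + eps * (rr^12 - 2 * rr^6)
      if (r < 0.5) clamped <- TRUE
    }
    if (probe$probe_charge != 0 && a$charge[i] != 0 && r <= 8) {
      e <- e + 332.0 * probe$probe_charge * a$charge[i] /
        (4 * max(r, 1e-12)^2)
      if (r < 0.5) clamped <- TRUE
    }
    if (probe$hb_emin != 0 && probe$senses %in% c("hba", "hbd") &&
        a$heavy[i] && isTRUE(a[[probe$senses]][i]) && r <= 5) {
      rr <- probe$hb_req / max(r, 1e-12)
      e <- e + probe$hb_emin * (5 * rr^12 - 6 * rr^10)
      if (r < 0.5) clamped <- TRUE
    }
  }
  if (clamped) e <- 5
  min(max(e, -100), 5)
}

oracle_mif <- function(mol, probe, grid, lj_table = default_lj_table()) {
  nodes <- grid_nodes(grid)
  e <- vapply(seq_len(nrow(nodes)), function(k)
    oracle_probe_energy(nodes[k, ], mol, probe, lj_table), numeric(1))
  if (isTRUE(probe$surface_shell)) {
    xyz <- as.matrix(mol$atoms[mol$atoms$heavy, c("x", "y", "z")])
    for (k in seq_len(nrow(nodes))) {
      dmin <- min(sqrt(rowSums((xyz - matrix(nodes[k, ], nrow(xyz), 3,
                                             byrow = TRUE))^2)))
      if (dmin < probe$r_probe || dmin > probe$r_probe + grid$spacing)
        e[k] <- 5
    }
  }
  e
}

# exhaustive pair search over node sets
oracle_correlogram <- function(nodes_by_probe, bin_width = 0.4,
                               max_dist = 30) {
  layout <- correlogram_layout(bin_width, max_dist)
  vals <- stats::setNames(numeric(nrow(layout)), layout$name)
  blocks <- unique(layout$block)
  for (block in blocks) {
    pq <- strsplit(block, "-")[[1]]
    a <- nodes_by_probe[[pq[1]]]
    b <- nodes_by_probe[[pq[2]]]
    if (is.null(a) || is.null(b) || !nrow(a) || !nrow(b)) next
    for (i in seq_len(nrow(a))) {
      jseq <- if (pq[1] == pq[2]) seq_len(nrow(b)) else seq_len(nrow(b))
      for (j in jseq) {
        if (pq[1] == pq[2] && j <= i) next
        d <- sqrt((a$x[i] - b$x[j])^2 + (a$y[i] - b$y[j])^2 +
                    (a$z[i] - b$z[j])^2)
        if (d >= max_dist) next
        bin <- floor(d / bin_width) + 1L
        nm <- layout$name[layout$block == block & layout$bin == bin]
        p <- a$energy[i] * b$energy[j]
        if (p > vals[nm]) vals[nm] <- p
      }
    }
  }
  vals
}

# per-outcome tally: build explicit outcome vectors, count, apply the
# published definitions
oracle_metrics_from_counts <- function(tp, fp, tn, fn) {
  truth <- c(rep(1, tp), rep(0, fp), rep(0, tn), rep(1, fn))
  pred <- c(rep(1, tp), rep(1, fp), rep(0, tn), rep(0, fn))
  TP <- sum(truth == 1 & pred == 1); FP <- sum(truth == 0 & pred == 1)
  TN <- sum(truth == 0 & pred == 0); FN <- sum(truth == 1 & pred == 0)
  den <- as.numeric(TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
  list(se = TP / (TP + FN), sp = TN / (TN + FP),
       acc = (TP + TN) / length(truth),
       mcc = if (den == 0) 0 else (as.numeric(TP) * TN - as.numeric(FP) * FN) / sqrt(den))
}

# frozen ligand-set fixture shared by slow tests
cached_ligand_run <- local({
  cache <- list()
  function(noise_sd, seed, n = 60) {
    key <- paste(noise_sd, seed, n)
    if (is.null(cache[[key]])) {
      spec <- default_pharmacophore_spec(noise_sd = noise_sd, seed = seed)
      ls1 <- gen_ligand_set(spec, n)
      gm <- trim_correlogram(
        build_descriptor_matrix(ls1$molecules, synthetic_grind_config()))
      cache[[key]] <<- list(ligands = ls1, gm = gm)
    }
    cache[[key]]
  }
})
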