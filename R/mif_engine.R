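# GRID-like molecular interaction fields on a regular lattice.
#
# Four probes are provided: DRY (hydrophobic), O (sp2 carbonyl oxygen,
# hydrogen-bond acceptor probe sensing donors), N1 (amide nitrogen, donor
# probe sensing acceptors) and TIP (molecular-shape/steric probe evaluated
# on the solvent-accessible shell). The total energy at a node is
#
#   E = sum E_lj + sum E_el + sum E_hb
#
# with a 12-6 Lennard-Jones term (Lorentz-Berthelot combination of probe
# and per-element parameters), a Coulomb term with distance-dependent
# dielectric eps(r) = 4r, and a 12-10 hydrogen-bond term between the probe
# and atoms whose pharmacophoric flag complements it. The literature-quoted
# per-probe energy cutoffs used downstream for node extraction are -0.5
# (DRY), -2.6 (O), -4.2 (N1) and -0.74 (TIP) kcal/mol. The GRID parameter
# sets themselves are proprietary, so the small per-element table below is
# this package's own versioned parameterization: the downstream encoding
# only requires well-behaved, minima-bearing fields.

COULOMB_K <- 332.0      # kcal * Angstrom / (mol * e^2)
LJ_TRUNCATION <- 8.0    # Angstrom
HB_TRUNCATION <- 5.0    # Angstrom
R_CLAMP <- 0.5          # below this node-atom distance the node is capped
ENERGY_FLOOR <- -100
ENERGY_CEILING <- 5

#' Per-element Lennard-Jones parameters
#'
#' `rmin` is the homonuclear minimum-energy distance (Angstrom) and `eps`
#' the well depth (kcal/mol). Combined with probe parameters by
#' Lorentz-Berthelot rules. Unlisted elements fall back to carbon values.
#'
#' @return data.frame with columns element, rmin, eps.
#' @export
default_lj_table <- function() {
  data.frame(
    element = c("C", "N", "O", "S", "F", "Cl", "Br", "P", "H"),
    rmin = c(3.8, 3.6, 3.4, 4.0, 3.3, 3.9, 4.2, 4.1, 2.0),
    eps = c(0.10, 0.16, 0.20, 0.25, 0.08, 0.30, 0.40, 0.20, 0.02))
}

#' Probe parameters for the four GRIND probes
#'
#' @param name one of "DRY", "O", "N1", "TIP".
#' @return a `probe_params` list: `name`, `energy_cutoff` (kcal/mol),
#'   `lj_eps`, `lj_rmin`, `probe_charge`, `hb_emin`, `hb_req`, `senses`
#'   (which atom flag the LJ/hb terms address), `surface_shell` (TIP only)
#'   and `r_probe` (shell inner radius).
#' @export
default_probe_params <- function(name = c("DRY", "O", "N1", "TIP")) {
  name <- match.arg(name)
  p <- switch(name,
    DRY = list(name = "DRY", energy_cutoff = -0.5, lj_eps = 0.25,
               lj_rmin = 4.0, probe_charge = 0, hb_emin = 0, hb_req = 2.8,
               senses = "hydrophobic", surface_shell = FALSE, r_probe = NA),
    O = list(name = "O", energy_cutoff = -2.6, lj_eps = 0.20,
             lj_rmin = 3.4, probe_charge = -0.45, hb_emin = 2.5,
             hb_req = 2.8, senses = "hbd", surface_shell = FALSE,
             r_probe = NA),
    N1 = list(name = "N1", energy_cutoff = -4.2, lj_eps = 0.16,
              lj_rmin = 3.5, probe_charge = 0.45, hb_emin = 2.5,
              hb_req = 2.8, senses = "hba", surface_shell = FALSE,
              r_probe = NA),
    TIP = list(name = "TIP", energy_cutoff = -0.74, lj_eps = 0.15,
               lj_rmin = 3.5, probe_charge = 0, hb_emin = 0, hb_req = 2.8,
               senses = "heavy", surface_shell = TRUE, r_probe = 3.5))
  stopifnot(p$energy_cutoff < 0, p$lj_rmin > 0)
  structure(p, class = "probe_params")
}

#' All four default probes
#' @return named list of `probe_params`.
#' @export
default_probes <- function() {
  setNames(lapply(c("DRY", "O", "N1", "TIP"), default_probe_params),
           c("DRY", "O", "N1", "TIP"))
}

#' Build a lattice covering a molecule
#'
#' Axis-aligned lattice covering the atom bounding box inflated by `margin`
#' on each side. The origin is snapped down to an integer multiple of the
#' spacing in world coordinates, so the lattice phase is absolute: two
#' molecules expressed in the same frame sample the identical set of node
#' positions, and translating molecule and grid jointly by a lattice vector
#' reproduces the energy array exactly.
#'
#' @param mol a `molecule3d`.
#' @param spacing lattice spacing, Angstrom.
#' @param margin box inflation per side, Angstrom.
#' @return a `grid_spec` with fields origin, spacing, dims.
#' @export
make_grid <- function(mol, spacing = 0.5, margin = 4.0) {
  if (spacing <= 0) stop("spacing must be positive")
  xyz <- coords(mol)
  lo <- apply(xyz, 2, min) - margin
  hi <- apply(xyz, 2, max) + margin
  origin <- floor(lo / spacing + 1e-9) * spacing
  dims <- pmax(1L, as.integer(ceiling((hi - origin) / spacing - 1e-9)) + 1L)
  grid_spec(origin, spacing, dims)
}

#' @rdname make_grid
#' @param origin lattice origin (3-vector, Angstrom).
#' @param dims node counts per axis.
#' @export
grid_spec <- function(origin, spacing, dims) {
  stopifnot(spacing > 0, all(dims >= 1))
  structure(list(origin = as.numeric(origin), spacing = spacing,
                 dims = as.integer(dims)),
            class = "grid_spec")
}

#' Node positions of a lattice
#'
#' Nodes are ordered with the x index varying fastest, then y, then z.
#'
#' @param grid a `grid_spec`.
#' @return matrix (n_nodes x 3).
#' @export
grid_nodes <- function(grid) {
  ax <- lapply(1:3, function(k)
    grid$origin[k] + grid$spacing * (seq_len(grid$dims[k]) - 1L))
  g <- expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]],
                   KEEP.OUT.ATTRS = FALSE)
  as.matrix(g)
}

lj_params_for <- function(elements, probe, lj_table) {
  i <- match(elements, lj_table$element)
  i[is.na(i)] <- match("C", lj_table$element)
  list(rmin = (lj_table$rmin[i] + probe$lj_rmin) / 2,
       eps = sqrt(lj_table$eps[i] * probe$lj_eps))
}

# Vectorized field evaluation: energies at each row of `nodes`. `D` (the
# node x atom distance matrix) can be supplied to share it across probes.
mif_energies <- function(nodes, mol, probe, lj_table = default_lj_table(),
                         spacing = NULL, D = NULL) {
  a <- mol$atoms
  nodes <- matrix(as.numeric(nodes), ncol = 3)
  n <- nrow(nodes)
  if (is.null(D)) D <- cross_dist(nodes, coords(mol))
  e_total <- numeric(n)

  # sparse accumulation of a pairwise term over selected atom columns
  sum_term <- function(cols, cutoff, fun) {
    out <- numeric(n)
    if (!length(cols)) return(out)
    Ds <- D[, cols, drop = FALSE]
    idx <- which(Ds <= cutoff)
    if (!length(idx)) return(out)
    ci <- (idx - 1L) %/% n + 1L
    ri <- idx - (ci - 1L) * n
    vals <- fun(pmax(Ds[idx], 1e-12), cols[ci])
    agg <- rowsum(vals, ri)
    out[as.integer(rownames(agg))] <- agg
    out
  }

  heavy <- which(a$heavy)
  lj_idx <- switch(probe$senses,
                   hydrophobic = which(a$heavy & a$hydrophobic),
                   heavy)
  involved <- lj_idx

  # Lennard-Jones over the sensed heavy-atom set
  if (length(lj_idx)) {
    lj <- lj_params_for(a$element, probe, lj_table)
    e_total <- e_total + sum_term(lj_idx, LJ_TRUNCATION, function(d, cols) {
      r6 <- (lj$rmin[cols] / d)^6
      lj$eps[cols] * (r6 * r6 - 2 * r6)
    })
  }

  # Electrostatics with distance-dependent dielectric eps(r) = 4r
  if (probe$probe_charge != 0 && any(a$charge != 0)) {
    qi <- which(a$charge != 0)
    involved <- union(involved, qi)
    e_total <- e_total + sum_term(qi, LJ_TRUNCATION, function(d, cols)
      COULOMB_K * probe$probe_charge * a$charge[cols] / (4 * d^2))
  }

  # 12-10 hydrogen bond term against complementary atoms
  if (probe$hb_emin != 0 && probe$senses %in% c("hba", "hbd")) {
    hb_idx <- which(a$heavy & a[[probe$senses]])
    involved <- union(involved, hb_idx)
    e_total <- e_total + sum_term(hb_idx, HB_TRUNCATION, function(d, cols) {
      rr <- probe$hb_req / d
      probe$hb_emin * (5 * rr^12 - 6 * rr^10)
    })
  }

  # nodes on top of an interacting atom cap at the storage ceiling
  clamped <- sum_term(involved, R_CLAMP, function(d, cols)
    rep(1, length(d))) > 0

  # TIP: restrict to the solvent-accessible shell
  if (isTRUE(probe$surface_shell)) {
    if (is.null(spacing)) spacing <- 0.5
    dmin <- rep(Inf, n)
    for (k in heavy) dmin <- pmin(dmin, D[, k])
    outside <- dmin < probe$r_probe | dmin > probe$r_probe + spacing
    e_total[outside] <- ENERGY_CEILING
  }
  e_total[clamped] <- ENERGY_CEILING
  clamp(e_total, ENERGY_FLOOR, ENERGY_CEILING)
}

#' Probe interaction energy at a single point
#'
#' Reference scalar entry point; [compute_mif()] evaluates the same model
#' on a whole lattice.
#'
#' @param node position (3-vector, Angstrom).
#' @param mol a `molecule3d` with atom flags assigned.
#' @param probe a `probe_params`.
#' @param lj_table per-element LJ parameters.
#' @return energy in kcal/mol (clamped to storage floor/ceiling).
#' @export
probe_energy <- function(node, mol, probe, lj_table = default_lj_table()) {
  as.numeric(mif_energies(matrix(node, ncol = 3), mol, probe, lj_table))
}

#' Compute a molecular interaction field
#'
#' @param mol a `molecule3d` with flags assigned.
#' @param probe a `probe_params`.
#' @param grid a `grid_spec`; defaults to [make_grid()] of the molecule.
#' @param lj_table per-element LJ parameters.
#' @return a `mif` object: `grid`, `probe`, `energies` (one value per node,
#'   ordered as [grid_nodes()]).
#' @export
compute_mif <- function(mol, probe, grid = make_grid(mol),
                        lj_table = default_lj_table()) {
  compute_mif_set(mol, list(probe), grid, lj_table)[[1]]
}

#' Compute several interaction fields on a shared lattice
#'
#' Evaluates multiple probes while computing the node-atom distance matrix
#' only once (the dominant cost for dense lattices).
#'
#' @param mol a `molecule3d` with flags assigned.
#' @param probes list of `probe_params`.
#' @param grid a `grid_spec`.
#' @param lj_table per-element LJ parameters.
#' @return list of `mif`, named after the probes when `probes` is named.
#' @export
compute_mif_set <- function(mol, probes, grid = make_grid(mol),
                            lj_table = default_lj_table()) {
  xyz <- coords(mol)
  hi <- grid$origin + (grid$dims - 1L) * grid$spacing
  if (any(apply(xyz, 2, min) < grid$origin) || any(apply(xyz, 2, max) > hi))
    warning("grid does not cover the molecule", call. = FALSE)
  nodes <- grid_nodes(grid)
  D <- cross_dist(nodes, xyz)
  out <- lapply(probes, function(p)
    structure(list(grid = grid, probe = p,
                   energies = mif_energies(nodes, mol, p, lj_table,
                                           spacing = grid$spacing, D = D)),
              class = "mif"))
  names(out) <- names(probes)
  out
}

#' @export
print.mif <- function(x, ...) {
  cat(sprintf("<mif %s: %d nodes, min %.3f kcal/mol, %d below cutoff %.2f>\n",
              x$probe$name, length(x$energies), min(x$energies),
              sum(x$energies <= x$probe$energy_cutoff),
              x$probe$energy_cutoff))
  invisible(x)
}

#' Export a field as OpenDX-style text (for visualization)
#'
#' @param mif a `mif` object.
#' @param path output path.
#' @export
write_mif_dx <- function(mif, path) {
  g <- mif$grid
  hdr <- c(
    sprintf("object 1 class gridpositions counts %d %d %d",
            g$dims[3], g$dims[2], g$dims[1]),
    sprintf("origin %g %g %g", g$origin[1], g$origin[2], g$origin[3]),
    sprintf("delta %g 0 0", g$spacing),
    sprintf("delta 0 %g 0", g$spacing),
    sprintf("delta 0 0 %g", g$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d",
            g$dims[3], g$dims[2], g$dims[1]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            length(mif$energies)))
  vals <- apply(matrix(c(mif$energies,
                         rep(NA, (3 - length(mif$energies) %% 3) %% 3)),
                       ncol = 3, byrow = TRUE), 1,
                function(r) paste(stats::na.omit(r), collapse = " "))
  writeLines(c(hdr, vals), path)
  invisible(path)
}
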