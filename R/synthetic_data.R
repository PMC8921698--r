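# Synthetic-data generators.
#
# The pipeline's statistical claims are tested against worlds with planted,
# analytically known structure: (a) rigid toy ligands whose activity is a
# stated linear function of realized feature-pair distances plus Gaussian
# noise, (b) pose ensembles with planted cluster structure, (c) labeled
# descriptor tables with informative and pure-noise columns. All generators
# are pure functions of (parameters, seed); sub-streams are derived with
# derive_seed().
#
# Ligand geometry is built so that correlogram ground truth is analytic:
# each pharmacophoric feature is a payload of atoms arranged on a shell
# around its anchor at the probe's equilibrium distance, which places the
# probe-field minimum AT the anchor; anchors sit on integer multiples of
# the lattice spacing (and make_grid snaps the lattice phase), so the
# extracted node of a realized feature is the anchor itself and a realized
# pair's node-node distance equals its anchor distance. Feature groups are
# translated per ligand by random lattice-multiple offsets so that
# cross-pair distances scatter across bins instead of duplicating the
# planted indicator columns.

#' Pharmacophore specification for the ligand generator
#'
#' @param features list of `list(class, anchor)` where `class` is "DRY"
#'   (hydrophobic payload), "N1" (hydrogen-bond acceptor payload, sensed by
#'   the N1 probe) or "O" (donor payload, sensed by the O probe), and
#'   `anchor` a 3-vector in Angstrom.
#' @param signal_pairs data.frame with columns i, j (feature indices),
#'   distance (target anchor distance, Angstrom), beta (activity effect,
#'   log units), tol (realization tolerance, Angstrom).
#' @param baseline baseline pIC50, log units.
#' @param noise_sd Gaussian activity noise, log units.
#' @param seed integer seed.
#' @return a `pharmacophore_spec`.
#' @export
pharmacophore_spec <- function(features, signal_pairs, baseline = 6,
                               noise_sd = 0.2, seed = 1) {
  stopifnot(length(features) >= 2, is.data.frame(signal_pairs),
            all(c("i", "j", "distance", "beta", "tol") %in%
                  names(signal_pairs)),
            all(signal_pairs$distance > 0), noise_sd >= 0)
  for (f in features)
    stopifnot(f$class %in% c("DRY", "N1", "O"), length(f$anchor) == 3)
  structure(list(features = features, signal_pairs = signal_pairs,
                 baseline = baseline, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "pharmacophore_spec")
}

#' Default two-pair pharmacophore
#'
#' Four features on a lattice-commensurate frame planting two disjoint
#' signal pairs: a DRY/N1 pair at 16.5 Angstrom (beta = 1.0) and a DRY/DRY
#' pair at sqrt(16^2 + 2.5^2) = 16.19 Angstrom (beta = 0.8) -- mirroring
#' the hydrophobic/acceptor and hydrophobic/hydrophobic distance signatures
#' that drive potency in the modeled inhibitor series. The two pair groups
#' are based more than 20 Angstrom apart so that *cross*-group node
#' distances (which vary with the random per-ligand frame offsets) can
#' never fall into a planted or displaced-state bin (all below 20
#' Angstrom): the planted bins stay analytically clean indicators.
#'
#' @param noise_sd activity noise, log units (default 0.2).
#' @param seed integer seed.
#' @return a `pharmacophore_spec`.
#' @export
default_pharmacophore_spec <- function(noise_sd = 0.2, seed = 1) {
  pharmacophore_spec(
    features = list(
      list(class = "DRY", anchor = c(0, 0, 0)),
      list(class = "N1", anchor = c(16.5, 0, 0)),
      list(class = "DRY", anchor = c(0, 26, 0)),
      list(class = "DRY", anchor = c(16, 28.5, 0))),
    signal_pairs = data.frame(
      i = c(1, 3), j = c(2, 4),
      distance = c(16.5, sqrt(16^2 + 2.5^2)),
      beta = c(1.0, 0.8), tol = 0.3),
    baseline = 6, noise_sd = noise_sd, seed = seed)
}

# Payload shell radii: the probe-payload equilibrium distances that center
# each probe's field minimum on the anchor (see default_probe_params and
# default_lj_table: DRY/C combined rmin = (4.0 + 3.8)/2 = 3.9; hydrogen
# bonds at hb_req = 2.8). DRY payloads are octahedra (6 C), giving the
# anchor a 6 * eps_ij = 0.95 kcal/mol well, well below the -0.5 cutoff and
# clearly separated from incidental minima.
PAYLOAD_RADIUS <- c(DRY = 3.9, N1 = 2.8, O = 2.8)

octa_dirs <- function() {
  rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
        c(0, 0, 1), c(0, 0, -1))
}
tri_dirs <- function() {
  rbind(c(1, 0, 0), c(-0.5, 0, sqrt(3) / 2), c(-0.5, 0, -sqrt(3) / 2))
}

payload_atoms <- function(class, anchor) {
  r <- PAYLOAD_RADIUS[[class]]
  if (class == "DRY") {
    pos <- sweep(r * octa_dirs(), 2, anchor, `+`)
    list(atoms = data.frame(element = "C", x = pos[, 1], y = pos[, 2],
                            z = pos[, 3], charge = 0),
         bonds = NULL)
  } else if (class == "N1") {
    pos <- sweep(r * tri_dirs(), 2, anchor, `+`)
    list(atoms = data.frame(element = "O", x = pos[, 1], y = pos[, 2],
                            z = pos[, 3], charge = 0),
         bonds = NULL)
  } else {
    posN <- sweep(r * tri_dirs(), 2, anchor, `+`)
    posH <- sweep((r + 1.0) * tri_dirs(), 2, anchor, `+`)
    list(atoms = data.frame(element = rep(c("N", "H"), each = 3),
                            x = c(posN[, 1], posH[, 1]),
                            y = c(posN[, 2], posH[, 2]),
                            z = c(posN[, 3], posH[, 3]), charge = 0),
         bonds = data.frame(i = 1:3, j = 4:6, order = 1))
  }
}

# Feature groups: connected components of the signal-pair graph (features
# of one pair must keep their mutual geometry; independent groups are
# translated independently).
feature_groups <- function(n_features, pairs) {
  group <- seq_len(n_features)
  repeat {
    changed <- FALSE
    for (r in seq_len(nrow(pairs))) {
      g <- min(group[pairs$i[r]], group[pairs$j[r]])
      if (group[pairs$i[r]] != g || group[pairs$j[r]] != g) {
        group[group == group[pairs$i[r]]] <- g
        group[group == group[pairs$j[r]]] <- g
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(group, unique(group))
}

#' Generate a synthetic ligand set with planted distance signals
#'
#' Each ligand is a rigid toy scaffold (a short carbon chain, kept outside
#' interaction range of the features) decorated with pharmacophoric
#' payloads. For every ligand a random subset of signal pairs is
#' geometrically realized (both anchors at their target distance); an
#' unrealized pair has one feature displaced 2-3 Angstrom along the pair
#' axis. Activity is
#' `pIC50 = baseline + sum_k beta_k * 1[pair k realized] + N(0, noise_sd^2)`
#' where realization is re-measured from the emitted coordinates, so the
#' returned bookkeeping matches the geometry exactly.
#'
#' @param spec a `pharmacophore_spec`.
#' @param n number of ligands (>= 2).
#' @return list(molecules, activities, ground_truth) where `ground_truth`
#'   has one row per (ligand, pair) with the realized flag and measured
#'   anchor distance, plus attribute `planted` describing each pair's probe
#'   block and target distance.
#' @export
gen_ligand_set <- function(spec, n) {
  stopifnot(inherits(spec, "pharmacophore_spec"), n >= 2)
  feats <- spec$features
  pairs <- spec$signal_pairs
  n_f <- length(feats)
  groups <- feature_groups(n_f, pairs)
  offsets_grid <- seq(-3, 3, by = 0.5)

  block_of <- function(ci, cj) {
    hit <- BLOCK_ORDER[BLOCK_ORDER %in%
                         c(paste(ci, cj, sep = "-"), paste(cj, ci, sep = "-"))]
    hit[1]
  }
  planted <- data.frame(
    pair = seq_len(nrow(pairs)),
    block = mapply(function(i, j) block_of(feats[[i]]$class,
                                           feats[[j]]$class),
                   pairs$i, pairs$j),
    distance = pairs$distance, beta = pairs$beta)

  # Features in different groups must not drift into each other's
  # interaction range: a foreign payload within ~8.5 A of an anchor would
  # distort that anchor's field minimum and break the analytic ground
  # truth, so offsets are re-drawn (deterministically) until clear.
  sep_min_groups <- 10

  mols <- vector("list", n)
  gt <- list()
  act <- list()
  for (l in seq_len(n)) {
    state <- with_seed(derive_seed(spec$seed, l * 1000L),
                       rbinom(nrow(pairs), 1, 0.5) == 1)
    pos <- NULL
    for (attempt in seq_len(50)) {
      off <- with_seed(derive_seed(spec$seed, l * 1000L + attempt * 10L),
                       matrix(sample(offsets_grid, 3 * max(groups),
                                     replace = TRUE), ncol = 3))
      disp_mag <- with_seed(derive_seed(spec$seed,
                                        l * 1000L + attempt * 10L + 1L),
                            sample(c(2, 2.5, 3), nrow(pairs),
                                   replace = TRUE))
      cand_pos <- lapply(seq_len(n_f), function(fi)
        feats[[fi]]$anchor + off[groups[fi], ])
      # break unrealized pairs by displacing a feature not needed elsewhere
      in_on_pair <- rep(FALSE, n_f)
      for (r in which(state))
        in_on_pair[c(pairs$i[r], pairs$j[r])] <- TRUE
      for (r in which(!state)) {
        cand <- c(pairs$j[r], pairs$i[r])
        cand <- cand[!in_on_pair[cand]]
        if (!length(cand)) next
        f <- cand[1]
        other <- setdiff(c(pairs$i[r], pairs$j[r]), f)[1]
        axis <- cand_pos[[f]] - cand_pos[[other]]
        axis <- axis / sqrt(sum(axis^2))
        cand_pos[[f]] <- cand_pos[[f]] + disp_mag[r] * axis
        in_on_pair[f] <- TRUE   # displace at most once
      }
      pmat <- do.call(rbind, cand_pos)
      dmat <- cross_dist(pmat, pmat)
      cross_group <- outer(groups, groups, `!=`)
      chain_xyz <- rbind(c(7, 14, 0), c(8.5, 14, 0), c(10, 14, 0))
      chain_clear <- min(cross_dist(pmat, chain_xyz)) >= sep_min_groups
      if (all(dmat[upper.tri(dmat) & cross_group] >= sep_min_groups) &&
          chain_clear) {
        pos <- cand_pos
        break
      }
    }
    if (is.null(pos))
      stop("could not place feature groups clear of each other; ",
           "anchors too close for the stated offsets")
    pmat <- do.call(rbind, pos)
    dmat <- cross_dist(pmat, pmat)
    if (any(dmat[upper.tri(dmat)] < 1.5))
      stop("infeasible geometry: two features closer than 1.5 Angstrom")

    # assemble atoms: scaffold chain first (in the pocket between the two
    # feature groups, outside the 8 A interaction range of every feature),
    # then payloads. The chain carbons carry fluorines so they fail the
    # hydrophobic flag rule: the scaffold is invisible to the DRY probe
    # and contributes no spurious nodes.
    chain <- data.frame(element = rep(c("C", "F"), each = 3),
                        x = c(7, 8.5, 10, 7, 8.5, 10), y = 14,
                        z = rep(c(0, 1.3), each = 3), charge = 0)
    atoms <- chain
    bonds <- data.frame(i = c(1, 2, 1, 2, 3), j = c(2, 3, 4, 5, 6),
                        order = 1)
    for (fi in seq_len(n_f)) {
      pl <- payload_atoms(feats[[fi]]$class, pos[[fi]])
      base <- nrow(atoms)
      atoms <- rbind(atoms, pl$atoms)
      if (!is.null(pl$bonds))
        bonds <- rbind(bonds, data.frame(i = pl$bonds$i + base,
                                         j = pl$bonds$j + base,
                                         order = pl$bonds$order))
    }
    # realization re-measured from emitted geometry
    d_meas <- mapply(function(i, j) vec_dist(pos[[i]], pos[[j]]),
                     pairs$i, pairs$j)
    realized <- abs(d_meas - pairs$distance) <= pairs$tol
    noise <- if (spec$noise_sd > 0)
      with_seed(derive_seed(spec$seed, l * 1000L + 2L),
                rnorm(1, 0, spec$noise_sd)) else 0
    pic50 <- spec$baseline + sum(pairs$beta * realized) + noise
    id <- sprintf("lig%03d", l)
    mol <- molecule3d(id, atoms, bonds, pic50 = pic50,
                      scaffold_atoms = 1:3)
    mols[[l]] <- assign_atom_flags(mol)
    gt[[l]] <- data.frame(compound_id = id, pair = seq_len(nrow(pairs)),
                          realized = realized, distance = d_meas)
    clogp <- with_seed(derive_seed(spec$seed, l * 1000L + 3L),
                       rnorm(1, 4, 1))
    act[[l]] <- data.frame(compound_id = id, pic50 = pic50,
                           ic50 = 10^(9 - pic50), clogp = clogp,
                           lipe = pic50 - clogp)
  }
  ground_truth <- do.call(rbind, gt)
  attr(ground_truth, "planted") <- planted
  list(molecules = mols, activities = do.call(rbind, act),
       ground_truth = ground_truth)
}

rotation_z <- function(theta) {
  rbind(c(cos(theta), -sin(theta), 0),
        c(sin(theta), cos(theta), 0),
        c(0, 0, 1))
}

# Rigid 8-atom scaffold used by the pose generator: a planar hexagon with
# two substituent carbons.
pose_scaffold_coords <- function() {
  ang <- 2 * pi * (0:5) / 6
  ring <- cbind(1.4 * cos(ang), 1.4 * sin(ang), 0)
  rbind(ring, c(2.9, 0, 0), c(-2.9, 0, 0))
}

#' Generate docked-pose ensembles with planted cluster structure
#'
#' Every pose is the rigid scaffold transformed by a sampled cluster center
#' (rotation + translation) plus isotropic Gaussian atomic jitter; the true
#' center index per pose is returned for ground-truth tests.
#'
#' @param n_ligands,n_poses counts.
#' @param cluster_centers list of binding modes, each either a translation
#'   3-vector or a `list(R = 3x3 rotation, t = translation)`.
#' @param membership_probs simplex weights over centers.
#' @param jitter_sd per-coordinate Gaussian jitter, Angstrom (>= 0).
#' @param seed integer seed.
#' @return list of `pose_ensemble` with attribute `true_labels`
#'   (data.frame ligand_id, pose, center).
#' @export
gen_pose_ensemble <- function(n_ligands, n_poses, cluster_centers,
                              membership_probs = NULL, jitter_sd = 0.1,
                              seed = 1) {
  if (!length(cluster_centers)) stop("cluster_centers must be non-empty")
  stopifnot(jitter_sd >= 0, n_ligands >= 1, n_poses >= 1)
  centers <- lapply(cluster_centers, function(cc) {
    if (is.list(cc)) list(R = cc$R %||% diag(3), t = as.numeric(cc$t))
    else list(R = diag(3), t = as.numeric(cc))
  })
  k <- length(centers)
  if (is.null(membership_probs)) membership_probs <- rep(1 / k, k)
  if (abs(sum(membership_probs) - 1) > 1e-8)
    stop("membership_probs must sum to 1")
  base <- pose_scaffold_coords()
  labels <- list()
  ensembles <- vector("list", n_ligands)
  for (li in seq_len(n_ligands)) {
    id <- sprintf("lig%03d", li)
    which_center <- with_seed(derive_seed(seed, li * 3L),
                              sample.int(k, n_poses, replace = TRUE,
                                         prob = membership_probs))
    jit <- if (jitter_sd > 0)
      with_seed(derive_seed(seed, li * 3L + 1L),
                array(rnorm(n_poses * nrow(base) * 3, 0, jitter_sd),
                      dim = c(nrow(base), 3, n_poses)))
    else array(0, dim = c(nrow(base), 3, n_poses))
    poses <- lapply(seq_len(n_poses), function(pi) {
      cc <- centers[[which_center[pi]]]
      xyz <- base %*% t(cc$R) + matrix(cc$t, nrow(base), 3, byrow = TRUE) +
        jit[, , pi]
      molecule3d(sprintf("%s_p%03d", id, pi),
                 data.frame(element = "C", x = xyz[, 1], y = xyz[, 2],
                            z = xyz[, 3], charge = 0))
    })
    ensembles[[li]] <- pose_ensemble(id, poses, scaffold_atoms = 1:6)
    labels[[li]] <- data.frame(ligand_id = id, pose = seq_len(n_poses),
                               center = which_center)
  }
  attr(ensembles, "true_labels") <- do.call(rbind, labels)
  ensembles
}

#' Generate a labeled descriptor table with planted informative columns
#'
#' Informative columns are class-shifted Gaussians (means differ by
#' `effect_size` standard deviations); noise columns are independent
#' standard Gaussians. Labels are flipped with probability `flip_rate`.
#' Column names mark ground truth (`inf_*`, `noise_*`) for tests only.
#'
#' @param n_samples sample count.
#' @param n_informative,n_noise column counts (n_informative may be 0).
#' @param class_balance fraction of class-1 samples.
#' @param flip_rate label noise in [0, 0.5).
#' @param effect_size class-mean separation in SD units.
#' @param seed integer seed.
#' @return list(table (data.frame), labels (0/1 integer vector),
#'   true_labels).
#' @export
gen_descriptor_table <- function(n_samples, n_informative, n_noise,
                                 class_balance = 0.5, flip_rate = 0,
                                 effect_size = 1.5, seed = 1) {
  stopifnot(n_samples > 0, n_noise >= 0, n_informative >= 0,
            flip_rate >= 0, flip_rate < 0.5,
            class_balance > 0, class_balance < 1)
  n1 <- round(n_samples * class_balance)
  y_true <- c(rep(1L, n1), rep(0L, n_samples - n1))
  X <- with_seed(derive_seed(seed, 1), {
    Xi <- if (n_informative > 0)
      matrix(rnorm(n_samples * n_informative), n_samples) +
        outer(y_true, rep(effect_size, n_informative))
    else NULL
    Xn <- if (n_noise > 0)
      matrix(rnorm(n_samples * n_noise), n_samples) else NULL
    cbind(Xi, Xn)
  })
  colnames(X) <- c(if (n_informative > 0) paste0("inf_", seq_len(n_informative)),
                   if (n_noise > 0) paste0("noise_", seq_len(n_noise)))
  flips <- with_seed(derive_seed(seed, 2),
                     runif(n_samples) < flip_rate)
  y <- ifelse(flips, 1L - y_true, y_true)
  list(table = as.data.frame(X), labels = as.integer(y),
       true_labels = y_true)
}
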