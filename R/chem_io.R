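# Molecule container and standard-format I/O (SDF V2000, MOL2).
#
# A Molecule3D is the unit consumed by the interaction-field and RMSD
# machinery: atoms with coordinates (Angstrom, right-handed, as stored in
# the file -- no recentering at read time), partial charges (elementary
# charge units) and pharmacophoric flags.

#' Construct a Molecule3D
#'
#' @param id compound identifier.
#' @param atoms data.frame with columns `element`, `x`, `y`, `z` and
#'   optionally `charge`. Flag columns (`hydrophobic`, `hba`, `hbd`) are
#'   added by [assign_atom_flags()]; `heavy` is derived (every non-hydrogen
#'   atom is heavy).
#' @param bonds data.frame with columns `i`, `j`, `order` (1-based atom
#'   indices), or NULL.
#' @param pic50 optional activity in -log10(molar) units.
#' @param scaffold_atoms optional ordered vector of heavy-atom indices
#'   shared across all poses/compounds of a chemical class.
#' @return an object of class `molecule3d`.
#' @export
molecule3d <- function(id, atoms, bonds = NULL, pic50 = NULL,
                       scaffold_atoms = NULL) {
  stopifnot(is.data.frame(atoms), nrow(atoms) >= 1,
            all(c("element", "x", "y", "z") %in% names(atoms)))
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("atom positions must be finite")
  if (is.null(atoms$charge)) atoms$charge <- 0
  atoms$heavy <- atoms$element != "H"
  for (f in c("hydrophobic", "hba", "hbd"))
    if (is.null(atoms[[f]])) atoms[[f]] <- FALSE
  if (!is.null(bonds) && nrow(bonds)) {
    if (any(bonds$i < 1 | bonds$i > nrow(atoms) |
            bonds$j < 1 | bonds$j > nrow(atoms)))
      stop("bond indices out of range")
  }
  if (!is.null(scaffold_atoms)) {
    if (any(scaffold_atoms < 1 | scaffold_atoms > nrow(atoms)))
      stop("scaffold_atoms out of range")
    if (!all(atoms$heavy[scaffold_atoms]))
      stop("scaffold_atoms must index heavy atoms")
  }
  structure(list(id = as.character(id), atoms = atoms,
                 bonds = bonds, pic50 = pic50,
                 scaffold_atoms = scaffold_atoms),
            class = "molecule3d")
}

#' @export
print.molecule3d <- function(x, ...) {
  cat(sprintf("<molecule3d '%s': %d atoms (%d heavy), %d bonds%s>\n",
              x$id, nrow(x$atoms), sum(x$atoms$heavy),
              if (is.null(x$bonds)) 0L else nrow(x$bonds),
              if (is.null(x$pic50)) "" else sprintf(", pIC50 %.2f", x$pic50)))
  invisible(x)
}

coords <- function(mol) as.matrix(mol$atoms[, c("x", "y", "z")])

#' Read molecules from an SDF (V2000) or MOL2 file
#'
#' One `molecule3d` per record. 3D coordinates are preserved to input
#' precision. Partial charges are read from a named SDF property field
#' (whitespace-separated list, one value per atom); when the tag is absent
#' they are zero-filled with a warning. A `PIC50` property, if present, is
#' attached to the molecule.
#'
#' @param path file path.
#' @param format "sdf" or "mol2".
#' @param charge_prop SDF property tag holding partial charges.
#' @return list of `molecule3d`.
#' @export
read_molecules <- function(path, format = c("sdf", "mol2"),
                           charge_prop = "PARTIAL_CHARGES") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file does not exist: ", path)
  lines <- readLines(path, warn = FALSE)
  if (format == "sdf") read_sdf_lines(lines, charge_prop) else
    read_mol2_lines(lines)
}

read_sdf_lines <- function(lines, charge_prop) {
  # records are terminated by "$$$$"
  ends <- which(trimws(lines) == "$$$$")
  if (!length(ends)) ends <- length(lines)
  starts <- c(1L, head(ends, -1L) + 1L)
  mols <- vector("list", length(starts))
  warned_charge <- FALSE
  for (k in seq_along(starts)) {
    rec <- lines[starts[k]:ends[k]]
    rec <- rec[seq_len(max(which(trimws(rec) != "$$$$"), 0L))]
    if (!length(rec) || all(!nzchar(trimws(rec)))) next
    mols[[k]] <- tryCatch(
      parse_sdf_record(rec, charge_prop, warned_charge),
      error = function(e) stop(sprintf("unparseable SDF record %d: %s",
                                       k, conditionMessage(e)), call. = FALSE))
    if (isTRUE(attr(mols[[k]], "charge_warning")) && !warned_charge) {
      warning("no '", charge_prop, "' property; partial charges zero-filled",
              call. = FALSE)
      warned_charge <- TRUE
    }
    attr(mols[[k]], "charge_warning") <- NULL
  }
  mols <- Filter(Negate(is.null), mols)
  if (any(vapply(mols, function(m) all(abs(m$atoms$z) < 1e-12), logical(1)) &
          vapply(mols, function(m) nrow(m$atoms) > 1, logical(1))))
    warning("molecule(s) with all z = 0: possibly 2D-only coordinates",
            call. = FALSE)
  mols
}

parse_sdf_record <- function(rec, charge_prop, quiet) {
  if (length(rec) < 4) stop("record too short")
  id <- trimws(rec[1])
  counts <- rec[4]
  natoms <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nbonds <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(natoms) || natoms < 1) stop("bad counts line")
  atom_lines <- rec[5:(4 + natoms)]
  atoms <- suppressWarnings(data.frame(
    element = trimws(substr(atom_lines, 32, 34)),
    x = as.numeric(substr(atom_lines, 1, 10)),
    y = as.numeric(substr(atom_lines, 11, 20)),
    z = as.numeric(substr(atom_lines, 21, 30))))
  if (anyNA(atoms$x) || anyNA(atoms$y) || anyNA(atoms$z) ||
      any(!nzchar(atoms$element))) stop("bad atom block")
  bonds <- NULL
  if (!is.na(nbonds) && nbonds > 0) {
    bl <- rec[(5 + natoms):(4 + natoms + nbonds)]
    bonds <- data.frame(i = as.integer(substr(bl, 1, 3)),
                        j = as.integer(substr(bl, 4, 6)),
                        order = as.integer(substr(bl, 7, 9)))
    if (anyNA(bonds)) stop("bad bond block")
  }
  props <- parse_sdf_properties(rec[-seq_len(4 + natoms + max(nbonds, 0))])
  charge_warning <- FALSE
  if (!is.null(props[[charge_prop]])) {
    q <- as.numeric(strsplit(trimws(paste(props[[charge_prop]],
                                          collapse = " ")), "\\s+")[[1]])
    if (length(q) != natoms) stop("charge property length mismatch")
    atoms$charge <- q
  } else {
    atoms$charge <- 0
    charge_warning <- TRUE
  }
  pic50 <- if (!is.null(props$PIC50))
    as.numeric(props$PIC50[1]) else NULL
  if (!nzchar(id)) id <- "unnamed"
  m <- molecule3d(id, atoms, bonds, pic50 = pic50)
  attr(m, "charge_warning") <- charge_warning
  m
}

parse_sdf_properties <- function(lines) {
  props <- list()
  i <- 1L
  while (i <= length(lines)) {
    ln <- lines[i]
    if (grepl("^>\\s*<", ln)) {
      tag <- sub("^>\\s*<([^>]+)>.*$", "\\1", ln)
      vals <- character()
      i <- i + 1L
      while (i <= length(lines) && nzchar(trimws(lines[i]))) {
        vals <- c(vals, lines[i]); i <- i + 1L
      }
      props[[tag]] <- vals
    }
    i <- i + 1L
  }
  props
}

#' Write molecules to an SDF (V2000) file
#'
#' Coordinates are written at 1e-4 Angstrom precision; partial charges go
#' into the `charge_prop` property tag and pIC50 (when present) into
#' `PIC50`, so that `read_molecules(write_molecules(x))` round-trips.
#'
#' @param mols list of `molecule3d` (or a single one).
#' @param path output path.
#' @param charge_prop property tag for partial charges.
#' @export
write_molecules <- function(mols, path, charge_prop = "PARTIAL_CHARGES") {
  if (inherits(mols, "molecule3d")) mols <- list(mols)
  out <- character()
  for (m in mols) {
    a <- m$atoms
    nb <- if (is.null(m$bonds)) 0L else nrow(m$bonds)
    rec <- c(m$id, "  flapqsar", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                     nrow(a), nb),
             sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                     a$x, a$y, a$z, a$element))
    if (nb > 0)
      rec <- c(rec, sprintf("%3d%3d%3d  0", m$bonds$i, m$bonds$j,
                            m$bonds$order))
    rec <- c(rec, "M  END",
             sprintf(">  <%s>", charge_prop),
             paste(sprintf("%.6f", a$charge), collapse = " "), "")
    if (!is.null(m$pic50))
      rec <- c(rec, ">  <PIC50>", sprintf("%.6f", m$pic50), "")
    rec <- c(rec, "$$$$")
    out <- c(out, rec)
  }
  writeLines(out, path)
  invisible(path)
}

read_mol2_lines <- function(lines) {
  mol_starts <- grep("^@<TRIPOS>MOLECULE", lines)
  if (!length(mol_starts)) stop("no MOLECULE section in MOL2 file")
  bounds <- c(mol_starts, length(lines) + 1L)
  mols <- list()
  for (k in seq_along(mol_starts)) {
    rec <- lines[bounds[k]:(bounds[k + 1] - 1L)]
    id <- trimws(rec[2])
    astart <- grep("^@<TRIPOS>ATOM", rec)[1]
    if (is.na(astart)) stop(sprintf("unparseable MOL2 record %d: no ATOM section", k))
    aend <- grep("^@<TRIPOS>", rec)
    aend <- min(c(aend[aend > astart], length(rec) + 1L)) - 1L
    fields <- strsplit(trimws(rec[(astart + 1L):aend]), "\\s+")
    fields <- fields[lengths(fields) >= 6]
    atoms <- data.frame(
      element = sub("\\..*$", "", vapply(fields, `[[`, "", 6L)),
      x = as.numeric(vapply(fields, `[[`, "", 3L)),
      y = as.numeric(vapply(fields, `[[`, "", 4L)),
      z = as.numeric(vapply(fields, `[[`, "", 5L)),
      charge = vapply(fields, function(f)
        if (length(f) >= 9) as.numeric(f[9]) else 0, numeric(1)))
    bstart <- grep("^@<TRIPOS>BOND", rec)[1]
    bonds <- NULL
    if (!is.na(bstart)) {
      bend <- grep("^@<TRIPOS>", rec)
      bend <- min(c(bend[bend > bstart], length(rec) + 1L)) - 1L
      bf <- strsplit(trimws(rec[(bstart + 1L):bend]), "\\s+")
      bf <- bf[lengths(bf) >= 4]
      if (length(bf))
        bonds <- data.frame(
          i = as.integer(vapply(bf, `[[`, "", 2L)),
          j = as.integer(vapply(bf, `[[`, "", 3L)),
          order = suppressWarnings(
            as.integer(vapply(bf, `[[`, "", 4L))))
      if (!is.null(bonds)) bonds$order[is.na(bonds$order)] <- 1L
    }
    mols[[k]] <- tryCatch(molecule3d(id, atoms, bonds),
                          error = function(e)
                            stop(sprintf("unparseable MOL2 record %d: %s",
                                         k, conditionMessage(e)), call. = FALSE))
  }
  mols
}

#' Default pharmacophoric flag rules
#'
#' The rule table the probes sense: hydrophobic atoms are carbon or sulfur
#' with no bonded N/O/F; hydrogen-bond acceptors are N or O with no bonded
#' hydrogen (a pyridine-type N or carbonyl O); donors are N or O bonded to
#' at least one hydrogen. All entries are overridable.
#'
#' @return a list of rule vectors.
#' @export
default_flag_rules <- function() {
  list(hydrophobic_elements = c("C", "S"),
       hydrophobic_block = c("N", "O", "F"),
       hba_elements = c("N", "O"),
       hbd_elements = c("N", "O"),
       known_elements = c("C", "N", "O", "S", "F", "Cl", "Br", "I", "P", "H"))
}

#' Assign pharmacophoric atom flags
#'
#' Deterministic and idempotent. Flags define which atoms each probe
#' senses: the DRY probe interacts with hydrophobic atoms, the N1 (amide N,
#' donor) probe with acceptors, and the O (carbonyl O, acceptor) probe with
#' donors.
#'
#' @param mol a `molecule3d` with bonds present.
#' @param rules flag-rule table, see [default_flag_rules()].
#' @return the molecule with `hydrophobic`, `hba`, `hbd` columns set.
#' @export
assign_atom_flags <- function(mol, rules = default_flag_rules()) {
  stopifnot(inherits(mol, "molecule3d"))
  a <- mol$atoms
  n <- nrow(a)
  nb <- vector("list", n)
  if (!is.null(mol$bonds) && nrow(mol$bonds)) {
    for (r in seq_len(nrow(mol$bonds))) {
      i <- mol$bonds$i[r]; j <- mol$bonds$j[r]
      nb[[i]] <- c(nb[[i]], j); nb[[j]] <- c(nb[[j]], i)
    }
  }
  unknown <- setdiff(unique(a$element), rules$known_elements)
  if (length(unknown))
    warning("unknown element(s) treated as non-flagged: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  bonded_elements <- function(i) a$element[nb[[i]]]
  a$hydrophobic <- vapply(seq_len(n), function(i) {
    a$element[i] %in% rules$hydrophobic_elements &&
      !any(bonded_elements(i) %in% rules$hydrophobic_block)
  }, logical(1))
  has_h <- vapply(seq_len(n), function(i) "H" %in% bonded_elements(i),
                  logical(1))
  a$hba <- a$element %in% rules$hba_elements & !has_h
  a$hbd <- a$element %in% rules$hbd_elements & has_h
  a$hydrophobic[a$element %in% unknown] <- FALSE
  a$hba[a$element %in% unknown] <- FALSE
  a$hbd[a$element %in% unknown] <- FALSE
  mol$atoms <- a
  mol
}
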