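#' Construct a molecular structure
#'
#' The central container of the package: a flat atom table plus a bond table,
#' used for both carriers (graphene/GO sheets) and ligands. Coordinates are in
#' Angstrom, partial charges in elementary charge units. Bond orders follow the
#' SYBYL convention: \code{"1"}, \code{"2"}, \code{"3"} or \code{"ar"}
#' (aromatic); amide bonds read from files as \code{"am"} are kept as such.
#'
#' @param atoms data.frame with columns \code{element} (symbol), \code{type}
#'   (SYBYL atom type, e.g. \code{"C.ar"}), \code{x}, \code{y}, \code{z} (Angstrom),
#'   and optionally \code{charge} (partial charge, e) and \code{formal_charge}
#'   (integer e). Missing charge columns default to zero.
#' @param bonds data.frame with columns \code{i}, \code{j} (1-based atom
#'   indices) and \code{order} (character as above). May have zero rows.
#' @param name molecule name.
#' @param annotations named list of free-form metadata (energies, provenance,
#'   unparsed file records).
#' @return An object of class \code{qmol}.
#' @examples
#' m <- molecule(
#'   atoms = data.frame(element = c("C", "O"), type = c("C.3", "O.3"),
#'                      x = c(0, 1.43), y = 0, z = 0),
#'   bonds = data.frame(i = 1, j = 2, order = "1"),
#'   name = "fragment")
#' n_atoms(m)
#' @export
molecule <- function(atoms, bonds = NULL, name = "MOL", annotations = list()) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  if (is.null(atoms$charge)) atoms[["charge"]] <- rep(0, nrow(atoms))
  if (is.null(atoms$formal_charge))
    atoms[["formal_charge"]] <- rep(0L, nrow(atoms))
  if (is.null(atoms$type)) atoms[["type"]] <- atoms$element
  atoms <- atoms[, c("element", "type", "x", "y", "z", "charge", "formal_charge")]
  if (is.null(bonds) || nrow(as.data.frame(bonds)) == 0) {
    bonds <- data.frame(i = integer(), j = integer(), order = character(),
                        stringsAsFactors = FALSE)
  } else {
    bonds <- as.data.frame(bonds, stringsAsFactors = FALSE)
    bonds$order <- as.character(bonds$order)
    bonds <- bonds[, c("i", "j", "order")]
  }
  rownames(atoms) <- NULL
  rownames(bonds) <- NULL
  m <- structure(list(atoms = atoms, bonds = bonds, name = name,
                      annotations = annotations),
                 class = "qmol")
  validate_molecule(m)
  m
}

#' Validate a molecular structure
#'
#' Checks the structural invariants: bond indices reference existing atoms,
#' no self bonds, no duplicate bonds, finite coordinates.
#'
#' @param m a \code{qmol}.
#' @return \code{m}, invisibly; stops on violation.
#' @export
validate_molecule <- function(m) {
  a <- m$atoms; b <- m$bonds
  if (!all(is.finite(as.matrix(a[, c("x", "y", "z")]))))
    stop("non-finite atom coordinates")
  if (nrow(b)) {
    if (any(b$i < 1 | b$i > nrow(a) | b$j < 1 | b$j > nrow(a)))
      stop("bond references a non-existent atom")
    if (any(b$i == b$j)) stop("self-bond found")
    key <- paste(pmin(b$i, b$j), pmax(b$i, b$j))
    if (anyDuplicated(key)) stop("duplicate bond found")
  }
  invisible(m)
}

#' @export
print.qmol <- function(x, ...) {
  cat(sprintf("<qmol> %s: %d atoms, %d bonds, formal charge %+d\n",
              x$name, nrow(x$atoms), nrow(x$bonds), total_formal_charge(x)))
  if (length(x$annotations))
    cat("  annotations:", paste(names(x$annotations), collapse = ", "), "\n")
  invisible(x)
}

#' Number of atoms
#' @param m a \code{qmol}.
#' @return integer count.
#' @export
n_atoms <- function(m) nrow(m$atoms)

#' Atom coordinates as a matrix
#' @param m a \code{qmol}.
#' @return numeric n x 3 matrix (Angstrom).
#' @export
coords <- function(m) as.matrix(m$atoms[, c("x", "y", "z")])

#' Replace atom coordinates
#' @param m a \code{qmol}.
#' @param value numeric n x 3 matrix.
#' @return the updated molecule.
#' @export
`coords<-` <- function(m, value) {
  stopifnot(nrow(value) == nrow(m$atoms), ncol(value) == 3)
  m$atoms$x <- value[, 1]; m$atoms$y <- value[, 2]; m$atoms$z <- value[, 3]
  m
}

#' Total formal charge of a structure
#'
#' Sums the per-atom formal charges; used to set the total charge (with spin
#' multiplicity 1, the package-wide default for ground-state carriers) when a
#' structure is handed to an external quantum-chemistry engine.
#'
#' @param m a \code{qmol}.
#' @return integer total charge (e).
#' @export
total_formal_charge <- function(m) as.integer(round(sum(m$atoms$formal_charge)))

#' Longest intramolecular distance
#'
#' Maximum pairwise Euclidean distance between any two atoms; the size measure
#' compared against the carrier diameter when pre-filtering a screening
#' library. A single atom has length 0.
#'
#' @param m a \code{qmol} with at least one atom.
#' @return distance in Angstrom.
#' @export
longest_intramolecular_distance <- function(m) {
  if (n_atoms(m) == 0) stop("empty structure")
  if (n_atoms(m) == 1) return(0)
  max(stats::dist(coords(m)))
}

#' Neighbor list from the bond table
#' @param m a \code{qmol}.
#' @return list: element k holds the atom indices bonded to atom k.
#' @keywords internal
neighbor_list <- function(m) {
  nb <- vector("list", n_atoms(m))
  b <- m$bonds
  for (r in seq_len(nrow(b))) {
    nb[[b$i[r]]] <- c(nb[[b$i[r]]], b$j[r])
    nb[[b$j[r]]] <- c(nb[[b$j[r]]], b$i[r])
  }
  nb
}

#' Rigidly transform a structure
#' @param m a \code{qmol}.
#' @param rotation 3 x 3 rotation matrix (applied about the origin).
#' @param translation length-3 shift (Angstrom).
#' @return the transformed molecule.
#' @export
transform_molecule <- function(m, rotation = diag(3), translation = c(0, 0, 0)) {
  xyz <- coords(m) %*% t(rotation)
  xyz <- sweep(xyz, 2, translation, `+`)
  coords(m) <- xyz
  m
}

#' A carrier/ligand pair with the carrier held rigid
#'
#' Bundles the two structures of a graphene-based drug delivery system (GDDS).
#' Pose application only ever moves the ligand; the carrier coordinates are
#' part of the reference frame.
#'
#' @param carrier carrier \code{qmol} (graphene/GO sheet).
#' @param ligand ligand \code{qmol} in its reference conformation.
#' @param genome optional pose genome already applied to \code{ligand}.
#' @return object of class \code{complex_pose}.
#' @export
complex_pose <- function(carrier, ligand, genome = NULL) {
  structure(list(carrier = carrier, ligand = ligand, genome = genome),
            class = "complex_pose")
}

#' @export
print.complex_pose <- function(x, ...) {
  cat(sprintf("<complex_pose> carrier %s (%d atoms) + ligand %s (%d atoms)\n",
              x$carrier$name, n_atoms(x$carrier),
              x$ligand$name, n_atoms(x$ligand)))
  invisible(x)
}
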