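#' Read a Tripos Mol2 file
#'
#' Parses the \code{@<TRIPOS>MOLECULE}, \code{ATOM} and \code{BOND} record
#' blocks of a SYBYL Mol2 file. Any other record blocks (e.g.
#' \code{SUBSTRUCTURE}) are kept verbatim in the molecule's annotations, and
#' leading \code{#} comment lines are preserved under annotation
#' \code{"comments"} so that energy annotations written by [write_mol2()]
#' survive a round trip.
#'
#' @param path path to a Mol2 file.
#' @return a \code{qmol}.
#' @seealso [write_mol2()]
#' @export
read_mol2 <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  comments <- grep("^\\s*#", lines, value = TRUE)
  hdr <- grep("^@<TRIPOS>", lines)
  if (!length(hdr)) stop("no @<TRIPOS> records in ", path)
  blocks <- list()
  for (k in seq_along(hdr)) {
    from <- hdr[k] + 1
    to <- if (k < length(hdr)) hdr[k + 1] - 1 else length(lines)
    nm <- sub("^@<TRIPOS>", "", trimws(lines[hdr[k]]))
    body <- lines[seq(from, length.out = max(0, to - from + 1))]
    body <- body[!grepl("^\\s*#", body)]
    blocks[[nm]] <- c(blocks[[nm]], list(list(start = hdr[k], body = body)))
  }
  if (is.null(blocks$MOLECULE)) stop("missing @<TRIPOS>MOLECULE block in ", path)
  mol_body <- blocks$MOLECULE[[1]]$body
  name <- if (length(mol_body)) trimws(mol_body[1]) else "MOL"
  if (is.null(blocks$ATOM)) stop("missing @<TRIPOS>ATOM block in ", path)
  if (is.null(blocks$BOND)) stop("missing @<TRIPOS>BOND block in ", path)

  parse_atom_line <- function(ln, lineno) {
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(f) < 6)
      stop(sprintf("malformed ATOM record at line %d: '%s'", lineno, ln))
    xyz <- suppressWarnings(as.numeric(f[3:5]))
    if (any(is.na(xyz)))
      stop(sprintf("non-numeric coordinates in ATOM record at line %d", lineno))
    chg <- if (length(f) >= 9) suppressWarnings(as.numeric(f[9])) else 0
    if (is.na(chg)) chg <- 0
    list(name = f[2], x = xyz[1], y = xyz[2], z = xyz[3], type = f[6], charge = chg)
  }
  ab <- blocks$ATOM[[1]]
  keep <- nzchar(trimws(ab$body))
  atom_lines <- ab$body[keep]
  linenos <- ab$start + which(keep)
  recs <- mapply(parse_atom_line, atom_lines, linenos, SIMPLIFY = FALSE)
  atoms <- data.frame(
    element = vapply(recs, function(r) sub("\\..*$", "", r$type), ""),
    type = vapply(recs, `[[`, "", "type"),
    x = vapply(recs, `[[`, 0, "x"),
    y = vapply(recs, `[[`, 0, "y"),
    z = vapply(recs, `[[`, 0, "z"),
    charge = vapply(recs, `[[`, 0, "charge"),
    stringsAsFactors = FALSE)

  bb <- blocks$BOND[[1]]
  keep <- nzchar(trimws(bb$body))
  bond_lines <- bb$body[keep]
  linenos <- bb$start + which(keep)
  bonds <- do.call(rbind, mapply(function(ln, lineno) {
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(f) < 4)
      stop(sprintf("malformed BOND record at line %d: '%s'", lineno, ln))
    ij <- suppressWarnings(as.integer(f[2:3]))
    if (any(is.na(ij)))
      stop(sprintf("non-integer atom index in BOND record at line %d", lineno))
    data.frame(i = ij[1], j = ij[2], order = f[4], stringsAsFactors = FALSE)
  }, bond_lines, linenos, SIMPLIFY = FALSE))

  ann <- list()
  extra <- setdiff(names(blocks), c("MOLECULE", "ATOM", "BOND"))
  for (nm in extra)
    ann[[paste0("mol2_", nm)]] <- unlist(lapply(blocks[[nm]], `[[`, "body"))
  if (length(comments)) ann$comments <- comments
  # formal charges round-trip through a dedicated comment line
  fc <- grep("^#\\s*FORMAL_CHARGES\\s", comments, value = TRUE)
  m <- molecule(atoms, bonds, name = name, annotations = ann)
  if (length(fc)) {
    v <- as.integer(strsplit(trimws(sub("^#\\s*FORMAL_CHARGES", "", fc[1])),
                             "\\s+")[[1]])
    if (length(v) == nrow(atoms)) m$atoms$formal_charge <- v
  }
  m
}

#' Write a Tripos Mol2 file
#'
#' Emits standard \code{MOLECULE}/\code{ATOM}/\code{BOND} records in the SYBYL
#' dialect (atom types like \code{C.ar}, charge column always present). Energy
#' results are written as leading \code{#} comment lines so the file remains
#' readable by third-party viewers.
#'
#' @param m a \code{qmol}.
#' @param path output path.
#' @param energies optional [energy_report()]; its components are echoed as
#'   \code{# E_GDDS=...}, \code{# E_Delta=...} comment lines (kcal/mol).
#' @return \code{path}, invisibly.
#' @export
write_mol2 <- function(m, path, energies = NULL) {
  a <- m$atoms; b <- m$bonds
  out <- character()
  if (!is.null(energies)) {
    for (nm in c("E_GDDS", "E_G", "E_lig", "E_Delta")) {
      if (!is.null(energies[[nm]]) && is.finite(energies[[nm]]))
        out <- c(out, sprintf("# %s=%.4f kcal/mol", nm, energies[[nm]]))
    }
  }
  if (any(a$formal_charge != 0))
    out <- c(out, paste("# FORMAL_CHARGES", paste(a$formal_charge, collapse = " ")))
  out <- c(out,
           "@<TRIPOS>MOLECULE",
           m$name,
           sprintf("%5d %5d %5d %5d %5d", nrow(a), nrow(b), 1, 0, 0),
           "SMALL",
           "USER_CHARGES",
           "@<TRIPOS>ATOM")
  ids <- seq_len(nrow(a))
  out <- c(out, sprintf("%7d %-8s %10.4f %10.4f %10.4f %-8s %3d %-8s %10.6f",
                        ids, paste0(a$element, ids), a$x, a$y, a$z, a$type,
                        1L, m$name, a$charge))
  out <- c(out, "@<TRIPOS>BOND")
  if (nrow(b))
    out <- c(out, sprintf("%6d %5d %5d %4s", seq_len(nrow(b)), b$i, b$j, b$order))
  writeLines(out, path)
  invisible(path)
}

#' Write an XYZ file
#'
#' Plain XYZ output used to hand a geometry to an external energy engine. The
#' comment line carries the total formal charge and the spin multiplicity
#' (always 1: the package targets closed-shell ground states).
#'
#' @param m a \code{qmol}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_xyz <- function(m, path) {
  a <- m$atoms
  writeLines(c(
    as.character(nrow(a)),
    sprintf("charge=%d multiplicity=1 %s", total_formal_charge(m), m$name),
    sprintf("%-3s %14.8f %14.8f %14.8f", a$element, a$x, a$y, a$z)
  ), path)
  invisible(path)
}

#' Read ligands from an SDF file
#'
#' Thin wrapper over \pkg{ChemmineR}'s SDF reader; converts each record into a
#' \code{qmol} and assigns SYBYL atom types from the connection table.
#'
#' @param path path to an SDF (V2000) file.
#' @return list of \code{qmol} ligands.
#' @export
read_sdf <- function(path) {
  if (!requireNamespace("ChemmineR", quietly = TRUE))
    stop("reading SDF requires the ChemmineR package")
  sdfset <- ChemmineR::read.SDFset(path)
  lapply(seq_along(sdfset), function(k) {
    sdf <- sdfset[[k]]
    ab <- ChemmineR::atomblock(sdf)
    bb <- ChemmineR::bondblock(sdf)
    el <- sub("_.*$", "", rownames(ab))
    atoms <- data.frame(element = el, type = el,
                        x = ab[, 1], y = ab[, 2], z = ab[, 3],
                        stringsAsFactors = FALSE)
    ord <- as.character(bb[, 3])
    bonds <- data.frame(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
                        order = ifelse(ord == "4", "ar", ord),
                        stringsAsFactors = FALSE)
    m <- molecule(atoms, bonds, name = ChemmineR::sdfid(sdf))
    assign_atom_types(m)
  })
}

#' Read ligands from a SMILES list
#'
#' Converts SMILES strings to 3D-less SDF records via \pkg{ChemmineR} /
#' \pkg{ChemmineOB} (OpenBabel) and then to \code{qmol} objects. Coordinates
#' are whatever the converter emits (2D); callers needing a docked 3D pose
#' should supply Mol2/SDF geometries instead.
#'
#' @param smiles character vector of SMILES strings (optionally named).
#' @return list of \code{qmol} ligands.
#' @export
read_smiles <- function(smiles) {
  if (!requireNamespace("ChemmineR", quietly = TRUE) ||
      !requireNamespace("ChemmineOB", quietly = TRUE))
    stop("reading SMILES requires the ChemmineR and ChemmineOB packages")
  sdfset <- ChemmineR::smiles2sdf(smiles)
  tf <- tempfile(fileext = ".sdf")
  on.exit(unlink(tf))
  ChemmineR::write.SDF(sdfset, tf)
  mols <- read_sdf(tf)
  if (!is.null(names(smiles)))
    for (k in seq_along(mols)) mols[[k]]$name <- names(smiles)[k]
  mols
}
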