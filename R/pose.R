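# Ligand pose degrees of freedom: one torsion per freely rotatable bond, a
# rigid-body translation (Angstrom) and a rotation encoded as a quaternion
# that is normalized on decode. The fixed variable order is
# (torsions..., tx, ty, tz, q1..q4).

# is bond r of m part of a cycle? (removing it keeps endpoints connected)
bond_in_ring <- function(m, r) {
  b <- m$bonds
  i0 <- b$i[r]; j0 <- b$j[r]
  adj <- neighbor_list(m)
  seen <- logical(n_atoms(m)); seen[i0] <- TRUE
  queue <- i0
  while (length(queue)) {
    k <- queue[1]; queue <- queue[-1]
    nbs <- adj[[k]]
    if (k == i0) nbs <- setdiff(nbs, j0)
    if (k == j0) nbs <- setdiff(nbs, i0)
    # skip the edge itself in either direction
    nbs <- nbs[!(k == i0 & nbs == j0) & !(k == j0 & nbs == i0)]
    fresh <- nbs[!seen[nbs]]
    seen[fresh] <- TRUE
    queue <- c(queue, fresh)
  }
  seen[j0]
}

#' Detect freely rotatable bonds of a ligand
#'
#' Single, non-ring, non-amide bonds between heavy atoms. Bonds whose rotation
#' only permutes equivalent terminal atoms are excluded: a side whose other
#' substituents are all degree-one atoms of one element (methyl, CF3, hydroxyl,
#' primary amine, ...) contributes no new conformation.
#'
#' @param m a ligand \code{qmol}.
#' @return integer vector of row indices into \code{m$bonds}; attribute
#'   \code{pairs} holds the corresponding (i, j) atom index matrix.
#' @examples
#' detect_rotatable_bonds(make_fixture("n_butane"))  # the C2-C3 bond only
#' @export
detect_rotatable_bonds <- function(m) {
  b <- m$bonds
  el <- m$atoms$element
  nb <- neighbor_list(m)
  deg <- lengths(nb)
  is_carbonyl_c <- function(k) {
    el[k] == "C" && any(vapply(nb[[k]], function(j) {
      el[j] == "O" && any((b$i == k & b$j == j & b$order == "2") |
                            (b$i == j & b$j == k & b$order == "2"))
    }, TRUE))
  }
  terminal_side <- function(k, other) {
    subs <- setdiff(nb[[k]], other)
    if (!length(subs)) return(TRUE)
    all(deg[subs] == 1) && length(unique(el[subs])) == 1
  }
  out <- integer()
  for (r in seq_len(nrow(b))) {
    if (b$order[r] != "1") next
    i <- b$i[r]; j <- b$j[r]
    if (el[i] == "H" || el[j] == "H") next
    amide <- (el[i] == "N" && is_carbonyl_c(j)) ||
      (el[j] == "N" && is_carbonyl_c(i))
    if (amide) next
    if (terminal_side(i, j) || terminal_side(j, i)) next
    if (bond_in_ring(m, r)) next
    out <- c(out, r)
  }
  attr(out, "pairs") <- cbind(i = b$i[out], j = b$j[out])
  out
}

#' Construct a pose genome
#'
#' @param torsions torsion increments (radians), one per rotatable bond.
#' @param translation rigid displacement of the ligand centroid (Angstrom).
#' @param quaternion length-4 rotation parameters; normalized when applied,
#'   an all-zero vector decodes to the identity rotation.
#' @param bounds 2-column matrix (min, max) per variable in the order
#'   (torsions, translation, quaternion); see [default_pose_bounds()].
#' @return list of class \code{pose_genome}.
#' @export
pose_genome <- function(torsions, translation, quaternion, bounds) {
  g <- structure(list(torsions = as.numeric(torsions),
                      translation = as.numeric(translation),
                      quaternion = as.numeric(quaternion),
                      bounds = bounds),
                 class = "pose_genome")
  v <- genome_values(g)
  if (any(v < bounds[, 1] - 1e-9 | v > bounds[, 2] + 1e-9))
    stop("pose genome variable out of bounds")
  g
}

genome_values <- function(g) c(g$torsions, g$translation, g$quaternion)

values_to_genome <- function(v, n_torsions, bounds) {
  pose_genome(torsions = v[seq_len(n_torsions)],
              translation = v[n_torsions + 1:3],
              quaternion = v[n_torsions + 4:7],
              bounds = bounds)
}

#' Default search bounds for a carrier/ligand pair
#'
#' Torsions span a full turn; the translation keeps the ligand centroid inside
#' a box equal to the carrier's xy bounding box expanded by 10 Angstrom and
#' spanning z = -8 to +8 Angstrom (translations are expressed relative to the
#' ligand's reference centroid); quaternion components are raw in [-1, 1].
#'
#' @param carrier carrier \code{qmol} (sheet in the z = 0 plane).
#' @param ligand ligand \code{qmol}.
#' @param n_torsions number of rotatable bonds.
#' @return 2-column bounds matrix, one row per variable.
#' @export
default_pose_bounds <- function(carrier, ligand, n_torsions) {
  xyz <- coords(carrier)
  cen <- colMeans(coords(ligand))
  lo <- c(min(xyz[, 1]) - 10, min(xyz[, 2]) - 10, -8) - cen
  hi <- c(max(xyz[, 1]) + 10, max(xyz[, 2]) + 10, 8) - cen
  rbind(
    matrix(rep(c(-pi, pi), each = n_torsions), ncol = 2),
    cbind(lo, hi),
    matrix(rep(c(-1, 1), each = 4), ncol = 2),
    deparse.level = 0)
}

#' Encode a pose genome as a bit vector
#'
#' Each variable is linearly quantized onto its (min, max) interval with
#' 2^bits levels and written big-endian, variables in the fixed order
#' (torsions, translation x/y/z, q1..q4).
#'
#' @param genome a [pose_genome()].
#' @param bits_per_variable quantization width (default 16).
#' @return integer vector of 0/1 bits.
#' @export
encode_pose <- function(genome, bits_per_variable = 16) {
  encode_values(genome_values(genome), genome$bounds, bits_per_variable)
}

encode_values <- function(v, bounds, bits) {
  if (any(v < bounds[, 1] - 1e-9 | v > bounds[, 2] + 1e-9))
    stop("variable out of bounds")
  levels <- 2^bits - 1
  step <- (bounds[, 2] - bounds[, 1]) / levels
  lev <- round((v - bounds[, 1]) / step)
  lev <- pmin(pmax(lev, 0), levels)
  out <- integer(length(v) * bits)
  for (k in seq_along(v)) {
    x <- lev[k]
    for (p in bits:1) {
      out[(k - 1) * bits + p] <- x %% 2
      x <- x %/% 2
    }
  }
  out
}

decode_values <- function(bits, bounds, bits_per_variable) {
  nv <- nrow(bounds)
  if (length(bits) != nv * bits_per_variable)
    stop("bit count does not match the variable layout")
  step <- (bounds[, 2] - bounds[, 1]) / (2^bits_per_variable - 1)
  pw <- 2^((bits_per_variable - 1):0)
  lev <- vapply(seq_len(nv), function(k)
    sum(bits[(k - 1) * bits_per_variable + seq_len(bits_per_variable)] * pw), 0)
  bounds[, 1] + lev * step
}

quaternion_matrix <- function(q) {
  n <- sqrt(sum(q^2))
  if (n < 1e-12) return(diag(3))  # degenerate all-zero quaternion: identity
  q <- q / n
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# rotate coordinates `xyz` of atom set `move` about the axis a->b by angle t
rotate_about_bond <- function(xyz, move, pa, pb, t) {
  ax <- pb - pa
  ax <- ax / sqrt(sum(ax^2))
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
              3, 3, byrow = TRUE)
  R <- diag(3) + sin(t) * K + (1 - cos(t)) * (K %*% K)
  rel <- sweep(xyz[move, , drop = FALSE], 2, pa)
  xyz[move, ] <- sweep(rel %*% t(R), 2, pa, `+`)
  xyz
}

#' Apply a pose genome to a ligand
#'
#' Starting from the ligand's reference conformation: each torsion increment
#' rotates the smaller fragment about its bond, then the (normalized)
#' quaternion rotates the whole ligand about its centroid, then the
#' translation displaces it. Bond lengths and angles are untouched; only
#' torsions, orientation and position change.
#'
#' @param ligand ligand \code{qmol} in the reference conformation.
#' @param genome a [pose_genome()].
#' @param rot_bonds result of [detect_rotatable_bonds()] for this ligand.
#' @return the posed ligand \code{qmol}.
#' @export
apply_pose <- function(ligand, genome, rot_bonds) {
  xyz <- coords(ligand)
  prs <- attr(rot_bonds, "pairs")
  nb <- neighbor_list(ligand)
  for (k in seq_along(genome$torsions)) {
    i <- prs[k, 1]; j <- prs[k, 2]
    side_j <- fragment_atoms(nb, j, i)
    side_i <- fragment_atoms(nb, i, j)
    if (length(side_j) <= length(side_i)) {
      xyz <- rotate_about_bond(xyz, setdiff(side_j, j), xyz[i, ], xyz[j, ],
                               genome$torsions[k])
    } else {
      xyz <- rotate_about_bond(xyz, setdiff(side_i, i), xyz[j, ], xyz[i, ],
                               -genome$torsions[k])
    }
  }
  cen <- colMeans(xyz)
  R <- quaternion_matrix(genome$quaternion)
  xyz <- sweep(sweep(xyz, 2, cen) %*% t(R), 2, cen + genome$translation, `+`)
  coords(ligand) <- xyz
  ligand
}

# atoms reachable from `start` without passing through `blocked`
fragment_atoms <- function(nb, start, blocked) {
  seen <- logical(length(nb))
  seen[c(start, blocked)] <- TRUE
  queue <- start
  while (length(queue)) {
    k <- queue[1]; queue <- queue[-1]
    fresh <- nb[[k]][!seen[nb[[k]]]]
    seen[fresh] <- TRUE
    queue <- c(queue, fresh)
  }
  out <- which(seen)
  setdiff(out, blocked)
}

#' Decode a bit chromosome into a complex pose
#'
#' @param bits integer 0/1 vector whose length matches the variable layout.
#' @param carrier carrier \code{qmol} (returned untouched).
#' @param ligand ligand \code{qmol} reference conformation.
#' @param rot_bonds rotatable bonds of the ligand.
#' @param bounds variable bounds (defaults to [default_pose_bounds()]).
#' @param bits_per_variable quantization width.
#' @return a [complex_pose()] with the posed ligand and its genome.
#' @export
decode_chromosome <- function(bits, carrier, ligand,
                              rot_bonds = detect_rotatable_bonds(ligand),
                              bounds = default_pose_bounds(carrier, ligand,
                                                           length(rot_bonds)),
                              bits_per_variable = 16) {
  v <- decode_values(bits, bounds, bits_per_variable)
  g <- values_to_genome(v, length(rot_bonds), bounds)
  complex_pose(carrier, apply_pose(ligand, g, rot_bonds), genome = g)
}
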