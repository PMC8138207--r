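# Tripos-style molecular-mechanics energy: harmonic bond stretch and angle
# bend, periodic torsions, quadratic out-of-plane for sp2 centers, 6-12
# Lennard-Jones, and Coulomb electrostatics with a distance-dependent
# dielectric eps(r) = 4r. 1-2 and 1-3 pairs are excluded from the nonbonded
# sums, 1-4 pairs scaled by 0.5 (both vdW and electrostatic). Energies in
# kcal/mol, distances in Angstrom.

COULOMB_K <- 332.0637  # kcal mol^-1 A e^-2

# per-type vdW radius (A) and well depth (kcal/mol). Carbon uses the common
# aromatic-carbon values (R* 1.90, eps 0.086): summed over a graphene sheet
# they reproduce the physical pi-stacking distance (~3.4 A), where the older
# 1.70 A radius collapses a stacked ring to ~3.0 A.
VDW_PARAMS <- list(
  "C.3" = c(1.90, 0.086), "C.2" = c(1.90, 0.086), "C.ar" = c(1.90, 0.086),
  "C.1" = c(1.90, 0.086), "H" = c(1.46, 0.030),
  "O.3" = c(1.52, 0.116), "O.2" = c(1.48, 0.105), "O.co2" = c(1.48, 0.105),
  "N.3" = c(1.55, 0.095), "N.2" = c(1.55, 0.095), "N.ar" = c(1.55, 0.095),
  "N.am" = c(1.55, 0.095), "N.1" = c(1.55, 0.095), "N.4" = c(1.55, 0.095),
  "S.3" = c(1.80, 0.314), "S.2" = c(1.80, 0.314), "P.3" = c(1.80, 0.314),
  "F" = c(1.47, 0.109), "Cl" = c(1.75, 0.314), "Br" = c(1.85, 0.434),
  "I" = c(1.98, 0.623),
  "Ar" = c(1.88, 0.234))  # noble-gas probe used in tests

# harmonic bond parameters: r0 (A), k (kcal mol^-1 A^-2), E = k/2 (r-r0)^2
BOND_PARAMS <- list(
  "C.3-C.3" = c(1.540, 1268), "C.3-H" = c(1.100, 1325),
  "C.ar-C.ar" = c(1.395, 2800), "C.ar-H" = c(1.084, 1400),
  "C.2-C.2" = c(1.335, 2680), "C.2-H" = c(1.089, 1400),
  "C.2-O.2" = c(1.220, 2800), "C.2-O.3" = c(1.330, 2400),
  "C.2-O.co2" = c(1.260, 2800), "C.3-O.3" = c(1.430, 1238),
  "O.3-H" = c(0.950, 2014), "C.ar-C.3" = c(1.525, 1280),
  "C.ar-C.2" = c(1.510, 1400), "C.2-C.3" = c(1.501, 1278),
  "C.ar-O.3" = c(1.360, 1400), "C.3-N.3" = c(1.470, 1520),
  "N.3-H" = c(1.010, 1384), "N.am-H" = c(1.010, 1384),
  "C.ar-N.ar" = c(1.346, 2610), "C.2-N.am" = c(1.345, 2600),
  "C.3-N.am" = c(1.450, 1520), "C.ar-C.1" = c(1.440, 1600),
  "C.1-N.1" = c(1.158, 3200), "C.1-C.1" = c(1.204, 3400),
  "C.ar-F" = c(1.330, 1600), "C.3-F" = c(1.360, 1200),
  "C.ar-Cl" = c(1.750, 900), "C.3-S.3" = c(1.810, 800),
  "Ar-Ar" = c(3.760, 100))

COVALENT_RADII <- c(C = 0.77, H = 0.37, O = 0.73, N = 0.75, S = 1.02,
                    P = 1.06, F = 0.71, Cl = 0.99, Br = 1.14, I = 1.33,
                    Ar = 1.88)

# angle-bend defaults keyed by center hybridization:
# theta0 (deg), k (kcal mol^-1 deg^-2), E = k/2 (theta-theta0)^2
angle_params_for <- function(center_type) {
  if (center_type %in% c("C.1", "N.1")) c(180, 0.01)
  else if (grepl("\\.(2|ar|am|co2)$", center_type)) c(120, 0.024)
  else c(109.5, 0.02)
}

# torsion defaults by the central-bond atom hybridizations:
# E = V/2 (1 + s cos(n phi)) per path
torsion_params_for <- function(tj, tk, order) {
  sp2 <- function(t) grepl("\\.(2|ar|am)$", t)
  if (order == "ar" || (sp2(tj) && sp2(tk))) c(V = 2.0, n = 2, s = -1)
  else if (sp2(tj) || sp2(tk)) c(V = 0.12, n = 6, s = 1)
  else c(V = 0.2, n = 3, s = 1)
}

OOP_K <- 120  # kcal mol^-1 A^-2, quadratic in the center's out-of-plane height

lookup_bond_param <- function(ti, tj) {
  key1 <- paste(ti, tj, sep = "-"); key2 <- paste(tj, ti, sep = "-")
  p <- BOND_PARAMS[[key1]]
  if (is.null(p)) p <- BOND_PARAMS[[key2]]
  if (is.null(p)) {
    e1 <- sub("\\..*$", "", ti); e2 <- sub("\\..*$", "", tj)
    r0 <- unname(COVALENT_RADII[e1] + COVALENT_RADII[e2])
    if (is.na(r0)) r0 <- 1.5
    warning(sprintf("no bond parameters for %s-%s: falling back to r0=%.2f A, k=1200",
                    ti, tj, r0), call. = FALSE)
    p <- c(r0, 1200)
  }
  p
}

# precompute every term list for one structure
ff_context <- function(m) {
  n <- n_atoms(m)
  types <- m$atoms$type
  q <- m$atoms$charge
  vd <- lapply(types, function(t) {
    p <- VDW_PARAMS[[t]]
    if (is.null(p)) stop("no vdW parameters for atom type ", t)
    p
  })
  rstar <- vapply(vd, `[`, 0, 1); eps <- vapply(vd, `[`, 0, 2)
  b <- m$bonds
  bp <- t(vapply(seq_len(nrow(b)), function(r)
    lookup_bond_param(types[b$i[r]], types[b$j[r]]), c(0, 0)))
  nb <- neighbor_list(m)
  # angles: center j with neighbour pair (i,k)
  ang <- list()
  for (j in seq_len(n)) {
    nbs <- nb[[j]]
    if (length(nbs) >= 2) {
      prs <- utils::combn(nbs, 2)
      pa <- angle_params_for(types[j])
      for (cidx in seq_len(ncol(prs)))
        ang[[length(ang) + 1]] <- c(prs[1, cidx], j, prs[2, cidx], pa)
    }
  }
  ang <- if (length(ang)) do.call(rbind, ang) else matrix(0, 0, 5)
  # torsions: each path i-j-k-l over every single/aromatic bond j-k
  tor <- list()
  for (r in seq_len(nrow(b))) {
    j <- b$i[r]; k <- b$j[r]
    ni <- setdiff(nb[[j]], k); nl <- setdiff(nb[[k]], j)
    if (!length(ni) || !length(nl)) next
    tp <- torsion_params_for(types[j], types[k], b$order[r])
    for (i in ni) for (l in nl) if (i != l)
      tor[[length(tor) + 1]] <- c(i, j, k, l, tp)
  }
  tor <- if (length(tor)) do.call(rbind, tor) else matrix(0, 0, 7)
  # out-of-plane: trigonal sp2 centers
  oop <- list()
  for (j in seq_len(n)) {
    if (grepl("\\.(2|ar|am|co2)$", types[j]) && length(nb[[j]]) == 3)
      oop[[length(oop) + 1]] <- c(j, nb[[j]])
  }
  oop <- if (length(oop)) do.call(rbind, oop) else matrix(0, 0, 4)
  # nonbonded pair list with topological exclusions
  topo <- bond_distance_classes(n, b)
  pair <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  cls <- topo[cbind(pair[, 1], pair[, 2])]
  keep <- cls >= 4L   # 4 means 1-4, 9 means further apart
  pair <- pair[keep, , drop = FALSE]
  scale <- ifelse(cls[keep] == 4L, 0.5, 1.0)
  list(n = n,
       bond_i = b$i, bond_j = b$j, bond_r0 = bp[, 1], bond_k = bp[, 2],
       ang = ang, tor = tor, oop = oop,
       nb_i = pair[, 1], nb_j = pair[, 2], nb_scale = scale,
       nb_rstar = rstar[pair[, 1]] + rstar[pair[, 2]],
       nb_eps = sqrt(eps[pair[, 1]] * eps[pair[, 2]]),
       nb_qq = q[pair[, 1]] * q[pair[, 2]],
       rstar = rstar, eps = eps, q = q)
}

# topological distance class matrix: 2 = bonded, 3 = 1-3, 4 = 1-4, 9 = beyond
bond_distance_classes <- function(n, b) {
  cls <- matrix(9L, n, n)
  adj <- vector("list", n)
  for (r in seq_len(nrow(b))) {
    adj[[b$i[r]]] <- c(adj[[b$i[r]]], b$j[r])
    adj[[b$j[r]]] <- c(adj[[b$j[r]]], b$i[r])
  }
  for (i in seq_len(n)) {
    d1 <- adj[[i]]
    d2 <- setdiff(unique(unlist(adj[d1])), c(i, d1))
    d3 <- setdiff(unique(unlist(adj[d2])), c(i, d1, d2))
    cls[i, d3] <- pmin(cls[i, d3], 4L)
    cls[i, d2] <- pmin(cls[i, d2], 3L)
    cls[i, d1] <- pmin(cls[i, d1], 2L)
  }
  cls
}

dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1])
  bn <- sqrt(sum(b2^2))
  atan2(sum(m1 * n2) / bn, sum(n1 * n2))
}

# evaluate all terms of a context at given coordinates
eval_ff <- function(ctx, xyz) {
  terms <- c(bond = 0, angle = 0, torsion = 0, oop = 0, vdw = 0, elec = 0)
  if (length(ctx$bond_i)) {
    dv <- xyz[ctx$bond_i, , drop = FALSE] - xyz[ctx$bond_j, , drop = FALSE]
    r <- sqrt(rowSums(dv^2))
    terms["bond"] <- sum(0.5 * ctx$bond_k * (r - ctx$bond_r0)^2)
  }
  if (nrow(ctx$ang)) {
    v1 <- xyz[ctx$ang[, 1], , drop = FALSE] - xyz[ctx$ang[, 2], , drop = FALSE]
    v2 <- xyz[ctx$ang[, 3], , drop = FALSE] - xyz[ctx$ang[, 2], , drop = FALSE]
    cosd <- rowSums(v1 * v2) /
      sqrt(rowSums(v1^2) * rowSums(v2^2))
    th <- acos(pmin(1, pmax(-1, cosd))) * 180 / pi
    terms["angle"] <- sum(0.5 * ctx$ang[, 5] * (th - ctx$ang[, 4])^2)
  }
  if (nrow(ctx$tor)) {
    phi <- vapply(seq_len(nrow(ctx$tor)), function(r)
      dihedral_angle(xyz[ctx$tor[r, 1], ], xyz[ctx$tor[r, 2], ],
                     xyz[ctx$tor[r, 3], ], xyz[ctx$tor[r, 4], ]), 0)
    terms["torsion"] <- sum(ctx$tor[, 5] / 2 *
                              (1 + ctx$tor[, 7] * cos(ctx$tor[, 6] * phi)))
  }
  if (nrow(ctx$oop)) {
    h <- vapply(seq_len(nrow(ctx$oop)), function(r) {
      p <- xyz[ctx$oop[r, 1], ]
      p1 <- xyz[ctx$oop[r, 2], ]; p2 <- xyz[ctx$oop[r, 3], ]
      p3 <- xyz[ctx$oop[r, 4], ]
      u <- p2 - p1; v <- p3 - p1
      nrm <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
               u[1] * v[2] - u[2] * v[1])
      nn <- sqrt(sum(nrm^2))
      if (nn < 1e-12) 0 else abs(sum((p - p1) * nrm)) / nn
    }, 0)
    terms["oop"] <- sum(OOP_K * h^2)
  }
  if (length(ctx$nb_i)) {
    dv <- xyz[ctx$nb_i, , drop = FALSE] - xyz[ctx$nb_j, , drop = FALSE]
    r2 <- rowSums(dv^2)
    s6 <- (ctx$nb_rstar^2 / r2)^3
    terms["vdw"] <- sum(ctx$nb_scale * ctx$nb_eps * (s6^2 - 2 * s6))
    terms["elec"] <- sum(ctx$nb_scale * COULOMB_K * ctx$nb_qq / (4 * r2))
  }
  terms
}

#' Build an energy report
#'
#' @param E_GDDS total potential energy of the carrier/ligand complex
#'   (kcal/mol).
#' @param E_G carrier-alone potential energy (kcal/mol).
#' @param E_lig ligand-alone potential energy at the same geometry (kcal/mol).
#' @param terms named numeric vector of energy components.
#' @return list of class \code{energy_report}; \code{E_Delta} is always
#'   computed as \code{E_GDDS - E_G - E_lig}, the binding energy (more
#'   negative = more stable complex).
#' @export
energy_report <- function(E_GDDS, E_G = NA_real_, E_lig = NA_real_,
                          terms = numeric()) {
  structure(list(E_GDDS = E_GDDS, E_G = E_G, E_lig = E_lig,
                 E_Delta = E_GDDS - E_G - E_lig, terms = terms),
            class = "energy_report")
}

#' @export
print.energy_report <- function(x, ...) {
  cat(sprintf("<energy_report> E_GDDS = %.4f kcal/mol", x$E_GDDS))
  if (is.finite(x$E_Delta))
    cat(sprintf("; E_G = %.4f; E_lig = %.4f; E_Delta = %.4f", x$E_G, x$E_lig,
                x$E_Delta))
  cat("\n")
  if (length(x$terms))
    cat("  terms:", paste(sprintf("%s=%.3f", names(x$terms), x$terms),
                          collapse = " "), "\n")
  invisible(x)
}

#' Potential energy of a structure or complex
#'
#' Evaluates the internal force field. For a single structure the report
#' carries the total in \code{E_GDDS}. For a [complex_pose()] it also
#' evaluates the isolated carrier and ligand at the same geometry and fills
#' \code{E_G}, \code{E_lig} and the binding energy \code{E_Delta}; the
#' \code{intermolecular} term is the nonbonded cross energy.
#'
#' @param x a \code{qmol} or \code{complex_pose} with types and charges
#'   assigned.
#' @return an [energy_report()].
#' @export
potential_energy <- function(x) {
  if (inherits(x, "qmol")) {
    ctx <- ff_context(x)
    terms <- eval_ff(ctx, coords(x))
    return(energy_report(sum(terms), terms = terms))
  }
  if (!inherits(x, "complex_pose")) stop("need a qmol or complex_pose")
  ctxC <- ff_context(x$carrier)
  ctxL <- ff_context(x$ligand)
  tC <- eval_ff(ctxC, coords(x$carrier))
  tL <- eval_ff(ctxL, coords(x$ligand))
  cross <- cross_energy(ctxC, coords(x$carrier), ctxL, coords(x$ligand))
  terms <- tC + tL
  terms["vdw"] <- terms["vdw"] + cross["vdw"]
  terms["elec"] <- terms["elec"] + cross["elec"]
  terms <- c(terms, intermolecular = unname(sum(cross)))
  energy_report(sum(tC) + sum(tL) + sum(cross),
                E_G = sum(tC), E_lig = sum(tL), terms = terms)
}

# nonbonded energy between two fragments (all pairs, unscaled)
cross_energy <- function(ctxA, xyzA, ctxB, xyzB) {
  rstar <- outer(ctxA$rstar, ctxB$rstar, `+`)
  eps <- sqrt(outer(ctxA$eps, ctxB$eps))
  qq <- outer(ctxA$q, ctxB$q)
  r2 <- outer(rowSums(xyzA^2), rowSums(xyzB^2), `+`) -
    2 * (xyzA %*% t(xyzB))
  r2[r2 < 1e-12] <- 1e-12
  s6 <- (rstar^2 / r2)^3
  c(vdw = sum(eps * (s6^2 - 2 * s6)),
    elec = sum(COULOMB_K * qq / (4 * r2)))
}

#' Internal force-field energy engine
#'
#' Engine object used by the pose-search and cascade drivers. Its
#' \code{prepare(carrier, ligand)} method precomputes the per-structure term
#' lists and the carrier self-energy (the carrier is rigid during a search),
#' returning a fast closure that maps ligand coordinates to an
#' [energy_report()].
#'
#' @return list of class \code{qga_engine}, kind \code{"internal_ff"}.
#' @seealso [mock_engine()], [external_engine()]
#' @export
ff_engine <- function() {
  eng <- list(kind = "internal_ff")
  eng$prepare <- function(carrier, ligand) {
    ctxC <- ff_context(carrier)
    ctxL <- ff_context(ligand)
    xyzC <- coords(carrier)
    E_G <- sum(eval_ff(ctxC, xyzC))
    function(lig_xyz) {
      tL <- eval_ff(ctxL, lig_xyz)
      cross <- cross_energy(ctxC, xyzC, ctxL, lig_xyz)
      energy_report(E_G + sum(tL) + sum(cross), E_G = E_G, E_lig = sum(tL),
                    terms = c(tL, intermolecular = unname(sum(cross))))
    }
  }
  eng$score <- function(pose) potential_energy(pose)
  structure(eng, class = "qga_engine")
}

#' @export
print.qga_engine <- function(x, ...) {
  cat(sprintf("<qga_engine> kind: %s\n", x$kind)); invisible(x)
}
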