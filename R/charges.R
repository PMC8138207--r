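# Gasteiger-Marsili partial equalization of orbital electronegativity (PEOE).
# Electronegativity of an atom is chi(q) = a + b q + c q^2; each iteration
# moves charge across every bond from the less to the more electronegative
# atom, damped by (1/2)^k, so the total charge is conserved exactly.

GASTEIGER_PARAMS <- list(
  "H"     = c(7.17, 6.24, -0.56),
  "C.3"   = c(7.98, 9.18, 1.88),
  "C.2"   = c(8.79, 9.32, 1.51),
  "C.ar"  = c(8.79, 9.32, 1.51),
  "C.1"   = c(10.39, 9.45, 0.73),
  "N.3"   = c(11.54, 10.82, 1.36),
  "N.4"   = c(11.54, 10.82, 1.36),
  "N.am"  = c(11.54, 10.82, 1.36),
  "N.2"   = c(12.87, 11.15, 0.85),
  "N.ar"  = c(12.87, 11.15, 0.85),
  "N.1"   = c(15.68, 11.70, -0.27),
  "O.3"   = c(14.18, 12.92, 1.39),
  "O.2"   = c(17.07, 13.79, 0.47),
  "O.co2" = c(15.62, 13.36, 0.93),  # midpoint of the two resonance oxygens
  "F"     = c(14.66, 13.85, 2.31),
  "Cl"    = c(11.00, 9.69, 1.35),
  "Br"    = c(10.08, 8.47, 1.16),
  "I"     = c(9.90, 7.96, 0.96),
  "S.3"   = c(10.14, 9.13, 1.38),
  "S.2"   = c(10.14, 9.13, 1.38),
  "P.3"   = c(8.90, 8.24, 0.96))

#' Assign Gasteiger partial charges
#'
#' Iterative electronegativity equalization (PEOE) over the bond graph,
#' starting from the formal charges. Charge flows pairwise across bonds, so
#' the partial charges sum to the total formal charge to machine precision and
#' symmetry-equivalent atoms receive identical charges.
#'
#' @param m a \code{qmol} with SYBYL types assigned
#'   (see [assign_atom_types()]).
#' @param max_iter iteration cap; the damping factor makes convergence
#'   geometric, so hitting the cap signals a malformed structure and raises an
#'   error.
#' @param tol stop once the largest per-bond charge transfer of a cycle falls
#'   below this value (e).
#' @return the molecule with \code{atoms$charge} filled in.
#' @export
assign_partial_charges <- function(m, max_iter = 60, tol = 1e-8) {
  types <- m$atoms$type
  par <- lapply(types, function(t) {
    p <- GASTEIGER_PARAMS[[t]]
    if (is.null(p))
      stop("no Gasteiger parameters for atom type ", t)
    p
  })
  A <- vapply(par, `[`, 0, 1); B <- vapply(par, `[`, 0, 2)
  C <- vapply(par, `[`, 0, 3)
  # chi+ of the cation limit, used as the normalizing electronegativity;
  # hydrogen uses the conventional 20.02
  chi_plus <- A + B + C
  chi_plus[types == "H"] <- 20.02
  q <- as.numeric(m$atoms$formal_charge)
  bi <- m$bonds$i; bj <- m$bonds$j
  damp <- 1
  for (it in seq_len(max_iter)) {
    damp <- damp * 0.5
    chi <- A + B * q + C * q^2
    dchi <- chi[bj] - chi[bi]
    denom <- ifelse(dchi > 0, chi_plus[bi], chi_plus[bj])
    dq <- dchi / denom * damp
    delta <- numeric(length(q))
    for (r in seq_along(dq)) {
      delta[bi[r]] <- delta[bi[r]] + dq[r]
      delta[bj[r]] <- delta[bj[r]] - dq[r]
    }
    q <- q + delta
    if (!length(dq) || max(abs(dq)) < tol) {
      m$atoms$charge <- q
      return(m)
    }
  }
  stop("Gasteiger charge iteration did not converge within ", max_iter,
       " cycles")
}
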