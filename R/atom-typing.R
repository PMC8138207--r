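#' Assign SYBYL atom types from elements and bonds
#'
#' Hybridization/aromaticity-based typing in the SYBYL dialect used throughout
#' the package: aromatic carbon \code{C.ar}, sp3 carbon \code{C.3}, hydroxyl
#' oxygen \code{O.3}, carbonyl oxygen \code{O.2}, carboxylate oxygens
#' \code{O.co2}, amide nitrogen \code{N.am}, and so on. Types already matching
#' the SYBYL pattern (containing a dot, or H/halogens) are recomputed anyway so
#' the function is idempotent on its own output.
#'
#' @param m a \code{qmol} with elements and bond orders known.
#' @return the molecule with \code{atoms$type} filled in.
#' @export
assign_atom_types <- function(m) {
  el <- m$atoms$element
  nb <- neighbor_list(m)
  b <- m$bonds
  ord <- function(i, j) {
    hit <- (b$i == i & b$j == j) | (b$i == j & b$j == i)
    b$order[hit][1]
  }
  orders_of <- lapply(seq_len(n_atoms(m)), function(k)
    vapply(nb[[k]], function(j) ord(k, j), ""))
  fc <- m$atoms$formal_charge
  types <- character(n_atoms(m))
  for (k in seq_len(n_atoms(m))) {
    o <- orders_of[[k]]
    nbs <- nb[[k]]
    types[k] <- switch(el[k],
      H = "H",
      C = {
        if (any(o == "ar")) "C.ar"
        else if (any(o == "3")) "C.1"
        else if (sum(o == "2") == 2) "C.1"   # cumulated sp carbon
        else if (any(o == "2")) "C.2"
        else "C.3"
      },
      O = {
        cnb <- nbs[el[nbs] == "C"]
        carboxylate <- length(cnb) == 1 && {
          oo <- nb[[cnb]][el[nb[[cnb]]] == "O"]
          length(oo) == 2 && sum(fc[oo]) <= -1
        }
        if (carboxylate) "O.co2"
        else if (any(o == "2") || any(o == "ar")) "O.2"
        else "O.3"
      },
      N = {
        if (any(o == "ar")) "N.ar"
        else if (any(o == "3")) "N.1"
        else if (any(o == "2")) "N.2"
        else if (fc[k] > 0) "N.4"
        else {
          amide <- any(vapply(nbs[el[nbs] == "C"], function(cc)
            any(el[nb[[cc]]] == "O" &
                  vapply(nb[[cc]], function(j) ord(cc, j), "") == "2"),
            TRUE))
          if (isTRUE(amide)) "N.am" else "N.3"
        }
      },
      S = if (any(o == "2")) "S.2" else "S.3",
      P = "P.3",
      F = "F", Cl = "Cl", Br = "Br", I = "I",
      stop(sprintf("cannot assign a SYBYL type to atom %d (element '%s')",
                   k, el[k]))
    )
  }
  m$atoms$type <- types
  m
}
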