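# Honeycomb lattice convention: hexagon-center origin, C-C bond length 1.42 A,
# armchair axis along x, sheet in the z = 0 plane. Edge carbons (two carbon
# neighbours) are hydrogen-terminated in-plane at 1.09 A. Calibrated so the
# 21.760 A circular cut contains 138 C + 30 H = 168 atoms.

CC_BOND <- 1.42
CH_BOND <- 1.09

# all carbon sites of a finite honeycomb patch covering radius rmax
honeycomb_sites <- function(rmax) {
  a <- CC_BOND
  a1 <- c(1.5 * a,  sqrt(3) * a / 2)
  a2 <- c(1.5 * a, -sqrt(3) * a / 2)
  nmax <- ceiling(rmax / a) + 2
  grid <- expand.grid(n1 = -nmax:nmax, n2 = -nmax:nmax)
  origins <- cbind(grid$n1 * a1[1] + grid$n2 * a2[1],
                   grid$n1 * a1[2] + grid$n2 * a2[2])
  pts <- rbind(origins, sweep(origins, 2, c(a, 0), `+`))
  # shift so that a hexagon center sits at the origin
  pts <- sweep(pts, 2, c(a / 2, sqrt(3) * a / 2))
  unique(round(pts, 6))
}

# assemble a terminated sheet from selected carbon xy positions
assemble_sheet <- function(pts, name, annotations) {
  if (nrow(pts) < 6) stop("cut region too small to contain one hexagon ring")
  # drop dangling carbons (< 2 carbon neighbours) until stable
  repeat {
    d <- as.matrix(stats::dist(pts))
    nb <- rowSums(d > 0.1 & d < CC_BOND * 1.1)
    if (all(nb >= 2)) break
    pts <- pts[nb >= 2, , drop = FALSE]
    if (nrow(pts) < 6) stop("cut region too small to contain one hexagon ring")
  }
  nC <- nrow(pts)
  d <- as.matrix(stats::dist(pts))
  adj <- d > 0.1 & d < CC_BOND * 1.1
  atoms <- data.frame(element = "C", type = "C.ar",
                      x = pts[, 1], y = pts[, 2], z = 0,
                      stringsAsFactors = FALSE)
  pr <- which(upper.tri(adj) & adj, arr.ind = TRUE)
  bonds <- data.frame(i = pr[, 1], j = pr[, 2], order = "ar",
                      stringsAsFactors = FALSE)
  # one in-plane hydrogen per two-coordinate edge carbon
  for (k in which(rowSums(adj) == 2)) {
    nbs <- which(adj[k, ])
    dir <- pts[k, ] - colMeans(pts[nbs, , drop = FALSE])
    dir <- dir / sqrt(sum(dir^2))
    atoms <- rbind(atoms, data.frame(element = "H", type = "H",
                                     x = pts[k, 1] + CH_BOND * dir[1],
                                     y = pts[k, 2] + CH_BOND * dir[2],
                                     z = 0, stringsAsFactors = FALSE))
    bonds <- rbind(bonds, data.frame(i = k, j = nrow(atoms), order = "1",
                                     stringsAsFactors = FALSE))
  }
  annotations$n_carbon <- nC
  molecule(atoms, bonds, name = name, annotations = annotations)
}

#' Build a circular pristine graphene model
#'
#' Cuts a honeycomb lattice (C-C 1.42 Angstrom, hexagon center at the origin,
#' armchair axis along x) with a circle of the given diameter: carbons are
#' kept iff their distance from the center is at most the radius, dangling
#' carbons are dropped, and every remaining two-coordinate edge carbon is
#' terminated with an in-plane hydrogen. All ring carbons are typed
#' \code{C.ar} and ring bonds aromatic; the sheet lies in the z = 0 plane.
#' Under this convention a diameter of 21.760 Angstrom yields 168 atoms
#' (138 C + 30 H).
#'
#' @param diameter circle diameter in Angstrom; must be at least about one
#'   hexagon (2.84 Angstrom).
#' @return a \code{qmol} with annotations \code{shape}, \code{diameter} and
#'   \code{n_carbon}.
#' @examples
#' g <- build_circular_graphene(21.760)
#' n_atoms(g)  # 168
#' @export
build_circular_graphene <- function(diameter) {
  if (diameter < 2 * CC_BOND) stop("diameter too small to contain one ring")
  r <- diameter / 2
  pts <- honeycomb_sites(r)
  keep <- sqrt(rowSums(pts^2)) <= r + 1e-9
  assemble_sheet(pts[keep, , drop = FALSE],
                 name = sprintf("graphene_circ_%.3f", diameter),
                 annotations = list(shape = "circular", diameter = diameter))
}

#' Build a rectangular pristine graphene model
#'
#' Axis-aligned rectangular cut of the same lattice as
#' [build_circular_graphene()], with identical termination and typing rules.
#'
#' @param width extent along x (Angstrom).
#' @param height extent along y (Angstrom).
#' @return a \code{qmol} with annotations \code{shape}, \code{width},
#'   \code{height} and \code{n_carbon}.
#' @export
build_rectangular_graphene <- function(width, height) {
  if (width < 2 * CC_BOND || height < 2 * CC_BOND)
    stop("degenerate dimensions: each side must hold at least one hexagon")
  pts <- honeycomb_sites(sqrt(width^2 + height^2) / 2)
  keep <- abs(pts[, 1]) <= width / 2 + 1e-9 & abs(pts[, 2]) <= height / 2 + 1e-9
  assemble_sheet(pts[keep, , drop = FALSE],
                 name = sprintf("graphene_rect_%.1fx%.1f", width, height),
                 annotations = list(shape = "rectangular",
                                    width = width, height = height))
}

#' Inspect aromaticity of a structure
#'
#' Applies the two checks used to accept generated GO models: Hueckel's
#' 4n + 2 rule on the pi-electron count (one electron per conjugated aromatic
#' carbon) and full connectivity of the pi system (all aromatic atoms joined
#' through aromatic bonds form a single component). Functionalized carbons are
#' re-typed by the builder and therefore drop out of the count.
#'
#' @param m a \code{qmol} with atom types assigned.
#' @return list of class \code{aromaticity_report} with fields
#'   \code{pi_electron_count}, \code{hueckel_ok} and \code{pi_connected}.
#' @export
check_hueckel <- function(m) {
  pi_atoms <- which(m$atoms$type %in% c("C.ar", "N.ar"))
  n_pi <- length(pi_atoms)
  ok <- n_pi > 0 && n_pi %% 4 == 2
  connected <- FALSE
  if (n_pi > 0) {
    b <- m$bonds[m$bonds$order == "ar", , drop = FALSE]
    b <- b[b$i %in% pi_atoms & b$j %in% pi_atoms, , drop = FALSE]
    idx <- match(seq_len(n_atoms(m)), pi_atoms)
    adj <- vector("list", n_pi)
    for (r in seq_len(nrow(b))) {
      bi <- idx[b$i[r]]; bj <- idx[b$j[r]]
      adj[[bi]] <- c(adj[[bi]], bj)
      adj[[bj]] <- c(adj[[bj]], bi)
    }
    seen <- logical(n_pi); queue <- 1L; seen[1] <- TRUE
    while (length(queue)) {
      k <- queue[1]; queue <- queue[-1]
      fresh <- adj[[k]][!seen[adj[[k]]]]
      seen[fresh] <- TRUE
      queue <- c(queue, fresh)
    }
    connected <- all(seen)
  }
  structure(list(pi_electron_count = n_pi, hueckel_ok = ok,
                 pi_connected = connected),
            class = "aromaticity_report")
}

#' @export
print.aromaticity_report <- function(x, ...) {
  cat(sprintf("<aromaticity_report> %d pi electrons; 4n+2: %s; connected: %s\n",
              x$pi_electron_count, x$hueckel_ok, x$pi_connected))
  invisible(x)
}
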