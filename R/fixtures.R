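# Deterministic catalog of small test molecules and mini-carriers. Everything
# is generated from internal templates or the lattice builder, so the whole
# package is testable offline. Fixtures come back typed and charged.

hexagon_ring <- function(radius = 1.395, z = 0) {
  ang <- seq(0, 2 * pi, length.out = 7)[1:6]
  cbind(radius * cos(ang), radius * sin(ang), z)
}

fixture_benzene <- function() {
  ring <- hexagon_ring()
  h <- hexagon_ring(radius = 1.395 + 1.09)
  atoms <- data.frame(element = rep(c("C", "H"), each = 6),
                      type = rep(c("C.ar", "H"), each = 6),
                      x = c(ring[, 1], h[, 1]), y = c(ring[, 2], h[, 2]),
                      z = 0, stringsAsFactors = FALSE)
  bonds <- rbind(
    data.frame(i = 1:6, j = c(2:6, 1), order = "ar"),
    data.frame(i = 1:6, j = 7:12, order = "1"))
  molecule(atoms, bonds, name = "benzene")
}

fixture_biphenyl <- function() {
  # two coplanar rings bridged by a 1.48 A single bond along x
  r <- 1.395
  shift <- r + 1.48 / 2
  ring1 <- hexagon_ring(r); ring1[, 1] <- ring1[, 1] - shift
  ring2 <- hexagon_ring(r); ring2[, 1] <- ring2[, 1] + shift
  # ring1 atom 1 sits at x = r - shift (toward ring2); ring2 atom 4 faces it
  atoms <- data.frame(element = "C", type = "C.ar",
                      x = c(ring1[, 1], ring2[, 1]),
                      y = c(ring1[, 2], ring2[, 2]), z = 0,
                      stringsAsFactors = FALSE)
  bonds <- rbind(
    data.frame(i = 1:6, j = c(2:6, 1), order = "ar"),
    data.frame(i = 7:12, j = c(8:12, 7), order = "ar"),
    data.frame(i = 1, j = 10, order = "1"))
  # hydrogens on every carbon except the two bridgeheads (1 and 10)
  m <- molecule(atoms, bonds, name = "biphenyl")
  nb <- neighbor_list(m)
  a <- m$atoms; b <- m$bonds
  for (k in setdiff(1:12, c(1, 10))) {
    dir <- as.numeric(a[k, c("x", "y", "z")]) -
      colMeans(as.matrix(a[nb[[k]], c("x", "y", "z")]))
    dir <- dir / sqrt(sum(dir^2))
    a <- rbind(a, data.frame(element = "H", type = "H",
                             x = a$x[k] + 1.09 * dir[1],
                             y = a$y[k] + 1.09 * dir[2],
                             z = a$z[k] + 1.09 * dir[3],
                             charge = 0, formal_charge = 0L,
                             stringsAsFactors = FALSE))
    b <- rbind(b, data.frame(i = k, j = nrow(a), order = "1"))
  }
  molecule(a, b, name = "biphenyl")
}

fixture_table <- function(rows, bonds, name) {
  atoms <- do.call(rbind, lapply(rows, function(r)
    data.frame(element = r[1], type = r[1],
               x = as.numeric(r[2]), y = as.numeric(r[3]),
               z = as.numeric(r[4]), stringsAsFactors = FALSE)))
  m <- molecule(atoms, bonds, name = name)
  assign_atom_types(m)
}

fixture_n_butane <- function() {
  rows <- list(
    c("C", -1.5505, -0.3601, 0.4107), c("C", -0.7096, 0.4025, -0.6015),
    c("C", 0.7327, -0.0965, -0.6937), c("C", 1.5329, 0.1260, 0.5803),
    c("H", -1.1919, -0.2001, 1.4317), c("H", -1.5372, -1.4347, 0.2028),
    c("H", -2.5902, -0.0197, 0.3675), c("H", -0.7200, 1.4701, -0.3531),
    c("H", -1.1763, 0.3022, -1.5887), c("H", 1.2315, 0.4311, -1.5155),
    c("H", 0.7431, -1.1626, -0.9490), c("H", 1.1414, -0.4710, 1.4092),
    c("H", 1.5180, 1.1801, 0.8748), c("H", 2.5761, -0.1674, 0.4245))
  bonds <- data.frame(
    i = c(1, 2, 3, 1, 1, 1, 2, 2, 3, 3, 4, 4, 4),
    j = c(2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 13, 14),
    order = "1")
  fixture_table(rows, bonds, "n_butane")
}

fixture_methanol <- function() {
  rows <- list(
    c("C", -0.3706, -0.0212, -0.0012), c("O", 0.9450, -0.3921, -0.3697),
    c("H", -0.4924, -0.1322, 1.0791), c("H", -1.0808, -0.6737, -0.5145),
    c("H", -0.5536, 1.0154, -0.2947), c("H", 1.5524, 0.2038, 0.1010))
  bonds <- data.frame(i = c(1, 1, 1, 1, 2), j = c(2, 3, 4, 5, 6), order = "1")
  fixture_table(rows, bonds, "methanol")
}

# seven fused rings (coronene-like patch): the 7.6 A circular lattice cut
fixture_coronene_patch <- function() {
  m <- build_circular_graphene(7.6)
  m$name <- "coronene_patch"
  m
}

fixture_go_patch_oh <- function() {
  # coronene patch decorated by hand with one basal hydroxyl (upper face);
  # built directly rather than through the ensemble generator because a
  # 24-carbon patch cannot keep 4n+2 after losing one pi carbon
  base <- fixture_coronene_patch()
  sites <- sheet_sites(base)
  pl <- list(oh = sites$basal[1], ep = matrix(integer(), 0, 2),
             cooh = integer(), cooh_h = integer(), side = 1)
  m <- apply_placement(base, pl)
  m$name <- "go_patch_oh"
  m
}

FIXTURE_BUILDERS <- list(
  benzene = fixture_benzene,
  n_butane = fixture_n_butane,
  biphenyl = fixture_biphenyl,
  methanol = fixture_methanol,
  coronene_patch = fixture_coronene_patch,
  go_patch_oh = fixture_go_patch_oh)

#' Built-in test molecules and mini-carriers
#'
#' Deterministic catalog used by the examples and the test-suite: benzene,
#' n-butane, biphenyl, methanol, a seven-ring coronene-like graphene patch
#' and the same patch bearing one hydroxyl. Structures come back typed,
#' Gasteiger-charged and validated; repeated calls are bit-identical.
#'
#' @param name one of \code{fixture_names()}.
#' @return a \code{qmol}.
#' @examples
#' make_fixture("benzene")
#' @export
make_fixture <- function(name) {
  b <- FIXTURE_BUILDERS[[name]]
  if (is.null(b))
    stop("unknown fixture '", name, "'; available: ",
         paste(names(FIXTURE_BUILDERS), collapse = ", "))
  m <- b()
  m <- assign_partial_charges(m)
  validate_molecule(m)
  m
}

#' @rdname make_fixture
#' @export
fixture_names <- function() names(FIXTURE_BUILDERS)
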