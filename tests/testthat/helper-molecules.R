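# shared, lazily built test molecules (typed + charged)

fx <- local({
  cache <- list()
  function(name) {
    if (is.null(cache[[name]])) cache[[name]] <<- make_fixture(name)
    cache[[name]]
  }
})

# a rigid rotation matrix about an arbitrary axis
rotation_matrix <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# renumber atoms of a molecule under a permutation
renumber_molecule <- function(m, perm) {
  inv <- match(seq_along(perm), perm)
  a <- m$atoms[perm, ]
  b <- m$bonds
  b$i <- inv[b$i]; b$j <- inv[b$j]
  molecule(a, b, name = paste0(m$name, "_renumbered"))
}
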