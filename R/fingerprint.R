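# Extended-connectivity (Morgan) fingerprint, radius 5 ("ECFP10"), folded to
# 2048 bits. Works on the heavy-atom molecular graph only: 3D coordinates and
# atom numbering never enter the hash, so rigidly moved or renumbered copies
# of a model share a fingerprint.

# deterministic 31-bit rolling hash over a non-negative integer vector;
# arithmetic stays below 2^52 so doubles are exact
hash_ints <- function(v) {
  h <- 99991
  for (x in v) h <- (h * 1000003 + (x %% 2147483647)) %% 2147483647
  h
}

BOND_LABEL <- c("1" = 1, "2" = 2, "3" = 3, "ar" = 4, "am" = 5)

#' Circular (extended-connectivity) fingerprint of a structure
#'
#' Morgan-style iterative neighbourhood hashing to radius 5 (diameter 10) on
#' the heavy-atom graph, folded onto 2048 bits. Initial atom invariants are
#' (atomic element, heavy degree, attached hydrogen count, formal charge,
#' aromatic flag); each iteration hashes an atom's current identifier with the
#' sorted (bond label, neighbour identifier) list. Used to detect GO models
#' that are the same chemical structure in different orientations or atom
#' orders.
#'
#' @param m a \code{qmol} with elements and bonds assigned.
#' @return logical vector of length 2048 (class \code{ecfp}).
#' @export
circular_fingerprint <- function(m) {
  el <- m$atoms$element
  heavy <- which(el != "H")
  idx <- match(seq_len(n_atoms(m)), heavy)
  nb <- neighbor_list(m)
  b <- m$bonds
  key <- paste(pmin(b$i, b$j), pmax(b$i, b$j))
  order_of <- structure(BOND_LABEL[b$order], names = key)
  elem_code <- as.integer(factor(el, levels = c(
    "H", "C", "N", "O", "F", "P", "S", "Cl", "Br", "I", "B", "Si")))
  elem_code[is.na(elem_code)] <- 99L
  aromatic <- rep(0L, n_atoms(m))
  for (r in seq_len(nrow(b))) if (b$order[r] == "ar")
    aromatic[c(b$i[r], b$j[r])] <- 1L
  ids <- vapply(heavy, function(k) {
    nbs <- nb[[k]]
    hash_ints(c(elem_code[k], sum(el[nbs] != "H"), sum(el[nbs] == "H"),
                m$atoms$formal_charge[k] + 8, aromatic[k]))
  }, 0)
  features <- ids
  for (radius in 1:5) {
    new_ids <- vapply(seq_along(heavy), function(hk) {
      k <- heavy[hk]
      nbs <- nb[[k]]; nbs <- nbs[el[nbs] != "H"]
      if (!length(nbs)) return(hash_ints(c(radius, ids[hk])))
      lab <- vapply(nbs, function(j)
        order_of[[paste(min(k, j), max(k, j))]], 0)
      pairs <- cbind(lab, ids[idx[nbs]])
      pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
      hash_ints(c(radius, ids[hk], as.vector(t(pairs))))
    }, 0)
    ids <- new_ids
    features <- c(features, ids)
  }
  bits <- logical(2048)
  bits[(features %% 2048) + 1] <- TRUE
  structure(bits, class = "ecfp")
}

# compact string key for fingerprint comparison
fingerprint_key <- function(fp) paste(which(fp), collapse = ",")

#' Remove duplicated models by fingerprint equality
#'
#' Keeps the first model of each distinct 2048-bit circular fingerprint,
#' preserving input order. Two models sharing a fingerprint are treated as
#' duplicates without any further graph comparison (bit collisions are
#' accepted).
#'
#' @param models list of \code{qmol}.
#' @return filtered list.
#' @export
deduplicate_models <- function(models) {
  keys <- vapply(models, function(m) fingerprint_key(circular_fingerprint(m)), "")
  models[!duplicated(keys)]
}
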