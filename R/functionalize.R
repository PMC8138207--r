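# GO ensemble generation: decorate a pristine sheet with hydroxyl, epoxy and
# carboxyl groups. Every substituted carbon leaves the pi system (the hydroxyl
# carbon, both epoxy carbons and the carboxylated edge carbon), so one
# (OH, epoxy, COOH) triple removes 4 pi electrons and a sheet with 4n+2 pi
# electrons keeps satisfying Hueckel's rule at every functionalization level.

#' Specify a GO functionalization request
#'
#' @param n_hydroxyl,n_epoxy,n_carboxyl non-negative group counts; not all
#'   zero. Hydroxyl and epoxy go on basal-plane (interior) carbons, epoxy
#'   bridging two adjacent ones; carboxyl substitutes an edge hydrogen.
#' @param surface_mode \code{"upper"}, \code{"lower"} or \code{"dual"}: which
#'   face(s) of the sheet receive the basal groups.
#' @param manner \code{"random"} (seeded sampling without replacement) or
#'   \code{"systematic"} (lexicographic enumeration of placement combinations).
#' @param max_models number of models to emit.
#' @param seed RNG seed used by the random manner.
#' @return list of class \code{functionalization_spec}.
#' @export
functionalization_spec <- function(n_hydroxyl = 0, n_epoxy = 0, n_carboxyl = 0,
                                   surface_mode = c("upper", "lower", "dual"),
                                   manner = c("random", "systematic"),
                                   max_models = 1, seed = 1L) {
  surface_mode <- match.arg(surface_mode)
  manner <- match.arg(manner)
  if (max_models < 1) stop("max_models must be >= 1")
  if (n_hydroxyl + n_epoxy + n_carboxyl == 0)
    stop("nothing to do: all functional-group counts are zero")
  if (min(n_hydroxyl, n_epoxy, n_carboxyl) < 0) stop("negative group count")
  structure(list(n_hydroxyl = n_hydroxyl, n_epoxy = n_epoxy,
                 n_carboxyl = n_carboxyl, surface_mode = surface_mode,
                 manner = manner, max_models = max_models, seed = seed),
            class = "functionalization_spec")
}

# run code under a temporary RNG state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# classify carbon sites of a pristine sheet
sheet_sites <- function(base) {
  nb <- neighbor_list(base)
  el <- base$atoms$element
  carbons <- which(el == "C")
  n_c_nb <- vapply(carbons, function(k) sum(el[nb[[k]]] == "C"), 0L)
  h_of <- vapply(carbons, function(k) {
    h <- nb[[k]][el[nb[[k]]] == "H"]
    if (length(h)) h[1] else NA_integer_
  }, 0L)
  basal <- carbons[n_c_nb == 3]
  edge <- carbons[!is.na(h_of)]
  b <- base$bonds
  cc <- b[b$i %in% basal & b$j %in% basal, c("i", "j")]
  list(basal = basal, edge = edge, edge_h = h_of[!is.na(h_of)],
       basal_pairs = as.matrix(cc))
}

rot_xy <- function(v, deg) {
  t <- deg * pi / 180
  c(cos(t) * v[1] - sin(t) * v[2], sin(t) * v[1] + cos(t) * v[2], v[3])
}

# attach the three group types to a copy of the base sheet; placement is a
# list(oh = sites, ep = pair matrix, cooh = sites, side = +-1 per group)
apply_placement <- function(base, pl) {
  m <- base
  a <- m$atoms; b <- m$bonds
  add_atom <- function(element, type, xyz) {
    a <<- rbind(a, data.frame(element = element, type = type,
                              x = xyz[1], y = xyz[2], z = xyz[3],
                              charge = 0, formal_charge = 0L,
                              stringsAsFactors = FALSE))
    nrow(a)
  }
  add_bond <- function(i, j, order) {
    b <<- rbind(b, data.frame(i = i, j = j, order = order,
                              stringsAsFactors = FALSE))
  }
  demote <- function(carbons, new_type) {
    a$type[carbons] <<- new_type
    hit <- (b$i %in% carbons | b$j %in% carbons) & b$order == "ar"
    b$order[hit] <<- "1"
  }
  side <- pl$side; s_idx <- 0
  for (c_oh in pl$oh) {
    s_idx <- s_idx + 1; s <- side[s_idx]
    p <- as.numeric(a[c_oh, c("x", "y", "z")])
    o <- add_atom("O", "O.3", p + c(0, 0, s * 1.43))
    h <- add_atom("H", "H", p + c(0.91, 0, s * (1.43 + 0.30)))
    demote(c_oh, "C.3")
    add_bond(c_oh, o, "1"); add_bond(o, h, "1")
  }
  if (length(pl$ep)) for (r in seq_len(nrow(pl$ep))) {
    s_idx <- s_idx + 1; s <- side[s_idx]
    c1 <- pl$ep[r, 1]; c2 <- pl$ep[r, 2]
    mid <- colMeans(as.matrix(a[c(c1, c2), c("x", "y", "z")]))
    o <- add_atom("O", "O.3", mid + c(0, 0, s * 1.25))
    demote(c(c1, c2), "C.3")
    add_bond(c1, o, "1"); add_bond(c2, o, "1")
  }
  drop_atoms <- integer()
  k_c <- 0
  for (c_ed in pl$cooh) {
    k_c <- k_c + 1
    h_old <- pl$cooh_h[k_c]
    p <- as.numeric(a[c_ed, c("x", "y", "z")])
    d <- as.numeric(a[h_old, c("x", "y", "z")]) - p
    d <- d / sqrt(sum(d^2))
    cc <- add_atom("C", "C.2", p + 1.50 * d)
    o2 <- add_atom("O", "O.2", p + 1.50 * d + 1.21 * rot_xy(d, 120))
    o3 <- add_atom("O", "O.3", p + 1.50 * d + 1.34 * rot_xy(d, -120))
    hh <- add_atom("H", "H", p + 1.50 * d + 1.34 * rot_xy(d, -120) + 0.97 * d)
    demote(c_ed, "C.2")
    add_bond(c_ed, cc, "1"); add_bond(cc, o2, "2")
    add_bond(cc, o3, "1"); add_bond(o3, hh, "1")
    drop_atoms <- c(drop_atoms, h_old)
  }
  if (length(drop_atoms)) {
    keep <- setdiff(seq_len(nrow(a)), drop_atoms)
    remap <- match(seq_len(nrow(a)), keep)
    a <- a[keep, , drop = FALSE]
    b <- b[!(b$i %in% drop_atoms | b$j %in% drop_atoms), , drop = FALSE]
    b$i <- remap[b$i]; b$j <- remap[b$j]
  }
  molecule(a, b, name = m$name, annotations = m$annotations)
}

# draw one random placement; returns NULL when sites collide
draw_placement <- function(sites, spec) {
  used <- integer()
  pick <- function(pool, n) {
    pool <- setdiff(pool, used)
    if (length(pool) < n) return(NULL)
    out <- if (length(pool) == 1) pool else sample(pool, n)
    used <<- c(used, out)
    out
  }
  oh <- pick(sites$basal, spec$n_hydroxyl)
  if (is.null(oh) && spec$n_hydroxyl > 0) return(NULL)
  ep <- matrix(integer(), 0, 2)
  if (spec$n_epoxy > 0) {
    for (k in seq_len(spec$n_epoxy)) {
      free <- sites$basal_pairs[!(sites$basal_pairs[, 1] %in% used) &
                                !(sites$basal_pairs[, 2] %in% used), ,
                                drop = FALSE]
      if (!nrow(free)) return(NULL)
      r <- if (nrow(free) == 1) 1 else sample(nrow(free), 1)
      ep <- rbind(ep, free[r, ])
      used <- c(used, free[r, ])
    }
  }
  cooh <- pick(sites$edge, spec$n_carboxyl)
  if (is.null(cooh) && spec$n_carboxyl > 0) return(NULL)
  n_groups <- spec$n_hydroxyl + spec$n_epoxy
  side <- switch(spec$surface_mode,
                 upper = rep(1, n_groups),
                 lower = rep(-1, n_groups),
                 dual = sample(c(-1, 1), n_groups, replace = TRUE))
  list(oh = oh, ep = ep, cooh = cooh,
       cooh_h = sites$edge_h[match(cooh, sites$edge)], side = side)
}

# deterministic placement stream for the systematic manner: lexicographic
# combinations of hydroxyl sites x epoxy pairs x carboxyl sites
systematic_placements <- function(sites, spec, limit) {
  oh_c <- if (spec$n_hydroxyl) utils::combn(sites$basal, spec$n_hydroxyl,
                                            simplify = FALSE) else list(integer())
  ep_c <- if (spec$n_epoxy) utils::combn(seq_len(nrow(sites$basal_pairs)),
                                         spec$n_epoxy, simplify = FALSE) else list(integer())
  co_c <- if (spec$n_carboxyl) utils::combn(sites$edge, spec$n_carboxyl,
                                            simplify = FALSE) else list(integer())
  out <- list()
  n_groups <- spec$n_hydroxyl + spec$n_epoxy
  side <- switch(spec$surface_mode,
                 upper = rep(1, n_groups), lower = rep(-1, n_groups),
                 dual = rep_len(c(1, -1), n_groups))
  for (oh in oh_c) {
    for (epi in ep_c) {
      ep <- sites$basal_pairs[epi, , drop = FALSE]
      if (anyDuplicated(c(oh, as.vector(ep)))) next
      for (cooh in co_c) {
        out[[length(out) + 1]] <-
          list(oh = oh, ep = ep, cooh = cooh,
               cooh_h = sites$edge_h[match(cooh, sites$edge)], side = side)
        if (length(out) >= limit) return(out)
      }
    }
  }
  out
}

#' Generate an ensemble of graphene-oxide models
#'
#' Decorates a pristine sheet with the requested numbers of hydroxyl, epoxy
#' and carboxyl groups. Hydroxyl and epoxy oxygens sit on basal-plane carbons
#' (epoxy bridging two adjacent ones) on the face(s) chosen by
#' \code{surface_mode}; carboxyl replaces an edge hydrogen. Substituted
#' carbons are re-typed out of the aromatic system. Candidate models that fail
#' [check_hueckel()] (4n + 2 or pi connectivity) or that duplicate an already
#' accepted model's 2048-bit circular fingerprint are rejected and redrawn, so
#' the returned ensemble is fingerprint-unique.
#'
#' @param base pristine sheet from [build_circular_graphene()] or
#'   [build_rectangular_graphene()].
#' @param spec a [functionalization_spec()].
#' @return list of \code{max_models} GO models (\code{qmol}).
#' @examples
#' g <- build_circular_graphene(12)
#' gos <- functionalize_graphene(g, functionalization_spec(
#'   n_hydroxyl = 1, n_epoxy = 1, n_carboxyl = 1, max_models = 3, seed = 7))
#' length(gos)
#' @export
functionalize_graphene <- function(base, spec) {
  stopifnot(inherits(spec, "functionalization_spec"))
  # every substituted carbon leaves the pi system (OH: 1, epoxy: 2, COOH: 1),
  # so 4n+2 can only be preserved when the total removal is a multiple of 4 -
  # fail fast instead of rejecting every candidate
  removal <- spec$n_hydroxyl + 2 * spec$n_epoxy + spec$n_carboxyl
  base_pi <- check_hueckel(base)$pi_electron_count
  if (base_pi - removal <= 0 || (base_pi - removal) %% 4 != 2)
    stop(sprintf(paste0("requested counts remove %d pi carbons from %d, ",
                        "leaving %d: cannot satisfy Hueckel's 4n+2 rule ",
                        "(the removal must be a multiple of 4)"),
                 removal, base_pi, base_pi - removal))
  sites <- sheet_sites(base)
  if (spec$n_hydroxyl + 2 * spec$n_epoxy > length(sites$basal))
    stop("not enough basal-plane carbons for the requested hydroxyl/epoxy count")
  if (spec$n_carboxyl > length(sites$edge))
    stop("not enough edge carbons for the requested carboxyl count")
  accepted <- list(); fps <- character()
  attempts <- 0
  max_attempts <- 200 + 60 * spec$max_models
  if (spec$manner == "systematic") {
    stream <- systematic_placements(sites, spec, limit = 50 * spec$max_models)
    stream_i <- 0
  }
  with_seed(spec$seed, {
    while (length(accepted) < spec$max_models) {
      attempts <- attempts + 1
      if (attempts > max_attempts)
        stop(sprintf(paste0("could not generate %d acceptable GO models in %d ",
                            "attempts (constraints: Hueckel 4n+2, pi ",
                            "connectivity, fingerprint uniqueness)"),
                     spec$max_models, max_attempts))
      if (spec$manner == "random") {
        pl <- draw_placement(sites, spec)
      } else {
        stream_i <- stream_i + 1
        if (stream_i > length(stream))
          stop("systematic enumeration exhausted before reaching max_models")
        pl <- stream[[stream_i]]
      }
      if (is.null(pl)) next
      cand <- apply_placement(base, pl)
      rep <- check_hueckel(cand)
      if (!rep$hueckel_ok || !rep$pi_connected) next
      fp <- fingerprint_key(circular_fingerprint(cand))
      if (fp %in% fps) next
      cand$name <- sprintf("%s_GO%d", base$name, length(accepted) + 1)
      cand$annotations$functionalization <-
        list(n_hydroxyl = spec$n_hydroxyl, n_epoxy = spec$n_epoxy,
             n_carboxyl = spec$n_carboxyl)
      fps <- c(fps, fp)
      accepted[[length(accepted) + 1]] <- cand
    }
  })
  accepted
}

#' Count functional groups on a GO model
#'
#' Substructure counts used to verify that an emitted model carries exactly
#' the requested decoration: hydroxyl = O.3 bonded to one sheet carbon and one
#' H; epoxy = O.3 bridging two carbons; carboxyl = C.2 bonded to one O.2 and
#' one O.3-H.
#'
#' @param m a GO model.
#' @return named integer vector \code{c(hydroxyl=, epoxy=, carboxyl=)}.
#' @export
count_functional_groups <- function(m) {
  nb <- neighbor_list(m)
  el <- m$atoms$element; ty <- m$atoms$type
  n_oh <- n_ep <- n_co <- 0L
  for (k in which(ty == "O.3")) {
    nbs <- nb[[k]]
    nC <- sum(el[nbs] == "C"); nH <- sum(el[nbs] == "H")
    if (nC == 2 && nH == 0) n_ep <- n_ep + 1L
    if (nC == 1 && nH == 1) {
      # hydroxyl oxygen: carboxylic O-H is counted with its carbonyl carbon
      cnb <- nbs[el[nbs] == "C"]
      has_o2 <- any(ty[nb[[cnb]]] == "O.2")
      if (has_o2) n_co <- n_co + 1L else n_oh <- n_oh + 1L
    }
  }
  c(hydroxyl = n_oh, epoxy = n_ep, carboxyl = n_co)
}
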