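# Batch screening of a ligand library against one carrier: hydrophobicity and
# size pre-filters, repeated cascade runs per ligand, ranking by average
# binding energy (most negative first).

# Crippen-style atomic logP contributions keyed by SYBYL type. A coarse
# surrogate for a full fragment scheme: per-atom additive increments chosen so
# common hydrophobic scaffolds land near their literature logP.
LOGP_CONTRIB <- c(
  "C.3" = 0.14, "C.2" = 0.11, "C.ar" = 0.29, "C.1" = 0.13,
  "H" = 0.11,
  "O.3" = -0.55, "O.2" = -0.25, "O.co2" = -0.40,
  "N.3" = -0.70, "N.2" = -0.40, "N.ar" = -0.26, "N.am" = -0.70,
  "N.1" = -0.40, "N.4" = -1.00,
  "S.3" = 0.40, "S.2" = 0.40, "P.3" = 0.00,
  "F" = 0.26, "Cl" = 0.64, "Br" = 0.81, "I" = 1.00)

#' Estimate logP by atomic contributions
#'
#' Crippen-style additive estimate over SYBYL atom types; hydrogens on
#' heteroatoms count as polar (contribution 0). Intended for the coarse
#' hydrophobicity pre-filter of a screen, not as a reference logP.
#'
#' @param m a \code{qmol} with types assigned.
#' @return estimated logP (dimensionless).
#' @export
crippen_logp <- function(m) {
  ty <- m$atoms$type
  contrib <- LOGP_CONTRIB[ty]
  contrib[is.na(contrib)] <- 0
  # hydrogens bound to N/O are polar, not lipophilic
  nb <- neighbor_list(m)
  h <- which(m$atoms$element == "H")
  polar_h <- h[vapply(h, function(k)
    any(m$atoms$element[nb[[k]]] %in% c("N", "O")), TRUE)]
  contrib[polar_h] <- 0
  sum(contrib)
}

#' Pre-filter a screening library
#'
#' Keeps ligands that are (a) hydrophobic enough, estimated logP strictly
#' greater than \code{logp_threshold}, and (b) small enough to fit the
#' carrier: longest intramolecular distance at most the carrier diameter
#' (circular) or smallest side (rectangular).
#'
#' @param ligands list of \code{qmol} with types assigned.
#' @param carrier carrier built by this package (its annotations carry the
#'   diameter or the rectangle sides).
#' @param logp_threshold hydrophobicity cutoff (default 5.0).
#' @return the retained ligands; attribute \code{filter_counts} records how
#'   many passed each filter.
#' @export
filter_library <- function(ligands, carrier, logp_threshold = 5.0) {
  ann <- carrier$annotations
  size_limit <- if (!is.null(ann$diameter)) ann$diameter
                else if (!is.null(ann$width)) min(ann$width, ann$height)
                else longest_intramolecular_distance(carrier)
  logp <- vapply(ligands, crippen_logp, 0)
  span <- vapply(ligands, longest_intramolecular_distance, 0)
  pass_logp <- logp > logp_threshold
  pass_size <- span <= size_limit
  keep <- pass_logp & pass_size
  message(sprintf(
    "filter_library: %d/%d pass logP > %.1f; %d/%d fit within %.2f A; %d kept",
    sum(pass_logp), length(ligands), logp_threshold,
    sum(pass_size), length(ligands), size_limit, sum(keep)))
  out <- ligands[keep]
  attr(out, "filter_counts") <- c(input = length(ligands),
                                  logp = sum(pass_logp),
                                  size = sum(pass_size), kept = sum(keep))
  out
}

#' Screen a ligand library against one carrier
#'
#' Runs the cascade \code{repeats} times per ligand (seeds \code{S, S+1, ...}
#' applied to the first layer), records the best pose's binding energy of each
#' repeat, averages them, and ranks ligands by ascending average binding
#' energy (most negative = rank 1, ties broken by ligand id). A failing
#' ligand is flagged, never dropped.
#'
#' @param ligands list of \code{qmol} with types and charges assigned.
#' @param carrier carrier \code{qmol} with types and charges assigned.
#' @param cascade a [cascade_config()].
#' @param repeats runs per ligand (default 3).
#' @param seed base RNG seed; repeat r uses \code{seed + r - 1}.
#' @return data.frame of class \code{screen_records}: \code{ligand},
#'   \code{rank}, \code{avg_binding_energy}, one \code{E_rep*} column per
#'   repeat (kcal/mol) and \code{failed}.
#' @export
screen_library <- function(ligands, carrier, cascade, repeats = 3, seed = 1) {
  stopifnot(repeats >= 1)
  ids <- vapply(seq_along(ligands), function(k) {
    nm <- ligands[[k]]$name
    if (is.null(nm) || !nzchar(nm)) sprintf("ligand_%d", k) else nm
  }, "")
  energies <- matrix(NA_real_, length(ligands), repeats)
  failed <- logical(length(ligands))
  for (k in seq_along(ligands)) {
    for (r in seq_len(repeats)) {
      casc_r <- cascade
      casc_r$layers[[1]]$config$seed <- seed + r - 1
      res <- tryCatch(run_cascade(carrier, ligands[[k]], casc_r),
                      error = function(e) e)
      if (inherits(res, "error")) {
        failed[k] <- TRUE
        warning(sprintf("ligand %s repeat %d failed: %s", ids[k], r,
                        conditionMessage(res)), call. = FALSE)
      } else {
        energies[k, r] <- res$best_pose$energy$E_Delta
      }
    }
  }
  avg <- rowMeans(energies)
  ord <- order(avg, ids, na.last = TRUE)
  rank <- integer(length(ligands))
  rank[ord] <- seq_along(ord)
  out <- data.frame(ligand = ids, rank = rank, avg_binding_energy = avg,
                    stringsAsFactors = FALSE)
  for (r in seq_len(repeats)) out[[sprintf("E_rep%d", r)]] <- energies[, r]
  out$failed <- failed
  out <- out[order(out$rank), ]
  rownames(out) <- NULL
  class(out) <- c("screen_records", class(out))
  out
}
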