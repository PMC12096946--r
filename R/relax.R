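# Greedy rotamer relaxation: after assembling a dimer from per-residue
# default rotamers, side chains at the interface can overlap.  One or two
# greedy passes re-picking each residue's rotamer against the current
# coordinates remove hard clashes without any force-field energetics.

count_clashes <- function(xyz_res, xyz_other, clash = 2.4) {
  if (!nrow(xyz_res) || !nrow(xyz_other)) return(0L)
  d2 <- outer(rowSums(xyz_res^2), rowSums(xyz_other^2), "+") -
    2 * xyz_res %*% t(xyz_other)
  sum(d2 < clash^2)
}

#' Relax side-chain rotamers to remove steric clashes
#'
#' Greedy pass over all residues of a single-model ensemble: each side
#' chain is rebuilt from the built-in rotamer table keeping the chi set
#' with the fewest heavy-atom clashes (< `clash` Angstrom) against the rest
#' of the structure.  Backbone atoms are never moved.
#'
#' Charged side chains (Lys/Arg/Asp/Glu) prefer solvent in real, hydrated
#' structures; among equally clash-free rotamers theirs is chosen to point
#' away from the partner chain(s).
#'
#' @param ens Single-model [StructureEnsemble].
#' @param passes Number of greedy sweeps.
#' @param clash Clash distance threshold, Angstrom.
#' @param orient_charged_outward Apply the solvent-orientation preference
#'   for charged side chains.
#' @return The relaxed ensemble; attribute `clashes` holds the remaining
#'   clash count.
#' @export
relax_rotamers <- function(ens, passes = 2L, clash = 2.4,
                           orient_charged_outward = TRUE) {
  stopifnot(n_models(ens) == 1L)
  a <- ens$atoms
  xyz <- model_xyz(ens, 1L)
  heavy <- !(a$element %in% c("H", "D"))
  res <- residues(ens)
  bb_set <- c("N", "CA", "C", "O", "OXT")
  for (p in seq_len(passes)) {
    for (r in seq_len(nrow(res))) {
      rid <- res$resid[r]
      rots <- ROTAMERS[[rid]]
      if (is.null(rots) || length(rots) < 2) next
      rrows <- which(a$chain == res$chain[r] & a$resno == res$resno[r])
      side_rows <- rrows[!(a$elety[rrows] %in% bb_set)]
      if (!length(side_rows)) next
      other <- which(heavy)
      other <- setdiff(other, rrows)
      Np <- xyz[rrows[a$elety[rrows] == "N"][1], ]
      CAp <- xyz[rrows[a$elety[rrows] == "CA"][1], ]
      Cp <- xyz[rrows[a$elety[rrows] == "C"][1], ]
      charged <- orient_charged_outward &&
        rid %in% c("LYS", "ARG", "ASP", "GLU")
      partner <- which(heavy & a$chain != res$chain[r])
      cands <- lapply(rots, function(chi) {
        sc <- build_sidechain(rid, Np, CAp, Cp, chi = chi)
        list(sc = sc, cl = count_clashes(sc, xyz[other, , drop = FALSE],
                                         clash))
      })
      cls <- vapply(cands, function(x) x$cl, numeric(1))
      best_set <- which(cls == min(cls))
      pick <- best_set[1]
      if (charged && length(partner) && length(best_set) > 1) {
        # solvent preference: farthest from the partner chain(s)
        dmin <- vapply(best_set, function(k) {
          sc <- cands[[k]]$sc
          d2 <- outer(rowSums(sc^2),
                      rowSums(xyz[partner, , drop = FALSE]^2), "+") -
            2 * sc %*% t(xyz[partner, , drop = FALSE])
          min(d2)
        }, numeric(1))
        pick <- best_set[which.max(dmin)]
      }
      best_sc <- cands[[pick]]$sc
      ord <- match(a$elety[side_rows], rownames(best_sc))
      xyz[side_rows, ] <- best_sc[ord, , drop = FALSE]
    }
  }
  out <- ens
  out$xyz[1, , ] <- xyz
  # residual clash tally between non-adjacent residues (covalent neighbours
  # are excluded so peptide-bond geometry is not counted)
  total <- 0L
  for (r in seq_len(nrow(res))) {
    rrows <- which(a$chain == res$chain[r] & a$resno == res$resno[r] & heavy)
    far <- which(heavy & (a$chain != res$chain[r] |
                            abs(a$resno - res$resno[r]) >= 2))
    total <- total + count_clashes(xyz[rrows, , drop = FALSE],
                                   xyz[far, , drop = FALSE], clash)
  }
  attr(out, "meta") <- attr(ens, "meta")
  attr(out, "clashes") <- total %/% 2L
  out
}
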