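# Kabsch-Sander backbone hydrogen-bond energies and a minimal DSSP-style
# alpha-helix assignment (H / E / C collapsed to helix vs not-helix), plus
# per-model and ensemble percentage helicity.

KS_CONST <- 0.084 * 332        # kcal/mol * Angstrom
KS_CUTOFF <- -0.5              # bond called when E < -0.5 kcal/mol
KS_EMIN <- -9.9                # energy floor for near-overlapping geometry
CHAIN_BREAK_CA <- 4.5          # CA-CA distance terminating a segment

# Backbone geometry table for one model: one row per residue with N, CA,
# C, O coordinates, an idealized amide H (built from N, CA and the
# preceding C when the structure carries no hydrogens), segment ids and
# donor capability (PRO and segment starts cannot donate).
backbone_table <- function(ens, chains = NULL, model = 1L) {
  res <- residues(ens, chain = chains)
  xyz <- model_xyz(ens, model)
  get <- function(ch, rn, at) {
    i <- atom_index(ens, ch, rn, at)
    if (is.na(i)) rep(NA_real_, 3) else xyz[i, ]
  }
  n <- nrow(res)
  N <- CA <- C <- O <- H <- matrix(NA_real_, n, 3)
  for (k in seq_len(n)) {
    N[k, ] <- get(res$chain[k], res$resno[k], "N")
    CA[k, ] <- get(res$chain[k], res$resno[k], "CA")
    C[k, ] <- get(res$chain[k], res$resno[k], "C")
    O[k, ] <- get(res$chain[k], res$resno[k], "O")
  }
  seg <- integer(n); sid <- 0L
  for (k in seq_len(n)) {
    newseg <- k == 1 || res$chain[k] != res$chain[k - 1] ||
      res$resno[k] != res$resno[k - 1] + 1L ||
      any(is.na(CA[k, ])) || any(is.na(CA[k - 1, ])) ||
      vnorm(CA[k, ] - CA[k - 1, ]) > CHAIN_BREAK_CA
    if (newseg) sid <- sid + 1L
    seg[k] <- sid
  }
  donor <- rep(TRUE, n)
  for (k in seq_len(n)) {
    has_prev <- k > 1 && seg[k] == seg[k - 1]
    if (res$resid[k] == "PRO" || !has_prev ||
        any(is.na(N[k, ])) || any(is.na(CA[k, ]))) {
      donor[k] <- FALSE
    } else {
      ih <- atom_index(ens, res$chain[k], res$resno[k], "H")
      H[k, ] <- if (!is.na(ih)) xyz[ih, ] else
        amide_h(N[k, ], CA[k, ], C[k - 1, ])
    }
  }
  list(res = res, N = N, CA = CA, C = C, O = O, H = H, seg = seg,
       donor = donor)
}

ks_energy_pair <- function(Nd, Hd, Ca, Oa) {
  rON <- vnorm(Oa - Nd); rCH <- vnorm(Ca - Hd)
  rOH <- vnorm(Oa - Hd); rCN <- vnorm(Ca - Nd)
  if (min(rON, rCH, rOH, rCN) < 0.5) return(KS_EMIN)
  max(KS_EMIN, KS_CONST * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN))
}

#' Kabsch-Sander backbone hydrogen-bond energy
#'
#' Electrostatic energy E = 0.084 * 332 * (1/rON + 1/rCH - 1/rOH - 1/rCN)
#' kcal/mol between the amide of `donor` and the carbonyl of `acceptor`.
#' A bond is called when E < -0.5 kcal/mol.  The amide hydrogen is built
#' at 1.01 Angstrom along the N-H bisector convention when the structure
#' carries no hydrogens.
#'
#' @param ens A [StructureEnsemble].
#' @param donor,acceptor Residue addresses `list(chain=, resno=)`.
#' @param model Model index.
#' @return Energy in kcal/mol, or `NA` (with a message) when backbone
#'   atoms are missing or the donor cannot carry an amide hydrogen.
#' @export
backbone_hbond_energy <- function(ens, donor, acceptor, model = 1L) {
  bt <- backbone_table(ens, model = model)
  di <- which(bt$res$chain == donor$chain & bt$res$resno == donor$resno)
  ai <- which(bt$res$chain == acceptor$chain &
                bt$res$resno == acceptor$resno)
  if (!length(di) || !length(ai)) {
    message("backbone_hbond_energy: residue not found; returning NA")
    return(NA_real_)
  }
  if (!bt$donor[di] || any(is.na(bt$C[ai, ])) || any(is.na(bt$O[ai, ]))) {
    message("backbone_hbond_energy: incomplete backbone; returning NA")
    return(NA_real_)
  }
  if (bt$res$chain[di] == bt$res$chain[ai] &&
      abs(bt$res$resno[di] - bt$res$resno[ai]) < 2) {
    message("backbone_hbond_energy: sequence-adjacent pair excluded")
    return(NA_real_)
  }
  ks_energy_pair(bt$N[di, ], bt$H[di, ], bt$C[ai, ], bt$O[ai, ])
}

# All backbone hydrogen bonds of one model: every donor/acceptor pair with
# E < cutoff, plus each donor's best-energy acceptor.
kabsch_sander <- function(ens, chains = NULL, model = 1L) {
  bt <- backbone_table(ens, chains = chains, model = model)
  n <- nrow(bt$res)
  donors <- which(bt$donor)
  acceptors <- which(stats::complete.cases(cbind(bt$C, bt$O)))
  bonds <- list(); bk <- 0L
  best_acc <- rep(NA_integer_, n); best_E <- rep(NA_real_, n)
  for (di in donors) {
    Ebest <- Inf; abest <- NA_integer_
    for (ai in acceptors) {
      if (di == ai) next
      if (bt$res$chain[di] == bt$res$chain[ai] &&
          abs(bt$res$resno[di] - bt$res$resno[ai]) < 2) next
      # cheap distance prefilter: N-O beyond 5.2 A cannot reach -0.5
      if (vnorm(bt$O[ai, ] - bt$N[di, ]) > 5.2) next
      E <- ks_energy_pair(bt$N[di, ], bt$H[di, ], bt$C[ai, ], bt$O[ai, ])
      if (E < KS_CUTOFF) {
        bk <- bk + 1L
        bonds[[bk]] <- data.frame(
          donor_chain = bt$res$chain[di], donor_resno = bt$res$resno[di],
          acc_chain = bt$res$chain[ai], acc_resno = bt$res$resno[ai],
          energy = E, stringsAsFactors = FALSE)
        if (E < Ebest) { Ebest <- E; abest <- ai }
      }
    }
    if (!is.na(abest)) { best_acc[di] <- abest; best_E[di] <- Ebest }
  }
  bonds <- if (bk) do.call(rbind, bonds) else
    data.frame(donor_chain = character(0), donor_resno = integer(0),
               acc_chain = character(0), acc_resno = integer(0),
               energy = numeric(0))
  list(res = bt$res, bonds = bonds, best_acceptor = best_acc,
       best_energy = best_E, seg = bt$seg)
}

#' Assign per-residue helical state
#'
#' Minimal DSSP-style alpha rule: a 4-turn exists at position k when the
#' amide of residue k+4 hydrogen-bonds the carbonyl of residue k
#' (Kabsch-Sander E < -0.5 kcal/mol, same segment); residue r is labelled
#' `H` when turns exist at both r-1 and r.  Everything else is `C`
#' (3-10/pi helices and strands are not distinguished); chains shorter
#' than 5 residues are all `C`.
#'
#' @param ens A [StructureEnsemble].
#' @param chains Chains to assign (default all).
#' @param model Model index.
#' @return Data frame (chain, resno, resid, ss) with attribute
#'   `helicity` = fraction of residues labelled `H`.
#' @export
assign_ss <- function(ens, chains = NULL, model = 1L) {
  ks <- kabsch_sander(ens, chains = chains, model = model)
  res <- ks$res
  n <- nrow(res)
  pos <- seq_len(n)
  # 4-turn at positional index k: bond donor k+4 -> acceptor k, contiguous
  turn <- rep(FALSE, n)
  if (nrow(ks$bonds)) {
    key <- paste(res$chain, res$resno)
    dpos <- match(paste(ks$bonds$donor_chain, ks$bonds$donor_resno), key)
    apos <- match(paste(ks$bonds$acc_chain, ks$bonds$acc_resno), key)
    ok <- !is.na(dpos) & !is.na(apos) & (dpos - apos == 4L) &
      ks$seg[dpos] == ks$seg[apos]
    turn[apos[ok]] <- TRUE
  }
  ss <- rep("C", n)
  for (r in pos) {
    if (r >= 2 && turn[r - 1] && turn[r]) ss[r] <- "H"
  }
  # chains shorter than 5 residues cannot form a 4-turn ladder
  for (ch in unique(res$chain)) {
    if (sum(res$chain == ch) < 5) ss[res$chain == ch] <- "C"
  }
  out <- data.frame(chain = res$chain, resno = res$resno,
                    resid = res$resid, ss = ss, stringsAsFactors = FALSE)
  attr(out, "helicity") <- mean(ss == "H")
  out
}

#' Percentage alpha-helicity of an ensemble
#'
#' Mean over models of the per-model fraction of residues labelled `H` by
#' [assign_ss()] within a selection.
#'
#' @param ens A [StructureEnsemble].
#' @param chains Chains to include (default all).
#' @param resno Optional residue-number filter for the helicity
#'   denominator.
#' @return List: `per_model` fractions, `mean`.
#' @export
ensemble_helicity <- function(ens, chains = NULL, resno = NULL) {
  per <- vapply(seq_len(n_models(ens)), function(m) {
    ssa <- assign_ss(ens, chains = chains, model = m)
    if (!is.null(resno)) ssa <- ssa[ssa$resno %in% resno, , drop = FALSE]
    if (!nrow(ssa)) stop("input error: empty helicity selection")
    mean(ssa$ss == "H")
  }, numeric(1))
  list(per_model = per, mean = mean(per))
}
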