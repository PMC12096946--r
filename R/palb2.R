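# Ready-made constructors for the study system: the human PALB2
# coiled-coil homodimer and a PALB2-BRCA1-like antiparallel heterodimer.

#' Human PALB2 coiled-coil sequence
#'
#' Residues 6-42 of human PALB2 (UniProt Q86YC2 numbering), the coiled-coil
#' dimerization domain.  The returned string is indexed so that its first
#' character is residue 6.
#'
#' @return Character string of one-letter codes with attribute `start`.
#' @export
palb2cc_sequence <- function() {
  structure("GKPLSCEEKEKLKEKLAFLKREYSKTLARLQRAQRAE", start = 6L)
}

# heptad a/d (interface) residue numbers of PALB2cc
PALB2_INTERFACE <- c(14L, 17L, 21L, 24L, 28L, 31L, 35L, 38L, 42L)

#' Synthetic BRCA1-like coiled-coil sequence
#'
#' A designed (synthetic) stand-in for the BRCA1 coiled-coil segment,
#' numbered 1378-1424.  It is NOT the native human BRCA1 sequence: it is
#' constructed to reproduce the compositional features relevant to the
#' heterodimer analyses -- leucine/methionine interface positions L1392,
#' M1400, L1404, L1407, M1411, L1414 and L1418, acidic D1381, S1387, D1390
#' and D1419, four positively and seven negatively charged residues with a
#' strongly negative C-terminal end.
#'
#' @return Character string of one-letter codes with attribute `start`.
#' @export
brca1cc_synthetic_sequence <- function() {
  structure("SQEDKQKALSQADALQKEALQKMAQALNALQAQMAQLAQALDALQDE",
            start = 1378L)
}

BRCA1_INTERFACE <- c(1397L, 1400L, 1404L, 1407L, 1411L, 1414L, 1418L, 1421L)

#' Build the PALB2 coiled-coil homodimer model
#'
#' Antiparallel homodimer of PALB2cc (residues 6-42 in both chains) with
#' the leucine-zipper-like a/d interface facing inwards.  The antiparallel
#' register places the two chains symmetrically about the interface
#' midpoint so that the central L24/Y28 layer of one chain packs against
#' the Y28'/L24' layer of the other.
#'
#' The default superhelix radius is slightly wider than the canonical
#' 4.9 Angstrom so that rigid ideal-rotamer side chains pack without steric
#' overlap; side chains are relaxed greedily after assembly.
#'
#' @param params A [crick_params()] object (antiparallel).
#' @param relax If `TRUE`, run [relax_rotamers()] on the assembled dimer.
#' @return Single-model [StructureEnsemble], chains A and B.
#' @export
build_palb2_homodimer <- function(params = crick_params(superhelix_radius = 5.5),
                                  relax = TRUE) {
  seq <- palb2cc_sequence()
  sol <- solve_template_dihedrals(params)
  # register: chain B residue k sits at the axial height of chain A residue
  # 52 - k, bringing the Y28/Y28 aromatic pair together at the midpoint
  # with L24/L24 in the flanking layer
  z_shift <- (52 - 6 - 6) * sol$rise
  d <- build_coiled_coil(seq, seq, params, start_a = attr(seq, "start"),
                         start_b = attr(seq, "start"), chain_ids = c("A", "B"),
                         z_shift_b = z_shift,
                         interface_a = PALB2_INTERFACE,
                         interface_b = PALB2_INTERFACE)
  if (relax) d <- relax_rotamers(d)
  d
}

#' Build a PALB2-BRCA1-like coiled-coil heterodimer model
#'
#' Antiparallel heterodimer of PALB2cc (chain A, residues 6-42) with the
#' synthetic BRCA1-like coiled coil (chain B, residues 1378-1424; see
#' [brca1cc_synthetic_sequence()]).  The register pairs PALB2 residue i
#' with the BRCA1 position 1435 - i, which brings Y28 against the
#' M1411/L1407/L1404 layer and K18 within reach of D1419.
#'
#' @param params A [crick_params()] object (antiparallel).
#' @param relax If `TRUE`, run [relax_rotamers()] on the assembled dimer.
#' @return Single-model [StructureEnsemble], chains A (PALB2) and
#'   B (BRCA1-like).
#' @export
build_palb2_brca1_heterodimer <- function(params = crick_params(superhelix_radius = 5.5),
                                          relax = TRUE) {
  pa <- palb2cc_sequence()
  br <- brca1cc_synthetic_sequence()
  sol <- solve_template_dihedrals(params)
  # chain B residue m at the axial height of PALB2 residue 1435 - m
  z_shift <- (1435 - 1378 - 6) * sol$rise
  d <- build_coiled_coil(pa, br, params, start_a = attr(pa, "start"),
                         start_b = attr(br, "start"), chain_ids = c("A", "B"),
                         z_shift_b = z_shift,
                         interface_a = PALB2_INTERFACE,
                         interface_b = BRCA1_INTERFACE)
  if (relax) d <- relax_rotamers(d)
  d
}
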