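# Backbone and side-chain construction by natural-extension (NeRF) from
# ideal bond geometry.  Used by the synthetic builder and the unfolding
# emulator; analysis modules never depend on these ideal values.

BOND <- c(N_CA = 1.458, CA_C = 1.525, C_N = 1.329, C_O = 1.231)
ANG <- c(N_CA_C = 111.2, CA_C_N = 116.2, C_N_CA = 121.7, CA_C_O = 120.5)
# improper dihedral C-N-CA-CB for an L-amino acid
CB_IMPROPER <- -122.6
CB_ANGLE <- 110.5
CB_BOND <- 1.530

# Build backbone N/CA/C for n residues from dihedral lists.
# anchor: optional list(N=, CA=, C=, psi=) describing the preceding residue.
backbone_chain <- function(phi, psi, omega = NULL, anchor = NULL) {
  n <- length(phi)
  stopifnot(length(psi) == n)
  if (is.null(omega)) omega <- rep(180, n)
  N <- CA <- C <- matrix(NA_real_, n, 3)
  if (is.null(anchor)) {
    N[1, ] <- c(0, 0, 0)
    CA[1, ] <- c(BOND["N_CA"], 0, 0)
    th <- ANG["N_CA_C"] * pi / 180
    C[1, ] <- CA[1, ] + BOND["CA_C"] * c(cos(pi - th), sin(pi - th), 0)
    start <- 2L
    pN <- N[1, ]; pCA <- CA[1, ]; pC <- C[1, ]; ppsi <- psi[1]
  } else {
    start <- 1L
    pN <- anchor$N; pCA <- anchor$CA; pC <- anchor$C; ppsi <- anchor$psi
  }
  if (start <= n) for (i in start:n) {
    N[i, ] <- place_atom(pN, pCA, pC, BOND["C_N"], ANG["CA_C_N"], ppsi)
    CA[i, ] <- place_atom(pCA, pC, N[i, ], BOND["N_CA"], ANG["C_N_CA"],
                          omega[i])
    C[i, ] <- place_atom(pC, N[i, ], CA[i, ], BOND["CA_C"], ANG["N_CA_C"],
                         phi[i])
    pN <- N[i, ]; pCA <- CA[i, ]; pC <- C[i, ]; ppsi <- psi[i]
  }
  list(N = N, CA = CA, C = C)
}

# Carbonyl oxygens for a built backbone; the last O uses psi directly.
backbone_oxygens <- function(bb, psi) {
  n <- nrow(bb$N)
  O <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    if (i < n) {
      u <- vunit(bb$C[i, ] - bb$CA[i, ]) + vunit(bb$C[i, ] - bb$N[i + 1, ])
      O[i, ] <- bb$C[i, ] + BOND["C_O"] * vunit(u)
    } else {
      O[i, ] <- place_atom(bb$N[i, ], bb$CA[i, ], bb$C[i, ], BOND["C_O"],
                           ANG["CA_C_O"], psi[i] + 180)
    }
  }
  O
}

# Side-chain heavy atoms for one residue given backbone N/CA/C.
# Returns a named matrix (possibly 0-row) of atom positions, CB first.
build_sidechain <- function(resid, N, CA, C, chi = NULL) {
  if (resid == "GLY") return(matrix(numeric(0), 0, 3))
  pos <- list(N = N, CA = CA, C = C)
  pos$CB <- place_atom(C, N, CA, CB_BOND, CB_ANGLE, CB_IMPROPER)
  zm <- SIDECHAIN_ZMAT[[resid]]
  if (is.null(chi)) {
    rot <- ROTAMERS[[resid]]
    chi <- if (is.null(rot)) numeric(0) else rot[[1]]
  }
  if (!is.null(zm)) {
    for (k in seq_len(nrow(zm))) {
      r <- zm[k, ]
      dih <- r$dih + if (r$chi > 0) chi[r$chi] else 0
      pos[[r$atom]] <- place_atom(pos[[r$a]], pos[[r$b]], pos[[r$c]],
                                  r$bond, r$ang, dih)
    }
  }
  nm <- c("CB", if (!is.null(zm)) zm$atom)
  out <- do.call(rbind, pos[nm])
  rownames(out) <- nm
  out
}

# atom names (in construction order) for a residue's heavy atoms
residue_atom_names <- function(resid) {
  side <- if (resid == "GLY") character(0)
          else c("CB", if (!is.null(SIDECHAIN_ZMAT[[resid]]))
                   SIDECHAIN_ZMAT[[resid]]$atom)
  c("N", "CA", "C", "O", side)
}

# Measure backbone dihedrals of one chain in one model.
# Returns data.frame(resno, phi, psi, omega); terminal values are NA.
backbone_dihedrals <- function(ens, chain, model = 1L) {
  res <- residues(ens, chain)
  n <- nrow(res)
  get <- function(rn, at) {
    i <- atom_index(ens, chain, rn, at)
    if (is.na(i)) stop("missing backbone atom ", at, " in residue ", rn)
    model_xyz(ens, model)[i, ]
  }
  phi <- psi <- omg <- rep(NA_real_, n)
  for (k in seq_len(n)) {
    rn <- res$resno[k]
    if (k > 1) {
      phi[k] <- vdihedral(get(res$resno[k - 1], "C"), get(rn, "N"),
                          get(rn, "CA"), get(rn, "C"))
      omg[k] <- vdihedral(get(res$resno[k - 1], "CA"), get(res$resno[k - 1], "C"),
                          get(rn, "N"), get(rn, "CA"))
    }
    if (k < n)
      psi[k] <- vdihedral(get(rn, "N"), get(rn, "CA"), get(rn, "C"),
                          get(res$resno[k + 1], "N"))
  }
  data.frame(resno = res$resno, phi = phi, psi = psi, omega = omg)
}

# Rebuild a terminal segment of one chain in a single-model ensemble with
# new phi/psi (ideal bond geometry, side chains re-grown from the default
# rotamer).  The window must touch one chain terminus.
rebuild_segment <- function(ens, chain, from, to, phi_new, psi_new) {
  stopifnot(n_models(ens) == 1L)
  res <- residues(ens, chain)
  rfirst <- res$resno[1]; rlast <- res$resno[nrow(res)]
  stopifnot(from >= rfirst, to <= rlast, from <= to)
  xyz <- model_xyz(ens, 1L)
  a <- ens$atoms
  getx <- function(rn, at) xyz[atom_index(ens, chain, rn, at), ]
  setx <- function(rn, at, v) {
    i <- atom_index(ens, chain, rn, at)
    if (!is.na(i)) xyz[i, ] <<- v
    invisible(NULL)
  }
  resid_of <- function(rn) res$resid[match(rn, res$resno)]
  place_side <- function(rn) {
    rid <- resid_of(rn)
    sc <- build_sidechain(rid, getx(rn, "N"), getx(rn, "CA"), getx(rn, "C"))
    for (nm in rownames(sc)) setx(rn, nm, sc[nm, ])
  }
  window <- from:to
  nw <- length(window)
  if (to == rlast && from > rfirst) {
    # forward rebuild anchored at residue from-1
    anch_rn <- from - 1L
    dih <- backbone_dihedrals(ens, chain)
    psi_prev <- dih$psi[match(anch_rn, dih$resno)]
    bb <- backbone_chain(phi_new, psi_new,
                         anchor = list(N = getx(anch_rn, "N"),
                                       CA = getx(anch_rn, "CA"),
                                       C = getx(anch_rn, "C"),
                                       psi = psi_prev))
    O <- backbone_oxygens(bb, psi_new)
    for (k in seq_len(nw)) {
      rn <- window[k]
      setx(rn, "N", bb$N[k, ]); setx(rn, "CA", bb$CA[k, ])
      setx(rn, "C", bb$C[k, ]); setx(rn, "O", O[k, ])
    }
    # anchor residue's O follows its (unchanged) C but new next N
    u <- vunit(getx(anch_rn, "C") - getx(anch_rn, "CA")) +
      vunit(getx(anch_rn, "C") - bb$N[1, ])
    setx(anch_rn, "O", getx(anch_rn, "C") + BOND["C_O"] * vunit(u))
    for (rn in window) place_side(rn)
  } else if (from == rfirst && to < rlast) {
    # backward rebuild anchored at residue to+1; phi_new/psi_new are per
    # window residue, plus phi of the anchor residue taken as given
    anch_rn <- to + 1L
    dihs <- backbone_dihedrals(ens, chain)
    phi_anchor <- dihs$phi[match(anch_rn, dihs$resno)]
    phi_next <- c(phi_new[-1], phi_anchor)  # phi of residue i+1 for each i
    pN <- getx(anch_rn, "N"); pCA <- getx(anch_rn, "CA")
    pC <- getx(anch_rn, "C")
    for (k in rev(seq_len(nw))) {
      rn <- window[k]
      Ci <- place_atom(pC, pCA, pN, BOND["C_N"], ANG["C_N_CA"], phi_next[k])
      CAi <- place_atom(pCA, pN, Ci, BOND["CA_C"], ANG["CA_C_N"], 180)
      Ni <- place_atom(pN, Ci, CAi, BOND["N_CA"], ANG["N_CA_C"], psi_new[k])
      u <- vunit(Ci - CAi) + vunit(Ci - pN)
      setx(rn, "N", Ni); setx(rn, "CA", CAi); setx(rn, "C", Ci)
      setx(rn, "O", Ci + BOND["C_O"] * vunit(u))
      pN <- Ni; pCA <- CAi; pC <- Ci
    }
    for (rn in window) place_side(rn)
  } else if (from == rfirst && to == rlast) {
    stop("rebuilding a whole chain is not supported; anchor one terminus")
  } else {
    stop("rebuild window must touch a chain terminus")
  }
  out <- ens
  out$xyz[1, , ] <- xyz
  out
}
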