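# Fixtures built in code: ideal helices, extended chains, tiny custom
# ensembles, and random coiled-coil dimers for oracle tests.

# single-chain backbone ensemble (N, CA, C, O only) from constant phi/psi
make_chain <- function(n, phi, psi, chain = "A", resid = "ALA",
                       start = 1L) {
  bb <- ccdimer:::backbone_chain(rep(phi, n), rep(psi, n))
  O <- ccdimer:::backbone_oxygens(bb, rep(psi, n))
  atoms <- do.call(rbind, lapply(seq_len(n), function(i)
    data.frame(elety = c("N", "CA", "C", "O"), resid = resid,
               chain = chain, resno = start + i - 1L, insert = "",
               element = c("N", "C", "C", "O"), stringsAsFactors = FALSE)))
  xyz <- array(NA_real_, c(1L, 4L * n, 3L))
  for (i in seq_len(n)) {
    xyz[1, (4 * i - 3):(4 * i), ] <- rbind(bb$N[i, ], bb$CA[i, ],
                                           bb$C[i, ], O[i, ])
  }
  ccdimer:::new_ensemble(atoms, xyz, source = "fixture")
}

ideal_helix <- function(n, chain = "A") make_chain(n, -57.8, -47.0, chain)
extended_chain <- function(n, chain = "A") make_chain(n, -140, 140, chain)

# arbitrary ensemble from an atom table and a list of coordinate matrices
make_ens <- function(atoms, coords) {
  if (!is.list(coords)) coords <- list(coords)
  xyz <- array(NA_real_, c(length(coords), nrow(atoms), 3L))
  for (m in seq_along(coords)) xyz[m, , ] <- coords[[m]]
  ccdimer:::new_ensemble(atoms, xyz, source = "fixture")
}

atom_row <- function(elety, resid, chain, resno,
                     element = substr(elety, 1, 1)) {
  data.frame(elety = elety, resid = resid, chain = chain, resno = resno,
             insert = "", element = element, stringsAsFactors = FALSE)
}

# a planar hexagonal PHE-like ring (CG..CZ) centred at `centre`, lying in
# the plane spanned by u, v (orthonormal)
ring_atoms <- function(chain, resno, centre, u, v, r = 1.39) {
  nm <- c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")
  ang <- c(90, 150, 30, 210, 330, 270) * pi / 180
  xyz <- t(vapply(ang, function(a) centre + r * (cos(a) * u + sin(a) * v),
                  numeric(3)))
  list(atoms = atom_row(nm, "PHE", chain, resno), xyz = xyz)
}

random_cc_dimer <- function(seed) {
  set.seed(seed)
  n <- sample(8:18, 1)
  aas <- c("A", "L", "V", "I", "K", "E", "S", "T", "Q", "F", "Y", "M")
  s1 <- paste(sample(aas, n, replace = TRUE), collapse = "")
  s2 <- paste(sample(aas, n, replace = TRUE), collapse = "")
  p <- crick_params(superhelix_radius = runif(1, 4.5, 6.5),
                    orientation = sample(c("parallel", "antiparallel"), 1))
  build_coiled_coil(s1, s2, p)
}

# brute-force O(N^2) heavy-atom pair count between two atom index groups
brute_pairs <- function(ens, ga, gb, cutoff, model = 1) {
  xa <- model_xyz(ens, model, ga)
  xb <- model_xyz(ens, model, gb)
  d <- sqrt(outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb))
  which(d <= cutoff + 1e-9, arr.ind = TRUE)
}

write_two_model_pdb <- function(path, drop_atom_in_model2 = FALSE) {
  lines <- c(
    "MODEL        1",
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  N   ALA B   1       8.000   0.000   0.000  1.00  0.00           N",
    "ATOM      4  CA  ALA B   1       9.458   0.000   0.000  1.00  0.00           C",
    "ENDMDL",
    "MODEL        2",
    "ATOM      1  N   ALA A   1       0.100   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.558   0.000   0.000  1.00  0.00           C",
    "ATOM      3  N   ALA B   1       8.100   0.000   0.000  1.00  0.00           N",
    if (!drop_atom_in_model2)
      "ATOM      4  CA  ALA B   1       9.558   0.000   0.000  1.00  0.00           C",
    "ENDMDL", "END")
  writeLines(lines, path)
  path
}
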