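# Synthetic coiled-coil structures with known ground truth: Crick-style
# dimer builder, Gaussian-perturbed ensembles, point mutants and progressive
# unfolding.  These generators make every analysis stage testable without
# any deposited data.

#' Crick-style coiled-coil parameters
#'
#' Geometric parameters of a two-stranded coiled coil.  The minor-helix
#' backbone is generated from ideal bond geometry, so `rise_per_residue`
#' and `residues_per_turn` are honoured as closely as ideal covalent
#' geometry allows; the left-handed supercoil of pitch `superhelix_pitch`
#' supplies the remaining twist so that the heptad interface stays
#' stationary along the dimer axis.
#'
#' @param superhelix_radius Distance of each helix axis from the dimer
#'   axis, Angstrom.
#' @param superhelix_pitch Axial length of one full supercoil turn,
#'   Angstrom (left-handed).
#' @param residues_per_turn Minor-helix residues per turn relative to the
#'   supercoiling frame (3.5 gives an exact heptad repeat).
#' @param rise_per_residue Axial rise per residue, Angstrom.
#' @param phase_a,phase_b Additional rotation (degrees) of each chain about
#'   its own helix axis, applied after the automatic interface-facing
#'   orientation.
#' @param orientation `"antiparallel"` or `"parallel"`.
#' @return An object of class `CrickParams`.
#' @export
crick_params <- function(superhelix_radius = 4.9, superhelix_pitch = 140,
                         residues_per_turn = 3.5, rise_per_residue = 1.51,
                         phase_a = 0, phase_b = 0,
                         orientation = c("antiparallel", "parallel")) {
  orientation <- match.arg(orientation)
  stopifnot(superhelix_radius > 0, superhelix_pitch != 0,
            residues_per_turn > 3, rise_per_residue > 0)
  structure(list(superhelix_radius = superhelix_radius,
                 superhelix_pitch = superhelix_pitch,
                 residues_per_turn = residues_per_turn,
                 rise_per_residue = rise_per_residue,
                 phase_a = phase_a, phase_b = phase_b,
                 orientation = orientation),
            class = "CrickParams")
}

# cache of solved minor-helix (phi, psi) per parameter set
.template_cache <- new.env(parent = emptyenv())

measure_helix <- function(phi, psi, n = 30) {
  bb <- backbone_chain(rep(phi, n), rep(psi, n))
  ca <- bb$CA
  centers <- t(vapply(seq_len(n - 3),
                      function(k) colMeans(ca[k:(k + 3), ]), numeric(3)))
  pc <- prcomp(centers)
  ax <- pc$rotation[, 1]
  if (sum((centers[nrow(centers), ] - centers[1, ]) * ax) < 0) ax <- -ax
  cen <- colMeans(centers)
  rel <- sweep(ca, 2, cen)
  rise <- mean(diff(as.vector(rel %*% ax)))
  e1 <- vunit(rel[1, ] - sum(rel[1, ] * ax) * ax)
  e2 <- vcross(ax, e1)
  ph <- atan2(rel %*% e2, rel %*% e1)
  d <- ((diff(as.vector(ph)) + pi) %% (2 * pi)) - pi
  c(twist = mean(d) * 180 / pi, rise = rise)
}

# Solve minor-helix (phi, psi) so that template twist plus supercoil frame
# rotation equals 360/residues_per_turn at the requested rise.
solve_template_dihedrals <- function(params) {
  key <- paste(params$residues_per_turn, params$rise_per_residue,
               params$superhelix_pitch)
  if (!is.null(.template_cache[[key]])) return(.template_cache[[key]])
  P <- params$superhelix_pitch
  rpt <- params$residues_per_turn
  rise_t <- params$rise_per_residue
  obj <- function(p) {
    m <- measure_helix(p[1], p[2])
    eff <- m["twist"] + 360 * m["rise"] / P
    ((eff - 360 / rpt) / 100)^2 + 0.02 * ((m["rise"] - rise_t) / 1.5)^2
  }
  o <- stats::optim(c(-60, -45), obj, control = list(reltol = 1e-13,
                                                     maxit = 5000))
  m <- measure_helix(o$par[1], o$par[2])
  out <- list(phi = o$par[1], psi = o$par[2],
              rise = unname(m["rise"]), twist = unname(m["twist"]))
  .template_cache[[key]] <- out
  out
}

# Build a straight full-atom helix template for one sequence; axis aligned
# to +z through the origin, CA of residue 1 at z = 0.
chain_template <- function(seq3, phi, psi) {
  n <- length(seq3)
  phi_v <- rep(phi, n); psi_v <- rep(psi, n)
  pro <- which(seq3 == "PRO")
  phi_v[pro] <- -65
  bb <- backbone_chain(phi_v, psi_v)
  O <- backbone_oxygens(bb, psi_v)
  names_l <- list(); xyz_l <- list(); res_l <- list()
  for (i in seq_len(n)) {
    sc <- build_sidechain(seq3[i], bb$N[i, ], bb$CA[i, ], bb$C[i, ])
    at <- rbind(N = bb$N[i, ], CA = bb$CA[i, ], C = bb$C[i, ], O = O[i, ], sc)
    names_l[[i]] <- rownames(at)
    xyz_l[[i]] <- at
    res_l[[i]] <- rep(i, nrow(at))
  }
  xyz <- do.call(rbind, xyz_l)
  # align helix axis to z
  ca_rows <- which(unlist(names_l) == "CA")
  ca <- xyz[ca_rows, , drop = FALSE]
  centers <- t(vapply(seq_len(n - 3),
                      function(k) colMeans(ca[k:(k + 3), ]), numeric(3)))
  pc <- prcomp(centers)
  ax <- pc$rotation[, 1]
  if (sum((centers[nrow(centers), ] - centers[1, ]) * ax) < 0) ax <- -ax
  z <- c(0, 0, 1)
  v <- vcross(ax, z)
  R <- if (vnorm(v) < 1e-9) diag(3) else
    rot_axis(v, acos(max(-1, min(1, sum(ax * z)))) * 180 / pi)
  xyz <- xyz %*% t(R)
  cen <- colMeans(xyz[ca_rows, , drop = FALSE][
    seq(2, n - 1), , drop = FALSE])
  xyz <- sweep(xyz, 2, c(cen[1], cen[2], 0))
  xyz[, 3] <- xyz[, 3] - xyz[ca_rows[1], 3]
  list(xyz = xyz, names = unlist(names_l), res_index = unlist(res_l),
       ca_rows = ca_rows)
}

circ_mean_deg <- function(deg) {
  r <- deg * pi / 180
  atan2(mean(sin(r)), mean(cos(r))) * 180 / pi
}

# rotate template about z so mean CB phase of interface residues is 180 deg
orient_interface <- function(tpl, interface_idx, extra_phase = 0) {
  rows <- which(tpl$names == "CB" & tpl$res_index %in% interface_idx)
  if (!length(rows)) rows <- which(tpl$names == "CA" &
                                     tpl$res_index %in% interface_idx)
  ph <- atan2(tpl$xyz[rows, 2], tpl$xyz[rows, 1]) * 180 / pi
  rot <- 180 - circ_mean_deg(ph) + extra_phase
  tpl$xyz <- tpl$xyz %*% t(rot_axis(c(0, 0, 1), rot))
  tpl
}

# Wrap a straight template (axis = z) onto the left-handed superhelix at
# azimuth delta (radians).
wrap_superhelix <- function(xyz, radius, pitch, delta) {
  z <- xyz[, 3]
  theta <- delta - 2 * pi * z / pitch
  dth <- -2 * pi / pitch
  tx <- -radius * dth * sin(theta); ty <- radius * dth * cos(theta)
  tn <- sqrt(tx^2 + ty^2 + 1)
  Tx <- tx / tn; Ty <- ty / tn; Tz <- 1 / tn
  e1x <- cos(theta); e1y <- sin(theta)              # radial, e1z = 0
  # e2 = T x e1
  e2x <- -Tz * e1y; e2y <- Tz * e1x; e2z <- Tx * e1y - Ty * e1x
  gx <- radius * cos(theta) + xyz[, 1] * e1x + xyz[, 2] * e2x
  gy <- radius * sin(theta) + xyz[, 1] * e1y + xyz[, 2] * e2y
  gz <- z + xyz[, 2] * e2z
  cbind(gx, gy, gz)
}

#' Build a two-chain coiled-coil dimer
#'
#' Generates an idealized two-stranded coiled coil: full backbone
#' (N, CA, C, O) plus side chains grown from the most common rotamer of
#' each residue.  Each chain is an ideal minor helix wrapped onto a
#' left-handed superhelix; hydrophobic heptad a/d positions of both chains
#' face the partner chain.  The heptad register and build parameters are
#' recorded as metadata.
#'
#' @param seq_a,seq_b Chain sequences (one-letter strings or vectors of
#'   one/three-letter codes).
#' @param params A [crick_params()] object.
#' @param start_a,start_b First (author) residue number of each chain.
#' @param chain_ids Two chain identifiers.
#' @param z_shift_b Axial placement of chain B, Angstrom.  For antiparallel
#'   dimers the default aligns the chains full-length; pass a different
#'   value to select another register.
#' @param interface_a,interface_b Residue numbers whose side chains should
#'   face the partner (used to orient each helix).  Default: heptad a/d
#'   positions counted from the first residue.
#' @return A single-model [StructureEnsemble] of the dimer.
#' @export
build_coiled_coil <- function(seq_a, seq_b, params = crick_params(),
                              start_a = 1L, start_b = 1L,
                              chain_ids = c("A", "B"), z_shift_b = NULL,
                              interface_a = NULL, interface_b = NULL) {
  to3 <- function(s) {
    if (length(s) == 1 && nchar(s) > 3) s <- strsplit(s, "")[[1]]
    aa_three(s)
  }
  s3a <- to3(seq_a); s3b <- to3(seq_b)
  if (length(s3a) < 7 || length(s3b) < 7)
    stop("coiled-coil chains must have at least 7 residues")
  sol <- solve_template_dihedrals(params)
  rise <- sol$rise
  heptad_ad <- function(n) which(((seq_len(n) - 1) %% 7) %in% c(0, 3))
  ia <- if (is.null(interface_a)) heptad_ad(length(s3a)) else
    interface_a - start_a + 1L
  ib <- if (is.null(interface_b)) heptad_ad(length(s3b)) else
    interface_b - start_b + 1L

  ta <- chain_template(s3a, sol$phi, sol$psi)
  ta <- orient_interface(ta, ia, params$phase_a)

  tb <- chain_template(s3b, sol$phi, sol$psi)
  anti <- params$orientation == "antiparallel"
  if (anti) {
    flip <- rot_axis(c(1, 0, 0), 180)
    tb$xyz <- tb$xyz %*% t(flip)
    tb$xyz[, 3] <- tb$xyz[, 3] - tb$xyz[tb$ca_rows[1], 3]
  }
  tb <- orient_interface(tb, ib, params$phase_b)
  if (is.null(z_shift_b))
    z_shift_b <- if (anti) (length(s3b) - 1) * rise else 0
  tb$xyz[, 3] <- tb$xyz[, 3] + z_shift_b

  ga <- wrap_superhelix(ta$xyz, params$superhelix_radius,
                        params$superhelix_pitch, 0)
  gb <- wrap_superhelix(tb$xyz, params$superhelix_radius,
                        params$superhelix_pitch, pi)

  mk_atoms <- function(tpl, chain, start, s3) {
    data.frame(elety = tpl$names, resid = s3[tpl$res_index], chain = chain,
               resno = start + tpl$res_index - 1L, insert = "",
               element = element_from_name(tpl$names),
               stringsAsFactors = FALSE)
  }
  atoms <- rbind(mk_atoms(ta, chain_ids[1], start_a, s3a),
                 mk_atoms(tb, chain_ids[2], start_b, s3b))
  xyz <- array(NA_real_, c(1L, nrow(atoms), 3L))
  xyz[1, , ] <- rbind(ga, gb)
  ens <- new_ensemble(atoms, xyz, source = "build_coiled_coil")
  attr(ens, "meta") <- list(params = params, rise = rise,
                            interface = stats::setNames(
                              list(start_a + ia - 1L, start_b + ib - 1L),
                              chain_ids),
                            z_shift_b = z_shift_b)
  ens
}

#' Gaussian perturbation ensemble
#'
#' Emulates fluctuation ensembles (NMR- or MD-like) by applying independent
#' isotropic Gaussian rigid-body displacements to each residue of a model.
#' With per-residue displacement sigma and many models, the measured
#' C-alpha RMSF converges to `sigma * sqrt(3)`.
#'
#' @param model A single-model [StructureEnsemble].
#' @param sigma Displacement standard deviation per coordinate axis,
#'   Angstrom; scalar or one value per residue (ordered as [residues()]).
#' @param n_models Number of models to generate.
#' @param seed Integer seed (mandatory; no hidden global RNG state).
#' @param per_atom If `TRUE`, displace atoms independently instead of
#'   rigidly per residue.
#' @return A [StructureEnsemble] with `n_models` models.
#' @export
perturb_ensemble <- function(model, sigma, n_models, seed, per_atom = FALSE) {
  stopifnot(n_models(model) == 1L, n_models >= 1L)
  res <- residues(model)
  if (length(sigma) == 1L) sigma <- rep(sigma, nrow(res))
  if (length(sigma) != nrow(res))
    stop("sigma must be scalar or one value per residue (",
         nrow(res), " residues)")
  if (any(sigma < 0)) stop("sigma must be non-negative")
  key <- paste(model$atoms$chain, model$atoms$resno, model$atoms$insert)
  rkey <- paste(res$chain, res$resno, res$insert)
  rid <- match(key, rkey)
  base <- model_xyz(model, 1L)
  xyz <- array(NA_real_, c(n_models, n_atoms(model), 3L))
  old <- .Random.seed_save()
  set.seed(seed)
  for (m in seq_len(n_models)) {
    if (per_atom) {
      shift <- matrix(rnorm(3 * n_atoms(model)), ncol = 3) *
        sigma[rid]
    } else {
      rshift <- matrix(rnorm(3 * nrow(res)), ncol = 3) * sigma
      shift <- rshift[rid, , drop = FALSE]
    }
    xyz[m, , ] <- base + shift
  }
  .Random.seed_restore(old)
  new_ensemble(model$atoms, xyz, source = paste0(model$source, "+perturb"))
}

# save/restore global RNG so seeded generators do not disturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Mutate a residue in place
#'
#' Replaces the side chain of one residue with the target amino acid.  The
#' backbone (N, CA, C, O) is untouched; the new side chain is grown with
#' ideal internal geometry, choosing among a small built-in rotamer table
#' the chi set with the fewest heavy-atom clashes (< 2.4 Angstrom) against
#' the rest of the first model.
#'
#' @param ens A [StructureEnsemble] (all models are mutated consistently).
#' @param chain,resno Residue address.
#' @param new_aa Target amino acid (one- or three-letter code).
#' @return A new [StructureEnsemble]; a `clashes` attribute reports the
#'   residual clash count of the chosen rotamer.
#' @export
mutate_residue <- function(ens, chain, resno, new_aa) {
  new3 <- aa_three(new_aa)
  a <- ens$atoms
  rrows <- which(a$chain == chain & a$resno == resno)
  if (!length(rrows)) stop("input error: residue ", chain, resno, " not found")
  bb_need <- c("N", "CA", "C")
  bb_idx <- vapply(bb_need, function(at) {
    i <- rrows[a$elety[rrows] == at]
    if (!length(i)) stop("residue lacks backbone atom ", at) else i[1]
  }, 1L)
  o_idx <- rrows[a$elety[rrows] == "O"][1]
  keep_rows <- c(bb_idx, if (!is.na(o_idx)) o_idx)
  other_heavy <- setdiff(which(!(a$element %in% c("H", "D"))), rrows)

  side_names <- setdiff(residue_atom_names(new3), c("N", "CA", "C", "O"))
  rots <- ROTAMERS[[new3]]
  if (is.null(rots)) rots <- list(numeric(0))
  m1 <- model_xyz(ens, 1L)
  clash_count <- function(sc) {
    if (!nrow(sc) || !length(other_heavy)) return(0L)
    d2 <- outer(rowSums(sc^2), rowSums(m1[other_heavy, , drop = FALSE]^2),
                "+") - 2 * sc %*% t(m1[other_heavy, , drop = FALSE])
    sum(d2 < 2.4^2)
  }
  cands <- lapply(rots, function(chi) {
    sc <- build_sidechain(new3, m1[bb_idx["N"], ], m1[bb_idx["CA"], ],
                          m1[bb_idx["C"], ], chi = chi)
    list(sc = sc, chi = chi, cl = clash_count(sc))
  })
  cls <- vapply(cands, function(x) x$cl, numeric(1))
  best_set <- which(cls == min(cls))
  pick <- best_set[1]
  partner <- which(!(a$element %in% c("H", "D")) & a$chain != chain)
  if (new3 %in% c("LYS", "ARG", "ASP", "GLU") && length(partner) &&
      length(best_set) > 1) {
    # charged side chains prefer solvent: farthest from partner chain(s)
    dmin <- vapply(best_set, function(k) {
      sc <- cands[[k]]$sc
      d2 <- outer(rowSums(sc^2),
                  rowSums(m1[partner, , drop = FALSE]^2), "+") -
        2 * sc %*% t(m1[partner, , drop = FALSE])
      min(d2)
    }, numeric(1))
    pick <- best_set[which.max(dmin)]
  }
  best <- cands[[pick]]$sc; best_cl <- cands[[pick]]$cl
  best_chi <- cands[[pick]]$chi
  # assemble new atom table: residue rows replaced in place
  pre <- seq_len(min(rrows) - 1L)
  post <- setdiff(seq_len(nrow(a)), c(pre, rrows))
  new_names <- c("N", "CA", "C", "O", side_names)
  new_res <- data.frame(elety = new_names, resid = new3, chain = chain,
                        resno = resno, insert = a$insert[rrows[1]],
                        element = element_from_name(new_names),
                        stringsAsFactors = FALSE)
  atoms2 <- rbind(a[pre, , drop = FALSE], new_res, a[post, , drop = FALSE])
  nmod <- n_models(ens)
  xyz2 <- array(NA_real_, c(nmod, nrow(atoms2), 3L))
  for (m in seq_len(nmod)) {
    mm <- model_xyz(ens, m)
    bbm <- mm[bb_idx, , drop = FALSE]
    om <- if (!is.na(o_idx)) mm[o_idx, , drop = FALSE] else
      matrix(place_atom(bbm[1, ], bbm[2, ], bbm[3, ], BOND["C_O"],
                        ANG["CA_C_O"], 0), 1, 3)
    scm <- build_sidechain(new3, bbm[1, ], bbm[2, ], bbm[3, ],
                           chi = best_chi)
    blk <- rbind(bbm, om, scm)
    xyz2[m, , ] <- rbind(mm[pre, , drop = FALSE], blk,
                         mm[post, , drop = FALSE])
  }
  out <- new_ensemble(atoms2, xyz2, source = paste0(ens$source, "+mut"))
  attr(out, "meta") <- attr(ens, "meta")
  attr(out, "clashes") <- best_cl
  out
}

# coil-region dihedral sampling used by the unfolding/fraying emulators
sample_coil_dihedrals <- function(n) {
  list(phi = runif(n, -160, -60), psi = runif(n, 90, 175))
}

#' Progressive C-terminal unfolding ensemble
#'
#' Emulates progressive unfolding of a helix: model k randomizes the
#' backbone dihedrals of a growing C-terminal window (from a residue within
#' `start_residue`..end up to the full `start_residue`..end span in the
#' last model), preserving ideal bond geometry.  Side chains of rebuilt
#' residues are regrown from the default rotamer.
#'
#' @param model A single-model [StructureEnsemble].
#' @param chain Chain to unfold.
#' @param start_residue First residue of the maximal unfolding window.
#' @param n_models Number of models.
#' @param seed Integer seed.
#' @return A [StructureEnsemble] with `n_models` models.
#' @export
emulate_unfolding <- function(model, chain, start_residue, n_models, seed) {
  stopifnot(n_models(model) == 1L)
  res <- residues(model, chain)
  rlast <- res$resno[nrow(res)]
  old <- .Random.seed_save()
  set.seed(seed)
  out <- vector("list", n_models)
  for (k in seq_len(n_models)) {
    if (start_residue > rlast) { out[[k]] <- model; next }
    wmax <- rlast - start_residue + 1L
    w <- max(1L, ceiling(k / n_models * wmax))
    from <- rlast - w + 1L
    d <- sample_coil_dihedrals(w)
    out[[k]] <- rebuild_segment(model, chain, from, rlast, d$phi, d$psi)
  }
  .Random.seed_restore(old)
  stack_models(out, source = paste0(model$source, "+unfold"))
}

# Fray (randomize) a fixed terminal window of one chain in a single model;
# used by the MD-like ensemble generator.  Window must touch a terminus.
fray_segment <- function(model, chain, from, to) {
  w <- to - from + 1L
  d <- sample_coil_dihedrals(w)
  rebuild_segment(model, chain, from, to, d$phi, d$psi)
}

#' MD-like ensemble generator
#'
#' Produces a fluctuation ensemble around a model the way a short
#' molecular-dynamics trajectory samples one: optional terminal fraying
#' (fresh coil dihedrals per model per window), per-residue Gaussian
#' rigid-body displacement, and an optional rigid separation of one chain
#' from the rest along the interface normal (a destabilized-dimer
#' emulation).
#'
#' @param model Single-model [StructureEnsemble].
#' @param n_models Models to generate.
#' @param seed Integer seed.
#' @param sigma Scalar or per-residue displacement sigma, Angstrom.
#' @param fray List of windows `list(chain=, from=, to=, prob=)` to
#'   re-randomize per model (each must touch a chain terminus); `prob`
#'   (default 1) applies the window to that fraction of models, emulating
#'   transient fraying.
#' @param separation Rigid displacement (Angstrom) of `separate_chain` away
#'   from the other chains' centroid.
#' @param separate_chain Chain moved by `separation`.
#' @return A [StructureEnsemble].
#' @export
md_like_ensemble <- function(model, n_models, seed, sigma = 0.25,
                             fray = list(), separation = 0,
                             separate_chain = NULL) {
  stopifnot(n_models(model) == 1L)
  base <- model
  if (separation > 0) {
    stopifnot(!is.null(separate_chain))
    sel_b <- which(base$atoms$chain == separate_chain)
    sel_a <- setdiff(seq_len(n_atoms(base)), sel_b)
    dirv <- vunit(colMeans(model_xyz(base, 1)[sel_b, , drop = FALSE]) -
                    colMeans(model_xyz(base, 1)[sel_a, , drop = FALSE]))
    base$xyz[1, sel_b, ] <- sweep(base$xyz[1, sel_b, , drop = TRUE], 2,
                                  -separation * dirv)
  }
  old <- .Random.seed_save()
  set.seed(seed)
  models <- vector("list", n_models)
  for (m in seq_len(n_models)) {
    mm <- base
    for (w in fray) {
      if (is.null(w$prob) || runif(1) < w$prob)
        mm <- fray_segment(mm, w$chain, w$from, w$to)
    }
    models[[m]] <- mm
  }
  .Random.seed_restore(old)
  ens <- stack_models(models, source = paste0(model$source, "+mdlike"))
  # per-residue Gaussian displacement on top of the frayed frames
  res <- residues(ens)
  sig <- if (length(sigma) == 1L) rep(sigma, nrow(res)) else sigma
  stopifnot(length(sig) == nrow(res))
  key <- paste(ens$atoms$chain, ens$atoms$resno, ens$atoms$insert)
  rid <- match(key, paste(res$chain, res$resno, res$insert))
  old <- .Random.seed_save()
  set.seed(seed + 1000003L)
  for (m in seq_len(n_models)) {
    rshift <- matrix(rnorm(3 * nrow(res)), ncol = 3) * sig
    ens$xyz[m, , ] <- ens$xyz[m, , ] + rshift[rid, , drop = FALSE]
  }
  .Random.seed_restore(old)
  ens
}

#' Subset an ensemble to selected chains
#'
#' @param ens A [StructureEnsemble].
#' @param chains Chain IDs to keep.
#' @return A [StructureEnsemble] restricted to those chains.
#' @export
extract_chains <- function(ens, chains) {
  idx <- which(ens$atoms$chain %in% chains)
  if (!length(idx)) stop("no atoms in chains ", paste(chains, collapse = ","))
  out <- new_ensemble(ens$atoms[idx, , drop = FALSE],
                      ens$xyz[, idx, , drop = FALSE], source = ens$source)
  attr(out, "meta") <- attr(ens, "meta")
  out
}
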