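# Helix-axis fitting, crossing angles, aromatic ring-pair geometry and
# stacking classes, met-aromatic and CH-pi interaction detection.

#' Fit a helix axis
#'
#' Local helical centres (mean of four consecutive CA atoms) are fitted by
#' their principal direction; the sign is chosen so the axis points from
#' the N- to the C-terminal end of the range.
#'
#' @param ens A [StructureEnsemble].
#' @param chain Chain ID.
#' @param resno_range Integer vector `c(first, last)`; default: whole
#'   chain.  At least 7 consecutive residues with CA are required.
#' @param model Model index.
#' @return Object of class `HelixAxis`: `anchor` (centroid), `direction`
#'   (unit, N to C), `residue_range`, `fit_rmsd` (Angstrom).
#' @export
fit_helix_axis <- function(ens, chain, resno_range = NULL, model = 1L) {
  res <- residues(ens, chain)
  if (is.null(resno_range)) resno_range <- range(res$resno)
  rns <- resno_range[1]:resno_range[2]
  if (length(rns) < 7) stop("fit error: need at least 7 residues")
  idx <- vapply(rns, function(rn) atom_index(ens, chain, rn, "CA"), 1L)
  if (any(is.na(idx))) stop("fit error: broken chain in range (missing CA)")
  ca <- model_xyz(ens, model, idx)
  if (any(row_dist(ca[-1, , drop = FALSE],
                   ca[-nrow(ca), , drop = FALSE]) > CHAIN_BREAK_CA))
    stop("fit error: chain break within residue range")
  centers <- t(vapply(seq_len(nrow(ca) - 3),
                      function(k) colMeans(ca[k:(k + 3), ]), numeric(3)))
  pc <- prcomp(centers)
  dir <- pc$rotation[, 1]
  if (sum((centers[nrow(centers), ] - centers[1, ]) * dir) < 0) dir <- -dir
  anchor <- colMeans(centers)
  rel <- sweep(centers, 2, anchor)
  perp <- rel - (rel %*% dir) %*% t(dir)
  structure(list(anchor = anchor, direction = as.vector(dir),
                 residue_range = resno_range, chain = chain,
                 fit_rmsd = sqrt(mean(rowSums(perp^2)))),
            class = "HelixAxis")
}

#' Crossing angle and mutual orientation of two helix axes
#'
#' The raw angle is the arc-cosine of the dot product of the two N-to-C
#' direction vectors (0-180 degrees); axes are antiparallel when it
#' exceeds 90 degrees.  The packing angle `min(theta, 180 - theta)` is
#' also reported so that antiparallel coiled-coil crossing angles are
#' comparable with the conventional small-angle statement.
#'
#' @param axis_a,axis_b `HelixAxis` objects.
#' @return List: `angle` (deg, 0-180), `packing_angle` (deg, 0-90),
#'   `orientation` (`"parallel"`/`"antiparallel"`).
#' @export
crossing_angle <- function(axis_a, axis_b) {
  d <- sum(axis_a$direction * axis_b$direction)
  ang <- acos(max(-1, min(1, d))) * 180 / pi
  list(angle = ang, packing_angle = min(ang, 180 - ang),
       orientation = if (ang > 90) "antiparallel" else "parallel")
}

ring_coords <- function(ens, chain, resno, model) {
  a <- ens$atoms
  rid <- a$resid[which(a$chain == chain & a$resno == resno)][1]
  if (is.na(rid) || !(rid %in% names(RING_ATOMS)))
    stop("geometry error: residue ", chain, resno,
         " is not aromatic (TYR/PHE/TRP/HIS)")
  idx <- vapply(RING_ATOMS[[rid]],
                function(at) atom_index(ens, chain, resno, at), 1L)
  if (any(is.na(idx)))
    stop("geometry error: incomplete aromatic ring at ", chain, resno)
  list(xyz = model_xyz(ens, model, idx), resid = rid,
       cz = atom_index(ens, chain, resno, "CZ"))
}

ring_normal <- function(xyz) {
  cen <- colMeans(xyz)
  sv <- svd(sweep(xyz, 2, cen))
  list(centroid = cen, normal = sv$v[, 3])
}

#' Aromatic ring-pair geometry and stacking class
#'
#' Interplanar angle (between least-squares ring normals, folded into
#' 0-90 degrees), CZ-CZ distance (TYR/PHE; centroid distance otherwise)
#' and centroid distance for two aromatic residues.  The pair is classed
#' `parallel` when the angle is below `parallel_max` and `edge_to_face`
#' when above `edge_min`, in both cases requiring centroid distance <=
#' `max_centroid`; otherwise `none`.
#'
#' @param ens A [StructureEnsemble].
#' @param res_a,res_b Residue addresses `list(chain=, resno=)`.
#' @param model Model index.
#' @param parallel_max,edge_min,max_centroid Class thresholds (degrees,
#'   degrees, Angstrom).
#' @return Object of class `RingGeometry`: `interplanar_angle`,
#'   `cz_cz_distance`, `centroid_distance`, `class`.
#' @export
ring_geometry <- function(ens, res_a, res_b, model = 1L,
                          parallel_max = 30, edge_min = 60,
                          max_centroid = 7.5) {
  ra <- ring_coords(ens, res_a$chain, res_a$resno, model)
  rb <- ring_coords(ens, res_b$chain, res_b$resno, model)
  na_ <- ring_normal(ra$xyz); nb <- ring_normal(rb$xyz)
  ang <- acos(min(1, abs(sum(na_$normal * nb$normal)))) * 180 / pi
  cend <- vnorm(na_$centroid - nb$centroid)
  czd <- if (!is.na(ra$cz) && !is.na(rb$cz))
    vnorm(model_xyz(ens, model, ra$cz) - model_xyz(ens, model, rb$cz))
  else cend
  cls <- if (cend <= max_centroid && ang < parallel_max) "parallel"
         else if (cend <= max_centroid && ang > edge_min) "edge_to_face"
         else "none"
  structure(list(interplanar_angle = ang, cz_cz_distance = czd,
                 centroid_distance = cend, class = cls),
            class = "RingGeometry")
}

#' Ring-pair geometry across an ensemble
#'
#' Per-model [ring_geometry()] records plus the fraction of models in each
#' stacking class.
#'
#' @inheritParams ring_geometry
#' @param ... Passed to [ring_geometry()].
#' @return List: `per_model` data frame (angle, cz_cz, centroid, class),
#'   `fractions` named vector (parallel, edge_to_face, none).
#' @export
ring_class_series <- function(ens, res_a, res_b, ...) {
  rows <- lapply(seq_len(n_models(ens)), function(m) {
    g <- ring_geometry(ens, res_a, res_b, model = m, ...)
    data.frame(model = m, interplanar_angle = g$interplanar_angle,
               cz_cz_distance = g$cz_cz_distance,
               centroid_distance = g$centroid_distance, class = g$class,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)
  fr <- c(parallel = mean(per$class == "parallel"),
          edge_to_face = mean(per$class == "edge_to_face"),
          none = mean(per$class == "none"))
  list(per_model = per, fractions = fr)
}

#' Detect met-aromatic and CH-pi interactions
#'
#' A methionine SD sulfur within `met_max` of an aromatic ring centroid is
#' a met-aromatic interaction; an apolar side-chain carbon within
#' `chpi_max` of a centroid and within `chpi_angle` degrees of the ring
#' normal is a CH-pi interaction.
#'
#' @param ens A [StructureEnsemble].
#' @param model Model index.
#' @param met_max,chpi_max Distance gates, Angstrom.
#' @param chpi_angle Maximum angle between the centroid-to-carbon vector
#'   and the ring normal, degrees.
#' @return Data frame of interactions (type, aromatic residue, partner
#'   atom, distance, off-normal angle).
#' @export
met_aromatic_and_chpi <- function(ens, model = 1L, met_max = 6.0,
                                  chpi_max = 4.5, chpi_angle = 40) {
  a <- ens$atoms
  res <- residues(ens)
  arom <- res[res$resid %in% names(RING_ATOMS), , drop = FALSE]
  out <- list(); k <- 0L
  xyz <- model_xyz(ens, model)
  for (r in seq_len(nrow(arom))) {
    rg <- tryCatch(ring_coords(ens, arom$chain[r], arom$resno[r], model),
                   error = function(e) NULL)
    if (is.null(rg)) next
    nr <- ring_normal(rg$xyz)
    # methionine SD partners
    sd_idx <- which(a$resid == "MET" & a$elety == "SD" &
                      !(a$chain == arom$chain[r] & a$resno == arom$resno[r]))
    for (i in sd_idx) {
      d <- vnorm(xyz[i, ] - nr$centroid)
      if (d <= met_max) {
        k <- k + 1L
        out[[k]] <- data.frame(type = "met_aromatic",
                               chain = arom$chain[r], resno = arom$resno[r],
                               resid = arom$resid[r],
                               partner_chain = a$chain[i],
                               partner_resno = a$resno[i],
                               partner_atom = a$elety[i], distance = d,
                               off_normal = NA_real_,
                               stringsAsFactors = FALSE)
      }
    }
    # aliphatic CH-pi partners
    al_idx <- which(a$element == "C" & is_apolar(a$resid, a$elety) &
                      !(a$resid %in% names(RING_ATOMS) &
                          a$elety %in% unlist(RING_ATOMS)) &
                      !(a$chain == arom$chain[r] & a$resno == arom$resno[r]))
    for (i in al_idx) {
      v <- xyz[i, ] - nr$centroid
      d <- vnorm(v)
      if (d > chpi_max) next
      off <- acos(min(1, abs(sum(vunit(v) * nr$normal)))) * 180 / pi
      if (off <= chpi_angle) {
        k <- k + 1L
        out[[k]] <- data.frame(type = "ch_pi",
                               chain = arom$chain[r], resno = arom$resno[r],
                               resid = arom$resid[r],
                               partner_chain = a$chain[i],
                               partner_resno = a$resno[i],
                               partner_atom = a$elety[i], distance = d,
                               off_normal = off, stringsAsFactors = FALSE)
      }
    }
  }
  if (!k) return(data.frame(type = character(0), chain = character(0),
                            resno = integer(0), resid = character(0),
                            partner_chain = character(0),
                            partner_resno = integer(0),
                            partner_atom = character(0),
                            distance = numeric(0), off_normal = numeric(0)))
  do.call(rbind, out)
}
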