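# Shrake-Rupley solvent-accessible surface area, buried surface area of a
# dimer, and axial formal-charge profiles.

# Bondi van der Waals radii (Angstrom) by element
BONDI_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20,
                 P = 1.80, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
                 SE = 1.90)

# Deterministic quasi-uniform sphere points (golden-spiral lattice)
sphere_points <- function(n) {
  k <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * k / n)
  theta <- pi * (1 + sqrt(5)) * k
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Per-atom SASA by deterministic sphere-point sampling: `n_points` points
#' on each atom's solvent-expanded sphere (van der Waals radius plus probe)
#' are tested against all neighbouring expanded spheres; the accessible
#' fraction times the sphere area is the atom's SASA.
#'
#' @param ens A [StructureEnsemble].
#' @param selection Atom indices (default: all heavy atoms).
#' @param probe_radius Probe radius, Angstrom (water: 1.4).
#' @param n_points Sphere points per atom.
#' @param model Model index.
#' @return Object of class `SasaResult`: `per_atom` (Angstrom^2),
#'   `per_residue` data frame, `total`, `probe_radius`, `n_points`.
#' @export
sasa <- function(ens, selection = NULL, probe_radius = 1.4, n_points = 960,
                 model = 1L) {
  a <- ens$atoms
  if (is.null(selection))
    selection <- which(!(a$element %in% c("H", "D")))
  el <- a$element[selection]
  unknown <- setdiff(unique(el), names(BONDI_RADII))
  if (length(unknown))
    stop("unknown van der Waals radius for element(s): ",
         paste(unknown, collapse = ","))
  r <- BONDI_RADII[el] + probe_radius
  xyz <- model_xyz(ens, model, selection)
  n <- length(selection)
  pts <- sphere_points(n_points)
  maxr <- max(r)
  nb <- pair_search(xyz, xyz, 2 * maxr)
  nb <- nb[nb$i != nb$j & nb$d < r[nb$i] + r[nb$j], , drop = FALSE]
  nb_by_i <- split(nb$j, factor(nb$i, levels = seq_len(n)))
  per_atom <- numeric(n)
  for (i in seq_len(n)) {
    js <- nb_by_i[[i]]
    p <- sweep(pts * r[i], 2, xyz[i, ], "+")
    if (length(js)) {
      acc <- rep(TRUE, n_points)
      for (j in js) {
        if (!any(acc)) break
        d2 <- rowSums(sweep(p[acc, , drop = FALSE], 2, xyz[j, ])^2)
        acc[acc] <- d2 > r[j]^2
      }
      frac <- mean(acc)
    } else frac <- 1
    per_atom[i] <- frac * 4 * pi * r[i]^2
  }
  rsplit <- paste(a$chain[selection], a$resno[selection])
  pr <- aggregate(per_atom, list(key = rsplit), sum)
  key1 <- !duplicated(rsplit)
  per_res <- data.frame(chain = a$chain[selection][key1],
                        resno = a$resno[selection][key1],
                        resid = a$resid[selection][key1],
                        stringsAsFactors = FALSE)
  per_res$sasa <- pr$x[match(paste(per_res$chain, per_res$resno), pr$key)]
  structure(list(per_atom = per_atom, selection = selection,
                 per_residue = per_res[order(per_res$chain, per_res$resno), ],
                 total = sum(per_atom), probe_radius = probe_radius,
                 n_points = n_points),
            class = "SasaResult")
}

#' Buried surface area of a two-chain complex
#'
#' BSA = SASA(A alone) + SASA(B alone) - SASA(complex), heavy atoms only,
#' both-sides total (no division by two).
#'
#' @param ens A [StructureEnsemble] containing both chains.
#' @param chain_a,chain_b Chain IDs.
#' @param model Model index.
#' @param ... Passed to [sasa()] (probe radius, points).
#' @return Buried area, Angstrom^2.
#' @export
buried_surface_area <- function(ens, chain_a, chain_b, model = 1L, ...) {
  for (ch in c(chain_a, chain_b))
    if (!any(ens$atoms$chain == ch)) stop("input error: missing chain ", ch)
  ea <- extract_chains(ens, chain_a)
  eb <- extract_chains(ens, chain_b)
  eab <- extract_chains(ens, c(chain_a, chain_b))
  sasa(ea, model = model, ...)$total + sasa(eb, model = model, ...)$total -
    sasa(eab, model = model, ...)$total
}

#' Ensemble buried surface area
#'
#' @inheritParams buried_surface_area
#' @return List: `per_model`, `model1`, `mean`, `sd`.
#' @export
ensemble_bsa <- function(ens, chain_a, chain_b, ...) {
  per <- vapply(seq_len(n_models(ens)), function(m)
    buried_surface_area(ens, chain_a, chain_b, model = m, ...), numeric(1))
  list(per_model = per, model1 = per[1], mean = mean(per),
       sd = if (length(per) > 1) sd(per) else 0)
}

#' Axial charge-distribution profile
#'
#' Formal side-chain charges (Lys/Arg +1, Asp/Glu -1, His 0; termini
#' excluded) binned by the projection of each CA onto a helix axis.
#'
#' @param ens A [StructureEnsemble].
#' @param chain Chain ID.
#' @param axis A `HelixAxis` (default: fitted over the chain).
#' @param bin_width Bin width along the axis, Angstrom.
#' @param model Model index.
#' @return Object of class `ChargeProfile`: `bins` data frame (midpoint,
#'   charge), `net_charge`.
#' @export
charge_profile <- function(ens, chain, axis = NULL, bin_width = 5,
                           model = 1L) {
  if (is.null(axis)) axis <- fit_helix_axis(ens, chain, model = model)
  res <- residues(ens, chain)
  ca_idx <- vapply(res$resno, function(rn) atom_index(ens, chain, rn, "CA"),
                   1L)
  keep <- !is.na(ca_idx)
  res <- res[keep, , drop = FALSE]; ca_idx <- ca_idx[keep]
  q <- FORMAL_CHARGE[res$resid]
  q[is.na(q)] <- 0L
  proj <- as.vector(sweep(model_xyz(ens, model, ca_idx), 2, axis$anchor) %*%
                      axis$direction)
  br <- range(proj)
  breaks <- seq(floor(br[1] / bin_width) * bin_width,
                ceiling(br[2] / bin_width) * bin_width, by = bin_width)
  if (length(breaks) < 2) breaks <- c(breaks, breaks + bin_width)
  bin <- cut(proj, breaks, include.lowest = TRUE)
  charge <- tapply(q, bin, sum)
  charge[is.na(charge)] <- 0
  mids <- (head(breaks, -1) + tail(breaks, -1)) / 2
  structure(list(bins = data.frame(mid = mids,
                                   charge = as.integer(charge)),
                 net_charge = as.integer(sum(q))),
            class = "ChargeProfile")
}
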