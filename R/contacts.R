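# Heavy-atom contact networks: enumeration (cell-list neighbour search),
# classification (hydrophobic / hydrogen bond / van der Waals / salt
# bridge), backbone hydrogen-bond counting, native-contact retention,
# salt-bridge occupancy and wild-type-normalized replicate statistics.

# Cell-list neighbour search between two coordinate sets.  Returns a
# data.frame(i, j, d) of pairs with d <= cutoff; i indexes rows of `xa`,
# j rows of `xb`.  Exact (verified against the O(N^2) scan in tests).
pair_search <- function(xa, xb, cutoff, method = c("cell", "brute")) {
  method <- match.arg(method)
  if (!nrow(xa) || !nrow(xb))
    return(data.frame(i = integer(0), j = integer(0), d = numeric(0)))
  if (method == "brute") {
    d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
    hit <- which(d2 <= cutoff^2 + 1e-9, arr.ind = TRUE)
    return(data.frame(i = hit[, 1], j = hit[, 2],
                      d = sqrt(pmax(d2[hit], 0))))
  }
  cell <- function(x) floor(x / cutoff)
  ca <- cell(xa); cb <- cell(xb)
  enc <- function(m) (m[, 1] * 2097152 + m[, 2]) * 2097152 + m[, 3]
  dtb <- data.table::data.table(ck = enc(cb), j = seq_len(nrow(xb)))
  data.table::setkey(dtb, ck)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  out_i <- list(); out_j <- list(); k <- 0L
  for (o in seq_len(nrow(offs))) {
    keya <- enc(sweep(ca, 2, -offs[o, ]))
    dta <- data.table::data.table(ck = keya, i = seq_len(nrow(xa)))
    m <- dtb[dta, on = "ck", nomatch = NULL, allow.cartesian = TRUE]
    if (nrow(m)) { k <- k + 1L; out_i[[k]] <- m$i; out_j[[k]] <- m$j }
  }
  if (!k) return(data.frame(i = integer(0), j = integer(0), d = numeric(0)))
  i <- unlist(out_i); j <- unlist(out_j)
  d <- sqrt(rowSums((xa[i, , drop = FALSE] - xb[j, , drop = FALSE])^2))
  keep <- d <= cutoff + 1e-9
  data.frame(i = i[keep], j = j[keep], d = d[keep])
}

#' Enumerate heavy-atom contacts between two atom groups
#'
#' Every unordered heavy-atom pair (one atom from each group) within
#' `cutoff` becomes a contact record.  When the two groups are identical
#' (intra-protomer mode) pairs within the same residue and between
#' sequence-adjacent residues (|i - j| < `neighbor_exclusion`) are
#' excluded, so counts measure tertiary packing.
#'
#' @param ens A [StructureEnsemble].
#' @param group_a,group_b Atom index vectors (see [select_atoms()]); must be
#'   heavy atoms.  Pass identical vectors for intra-group contacts.
#' @param cutoff Distance cutoff, Angstrom.
#' @param model Model index.
#' @param neighbor_exclusion Minimum |residue number difference| for
#'   intra-chain pairs (default 2: self and adjacent excluded).
#' @param method `"cell"` (cell-list search) or `"brute"`.
#' @return Data frame of contact records: chain/resno/resid/elety for both
#'   atoms, `distance`, and `scope` (`inter_protomer`/`intra_protomer`).
#' @export
atom_contacts <- function(ens, group_a, group_b, cutoff, model = 1L,
                          neighbor_exclusion = 2L,
                          method = c("cell", "brute")) {
  method <- match.arg(method)
  stopifnot(cutoff > 0)
  a <- ens$atoms
  if (any(a$element[c(group_a, group_b)] %in% c("H", "D")))
    stop("contact groups must be heavy-atom selections")
  same <- identical(sort(group_a), sort(group_b))
  if (!same && length(intersect(group_a, group_b)))
    stop("input error: overlapping groups in inter-group mode")
  xa <- model_xyz(ens, model, group_a)
  xb <- model_xyz(ens, model, group_b)
  p <- pair_search(xa, xb, cutoff, method)
  ga <- group_a[p$i]; gb <- group_b[p$j]
  if (same) {
    keep <- ga < gb
    ga <- ga[keep]; gb <- gb[keep]; p <- p[keep, , drop = FALSE]
    samechain <- a$chain[ga] == a$chain[gb]
    keep <- !(samechain & abs(a$resno[ga] - a$resno[gb]) < neighbor_exclusion)
    ga <- ga[keep]; gb <- gb[keep]; p <- p[keep, , drop = FALSE]
  } else {
    # canonical order for unordered storage
    swap <- ga > gb
    tmp <- ga[swap]; ga[swap] <- gb[swap]; gb[swap] <- tmp
  }
  scope <- ifelse(a$chain[ga] == a$chain[gb], "intra_protomer",
                  "inter_protomer")
  data.frame(chain_a = a$chain[ga], resno_a = a$resno[ga],
             resid_a = a$resid[ga], elety_a = a$elety[ga],
             chain_b = a$chain[gb], resno_b = a$resno[gb],
             resid_b = a$resid[gb], elety_b = a$elety[gb],
             distance = p$d, scope = scope, stringsAsFactors = FALSE)
}

#' Count inter-protomer residue pairs in contact
#'
#' Number of unordered residue pairs across the interface of two chains
#' with at least one heavy-atom pair within `cutoff`.
#'
#' @param ens A [StructureEnsemble].
#' @param chain_a,chain_b Two distinct chain IDs.
#' @param cutoff Distance cutoff, Angstrom (7 by default).
#' @param model Model index.
#' @return Integer count.
#' @export
residue_contact_count <- function(ens, chain_a, chain_b, cutoff = 7,
                                  model = 1L) {
  if (identical(chain_a, chain_b))
    stop("input error: chains must be distinct")
  ga <- select_atoms(ens, chains = chain_a, heavy_only = TRUE)
  gb <- select_atoms(ens, chains = chain_b, heavy_only = TRUE)
  rec <- atom_contacts(ens, ga, gb, cutoff, model = model)
  length(unique(paste(rec$resno_a, rec$resno_b)))
}

# donor/acceptor element sets for the geometric hydrogen-bond rule
.is_NO <- function(el) el %in% c("N", "O")

# basic (positive) and acidic (negative) side-chain atom names
SALT_BASIC <- list(LYS = "NZ", ARG = c("NH1", "NH2", "NE"))
SALT_ACIDIC <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))

is_salt_basic <- function(resid, elety) {
  (resid == "LYS" & elety == "NZ") |
    (resid == "ARG" & elety %in% c("NH1", "NH2", "NE"))
}
is_salt_acidic <- function(resid, elety) {
  (resid == "ASP" & elety %in% c("OD1", "OD2")) |
    (resid == "GLU" & elety %in% c("OE1", "OE2")) |
    elety == "OXT"
}

is_apolar <- function(resid, elety) {
  mapply(function(r, e) e %in% APOLAR_ATOMS[[r]], resid, elety,
         USE.NAMES = FALSE)
}

# idealized amide hydrogen from N, CA and the preceding C
amide_h <- function(N, CA, Cprev) {
  N + 1.01 * vunit(vunit(N - Cprev) + vunit(N - CA))
}

#' Classify contact records
#'
#' Assigns each contact a type with the precedence salt bridge > hydrogen
#' bond > hydrophobic > van der Waals:
#' * `salt_bridge`: Lys NZ / Arg NH1,NH2,NE vs Asp OD* / Glu OE* / OXT at
#'   <= 4.0 Angstrom;
#' * `hydrogen_bond`: N/O donor-acceptor pair <= 3.5 Angstrom with a
#'   D-H...A angle >= 120 degrees (the amide H is built from ideal geometry
#'   when absent; when no H can be placed the angle test is waived);
#' * `hydrophobic`: two apolar side-chain carbons/sulfurs <= 4.5 Angstrom;
#' * `van_der_waals`: any other heavy-atom pair <= 4.5 Angstrom;
#' * `unclassified` otherwise.
#'
#' @param records Output of [atom_contacts()].
#' @param ens The ensemble the records came from.
#' @param model Model index used for angle geometry.
#' @return `records` with an added `type` column.
#' @export
classify_contacts <- function(records, ens, model = 1L) {
  if (!nrow(records)) {
    records$type <- character(0)
    return(records)
  }
  a <- ens$atoms
  xyz <- model_xyz(ens, model)
  ela <- a$element[match(paste(records$chain_a, records$resno_a, records$elety_a),
                         paste(a$chain, a$resno, a$elety))]
  elb <- a$element[match(paste(records$chain_b, records$resno_b, records$elety_b),
                         paste(a$chain, a$resno, a$elety))]
  type <- rep("unclassified", nrow(records))
  d <- records$distance

  sb <- (is_salt_basic(records$resid_a, records$elety_a) &
           is_salt_acidic(records$resid_b, records$elety_b)) |
    (is_salt_basic(records$resid_b, records$elety_b) &
       is_salt_acidic(records$resid_a, records$elety_a))
  type[sb & d <= 4.0] <- "salt_bridge"

  hb_cand <- which(type == "unclassified" & .is_NO(ela) & .is_NO(elb) &
                     d <= 3.5)
  for (k in hb_cand) {
    ok <- FALSE
    for (ord in 1:2) {
      dc <- if (ord == 1) "a" else "b"; ac <- if (ord == 1) "b" else "a"
      del <- if (ord == 1) ela[k] else elb[k]
      dch <- records[[paste0("chain_", dc)]][k]
      drn <- records[[paste0("resno_", dc)]][k]
      det <- records[[paste0("elety_", dc)]][k]
      if (del != "N" && !(det %in% c("OG", "OG1", "OH", "SG"))) next
      acc <- xyz[atom_index(ens, records[[paste0("chain_", ac)]][k],
                            records[[paste0("resno_", ac)]][k],
                            records[[paste0("elety_", ac)]][k]), ]
      if (det == "N") {
        iN <- atom_index(ens, dch, drn, "N")
        iCA <- atom_index(ens, dch, drn, "CA")
        iCp <- atom_index(ens, dch, drn - 1L, "C")
        if (!is.na(iCA) && !is.na(iCp)) {
          H <- amide_h(xyz[iN, ], xyz[iCA, ], xyz[iCp, ])
          if (vangle(xyz[iN, ], H, acc) >= 120) ok <- TRUE
        } else ok <- TRUE   # terminal amine: no placeable H, accept distance
      } else ok <- TRUE     # rotatable OH/SH donor: distance criterion only
      if (ok) break
    }
    if (ok) type[k] <- "hydrogen_bond"
  }

  hp <- type == "unclassified" & d <= 4.5 &
    is_apolar(records$resid_a, records$elety_a) &
    is_apolar(records$resid_b, records$elety_b) &
    ela %in% c("C", "S") & elb %in% c("C", "S")
  type[hp] <- "hydrophobic"
  type[type == "unclassified" & d <= 4.5] <- "van_der_waals"
  records$type <- type
  records
}

#' Contact network summary
#'
#' Aggregates atom-pair contact records into residue-pair edges with
#' atom-pair multiplicity and a tally of contact types.
#'
#' @param records Classified records (see [classify_contacts()]).
#' @return Data frame with one row per residue pair.
#' @export
contact_network <- function(records) {
  if (!nrow(records))
    return(data.frame(chain_a = character(0), resno_a = integer(0),
                      chain_b = character(0), resno_b = integer(0),
                      n_atom_pairs = integer(0)))
  key <- paste(records$chain_a, records$resno_a, records$chain_b,
               records$resno_b, sep = "|")
  sp <- split(seq_len(nrow(records)), key)
  out <- do.call(rbind, lapply(sp, function(ix) {
    r1 <- records[ix[1], ]
    tt <- if ("type" %in% names(records)) table(records$type[ix]) else NULL
    data.frame(chain_a = r1$chain_a, resno_a = r1$resno_a,
               resid_a = r1$resid_a, chain_b = r1$chain_b,
               resno_b = r1$resno_b, resid_b = r1$resid_b,
               n_atom_pairs = length(ix),
               min_distance = min(records$distance[ix]),
               n_hydrophobic = if (is.null(tt)) NA else sum(tt[names(tt) == "hydrophobic"]),
               n_hbond = if (is.null(tt)) NA else sum(tt[names(tt) == "hydrogen_bond"]),
               n_vdw = if (is.null(tt)) NA else sum(tt[names(tt) == "van_der_waals"]),
               n_salt = if (is.null(tt)) NA else sum(tt[names(tt) == "salt_bridge"]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$chain_a, out$resno_a, out$chain_b, out$resno_b), ]
}

#' Count backbone hydrogen bonds
#'
#' Counts backbone N-H...O=C hydrogen bonds over a selection using the
#' Kabsch-Sander energy criterion (E < -0.5 kcal/mol; see
#' [backbone_hbond_energy()]).  Each amide donates at most one bond (its
#' best-energy acceptor); pairs closer than |i - j| = 2 in sequence are
#' excluded.
#'
#' @param ens A [StructureEnsemble].
#' @param chains Chains to include (default: all).
#' @param model Model index.
#' @return Integer count.
#' @export
backbone_hbond_count <- function(ens, chains = NULL, model = 1L) {
  hb <- kabsch_sander(ens, chains = chains, model = model)
  sum(!is.na(hb$best_acceptor))
}

#' Native-contact retention across an ensemble
#'
#' The native set is every qualifying heavy-atom pair of the reference
#' model that involves `site_selection` (optionally restricted to a
#' partner selection); the per-model fraction is the share of native pairs
#' still within `cutoff`.
#'
#' @param ens Ensemble to score.
#' @param reference Single-model [StructureEnsemble] sharing the topology
#'   of `ens`.
#' @param site_selection Atom indices anchoring the native set.
#' @param cutoff Distance cutoff, Angstrom (10 by default).
#' @param partner_selection Optional atom indices for the other side;
#'   default: all heavy atoms outside the residues of `site_selection`.
#' @return List with `per_model` fractions and their `mean`.
#' @export
native_contact_fraction <- function(ens, reference, site_selection,
                                    cutoff = 10, partner_selection = NULL) {
  a <- ens$atoms
  ra <- reference$atoms
  if (!identical(a$elety, ra$elety) || !identical(a$resno, ra$resno))
    stop("reference must share the ensemble topology")
  if (is.null(partner_selection)) {
    site_res <- unique(paste(a$chain[site_selection], a$resno[site_selection]))
    partner_selection <- which(!(paste(a$chain, a$resno) %in% site_res) &
                                 !(a$element %in% c("H", "D")))
  }
  xr_a <- model_xyz(reference, 1L, site_selection)
  xr_b <- model_xyz(reference, 1L, partner_selection)
  nat <- pair_search(xr_a, xr_b, cutoff)
  if (!nrow(nat)) stop("input error: empty native contact set")
  per <- vapply(seq_len(n_models(ens)), function(m) {
    xa <- model_xyz(ens, m, site_selection)
    xb <- model_xyz(ens, m, partner_selection)
    dm <- sqrt(rowSums((xa[nat$i, , drop = FALSE] -
                          xb[nat$j, , drop = FALSE])^2))
    mean(dm <= cutoff + 1e-9)
  }, numeric(1))
  list(per_model = per, mean = mean(per), n_native = nrow(nat))
}

#' Salt-bridge occupancy over an ensemble
#'
#' Fraction of models in which any basic side-chain nitrogen of `res_a`
#' lies within 4.0 Angstrom of an acidic side-chain oxygen of `res_b`
#' (or vice versa).
#'
#' @param ens A [StructureEnsemble].
#' @param res_a,res_b Residue addresses `list(chain=, resno=)`.
#' @return Fraction in \[0, 1\].
#' @export
salt_bridge_occupancy <- function(ens, res_a, res_b) {
  a <- ens$atoms
  rows <- function(r) which(a$chain == r$chain & a$resno == r$resno)
  ia <- rows(res_a); ib <- rows(res_b)
  if (!length(ia) || !length(ib)) stop("residue not found")
  pick <- function(ix) {
    bas <- ix[is_salt_basic(a$resid[ix], a$elety[ix])]
    aci <- ix[is_salt_acidic(a$resid[ix], a$elety[ix])]
    list(bas = bas, aci = aci)
  }
  pa <- pick(ia); pb <- pick(ib)
  if (length(pa$bas) && length(pb$aci)) { g1 <- pa$bas; g2 <- pb$aci }
  else if (length(pb$bas) && length(pa$aci)) { g1 <- pb$bas; g2 <- pa$aci }
  else stop("input error: residues are not an ionizable basic/acidic pair")
  hits <- vapply(seq_len(n_models(ens)), function(m) {
    x1 <- model_xyz(ens, m, g1); x2 <- model_xyz(ens, m, g2)
    d2 <- outer(rowSums(x1^2), rowSums(x2^2), "+") - 2 * x1 %*% t(x2)
    any(d2 <= 4.0^2)
  }, logical(1))
  mean(hits)
}

#' Replicate contact statistics with wild-type normalization
#'
#' Given per-replicate mean counts for a wild-type and a mutant group,
#' computes the mutant value normalized by the wild-type group mean and a
#' one-tailed pooled-variance (equal-variance) two-sample t test in the
#' direction of the observed difference.
#'
#' @param wt,mut Numeric vectors of per-replicate means (>= 2 each).
#' @return List: `mean_wt`, `mean_mut`, `sd_wt`, `sd_mut`, `normalized`
#'   (mut/wt), `t`, `df`, `p` (one-tailed).
#' @export
contact_stats <- function(wt, mut) {
  stopifnot(length(wt) >= 2, length(mut) >= 2)
  m1 <- mean(wt); m2 <- mean(mut)
  if (m1 == 0) stop("normalization error: wild-type group mean is zero")
  n1 <- length(wt); n2 <- length(mut)
  sp2 <- ((n1 - 1) * stats::var(wt) + (n2 - 1) * stats::var(mut)) /
    (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tval <- if (se == 0) { if (m2 == m1) 0 else sign(m2 - m1) * Inf }
          else (m2 - m1) / se
  df <- n1 + n2 - 2
  p <- if (is.infinite(tval)) 0 else stats::pt(abs(tval), df,
                                               lower.tail = FALSE)
  list(mean_wt = m1, mean_mut = m2, sd_wt = stats::sd(wt),
       sd_mut = stats::sd(mut), normalized = m2 / m1, t = tval, df = df,
       p = p)
}
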