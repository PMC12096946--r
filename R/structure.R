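#' @importFrom stats prcomp pt rnorm runif sd setNames aggregate var complete.cases
#' @importFrom utils head tail
#' @importFrom data.table data.table setkey
NULL

# Internal constructor.  `atoms` is one row per atom (topology shared by all
# models); `xyz` is an array [n_models, n_atoms, 3] in Angstrom.
new_ensemble <- function(atoms, xyz, source = "constructed") {
  stopifnot(is.data.frame(atoms), length(dim(xyz)) == 3L,
            dim(xyz)[2] == nrow(atoms), dim(xyz)[3] == 3L)
  if (any(!is.finite(xyz))) stop("non-finite coordinates in ensemble")
  atoms$element <- toupper(atoms$element)
  if (any(is.na(atoms$element) | atoms$element == ""))
    stop("every atom must carry a chemical element after ingestion")
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, xyz = xyz, source = source),
            class = "StructureEnsemble")
}

#' Number of models / atoms in an ensemble
#'
#' @param ens A `StructureEnsemble`.
#' @return Integer count.
#' @export
n_models <- function(ens) dim(ens$xyz)[1]

#' @rdname n_models
#' @export
n_atoms <- function(ens) dim(ens$xyz)[2]

#' @export
print.StructureEnsemble <- function(x, ...) {
  cat(sprintf("StructureEnsemble: %d model(s), %d atoms, chains %s [%s]\n",
              n_models(x), n_atoms(x),
              paste(unique(x$atoms$chain), collapse = ","), x$source))
  invisible(x)
}

#' Coordinates of one model
#'
#' @param ens A `StructureEnsemble`.
#' @param model Model index (1-based).
#' @param idx Optional atom indices.
#' @return Numeric matrix with one row per atom and columns x, y, z.
#' @export
model_xyz <- function(ens, model = 1L, idx = NULL) {
  stopifnot(model >= 1L, model <= n_models(ens))
  m <- ens$xyz[model, , , drop = FALSE]
  dim(m) <- dim(ens$xyz)[2:3]
  colnames(m) <- c("x", "y", "z")
  if (!is.null(idx)) m <- m[idx, , drop = FALSE]
  m
}

#' Extract a single model as a one-model ensemble
#'
#' @inheritParams model_xyz
#' @return A `StructureEnsemble` with one model.
#' @export
get_model <- function(ens, model = 1L) {
  xyz <- ens$xyz[model, , , drop = FALSE]
  new_ensemble(ens$atoms, xyz, source = ens$source)
}

#' Assemble several single-topology models into one ensemble
#'
#' All inputs must share an identical topology (chains, residue numbers and
#' atom names in the same order).
#'
#' @param models List of `StructureEnsemble` objects.
#' @param source Provenance string.
#' @return A `StructureEnsemble`.
#' @export
stack_models <- function(models, source = "stacked") {
  stopifnot(length(models) >= 1L)
  ref <- models[[1]]$atoms
  for (k in seq_along(models)) {
    a <- models[[k]]$atoms
    bad <- which(a$chain != ref$chain | a$resno != ref$resno |
                   a$elety != ref$elety)
    if (nrow(a) != nrow(ref) || length(bad))
      stop(sprintf("topology mismatch at input %d (first differing atom: %s)",
                   k, if (length(bad)) paste(a$chain[bad[1]], a$resno[bad[1]],
                                             a$elety[bad[1]]) else "atom count"))
  }
  nm <- sum(vapply(models, n_models, 1L))
  xyz <- array(NA_real_, c(nm, nrow(ref), 3L))
  at <- 1L
  for (m in models) {
    for (i in seq_len(n_models(m))) {
      xyz[at, , ] <- m$xyz[i, , ]
      at <- at + 1L
    }
  }
  new_ensemble(ref, xyz, source = source)
}

# Map bio3d pdb object (multi=TRUE) to StructureEnsemble, dropping waters and
# hetero residues, resolving altlocs to the highest-occupancy conformer.
from_bio3d <- function(pdb, source) {
  at <- pdb$atom
  keep <- at$type == "ATOM"
  drop_het <- sum(!keep)
  if (drop_het > 0)
    message(sprintf("read_structure: dropping %d water/hetero atoms", drop_het))
  # altloc resolution: keep blank altloc; among duplicated (chain,resno,elety)
  # keep highest occupancy, ties broken in favour of altloc "A".
  alt <- at$alt
  alt[is.na(alt)] <- ""
  occ <- at$o
  occ[is.na(occ)] <- 1
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "|")
  sel <- rep(TRUE, nrow(at))
  for (k in unique(key[keep & duplicated(key) & alt != ""])) {
    idx <- which(key == k & keep)
    best <- idx[order(-occ[idx], alt[idx])][1]
    sel[setdiff(idx, best)] <- FALSE
  }
  keep <- keep & sel
  at <- at[keep, , drop = FALSE]
  ele <- at$elesy
  blank <- is.na(ele) | ele == ""
  if (any(blank)) {
    inferred <- suppressWarnings(bio3d::atom2ele(at$elety[blank]))
    message(sprintf("read_structure: inferred element for %d atoms from names",
                    sum(blank)))
    ele[blank] <- inferred
  }
  ins <- at$insert
  ins[is.na(ins)] <- ""
  atoms <- data.frame(elety = at$elety, resid = at$resid, chain = at$chain,
                      resno = at$resno, insert = ins, element = toupper(ele),
                      stringsAsFactors = FALSE)
  xyzm <- pdb$xyz
  if (is.null(dim(xyzm))) xyzm <- matrix(xyzm, nrow = 1)
  nmod <- nrow(xyzm)
  natom_file <- ncol(xyzm) / 3
  xyz <- array(NA_real_, c(nmod, nrow(atoms), 3L))
  widx <- which(keep)
  for (m in seq_len(nmod)) {
    mm <- matrix(xyzm[m, ], ncol = 3, byrow = TRUE)
    if (nrow(mm) != natom_file) stop("corrupt coordinate block")
    xyz[m, , ] <- mm[widx, , drop = FALSE]
  }
  new_ensemble(atoms, xyz, source = source)
}

#' Read a multi-model protein structure
#'
#' Reads PDB or mmCIF files (or a directory of per-frame PDB files treated as
#' one ensemble).  All MODEL blocks become models of one
#' [StructureEnsemble]; author chain identifiers and residue numbers are
#' preserved; hydrogens are retained (use [strip_hydrogens()] to remove
#' them).  Waters and hetero residues are dropped with a message.
#'
#' @param path File (or directory) to read.
#' @param format One of `"auto"`, `"pdb"`, `"cif"`.
#' @return A [StructureEnsemble].
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.pdb$", full.names = TRUE))
    if (!length(files)) stop("directory contains no .pdb files: ", path)
    models <- lapply(files, read_structure, format = format)
    return(stack_models(models, source = path))
  }
  if (format == "auto")
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)) "cif" else "pdb"
  if (format == "pdb") check_model_blocks(path)
  pdb <- tryCatch(
    if (format == "cif") bio3d::read.cif(path, multi = TRUE, verbose = FALSE)
    else bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
    error = function(e) stop("parse error reading ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  ens <- from_bio3d(pdb, source = path)
  check_topology(ens)
  ens
}

# Verify that every MODEL block of a PDB file carries the same atom list;
# report the first differing atom as a topology error.
check_model_blocks <- function(path) {
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^MODEL", lines)
  if (length(starts) < 2) return(invisible(NULL))
  ends <- grep("^ENDMDL", lines)
  if (length(ends) < length(starts)) ends <- c(ends, length(lines))
  keys <- lapply(seq_along(starts), function(k) {
    blk <- lines[starts[k]:ends[k]]
    at <- blk[grepl("^ATOM|^HETATM", blk)]
    paste(substr(at, 22, 22), trimws(substr(at, 23, 27)),
          trimws(substr(at, 13, 16)))
  })
  for (k in seq_along(keys)[-1]) {
    a <- keys[[1]]; b <- keys[[k]]
    n <- min(length(a), length(b))
    diff <- which(a[seq_len(n)] != b[seq_len(n)])
    if (length(diff) || length(a) != length(b)) {
      at <- if (length(diff)) a[diff[1]] else
        a[min(length(a), length(b)) + 1]
      stop(sprintf("topology error: model %d differs from model 1 at atom %s",
                   k, at))
    }
  }
  invisible(NULL)
}

# Multi-model files parsed by bio3d share one atom table, so per-model atom
# dropout shows up as a truncated/NA coordinate block rather than a differing
# atom list; surface it as a topology error.
check_topology <- function(ens) {
  for (m in seq_len(n_models(ens))) {
    bad <- which(!stats::complete.cases(ens$xyz[m, , ]))
    if (length(bad)) {
      a <- ens$atoms[bad[1], ]
      stop(sprintf("topology error: model %d lacks coordinates starting at %s %s%d %s",
                   m, a$chain, a$resid, a$resno, a$elety))
    }
  }
  invisible(ens)
}

#' Remove hydrogen atoms
#'
#' @param ens A [StructureEnsemble].
#' @return A new ensemble containing only non-hydrogen atoms; the input is
#'   unmodified.  Idempotent.
#' @export
strip_hydrogens <- function(ens) {
  keep <- which(!(ens$atoms$element %in% c("H", "D")))
  new_ensemble(ens$atoms[keep, , drop = FALSE],
               ens$xyz[, keep, , drop = FALSE], source = ens$source)
}

#' Select atoms
#'
#' Returns atom indices in deterministic order (chain, residue number,
#' original file order within a residue).  An empty selection is allowed.
#'
#' @param ens A [StructureEnsemble].
#' @param chains Character vector of chain IDs, or `NULL` for all.
#' @param resno Integer vector of residue numbers, or `NULL` for all.
#' @param elety Character vector of atom names, or `NULL` for all.
#' @param heavy_only If `TRUE`, restrict to non-hydrogen atoms.
#' @return Integer vector of atom indices into `ens$atoms`.
#' @export
select_atoms <- function(ens, chains = NULL, resno = NULL, elety = NULL,
                         heavy_only = FALSE) {
  a <- ens$atoms
  if (!is.null(chains)) {
    unknown <- setdiff(chains, unique(a$chain))
    if (length(unknown))
      stop("selection error: unknown chain(s) ", paste(unknown, collapse = ","))
  }
  keep <- rep(TRUE, nrow(a))
  if (!is.null(chains)) keep <- keep & a$chain %in% chains
  if (!is.null(resno)) keep <- keep & a$resno %in% resno
  if (!is.null(elety)) keep <- keep & a$elety %in% elety
  if (heavy_only) keep <- keep & !(a$element %in% c("H", "D"))
  idx <- which(keep)
  idx[order(a$chain[idx], a$resno[idx], idx)]
}

#' Write an ensemble to a PDB file
#'
#' Multi-model ensembles produce one MODEL/ENDMDL block per model.
#' Coordinates round-trip through [read_structure()] to the fixed-width PDB
#' precision of 1e-3 Angstrom.
#'
#' @param ens A [StructureEnsemble].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(ens, path) {
  a <- ens$atoms
  nm <- n_models(ens)
  xyzm <- matrix(NA_real_, nrow = nm, ncol = 3L * nrow(a))
  for (m in seq_len(nm)) xyzm[m, ] <- as.vector(t(model_xyz(ens, m)))
  ok <- tryCatch({
    bio3d::write.pdb(file = path, xyz = xyzm, type = rep("ATOM", nrow(a)),
                     resno = a$resno, resid = a$resid, eleno = seq_len(nrow(a)),
                     elety = a$elety, chain = a$chain, insert = a$insert,
                     elesy = a$element)
    TRUE
  }, error = function(e) stop("I/O error writing ", path, ": ",
                              conditionMessage(e), call. = FALSE))
  invisible(path)
}

#' Residue table of an ensemble
#'
#' @param ens A [StructureEnsemble].
#' @param chain Optional chain filter.
#' @return Data frame with one row per residue: chain, resno, resid.
#' @export
residues <- function(ens, chain = NULL) {
  a <- ens$atoms
  if (!is.null(chain)) a <- a[a$chain %in% chain, , drop = FALSE]
  u <- !duplicated(paste(a$chain, a$resno, a$insert))
  out <- a[u, c("chain", "resno", "insert", "resid")]
  out <- out[order(out$chain, out$resno), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# index of a single named atom; NA if absent
atom_index <- function(ens, chain, resno, elety) {
  a <- ens$atoms
  i <- which(a$chain == chain & a$resno == resno & a$elety == elety)
  if (length(i)) i[1] else NA_integer_
}
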