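# Kabsch superposition, RMSD, per-residue RMSF over ensembles, and
# replicate-level summary statistics.

kabsch_fit <- function(mobile, ref) {
  cm <- colMeans(mobile); cr <- colMeans(ref)
  A <- sweep(mobile, 2, cm); B <- sweep(ref, 2, cr)
  H <- t(A) %*% B
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  t_vec <- cr - as.vector(R %*% cm)
  list(R = R, t = t_vec)
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Optimal rotation/translation of `mobile` onto `reference` over a
#' selection, with the post-fit RMSD.
#'
#' @param mobile,reference Single-model [StructureEnsemble]s (or ensemble
#'   plus `model` index).
#' @param selection Atom indices (mapped 1:1 between the two structures);
#'   default: all CA atoms.
#' @param model_mobile,model_ref Model indices.
#' @return Object of class `SuperpositionResult`: `rotation` (3x3, det
#'   +1), `translation`, `rmsd` (Angstrom), `selection`.
#' @export
superpose <- function(mobile, reference, selection = NULL,
                      model_mobile = 1L, model_ref = 1L) {
  if (is.null(selection))
    selection <- select_atoms(mobile, elety = "CA")
  if (length(selection) < 3) stop("need at least 3 atoms to superpose")
  xm <- model_xyz(mobile, model_mobile, selection)
  xr <- model_xyz(reference, model_ref, selection)
  f <- kabsch_fit(xm, xr)
  moved <- sweep(xm %*% t(f$R), 2, -f$t)
  structure(list(rotation = f$R, translation = f$t,
                 rmsd = sqrt(mean(rowSums((moved - xr)^2))),
                 selection = selection),
            class = "SuperpositionResult")
}

#' Apply a superposition to a whole ensemble model
#'
#' @param ens A [StructureEnsemble].
#' @param sup A `SuperpositionResult`.
#' @param model Model to transform (default: all models).
#' @return The transformed ensemble.
#' @export
apply_superposition <- function(ens, sup, model = NULL) {
  ms <- if (is.null(model)) seq_len(n_models(ens)) else model
  for (m in ms) {
    ens$xyz[m, , ] <- sweep(ens$xyz[m, , ] %*% t(sup$rotation), 2,
                            -sup$translation)
  }
  ens
}

#' Per-residue RMSF of an ensemble
#'
#' All models are superposed onto an iteratively refined mean structure
#' over the selection (default: all CA atoms); RMSF_i is the root mean
#' square deviation of atom i from its ensemble-mean position.
#'
#' @param ens A [StructureEnsemble] with >= 2 models.
#' @param selection Atom indices (default: all CA).
#' @param iterations Mean-refinement iterations.
#' @return Data frame: chain, resno, elety, rmsf (Angstrom).
#' @export
rmsf <- function(ens, selection = NULL, iterations = 3L) {
  if (n_models(ens) < 2) stop("need at least 2 models for RMSF")
  if (is.null(selection)) selection <- select_atoms(ens, elety = "CA")
  nm <- n_models(ens)
  coords <- lapply(seq_len(nm), function(m) model_xyz(ens, m, selection))
  ref <- coords[[1]]
  for (it in seq_len(iterations)) {
    fitted <- lapply(coords, function(x) {
      f <- kabsch_fit(x, ref)
      sweep(x %*% t(f$R), 2, -f$t)
    })
    ref <- Reduce(`+`, fitted) / nm
  }
  fitted <- lapply(coords, function(x) {
    f <- kabsch_fit(x, ref)
    sweep(x %*% t(f$R), 2, -f$t)
  })
  mean_xyz <- Reduce(`+`, fitted) / nm
  dev2 <- Reduce(`+`, lapply(fitted, function(x)
    rowSums((x - mean_xyz)^2))) / nm
  a <- ens$atoms
  data.frame(chain = a$chain[selection], resno = a$resno[selection],
             elety = a$elety[selection], rmsf = sqrt(dev2),
             stringsAsFactors = FALSE)
}

#' Replicate summary statistics
#'
#' The mean of each replicate's per-model series, their group mean, and
#' the sample (n-1) standard deviation of the replicate means.
#'
#' @param series List of numeric vectors (one per replicate, >= 2).
#' @return List: `replicate_means`, `mean`, `sd`.
#' @export
replicate_summary <- function(series) {
  stopifnot(length(series) >= 2)
  rm_ <- vapply(series, mean, numeric(1))
  list(replicate_means = rm_, mean = mean(rm_), sd = sd(rm_))
}
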