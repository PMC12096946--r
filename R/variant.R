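# Per-variant comparison reports: wild-type-normalized contact / hydrogen
# bond / helicity metrics with replicate statistics and an impact call per
# structural context (protomer, homodimer, heterodimer), plus the
# synthetic six-variant phenotype suite used to validate the pipeline.

#' Parse a variant label
#'
#' @param label Variant string such as `"L35P"`.
#' @param chain Chain carrying the variant.
#' @return Object of class `VariantSpec`: `label`, `chain`, `position`,
#'   `from_aa`, `to_aa` (three-letter).
#' @export
variant_spec <- function(label, chain = "A") {
  m <- regmatches(label, regexec("^([A-Za-z])([0-9]+)([A-Za-z])$", label))[[1]]
  if (length(m) != 4) stop("cannot parse variant label: ", label)
  structure(list(label = toupper(label), chain = chain,
                 position = as.integer(m[3]),
                 from_aa = aa_three(m[2]), to_aa = aa_three(m[4])),
            class = "VariantSpec")
}

check_variant <- function(ens, variant) {
  a <- ens$atoms
  rid <- a$resid[a$chain == variant$chain & a$resno == variant$position][1]
  if (is.na(rid)) stop("input error: variant position ", variant$chain,
                       variant$position, " absent")
  invisible(rid)
}

#' Contacts at a mutation site
#'
#' Heavy-atom contacts between one residue and a partner chain, per model.
#'
#' @param ens A [StructureEnsemble].
#' @param chain,resno Site residue address.
#' @param partner_chain Chain on the other side of the interface.
#' @param cutoff Distance cutoff, Angstrom (10 by default).
#' @return List: `per_model` counts, `mean`.
#' @export
site_contacts <- function(ens, chain, resno, partner_chain, cutoff = 10) {
  ga <- select_atoms(ens, chains = chain, resno = resno, heavy_only = TRUE)
  if (!length(ga)) stop("input error: site residue not found")
  gb <- select_atoms(ens, chains = partner_chain, heavy_only = TRUE)
  per <- vapply(seq_len(n_models(ens)), function(m) {
    nrow(atom_contacts(ens, ga, gb, cutoff, model = m))
  }, numeric(1))
  list(per_model = per, mean = mean(per))
}

#' Classify a normalized metric into an impact call
#'
#' @param normalized Mutant metric divided by the wild-type group mean.
#' @param p One-tailed p-value of the group comparison.
#' @param thresholds List: `reduced` (upper bound for a reduced call),
#'   `slight` and `enhanced` (lower bounds for slightly enhanced /
#'   enhanced), `alpha` (significance level).
#' @return One of `"reduced"`, `"no_effect"`, `"slightly_enhanced"`,
#'   `"enhanced"`.
#' @export
classify_impact <- function(normalized, p,
                            thresholds = list(reduced = 0.8, slight = 1.05,
                                              enhanced = 1.2, alpha = 0.05)) {
  stopifnot(normalized > 0, p >= 0, p <= 1)
  if (p < thresholds$alpha) {
    if (normalized <= thresholds$reduced) return("reduced")
    if (normalized >= thresholds$enhanced) return("enhanced")
    if (normalized >= thresholds$slight) return("slightly_enhanced")
  }
  "no_effect"
}

# per-replicate per-model metric series for one context
context_metrics <- function(reps, context, variant = NULL,
                            reference = NULL) {
  lapply(reps, function(ens) {
    chains <- unique(ens$atoms$chain)
    nm <- n_models(ens)
    if (context == "heterodimer") {
      stopifnot(!is.null(variant))
      partner <- setdiff(chains, variant$chain)[1]
      if (!is.null(reference)) {
        # retained native contacts at the site (native set from the
        # group's own reference model) -- robust to disordered-segment
        # excursions, as in trajectory native-contact analyses
        site_sel <- select_atoms(ens, chains = variant$chain,
                                 resno = variant$position,
                                 heavy_only = TRUE)
        part_sel <- select_atoms(ens, chains = partner, heavy_only = TRUE)
        nc <- native_contact_fraction(ens, reference, site_sel,
                                      cutoff = 10,
                                      partner_selection = part_sel)
        return(list(site_contacts = nc$per_model * nc$n_native))
      }
      sc <- site_contacts(ens, variant$chain, variant$position, partner,
                          cutoff = 10)
      list(site_contacts = sc$per_model)
    } else if (context == "homodimer") {
      ga <- select_atoms(ens, chains = chains[1], heavy_only = TRUE)
      gb <- select_atoms(ens, chains = chains[2], heavy_only = TRUE)
      inter <- vapply(seq_len(nm), function(m)
        nrow(atom_contacts(ens, ga, gb, 7, model = m)), numeric(1))
      list(inter_contacts = inter)
    } else {                                  # protomer
      g <- select_atoms(ens, heavy_only = TRUE)
      intra <- vapply(seq_len(nm), function(m)
        nrow(atom_contacts(ens, g, g, 7, model = m)), numeric(1))
      hb <- vapply(seq_len(nm), function(m)
        backbone_hbond_count(ens, model = m), numeric(1))
      hel <- ensemble_helicity(ens)$per_model
      list(intra_contacts = intra, backbone_hbonds = hb, helicity = hel)
    }
  })
}

HEADLINE_METRIC <- c(protomer = "intra_contacts",
                     homodimer = "inter_contacts",
                     heterodimer = "site_contacts")

#' Build a per-variant comparison report
#'
#' For each structural context available in both inputs (`protomer`,
#' `homodimer`, `heterodimer`), computes wild-type-normalized metrics from
#' replicate ensembles (per-frame means per replicate, pooled-variance
#' one-tailed t test across replicate means) and an impact call from the
#' context's headline metric: intra-protomer contacts (protomer),
#' inter-protomer contacts at 7 A (homodimer), and mutation-site contacts
#' at 10 A (heterodimer).
#'
#' @param wt,mut Named lists of contexts, each a list of >= 2 replicate
#'   [StructureEnsemble]s.
#' @param variant A [variant_spec()].
#' @param references Optional `list(wt =, mut =)` of single-model
#'   reference structures; when given, the heterodimer site metric is the
#'   per-model count of retained native contacts (10 Angstrom) relative
#'   to each group's own reference instead of the raw per-model count.
#' @param thresholds Passed to [classify_impact()].
#' @return Object of class `VariantReport`.
#' @export
build_report <- function(wt, mut, variant, references = NULL,
                         thresholds = list(reduced = 0.8, slight = 1.05,
                                           enhanced = 1.2, alpha = 0.05)) {
  contexts <- c("protomer", "homodimer", "heterodimer")
  out <- list(variant = variant, contexts = list(), calls = character(0))
  for (ctx in contexts) {
    if (is.null(wt[[ctx]]) || is.null(mut[[ctx]])) {
      out$contexts[[ctx]] <- list(status = "not assessed")
      out$calls[ctx] <- NA_character_
      next
    }
    mw <- context_metrics(wt[[ctx]], ctx, variant, references$wt)
    mm <- context_metrics(mut[[ctx]], ctx, variant, references$mut)
    metrics <- names(mw[[1]])
    stats <- list()
    for (met in metrics) {
      wrep <- vapply(mw, function(r) mean(r[[met]]), numeric(1))
      mrep <- vapply(mm, function(r) mean(r[[met]]), numeric(1))
      stats[[met]] <- contact_stats(wrep, mrep)
    }
    hl <- stats[[HEADLINE_METRIC[ctx]]]
    out$contexts[[ctx]] <- list(status = "assessed", stats = stats)
    out$calls[ctx] <- classify_impact(hl$normalized, hl$p, thresholds)
  }
  class(out) <- "VariantReport"
  out
}

#' @export
print.VariantReport <- function(x, ...) {
  cat(sprintf("Variant %s (chain %s)\n", x$variant$label, x$variant$chain))
  for (ctx in names(x$contexts)) {
    c_ <- x$contexts[[ctx]]
    if (c_$status != "assessed") {
      cat(sprintf("  %-11s not assessed\n", ctx)); next
    }
    for (met in names(c_$stats)) {
      s <- c_$stats[[met]]
      cat(sprintf("  %-11s %-16s normalized %.3f  p %.4f%s\n", ctx, met,
                  s$normalized, s$p,
                  if (met == HEADLINE_METRIC[ctx])
                    paste0("  -> ", x$calls[ctx]) else ""))
    }
  }
  invisible(x)
}

# ---------------------------------------------------------------------------
# Synthetic six-variant phenotype suite
# ---------------------------------------------------------------------------

#' Phenotype emulation parameters of the six-variant suite
#'
#' Ground-truth generator settings emulating each variant's described
#' structural phenotype on synthetic ensembles: `unfold_from` randomizes a
#' C-terminal window of the PALB2 chain(s); `separation` pushes the dimer
#' chains apart (destabilized interface); `sigma_scale` scales the global
#' fluctuation amplitude; `tail_to` / `cterm_from` set how much of the
#' BRCA1-like chain's terminal regions stays disordered in the
#' heterodimer (ordering of these regions is the contact-gain phenotype).
#'
#' @return Nested list keyed by variant label and context.
#' @export
variant_phenotypes <- function() {
  list(
    K18R = list(heterodimer = list(loose_scale = 1)),
    L24S = list(),
    Y28C = list(protomer = list(unfold_from = 29L),
                homodimer = list(separation = 1.2, sigma_scale = 1.4)),
    T31I = list(),
    R37H = list(heterodimer = list(tail_to = 1392L)),
    L35P = list(protomer = list(unfold_from = 32L),
                homodimer = list(unfold_from = 32L, separation = 1.0),
                heterodimer = list(unfold_from = 33L))
  )
}

WT_HET_TAIL_TO <- 1401L     # BRCA1-like N-terminal disorder in the wt
WT_HET_LOOSE <- 1421:1424   # loosely packed BRCA1-like C-end in the wt
WT_HET_LOOSE_SCALE <- 4.5   # its fluctuation multiplier

suite_windows <- function(context, chains, unfold_from = NA,
                          tail_to = WT_HET_TAIL_TO) {
  w <- list()
  if (!is.na(unfold_from)) {
    for (ch in chains)
      w <- c(w, list(list(chain = ch, from = unfold_from, to = 42L)))
  }
  if (context == "heterodimer")
    w <- c(w, list(list(chain = "B", from = 1378L, to = tail_to)))
  w
}

# generate one context's replicate ensembles for one protein form
suite_ensembles <- function(model, context, n_models, n_replicates, seed,
                            pheno = list()) {
  sigma_base <- if (context == "protomer") 0.45 else 0.30
  sigma_scale <- if (is.null(pheno$sigma_scale)) 1 else pheno$sigma_scale
  res <- residues(model)
  sig <- rep(sigma_base * sigma_scale, nrow(res))
  if (context == "heterodimer") {
    loose_scale <- if (is.null(pheno$loose_scale)) WT_HET_LOOSE_SCALE else
      pheno$loose_scale
    sig[res$chain == "B" & res$resno %in% WT_HET_LOOSE] <-
      sigma_base * sigma_scale * loose_scale
  }
  unfold_from <- if (is.null(pheno$unfold_from)) NA else pheno$unfold_from
  tail_to <- if (is.null(pheno$tail_to)) WT_HET_TAIL_TO else pheno$tail_to
  pal_chains <- if (context == "heterodimer") "A" else
    unique(model$atoms$chain)
  fray <- suite_windows(context, pal_chains, unfold_from, tail_to)
  sep <- if (is.null(pheno$separation)) 0 else pheno$separation
  lapply(seq_len(n_replicates), function(r) {
    md_like_ensemble(model, n_models, seed + 7919L * r, sigma = sig,
                     fray = fray, separation = sep,
                     separate_chain = if (sep > 0) "B" else NULL)
  })
}

# apply a variant to the base models of each context
suite_mutant_models <- function(base, variant) {
  v <- variant
  list(
    protomer = mutate_residue(base$protomer, "A", v$position, v$to_aa),
    homodimer = mutate_residue(mutate_residue(base$homodimer, "A",
                                              v$position, v$to_aa),
                               "B", v$position, v$to_aa),
    heterodimer = mutate_residue(base$heterodimer, "A", v$position, v$to_aa)
  )
}

#' Run the synthetic six-variant phenotype suite
#'
#' Builds the PALB2 homodimer, protomer and PALB2-BRCA1-like heterodimer,
#' emulates each variant's described structural phenotype with the
#' generator settings of [variant_phenotypes()], and produces a
#' [build_report()] per variant.
#'
#' @param seed Integer seed for all generators.
#' @param n_models Models per replicate ensemble (protomer/homodimer).
#' @param n_models_het Models per replicate in the heterodimer context
#'   (larger by default: the site metric is cheap and benefits from
#'   tighter replicate means).
#' @param n_replicates Replicates per group.
#' @param variants Variant labels to run.
#' @return List: `reports` (per variant), `calls` data frame with one row
#'   per variant and one column per context.
#' @export
simulate_variant_suite <- function(seed = 1L, n_models = 8L,
                                   n_models_het = 20L,
                                   n_replicates = 3L,
                                   variants = c("K18R", "L24S", "Y28C",
                                                "T31I", "R37H", "L35P")) {
  homod <- build_palb2_homodimer()
  het <- build_palb2_brca1_heterodimer()
  base <- list(protomer = extract_chains(homod, "A"), homodimer = homod,
               heterodimer = het)
  contexts <- names(base)
  nmod <- c(protomer = n_models, homodimer = n_models,
            heterodimer = n_models_het)
  wt <- lapply(stats::setNames(contexts, contexts), function(ctx)
    suite_ensembles(base[[ctx]], ctx, nmod[[ctx]], n_replicates,
                    seed + 101L * match(ctx, contexts)))
  phen <- variant_phenotypes()
  reports <- list()
  for (v in variants) {
    vs <- variant_spec(v)
    mut_models <- suite_mutant_models(base, vs)
    mut <- lapply(stats::setNames(contexts, contexts), function(ctx)
      suite_ensembles(mut_models[[ctx]], ctx, nmod[[ctx]], n_replicates,
                      seed + 101L * match(ctx, contexts) +
                        13L * match(v, variants),
                      pheno = if (is.null(phen[[v]][[ctx]])) list() else
                        phen[[v]][[ctx]]))
    reports[[v]] <- build_report(wt, mut, vs,
                                 references = list(wt = base$heterodimer,
                                                   mut = mut_models$heterodimer))
  }
  calls <- do.call(rbind, lapply(names(reports), function(v)
    data.frame(variant = v, protomer = reports[[v]]$calls["protomer"],
               homodimer = reports[[v]]$calls["homodimer"],
               heterodimer = reports[[v]]$calls["heterodimer"],
               stringsAsFactors = FALSE)))
  rownames(calls) <- NULL
  list(reports = reports, calls = calls)
}
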