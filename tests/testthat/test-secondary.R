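test_that("Kabsch-Sander energies call helical bonds and reject others", {
  h <- ideal_helix(12)
  e <- backbone_hbond_energy(h, list(chain = "A", resno = 9),
                             list(chain = "A", resno = 5))
  expect_lt(e, -0.5)
  # residues far apart: negligible energy (1/r decay)
  far <- make_ens(rbind(ideal_helix(12)$atoms),
                  model_xyz(h, 1))
  sep <- h
  shift <- which(sep$atoms$resno >= 10)
  sep$xyz[1, shift, 1] <- sep$xyz[1, shift, 1] + 40
  e_far <- backbone_hbond_energy(sep, list(chain = "A", resno = 11),
                                 list(chain = "A", resno = 2))
  expect_lt(abs(e_far), 0.05)
  expect_message(
    e_adj <- backbone_hbond_energy(h, list(chain = "A", resno = 5),
                                   list(chain = "A", resno = 6)),
    "adjacent")
  expect_true(is.na(e_adj))
})

test_that("ideal helices yield the N-4 bond ladder and full interior helicity", {
  for (n in c(20, 30)) {
    h <- ideal_helix(n)
    expect_equal(backbone_hbond_count(h), n - 4)
    ss <- assign_ss(h)
    expect_true(all(ss$ss[5:(n - 5)] == "H"))
  }
  expect_gte(attr(assign_ss(ideal_helix(30)), "helicity"), 0.8)
  ext <- extended_chain(20)
  expect_equal(backbone_hbond_count(ext), 0L)
  expect_equal(attr(assign_ss(ext), "helicity"), 0)
})

test_that("short chains are assigned all-coil", {
  h <- ideal_helix(4)
  expect_true(all(assign_ss(h)$ss == "C"))
})

test_that("assignment matches frozen reference DSSP labels on fixtures", {
  ref <- read.delim(test_path("dssp-reference-labels.tsv"))
  d <- build_palb2_homodimer()
  u <- emulate_unfolding(extract_chains(d, "A"), "A", 20, 4, seed = 11)
  agree <- function(ens, tag, model = 1) {
    ss <- assign_ss(ens, model = model)
    r <- ref[ref$fixture == tag, ]
    m <- merge(ss, r, by = c("chain", "resno"))
    mean((m$ss == "H") == (trimws(m$dssp) == "H"))
  }
  expect_gte(agree(d, "dimer"), 0.9)
  expect_gte(agree(get_model(u, 4), "unfold"), 0.9)
})

test_that("helicity is invariant under rigid motion and symmetric in chains", {
  d <- build_palb2_homodimer()
  h0 <- attr(assign_ss(d), "helicity")
  rot <- ccdimer:::rot_axis(c(1, 2, 3), 71)
  d2 <- d
  d2$xyz[1, , ] <- sweep(d2$xyz[1, , ] %*% t(rot), 2, -c(5, -3, 11))
  expect_equal(attr(assign_ss(d2), "helicity"), h0, tolerance = 1e-9)
  hA <- attr(assign_ss(d, chains = "A"), "helicity")
  hB <- attr(assign_ss(d, chains = "B"), "helicity")
  expect_equal(hA, hB, tolerance = 0.06)
})

test_that("ensemble helicity tracks unfolding and handles tiny selections", {
  ident <- perturb_ensemble(ideal_helix(15), 0, 4, seed = 1)
  eh <- ensemble_helicity(ident)
  expect_true(all(eh$per_model == eh$per_model[1]))
  m <- extract_chains(build_palb2_homodimer(), "A")
  u <- emulate_unfolding(m, "A", 15, 10, seed = 6)
  h <- ensemble_helicity(u, resno = 15:42)$per_model
  expect_lt(suppressWarnings(cor(seq_along(h), h, method = "spearman")), 0)
  one <- ensemble_helicity(u, resno = 20)
  expect_true(all(one$per_model %in% c(0, 1)))
  expect_error(ensemble_helicity(u, resno = 999), "empty")
})
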