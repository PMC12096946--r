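test_that("coiled-coil builder honours rise, orientation and radius", {
  seq28 <- strrep("A", 28)
  p <- crick_params(superhelix_radius = 4.9, orientation = "parallel")
  d <- build_coiled_coil(seq28, seq28, p)
  for (ch in c("A", "B")) {
    ca <- model_xyz(d, 1, select_atoms(d, chains = ch, elety = "CA"))
    dd <- sqrt(rowSums((ca[-1, ] - ca[-nrow(ca), ])^2))
    expect_true(all(dd >= 3.7 & dd <= 3.9))
  }
  anti <- build_coiled_coil(seq28, seq28,
                            crick_params(orientation = "antiparallel"))
  dirv <- function(ens, ch) {
    ca <- model_xyz(ens, 1, select_atoms(ens, chains = ch, elety = "CA"))
    (ca[nrow(ca), ] - ca[1, ]) / sqrt(sum((ca[nrow(ca), ] - ca[1, ])^2))
  }
  expect_lt(sum(dirv(anti, "A") * dirv(anti, "B")), 0)
  expect_gt(sum(dirv(d, "A") * dirv(d, "B")), 0)

  # superhelix radius recovery by an independent least-squares axis oracle:
  # per-turn CA centroids of one chain, distance from the global axis
  for (r0 in c(4.9, 6.0)) {
    dd <- build_coiled_coil(strrep("A", 28), strrep("A", 28),
                            crick_params(superhelix_radius = r0,
                                         orientation = "parallel"))
    ca <- model_xyz(dd, 1, select_atoms(dd, chains = "A", elety = "CA"))
    all_ca <- model_xyz(dd, 1, select_atoms(dd, elety = "CA"))
    pc <- prcomp(all_ca)
    ax <- pc$rotation[, 1]
    cen <- colMeans(all_ca)
    cents <- t(sapply(seq(1, 28 - 6, by = 7), function(k)
      colMeans(ca[k:(k + 6), ])))
    rel <- sweep(cents, 2, cen)
    perp <- rel - (rel %*% ax) %*% t(ax)
    expect_lt(max(abs(sqrt(rowSums(perp^2)) - r0)), 0.3)
  }
})

test_that("gaussian perturbation is seeded, exact at sigma zero, and
          recovers sigma*sqrt(3) as RMSF", {
  m <- get_model(build_palb2_homodimer(), 1)
  z <- perturb_ensemble(m, 0, 3, seed = 1)
  expect_equal(z$xyz[1, , ], z$xyz[3, , ])
  expect_equal(z$xyz[1, , ], m$xyz[1, , ])
  a <- perturb_ensemble(m, 0.5, 4, seed = 9)
  b <- perturb_ensemble(m, 0.5, 4, seed = 9)
  expect_identical(a$xyz, b$xyz)
  expect_false(identical(a$xyz, perturb_ensemble(m, 0.5, 4, seed = 10)$xyz))
  # parameter recovery: many models over the full dimer (a small fit
  # selection would lose a visible share of variance to the 6 rigid DOF)
  pe <- perturb_ensemble(m, 0.5, 1500, seed = 3)
  r <- rmsf(pe)
  expect_true(all(abs(r$rmsf - 0.5 * sqrt(3)) / (0.5 * sqrt(3)) < 0.05))
})

test_that("sigma vector must match the residue count", {
  m <- get_model(build_palb2_homodimer(), 1)
  expect_error(perturb_ensemble(m, rep(0.1, 3), 2, seed = 1),
               "per residue")
})

test_that("point mutation keeps the backbone and changes only the side chain", {
  d <- build_palb2_homodimer()
  bb <- select_atoms(d, chains = "A", resno = 24,
                     elety = c("N", "CA", "C", "O"))
  same <- mutate_residue(d, "A", 24, "L")
  bb2 <- select_atoms(same, chains = "A", resno = 24,
                      elety = c("N", "CA", "C", "O"))
  expect_equal(model_xyz(same, 1, bb2), model_xyz(d, 1, bb))
  expect_equal(unique(same$atoms$resid[same$atoms$chain == "A" &
                                         same$atoms$resno == 24]), "LEU")
  pro <- mutate_residue(d, "A", 35, "P")
  expect_setequal(pro$atoms$elety[pro$atoms$chain == "A" &
                                    pro$atoms$resno == 35],
                  c("N", "CA", "C", "O", "CB", "CG", "CD"))
  cys <- mutate_residue(d, "A", 28, "C")
  expect_equal(sum(cys$atoms$chain == "A" & cys$atoms$resno == 28), 6L)
  expect_equal(sum(d$atoms$chain == "A" & d$atoms$resno == 28), 12L)
  expect_error(mutate_residue(d, "A", 24, "X"), "unknown")
  expect_error(mutate_residue(d, "A", 999, "A"), "not found")
})

test_that("progressive unfolding grows a randomized window", {
  m <- extract_chains(build_palb2_homodimer(), "A")
  beyond <- emulate_unfolding(m, "A", 99, 3, seed = 2)
  expect_equal(beyond$xyz[2, , ], m$xyz[1, , ])
  u <- emulate_unfolding(m, "A", 20, 8, seed = 4)
  h_first <- ensemble_helicity(get_model(u, 1), resno = 20:42)$mean
  h_last <- ensemble_helicity(get_model(u, 8), resno = 20:42)$mean
  expect_lt(h_last, h_first)
  # full-chain randomization: last quarter of models below 20% helix
  u2 <- emulate_unfolding(m, "A", 8, 8, seed = 5)
  for (k in 7:8)
    expect_lt(ensemble_helicity(get_model(u2, k), resno = 8:42)$mean, 0.2)
})

test_that("PALB2 homodimer has a leucine-zipper interface and round-trips", {
  d <- build_palb2_homodimer()
  ga <- select_atoms(d, chains = "A", heavy_only = TRUE)
  gb <- select_atoms(d, chains = "B", heavy_only = TRUE)
  rec <- atom_contacts(d, ga, gb, 7)
  ad <- c(14, 17, 21, 24, 28, 31, 35, 38, 42)
  in_contact <- vapply(ad, function(rn)
    any(rec$resno_a == rn | rec$resno_b == rn), logical(1))
  expect_gte(mean(in_contact), 0.8)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(d, f)
  back <- read_structure(f)
  expect_identical(back$atoms$resid, d$atoms$resid)
  expect_lt(max(abs(back$xyz - d$xyz)), 1e-3 + 1e-9)
})

test_that("study sequences carry the expected composition", {
  pa <- palb2cc_sequence()
  expect_equal(nchar(pa), 37L)
  expect_equal(attr(pa, "start"), 6L)
  s <- strsplit(pa, "")[[1]]
  rn <- seq(6, 42)
  expect_equal(s[rn %in% c(9, 17, 21, 24, 35)], rep("L", 5))
  expect_equal(s[rn == 28], "Y")
  expect_equal(s[rn == 31], "T")
  expect_equal(sum(s %in% c("K", "R")) - sum(s %in% c("D", "E")), 5L)
  br <- brca1cc_synthetic_sequence()
  b <- strsplit(br, "")[[1]]
  bn <- seq(1378, 1424)
  expect_equal(b[bn %in% c(1392, 1404, 1407, 1414, 1418)], rep("L", 5))
  expect_equal(b[bn %in% c(1400, 1411)], rep("M", 2))
  expect_equal(b[bn %in% c(1381, 1390, 1419)], rep("D", 3))
  expect_equal(sum(b %in% c("K", "R")), 4L)
  expect_equal(sum(b %in% c("D", "E")), 7L)
})
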