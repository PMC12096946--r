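test_that("contact enumeration respects the cutoff boundary", {
  at <- rbind(atom_row("CA", "ALA", "A", 1), atom_row("CA", "ALA", "B", 1))
  near <- make_ens(at, rbind(c(0, 0, 0), c(6.9, 0, 0)))
  farr <- make_ens(at, rbind(c(0, 0, 0), c(7.1, 0, 0)))
  ga <- 1L; gb <- 2L
  expect_equal(nrow(atom_contacts(near, ga, gb, 7)), 1L)
  expect_equal(nrow(atom_contacts(farr, ga, gb, 7)), 0L)
})

test_that("cell-list search equals the brute-force scan on random dimers", {
  for (seed in 1:10) {
    d <- random_cc_dimer(seed)
    ga <- select_atoms(d, chains = "A", heavy_only = TRUE)
    gb <- select_atoms(d, chains = "B", heavy_only = TRUE)
    for (cutoff in c(4.5, 7, 10)) {
      cell <- atom_contacts(d, ga, gb, cutoff, method = "cell")
      brute <- atom_contacts(d, ga, gb, cutoff, method = "brute")
      expect_equal(nrow(cell), nrow(brute))
      expect_equal(nrow(cell), nrow(brute_pairs(d, ga, gb, cutoff)))
    }
  }
})

test_that("counts are symmetric, rigid-motion invariant and cutoff-monotone", {
  d <- random_cc_dimer(99)
  ga <- select_atoms(d, chains = "A", heavy_only = TRUE)
  gb <- select_atoms(d, chains = "B", heavy_only = TRUE)
  expect_equal(nrow(atom_contacts(d, ga, gb, 7)),
               nrow(atom_contacts(d, gb, ga, 7)))
  rot <- ccdimer:::rot_axis(c(1, 1, 0), 33)
  d2 <- d
  d2$xyz[1, , ] <- sweep(d2$xyz[1, , ] %*% t(rot), 2, -c(2, 9, -4))
  expect_equal(nrow(atom_contacts(d2, ga, gb, 7)),
               nrow(atom_contacts(d, ga, gb, 7)))
  counts <- vapply(c(4, 5.5, 7, 8.5, 10), function(ct)
    nrow(atom_contacts(d, ga, gb, ct)), numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("intra-protomer mode excludes self and sequence-adjacent pairs", {
  d <- build_palb2_homodimer()
  g <- select_atoms(d, chains = "A", heavy_only = TRUE)
  rec <- atom_contacts(d, g, g, 7)
  expect_true(all(abs(rec$resno_a - rec$resno_b) >= 2))
  expect_error(atom_contacts(d, g, c(g[1], select_atoms(d, chains = "B")),
                             7), "overlapping")
})

test_that("residue-pair interface counts behave and include the central
          leucine layer", {
  d <- build_palb2_homodimer()
  rec <- atom_contacts(d, select_atoms(d, chains = "A", heavy_only = TRUE),
                       select_atoms(d, chains = "B", heavy_only = TRUE), 7)
  expect_true(any(rec$resno_a == 24 & rec$resno_b == 24))
  n <- residue_contact_count(d, "A", "B", 7)
  expect_equal(n, length(unique(paste(rec$resno_a, rec$resno_b))))
  far <- d
  bidx <- which(far$atoms$chain == "B")
  far$xyz[1, bidx, 1] <- far$xyz[1, bidx, 1] + 100
  expect_equal(residue_contact_count(far, "A", "B", 7), 0L)
  expect_error(residue_contact_count(d, "A", "A"), "distinct")
})

test_that("contacts are classified by chemistry with the documented rules", {
  at <- rbind(atom_row("NZ", "LYS", "A", 20, element = "N"),
              atom_row("OE1", "GLU", "B", 27, element = "O"),
              atom_row("CD1", "LEU", "A", 24, element = "C"),
              atom_row("CD2", "LEU", "B", 24, element = "C"),
              atom_row("CB", "SER", "A", 40, element = "C"),
              atom_row("CB", "ALA", "B", 40, element = "C"))
  xyz <- rbind(c(0, 0, 0), c(3.2, 0, 0),
               c(0, 10, 0), c(4.0, 10, 0),
               c(0, 20, 0), c(4.0, 20, 0))
  e <- make_ens(at, xyz)
  ga <- which(at$chain == "A"); gb <- which(at$chain == "B")
  rec <- classify_contacts(atom_contacts(e, ga, gb, 7), e)
  get_type <- function(a_name) rec$type[rec$elety_a == a_name |
                                          rec$elety_b == a_name][1]
  expect_equal(get_type("NZ"), "salt_bridge")
  expect_equal(get_type("CD1"), "hydrophobic")
  expect_equal(get_type("CB"), "van_der_waals")  # Ser CB is not apolar
  # backbone O...N pair at helical geometry is a hydrogen bond
  h <- ideal_helix(12)
  iN <- ccdimer:::atom_index(h, "A", 9, "N")
  iO <- ccdimer:::atom_index(h, "A", 5, "O")
  hb <- classify_contacts(atom_contacts(h, iN, iO, 3.5), h)
  expect_equal(hb$type, "hydrogen_bond")
})

test_that("native-contact retention is 1 for the reference and decays as
          designed", {
  d <- build_palb2_homodimer()
  ga <- select_atoms(d, chains = "A", resno = 24, heavy_only = TRUE)
  gb <- select_atoms(d, chains = "B", heavy_only = TRUE)
  self <- native_contact_fraction(perturb_ensemble(get_model(d, 1), 0, 2,
                                                   seed = 1),
                                  d, ga, cutoff = 10,
                                  partner_selection = gb)
  expect_equal(self$mean, 1.0)
  moved <- get_model(d, 1)
  bidx <- which(moved$atoms$chain == "B")
  moved$xyz[1, bidx, 1] <- moved$xyz[1, bidx, 1] + 50
  gone <- native_contact_fraction(perturb_ensemble(moved, 0, 2, seed = 1),
                                  d, ga, cutoff = 10,
                                  partner_selection = gb)
  expect_equal(gone$mean, 0.0)
  pe <- perturb_ensemble(get_model(d, 1), 0.3, 30, seed = 8)
  soft <- native_contact_fraction(pe, d, ga, cutoff = 10,
                                  partner_selection = gb)
  expect_gte(soft$mean, 0.9)
  expect_error(native_contact_fraction(gone <- perturb_ensemble(moved, 0, 2,
                                                                seed = 1),
                                       moved, ga, cutoff = 2,
                                       partner_selection = gb),
               "empty native")
})

test_that("salt-bridge occupancy counts bridged models", {
  at <- rbind(atom_row("NZ", "LYS", "A", 1, element = "N"),
              atom_row("OD1", "ASP", "B", 2, element = "O"))
  coords <- lapply(1:10, function(m)
    rbind(c(0, 0, 0), c(if (m <= 7) 3.5 else 6.0, 0, 0)))
  e <- make_ens(at, coords)
  expect_equal(salt_bridge_occupancy(e, list(chain = "A", resno = 1),
                                     list(chain = "B", resno = 2)), 0.7)
  never <- make_ens(at, lapply(1:5, function(m) rbind(c(0, 0, 0),
                                                      c(8, 0, 0))))
  expect_equal(salt_bridge_occupancy(never, list(chain = "A", resno = 1),
                                     list(chain = "B", resno = 2)), 0)
  at2 <- rbind(atom_row("CB", "ALA", "A", 1, element = "C"),
               atom_row("OD1", "ASP", "B", 2, element = "O"))
  e2 <- make_ens(at2, rbind(c(0, 0, 0), c(3, 0, 0)))
  expect_error(salt_bridge_occupancy(e2, list(chain = "A", resno = 1),
                                     list(chain = "B", resno = 2)),
               "ionizable")
})

test_that("replicate statistics match the pooled-variance t closed form", {
  s <- contact_stats(c(10, 10, 10), c(10, 10, 10))
  expect_equal(s$t, 0)
  expect_equal(s$p, 0.5)
  expect_equal(s$normalized, 1.0)
  sep <- contact_stats(c(10, 10, 10), c(5, 5, 5))
  expect_equal(sep$normalized, 0.5)
  expect_equal(sep$p, 0)
  wt <- c(100, 98, 102); mut <- c(80, 84, 82)
  s2 <- contact_stats(wt, mut)
  sp2 <- (2 * var(wt) + 2 * var(mut)) / 4
  t_hand <- (mean(mut) - mean(wt)) / sqrt(sp2 * (2 / 3))
  expect_equal(s2$t, t_hand, tolerance = 1e-9)
  expect_equal(s2$p, pt(abs(t_hand), 4, lower.tail = FALSE),
               tolerance = 1e-9)
  tt <- t.test(mut, wt, var.equal = TRUE, alternative = "less")
  expect_equal(s2$p, tt$p.value, tolerance = 1e-9)
  expect_error(contact_stats(c(0, 0), c(1, 2)), "normalization")
})
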