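test_that("helix axes fit straight helices tightly and orient N to C", {
  h <- ideal_helix(20)
  ax <- fit_helix_axis(h, "A", c(1, 20))
  expect_lt(ax$fit_rmsd, 0.3)
  ca <- model_xyz(h, 1, select_atoms(h, chains = "A", elety = "CA"))
  constr <- (ca[20, ] - ca[1, ]); constr <- constr / sqrt(sum(constr^2))
  expect_gt(abs(sum(ax$direction * constr)), 0.99)
  expect_error(fit_helix_axis(h, "A", c(1, 5)), "at least 7")
  # invariance under rigid motion (up to the same rotation)
  rot <- ccdimer:::rot_axis(c(0, 1, 1), 54)
  h2 <- h
  h2$xyz[1, , ] <- sweep(h2$xyz[1, , ] %*% t(rot), 2, -c(1, 2, 3))
  ax2 <- fit_helix_axis(h2, "A", c(1, 20))
  expect_equal(as.vector(rot %*% ax$direction), ax2$direction,
               tolerance = 1e-6)
  expect_equal(ax$fit_rmsd, ax2$fit_rmsd, tolerance = 1e-9)
})

test_that("crossing angles distinguish parallel from antiparallel", {
  h <- ideal_helix(20)
  ax <- fit_helix_axis(h, "A", c(1, 20))
  same <- crossing_angle(ax, ax)
  expect_equal(same$angle, 0, tolerance = 1e-9)
  expect_equal(same$orientation, "parallel")
  rev_ax <- ax; rev_ax$direction <- -ax$direction
  opp <- crossing_angle(ax, rev_ax)
  expect_equal(opp$angle, 180, tolerance = 1e-9)
  expect_equal(opp$orientation, "antiparallel")
  d <- build_palb2_homodimer()
  axA <- fit_helix_axis(d, "A", c(11, 39))
  axB <- fit_helix_axis(d, "B", c(11, 39))
  cr <- crossing_angle(axA, axB)
  expect_equal(cr$orientation, "antiparallel")
  revB <- axB; revB$direction <- -axB$direction
  expect_equal(cr$angle + crossing_angle(axA, revB)$angle, 180,
               tolerance = 1e-9)
  # packing angle close to the supercoil construction value 2*atan(2*pi*R/P)
  p <- ccdimer:::crick_params(superhelix_radius = 5.5)
  expected <- 2 * atan(2 * pi * p$superhelix_radius /
                         p$superhelix_pitch) * 180 / pi
  expect_lt(abs(cr$packing_angle - expected), 5)
})

test_that("ring geometry classifies parallel, edge-to-face and distant pairs", {
  u <- c(1, 0, 0); v <- c(0, 1, 0); w <- c(0, 0, 1)
  r1 <- ring_atoms("A", 1, c(0, 0, 0), u, v)
  stack <- ring_atoms("B", 2, c(0, 0, 3.5), u, v)
  tshape <- ring_atoms("B", 2, c(0, 0, 5), u, w)
  far <- ring_atoms("B", 2, c(0, 0, 20), u, v)
  mk <- function(r2) make_ens(rbind(r1$atoms, r2$atoms),
                              rbind(r1$xyz, r2$xyz))
  g1 <- ring_geometry(mk(stack), list(chain = "A", resno = 1),
                      list(chain = "B", resno = 2))
  expect_lt(g1$interplanar_angle, 5)
  expect_equal(g1$class, "parallel")
  g2 <- ring_geometry(mk(tshape), list(chain = "A", resno = 1),
                      list(chain = "B", resno = 2))
  expect_gt(g2$interplanar_angle, 85)
  expect_equal(g2$class, "edge_to_face")
  g3 <- ring_geometry(mk(far), list(chain = "A", resno = 1),
                      list(chain = "B", resno = 2))
  expect_equal(g3$class, "none")
  expect_true(g1$interplanar_angle >= 0 && g1$interplanar_angle <= 90)
  expect_error(ring_geometry(mk(stack), list(chain = "A", resno = 1),
                             list(chain = "Q", resno = 9)), "geometry error")
})

test_that("ring class fractions follow the constructed mixture and are
          rotation invariant", {
  u <- c(1, 0, 0); v <- c(0, 1, 0); w <- c(0, 0, 1)
  r1 <- ring_atoms("A", 1, c(0, 0, 0), u, v)
  coords <- lapply(1:10, function(m) {
    r2 <- if (m <= 7) ring_atoms("B", 2, c(0, 0, 3.5), u, v)
          else ring_atoms("B", 2, c(0, 0, 5), u, w)
    rbind(r1$xyz, r2$xyz)
  })
  e <- make_ens(rbind(r1$atoms, ring_atoms("B", 2, c(0, 0, 1), u, v)$atoms),
                coords)
  s <- ring_class_series(e, list(chain = "A", resno = 1),
                         list(chain = "B", resno = 2))
  expect_equal(unname(s$fractions["parallel"]), 0.7)
  expect_equal(unname(s$fractions["edge_to_face"]), 0.3)
  rot <- ccdimer:::rot_axis(c(2, -1, 5), 123)
  e2 <- e
  for (m in 1:10) e2$xyz[m, , ] <- sweep(e2$xyz[m, , ] %*% t(rot), 2,
                                         -c(4, 4, -9))
  s2 <- ring_class_series(e2, list(chain = "A", resno = 1),
                          list(chain = "B", resno = 2))
  expect_equal(s$fractions, s2$fractions)
})

test_that("met-aromatic and CH-pi detection uses distance and normal gates", {
  u <- c(1, 0, 0); v <- c(0, 1, 0)
  r1 <- ring_atoms("A", 10, c(0, 0, 0), u, v)
  sd_near <- atom_row("SD", "MET", "B", 5, element = "S")
  ld <- atom_row("CD1", "LEU", "B", 7, element = "C")
  at <- rbind(r1$atoms, sd_near, ld)
  e_near <- make_ens(at, rbind(r1$xyz, c(0, 0, 5), c(0, 0, -3.5)))
  hits <- met_aromatic_and_chpi(e_near)
  expect_true(any(hits$type == "met_aromatic" & hits$partner_atom == "SD"))
  expect_true(any(hits$type == "ch_pi" & hits$partner_atom == "CD1"))
  e_far <- make_ens(at, rbind(r1$xyz, c(0, 0, 10), c(10, 0, 0)))
  expect_equal(nrow(met_aromatic_and_chpi(e_far)), 0L)
  # carbon at 4 A but 90 degrees off the normal is not CH-pi
  e_side <- make_ens(at, rbind(r1$xyz, c(0, 0, 10), c(4, 0, 0)))
  expect_false(any(met_aromatic_and_chpi(e_side)$type == "ch_pi"))
})
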