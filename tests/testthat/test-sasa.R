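test_that("isolated and well-separated atoms reproduce analytic areas", {
  at <- rbind(atom_row("C1", "LIG", "A", 1, element = "C"),
              atom_row("C2", "LIG", "A", 3, element = "C"))
  e <- make_ens(at, rbind(c(0, 0, 0), c(50, 0, 0)))
  s <- sasa(e)
  sphere <- 4 * pi * (1.7 + 1.4)^2
  expect_lt(abs(s$per_atom[1] - sphere) / sphere, 0.01)
  expect_lt(abs(s$total - 2 * sphere) / (2 * sphere), 0.01)
  e_unknown <- make_ens(atom_row("XX", "LIG", "A", 1, element = "ZZ"),
                        matrix(0, 1, 3))
  expect_error(sasa(e_unknown), "ZZ")
})

test_that("two overlapping spheres match the spherical-cap closed form", {
  at <- rbind(atom_row("C1", "LIG", "A", 1, element = "C"),
              atom_row("C2", "LIG", "A", 3, element = "C"))
  R <- 1.7 + 1.4
  for (d in c(2.0, 3.0, 4.0, 5.5)) {
    e <- make_ens(at, rbind(c(0, 0, 0), c(d, 0, 0)))
    s <- sasa(e)
    h <- R - d / 2                       # equal radii: symmetric caps
    analytic <- 4 * pi * R^2 - 2 * pi * R * h
    expect_lt(abs(s$per_atom[1] - analytic) / analytic, 0.02)
    expect_lt(abs(s$per_atom[2] - analytic) / analytic, 0.02)
  }
})

test_that("buried surface area is zero when apart, grows on approach, and
          is symmetric", {
  d <- build_palb2_homodimer()
  bidx <- which(d$atoms$chain == "B")
  aidx <- which(d$atoms$chain == "A")
  away <- colMeans(model_xyz(d, 1, bidx)) - colMeans(model_xyz(d, 1, aidx))
  away <- away / sqrt(sum(away^2))
  shift_b <- function(extra) {
    e <- d
    e$xyz[1, bidx, ] <- sweep(e$xyz[1, bidx, , drop = TRUE], 2,
                              -extra * away)
    e
  }
  expect_lt(abs(buried_surface_area(shift_b(100), "A", "B",
                                    n_points = 240)), 1)
  series <- vapply(c(20, 10, 5, 0), function(extra)
    buried_surface_area(shift_b(extra), "A", "B", n_points = 240),
    numeric(1))
  expect_true(all(diff(series) >= -1e-6))
  expect_gt(series[4], series[1] + 100)
  expect_true(all(series >= -1e-6))
  b1 <- buried_surface_area(d, "A", "B", n_points = 240)
  b2 <- buried_surface_area(d, "B", "A", n_points = 240)
  expect_equal(b1, b2, tolerance = 1e-9)
  expect_error(buried_surface_area(d, "A", "Q"), "missing chain")
})

test_that("SASA is stable under rigid motion and point-count refinement", {
  d <- extract_chains(build_palb2_homodimer(), "A")
  s1 <- sasa(d, n_points = 480)$total
  rot <- ccdimer:::rot_axis(c(3, 1, -2), 67)
  d2 <- d
  d2$xyz[1, , ] <- sweep(d2$xyz[1, , ] %*% t(rot), 2, -c(7, -2, 1))
  expect_lt(abs(sasa(d2, n_points = 480)$total - s1) / s1, 0.005)
  s2 <- sasa(d, n_points = 960)$total
  expect_lt(abs(s2 - s1) / s1, 0.01)
})

test_that("charge profiles sum to the formal net charge", {
  polyA <- build_coiled_coil(strrep("A", 14), strrep("A", 14),
                             crick_params(orientation = "parallel"))
  cpA <- charge_profile(polyA, "A")
  expect_equal(cpA$net_charge, 0L)
  expect_true(all(cpA$bins$charge == 0L))
  d <- build_palb2_homodimer()
  cp <- charge_profile(d, "A")
  s <- strsplit(palb2cc_sequence(), "")[[1]]
  expected <- sum(s %in% c("K", "R")) - sum(s %in% c("D", "E"))
  expect_equal(cp$net_charge, as.integer(expected))
  expect_gt(cp$net_charge, 0)
  expect_equal(sum(cp$bins$charge), cp$net_charge)
  # C-terminal half carries the positive excess
  ax <- fit_helix_axis(d, "A", c(11, 39))
  mid <- median(cp$bins$mid)
  ca <- model_xyz(d, 1, select_atoms(d, chains = "A", elety = "CA"))
  proj <- as.vector(sweep(ca, 2, ax$anchor) %*% ax$direction)
  cterm_high <- proj[length(proj)] > proj[1]
  upper <- sum(cp$bins$charge[cp$bins$mid > mid])
  lower <- sum(cp$bins$charge[cp$bins$mid <= mid])
  cpos <- if (cterm_high) upper else lower
  npos <- if (cterm_high) lower else upper
  expect_gt(cpos, npos)
})
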