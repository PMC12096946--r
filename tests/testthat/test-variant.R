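test_that("variant labels parse into specs", {
  v <- variant_spec("L35P")
  expect_equal(v$position, 35L)
  expect_equal(v$from_aa, "LEU")
  expect_equal(v$to_aa, "PRO")
  expect_error(variant_spec("L35"), "parse")
})

test_that("site contacts count interface neighbourhoods correctly", {
  d <- build_palb2_homodimer()
  buried <- site_contacts(d, "A", 24, "B", cutoff = 10)
  expect_gt(buried$mean, 0)
  # a solvent-facing residue has no tight cross-chain packing
  solvent <- site_contacts(d, "A", 13, "B", cutoff = 4.5)
  expect_equal(solvent$mean, 0)
  # equals a brute-force restricted scan
  ga <- select_atoms(d, chains = "A", resno = 24, heavy_only = TRUE)
  gb <- select_atoms(d, chains = "B", heavy_only = TRUE)
  expect_equal(buried$per_model[1], nrow(brute_pairs(d, ga, gb, 10)))
  # removing the interface side chain strictly decreases the site count
  ala <- mutate_residue(d, "A", 24, "A")
  expect_lt(site_contacts(ala, "A", 24, "B", cutoff = 10)$mean,
            buried$mean)
  expect_error(site_contacts(d, "A", 999, "B"), "not found")
})

test_that("impact calls follow the threshold bands", {
  expect_equal(classify_impact(1.0, 0.5), "no_effect")
  expect_equal(classify_impact(0.5, 0.001), "reduced")
  expect_equal(classify_impact(1.1, 0.01), "slightly_enhanced")
  expect_equal(classify_impact(1.5, 0.01), "enhanced")
  expect_equal(classify_impact(0.5, 0.2), "no_effect")   # not significant
  expect_equal(classify_impact(0.95, 0.001), "no_effect")
})

test_that("wild-type against itself is a null report", {
  d <- build_palb2_homodimer()
  mono <- extract_chains(d, "A")
  mk <- function(model, seeds) lapply(seeds, function(s)
    md_like_ensemble(model, 5, s, sigma = 0.3))
  wt <- list(protomer = mk(mono, c(1, 2, 3)),
             homodimer = mk(d, c(4, 5, 6)))
  mut <- list(protomer = mk(mono, c(7, 8, 9)),
              homodimer = mk(d, c(10, 11, 12)))
  rep_ <- build_report(wt, mut, variant_spec("L24L"))
  for (ctx in c("protomer", "homodimer")) {
    hl <- rep_$contexts[[ctx]]$stats[[ccdimer:::HEADLINE_METRIC[ctx]]]
    expect_equal(hl$normalized, 1.0, tolerance = 0.05)
    expect_equal(unname(rep_$calls[ctx]), "no_effect")
  }
  expect_equal(rep_$contexts$heterodimer$status, "not assessed")
})

test_that("swapping groups inverts the normalized metric", {
  d <- build_palb2_homodimer()
  mk <- function(seeds) lapply(seeds, function(s)
    md_like_ensemble(d, 5, s, sigma = 0.3))
  mk_sep <- function(seeds) lapply(seeds, function(s)
    md_like_ensemble(d, 5, s, sigma = 0.3, separation = 1.5,
                     separate_chain = "B"))
  a <- mk(c(1, 2, 3)); b <- mk_sep(c(4, 5, 6))
  r1 <- build_report(list(homodimer = a), list(homodimer = b),
                     variant_spec("Y28C"))
  r2 <- build_report(list(homodimer = b), list(homodimer = a),
                     variant_spec("Y28C"))
  n1 <- r1$contexts$homodimer$stats$inter_contacts$normalized
  n2 <- r2$contexts$homodimer$stats$inter_contacts$normalized
  expect_equal(n1 * n2, 1, tolerance = 1e-9)
})

test_that("an unfolding mutant phenotype is called reduced", {
  d <- build_palb2_homodimer()
  mono <- extract_chains(d, "A")
  wt <- list(protomer = lapply(1:3, function(s)
    md_like_ensemble(mono, 5, s, sigma = 0.45)))
  mut_model <- mutate_residue(mono, "A", 35, "P")
  mut <- list(protomer = lapply(4:6, function(s)
    md_like_ensemble(mut_model, 5, s, sigma = 0.45,
                     fray = list(list(chain = "A", from = 32L, to = 42L)))))
  rep_ <- build_report(wt, mut, variant_spec("L35P"))
  expect_equal(unname(rep_$calls["protomer"]), "reduced")
})
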