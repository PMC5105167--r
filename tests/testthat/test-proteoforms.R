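test_that("site abundances normalize to fractions summing to one", {
  s <- site_table("N1", list(mod_isoform("a", abundance = 2),
                             mod_isoform("b", "Hex1", abundance = 2)))
  expect_equal(normalize_site(s), c(0.5, 0.5))
  s1 <- site_table("N2", list(mod_isoform("only", abundance = 1)))
  expect_equal(normalize_site(s1), 1)
  s2 <- site_table("N3", list(
    mod_isoform("a", abundance = 3), mod_isoform("b", "Hex1", abundance = 1),
    mod_isoform("c", "Hex2", abundance = 1),
    mod_isoform("d", "Hex3", abundance = 5)))
  expect_equal(normalize_site(s2), c(0.3, 0.1, 0.1, 0.5))
  expect_equal(sum(normalize_site(s2)), 1, tolerance = 1e-12)
  # a site with no signal at all is rejected at construction
  expect_error(site_table("N4", list(mod_isoform("a", abundance = 0))),
               "positive abundance")
})

test_that("backbone masses follow the average residue table", {
  expect_equal(backbone_mass_from_sequence("G"), 75.067, tolerance = 1e-3)
  seq <- "ACDEFGHIKLMNPQRSTVWY"
  expect_equal(backbone_mass_from_sequence(seq, 1),
               backbone_mass_from_sequence(seq, 0) - 2.0159,
               tolerance = 1e-4)
  expect_equal(backbone_mass_from_sequence(rhepo_sequence(), 2),
               18235.99, tolerance = 0.5)
  expect_error(backbone_mass_from_sequence("ACDX"), "position 4")
})

test_that("proteoform enumeration implements the independence model", {
  two_iso <- function(id) site_table(id, list(
    mod_isoform("u", abundance = 1),
    mod_isoform("m", delta_da = 100, abundance = 1)))
  pm <- protein_model("p", 1000, list(two_iso("S1"), two_iso("S2")))
  pf <- enumerate_proteoforms(pm)
  expect_equal(sort(pf$total_mass), c(1000, 1100, 1100, 1200))
  expect_equal(pf$probability, rep(0.25, 4))

  pm1 <- protein_model("p1", 10000, list(site_table("S1", list(
    mod_isoform("u", abundance = 3),
    mod_isoform("hex", "Hex1", abundance = 7)))))
  pf1 <- enumerate_proteoforms(pm1)
  expect_equal(pf1$total_mass, c(10000, 10000 + 162.1424))
  expect_equal(pf1$probability, c(0.3, 0.7))

  # 3 sites x 3 isoforms against the independent nested-loop oracle
  pm3 <- random_model(11, n_sites = 3, max_iso = 3)
  pf3 <- enumerate_proteoforms(pm3)
  oracle <- brute_force_proteoforms(pm3)
  o1 <- pf3[order(pf3$total_mass, pf3$probability), ]
  o2 <- oracle[order(oracle$total_mass, oracle$probability), ]
  expect_equal(o1$total_mass, o2$total_mass, tolerance = 1e-12)
  expect_equal(o1$probability, o2$probability, tolerance = 1e-12)

  expect_error(enumerate_proteoforms(pm, max_combinations = 3),
               "site_convolution")
})

test_that("probabilities conserve and the mean mass is linear in sites", {
  for (seed in 1:10) {
    pm <- random_model(seed, n_sites = sample(1:4, 1), max_iso = 4)
    pf <- enumerate_proteoforms(pm)
    expect_equal(sum(pf$probability), 1, tolerance = 1e-9)
    expected_mean <- pm$backbone_mass +
      sum(vapply(pm$sites, function(s) {
        p <- normalize_site(s)
        m <- vapply(s$isoforms,
                    function(i) composition_mass(i$composition), numeric(1))
        sum(p * m)
      }, numeric(1)))
    expect_equal(sum(pf$probability * pf$total_mass), expected_mean,
                 tolerance = 1e-6)
  }
})

test_that("merging collapses positional isomers and conserves abundance", {
  pf <- data.frame(total_mass = c(5000, 5000), probability = c(0.25, 0.25))
  zc <- build_zero_charge_spectrum(pf)
  expect_equal(nrow(zc), 1L)
  expect_equal(zc$abundance, 0.5)

  pf2 <- data.frame(total_mass = c(100.000, 100.005),
                    probability = c(0.4, 0.6))
  zc2 <- build_zero_charge_spectrum(pf2, merge_tol = 0.01)
  expect_equal(nrow(zc2), 1L)
  expect_equal(zc2$mass, (100.000 * 0.4 + 100.005 * 0.6))

  set.seed(3)
  pf3 <- data.frame(total_mass = round(stats::runif(50, 1000, 1010), 1),
                    probability = stats::runif(50))
  zc3 <- build_zero_charge_spectrum(pf3, merge_tol = 0)
  expect_equal(nrow(zc3), length(unique(pf3$total_mass)))
  expect_equal(sum(zc3$abundance), sum(pf3$probability), tolerance = 1e-12)
})

test_that("site convolution equals brute-force enumeration", {
  # single site: the site's distribution shifted by the backbone
  pm1 <- random_model(5, n_sites = 1, max_iso = 4)
  zc <- site_convolution(pm1, merge_tol = 1e-6, prune_threshold = 0)
  d <- brute_force_proteoforms(pm1)
  expect_equal(sort(zc$mass), sort(d$total_mass), tolerance = 1e-9)

  for (seed in 1:8) {
    n <- sample(2:6, 1)
    pm <- random_model(seed + 100, n_sites = n, max_iso = 4)
    conv <- site_convolution(pm, merge_tol = 1e-6, prune_threshold = 0)
    bf <- brute_force_proteoforms(pm)
    ref <- oracle_merge(bf$total_mass, bf$probability, 1e-6)
    expect_equal(nrow(conv), nrow(ref))
    expect_lt(max(abs(conv$mass - ref$mass)), 1e-9)
    expect_lt(max(abs(conv$abundance - ref$abundance)), 1e-9)
  }
})

test_that("convolution stays bounded on a properdin-scale binary model", {
  cman <- function(id, occ) site_table(id, list(
    mod_isoform("u", abundance = 1 - occ),
    mod_isoform("man", "Hex1", abundance = occ)))
  set.seed(9)
  sites <- lapply(1:22, function(i) cman(paste0("W", i),
                                         stats::runif(1, 0.2, 0.95)))
  pm <- protein_model("binary22", 48000, sites)
  zc <- site_convolution(pm, merge_tol = 0.01, prune_threshold = 0)
  expect_lte(nrow(zc), 5000)
  expect_equal(sum(zc$abundance), 1, tolerance = 1e-9)
  expect_equal(attr(zc, "retained_probability"), 1, tolerance = 1e-9)
  # enumeration refuses a 4M-combination model
  expect_error(enumerate_proteoforms(pm), "site_convolution")
})
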