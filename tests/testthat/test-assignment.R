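test_that("the modal rhEPO masses are assigned their glycan compositions", {
  a <- assign_composition(29888.12, 18235.99, tolerance_ppm = 35,
                          bounds = rhepo_bounds())
  expect_gte(nrow(a), 1)
  expect_equal(a$composition[1], "Hex22HexNAc19Fuc3Sia13")
  expect_equal(a$theoretical_mass[1], 29888.61, tolerance = 0.01)
  expect_lt(abs(a$error_ppm[1]), 35)

  d <- assign_composition(26102.55, 18235.99, tolerance_ppm = 35,
                          bounds = rhepo_bounds())
  expect_equal(d$composition[1], "Hex22HexNAc19Fuc3")
  expect_equal(d$theoretical_mass[1], 26102.26, tolerance = 0.01)

  # measured == backbone: the empty composition, and only that
  e <- assign_composition(18235.99, 18235.99, tolerance_ppm = 5,
                          bounds = search_bounds(c(Hex = 5, HexNAc = 5)))
  expect_equal(nrow(e), 1L)
  expect_identical(e$composition, "")

  # below the backbone: nothing
  expect_equal(nrow(assign_composition(18000, 18235.99)), 0L)
})

test_that("the bounded search is complete against brute force", {
  table <- monosaccharide_masses()
  bounds <- search_bounds(c(Hex = 6, HexNAc = 5, Fuc = 3, Sia = 4),
                          sia_constraint = FALSE)
  grid <- expand.grid(Hex = 0:6, HexNAc = 0:5, Fuc = 0:3, Sia = 0:4)
  grid_mass <- as.matrix(grid) %*%
    table[c("Hex", "HexNAc", "Fuc", "Sia")]
  for (target in c(1000, 1500.3, 2000.7, 2905.9)) {
    measured <- 10000 + target
    tol_da <- 100e-6 * measured
    hits <- assign_composition(measured, 10000, tolerance_ppm = 100,
                               bounds = bounds)
    expect_equal(nrow(hits), sum(abs(grid_mass - target) <= tol_da))
    if (nrow(hits) > 0)
      expect_true(all(abs(hits$error_ppm) <= 100))
  }
})

test_that("planted compositions are recovered top-1", {
  set.seed(17)
  table <- monosaccharide_masses()
  # bounds tight around the planting family: Fuc capped at the sampler's
  # range, since 5 Fuc and 2 (Hex+HexNAc) differ by only 0.04 Da and are
  # genuinely indistinguishable at intact-mass accuracy
  bounds <- search_bounds(c(Hex = 30, HexNAc = 25, Fuc = 4, Sia = 20),
                          sia_constraint = FALSE,
                          hex_hexnac_diff = 3, sia_le_hexnac_minus = 6)
  hits <- 0L
  n_trials <- 25L
  for (i in seq_len(n_trials)) {
    n <- sample(7:22, 1)
    a <- n - 6          # antennae available for sialylation
    comp <- glycan_composition(c(Hex = n + 3, HexNAc = n,
                                 Fuc = sample(0:4, 1),
                                 Sia = sample(0:min(a, 15), 1)))
    truth <- format_composition(comp)
    measured <- 18235.99 + composition_mass(comp, table) +
      stats::runif(1, -0.2, 0.2)  # ~7 ppm measurement error
    res <- assign_composition(measured, 18235.99, tolerance_ppm = 35,
                              bounds = bounds)
    if (nrow(res) > 0 && res$composition[1] == truth) hits <- hits + 1L
  }
  expect_equal(hits, n_trials)
})

test_that("assignment ranking is deterministic", {
  a1 <- assign_composition(29888.12, 18235.99, tolerance_ppm = 35)
  a2 <- assign_composition(29888.12, 18235.99, tolerance_ppm = 35)
  expect_identical(a1, a2)
  expect_true(all(diff(abs(a1$error_ppm)) >= -1e-12))
})

test_that("spectrum annotation flags single-residue ladders", {
  backbone <- 48000
  base <- backbone + composition_mass(parse_composition("Hex10HexNAc2"))
  peaks <- zero_charge_spectrum(base + 162.1424 * (0:3),
                                c(0.4, 0.3, 0.2, 0.1))
  ann <- annotate_spectrum(peaks, backbone, tolerance_ppm = 20,
                           bounds = search_bounds(
                             c(Hex = 16, HexNAc = 4),
                             sia_constraint = FALSE))
  expect_true(all(ann$annotations$n_candidates >= 1))
  hex_counts <- vapply(ann$annotations$composition, function(txt) {
    cc <- parse_composition(txt)
    as.integer(cc[match("Hex", names(cc))])
  }, integer(1), USE.NAMES = FALSE)
  expect_equal(diff(hex_counts), rep(1L, 3))
  expect_equal(nrow(ann$ladders), 3L)
  expect_true(all(ann$ladders$residue == "Hex"))

  # a peak below the backbone is annotated with a reason, not a candidate
  low <- zero_charge_spectrum(c(47000, base), c(0.5, 0.5))
  ann2 <- annotate_spectrum(low, backbone, tolerance_ppm = 20,
                            bounds = search_bounds(c(Hex = 16, HexNAc = 4),
                                                   sia_constraint = FALSE))
  expect_equal(ann2$annotations$reason[1], "below backbone mass")
  expect_equal(ann2$annotations$n_candidates[1], 0L)
})
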