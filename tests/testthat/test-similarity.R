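test_that("binning conserves in-range intensity and places points", {
  spec <- mz_spectrum(1000.5, 2)
  b <- bin_spectrum(spec, width = 1, range = c(1000, 1001), origin = 1000)
  expect_equal(b$intensities[1], 2)

  set.seed(12)
  spec2 <- mz_spectrum(sort(stats::runif(200, 500, 600)),
                       stats::runif(200))
  b2 <- bin_spectrum(spec2, width = 2.5)
  expect_equal(sum(b2$intensities), sum(spec2$intensity), tolerance = 1e-9)
})

test_that("wide-enough bins co-bin or neighbour close peaks at any origin", {
  # two points 0.4 apart: with width >= 0.8 no bin origin can place them
  # further than adjacent bins
  spec <- mz_spectrum(c(100.0, 100.4), c(1, 1))
  for (origin in seq(99, 100, by = 0.01)) {
    b <- bin_spectrum(spec, width = 0.8, range = c(99, 101),
                      origin = origin)
    filled <- which(b$intensities > 0)
    expect_lte(diff(range(filled)), 1)
  }
})

test_that("Pearson similarity has the textbook invariances", {
  set.seed(4)
  # one point per unit bin, so bin vectors transform exactly with the points
  a <- mz_spectrum(seq(2500.5, 2599.5, by = 1), stats::runif(100))
  expect_equal(pearson_similarity(a, a, 1)$r, 1, tolerance = 1e-12)
  # affine intensity transform leaves r at 1
  b <- mz_spectrum(a$mz, a$intensity * 5 + 0.2)
  expect_equal(pearson_similarity(a, b, 1)$r, 1, tolerance = 1e-12)
  # symmetry
  c <- mz_spectrum(sort(stats::runif(80, 2500, 3500)), stats::runif(80))
  expect_equal(pearson_similarity(a, c, 5)$r,
               pearson_similarity(c, a, 5)$r, tolerance = 1e-12)
  expect_gte(pearson_similarity(a, c, 5)$r, -1)
  expect_lte(pearson_similarity(a, c, 5)$r, 1)
  # zero variance is an explicit error, never a silent 0
  flat <- mz_spectrum(a$mz, rep(1, 100))
  expect_error(pearson_similarity(a, flat, 1), "zero variance")
})

test_that("similarity falls as sialylation distributions separate", {
  make_model <- function(sia_weights) {
    isoforms <- lapply(0:4, function(s) {
      mod_isoform(paste0("S", s),
                  glycan_composition(c(Hex = 7, HexNAc = 6,
                                       Sia = as.integer(s))),
                  abundance = sia_weights[s + 1])
    })
    protein_model("m", 18000,
                  list(site_table("N1", isoforms),
                       site_table("N2", isoforms)))
  }
  base <- make_model(c(1, 2, 4, 2, 1))
  ref <- construct_pseudo_native(base, envelope = charge_envelope(8:10))
  r <- vapply(list(c(1, 2, 4, 2, 1), c(2, 4, 2, 1, 1), c(4, 2, 1, 1, 2),
                   c(8, 1, 1, 1, 1)),
              function(w) {
                other <- construct_pseudo_native(
                  make_model(w), envelope = charge_envelope(8:10))
                pearson_similarity(ref, other, 2)$r
              }, numeric(1))
  expect_equal(r[1], 1, tolerance = 1e-9)
  expect_true(all(diff(r) < 0))
  expect_lt(r[4], 0.9)
})

test_that("peak pairs match greedily by intensity and proximity", {
  a <- zero_charge_spectrum(seq(29000, 30900, by = 100),
                            c(20:11, 10:1) / 20)
  pairs_self <- match_peak_pairs(a, a, top_n = 20, tol = 1)
  expect_equal(nrow(pairs_self), 20)
  expect_true(all(pairs_self$delta == 0))

  b <- zero_charge_spectrum(a$mass + 0.2, a$abundance)
  pairs <- match_peak_pairs(a, b, top_n = 20, tol = 0.5)
  expect_equal(nrow(pairs), 20)
  expect_equal(pairs$delta, rep(0.2, 20), tolerance = 1e-9)

  # low-rank decoys interleaved between real peaks never reach top_n
  decoys <- zero_charge_spectrum(seq(29050, 30050, by = 100),
                                 rep(0.001, 11))
  a2 <- zero_charge_spectrum(c(a$mass, decoys$mass),
                             c(a$abundance, decoys$abundance))
  pairs2 <- match_peak_pairs(a2, a2, top_n = 20, tol = 1, min_frac = 0)
  expect_true(all(pairs2$intensity_a >= 1 / 20))

  expect_warning(match_peak_pairs(
    zero_charge_spectrum(c(29000, 29100), c(1, 1)), b, top_n = 20,
    tol = 0.5), "only")
})

test_that("the optimal bin width is the median of 60 pair widths", {
  # 20 planted pair separations at charges 8, 9, 10
  deltas <- seq(0.5, 10, by = 0.5)
  a <- zero_charge_spectrum(seq(29000, by = 200, length.out = 20),
                            seq(2, 1.05, by = -0.05))
  b <- zero_charge_spectrum(a$mass + deltas, a$abundance)
  w <- optimal_bin_width(a, b, charges = c(8, 9, 10), top_n = 20,
                         tol = 50)
  cand <- attr(w, "candidates")
  expect_length(cand, 60)
  # independent hand computation of the 60 candidate widths
  hand <- as.numeric(sapply(c(8, 9, 10), function(z) 2 * deltas / z))
  expect_equal(sort(cand), sort(hand), tolerance = 1e-9)
  expect_equal(as.numeric(w), stats::median(hand), tolerance = 1e-9)

  # identical spectra: all separations zero, floor width returned
  w0 <- optimal_bin_width(a, a, min_width = 0.1)
  expect_equal(as.numeric(w0), 0.1)
})

test_that("the bin-width scan covers the default grid and finds structure", {
  set.seed(8)
  mass <- sort(stats::runif(40, 28000, 31000))
  inten <- stats::runif(40)
  a <- zero_charge_spectrum(mass, inten)
  scan_flat <- binwidth_scan(a, a, w_min = 1, w_max = 20, step = 0.1)
  expect_length(scan_flat$widths, 191)
  expect_true(scan_flat$flat)
  expect_true(all(abs(scan_flat$r_values - 1) < 1e-9))

  # jittered positions: r rises with width, an inflection exists
  b <- zero_charge_spectrum(mass + stats::rnorm(40, 0, 2), inten)
  scan <- binwidth_scan(a, b, selected = 4)
  expect_false(scan$flat)
  expect_true(is.finite(scan$inflection))
  lo <- mean(scan$r_values[scan$widths <= 2])
  hi <- mean(scan$r_values[scan$widths >= 15])
  expect_gt(hi, lo)
  expect_true(is.logical(scan$selected_close))
})

test_that("repeated scoring of the same inputs is bit-identical", {
  set.seed(99)
  a <- mz_spectrum(sort(stats::runif(150, 2500, 3500)), stats::runif(150))
  b <- mz_spectrum(sort(stats::runif(150, 2500, 3500)), stats::runif(150))
  r1 <- pearson_similarity(a, b, 3)$r
  r2 <- pearson_similarity(a, b, 3)$r
  expect_identical(r1, r2)
})
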