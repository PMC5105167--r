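.proton_mass <- 1.007276  # physical proton, Da

#' m/z spectrum
#'
#' Sorted (m/z, intensity) pairs, either centroid sticks or a profile trace
#' on a regular grid.
#'
#' @param mz m/z values in Th.
#' @param intensity matching intensities (>= 0).
#' @param mode `"centroid"` or `"profile"`.
#' @return object of class `mz_spectrum` (a data.frame with columns `mz`,
#'   `intensity`).
#' @export
mz_spectrum <- function(mz = numeric(), intensity = numeric(),
                        mode = c("centroid", "profile")) {
  mode <- match.arg(mode)
  stopifnot(length(mz) == length(intensity), all(intensity >= 0))
  ord <- order(mz)
  out <- data.frame(mz = mz[ord], intensity = intensity[ord])
  attr(out, "mode") <- mode
  class(out) <- c("mz_spectrum", "data.frame")
  out
}

#' @export
print.mz_spectrum <- function(x, ...) {
  cat(sprintf("<m/z spectrum> %s, %d point(s)", attr(x, "mode"), nrow(x)))
  if (nrow(x) > 0L)
    cat(sprintf(", %.2f - %.2f Th", min(x$mz), max(x$mz)))
  cat("\n")
  invisible(x)
}

#' Electrospray charge envelope
#'
#' The set of charge states [M+zH]z+ over which an intact protein's signal is
#' spread in native ESI, with their relative abundances (normalized to sum
#' to 1).
#'
#' @param charges positive integer charge states (unique).
#' @param abundances relative abundances; default uniform.
#' @return object of class `charge_envelope`.
#' @export
#' @examples
#' charge_envelope(8:10)  # the typical native rhEPO envelope
charge_envelope <- function(charges, abundances = NULL) {
  charges <- as.integer(charges)
  stopifnot(length(charges) >= 1L, all(charges >= 1L),
            !anyDuplicated(charges))
  if (is.null(abundances)) abundances <- rep(1, length(charges))
  stopifnot(length(abundances) == length(charges), all(abundances >= 0),
            sum(abundances) > 0)
  structure(list(charges = charges,
                 abundances = abundances / sum(abundances)),
            class = "charge_envelope")
}

#' Resolution model for profile rendering
#'
#' Resolving power as a function of m/z: R(mz) = R_ref * (mz_ref / mz)^p.
#' The default (R 17,500 at m/z 200, p = 0.5) is the Orbitrap-like square
#' root fall-off of the instrument setting used for native MS of intact
#' glycoproteins.
#'
#' @param R_ref resolving power at the reference m/z.
#' @param mz_ref reference m/z in Th.
#' @param exponent scaling power p.
#' @return object of class `resolution_model`.
#' @export
resolution_model <- function(R_ref = 17500, mz_ref = 200, exponent = 0.5) {
  stopifnot(R_ref > 0, mz_ref > 0)
  structure(list(R_ref = R_ref, mz_ref = mz_ref, exponent = exponent),
            class = "resolution_model")
}

.fwhm_at <- function(mz, res) {
  R <- res$R_ref * (res$mz_ref / mz)^res$exponent
  mz / R
}

#' Project a zero-charge spectrum into m/z space
#'
#' Each neutral mass M emits one centroid per charge state z at
#' Q = (M + z * m_proton) / z, with intensity P * A_z. Coincident centroids
#' are summed; total intensity equals the total zero-charge abundance.
#'
#' @param spectrum a [zero_charge_spectrum()].
#' @param envelope a [charge_envelope()].
#' @param proton_mass proton mass in Da.
#' @return centroid [mz_spectrum()].
#' @export
to_mz <- function(spectrum, envelope, proton_mass = .proton_mass) {
  stopifnot(inherits(spectrum, "zero_charge_spectrum"),
            proton_mass > 0)
  if (!inherits(envelope, "charge_envelope"))
    stop("envelope must be a charge_envelope")
  if (nrow(spectrum) == 0L) return(mz_spectrum())
  z <- envelope$charges
  az <- envelope$abundances
  mz <- as.vector(outer(spectrum$mass, z,
                        function(m, z) (m + z * proton_mass) / z))
  int <- as.vector(outer(spectrum$abundance, az, `*`))
  # sum exactly coincident points
  if (anyDuplicated(mz)) {
    int <- as.numeric(tapply(int, mz, sum))
    mz <- sort(unique(mz))
  }
  mz_spectrum(mz, int, mode = "centroid")
}

#' Render a centroid spectrum to profile mode
#'
#' Each centroid becomes a Gaussian of area equal to its intensity, with
#' FWHM = mz / R(mz) from the resolution model, sampled on a regular m/z
#' grid. Peak areas are conserved (the trace integrates back to the summed
#' stick intensities).
#'
#' @param centroid centroid [mz_spectrum()].
#' @param res a [resolution_model()].
#' @param grid_step grid spacing in Th; default (and maximum) is a quarter
#'   of the narrowest peak FWHM in range. A coarser request is refined with
#'   a warning.
#' @param pad extend the grid this many FWHM beyond the outermost centroids.
#' @return profile [mz_spectrum()].
#' @export
render_profile <- function(centroid, res = resolution_model(),
                           grid_step = NULL, pad = 5) {
  stopifnot(inherits(centroid, "mz_spectrum"))
  if (nrow(centroid) == 0L) return(mz_spectrum(mode = "profile"))
  fwhm <- .fwhm_at(centroid$mz, res)
  max_step <- min(fwhm) / 4
  if (is.null(grid_step)) {
    grid_step <- max_step
  } else if (grid_step > max_step) {
    warning(sprintf("grid_step %.4g Th too coarse; refined to %.4g Th",
                    grid_step, max_step))
    grid_step <- max_step
  }
  lo <- min(centroid$mz - pad * fwhm)
  hi <- max(centroid$mz + pad * fwhm)
  grid <- seq(lo, hi, by = grid_step)
  y <- numeric(length(grid))
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  for (i in seq_len(nrow(centroid))) {
    win <- 6 * sigma[i]
    j0 <- findInterval(centroid$mz[i] - win, grid) + 1L
    j1 <- findInterval(centroid$mz[i] + win, grid)
    if (j1 < j0) next
    j <- j0:j1
    y[j] <- y[j] + centroid$intensity[i] *
      stats::dnorm(grid[j], centroid$mz[i], sigma[i])
  }
  mz_spectrum(grid, y, mode = "profile")
}

#' Construct the pseudo-native MS spectrum of a protein model
#'
#' The headline pipeline: convolve the site-specific modification tables
#' into the zero-charge proteoform distribution ([site_convolution()]),
#' project it through the charge envelope ([to_mz()]) and render a
#' profile-mode trace ([render_profile()]) directly comparable with an
#' experimental native MS spectrum.
#'
#' @inheritParams site_convolution
#' @inheritParams to_mz
#' @inheritParams render_profile
#' @return profile [mz_spectrum()].
#' @export
construct_pseudo_native <- function(protein, envelope = charge_envelope(8:10),
                                    res = resolution_model(),
                                    grid_step = NULL, merge_tol = 0.01,
                                    prune_threshold = 1e-8,
                                    table = monosaccharide_masses()) {
  zc <- site_convolution(protein, merge_tol = merge_tol,
                         prune_threshold = prune_threshold, table = table)
  render_profile(to_mz(zc, envelope), res = res, grid_step = grid_step)
}

#' Estimate charge-state abundances from an experimental spectrum
#'
#' Sums intensity inside each charge state's expected m/z window
#' (mass range projected to that charge) and normalizes, giving an
#' empirical A_z for simulating a matched envelope.
#'
#' @param spectrum experimental [mz_spectrum()].
#' @param charges candidate charge states.
#' @param mass_range neutral mass range (Da) of the protein's proteoforms.
#' @param proton_mass proton mass in Da.
#' @return a [charge_envelope()].
#' @export
estimate_envelope <- function(spectrum, charges, mass_range,
                              proton_mass = .proton_mass) {
  stopifnot(inherits(spectrum, "mz_spectrum"), length(mass_range) == 2L)
  a <- vapply(charges, function(z) {
    lo <- (mass_range[1] + z * proton_mass) / z
    hi <- (mass_range[2] + z * proton_mass) / z
    sum(spectrum$intensity[spectrum$mz >= lo & spectrum$mz <= hi])
  }, numeric(1))
  if (sum(a) <= 0) stop("no intensity found in any charge-state window")
  charge_envelope(charges, a)
}
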