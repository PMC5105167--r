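# run expr with a local RNG state so generators are reproducible without
# clobbering the caller's random stream
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed",
                                          envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Measurement noise model for synthetic spectra
#'
#' Multiplicative log-normal intensity noise (heteroscedastic and strictly
#' positive, like real ion counts), Gaussian ppm-scaled m/z jitter (like
#' mass-accuracy drift), per-peak dropout and a flat baseline.
#'
#' @param intensity_cv coefficient of variation of the log-normal intensity
#'   factor.
#' @param mz_jitter_ppm standard deviation of the position jitter, in ppm.
#' @param dropout_prob probability that a centroid is lost entirely.
#' @param baseline_level flat baseline as a fraction of the base peak.
#' @param seed RNG seed; every stochastic operation in this package takes an
#'   explicit seed.
#' @return object of class `noise_model`.
#' @export
noise_model <- function(intensity_cv = 0.1, mz_jitter_ppm = 10,
                        dropout_prob = 0, baseline_level = 0, seed = 1L) {
  stopifnot(intensity_cv >= 0, mz_jitter_ppm >= 0,
            dropout_prob >= 0, dropout_prob < 1, baseline_level >= 0)
  structure(list(intensity_cv = intensity_cv,
                 mz_jitter_ppm = mz_jitter_ppm,
                 dropout_prob = dropout_prob,
                 baseline_level = baseline_level,
                 seed = as.integer(seed)),
            class = "noise_model")
}

# one N-glycoform: complex-type core Hex3HexNAc2 with a antennae
# (each adding HexHexNAc), optional core fucose, s terminal sialic acids
.nglycoform <- function(antennae, fucose, sia) {
  glycan_composition(c(Hex = 3L + antennae, HexNAc = 2L + antennae,
                       Fuc = as.integer(fucose), Sia = as.integer(sia)))
}

.nglycoform_label <- function(antennae, fucose, sia) {
  sprintf("A%d%sS%d", antennae, if (fucose) "F" else "", sia)
}

.dirichlet <- function(k, conc = 1) {
  g <- stats::rgamma(k, shape = conc)
  if (sum(g) <= 0) g <- rep(1, k)
  g / sum(g)
}

# an N-site with glycoforms spanning antennarity and sialylation
.gen_nsite <- function(site_id, n_isoforms, conc) {
  pool <- expand.grid(a = 2:4, f = 0:1, s = 0:4)
  pool <- pool[pool$s <= pool$a, ]
  pool <- pool[order(-pool$a, -pool$s, pool$f), ]  # tetra-sialylated first
  take <- utils::head(pool, n_isoforms)
  ab <- .dirichlet(nrow(take), conc)
  isoforms <- lapply(seq_len(nrow(take)), function(i) {
    mod_isoform(.nglycoform_label(take$a[i], take$f[i], take$s[i]),
                .nglycoform(take$a[i], take$f[i], take$s[i]),
                abundance = ab[i])
  })
  site_table(site_id, isoforms, kind = "N")
}

# a mucin-type O-site: unoccupied + core 1 with 0..2 sialic acids
.gen_osite <- function(site_id, conc, include_unoccupied = TRUE) {
  isoforms <- list()
  if (include_unoccupied)
    isoforms <- list(mod_isoform("unoccupied"))
  for (s in 0:2) {
    isoforms[[length(isoforms) + 1L]] <-
      mod_isoform(sprintf("core1S%d", s),
                  glycan_composition(c(Hex = 1L, HexNAc = 1L,
                                       Sia = as.integer(s))))
  }
  ab <- .dirichlet(length(isoforms), conc)
  for (i in seq_along(isoforms)) isoforms[[i]]$abundance <- ab[i]
  site_table(site_id, isoforms, kind = "O")
}

# a binary C-mannosylation site with given occupancy
.gen_csite <- function(site_id, occupancy) {
  site_table(site_id, list(
    mod_isoform("unoccupied", abundance = 1 - occupancy),
    mod_isoform("CMan", glycan_composition(c(Hex = 1L)),
                abundance = occupancy)
  ), kind = "C")
}

#' Generate a ground-truth protein model
#'
#' Builds reproducible synthetic site tables with the statistical structure
#' the pipeline assumes. Presets:
#' \describe{
#'   \item{`"rhepo"`}{three N-sites (N24/N38/N83 with 10, 9 and 8
#'     glycoforms: complex di/tri/tetra-antennary N-glycans carrying up to
#'     one sialic acid per antenna, with and without core fucose) plus the
#'     S126 O-site (core 1 with 0-2 sialic acids), on the rhEPO backbone.}
#'   \item{`"properdin"`}{17 binary C-mannosylation sites with heterogeneous
#'     occupancy, four O-sites and one N-site on a 48 kDa backbone.}
#'   \item{`"custom"`}{`n_sites` N-style sites with up to `max_isoforms`
#'     glycoforms each on a 20 kDa backbone.}
#' }
#' Site abundances are Dirichlet-distributed (concentration
#' `dirichlet_conc`, default 1 = uniform over the simplex).
#'
#' @param seed RNG seed; the model is byte-identical for a fixed seed.
#' @param preset `"custom"`, `"rhepo"` or `"properdin"`.
#' @param n_sites,max_isoforms custom-preset dimensions.
#' @param dirichlet_conc Dirichlet concentration for site abundances.
#' @return a [protein_model()].
#' @export
gen_protein_model <- function(seed, preset = c("custom", "rhepo",
                                               "properdin"),
                              n_sites = 3, max_isoforms = 4,
                              dirichlet_conc = 1) {
  preset <- match.arg(preset)
  .with_seed(seed, {
    if (preset == "rhepo") {
      sites <- list(
        .gen_nsite("N24", 10, dirichlet_conc),
        .gen_nsite("N38", 9, dirichlet_conc),
        .gen_nsite("N83", 8, dirichlet_conc),
        .gen_osite("S126", dirichlet_conc)
      )
      protein_model("rhEPO-synthetic",
                    backbone_mass_from_sequence(rhepo_sequence(), 2), sites)
    } else if (preset == "properdin") {
      occ <- stats::runif(17, 0.3, 1)
      # the central Trp of each repeat motif is near-fully occupied
      occ[seq(2, 17, by = 3)] <- stats::runif(length(seq(2, 17, by = 3)),
                                              0.97, 1)
      csites <- lapply(1:17, function(i)
        .gen_csite(sprintf("W%02d", i), occ[i]))
      osites <- lapply(1:4, function(i)
        .gen_osite(sprintf("O%d", i), dirichlet_conc))
      nsite <- list(.gen_nsite("N401", 4, dirichlet_conc))
      protein_model("properdin-synthetic", 48000,
                    c(csites, osites, nsite))
    } else {
      stopifnot(n_sites >= 1, max_isoforms >= 1)
      sites <- lapply(seq_len(n_sites), function(i) {
        k <- sample(seq_len(max_isoforms), 1)
        .gen_nsite(sprintf("N%d", i * 10), max(k, 1), dirichlet_conc)
      })
      protein_model(sprintf("synthetic-%d", seed), 20000, sites)
    }
  })
}

#' Generate a noisy synthetic "experimental" spectrum
#'
#' Takes the model's pseudo-native centroids, perturbs them per the noise
#' model (position jitter, intensity noise, dropout), renders the profile
#' and adds the flat baseline. With all noise parameters zero the output is
#' identical to [construct_pseudo_native()].
#'
#' @inheritParams construct_pseudo_native
#' @param noise a [noise_model()]; its `seed` drives all randomness here.
#' @return profile [mz_spectrum()].
#' @export
gen_experimental_spectrum <- function(protein,
                                      envelope = charge_envelope(8:10),
                                      res = resolution_model(),
                                      noise = noise_model(),
                                      grid_step = NULL, merge_tol = 0.01,
                                      prune_threshold = 1e-8,
                                      table = monosaccharide_masses()) {
  stopifnot(inherits(noise, "noise_model"))
  zc <- site_convolution(protein, merge_tol = merge_tol,
                         prune_threshold = prune_threshold, table = table)
  cen <- to_mz(zc, envelope)
  cen <- .with_seed(noise$seed, {
    n <- nrow(cen)
    mz <- cen$mz
    int <- cen$intensity
    if (noise$mz_jitter_ppm > 0)
      mz <- mz * (1 + stats::rnorm(n, 0, noise$mz_jitter_ppm * 1e-6))
    if (noise$intensity_cv > 0)
      int <- int * stats::rlnorm(n, 0, noise$intensity_cv)
    if (noise$dropout_prob > 0) {
      keep <- stats::runif(n) >= noise$dropout_prob
      if (!any(keep)) keep[which.max(int)] <- TRUE
      mz <- mz[keep]; int <- int[keep]
    }
    mz_spectrum(mz, int, mode = "centroid")
  })
  prof <- render_profile(cen, res = res, grid_step = grid_step)
  if (noise$baseline_level > 0 && nrow(prof) > 0L)
    prof$intensity <- prof$intensity +
      noise$baseline_level * max(prof$intensity)
  prof
}

#' Perturb a model's sialylation distribution
#'
#' Redistributes abundance among the isoforms of each site that share the
#' same sialic-acid-stripped base composition (log-normal factors of
#' standard deviation `sd`, renormalized to preserve each group's total).
#' This is noise that targets sialylation heterogeneity specifically: the
#' desialylated model is untouched, so in-silico sialidase exactly removes
#' the perturbation.
#'
#' @param protein a [protein_model()].
#' @param sd log-scale standard deviation of the redistribution factors.
#' @param seed RNG seed.
#' @return the perturbed [protein_model()].
#' @export
perturb_sialylation <- function(protein, sd = 0.5, seed = 1L) {
  stopifnot(inherits(protein, "protein_model"), sd >= 0)
  strip <- c("Sia", "NeuGc", "Acetyl", "Hydroxyl")
  .with_seed(seed, {
    sites <- lapply(protein$sites, function(site) {
      key <- vapply(site$isoforms, function(iso) {
        if (!is.null(iso$delta_da)) return(sprintf("raw:%.6f", iso$delta_da))
        cnt <- stats::setNames(as.integer(iso$composition),
                               names(iso$composition))
        format_composition(glycan_composition(
          cnt[!(names(cnt) %in% strip)]))
      }, character(1))
      ab <- vapply(site$isoforms, `[[`, numeric(1), "abundance")
      fac <- stats::rlnorm(length(ab), 0, sd)
      new_ab <- ab * fac
      for (k in unique(key)) {
        g <- key == k
        tot <- sum(ab[g]); newtot <- sum(new_ab[g])
        if (newtot > 0) new_ab[g] <- new_ab[g] * tot / newtot
      }
      for (i in seq_along(site$isoforms))
        site$isoforms[[i]]$abundance <- new_ab[i]
      site
    })
    protein_model(protein$name, protein$backbone_mass, sites)
  })
}

#' Construction-vs-experiment recovery experiment
#'
#' For each noise level, simulates `n_reps` noisy experimental spectra of
#' the protein and scores each against the noise-free construction,
#' summarizing the Pearson r per level.
#'
#' @param protein a [protein_model()].
#' @param noise_grid list of [noise_model()] objects (their `seed` fields
#'   are overridden per replicate).
#' @param n_reps replicates per level.
#' @param seed base seed; replicate seeds are derived deterministically.
#' @param width bin width for scoring.
#' @inheritParams construct_pseudo_native
#' @return data.frame with one row per noise level: `level`, `mean_r`,
#'   `sd_r`, `n`.
#' @export
recovery_experiment <- function(protein, noise_grid, n_reps = 5, seed = 1L,
                                width = 1,
                                envelope = charge_envelope(8:10),
                                res = resolution_model(),
                                grid_step = NULL) {
  stopifnot(length(noise_grid) >= 1L, n_reps >= 1)
  ref <- construct_pseudo_native(protein, envelope = envelope, res = res,
                                 grid_step = grid_step)
  rows <- lapply(seq_along(noise_grid), function(li) {
    nm <- noise_grid[[li]]
    stopifnot(inherits(nm, "noise_model"))
    r <- vapply(seq_len(n_reps), function(rep) {
      nm$seed <- as.integer((seed * 1000L + li * 100L + rep) %% .Machine$integer.max)
      exp_spec <- gen_experimental_spectrum(protein, envelope = envelope,
                                            res = res, noise = nm,
                                            grid_step = grid_step)
      pearson_similarity(ref, exp_spec, width)$r
    }, numeric(1))
    data.frame(level = li, mean_r = mean(r),
               sd_r = if (n_reps > 1) stats::sd(r) else 0, n = n_reps)
  })
  do.call(rbind, rows)
}
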