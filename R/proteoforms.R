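#' Zero-charge proteoform spectrum
#'
#' Sorted (mass, abundance) pairs representing the neutral-mass distribution
#' of a protein's proteoforms. Abundances sum to the retained probability
#' (1 when no pruning was applied).
#'
#' @param mass numeric vector of masses (Da).
#' @param abundance matching abundances (>= 0).
#' @param retained_probability total probability retained after pruning.
#' @return object of class `zero_charge_spectrum` (a data.frame with columns
#'   `mass`, `abundance`).
#' @export
zero_charge_spectrum <- function(mass = numeric(), abundance = numeric(),
                                 retained_probability = sum(abundance)) {
  stopifnot(length(mass) == length(abundance), all(abundance >= 0))
  ord <- order(mass)
  out <- data.frame(mass = mass[ord], abundance = abundance[ord])
  attr(out, "retained_probability") <- retained_probability
  class(out) <- c("zero_charge_spectrum", "data.frame")
  out
}

#' @export
print.zero_charge_spectrum <- function(x, ...) {
  cat(sprintf("<zero-charge spectrum> %d peak(s), retained probability %.6f\n",
              nrow(x), attr(x, "retained_probability")))
  if (nrow(x) > 0L)
    cat(sprintf("  mass range %.2f - %.2f Da\n", min(x$mass), max(x$mass)))
  invisible(x)
}

# per-site (mass, probability) pairs
.site_distribution <- function(site, table) {
  p <- normalize_site(site)
  m <- vapply(site$isoforms, .isoform_mass, numeric(1), table = table)
  list(mass = m, prob = p,
       labels = vapply(site$isoforms, `[[`, character(1), "label"))
}

#' Enumerate all proteoforms of a protein model
#'
#' Under the independence model, every combination of one isoform per site is
#' a proteoform with mass M = M_backbone + sum of the chosen per-site mass
#' deltas, and probability P = product of the chosen normalized per-site
#' abundances. Probabilities over the full enumeration sum to 1.
#'
#' @param protein a [protein_model()].
#' @param prune_threshold drop proteoforms with probability below this
#'   (default 0 = keep all).
#' @param table residue mass table.
#' @param max_combinations guard against combinatorial explosion; models with
#'   more combinations than this must either prune or use
#'   [site_convolution()].
#' @return data.frame with columns `total_mass`, `probability`, `choices`
#'   (per-site isoform labels, "|"-separated).
#' @export
enumerate_proteoforms <- function(protein, prune_threshold = 0,
                                  table = monosaccharide_masses(),
                                  max_combinations = 1e6) {
  stopifnot(inherits(protein, "protein_model"),
            prune_threshold >= 0, prune_threshold < 1)
  dists <- lapply(protein$sites, .site_distribution, table = table)
  k <- vapply(dists, function(d) length(d$prob), integer(1))
  n_comb <- prod(k)
  if (length(k) == 0L) n_comb <- 1
  if (n_comb > max_combinations)
    stop(sprintf(paste0("model has %.3g isoform combinations ",
                        "(cap %.3g); use site_convolution() instead"),
                 n_comb, max_combinations))
  if (length(dists) == 0L) {
    return(data.frame(total_mass = protein$backbone_mass, probability = 1,
                      choices = ""))
  }
  idx <- expand.grid(lapply(k, seq_len), KEEP.OUT.ATTRS = FALSE)
  mass <- rep(protein$backbone_mass, nrow(idx))
  prob <- rep(1, nrow(idx))
  lab <- matrix("", nrow(idx), length(dists))
  for (i in seq_along(dists)) {
    j <- idx[[i]]
    mass <- mass + dists[[i]]$mass[j]
    prob <- prob * dists[[i]]$prob[j]
    lab[, i] <- dists[[i]]$labels[j]
  }
  keep <- prob >= prune_threshold
  data.frame(total_mass = mass[keep], probability = prob[keep],
             choices = apply(lab[keep, , drop = FALSE], 1, paste,
                             collapse = "|"))
}

# merge sorted (mass, abundance) pairs whose neighbours are within tol,
# summing abundance at the probability-weighted mean mass
.merge_peaks <- function(mass, abundance, tol) {
  if (length(mass) == 0L)
    return(list(mass = numeric(), abundance = numeric()))
  ord <- order(mass)
  mass <- mass[ord]; abundance <- abundance[ord]
  grp <- cumsum(c(1, as.integer(diff(mass) > tol)))
  a <- as.numeric(tapply(abundance, grp, sum))
  wm <- as.numeric(tapply(mass * abundance, grp, sum))
  tot <- a
  zero <- tot <= 0
  # zero-abundance groups fall back to the plain mean mass
  m <- ifelse(zero, as.numeric(tapply(mass, grp, mean)), wm / ifelse(zero, 1, tot))
  list(mass = m, abundance = a)
}

#' Collapse proteoforms into a zero-charge spectrum
#'
#' Proteoforms whose masses differ by at most `merge_tol` are merged into one
#' peak by summing probabilities at the probability-weighted mean mass;
#' positional isomers (identical total mass from different site assignments)
#' therefore collapse to a single peak, as they do in a measured spectrum.
#'
#' @param proteoforms data.frame from [enumerate_proteoforms()].
#' @param merge_tol merge tolerance in Da (default 0.01, far below
#'   native-MS peak widths).
#' @return a [zero_charge_spectrum()].
#' @export
build_zero_charge_spectrum <- function(proteoforms, merge_tol = 0.01) {
  stopifnot(merge_tol >= 0)
  m <- .merge_peaks(proteoforms$total_mass, proteoforms$probability,
                    merge_tol)
  zero_charge_spectrum(m$mass, m$abundance)
}

#' Proteoform mass distribution by iterated site convolution
#'
#' Scalable equivalent of [enumerate_proteoforms()] +
#' [build_zero_charge_spectrum()]: the per-site (mass, probability)
#' distributions are convolved one site at a time, merging peaks within
#' `merge_tol` and dropping peaks below `prune_threshold` after each step.
#' For proteins with many sites (e.g. >20 C-mannosylation/O-/N-sites) this
#' keeps the peak count bounded while full enumeration would explode.
#' Pruned probability is visible as `retained_probability < 1`; no
#' renormalization is applied.
#'
#' @inheritParams enumerate_proteoforms
#' @param merge_tol merge tolerance in Da.
#' @return a [zero_charge_spectrum()].
#' @export
site_convolution <- function(protein, merge_tol = 0.01,
                             prune_threshold = 1e-8,
                             table = monosaccharide_masses()) {
  stopifnot(inherits(protein, "protein_model"),
            merge_tol >= 0, prune_threshold >= 0, prune_threshold < 1)
  mass <- protein$backbone_mass
  prob <- 1
  for (site in protein$sites) {
    d <- .site_distribution(site, table)
    np <- length(mass)
    nd <- length(d$mass)
    new_mass <- rep(mass, times = nd) + rep(d$mass, each = np)
    new_prob <- rep(prob, times = nd) * rep(d$prob, each = np)
    m <- .merge_peaks(new_mass, new_prob, merge_tol)
    keep <- m$abundance >= prune_threshold
    mass <- m$mass[keep]
    prob <- m$abundance[keep]
  }
  zero_charge_spectrum(mass, prob)
}
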