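#' Search bounds for composition assignment
#'
#' Per-building-block maximum counts for the bounded integer search, plus an
#' optional structural constraint tying the sialic-acid decorations to the
#' number of sialic acids: Acetyl + Hydroxyl <= Sia + NeuGc (O-acetylation
#' and the NeuAc-to-NeuGc hydroxyl sit on sialic-acid residues).
#'
#' The defaults are sized for a heavily sialylated N/O-glycosylated protein
#' of the rhEPO class.
#'
#' Optional glycan-architecture constraints sharpen the search when the
#' protein's glycosylation topology is known: `hex_hexnac_diff` pins
#' Hex - HexNAc to a fixed value (complex-type N-glycans have Hex = HexNAc
#' + 1 per core, so e.g. three complex N-glycans plus one core-1 O-glycan
#' give a difference of 3), and `sia_le_hexnac_minus` caps the number of
#' sialic acids at HexNAc minus the given offset (one sialic acid per
#' antenna; the offset is the number of non-antenna HexNAc residues).
#'
#' @param max_counts named integer vector of per-block maxima.
#' @param sia_constraint enforce Acetyl + Hydroxyl <= Sia + NeuGc.
#' @param hex_hexnac_diff `NA` or required value of Hex - HexNAc.
#' @param sia_le_hexnac_minus `NA` or offset k enforcing
#'   Sia + NeuGc <= HexNAc - k.
#' @return object of class `search_bounds`.
#' @export
search_bounds <- function(max_counts = c(Hex = 30, HexNAc = 25, Fuc = 6,
                                         Sia = 20, Acetyl = 4, Hydroxyl = 4,
                                         Pho = 2),
                          sia_constraint = TRUE,
                          hex_hexnac_diff = NA,
                          sia_le_hexnac_minus = NA) {
  stopifnot(all(max_counts >= 0), !is.null(names(max_counts)))
  structure(list(max_counts = max_counts, sia_constraint = sia_constraint,
                 hex_hexnac_diff = hex_hexnac_diff,
                 sia_le_hexnac_minus = sia_le_hexnac_minus),
            class = "search_bounds")
}

#' Assignment bounds for the rhEPO glycosylation topology
#'
#' Base-series bounds for a protein carrying three complex-type N-glycans
#' and one core-1 O-glycan (the rhEPO arrangement): the four glycan blocks
#' only, Hex pinned to HexNAc + 3 and at most one sialic acid per antenna
#' (Sia <= HexNAc - 6). The +42 Da O-acetyl and +16 Da NeuGc satellites are
#' annotated relative to base-series peaks, not searched here.
#'
#' @return a [search_bounds()].
#' @export
rhepo_bounds <- function() {
  search_bounds(c(Hex = 30, HexNAc = 25, Fuc = 6, Sia = 20),
                sia_constraint = FALSE,
                hex_hexnac_diff = 3, sia_le_hexnac_minus = 6)
}

# depth-first bounded integer search over residue counts, blocks in
# descending-mass order, pruned by the remaining reachable mass window
.dfs_compositions <- function(target, masses, maxima, tol) {
  nb <- length(masses)
  # suffix_cap[i]: largest mass attainable with blocks i..nb
  suffix_cap <- rev(cumsum(rev(maxima * masses)))
  suffix_cap <- c(suffix_cap, 0)
  results <- list()
  counts <- integer(nb)
  recurse <- function(i, remaining) {
    if (i > nb) {
      if (abs(remaining) <= tol)
        results[[length(results) + 1L]] <<- counts
      return(invisible())
    }
    # counts for this block that keep the remainder reachable
    c_max <- min(maxima[i], floor((remaining + tol) / masses[i]))
    if (c_max < 0) c_max <- -1L  # loop below won't run
    for (cc in 0:c_max) {
      rem <- remaining - cc * masses[i]
      if (rem > suffix_cap[i + 1L] + tol) next
      counts[i] <<- cc
      recurse(i + 1L, rem)
      counts[i] <<- 0L
    }
  }
  if (nb > 0L) recurse(1L, target)
  else if (abs(target) <= tol) results <- list(integer())
  results
}

#' Assign overall PTM compositions to a measured intact-protein mass
#'
#' Finds every glycan/PTM composition within the search bounds whose
#' theoretical mass matches the measured mass minus the backbone mass within
#' the tolerance, ranked by absolute ppm error then by total residue count.
#' The search is exact and complete with respect to the bounds.
#'
#' @param measured_mass measured intact-protein mass in Da.
#' @param backbone_mass polypeptide backbone mass in Da.
#' @param tolerance_ppm mass tolerance in ppm of the measured mass (default
#'   50 ppm, comfortable headroom over the accuracy of native intact-mass
#'   measurements).
#' @param bounds a [search_bounds()].
#' @param table residue mass table.
#' @return data.frame with columns `composition`, `theoretical_mass`,
#'   `error_da`, `error_ppm`, `n_residues`, `rank`; zero rows when nothing
#'   matches (including measured below backbone).
#' @export
#' @examples
#' assign_composition(29888.12, 18235.99, tolerance_ppm = 35)
assign_composition <- function(measured_mass, backbone_mass,
                               tolerance_ppm = 50,
                               bounds = search_bounds(),
                               table = monosaccharide_masses()) {
  stopifnot(tolerance_ppm > 0, inherits(bounds, "search_bounds"))
  empty <- data.frame(composition = character(),
                      theoretical_mass = numeric(), error_da = numeric(),
                      error_ppm = numeric(), n_residues = integer(),
                      rank = integer())
  target <- measured_mass - backbone_mass
  tol_da <- tolerance_ppm * 1e-6 * measured_mass
  if (target < -tol_da) return(empty)
  blocks <- names(bounds$max_counts)
  missing <- setdiff(blocks, names(table))
  if (length(missing) > 0L)
    stop("no residue mass for bounded block(s): ",
         paste(missing, collapse = ", "))
  ord <- order(-table[blocks])
  blocks <- blocks[ord]
  masses <- as.numeric(table[blocks])
  maxima <- as.integer(bounds$max_counts[blocks])
  hits <- .dfs_compositions(target, masses, maxima, tol_da)
  if (length(hits) == 0L) return(empty)
  comps <- lapply(hits, function(cnt) {
    glycan_composition(stats::setNames(cnt, blocks))
  })
  ok <- vapply(comps, function(cp) {
    cnt <- stats::setNames(as.integer(cp), names(cp))
    get0 <- function(n) if (n %in% names(cnt)) cnt[[n]] else 0L
    pass <- TRUE
    if (bounds$sia_constraint)
      pass <- get0("Acetyl") + get0("Hydroxyl") <=
        get0("Sia") + get0("NeuGc")
    if (pass && !is.na(bounds$hex_hexnac_diff))
      pass <- get0("Hex") - get0("HexNAc") == bounds$hex_hexnac_diff
    if (pass && !is.na(bounds$sia_le_hexnac_minus))
      pass <- get0("Sia") + get0("NeuGc") <=
        get0("HexNAc") - bounds$sia_le_hexnac_minus
    pass
  }, logical(1))
  comps <- comps[ok]
  if (length(comps) == 0L) return(empty)
  theo <- backbone_mass +
    vapply(comps, composition_mass, numeric(1), table = table)
  err_da <- measured_mass - theo
  err_ppm <- err_da / measured_mass * 1e6
  txt <- vapply(comps, format_composition, character(1))
  n_res <- vapply(comps, function(cp) sum(as.integer(cp)), integer(1))
  ord <- order(abs(err_ppm), n_res, txt)
  out <- data.frame(composition = txt[ord], theoretical_mass = theo[ord],
                    error_da = err_da[ord], error_ppm = err_ppm[ord],
                    n_residues = n_res[ord])
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Annotate a zero-charge spectrum with PTM compositions
#'
#' Runs [assign_composition()] on every peak and additionally reports
#' adjacent-peak mass differences that match a single residue mass (e.g.
#' the 162.14 Da hexose ladders typical of C-mannosylation heterogeneity).
#'
#' @param peaks a [zero_charge_spectrum()].
#' @param backbone_mass backbone mass in Da.
#' @param tolerance_ppm assignment tolerance (ppm of each peak mass).
#' @param bounds a [search_bounds()].
#' @param ladder_tol_da tolerance for flagging adjacent-peak residue
#'   ladders, in Da.
#' @param table residue mass table.
#' @return list with `annotations` (one row per peak: top candidate or the
#'   reason none exists), `candidates` (full ranked tables per peak) and
#'   `ladders` (adjacent deltas matching one residue).
#' @export
annotate_spectrum <- function(peaks, backbone_mass, tolerance_ppm = 50,
                              bounds = search_bounds(), ladder_tol_da = 0.5,
                              table = monosaccharide_masses()) {
  stopifnot(inherits(peaks, "zero_charge_spectrum"))
  cand <- lapply(peaks$mass, function(m) {
    assign_composition(m, backbone_mass, tolerance_ppm, bounds, table)
  })
  ann <- data.frame(
    mass = peaks$mass,
    abundance = peaks$abundance,
    composition = vapply(cand, function(x)
      if (nrow(x) > 0L) x$composition[1] else NA_character_, character(1)),
    theoretical_mass = vapply(cand, function(x)
      if (nrow(x) > 0L) x$theoretical_mass[1] else NA_real_, numeric(1)),
    error_ppm = vapply(cand, function(x)
      if (nrow(x) > 0L) x$error_ppm[1] else NA_real_, numeric(1)),
    n_candidates = vapply(cand, nrow, integer(1))
  )
  ann$reason <- ifelse(ann$n_candidates > 0L, "",
                       ifelse(peaks$mass < backbone_mass,
                              "below backbone mass",
                              "no composition within tolerance"))
  ladders <- data.frame(from = numeric(), to = numeric(),
                        delta = numeric(), residue = character())
  if (nrow(peaks) >= 2L) {
    d <- diff(peaks$mass)
    for (i in seq_along(d)) {
      hit <- which(abs(d[i] - table) <= ladder_tol_da)
      if (length(hit) > 0L) {
        j <- hit[which.min(abs(d[i] - table[hit]))]
        ladders <- rbind(ladders, data.frame(
          from = peaks$mass[i], to = peaks$mass[i + 1],
          delta = d[i], residue = names(table)[j]))
      }
    }
  }
  list(annotations = ann, candidates = cand, ladders = ladders)
}
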