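# Average residue masses for the 20 standard amino acids (Da), plus water.
.aa_residue_masses <- c(
  G = 57.0519,  A = 71.0788,  S = 87.0782,  P = 97.1167,  V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132
)
.water_mass <- 18.01528
.hydrogen_mass <- 1.00794  # H atom (average)

#' Average mass of a polypeptide backbone
#'
#' Sums average residue masses over a one-letter amino-acid sequence, adds
#' one water for the termini, and subtracts two hydrogen atoms per disulfide
#' bridge (each cystine loses 2 H relative to two free cysteines).
#'
#' @param sequence one-letter amino-acid string.
#' @param n_disulfides number of disulfide bridges.
#' @return backbone mass in Da.
#' @export
#' @examples
#' backbone_mass_from_sequence("G")                 # glycine: 75.067 Da
#' backbone_mass_from_sequence(rhepo_sequence(), 2) # approx 18,235.9 Da
backbone_mass_from_sequence <- function(sequence, n_disulfides = 0) {
  stopifnot(is.character(sequence), length(sequence) == 1L,
            n_disulfides >= 0)
  aa <- strsplit(toupper(sequence), "")[[1]]
  unknown <- which(!(aa %in% names(.aa_residue_masses)))
  if (length(unknown) > 0L)
    stop(sprintf("unknown residue code '%s' at position %d",
                 aa[unknown[1]], unknown[1]))
  sum(.aa_residue_masses[aa]) + .water_mass -
    2 * .hydrogen_mass * n_disulfides
}

#' Mature recombinant human erythropoietin backbone sequence
#'
#' The 165-residue mature chain of human erythropoietin (UniProt P01588,
#' residues 28-193 with the C-terminal Arg removed, as in the recombinant
#' products). N-glycosylation sites N24/N38/N83 and the O-glycosylation site
#' S126 are positions in this chain. With its two disulfide bridges
#' (C7-C161, C29-C33) the average backbone mass is about 18,235.9 Da.
#'
#' @return character scalar, one-letter codes.
#' @export
rhepo_sequence <- function() {
  paste0(
    "APPRLICDSRVLERYLLEAKEAENITTGCAEHCSLNENITVPDTKVNFYAWKRMEVGQ",
    "QAVEVWQGLALLSEAVLRGQALLVNSSQPWEPLQLHVDKAVSGLRSLTTLLRALGAQK",
    "EAISPPDAASAAPLRTITADTFRKLFRVYSNFLRGKLKLYTGEACRTGD"
  )
}

#' Modification-site isoform
#'
#' One possible state of a modification site: a glycan composition (or a raw
#' mass delta for non-glycan modifications) together with its raw abundance,
#' typically an extracted-ion-chromatogram (XIC) area in arbitrary units.
#' The unmodified state is an isoform of mass 0.
#'
#' @param label isoform label, unique within its site.
#' @param composition a [glycan_composition()] / string, or `NULL` when
#'   `delta_da` is given directly.
#' @param abundance raw abundance (>= 0).
#' @param delta_da raw mass delta in Da (used when `composition` is NULL).
#' @return object of class `mod_isoform`.
#' @export
mod_isoform <- function(label, composition = NULL, abundance = 1,
                        delta_da = NULL) {
  stopifnot(is.character(label), length(label) == 1L, abundance >= 0)
  if (!is.null(composition)) {
    composition <- as_glycan_composition(composition)
    if (!is.null(delta_da))
      stop("give either a composition or a raw delta_da, not both")
  } else if (is.null(delta_da)) {
    composition <- glycan_composition()  # unmodified
  }
  structure(list(label = label, composition = composition,
                 delta_da = delta_da, abundance = abundance),
            class = "mod_isoform")
}

.isoform_mass <- function(iso, table = monosaccharide_masses()) {
  if (!is.null(iso$delta_da)) return(iso$delta_da)
  composition_mass(iso$composition, table)
}

#' Modification-site table
#'
#' The set of isoforms observed at one modification site (including the
#' unoccupied state where seen), with their raw abundances.
#'
#' @param site_id site label, e.g. `"N24"`.
#' @param isoforms list of [mod_isoform()] objects (k >= 1).
#' @param kind site kind: `"N"`, `"O"`, `"C"` (C-mannosylation) or
#'   `"other"`; used by the in-silico enzyme transforms.
#' @return object of class `site_table`.
#' @export
site_table <- function(site_id, isoforms, kind = c("N", "O", "C", "other")) {
  kind <- match.arg(kind)
  stopifnot(length(isoforms) >= 1L)
  if (!all(vapply(isoforms, inherits, logical(1), "mod_isoform")))
    stop("isoforms must be mod_isoform objects")
  labels <- vapply(isoforms, `[[`, character(1), "label")
  if (anyDuplicated(labels))
    stop("duplicate isoform labels in site ", site_id)
  ab <- vapply(isoforms, `[[`, numeric(1), "abundance")
  if (all(ab <= 0))
    stop("site ", site_id, " has no isoform with positive abundance")
  structure(list(site_id = site_id, kind = kind, isoforms = isoforms),
            class = "site_table")
}

#' Normalize site abundances to fractions
#'
#' Converts the raw (XIC-area) abundances of a site's isoforms into
#' normalized relative abundances P_ij = A_ij / sum_j A_ij, which sum to 1.
#'
#' @param site a [site_table()].
#' @return numeric vector of fractions, one per isoform.
#' @export
normalize_site <- function(site) {
  stopifnot(inherits(site, "site_table"))
  a <- vapply(site$isoforms, `[[`, numeric(1), "abundance")
  s <- sum(a)
  if (s <= 0) stop("degenerate site: all abundances are zero")
  a / s
}

#' Protein model: backbone plus independent modification sites
#'
#' @param name protein name.
#' @param backbone_mass polypeptide mass in Da (after disulfide correction).
#' @param sites list of [site_table()] objects.
#' @return object of class `protein_model`.
#' @export
protein_model <- function(name, backbone_mass, sites = list()) {
  stopifnot(is.numeric(backbone_mass), backbone_mass > 0)
  if (!all(vapply(sites, inherits, logical(1), "site_table")))
    stop("sites must be site_table objects")
  ids <- vapply(sites, `[[`, character(1), "site_id")
  if (anyDuplicated(ids)) stop("duplicate site ids")
  structure(list(name = name, backbone_mass = backbone_mass, sites = sites),
            class = "protein_model")
}

#' @export
print.protein_model <- function(x, ...) {
  k <- vapply(x$sites, function(s) length(s$isoforms), integer(1))
  cat(sprintf("<protein model> %s\n  backbone: %.2f Da\n  %d site(s): %s\n",
              x$name, x$backbone_mass, length(x$sites),
              paste(sprintf("%s[%d]",
                            vapply(x$sites, `[[`, character(1), "site_id"), k),
                    collapse = " ")))
  invisible(x)
}

#' @export
print.site_table <- function(x, ...) {
  cat(sprintf("<site table> %s (%s-linked), %d isoform(s)\n",
              x$site_id, x$kind, length(x$isoforms)))
  p <- normalize_site(x)
  for (i in seq_along(x$isoforms)) {
    iso <- x$isoforms[[i]]
    cat(sprintf("  %-18s %10.4f Da  P=%.4f\n", iso$label,
                .isoform_mass(iso), p[i]))
  }
  invisible(x)
}
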