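# merge isoforms that became identical after an enzyme transform,
# summing abundances; keeps the first label encountered
.merge_identical_isoforms <- function(isoforms) {
  keys <- vapply(isoforms, function(iso) {
    if (!is.null(iso$delta_da)) sprintf("raw:%.6f", iso$delta_da)
    else paste0("comp:", format_composition(iso$composition))
  }, character(1))
  out <- list()
  for (i in seq_along(isoforms)) {
    k <- keys[i]
    if (is.null(out[[k]])) out[[k]] <- isoforms[[i]]
    else out[[k]]$abundance <- out[[k]]$abundance + isoforms[[i]]$abundance
  }
  unname(out)
}

#' In-silico sialidase treatment
#'
#' Removes all sialic-acid residues from every isoform of every site:
#' Sia and NeuGc counts are set to zero, along with the Acetyl and Hydroxyl
#' blocks that ride on sialic acids (O-acetylation and the NeuAc-to-NeuGc
#' hydroxyl). Isoforms that become identical are merged by summing their
#' abundances. Raw-mass isoforms carry no composition and pass through
#' unchanged with a warning.
#'
#' @param protein a [protein_model()].
#' @return the desialylated [protein_model()].
#' @export
apply_sialidase <- function(protein) {
  stopifnot(inherits(protein, "protein_model"))
  strip <- c("Sia", "NeuGc", "Acetyl", "Hydroxyl")
  warned <- FALSE
  sites <- lapply(protein$sites, function(site) {
    isoforms <- lapply(site$isoforms, function(iso) {
      if (!is.null(iso$delta_da)) {
        if (!warned) {
          warning("raw-mass isoforms are not desialylated (no composition)")
          warned <<- TRUE
        }
        return(iso)
      }
      cnt <- stats::setNames(as.integer(iso$composition),
                             names(iso$composition))
      cnt <- cnt[!(names(cnt) %in% strip)]
      iso$composition <- glycan_composition(cnt)
      iso
    })
    site$isoforms <- .merge_identical_isoforms(isoforms)
    site
  })
  protein_model(paste0(protein$name, "+sialidase"),
                protein$backbone_mass, sites)
}

#' In-silico PNGase F treatment
#'
#' Removes the N-glycans: every N-linked site loses its glycan isoforms.
#' PNGase F cleaves the glycan from asparagine and converts that asparagine
#' to aspartate, so with `deamidation_shift = TRUE` (default) the occupied
#' fraction of each N-site is left as a +0.9840 Da isoform; the unoccupied
#' fraction (if the site had an unmodified isoform) stays at 0 Da. With the
#' flag off every N-site collapses to a single unmodified isoform.
#'
#' @param protein a [protein_model()]; site kinds must be annotated
#'   ("N"/"O"/"C"/"other").
#' @param deamidation_shift apply the Asn-to-Asp +0.9840 Da shift to the
#'   occupied fraction of each cleaved N-site.
#' @return the de-N-glycosylated [protein_model()].
#' @export
apply_pngasef <- function(protein, deamidation_shift = TRUE) {
  stopifnot(inherits(protein, "protein_model"))
  deamidation_da <- 0.9840
  sites <- lapply(protein$sites, function(site) {
    if (site$kind != "N") return(site)
    masses <- vapply(site$isoforms, .isoform_mass, numeric(1))
    ab <- vapply(site$isoforms, `[[`, numeric(1), "abundance")
    occupied <- masses > 1e-9
    a_occ <- sum(ab[occupied])
    a_un <- sum(ab[!occupied])
    if (!deamidation_shift || a_occ == 0) {
      site$isoforms <- list(mod_isoform("unmodified", abundance = sum(ab)))
    } else if (a_un == 0) {
      site$isoforms <- list(mod_isoform("deamidated",
                                        delta_da = deamidation_da,
                                        abundance = a_occ))
    } else {
      site$isoforms <- list(
        mod_isoform("unmodified", abundance = a_un),
        mod_isoform("deamidated", delta_da = deamidation_da,
                    abundance = a_occ))
    }
    site
  })
  protein_model(paste0(protein$name, "+PNGaseF"),
                protein$backbone_mass, sites)
}
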