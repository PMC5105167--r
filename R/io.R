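#' Read a site table file into a protein model
#'
#' The site-table format is delimited text with header
#' `protein,site,kind,isoform_label,composition,abundance`; one row per
#' isoform, sites grouped by their `site` id in order of first appearance.
#' An empty `composition` field is the unmodified isoform (mass 0); a field
#' of the form `delta:123.45` injects a raw mass delta in Da.
#'
#' @param path file path (CSV).
#' @param backbone_mass backbone mass in Da (not stored in the file).
#' @param name protein name; defaults to the file's `protein` column.
#' @return a [protein_model()].
#' @export
read_site_table <- function(path, backbone_mass, name = NULL) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  req <- c("protein", "site", "kind", "isoform_label", "composition",
           "abundance")
  if (!identical(names(tab)[seq_along(req)], req))
    stop("site table must have header: ", paste(req, collapse = ","))
  ab <- suppressWarnings(as.numeric(tab$abundance))
  if (anyNA(ab))
    stop("non-numeric abundance at line ", which(is.na(ab))[1] + 1L)
  if (anyDuplicated(paste(tab$site, tab$isoform_label)))
    stop("duplicate (site, isoform_label) pair in ", path)
  if (is.null(name)) name <- tab$protein[1]
  sites <- lapply(unique(tab$site), function(sid) {
    rows <- which(tab$site == sid)
    kind <- tab$kind[rows[1]]
    if (!(kind %in% c("N", "O", "C"))) kind <- "other"
    isoforms <- lapply(rows, function(i) {
      comp_txt <- trimws(tab$composition[i])
      if (startsWith(comp_txt, "delta:")) {
        mod_isoform(tab$isoform_label[i],
                    delta_da = as.numeric(sub("^delta:", "", comp_txt)),
                    abundance = ab[i])
      } else {
        mod_isoform(tab$isoform_label[i], parse_composition(comp_txt),
                    abundance = ab[i])
      }
    })
    site_table(sid, isoforms, kind = kind)
  })
  protein_model(name, backbone_mass, sites)
}

#' Write a protein model's site tables to file
#'
#' Inverse of [read_site_table()] (the backbone mass is not stored).
#'
#' @param protein a [protein_model()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_site_table <- function(protein, path) {
  stopifnot(inherits(protein, "protein_model"))
  rows <- do.call(rbind, lapply(protein$sites, function(site) {
    do.call(rbind, lapply(site$isoforms, function(iso) {
      comp <- if (!is.null(iso$delta_da))
        sprintf("delta:%.6f", iso$delta_da)
      else format_composition(iso$composition)
      data.frame(protein = protein$name, site = site$site_id,
                 kind = site$kind, isoform_label = iso$label,
                 composition = comp, abundance = iso$abundance)
    }))
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a spectrum from file
#'
#' Two-column delimited text (whitespace or comma; optional header) gives
#' m/z and intensity; mzML is read through the mzR package when installed.
#' Points are sorted; exact-duplicate positions are summed with a warning.
#' Mode is detected as profile when the points form a dense, near-uniform
#' grid.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"txt"` or `"mzml"`.
#' @return an [mz_spectrum()].
#' @export
read_spectrum <- function(path, format = c("auto", "txt", "mzml")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.mzml$", path, ignore.case = TRUE)) "mzml"
              else "txt"
  if (format == "mzml") {
    if (!requireNamespace("mzR", quietly = TRUE))
      stop("reading mzML requires the mzR package")
    handle <- mzR::openMSfile(path)
    on.exit(mzR::close(handle))
    pk <- mzR::peaks(handle, 1)
    mat <- as.matrix(pk)
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) stop("empty spectrum file: ", path)
    lines <- gsub(",", " ", lines)
    first <- strsplit(trimws(lines[1]), "\\s+")[[1]]
    if (suppressWarnings(anyNA(as.numeric(first)))) lines <- lines[-1]
    if (length(lines) == 0L) stop("empty spectrum file: ", path)
    fields <- strsplit(trimws(lines), "\\s+")
    if (any(vapply(fields, length, integer(1)) < 2L))
      stop("spectrum rows must have two columns (m/z, intensity)")
    mat <- cbind(as.numeric(vapply(fields, `[[`, character(1), 1)),
                 as.numeric(vapply(fields, `[[`, character(1), 2)))
    if (anyNA(mat)) stop("non-numeric value in spectrum file ", path)
  }
  mz <- mat[, 1]; int <- mat[, 2]
  if (is.unsorted(mz)) {
    ord <- order(mz); mz <- mz[ord]; int <- int[ord]
  }
  if (anyDuplicated(mz)) {
    warning("duplicate m/z values summed in ", path)
    int <- as.numeric(tapply(int, mz, sum))
    mz <- sort(unique(mz))
  }
  steps <- diff(mz)
  mode <- if (length(mz) >= 50L && length(steps) > 0L &&
              stats::sd(steps) < 0.01 * mean(steps)) "profile"
          else "centroid"
  mz_spectrum(mz, int, mode = mode)
}

#' Write a spectrum to two-column text
#'
#' @param spec an [mz_spectrum()] or [zero_charge_spectrum()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spec, path) {
  pts <- .as_points(spec)
  utils::write.table(data.frame(pts$pos, pts$intensity), path,
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(path)
}
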