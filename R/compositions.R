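#' Default monosaccharide / small-modification residue mass table
#'
#' Average residue masses (Da) of the building blocks used for intact-protein
#' PTM mass arithmetic: hexose (Hex; also Man/Gal), N-acetylhexosamine
#' (HexNAc; also GlcNAc), deoxyhexose (Fuc; also dHex), N-acetylneuraminic
#' acid (Sia; also Neu5Ac/NeuAc), N-glycolylneuraminic acid (NeuGc; also
#' Neu5Gc), phosphorylation (Pho), O-acetylation (Acetyl) and the
#' -CH3 to -CH2OH replacement (Hydroxyl) that converts NeuAc into NeuGc.
#' Average (not monoisotopic) masses are the appropriate scale for native MS
#' of intact glycoproteins, where isotope envelopes are unresolved.
#'
#' NeuGc can be written either as its own building block (307.2573 Da) or as
#' Sia + Hydroxyl (291.2579 + 15.9994); the two encodings have identical mass
#' and both are accepted.
#'
#' @param file optional path to a delimited text file (columns `name`,
#'   `mass_da`, header required) overriding the default table, e.g. to use
#'   monoisotopic variants.
#' @return named numeric vector of residue masses in Da.
#' @export
#' @examples
#' monosaccharide_masses()[["Hex"]]
monosaccharide_masses <- function(file = NULL) {
  if (is.null(file)) {
    return(c(
      Hex      = 162.1424,
      HexNAc   = 203.1950,
      Fuc      = 146.1430,
      Sia      = 291.2579,
      NeuGc    = 307.2573,
      Pho      = 79.9799,
      Acetyl   = 42.0373,
      Hydroxyl = 15.9994
    ))
  }
  tab <- utils::read.table(file, header = TRUE, sep = "",
                           stringsAsFactors = FALSE)
  if (ncol(tab) == 1L)  # comma-delimited fallback
    tab <- utils::read.csv(file, stringsAsFactors = FALSE)
  if (!all(c("name", "mass_da") %in% names(tab)))
    stop("residue table must have columns 'name' and 'mass_da'")
  masses <- as.numeric(tab$mass_da)
  if (anyNA(masses) || any(masses <= 0))
    stop("residue masses must be positive numbers")
  if (anyDuplicated(tab$name))
    stop("duplicate building-block names in residue table")
  stats::setNames(masses, tab$name)
}

# synonyms accepted on input; canonical name on the right
.block_aliases <- c(
  dHex   = "Fuc",
  Neu5Ac = "Sia",
  NeuAc  = "Sia",
  Neu5Gc = "NeuGc",
  Man    = "Hex",
  Gal    = "Hex",
  GlcNAc = "HexNAc",
  GalNAc = "HexNAc"
)

# canonical ordering for formatted output (stable for diffing)
.block_order <- c("Hex", "HexNAc", "Fuc", "Sia", "NeuGc",
                  "Hydroxyl", "Acetyl", "Pho")

.canonical_block <- function(name) {
  ifelse(name %in% names(.block_aliases), .block_aliases[name], name)
}

#' Create a glycan composition
#'
#' A glycan composition is a bag of building blocks: a named non-negative
#' integer count vector. Zero counts are dropped and names are put in
#' canonical order, so two compositions with equal counts are `identical()`.
#'
#' @param counts named integer vector (or empty for the null composition);
#'   alias names (dHex, Neu5Ac, Neu5Gc, Man, Gal, GlcNAc, GalNAc) are mapped
#'   to their canonical block.
#' @return object of class `glycan_composition`.
#' @export
glycan_composition <- function(counts = integer()) {
  if (length(counts) == 0L) {
    out <- integer()
    class(out) <- "glycan_composition"
    return(out)
  }
  if (is.null(names(counts)) || any(names(counts) == ""))
    stop("composition counts must be named")
  if (any(counts < 0)) stop("composition counts must be non-negative")
  nm <- .canonical_block(names(counts))
  counts <- as.integer(counts)
  agg <- tapply(counts, nm, sum)
  agg <- agg[agg > 0L]
  ord <- order(match(names(agg), .block_order, nomatch = length(.block_order) + 1L),
               names(agg))
  out <- as.integer(agg[ord])
  names(out) <- names(agg)[ord]
  class(out) <- "glycan_composition"
  out
}

#' Parse a glycan composition string
#'
#' Accepts the concatenated `Name<count>` notation used to annotate intact
#' glycoprotein spectra (e.g. `"Hex22HexNAc19Fuc3Sia13"`) as well as the
#' `Name(count)` dialect (`"HexNAc(2)Hex(5)"`). A missing count means 1.
#' The empty string is the empty (unmodified) composition.
#'
#' @param text composition string.
#' @param table residue mass table; its names (plus the standard aliases)
#'   define the accepted building-block vocabulary.
#' @return a [glycan_composition()].
#' @export
#' @examples
#' parse_composition("Hex22HexNAc19Fuc3Sia13")
parse_composition <- function(text, table = monosaccharide_masses()) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  if (nchar(text) == 0L) return(glycan_composition())
  vocab <- unique(c(names(table), names(.block_aliases)))
  # longest-first so e.g. "HexNAc" wins over "Hex"
  vocab <- vocab[order(-nchar(vocab))]
  names_out <- character()
  counts_out <- integer()
  pos <- 1L
  n <- nchar(text)
  while (pos <= n) {
    rest <- substr(text, pos, n)
    hit <- NA_character_
    for (v in vocab) {
      if (startsWith(rest, v)) { hit <- v; break }
    }
    if (is.na(hit)) {
      bad <- sub("([A-Za-z][a-z0-9]*).*", "\\1", rest)
      stop(sprintf("unknown building-block name at position %d: '%s'",
                   pos, bad))
    }
    pos <- pos + nchar(hit)
    rest <- substr(text, pos, n)
    cnt <- 1L
    m <- regmatches(rest, regexpr("^\\((\\d+)\\)|^\\d+", rest))
    if (length(m) == 1L && nchar(m) > 0L) {
      cnt <- as.integer(gsub("[()]", "", m))
      pos <- pos + nchar(m)
    }
    names_out <- c(names_out, hit)
    counts_out <- c(counts_out, cnt)
  }
  glycan_composition(stats::setNames(counts_out, names_out))
}

#' Format a glycan composition as a canonical string
#'
#' Inverse of [parse_composition()]: blocks in canonical order
#' (Hex, HexNAc, Fuc, Sia, NeuGc, Hydroxyl, Acetyl, Pho, then others),
#' each followed by its count.
#'
#' @param comp a [glycan_composition()].
#' @return character scalar; `""` for the empty composition.
#' @export
format_composition <- function(comp) {
  comp <- as_glycan_composition(comp)
  if (length(comp) == 0L) return("")
  paste0(names(comp), as.integer(comp), collapse = "")
}

#' @export
print.glycan_composition <- function(x, ...) {
  txt <- format_composition(x)
  cat("<glycan composition> ", if (nzchar(txt)) txt else "(empty)", "\n",
      sep = "")
  invisible(x)
}

#' Coerce to glycan composition
#' @param x a `glycan_composition`, a named count vector, or a string.
#' @return a [glycan_composition()].
#' @export
as_glycan_composition <- function(x) {
  if (inherits(x, "glycan_composition")) return(x)
  if (is.character(x)) return(parse_composition(x))
  if (is.numeric(x)) return(glycan_composition(x))
  stop("cannot coerce to glycan_composition")
}

#' @export
`+.glycan_composition` <- function(e1, e2) {
  e1 <- as_glycan_composition(e1); e2 <- as_glycan_composition(e2)
  glycan_composition(c(stats::setNames(as.integer(e1), names(e1)),
                       stats::setNames(as.integer(e2), names(e2))))
}

#' Average mass of a glycan composition
#'
#' Sum of count times residue mass over all building blocks; additive in the
#' composition, zero for the empty composition.
#'
#' @param comp a [glycan_composition()] (or string / named counts).
#' @param table residue mass table from [monosaccharide_masses()].
#' @return mass in Da.
#' @export
#' @examples
#' composition_mass(parse_composition("Hex22HexNAc19Fuc3Sia13"))
composition_mass <- function(comp, table = monosaccharide_masses()) {
  comp <- as_glycan_composition(comp)
  if (length(comp) == 0L) return(0)
  missing <- setdiff(names(comp), names(table))
  if (length(missing) > 0L)
    stop("no residue mass for: ", paste(missing, collapse = ", "))
  sum(as.integer(comp) * table[names(comp)])
}
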