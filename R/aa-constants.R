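## Physical constants and chemistry tables.
##
## Residue masses and modification deltas are shipped as plain-text tables
## under inst/extdata and parsed once per session; elemental isotope
## abundances are frozen here as package constants so that theoretical
## envelopes are bit-reproducible across platforms.

#' @keywords internal
VALID_RESIDUES <- c("G", "A", "S", "P", "V", "T", "C", "L", "I", "N",
                    "D", "Q", "K", "E", "M", "H", "F", "R", "Y", "W")

## Residues considered basic (side chains); the free N-terminal amine is
## counted separately.
#' @keywords internal
BASIC_RESIDUES <- c("R", "K", "H")

#' @keywords internal
NON_BASIC_RESIDUES <- setdiff(VALID_RESIDUES, BASIC_RESIDUES)

#' @keywords internal
PROTON_MASS <- 1.007276

#' @keywords internal
WATER_MASS <- 18.010565

## C13 - C12 mass difference, used as the isotope peak spacing for all
## offsets (carbon dominates peptide isotope patterns; a single spacing
## matches centroided-data precision).
#' @keywords internal
ISOTOPE_SPACING <- 1.0033548

## Natural isotope abundances by integer mass offset from the monoisotope.
## Sulfur's 36S sits at offset 4 (no stable 35S), hence the explicit zero.
.ELEMENT_ISOTOPES <- list(
  C = c(0.9893, 0.0107),
  H = c(0.999885, 0.000115),
  N = c(0.99636, 0.00364),
  O = c(0.99757, 0.00038, 0.00205),
  S = c(0.9499, 0.0075, 0.0425, 0.0000, 0.0001)
)

.pepcsd_cache <- new.env(parent = emptyenv())

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "pepcsd")
  if (!nzchar(path)) stop("missing packaged data file: ", file)
  path
}

#' Amino-acid residue table
#'
#' Monoisotopic residue masses and CHNOS elemental compositions for the 20
#' standard amino acids, as shipped with the package.
#'
#' @return A data frame with one row per residue letter.
#' @export
amino_acid_table <- function() {
  if (is.null(.pepcsd_cache$aa)) {
    tab <- utils::read.delim(.extdata("amino_acids.tsv"),
                             stringsAsFactors = FALSE)
    rownames(tab) <- tab$aa
    .pepcsd_cache$aa <- tab
  }
  .pepcsd_cache$aa
}

#' Modification table
#'
#' Supported fixed and variable modifications, named in MaxQuant convention,
#' with their monoisotopic mass deltas and elemental composition deltas.
#'
#' @return A data frame with one row per modification.
#' @export
modification_table <- function() {
  if (is.null(.pepcsd_cache$mods)) {
    tab <- utils::read.delim(.extdata("modifications.tsv"),
                             stringsAsFactors = FALSE)
    rownames(tab) <- tab$name
    .pepcsd_cache$mods <- tab
  }
  .pepcsd_cache$mods
}

## Residue masses as a named vector (internal convenience).
.aa_masses <- function() {
  tab <- amino_acid_table()
  stats::setNames(tab$monoisotopic_mass, tab$aa)
}

.mod_row <- function(kind_name) {
  tab <- modification_table()
  i <- match(kind_name, rownames(tab))
  if (is.na(i)) stop("unknown modification: '", kind_name, "'")
  tab[i, , drop = FALSE]
}

## Run a block with a private RNG stream; leaves the caller's stream intact.
## seed = NULL means use (and advance) the current stream.
.with_seed <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}
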