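## Peptide sequence chemistry: masses, elemental composition, basic-site
## counting, theoretical isotope envelopes and ion m/z arithmetic.

#' Construct a peptide record
#'
#' A peptide record bundles a sequence over the 20 standard amino-acid
#' letters with its fixed cysteine modification and variable modifications,
#' and carries the derived monoisotopic mass and basic-site count. The
#' basic-site count is 1 (the N-terminal amine) plus the number of R, K and
#' H residues; by default the N-terminus still counts when acetylated (see
#' `count_nterm_when_acetylated`).
#'
#' @param sequence Character scalar, residues from the 20 standard letters.
#' @param fixed_cys_mod One of `"carbamidomethyl"`, `"n_ethylmaleimide"`,
#'   `"none"`; applied to every cysteine.
#' @param oxidation_sites Integer vector of methionine positions carrying
#'   Oxidation (M). Use `NA` entries if sites are unknown (e.g. parsed from
#'   an evidence table that reports only a count); only the count affects
#'   mass.
#' @param nterm_acetyl Logical, Acetyl (Protein N-term) present.
#' @param count_nterm_when_acetylated Logical; whether the N-terminal amine
#'   is still counted as a basic site when acetylated. Default `TRUE`.
#' @return An object of class `peptide_record`.
#' @examples
#' p <- peptide("TNSTFNQVVLKR")
#' p$basic_site_count  # 3: N-terminus + K + R
#' @export
peptide <- function(sequence,
                    fixed_cys_mod = c("carbamidomethyl", "n_ethylmaleimide",
                                      "none"),
                    oxidation_sites = integer(0),
                    nterm_acetyl = FALSE,
                    count_nterm_when_acetylated = TRUE) {
  fixed_cys_mod <- match.arg(fixed_cys_mod)
  stopifnot(is.character(sequence), length(sequence) == 1L)
  residues <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- setdiff(residues, VALID_RESIDUES)
  if (length(bad) > 0) {
    stop("invalid residue letter(s) in sequence: ",
         paste(unique(bad), collapse = ", "))
  }
  if (length(residues) < 1L) stop("empty sequence")
  n_ox <- length(oxidation_sites)
  known_sites <- oxidation_sites[!is.na(oxidation_sites)]
  if (length(known_sites) > 0) {
    if (any(known_sites < 1L | known_sites > length(residues))) {
      stop("oxidation site outside sequence")
    }
    if (any(residues[known_sites] != "M")) {
      stop("oxidation site is not a methionine")
    }
  }
  rec <- structure(
    list(sequence = sequence,
         residues = residues,
         fixed_cys_mod = fixed_cys_mod,
         oxidation_sites = oxidation_sites,
         n_oxidation = n_ox,
         nterm_acetyl = isTRUE(nterm_acetyl),
         count_nterm_when_acetylated = isTRUE(count_nterm_when_acetylated)),
    class = "peptide_record")
  rec$monoisotopic_mass <- monoisotopic_mass(rec)
  rec$basic_site_count <- count_basic_sites(rec)
  rec
}

#' @export
print.peptide_record <- function(x, ...) {
  mods <- c(if (x$fixed_cys_mod != "none" && any(x$residues == "C"))
              x$fixed_cys_mod,
            if (x$n_oxidation > 0) sprintf("%dx oxidation (M)", x$n_oxidation),
            if (x$nterm_acetyl) "N-term acetyl")
  cat(sprintf("<peptide> %s  mass=%.4f Da  basic sites=%d%s\n",
              x$sequence, x$monoisotopic_mass, x$basic_site_count,
              if (length(mods)) paste0("  [", paste(mods, collapse = ", "), "]")
              else ""))
  invisible(x)
}

#' Does a peptide carry variable modifications?
#' @param peptide A `peptide_record`.
#' @return Logical scalar.
#' @export
has_variable_mods <- function(peptide) {
  peptide$n_oxidation > 0 || peptide$nterm_acetyl
}

#' Count basic sites
#'
#' Number of protonatable basic positions: the N-terminal amine plus one per
#' arginine, lysine or histidine residue. Controls the naive charge
#' expectation for a peptide in positive-ion electrospray.
#'
#' @param peptide A `peptide_record` or a plain sequence string.
#' @return Integer >= 1 (>= 0 if an acetylated N-terminus is configured not
#'   to count).
#' @examples
#' count_basic_sites("TNSTFNQVVLKR")  # 3
#' count_basic_sites("ASGQAFELILSPR") # 2
#' @export
count_basic_sites <- function(peptide) {
  if (is.character(peptide)) peptide <- pepcsd::peptide(peptide)
  side <- sum(peptide$residues %in% BASIC_RESIDUES)
  nterm <- if (peptide$nterm_acetyl && !peptide$count_nterm_when_acetylated)
    0L else 1L
  as.integer(side + nterm)
}

#' Monoisotopic peptide mass
#'
#' Sum of residue monoisotopic masses plus one water, plus fixed and
#' variable modification deltas.
#'
#' @param peptide A `peptide_record` or sequence string.
#' @return Mass in Da.
#' @examples
#' monoisotopic_mass("PEPTIDE")  # 799.3600
#' @export
monoisotopic_mass <- function(peptide) {
  if (is.character(peptide)) peptide <- pepcsd::peptide(peptide)
  masses <- .aa_masses()
  m <- sum(masses[peptide$residues]) + WATER_MASS
  n_cys <- sum(peptide$residues == "C")
  if (n_cys > 0 && peptide$fixed_cys_mod != "none") {
    mod_name <- switch(peptide$fixed_cys_mod,
                       carbamidomethyl = "Carbamidomethyl (C)",
                       n_ethylmaleimide = "N-ethylmaleimide (C)")
    m <- m + n_cys * .mod_row(mod_name)$monoisotopic_delta
  }
  if (peptide$n_oxidation > 0) {
    m <- m + peptide$n_oxidation * .mod_row("Oxidation (M)")$monoisotopic_delta
  }
  if (peptide$nterm_acetyl) {
    m <- m + .mod_row("Acetyl (Protein N-term)")$monoisotopic_delta
  }
  unname(m)
}

#' Elemental composition of a peptide
#'
#' CHNOS atom counts including water and modifications. Drives the isotope
#' envelope computation.
#'
#' @param peptide A `peptide_record` or sequence string.
#' @return Named integer vector with elements C, H, N, O, S.
#' @export
elemental_composition <- function(peptide) {
  if (is.character(peptide)) peptide <- pepcsd::peptide(peptide)
  aa <- amino_acid_table()
  elems <- c("C", "H", "N", "O", "S")
  counts <- colSums(aa[peptide$residues, elems, drop = FALSE])
  counts["H"] <- counts["H"] + 2  # water
  counts["O"] <- counts["O"] + 1
  add_mod <- function(name, times = 1L) {
    row <- .mod_row(name)
    counts[elems] + times * unlist(row[elems])
  }
  n_cys <- sum(peptide$residues == "C")
  if (n_cys > 0 && peptide$fixed_cys_mod != "none") {
    mod_name <- switch(peptide$fixed_cys_mod,
                       carbamidomethyl = "Carbamidomethyl (C)",
                       n_ethylmaleimide = "N-ethylmaleimide (C)")
    counts <- add_mod(mod_name, n_cys)
  }
  if (peptide$n_oxidation > 0) counts <- add_mod("Oxidation (M)",
                                                 peptide$n_oxidation)
  if (peptide$nterm_acetyl) counts <- add_mod("Acetyl (Protein N-term)")
  stats::setNames(as.integer(round(counts)), elems)
}

## Distribution of the isotope-offset sum for n atoms of one element:
## the single-atom offset distribution convolved n times, computed by
## binary exponentiation with tail truncation.
.element_offset_dist <- function(single, n, tail_tol = 1e-12) {
  if (n == 0) return(1)
  acc <- 1
  base <- single
  while (n > 0) {
    if (n %% 2 == 1) acc <- .conv_trunc(acc, base, tail_tol)
    n <- n %/% 2
    if (n > 0) base <- .conv_trunc(base, base, tail_tol)
  }
  acc
}

.conv_trunc <- function(a, b, tail_tol) {
  out <- stats::convolve(a, rev(b), type = "open")
  out[out < 0] <- 0  # FFT round-off
  ## drop a negligible high-offset tail to keep vectors short
  keep <- max(which(out > tail_tol * max(out)))
  out[seq_len(keep)]
}

#' Theoretical isotope envelope
#'
#' Aggregated isotope distribution of a peptide on integer isotope offsets
#' 0, 1, 2, ..., obtained by convolving the natural isotope distributions of
#' C, H, N, O and S according to the peptide's elemental composition
#' (isotope fine structure is collapsed onto integer offsets). The envelope
#' is truncated at the given cumulative coverage and renormalized to sum
#' to 1.
#'
#' @param peptide A `peptide_record`, sequence string, or named CHNOS count
#'   vector.
#' @param coverage Minimum cumulative abundance retained before
#'   renormalization (default 0.999).
#' @return An object of class `isotope_envelope`: list with
#'   `relative_abundances` (sums to 1) and `isotope_spacing` (Da).
#' @export
isotope_envelope <- function(peptide, coverage = 0.999) {
  stopifnot(coverage > 0, coverage <= 1)
  counts <- if (is.numeric(peptide)) {
    stopifnot(all(c("C", "H", "N", "O", "S") %in% names(peptide)))
    peptide[c("C", "H", "N", "O", "S")]
  } else {
    elemental_composition(peptide)
  }
  if (any(counts < 0)) stop("negative atom count")
  dist <- 1
  for (el in names(.ELEMENT_ISOTOPES)) {
    dist <- .conv_trunc(dist,
                        .element_offset_dist(.ELEMENT_ISOTOPES[[el]],
                                             counts[[el]]),
                        1e-12)
  }
  dist <- dist / sum(dist)
  n_keep <- which(cumsum(dist) >= coverage)[1]
  ab <- dist[seq_len(n_keep)]
  ab <- ab / sum(ab)
  structure(list(relative_abundances = ab,
                 isotope_spacing = ISOTOPE_SPACING),
            class = "isotope_envelope")
}

#' m/z of a peptide ion
#'
#' @param mass Neutral monoisotopic mass (Da).
#' @param charge Positive integer charge 1..5.
#' @param isotope_offset Integer isotope offset (0 = monoisotope).
#' @param spacing Isotope spacing in Da (default the C13-C12 difference).
#' @return m/z value(s); vectorized over any argument.
#' @examples
#' ion_mz(1600, 2)  # 801.007
#' @export
ion_mz <- function(mass, charge, isotope_offset = 0,
                   spacing = ISOTOPE_SPACING) {
  if (any(charge < 1)) stop("charge must be >= 1")
  (mass + isotope_offset * spacing + charge * PROTON_MASS) / charge
}
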