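# Shared fixtures: all synthetic, built in code at test time.

pcols <- paste0("p", 1:5)

# random CSDs via normalized Gamma draws (Dirichlet)
random_csds <- function(n, alpha = rep(1, 5)) {
  m <- matrix(stats::rgamma(n * 5, shape = alpha), ncol = 5, byrow = TRUE)
  m / rowSums(m)
}

# Independent brute-force isotope envelope oracle: convolves the
# single-atom offset distribution one atom at a time (naive O(n*k) loop,
# no binary exponentiation, no FFT).
oracle_envelope <- function(counts, coverage = 0.999) {
  iso <- list(C = c(0.9893, 0.0107),
              H = c(0.999885, 0.000115),
              N = c(0.99636, 0.00364),
              O = c(0.99757, 0.00038, 0.00205),
              S = c(0.9499, 0.0075, 0.0425, 0, 0.0001))
  conv <- function(a, b) {
    out <- rep(0, length(a) + length(b) - 1)
    for (i in seq_along(a)) {
      for (j in seq_along(b)) out[i + j - 1] <- out[i + j - 1] + a[i] * b[j]
    }
    out
  }
  dist <- 1
  for (el in names(iso)) {
    n <- counts[[el]]
    if (n == 0) next
    for (k in seq_len(n)) dist <- conv(dist, iso[[el]])
    dist <- dist[dist > 1e-15 * max(dist)]
  }
  dist <- dist / sum(dist)
  keep <- which(cumsum(dist) >= coverage)[1]
  dist <- dist[seq_len(keep)]
  dist / sum(dist)
}

# Build a centroided scan containing the theoretical envelopes of one
# peptide at the given charges and total intensities (exact positions).
scan_with_envelopes <- function(peptide, charges, intensities,
                                extra_mz = numeric(0),
                                extra_intensity = numeric(0)) {
  if (is.character(peptide)) peptide <- pepcsd::peptide(peptide)
  env <- isotope_envelope(peptide)
  ab <- env$relative_abundances
  mz <- numeric(0); int <- numeric(0)
  for (i in seq_along(charges)) {
    mz <- c(mz, ion_mz(peptide$monoisotopic_mass, charges[i],
                       seq_along(ab) - 1))
    int <- c(int, intensities[i] * ab)
  }
  mz <- c(mz, extra_mz); int <- c(int, extra_intensity)
  o <- order(mz)
  cbind(mz = mz[o], intensity = int[o])
}

# Ground-truth count-coefficient vector implied by a charging model on
# one side, in regression feature space (mass is linear in counts, so the
# mass slope folds into each residue's coefficient via its mass; cysteine
# carries its fixed modification).
implied_count_coefficients <- function(model, side = c("under", "over")) {
  side <- match.arg(side)
  aa <- amino_acid_table()
  masses <- stats::setNames(aa$monoisotopic_mass, aa$aa)
  masses["C"] <- masses["C"] + 57.02146
  res <- if (side == "under") model$residue_under else model$residue_over
  res + model$mass_slope * masses[names(res)]
}

region_side <- function(region) {
  if (region$lower_charge + 1 == region$basic_sites) "under" else "over"
}

# merge extracted readings with simulator ground truth and compute
# per-peptide total variation
roundtrip_tv <- function(readings, ground_truth) {
  m <- merge(readings, ground_truth, by = "sequence",
             suffixes = c("", ".gt"))
  tv <- rowSums(abs(as.matrix(m[, pcols]) -
                      as.matrix(m[, paste0(pcols, ".gt")]))) / 2
  data.frame(sequence = m$sequence, tv = tv,
             observable = m$observable, clean = m$clean)
}
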