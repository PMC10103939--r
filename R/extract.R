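## CSD extraction: per-scan, per-charge intensity estimation with three
## presence filters (m/z offset, envelope-shape cosine, chimeric-peak
## absence) and an absence rule, then intensity-weighted aggregation
## across the elution.

#' Extraction configuration
#'
#' Thresholds of the extraction scheme. A charge state is called *present*
#' in a scan only if (i) observed peaks match every compared theoretical
#' isotope position within `mz_tolerance_ppm`, (ii) the cosine similarity
#' between matched intensities and theoretical abundances exceeds
#' `cosine_threshold`, and (iii) no unmatched peak within the envelope's
#' m/z span exceeds `chimeric_intensity_fraction` of the matched base
#' peak. It is called *absent* (intensity 0) when no peak lies within
#' `absence_vicinity_ppm` of any compared position; anything in between is
#' *unconfident* and invalidates the scan for that peptide.
#'
#' @param mz_tolerance_ppm Matching tolerance for isotope peaks (default
#'   10 ppm).
#' @param cosine_threshold Envelope-shape similarity threshold (default
#'   0.98).
#' @param absence_vicinity_ppm Vicinity that must be empty for an absence
#'   call (default 20 ppm).
#' @param chimeric_intensity_fraction Unmatched-peak intensity fraction
#'   (of the matched base peak) that triggers the chimeric flag (default
#'   0.2).
#' @param min_isotope_peaks Minimum number of compared isotope peaks
#'   (default 2).
#' @param compared_coverage Envelope abundance coverage of the compared
#'   prefix (default 0.95).
#' @param rt_window Half-width, in seconds, of the scan window around the
#'   identification (default 30).
#' @param min_scans Minimum number of valid per-scan readings for a
#'   peptide-level CSD (default 1).
#' @param envelope_coverage Coverage of the theoretical envelope itself
#'   (default 0.999).
#' @return A list of class `extraction_config`.
#' @export
extraction_config <- function(mz_tolerance_ppm = 10, cosine_threshold = 0.98,
                              absence_vicinity_ppm = 20,
                              chimeric_intensity_fraction = 0.2,
                              min_isotope_peaks = 2,
                              compared_coverage = 0.95,
                              rt_window = 30, min_scans = 1,
                              envelope_coverage = 0.999) {
  stopifnot(cosine_threshold > 0, cosine_threshold <= 1,
            mz_tolerance_ppm > 0, absence_vicinity_ppm >= mz_tolerance_ppm,
            min_isotope_peaks >= 1, min_scans >= 1)
  structure(list(mz_tolerance_ppm = mz_tolerance_ppm,
                 cosine_threshold = cosine_threshold,
                 absence_vicinity_ppm = absence_vicinity_ppm,
                 chimeric_intensity_fraction = chimeric_intensity_fraction,
                 min_isotope_peaks = min_isotope_peaks,
                 compared_coverage = compared_coverage,
                 rt_window = rt_window, min_scans = min_scans,
                 envelope_coverage = envelope_coverage),
            class = "extraction_config")
}

## Nearest peak index within tol_ppm of each target m/z (NA if none).
.match_nearest <- function(peak_mz, targets, tol_ppm) {
  if (length(peak_mz) == 0) return(rep(NA_integer_, length(targets)))
  i <- findInterval(targets, peak_mz)
  lo <- pmax(i, 1L)
  hi <- pmin(i + 1L, length(peak_mz))
  d_lo <- abs(peak_mz[lo] - targets)
  d_hi <- abs(peak_mz[hi] - targets)
  best <- ifelse(d_lo <= d_hi, lo, hi)
  dist_ppm <- abs(peak_mz[best] - targets) / targets * 1e6
  ifelse(dist_ppm <= tol_ppm, best, NA_integer_)
}

## Internal: precomputed per-peptide envelope data reused across scans.
.envelope_template <- function(peptide, config) {
  env <- isotope_envelope(peptide, coverage = config$envelope_coverage)
  cmp <- .compared_offsets(env, min_n = config$min_isotope_peaks,
                           coverage = config$compared_coverage)
  list(envelope = env, compared = cmp,
       abundances = env$relative_abundances[cmp + 1L],
       mass = peptide$monoisotopic_mass)
}

#' Call one charge state of a peptide in one scan
#'
#' Applies the three presence filters and the absence rule of
#' [extraction_config()] to a centroided scan.
#'
#' @param scan Two-column matrix (`mz`, `intensity`) sorted by m/z.
#' @param peptide A `peptide_record` (or sequence string).
#' @param charge Charge state 1..5.
#' @param config An [extraction_config()].
#' @param mz_min,mz_max Instrument window; a charge whose monoisotopic m/z
#'   falls outside is structurally unobservable (status
#'   `"unobservable"`, excluded from the every-charge confidence
#'   requirement).
#' @return A list (class `charge_call`): `status` (`"present"`,
#'   `"absent"`, `"unconfident"` or `"unobservable"`), `intensity` (sum of
#'   matched intensities; 0 unless present), and `diagnostics`
#'   (`mz_offset_ppm`, `cosine_similarity`, `chimeric_flag`).
#' @export
find_envelope <- function(scan, peptide, charge, config = extraction_config(),
                          mz_min = 300, mz_max = 1800) {
  stopifnot(charge >= 1, charge <= 5)
  if (is.character(peptide)) peptide <- pepcsd::peptide(peptide)
  tmpl <- .envelope_template(peptide, config)
  .find_envelope_impl(scan, tmpl, charge, config, mz_min, mz_max)
}

.find_envelope_impl <- function(scan, tmpl, charge, config, mz_min, mz_max) {
  no_diag <- list(mz_offset_ppm = NA_real_, cosine_similarity = NA_real_,
                  chimeric_flag = FALSE)
  call_out <- function(status, intensity = 0, diagnostics = no_diag) {
    structure(list(status = status, intensity = intensity,
                   diagnostics = diagnostics), class = "charge_call")
  }
  mono_mz <- ion_mz(tmpl$mass, charge, 0)
  if (mono_mz < mz_min || mono_mz > mz_max) return(call_out("unobservable"))
  targets <- ion_mz(tmpl$mass, charge, tmpl$compared)
  peak_mz <- scan[, 1]
  peak_int <- scan[, 2]
  hit <- .match_nearest(peak_mz, targets, config$mz_tolerance_ppm)
  near <- .match_nearest(peak_mz, targets, config$absence_vicinity_ppm)
  if (all(is.na(near))) return(call_out("absent"))
  if (any(is.na(hit))) return(call_out("unconfident"))
  obs <- peak_int[hit]
  theo <- tmpl$abundances
  cosine <- sum(obs * theo) / sqrt(sum(obs^2) * sum(theo^2))
  offs <- abs(peak_mz[hit] - targets) / targets * 1e6
  ## chimeric scan: unmatched peaks inside the envelope span
  span <- range(targets)
  tol <- config$mz_tolerance_ppm * 1e-6 * span
  in_span <- which(peak_mz >= span[1] - tol[1] & peak_mz <= span[2] + tol[2])
  stray <- setdiff(in_span, hit)
  chimeric <- length(stray) > 0 &&
    max(peak_int[stray]) >
      config$chimeric_intensity_fraction * max(obs)
  diag <- list(mz_offset_ppm = max(offs), cosine_similarity = cosine,
               chimeric_flag = chimeric)
  if (chimeric || cosine <= config$cosine_threshold) {
    return(call_out("unconfident", 0, diag))
  }
  call_out("present", sum(obs), diag)
}

#' Per-scan CSD of a peptide
#'
#' Runs [find_envelope()] for charges 1..5 and returns a normalized CSD
#' only when every (structurally observable) charge is confidently present
#' or absent and at least one is present; otherwise the scan contributes
#' no reading.
#'
#' @inheritParams find_envelope
#' @return `NULL`, or a list with `csd` (probabilities over 1+..5+, zeros
#'   at absent and unobservable charges), `total_intensity`, and `calls`.
#' @export
per_scan_csd <- function(scan, peptide, config = extraction_config(),
                         mz_min = 300, mz_max = 1800) {
  if (is.character(peptide)) peptide <- pepcsd::peptide(peptide)
  tmpl <- .envelope_template(peptide, config)
  .per_scan_csd_impl(scan, tmpl, config, mz_min, mz_max)
}

.per_scan_csd_impl <- function(scan, tmpl, config, mz_min, mz_max) {
  calls <- lapply(1:5, function(z)
    .find_envelope_impl(scan, tmpl, z, config, mz_min, mz_max))
  status <- vapply(calls, `[[`, "", "status")
  if (any(status == "unconfident")) return(NULL)
  if (!any(status == "present")) return(NULL)
  intensity <- vapply(calls, `[[`, 0, "intensity")
  total <- sum(intensity)
  list(csd = intensity / total, total_intensity = total, calls = calls)
}

#' Extract one peptide's CSD reading from a run
#'
#' Selects MS1 scans within `rt_window` of the identification, extends the
#' window outward while the identified charge state remains present
#' (elution tracking), computes per-scan CSDs and aggregates them by
#' intensity-weighted average.
#'
#' @param run An `ms_run`.
#' @param peptide A `peptide_record` or sequence string.
#' @param identified_charge Charge of the MS2 identification.
#' @param retention_time Retention time of the identification (seconds).
#' @param config An [extraction_config()].
#' @param mz_min,mz_max Instrument window; defaults taken from the run if
#'   recorded there.
#' @return `NULL` (too few valid scans), or a list of class `csd_reading`:
#'   `csd`, `total_intensity`, `n_scans`, and `per_scan` (data frame with
#'   scan index, rt, per-scan probabilities and intensity).
#' @export
extract_peptide <- function(run, peptide, identified_charge, retention_time,
                            config = extraction_config(),
                            mz_min = NULL, mz_max = NULL) {
  if (is.character(peptide)) peptide <- pepcsd::peptide(peptide)
  if (is.null(mz_min)) mz_min <- if (is.na(run$mz_min)) 300 else run$mz_min
  if (is.null(mz_max)) mz_max <- if (is.na(run$mz_max)) 1800 else run$mz_max
  tmpl <- .envelope_template(peptide, config)

  in_window <- which(abs(run$rt - retention_time) <= config$rt_window)
  if (length(in_window) == 0) return(NULL)
  lo <- min(in_window); hi <- max(in_window)
  ident_present <- function(i) {
    call <- .find_envelope_impl(run$peaks[[i]], tmpl, identified_charge,
                                config, mz_min, mz_max)
    call$status == "present"
  }
  while (lo > 1 && ident_present(lo - 1)) lo <- lo - 1
  while (hi < length(run$rt) && ident_present(hi + 1)) hi <- hi + 1

  rows <- list()
  for (i in lo:hi) {
    res <- .per_scan_csd_impl(run$peaks[[i]], tmpl, config, mz_min, mz_max)
    if (is.null(res)) next
    rows[[length(rows) + 1]] <- c(scan = run$scan_index[i], rt = run$rt[i],
                                  res$csd, intensity = res$total_intensity)
  }
  if (length(rows) < config$min_scans) return(NULL)
  per_scan <- as.data.frame(do.call(rbind, rows))
  names(per_scan) <- c("scan", "rt", paste0("p", 1:5), "intensity")
  w <- per_scan$intensity
  csd_mat <- as.matrix(per_scan[, paste0("p", 1:5)])
  csd <- colSums(csd_mat * w) / sum(w)
  csd <- csd / sum(csd)
  structure(list(sequence = peptide$sequence, csd = unname(csd),
                 total_intensity = sum(w), n_scans = nrow(per_scan),
                 per_scan = per_scan), class = "csd_reading")
}

#' @export
print.csd_reading <- function(x, ...) {
  cat(sprintf("<csd_reading> %s  n_scans=%d  CSD = (%s)\n", x$sequence,
              x$n_scans, paste(sprintf("%.3f", x$csd), collapse = ", ")))
  invisible(x)
}

#' Extract CSD readings for all identified peptides in a run
#'
#' Applies [extract_peptide()] to every identification; multiple
#' identifications of the same peptide (sequence + modifications) are
#' merged by intensity-weighted average, yielding one reading per unique
#' peptide.
#'
#' @param run An `ms_run`.
#' @param identifications Data frame with columns `sequence`,
#'   `modifications`, `charge`, `retention_time` (as produced by
#'   [render_ms_run()] or [read_identifications()]).
#' @param config An [extraction_config()].
#' @param mz_min,mz_max Instrument window overrides.
#' @param verbose Log skipped peptides with reasons.
#' @return Data frame with one row per unique peptide: `sequence`,
#'   `modifications`, `mass`, `basic_sites`, `p1`..`p5`, `mean_charge`,
#'   `total_intensity`, `n_scans`. Skip reasons are attached as attribute
#'   `"skipped"`.
#' @export
extract_run <- function(run, identifications, config = extraction_config(),
                        mz_min = NULL, mz_max = NULL, verbose = FALSE) {
  required <- c("sequence", "modifications", "charge", "retention_time")
  missing_cols <- setdiff(required, names(identifications))
  if (length(missing_cols) > 0) {
    stop("identifications table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  acc <- new.env(parent = emptyenv())
  skipped <- list()
  for (i in seq_len(nrow(identifications))) {
    row <- identifications[i, ]
    pep <- tryCatch(.peptide_from_mods(row$sequence, row$modifications),
                    error = function(e) e)
    if (inherits(pep, "error")) {
      skipped[[length(skipped) + 1]] <-
        data.frame(sequence = row$sequence, reason = conditionMessage(pep))
      next
    }
    reading <- extract_peptide(run, pep, row$charge, row$retention_time,
                               config, mz_min, mz_max)
    if (is.null(reading)) {
      skipped[[length(skipped) + 1]] <-
        data.frame(sequence = row$sequence,
                   reason = "too few confident scans")
      if (verbose) message("skipped ", row$sequence,
                           ": too few confident scans")
      next
    }
    key <- paste(row$sequence, row$modifications, sep = "//")
    prev <- acc[[key]]
    if (is.null(prev)) {
      acc[[key]] <- list(peptide = pep, modifications = row$modifications,
                         csd_w = reading$csd * reading$total_intensity,
                         w = reading$total_intensity,
                         n_scans = reading$n_scans)
    } else {
      prev$csd_w <- prev$csd_w + reading$csd * reading$total_intensity
      prev$w <- prev$w + reading$total_intensity
      prev$n_scans <- prev$n_scans + reading$n_scans
      acc[[key]] <- prev
    }
  }
  keys <- ls(acc)
  rows <- lapply(keys, function(k) {
    e <- acc[[k]]
    csd <- e$csd_w / e$w
    csd <- csd / sum(csd)
    data.frame(sequence = e$peptide$sequence,
               modifications = e$modifications,
               mass = e$peptide$monoisotopic_mass,
               basic_sites = e$peptide$basic_site_count,
               p1 = csd[1], p2 = csd[2], p3 = csd[3], p4 = csd[4],
               p5 = csd[5], mean_charge = sum((1:5) * csd),
               total_intensity = e$w, n_scans = e$n_scans,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    utils::read.table(text = "",
                      col.names = c("sequence", "modifications", "mass",
                                    "basic_sites", paste0("p", 1:5),
                                    "mean_charge", "total_intensity",
                                    "n_scans"))
  out <- out[order(out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(sequence = character(0), reason = character(0))
  out
}
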