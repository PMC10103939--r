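## MS1 spectra containers and readers/writers.
##
## The internal spectra format is a plain tab-separated table with a
## '#'-prefixed header line and columns scan_index, rt_seconds, mz,
## intensity, so that the package is fully testable with zero
## binary-format dependencies. mzML support (read and write) goes through
## Bioconductor's mzR.

#' Construct an MS1 run
#'
#' @param scan_index Integer scan indices.
#' @param rt Retention times in seconds, one per scan, non-decreasing.
#' @param peaks List of two-column matrices (`mz`, `intensity`), one per
#'   scan, each sorted by m/z.
#' @param mz_min,mz_max Instrument acquisition window, if known.
#' @return An object of class `ms_run`.
#' @export
ms_run <- function(scan_index, rt, peaks, mz_min = NA_real_,
                   mz_max = NA_real_) {
  stopifnot(length(scan_index) == length(rt),
            length(peaks) == length(rt))
  o <- order(rt)
  structure(list(scan_index = as.integer(scan_index)[o], rt = rt[o],
                 peaks = peaks[o], mz_min = mz_min, mz_max = mz_max),
            class = "ms_run")
}

#' @export
print.ms_run <- function(x, ...) {
  np <- sum(vapply(x$peaks, nrow, integer(1)))
  cat(sprintf("<ms_run> %d MS1 scans, rt %.1f-%.1f s, %d peaks\n",
              length(x$scan_index), min(x$rt), max(x$rt), np))
  invisible(x)
}

#' Centroid a profile-mode spectrum
#'
#' Splits contiguous above-zero runs of profile points at local intensity
#' minima; each resulting cluster becomes a single centroid at the
#' intensity-weighted mean m/z with the summed intensity.
#'
#' @param mz,intensity Profile points, sorted by m/z.
#' @return Two-column matrix (`mz`, `intensity`) of centroids.
#' @export
centroid_profile <- function(mz, intensity) {
  stopifnot(length(mz) == length(intensity))
  if (length(mz) == 0) return(cbind(mz = numeric(0), intensity = numeric(0)))
  if (is.unsorted(mz)) stop("profile points must be sorted by m/z")
  pos <- intensity > 0
  ## run-length segmentation of above-zero stretches
  r <- rle(pos)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  out_mz <- numeric(0); out_int <- numeric(0)
  for (j in which(r$values)) {
    i0 <- starts[j]; i1 <- ends[j]
    seg_int <- intensity[i0:i1]
    seg_mz <- mz[i0:i1]
    ## split at strict local minima (a point lower than both neighbours)
    cuts <- integer(0)
    if (length(seg_int) >= 3) {
      interior <- 2:(length(seg_int) - 1)
      is_min <- seg_int[interior] < seg_int[interior - 1] &
        seg_int[interior] < seg_int[interior + 1]
      cuts <- interior[is_min]
    }
    bounds <- c(0, cuts, length(seg_int))
    for (k in seq_len(length(bounds) - 1)) {
      ## the minimum point itself is shared: assign it to the left cluster
      idx <- (bounds[k] + 1):bounds[k + 1]
      w <- seg_int[idx]
      out_mz <- c(out_mz, sum(seg_mz[idx] * w) / sum(w))
      out_int <- c(out_int, sum(w))
    }
  }
  cbind(mz = out_mz, intensity = out_int)
}

#' Write an MS1 run to the internal spectra TSV format
#'
#' @param run An `ms_run`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_spectra_tsv <- function(run, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#scan_index\trt_seconds\tmz\tintensity", con)
  for (i in seq_along(run$scan_index)) {
    pk <- run$peaks[[i]]
    if (nrow(pk) == 0) next
    lines <- sprintf("%d\t%.4f\t%.6f\t%.6g",
                     run$scan_index[i], run$rt[i], pk[, "mz"],
                     pk[, "intensity"])
    writeLines(lines, con)
  }
  invisible(path)
}

.read_spectra_tsv <- function(path) {
  tab <- utils::read.delim(path, comment.char = "", header = FALSE,
                           skip = 1,
                           col.names = c("scan_index", "rt_seconds",
                                         "mz", "intensity"))
  if (nrow(tab) == 0) stop("no MS1 peaks in ", path)
  scans <- sort(unique(tab$scan_index))
  rts <- vapply(scans, function(s) tab$rt_seconds[tab$scan_index == s][1],
                numeric(1))
  peaks <- lapply(scans, function(s) {
    sub <- tab[tab$scan_index == s, ]
    o <- order(sub$mz)
    cbind(mz = sub$mz[o], intensity = sub$intensity[o])
  })
  ms_run(scan_index = scans, rt = rts, peaks = peaks)
}

.read_mzml <- function(path, centroid_profiles = TRUE) {
  handle <- mzR::openMSfile(path)
  on.exit(mzR::close(handle))
  hdr <- mzR::header(handle)
  ms1 <- which(hdr$msLevel == 1L)
  if (length(ms1) == 0) stop("no MS1 scans in ", path)
  pk <- mzR::peaks(handle, scans = ms1)
  if (is.matrix(pk)) pk <- list(pk)
  peaks <- vector("list", length(ms1))
  for (i in seq_along(ms1)) {
    m <- pk[[i]]
    colnames(m) <- c("mz", "intensity")
    centroided <- hdr$centroided[ms1[i]]
    if (isFALSE(centroided) && centroid_profiles) {
      m <- centroid_profile(m[, "mz"], m[, "intensity"])
    }
    peaks[[i]] <- m[order(m[, "mz"]), , drop = FALSE]
  }
  ms_run(scan_index = hdr$acquisitionNum[ms1],
         rt = hdr$retentionTime[ms1], peaks = peaks)
}

#' Read MS1 spectra
#'
#' Loads MS1 scans from an mzML file (via mzR; profile-mode spectra are
#' centroided with [centroid_profile()]) or from the internal spectra TSV
#' format, chosen by file extension. Scans are returned sorted by
#' retention time.
#'
#' @param path Input file (`.mzML` or `.tsv`).
#' @param centroid_profiles Centroid profile-mode mzML spectra (default
#'   `TRUE`).
#' @return An `ms_run`.
#' @export
read_spectra <- function(path, centroid_profiles = TRUE) {
  if (grepl("\\.mzml$", path, ignore.case = TRUE)) {
    .read_mzml(path, centroid_profiles)
  } else {
    .read_spectra_tsv(path)
  }
}

#' Write an MS1 run to mzML
#'
#' Writes centroid MS1 spectra through mzR.
#'
#' @param run An `ms_run`.
#' @param path Output `.mzML` file.
#' @return `path`, invisibly.
#' @export
write_mzml <- function(run, path) {
  n <- length(run$scan_index)
  counts <- vapply(run$peaks, nrow, integer(1))
  na <- rep(NA_real_, n)
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = run$scan_index,
    msLevel = rep(1L, n), polarity = rep(1L, n),
    peaksCount = counts,
    totIonCurrent = vapply(run$peaks, function(p)
      if (nrow(p)) sum(p[, "intensity"]) else 0, numeric(1)),
    retentionTime = run$rt,
    basePeakMZ = vapply(run$peaks, function(p)
      if (nrow(p)) p[which.max(p[, "intensity"]), "mz"] else 0, numeric(1)),
    basePeakIntensity = vapply(run$peaks, function(p)
      if (nrow(p)) max(p[, "intensity"]) else 0, numeric(1)),
    collisionEnergy = na, ionisationEnergy = rep(0, n),
    lowMZ = vapply(run$peaks, function(p)
      if (nrow(p)) min(p[, "mz"]) else 0, numeric(1)),
    highMZ = vapply(run$peaks, function(p)
      if (nrow(p)) max(p[, "mz"]) else 0, numeric(1)),
    precursorScanNum = rep(0L, n), precursorMZ = rep(0, n),
    precursorCharge = rep(0L, n), precursorIntensity = rep(0, n),
    mergedScan = rep(0L, n), mergedResultScanNum = rep(0L, n),
    mergedResultStartScanNum = rep(0L, n),
    mergedResultEndScanNum = rep(0L, n),
    injectionTime = rep(0, n), filterString = rep(NA_character_, n),
    spectrumId = sprintf("scan=%d", run$scan_index),
    centroided = rep(TRUE, n), ionMobilityDriftTime = na,
    isolationWindowTargetMZ = na, isolationWindowLowerOffset = na,
    isolationWindowUpperOffset = na,
    scanWindowLowerLimit = na, scanWindowUpperLimit = na,
    stringsAsFactors = FALSE)
  mzR::writeMSData(object = unname(run$peaks), file = path, header = hdr)
  invisible(path)
}
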