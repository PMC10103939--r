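## Identification tables, CSD tables, configuration files, and the
## end-to-end pipeline.

## Map a MaxQuant-style modification string onto a peptide record.
## Understands "Unmodified", "", "Oxidation (M)", "2 Oxidation (M)",
## "Acetyl (Protein N-term)" and comma/semicolon-separated combinations.
.peptide_from_mods <- function(sequence, modifications,
                               fixed_cys_mod = "carbamidomethyl") {
  n_ox <- 0L
  acetyl <- FALSE
  s <- trimws(modifications)
  if (nzchar(s) && !identical(tolower(s), "unmodified")) {
    tokens <- trimws(strsplit(s, "[,;]")[[1]])
    for (tok in tokens) {
      if (!nzchar(tok)) next
      mult <- 1L
      m <- regmatches(tok, regexec("^([0-9]+)[ x]\\s*(.*)$", tok))[[1]]
      if (length(m) == 3) {
        mult <- as.integer(m[2])
        tok <- m[3]
      }
      if (identical(tok, "Oxidation (M)")) {
        n_ox <- n_ox + mult
      } else if (identical(tok, "Acetyl (Protein N-term)")) {
        acetyl <- TRUE
      } else {
        stop("unparseable modification: '", tok, "'")
      }
    }
  }
  peptide(sequence, fixed_cys_mod = fixed_cys_mod,
          oxidation_sites = rep(NA_integer_, n_ox), nterm_acetyl = acetyl)
}

#' Read an identification table
#'
#' Parses a MaxQuant-evidence-like TSV with columns Sequence,
#' Modifications, Charge, Retention time and MS/MS scan number. Rows whose
#' modification string cannot be mapped to the supported modifications are
#' skipped with a warning.
#'
#' @param path TSV file.
#' @return Data frame with columns `sequence`, `modifications`, `charge`,
#'   `retention_time`, `ms2_scan`.
#' @export
read_identifications <- function(path) {
  tab <- utils::read.delim(path, check.names = TRUE,
                           stringsAsFactors = FALSE)
  required <- c(Sequence = "Sequence", Modifications = "Modifications",
                Charge = "Charge", `Retention time` = "Retention.time",
                `MS/MS scan number` = "MS.MS.scan.number")
  missing_cols <- required[!(required %in% names(tab))]
  if (length(missing_cols) > 0) {
    stop("identification table lacks required column(s): ",
         paste(names(missing_cols), collapse = ", "))
  }
  out <- data.frame(sequence = tab$Sequence,
                    modifications = tab$Modifications,
                    charge = as.integer(tab$Charge),
                    retention_time = as.numeric(tab$Retention.time),
                    ms2_scan = as.integer(tab$MS.MS.scan.number),
                    stringsAsFactors = FALSE)
  out$modifications[tolower(trimws(out$modifications)) == "unmodified"] <- ""
  ok <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    res <- tryCatch(.peptide_from_mods(out$sequence[i],
                                       out$modifications[i]),
                    error = function(e) e)
    if (inherits(res, "error")) {
      warning("skipping row ", i, " (", out$sequence[i], "): ",
              conditionMessage(res))
      ok[i] <- FALSE
    }
  }
  out[ok, , drop = FALSE]
}

#' Write an identification table
#'
#' Inverse of [read_identifications()], in MaxQuant column convention.
#'
#' @param identifications Data frame with `sequence`, `modifications`,
#'   `charge`, `retention_time`, `ms2_scan`.
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_identifications <- function(identifications, path) {
  tab <- data.frame(
    Sequence = identifications$sequence,
    Modifications = ifelse(nzchar(identifications$modifications),
                           identifications$modifications, "Unmodified"),
    Charge = identifications$charge,
    `Retention time` = identifications$retention_time,
    `MS/MS scan number` = identifications$ms2_scan,
    check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a CSD reading table
#'
#' Probabilities are serialized with 6 decimals, masses with 4.
#'
#' @param readings Reading table from [extract_run()].
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_csd_table <- function(readings, path) {
  tab <- readings
  for (col in paste0("p", 1:5)) tab[[col]] <- sprintf("%.6f", tab[[col]])
  tab$mass <- sprintf("%.4f", tab$mass)
  tab$mean_charge <- sprintf("%.6f", tab$mean_charge)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a CSD reading table
#' @param path TSV written by [write_csd_table()].
#' @return Reading table (data frame).
#' @export
read_csd_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  tab$modifications[is.na(tab$modifications)] <- ""
  tab
}

#' Pipeline configuration
#'
#' Bundles the simulator, extraction and basicity settings for
#' [pipeline_run()]. All entries are plain scalars or short vectors and
#' round-trip through [write_config()]/[read_config()].
#'
#' @param n_peptides Peptides to simulate.
#' @param seed Integer seed for the whole pipeline.
#' @param intensity_cv,mz_jitter_ppm,detection_floor,chimeric_rate Noise
#'   settings (see [ms_noise()]).
#' @param mz_min,mz_max Instrument window.
#' @param extraction An [extraction_config()].
#' @param basicity A [basicity_config()].
#' @param trend_splines,trend_smoothing Trend-fit settings.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_peptides = 1500, seed = 1,
                            intensity_cv = 0.1, mz_jitter_ppm = 2,
                            detection_floor = 0, chimeric_rate = 0,
                            mz_min = 300, mz_max = 1800,
                            extraction = extraction_config(),
                            basicity = basicity_config(),
                            trend_splines = 20, trend_smoothing = 5) {
  structure(list(n_peptides = n_peptides, seed = seed,
                 intensity_cv = intensity_cv,
                 mz_jitter_ppm = mz_jitter_ppm,
                 detection_floor = detection_floor,
                 chimeric_rate = chimeric_rate,
                 mz_min = mz_min, mz_max = mz_max,
                 extraction = extraction, basicity = basicity,
                 trend_splines = trend_splines,
                 trend_smoothing = trend_smoothing),
            class = "pipeline_config")
}

#' Write a pipeline configuration as plain key-value text
#' @param config A [pipeline_config()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  flat <- c(config[!(names(config) %in% c("extraction", "basicity"))],
            stats::setNames(config$extraction,
                            paste0("extraction.",
                                   names(config$extraction))),
            stats::setNames(config$basicity,
                            paste0("basicity.", names(config$basicity))))
  lines <- vapply(names(flat), function(k) {
    paste0(k, " = ", paste(format(flat[[k]], digits = 15), collapse = ","))
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a pipeline configuration from key-value text
#' @param path File written by [write_config()].
#' @return A [pipeline_config()].
#' @export
read_config <- function(path) {
  lines <- grep("=", readLines(path), value = TRUE, fixed = TRUE)
  kv <- lapply(strsplit(lines, "=", fixed = TRUE), trimws)
  keys <- vapply(kv, `[`, "", 1)
  vals <- lapply(kv, function(x) {
    v <- strsplit(x[2], ",", fixed = TRUE)[[1]]
    suppressWarnings(num <- as.numeric(v))
    if (any(is.na(num))) v else num
  })
  names(vals) <- keys
  pick <- function(prefix) {
    sub <- vals[startsWith(keys, prefix)]
    stats::setNames(sub, sub("^.*\\.", "", names(sub)))
  }
  top <- vals[!grepl(".", keys, fixed = TRUE)]
  do.call(pipeline_config,
          c(top, list(extraction = do.call(extraction_config,
                                           pick("extraction.")),
                      basicity = do.call(basicity_config,
                                         pick("basicity.")))))
}

#' Run the end-to-end pipeline on a synthetic run
#'
#' Simulates a run, writes spectra and identifications, extracts CSD
#' readings, fits mean-charge-versus-mass trends per basic-site count,
#' and (when the run qualifies) fits intrinsic-basicity profiles for the
#' four canonical charging regions. Deterministic per seed.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with `readings`, `trends`, `profiles`,
#'   `qualified`, and the paths written (`csd.tsv`, `trends.tsv`,
#'   `profiles.tsv`, `report.log`, plus the simulated inputs).
#' @export
pipeline_run <- function(config = pipeline_config(), out_dir = tempfile()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "report.log")
  log_con <- file(log_path, "w")
  on.exit(close(log_con))
  say <- function(...) writeLines(sprintf(...), log_con)

  say("stage simulate: n_peptides=%d seed=%d", config$n_peptides,
      config$seed)
  noise <- ms_noise(mz_jitter_ppm = config$mz_jitter_ppm,
                    intensity_cv = config$intensity_cv,
                    detection_floor = config$detection_floor,
                    chimeric_rate = config$chimeric_rate)
  instrument <- ms_instrument(mz_min = config$mz_min,
                              mz_max = config$mz_max)
  sim <- simulate_run(config$n_peptides, noise = noise,
                      instrument = instrument, seed = config$seed)
  spectra_path <- file.path(out_dir, "spectra.tsv")
  ids_path <- file.path(out_dir, "identifications.tsv")
  write_spectra_tsv(sim$ms_run, spectra_path)
  write_identifications(sim$identifications, ids_path)
  say("stage simulate: %d MS1 scans, %d identifications, %d observable",
      length(sim$ms_run$scan_index), nrow(sim$identifications),
      sum(sim$ground_truth$observable))

  run <- read_spectra(spectra_path)
  ids <- read_identifications(ids_path)
  readings <- extract_run(run, ids, config$extraction,
                          mz_min = config$mz_min, mz_max = config$mz_max)
  skipped <- attr(readings, "skipped")
  say("stage extract: %d readings, %d skipped", nrow(readings),
      nrow(skipped))
  if (nrow(skipped) > 0) {
    for (r in unique(skipped$reason)) {
      say("stage extract: skipped %d peptide(s): %s",
          sum(skipped$reason == r), r)
    }
  }
  csd_path <- file.path(out_dir, "csd.tsv")
  write_csd_table(readings, csd_path)

  ## clamping of >5 basic-site counts is expected at this scale; the
  ## per-peptide warning is informative interactively but noise here
  regimes <- vapply(seq_len(nrow(readings)), function(i) {
    suppressWarnings(
      classify_regime(as.numeric(readings[i, paste0("p", 1:5)]),
                      readings$basic_sites[i]))
  }, "")
  for (r in c("undercharged", "matched", "overcharged")) {
    say("stage trends: regime %s: %.1f%%", r, 100 * mean(regimes == r))
  }
  trend_rows <- list()
  for (b in sort(unique(readings$basic_sites))) {
    sub <- readings[readings$basic_sites == b, ]
    if (nrow(sub) < config$trend_splines) {
      say("stage trends: b=%d skipped (%d points)", b, nrow(sub))
      next
    }
    curve <- fit_trend(sub$mass, sub$mean_charge,
                       n_splines = config$trend_splines,
                       smoothing = config$trend_smoothing,
                       basic_site_count = b)
    grid <- seq(curve$domain[1], curve$domain[2], length.out = 50)
    trend_rows[[length(trend_rows) + 1]] <-
      data.frame(basic_sites = b, mass = grid,
                 fitted_mean_charge = predict(curve, grid))
    say("stage trends: b=%d fitted on %d points, transition at %.0f Da",
        b, nrow(sub), regime_transition_mass(curve))
  }
  trends <- if (length(trend_rows)) do.call(rbind, trend_rows) else
    data.frame(basic_sites = integer(0), mass = numeric(0),
               fitted_mean_charge = numeric(0))
  trends_path <- file.path(out_dir, "trends.tsv")
  utils::write.table(trends, trends_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  qualified <- run_qualifies(readings, config = config$basicity)
  counts <- attr(qualified, "counts")
  say("stage basicity: region counts %s",
      paste(sprintf("%s=%d", names(canonical_regions()), counts),
            collapse = " "))
  profiles <- list()
  prof_rows <- list()
  if (qualified) {
    for (reg in canonical_regions()) {
      prof <- fit_intrinsic_basicity(readings, reg, config$basicity,
                                     run_id = "synthetic")
      profiles[[reg$label]] <- prof
      adj <- mass_adjust(prof, config$basicity)
      prof_rows[[length(prof_rows) + 1]] <- rbind(
        data.frame(run = "synthetic", region = reg$label,
                   feature_kind = "count", amino_acid = VALID_RESIDUES,
                   coefficient = unname(prof$count_coefficients),
                   mass_adjusted = unname(adj[match(VALID_RESIDUES,
                                                    names(adj))])),
        data.frame(run = "synthetic", region = reg$label,
                   feature_kind = "nterm", amino_acid = VALID_RESIDUES,
                   coefficient = unname(prof$nterm_coefficients),
                   mass_adjusted = NA_real_),
        data.frame(run = "synthetic", region = reg$label,
                   feature_kind = "intercept", amino_acid = "",
                   coefficient = prof$intercept,
                   mass_adjusted = NA_real_))
      say("stage basicity: region %s fitted on %d peptides", reg$label,
          prof$n_peptides)
    }
  } else {
    say("stage basicity: run disqualified (need >%d eligible peptides %s)",
        config$basicity$min_region_peptides, "in every canonical region")
  }
  prof_tab <- if (length(prof_rows)) do.call(rbind, prof_rows) else
    data.frame(run = character(0), region = character(0),
               feature_kind = character(0), amino_acid = character(0),
               coefficient = numeric(0), mass_adjusted = numeric(0))
  profiles_path <- file.path(out_dir, "profiles.tsv")
  utils::write.table(prof_tab, profiles_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  invisible(list(readings = readings, trends = trends, profiles = profiles,
                 qualified = isTRUE(as.logical(qualified)),
                 paths = list(csd = csd_path, trends = trends_path,
                              profiles = profiles_path, log = log_path,
                              spectra = spectra_path, ids = ids_path)))
}
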