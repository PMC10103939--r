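## Synthetic LC-MS1 simulator: ground-truth peptides with charge state
## distributions, rendered into noisy centroided MS1 runs plus
## identification tables, so every downstream stage is testable without
## instrument data.

.aa_order <- function() VALID_RESIDUES

## Named coefficient vector over the 20 residues from a sparse spec.
.aa_vector <- function(...) {
  v <- stats::setNames(rep(0, 20), .aa_order())
  dots <- c(...)
  if (length(dots)) v[names(dots)] <- dots
  v
}

#' Charging model parameters for the simulator
#'
#' The generative model for ground-truth CSDs is a chain of adjacent
#' log-odds: for charges k and k+1 (k = 1..4),
#' `log(p(k+1)/pk) = intercept_k + mass_slope * mass + basic_site_effect[b]
#' (only when k+1 <= b) + sum(residue coefficients * residue counts) +
#' nterm coefficient of the first residue`, normalized over charges 1..5.
#' Residue and N-terminal coefficient sets differ between the undercharging
#' side (k+1 <= b, where the basic-site count is not yet saturated) and the
#' overcharging side, mirroring the distinct sequence determinants of the
#' two regimes; setting both sets equal recovers a single-determinant model.
#'
#' Defaults emulate tryptic peptide charging: the mean charge increases
#' with mass, the basic-site count raises charging only on the
#' undercharging side, glutamine promotes and aspartate suppresses
#' overcharging, and N-terminal R/K/H suppress undercharging-side charging
#' (Coulombic repulsion with the N-terminal amine), with proline acting the
#' opposite way.
#'
#' @param adjacent_log_odds_intercepts Length-4 intercepts for charge pairs
#'   (1,2), (2,3), (3,4), (4,5).
#' @param mass_slope Per-Da slope shared by all adjacent pairs.
#' @param basic_site_effect Length-5 additive effect indexed by basic-site
#'   count, applied on the undercharging side only.
#' @param residue_under,residue_over Named length-20 residue-count
#'   coefficient vectors for the two sides.
#' @param nterm_under,nterm_over Named length-20 N-terminal identity
#'   coefficient vectors.
#' @param min_probability Charge states whose probability falls below this
#'   are treated as unmeasurable, set to zero and the CSD renormalized
#'   (default 1e-3).
#' @return An object of class `charging_model`.
#' @export
charging_model <- function(
    adjacent_log_odds_intercepts = c(-0.5, -4.5, -8.5, -12.5),
    mass_slope = 0.0023,
    basic_site_effect = c(0, 0, 1.6, 3.2, 4.8),
    residue_under = .aa_vector(P = 0.30, I = 0.10, L = 0.10, F = 0.10,
                               D = -0.10, E = -0.05),
    residue_over = .aa_vector(Q = 0.30, N = 0.05, E = 0.10, D = -0.30,
                              A = 0.15, V = 0.15, I = 0.15, L = 0.15),
    nterm_under = .aa_vector(R = -1.2, K = -1.0, H = -0.8, P = 0.5),
    nterm_over = .aa_vector(),
    min_probability = 1e-3) {
  stopifnot(length(adjacent_log_odds_intercepts) == 4,
            length(basic_site_effect) == 5,
            length(residue_under) == 20, length(residue_over) == 20,
            length(nterm_under) == 20, length(nterm_over) == 20,
            min_probability >= 0, min_probability < 0.2)
  structure(list(
    intercepts = adjacent_log_odds_intercepts,
    mass_slope = mass_slope,
    basic_site_effect = basic_site_effect,
    residue_under = residue_under[.aa_order()],
    residue_over = residue_over[.aa_order()],
    nterm_under = nterm_under[.aa_order()],
    nterm_over = nterm_over[.aa_order()],
    min_probability = min_probability), class = "charging_model")
}

#' Ground-truth CSD of a peptide under a charging model
#'
#' Evaluates the adjacent-log-odds chain of [charging_model()] and returns
#' the normalized distribution over charges 1+..5+, with sub-threshold
#' probabilities truncated to exact zeros.
#'
#' @param peptide A `peptide_record` or sequence string.
#' @param model A `charging_model`.
#' @return A valid CSD (numeric length 5).
#' @export
ground_truth_csd <- function(peptide, model = charging_model()) {
  if (is.character(peptide)) peptide <- pepcsd::peptide(peptide)
  counts <- table(factor(peptide$residues, levels = .aa_order()))
  counts <- as.numeric(counts)
  first <- peptide$residues[1]
  b <- peptide$basic_site_count
  m <- peptide$monoisotopic_mass
  eta <- vapply(1:4, function(k) {
    under <- (k + 1) <= b
    res <- if (under) model$residue_under else model$residue_over
    nt <- if (under) model$nterm_under else model$nterm_over
    model$intercepts[k] + model$mass_slope * m +
      (if (under) model$basic_site_effect[min(b, 5)] else 0) +
      sum(res * counts) + nt[[first]]
  }, numeric(1))
  logp <- c(0, cumsum(eta))
  logp <- logp - max(logp)
  p <- exp(logp) / sum(exp(logp))
  p[p < model$min_probability] <- 0
  p / sum(p)
}

#' Generate random tryptic-like peptides
#'
#' Random sequences obeying the protease rule (trypsin: C-terminal K or R,
#' at most two internal K/R mimicking missed cleavages), with length >= 7
#' and monoisotopic mass inside `mass_range`. Sequences are unique within
#' one call and the output is deterministic per seed.
#'
#' @param n Number of peptides.
#' @param protease `"trypsin"` or `"other"` (no terminal constraint).
#' @param mass_range Length-2 mass interval in Da (default 700-4600).
#' @param seed Integer seed, or `NULL` to use the current RNG stream.
#' @param basic_sites Optional integer; keep only peptides with exactly
#'   this basic-site count (rejection sampling).
#' @param max_length Maximum sequence length (default 40).
#' @param max_tries Bounded retries per peptide before failing.
#' @return List of `peptide_record`s.
#' @export
generate_peptides <- function(n, protease = c("trypsin", "other"),
                              mass_range = c(700, 4600), seed = NULL,
                              basic_sites = NULL, max_length = 40,
                              max_tries = 2000) {
  protease <- match.arg(protease)
  stopifnot(n >= 1, length(mass_range) == 2, mass_range[1] < mass_range[2])
  ## sampling weights loosely following proteome residue frequencies;
  ## internal positions exclude K/R for trypsin (placed explicitly below)
  freq <- c(G = 7, A = 8, S = 7, P = 5, V = 6, T = 5, C = 1.5, L = 9,
            I = 5, N = 4, D = 5, Q = 4, K = 5, E = 6, M = 2, H = 2,
            F = 4, R = 5, Y = 3, W = 1)
  .with_seed(seed, {
    out <- vector("list", n)
    seen <- character(0)
    for (i in seq_len(n)) {
      rec <- NULL
      for (try in seq_len(max_tries)) {
        len <- sample(7:max_length, 1)
        if (protease == "trypsin") {
          body_alpha <- setdiff(.aa_order(), c("K", "R"))
          body <- sample(body_alpha, len - 1, replace = TRUE,
                         prob = freq[body_alpha])
          n_missed <- sample(0:2, 1, prob = c(0.6, 0.3, 0.1))
          n_missed <- min(n_missed, len - 2)
          if (n_missed > 0) {
            pos <- sample(seq_len(len - 2), n_missed)
            body[pos] <- sample(c("K", "R"), n_missed, replace = TRUE)
          }
          seqc <- c(body, sample(c("K", "R"), 1))
        } else {
          seqc <- sample(.aa_order(), len, replace = TRUE,
                         prob = freq[.aa_order()])
        }
        s <- paste(seqc, collapse = "")
        if (s %in% seen) next
        cand <- peptide(s)
        if (cand$monoisotopic_mass < mass_range[1] ||
            cand$monoisotopic_mass > mass_range[2]) next
        if (!is.null(basic_sites) &&
            cand$basic_site_count != basic_sites) next
        rec <- cand
        break
      }
      if (is.null(rec)) {
        stop("could not satisfy peptide constraints after ", max_tries,
             " tries (peptide ", i, ")")
      }
      seen <- c(seen, rec$sequence)
      out[[i]] <- rec
    }
    out
  })
}

#' Ground-truth CSD readings without spectrum rendering
#'
#' Fast path for statistical experiments: evaluates the charging model for
#' each peptide and returns a reading table in the same layout as
#' [extract_run()], optionally perturbed by multiplicative log-normal noise
#' on the nonzero probabilities (renormalized), emulating replicate
#' measurement error.
#'
#' @param peptides List of `peptide_record`s.
#' @param model A `charging_model`.
#' @param csd_noise_cv Coefficient of variation of the per-state noise
#'   (default 0 = exact ground truth).
#' @param seed Integer seed or `NULL`.
#' @return A CSD reading table (data frame).
#' @export
simulate_csd_readings <- function(peptides, model = charging_model(),
                                  csd_noise_cv = 0, seed = NULL) {
  .with_seed(seed, {
    sdlog <- sqrt(log(1 + csd_noise_cv^2))
    rows <- lapply(peptides, function(p) {
      csd <- ground_truth_csd(p, model)
      if (csd_noise_cv > 0) {
        nz <- csd > 0
        csd[nz] <- csd[nz] * stats::rlnorm(sum(nz), 0, sdlog)
        csd <- csd / sum(csd)
      }
      data.frame(sequence = p$sequence, modifications = "",
                 mass = p$monoisotopic_mass,
                 basic_sites = p$basic_site_count,
                 p1 = csd[1], p2 = csd[2], p3 = csd[3], p4 = csd[4],
                 p5 = csd[5],
                 mean_charge = sum((1:5) * csd),
                 total_intensity = 1, n_scans = 1L,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Noise model for the spectrum renderer
#'
#' @param mz_jitter_ppm Gaussian m/z perturbation, standard deviation in
#'   parts per million (default 0).
#' @param intensity_cv Coefficient of variation of multiplicative
#'   log-normal intensity noise per peak (default 0).
#' @param detection_floor Hard intensity cutoff below which peaks are not
#'   recorded (default 0).
#' @param chimeric_rate Fraction of peptide-scan-charge envelopes receiving
#'   one contaminant peak within the envelope m/z span (default 0).
#' @return A list of class `ms_noise`.
#' @export
ms_noise <- function(mz_jitter_ppm = 0, intensity_cv = 0,
                     detection_floor = 0, chimeric_rate = 0) {
  stopifnot(mz_jitter_ppm >= 0, intensity_cv >= 0, detection_floor >= 0,
            chimeric_rate >= 0, chimeric_rate <= 1)
  structure(list(mz_jitter_ppm = mz_jitter_ppm, intensity_cv = intensity_cv,
                 detection_floor = detection_floor,
                 chimeric_rate = chimeric_rate), class = "ms_noise")
}

#' Instrument acquisition settings for the renderer
#'
#' @param mz_min,mz_max Acquisition m/z window (defaults 300 and 1800).
#' @param scan_interval MS1 scan spacing in seconds.
#' @param run_seconds Total run length in seconds.
#' @param elution_fwhm_scans Full width at half maximum of the Gaussian
#'   elution profiles, in scans (default 10).
#' @return A list of class `ms_instrument`.
#' @export
ms_instrument <- function(mz_min = 300, mz_max = 1800, scan_interval = 1,
                          run_seconds = 600, elution_fwhm_scans = 10) {
  stopifnot(mz_min < mz_max, scan_interval > 0, run_seconds > 10)
  structure(list(mz_min = mz_min, mz_max = mz_max,
                 scan_interval = scan_interval, run_seconds = run_seconds,
                 elution_fwhm_scans = elution_fwhm_scans),
            class = "ms_instrument")
}

## Prefix of envelope peaks compared during extraction: smallest prefix
## covering `coverage` of abundance, at least `min_n` peaks.
.compared_offsets <- function(envelope, min_n = 2, coverage = 0.95) {
  ab <- envelope$relative_abundances
  k <- which(cumsum(ab) >= coverage)[1]
  k <- max(k, min(min_n, length(ab)))
  seq_len(k) - 1L
}

#' Render peptides into a noisy centroided MS1 run
#'
#' Each peptide receives a Gaussian elution profile (random apex retention
#' time and log-normal amplitude). In every MS1 scan covering the profile,
#' each charge state of the peptide's ground-truth CSD deposits its
#' theoretical isotope peaks at [ion_mz()] positions with intensity
#' `profile(rt) * p_z * abundance`, perturbed by log-normal intensity noise
#' and Gaussian m/z jitter; peaks below the detection floor or outside the
#' acquisition window are dropped. Optionally a contaminant ("chimeric")
#' peak is injected within a fraction of envelope spans at 10-100% of the
#' envelope base peak. One identification record per peptide is produced
#' at the scan nearest its elution apex, with the identified charge drawn
#' from the ground-truth CSD.
#'
#' A peptide is flagged `observable` when every charge state in its CSD
#' support has all compared isotope peaks inside the acquisition window
#' (only for such peptides can the extraction scheme recover the full
#' ground-truth CSD even in principle). It is additionally flagged `clean`
#' when no foreign peak — another peptide's isotope peak or an injected
#' contaminant — falls inside any of its envelope m/z spans while it
#' elutes; peptides that are observable but not clean are legitimate prey
#' for the extraction scheme's chimeric filter.
#'
#' @param peptides List of `peptide_record`s.
#' @param csds Matrix (n x 5) or list of ground-truth CSDs, one per
#'   peptide; defaults to evaluating `model` on each peptide.
#' @param model Charging model used when `csds` is `NULL`.
#' @param noise An [ms_noise()] object.
#' @param instrument An [ms_instrument()] object.
#' @param seed Integer seed or `NULL`.
#' @param envelope_coverage Cumulative abundance rendered per envelope.
#' @param amplitude_meanlog,amplitude_sdlog Log-normal elution amplitude
#'   parameters.
#' @return An object of class `simulated_run`: list with `ms_run`,
#'   `identifications` (data frame), `ground_truth` (data frame with
#'   `p1..p5`, elution parameters and the `observable` and `clean`
#'   flags), `peptides`, and `chimeric` bookkeeping of injected
#'   contaminants.
#' @export
render_ms_run <- function(peptides, csds = NULL, model = charging_model(),
                          noise = ms_noise(), instrument = ms_instrument(),
                          seed = NULL, envelope_coverage = 0.999,
                          amplitude_meanlog = log(1e6),
                          amplitude_sdlog = 1) {
  stopifnot(length(peptides) >= 1)
  n <- length(peptides)
  if (is.null(csds)) {
    csds <- t(vapply(peptides, ground_truth_csd, numeric(5), model = model))
  } else if (is.list(csds)) {
    csds <- do.call(rbind, csds)
  }
  stopifnot(nrow(csds) == n, ncol(csds) == 5)

  ins <- instrument
  sigma <- ins$elution_fwhm_scans * ins$scan_interval / (2 * sqrt(2 * log(2)))
  scan_rt <- seq(0, ins$run_seconds, by = ins$scan_interval)
  n_scans <- length(scan_rt)

  .with_seed(seed, {
    apex <- stats::runif(n, 4 * sigma, ins$run_seconds - 4 * sigma)
    amplitude <- stats::rlnorm(n, amplitude_meanlog, amplitude_sdlog)

    peak_tabs <- vector("list", n)
    chim_tabs <- vector("list", n)
    observable <- logical(n)
    scan_range <- matrix(NA_integer_, n, 2)
    spans <- vector("list", n)     # per support charge: envelope m/z span
    own_mz <- vector("list", n)    # all rendered m/z positions
    for (i in seq_len(n)) {
      p <- peptides[[i]]
      csd <- csds[i, ]
      env <- isotope_envelope(p, coverage = envelope_coverage)
      ab <- env$relative_abundances
      cmp <- .compared_offsets(env)
      support <- which(csd > 0)
      cmp_mz <- outer(cmp, support,
                      function(o, z) ion_mz(p$monoisotopic_mass, z, o))
      observable[i] <- all(cmp_mz >= ins$mz_min & cmp_mz <= ins$mz_max)
      scans <- which(abs(scan_rt - apex[i]) <= 4 * sigma)
      if (length(scans) == 0) { observable[i] <- FALSE; next }
      scan_range[i, ] <- range(scans)
      spans[[i]] <- cbind(lo = ion_mz(p$monoisotopic_mass, support, 0),
                          hi = ion_mz(p$monoisotopic_mass, support,
                                      length(ab) - 1L))
      profile <- amplitude[i] *
        exp(-(scan_rt[scans] - apex[i])^2 / (2 * sigma^2))
      grid <- expand.grid(offset = seq_along(ab) - 1L, z = support)
      mz0 <- ion_mz(p$monoisotopic_mass, grid$z, grid$offset)
      base_ab <- ab[grid$offset + 1L] * csd[grid$z]
      tab <- data.frame(
        scan = rep(scans, each = nrow(grid)),
        mz = rep(mz0, times = length(scans)),
        intensity = as.vector(outer(base_ab, profile)),
        peptide = i,
        z = rep(grid$z, times = length(scans)))
      if (noise$chimeric_rate > 0) {
        envs <- unique(tab[, c("scan", "z")])
        hit <- stats::runif(nrow(envs)) < noise$chimeric_rate
        envs <- envs[hit, , drop = FALSE]
        if (nrow(envs) > 0) {
          span_lo <- ion_mz(p$monoisotopic_mass, envs$z, 0)
          span_hi <- ion_mz(p$monoisotopic_mass, envs$z, length(ab) - 1L)
          prof_at <- amplitude[i] *
            exp(-(scan_rt[envs$scan] - apex[i])^2 / (2 * sigma^2))
          base_peak <- prof_at * max(ab) * csd[envs$z]
          chim <- data.frame(
            scan = envs$scan,
            mz = stats::runif(nrow(envs), span_lo, span_hi),
            intensity = stats::runif(nrow(envs), 0.1, 1) * base_peak,
            peptide = i, z = envs$z)
          chim_tabs[[i]] <- chim
          tab <- rbind(tab, chim)
        }
      }
      peak_tabs[[i]] <- tab
      own_mz[[i]] <- unique(tab$mz)
    }

    ## cross-peptide interference bookkeeping: peptide i is clean when no
    ## foreign peak sits inside any of its envelope spans (30 ppm pad)
    ## while it elutes
    clean <- observable | TRUE
    in_spans <- function(mz, sp) {
      pad <- 30e-6
      any(vapply(seq_len(nrow(sp)), function(r)
        any(mz >= sp[r, "lo"] * (1 - pad) & mz <= sp[r, "hi"] * (1 + pad)),
        logical(1)))
    }
    for (i in seq_len(n)) {
      if (is.null(spans[[i]])) { clean[i] <- FALSE; next }
      if (!is.null(chim_tabs[[i]]) && nrow(chim_tabs[[i]]) > 0) {
        clean[i] <- FALSE
        next
      }
      for (j in seq_len(n)) {
        if (j == i || is.null(own_mz[[j]])) next
        if (scan_range[j, 1] > scan_range[i, 2] ||
            scan_range[j, 2] < scan_range[i, 1]) next
        if (in_spans(own_mz[[j]], spans[[i]])) { clean[i] <- FALSE; break }
      }
    }
    peaks <- do.call(rbind, peak_tabs)
    chimeric <- do.call(rbind, chim_tabs)
    if (is.null(chimeric)) {
      chimeric <- data.frame(scan = integer(0), mz = numeric(0),
                             intensity = numeric(0), peptide = integer(0),
                             z = integer(0))
    }

    if (noise$intensity_cv > 0) {
      sdlog <- sqrt(log(1 + noise$intensity_cv^2))
      peaks$intensity <- peaks$intensity *
        stats::rlnorm(nrow(peaks), 0, sdlog)
    }
    if (noise$mz_jitter_ppm > 0) {
      peaks$mz <- peaks$mz *
        (1 + stats::rnorm(nrow(peaks), 0, noise$mz_jitter_ppm * 1e-6))
    }
    keep <- peaks$intensity > noise$detection_floor &
      peaks$mz >= ins$mz_min & peaks$mz <= ins$mz_max
    peaks <- peaks[keep, , drop = FALSE]

    scan_peaks <- vector("list", n_scans)
    split_idx <- split(seq_len(nrow(peaks)), factor(peaks$scan,
                                                    levels = seq_len(n_scans)))
    for (s in seq_len(n_scans)) {
      idx <- split_idx[[s]]
      if (length(idx) == 0) {
        scan_peaks[[s]] <- cbind(mz = numeric(0), intensity = numeric(0))
      } else {
        o <- idx[order(peaks$mz[idx])]
        scan_peaks[[s]] <- cbind(mz = peaks$mz[o],
                                 intensity = peaks$intensity[o])
      }
    }
    run <- ms_run(scan_index = seq_len(n_scans), rt = scan_rt,
                  peaks = scan_peaks, mz_min = ins$mz_min,
                  mz_max = ins$mz_max)

    ident_scan <- vapply(apex, function(a) which.min(abs(scan_rt - a)),
                         integer(1))
    ident_charge <- vapply(seq_len(n), function(i) {
      sample(1:5, 1, prob = csds[i, ])
    }, integer(1))
    identifications <- data.frame(
      sequence = vapply(peptides, `[[`, "", "sequence"),
      modifications = "",
      charge = ident_charge,
      retention_time = scan_rt[ident_scan],
      ms2_scan = ident_scan,
      stringsAsFactors = FALSE)

    ground_truth <- data.frame(
      sequence = identifications$sequence,
      modifications = "",
      mass = vapply(peptides, `[[`, 0, "monoisotopic_mass"),
      basic_sites = vapply(peptides, `[[`, 0L, "basic_site_count"),
      p1 = csds[, 1], p2 = csds[, 2], p3 = csds[, 3], p4 = csds[, 4],
      p5 = csds[, 5],
      apex_rt = apex, sigma = sigma, amplitude = amplitude,
      observable = observable, clean = clean,
      stringsAsFactors = FALSE)

    structure(list(ms_run = run, identifications = identifications,
                   ground_truth = ground_truth, peptides = peptides,
                   chimeric = chimeric, instrument = ins, noise = noise),
              class = "simulated_run")
  })
}

#' @export
print.simulated_run <- function(x, ...) {
  cat(sprintf(paste0("<simulated_run> %d peptides (%d observable, ",
                     "%d clean), %d MS1 scans, %d contaminant peaks\n"),
              nrow(x$ground_truth), sum(x$ground_truth$observable),
              sum(x$ground_truth$clean), length(x$ms_run$scan_index),
              nrow(x$chimeric)))
  invisible(x)
}

#' One-call synthetic run
#'
#' Convenience wrapper: generate peptides, evaluate the charging model and
#' render the run.
#'
#' @param n_peptides Number of peptides to simulate.
#' @param model A [charging_model()].
#' @param noise An [ms_noise()].
#' @param instrument An [ms_instrument()].
#' @param mass_range Peptide mass interval (Da).
#' @param seed Integer seed or `NULL`.
#' @param ... Passed to [render_ms_run()].
#' @return A `simulated_run`.
#' @export
simulate_run <- function(n_peptides = 100, model = charging_model(),
                         noise = ms_noise(), instrument = ms_instrument(),
                         mass_range = c(700, 4600), seed = NULL, ...) {
  .with_seed(seed, {
    peptides <- generate_peptides(n_peptides, mass_range = mass_range)
    render_ms_run(peptides, model = model, noise = noise,
                  instrument = instrument, ...)
  })
}
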