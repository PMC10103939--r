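test_that("profile centroiding splits clusters at local minima", {
  # symmetric triangular peak -> one centroid at the apex
  mz <- seq(500.00, 500.08, by = 0.01)
  int <- c(0, 1, 2, 3, 4, 3, 2, 1, 0)
  cen <- centroid_profile(mz, int)
  expect_identical(nrow(cen), 1L)
  expect_equal(unname(cen[1, "mz"]), 500.04, tolerance = 1e-9)
  expect_equal(unname(cen[1, "intensity"]), sum(int), tolerance = 1e-12)

  # two baseline-separated peaks -> two centroids
  mz2 <- c(mz, mz + 1)
  int2 <- c(int, 2 * int)
  cen2 <- centroid_profile(mz2, int2)
  expect_identical(nrow(cen2), 2L)

  # overlapping doublet with a clear interior minimum -> split there
  mz3 <- seq(600.00, 600.10, by = 0.01)
  int3 <- c(1, 3, 5, 3, 2, 1, 2, 4, 6, 3, 1)
  cen3 <- centroid_profile(mz3, int3)
  expect_identical(nrow(cen3), 2L)
  expect_lt(cen3[1, "mz"], 600.05)
  expect_gt(cen3[2, "mz"], 600.05)

  expect_identical(nrow(centroid_profile(numeric(0), numeric(0))), 0L)
})

test_that("the three presence filters and the absence rule behave as
           specified on constructed scans", {
  pep <- peptide("ASGQAFELILSPR")
  cfg <- extraction_config()

  # noiseless rendered envelope: present, cosine 1, full intensity
  scan <- scan_with_envelopes(pep, charges = 2, intensities = 1000)
  call <- find_envelope(scan, pep, 2, cfg)
  expect_identical(call$status, "present")
  expect_equal(call$diagnostics$cosine_similarity, 1, tolerance = 1e-12)
  env <- isotope_envelope(pep)
  cmp_ab <- env$relative_abundances[
    seq_len(which(cumsum(env$relative_abundances) >= 0.95)[1])]
  expect_equal(call$intensity, 1000 * sum(cmp_ab), tolerance = 1e-9)

  # empty vicinity: absent with zero intensity
  far <- cbind(mz = c(400, 900), intensity = c(10, 10))
  call2 <- find_envelope(far, pep, 2, cfg)
  expect_identical(call2$status, "absent")
  expect_identical(call2$intensity, 0)

  # contaminant at 50% of base peak inside the span: chimeric, unconfident
  base_peak <- 1000 * max(env$relative_abundances)
  mid <- ion_mz(pep$monoisotopic_mass, 2, 0.5)
  scan3 <- scan_with_envelopes(pep, 2, 1000, extra_mz = mid,
                               extra_intensity = 0.5 * base_peak)
  call3 <- find_envelope(scan3, pep, 2, cfg)
  expect_identical(call3$status, "unconfident")
  expect_true(call3$diagnostics$chimeric_flag)

  # contaminant below the chimeric fraction does not invalidate the call
  scan4 <- scan_with_envelopes(pep, 2, 1000, extra_mz = mid,
                               extra_intensity = 0.1 * base_peak)
  expect_identical(find_envelope(scan4, pep, 2, cfg)$status, "present")

  # distorted envelope shape: near positions but wrong ratios
  scan5 <- scan3 <- scan_with_envelopes(pep, 2, 1000)
  scan5[1, "intensity"] <- scan5[1, "intensity"] * 0.2
  call5 <- find_envelope(scan5, pep, 2, cfg)
  expect_identical(call5$status, "unconfident")
  expect_lt(call5$diagnostics$cosine_similarity, 0.98)

  # a charge whose monoisotopic m/z is out of the window is unobservable
  heavy <- generate_peptides(1, mass_range = c(2500, 4600), seed = 3)[[1]]
  expect_identical(
    find_envelope(cbind(mz = 1000, intensity = 1), heavy, 1, cfg)$status,
    "unobservable")
})

test_that("tightening the cosine threshold never adds present calls", {
  peps <- generate_peptides(20, seed = 61)
  sim <- render_ms_run(peps, noise = ms_noise(mz_jitter_ppm = 5,
                                              intensity_cv = 0.3),
                       seed = 62)
  loose <- extraction_config(cosine_threshold = 0.9)
  tight <- extraction_config(cosine_threshold = 0.995)
  gt <- sim$ground_truth
  n_loose <- 0; n_tight <- 0; violations <- 0
  for (i in seq_along(peps)) {
    s <- which.min(abs(sim$ms_run$rt - gt$apex_rt[i]))  # apex scan
    for (z in which(gt[i, pcols] > 0)) {
      cl <- find_envelope(sim$ms_run$peaks[[s]], peps[[i]], z, loose)
      ct <- find_envelope(sim$ms_run$peaks[[s]], peps[[i]], z, tight)
      n_loose <- n_loose + (cl$status == "present")
      n_tight <- n_tight + (ct$status == "present")
      if (ct$status == "present" && cl$status != "present") {
        violations <- violations + 1
      }
    }
  }
  expect_identical(violations, 0)
  expect_gt(n_loose, 10)       # the comparison actually exercised calls
  expect_lte(n_tight, n_loose) # stringency is monotone
})

test_that("per-scan CSDs require every charge confident and normalize
           matched intensities", {
  pep <- peptide("ASGQAFELILSPR")
  # charges 2 and 3 present at 100 and 300: CSD (0, .25, .75, 0, 0)
  scan <- scan_with_envelopes(pep, charges = c(2, 3),
                              intensities = c(100, 300))
  res <- per_scan_csd(scan, pep)
  expect_equal(res$csd, c(0, 0.25, 0.75, 0, 0), tolerance = 1e-9)
  env <- isotope_envelope(pep)
  cmp_frac <- sum(env$relative_abundances[
    seq_len(which(cumsum(env$relative_abundances) >= 0.95)[1])])
  expect_equal(res$total_intensity, 400 * cmp_frac, tolerance = 1e-6)

  # any unconfident charge invalidates the scan
  base_peak <- 100 * max(env$relative_abundances)
  bad <- scan_with_envelopes(pep, c(2, 3), c(100, 300),
                             extra_mz = ion_mz(pep$monoisotopic_mass, 2,
                                               0.5),
                             extra_intensity = base_peak)
  expect_null(per_scan_csd(bad, pep))

  # all absent: no reading
  expect_null(per_scan_csd(cbind(mz = 500, intensity = 1), pep))
})

test_that("elution aggregation is an intensity-weighted average", {
  pep <- peptide("ASGQAFELILSPR")
  s1 <- scan_with_envelopes(pep, 2, 100)            # (0,1,0,0,0) @ 100
  s2 <- scan_with_envelopes(pep, c(2, 3), c(150, 150))  # (0,.5,.5,0,0) @ 300
  run <- ms_run(scan_index = 1:2, rt = c(10, 11), peaks = list(s1, s2))
  reading <- extract_peptide(run, pep, 2, 10)
  # weights are matched intensities: 100 and 300 (up to the shared
  # compared-envelope fraction, which cancels in the weighting)
  expect_equal(reading$csd, c(0, 0.625, 0.375, 0, 0), tolerance = 1e-9)
  expect_identical(reading$n_scans, 2L)

  # single valid scan: that scan's CSD unchanged
  run1 <- ms_run(1, 10, list(s2))
  expect_equal(extract_peptide(run1, pep, 2, 10)$csd,
               c(0, 0.5, 0.5, 0, 0), tolerance = 1e-9)

  # no scans in the window: no reading
  expect_null(extract_peptide(run, pep, 2, 500))
})

test_that("run-level extraction recovers ground truth on a noiseless run
           and deduplicates identifications", {
  peps <- generate_peptides(30, seed = 201)
  sim <- render_ms_run(peps, seed = 202)
  readings <- extract_run(sim$ms_run, sim$identifications)
  gt <- sim$ground_truth
  rt <- roundtrip_tv(readings, gt)
  target <- gt$sequence[gt$observable & gt$clean]
  expect_true(all(target %in% readings$sequence))
  expect_lt(max(rt$tv[rt$observable & rt$clean]), 1e-9)
  # every emitted CSD is a valid distribution
  for (i in seq_len(nrow(readings))) {
    expect_silent(validate_csd(as.numeric(readings[i, pcols])))
  }

  # duplicate identifications collapse to one row per unique peptide
  dup_ids <- rbind(sim$identifications, sim$identifications[1:5, ])
  readings2 <- extract_run(sim$ms_run, dup_ids)
  expect_identical(nrow(readings2), nrow(readings))
  expect_identical(anyDuplicated(paste(readings2$sequence,
                                       readings2$modifications)), 0L)
})

test_that("contaminant injection reduces yield but never corrupts the
           emitted readings", {
  peps <- generate_peptides(40, seed = 211)
  clean_sim <- render_ms_run(peps, seed = 212)
  chim_sim <- render_ms_run(peps, noise = ms_noise(chimeric_rate = 0.3),
                            seed = 212)
  r_clean <- extract_run(clean_sim$ms_run, clean_sim$identifications)
  r_chim <- extract_run(chim_sim$ms_run, chim_sim$identifications)
  expect_lte(sum(r_chim$n_scans), sum(r_clean$n_scans))
  # whatever survives the filters is still exact (no other noise source)
  rt <- roundtrip_tv(r_chim, chim_sim$ground_truth)
  expect_lt(max(rt$tv[rt$observable]), 1e-9)
})
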