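test_that("generated peptides obey protease and mass constraints,
           deterministically per seed", {
  peps <- generate_peptides(100, seed = 7)
  expect_length(peps, 100)
  last <- vapply(peps, function(p) p$residues[length(p$residues)], "")
  expect_true(all(last %in% c("K", "R")))
  internal_kr <- vapply(peps, function(p)
    sum(p$residues[-length(p$residues)] %in% c("K", "R")), numeric(1))
  expect_true(all(internal_kr <= 2))
  masses <- vapply(peps, `[[`, 0, "monoisotopic_mass")
  expect_true(all(masses >= 700 & masses <= 4600))
  expect_true(all(vapply(peps, function(p) length(p$residues), 0L) >= 7))

  again <- generate_peptides(100, seed = 7)
  expect_identical(vapply(again, `[[`, "", "sequence"),
                   vapply(peps, `[[`, "", "sequence"))

  b <- vapply(generate_peptides(1000, seed = 8), `[[`, 0L,
              "basic_site_count")
  expect_true(all(c(2, 3, 4) %in% b))
  expect_gte(length(unique(b)), 4)

  b3 <- generate_peptides(20, basic_sites = 3, seed = 9)
  expect_true(all(vapply(b3, `[[`, 0L, "basic_site_count") == 3L))
})

test_that("ground-truth CSDs are valid and follow the log-odds chain", {
  zero_model <- charging_model(
    adjacent_log_odds_intercepts = rep(0, 4), mass_slope = 0,
    basic_site_effect = rep(0, 5),
    residue_under = setNames(rep(0, 20), rownames(amino_acid_table())),
    residue_over = setNames(rep(0, 20), rownames(amino_acid_table())),
    nterm_under = setNames(rep(0, 20), rownames(amino_acid_table())),
    nterm_over = setNames(rep(0, 20), rownames(amino_acid_table())))
  expect_equal(ground_truth_csd("GGGGGGK", zero_model), rep(0.2, 5),
               tolerance = 1e-12)

  # mean charge non-decreasing in mass when only the mass slope acts
  model <- charging_model()
  peps <- generate_peptides(200, seed = 31)
  masses <- vapply(peps, `[[`, 0, "monoisotopic_mass")
  b <- vapply(peps, `[[`, 0L, "basic_site_count")
  mc <- vapply(peps, function(p)
    mean_charge(ground_truth_csd(p, model)), numeric(1))
  for (bi in unique(b)) {
    sub <- b == bi
    if (sum(sub) < 10) next
    expect_gt(stats::cor(masses[sub], mc[sub], method = "spearman"), 0.7)
  }

  # raising a residue coefficient raises the adjacent odds
  base <- ground_truth_csd("AAAGGGLK", model)
  bumped <- charging_model(residue_over = local({
    v <- model$residue_over; v["A"] <- v["A"] + 1; v
  }))
  alt <- ground_truth_csd("AAAGGGLK", bumped)
  # b = 2 here, so pair (2,3) is on the overcharging side
  expect_gt(alt[3] / alt[2], base[3] / base[2])

  # every CSD is a valid distribution
  for (p in peps[1:50]) expect_silent(validate_csd(ground_truth_csd(p)))
})

test_that("renderer respects the m/z window, conserves noiseless signal,
           and is deterministic per seed", {
  peps <- generate_peptides(15, seed = 71)
  sim <- render_ms_run(peps, seed = 72)
  all_mz <- unlist(lapply(sim$ms_run$peaks, function(m) m[, "mz"]))
  expect_true(all(all_mz >= 300 & all_mz <= 1800))

  sim2 <- render_ms_run(peps, seed = 72)
  expect_identical(sim$ms_run$peaks, sim2$ms_run$peaks)
  expect_identical(sim$identifications, sim2$identifications)

  # with noise off, per-scan signal of an isolated peptide equals its
  # Gaussian profile (times the in-window envelope fraction)
  one <- render_ms_run(peps[1], seed = 73)
  gt <- one$ground_truth
  i <- which(vapply(one$ms_run$peaks, nrow, 0L) > 0)
  tot <- vapply(i, function(s) sum(one$ms_run$peaks[[s]][, "intensity"]),
                numeric(1))
  profile <- gt$amplitude *
    exp(-(one$ms_run$rt[i] - gt$apex_rt)^2 / (2 * gt$sigma^2))
  if (gt$observable) {
    expect_equal(tot, profile, tolerance = 2e-3)
  }

  expect_true(all(sim$identifications$charge %in% 1:5))
  expect_true(all(sim$identifications$sequence %in%
                    sim$ground_truth$sequence))
})

test_that("chimeric contaminants are injected at the requested rate", {
  peps <- generate_peptides(40, seed = 81)
  sim <- render_ms_run(peps, noise = ms_noise(chimeric_rate = 0.2),
                       seed = 82)
  # total envelope count: scans in the 4-sigma elution times support size
  gt <- sim$ground_truth
  n_env <- sum(vapply(seq_len(nrow(gt)), function(i) {
    scans <- sum(abs(sim$ms_run$rt - gt$apex_rt[i]) <= 4 * gt$sigma[i])
    support <- sum(gt[i, pcols] > 0)
    scans * support
  }, numeric(1)))
  frac <- nrow(sim$chimeric) / n_env
  expect_gt(frac, 0.15)
  expect_lt(frac, 0.25)
})

test_that("simulated readings reproduce ground truth exactly without
           noise and stay close with noise", {
  peps <- generate_peptides(50, seed = 91)
  exact <- simulate_csd_readings(peps, csd_noise_cv = 0)
  for (i in seq_len(nrow(exact))) {
    expect_equal(as.numeric(exact[i, pcols]),
                 ground_truth_csd(peps[[i]]), tolerance = 1e-12)
  }
  noisy <- simulate_csd_readings(peps, csd_noise_cv = 0.1, seed = 92)
  tv <- rowSums(abs(as.matrix(noisy[, pcols]) -
                      as.matrix(exact[, pcols]))) / 2
  expect_gt(mean(tv), 0)
  expect_lt(stats::median(tv), 0.1)
})
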