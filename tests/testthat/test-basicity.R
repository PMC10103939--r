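test_that("region labels and fractional targets follow the charging-region
           rules", {
  regs <- canonical_regions()
  expect_identical(vapply(regs, `[[`, "", "label"),
                   c(`#2O` = "#2O", `#3O` = "#3O", `#3U` = "#3U",
                     `#4U` = "#4U"))
  expect_warning(charging_region(4, 2), "non-canonical")

  r3u <- regs[["#3U"]]
  # three basic sites, charging across 2+/3+
  expect_equal(assign_region(c(0, 0.44, 0.56, 0, 0), 3, r3u), 0.56)
  # wrong basic-site count, variable mods, or empty charge pair: excluded
  expect_true(is.na(assign_region(c(0, 0.44, 0.56, 0, 0), 2, r3u)))
  expect_true(is.na(assign_region(c(0, 0.44, 0.56, 0, 0), 3, r3u,
                                  variable_mods = TRUE)))
  expect_true(is.na(assign_region(c(0.5, 0, 0, 0.5, 0), 3, r3u)))
})

test_that("feature vectors encode counts and N-terminal identity", {
  f <- build_features("AAR")
  expect_identical(sum(f), 3 + 1)  # counts sum to length, one indicator
  expect_identical(unname(f["count_A"]), 2)
  expect_identical(unname(f["count_R"]), 1)
  expect_identical(unname(f["nterm_A"]), 1)
  expect_identical(sum(f[grep("^nterm_", names(f))]), 1)
  f2 <- build_features("RTNSTFNQVVLK")
  expect_identical(unname(f2["nterm_R"]), 1)
  expect_identical(sum(f2[grep("^count_", names(f2))]), 12)
  expect_error(build_features("AZA"), "invalid residue")
})

test_that("fractional logistic regression agrees with an independent GLM
           at lambda = 0 and shrinks under heavy ridge", {
  set.seed(15)
  n <- 400
  X <- cbind(rnorm(n), rpois(n, 3), runif(n))
  eta <- -0.5 + X %*% c(0.8, -0.3, 1.2)
  y <- plogis(eta + rnorm(n, 0, 0.3))
  fit <- fractional_logit_fit(X, y, lambda = 0)
  glm_fit <- suppressWarnings(
    glm(y ~ X, family = quasibinomial()))
  expect_equal(fit$intercept, unname(coef(glm_fit)[1]), tolerance = 1e-6)
  expect_equal(fit$coefficients, unname(coef(glm_fit)[-1]),
               tolerance = 1e-6)

  heavy <- fractional_logit_fit(X, y, lambda = 1e8)
  expect_lt(max(abs(heavy$coefficients)), 1e-4)
  # intercept is unpenalized: absorbs the mean response
  expect_equal(plogis(heavy$intercept), mean(y), tolerance = 1e-3)

  # intercept-only closed form
  const <- fractional_logit_fit(matrix(nrow = 50, ncol = 0),
                                rep(0.3, 50), lambda = 0)
  expect_equal(const$intercept, qlogis(0.3), tolerance = 1e-8)

  # collinear design rejected at lambda = 0
  expect_error(fractional_logit_fit(cbind(X, X[, 1]), y, lambda = 0),
               "rank-deficient")
})

test_that("intrinsic-basicity coefficients recover the generator's
           residue effects", {
  model <- charging_model()
  reg <- canonical_regions()[["#3U"]]
  peps <- generate_peptides(2500, basic_sites = 3, seed = 401)
  readings <- simulate_csd_readings(peps, model, csd_noise_cv = 0.1,
                                    seed = 402)
  prof <- fit_intrinsic_basicity(readings, reg, run_id = "sim")
  truth <- implied_count_coefficients(model, "under")
  nb <- setdiff(names(truth), c("R", "K", "H"))
  expect_gte(cor(prof$count_coefficients[nb], truth[nb]), 0.9)
  # N-terminal basic residues suppress charging on the undercharging side
  expect_lt(prof$nterm_coefficients["R"], prof$nterm_coefficients["G"])
  expect_identical(prof$n_peptides + sum(is.na(
    vapply(seq_len(nrow(readings)), function(i)
      assign_region(as.numeric(readings[i, pcols]),
                    readings$basic_sites[i], reg), numeric(1)))),
    nrow(readings))
})

test_that("run qualification applies the strict >100 rule per region", {
  model <- charging_model()
  mk <- function(n_per_region) {
    rows <- list()
    for (reg in canonical_regions()) {
      target_mass <- if (region_side(reg) == "under") c(900, 2200)
                     else c(1800, 3600)
      peps <- generate_peptides(n_per_region,
                                basic_sites = reg$basic_sites,
                                mass_range = target_mass,
                                seed = 500 + reg$basic_sites * 7 +
                                  reg$lower_charge)
      rows[[reg$label]] <- simulate_csd_readings(peps, model)
    }
    do.call(rbind, rows)
  }
  readings <- mk(170)
  expect_true(run_qualifies(readings))
  expect_false(run_qualifies(readings[1:120, ]))
  expect_false(run_qualifies(readings,
                             config = basicity_config(
                               min_region_peptides = 1e6)))
  counts <- attr(run_qualifies(readings), "counts")
  expect_length(counts, 4)
  # boundary: exactly min_region_peptides eligible peptides is not enough
  eligible_b2 <- readings[readings$basic_sites == 2 &
                            readings$p2 > 0 & readings$p3 > 0, ]
  one_region <- eligible_b2[1:100, ]
  expect_false(run_qualifies(one_region,
                             regions = canonical_regions()["#2O"]))
  expect_true(run_qualifies(one_region,
                            regions = canonical_regions()["#2O"],
                            config = basicity_config(
                              min_region_peptides = 99)))
})

test_that("Huber mass adjustment removes the mass trend robustly", {
  aa <- amino_acid_table()
  masses <- setNames(aa$monoisotopic_mass, aa$aa)
  masses["C"] <- masses["C"] + 57.02146
  nb <- setdiff(aa$aa, c("R", "K", "H"))

  # exactly linear coefficients: residuals all zero
  lin <- 0.05 + 0.002 * masses[nb]
  expect_lt(max(abs(mass_adjust(lin))), 1e-8)

  # one large outlier: near-L1 fit leaves it intact, others near zero
  out <- lin
  out["Q"] <- out["Q"] + 0.5
  res <- mass_adjust(out)
  expect_equal(unname(res["Q"]), 0.5, tolerance = 0.02)
  expect_lt(max(abs(res[setdiff(nb, "Q")])), 0.02)

  # optimality against a brute-force 2-parameter grid oracle
  huber_obj <- function(a, b, delta = 0.01) {
    r <- out - (a + b * masses[nb])
    sum(ifelse(abs(r) <= delta, r^2 / 2, delta * (abs(r) - delta / 2)))
  }
  fit <- attr(res, "fit")
  grid_best <- min(outer(
    seq(fit[1] - 0.02, fit[1] + 0.02, length.out = 81),
    seq(fit[2] - 2e-4, fit[2] + 2e-4, length.out = 81),
    Vectorize(huber_obj)))
  expect_lte(huber_obj(fit[1], fit[2]), grid_best + 1e-10)

  # affine-in-mass shifts leave residuals unchanged
  shifted <- out + 0.3 + 0.001 * masses[nb]
  expect_equal(mass_adjust(shifted), res, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("profile correlations and clustering separate coefficient
           regimes", {
  mk_prof <- function(coefs, label, run_id) {
    reg <- canonical_regions()[[label]]
    structure(list(count_coefficients = coefs,
                   nterm_coefficients = setNames(rep(0, 20), names(coefs)),
                   intercept = 0, region = reg, run_id = run_id,
                   n_peptides = 1000), class = "basicity_profile")
  }
  set.seed(16)
  aa20 <- rownames(amino_acid_table())
  base_o <- setNames(rnorm(20), aa20)
  base_u <- setNames(rnorm(20), aa20)
  profs <- list(
    mk_prof(base_o + rnorm(20, 0, 0.05), "#2O", "r1"),
    mk_prof(base_o + rnorm(20, 0, 0.05), "#3O", "r1"),
    mk_prof(base_u + rnorm(20, 0, 0.05), "#3U", "r1"),
    mk_prof(base_u + rnorm(20, 0, 0.05), "#4U", "r1"))
  R <- profile_correlations(profs)
  expect_equal(unname(diag(R)), rep(1, 4), tolerance = 1e-12)
  expect_equal(R, t(R), tolerance = 1e-12)
  neg <- profile_correlations(list(profs[[1]], mk_prof(-base_o, "#2O",
                                                       "r2")))
  expect_lt(neg[1, 2], -0.9)

  cl <- cluster_profiles(R, k = 2)
  lab <- unname(cl$labels)
  expect_identical(lab[1], lab[2])
  expect_identical(lab[3], lab[4])
  expect_false(lab[1] == lab[3])

  # permutation invariance of memberships
  cl2 <- cluster_profiles(R[c(3, 1, 4, 2), c(3, 1, 4, 2)], k = 2)
  lab2 <- unname(cl2$labels)
  expect_identical(lab2[2] == lab2[4], lab[1] == lab[2])
  expect_error(cluster_profiles(R[1, 1, drop = FALSE]), "at least 2")
})
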