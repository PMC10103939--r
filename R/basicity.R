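## Region-stratified intrinsic-basicity estimation: feature construction,
## fractional-target logistic regression with L2 regularization, robust
## (Huber) mass adjustment, run-qualification filters, and region-run
## correlation / clustering.

#' Define a charging region
#'
#' A charging region selects peptides with `basic_sites` basic sites and
#' analyzes charging across the adjacent charge states `lower_charge` and
#' `lower_charge + 1`. The four canonical regions are #2O (b=2, 2+/3+),
#' #3O (b=3, 3+/4+), #3U (b=3, 2+/3+) and #4U (b=4, 3+/4+); "O" marks
#' regions where the lower charge equals the basic-site count
#' (overcharging side), "U" regions where the upper charge does
#' (undercharging side). Other combinations are allowed but flagged
#' non-canonical.
#'
#' @param basic_sites Basic-site count b.
#' @param lower_charge Lower charge k of the adjacent pair.
#' @return An object of class `charging_region` with a derived `label`.
#' @examples
#' charging_region(3, 2)  # region #3U
#' @export
charging_region <- function(basic_sites, lower_charge) {
  stopifnot(basic_sites >= 1, lower_charge >= 1, lower_charge <= 4)
  side <- if (lower_charge == basic_sites) "O"
          else if (lower_charge + 1 == basic_sites) "U"
          else "?"
  label <- paste0("#", basic_sites, side)
  canonical <- label %in% c("#2O", "#3O", "#3U", "#4U")
  if (!canonical) {
    warning("non-canonical charging region ", label,
            " (b=", basic_sites, ", k=", lower_charge, ")")
  }
  structure(list(basic_sites = as.integer(basic_sites),
                 lower_charge = as.integer(lower_charge),
                 label = label, canonical = canonical),
            class = "charging_region")
}

#' The four canonical charging regions
#' @return Named list of `charging_region` objects (#2O, #3O, #3U, #4U).
#' @export
canonical_regions <- function() {
  list(`#2O` = charging_region(2, 2), `#3O` = charging_region(3, 3),
       `#3U` = charging_region(3, 2), `#4U` = charging_region(4, 3))
}

#' @export
print.charging_region <- function(x, ...) {
  cat(sprintf("<charging_region> %s: %d basic sites, charging %d+/%d+\n",
              x$label, x$basic_sites, x$lower_charge, x$lower_charge + 1L))
  invisible(x)
}

#' Fractional regression target of a reading within a region
#'
#' A reading is eligible when its basic-site count matches the region, it
#' carries no variable modifications, and the two charge states in
#' question have nonzero combined probability; the target is then
#' `p(k+1) / (pk + p(k+1))`.
#'
#' @param csd A valid CSD.
#' @param basic_sites Basic-site count of the peptide.
#' @param region A `charging_region`.
#' @param variable_mods Logical, whether the peptide carries variable
#'   modifications (excluded when `TRUE`).
#' @return The fractional target in \[0, 1\], or `NA_real_` when
#'   excluded.
#' @export
assign_region <- function(csd, basic_sites, region, variable_mods = FALSE) {
  validate_csd(csd)
  if (basic_sites != region$basic_sites || isTRUE(variable_mods)) {
    return(NA_real_)
  }
  k <- region$lower_charge
  denom <- csd[k] + csd[k + 1]
  if (denom <= 0) return(NA_real_)
  csd[k + 1] / denom
}

#' Composition features of a peptide sequence
#'
#' The 40 regression features: 20 amino-acid counts followed by 20 binary
#' indicators of the N-terminal residue identity.
#'
#' @param sequence Peptide sequence string (or `peptide_record`).
#' @return Named numeric vector of length 40 (`count_A`..`count_W`,
#'   `nterm_A`..`nterm_W`, in fixed residue order).
#' @export
build_features <- function(sequence) {
  if (inherits(sequence, "peptide_record")) sequence <- sequence$sequence
  residues <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- setdiff(residues, VALID_RESIDUES)
  if (length(bad) > 0) stop("invalid residue letter(s): ",
                            paste(unique(bad), collapse = ", "))
  counts <- as.numeric(table(factor(residues, levels = VALID_RESIDUES)))
  nterm <- as.numeric(VALID_RESIDUES == residues[1])
  stats::setNames(c(counts, nterm),
                  c(paste0("count_", VALID_RESIDUES),
                    paste0("nterm_", VALID_RESIDUES)))
}

#' Configuration for the intrinsic-basicity analysis
#'
#' @param l2_lambda Ridge penalty on the 40 feature coefficients (the
#'   intercept is unpenalized); default 0.01.
#' @param huber_delta Huber transition parameter of the mass-adjustment
#'   regression, on the raw coefficient scale; default 0.01.
#' @param min_region_peptides Strict lower bound on eligible peptides per
#'   canonical region for a run to qualify; default 100.
#' @return A list of class `basicity_config`.
#' @export
basicity_config <- function(l2_lambda = 0.01, huber_delta = 0.01,
                            min_region_peptides = 100) {
  stopifnot(l2_lambda >= 0, huber_delta > 0, min_region_peptides >= 0)
  structure(list(l2_lambda = l2_lambda, huber_delta = huber_delta,
                 min_region_peptides = min_region_peptides),
            class = "basicity_config")
}

#' Fractional-response ridge logistic regression
#'
#' Minimizes `sum(BCE(y_i, sigmoid(x_i w + w0))) + lambda * ||w||^2` over
#' coefficients `w` and unpenalized intercept `w0`, where the binary
#' cross-entropy loss accepts fractional targets `y` in \[0, 1\] natively
#' (no pseudo-observation expansion). Solved by damped Newton iterations;
#' the objective is convex, and convergence is declared at gradient
#' max-norm below `tol`.
#'
#' @param x Numeric design matrix (n x p), without intercept column.
#' @param y Fractional targets in \[0, 1\].
#' @param lambda Ridge penalty on the `p` coefficients.
#' @param tol Gradient max-norm tolerance (default 1e-8).
#' @param max_iter Maximum Newton iterations.
#' @return List with `intercept`, `coefficients` (length p), `converged`,
#'   `iterations`.
#' @export
fractional_logit_fit <- function(x, y, lambda = 0, tol = 1e-8,
                                 max_iter = 100) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(y), all(y >= 0), all(y <= 1), lambda >= 0)
  if (lambda == 0 && ncol(x) > 0) {
    r <- qr(cbind(1, x))$rank
    if (r < ncol(x) + 1) {
      stop("design matrix is rank-deficient (collinear features); ",
           "use lambda > 0 or drop redundant columns")
    }
  }
  n <- nrow(x); p <- ncol(x)
  X <- cbind(intercept = 1, x)
  pen <- c(0, rep(lambda, p))  # intercept unpenalized
  beta <- rep(0, p + 1)
  obj <- function(b) {
    eta <- drop(X %*% b)
    ## numerically stable BCE: log(1+exp(eta)) - y*eta
    sum(ifelse(eta > 0, eta + log1p(exp(-eta)), log1p(exp(eta))) - y * eta) +
      sum(pen * b^2)
  }
  f <- obj(beta)
  iter <- 0
  repeat {
    iter <- iter + 1
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    grad <- drop(crossprod(X, mu - y)) + 2 * pen * beta
    if (max(abs(grad)) < tol || iter > max_iter) break
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(X * w, X) + diag(2 * pen, p + 1)
    step <- tryCatch(solve(H, grad), error = function(e) {
      solve(H + diag(1e-8, p + 1), grad)
    })
    ## step halving keeps the damped Newton iteration globally convergent
    alpha <- 1
    repeat {
      cand <- beta - alpha * step
      fc <- obj(cand)
      if (fc <= f + 1e-12 || alpha < 1e-8) break
      alpha <- alpha / 2
    }
    beta <- cand
    f <- fc
  }
  list(intercept = unname(beta[1]), coefficients = unname(beta[-1]),
       converged = iter <= max_iter, iterations = iter)
}

#' Fit intrinsic basicities for one charging region
#'
#' Builds the 40 composition features for every eligible reading in the
#' region, and fits the fractional-target ridge logistic regression of
#' [fractional_logit_fit()]. The fitted count coefficients are the
#' calculated intrinsic basicities: the per-amino-acid contribution to the
#' log-odds of carrying the higher of the two charge states.
#'
#' @param readings CSD reading table (see [extract_run()]); rows with
#'   nonempty `modifications` are excluded as variable-modified.
#' @param region A `charging_region`.
#' @param config A [basicity_config()].
#' @param run_id Identifier stored in the profile.
#' @return An object of class `basicity_profile`: `count_coefficients`
#'   and `nterm_coefficients` (named length-20), `intercept`, `region`,
#'   `run_id`, `n_peptides`.
#' @export
fit_intrinsic_basicity <- function(readings, region,
                                   config = basicity_config(),
                                   run_id = NA_character_) {
  pcols <- paste0("p", 1:5)
  csd_mat <- as.matrix(readings[, pcols])
  y <- vapply(seq_len(nrow(readings)), function(i) {
    assign_region(csd_mat[i, ], readings$basic_sites[i], region,
                  variable_mods = nzchar(readings$modifications[i]))
  }, numeric(1))
  keep <- !is.na(y)
  if (sum(keep) < 2) stop("fewer than 2 eligible peptides in region ",
                          region$label)
  y <- y[keep]
  if (stats::var(y) == 0 && config$l2_lambda == 0) {
    stop("constant regression target in region ", region$label)
  }
  X <- t(vapply(readings$sequence[keep], build_features, numeric(40)))
  fit <- fractional_logit_fit(X, y, lambda = config$l2_lambda)
  structure(list(
    count_coefficients = stats::setNames(fit$coefficients[1:20],
                                         VALID_RESIDUES),
    nterm_coefficients = stats::setNames(fit$coefficients[21:40],
                                         VALID_RESIDUES),
    intercept = fit$intercept, region = region, run_id = run_id,
    n_peptides = sum(keep), converged = fit$converged),
    class = "basicity_profile")
}

#' @export
print.basicity_profile <- function(x, ...) {
  top <- sort(x$count_coefficients[NON_BASIC_RESIDUES], decreasing = TRUE)
  cat(sprintf(paste0("<basicity_profile> region %s, run %s, %d peptides\n",
                     "  highest: %s  lowest: %s\n"),
              x$region$label, x$run_id, x$n_peptides,
              paste(sprintf("%s=%.2f", names(top)[1:3], top[1:3]),
                    collapse = " "),
              paste(sprintf("%s=%.2f", rev(names(top))[1:3],
                            rev(top)[1:3]), collapse = " ")))
  invisible(x)
}

#' Does a run qualify for the basicity analysis?
#'
#' A run qualifies when every canonical region contains strictly more than
#' `min_region_peptides` eligible peptides exhibiting nonzero probability
#' on both charge states in question.
#'
#' @param readings CSD reading table.
#' @param regions List of `charging_region`s (default the four canonical
#'   ones).
#' @param config A [basicity_config()].
#' @return Logical; per-region counts attached as attribute `"counts"`.
#' @export
run_qualifies <- function(readings, regions = canonical_regions(),
                          config = basicity_config()) {
  pcols <- paste0("p", 1:5)
  csd_mat <- as.matrix(readings[, pcols])
  counts <- vapply(regions, function(reg) {
    k <- reg$lower_charge
    sum(readings$basic_sites == reg$basic_sites &
          !nzchar(readings$modifications) &
          csd_mat[, k] > 0 & csd_mat[, k + 1] > 0)
  }, numeric(1))
  ok <- all(counts > config$min_region_peptides)
  attr(ok, "counts") <- counts
  ok
}

## Huber loss IRLS: minimize sum(rho_delta(y - a - b*x)). Weights are 1 in
## the quadratic core and delta/|r| in the linear tails.
.huber_line_fit <- function(x, y, delta, tol = 1e-8, max_iter = 500) {
  X <- cbind(1, x)
  beta <- drop(solve(crossprod(X), crossprod(X, y)))  # OLS start
  for (i in seq_len(max_iter)) {
    r <- y - drop(X %*% beta)
    w <- ifelse(abs(r) <= delta, 1, delta / pmax(abs(r), 1e-300))
    new_beta <- drop(solve(crossprod(X * w, X), crossprod(X * w, y)))
    if (max(abs(new_beta - beta)) < tol) {
      return(list(coefficients = new_beta, iterations = i,
                  converged = TRUE))
    }
    beta <- new_beta
  }
  stop("Huber regression did not converge within ", max_iter, " iterations")
}

#' Mass-adjusted intrinsic basicities
#'
#' Removes the portion of the intrinsic basicities explained by residue
#' mass: fits `basicity ~ a + b * mass` over the 17 non-basic amino acids
#' by minimizing a Huber loss (quadratic below `delta`, linear above;
#' effectively L1 with a smooth core at the default `delta` = 0.01, so
#' amino acids far off the mass trend are not over-penalized), and returns
#' the residuals.
#'
#' @param profile A `basicity_profile`, or a named numeric vector of count
#'   coefficients covering the 17 non-basic residues.
#' @param config A [basicity_config()] (supplies `huber_delta`).
#' @param use_modified_cys_mass Use the fixed-modification cysteine mass
#'   (carbamidomethyl by default) as C's residue mass (default `TRUE`).
#' @param fixed_cys_mod Which fixed cysteine modification to apply when
#'   `use_modified_cys_mass` is `TRUE`.
#' @return Named residual vector over the 17 non-basic amino acids, with
#'   the fitted line as attribute `"fit"`.
#' @export
mass_adjust <- function(profile, config = basicity_config(),
                        use_modified_cys_mass = TRUE,
                        fixed_cys_mod = c("carbamidomethyl",
                                          "n_ethylmaleimide")) {
  fixed_cys_mod <- match.arg(fixed_cys_mod)
  coefs <- if (inherits(profile, "basicity_profile"))
    profile$count_coefficients else profile
  if (!all(NON_BASIC_RESIDUES %in% names(coefs))) {
    stop("need coefficients for all 17 non-basic amino acids")
  }
  v <- coefs[NON_BASIC_RESIDUES]
  masses <- .aa_masses()[NON_BASIC_RESIDUES]
  if (use_modified_cys_mass) {
    mod_name <- switch(fixed_cys_mod,
                       carbamidomethyl = "Carbamidomethyl (C)",
                       n_ethylmaleimide = "N-ethylmaleimide (C)")
    masses["C"] <- masses["C"] + .mod_row(mod_name)$monoisotopic_delta
  }
  fit <- .huber_line_fit(masses, v, delta = config$huber_delta)
  res <- v - (fit$coefficients[1] + fit$coefficients[2] * masses)
  attr(res, "fit") <- fit$coefficients
  res
}

#' Pearson correlations between basicity profiles
#'
#' Correlation matrix over all region-run profile pairs, computed on the
#' count coefficients of the 17 non-basic amino acids.
#'
#' @param profiles List of `basicity_profile`s.
#' @return Symmetric correlation matrix, labelled `region/run`; entries
#'   involving a constant coefficient vector are `NA`.
#' @export
profile_correlations <- function(profiles) {
  stopifnot(length(profiles) >= 1)
  M <- vapply(profiles, function(p)
    p$count_coefficients[NON_BASIC_RESIDUES], numeric(17))
  labels <- vapply(profiles, function(p)
    paste(p$region$label, p$run_id, sep = "/"), "")
  colnames(M) <- make.unique(labels)
  constant <- apply(M, 2, stats::sd) == 0
  if (any(constant)) {
    warning("constant coefficient vector(s): ",
            paste(colnames(M)[constant], collapse = ", "))
  }
  suppressWarnings(stats::cor(M))
}

#' Cluster basicity profiles by correlation
#'
#' Hierarchical agglomerative clustering with average linkage on the
#' distance 1 - r.
#'
#' @param correlations Correlation matrix from [profile_correlations()].
#' @param k Number of clusters for the cut (default 2, the
#'   overcharging/undercharging split).
#' @return List with `order` (leaf order), `labels` (cluster memberships,
#'   named), and the `hclust` object.
#' @export
cluster_profiles <- function(correlations, k = 2) {
  if (nrow(correlations) < 2) stop("need at least 2 profiles to cluster")
  d <- stats::as.dist(1 - correlations)
  hc <- stats::hclust(d, method = "average")
  list(order = hc$order, labels = stats::cutree(hc, k = k), hclust = hc)
}
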