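## CSD comparison and batch correction.
##
## A charge state distribution (CSD) is represented throughout the package
## as a plain numeric vector of length 5: probabilities over charges 1+..5+.

#' Validate a charge state distribution
#'
#' @param p Numeric vector of length 5, nonnegative, summing to 1.
#' @param tol Tolerance on the sum (default 1e-6).
#' @return `p`, invisibly, or an error.
#' @export
validate_csd <- function(p, tol = 1e-6) {
  if (!is.numeric(p) || length(p) != 5L) {
    stop("a CSD must be a numeric vector of 5 charge-state probabilities")
  }
  if (any(p < 0)) stop("CSD probabilities must be nonnegative")
  if (abs(sum(p) - 1) > tol) {
    stop("CSD probabilities must sum to 1 (got ", format(sum(p)), ")")
  }
  invisible(p)
}

#' Total variation distance between two CSDs
#'
#' Half the sum of absolute probability differences. Ranges from 0
#' (identical) to 1 (disjoint support); the package's standard error
#' measure between CSD readings of the same peptide.
#'
#' @param p,q Valid CSDs (see [validate_csd()]).
#' @return A number in \[0, 1\].
#' @examples
#' total_variation(c(0.96, 0.04, 0, 0, 0), c(0.88, 0.12, 0, 0, 0))  # 0.08
#' @export
total_variation <- function(p, q) {
  validate_csd(p)
  validate_csd(q)
  sum(abs(p - q)) / 2
}

#' Apply a one-parameter batch correction to a CSD
#'
#' Scales the probability of charge state k+ by beta^k and renormalizes:
#' an additive shift on the log-probability ("energy") scale whose magnitude
#' is linear in charge. beta > 1 shifts mass towards higher charges.
#' Zero-probability charge states stay exactly zero.
#'
#' @param p A valid CSD.
#' @param beta Positive batch parameter.
#' @return The corrected CSD.
#' @export
apply_batch_correction <- function(p, beta) {
  validate_csd(p)
  if (!is.numeric(beta) || length(beta) != 1L || beta <= 0) {
    stop("beta must be a positive scalar")
  }
  w <- beta^(1:5) * p
  w / sum(w)
}

## Golden-section minimization of f on [lo, hi].
.golden_section <- function(f, lo, hi, tol = 1e-4) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  x1 <- b - gr * (b - a)
  x2 <- a + gr * (b - a)
  f1 <- f(x1); f2 <- f(x2)
  while (b - a > tol) {
    if (f1 <= f2) {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - gr * (b - a); f1 <- f(x1)
    } else {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + gr * (b - a); f2 <- f(x2)
    }
  }
  (a + b) / 2
}

## Shared-peptide CSD matrices for two reading tables (see extract_run for
## the table layout). Peptides are keyed by sequence + modifications.
.shared_csds <- function(readings_a, readings_b) {
  key <- function(d) paste(d$sequence, d$modifications, sep = "//")
  ka <- key(readings_a); kb <- key(readings_b)
  shared <- intersect(ka, kb)
  if (length(shared) == 0) stop("no shared peptides between the two runs")
  pcols <- paste0("p", 1:5)
  list(a = as.matrix(readings_a[match(shared, ka), pcols]),
       b = as.matrix(readings_b[match(shared, kb), pcols]),
       peptides = shared)
}

.mean_tv <- function(A, B) {
  mean(rowSums(abs(A - B)) / 2)
}

#' Mean replicate error between two runs
#'
#' Arithmetic mean of the per-peptide total variation over peptides with a
#' CSD reading in both runs.
#'
#' @param readings_a,readings_b CSD reading tables as returned by
#'   [extract_run()] (must contain `sequence`, `modifications`, `p1`..`p5`).
#' @return Mean total variation.
#' @export
replicate_error <- function(readings_a, readings_b) {
  s <- .shared_csds(readings_a, readings_b)
  .mean_tv(s$a, s$b)
}

#' Fit a one-parameter batch correction between two runs
#'
#' Finds the beta minimizing the total error, i.e. the sum of total
#' variation between corrected run-A readings and run-B readings over all
#' shared peptides, by golden-section search on log(beta) in \[-2, 2\].
#'
#' @inheritParams replicate_error
#' @param log_beta_range Search interval on the natural-log scale.
#' @param tol Golden-section tolerance on log(beta).
#' @return List with `beta`, `corrected_error` and `uncorrected_error`
#'   (both mean total variation over shared peptides).
#' @export
fit_batch_correction <- function(readings_a, readings_b,
                                 log_beta_range = c(-2, 2), tol = 1e-4) {
  s <- .shared_csds(readings_a, readings_b)
  corrected_tv <- function(log_beta) {
    beta <- exp(log_beta)
    W <- sweep(s$a, 2, beta^(1:5), "*")
    W <- W / rowSums(W)
    .mean_tv(W, s$b)
  }
  opt <- .golden_section(corrected_tv, log_beta_range[1], log_beta_range[2],
                         tol = tol)
  uncorrected <- .mean_tv(s$a, s$b)
  corrected <- corrected_tv(opt)
  beta <- exp(opt)
  ## beta = 1 is in the search set; never report a correction that hurts
  if (corrected > uncorrected) {
    beta <- 1
    corrected <- uncorrected
  }
  list(beta = beta, corrected_error = corrected,
       uncorrected_error = uncorrected,
       n_shared = length(s$peptides))
}
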