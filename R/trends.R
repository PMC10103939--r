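## Mean charge, under/matched/over regime classification, and monotone
## penalized-spline trends of mean charge versus mass stratified by
## basic-site count.

#' Mean charge of a CSD
#'
#' @param p A valid CSD over charges 1+..5+.
#' @return Expected charge, in \[1, 5\].
#' @export
mean_charge <- function(p) {
  validate_csd(p)
  sum((1:5) * p)
}

#' Classify a peptide's charging regime
#'
#' A peptide is `matched` when its CSD is concentrated solely on the charge
#' state equal to its basic-site count (probability >= 1 - tol there);
#' otherwise it is `undercharged` when its mean charge is below the
#' basic-site count and `overcharged` when above. The three regimes
#' partition any dataset exhaustively (a non-matched CSD with mean charge
#' exactly equal to the basic-site count is classified `matched`).
#'
#' @param p A valid CSD.
#' @param basic_sites Basic-site count of the peptide.
#' @param tol Tolerance on the concentrated-probability test (default 1e-6).
#' @return One of `"undercharged"`, `"matched"`, `"overcharged"`.
#' @export
classify_regime <- function(p, basic_sites, tol = 1e-6) {
  validate_csd(p)
  stopifnot(length(basic_sites) == 1L, basic_sites >= 1)
  ## charges above 5 cannot be observed: clamp the comparison point and
  ## flag, so e.g. a 6-basic-site peptide is judged against 5+
  b <- basic_sites
  if (b > 5) {
    warning("basic-site count ", b, " above the observable charge range; ",
            "clamped to 5 for regime comparison")
    b <- 5
  }
  m <- mean_charge(p)
  if (p[b] >= 1 - tol || m == b) return("matched")
  if (m < b) "undercharged" else "overcharged"
}

#' Observable charge states for a peptide mass
#'
#' Charges whose monoisotopic ion m/z falls inside the instrument
#' acquisition window.
#'
#' @param mass Neutral monoisotopic mass (Da).
#' @param mz_min,mz_max Instrument m/z window (defaults 300 and 1800).
#' @param charges Candidate charges (default 1..5).
#' @return Integer vector, subset of `charges`.
#' @export
observable_charges <- function(mass, mz_min = 300, mz_max = 1800,
                               charges = 1:5) {
  mz <- ion_mz(mass, charges)
  charges[mz >= mz_min & mz <= mz_max]
}

#' Fit a monotone spline trend of mean charge versus mass
#'
#' Penalized least-squares fit over a cubic P-spline basis (default 20
#' basis functions) with a second-order difference penalty and a
#' non-decreasing constraint, enforced through non-negativity of first
#' differences of the spline coefficients (a sufficient condition for
#' monotonicity of a B-spline expansion). Solved with a quadratically
#' constrained penalized least-squares routine.
#'
#' @param mass Numeric vector of peptide masses (Da).
#' @param mean_charge Numeric vector of mean charges, same length.
#' @param n_splines Number of cubic basis functions (default 20).
#' @param smoothing Second-difference penalty weight (default 5).
#' @param basic_site_count Optional integer attached to the curve for
#'   regime bookkeeping.
#' @return An object of class `csd_trend` with a `predict()` method.
#' @export
fit_trend <- function(mass, mean_charge, n_splines = 20, smoothing = 5,
                      basic_site_count = NA_integer_) {
  stopifnot(length(mass) == length(mean_charge))
  ok <- is.finite(mass) & is.finite(mean_charge)
  mass <- mass[ok]; y <- mean_charge[ok]
  if (length(mass) < n_splines) {
    stop("need at least ", n_splines, " points to fit the trend")
  }
  if (diff(range(mass)) <= 0) stop("degenerate mass range")
  dat <- data.frame(x = mass, y = y)
  sm <- mgcv::smoothCon(mgcv::s(x, k = n_splines, bs = "ps", m = c(2, 2)),
                        data = dat, absorb.cons = FALSE)[[1]]
  X <- sm$X
  k <- ncol(X)
  ## Ain p >= bin encodes non-decreasing coefficients
  Ain <- diff(diag(k))
  G <- list(X = X, y = y, w = rep(1, length(y)),
            S = list(sm$S[[1]]), sp = smoothing, off = 0,
            p = seq(min(y), max(y), length.out = k) +
              seq(0, 1e-6, length.out = k),
            C = matrix(0, 0, 0), Ain = Ain, bin = rep(0, k - 1))
  coefs <- mgcv::pcls(G)
  structure(list(sm = sm, coefficients = coefs,
                 domain = range(mass),
                 n_splines = n_splines, smoothing = smoothing,
                 basic_site_count = basic_site_count,
                 n_points = length(y)),
            class = "csd_trend")
}

#' Evaluate a fitted trend curve
#'
#' @param object A `csd_trend`.
#' @param mass Masses at which to evaluate; clamped to the fitted domain.
#' @param ... Unused.
#' @return Fitted mean charge at each mass.
#' @export
predict.csd_trend <- function(object, mass, ...) {
  x <- pmin(pmax(mass, object$domain[1]), object$domain[2])
  X <- mgcv::PredictMat(object$sm, data.frame(x = x))
  drop(X %*% object$coefficients)
}

#' @export
print.csd_trend <- function(x, ...) {
  cat(sprintf(paste0("<csd_trend> %d points, mass %.0f-%.0f Da, ",
                     "%d splines, smoothing %g%s\n"),
              x$n_points, x$domain[1], x$domain[2], x$n_splines, x$smoothing,
              if (!is.na(x$basic_site_count))
                sprintf(", b=%d", x$basic_site_count) else ""))
  invisible(x)
}

#' Mass at which a trend crosses into overcharging
#'
#' Smallest mass in the fitted domain where the fitted mean charge reaches
#' the basic-site count (the dashed-to-solid switch in mean-charge-vs-mass
#' trend plots), or `NA` if the curve never crosses.
#'
#' @param curve A `csd_trend`.
#' @param basic_sites Basic-site count; defaults to the one stored in the
#'   curve.
#' @param grid_size Resolution of the evaluation grid.
#' @return Mass in Da, or `NA_real_`.
#' @export
regime_transition_mass <- function(curve, basic_sites = NULL,
                                   grid_size = 512) {
  b <- if (is.null(basic_sites)) curve$basic_site_count else basic_sites
  if (is.na(b)) stop("no basic-site count available for the transition test")
  grid <- seq(curve$domain[1], curve$domain[2], length.out = grid_size)
  fitted <- predict(curve, grid)
  i <- which(fitted >= b)[1]
  if (is.na(i)) NA_real_ else grid[i]
}
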