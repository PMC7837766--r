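#' @useDynLib dvhgru, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif median quantile cor sd setNames
#' @importFrom utils head tail
NULL

# Fixed percent-volume grid: v = 1..100 %, bin width 1 %.
DVH_GRID <- 1:100
DVH_NBINS <- 100L

# Equality tolerance for dose comparisons, Gy (absolute).
DOSE_TOL <- 1e-9

#' Construct and validate a cumulative dose-volume histogram
#'
#' A `dvh` object is a cumulative DVH sampled on the fixed percent-volume
#' grid: `doses[j]` is the dose (Gy) received by at least `j`% of the organ
#' volume, for `j = 1, ..., 100`. The curve must be non-negative and
#' monotone non-increasing in volume.
#'
#' @param doses Numeric vector of exactly 100 doses in Gy, ordered by
#'   percent volume 1..100.
#' @return An object of class `dvh` (a numeric vector of length 100 with an
#'   attached volume grid).
#' @examples
#' d <- dvh(seq(60, 0, length.out = 100))
#' max_dose(d)
#' @export
dvh <- function(doses) {
  doses <- as.numeric(doses)
  validate_dvh_doses(doses)
  structure(doses, class = "dvh")
}

validate_dvh_doses <- function(doses) {
  if (length(doses) != DVH_NBINS) {
    stop("a DVH must have exactly ", DVH_NBINS, " dose bins, got ",
         length(doses), call. = FALSE)
  }
  if (anyNA(doses)) stop("DVH doses contain NA", call. = FALSE)
  if (any(doses < 0)) {
    j <- which(doses < 0)[1L]
    stop(sprintf("DVH doses must be non-negative; doses[%d] = %g Gy", j,
                 doses[j]), call. = FALSE)
  }
  dd <- diff(doses)
  if (any(dd > DOSE_TOL)) {
    j <- which(dd > DOSE_TOL)[1L]
    stop(sprintf(
      "DVH doses must be non-increasing in volume; doses[%d] = %g < doses[%d] = %g Gy",
      j, doses[j], j + 1L, doses[j + 1L]), call. = FALSE)
  }
  invisible(doses)
}

#' @export
print.dvh <- function(x, ...) {
  cat(sprintf(
    "<dvh> 100 bins (v = 1..100%%), Dmax(1%%) = %.2f Gy, mean = %.2f Gy\n",
    x[1L], mean(unclass(x))))
  invisible(x)
}

is_dvh <- function(x) inherits(x, "dvh")

#' Resample an arbitrary cumulative DVH onto the percent-volume grid
#'
#' Takes a cumulative DVH given as (dose, volume) sample points, with
#' cumulative volume in percent non-increasing in dose, and inverts it by
#' linear interpolation in the (volume -> dose) direction onto the fixed
#' grid v = 1..100 %. Vertical steps (several doses at the same volume) are
#' resolved by taking the maximum dose at that volume, which is the
#' conservative choice for serial organs.
#'
#' @param samples A two-column matrix or data.frame: dose (Gy), cumulative
#'   volume (%). At least two points; volumes must span \[0, 100\].
#' @return A [dvh] object.
#' @examples
#' # straight-line DVH V(d) = 100 - d
#' d <- resample_dvh(cbind(dose = 0:100, volume = 100:0))
#' d[1]   # 99 Gy at v = 1%
#' @export
resample_dvh <- function(samples) {
  samples <- as.matrix(samples)
  if (ncol(samples) != 2L || nrow(samples) < 2L) {
    stop("samples must be an n x 2 (dose, volume) table with n >= 2",
         call. = FALSE)
  }
  dose <- as.numeric(samples[, 1L])
  vol <- as.numeric(samples[, 2L])
  if (anyNA(dose) || anyNA(vol)) stop("samples contain NA", call. = FALSE)
  ord <- order(dose, -vol)  # vertical steps: larger volume first
  dose <- dose[ord]
  vol <- vol[ord]
  dv <- diff(vol)
  if (any(dv > 1e-9)) {
    j <- which(dv > 1e-9)[1L]
    stop(sprintf(
      paste0("cumulative volume must be non-increasing in dose; ",
             "V(%g Gy) = %g%% < V(%g Gy) = %g%%"),
      dose[j], vol[j], dose[j + 1L], vol[j + 1L]), call. = FALSE)
  }
  if (min(vol) > 1 + 1e-9 || max(vol) < 100 - 1e-9) {
    stop(sprintf(
      "cumulative volume must cover the 1..100%% grid, got [%g, %g]%%",
      min(vol), max(vol)), call. = FALSE)
  }
  # Invert: for each grid volume take the largest dose whose cumulative
  # volume is >= v (ties in volume resolved toward the maximum dose).
  # approx() on (vol, dose) with decreasing vol: reverse so x is increasing;
  # ties = max picks the maximum dose at a repeated volume.
  out <- stats::approx(x = rev(vol), y = rev(dose), xout = DVH_GRID,
                       method = "linear", ties = max)$y
  dvh(pmax(out, 0))
}

#' Generalized equivalent uniform dose (gEUD)
#'
#' The gEUD of a DVH sampled at 100 equal-volume bins is the power mean
#' \deqn{EUD = \left(\sum_j \Delta v \, D_j^a\right)^{1/a}, \quad \Delta v = 0.01,}
#' with organ-specific exponent `a`: `a = 1` gives the mean dose (parallel
#' organs), large `a` approaches the maximum dose (serial organs).
#'
#' @param dvh A [dvh] object (or validated numeric vector of 100 doses).
#' @param a Exponent, `a >= 1`.
#' @return The gEUD in Gy; always within `[min(doses), max(doses)]`.
#' @examples
#' compute_eud(dvh(rep(50, 100)), a = 8)  # 50
#' @export
compute_eud <- function(dvh, a) {
  doses <- as_dose_vector(dvh)
  if (!is.numeric(a) || length(a) != 1L || is.na(a) || a <= 0) {
    stop("`a` must be a single positive number", call. = FALSE)
  }
  if (any(doses < 0)) stop("doses must be non-negative", call. = FALSE)
  power_mean(doses, a)
}

# power mean of equally weighted samples, numerically stabilised by
# factoring out the maximum so large exponents do not overflow
power_mean <- function(x, a) {
  m <- max(x)
  if (m == 0) return(0)
  mean((x / m)^a)^(1 / a) * m
}

as_dose_vector <- function(dvh) {
  if (is_dvh(dvh)) return(unclass(dvh))
  doses <- as.numeric(dvh)
  validate_dvh_doses(doses)
  doses
}

#' Maximum dose of a DVH
#'
#' Defined as the dose at the smallest sampled volume bin (v = 1%); no
#' extrapolation toward 0% volume is attempted.
#'
#' @param dvh A [dvh] object.
#' @return Dose in Gy.
#' @export
max_dose <- function(dvh) {
  as_dose_vector(dvh)[1L]
}

#' Dose-sensitivity weights
#'
#' The sensitivity of the gEUD to each dose bin, normalised to sum to one:
#' \deqn{s_j = D_j^{k-1} / \sum_i D_i^{k-1}.}
#' With `k = 1` the weights are uniform; with `k > 1` mass concentrates on
#' the high-dose bins, which is what makes the weighted training loss focus
#' on the maximum-dose region of serial organs.
#'
#' @param doses Non-negative numeric vector (need not be a full DVH).
#' @param k Exponent, `k >= 1`. For `k > 1` the doses must not be all zero.
#' @return Numeric weight vector summing to 1.
#' @examples
#' sensitivity_weights(c(1, 2), k = 2)  # 1/3, 2/3
#' @export
sensitivity_weights <- function(doses, k) {
  doses <- as.numeric(doses)
  if (length(doses) == 0L || anyNA(doses)) {
    stop("doses must be a non-empty numeric vector without NA", call. = FALSE)
  }
  if (any(doses < 0)) stop("doses must be non-negative", call. = FALSE)
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 1) {
    stop("`k` must be a single number >= 1", call. = FALSE)
  }
  if (k == 1) return(rep(1 / length(doses), length(doses)))
  m <- max(doses)
  if (m == 0) {
    stop("sensitivity weights are undefined for all-zero doses when k > 1",
         call. = FALSE)
  }
  w <- (doses / m)^(k - 1)   # rescaling by the max keeps large k finite
  w / sum(w)
}
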