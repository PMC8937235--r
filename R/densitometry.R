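#' Gel lane band-intensity profile
#'
#' Intensities \code{I_b} for bands b = 0..n of a primer-extension ladder:
#' band 0 is the unextended primer, n the highest detectable band.  Arbitrary
#' fluorescence units; every derived statistic is scale-invariant.
#'
#' @param intensities Non-negative numeric vector, element i being band i-1.
#' @param meta Metadata list (template name, circle length, timepoint, ...).
#' @return Object of class \code{lane_profile}.
#' @export
lane_profile <- function(intensities, meta = list()) {
  intensities <- as.numeric(intensities)
  if (length(intensities) < 2L) stop("a lane needs bands 0..n with n >= 1")
  if (any(intensities < 0 | is.na(intensities))) {
    stop("band intensities must be non-negative and finite")
  }
  structure(list(intensity = intensities,
                 n = length(intensities) - 1L, meta = meta),
            class = "lane_profile")
}

#' @export
print.lane_profile <- function(x, ...) {
  cat("<lane_profile> bands 0..", x$n, ", total intensity ",
      format(sum(x$intensity)), "\n", sep = "")
  invisible(x)
}

#' Per-junction extension efficiency from a lane
#'
#' Efficiency of ligation junction b is the intensity-weighted fraction of
#' molecules that reached band b-1 and were extended through junction b:
#' \code{E_b = sum(I_b..I_n) / sum(I_{b-1}..I_n)}.  A zero denominator gives
#' \code{NA} (absence of signal, deliberately distinct from a true
#' inefficiency of 0).
#'
#' @param lane A \code{\link{lane_profile}}.
#' @return Numeric vector \code{E_1..E_n} in [0, 1] (NA where undefined).
#' @export
#' @examples
#' extension_efficiency(lane_profile(c(1, 1, 1, 1)))  # 0.75 0.667 0.5
extension_efficiency <- function(lane) {
  stopifnot(inherits(lane, "lane_profile"))
  I <- lane$intensity
  S <- rev(cumsum(rev(I)))            # S[i] = sum of bands (i-1)..n
  E <- S[-1L] / S[-length(S)]
  E[S[-length(S)] == 0] <- NA_real_
  E
}

#' Fraction of molecules surviving to band k or beyond
#'
#' \code{sum(I_k..I_n) / sum(I_0..I_n)}; equals the telescoped product
#' \code{prod(E_1..E_k)} whenever all terms are defined.
#'
#' @param lane A \code{\link{lane_profile}}.
#' @param k Band index 1..n.
#' @return Fraction in [0, 1].
#' @export
survival_fraction <- function(lane, k) {
  stopifnot(inherits(lane, "lane_profile"), k >= 1, k <= lane$n)
  tot <- sum(lane$intensity)
  if (tot == 0) stop("empty lane: zero total intensity")
  sum(lane$intensity[(k + 1L):(lane$n + 1L)]) / tot
}

#' Mean extension efficiency through a junction
#'
#' Arithmetic mean of \code{E_1..E_through} (the conventional reading of mean
#' junction efficiency); the geometric mean is available since
#' \code{prod(E)} carries the survival interpretation.
#'
#' @param series Efficiency series from \code{\link{extension_efficiency}}.
#' @param through Last junction included (default: full series).
#' @param type \code{"arithmetic"} (default) or \code{"geometric"}.
#' @return Scalar mean efficiency.
#' @export
mean_efficiency <- function(series, through = length(series),
                            type = c("arithmetic", "geometric")) {
  type <- match.arg(type)
  stopifnot(through >= 1, through <= length(series))
  E <- series[seq_len(through)]
  if (anyNA(E)) stop("efficiency series undefined within 1..through")
  if (type == "arithmetic") mean(E) else exp(mean(log(E)))
}

#' Detect periodic modulation of junction efficiency
#'
#' Junction accessibility on a small circular template oscillates with the
#' helical pitch of the template duplex; this estimator removes a linear trend
#' from the efficiency series, least-squares fits a sinusoid at each scanned
#' period over junction positions \code{b * step_nt} (one triplet = 3 bp of
#' new duplex), and returns the period maximizing variance explained.
#'
#' @param series Efficiency series (\code{E_1..E_n}).
#' @param step_nt Spacing between junctions in bp (default 3).
#' @param periods Periods to scan, in bp (default 2-20 bp in 0.05 bp steps).
#' @param r2_threshold Minimum R-squared to call a period significant
#'   (default 0.2); below it the period is \code{NA} ("no significant
#'   period").  Periods at or below twice the junction spacing are scanned
#'   and reported but never selected while identifiable (longer) periods are
#'   in range, since the sampling cannot distinguish them from their aliases.
#' @return List with \code{period_bp} (NA when not significant),
#'   \code{r_squared}, and the full \code{scan} tibble.
#' @export
periodicity <- function(series, step_nt = 3,
                        periods = seq(2, 20, by = 0.05),
                        r2_threshold = 0.2) {
  ok <- !is.na(series)
  if (sum(ok) < 5L) stop("need at least 5 defined efficiencies")
  x <- (seq_along(series) * step_nt)[ok]
  y <- series[ok]
  # Variance left after removing mean and linear trend: the baseline any
  # sinusoid must explain.  The sinusoid is fit jointly with the trend so a
  # trend/oscillation overlap at finite sample size does not bias the peak.
  tss <- sum(stats::resid(stats::lm(y ~ x))^2)
  if (tss <= 1e-12 * max(sum(y^2), 1)) {
    return(list(period_bp = NA_real_, r_squared = 0,
                scan = tibble::tibble(period_bp = periods, r_squared = 0)))
  }
  r2 <- vapply(periods, function(p) {
    s <- sin(2 * pi * x / p); cc <- cos(2 * pi * x / p)
    fit <- stats::lm(y ~ x + s + cc)
    1 - sum(stats::resid(fit)^2) / tss
  }, numeric(1))
  # Junctions are sampled every step_nt bp, so periods below 2*step_nt are
  # indistinguishable from their aliases 1/(1/step_nt - 1/P): the best fit is
  # therefore chosen among identifiable periods (> 2*step_nt) whenever any
  # are scanned; exact ties resolve toward the longest period.
  cand <- if (any(periods > 2 * step_nt)) which(periods > 2 * step_nt)
          else seq_along(periods)
  top <- max(r2[cand], na.rm = TRUE)
  best <- max(cand[r2[cand] >= top - 1e-9])
  list(period_bp = if (r2[best] >= r2_threshold) periods[best] else NA_real_,
       r_squared = r2[best],
       scan = tibble::tibble(period_bp = periods, r_squared = r2))
}

#' Time course of lane profiles
#'
#' @param times Numeric vector of strictly increasing timepoints.
#' @param lanes List of \code{\link{lane_profile}}s, one per timepoint, all
#'   with the same band range.
#' @return Object of class \code{time_course}.
#' @export
time_course <- function(times, lanes) {
  stopifnot(length(times) == length(lanes), !is.unsorted(times, strictly = TRUE))
  ns <- vapply(lanes, function(l) l$n, integer(1))
  if (length(unique(ns)) != 1L) stop("all lanes must share the band range")
  structure(list(times = times, lanes = lanes, n = ns[1L]),
            class = "time_course")
}

#' Band-formation velocity from a time course
#'
#' Ordinary least-squares slope of a band's intensity fraction of the lane
#' total against time; fractions (rather than absolute intensities) remove
#' lane-loading variation.  Velocities of the full-length band and the first
#' beyond-full-length band are the extension and strand-invasion velocities
#' of the system.
#'
#' @param tc A \code{\link{time_course}}.
#' @param band Band index (0..n).
#' @param window Optional numeric length-2 time window.
#' @return Slope (fraction per unit time).
#' @export
band_velocity <- function(tc, band, window = range(tc$times)) {
  stopifnot(inherits(tc, "time_course"), band >= 0, band <= tc$n)
  sel <- tc$times >= window[1L] & tc$times <= window[2L]
  if (sum(sel) < 2L) stop("need at least 2 timepoints in window")
  frac <- vapply(tc$lanes[sel], function(l) {
    l$intensity[band + 1L] / sum(l$intensity)
  }, numeric(1))
  unname(stats::coef(stats::lm(frac ~ tc$times[sel]))[2L])
}

#' Circle size at which circular efficiency reaches the linear reference
#'
#' Fits an ordinary least-squares line through (circle size, mean efficiency)
#' points and returns the size where the line crosses the mean efficiency of
#' the linear template; extrapolation outside the observed size range is
#' flagged.
#'
#' @param sizes_nt Circle sizes in nt (>= 2 distinct values).
#' @param mean_eff Mean extension efficiencies at those sizes.
#' @param linear_reference Mean efficiency of the linear template.
#' @return Crossing size in nt with attribute \code{extrapolated}.
#' @export
#' @examples
#' parity_size(c(40, 80), c(0.5, 0.7), 0.9)  # 120
parity_size <- function(sizes_nt, mean_eff, linear_reference) {
  stopifnot(length(sizes_nt) == length(mean_eff),
            length(unique(sizes_nt)) >= 2L)
  fit <- stats::lm(mean_eff ~ sizes_nt)
  b <- stats::coef(fit)
  if (abs(b[2L]) < 1e-10 * max(abs(mean_eff), 1) / diff(range(sizes_nt))) {
    if (isTRUE(all.equal(unname(b[1L]), linear_reference))) {
      stop("flat fit lies on the reference: crossing size undefined")
    }
    stop("zero slope: fitted line never reaches the linear reference")
  }
  size <- unname((linear_reference - b[1L]) / b[2L])
  structure(size,
            extrapolated = size < min(sizes_nt) || size > max(sizes_nt))
}

#' Read a lane profile from TSV
#'
#' Expects columns \code{band_index} (0-based, 0 = unextended primer) and
#' \code{intensity}.
#'
#' @param path TSV path.
#' @param meta Metadata to attach.
#' @return A \code{\link{lane_profile}}.
#' @export
read_lane_tsv <- function(path, meta = list()) {
  d <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(all(c("band_index", "intensity") %in% names(d)))
  d <- d[order(d$band_index), ]
  if (!identical(as.integer(d$band_index), seq_len(nrow(d)) - 1L)) {
    stop("band_index must run 0..n without gaps")
  }
  lane_profile(d$intensity, meta = meta)
}

#' Write a lane profile to TSV
#'
#' @param lane A \code{\link{lane_profile}}.
#' @param path Output path.
#' @export
write_lane_tsv <- function(lane, path) {
  readr::write_tsv(tibble::tibble(band_index = 0:lane$n,
                                  intensity = lane$intensity), path)
  invisible(path)
}
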