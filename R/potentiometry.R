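#' Construct a differential-potentiometry trace
#'
#' @param times sampling times in seconds from start (strictly increasing;
#'   nominal 10 s cadence, small irregularities tolerated).
#' @param potentials potential readings (mV), same length as \code{times}.
#' @param solution_pair identifiers of the two solutions, \code{c(id1, id2)}.
#' @param polarity convention tag: \code{"E1-E2"} means the recorded potential
#'   is E(GE1) - E(GE2) and the derived acidity difference is
#'   pH(solution1) - pH(solution2).
#' @return list of class \code{"potential_trace"}.
#' @export
potential_trace <- function(times, potentials,
                            solution_pair = c("solution1", "solution2"),
                            polarity = c("E1-E2", "E2-E1")) {
  polarity <- match.arg(polarity)
  times <- as.numeric(times); potentials <- as.numeric(potentials)
  if (length(times) != length(potentials)) stop("times and potentials must match")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(!is.finite(potentials))) stop("potentials must be finite")
  structure(list(times = times, potentials = potentials,
                 solution_pair = solution_pair, polarity = polarity),
            class = "potential_trace")
}

#' Select the most stable window of a potential trace
#'
#' Slides a fixed-length window (15 min by default) across the trace,
#' computed over time rather than sample count so slightly irregular sampling
#' is handled, and selects the window with the smallest standard deviation.
#' Drift is the least-squares slope of potential against time within that
#' window, expressed in mV/h.  The quality-control verdict follows the
#' acceptance criteria for a measurement series: window standard deviation
#' below \code{sd_max} (1 mV) and absolute drift below \code{drift_max}
#' (4 mV/h).
#'
#' @param trace a \code{\link{potential_trace}}.
#' @param window_s window length in seconds (default 900 = 15 min).
#' @param sd_max,drift_max QC thresholds (mV, mV/h).
#' @return list of class \code{"trace_qc"}: \code{window_start},
#'   \code{window_end} (s), \code{window_sd} (mV), \code{drift} (mV/h),
#'   \code{mean_potential} (mV), \code{n}, \code{passed}.
#' @export
select_stable_window <- function(trace, window_s = 900, sd_max = 1, drift_max = 4) {
  stopifnot(inherits(trace, "potential_trace"))
  t <- trace$times; p <- trace$potentials
  if (max(t) - min(t) < window_s)
    stop("trace shorter than one ", window_s, " s window")
  best <- NULL
  for (i in seq_along(t)) {
    if (t[i] + window_s > max(t) + 1e-9) break
    j <- which(t >= t[i] & t <= t[i] + window_s)
    if (length(j) < 3) next
    s <- sd(p[j])
    if (is.null(best) || s < best$sd - 1e-15) best <- list(i = i, j = j, sd = s)
  }
  if (is.null(best)) stop("no window with at least 3 samples found")
  j <- best$j
  slope <- if (sd(t[j]) == 0) 0 else
    stats::cov(t[j], p[j]) / stats::var(t[j])     # mV per second
  drift <- slope * 3600
  qc <- list(window_start = t[best$i], window_end = t[max(j)],
             window_sd = best$sd, drift = drift,
             mean_potential = mean(p[j]), n = length(j),
             passed = best$sd < sd_max && abs(drift) < drift_max)
  structure(qc, class = "trace_qc")
}

#' @export
print.trace_qc <- function(x, ...) {
  cat(sprintf("Stable window %.0f-%.0f s: mean %.2f mV, sd %.3f mV, drift %.2f mV/h -> %s\n",
              x$window_start, x$window_end, x$mean_potential, x$window_sd,
              x$drift, if (x$passed) "PASS" else "FAIL"))
  invisible(x)
}

#' Unified acidity difference from a potential difference
#'
#' \eqn{\Delta pH_{abs} = \Delta E / \mathrm{slope}_{mean}}.  With the
#' calibrated mean electrode slope of -58.35 mV per pH unit, a potential
#' difference of +58.35 mV corresponds to -1.0 pH units; the direction is
#' defined by the trace's polarity convention (\eqn{\Delta E = E_1 - E_2}
#' maps to \eqn{pH_1 - pH_2}).
#'
#' @param delta_e potential difference (mV); typically the stable-window mean.
#' @param slope mean electrode slope (mV per pH unit, default -58.35).
#' @return acidity difference in pH units.
#' @export
delta_phabs <- function(delta_e, slope = -58.35) {
  if (!is.numeric(slope) || slope == 0) stop("electrode slope must be nonzero")
  if (any(!is.finite(delta_e))) stop("delta_e must be finite")
  delta_e / slope
}

#' Anchor a pH_abs ladder to bridging solutions
#'
#' Fits the ladder of potentiometric acidity differences and aligns it with
#' the conventional aqueous pH scale through bridging solutions of known
#' aqueous-aligned unified acidity.  The defaults are the two bridging
#' solutions used for 1,2-difluorobenzene: acetonitrile/pH 4 aqueous formate
#' 60/40 v/v (pH_abs(H2O) = 6.0) and 10 mM ammonium formate in absolute
#' ethanol (pH_abs(H2O) = 8.9).
#'
#' @param measurements pairwise \code{delta} pH_abs measurements (see
#'   \code{\link{fit_ladder}}).
#' @param bridges named numeric vector of bridging-solution reference values.
#' @param ... further arguments for \code{\link{fit_ladder}} (e.g.
#'   \code{exclude_threshold = 0.75}).
#' @return a \code{\link{fit_ladder}} object; values are pH_abs(H2O).
#' @export
anchor_bridging <- function(measurements,
                            bridges = c("MeCN/formate 60/40" = 6.0,
                                        "NH4-formate/EtOH" = 8.9),
                            ...) {
  fit_ladder(measurements, anchor_set(bridges, mode = "bridging"), ...)
}

#' Combine uncertainty components by root sum of squares
#'
#' The combined standard uncertainty of aqueous-aligned unified acidity
#' values is the root sum of squares of its components — for the
#' 1,2-difluorobenzene scale: bridging-solution reference uncertainty
#' (0.13 pH), residual liquid-junction potential (6.3 mV / 58.35 mV per pH =
#' 0.11 pH) and the scale's consistency standard deviation (0.30 pH), giving
#' 0.34 pH.  The recommended (conservative) value rounds the combined
#' estimate upward to one decimal.
#'
#' @param components nonnegative numeric vector of uncertainty components
#'   (pH units).
#' @return list of class \code{"uncertainty_budget"}: \code{components},
#'   \code{u_combined}, \code{u_recommended}.
#' @examples
#' combine_uncertainty(c(bridge = 0.13, junction = 0.11, consistency = 0.30))
#' @export
combine_uncertainty <- function(components) {
  if (any(!is.finite(components)) || any(components < 0))
    stop("uncertainty components must be nonnegative")
  u <- sqrt(sum(components^2))
  structure(list(components = components, u_combined = u,
                 u_recommended = ceiling(u * 10 - 1e-9) / 10),
            class = "uncertainty_budget")
}

#' @export
print.uncertainty_budget <- function(x, ...) {
  cat("Uncertainty budget (RSS):",
      paste(format(x$components), collapse = " + "), "->",
      format(signif(x$u_combined, 3)),
      "; recommended", format(x$u_recommended), "\n")
  invisible(x)
}
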