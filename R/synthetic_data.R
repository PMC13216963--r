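#' Generate a synthetic measurement ladder
#'
#' Emulates the measurement structure behind an acidity or unified-acidity
#' ladder: true node values drawn uniformly over \code{value_range}, a
#' random spanning tree to guarantee connectivity plus extra random edges,
#' Gaussian measurement noise on each pairwise difference, and optional
#' planted outlier edges (shifted by \code{+-outlier_magnitude}).  The
#' defaults mirror the dimensions of the experimental pKa ladder in
#' 1,2-difluorobenzene: 33 nodes, 64 measurements, sigma = 0.07 pK units over
#' a 15.6-unit span.
#'
#' @param n_nodes number of acids/solutions.
#' @param n_edges number of pairwise measurements (>= n_nodes - 1).
#' @param value_range range of true scale values (pK units).
#' @param noise_sd measurement noise standard deviation (pK units).
#' @param n_outliers number of planted inconsistent measurements.
#' @param outlier_magnitude absolute shift applied to outlier edges.
#' @param seed RNG seed; the output is a pure function of the arguments.
#' @return list: \code{truth} (named true values), \code{measurements}
#'   (data frame for \code{\link{fit_ladder}}), \code{outlier_idx} (rows of
#'   the planted outliers).
#' @export
gen_ladder <- function(n_nodes = 33, n_edges = 64, value_range = c(0, 15.6),
                       noise_sd = 0.07, n_outliers = 0, outlier_magnitude = 1.0,
                       seed = 1) {
  if (n_edges < n_nodes - 1)
    stop("edge density too low for a connected graph: need at least n_nodes - 1 edges")
  with_seed(seed, {
    ids <- sprintf("acid%02d", seq_len(n_nodes))
    truth <- setNames(sort(runif(n_nodes, value_range[1], value_range[2]),
                           decreasing = TRUE), ids)
    # random spanning tree: attach each node to a random earlier node
    a <- character(0); b <- character(0)
    ord <- sample(ids)
    for (i in seq_along(ord)[-1]) {
      a <- c(a, ord[sample(i - 1, 1)]); b <- c(b, ord[i])
    }
    extra <- n_edges - (n_nodes - 1)
    # give single-link nodes a second connection first (each compound on the
    # experimental scale is tied in by at least two measurements), then add
    # random extra edges
    deg <- table(factor(c(a, b), levels = ids))
    for (nd in sample(names(deg)[deg < 2])) {
      if (extra <= 0) break
      a <- c(a, nd); b <- c(b, sample(setdiff(ids, nd), 1))
      extra <- extra - 1
    }
    for (k in seq_len(extra)) {
      pair <- sample(ids, 2)
      a <- c(a, pair[1]); b <- c(b, pair[2])
    }
    delta <- truth[b] - truth[a] + rnorm(n_edges, 0, noise_sd)
    outlier_idx <- integer(0)
    if (n_outliers > 0) {
      outlier_idx <- sample(n_edges, n_outliers)
      delta[outlier_idx] <- delta[outlier_idx] +
        sample(c(-1, 1), n_outliers, replace = TRUE) * outlier_magnitude
    }
    meas <- data.frame(node_a = a, node_b = b, delta = unname(delta),
                       kind = "pK_ip",
                       source = ifelse(seq_len(n_edges) %in% outlier_idx,
                                       "outlier", "clean"),
                       stringsAsFactors = FALSE)
    list(truth = truth, measurements = meas, outlier_idx = sort(outlier_idx))
  })
}

#' Solve the two-acid proton-sharing equilibrium
#'
#' Two acids HA1 and HA2 (totals \code{c1}, \code{c2}) compete for a
#' substoichiometric amount of added base.  The dissociation degrees satisfy
#' the mass balance \eqn{c_1\alpha_1 + c_2\alpha_2 = base} and the acidity
#' relation \eqn{\log_{10}[\alpha_1(1-\alpha_2)/(\alpha_2(1-\alpha_1))] =
#' \Delta pK} with \eqn{\Delta pK = pK(HA_2) - pK(HA_1)}.  Parameterising by
#' the odds of acid 2 makes the mass balance strictly monotone, so the root
#' is found by bisection-safeguarded one-dimensional root finding.
#'
#' @param delta_pk relative acidity pK(HA2) - pK(HA1).
#' @param c1,c2 total concentrations (mol/L).
#' @param base_added equivalents of base added (mol/L), in
#'   \code{[0, c1 + c2]}.
#' @param tol mass-balance tolerance (mol/L fraction).
#' @return named numeric \code{c(alpha1, alpha2)}.
#' @examples
#' solve_two_acid_equilibrium(1.0, 1e-4, 1e-4, 1e-4)  # ~ (0.76, 0.24)
#' @export
solve_two_acid_equilibrium <- function(delta_pk, c1, c2, base_added, tol = 1e-12) {
  if (c1 <= 0 || c2 <= 0) stop("total concentrations must be positive")
  if (base_added < 0 || base_added > c1 + c2)
    stop("base_added must lie in [0, c1 + c2]")
  if (base_added == 0) return(c(alpha1 = 0, alpha2 = 0))
  if (base_added == c1 + c2) return(c(alpha1 = 1, alpha2 = 1))
  # odds(alpha1) = 10^delta_pk * odds(alpha2); logistic form is overflow-safe
  alphas <- function(logt) c(alpha1 = stats::plogis(logt + delta_pk * log(10)),
                             alpha2 = stats::plogis(logt))
  bal <- function(logt) {
    a <- alphas(logt)
    c1 * a[["alpha1"]] + c2 * a[["alpha2"]] - base_added
  }
  root <- uniroot(bal, lower = -700, upper = 700, tol = tol)$root
  alphas(root)
}

gaussian_bands <- function(wl, centers, widths, heights) {
  rowSums(vapply(seq_along(centers), function(i)
    heights[i] * exp(-((wl - centers[i]) / widths[i])^2 / 2),
    numeric(length(wl))))
}

#' Generate a synthetic two-acid titration experiment
#'
#' Builds Beer-Lambert mixture spectra for the joint titration of two acids
#' with a known relative acidity: each of the four pure forms gets a
#' molar-absorptivity curve made of 1-3 Gaussian bands (randomised within
#' ranges that keep the four-component basis well conditioned), the
#' dissociation state at each titrant step comes from
#' \code{\link{solve_two_acid_equilibrium}}, and seeded Gaussian absorbance
#' noise is added.  Concentrations default to the e-4 to e-5 mol/L range of
#' the spectrophotometric titrations.
#'
#' @param delta_pk true relative acidity pK(HA2) - pK(HA1).
#' @param c1,c2 total acid concentrations (mol/L).
#' @param n_steps number of titration steps (spectra).
#' @param noise_sd absorbance noise standard deviation.
#' @param wavelengths wavelength grid (nm).
#' @param path_length optical path length (cm); absorbances scale with it.
#' @param seed RNG seed.
#' @return list: \code{basis} (a \code{\link{pure_form_basis}}),
#'   \code{mixtures} (a \code{\link{spectrum_matrix}}), \code{truth} (data
#'   frame of per-step base added and true dissociation degrees),
#'   \code{delta_pk}.
#' @export
gen_titration <- function(delta_pk = 1.20, c1 = 1e-4, c2 = 1e-4,
                          n_steps = 20, noise_sd = 0.002,
                          wavelengths = seq(300, 500, length.out = 200),
                          path_length = 1, seed = 1) {
  with_seed(seed, {
    wl <- wavelengths
    eps <- matrix(0, length(wl), 4, dimnames = list(NULL, c("HA1", "A1", "HA2", "A2")))
    # distinct band centres per form keep the basis well conditioned
    base_centers <- c(330, 430, 360, 470)
    for (f in 1:4) {
      nb <- sample(1:3, 1)
      centers <- base_centers[f] + runif(nb, -15, 15)
      widths <- runif(nb, 12, 25)
      heights <- runif(nb, 0.4, 1) * 1.2e4   # molar absorptivity, L/(mol cm)
      eps[, f] <- gaussian_bands(wl, centers, widths, heights)
    }
    basis <- pure_form_basis(wl, sweep(eps, 2, c(c1, c1, c2, c2) * path_length, "*"),
                             ref_conc = c(c1, c1, c2, c2))
    base_steps <- seq(0, c1 + c2, length.out = n_steps)
    truth <- data.frame(step = paste0("step", seq_len(n_steps)),
                        base_added = base_steps, alpha1 = NA_real_,
                        alpha2 = NA_real_)
    A <- matrix(0, length(wl), n_steps)
    for (i in seq_len(n_steps)) {
      al <- solve_two_acid_equilibrium(delta_pk, c1, c2, base_steps[i])
      truth$alpha1[i] <- al[["alpha1"]]; truth$alpha2[i] <- al[["alpha2"]]
      conc <- c(c1 * (1 - al[["alpha1"]]), c1 * al[["alpha1"]],
                c2 * (1 - al[["alpha2"]]), c2 * al[["alpha2"]])
      A[, i] <- eps %*% conc * path_length
    }
    A <- A + matrix(rnorm(length(A), 0, noise_sd), nrow(A))
    mixtures <- spectrum_matrix(wl, A, truth$step)
    list(basis = basis, mixtures = mixtures, truth = truth, delta_pk = delta_pk)
  })
}

#' Generate a synthetic potentiometry trace
#'
#' Baseline plus linear drift plus Gaussian noise, sampled at a fixed
#' cadence; emulates a differential-potentiometry record so QC behaviour is
#' predictable from the generator parameters.
#'
#' @param duration_s record length (s), default 1 h.
#' @param cadence_s sampling interval (s), default 10.
#' @param baseline_mV mean potential (mV).
#' @param drift_mV_h linear drift (mV per hour).
#' @param noise_sd_mV white-noise standard deviation (mV).
#' @param seed RNG seed.
#' @return a \code{\link{potential_trace}}.
#' @export
gen_trace <- function(duration_s = 3600, cadence_s = 10, baseline_mV = 50,
                      drift_mV_h = 0, noise_sd_mV = 0.3, seed = 1) {
  with_seed(seed, {
    t <- seq(0, duration_s, by = cadence_s)
    p <- baseline_mV + drift_mV_h * t / 3600 + rnorm(length(t), 0, noise_sd_mV)
    potential_trace(t, p)
  })
}

#' Generate realistic synthetic ionic radii
#'
#' Mean ionic radii for delocalised organic anions (4.0-5.5 Angstrom) and
#' phosphazenium-type cations (4.25-4.75 Angstrom), the ranges over which the
#' Fuoss ion-pairing correction between any two acids stays within about
#' 0.2 pK units.
#'
#' @param n_anions number of anion radii to draw.
#' @param seed RNG seed.
#' @return list: \code{anions} (numeric vector, Angstrom), \code{cation}
#'   (scalar, Angstrom).
#' @export
gen_radii <- function(n_anions = 10, seed = 1) {
  with_seed(seed, list(anions = runif(n_anions, 4.0, 5.5),
                       cation = runif(1, 4.25, 4.75)))
}
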