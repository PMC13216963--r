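#' Construct a titration spectrum matrix
#'
#' Bundles the wavelength grid and per-step absorbance spectra of one cuvette
#' experiment.  Columns of \code{absorbance} are successive titration steps.
#'
#' @param wavelengths numeric vector of wavelengths (nm), strictly increasing.
#' @param absorbance numeric matrix, \code{length(wavelengths)} rows, one
#'   column per recorded spectrum; all values finite.
#' @param step_labels optional character vector of column identifiers.
#' @return An object of class \code{"spectrum_matrix"}.
#' @export
spectrum_matrix <- function(wavelengths, absorbance, step_labels = NULL) {
  wavelengths <- as.numeric(wavelengths)
  absorbance <- as.matrix(absorbance)
  if (any(diff(wavelengths) <= 0)) stop("wavelengths must be strictly increasing")
  if (nrow(absorbance) != length(wavelengths))
    stop("absorbance must have one row per wavelength")
  if (!all(is.finite(absorbance))) stop("all absorbances must be finite")
  if (is.null(step_labels)) step_labels <- colnames(absorbance)
  if (is.null(step_labels)) step_labels <- paste0("step", seq_len(ncol(absorbance)))
  if (length(step_labels) != ncol(absorbance))
    stop("step_labels must match the number of spectra")
  colnames(absorbance) <- step_labels
  structure(list(wavelengths = wavelengths, absorbance = absorbance,
                 step_labels = step_labels),
            class = "spectrum_matrix")
}

#' Construct a pure-form basis for two acids
#'
#' The four basis spectra are those of the fully protonated (HA) and fully
#' deprotonated (A-) forms of each acid, recorded on the wavelength grid of
#' the mixtures they will be unmixed against.  Each basis spectrum is tied to
#' the concentration at which it was recorded so that unmixing coefficients
#' are concentrations.
#'
#' @param wavelengths wavelength grid (nm), strictly increasing.
#' @param spectra numeric matrix with 4 columns in the order
#'   \code{HA1, A1, HA2, A2}.
#' @param ref_conc reference concentration (mol/L) of each basis spectrum;
#'   length 4 or a scalar recycled to 4.
#' @param acids identifiers of the two acids.
#' @return An object of class \code{"pure_form_basis"}.
#' @export
pure_form_basis <- function(wavelengths, spectra, ref_conc = 1,
                            acids = c("acid1", "acid2")) {
  spectra <- as.matrix(spectra)
  if (ncol(spectra) != 4L) stop("basis must have 4 components: HA1, A1, HA2, A2")
  if (nrow(spectra) != length(wavelengths))
    stop("basis spectra must share the mixture wavelength grid")
  if (!all(is.finite(spectra))) stop("basis spectra must be finite")
  ref_conc <- rep_len(as.numeric(ref_conc), 4L)
  if (any(ref_conc <= 0)) stop("reference concentrations must be positive")
  colnames(spectra) <- c("HA1", "A1", "HA2", "A2")
  structure(list(wavelengths = as.numeric(wavelengths), spectra = spectra,
                 ref_conc = ref_conc, acids = acids),
            class = "pure_form_basis")
}

basis_condition <- function(basis) {
  # condition number of the molar-absorptivity matrix (unit-concentration scale)
  m <- sweep(basis$spectra, 2L, basis$ref_conc, "/")
  sv <- svd(m, nu = 0, nv = 0)$d
  if (min(sv) == 0) Inf else max(sv) / min(sv)
}

#' Unmix titration spectra into dissociation degrees
#'
#' Each mixture spectrum is modelled as a linear combination of the four
#' pure-form basis spectra (plus, optionally, a flat baseline term) and the
#' coefficients are obtained by unweighted linear least squares over all
#' wavelengths.  The dissociation degree of acid i is the deprotonated
#' coefficient normalised by the sum of that acid's two coefficients, so any
#' common dilution factor cancels.  Points whose dissociation degrees fall
#' outside the inclusion window are flagged unusable: near the titration
#' endpoints the relative-acidity estimate has unbounded variance.
#'
#' @param mixtures a \code{\link{spectrum_matrix}}.
#' @param basis a \code{\link{pure_form_basis}} on the same wavelength grid.
#' @param window inclusion window for usable dissociation degrees,
#'   default \code{c(0.05, 0.95)} applied to both acids.
#' @param baseline add a constant-offset regressor (off by default).
#' @param nonneg constrain coefficients to be nonnegative (off by default;
#'   plain multilinear regression otherwise).
#' @param cond_max maximum allowed condition number of the basis.
#' @param coef_tol negative-coefficient tolerance (fraction of the acid's
#'   total) beyond which a point is flagged when \code{nonneg = FALSE}.
#' @return A data frame of class \code{"dissociation_points"} with columns
#'   \code{step}, \code{alpha1}, \code{alpha2}, \code{usable}, \code{reason}.
#' @examples
#' tit <- gen_titration(delta_pk = 1.0, n_steps = 8, noise_sd = 0, seed = 1)
#' pts <- unmix_spectra(tit$mixtures, tit$basis)
#' @export
unmix_spectra <- function(mixtures, basis, window = c(0.05, 0.95),
                          baseline = FALSE, nonneg = FALSE,
                          cond_max = 1e8, coef_tol = 0.05) {
  stopifnot(inherits(mixtures, "spectrum_matrix"), inherits(basis, "pure_form_basis"))
  if (length(mixtures$wavelengths) != length(basis$wavelengths) ||
      max(abs(mixtures$wavelengths - basis$wavelengths)) > 1e-9)
    stop("mixtures and basis must share a common wavelength grid")
  kappa <- basis_condition(basis)
  if (!is.finite(kappa) || kappa > cond_max)
    stop(sprintf(paste0("ill-conditioned basis for acid pair '%s'/'%s' ",
                        "(condition number %.3g exceeds %.3g)"),
                 basis$acids[1], basis$acids[2], kappa, cond_max))
  # design matrix on the unit-concentration (molar absorptivity) scale
  X <- sweep(basis$spectra, 2L, basis$ref_conc, "/")
  if (baseline) X <- cbind(X, offset = 1)
  n <- ncol(mixtures$absorbance)
  out <- data.frame(step = mixtures$step_labels,
                    alpha1 = NA_real_, alpha2 = NA_real_,
                    usable = FALSE, reason = "", stringsAsFactors = FALSE)
  for (j in seq_len(n)) {
    y <- mixtures$absorbance[, j]
    cf <- if (nonneg) {
      v <- pracma::lsqnonneg(X, y)$x
      if (baseline) v else v
    } else {
      lm.fit(X, y)$coefficients
    }
    cf4 <- cf[1:4]
    tot1 <- cf4[1] + cf4[2]
    tot2 <- cf4[3] + cf4[4]
    reasons <- character(0)
    if (!nonneg) {
      if (tot1 > 0 && min(cf4[1:2]) < -coef_tol * tot1 ||
          tot2 > 0 && min(cf4[3:4]) < -coef_tol * tot2)
        reasons <- c(reasons, "negative coefficient beyond tolerance")
    }
    if (tot1 <= .Machine$double.eps^0.5 * max(abs(cf4), 1)) {
      reasons <- c(reasons, "acid 1 absent"); a1 <- NA_real_
    } else a1 <- cf4[2] / tot1
    if (tot2 <= .Machine$double.eps^0.5 * max(abs(cf4), 1)) {
      reasons <- c(reasons, "acid 2 absent"); a2 <- NA_real_
    } else a2 <- cf4[4] / tot2
    out$alpha1[j] <- a1
    out$alpha2[j] <- a2
    inside <- !is.na(a1) && !is.na(a2) &&
      a1 >= window[1] && a1 <= window[2] &&
      a2 >= window[1] && a2 <= window[2]
    out$usable[j] <- inside && length(reasons) == 0
    if (!inside && length(reasons) == 0)
      reasons <- "dissociation degree outside inclusion window"
    out$reason[j] <- paste(reasons, collapse = "; ")
  }
  attr(out, "acids") <- basis$acids
  attr(out, "condition_number") <- kappa
  class(out) <- c("dissociation_points", class(out))
  out
}

#' Relative ion-pair acidity from a pair of dissociation degrees
#'
#' For two acids observed in the same solution, the difference of their
#' ion-pair acidity constants follows from the two dissociation degrees:
#' \deqn{\Delta pK_{ip} = \log_{10}\frac{\alpha_1 (1-\alpha_2)}
#'   {\alpha_2 (1-\alpha_1)}}
#' with the convention \eqn{\Delta pK_{ip} = pK_{ip}(HA_2) - pK_{ip}(HA_1)}.
#' Vectorised; both degrees must lie strictly inside (0, 1).
#'
#' @param alpha1,alpha2 dissociation degrees of acids 1 and 2.
#' @return numeric vector of relative acidities (pK units).
#' @examples
#' delta_pkip_from_alphas(0.9, 0.5)  # log10(9)
#' @export
delta_pkip_from_alphas <- function(alpha1, alpha2) {
  if (any(!is.finite(alpha1)) || any(!is.finite(alpha2)))
    stop("dissociation degrees must be finite")
  if (any(alpha1 <= 0 | alpha1 >= 1) || any(alpha2 <= 0 | alpha2 >= 1))
    stop("dissociation degrees must lie strictly inside (0, 1); endpoint spectra give infinite estimates")
  log10(alpha1 * (1 - alpha2) / (alpha2 * (1 - alpha1)))
}

#' Aggregate per-spectrum relative acidities for one acid pair
#'
#' Evaluates the relative acidity at every usable dissociation point and
#' aggregates across the titration (unweighted mean by default, median
#' selectable).  The spread is the sample standard deviation of the per-point
#' estimates (0 for a single point).
#'
#' @param points a \code{\link{unmix_spectra}} result (or any data frame with
#'   \code{alpha1}, \code{alpha2}, \code{usable}).
#' @param acids identifiers of the two acids; defaults to those attached to
#'   \code{points}.
#' @param method aggregation rule, \code{"mean"} (default) or \code{"median"}.
#' @return one-row data frame of class \code{"pair_result"}:
#'   \code{acid1, acid2, delta_pkip, n_points, spread}.
#' @export
aggregate_pair <- function(points, acids = attr(points, "acids"),
                           method = c("mean", "median")) {
  method <- match.arg(method)
  if (is.null(acids)) acids <- c("acid1", "acid2")
  use <- which(points$usable)
  if (length(use) == 0) {
    rs <- points$reason[points$reason != ""]
    stop("no usable dissociation points: ",
         paste(unique(rs), collapse = "; "))
  }
  vals <- delta_pkip_from_alphas(points$alpha1[use], points$alpha2[use])
  est <- if (method == "mean") mean(vals) else median(vals)
  spread <- if (length(vals) > 1) sd(vals) else 0
  structure(data.frame(acid1 = acids[1], acid2 = acids[2],
                       delta_pkip = est, n_points = length(vals),
                       spread = spread, stringsAsFactors = FALSE),
            class = c("pair_result", "data.frame"))
}
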