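#' Proton-transfer constants linking a solvent scale to the aqueous scale
#'
#' The unified acidity of a solution in solvent S, aligned to the aqueous pH
#' scale, differs from its solvent-scale value by the Gibbs energy of
#' transferring the proton from S to water.  Defaults hold the solvation
#' Gibbs energies of the proton in 1,2-difluorobenzene (-899 kJ/mol) and in
#' water (-1105 kJ/mol).
#'
#' @param dG_solv_s proton solvation Gibbs energy in the working solvent
#'   (kJ/mol, negative).
#' @param dG_solv_w proton solvation Gibbs energy in water (kJ/mol, negative).
#' @param temperature K (default 298.15).
#' @param R gas constant (kJ/(mol K)).
#' @return list of class \code{"proton_transfer_constants"} including the
#'   derived \code{RTln10} (kJ/mol) and the additive \code{shift}
#'   \eqn{(\Delta G_w - \Delta G_s)/(RT \ln 10)} in pH units.
#' @export
proton_transfer_constants <- function(dG_solv_s = -899, dG_solv_w = -1105,
                                      temperature = 298.15, R = 8.31446261815324e-3) {
  if (dG_solv_s >= 0 || dG_solv_w >= 0)
    stop("proton solvation Gibbs energies must be negative")
  if (temperature <= 0) stop("temperature must be positive")
  RTln10 <- R * temperature * log(10)
  structure(list(dG_solv_s = dG_solv_s, dG_solv_w = dG_solv_w,
                 temperature = temperature, RTln10 = RTln10,
                 shift = (dG_solv_w - dG_solv_s) / RTln10),
            class = "proton_transfer_constants")
}

#' Aqueous-aligned unified acidity from a solvent-scale pKa
#'
#' For an equimolar buffer of an acid and its conjugate base the
#' solvent-scale pH equals the acid's pKa (ideal-solution assumption,
#' activity and homoconjugation corrections neglected); aligning to the
#' aqueous scale adds the constant proton-transfer shift:
#' \deqn{pH_{abs}^{H_2O} = pK_a(S) + \frac{\Delta_{solv}G^\circ_w(H^+) -
#'   \Delta_{solv}G^\circ_S(H^+)}{RT\ln 10}}
#' The conversion is affine with unit slope, so differences of converted
#' values equal differences of pKa values.
#'
#' @param pka solvent-scale pKa value(s) of the buffer acid.
#' @param constants a \code{\link{proton_transfer_constants}}.
#' @return pH_abs(H2O) value(s).
#' @examples
#' pka_to_phabs_h2o(40.8)  # picric acid buffer in 1,2-DFB -> ~4.7
#' @export
pka_to_phabs_h2o <- function(pka, constants = proton_transfer_constants()) {
  stopifnot(inherits(constants, "proton_transfer_constants"))
  if (any(!is.finite(pka))) stop("pKa values must be finite")
  pka + constants$shift
}

#' Map a solvation-energy uncertainty to pH units
#'
#' A standard uncertainty u_G (kJ/mol) on either proton solvation Gibbs
#' energy propagates to u_G / (RT ln 10) pH units: 10 kJ/mol corresponds to
#' about 1.75 pH units at 298.15 K.
#'
#' @param u_G standard uncertainty in kJ/mol.
#' @param constants a \code{\link{proton_transfer_constants}}.
#' @return standard uncertainty in pH units.
#' @export
phabs_uncertainty_from_gibbs <- function(u_G, constants = proton_transfer_constants()) {
  if (any(u_G < 0)) stop("uncertainty must be nonnegative")
  u_G / constants$RTln10
}

#' Compare pKa-derived and potentiometric unified acidity values
#'
#' Per-buffer differences (pKa-derived minus potentiometric) and their
#' root-mean-square, the figure of merit for agreement between the
#' spectrophotometric/computational and potentiometric routes.
#'
#' @param from_pka named or plain numeric vector of pKa-derived pH_abs(H2O)
#'   values.
#' @param from_potentiometry matching potentiometric values.
#' @return list of class \code{"phabs_comparison"}: \code{differences},
#'   \code{rms}, \code{mean_difference}, \code{n}.
#' @export
compare_scales <- function(from_pka, from_potentiometry) {
  if (!is.null(names(from_pka)) && !is.null(names(from_potentiometry))) {
    common <- intersect(names(from_pka), names(from_potentiometry))
    from_pka <- from_pka[common]; from_potentiometry <- from_potentiometry[common]
  }
  ok <- is.finite(from_pka) & is.finite(from_potentiometry)
  if (!any(ok)) stop("no buffers with both values")
  d <- from_pka[ok] - from_potentiometry[ok]
  structure(list(differences = d, rms = sqrt(mean(d^2)),
                 mean_difference = mean(d), n = sum(ok)),
            class = "phabs_comparison")
}

#' @export
print.phabs_comparison <- function(x, ...) {
  cat(sprintf("pKa-derived vs potentiometric pH_abs(H2O): n = %d, mean diff = %+.2f, RMS = %.2f\n",
              x$n, x$mean_difference, x$rms))
  invisible(x)
}
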