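FIXTURE_FILES <- c(
  table3     = "table3_acidity.csv",
  table5     = "table5_estimates.csv",
  table2_kong = "table2_kong.csv",
  anchors    = "anchor_compounds.csv"
)

FIXTURE_MD5 <- c(
  table3      = "71d8e9a46d82953790d0d61a6d91f286",
  table5      = "d497abedddb3a67d9acbd63cd0ef6671",
  table2_kong = "ab5e2169dbf210237f6672f50ec69ef4",
  anchors     = "bdaaead1288dfe2d17a7f618651aaa79"
)

#' Load a packaged reference table
#'
#' The package ships the published acidity tables for 1,2-difluorobenzene as
#' plain CSV: \code{"table3"} — the 33 directly measured acids with their
#' 1,2-DFB values and literature MeCN / 1,2-DCE values plus a compound-class
#' tag; \code{"table5"} — MeCN- and DCE-derived pKa estimates for 104
#' further compounds (recommended values and uncertainties are computed by
#' \code{\link{recommend_pka}}, not stored); \code{"table2_kong"} — 40
#' literature pKa values on the Kong et al. anchoring, to be offset-corrected
#' with \code{\link{offset_correct}}; \code{"anchors"} — the nine compounds
#' whose computed pKa values anchored the experimental scale.  Each file is
#' checksum-pinned to guard against transcription drift.
#'
#' @param name one of \code{"table3"}, \code{"table5"}, \code{"table2_kong"},
#'   \code{"anchors"}.
#' @return data frame.
#' @examples
#' t3 <- load_fixture("table3")
#' nrow(t3)  # 33
#' @export
load_fixture <- function(name = c("table3", "table5", "table2_kong", "anchors")) {
  name <- match.arg(name)
  path <- system.file("extdata", FIXTURE_FILES[[name]], package = "acidscale",
                      mustWork = TRUE)
  sum <- unname(tools::md5sum(path))
  if (!identical(sum, unname(FIXTURE_MD5[[name]])))
    stop("checksum mismatch for fixture '", name,
         "': file has drifted from the packaged transcription")
  df <- read.csv(path, stringsAsFactors = FALSE)
  rc <- c(table3 = 33L, table5 = 104L, table2_kong = 40L, anchors = 9L)
  if (nrow(df) != rc[[name]])
    stop("fixture '", name, "' has ", nrow(df), " rows, expected ", rc[[name]])
  df
}

#' Default analysis configuration
#'
#' All tunable constants and thresholds of the pipeline with their default
#' values: solvent permittivity, measurement temperatures, electrode slope,
#' proton solvation energies, the bridging-solution anchors, the
#' dissociation-degree inclusion window, the QC and exclusion thresholds and
#' the uncertainty rules.
#'
#' @return named list.
#' @export
default_config <- function() {
  list(
    epsilon_r = 13.4,                 # relative permittivity of 1,2-DFB
    temperature_pka_K = 297.25,       # 24.1 C, spectrophotometric titrations
    temperature_phabs_K = 298.15,     # 25.0 C, potentiometry / conversions
    electrode_slope_mV = -58.35,      # mean glass-electrode slope per pH unit
    dG_solv_H_dfb_kJmol = -899,
    dG_solv_H_water_kJmol = -1105,
    bridge_phabs = c("MeCN/formate 60/40" = 6.0, "NH4-formate/EtOH" = 8.9),
    alpha_window = c(0.05, 0.95),     # usable dissociation-degree window
    exclusion_threshold = 0.75,       # pH units, inconsistent-series cutoff
    qc_sd_max_mV = 1,
    qc_drift_max_mV_h = 4,
    qc_window_s = 900,
    baseline_uncertainty = 0.5,       # dual-source estimate floor, pK units
    single_source_uncertainty = 1.0,  # pK units
    report_digits = 1
  )
}

#' Read titration spectra from CSV
#'
#' Expected layout: first column \code{wavelength_nm}, one further column per
#' titration step.
#'
#' @param path CSV file path.
#' @return a \code{\link{spectrum_matrix}}.
#' @export
read_spectra_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  if (names(df)[1] != "wavelength_nm")
    stop("first column must be 'wavelength_nm'")
  spectrum_matrix(df[[1]], as.matrix(df[-1]), names(df)[-1])
}

#' Write titration spectra to CSV
#'
#' @param spectra a \code{\link{spectrum_matrix}}.
#' @param path output path.
#' @export
write_spectra_csv <- function(spectra, path) {
  df <- data.frame(wavelength_nm = spectra$wavelengths,
                   spectra$absorbance, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read pairwise ladder measurements from CSV
#'
#' Columns: \code{node_a,node_b,delta} and optional \code{kind,source}.
#'
#' @param path CSV file path.
#' @return validated measurement data frame.
#' @export
read_measurements_csv <- function(path) {
  check_measurements(read.csv(path, stringsAsFactors = FALSE))
}

#' Write a scale report to CSV files
#'
#' @param report a \code{\link{scale_report}}.
#' @param nodes_path,edges_path output paths (either may be \code{NULL}).
#' @param digits reporting precision for scale values.
#' @export
write_scale_csv <- function(report, nodes_path = NULL, edges_path = NULL,
                            digits = 1) {
  stopifnot(inherits(report, "scale_report"))
  if (!is.null(nodes_path)) {
    nd <- report$nodes
    nd$value <- round_half_up(nd$value, digits)
    write.csv(nd, nodes_path, row.names = FALSE)
  }
  if (!is.null(edges_path)) write.csv(report$edges, edges_path, row.names = FALSE)
  invisible(report)
}

#' Read a potentiometry trace from CSV
#'
#' Columns: \code{time_s,potential_mV}.
#'
#' @param path CSV file path.
#' @param ... passed to \code{\link{potential_trace}} (solution pair,
#'   polarity).
#' @return a \code{\link{potential_trace}}.
#' @export
read_trace_csv <- function(path, ...) {
  df <- read.csv(path)
  if (!all(c("time_s", "potential_mV") %in% names(df)))
    stop("trace CSV needs columns time_s, potential_mV")
  potential_trace(df$time_s, df$potential_mV, ...)
}

#' Write a potentiometry trace to CSV
#'
#' @param trace a \code{\link{potential_trace}}.
#' @param path output path.
#' @export
write_trace_csv <- function(trace, path) {
  write.csv(data.frame(time_s = trace$times, potential_mV = trace$potentials),
            path, row.names = FALSE)
  invisible(path)
}

#' Read species ionic radii from CSV
#'
#' Columns: \code{species,r_sphere_A,r_cuboid_A,r_surface_A,charge}.  Returns
#' a named list of \code{\link{mean_radius}} objects.
#'
#' @param path CSV file path.
#' @return named list of \code{ion_radius} objects.
#' @export
read_radii_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "r_sphere_A", "r_cuboid_A", "r_surface_A")
  if (!all(need %in% names(df))) stop("radii CSV needs columns ",
                                      paste(need, collapse = ", "))
  out <- lapply(seq_len(nrow(df)), function(i)
    mean_radius(df$r_sphere_A[i], df$r_cuboid_A[i], df$r_surface_A[i],
                species = df$species[i]))
  names(out) <- df$species
  out
}
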