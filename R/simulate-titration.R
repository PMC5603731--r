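#' Parameter set for a simulated binding titration
#'
#' Settings for [simulate_titration()]: a fixed protein concentration is
#' titrated with increasing total ligand and the readout follows the 1:1
#' ligand-depletion isotherm of [fraction_bound()]. Two readout modes are
#' supported: `"fluorescence"` (a single response channel interpolating
#' between `response_free` and `response_sat`; quench experiments simply
#' set `response_sat < response_free`) and `"nmr_csp"` (fast-exchange
#' chemical-shift perturbations for `n_residues` residues sharing the
#' true Kd but with distinct saturation amplitudes).
#'
#' @param protein_total Protein concentration (uM), > 0.
#' @param ligand_points Ordered total ligand concentrations (uM),
#'   non-negative and strictly increasing; the default spans 0 to
#'   40 x `kd_true` over 10 points.
#' @param kd_true True dissociation constant (uM).
#' @param response_free,response_sat Readout at zero and saturating
#'   ligand (fluorescence mode).
#' @param noise_sd Gaussian noise sd added per point (response units in
#'   fluorescence mode, ppm in CSP mode).
#' @param readout_mode `"fluorescence"` or `"nmr_csp"`.
#' @param n_residues Number of residues emitted in CSP mode.
#' @param seed Integer seed.
#' @return A list of class `titration_sim_params`.
#' @export
titration_sim_params <- function(protein_total = 5,
                                 ligand_points = NULL,
                                 kd_true = 10,
                                 response_free = 1,
                                 response_sat = 0.4,
                                 noise_sd = 0,
                                 readout_mode = c("fluorescence", "nmr_csp"),
                                 n_residues = 5,
                                 seed = 1L) {
  readout_mode <- match.arg(readout_mode)
  check_scalar(protein_total, "protein_total", 0, open_lower = TRUE)
  check_scalar(kd_true, "kd_true", 0, open_lower = TRUE)
  check_scalar(noise_sd, "noise_sd", 0)
  check_count(n_residues, "n_residues", min = 1L)
  if (is.null(ligand_points)) {
    ligand_points <- seq(0, 40 * kd_true, length.out = 10)
  }
  if (length(ligand_points) == 0) abort("`ligand_points` must be non-empty.")
  if (any(ligand_points < 0) || any(diff(ligand_points) <= 0)) {
    abort("`ligand_points` must be non-negative and strictly increasing.")
  }
  structure(
    list(
      protein_total = protein_total, ligand_points = ligand_points,
      kd_true = kd_true, response_free = response_free,
      response_sat = response_sat, noise_sd = noise_sd,
      readout_mode = readout_mode, n_residues = as.integer(n_residues),
      seed = as.integer(seed)
    ),
    class = "titration_sim_params"
  )
}

#' Simulate a binding titration series
#'
#' Draws a titration from the 1:1 ligand-depletion isotherm. In
#' fluorescence mode the noiseless response is
#' `response_free + (response_sat - response_free) * f` with `f` the
#' fraction of protein bound; in CSP mode each residue's combined shift
#' is `A_r * f` with saturation amplitudes `A_r` spaced evenly over
#' 0.02 to 0.12 ppm. Gaussian noise of sd `noise_sd` is added per point.
#'
#' @param params A [titration_sim_params()] object.
#' @return A tibble. Fluorescence mode: columns `ligand_uM`, `response`.
#'   CSP mode: `residue`, `ligand_uM`, `csp`. Attributes carry the
#'   generator `params` and the readout `mode`.
#' @examples
#' simulate_titration(titration_sim_params(kd_true = 1.3, noise_sd = 0.01))
#' @export
simulate_titration <- function(params) {
  stopifnot(inherits(params, "titration_sim_params"))
  p <- params
  set.seed(p$seed)
  f <- fraction_bound(p$protein_total, p$ligand_points, p$kd_true)
  if (p$readout_mode == "fluorescence") {
    y <- p$response_free + (p$response_sat - p$response_free) * f
    out <- tibble(
      ligand_uM = p$ligand_points,
      response = y + rnorm(length(y), 0, p$noise_sd)
    )
  } else {
    amps <- seq(0.02, 0.12, length.out = p$n_residues)
    out <- tidyr::expand_grid(
      residue = sprintf("R%02d", seq_len(p$n_residues)),
      ligand_uM = p$ligand_points
    )
    out$csp <- rep(amps, each = length(p$ligand_points)) *
      rep(f, times = p$n_residues) +
      rnorm(nrow(out), 0, p$noise_sd)
  }
  structure(out,
    params = p, mode = p$readout_mode,
    class = c("titration_series", class(out))
  )
}
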