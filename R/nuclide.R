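#' Radionuclide physical constants
#'
#' A `nuclide_spec` carries the two physical constants the organ-level dose
#' model needs: the physical half-life (which bounds all fitted effective
#' decay rates from below, since biological clearance can only speed up the
#' observed washout) and the mean energy deposited locally per decay.
#'
#' For Lu-177 the locally absorbed energy is dominated by its beta emissions
#' (mean beta energy ~0.134 MeV) plus conversion/Auger electrons; the default
#' of 0.147 MeV per decay is the standard electron (non-photon) energy per
#' decay from nuclear data compilations. Gamma dose to distant organs is not
#' modeled.
#'
#' @param physical_half_life_h Physical half-life in hours. Must be > 0.
#' @param mean_energy_per_decay_MeV Mean locally deposited energy per decay
#'   in MeV. Must be > 0.
#'
#' @return An object of class `nuclide_spec` with elements
#'   `physical_half_life_h`, `mean_energy_per_decay_MeV`, and the derived
#'   physical decay constant `lambda_phys` (per hour).
#' @examples
#' lu <- nuclide_lu177()
#' lu$lambda_phys            # ln(2) / 159.5
#' @export
nuclide_spec <- function(physical_half_life_h, mean_energy_per_decay_MeV) {
  stopifnot(is.numeric(physical_half_life_h), length(physical_half_life_h) == 1L,
            is.numeric(mean_energy_per_decay_MeV), length(mean_energy_per_decay_MeV) == 1L)
  if (!is.finite(physical_half_life_h) || physical_half_life_h <= 0)
    stop("physical_half_life_h must be a positive finite number", call. = FALSE)
  if (!is.finite(mean_energy_per_decay_MeV) || mean_energy_per_decay_MeV <= 0)
    stop("mean_energy_per_decay_MeV must be a positive finite number", call. = FALSE)
  structure(
    list(physical_half_life_h = physical_half_life_h,
         mean_energy_per_decay_MeV = mean_energy_per_decay_MeV,
         lambda_phys = log(2) / physical_half_life_h),
    class = "nuclide_spec"
  )
}

#' @rdname nuclide_spec
#' @export
nuclide_lu177 <- function() {
  nuclide_spec(physical_half_life_h = 159.5, mean_energy_per_decay_MeV = 0.147)
}

#' @export
print.nuclide_spec <- function(x, ...) {
  cat(sprintf("<nuclide_spec> T_phys = %.2f h, E_local = %.4f MeV/decay, lambda_phys = %.3e /h\n",
              x$physical_half_life_h, x$mean_energy_per_decay_MeV, x$lambda_phys))
  invisible(x)
}

#' Organs recognised by the pipeline
#'
#' The whole-body tumor compartment and the four organs at risk tracked by
#' the dosimetry comparison.
#' @return Character vector of organ labels.
#' @export
organ_levels <- function() {
  c("kidneys", "liver", "spleen", "bone_marrow", "tumor")
}
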