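#' Confocal volume from a dye calibration fit
#'
#' Converts the diffusion time of a reference dye of known diffusion
#' coefficient into the lateral waist `w0 = sqrt(4 D_dye tau_D)` and the
#' effective confocal volume `V = pi^{3/2} w0^3 k` (litres).  The default
#' `D_dye` of 521.46 um^2/s is the literature value for Alexa 568 in
#' water; with a measured `tau_D` of ~24.3 us this yields a ~225 nm
#' waist and, for `k = 5`, ~0.317 fL.
#'
#' @param tau_d Dye diffusion time from [fit_triplet_diffusion()], s.
#' @param k Structural parameter (from the same fit).
#' @param D_dye Reference dye diffusion coefficient, um^2/s.
#' @return Object of class `confocal_volume`: list with `w0` (um), `k`,
#'   `V` (litres) and `D_dye` (um^2/s).
#' @export
#' @examples
#' cv <- confocal_volume_from_dye(tau_d = 24.27e-6, k = 5)
#' cv$w0   # ~0.225 um
#' cv$V    # ~3.17e-16 L
confocal_volume_from_dye <- function(tau_d, k, D_dye = 521.46) {
  check_scalar(tau_d, "tau_d", positive = TRUE)
  check_scalar(k, "k", positive = TRUE)
  check_scalar(D_dye, "D_dye", positive = TRUE)
  w0 <- sqrt(4 * D_dye * tau_d)
  structure(list(w0 = w0, k = k, V = effective_volume_litres(w0, k),
                 D_dye = D_dye),
            class = "confocal_volume")
}

#' @export
print.confocal_volume <- function(x, ...) {
  cat(sprintf("<confocal_volume> w0 = %.4g um, k = %.3g, V = %.4g fL (D_dye = %.5g um^2/s)\n",
              x$w0, x$k, x$V * 1e15, x$D_dye))
  invisible(x)
}

#' Diffusion time implied by a waist and diffusion coefficient
#'
#' Inverse of the waist relation: `tau_D = w0^2 / (4 D)`.  Useful for
#' checking calibration round trips and for predicting the diffusion
#' time of a species of known mobility.
#'
#' @param w0 Lateral waist, um.
#' @param D Diffusion coefficient, um^2/s.
#' @return Diffusion time in seconds.
#' @export
diffusion_time <- function(w0, D) {
  check_scalar(w0, "w0", positive = TRUE)
  check_scalar(D, "D", positive = TRUE)
  w0^2 / (4 * D)
}

#' Molar concentration from a fitted particle number
#'
#' `C = N / (V NA)`: the fitted mean particle number in the effective
#' confocal volume divided by that volume and the Avogadro constant.
#'
#' @param N Fitted particle number (dimensionless, >= 0).
#' @param volume A [confocal_volume_from_dye()] result, or a volume in
#'   litres.
#' @return Object of class `concentration_estimate`: list with `C`
#'   (mol/L), `C_nM` (nmol/L), `N` and `V` (L).
#' @export
#' @examples
#' cv <- confocal_volume_from_dye(24.27e-6, 5)
#' concentration_from_fit(1.91, cv)$C_nM   # ~10 nM
concentration_from_fit <- function(N, volume) {
  check_scalar(N, "N", nonneg = TRUE)
  V <- if (inherits(volume, "confocal_volume")) volume$V else volume
  check_scalar(V, "V", positive = TRUE)
  C <- N / (V * .const$avogadro)
  structure(list(C = C, C_nM = C * 1e9, N = N, V = V),
            class = "concentration_estimate")
}

#' @export
print.concentration_estimate <- function(x, ...) {
  cat(sprintf("<concentration_estimate> C = %.4g nM (N = %.4g in %.4g fL)\n",
              x$C_nM, x$N, x$V * 1e15))
  invisible(x)
}
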