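#' Physical constants for dielectric calculations
#'
#' The loss index and the conductivity of a material are linked by
#' \eqn{\sigma = \omega \epsilon_0 \epsilon''}, where \eqn{\omega} is the
#' angular frequency of the field and \eqn{\epsilon_0} the vacuum
#' permittivity. At 7 T the proton Larmor frequency is 297.2 MHz, which is
#' also inside the 200--400 MHz band of coaxial-probe dielectric
#' measurements, so it is used as the default evaluation frequency.
#'
#' @param larmor_MHz Evaluation frequency in MHz.
#' @return A list with `eps0` (F/m), `larmor_MHz`, and the angular frequency
#'   `w` (rad/s).
#' @examples
#' physical_constants()$w
#' @export
physical_constants <- function(larmor_MHz = 297.2) {
  stopifnot(is.numeric(larmor_MHz), length(larmor_MHz) == 1, larmor_MHz > 0)
  list(
    eps0 = 8.8541878128e-12,
    larmor_MHz = larmor_MHz,
    w = 2 * pi * larmor_MHz * 1e6
  )
}

#' Convert between conductivity and loss index
#'
#' @param sigma Conductivity in S/m.
#' @param loss_index Dimensionless loss index (imaginary permittivity).
#' @param constants As returned by [physical_constants()].
#' @return The converted quantity.
#' @export
loss_index_from_sigma <- function(sigma, constants = physical_constants()) {
  sigma / (constants$w * constants$eps0)
}

#' @rdname loss_index_from_sigma
#' @export
sigma_from_loss_index <- function(loss_index, constants = physical_constants()) {
  loss_index * constants$w * constants$eps0
}
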