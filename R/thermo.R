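#' Microscopic rates from exchange parameters
#'
#' Splits \eqn{k_{ex} = k_1 + k_{-1}} into the forward (ground to
#' excited) and reverse rates using detailed balance:
#' \eqn{k_1 = k_{ex}\,p_{excited}},
#' \eqn{k_{-1} = k_{ex}\,(1 - p_{excited})}.
#'
#' @param k_ex Exchange rate in s\eqn{^{-1}}; positive.
#' @param p_excited Excited-state population, strictly inside (0, 1).
#' @return Named vector \code{c(k1 = , k_minus1 = )} in s\eqn{^{-1}}.
#' @examples
#' rates_from_exchange(2490, 0.032)
#' @export
rates_from_exchange <- function(k_ex, p_excited) {
  .check_number(k_ex, "k_ex", lower = 0, strict_lower = TRUE)
  .check_number(p_excited, "p_excited", lower = 0, upper = 1,
                strict_lower = TRUE, strict_upper = TRUE)
  c(k1 = k_ex * p_excited, k_minus1 = k_ex * (1 - p_excited))
}

#' Gibbs free-energy difference from state populations
#'
#' \eqn{\Delta G = -R T \ln(p_{excited}/p_{ground})}, the free energy of
#' the excited state relative to the ground state.
#'
#' @param p_ground,p_excited State populations; positive, summing to at
#'   most 1 (within 1e-6).
#' @param temperature Temperature in K.
#' @return \eqn{\Delta G} in J mol\eqn{^{-1}}.
#' @examples
#' populations_to_dG(0.968, 0.032, 293) / 1000  # ~8.30 kJ/mol
#' @export
populations_to_dG <- function(p_ground, p_excited, temperature) {
  .check_number(p_ground, "p_ground", lower = 0, strict_lower = TRUE)
  .check_number(p_excited, "p_excited", lower = 0, strict_lower = TRUE)
  if (p_ground + p_excited > 1 + 1e-6)
    .stopf("populations sum to %g > 1", p_ground + p_excited)
  .check_number(temperature, "temperature", lower = 0, strict_lower = TRUE)
  -.R_GAS * temperature * log(p_excited / p_ground)
}

#' Eyring activation free energy
#'
#' Inverts the Eyring equation
#' \eqn{k = \kappa (k_B T / h) \exp(-\Delta G^\ddagger / RT)} for the
#' activation free energy, with transmission coefficient \eqn{\kappa}
#' (1 by default).
#'
#' @param rate Rate constant in s\eqn{^{-1}}; positive.
#' @param temperature Temperature in K.
#' @param kappa Transmission coefficient.
#' @return \eqn{\Delta G^\ddagger} in J mol\eqn{^{-1}}.
#' @examples
#' eyring_dG(79.68, 293) / 1000  # ~61.0 kJ/mol
#' @export
eyring_dG <- function(rate, temperature, kappa = 1) {
  .check_number(rate, "rate", lower = 0, strict_lower = TRUE)
  .check_number(temperature, "temperature", lower = 0, strict_lower = TRUE)
  .check_number(kappa, "kappa", lower = 0, strict_lower = TRUE)
  -.R_GAS * temperature * log(rate * .PLANCK / (kappa * .K_B * temperature))
}

#' Thermo-kinetic summary of a two-state exchange
#'
#' Composes the full chain from global exchange parameters: microscopic
#' rates, state half-lives (\eqn{\ln 2 / k}), the Gibbs free-energy
#' difference between the states, and the Eyring activation free
#' energies of the forward and reverse transitions (\eqn{\kappa = 1}).
#' The identity \eqn{\Delta G = \Delta G^\ddagger_{fwd} -
#' \Delta G^\ddagger_{rev}} holds by construction.
#'
#' @param exch An [exchange_params()] object, or the excited-state
#'   population (then also supply \code{k_ex} and \code{temperature}).
#' @param k_ex,temperature Used when \code{exch} is a bare population.
#' @param kappa Transmission coefficient for the Eyring conversion.
#' @return An object of class \code{"kinetic_summary"}: list with
#'   \code{k1}, \code{k_minus1} (s\eqn{^{-1}}), \code{t_half_ground},
#'   \code{t_half_excited} (s), \code{dG}, \code{dG_forward},
#'   \code{dG_reverse} (J mol\eqn{^{-1}}), \code{temperature},
#'   \code{kappa}.
#' @examples
#' kinetic_summary(exchange_params(0.032, 2490, 293))
#' @export
kinetic_summary <- function(exch, k_ex = NULL, temperature = 293, kappa = 1) {
  if (!inherits(exch, "exchange_params"))
    exch <- exchange_params(exch, k_ex, temperature)
  p <- exch$p_excited
  .check_number(p, "p_excited", lower = 0, upper = 0.5, strict_lower = TRUE)
  k <- rates_from_exchange(exch$k_ex, p)
  tt <- exch$temperature
  out <- list(
    k1 = k[["k1"]], k_minus1 = k[["k_minus1"]],
    t_half_ground = log(2) / k[["k1"]],
    t_half_excited = log(2) / k[["k_minus1"]],
    dG = populations_to_dG(1 - p, p, tt),
    dG_forward = eyring_dG(k[["k1"]], tt, kappa),
    dG_reverse = eyring_dG(k[["k_minus1"]], tt, kappa),
    temperature = tt, kappa = kappa,
    k_ex = exch$k_ex, p_excited = p)
  structure(out, class = "kinetic_summary")
}

#' @export
print.kinetic_summary <- function(x, ...) {
  kj <- function(v) sprintf("%.3g kJ/mol", v / 1000)
  cat("Two-state thermo-kinetic summary\n")
  cat(sprintf("  T = %g K, kappa = %g\n", x$temperature, x$kappa))
  cat(sprintf("  k_ex = %.4g s^-1, p_excited = %.4g\n", x$k_ex, x$p_excited))
  cat(sprintf("  k1 (ground->excited)   = %.4g s^-1   half-life %.2g ms\n",
              x$k1, 1000 * x$t_half_ground))
  cat(sprintf("  k-1 (excited->ground)  = %.4g s^-1   half-life %.2g ms\n",
              x$k_minus1, 1000 * x$t_half_excited))
  cat(sprintf("  dG (excited - ground)  = %s\n", kj(x$dG)))
  cat(sprintf("  dG+ (ground -> TS)     = %s\n", kj(x$dG_forward)))
  cat(sprintf("  dG+ (excited -> TS)    = %s\n", kj(x$dG_reverse)))
  invisible(x)
}

#' @export
as.data.frame.kinetic_summary <- function(x, ...) {
  data.frame(quantity = c("k1_s1", "k_minus1_s1", "t_half_ground_s",
                          "t_half_excited_s", "dG_J_mol", "dG_forward_J_mol",
                          "dG_reverse_J_mol", "temperature_K", "kappa"),
             value = c(x$k1, x$k_minus1, x$t_half_ground, x$t_half_excited,
                       x$dG, x$dG_forward, x$dG_reverse, x$temperature,
                       x$kappa))
}
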