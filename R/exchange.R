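#' Global two-state exchange parameters
#'
#' Container for the global parameters of a two-site exchange process
#' A (ground) \eqn{\rightleftharpoons} B (excited): the excited-state
#' population \eqn{p_B}, the exchange rate \eqn{k_{ex} = k_1 + k_{-1}},
#' and the temperature at which they apply.
#'
#' @param p_excited Population of the minor (excited) state, in
#'   \eqn{[0, 0.5]} by the minor-state convention.
#' @param k_ex Exchange rate \eqn{k_1 + k_{-1}} in s\eqn{^{-1}}; must be
#'   positive.
#' @param temperature Temperature in kelvin.
#' @return An object of class \code{"exchange_params"}.
#' @examples
#' exchange_params(p_excited = 0.032, k_ex = 2490, temperature = 293)
#' @export
exchange_params <- function(p_excited, k_ex, temperature = 293) {
  .check_number(p_excited, "p_excited", lower = 0, upper = 0.5)
  .check_number(k_ex, "k_ex", lower = 0, strict_lower = TRUE)
  .check_number(temperature, "temperature", lower = 0, strict_lower = TRUE)
  structure(list(p_excited = p_excited, k_ex = k_ex,
                 temperature = temperature),
            class = "exchange_params")
}

#' @export
print.exchange_params <- function(x, ...) {
  cat(sprintf("Two-state exchange: p_excited = %.4g, k_ex = %.6g s^-1, T = %g K\n",
              x$p_excited, x$k_ex, x$temperature))
  invisible(x)
}

#' Per-probe parameters of the dispersion forward model
#'
#' Residue-specific parameters of one relaxation-dispersion probe: the
#' absolute chemical-shift differences between the exchanging states and
#' the exchange-free transverse relaxation rate per static field.
#'
#' @param probe_id Label, e.g. \code{"T115-CG2"}.
#' @param nucleus_mode \code{"N15_SQ"} (backbone amide single quantum) or
#'   \code{"CH3_MQ"} (methyl \eqn{^{13}}C-\eqn{^1}H multiple quantum).
#' @param dw_X Heteronucleus shift difference \eqn{|\Delta\omega_X|} in ppm
#'   (\eqn{^{15}}N or \eqn{^{13}}C depending on mode); non-negative.
#' @param dw_H Proton shift difference \eqn{|\Delta\omega_H|} in ppm; must
#'   be 0 for \code{"N15_SQ"}.
#' @param relative_sign Sign (+1/-1) of \eqn{\Delta\omega_H} relative to
#'   \eqn{\Delta\omega_X}; only meaningful for multiple-quantum probes.
#' @param r2_base Named numeric vector of exchange-free rates
#'   \eqn{R_{2,0}} in s\eqn{^{-1}}, names = \eqn{^1}H field in MHz.
#' @return An object of class \code{"probe_params"}.
#' @export
probe_params <- function(probe_id, nucleus_mode = c("N15_SQ", "CH3_MQ"),
                         dw_X, dw_H = 0, relative_sign = 1,
                         r2_base = numeric()) {
  nucleus_mode <- match.arg(nucleus_mode)
  .check_number(dw_X, "dw_X", lower = 0)
  .check_number(dw_H, "dw_H", lower = 0)
  if (nucleus_mode == "N15_SQ" && dw_H != 0)
    .stopf("dw_H must be 0 for an N15_SQ probe (got %g)", dw_H)
  if (!relative_sign %in% c(-1, 1))
    .stopf("relative_sign must be +1 or -1")
  if (length(r2_base) && (is.null(names(r2_base)) || any(r2_base < 0)))
    .stopf("r2_base must be a named (by field, MHz) vector of non-negative rates")
  structure(list(probe_id = probe_id, nucleus_mode = nucleus_mode,
                 dw_X = dw_X, dw_H = dw_H, relative_sign = relative_sign,
                 r2_base = r2_base),
            class = "probe_params")
}

#' Constant-time CPMG schedule
#'
#' The refocusing-frequency grid of a constant-time CPMG experiment.  The
#' convention is \eqn{\nu_{cpmg} = n_\pi / (2 T_{relax})} with an even
#' number \eqn{n_\pi} of refocusing pulses in the relaxation period;
#' defaults mirror 30 ms periods with 16 frequencies between 66 and
#' 2000 Hz for methyl experiments and 60 ms with 11 frequencies between
#' 33 and 1000 Hz for amide experiments.
#'
#' @param nucleus_mode \code{"N15_SQ"} or \code{"CH3_MQ"}.
#' @param t_relax Relaxation period in s; defaults to 0.030 s for
#'   \code{"CH3_MQ"} and 0.060 s for \code{"N15_SQ"}.
#' @param nu_list CPMG frequencies in Hz; every value must correspond to
#'   an even pulse count in \code{t_relax}.
#' @return An object of class \code{"cpmg_schedule"}.
#' @export
cpmg_schedule <- function(nucleus_mode = c("CH3_MQ", "N15_SQ"),
                          t_relax = NULL, nu_list = NULL) {
  nucleus_mode <- match.arg(nucleus_mode)
  if (is.null(t_relax)) t_relax <- .T_RELAX_DEFAULT[[nucleus_mode]]
  .check_number(t_relax, "t_relax", lower = 0, strict_lower = TRUE)
  if (is.null(nu_list)) {
    n <- if (nucleus_mode == "CH3_MQ")
      c(4L, 6L, 8L, 10L, 12L, 14L, 18L, 24L, 30L, 38L, 48L, 60L, 72L, 88L, 104L, 120L)
    else
      c(4L, 6L, 8L, 12L, 16L, 22L, 30L, 40L, 60L, 90L, 120L)
    nu_list <- n / (2 * t_relax)
  }
  pulses_for_nu(nu_list, t_relax)  # validates commensurability
  structure(list(nucleus_mode = nucleus_mode, t_relax = t_relax,
                 nu_list = sort(nu_list)),
            class = "cpmg_schedule")
}

#' Refocusing pulse count for a CPMG frequency
#'
#' Inverts \eqn{\nu_{cpmg} = n_\pi/(2 T_{relax})} and checks that the
#' frequency corresponds to an even integer pulse count.
#'
#' @param nu_cpmg CPMG frequency/frequencies in Hz.
#' @param t_relax Relaxation period in s.
#' @param tol Relative tolerance on commensurability.
#' @return Integer vector of pulse counts.
#' @export
pulses_for_nu <- function(nu_cpmg, t_relax, tol = 1e-3) {
  if (any(!is.finite(nu_cpmg)) || any(nu_cpmg <= 0))
    .stopf("nu_cpmg must be positive and finite")
  n_exact <- 2 * t_relax * nu_cpmg
  n <- round(n_exact)
  bad <- abs(n_exact - n) > tol * pmax(1, n_exact) | n < 2 | (n %% 2) != 0
  if (any(bad))
    .stopf("nu_cpmg = %s Hz is not commensurate with an even pulse count in t_relax = %g s",
           paste(format(nu_cpmg[bad]), collapse = ", "), t_relax)
  as.integer(n)
}

#' Effective relaxation rate from peak intensities
#'
#' \eqn{R_{2,eff} = -\ln(I_\nu / I_{ref}) / T_{relax}}: the dispersion
#' observable, computed from the intensity at a given CPMG frequency and
#' the reference intensity recorded without the relaxation period.
#'
#' @param i_nu Peak intensity at the CPMG frequency; positive.
#' @param i_ref Reference intensity; positive.
#' @param t_relax Relaxation period in s; positive.
#' @return Rate in s\eqn{^{-1}}.
#' @seealso [intensity_from_r2eff()] for the inverse.
#' @examples
#' r2eff_from_intensity(0.5, 1, 0.030)  # ln(2)/0.030 = 23.105 s^-1
#' @export
r2eff_from_intensity <- function(i_nu, i_ref, t_relax) {
  if (any(!is.finite(i_nu)) || any(i_nu <= 0))
    .stopf("i_nu must be positive (got %s)", paste(format(i_nu[i_nu <= 0 | !is.finite(i_nu)]), collapse = ", "))
  if (any(!is.finite(i_ref)) || any(i_ref <= 0))
    .stopf("i_ref must be positive (got %s)", paste(format(i_ref[i_ref <= 0 | !is.finite(i_ref)]), collapse = ", "))
  .check_number(t_relax, "t_relax", lower = 0, strict_lower = TRUE)
  -log(i_nu / i_ref) / t_relax
}

#' @rdname r2eff_from_intensity
#' @param r2eff Effective relaxation rate in s\eqn{^{-1}}.
#' @export
intensity_from_r2eff <- function(r2eff, i_ref, t_relax) {
  .check_number(t_relax, "t_relax", lower = 0, strict_lower = TRUE)
  i_ref * exp(-r2eff * t_relax)
}

#' Chemical-shift difference in angular frequency units
#'
#' Converts a shift difference in ppm to rad/s at a given spectrometer
#' field, using the nucleus' gyromagnetic ratio relative to \eqn{^1}H
#' (0.10136 for \eqn{^{15}}N, 0.25144 for \eqn{^{13}}C, 1 for \eqn{^1}H).
#'
#' @param dw_ppm Shift difference in ppm.
#' @param field_MHz \eqn{^1}H Larmor frequency of the spectrometer in MHz.
#' @param nucleus One of \code{"H1"}, \code{"C13"}, \code{"N15"}.
#' @return Angular frequency in rad/s.
#' @export
ppm_to_rad <- function(dw_ppm, field_MHz, nucleus = c("H1", "C13", "N15")) {
  nucleus <- match.arg(nucleus)
  rel <- switch(nucleus, H1 = 1, C13 = .GAMMA_REL[["CH3_MQ"]],
                N15 = .GAMMA_REL[["N15_SQ"]])
  2 * pi * dw_ppm * field_MHz * rel
}

# exchange contribution (r2_base = 0) for one probe at one field;
# n integer pulse counts
.rex_model <- function(nucleus_mode, p_excited, k_ex, dw_X, dw_H,
                       relative_sign, field_MHz, n, t_relax) {
  if (p_excited == 0 || (dw_X == 0 && dw_H == 0)) return(rep(0, length(n)))
  off_x <- ppm_to_rad(dw_X, field_MHz,
                      if (nucleus_mode == "N15_SQ") "N15" else "C13")
  if (nucleus_mode == "N15_SQ") {
    .cpmg_rex_core(p_excited, k_ex, off_x, -off_x, n, t_relax)
  } else {
    off_h <- relative_sign * ppm_to_rad(dw_H, field_MHz, "H1")
    dq <- .cpmg_rex_core(p_excited, k_ex, off_h + off_x, off_h - off_x, n, t_relax)
    zq <- .cpmg_rex_core(p_excited, k_ex, off_h - off_x, off_h + off_x, n, t_relax)
    (dq + zq) / 2
  }
}

.r2_base_at <- function(probe, field_MHz) {
  if (!length(probe$r2_base)) .stopf("probe '%s' has no r2_base entries", probe$probe_id)
  idx <- which(abs(as.numeric(names(probe$r2_base)) - field_MHz) < 1e-6)
  if (!length(idx))
    .stopf("probe '%s' has no r2_base for field %g MHz", probe$probe_id, field_MHz)
  probe$r2_base[[idx[1]]]
}

#' Two-state CPMG dispersion forward model
#'
#' Effective transverse relaxation rate \eqn{R_{2,eff}(\nu_{cpmg})} of a
#' probe under two-site chemical exchange during an ideal even-pulse
#' constant-time CPMG train, by numerical propagation of the
#' Bloch-McConnell evolution of the two-site coherence.  For
#' multiple-quantum probes the result is the average over the
#' double-quantum and zero-quantum coherence pathways; it reduces to the
#' single-quantum model when \code{dw_H = 0}.
#'
#' @param exch [exchange_params()].
#' @param probe [probe_params()]; must carry an \code{r2_base} entry for
#'   the requested field.
#' @param field_MHz Spectrometer \eqn{^1}H frequency in MHz.
#' @param nu_cpmg CPMG frequencies in Hz (vectorized).
#' @param t_relax Relaxation period in s; defaults to the per-mode
#'   standard (0.030 s methyl MQ, 0.060 s amide SQ).
#' @return \eqn{R_{2,eff}} in s\eqn{^{-1}}, one value per frequency.
#' @examples
#' ex <- exchange_params(0.032, 2490, 293)
#' pr <- probe_params("T115-CG2", "CH3_MQ", dw_X = 1, dw_H = 0.1,
#'                    r2_base = c("850" = 15))
#' cpmg_r2eff(ex, pr, 850, c(100, 500, 2000))
#' @export
cpmg_r2eff <- function(exch, probe, field_MHz, nu_cpmg, t_relax = NULL) {
  stopifnot(inherits(exch, "exchange_params"), inherits(probe, "probe_params"))
  if (is.null(t_relax)) t_relax <- .T_RELAX_DEFAULT[[probe$nucleus_mode]]
  n <- pulses_for_nu(nu_cpmg, t_relax)
  base <- .r2_base_at(probe, field_MHz)
  base + .rex_model(probe$nucleus_mode, exch$p_excited, exch$k_ex,
                    probe$dw_X, probe$dw_H, probe$relative_sign,
                    field_MHz, n, t_relax)
}

#' @rdname cpmg_r2eff
#' @export
sq_cpmg_r2eff <- function(exch, probe, field_MHz, nu_cpmg, t_relax = NULL) {
  if (probe$nucleus_mode != "N15_SQ")
    .stopf("sq_cpmg_r2eff requires an N15_SQ probe")
  cpmg_r2eff(exch, probe, field_MHz, nu_cpmg, t_relax)
}

#' @rdname cpmg_r2eff
#' @export
mq_cpmg_r2eff <- function(exch, probe, field_MHz, nu_cpmg, t_relax = NULL) {
  if (probe$nucleus_mode != "CH3_MQ")
    .stopf("mq_cpmg_r2eff requires a CH3_MQ probe")
  cpmg_r2eff(exch, probe, field_MHz, nu_cpmg, t_relax)
}
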