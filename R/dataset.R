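#' Relaxation-dispersion dataset
#'
#' Bundles per-probe \eqn{R_{2,eff}(\nu_{cpmg})} curves, possibly at
#' several static fields, together with the constant-time schedule per
#' experiment type and the sample temperature.
#'
#' @param points A data frame with columns \code{probe_id},
#'   \code{nucleus_mode} (\code{"N15_SQ"}/\code{"CH3_MQ"}),
#'   \code{field_MHz}, \code{nu_cpmg}, \code{r2eff}, \code{sigma}.
#' @param temperature Sample temperature in K.
#' @param t_relax Named vector of relaxation periods (s) per nucleus
#'   mode.
#' @param relative_sign Named vector (by probe id) of \eqn{\Delta\omega_H}
#'   relative signs for MQ probes, or a single value recycled; default +1.
#' @return An object of class \code{"dispersion_dataset"}: list with
#'   elements \code{points} (the validated data frame), \code{t_relax},
#'   \code{temperature}, \code{relative_sign}.
#' @export
dispersion_dataset <- function(points, temperature = 293,
                               t_relax = .T_RELAX_DEFAULT,
                               relative_sign = 1) {
  req <- c("probe_id", "nucleus_mode", "field_MHz", "nu_cpmg", "r2eff", "sigma")
  miss <- setdiff(req, names(points))
  if (length(miss))
    .stopf("points is missing column(s): %s", paste(miss, collapse = ", "))
  points <- as.data.frame(points)[req]
  if (!all(points$nucleus_mode %in% .NUCLEUS_MODES))
    .stopf("unknown nucleus_mode value(s): %s",
           paste(unique(setdiff(points$nucleus_mode, .NUCLEUS_MODES)), collapse = ", "))
  if (any(points$nu_cpmg <= 0)) .stopf("all nu_cpmg must be positive")
  if (any(points$sigma <= 0) || any(!is.finite(points$sigma)))
    .stopf("all sigma must be positive; use apply_error_floor() for missing uncertainties")
  .check_number(temperature, "temperature", lower = 0, strict_lower = TRUE)
  for (pid in unique(points$probe_id)) {
    sub <- points[points$probe_id == pid, ]
    if (length(unique(sub$nucleus_mode)) != 1L)
      .stopf("probe '%s' mixes nucleus modes", pid)
    if (length(unique(sub$nu_cpmg)) < 2L)
      .stopf("probe '%s' has fewer than 2 distinct nu_cpmg values", pid)
    pulses_for_nu(sub$nu_cpmg, t_relax[[sub$nucleus_mode[1]]])
  }
  if (is.null(names(relative_sign)))
    relative_sign <- setNames(rep(relative_sign[1], length(unique(points$probe_id))),
                              unique(points$probe_id))
  structure(list(points = points, temperature = temperature,
                 t_relax = t_relax, relative_sign = relative_sign),
            class = "dispersion_dataset")
}

#' @export
print.dispersion_dataset <- function(x, ...) {
  pid <- unique(x$points$probe_id)
  cat(sprintf("Dispersion dataset: %d curves, %d points, fields %s MHz, T = %g K\n",
              length(pid), nrow(x$points),
              paste(sort(unique(x$points$field_MHz)), collapse = "/"),
              x$temperature))
  invisible(x)
}

#' @export
`[.dispersion_dataset` <- function(x, probes) {
  keep <- x$points$probe_id %in% probes
  dispersion_dataset(x$points[keep, , drop = FALSE], x$temperature,
                     x$t_relax, x$relative_sign[probes[probes %in% names(x$relative_sign)]])
}

#' Probe identifiers of a dataset
#' @param data A [dispersion_dataset()].
#' @return Character vector of probe ids, in order of first appearance.
#' @export
curve_ids <- function(data) unique(data$points$probe_id)

#' Error floor on dispersion uncertainties
#'
#' Uncertainties smaller than a fixed fraction (default 2\%) of the
#' \eqn{R_{2,eff}} value are raised to that fraction.
#'
#' @param r2eff Rates in s\eqn{^{-1}} (non-negative).
#' @param sigma_raw Raw uncertainties in s\eqn{^{-1}} (non-negative).
#' @param floor_fraction Fraction of the rate used as the floor.
#' @return \code{pmax(sigma_raw, floor_fraction * r2eff)}.
#' @examples
#' apply_error_floor(50, 0.5)  # -> 1.0
#' @export
apply_error_floor <- function(r2eff, sigma_raw, floor_fraction = 0.02) {
  if (any(r2eff < 0)) .stopf("r2eff must be non-negative (got %g)", min(r2eff))
  if (any(sigma_raw < 0)) .stopf("sigma_raw must be non-negative (got %g)", min(sigma_raw))
  pmax(sigma_raw, floor_fraction * r2eff)
}

#' Exchange contribution of a dispersion curve
#'
#' Per field, the difference between \eqn{R_{2,eff}} at the lowest and at
#' the highest CPMG frequency; the maximum over fields is returned.  This
#' is the \eqn{R_{ex}} amplitude used by the inclusion filter.
#'
#' @param curve Data frame with columns \code{field_MHz}, \code{nu_cpmg},
#'   \code{r2eff} (one probe's points).
#' @return \eqn{R_{ex}} estimate in s\eqn{^{-1}}.
#' @export
rex_estimate <- function(curve) {
  if (nrow(curve) < 2L) .stopf("a curve needs at least 2 points")
  by_field <- split(curve, curve$field_MHz)
  vals <- vapply(by_field, function(sub) {
    sub$r2eff[which.min(sub$nu_cpmg)] - sub$r2eff[which.max(sub$nu_cpmg)]
  }, numeric(1))
  max(vals)
}

#' Per-probe exchange contributions
#' @inheritParams curve_ids
#' @return Named vector of [rex_estimate()] values per probe.
#' @export
rex_estimates <- function(data) {
  stopifnot(inherits(data, "dispersion_dataset"))
  vapply(split(data$points, data$points$probe_id)[curve_ids(data)],
         rex_estimate, numeric(1))
}

#' Filter curves by exchange contribution
#'
#' Retains curves whose exchange contribution \eqn{R_{ex}} is at least
#' \code{rex_min} (inclusive), mirroring the usual practice of analysing
#' only probes with \eqn{R_{ex} \ge 2} s\eqn{^{-1}}.
#'
#' @inheritParams curve_ids
#' @param rex_min Inclusion threshold in s\eqn{^{-1}}.
#' @return The filtered [dispersion_dataset()]; the dropped probe ids are
#'   attached as attribute \code{"excluded"}.  An empty result triggers a
#'   warning, not an error.
#' @export
filter_curves <- function(data, rex_min = 2) {
  stopifnot(inherits(data, "dispersion_dataset"))
  rex <- rex_estimates(data)
  keep <- names(rex)[rex >= rex_min]
  dropped <- setdiff(names(rex), keep)
  if (!length(keep)) {
    warning("no curve passes the Rex filter; returning an empty dataset")
    out <- data
    out$points <- data$points[0, ]
  } else {
    out <- data
    out$points <- data$points[data$points$probe_id %in% keep, , drop = FALSE]
    out$relative_sign <- data$relative_sign[names(data$relative_sign) %in% keep]
  }
  attr(out, "excluded") <- dropped
  out
}
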