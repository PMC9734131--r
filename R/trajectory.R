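#' Violation thresholds from a reference ensemble
#'
#' For each state-specific restraint pair, the violation threshold is
#' \eqn{d^{viol}_{ij} = \langle d_{ij}\rangle + 2\sigma(d_{ij})}, where
#' mean and standard deviation are taken over the reference bundle
#' (population standard deviation by default, since the bundle is the
#' complete reference set).
#'
#' @param reference_ensemble A [conformer_ensemble()] with \eqn{\ge} 2
#'   models (e.g. a 20-member refined bundle).
#' @param state_restraints A [restraint_table()] of the state's specific
#'   restraints; only the atom pairs are used.
#' @param state_label Label of the state the thresholds describe.
#' @param sd_type \code{"population"} (divide by n) or \code{"sample"}
#'   (n-1).
#' @return An object of class \code{"violation_spec"}: data frame of
#'   pairs with \code{mean}, \code{sd} and \code{d_viol} (\AA{}).
#' @export
build_violation_spec <- function(reference_ensemble, state_restraints,
                                 state_label = "reference",
                                 sd_type = c("population", "sample")) {
  stopifnot(inherits(reference_ensemble, "conformer_ensemble"))
  sd_type <- match.arg(sd_type)
  if (n_models(reference_ensemble) < 2)
    .stopf("the reference ensemble needs at least 2 models")
  rs <- .validate_restraints(as.data.frame(state_restraints))
  if (!nrow(rs)) .stopf("state_restraints is empty")
  n <- n_models(reference_ensemble)
  rows <- lapply(seq_len(nrow(rs)), function(r) {
    d <- vapply(reference_ensemble$models, function(m)
      restraint_distance(m, reference_ensemble$atoms, rs[r, ]), numeric(1))
    mu <- mean(d)
    s <- if (sd_type == "population") sqrt(mean((d - mu)^2)) else sd(d)
    data.frame(id = rs$id[r], resid_i = rs$resid_i[r], atoms_i = rs$atoms_i[r],
               resid_j = rs$resid_j[r], atoms_j = rs$atoms_j[r],
               mean = mu, sd = s, d_viol = mu + 2 * s)
  })
  pairs <- do.call(rbind, rows)
  if (any(pairs$d_viol <= 0)) .stopf("non-positive violation threshold")
  structure(list(state_label = state_label, pairs = pairs,
                 sd_type = sd_type),
            class = "violation_spec")
}

#' @export
print.violation_spec <- function(x, ...) {
  cat(sprintf("Violation spec '%s': %d pairs, d_viol %.2f-%.2f A\n",
              x$state_label, nrow(x$pairs), min(x$pairs$d_viol),
              max(x$pairs$d_viol)))
  invisible(x)
}

#' Per-frame restraint-violation statistic
#'
#' Along a trajectory, the violation relative to a reference state is
#' \eqn{V = \frac{1}{N}\sum_{ij} \max(0, d_{ij} - d^{viol}_{ij})}:
#' the average positive excess of the pair distances (methyl barycenter
#' geometry) over their state-specific thresholds.
#'
#' @param trajectory A [conformer_ensemble()] whose models are frames
#'   (optionally carrying \code{times}).
#' @param spec A [build_violation_spec()] result.
#' @return An object of class \code{"violation_series"}: \code{times},
#'   \code{V} (\AA{}, one value per frame), \code{state_label},
#'   \code{n_pairs}.
#' @export
violation_series <- function(trajectory, spec) {
  stopifnot(inherits(trajectory, "conformer_ensemble"),
            inherits(spec, "violation_spec"))
  pairs <- spec$pairs
  np <- nrow(pairs)
  v <- vapply(trajectory$models, function(m) {
    d <- vapply(seq_len(np), function(r)
      restraint_distance(m, trajectory$atoms, pairs[r, ]), numeric(1))
    mean(pmax(0, d - pairs$d_viol))
  }, numeric(1))
  times <- trajectory$times
  if (is.null(times)) times <- seq_along(trajectory$models)
  structure(list(times = times, V = v, state_label = spec$state_label,
                 n_pairs = np), class = "violation_series")
}

#' @export
print.violation_series <- function(x, ...) {
  cat(sprintf("Violation series vs '%s': %d frames, %d pairs, V in [%.3g, %.3g] A\n",
              x$state_label, length(x$V), x$n_pairs, min(x$V), max(x$V)))
  invisible(x)
}

#' @export
plot.violation_series <- function(x, ...) {
  plot(x$times, x$V, type = "l", xlab = "frame / time",
       ylab = "V (Angstrom)", main = paste("violations vs", x$state_label), ...)
  invisible(x)
}

.moving_average <- function(x, w) {
  if (w <= 1) return(x)
  n <- length(x)
  cs <- cumsum(c(0, x))
  half <- floor(w / 2)
  lo <- pmax(0, seq_len(n) - half - 1)
  hi <- pmin(n, seq_len(n) + half)
  (cs[hi + 1] - cs[lo + 1]) / (hi - lo)
}

#' Classify a trajectory by its violation behaviour
#'
#' After smoothing both violation series with a centred moving average,
#' a trajectory started in the "home" state is \code{"stable"} when the
#' smoothed home-state violation stays below \code{eps_stable}
#' throughout, \code{"transitioned"} when over the final fraction of
#' frames the other state's violation has dropped below
#' \code{eps_arrive} while the home state's exceeds \code{eps_depart},
#' and \code{"neither"} otherwise.
#'
#' @param v_home [violation_series()] against the starting state.
#' @param v_other [violation_series()] against the other state; must be
#'   on the same frame grid.
#' @param eps_stable,eps_arrive,eps_depart Thresholds in \AA{}.
#' @param window Moving-average window, frames.
#' @param final_fraction Fraction of trailing frames examined for
#'   arrival.
#' @return \code{"stable"}, \code{"transitioned"} or \code{"neither"}.
#' @export
classify_trajectory <- function(v_home, v_other, eps_stable = 0.5,
                                eps_arrive = 0.5, eps_depart = 1.0,
                                window = 10, final_fraction = 0.2) {
  stopifnot(inherits(v_home, "violation_series"),
            inherits(v_other, "violation_series"))
  if (length(v_home$V) != length(v_other$V))
    .stopf("violation series have different lengths (%d vs %d)",
           length(v_home$V), length(v_other$V))
  if (max(abs(rank(v_home$times) - rank(v_other$times))) > 0)
    .stopf("violation series are not on the same time grid")
  sh <- .moving_average(v_home$V, window)
  so <- .moving_average(v_other$V, window)
  if (all(sh < eps_stable)) return("stable")
  n <- length(sh)
  tail_idx <- seq(n - ceiling(final_fraction * n) + 1, n)
  if (all(so[tail_idx] < eps_arrive) && all(sh[tail_idx] > eps_depart))
    return("transitioned")
  "neither"
}
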