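#' @export
print.cpmg_fit <- function(x, ...) {
  cat("Global two-state CPMG dispersion fit\n")
  cat(sprintf("  curves: %d   points: %d   parameters: %d\n",
              length(x$probes), x$n_points, x$n_params))
  cat(sprintf("  k_ex      = %.6g s^-1%s\n", x$exch$k_ex,
              .pm(x$uncertainties, "k_ex", " s^-1")))
  cat(sprintf("  p_excited = %.4g%s\n", x$exch$p_excited,
              .pm(x$uncertainties, "p_excited", "")))
  cat(sprintf("  chi2 = %.5g  (reduced %.4g)%s\n", x$chi2, x$reduced_chi2,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

.pm <- function(unc, name, unit) {
  if (is.null(unc) || !name %in% names(unc)) return("")
  sprintf(" +/- %.3g%s", unc[[name]], unit)
}

#' Summary of a global dispersion fit
#' @param object A \code{"cpmg_fit"}.
#' @param ... Unused.
#' @return A \code{"summary.cpmg_fit"}: global parameters with
#'   uncertainties, a per-probe parameter table, and fit statistics.
#' @export
summary.cpmg_fit <- function(object, ...) {
  tab <- do.call(rbind, lapply(object$probes, function(p) {
    data.frame(probe_id = p$probe_id, nucleus = p$nucleus_mode,
               dw_X_ppm = p$dw_X, dw_H_ppm = p$dw_H,
               r2_base = paste(sprintf("%s:%.3g", names(p$r2_base), p$r2_base),
                               collapse = " "))
  }))
  rownames(tab) <- NULL
  if (!is.null(object$uncertainties)) {
    sx <- object$uncertainties[paste0("dw_X.", tab$probe_id)]
    tab$dw_X_sd <- as.numeric(sx)
  }
  structure(list(fit = object, probe_table = tab), class = "summary.cpmg_fit")
}

#' @export
print.summary.cpmg_fit <- function(x, ...) {
  print(x$fit)
  cat("\nPer-probe parameters:\n")
  print(x$probe_table, row.names = FALSE, digits = 4)
  if (!is.null(x$fit$mc))
    cat(sprintf("\nMonte-Carlo: %d repeats, %d dropped, seed %s\n",
                x$fit$mc$n_repeats, x$fit$mc$n_dropped,
                format(x$fit$mc$seed)))
  invisible(x)
}

#' @export
coef.cpmg_fit <- function(object, ...) {
  dw <- unlist(lapply(object$probes, function(p) {
    v <- c(setNames(p$dw_X, paste0("dw_X.", p$probe_id)))
    if (p$nucleus_mode == "CH3_MQ")
      v <- c(v, setNames(p$dw_H, paste0("dw_H.", p$probe_id)))
    v
  }))
  c(k_ex = object$exch$k_ex, p_excited = object$exch$p_excited, dw)
}

#' Model predictions for a dispersion fit
#'
#' @param object A \code{"cpmg_fit"}.
#' @param newdata Optional data frame with columns \code{probe_id},
#'   \code{field_MHz}, \code{nu_cpmg}; defaults to the fitted points.
#' @param ... Unused.
#' @return Predicted \eqn{R_{2,eff}} in s\eqn{^{-1}}.
#' @export
predict.cpmg_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$data$points
  out <- numeric(nrow(newdata))
  for (pid in unique(newdata$probe_id)) {
    pr <- object$probes[[pid]]
    if (is.null(pr)) .stopf("probe '%s' not in the fit", pid)
    trel <- object$data$t_relax[[pr$nucleus_mode]]
    idx <- which(newdata$probe_id == pid)
    for (i in idx)
      out[i] <- cpmg_r2eff(object$exch, pr, newdata$field_MHz[i],
                           newdata$nu_cpmg[i], trel)
  }
  out
}

#' @export
fitted.cpmg_fit <- function(object, ...) predict(object)

#' Residuals of a dispersion fit
#' @param object A \code{"cpmg_fit"}.
#' @param type \code{"pearson"} (default; residual over sigma) or
#'   \code{"response"}.
#' @param ... Unused.
#' @return Numeric vector aligned with the dataset's points.
#' @export
residuals.cpmg_fit <- function(object, type = c("pearson", "response"), ...) {
  type <- match.arg(type)
  r <- object$data$points$r2eff - fitted(object)
  if (type == "pearson") r <- r / object$data$points$sigma
  r
}

#' Plot fitted dispersion curves
#'
#' Observed \eqn{R_{2,eff}} points with the fitted model curve, one panel
#' per probe, one trace per field.
#'
#' @param x A \code{"cpmg_fit"}.
#' @param probes Probe ids to display (default: up to first 4).
#' @param ... Passed to [graphics::matplot()].
#' @return \code{x}, invisibly.
#' @export
plot.cpmg_fit <- function(x, probes = head(names(x$probes), 4), ...) {
  old <- par(mfrow = c(ceiling(length(probes) / 2), min(2, length(probes))),
             mar = c(4, 4, 2, 1))
  on.exit(par(old))
  pts <- x$data$points
  for (pid in probes) {
    pr <- x$probes[[pid]]
    sub <- pts[pts$probe_id == pid, ]
    trel <- x$data$t_relax[[pr$nucleus_mode]]
    fields <- sort(unique(sub$field_MHz))
    nu_grid <- seq(2, 120, by = 2) / (2 * trel)
    plot(sub$nu_cpmg, sub$r2eff, pch = 19, col = match(sub$field_MHz, fields),
         xlab = expression(nu[cpmg] ~ "(Hz)"),
         ylab = expression(R["2,eff"] ~ (s^-1)), main = pid, ...)
    for (f in fields)
      lines(nu_grid, cpmg_r2eff(x$exch, pr, f, nu_grid, trel),
            col = match(f, fields))
    legend("topright", legend = paste(fields, "MHz"), lty = 1, bty = "n",
           col = seq_along(fields), cex = 0.8)
  }
  invisible(x)
}

#' Simulate datasets from a fitted dispersion model
#'
#' Draws new synthetic datasets at the fitted parameters, using the
#' multiplicative-noise generator of the synthetic-data module with the
#' dataset's own frequency schedules and fields.
#'
#' @param object A \code{"cpmg_fit"}.
#' @param nsim Number of datasets.
#' @param seed RNG seed.
#' @param noise_fraction Gaussian noise level as a fraction of
#'   \eqn{R_{2,eff}}; default 0.02.
#' @param ... Unused.
#' @return A list of [dispersion_dataset()] objects (length \code{nsim}).
#' @export
simulate.cpmg_fit <- function(object, nsim = 1, seed = 1,
                              noise_fraction = 0.02, ...) {
  truth <- synthetic_truth(
    exch = object$exch, probes = object$probes,
    fields_MHz = sort(unique(object$data$points$field_MHz)),
    noise_fraction = noise_fraction, seed = seed)
  modes <- unique(object$data$points$nucleus_mode)
  scheds <- lapply(modes, function(m) {
    nu <- sort(unique(object$data$points$nu_cpmg[object$data$points$nucleus_mode == m]))
    cpmg_schedule(m, t_relax = object$data$t_relax[[m]], nu_list = nu)
  })
  .with_seed(seed, lapply(seq_len(nsim), function(i) {
    truth$seed <- sample.int(.Machine$integer.max, 1)
    gen_dispersion_dataset(truth, if (length(scheds) == 1L) scheds[[1]] else scheds)
  }))
}
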