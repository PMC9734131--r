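# Fitting engine: variable-projection style decomposition.  The global
# parameters (k_ex, p_excited) are optimized in an outer loop; for fixed
# globals each probe's shift differences are optimized independently
# (L-BFGS-B) and the per-field exchange-free baselines R2,0 have a
# closed-form weighted least-squares solution because the exchange
# contribution is additive for site-independent relaxation.

.default_control <- function(control = list()) {
  def <- list(outer_maxit = 2000, outer_reltol = 1e-8,
              inner_factr = 1e7, inner_maxit = 200,
              dw_upper = c(10, 3),
              dw_starts = list(c(0.3, 0.03), c(1, 0.1), c(2.5, 0.3)))
  def[names(control)] <- control
  def
}

#' Default grid axes for the exchange-parameter grid search
#'
#' @param n Number of nodes.
#' @return Numeric axis: \code{default_kex_axis()} is log-spaced over
#'   100--10000 s\eqn{^{-1}}; \code{default_p_axis()} is linear over
#'   0.005--0.20.
#' @export
default_kex_axis <- function(n = 25) exp(seq(log(100), log(10000), length.out = n))

#' @rdname default_kex_axis
#' @export
default_p_axis <- function(n = 20) seq(0.005, 0.20, length.out = n)

# per-probe precomputation; probes and points are put in a canonical
# order so that fit results are exactly invariant to input ordering
.prep_data <- function(data) {
  stopifnot(inherits(data, "dispersion_dataset"))
  pts <- data$points
  ids <- sort(unique(pts$probe_id))
  probes <- lapply(ids, function(pid) {
    sub <- pts[pts$probe_id == pid, , drop = FALSE]
    sub <- sub[order(sub$field_MHz, sub$nu_cpmg), , drop = FALSE]
    mode <- sub$nucleus_mode[1]
    trel <- data$t_relax[[mode]]
    rs <- if (pid %in% names(data$relative_sign)) data$relative_sign[[pid]] else 1
    by_field <- lapply(split(sub, sub$field_MHz), function(fs) {
      list(field = fs$field_MHz[1],
           n = pulses_for_nu(fs$nu_cpmg, trel),
           nu = fs$nu_cpmg, y = fs$r2eff, w = 1 / fs$sigma^2)
    })
    fields <- vapply(by_field, `[[`, numeric(1), "field")
    list(id = pid, mode = mode, t_relax = trel, relative_sign = rs,
         by_field = by_field, npar_dw = if (mode == "CH3_MQ") 2L else 1L,
         # flattened arrays for the compiled chi-square objective
         fac_x = 2 * pi * fields * .GAMMA_REL[[mode]],
         fac_h = 2 * pi * fields,
         field_idx = rep(seq_along(by_field) - 1L,
                         vapply(by_field, function(f) length(f$n), integer(1))),
         n_all = unlist(lapply(by_field, `[[`, "n"), use.names = FALSE),
         y_all = unlist(lapply(by_field, `[[`, "y"), use.names = FALSE),
         w_all = unlist(lapply(by_field, `[[`, "w"), use.names = FALSE))
  })
  names(probes) <- ids
  list(probes = probes, n_points = nrow(pts))
}

# chi2 for one probe at fixed globals and dw, with analytic baselines
.probe_chi2_dw <- function(pr, kex, p, dw) {
  dw_x <- dw[1]
  dw_h <- if (pr$npar_dw == 2L) dw[2] else 0
  chi2 <- 0
  r2base <- numeric(length(pr$by_field))
  names(r2base) <- names(pr$by_field)
  for (k in seq_along(pr$by_field)) {
    f <- pr$by_field[[k]]
    rex <- .rex_model(pr$mode, p, kex, dw_x, dw_h, pr$relative_sign,
                      f$field, f$n, pr$t_relax)
    resid0 <- f$y - rex
    base <- sum(f$w * resid0) / sum(f$w)
    if (base < 0) base <- 0
    r2base[k] <- base
    chi2 <- chi2 + sum(f$w * (resid0 - base)^2)
  }
  list(chi2 = chi2, r2base = r2base)
}

# optimize dw for one probe at fixed globals
.fit_probe <- function(pr, kex, p, start = NULL, ctrl = .default_control()) {
  np <- pr$npar_dw
  upper <- ctrl$dw_upper[seq_len(np)]
  mq <- pr$npar_dw == 2L
  obj <- function(par)
    .probe_chi2_core(mq, p, kex, par[1], if (mq) par[2] else 0,
                     pr$relative_sign, pr$fac_x, pr$fac_h, pr$field_idx,
                     pr$n_all, pr$y_all, pr$w_all, pr$t_relax)
  starts <- list()
  if (!is.null(start)) starts <- list(pmin(pmax(start[seq_len(np)], 0), upper))
  if (is.null(start))
    starts <- lapply(ctrl$dw_starts, function(s) s[seq_len(np)])
  best <- NULL
  for (s in starts) {
    o <- tryCatch(
      optim(s, obj, method = "L-BFGS-B", lower = rep(0, np), upper = upper,
            control = list(factr = ctrl$inner_factr, maxit = ctrl$inner_maxit)),
      error = function(e) NULL)
    if (is.null(o)) next
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best)) stop("probe optimization failed for '", pr$id, "'")
  res <- .probe_chi2_dw(pr, kex, p, best$par)
  list(dw = best$par, chi2 = res$chi2, r2base = res$r2base)
}

# total chi2 at fixed globals; dw warm starts kept in `state` (an env
# with element `dw`, a named list).  With update = FALSE the warm
# starts are only filled in when missing, keeping the objective a
# deterministic function of (k_ex, p) for the outer optimizer.
.total_chi2 <- function(prep, kex, p, state, ctrl, update = TRUE) {
  tot <- 0
  for (pr in prep$probes) {
    res <- .fit_probe(pr, kex, p, start = state$dw[[pr$id]], ctrl = ctrl)
    if (update || is.null(state$dw[[pr$id]])) state$dw[[pr$id]] <- res$dw
    tot <- tot + res$chi2
  }
  tot
}

#' Exchange-parameter grid search
#'
#' Minimizes the global \eqn{\chi^2} over a fixed grid of
#' \eqn{(k_{ex}, p_{excited})} nodes.  At every node the globals are held
#' fixed while each probe's shift differences and per-field baselines are
#' freely optimized; the surface minimum serves as the starting point of
#' the global fit.  Degenerate surfaces are flagged: \code{"flat"} when
#' the surface shows no structure beyond noise (unidentifiable, e.g. no
#' shift differences) and \code{"ridge"} when the near-minimum region
#' spans most of the population axis (fast-exchange degeneracy, where
#' only the product \eqn{p\,\Delta\omega^2} is determined).
#'
#' @param data A [dispersion_dataset()], typically already passed through
#'   [filter_curves()].
#' @param kex_axis,p_axis Strictly increasing grid axes.
#' @param control Engine options, see [fit_dispersion()].
#' @return An object of class \code{"cpmg_grid"}: axes, \eqn{\chi^2}
#'   surface (rows = \code{kex_axis}, columns = \code{p_axis}), the
#'   arg-min node and flags.
#' @export
grid_search <- function(data, kex_axis = default_kex_axis(),
                        p_axis = default_p_axis(), control = list()) {
  ctrl <- .default_control(control)
  if (is.unsorted(kex_axis, strictly = TRUE) || is.unsorted(p_axis, strictly = TRUE))
    .stopf("grid axes must be strictly increasing")
  prep <- .prep_data(data)
  if (!length(prep$probes)) .stopf("dataset has no curves")
  nk <- length(kex_axis); np <- length(p_axis)
  chi2 <- matrix(0, nk, np)
  per_probe <- vector("list", length(prep$probes))
  names(per_probe) <- names(prep$probes)
  for (pid in names(prep$probes)) {
    pr <- prep$probes[[pid]]
    # multistarted fit at the first node seeds the warm-started sweep
    st <- .fit_probe(pr, kex_axis[1], p_axis[1], start = NULL, ctrl = ctrl)
    res <- .grid_probe_core(pr$npar_dw == 2L, pr$relative_sign,
                            pr$fac_x, pr$fac_h, pr$field_idx, pr$n_all,
                            pr$y_all, pr$w_all, pr$t_relax,
                            kex_axis, p_axis, st$dw[1],
                            if (pr$npar_dw == 2L) st$dw[2] else 0,
                            ctrl$dw_upper[1], ctrl$dw_upper[2], 150L)
    chi2 <- chi2 + res$chi2
    per_probe[[pid]] <- res
  }
  bi <- which(chi2 == min(chi2), arr.ind = TRUE)[1, ]
  best <- list(chi2 = min(chi2), i = bi[[1]], j = bi[[2]])
  best$dw <- lapply(names(per_probe), function(pid) {
    r <- per_probe[[pid]]
    if (prep$probes[[pid]]$npar_dw == 2L)
      c(r$dwx[best$i, best$j], r$dwh[best$i, best$j])
    else r$dwx[best$i, best$j]
  })
  names(best$dw) <- names(per_probe)
  flags <- character()
  rng <- range(chi2, na.rm = TRUE)
  # a surface is "flat" when its total relief does not exceed what
  # re-fitting the free per-node shift parameters to noise can produce
  n_dw <- sum(vapply(prep$probes, `[[`, integer(1), "npar_dw"))
  if (diff(rng) <= max(1e-8, 0.02 * rng[1], stats::qchisq(0.99, n_dw))) {
    flags <- c(flags, "flat")
  } else {
    near <- which(chi2 <= best$chi2 + 9.21, arr.ind = TRUE)  # ~99% qchisq, 2 df
    if (nrow(near) && diff(range(near[, 2])) >= (np - 1) / 2)
      flags <- c(flags, "ridge")
  }
  structure(list(kex_axis = kex_axis, p_axis = p_axis, chi2_surface = chi2,
                 argmin = c(k_ex = kex_axis[best$i], p_excited = p_axis[best$j]),
                 argmin_index = c(best$i, best$j), chi2_min = best$chi2,
                 dw_argmin = best$dw, flags = flags,
                 n_points = prep$n_points),
            class = "cpmg_grid")
}

#' @export
print.cpmg_grid <- function(x, ...) {
  cat(sprintf("CPMG grid search (%d x %d nodes): argmin k_ex = %.4g s^-1, p_excited = %.4g, chi2 = %.4g\n",
              length(x$kex_axis), length(x$p_axis),
              x$argmin[["k_ex"]], x$argmin[["p_excited"]], x$chi2_min))
  if (length(x$flags))
    cat("identifiability flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.cpmg_grid <- function(x, ...) {
  image(log10(x$kex_axis), x$p_axis, log10(x$chi2_surface),
        xlab = "log10 k_ex (s^-1)", ylab = "p_excited",
        main = "log10 chi-square surface", ...)
  points(log10(x$argmin[["k_ex"]]), x$argmin[["p_excited"]], pch = 3, lwd = 2)
  invisible(x)
}

# core engine: optimize globals from an initial value with optional
# per-probe warm starts; returns raw parameter lists
.fit_engine <- function(data, init, warm_dw = NULL, control = list()) {
  ctrl <- .default_control(control)
  prep <- .prep_data(data)
  state <- new.env(parent = emptyenv())
  state$dw <- if (is.null(warm_dw)) list() else warm_dw
  tracker <- new.env(parent = emptyenv())
  tracker$best <- list(chi2 = Inf)
  p0 <- min(max(init[["p_excited"]], 1e-6), 0.5 - 1e-9)
  par0 <- c(log(init[["k_ex"]]), qlogis(2 * p0 - 1e-12))
  obj <- function(par) {
    kex <- exp(par[1]); p <- plogis(par[2]) / 2
    val <- .total_chi2(prep, kex, p, state, ctrl, update = FALSE)
    if (val < tracker$best$chi2)
      tracker$best <- list(chi2 = val, k_ex = kex, p_excited = p)
    val
  }
  opt <- optim(par0, obj, method = "Nelder-Mead",
               control = list(maxit = ctrl$outer_maxit,
                              reltol = ctrl$outer_reltol))
  b <- tracker$best
  # final tight per-probe polish at the best globals
  fits <- lapply(prep$probes, function(pr)
    .fit_probe(pr, b$k_ex, b$p_excited, start = state$dw[[pr$id]], ctrl = ctrl))
  chi2 <- sum(vapply(fits, `[[`, numeric(1), "chi2"))
  chi2_final <- min(chi2, b$chi2)
  # a chi2 at the numerical floor cannot satisfy a relative-change
  # stopping rule but is as converged as it gets
  list(k_ex = b$k_ex, p_excited = b$p_excited, chi2 = chi2_final,
       probe_fits = fits, prep = prep,
       converged = opt$convergence == 0 ||
         chi2_final <= 1e-8 * max(1, prep$n_points))
}

.fit_n_params <- function(prep) {
  2L + sum(vapply(prep$probes, function(pr)
    pr$npar_dw + length(pr$by_field), integer(1)))
}

#' Global two-state fit of CPMG dispersion data
#'
#' Fits the two-site exchange model to all curves of a dataset at once:
#' \eqn{k_{ex}} and \eqn{p_{excited}} are shared across probes while each
#' probe keeps its own shift differences (\eqn{|\Delta\omega_X|}, and
#' \eqn{|\Delta\omega_H|} for multiple-quantum probes) and per-field
#' exchange-free baseline.  Unless a starting point is supplied, a grid
#' search over \eqn{(k_{ex}, p_{excited})} locates the initialization;
#' the refined \eqn{\chi^2} never exceeds the best grid node's.
#'
#' @param data A [dispersion_dataset()].
#' @param init Optional starting point, a vector with elements
#'   \code{k_ex} and \code{p_excited}; when missing, [grid_search()] is
#'   run first.
#' @param filter_rex If non-\code{NULL}, [filter_curves()] is applied
#'   with this threshold before fitting.
#' @param kex_axis,p_axis Grid axes forwarded to [grid_search()].
#' @param control List of engine options: \code{outer_maxit},
#'   \code{outer_reltol} (Nelder-Mead on the globals), \code{inner_factr},
#'   \code{inner_maxit} (L-BFGS-B on the per-probe shifts),
#'   \code{dw_upper}, \code{dw_starts}.
#' @return An object of class \code{"cpmg_fit"} with components
#'   \code{exch} ([exchange_params()]), \code{probes} (list of fitted
#'   [probe_params()]), \code{chi2}, \code{reduced_chi2}, \code{n_points},
#'   \code{n_params}, \code{grid}, \code{converged}, and (after
#'   [monte_carlo_errors()]) \code{uncertainties}.
#' @seealso [monte_carlo_errors()], [jackknife_probes()],
#'   [predict.cpmg_fit()], [simulate.cpmg_fit()]
#' @export
fit_dispersion <- function(data, init = NULL, filter_rex = NULL,
                           kex_axis = default_kex_axis(),
                           p_axis = default_p_axis(), control = list()) {
  stopifnot(inherits(data, "dispersion_dataset"))
  if (!is.null(filter_rex)) data <- filter_curves(data, filter_rex)
  if (!length(curve_ids(data))) .stopf("no curves to fit")
  grid <- NULL
  warm <- NULL
  if (is.null(init)) {
    grid <- grid_search(data, kex_axis, p_axis, control)
    init <- grid$argmin
    warm <- grid$dw_argmin
  }
  eng <- .fit_engine(data, init, warm_dw = warm, control = control)
  if (!eng$converged)
    warning("global fit did not converge within the iteration budget")
  .as_cpmg_fit(eng, data, grid = grid, init = init, call = match.call())
}

.as_cpmg_fit <- function(eng, data, grid = NULL, init = NULL, call = NULL) {
  probes <- lapply(names(eng$probe_fits), function(pid) {
    pr <- eng$prep$probes[[pid]]
    f <- eng$probe_fits[[pid]]
    fields <- vapply(pr$by_field, `[[`, numeric(1), "field")
    probe_params(pid, pr$mode, dw_X = f$dw[1],
                 dw_H = if (pr$npar_dw == 2L) f$dw[2] else 0,
                 relative_sign = pr$relative_sign,
                 r2_base = setNames(as.numeric(f$r2base), format(fields)))
  })
  names(probes) <- names(eng$probe_fits)
  n_params <- .fit_n_params(eng$prep)
  structure(list(
    exch = exchange_params(eng$p_excited, eng$k_ex, data$temperature),
    probes = probes, chi2 = eng$chi2,
    n_points = eng$prep$n_points, n_params = n_params,
    reduced_chi2 = eng$chi2 / max(1, eng$prep$n_points - n_params),
    uncertainties = NULL, mc = NULL, grid = grid, init = init,
    data = data, converged = eng$converged, call = call),
    class = "cpmg_fit")
}

#' Monte-Carlo uncertainty estimation for a global fit
#'
#' Parametric resampling: each \eqn{R_{2,eff}} value is redrawn from a
#' normal distribution centred on the measured value with its own
#' uncertainty, the global fit is repeated (initialized at the original
#' optimum), and per-parameter standard deviations over the repeats are
#' reported.  Deterministic for a fixed seed.
#'
#' @param fit A [fit_dispersion()] result.
#' @param n_repeats Number of repeats (40 by default).
#' @param seed RNG seed (required for reproducibility).
#' @param data Dataset to resample; defaults to the fit's own data.
#' @param control Engine options, see [fit_dispersion()].
#' @return The fit with \code{uncertainties} (named vector: \code{k_ex},
#'   \code{p_excited}, \code{dw_X.<probe>}, \code{dw_H.<probe>}) and
#'   \code{mc} (draws, dropped-repeat count, seed) filled in.
#' @export
monte_carlo_errors <- function(fit, n_repeats = 40, seed = 1,
                               data = fit$data, control = list()) {
  stopifnot(inherits(fit, "cpmg_fit"))
  if (!fit$converged) warning("Monte-Carlo on an unconverged fit")
  warm <- lapply(fit$probes, function(p)
    if (p$nucleus_mode == "CH3_MQ") c(p$dw_X, p$dw_H) else p$dw_X)
  init <- c(k_ex = fit$exch$k_ex, p_excited = fit$exch$p_excited)
  draws <- .with_seed(seed, {
    lapply(seq_len(n_repeats), function(r) {
      d2 <- data
      d2$points$r2eff <- rnorm(nrow(d2$points), d2$points$r2eff, d2$points$sigma)
      tryCatch({
        eng <- .fit_engine(d2, init, warm_dw = warm, control = control)
        if (!eng$converged) return(NULL)
        dw <- unlist(lapply(names(eng$probe_fits), function(pid) {
          f <- eng$probe_fits[[pid]]
          if (length(f$dw) == 2L)
            setNames(f$dw, paste0(c("dw_X.", "dw_H."), pid))
          else setNames(f$dw, paste0("dw_X.", pid))
        }))
        c(k_ex = eng$k_ex, p_excited = eng$p_excited, dw)
      }, error = function(e) NULL)
    })
  })
  ok <- !vapply(draws, is.null, logical(1))
  n_dropped <- sum(!ok)
  if (n_dropped > 0.25 * n_repeats)
    warning(sprintf("%d of %d Monte-Carlo repeats failed to converge", n_dropped, n_repeats))
  if (!any(ok)) .stopf("all Monte-Carlo repeats failed")
  mat <- do.call(rbind, draws[ok])
  fit$uncertainties <- apply(mat, 2, sd)
  fit$mc <- list(draws = as.data.frame(mat), n_repeats = n_repeats,
                 n_dropped = n_dropped, seed = seed)
  fit
}

#' Jackknife consistency check across probes
#'
#' Leave-one-probe-out refits, testing whether every probe reports the
#' same exchange process.  A probe is flagged when its removal shifts
#' \eqn{k_{ex}} by more than \code{threshold} (3 Monte-Carlo standard
#' deviations when available, else 3 jackknife standard errors).
#'
#' @inheritParams monte_carlo_errors
#' @param threshold Absolute flag threshold on \eqn{k_{ex}} shifts, in
#'   s\eqn{^{-1}}; computed from the fit when \code{NULL}.
#' @return An object of class \code{"cpmg_jackknife"}: data frame of
#'   per-left-out-probe globals plus the threshold used.
#' @export
jackknife_probes <- function(fit, data = fit$data, threshold = NULL,
                             control = list()) {
  stopifnot(inherits(fit, "cpmg_fit"))
  ids <- curve_ids(data)
  if (length(ids) < 3L) .stopf("jackknife needs at least 3 curves (got %d)", length(ids))
  warm <- lapply(fit$probes, function(p)
    if (p$nucleus_mode == "CH3_MQ") c(p$dw_X, p$dw_H) else p$dw_X)
  init <- c(k_ex = fit$exch$k_ex, p_excited = fit$exch$p_excited)
  rows <- lapply(ids, function(pid) {
    keep <- setdiff(ids, pid)
    d2 <- data
    d2$points <- data$points[data$points$probe_id %in% keep, , drop = FALSE]
    eng <- .fit_engine(d2, init, warm_dw = warm[keep], control = control)
    data.frame(left_out = pid, k_ex = eng$k_ex, p_excited = eng$p_excited,
               converged = eng$converged)
  })
  tab <- do.call(rbind, rows)
  tab$delta_kex <- tab$k_ex - fit$exch$k_ex
  if (is.null(threshold)) {
    if (!is.null(fit$uncertainties)) {
      threshold <- 3 * fit$uncertainties[["k_ex"]]
    } else {
      n <- nrow(tab)
      se <- sqrt((n - 1) / n * sum((tab$k_ex - mean(tab$k_ex))^2))
      threshold <- 3 * se
    }
  }
  tab$flagged <- abs(tab$delta_kex) > threshold
  structure(list(table = tab, threshold = threshold,
                 k_ex = fit$exch$k_ex), class = "cpmg_jackknife")
}

#' @export
print.cpmg_jackknife <- function(x, ...) {
  cat(sprintf("Jackknife over %d probes (k_ex = %.4g s^-1, flag threshold %.3g s^-1)\n",
              nrow(x$table), x$k_ex, x$threshold))
  flagged <- x$table$left_out[x$table$flagged]
  if (length(flagged))
    cat("inconsistent probes:", paste(flagged, collapse = ", "), "\n")
  else cat("all probes consistent with a single exchange process\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}
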