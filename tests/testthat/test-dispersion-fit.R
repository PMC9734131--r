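make_two_point_curve <- function(pid, drop, base = 20) {
  data.frame(probe_id = pid, nucleus_mode = "CH3_MQ", field_MHz = 850,
             nu_cpmg = c(4, 120) / 0.06, r2eff = c(base + drop, base),
             sigma = 0.5)
}

test_that("the error floor raises small uncertainties to 2% of the rate", {
  expect_equal(apply_error_floor(50, 0.5), 1.0)
  expect_equal(apply_error_floor(50, 2.0), 2.0)
  expect_equal(apply_error_floor(0, 0.3), 0.3)
  expect_equal(apply_error_floor(c(50, 100), c(0.5, 3)), c(1, 3))
  expect_error(apply_error_floor(-1, 0.5), "non-negative")
  expect_error(apply_error_floor(1, -0.5), "non-negative")
})

test_that("the Rex estimate is the low-minus-high frequency difference, max over fields", {
  flat <- data.frame(field_MHz = 850, nu_cpmg = c(66.7, 500, 2000),
                     r2eff = c(20, 20, 20))
  expect_equal(rex_estimate(flat), 0)
  two <- data.frame(field_MHz = 850, nu_cpmg = c(66.7, 2000), r2eff = c(25, 20))
  expect_equal(rex_estimate(two), 5)
  expect_error(rex_estimate(two[1, ]), "2 points")
  # forward-model oracle: simulated curve's Rex equals the model difference
  ex <- exchange_params(0.032, 2490)
  pr <- probe_params("x", "CH3_MQ", dw_X = 1.4, dw_H = 0.1,
                     r2_base = c("700" = 10, "850" = 12))
  nu <- c(4, 12, 40, 120) / 0.06
  curve <- do.call(rbind, lapply(c(700, 850), function(f)
    data.frame(field_MHz = f, nu_cpmg = nu,
               r2eff = cpmg_r2eff(ex, pr, f, nu, 0.030))))
  expected <- max(vapply(c(700, 850), function(f) {
    y <- cpmg_r2eff(ex, pr, f, c(min(nu), max(nu)), 0.030)
    y[1] - y[2]
  }, numeric(1)))
  expect_equal(rex_estimate(curve), expected)
})

test_that("curve filtering keeps Rex >= threshold inclusively and warns when empty", {
  pts <- rbind(make_two_point_curve("a", 0.5), make_two_point_curve("b", 2.0),
               make_two_point_curve("c", 8.0))
  ds <- dispersion_dataset(pts)
  kept <- filter_curves(ds, 2)
  expect_setequal(curve_ids(kept), c("b", "c"))
  expect_identical(attr(kept, "excluded"), "a")
  flat <- dispersion_dataset(rbind(make_two_point_curve("a", 0),
                                   make_two_point_curve("b", 0)))
  expect_warning(out <- filter_curves(flat, 2), "no curve")
  expect_equal(nrow(out$points), 0)
  # the 21-probe synthetic reference set passes entirely by construction
  ds21 <- gen_dispersion_dataset(synthetic_truth(seed = 5))
  expect_length(curve_ids(filter_curves(ds21, 2)), 21)
})

test_that("grid search recovers a generating node exactly on noise-free data", {
  kex_axis <- c(1000, 1600, 2490, 3800, 6000)
  p_axis <- c(0.01, 0.02, 0.032, 0.05, 0.08)
  ds <- gen_dispersion_dataset(small_truth(n_probes = 1, noise = 0),
                               small_schedule())
  g <- grid_search(ds, kex_axis, p_axis)
  expect_equal(unname(g$argmin), c(2490, 0.032))
  expect_lt(g$chi2_min, 1e-6)
  expect_equal(g$chi2_surface[3, 3], g$chi2_min)
  expect_error(grid_search(ds, rev(kex_axis), p_axis), "increasing")
})

test_that("grid search localizes noisy data and flags degenerate surfaces", {
  ds <- gen_dispersion_dataset(small_truth(n_probes = 3, fields = c(700, 850),
                                           noise = 0.02, seed = 11))
  g <- grid_search(ds)
  kex_step <- g$kex_axis[2] / g$kex_axis[1]
  expect_lt(abs(log(g$argmin[["k_ex"]] / 2490)), log(kex_step) * 1.5)
  expect_lt(abs(g$argmin[["p_excited"]] - 0.032), diff(g$p_axis[1:2]) * 1.5)
  expect_length(g$flags, 0)
  # no shift differences anywhere: flat, unidentifiable surface
  pr0 <- lapply(1:2, function(i)
    probe_params(paste0("z", i), "CH3_MQ", dw_X = 0, dw_H = 0,
                 r2_base = c("850" = 15)))
  ds0 <- gen_dispersion_dataset(synthetic_truth(probes = pr0, fields_MHz = 850,
                                                noise_fraction = 0.02, seed = 2),
                                small_schedule())
  g0 <- grid_search(ds0, default_kex_axis(8), default_p_axis(8))
  expect_true("flat" %in% g0$flags)
  # fast-exchange-only data: p and dw are degenerate along a ridge
  dw_fast <- 0.15
  k_fast <- 60 * abs(ppm_to_rad(dw_fast, 850, "C13"))
  prf <- lapply(1:3, function(i)
    probe_params(paste0("f", i), "CH3_MQ", dw_X = dw_fast * i, dw_H = 0.01,
                 r2_base = c("850" = 15)))
  dsf <- gen_dispersion_dataset(synthetic_truth(exchange_params(0.05, k_fast),
                                                probes = prf, fields_MHz = 850,
                                                noise_fraction = 0.02, seed = 3),
                                small_schedule())
  gf <- grid_search(dsf, default_kex_axis(10), default_p_axis(10))
  expect_gt(length(gf$flags), 0)
})

test_that("the global fit recovers noise-free parameters to 4 significant digits", {
  truth <- small_truth(n_probes = 5, fields = c(700, 850), noise = 0)
  ds <- gen_dispersion_dataset(truth, small_schedule())
  fit <- fit_dispersion(ds, init = c(k_ex = 2000, p_excited = 0.05))
  expect_equal(fit$exch$k_ex, 2490, tolerance = 1e-4)
  expect_equal(fit$exch$p_excited, 0.032, tolerance = 1e-4)
  dw_true <- setNames(vapply(truth$probes, `[[`, numeric(1), "dw_X"),
                      vapply(truth$probes, `[[`, character(1), "probe_id"))
  dw_fit <- vapply(fit$probes, `[[`, numeric(1), "dw_X")[names(dw_true)]
  expect_equal(unname(dw_fit), unname(dw_true), tolerance = 1e-3)
})

test_that("the global fit never degrades the best grid node and ignores data order", {
  ds <- gen_dispersion_dataset(small_truth(n_probes = 3, seed = 21),
                               small_schedule())
  fit <- fit_dispersion(ds, kex_axis = default_kex_axis(8),
                        p_axis = default_p_axis(8))
  expect_lte(fit$chi2, fit$grid$chi2_min + 1e-9)
  expect_gt(fit$n_points, fit$n_params)
  # permuting rows leaves the optimum unchanged (same initialization)
  perm <- sample(nrow(ds$points))
  ds2 <- ds
  ds2$points <- ds$points[perm, ]
  init <- c(k_ex = fit$exch$k_ex, p_excited = fit$exch$p_excited)
  fit2 <- fit_dispersion(ds2, init = init)
  fit2b <- fit_dispersion(ds, init = init)
  expect_equal(fit2$exch$k_ex, fit2b$exch$k_ex)
  expect_equal(fit2$exch$p_excited, fit2b$exch$p_excited)
  # duplicating a curve under a new name must not move the exchange
  # parameters (checked on noise-free data, where the shared optimum is
  # exact and reweighting one probe cannot shift it)
  ds0 <- gen_dispersion_dataset(small_truth(n_probes = 3, noise = 0),
                                small_schedule())
  fit0 <- fit_dispersion(ds0, init = c(k_ex = 2200, p_excited = 0.05))
  dup <- ds0$points[ds0$points$probe_id == curve_ids(ds0)[1], ]
  dup$probe_id <- "dup"
  ds3 <- dispersion_dataset(rbind(ds0$points, dup))
  fit3 <- fit_dispersion(ds3, init = c(k_ex = 2200, p_excited = 0.05))
  expect_equal(fit3$exch$k_ex, fit0$exch$k_ex, tolerance = 1e-4)
  expect_equal(fit3$exch$p_excited, fit0$exch$p_excited, tolerance = 1e-4)
})

test_that("fit methods expose coefficients, predictions and residuals coherently", {
  ds <- gen_dispersion_dataset(small_truth(n_probes = 2, noise = 0),
                               small_schedule())
  fit <- fit_dispersion(ds, init = c(k_ex = 2490, p_excited = 0.032))
  co <- coef(fit)
  expect_named(co[1:2], c("k_ex", "p_excited"))
  expect_equal(unname(fitted(fit)), ds$points$r2eff, tolerance = 1e-4)
  expect_lt(max(abs(residuals(fit))), 1e-2)
  expect_equal(predict(fit, ds$points[3, ]), fitted(fit)[3])
  s <- summary(fit)
  expect_s3_class(s, "summary.cpmg_fit")
  expect_equal(nrow(s$probe_table), 2)
})

test_that("Monte-Carlo errors are seed-deterministic and shrink with the noise", {
  ds <- gen_dispersion_dataset(small_truth(n_probes = 3, seed = 31),
                               small_schedule())
  fit <- fit_dispersion(ds, init = c(k_ex = 2490, p_excited = 0.032))
  m1 <- monte_carlo_errors(fit, n_repeats = 6, seed = 99)
  m2 <- monte_carlo_errors(fit, n_repeats = 6, seed = 99)
  expect_identical(m1$uncertainties, m2$uncertainties)
  expect_gt(m1$uncertainties[["k_ex"]], 0)
  expect_named(m1$uncertainties)
  # near-zero measurement uncertainty collapses the parameter spread
  ds0 <- ds
  ds0$points$sigma <- 1e-7
  fit0 <- fit_dispersion(ds0, init = c(k_ex = 2490, p_excited = 0.032))
  m0 <- monte_carlo_errors(fit0, n_repeats = 4, seed = 1)
  expect_lt(m0$uncertainties[["k_ex"]] / fit0$exch$k_ex, 1e-4)
  expect_lt(m0$uncertainties[["p_excited"]], 1e-5)
})

test_that("Monte-Carlo spread agrees with across-seed regeneration within a factor 2", {
  truth <- small_truth(n_probes = 5, fields = 850, noise = 0.02)
  seeds <- 1:8
  kexs <- vapply(seeds, function(s) {
    ds <- gen_dispersion_dataset(small_truth(n_probes = 5, fields = 850,
                                             noise = 0.02, seed = s),
                                 small_schedule())
    fit_dispersion(ds, init = c(k_ex = 2490, p_excited = 0.032))$exch$k_ex
  }, numeric(1))
  ds <- gen_dispersion_dataset(truth, small_schedule())
  fit <- fit_dispersion(ds, init = c(k_ex = 2490, p_excited = 0.032))
  mc <- monte_carlo_errors(fit, n_repeats = 8, seed = 5)
  ratio <- mc$uncertainties[["k_ex"]] / sd(kexs)
  expect_gt(ratio, 0.5)
  expect_lt(ratio, 2)
})

test_that("jackknife flags probes that disagree with the shared exchange process", {
  truth <- small_truth(n_probes = 4, fields = c(700, 850), noise = 0.01,
                       seed = 41)
  ds <- gen_dispersion_dataset(truth, small_schedule())
  fit <- fit_dispersion(ds, init = c(k_ex = 2490, p_excited = 0.032))
  fit <- monte_carlo_errors(fit, n_repeats = 6, seed = 7)
  jk <- jackknife_probes(fit)
  expect_false(any(jk$table$flagged))
  # replace one probe with data generated at a 5x different exchange rate
  outlier <- synthetic_truth(exchange_params(0.032, 2490 / 5),
                             probes = wt_methyl_probes(1, c(700, 850)),
                             fields_MHz = c(700, 850), noise_fraction = 0.01,
                             seed = 42)
  od <- gen_dispersion_dataset(outlier, small_schedule())$points
  od$probe_id <- "outlier"
  ds2 <- dispersion_dataset(rbind(ds$points[ds$points$probe_id !=
                                            curve_ids(ds)[1], ], od))
  fit2 <- fit_dispersion(ds2, init = c(k_ex = 2490, p_excited = 0.032))
  fit2 <- monte_carlo_errors(fit2, n_repeats = 6, seed = 8)
  jk2 <- jackknife_probes(fit2)
  expect_true(jk2$table$flagged[jk2$table$left_out == "outlier"])
  # two curves are not enough to leave one out meaningfully
  ds_two <- dispersion_dataset(ds$points[ds$points$probe_id %in%
                                         curve_ids(ds)[1:2], ])
  fit_two <- fit_dispersion(ds_two, init = c(k_ex = 2490, p_excited = 0.032))
  expect_error(jackknife_probes(fit_two), "3 curves")
})
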