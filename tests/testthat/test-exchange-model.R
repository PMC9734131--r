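test_that("R2eff from intensities matches the log-ratio definition and inverts", {
  expect_equal(r2eff_from_intensity(1, 1, 0.030), 0)
  expect_equal(r2eff_from_intensity(0.5, 1, 0.030), log(2) / 0.030)
  expect_equal(r2eff_from_intensity(0.5, 1, 0.030), 23.105, tolerance = 1e-4)
  expect_equal(r2eff_from_intensity(0.5, 1, 0.060), 11.552, tolerance = 1e-4)
  for (r2 in c(0, 3.7, 45)) {
    i <- intensity_from_r2eff(r2, 2.5, 0.030)
    expect_equal(r2eff_from_intensity(i, 2.5, 0.030), r2, tolerance = 1e-10)
  }
  expect_error(r2eff_from_intensity(-1, 1, 0.030), "-1")
  expect_error(r2eff_from_intensity(1, 0, 0.030), "0")
  expect_error(r2eff_from_intensity(1, 1, 0), "t_relax")
})

test_that("dispersion is flat without shift difference, minor population, or exchange", {
  nu <- c(4, 8, 20, 60, 120) / 0.06
  base <- c("850" = 12)
  pr0 <- probe_params("x", "CH3_MQ", dw_X = 0, dw_H = 0, r2_base = base)
  ex <- exchange_params(0.032, 2490)
  expect_equal(cpmg_r2eff(ex, pr0, 850, nu), rep(12, 5))
  pr <- probe_params("x", "CH3_MQ", dw_X = 1.2, dw_H = 0.1, r2_base = base)
  expect_equal(cpmg_r2eff(exchange_params(0, 1000), pr, 850, nu), rep(12, 5))
  # very fast exchange quenches the dispersion to within 0.1 s^-1
  fast <- cpmg_r2eff(exchange_params(0.032, 5e6), pr, 850, nu)
  expect_true(all(abs(fast - 12) < 0.1))
})

test_that("parameter validation rejects unphysical exchange and schedules", {
  expect_error(exchange_params(0.6, 1000), "p_excited")
  expect_error(exchange_params(0.1, -5), "k_ex")
  expect_error(probe_params("x", "N15_SQ", dw_X = 1, dw_H = 0.2), "dw_H")
  expect_error(probe_params("x", "CH3_MQ", dw_X = -1), "dw_X")
  # 70 Hz in 30 ms -> 4.2 pulses; 50 Hz -> odd count
  expect_error(pulses_for_nu(70, 0.030), "commensurate")
  expect_error(pulses_for_nu(50, 0.030), "commensurate")
  expect_identical(pulses_for_nu(c(200, 400), 0.030), c(12L, 24L))
})

test_that("SQ model agrees with the Luz-Meiboom closed form in fast exchange", {
  for (dw_ppm in c(0.2, 0.5)) {
    for (field in c(600, 850)) {
      dw_rad <- ppm_to_rad(dw_ppm, field, "N15")
      k_ex <- 60 * abs(dw_rad)  # comfortably beyond the 50x threshold
      ex <- exchange_params(0.05, k_ex)
      pr <- probe_params("x", "N15_SQ", dw_X = dw_ppm,
                         r2_base = setNames(10, format(field)))
      nu <- c(4, 8, 16, 30, 60, 120) / 0.12
      rex <- cpmg_r2eff(ex, pr, field, nu, 0.060) - 10
      lm <- oracle_luz_meiboom(0.05, k_ex, dw_rad, nu)
      # within 1% of the low-frequency plateau
      expect_lt(max(abs(rex - lm)), 0.01 * lm[1])
      # low-nu excess over the baseline approaches pA*pB*dw^2/kex
      # (exactly, once the residual refocusing term at nu[1] is included)
      plateau <- 0.05 * 0.95 * dw_rad^2 / k_ex
      corr <- 1 - (4 * nu[1] / k_ex) * tanh(k_ex / (4 * nu[1]))
      expect_equal(rex[1], plateau * corr, tolerance = 0.01)
      expect_equal(rex[1], plateau, tolerance = 0.06)
    }
  }
})

test_that("fast-exchange dispersion amplitude scales with the square of the field", {
  dw_rad850 <- ppm_to_rad(0.3, 850, "N15")
  k_ex <- 60 * dw_rad850
  ex <- exchange_params(0.05, k_ex)
  pr <- probe_params("x", "N15_SQ", dw_X = 0.3,
                     r2_base = c("600" = 10, "850" = 10))
  nu <- c(4, 120) / 0.12
  rex_850 <- diff(-cpmg_r2eff(ex, pr, 850, nu, 0.060))
  rex_600 <- diff(-cpmg_r2eff(ex, pr, 600, nu, 0.060))
  expect_equal(rex_850 / rex_600, (850 / 600)^2, tolerance = 0.02)
})

test_that("SQ propagation matches the explicit conjugation-loop oracle", {
  ex <- exchange_params(0.032, 2490)
  pr <- probe_params("x", "N15_SQ", dw_X = 2, r2_base = c("850" = 10))
  ns <- c(4L, 8L, 16L, 40L, 90L, 120L)
  nu <- ns / 0.12
  model <- cpmg_r2eff(ex, pr, 850, nu, 0.060)
  dw_rad <- ppm_to_rad(2, 850, "N15")
  oracle <- 10 + vapply(ns, function(n)
    oracle_sq_rex(0.032, 2490, dw_rad, n, 0.060), numeric(1))
  expect_equal(model, oracle, tolerance = 1e-10)
})

test_that("MQ propagation matches the brute-force echo-train oracle", {
  ex <- exchange_params(0.032, 2490)
  pr <- probe_params("x", "CH3_MQ", dw_X = 1, dw_H = 0.1,
                     r2_base = c("850" = 15))
  ns <- c(4L, 8L, 16L, 40L, 90L, 120L)
  nu <- ns / 0.06
  model <- cpmg_r2eff(ex, pr, 850, nu, 0.030)
  oracle <- 15 + vapply(ns, function(n)
    oracle_mq_rex(0.032, 2490, ppm_to_rad(1, 850, "C13"),
                  ppm_to_rad(0.1, 850, "H1"), n, 0.030), numeric(1))
  expect_equal(model, oracle, tolerance = 1e-10)
  # relative sign of the proton shift changes the profile but not the
  # dwH = 0 limit
  pr_neg <- probe_params("x", "CH3_MQ", dw_X = 1, dw_H = 0.1,
                         relative_sign = -1, r2_base = c("850" = 15))
  oracle_neg <- 15 + vapply(ns, function(n)
    oracle_mq_rex(0.032, 2490, ppm_to_rad(1, 850, "C13"),
                  -ppm_to_rad(0.1, 850, "H1"), n, 0.030), numeric(1))
  expect_equal(cpmg_r2eff(ex, pr_neg, 850, nu, 0.030), oracle_neg,
               tolerance = 1e-10)
})

test_that("the MQ model collapses to the single-spin case when dw_H = 0", {
  ex <- exchange_params(0.04, 1800)
  nu <- c(4, 10, 24, 60, 120) / 0.06
  pr_mq <- probe_params("m", "CH3_MQ", dw_X = 1.3, dw_H = 0,
                        r2_base = c("850" = 14))
  # SQ probe with the 15N ppm scaled to give the identical rad/s offset
  pr_sq <- probe_params("s", "N15_SQ", dw_X = 1.3 * 0.25144 / 0.10136,
                        r2_base = c("850" = 14))
  mq <- cpmg_r2eff(ex, pr_mq, 850, nu, 0.030)
  sq <- cpmg_r2eff(ex, pr_sq, 850, nu, 0.030)
  expect_lt(max(abs(mq - sq)), 1e-6)
})

test_that("dispersion profiles flatten as the pulse rate grows", {
  ex <- exchange_params(0.032, 2490)
  pr <- probe_params("x", "CH3_MQ", dw_X = 1.5, dw_H = 0.12,
                     r2_base = c("850" = 15))
  r <- function(n) cpmg_r2eff(ex, pr, 850, n / 0.06, 0.030)
  # past the dispersion midpoint the n -> 2n differences shrink toward 0
  d <- vapply(c(32, 64, 128), function(n) abs(r(n) - r(2 * n)), numeric(1))
  expect_true(all(diff(d) < 0))
  expect_lt(d[3], 1)
})
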