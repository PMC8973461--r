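test_that("noise-free signals are recovered exactly, even from far-off starts", {
  sch <- paper_scheme()
  cfg <- sir_fit_config(kmf = 12.5)
  truth <- c(psr = 0.15, r1f = 1.0, sf = -1, m0f = 1)
  y <- sir_signal(sch, sir_params(psr = 0.15, r1f = 1.0))$signal

  fit <- fit_sir_voxel(y, sch, cfg)
  expect_true(fit$converged)
  expect_equal(unlist(fit[names(truth)]), truth, tolerance = 1e-6)

  # initial guess perturbed +/-50% from truth
  for (fac in c(0.5, 1.5)) {
    cfg2 <- sir_fit_config(kmf = 12.5,
                           init = list(psr = 0.15 * fac, r1f = fac,
                                       sf = -1 * min(fac, 1.05),
                                       m0f = fac))
    fit2 <- fit_sir_voxel(y, sch, cfg2)
    expect_equal(unlist(fit2[names(truth)]), truth, tolerance = 1e-6)
  }
})

test_that("a 3x3 noise-free grid recovers all four parameters", {
  sch <- paper_scheme()
  cfg <- sir_fit_config(kmf = 12.5)
  for (psr in c(0.05, 0.15, 0.25)) {
    for (r1f in c(0.5, 1.0, 1.5)) {
      y <- sir_signal(sch, sir_params(psr = psr, r1f = r1f))$signal
      fit <- fit_sir_voxel(y, sch, cfg)
      expect_equal(fit$psr, psr, tolerance = 1e-6)
      expect_equal(fit$r1f, r1f, tolerance = 1e-6)
      expect_equal(fit$sf, -1, tolerance = 1e-6)
      expect_equal(fit$m0f, 1, tolerance = 1e-6)
    }
  }
})

test_that("all-zero signal is skipped, flagged unconverged, maps filled with 0", {
  sch <- paper_scheme()
  fit <- fit_sir_voxel(rep(0, 4), sch, sir_fit_config(kmf = 12.5))
  expect_false(fit$converged)
  expect_equal(unlist(fit[c("psr", "r1f", "sf", "m0f")]),
               c(psr = 0, r1f = 0, sf = 0, m0f = 0))
})

test_that("model dispatch switches arity on fixed vs estimated kmf", {
  sch <- paper_scheme()
  y <- rep(0.5, 4)
  fn4 <- dispatch_sir_model(sir_fit_config(kmf = 12.5), sch, y)
  expect_identical(attr(fn4, "free"), c("psr", "r1f", "sf", "m0f"))

  sch5 <- sir_scheme(c(15, 15, 278, 600, 1007), c(648, 4171, 2730, 1000, 10))
  fn5 <- dispatch_sir_model(sir_fit_config(kmf = NULL), sch5, rep(0.5, 5))
  expect_identical(attr(fn5, "free"), c("psr", "r1f", "sf", "m0f", "kmf"))

  # 5 free parameters cannot be determined from 4 observations
  expect_error(dispatch_sir_model(sir_fit_config(kmf = NULL), sch, y),
               "under-determined")
  expect_error(dispatch_sir_model(sir_fit_config(kmf = 12.5), sch, rep(0.5, 3)),
               "match")
})

test_that("five-point scheme recovers kmf when it is estimated", {
  sch5 <- sir_scheme(c(15, 50, 278, 600, 1007), c(648, 4171, 2730, 1000, 10))
  truth <- sir_params(psr = 0.15, r1f = 1.0, kmf = 12.5)
  y <- sir_signal(sch5, truth)$signal
  fit <- fit_sir_voxel(y, sch5, sir_fit_config(kmf = NULL))
  expect_true(fit$converged)
  expect_equal(fit$kmf, 12.5, tolerance = 1e-4)
  expect_equal(fit$psr, 0.15, tolerance = 1e-5)
})

test_that("image fits are independent of mask, thread count and repetition", {
  ph <- sir_phantom(shape = c(6, 6))
  series <- add_rician_noise(simulate_sir_series(ph), snr = 250, seed = 99)
  cfg <- sir_fit_config(kmf = 12.5)
  fit_full <- fit_sir(series, cfg)

  # repetition: bit-identical
  expect_identical(fit_sir(series, cfg)$maps, fit_full$maps)

  # threads: identical maps
  fit_mt <- fit_sir(series, sir_fit_config(kmf = 12.5, threads = 2L))
  expect_identical(fit_mt$maps, fit_full$maps)

  # half mask: included half identical to full run, excluded half filled 0
  mask <- array(FALSE, c(6, 6, 1))
  mask[1:3, , ] <- TRUE
  series_m <- sir_series(series$data, series$scheme, mask = mask)
  fit_half <- fit_sir(series_m, cfg)
  expect_identical(fit_half$maps$psr[1:3, , ], fit_full$maps$psr[1:3, , ])
  expect_identical(fit_half$maps$r1f[1:3, , ], fit_full$maps$r1f[1:3, , ])
  expect_true(all(fit_half$maps$psr[4:6, , ] == 0))
  expect_true(all(!fit_half$maps$converged[4:6, , ]))
})

test_that("scheme/data length mismatch fails before any fitting", {
  ph <- sir_phantom(shape = c(4, 4))
  series <- simulate_sir_series(ph)
  series$scheme <- sir_scheme(c(15, 278, 1007), c(648, 2730, 10))
  expect_error(fit_sir(series, sir_fit_config(kmf = 12.5)), "volumes")
  expect_error(sir_series(series$data, series$scheme), "volumes")
})

test_that("bounds bracket estimates wherever the fit converged", {
  ph <- sir_phantom(shape = c(8, 8))
  series <- add_rician_noise(simulate_sir_series(ph), snr = 50, seed = 2)
  fit <- fit_sir(series, sir_fit_config(kmf = 12.5))
  conv <- fit$maps$converged
  cfg <- fit$config
  expect_true(all(fit$maps$psr[conv] >= cfg$lower$psr &
                    fit$maps$psr[conv] <= cfg$upper$psr))
  expect_true(all(fit$maps$r1f[conv] >= cfg$lower$r1f &
                    fit$maps$r1f[conv] <= cfg$upper$r1f))
  expect_true(all(fit$maps$sf[conv] >= cfg$lower$sf &
                    fit$maps$sf[conv] <= cfg$upper$sf))
})

test_that("tidy and glance summarize a fit at voxel and run level", {
  ph <- sir_phantom(shape = c(4, 4))
  series <- add_rician_noise(simulate_sir_series(ph), snr = 250, seed = 5)
  fit <- fit_sir(series, sir_fit_config(kmf = 12.5))

  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 16)
  expect_true(all(c("x", "y", "z", "psr", "r1f", "sf", "m0f",
                    "residual_norm", "iterations", "converged") %in% names(td)))

  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$n_fitted, 16)
  expect_gte(gl$convergence_rate, 0.9)
})
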