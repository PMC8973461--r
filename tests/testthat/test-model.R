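test_that("rate matrix matches direct substitution and decouples at PSR = 0", {
  A <- rate_matrix(sir_params(psr = 0.1, r1f = 1, r1m = 1, kmf = 12.5))
  expect_equal(unname(A), matrix(c(-2.25, 1.25, 12.5, -13.5), 2, 2))

  A0 <- rate_matrix(sir_params(psr = 0, r1f = 1, r1m = 1, kmf = 12.5))
  expect_equal(unname(A0), matrix(c(-1, 0, 12.5, -13.5), 2, 2))
  expect_identical(A0[2, 1], 0)  # free pool decoupled
})

test_that("rate matrix eigenvalues are real and negative across a sweep", {
  for (p in random_params(200, seed = 7)) {
    ev <- eigen(rate_matrix(p), only.values = TRUE)$values
    expect_true(all(Im(ev) == 0))
    expect_true(all(Re(ev) < 0))
  }
})

test_that("invalid parameters raise errors naming the offending field", {
  expect_error(sir_params(psr = -0.1, r1f = 1), "psr")
  expect_error(sir_params(psr = 0.1, r1f = 0), "r1f")
  expect_error(sir_params(psr = 0.1, r1f = 1, m0f = -2), "m0f")
  expect_error(sir_params(psr = 0.1, r1f = 1, kmf = -1), "kmf")
})

test_that("closed-form 2x2 exponential matches a general-purpose expm", {
  skip_if_not_installed("Matrix")
  for (p in random_params(300, seed = 11)) {
    A <- unname(rate_matrix(p))
    for (t in c(0.015, 0.278, 1.007, 4.171)) {
      E <- sirqmt:::expm2x2(A[1, 1], A[1, 2], A[2, 1], A[2, 2], t)
      Eref <- as.matrix(Matrix::expm(A * t))
      expect_lt(max(abs(matrix(c(E$e11, E$e21, E$e12, E$e22), 2, 2) - Eref)),
                1e-10)
    }
  }
})

test_that("degenerate (repeated eigenvalue) exponential uses the exact limit", {
  # kmf = 0 and r1f = r1m makes A = -r1f * I exactly
  p <- sir_params(psr = 0.2, r1f = 1.3, r1m = 1.3, kmf = 0)
  A <- unname(rate_matrix(p))
  E <- sirqmt:::expm2x2(A[1, 1], A[1, 2], A[2, 1], A[2, 2], 0.5)
  expect_equal(E$e11, exp(-1.3 * 0.5), tolerance = 1e-12)
  expect_equal(E$e12, 0)
  expect_equal(E$e22, exp(-1.3 * 0.5), tolerance = 1e-12)
})

test_that("long inversion times recover equilibrium magnetization", {
  for (p in random_params(25, seed = 3)) {
    mz <- longitudinal_magnetization(p, ti = 60 / p$r1f, td = 0.5)
    expect_lt(abs(mz[["mzf"]] - p$m0f), 1e-8 * p$m0f)
    mz_inf <- longitudinal_magnetization(p, ti = 1e6, td = 0.5)
    expect_equal(mz_inf[["mzf"]], p$m0f, tolerance = 1e-10)
    expect_equal(mz_inf[["mzm"]], p$psr * p$m0f, tolerance = 1e-10)
  }
})

test_that("td -> 0 reduces to recovery from full saturation of both pools", {
  for (p in random_params(20, seed = 5)) {
    A <- unname(rate_matrix(p))
    M0 <- c(p$m0f, p$psr * p$m0f)
    for (ti in c(0.015, 0.278, 1.007)) {
      expected <- as.vector((diag(2) - series_expm(A * ti)) %*% M0)
      mz <- longitudinal_magnetization(p, ti = ti, td = 1e-12)
      expect_equal(unname(mz), expected, tolerance = 1e-9)
    }
  }
})

test_that("PSR = 0 reduces exactly to the scalar inversion recovery form", {
  p <- sir_params(psr = 0, r1f = 1.1, sf = -1, m0f = 2, kmf = 12.5)
  sch <- paper_scheme()
  got <- sir_signal(sch, p, magnitude = FALSE)$signal
  scalar <- p$m0f * (exp(-p$r1f * sch$ti) * p$sf * (1 - exp(-p$r1f * sch$td)) +
                       1 - exp(-p$r1f * sch$ti))
  expect_lt(max(abs(got - scalar)), 1e-12)

  # td -> infinity limit is the textbook mono-exponential IR curve
  ti <- c(0.01, 0.1, 0.5, 2)
  got2 <- sir_signal(sir_scheme(ti, rep(1e3, 4), units = "s"), p,
                     magnitude = FALSE)$signal
  expect_equal(got2, p$m0f * (1 - 2 * exp(-p$r1f * ti)), tolerance = 1e-12)
})

test_that("signal matches an independent series-expansion evaluation", {
  sch <- paper_scheme()
  for (p in random_params(50, seed = 13)) {
    expect_equal(sir_signal(sch, p)$signal, oracle_signal(p, sch),
                 tolerance = 1e-10)
  }
})

test_that("magnitude flag returns |Mzf| and signed mode keeps the sign", {
  p <- sir_params(psr = 0.15, r1f = 1, sf = -1)
  sch <- paper_scheme()
  signed <- sir_signal(sch, p, magnitude = FALSE)$signal
  expect_lt(min(signed), 0)  # short-ti points are inverted
  expect_equal(sir_signal(sch, p)$signal, abs(signed))
  expect_true(all(sir_signal(sch, p)$signal >= 0))
})

test_that("signals scale exactly linearly in M0f", {
  sch <- paper_scheme()
  for (p in random_params(10, seed = 17)) {
    base <- sir_signal(sch, p, magnitude = FALSE)$signal
    p3 <- p; p3$m0f <- p$m0f * 3.7
    expect_equal(sir_signal(sch, p3, magnitude = FALSE)$signal, 3.7 * base,
                 tolerance = 1e-14)
  }
})

test_that("signed recovery increases from short ti to full recovery", {
  for (p in random_params(20, seed = 19)) {
    p$sf <- -1
    early <- longitudinal_magnetization(p, ti = 0.015, td = 0.648)[["mzf"]]
    late <- longitudinal_magnetization(p, ti = 1e6, td = 0.648)[["mzf"]]
    expect_gt(late, early)
  }
})

test_that("signal is continuous in the parameters over the simulation grid", {
  sch <- paper_scheme()
  base <- list(psr = 0.15, r1f = 1, r1m = 1, sf = -1, sm = 0.83,
               m0f = 1, kmf = 12.5)
  h <- 1e-6
  for (nm in names(base)) {
    up <- base; up[[nm]] <- base[[nm]] + h
    dn <- base; dn[[nm]] <- base[[nm]] - h
    d <- (do.call(sirqmt:::sir_mz_core, c(up, list(ti = sch$ti, td = sch$td))) -
          do.call(sirqmt:::sir_mz_core, c(dn, list(ti = sch$ti, td = sch$td)))) /
         (2 * h)
    expect_true(all(is.finite(d)))
    expect_lt(max(abs(d)), 100)
  }
})

test_that("biexponential rates equal eigenvalue magnitudes of the generator", {
  # triangular case: rates are the diagonal magnitudes
  p0 <- sir_params(psr = 0, r1f = 1, r1m = 1, kmf = 12.5)
  expect_equal(unname(biexponential_components(p0)), c(13.5, 1.0))

  for (p in random_params(100, seed = 23)) {
    rates <- biexponential_components(p)
    ev <- sort(-eigen(rate_matrix(p), only.values = TRUE)$values,
               decreasing = TRUE)
    expect_equal(unname(rates), ev, tolerance = 1e-10)
    expect_gte(rates[["fast"]], rates[["slow"]])
  }
})

test_that("scheme validates pairing, positivity and unit conversion", {
  expect_error(sir_scheme(c(1, 2, 3), c(1, 2)), "pair")
  expect_error(sir_scheme(c(1, -2), c(1, 2)), "> 0")
  s_ms <- sir_scheme(c(15, 1007), c(648, 10), units = "ms")
  s_s <- sir_scheme(c(0.015, 1.007), c(0.648, 0.010), units = "s")
  expect_equal(s_ms$ti, s_s$ti)
  expect_equal(s_ms$td, s_s$td)
})
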