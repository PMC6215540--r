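# The shared NLS engine: noiseless round trips, oracle agreement, phase
# selection, error propagation, and coverage of asymptotic uncertainties.

test_that("noiseless generator -> fit round trips recover parameters", {
  # Michaelis (butanone-scale constants)
  d <- data.frame(S = c(0.05, 0.1, 0.2, 0.5, 1, 2, 5, 10))
  d$v <- michaelis_velocity(d$S, michaelis_params(2.1, 0.34))
  f <- fit_nls("michaelis", d)
  expect_true(f$converged)
  expect_equal(unname(f$params), c(2.1, 0.34), tolerance = 1e-6)
  expect_lt(f$rss, 1e-12)

  # hyperbola
  h <- data.frame(S = c(25, 50, 100, 200, 400, 800, 1600))
  h$kobs <- hyperbolic_kobs(h$S, hyperbolic_reduction_params(59, 121))
  fh <- fit_nls("hyperbolic", h)
  expect_equal(unname(fh$params), c(59, 121), tolerance = 1e-6)

  # bell
  b <- generate_ph_dataset(ph_bell_params(2.1, 5.6, 9.2))
  fb <- fit_nls("ph_bell", b)
  expect_equal(unname(fb$params[c("pKa_low", "pKa_high")]), c(5.6, 9.2),
               tolerance = 1e-6)

  # isotherm with fixed enzyme concentration
  ti <- generate_titration(binding_isotherm_params(0.1, 50, 21.1))
  ft <- fit_nls("isotherm", ti, fixed = list(E0 = 50))
  expect_equal(unname(ft$params), c(0.1, 21.1), tolerance = 1e-6)

  # single exponential
  tr <- data.frame(t = seq(0, 1, by = 0.002))
  tr$A <- exponential_decay(tr$t, exponential_phases(0.112, 28.4, 0.01))
  fe <- fit_nls("exp1", tr)
  expect_equal(fe$params[["k1"]], 28.4, tolerance = 1e-6)
})

test_that("constant response gives a zero-slope linear fit with zero stderr", {
  d <- data.frame(x = 1:10, y = rep(2.5, 10))
  f <- fit_nls("linear", d)
  expect_equal(f$params[["slope"]], 0)
  expect_equal(f$stderr[["slope"]], 0)
})

test_that("a dense grid search never beats the NLS optimum", {
  set.seed(42)
  d <- data.frame(S = c(0.05, 0.1, 0.2, 0.5, 1, 2, 5, 10))
  d$v <- michaelis_velocity(d$S, michaelis_params(2.1, 0.34)) +
    rnorm(8, sd = 0.02)
  f <- fit_nls("michaelis", d)
  # coarse 25-point log lattice brackets the optimum
  lattice <- grid_search_2p(mm_curve, d, d$v,
                            2.1 * 10^seq(-0.5, 0.5, length.out = 5),
                            0.34 * 10^seq(-0.5, 0.5, length.out = 5))
  expect_equal(log10(lattice$par[1]), log10(f$params[["kcat"]]),
               tolerance = 0.25)
  expect_equal(log10(lattice$par[2]), log10(f$params[["Km"]]),
               tolerance = 0.25)
  # dense lattice: RSS never below the NLS optimum (minus numerical slack)
  dense <- grid_search_2p(mm_curve, d, d$v,
                          seq(1.8, 2.4, length.out = 120),
                          seq(0.2, 0.6, length.out = 120))
  expect_gte(dense$rss, f$rss - 1e-10)
})

test_that("fits are invariant to observation order", {
  d <- data.frame(S = c(0.05, 0.1, 0.2, 0.5, 1, 2, 5, 10))
  d$v <- michaelis_velocity(d$S, michaelis_params(2.1, 0.34)) +
    c(0.01, -0.02, 0.015, 0, -0.01, 0.02, -0.005, 0.01)
  f1 <- fit_nls("michaelis", d)
  f2 <- fit_nls("michaelis", d[sample(8), ])
  expect_identical(f1$params, f2$params)
})

test_that("under-determined and malformed inputs raise explicit errors", {
  expect_error(fit_nls("michaelis", data.frame(S = c(1, 2), v = c(1, 1.5))),
               "under-determined")
  expect_error(fit_nls("nope", data.frame(x = 1, y = 1)), "unknown model")
  expect_error(fit_nls("michaelis",
                       data.frame(S = c(1, 2, NA, 4), v = c(1, 2, 3, 4))),
               "non-finite")
})

test_that("phase-count selection follows the generating model", {
  tg <- seq(0, 1, by = 0.004)
  one <- data.frame(t = tg,
                    A = exponential_decay(tg, exponential_phases(0.1, 28.4, 0.01)))
  expect_identical(select_exponential_phases(one)$chosen, 1L)

  # reoxidation-like biphasic trace (0.47 and 0.06 s^-1)
  tg2 <- seq(0, 75, by = 0.25)
  two <- data.frame(t = tg2,
                    A = exponential_decay(tg2, exponential_phases(
                      c(-0.06, -0.04), c(0.47, 0.06), 0.12)))
  sel <- select_exponential_phases(two)
  expect_identical(sel$chosen, 2L)
  rates <- sort(sel$fits[["2"]]$params[c("k1", "k2")], decreasing = TRUE)
  expect_equal(unname(rates), c(0.47, 0.06), tolerance = 1e-6)

  flat <- data.frame(t = tg, A = rep(0.2, length(tg)))
  self <- select_exponential_phases(flat)
  expect_identical(self$chosen, 1L)
  expect_true(any(grepl("degenerate", self$flags)))
})

test_that("closely spaced rates are flagged poorly identifiable", {
  tg <- seq(0, 10, by = 0.02)
  tw <- data.frame(t = tg,
                   A = exponential_decay(tg, exponential_phases(
                     c(0.08, 0.05), c(1.2, 0.6), 0.02)))
  sel <- select_exponential_phases(tw)
  if (sel$chosen == 2L)
    expect_true(any(grepl("poorly-identifiable", sel$flags)))
})

test_that("ratio propagation matches the quadrature oracle", {
  r <- ratio_with_uncertainty(28.4, 0.5, 7.5, 0.2)
  oracle <- quadrature_ratio(28.4, 0.5, 7.5, 0.2)
  expect_equal(unname(r), unname(oracle), tolerance = 1e-12)
  expect_equal(r[["ratio"]], 3.79, tolerance = 1e-2)
  expect_equal(r[["stderr"]], 0.12, tolerance = 1e-1)
  expect_identical(unname(ratio_with_uncertainty(3, 0, 3, 0)), c(1, 0))
  expect_equal(ratio_with_uncertainty(170, 0, 0.34, 0)[["ratio"]], 500)
  expect_error(ratio_with_uncertainty(1, 0, 0, 0), "nonzero")
})

test_that("noisy estimates fall inside 4-sigma asymptotic bounds in >=95% of
           seeded replicates", {
  true <- c(kcat = 2.1, Km = 0.34)
  d0 <- data.frame(S = c(0.05, 0.1, 0.2, 0.5, 1, 2, 5, 10))
  mu <- michaelis_velocity(d0$S, michaelis_params(2.1, 0.34))
  sigma <- 0.02 * true[["kcat"]]
  covered <- vapply(seq_len(200), function(i) {
    set.seed(1000 + i)
    d <- d0; d$v <- mu + rnorm(nrow(d0), sd = sigma)
    f <- fit_nls("michaelis", d)
    all(abs(f$params - true) <= 4 * f$stderr)
  }, logical(1))
  expect_gte(mean(covered), 0.95)
})
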