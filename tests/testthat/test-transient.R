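# Stopped-flow module: exponential trace fits, pseudo-first-order guard,
# hyperbolic and linear concentration dependences, and the isotope effect.

test_that("reduction traces refit their generating rate constants", {
  tg <- seq(0, 1, by = 0.002)
  for (k in c(28.4, 7.5)) {
    tr <- generate_exponential_trace(exponential_phases(0.112, k, 0.01), tg)
    f <- fit_reduction_trace(tr)
    expect_equal(f$kobs, k, tolerance = 1e-6)
    expect_true(f$fit$converged)
  }
  flat <- absorbance_trace(tg, rep(0.12, length(tg)), 443)
  ff <- fit_reduction_trace(flat)
  expect_true(any(grepl("degenerate", ff$flags)))
})

test_that("pseudo-first-order guard uses the sevenfold threshold inclusively", {
  expect_true(pseudo_first_order_check(10, 100)$pass)
  expect_equal(pseudo_first_order_check(10, 100)$ratio, 10)
  expect_false(pseudo_first_order_check(10, 69)$pass)
  expect_true(pseudo_first_order_check(10, 70)$pass)
  expect_error(pseudo_first_order_check(0, 100), "E0")
})

test_that("guard violation is attached as a warning flag, fit still returned", {
  tg <- seq(0, 1, by = 0.002)
  tr <- generate_exponential_trace(exponential_phases(0.112, 28.4, 0.01), tg,
                                   meta = list(E0_uM = 10, NADPH_uM = 30))
  f <- fit_reduction_trace(tr)
  expect_true(any(grepl("pseudo-first-order", f$flags)))
  expect_equal(f$kobs, 28.4, tolerance = 1e-6)
})

test_that("hyperbolic NADPH dependence recovers kred and Kd, and flags the
           saturated regime", {
  grid <- data.frame(S = c(25, 50, 100, 200, 400, 800, 1600))
  grid$kobs <- hyperbolic_kobs(grid$S, hyperbolic_reduction_params(59, 121))
  f <- fit_kobs_vs_nadph(grid)
  expect_equal(f$kred, 59, tolerance = 1e-6)
  expect_equal(f$Kd, 121, tolerance = 1e-6)
  # concentration-independent kobs (tight-binding variant behaviour)
  sat <- data.frame(S = c(50, 100, 200, 400), kobs = rep(55, 4))
  fs <- fit_kobs_vs_nadph(sat)
  expect_true(any(grepl("saturated", fs$flags)))
  expect_equal(fs$kred, 55)
  expect_true(is.na(fs$Kd))
  expect_error(fit_kobs_vs_nadph(data.frame(S = c(50, 100), kobs = c(20, 30))),
               "under-determined")
})

test_that("noisy hyperbolic recovery stays within the reported uncertainty in
           >=95% of seeded replicates", {
  S <- c(25, 50, 100, 200, 400, 800, 1600)
  mu <- hyperbolic_kobs(S, hyperbolic_reduction_params(59, 121))
  sigma <- 0.02 * 59
  ok <- vapply(seq_len(200), function(i) {
    set.seed(2000 + i)
    # each k_obs point is the average of five replicate traces, as in the
    # stopped-flow acquisition protocol
    kobs <- mu + colMeans(matrix(rnorm(5 * 7, sd = sigma), nrow = 5))
    f <- fit_kobs_vs_nadph(data.frame(S = S, kobs = kobs))
    abs(f$kred - 59) <= 3 && abs(f$Kd - 121) <= 14
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("oxygen dependence: OLS slope matches the closed form and unit
           rescaling is exact", {
  pts <- data.frame(O2 = c(0.065, 0.13, 0.26), kobs = 40.1 * c(0.065, 0.13, 0.26) + 3)
  f <- fit_kobs_vs_oxygen(pts)
  expect_equal(f$slope, 40.1, tolerance = 1e-9)
  expect_equal(f$intercept, 3, tolerance = 1e-9)
  oracle <- ols_closed_form(pts$O2, pts$kobs)
  expect_equal(f$slope, oracle[["slope"]], tolerance = 1e-12)
  # mM -> uM changes the slope by exactly 1e3
  f_uM <- fit_kobs_vs_oxygen(data.frame(O2 = pts$O2 * 1000, kobs = pts$kobs))
  expect_equal(f_uM$slope * 1e3, f$slope, tolerance = 1e-12)
  # zero slope is recovered as a zero bimolecular constant
  fz <- fit_kobs_vs_oxygen(data.frame(O2 = c(0.05, 0.1, 0.2), kobs = rep(5, 3)))
  expect_equal(fz$slope, 0)
  expect_error(fit_kobs_vs_oxygen(data.frame(O2 = rep(0.13, 3), kobs = 1:3)),
               "3 distinct")
})

test_that("kinetic isotope effect comes out near 3.8 with propagated error", {
  tg <- seq(0, 1, by = 0.002)
  fH <- fit_reduction_trace(generate_exponential_trace(
    exponential_phases(0.112, 28.4, 0.01), tg))
  fD <- fit_reduction_trace(generate_exponential_trace(
    exponential_phases(0.112, 7.5, 0.01), tg))
  kie <- compute_kie(fH, fD)
  expect_equal(kie[["kie"]], 28.4 / 7.5, tolerance = 1e-6)
  expect_equal(round(kie[["kie"]], 1), 3.8)
  # stderr matches the quadrature oracle on the printed inputs
  oracle <- quadrature_ratio(28.4, 0.5, 7.5, 0.2)
  expect_equal(oracle[2], 0.12, tolerance = 0.05)
  expect_identical(compute_kie(fH, fH)[["kie"]], 1)
})

test_that("traces from the cycle simulator in the pseudo-first-order regime fit
           a single exponential matching the hyperbolic prediction", {
  p <- mechanism_params()
  for (nadph in c(100, 500)) {  # 20x and 100x over 5 uM enzyme
    tr <- generate_reduction_trace(5, nadph, p,
                                   times = seq(0, 0.4, by = 0.001))
    f <- fit_reduction_trace(tr, t_max = Inf)
    expect_gt(f$fit$r2, 0.999)
    pred <- hyperbolic_kobs(nadph, hyperbolic_reduction_params(59, 121))
    expect_equal(f$kobs, pred, tolerance = 0.05)
    # single-exponential emergence: residual RMS < 0.1% of amplitude
    rms <- sqrt(f$fit$rss / f$fit$n_obs)
    expect_lt(rms, 1e-3 * abs(f$phases$amplitudes[1]))
  }
})

test_that("reoxidation trace analysis extracts the uncoupling phases", {
  p <- mechanism_params()
  sim <- simulate_cycle(p, list(Ered = 20, NADP = 500, O2 = 130),
                        times = seq(0, 75, by = 0.05))
  f <- fit_reoxidation_trace(data.frame(t = sim$absorbance$t,
                                        A = sim$absorbance$A443))
  expect_identical(f$n_phases, 2L)
  # slow phase is uncoupled peroxyflavin decay at 0.47 s^-1
  expect_equal(min(f$phases$rates), 0.47, tolerance = 0.05)
})
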