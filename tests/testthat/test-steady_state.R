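# Steady-state pipeline: progress-curve slopes, Michaelis and inhibition
# fits, pH profile, thermostability, and the end-to-end route from simulated
# progress curves back to effective constants.

test_that("trace_to_velocity converts A340 slope to turnover", {
  tg <- seq(0, 60, by = 0.5)
  tr <- data.frame(t = tg, A = 0.7 - 0.00622 * tg)
  vr <- trace_to_velocity(tr, E0 = 0.5)
  expect_equal(vr$v_uM_s, 1.0, tolerance = 1e-9)   # 0.00622/6220 M/s
  expect_equal(vr$v, 2.0, tolerance = 1e-9)        # normalized by 0.5 uM
  flat <- data.frame(t = tg, A = rep(0.7, length(tg)))
  expect_equal(trace_to_velocity(flat, 0.5)$v, 0)
  expect_error(trace_to_velocity(data.frame(t = 0:3, A = c(1, .9, .8, .7)), 0.5),
               "5 points")
})

test_that("trace_to_velocity flags a non-monotone early segment", {
  tg <- seq(0, 60, by = 0.5)
  # early rise against the overall decline (continuous at the turning point)
  A <- ifelse(tg <= 3, 0.7 + 0.01 * tg, 0.73 - 0.005 * (tg - 3))
  vr <- trace_to_velocity(data.frame(t = tg, A = A), 0.5)
  expect_match(vr$flag, "non-monotone")
})

test_that("Michaelis datasets recover acetone- and butanone-scale constants", {
  for (truth in list(c(2.1, 0.34), c(1.4, 170))) {
    p <- michaelis_params(truth[1], truth[2])
    recs <- generate_velocity_dataset(
      p, S_grid = truth[2] * c(0.1, 0.25, 0.5, 1, 2, 5, 20))
    fit <- fit_michaelis_dataset(recs)
    expect_equal(fit$params$kcat, truth[1], tolerance = 1e-6)
    expect_equal(fit$params$Km, truth[2], tolerance = 1e-6)
    # catalytic efficiency consistent with the stored estimates, exactly
    expect_identical(fit$kcat_over_Km,
                     fit$params$kcat / fit$params$Km * 1e6)
  }
  expect_error(fit_michaelis_dataset(data.frame(S = rep(5, 6), v = rep(1, 6))),
               "under-determined")
})

test_that("saturation warning fires when the grid stops below Km", {
  p <- michaelis_params(1.4, 170)
  recs <- generate_velocity_dataset(p, S_grid = c(1, 2, 5, 10, 20))
  fit <- fit_michaelis_dataset(recs)
  expect_true(any(grepl("saturation", fit$flags)))
})

test_that("competitive-inhibition global fit recovers all three constants and
           nests the uninhibited fit", {
  p <- michaelis_params(2.0, 6.7, Ki = 166)
  recs <- generate_velocity_dataset(p, S_grid = c(0.2, 0.5, 1, 2, 5, 10, 25,
                                                  50, 100),
                                    I_grid = c(0, 250, 500, 1000))
  fit <- fit_competitive_inhibition(recs)
  expect_equal(fit$params$kcat, 2.0, tolerance = 1e-6)
  expect_equal(fit$params$Km, 6.7, tolerance = 1e-6)
  expect_equal(fit$params$Ki, 166, tolerance = 1e-6)
  # Lineweaver-Burk signature: apparent Km at each I equals Km(1 + I/Ki)
  for (I in c(250, 500, 1000)) {
    sub <- recs[recs$I == I, ]
    app <- fit_michaelis_dataset(sub[, c("S", "v")])
    expect_equal(app$params$Km, 6.7 * (1 + I / 166), tolerance = 1e-6)
    expect_equal(app$params$kcat, 2.0, tolerance = 1e-6)
  }
  # I = 0 subset reproduces the plain Michaelis fit
  plain <- fit_michaelis_dataset(recs[recs$I == 0, c("S", "v")])
  expect_equal(plain$params$kcat, fit$params$kcat, tolerance = 1e-6)
  expect_equal(plain$params$Km, fit$params$Km, tolerance = 1e-6)
  expect_error(fit_competitive_inhibition(recs[recs$I == 500, ]),
               "unidentifiable|I = 0")
})

test_that("fold changes reproduce the Km and uncoupling comparisons", {
  expect_equal(fold_change(170, 0.34), 500)
  expect_equal(fold_change(2.1, 0.26), 8.0769, tolerance = 1e-4)
  expect_identical(fold_change(3, 3), 1)
  expect_error(fold_change(1, 0), "> 0")
})

test_that("pH profile fit recovers both limb pKas and flags extrapolation", {
  truth <- ph_bell_params(2.1, 5.6, 9.2)
  fit <- fit_ph_profile(generate_ph_dataset(truth))
  expect_equal(fit$params$pKa_low, 5.6, tolerance = 1e-6)
  expect_equal(fit$params$pKa_high, 9.2, tolerance = 1e-6)
  expect_equal(fit$pH_opt, 7.4, tolerance = 1e-6)
  # basic limb sits above the sampled range -> flagged extrapolated
  narrow <- generate_ph_dataset(ph_bell_params(2.1, 5.6, 10.5),
                                pH_grid = seq(5.0, 9.0, by = 0.25))
  expect_true(any(grepl("pKa_high extrapolated",
                        fit_ph_profile(narrow)$flags)))
  expect_error(fit_ph_profile(data.frame(pH = c(6, 7, 8), v = c(1, 2, 1))),
               ">= 6")
})

test_that("thermostability summary normalizes to the coldest point and flags
           the >60% activity loss", {
  pts <- data.frame(temperature = c(5, 10, 20, 25, 30, 45),
                    v = c(1.0, 1.0, 0.98, 0.5, 0.35, 0.05))
  s <- thermostability_summary(pts)
  expect_equal(s$fraction[1], 1.0)
  expect_equal(s$fraction[s$temperature == 30], 0.35)
  expect_true(attr(s, "decline"))
  equal <- thermostability_summary(data.frame(temperature = c(5, 15, 25),
                                              v = c(2, 2, 2)))
  expect_true(all(equal$fraction == 1))
  expect_false(attr(equal, "decline"))
  expect_error(thermostability_summary(data.frame(temperature = numeric(),
                                                  v = numeric())), "empty")
})

test_that("progress curves simulated from the cycle recover the mechanism's
           effective Michaelis constants within 2%", {
  p <- mechanism_params(k_uncouple = 0)  # fully coupled turnover
  S_N <- 100; O2 <- 130; E0 <- 0.001
  # closed-form effective constants: mean cycle time decomposition
  T1 <- (p$koff_NADPH + p$k_red) / (p$k_red * p$kon_NADPH * S_N) + 1 / p$k_red
  C <- T1 + 1 / (p$k_O2 / 1000 * O2) + 1 / p$k_release
  kcat_eff <- 1 / C
  Km_eff <- kcat_eff / p$k_sub
  recs <- do.call(rbind, lapply(c(0.2, 0.5, 1, 2, 5, 20), function(K) {
    sim <- simulate_cycle(p, list(Eox = E0, NADPH = S_N, O2 = O2, ketone = K),
                          times = seq(0, 30, by = 0.1), wavelengths = "340")
    a <- sim$absorbance[sim$absorbance$t >= 5, ]  # discard pre-steady-state
    vr <- trace_to_velocity(data.frame(t = a$t - 5, A = a$A340), E0)
    data.frame(S = K, v = vr$v)
  }))
  fit <- fit_michaelis_dataset(recs)
  expect_equal(fit$params$kcat, kcat_eff, tolerance = 0.02)
  expect_equal(fit$params$Km, Km_eff, tolerance = 0.02)
})
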