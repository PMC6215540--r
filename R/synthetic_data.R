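# Seeded generators for every input the analysis pipeline consumes: a
# mass-action ODE simulator of the six-state Baeyer-Villiger monooxygenase
# catalytic cycle, a quasi-static two-couple Nernst equilibration generator,
# and direct model-plus-noise generators for velocity surfaces, titrations,
# pH profiles and exponential traces.

#' Gaussian noise specification
#'
#' @param sigma Standard deviation in observable units; non-negative.
#' @param seed Integer seed; identical (seed, sigma, grid) give identical
#'   output.
#' @return An object of class \code{noise_spec}.
#' @export
noise_spec <- function(sigma = 0, seed = 0L) {
  stopifnot(is.finite(sigma), sigma >= 0)
  structure(list(sigma = sigma, seed = as.integer(seed)),
            class = "noise_spec")
}

# evaluate expr with a local RNG stream; global .Random.seed is untouched
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.add_noise <- function(x, noise) {
  if (is.null(noise) || noise$sigma == 0) return(x)
  stopifnot(inherits(noise, "noise_spec"))
  .with_seed(noise$seed, x + stats::rnorm(length(x), sd = noise$sigma))
}

#' Microscopic parameters of the catalytic cycle
#'
#' Rate constants of the six-state mechanism: NADPH binding/release to the
#' oxidized enzyme, hydride transfer to FAD, reaction of the reduced flavin
#' with O2 to form the C4a-peroxyflavin, attack of the peroxyflavin on the
#' ketone carbonyl, collapse of the Criegee adduct, rate-limiting
#' hydroxyflavin dehydration/NADP+ release, and non-productive peroxyflavin
#' decay to H2O2 (uncoupling). Per-species extinction coefficients project
#' the state trajectories to absorbance at 340, 366 and 443 nm.
#'
#' Defaults follow the wild-type enzyme: hydride transfer 59 s^-1, NADPH
#' dissociation constant 121 uM with rapid-equilibrium binding
#' (koff = 1000 s^-1, kon = koff/Kd), flavin oxygenation 40.1 mM^-1 s^-1,
#' uncoupling 0.47 s^-1, a peroxyflavin-ketone constant of 6.2 uM^-1 s^-1
#' (reproducing the butanone-scale catalytic efficiency of ~6e6 M^-1 s^-1),
#' and a release rate chosen so that steady-state turnover at saturating
#' butanone in air-saturated buffer is about 2.1 s^-1. The Criegee intermediate is lumped with the peroxyflavin
#' substrate step unless \code{k_collapse} is set (> 0); it is spectrally
#' silent either way.
#'
#' @param kon_NADPH,koff_NADPH Binding/release of NADPH (uM^-1 s^-1, s^-1);
#'   their ratio defines Kd(NADPH).
#' @param k_red Hydride transfer rate (s^-1).
#' @param k_O2 Bimolecular flavin oxygenation constant (mM^-1 s^-1).
#' @param k_sub Bimolecular peroxyflavin + ketone constant (uM^-1 s^-1).
#' @param k_collapse Criegee collapse rate (s^-1); 0 lumps the Criegee step.
#' @param k_release Hydroxyflavin dehydration / NADP+ release rate (s^-1).
#' @param k_uncouple Peroxyflavin decay to H2O2 (s^-1).
#' @param eps Named list per wavelength (\code{"340"}, \code{"366"},
#'   \code{"443"}) of named extinction-coefficient vectors over the species
#'   \code{Eox}, \code{ES}, \code{Ered}, \code{Eperoxy}, \code{Ecriegee},
#'   \code{Ehydroxy}, \code{NADPH}, \code{NADP} (M^-1 cm^-1).
#' @return An object of class \code{mechanism_params}.
#' @export
mechanism_params <- function(kon_NADPH = 1000 / 121, koff_NADPH = 1000,
                             k_red = 59, k_O2 = 40.1, k_sub = 6.2,
                             k_collapse = 0, k_release = NULL,
                             k_uncouple = 0.47, eps = NULL) {
  rates <- c(kon_NADPH, koff_NADPH, k_red, k_O2, k_sub, k_collapse,
             k_uncouple)
  stopifnot(all(is.finite(rates)), all(rates >= 0), kon_NADPH > 0)
  if (is.null(k_release)) {
    # choose release so that turnover at saturating butanone (200 uM,
    # k_sub*S fast) in air-saturated buffer (0.13 mM post-mix O2) is ~2.1/s:
    # 1/kcat = 1/k_red + 1/(k_O2*[O2]) + 1/(k_sub*[S]) + 1/k_release
    inv <- 1 / 2.1 - 1 / k_red - 1 / (k_O2 / 1000 * 130) - 1 / (k_sub * 200)
    if (inv <= 0) stop("cannot derive k_release for target turnover")
    k_release <- 1 / inv
  }
  stopifnot(is.finite(k_release), k_release > 0)
  species <- c("Eox", "ES", "Ered", "Eperoxy", "Ecriegee", "Ehydroxy",
               "NADPH", "NADP")
  zero <- stats::setNames(numeric(length(species)), species)
  default_eps <- list(
    # bound NADPH absorbs like free NADPH at 340; NADP+ does not
    `340` = `[<-`(zero, c("NADPH", "ES"), 6220),
    # the C4a-peroxyflavin adduct is the 366 nm chromophore
    `366` = `[<-`(zero, "Eperoxy", 8000),
    # oxidized flavin at 443; reduced/adduct states ~0 there
    `443` = `[<-`(zero, c("Eox", "ES"), 12200)
  )
  if (is.null(eps)) eps <- default_eps
  else {
    for (wl in names(eps)) {
      v <- zero; v[names(eps[[wl]])] <- eps[[wl]]
      default_eps[[wl]] <- v
    }
    eps <- default_eps
  }
  structure(list(kon_NADPH = kon_NADPH, koff_NADPH = koff_NADPH,
                 k_red = k_red, k_O2 = k_O2, k_sub = k_sub,
                 k_collapse = k_collapse, k_release = k_release,
                 k_uncouple = k_uncouple, eps = eps,
                 Kd_NADPH = koff_NADPH / kon_NADPH),
            class = "mechanism_params")
}

#' Simulate the catalytic cycle by mass-action ODE integration
#'
#' Integrates the six enzyme states (oxidized, Michaelis complex, reduced
#' flavin-NADP+, C4a-peroxyflavin-NADP+, Criegee adduct, C4a-hydroxyflavin-
#' NADP+) together with the free NADPH, NADP+, O2 and ketone pools, using a
#' stiff-safe solver, and projects the trajectories to absorbance at the
#' requested wavelengths. Total enzyme and total nicotinamide (free NADPH +
#' free NADP+ + nicotinamide bound in enzyme states) are conserved.
#'
#' @param p A \code{\link{mechanism_params}} object.
#' @param init Named list/vector of initial concentrations (uM):
#'   \code{Eox}, \code{NADPH}, \code{O2}, \code{ketone} (all default 0
#'   except as given; enzyme starts fully oxidized unless other states are
#'   supplied).
#' @param times Increasing time grid (s).
#' @param wavelengths Wavelengths to project (subset of
#'   \code{names(p$eps)}).
#' @param path Path length (cm), default 1.
#' @return A list of class \code{cycle_simulation}: \code{trajectories}
#'   (data frame, time plus species in uM), \code{absorbance} (data frame,
#'   time plus \code{A<wavelength>} columns), \code{p} and conservation
#'   diagnostics \code{enzyme_drift}, \code{nicotinamide_drift} (max
#'   relative deviation).
#' @export
simulate_cycle <- function(p, init, times, wavelengths = c("340", "366", "443"),
                           path = 1) {
  stopifnot(inherits(p, "mechanism_params"))
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  species <- c("Eox", "ES", "Ered", "Eperoxy", "Ecriegee", "Ehydroxy",
               "NADPH", "NADP", "O2", "ketone")
  y0 <- stats::setNames(numeric(length(species)), species)
  init <- as.list(init)
  unknown <- setdiff(names(init), species)
  if (length(unknown)) stop("unknown species in init: ",
                            paste(unknown, collapse = ", "))
  y0[names(init)] <- unlist(init)
  if (any(y0 < 0)) stop("initial concentrations must be non-negative")
  lumped <- p$k_collapse == 0
  k_O2_uM <- p$k_O2 / 1000  # mM^-1 s^-1 -> uM^-1 s^-1

  deriv <- function(t, y, parms) {
    v_bind <- p$kon_NADPH * y[["Eox"]] * y[["NADPH"]]
    v_unb  <- p$koff_NADPH * y[["ES"]]
    v_red  <- p$k_red * y[["ES"]]
    v_ox   <- k_O2_uM * y[["Ered"]] * y[["O2"]]
    v_sub  <- p$k_sub * y[["Eperoxy"]] * y[["ketone"]]
    v_col  <- if (lumped) v_sub else p$k_collapse * y[["Ecriegee"]]
    v_unc  <- p$k_uncouple * y[["Eperoxy"]]
    v_rel  <- p$k_release * y[["Ehydroxy"]]
    list(c(
      Eox      = -v_bind + v_unb + v_unc + v_rel,
      ES       = v_bind - v_unb - v_red,
      Ered     = v_red - v_ox,
      Eperoxy  = v_ox - v_sub - v_unc,
      Ecriegee = if (lumped) 0 else v_sub - v_col,
      Ehydroxy = v_col - v_rel,
      NADPH    = -v_bind + v_unb,
      NADP     = v_unc + v_rel,
      O2       = -v_ox,
      ketone   = -v_sub
    ))
  }
  sol <- deSolve::ode(y = y0, times = times, func = deriv, parms = NULL,
                      method = "lsoda", rtol = 1e-10, atol = 1e-12)
  traj <- as.data.frame(sol)
  names(traj)[1] <- "t"
  if (any(traj[species] < -1e-8 * max(y0)))
    stop("integration produced negative concentrations beyond tolerance")
  traj[species] <- lapply(traj[species], pmax, 0)

  enz_states <- c("Eox", "ES", "Ered", "Eperoxy", "Ecriegee", "Ehydroxy")
  E_tot <- rowSums(traj[enz_states])
  E0 <- sum(y0[enz_states])
  nad_tot <- traj$NADPH + traj$NADP +
    rowSums(traj[c("ES", "Ered", "Eperoxy", "Ecriegee", "Ehydroxy")])
  N0 <- y0[["NADPH"]] + y0[["NADP"]] +
    sum(y0[c("ES", "Ered", "Eperoxy", "Ecriegee", "Ehydroxy")])
  enzyme_drift <- if (E0 > 0) max(abs(E_tot - E0)) / E0 else 0
  nicotinamide_drift <- if (N0 > 0) max(abs(nad_tot - N0)) / N0 else 0

  absorb <- data.frame(t = traj$t)
  for (wl in wavelengths) {
    e <- p$eps[[wl]]
    if (is.null(e)) stop("no extinction coefficients for wavelength ", wl)
    A <- numeric(nrow(traj))
    for (sp in names(e)) if (e[[sp]] > 0)
      A <- A + traj[[sp]] * 1e-6 * e[[sp]] * path
    absorb[[paste0("A", wl)]] <- A
  }
  structure(list(trajectories = traj, absorbance = absorb, p = p,
                 enzyme_drift = enzyme_drift,
                 nicotinamide_drift = nicotinamide_drift),
            class = "cycle_simulation")
}

#' Generate an anaerobic flavin-reduction trace at 443 nm
#'
#' Wraps \code{\link{simulate_cycle}} with O2 = 0 and no ketone, mirroring
#' the reductive half-reaction experiment: oxidized enzyme is mixed with
#' coenzyme and the flavin absorbance decay is monitored.
#'
#' @param E0 Post-mix enzyme concentration (uM).
#' @param NADPH0 Post-mix NADPH concentration (uM).
#' @param p A \code{\link{mechanism_params}} object.
#' @param times Time grid (s); default 0-1 s at 1 ms.
#' @param noise A \code{\link{noise_spec}} (AU units); default none.
#' @return An \code{\link{absorbance_trace}} at 443 nm with post-mix
#'   metadata.
#' @export
generate_reduction_trace <- function(E0, NADPH0, p = mechanism_params(),
                                     times = seq(0, 1, by = 0.001),
                                     noise = noise_spec()) {
  sim <- simulate_cycle(p, list(Eox = E0, NADPH = NADPH0), times,
                        wavelengths = "443")
  A <- .add_noise(sim$absorbance$A443, noise)
  absorbance_trace(sim$absorbance$t, A, wavelength = 443,
                   meta = list(E0_uM = E0, NADPH_uM = NADPH0, O2_mM = 0,
                               ketone_uM = 0, seed = noise$seed,
                               sigma = noise$sigma))
}

#' Generate a quasi-static two-couple dye-equilibration series
#'
#' Emulates the slow xanthine/xanthine oxidase reduction of enzyme plus
#' reference dye: for each total amount of delivered reducing equivalents R
#' the common solution potential E is found by bisection such that
#' \eqn{n_e C_e f_e(E) + n_d C_d f_d(E) = R}, where
#' \eqn{f(E) = 1/(1+10^{n(E-E^\circ)/0.0592})} is the n-electron Nernst
#' reduced fraction. Concentrations are projected to A458 (enzyme, at the
#' dye isosbestic) and A610 (dye only) through the endpoint calibration.
#'
#' @param E0_e_mV Enzyme midpoint potential (mV).
#' @param ne Enzyme electron count.
#' @param C_e Enzyme concentration (uM).
#' @param E0_d_mV Dye midpoint potential (mV).
#' @param nd Dye electron count.
#' @param C_d Dye concentration (uM).
#' @param schedule Delivered reducing equivalents (uM electron equivalents),
#'   within \code{[0, ne*C_e + nd*C_d]}; default an even 120-point interior
#'   grid, matching a per-minute spectral acquisition over a two-hour
#'   equilibration.
#' @param cal Endpoint calibration; default synthetic endpoints
#'   (\code{A458_ox/red}, \code{A610_ox/red}) scaled to the stated
#'   concentrations.
#' @param noise A \code{\link{noise_spec}} applied to both absorbance
#'   channels (AU).
#' @param nernst_slope_V Decadic Nernst slope (V), default 0.0592.
#' @return A list of class \code{massey_series}: \code{series} (data frame
#'   \code{t}, \code{A458}, \code{A610}), \code{cal}, \code{potential_mV}
#'   (solution potential per point) and the generating inputs.
#' @export
generate_massey_series <- function(E0_e_mV, ne, C_e, E0_d_mV, nd, C_d,
                                   schedule = NULL, cal = NULL,
                                   noise = noise_spec(),
                                   nernst_slope_V = optical_constants()$nernst_slope_V) {
  R_max <- ne * C_e + nd * C_d
  if (is.null(schedule))
    schedule <- seq(0.01, 0.99, length.out = 120) * R_max
  if (any(schedule < 0) || any(schedule > R_max))
    stop("schedule outside [0, ne*C_e + nd*C_d]")
  if (is.null(cal))
    cal <- list(A458_ox = beer_lambert(C_e, 11000),
                A458_red = beer_lambert(C_e, 600),
                A610_ox = beer_lambert(C_d, 20000),
                A610_red = beer_lambert(C_d, 800),
                E_total = C_e, D_total = C_d)
  f_red <- function(E_V, E0_V, n) 1 / (1 + 10^(n * (E_V - E0_V) / nernst_slope_V))
  solve_E <- function(R) {
    g <- function(E) ne * C_e * f_red(E, E0_e_mV / 1000, ne) +
                     nd * C_d * f_red(E, E0_d_mV / 1000, nd) - R
    stats::uniroot(g, interval = c(-2, 2), tol = 1e-13)$root
  }
  E_V <- vapply(schedule, solve_E, numeric(1))
  f_e <- f_red(E_V, E0_e_mV / 1000, ne)
  f_d <- f_red(E_V, E0_d_mV / 1000, nd)
  A458 <- cal$A458_ox + (cal$A458_red - cal$A458_ox) * f_e
  A610 <- cal$A610_ox + (cal$A610_red - cal$A610_ox) * f_d
  A458 <- .add_noise(A458, noise)
  A610 <- if (is.null(noise) || noise$sigma == 0) A610 else
    .add_noise(A610, noise_spec(noise$sigma, noise$seed + 1L))
  structure(list(series = data.frame(t = seq_along(schedule), A458 = A458,
                                     A610 = A610),
                 cal = cal, potential_mV = E_V * 1000, schedule = schedule,
                 E0_e_mV = E0_e_mV, ne = ne, E0_d_mV = E0_d_mV, nd = nd),
            class = "massey_series")
}

#' Generate a steady-state velocity dataset
#'
#' Evaluates the Michaelis-Menten / competitive-inhibition rate law on a
#' (substrate, inhibitor) grid and adds Gaussian noise.
#'
#' @param p A \code{\link{michaelis_params}} object (with \code{Ki} when the
#'   inhibitor grid has positive levels).
#' @param S_grid Substrate concentrations (uM), non-empty.
#' @param I_grid Inhibitor concentrations (uM), default 0.
#' @param E0 Enzyme concentration recorded with each observation (uM).
#' @param substrate_id Label for the records.
#' @param noise A \code{\link{noise_spec}} (velocity units).
#' @return A data frame of velocity records: \code{substrate_id}, \code{S},
#'   \code{I}, \code{E0}, \code{v} (s^-1 turnover), \code{unit}.
#' @export
generate_velocity_dataset <- function(p, S_grid, I_grid = 0, E0 = 0.025,
                                      substrate_id = "substrate",
                                      noise = noise_spec()) {
  stopifnot(inherits(p, "michaelis_params"))
  if (!length(S_grid)) stop("empty substrate grid")
  if (!length(I_grid)) stop("empty inhibitor grid")
  g <- expand.grid(S = S_grid, I = I_grid)
  v <- michaelis_velocity(g$S, p, g$I)
  v <- .add_noise(v, noise)
  data.frame(substrate_id = substrate_id, S = g$S, I = g$I, E0 = E0,
             v = v, unit = "s-1", stringsAsFactors = FALSE)
}

#' Generate a ligand-binding titration
#'
#' @param p A \code{\link{binding_isotherm_params}} object.
#' @param L0_grid Ligand concentrations (uM); should start at 0.
#' @param noise A \code{\link{noise_spec}} (AU).
#' @return Data frame with columns \code{L0} and \code{dA}.
#' @export
generate_titration <- function(p, L0_grid = seq(0, 200, by = 10),
                               noise = noise_spec()) {
  stopifnot(inherits(p, "binding_isotherm_params"))
  if (!length(L0_grid)) stop("empty ligand grid")
  L0_grid <- sort(L0_grid)
  dA <- quadratic_isotherm(L0_grid, p)
  data.frame(L0 = L0_grid, dA = .add_noise(dA, noise))
}

#' Generate a pH-activity profile
#'
#' @param p A \code{\link{ph_bell_params}} object.
#' @param pH_grid pH values; default 5.5-9.0 in 0.25 steps (the assay range).
#' @param noise A \code{\link{noise_spec}} (velocity units).
#' @return Data frame with columns \code{pH} and \code{v}.
#' @export
generate_ph_dataset <- function(p, pH_grid = seq(5.5, 9.0, by = 0.25),
                                noise = noise_spec()) {
  stopifnot(inherits(p, "ph_bell_params"))
  if (!length(pH_grid)) stop("empty pH grid")
  data.frame(pH = pH_grid, v = .add_noise(ph_bell(pH_grid, p), noise))
}

#' Generate an exponential stopped-flow trace from stated phases
#'
#' Direct evaluation of the multi-exponential trace model plus noise; used
#' to regenerate traces from printed observed rate constants without running
#' the full mechanism.
#'
#' @param p An \code{\link{exponential_phases}} object.
#' @param times Time grid (s).
#' @param wavelength Nominal wavelength (nm), default 443.
#' @param noise A \code{\link{noise_spec}} (AU).
#' @param meta Metadata list passed to the trace.
#' @return An \code{\link{absorbance_trace}}.
#' @export
generate_exponential_trace <- function(p, times = seq(0, 1, by = 0.001),
                                       wavelength = 443,
                                       noise = noise_spec(), meta = list()) {
  stopifnot(inherits(p, "exponential_phases"))
  A <- .add_noise(exponential_decay(times, p), noise)
  absorbance_trace(times, A, wavelength = wavelength, meta = meta)
}
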