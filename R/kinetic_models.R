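# Pure model equations shared by every analysis module. All functions are
# deterministic, vectorized in their first argument, and validate their
# parameter lists on entry. Internal units: concentrations in uM, time in s,
# potentials in volts internally (mV at interfaces), extinction coefficients
# in M^-1 cm^-1.

#' Optical and electrochemical constants
#'
#' Default constants used throughout the package: the NADPH/NADP+ difference
#' extinction coefficient at 340 nm, the extinction coefficient of free FAD
#' at 450 nm, the extinction coefficient of the holoenzyme flavin at 443 nm,
#' the decadic Nernst slope at 25 degrees C, and the midpoint potential of
#' the reference dye indigo disulfonate at pH 7.0. Any entry can be
#' overridden per call.
#'
#' @param ... Named overrides, e.g. \code{optical_constants(em_dye_mV = -110)}.
#'
#' @return A named list with elements \code{d_eps340} (M^-1 cm^-1),
#'   \code{eps450_freeFAD} (M^-1 cm^-1), \code{eps443_holo} (M^-1 cm^-1),
#'   \code{nernst_slope_V} (volts per decade at 25 C) and \code{em_dye_mV}
#'   (millivolts).
#' @export
#' @examples
#' optical_constants()$eps443_holo
optical_constants <- function(...) {
  defaults <- list(
    d_eps340       = 6220,    # NADPH minus NADP+, M^-1 cm^-1
    eps450_freeFAD = 11300,
    eps443_holo    = 12200,
    nernst_slope_V = 0.0592,  # 2.303 RT/F at 25 C, fixed not recomputed
    em_dye_mV      = -116     # indigo disulfonate, pH 7.0, n = 2
  )
  ov <- list(...)
  if (length(ov)) {
    unknown <- setdiff(names(ov), names(defaults))
    if (length(unknown))
      stop("unknown constant(s): ", paste(unknown, collapse = ", "))
    defaults[names(ov)] <- ov
  }
  defaults
}

#' Parameters of the quadratic tight-binding isotherm
#'
#' @param dA_max Maximum absorbance change at saturation (AU).
#' @param E0 Total enzyme concentration (uM); must be positive.
#' @param Kd Dissociation constant (uM); must be non-negative.
#' @return An object of class \code{binding_isotherm_params}.
#' @export
binding_isotherm_params <- function(dA_max, E0, Kd) {
  stopifnot(is.finite(dA_max), is.finite(E0), is.finite(Kd))
  if (E0 <= 0) stop("E0 must be > 0")
  if (Kd < 0) stop("Kd must be >= 0")
  structure(list(dA_max = dA_max, E0 = E0, Kd = Kd),
            class = "binding_isotherm_params")
}

#' Michaelis-Menten / competitive-inhibition parameters
#'
#' @param kcat Turnover number (s^-1); positive.
#' @param Km Michaelis constant (uM); positive.
#' @param Ki Optional competitive inhibition constant (uM); positive when given.
#' @return An object of class \code{michaelis_params}.
#' @export
michaelis_params <- function(kcat, Km, Ki = NULL) {
  stopifnot(is.finite(kcat), is.finite(Km))
  if (kcat <= 0) stop("kcat must be > 0")
  if (Km <= 0) stop("Km must be > 0")
  if (!is.null(Ki)) {
    stopifnot(is.finite(Ki))
    if (Ki <= 0) stop("Ki must be > 0 when present")
  }
  structure(list(kcat = kcat, Km = Km, Ki = Ki), class = "michaelis_params")
}

#' Bell-shaped pH-rate profile parameters
#'
#' Two ionizable groups bound catalysis: activity requires the group with the
#' lower pKa deprotonated and the group with the higher pKa protonated,
#' giving a bell with limbs at \code{pKa_low} and \code{pKa_high}.
#'
#' @param Y_H Maximal velocity when both groups are in their productive
#'   ionization state (velocity units).
#' @param pKa_low Acidic-limb pKa; must be below \code{pKa_high}.
#' @param pKa_high Basic-limb pKa.
#' @return An object of class \code{ph_bell_params}.
#' @export
ph_bell_params <- function(Y_H, pKa_low, pKa_high) {
  stopifnot(is.finite(Y_H), is.finite(pKa_low), is.finite(pKa_high))
  if (Y_H <= 0) stop("Y_H must be > 0")
  if (pKa_low >= pKa_high) stop("pKa_low must be < pKa_high")
  structure(list(Y_H = Y_H, pKa_low = pKa_low, pKa_high = pKa_high),
            class = "ph_bell_params")
}

#' Hyperbolic saturation parameters for flavin reduction
#'
#' @param kred Limiting rate constant of flavin reduction (s^-1); positive.
#' @param Kd_NADPH Apparent dissociation constant for the coenzyme (uM);
#'   positive.
#' @return An object of class \code{hyperbolic_reduction_params}.
#' @export
hyperbolic_reduction_params <- function(kred, Kd_NADPH) {
  stopifnot(is.finite(kred), is.finite(Kd_NADPH))
  if (kred <= 0) stop("kred must be > 0")
  if (Kd_NADPH <= 0) stop("Kd_NADPH must be > 0")
  structure(list(kred = kred, Kd_NADPH = Kd_NADPH),
            class = "hyperbolic_reduction_params")
}

#' Multi-exponential transient parameters
#'
#' One or two exponential phases plus a final offset, the standard stopped-flow
#' trace model. Phases are stored sorted by decreasing rate.
#'
#' @param amplitudes Numeric vector of phase amplitudes (AU), length 1 or 2.
#' @param rates Numeric vector of phase rate constants (s^-1), strictly
#'   positive, same length as \code{amplitudes}.
#' @param offset Final absorbance (AU).
#' @return An object of class \code{exponential_phases}.
#' @export
exponential_phases <- function(amplitudes, rates, offset = 0) {
  stopifnot(length(amplitudes) == length(rates),
            length(rates) >= 1L, length(rates) <= 2L,
            all(is.finite(amplitudes)), all(is.finite(rates)),
            is.finite(offset))
  if (any(rates <= 0)) stop("rates must be strictly positive")
  ord <- order(rates, decreasing = TRUE)
  structure(list(amplitudes = amplitudes[ord], rates = rates[ord],
                 offset = offset),
            class = "exponential_phases")
}

#' Quadratic tight-binding isotherm
#'
#' Absorbance change on titrating a ligand into a receptor whose concentration
#' is comparable to the dissociation constant, so ligand depletion cannot be
#' neglected:
#' \deqn{\Delta A = \frac{\Delta A_{max}}{2E_0}\left\{E_0+L_0+K_d -
#'   \sqrt{(E_0+L_0+K_d)^2 - 4E_0L_0}\right\}}
#'
#' @param L0 Total ligand concentration (uM); vectorized, non-negative.
#' @param p A \code{\link{binding_isotherm_params}} object.
#' @return Absorbance change (AU), in \code{[0, dA_max]}.
#' @export
#' @examples
#' p <- binding_isotherm_params(dA_max = 0.1, E0 = 50, Kd = 21.1)
#' quadratic_isotherm(50, p)
quadratic_isotherm <- function(L0, p) {
  stopifnot(inherits(p, "binding_isotherm_params"))
  if (any(!is.finite(L0)) || any(L0 < 0)) stop("L0 must be finite and >= 0")
  s <- p$E0 + L0 + p$Kd
  disc <- s^2 - 4 * p$E0 * L0
  # guard tiny negative discriminants from cancellation at stoichiometric points
  disc[disc < 0 & disc > -1e-9 * s^2] <- 0
  (p$dA_max / (2 * p$E0)) * (s - sqrt(disc))
}

#' Michaelis-Menten velocity with optional competitive inhibition
#'
#' \deqn{v = \frac{k_{cat}S}{K_m(1 + I/K_i) + S}}
#' With \code{I = 0} this reduces to the Michaelis-Menten equation.
#'
#' @param S Substrate concentration (uM); vectorized, non-negative.
#' @param p A \code{\link{michaelis_params}} object.
#' @param I Competitive inhibitor concentration (uM); requires \code{p$Ki}
#'   when positive.
#' @return Velocity in the same units as \code{kcat} (s^-1 turnover).
#' @export
michaelis_velocity <- function(S, p, I = 0) {
  stopifnot(inherits(p, "michaelis_params"))
  if (any(!is.finite(S)) || any(S < 0)) stop("S must be finite and >= 0")
  if (any(!is.finite(I)) || any(I < 0)) stop("I must be finite and >= 0")
  if (any(I > 0) && is.null(p$Ki))
    stop("inhibitor present but Ki not set in parameters")
  alpha <- if (is.null(p$Ki)) 1 else 1 + I / p$Ki
  p$kcat * S / (p$Km * alpha + S)
}

#' Bell-shaped pH-rate profile
#'
#' Velocity as a function of pH when catalysis requires one group deprotonated
#' (acidic limb, \code{pKa_low}) and another protonated (basic limb,
#' \code{pKa_high}):
#' \deqn{Y = \frac{Y_H}{1 + H/K_{a,low} + K_{a,high}/H}, \quad H = 10^{-pH}}
#' The maximum lies at pH = (pKa_low + pKa_high)/2.
#'
#' @param pH pH value(s) in (0, 14); vectorized.
#' @param p A \code{\link{ph_bell_params}} object.
#' @return Velocity (same units as \code{Y_H}).
#' @export
ph_bell <- function(pH, p) {
  stopifnot(inherits(p, "ph_bell_params"))
  if (any(!is.finite(pH)) || any(pH <= 0) || any(pH >= 14))
    stop("pH must lie in (0, 14)")
  H <- 10^(-pH)
  Ka_low <- 10^(-p$pKa_low)
  Ka_high <- 10^(-p$pKa_high)
  p$Y_H / (1 + H / Ka_low + Ka_high / H)
}

#' Hyperbolic dependence of the observed flavin-reduction rate on coenzyme
#'
#' \deqn{k_{obs} = \frac{k_{red}[NADPH]}{K_d + [NADPH]}}
#' Bounded above by \code{kred}.
#'
#' @param S NADPH concentration (uM); vectorized, non-negative.
#' @param p A \code{\link{hyperbolic_reduction_params}} object.
#' @return Observed rate constant (s^-1).
#' @export
hyperbolic_kobs <- function(S, p) {
  stopifnot(inherits(p, "hyperbolic_reduction_params"))
  if (any(!is.finite(S)) || any(S < 0)) stop("S must be finite and >= 0")
  p$kred * S / (p$Kd_NADPH + S)
}

#' Multi-exponential decay
#'
#' \deqn{A(t) = A_\infty + \sum_i a_i e^{-k_i t}}
#'
#' @param t Time (s); vectorized, non-negative.
#' @param p An \code{\link{exponential_phases}} object.
#' @return Absorbance (AU).
#' @export
exponential_decay <- function(t, p) {
  stopifnot(inherits(p, "exponential_phases"))
  if (any(!is.finite(t)) || any(t < 0)) stop("t must be finite and >= 0")
  out <- rep(p$offset, length(t))
  for (i in seq_along(p$rates))
    out <- out + p$amplitudes[i] * exp(-p$rates[i] * t)
  out
}

#' Beer-Lambert absorbance
#'
#' @param conc Chromophore concentration (uM); vectorized, non-negative.
#' @param epsilon Molar extinction coefficient (M^-1 cm^-1); non-negative.
#' @param path Optical path length (cm); non-negative. Default 1 cm.
#' @return Absorbance (AU).
#' @export
#' @examples
#' beer_lambert(20, 12200)  # 0.244 AU
beer_lambert <- function(conc, epsilon, path = 1) {
  if (any(!is.finite(conc)) || any(conc < 0)) stop("conc must be >= 0")
  if (any(!is.finite(epsilon)) || any(epsilon < 0)) stop("epsilon must be >= 0")
  if (any(!is.finite(path)) || any(path < 0)) stop("path must be >= 0")
  conc * 1e-6 * epsilon * path
}
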