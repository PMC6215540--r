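# Steady-state analysis: from A340 progress curves or tabulated initial
# velocities to Michaelis-Menten constants, competitive NADP+ inhibition,
# catalytic efficiencies, the uncoupled oxidation rate, the pH-rate profile
# and thermostability summaries.

#' Initial velocity from an NADPH-depletion progress curve
#'
#' Takes the linear-regression slope of A340 over the initial window of the
#' trace, converts it to a NADPH consumption rate via the NADPH/NADP+
#' difference extinction coefficient, and normalizes by the enzyme
#' concentration to a turnover rate. A falling A340 yields a positive
#' velocity. The window is the first \code{window_frac} of the total
#' absorbance change or the first \code{window_max_s} seconds, whichever is
#' shorter.
#'
#' @param trace Data frame with columns \code{t} (s) and \code{A} (AU at
#'   340 nm), or an \code{\link{absorbance_trace}}.
#' @param E0 Enzyme concentration (uM), positive.
#' @param window_frac Fraction of the total absorbance change defining the
#'   initial window (default 0.1).
#' @param window_max_s Maximum window length in seconds (default 30).
#' @param d_eps340 Difference extinction coefficient (M^-1 cm^-1); default
#'   from \code{\link{optical_constants}}.
#' @param path Path length (cm), default 1.
#'
#' @return A one-row data frame (a velocity record): \code{S}, \code{I},
#'   \code{E0} (uM, \code{S}/\code{I} NA when unknown), \code{v} (s^-1
#'   turnover), \code{v_uM_s} (raw uM/s), \code{unit}, and a \code{flag}
#'   column noting a non-monotone early segment.
#' @export
trace_to_velocity <- function(trace, E0, window_frac = 0.1, window_max_s = 30,
                              d_eps340 = optical_constants()$d_eps340,
                              path = 1) {
  if (inherits(trace, "absorbance_trace")) trace <- trace$samples
  trace <- as.data.frame(trace)
  if (!all(c("t", "A") %in% names(trace)) && ncol(trace) == 2L)
    names(trace) <- c("t", "A")
  if (E0 <= 0) stop("E0 must be > 0")
  total <- abs(trace$A[nrow(trace)] - trace$A[1])
  if (total == 0) {
    t_end <- min(max(trace$t), window_max_s)
  } else {
    crossed <- which(abs(trace$A - trace$A[1]) >= window_frac * total)
    t_end <- min(if (length(crossed)) trace$t[crossed[1]] else max(trace$t),
                 window_max_s)
  }
  win <- trace[trace$t <= t_end, , drop = FALSE]
  if (nrow(win) < 5L)
    stop("initial-velocity window contains fewer than 5 points")
  slope <- unname(stats::coef(stats::lm(A ~ t, data = win))[2])
  flag <- NA_character_
  net <- trace$A[nrow(trace)] - trace$A[1]
  if (net != 0 && slope != 0 && sign(slope) != sign(net))
    flag <- "non-monotone early segment"
  v_uM_s <- -slope / (d_eps340 * path) * 1e6
  data.frame(S = NA_real_, I = NA_real_, E0 = E0,
             v = v_uM_s / E0, v_uM_s = v_uM_s, unit = "s-1",
             flag = flag, stringsAsFactors = FALSE)
}

#' Fit the Michaelis-Menten equation to one substrate's velocity records
#'
#' @param records Data frame with columns \code{S} (uM) and \code{v} (s^-1
#'   turnover); at least 5 distinct substrate levels.
#' @return A list of class \code{michaelis_fit}: \code{params}
#'   (\code{\link{michaelis_params}}), \code{fit} (\code{fit_result}),
#'   \code{kcat_over_Km} and \code{kcat_over_Km_stderr} (M^-1 s^-1, error by
#'   first-order quadrature), and \code{flags} (saturation warning when
#'   \code{max(S)} is below the fitted Km).
#' @export
fit_michaelis_dataset <- function(records) {
  records <- as.data.frame(records)
  if (!all(c("S", "v") %in% names(records)))
    stop("records must contain columns S and v")
  if (length(unique(records$S)) < 5L)
    stop("under-determined: need >= 5 distinct substrate concentrations")
  fit <- fit_nls("michaelis", records[, c("S", "v")])
  kcat <- fit$params[["kcat"]]; Km <- fit$params[["Km"]]
  eff <- kcat / Km * 1e6  # s^-1 / uM -> M^-1 s^-1
  se <- fit$stderr
  eff_se <- if (all(is.finite(se))) {
    rel <- sqrt((se[["kcat"]] / kcat)^2 + (se[["Km"]] / Km)^2)
    eff * rel
  } else NA_real_
  flags <- character()
  if (max(records$S) < Km)
    flags <- c(flags, "saturation: max substrate below fitted Km")
  structure(list(params = michaelis_params(kcat, Km), fit = fit,
                 kcat_over_Km = eff, kcat_over_Km_stderr = eff_se,
                 flags = flags),
            class = "michaelis_fit")
}

#' Global fit of the competitive-inhibition rate law
#'
#' Fits \eqn{v = k_{cat}S/(K_m(1+I/K_i)+S)} simultaneously across all
#' (substrate, inhibitor) records.
#'
#' @param records Data frame with columns \code{S}, \code{I} (uM) and
#'   \code{v}; must span at least two inhibitor levels including \code{I = 0}.
#' @return A list of class \code{michaelis_fit} with \code{params} carrying
#'   \code{Ki}.
#' @export
fit_competitive_inhibition <- function(records) {
  records <- as.data.frame(records)
  if (!all(c("S", "I", "v") %in% names(records)))
    stop("records must contain columns S, I and v")
  ilv <- unique(records$I)
  if (length(ilv) < 2L)
    stop("Ki unidentifiable: need >= 2 inhibitor levels")
  if (!any(ilv == 0))
    stop("need an uninhibited (I = 0) series to anchor Km")
  fit <- fit_nls("michaelis_inhibition", records[, c("S", "I", "v")])
  kcat <- fit$params[["kcat"]]; Km <- fit$params[["Km"]]
  Ki <- fit$params[["Ki"]]
  eff <- kcat / Km * 1e6
  se <- fit$stderr
  eff_se <- if (all(is.finite(se[c("kcat", "Km")]))) {
    eff * sqrt((se[["kcat"]] / kcat)^2 + (se[["Km"]] / Km)^2)
  } else NA_real_
  structure(list(params = michaelis_params(kcat, Km, Ki), fit = fit,
                 kcat_over_Km = eff, kcat_over_Km_stderr = eff_se,
                 flags = character()),
            class = "michaelis_fit")
}

#' @export
print.michaelis_fit <- function(x, ...) {
  p <- x$params
  cat(sprintf("kcat = %.4g s^-1, Km = %.4g uM", p$kcat, p$Km))
  if (!is.null(p$Ki)) cat(sprintf(", Ki = %.4g uM", p$Ki))
  cat(sprintf("\nkcat/Km = %.4g M^-1 s^-1\n", x$kcat_over_Km))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Fold change between two positive quantities
#'
#' @param a Numerator.
#' @param b Denominator; must be positive.
#' @return \code{a / b}.
#' @export
#' @examples
#' fold_change(170, 0.34)  # 500
fold_change <- function(a, b) {
  stopifnot(is.finite(a), is.finite(b))
  if (b <= 0) stop("denominator must be > 0")
  a / b
}

#' Fit the bell-shaped pH-rate profile
#'
#' Fits velocity (not log velocity) against pH with the two-pKa bell model
#' (see \code{\link{ph_bell}}). A limb whose pKa falls outside the measured
#' pH range is flagged as extrapolated.
#'
#' @param points Data frame with columns \code{pH} and \code{v}; at least 6
#'   points.
#' @param log_scale Fit on the log-velocity scale instead (default FALSE).
#' @return A list of class \code{ph_fit}: \code{params}
#'   (\code{\link{ph_bell_params}}), \code{fit}, \code{pH_opt} (pH of maximal
#'   activity, the pKa midpoint) and \code{flags}.
#' @export
fit_ph_profile <- function(points, log_scale = FALSE) {
  points <- as.data.frame(points)
  if (!all(c("pH", "v") %in% names(points)) && ncol(points) == 2L)
    names(points) <- c("pH", "v")
  if (nrow(points) < 6L) stop("need >= 6 pH points spanning both limbs")
  dat <- points[, c("pH", "v")]
  if (log_scale) {
    if (any(dat$v <= 0)) stop("log-scale fit requires positive velocities")
    # fit log10 v with the bell evaluated inside the log
    resp <- log10(dat$v)
    fit <- fit_nls_log_bell(dat$pH, resp)
  } else {
    fit <- fit_nls("ph_bell", dat)
  }
  pkl <- fit$params[["pKa_low"]]; pkh <- fit$params[["pKa_high"]]
  flags <- fit$flags
  if (pkl > pkh) {
    # canonical ordering: re-run from the swapped start
    fit <- fit_nls("ph_bell", dat,
                   init = c(pKa_low = pkh, pKa_high = pkl))
    pkl <- fit$params[["pKa_low"]]; pkh <- fit$params[["pKa_high"]]
    flags <- c(flags, "limbs reordered to canonical pKa_low < pKa_high")
  }
  if (pkl < min(dat$pH)) flags <- c(flags, "pKa_low extrapolated below data")
  if (pkh > max(dat$pH)) flags <- c(flags, "pKa_high extrapolated above data")
  structure(list(params = ph_bell_params(fit$params[["Y_H"]], pkl, pkh),
                 fit = fit, pH_opt = (pkl + pkh) / 2, flags = flags),
            class = "ph_fit")
}

# log-scale variant: same parameters, response log10(v)
fit_nls_log_bell <- function(pH, log10v) {
  d <- data.frame(pH = pH, v = 10^log10v)
  start <- fit_nls("ph_bell", d)$params  # linear-scale fit seeds the log fit
  resid_fn <- function(par) {
    H <- 10^(-d$pH)
    yhat <- par[["Y_H"]] / (1 + H / 10^(-par[["pKa_low"]]) +
                              10^(-par[["pKa_high"]]) / H)
    log10(pmax(yhat, .Machine$double.xmin)) - log10v
  }
  lm_fit <- minpack.lm::nls.lm(
    par = start, lower = c(Y_H = 1e-12, pKa_low = 0, pKa_high = 0),
    fn = resid_fn,
    control = minpack.lm::nls.lm.control(ftol = 1e-10, ptol = 1e-10,
                                         maxiter = 500))
  params <- lm_fit$par; names(params) <- names(start)
  rss <- sum(resid_fn(params)^2)
  tss <- sum((log10v - mean(log10v))^2)
  new_fit_result("ph_bell_log", params,
                 stats::setNames(rep(NA_real_, 3), names(start)),
                 rss, if (tss > 0) 1 - rss / tss else NA_real_,
                 length(log10v), lm_fit$info %in% 1:4, lm_fit$niter, start)
}

#' @export
print.ph_fit <- function(x, ...) {
  p <- x$params
  cat(sprintf("pKa_low = %.3g, pKa_high = %.3g, Y_H = %.4g (pH_opt %.3g)\n",
              p$pKa_low, p$pKa_high, p$Y_H, x$pH_opt))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Residual-activity summary of a thermostability series
#'
#' Normalizes residual velocities to the lowest-temperature reference and
#' flags a pronounced decline: residual activity below 0.4 (more than 60\%
#' activity loss) at or above 25 degrees C.
#'
#' @param points Data frame with columns \code{temperature} (deg C) and
#'   \code{v} (residual velocity, any consistent unit).
#' @return Data frame with \code{temperature}, \code{v}, \code{fraction}
#'   (of the reference), plus attributes \code{reference_temperature} and
#'   \code{decline} (logical).
#' @export
thermostability_summary <- function(points) {
  points <- as.data.frame(points)
  if (!all(c("temperature", "v") %in% names(points)) && ncol(points) == 2L)
    names(points) <- c("temperature", "v")
  if (!nrow(points)) stop("empty thermostability input")
  points <- points[order(points$temperature), , drop = FALSE]
  ref <- points$v[1]
  if (!is.finite(ref) || ref <= 0)
    stop("reference (lowest-temperature) activity missing or non-positive")
  points$fraction <- points$v / ref
  decline <- any(points$temperature >= 25 & points$fraction < 0.4)
  attr(points, "reference_temperature") <- points$temperature[1]
  attr(points, "decline") <- decline
  points
}
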