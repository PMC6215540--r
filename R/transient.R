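# Stopped-flow transient analysis: exponential fitting of flavin reduction
# and reoxidation traces, hyperbolic k_obs vs [NADPH], linear k_obs vs [O2],
# and the kinetic isotope effect.

#' Stopped-flow absorbance trace container
#'
#' @param t Time (s), strictly increasing, starting at or after 0.
#' @param A Absorbance (AU), same length as \code{t}.
#' @param wavelength Monitoring wavelength (nm).
#' @param path Path length (cm), default 1.
#' @param meta Named list of post-mix metadata (concentrations in uM are half
#'   the syringe concentrations): typically \code{E0_uM}, \code{NADPH_uM},
#'   \code{NADP_uM}, \code{O2_mM}, \code{ketone_uM}.
#' @return An object of class \code{absorbance_trace} with element
#'   \code{samples} (data frame \code{t}, \code{A}).
#' @export
absorbance_trace <- function(t, A, wavelength, path = 1, meta = list()) {
  stopifnot(length(t) == length(A), all(is.finite(t)), all(is.finite(A)))
  if (t[1] < 0) stop("time must start at or after 0")
  if (any(diff(t) <= 0)) stop("time must be strictly increasing")
  structure(list(samples = data.frame(t = t, A = A),
                 wavelength = wavelength, path = path, meta = meta),
            class = "absorbance_trace")
}

#' @export
print.absorbance_trace <- function(x, ...) {
  cat(sprintf("absorbance trace: %d points, %g-%g s at %g nm (path %g cm)\n",
              nrow(x$samples), min(x$samples$t), max(x$samples$t),
              x$wavelength, x$path))
  invisible(x)
}

#' Pseudo-first-order condition check
#'
#' The bimolecular reduction step behaves as a single exponential only when
#' the coenzyme is in large excess over the enzyme; the working criterion is
#' at least sevenfold.
#'
#' @param E0 Enzyme concentration (uM), positive.
#' @param S0 Excess-reagent concentration (uM).
#' @return List with \code{pass} (logical, \code{S0/E0 >= 7}) and
#'   \code{ratio}.
#' @export
pseudo_first_order_check <- function(E0, S0) {
  if (E0 <= 0) stop("E0 must be > 0")
  ratio <- S0 / E0
  list(pass = ratio >= 7, ratio = ratio)
}

#' Fit a flavin-reduction trace with a single exponential
#'
#' Truncates to \code{t_max} (stopped-flow acquisition window for reduction),
#' fits one phase, and reports the rate as \code{kobs}. If the trace metadata
#' carry \code{E0_uM} and \code{NADPH_uM}, the pseudo-first-order guard is
#' evaluated; a violation attaches a warning flag but the fit is still
#' returned.
#'
#' @param trace An \code{\link{absorbance_trace}} (typically 443 nm) or a
#'   data frame with columns \code{t}, \code{A}.
#' @param t_max Fit window in seconds (default 1, the reduction acquisition
#'   window); \code{Inf} to use the full trace.
#' @return A list of class \code{reduction_fit}: \code{kobs}, \code{kobs_stderr},
#'   \code{phases} (\code{\link{exponential_phases}}), \code{fit}
#'   (\code{fit_result}) and \code{flags}.
#' @export
fit_reduction_trace <- function(trace, t_max = 1) {
  flags <- character()
  if (inherits(trace, "absorbance_trace")) {
    m <- trace$meta
    if (!is.null(m$E0_uM) && !is.null(m$NADPH_uM)) {
      chk <- pseudo_first_order_check(m$E0_uM, m$NADPH_uM)
      if (!chk$pass)
        flags <- c(flags, sprintf(
          "pseudo-first-order guard violated: [NADPH]/[E] = %.2f < 7",
          chk$ratio))
    }
    samples <- trace$samples
  } else {
    samples <- as.data.frame(trace)
    if (!all(c("t", "A") %in% names(samples)) && ncol(samples) == 2L)
      names(samples) <- c("t", "A")
  }
  samples <- samples[samples$t <= t_max, , drop = FALSE]
  fit <- fit_nls("exp1", samples)
  amp <- fit$params[["a1"]]
  signal <- diff(range(samples$A))
  if (abs(amp) < 1e-3 * max(signal, abs(mean(samples$A)), .Machine$double.eps))
    flags <- c(flags, "degenerate: near-zero amplitude")
  structure(list(kobs = fit$params[["k1"]],
                 kobs_stderr = fit$stderr[["k1"]],
                 phases = exponential_phases(amp, fit$params[["k1"]],
                                             fit$params[["offset"]]),
                 fit = fit, flags = c(flags, fit$flags)),
            class = "reduction_fit")
}

#' Fit a flavin-reoxidation trace
#'
#' Reoxidation at 440 nm is biphasic without substrate and monophasic with
#' substrate. By default the phase count is auto-selected by AICc
#' (\code{\link{select_exponential_phases}}); it can be forced.
#'
#' @param trace An \code{\link{absorbance_trace}} or data frame \code{t},
#'   \code{A}.
#' @param n_phases 1, 2 or \code{NULL} (auto-select).
#' @param t_max Fit window in seconds (default 75, the reoxidation
#'   acquisition window).
#' @return A list of class \code{reoxidation_fit}: \code{phases}
#'   (\code{\link{exponential_phases}}, rates sorted fast to slow),
#'   \code{n_phases}, \code{fit}, \code{selection} (when auto-selected) and
#'   \code{flags}.
#' @export
fit_reoxidation_trace <- function(trace, n_phases = NULL, t_max = 75) {
  samples <- if (inherits(trace, "absorbance_trace")) trace$samples
             else as.data.frame(trace)
  if (!all(c("t", "A") %in% names(samples)) && ncol(samples) == 2L)
    names(samples) <- c("t", "A")
  samples <- samples[samples$t <= t_max, , drop = FALSE]
  selection <- NULL
  if (is.null(n_phases)) {
    selection <- select_exponential_phases(samples)
    n_phases <- selection$chosen
    fit <- selection$fits[[as.character(n_phases)]]
    flags <- selection$flags
  } else {
    stopifnot(n_phases %in% 1:2)
    fit <- if (n_phases == 1L) fit_nls("exp1", samples)
           else .fit_exp2_robust(samples)
    flags <- fit$flags
  }
  phases <- if (n_phases == 1L)
    exponential_phases(fit$params[["a1"]], fit$params[["k1"]],
                       fit$params[["offset"]])
  else
    exponential_phases(c(fit$params[["a1"]], fit$params[["a2"]]),
                       c(fit$params[["k1"]], fit$params[["k2"]]),
                       fit$params[["offset"]])
  structure(list(phases = phases, n_phases = n_phases, fit = fit,
                 selection = selection, flags = flags),
            class = "reoxidation_fit")
}

#' Hyperbolic fit of observed reduction rates versus coenzyme concentration
#'
#' Recovers the limiting rate constant of flavin reduction and the apparent
#' coenzyme dissociation constant. A concentration-independent profile (the
#' tight-binding regime, where the enzyme is saturated at every accessible
#' concentration) makes the hyperbola unidentifiable; the limiting rate is
#' then reported alone with an explicit flag.
#'
#' @param points Data frame with columns \code{S} ([NADPH], uM) and
#'   \code{kobs} (s^-1); at least 4 concentrations.
#' @return A list of class \code{hyperbolic_fit}: \code{params}
#'   (\code{\link{hyperbolic_reduction_params}} or \code{NULL} when
#'   unidentifiable), \code{kred}, \code{Kd}, their standard errors,
#'   \code{fit} and \code{flags}.
#' @export
fit_kobs_vs_nadph <- function(points) {
  points <- as.data.frame(points)
  if (!all(c("S", "kobs") %in% names(points)) && ncol(points) == 2L)
    names(points) <- c("S", "kobs")
  if (length(unique(points$S)) < 4L)
    stop("under-determined: need >= 4 NADPH concentrations spanning Kd")
  spread <- diff(range(points$kobs))
  if (spread <= 1e-6 * max(abs(points$kobs))) {
    kred <- mean(points$kobs)
    return(structure(list(
      params = NULL, kred = kred, Kd = NA_real_,
      kred_stderr = stats::sd(points$kobs) / sqrt(nrow(points)),
      Kd_stderr = NA_real_, fit = NULL,
      flags = "saturated regime: kobs independent of [NADPH]; Kd unidentifiable"),
      class = "hyperbolic_fit"))
  }
  fit <- fit_nls("hyperbolic", points[, c("S", "kobs")])
  structure(list(
    params = hyperbolic_reduction_params(fit$params[["kred"]],
                                         fit$params[["Kd"]]),
    kred = fit$params[["kred"]], Kd = fit$params[["Kd"]],
    kred_stderr = fit$stderr[["kred"]], Kd_stderr = fit$stderr[["Kd"]],
    fit = fit, flags = fit$flags),
    class = "hyperbolic_fit")
}

#' @export
print.hyperbolic_fit <- function(x, ...) {
  cat(sprintf("kred = %.4g s^-1, Kd(NADPH) = %.4g uM\n", x$kred, x$Kd))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Linear fit of observed peroxyflavin-formation rates versus oxygen
#'
#' The slope is the bimolecular rate constant for the reaction of the
#' reduced flavin with O2 (mM^-1 s^-1 when O2 is supplied in mM); the
#' intercept is the O2-independent background rate.
#'
#' @param points Data frame with columns \code{O2} (mM) and \code{kobs}
#'   (s^-1); at least 3 distinct O2 levels.
#' @return A list of class \code{oxygen_fit}: \code{slope} (mM^-1 s^-1),
#'   \code{intercept} (s^-1), their standard errors and \code{fit}.
#' @export
fit_kobs_vs_oxygen <- function(points) {
  points <- as.data.frame(points)
  if (!all(c("O2", "kobs") %in% names(points)) && ncol(points) == 2L)
    names(points) <- c("O2", "kobs")
  if (length(unique(points$O2)) < 3L)
    stop("need >= 3 distinct O2 concentrations")
  fit <- fit_nls("linear", data.frame(x = points$O2, y = points$kobs))
  structure(list(slope = fit$params[["slope"]],
                 intercept = fit$params[["intercept"]],
                 slope_stderr = fit$stderr[["slope"]],
                 intercept_stderr = fit$stderr[["intercept"]],
                 fit = fit),
            class = "oxygen_fit")
}

#' Kinetic isotope effect from protiated and deuterated reduction fits
#'
#' Ratio of the fitted observed rate constants for reduction by NADPH versus
#' the 4R-deuterated coenzyme, with first-order error propagation.
#'
#' @param fit_H,fit_D Converged single-phase fits
#'   (\code{\link{fit_reduction_trace}} results or \code{fit_result}s of the
#'   \code{exp1} model).
#' @return Named numeric \code{c(kie, stderr)}.
#' @export
compute_kie <- function(fit_H, fit_D) {
  get_k <- function(f, lab) {
    if (inherits(f, "reduction_fit")) {
      if (!isTRUE(f$fit$converged)) stop(lab, " fit did not converge")
      c(f$kobs, f$kobs_stderr)
    } else if (inherits(f, "fit_result")) {
      if (!isTRUE(f$converged)) stop(lab, " fit did not converge")
      if (!"k1" %in% names(f$params) || "k2" %in% names(f$params))
        stop(lab, " fit must be single-phase")
      c(f$params[["k1"]], f$stderr[["k1"]])
    } else stop(lab, " must be a reduction_fit or fit_result")
  }
  h <- get_k(fit_H, "protiated"); d <- get_k(fit_D, "deuterated")
  r <- ratio_with_uncertainty(h[1], ifelse(is.finite(h[2]), h[2], 0),
                              d[1], ifelse(is.finite(d[2]), d[2], 0))
  c(kie = unname(r[["ratio"]]), stderr = unname(r[["stderr"]]))
}
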