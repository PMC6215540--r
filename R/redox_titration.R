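# Dye-equilibration redox potentiometry (Massey method), NADP+ binding
# titration analysis, and the SDS-release extinction-coefficient
# determination.
#
# In the Massey experiment, enzyme and a reference dye of known midpoint
# potential are reduced together slowly enough that the two couples stay at
# a common solution potential. Enzyme fractions are read at the dye's
# isosbestic wavelength (458 nm) and dye fractions at 610 nm where the
# flavin does not absorb; the enzyme midpoint potential then follows from
# the intercept of the log-log Nernst regression.

#' Extract oxidized/reduced concentrations from a two-wavelength redox series
#'
#' Linear interpolation between fully-oxidized and fully-reduced endpoint
#' absorbances converts A458 into enzyme fractions and A610 into dye
#' fractions. Points where either couple is less than 10\% or more than 90\%
#' reduced are retained but flagged unusable for the Nernst regression: the
#' log-ratios diverge at the endpoints.
#'
#' @param series Data frame with columns \code{A458} and \code{A610}
#'   (an optional \code{t} column is carried through).
#' @param cal Calibration list: \code{A458_ox}, \code{A458_red},
#'   \code{A610_ox}, \code{A610_red} (endpoint absorbances), \code{E_total}
#'   and \code{D_total} (uM).
#' @param window Usable reduced-fraction window, default \code{c(0.1, 0.9)}.
#' @return A data frame of class \code{redox_series}: \code{E_ox},
#'   \code{E_red}, \code{D_ox}, \code{D_red} (uM) and \code{usable}
#'   (logical).
#' @export
extract_redox_fractions <- function(series, cal, window = c(0.1, 0.9)) {
  series <- as.data.frame(series)
  need_cal <- c("A458_ox", "A458_red", "A610_ox", "A610_red",
                "E_total", "D_total")
  if (!all(need_cal %in% names(cal)))
    stop("calibration must provide: ", paste(need_cal, collapse = ", "))
  if (!all(c("A458", "A610") %in% names(series)))
    stop("series must contain columns A458 and A610")
  if (cal$A458_ox == cal$A458_red)
    stop("calibration error: equal endpoints at 458 nm")
  if (cal$A610_ox == cal$A610_red)
    stop("calibration error: equal endpoints at 610 nm")
  f_e <- (series$A458 - cal$A458_ox) / (cal$A458_red - cal$A458_ox)
  f_d <- (series$A610 - cal$A610_ox) / (cal$A610_red - cal$A610_ox)
  f_e <- pmin(pmax(f_e, 0), 1)
  f_d <- pmin(pmax(f_d, 0), 1)
  out <- data.frame(E_ox = (1 - f_e) * cal$E_total,
                    E_red = f_e * cal$E_total,
                    D_ox = (1 - f_d) * cal$D_total,
                    D_red = f_d * cal$D_total)
  if ("t" %in% names(series)) out <- cbind(t = series$t, out)
  out$usable <- f_e >= window[1] & f_e <= window[2] &
                f_d >= window[1] & f_d <= window[2]
  class(out) <- c("redox_series", class(out))
  out
}

#' Nernst regression for the enzyme midpoint potential
#'
#' Ordinary least squares of \eqn{\log_{10}(E_{red}/E_{ox})} on
#' \eqn{\log_{10}(D_{red}/D_{ox})} over the usable points. The slope
#' estimates \eqn{n_e/n_d}; the enzyme midpoint potential follows from the
#' intercept:
#' \deqn{E^\circ_e = E^\circ_d + \frac{0.0592 \cdot 1000}{n_e}\,b_0 \quad (mV)}
#'
#' @param series A \code{redox_series} (from
#'   \code{\link{extract_redox_fractions}}) or a data frame with columns
#'   \code{E_ox}, \code{E_red}, \code{D_ox}, \code{D_red} and optionally
#'   \code{usable}.
#' @param E0_dye_mV Dye midpoint potential (mV); default indigo disulfonate
#'   at pH 7.0.
#' @param nd Dye electron count (default 2).
#' @param ne Assumed enzyme electron count used to convert the intercept
#'   (default 2 for a two-electron flavin couple).
#' @param nernst_slope_V Decadic Nernst slope (V), default 0.0592 at 25 C.
#' @return A list of class \code{redox_fit}: \code{slope}, \code{intercept}
#'   (with standard errors), \code{E0_enzyme_mV}, \code{ne}, \code{nd},
#'   \code{E0_dye_mV}, \code{n_used} and \code{fit}.
#' @export
nernst_fit <- function(series, E0_dye_mV = optical_constants()$em_dye_mV,
                       nd = 2, ne = 2,
                       nernst_slope_V = optical_constants()$nernst_slope_V) {
  series <- as.data.frame(series)
  need <- c("E_ox", "E_red", "D_ox", "D_red")
  if (!all(need %in% names(series)))
    stop("series must contain columns: ", paste(need, collapse = ", "))
  keep <- if ("usable" %in% names(series)) series$usable else
    rep(TRUE, nrow(series))
  nonzero <- series$E_ox > 0 & series$E_red > 0 &
             series$D_ox > 0 & series$D_red > 0
  dropped <- sum(keep & !nonzero)
  if (dropped)
    message(dropped, " point(s) with a zero concentration excluded from the ",
            "Nernst fit")
  keep <- keep & nonzero
  if (sum(keep) < 4L) stop("need >= 4 usable points for the Nernst fit")
  x <- log10(series$D_red[keep] / series$D_ox[keep])
  y <- log10(series$E_red[keep] / series$E_ox[keep])
  fit <- fit_nls("linear", data.frame(x = x, y = y))
  intercept <- fit$params[["intercept"]]
  E0_enzyme <- E0_dye_mV + (nernst_slope_V * 1000 / ne) * intercept
  structure(list(slope = fit$params[["slope"]],
                 slope_stderr = fit$stderr[["slope"]],
                 intercept = intercept,
                 intercept_stderr = fit$stderr[["intercept"]],
                 E0_enzyme_mV = E0_enzyme, ne = ne, nd = nd,
                 E0_dye_mV = E0_dye_mV, n_used = sum(keep), fit = fit),
            class = "redox_fit")
}

#' @export
print.redox_fit <- function(x, ...) {
  cat(sprintf(
    "Nernst regression (n = %d): slope %.4g, intercept %.4g\n",
    x$n_used, x$slope, x$intercept))
  cat(sprintf("E0(enzyme) = %.4g mV vs E0(dye) = %g mV (ne = %g, nd = %g)\n",
              x$E0_enzyme_mV, x$E0_dye_mV, x$ne, x$nd))
  invisible(x)
}

#' Fit the quadratic tight-binding isotherm to a ligand titration
#'
#' Fits \code{dA_max} and \code{Kd} with the total enzyme concentration held
#' fixed at its known value (it is a measured quantity, not a free
#' parameter).
#'
#' @param series Data frame with columns \code{L0} (uM) and \code{dA} (AU).
#' @param E0 Total enzyme concentration (uM), known and fixed.
#' @return A list of class \code{titration_fit}: \code{params}
#'   (\code{\link{binding_isotherm_params}}), \code{Kd}, \code{Kd_stderr},
#'   \code{dA_max}, \code{dA_max_stderr}, \code{fit} and \code{flags}
#'   (saturation warning when \code{max(L0) < E0}; unidentifiability when
#'   the signal is flat).
#' @export
fit_binding_titration <- function(series, E0) {
  series <- as.data.frame(series)
  if (!all(c("L0", "dA") %in% names(series)) && ncol(series) == 2L)
    names(series) <- c("L0", "dA")
  if (length(unique(series$L0)) < 5L)
    stop("need >= 5 ligand concentrations")
  if (E0 <= 0) stop("E0 must be > 0")
  flags <- character()
  if (max(series$L0) < E0)
    flags <- c(flags, "saturation: max ligand below enzyme concentration")
  if (all(series$dA == 0)) {
    return(structure(list(params = NULL, Kd = NA_real_, Kd_stderr = NA_real_,
                          dA_max = 0, dA_max_stderr = NA_real_, fit = NULL,
                          flags = c(flags,
                                    "no signal: dA_max ~ 0, Kd unidentifiable")),
                     class = "titration_fit"))
  }
  fit <- fit_nls("isotherm", series[, c("L0", "dA")], fixed = list(E0 = E0))
  structure(list(
    params = binding_isotherm_params(fit$params[["dA_max"]], E0,
                                     max(fit$params[["Kd"]], 0)),
    Kd = fit$params[["Kd"]], Kd_stderr = fit$stderr[["Kd"]],
    dA_max = fit$params[["dA_max"]], dA_max_stderr = fit$stderr[["dA_max"]],
    fit = fit, flags = c(flags, fit$flags)),
    class = "titration_fit")
}

#' @export
print.titration_fit <- function(x, ...) {
  cat(sprintf("Kd = %.4g uM, dA_max = %.4g AU\n", x$Kd, x$dA_max))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Holoenzyme extinction coefficient from SDS-released flavin
#'
#' The FAD cofactor is released with SDS, its concentration read from the
#' free-FAD extinction coefficient at 450 nm, corrected back through the
#' dilution caused by the SDS addition, and divided into the holoenzyme
#' absorbance to give the bound-flavin extinction coefficient.
#'
#' @param A_holo Holoenzyme absorbance at 443 nm before SDS (AU).
#' @param A_released Free-FAD absorbance at 450 nm after SDS (AU).
#' @param dilution Dilution factor of the protein caused by the SDS addition
#'   (>= 1); e.g. 1.2 mL protein + 0.3 mL SDS gives 1.25.
#' @param eps_free Extinction coefficient of free FAD at 450 nm
#'   (M^-1 cm^-1), default 11300.
#' @param path Path length (cm), default 1.
#' @return Extinction coefficient of the holoenzyme flavin (M^-1 cm^-1).
#' @export
#' @examples
#' extinction_coefficient(0.135, 0.100, 1.25)  # ~12200 M^-1 cm^-1
extinction_coefficient <- function(A_holo, A_released, dilution,
                                   eps_free = optical_constants()$eps450_freeFAD,
                                   path = 1) {
  stopifnot(A_holo > 0, A_released > 0, eps_free > 0, path > 0)
  if (dilution < 1) stop("dilution factor must be >= 1")
  conc_released <- A_released / (eps_free * path)  # M, post-SDS
  conc_holo <- conc_released * dilution            # M, before dilution
  A_holo / (conc_holo * path)
}
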