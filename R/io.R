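# File formats and the closed-loop demo. Data travel as tidy comma-delimited
# text with unit-carrying headers (S_uM, t_s, A); results as JSON. The demo
# regenerates every benchmark quantity by a generator -> fit round trip and
# reports pass/fail against the recorded reference values.

.read_csv_checked <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("missing column(s) in ", basename(path), ": ",
         paste(missing_cols, collapse = ", "))
  for (col in required) {
    if (!is.numeric(df[[col]]))
      stop("non-numeric values in column ", col, " of ", basename(path))
    bad <- which(!is.finite(df[[col]]))
    if (length(bad))
      stop("non-finite value at row ", bad[1], ", column ", col,
           " of ", basename(path))
  }
  df
}

#' Read a steady-state velocity table
#'
#' Expects comma-delimited text with header
#' \code{substrate_id,S_uM,I_uM,E0_uM,v}; unit-carrying names are mapped to
#' the internal \code{S}, \code{I}, \code{E0}, \code{v} columns.
#'
#' @param path File path.
#' @return Data frame of velocity records.
#' @export
read_velocity_table <- function(path) {
  df <- .read_csv_checked(path, c("S_uM", "I_uM", "E0_uM", "v"))
  if (!"substrate_id" %in% names(df)) df$substrate_id <- "substrate"
  data.frame(substrate_id = as.character(df$substrate_id),
             S = df$S_uM, I = df$I_uM, E0 = df$E0_uM, v = df$v,
             stringsAsFactors = FALSE)
}

#' Write a steady-state velocity table
#'
#' @param records Data frame with columns \code{substrate_id}, \code{S},
#'   \code{I}, \code{E0}, \code{v}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_velocity_table <- function(records, path) {
  out <- data.frame(substrate_id = records$substrate_id, S_uM = records$S,
                    I_uM = records$I, E0_uM = records$E0, v = records$v)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a time-absorbance trace
#'
#' Expects comma-delimited text with header \code{t_s,A}. Time must be
#' strictly increasing; duplicated timestamps are rejected.
#'
#' @param path File path.
#' @param wavelength Wavelength to attach (nm), default NA.
#' @param meta Metadata list (e.g. from a JSON sidecar).
#' @return An \code{\link{absorbance_trace}}.
#' @export
read_trace <- function(path, wavelength = NA_real_, meta = list()) {
  df <- .read_csv_checked(path, c("t_s", "A"))
  if (any(duplicated(df$t_s)))
    stop("duplicated timestamps in ", basename(path))
  if (is.unsorted(df$t_s, strictly = TRUE))
    stop("non-monotone time column in ", basename(path))
  absorbance_trace(df$t_s, df$A, wavelength = wavelength, meta = meta)
}

#' Write a time-absorbance trace
#' @param trace An \code{\link{absorbance_trace}} or data frame \code{t},
#'   \code{A}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_trace <- function(trace, path) {
  s <- if (inherits(trace, "absorbance_trace")) trace$samples else
    as.data.frame(trace)
  utils::write.csv(data.frame(t_s = s$t, A = s$A), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a ligand titration (\code{L0_uM,dA})
#' @param path File path.
#' @return Data frame with columns \code{L0}, \code{dA}.
#' @export
read_titration <- function(path) {
  df <- .read_csv_checked(path, c("L0_uM", "dA"))
  data.frame(L0 = df$L0_uM, dA = df$dA)
}

#' Write an analysis report as JSON
#'
#' Numbers are written unrounded and unboxed so reports round-trip exactly.
#'
#' @param results A named list (nested lists/values are fine).
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_report <- function(results, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(results, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Closed-loop demonstration of the full pipeline
#'
#' Regenerates each benchmark quantity from scratch: synthetic inputs are
#' produced from the recorded wild-type constants, re-analyzed by the
#' corresponding fitting pipeline, and compared with the generating value.
#' Covers the kinetic isotope effect, the Michaelis-constant fold change for
#' acetone versus butanone, hyperbolic reduction kinetics, the Massey redox
#' regression, the pH bell, competitive NADP+ inhibition and the NADP+
#' binding isotherm.
#'
#' @param seed Integer seed used for every stochastic component (the default
#'   demo is noiseless, so the seed only enters the generators' noise
#'   streams).
#' @param out Optional path; when given, the report is written there as
#'   JSON.
#' @return A data frame of class \code{demo_report}: \code{quantity},
#'   \code{value}, \code{reference}, \code{rtol}, \code{pass}; attribute
#'   \code{all_pass}.
#' @export
run_demo <- function(seed = 1L, out = NULL) {
  seed <- as.integer(seed)
  rows <- list()
  add <- function(quantity, value, reference, rtol) {
    rows[[length(rows) + 1L]] <<- data.frame(
      quantity = quantity, value = value, reference = reference,
      rtol = rtol, pass = abs(value - reference) <= rtol * abs(reference))
  }

  # kinetic isotope effect from regenerated reduction traces
  tg <- seq(0, 1, by = 0.002)
  tr_H <- generate_exponential_trace(
    exponential_phases(0.112, 28.4, 0.01), tg,
    noise = noise_spec(0, seed))
  tr_D <- generate_exponential_trace(
    exponential_phases(0.112, 7.5, 0.01), tg,
    noise = noise_spec(0, seed + 1L))
  kie <- compute_kie(fit_reduction_trace(tr_H), fit_reduction_trace(tr_D))
  add("KIE (H/D flavin reduction)", round(kie[["kie"]], 1), 3.8, 1e-6)

  # Km fold change, acetone vs butanone
  add("Km fold change acetone/butanone", fold_change(170, 0.34), 500, 1e-9)

  # hyperbolic reduction kinetics
  hyp <- hyperbolic_reduction_params(59, 121)
  grid <- data.frame(S = c(25, 50, 100, 200, 400, 800, 1600))
  grid$kobs <- hyperbolic_kobs(grid$S, hyp)
  hf <- fit_kobs_vs_nadph(grid)
  add("kred (s^-1)", hf$kred, 59, 1e-4)
  add("Kd NADPH (uM)", hf$Kd, 121, 1e-4)

  # Massey redox regression
  ms <- generate_massey_series(-166, 2, 20, -116, 2, 20,
                               noise = noise_spec(0, seed))
  rs <- extract_redox_fractions(ms$series, ms$cal)
  nf <- nernst_fit(rs, E0_dye_mV = -116, nd = 2, ne = 2)
  add("Nernst slope", nf$slope, 1.0, 1e-4)
  add("E0 enzyme (mV)", nf$E0_enzyme_mV, -166, 1e-4)

  # pH bell
  pf <- fit_ph_profile(generate_ph_dataset(ph_bell_params(2.1, 5.6, 9.2),
                                           noise = noise_spec(0, seed)))
  add("pKa low", pf$params$pKa_low, 5.6, 1e-4)
  add("pKa high", pf$params$pKa_high, 9.2, 1e-4)

  # competitive NADP+ inhibition
  vr <- generate_velocity_dataset(
    michaelis_params(2.0, 6.7, 166),
    S_grid = c(0.2, 0.5, 1, 2, 5, 10, 25, 50, 100),
    I_grid = c(0, 250, 500, 1000), noise = noise_spec(0, seed))
  cf <- fit_competitive_inhibition(vr)
  add("Ki NADP+ (uM)", cf$params$Ki, 166, 1e-4)

  # NADP+ binding isotherm
  ti <- generate_titration(binding_isotherm_params(0.1, 50, 21.1),
                           noise = noise_spec(0, seed))
  bt <- fit_binding_titration(ti, E0 = 50)
  add("Kd NADP+ (uM)", bt$Kd, 21.1, 1e-4)

  report <- do.call(rbind, rows)
  attr(report, "all_pass") <- all(report$pass)
  attr(report, "seed") <- seed
  class(report) <- c("demo_report", class(report))
  if (!is.null(out)) {
    write_report(list(seed = seed,
                      results = lapply(seq_len(nrow(report)), function(i)
                        as.list(report[i, , drop = FALSE])),
                      all_pass = all(report$pass)), out)
  }
  report
}

#' @export
print.demo_report <- function(x, ...) {
  cat("Closed-loop pipeline demo (seed", attr(x, "seed"), ")\n")
  print.data.frame(x, digits = 6, row.names = FALSE)
  cat(if (isTRUE(attr(x, "all_pass"))) "all benchmarks passed\n"
      else "SOME BENCHMARKS FAILED\n")
  invisible(x)
}
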