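# Independent oracles used to cross-check the fitting engine. These stay
# deliberately naive (brute force, closed forms) and never call fit_nls.

# dense grid search over a 2-parameter model; returns the lattice point with
# the lowest RSS and that RSS
grid_search_2p <- function(fn, data, y, grid1, grid2) {
  best <- list(par = c(NA, NA), rss = Inf)
  for (p1 in grid1) for (p2 in grid2) {
    rss <- sum((fn(data, c(p1, p2)) - y)^2)
    if (rss < best$rss) best <- list(par = c(p1, p2), rss = rss)
  }
  best
}

# closed-form ordinary least squares slope/intercept
ols_closed_form <- function(x, y) {
  sx <- sum(x); sy <- sum(y); n <- length(x)
  slope <- (n * sum(x * y) - sx * sy) / (n * sum(x^2) - sx^2)
  c(intercept = (sy - slope * sx) / n, slope = slope)
}

# first-order quadrature propagation for a ratio, written independently
quadrature_ratio <- function(a, sa, b, sb) {
  r <- a / b
  c(r, abs(r) * sqrt((sa / a)^2 + (sb / b)^2))
}

mm_curve <- function(d, par) par[1] * d$S / (par[2] + d$S)
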