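# Independent numerical oracles, kept deliberately separate from the
# package's integration code path.

# Trapezoid integration of the product of two tabulated curves, both
# piecewise-linearly interpolated onto a fine common grid.
oracle_weighted_integral <- function(wl_s, v_s, wl_a, v_a, dx = 0.1) {
  lo <- max(min(wl_s), min(wl_a))
  hi <- min(max(wl_s), max(wl_a))
  x <- seq(lo, hi, by = dx)
  f <- approx(wl_s, v_s, xout = x)$y * approx(wl_a, v_a, xout = x)$y
  sum((f[-1] + f[-length(f)]) / 2) * dx
}

# Brute-force piecewise-linear interpolation (no approx()), for checking
# spd_resample element by element.
oracle_linear_interp <- function(x, y, xout) {
  vapply(xout, function(x0) {
    if (x0 <= x[1]) return(y[1])
    if (x0 >= x[length(x)]) return(y[length(y)])
    i <- max(which(x <= x0))
    if (x[i] == x0) return(y[i])
    y[i] + (y[i + 1] - y[i]) * (x0 - x[i]) / (x[i + 1] - x[i])
  }, numeric(1))
}

# Scale-factor bisection until a logical indicator flips; returns the
# flip-point scale.
bisect_flip <- function(indicator, lo, hi, iters = 80) {
  stopifnot(!indicator(lo), indicator(hi))
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (indicator(mid)) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# A random polychromatic (blue/green/red primary) white-light LED mixture,
# the realistic multi-primary lab source. Each alpha-opic integral of such a
# mixture has non-negligible mass inside its function's main lobe, which is
# the regime in which 1-nm tabulated quadrature is well-conditioned.
random_white_led <- function() {
  gaussian_led_spd(list(
    c(runif(1, 440, 480), runif(1, 15, 40), runif(1, 0.2, 1.5)),
    c(runif(1, 500, 560), runif(1, 20, 50), runif(1, 0.2, 1.5)),
    c(runif(1, 580, 660), runif(1, 20, 50), runif(1, 0.2, 1.5))))
}

ref_functions <- load_reference_functions()
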