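# 15-point Gauss-Kronrod rule on [-1, 1] (symmetric half stored).
.gk15_x <- c(0.991455371120813, 0.949107912342759, 0.864864423359769,
             0.741531185599394, 0.586087235467691, 0.405845151377397,
             0.207784955007898, 0.000000000000000)
.gk15_w <- c(0.022935322010529, 0.063092092629979, 0.104790010322250,
             0.140653259715525, 0.169004726639267, 0.190350578064785,
             0.204432940075298, 0.209482141084728)

#' Fixed 15-point Gauss-Kronrod nodes on an interval
#'
#' @param a,b Interval end points, `a <= b`.
#' @return List with `nodes` and `weights` (length 15 each); the weights
#'   include the interval Jacobian so `sum(w * f(nodes))` approximates the
#'   integral of `f` over `[a, b]`.
#' @export
gk15 <- function(a, b) {
  stopifnot(b >= a)
  half <- (b - a) / 2
  mid <- (a + b) / 2
  x <- c(-rev(.gk15_x[1:7]), .gk15_x[8], .gk15_x[7:1])
  w <- c(rev(.gk15_w[1:7]), .gk15_w[8], .gk15_w[7:1])
  list(nodes = mid + half * x, weights = half * w)
}

# Adaptive integral of a vectorized integrand over [a, b], split first at the
# interior break points (kinks/jumps), each smooth piece handled by
# pracma::quadgk.
integrate_adaptive <- function(f, a, b, breaks = numeric(), tol = 1e-8) {
  stopifnot(b >= a)
  if (b == a) return(0)
  pts <- sort(unique(c(a, b, breaks[breaks > a & breaks < b])))
  total <- 0
  for (k in seq_len(length(pts) - 1L)) {
    lo <- pts[k]; hi <- pts[k + 1L]
    probe <- f(c(lo + 1e-12 * (hi - lo), (lo + hi) / 2, hi))
    if (any(!is.finite(probe)))
      stop(sprintf("nonfinite integrand on subinterval [%g, %g]", lo, hi))
    total <- total + pracma::quadgk(f, lo, hi, tol = tol)
  }
  total
}
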