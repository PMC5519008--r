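# Rational snapping via continued fractions.  Lumped-reaction coefficients are
# quotients of small-integer flux combinations, so snapping to p/q with a small
# denominator recovers the exact printed stoichiometry; the denominator caps
# (1e6 at load time, 48 for lumps) bound the search.

#' Best rational approximation with bounded denominator
#'
#' Continued-fraction approximation of `x` by `p/q` with `q <= max_den`
#' (including semiconvergents, so the result is the best such rational).
#'
#' @param x Numeric scalar.
#' @param max_den Largest admissible denominator.
#' @return `c(p, q)` with `p/q` the best approximation, as doubles.
#' @export
rational_approx <- function(x, max_den) {
  if (!is.finite(x)) stop("rational_approx() needs a finite value")
  s <- if (x < 0) -1 else 1
  x <- abs(x)
  p0 <- 0; q0 <- 1; p1 <- 1; q1 <- 0
  r <- x
  repeat {
    a <- floor(r)
    p2 <- a * p1 + p0
    q2 <- a * q1 + q0
    if (q2 > max_den) {
      # largest semiconvergent still inside the cap
      k <- floor((max_den - q0) / q1)
      ps <- k * p1 + p0
      qs <- k * q1 + q0
      cand <- rbind(c(p1, q1), c(ps, qs))
      err <- abs(cand[, 1] / cand[, 2] - x)
      best <- cand[which.min(err), ]
      return(c(s * best[1], best[2]))
    }
    if (abs(r - a) < 1e-12 * max(1, q2)) return(c(s * p2, q2))
    p0 <- p1; q0 <- q1; p1 <- p2; q1 <- q2
    r <- 1 / (r - a)
  }
}

#' Snap values to nearby small rationals
#'
#' Replaces each value by the best rational `p/q` with `q <= max_den` when that
#' rational lies within `tol` (absolute, relative to `max(1, |x|)`); values
#' with no such rational are returned unchanged.
#'
#' @param x Numeric vector.
#' @param max_den Denominator cap.
#' @param tol Acceptance tolerance.
#' @return Numeric vector of the same length.
#' @export
snap_rational <- function(x, max_den = 1e6, tol = 1e-6) {
  vapply(x, function(v) {
    if (!is.finite(v) || v == 0) return(v)
    pq <- rational_approx(v, max_den)
    r <- pq[1] / pq[2]
    if (abs(r - v) <= tol * max(1, abs(v))) r else v
  }, numeric(1))
}
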