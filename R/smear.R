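#' Gaussian resolution smearing of a scattering curve
#'
#' Replaces each intensity by the Gaussian-weighted average of the curve
#' over q', with the per-point 1-sigma width taken from the `dq` column
#' (or the `dq` argument). Fixed-point quadrature over +/- 3 sigma is
#' used; nodes falling outside the curve support (or at q' <= 0) are
#' dropped and the kernel renormalized, so a constant curve is exactly
#' preserved. Points with `dq = 0` are returned unchanged.
#'
#' @param curve A [sans_curve] (tabulated data, interpolated linearly) or
#'   a function `q -> I` (evaluated exactly at the quadrature nodes).
#' @param q Evaluation grid; defaults to `curve$q` for tabulated input
#'   (required for function input).
#' @param dq 1-sigma resolution width(s) (A^-1); defaults to the curve's
#'   `dq` column. Recycled to the grid length.
#' @param n_nodes Number of quadrature nodes spanning +/- 3 sigma.
#' @return For tabulated input, a [sans_curve] with smeared `i`;
#'   for function input, the numeric vector of smeared intensities.
#' @export
gaussian_smear <- function(curve, q = NULL, dq = NULL, n_nodes = 25) {
  if (is.function(curve)) {
    if (is.null(q) || is.null(dq)) {
      abort("function input needs explicit `q` and `dq`.")
    }
    f <- curve
    support <- c(0, Inf)
  } else {
    stopifnot(is.data.frame(curve))
    if (is.null(q)) q <- curve$q
    if (is.null(dq)) {
      dq <- if ("dq" %in% names(curve)) curve$dq else 0
    }
    f <- function(x) approx(curve$q, curve$i, xout = x, rule = 1)$y
    support <- range(curve$q)
  }
  dq <- rep_len(dq, length(q))
  if (any(dq < 0)) abort("dq must be >= 0.")
  u <- seq(-3, 3, length.out = n_nodes)
  w0 <- exp(-u^2 / 2)
  i_s <- vapply(seq_along(q), function(k) {
    if (dq[k] == 0) return(f(q[k]))
    qs <- q[k] + u * dq[k]
    ok <- qs > 0 & qs >= support[1] & qs <= support[2]
    vals <- f(qs[ok])
    keep <- ok
    keep[ok] <- !is.na(vals)
    sum(w0[keep] * vals[!is.na(vals)]) / sum(w0[keep])
  }, numeric(1))
  if (is.function(curve)) {
    return(i_s)
  }
  out <- curve
  out$i <- i_s
  out
}
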