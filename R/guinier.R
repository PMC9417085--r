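#' Guinier analysis of the low-q region
#'
#' Weighted linear fit of `ln I` versus `q^2` over a low-q window chosen
#' self-consistently: starting from the lowest-q points, the window is
#' iterated until all included points satisfy `q * R_g <= qrg_max` and
#' the fitted radius of gyration is stable to 1%. Returns
#' `R_g = sqrt(-3 slope)` and the forward scattering
#' `I(0) = exp(intercept)` with propagated standard errors.
#'
#' @param curve A [sans_curve] or data frame with `q`, `i` and optionally
#'   `di` (used as weights).
#' @param qrg_max Upper limit of the dimensionless `q R_g` window
#'   (default 1.3).
#' @param min_points Minimum number of points in the window.
#' @return A `guinier_fit` object; see `tidy()`/`glance()` methods.
#' @export
#' @examples
#' p <- geometry_params("sphere", radius = 30, sld_core = 3e-6,
#'   sld_solvent = 0)
#' crv <- form_factor_intensity(p, q = seq(0.005, 0.1, by = 0.001))
#' glance(guinier_fit(crv))$rg # ~ sqrt(3/5) * 30
guinier_fit <- function(curve, qrg_max = 1.3, min_points = 5) {
  stopifnot(is.data.frame(curve), all(c("q", "i") %in% names(curve)))
  dat <- as_tibble(curve)[, intersect(c("q", "i", "di"), names(curve))]
  dat <- dat[dat$i > 0, ]
  if (nrow(dat) < min_points) abort("not enough positive-intensity points.")
  # relative-error weights for ln I; unit weights when no di provided
  w_all <- if ("di" %in% names(dat) && any(dat$di > 0)) {
    (dat$i / pmax(dat$di, 1e-12 * dat$i))^2
  } else {
    rep(1, nrow(dat))
  }
  fit_window <- function(n_in) {
    idx <- seq_len(n_in)
    lm(log(i) ~ I(q^2), data = dat[idx, ], weights = w_all[idx])
  }
  n_in <- max(min_points, min(nrow(dat), 10L))
  rg_prev <- Inf
  fit <- NULL
  for (iter in 1:50) {
    fit <- fit_window(n_in)
    slope <- coef(fit)[[2]]
    if (slope > 0) {
      se_slope <- sqrt(diag(vcov(fit)))[[2]]
      if (slope > 2 * se_slope) {
        abort("positive low-q slope: no Guinier regime.")
      }
      slope <- 0
    }
    rg <- sqrt(-3 * slope)
    if (rg == 0) break
    n_new <- max(min_points, sum(dat$q * rg <= qrg_max))
    converged <- abs(rg - rg_prev) <= 0.01 * rg
    if (n_new == n_in && (converged || iter > 1)) break
    rg_prev <- rg
    n_in <- n_new
  }
  b <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  slope <- min(b[[2]], 0)
  rg <- sqrt(-3 * slope)
  rg_se <- if (rg > 0) 3 * se[[2]] / (2 * rg) else NA_real_
  i0 <- exp(b[[1]])
  structure(
    list(
      rg = rg, rg_se = rg_se, i0 = i0, i0_se = i0 * se[[1]],
      n_points = n_in, q_max = dat$q[n_in], qrg_max_used = dat$q[n_in] * rg,
      fit = fit, data = dat[seq_len(n_in), ]
    ),
    class = "guinier_fit"
  )
}

#' @export
print.guinier_fit <- function(x, ...) {
  cat(sprintf(
    "Guinier fit: R_g = %.3f +/- %.3f A, I(0) = %.4g +/- %.2g cm^-1 (%d pts, q R_g <= %.2f)\n",
    x$rg, x$rg_se, x$i0, x$i0_se, x$n_points, x$qrg_max_used
  ))
  invisible(x)
}

#' @export
tidy.guinier_fit <- function(x, ...) {
  tibble(
    term = c("rg", "i0"),
    estimate = c(x$rg, x$i0),
    std.error = c(x$rg_se, x$i0_se)
  )
}

#' @export
glance.guinier_fit <- function(x, ...) {
  tibble(
    rg = x$rg, rg_se = x$rg_se, i0 = x$i0, i0_se = x$i0_se,
    n_points = x$n_points, q_max = x$q_max, q_rg_max = x$qrg_max_used
  )
}
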