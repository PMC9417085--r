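#' Scattering-length density of an H2O/D2O mixture
#'
#' Ideal volume-fraction mixing between the pure-water endpoint SLDs
#' (see [water_sld_constants()]).
#'
#' @param f_h2o Volume fraction of H2O in the solvent, in `[0, 1]`.
#'   Vectorised.
#' @param sld_h2o,sld_d2o Endpoint SLDs (A^-2); default the package
#'   constants.
#' @return Solvent SLD (A^-2).
#' @export
#' @examples
#' solvent_sld(0.5725) # ~2.41e-6 A^-2
solvent_sld <- function(f_h2o,
                        sld_h2o = water_sld_constants()$sld_h2o,
                        sld_d2o = water_sld_constants()$sld_d2o) {
  if (!is.numeric(f_h2o) || any(is.na(f_h2o))) {
    abort("`f_h2o` must be numeric without NA.")
  }
  if (any(f_h2o < 0 | f_h2o > 1)) {
    abort("`f_h2o` must lie in [0, 1] (volume fraction of H2O).")
  }
  f_h2o * sld_h2o + (1 - f_h2o) * sld_d2o
}

#' Invert the solvent SLD to an H2O fraction
#'
#' @param sld Target solvent SLD (A^-2).
#' @inheritParams solvent_sld
#' @return `f_h2o` in `[0, 1]`, or `NA` if the SLD is outside the water
#'   range (with a warning).
#' @export
f_h2o_for_sld <- function(sld,
                          sld_h2o = water_sld_constants()$sld_h2o,
                          sld_d2o = water_sld_constants()$sld_d2o) {
  f <- (sld - sld_d2o) / (sld_h2o - sld_d2o)
  out_of_range <- f < 0 | f > 1
  if (any(out_of_range, na.rm = TRUE)) {
    warn("requested SLD outside the [H2O, D2O] range; f_h2o set to NA.")
    f[out_of_range] <- NA_real_
  }
  f
}

parse_sequence <- function(sequence, residue_table) {
  if (length(sequence) != 1L || !nzchar(sequence)) {
    abort("`sequence` must be a single non-empty string of one-letter codes.")
  }
  res <- strsplit(toupper(gsub("[[:space:]]", "", sequence)), "")[[1]]
  unknown <- which(!res %in% residue_table$residue)
  if (length(unknown)) {
    abort(sprintf(
      "unknown residue code(s) %s at position(s) %s.",
      paste(unique(res[unknown]), collapse = ", "),
      paste(unknown, collapse = ", ")
    ))
  }
  res
}

#' Neutron SLD of a protein from its sequence, with H/D exchange
#'
#' Sums residue coherent scattering lengths over the sequence and divides
#' by the summed residue volumes. Each labile hydrogen contributes a
#' scattering length interpolated between H and D according to
#' `exchange_fraction * f_d2o`: the fraction of labile sites that actually
#' carry a deuteron when the solvent is a D2O fraction `f_d2o` and a
#' fraction `exchange_fraction` of sites is accessible to exchange.
#'
#' @param sequence One-letter amino-acid string.
#' @param f_d2o Volume fraction of D2O in the solvent, `[0, 1]`.
#' @param exchange_fraction Fraction of labile hydrogens that exchange
#'   (default 0.90).
#' @param residue_table Residue table, default
#'   [residue_scattering_table()]; override to change volumes or
#'   compositions.
#' @return SLD (A^-2). 1 fm = 1e-5 A is applied internally.
#' @export
#' @examples
#' molecule_sld("GG", f_d2o = 1, exchange_fraction = 0.9)
molecule_sld <- function(sequence, f_d2o, exchange_fraction = 0.9,
                         residue_table = residue_scattering_table()) {
  validate_residue_table(residue_table)
  check_number(f_d2o, "f_d2o", 0, 1)
  check_number(exchange_fraction, "exchange_fraction", 0, 1)
  res <- parse_sequence(sequence, residue_table)
  idx <- match(res, residue_table$residue)
  bl <- atomic_scattering_lengths()
  d_minus_h <- bl[["D"]] - bl[["H"]]
  frac_d <- exchange_fraction * f_d2o
  b_total <- sum(residue_table$b_protonated[idx] +
    residue_table$n_exchangeable[idx] * frac_d * d_minus_h) # fm
  v_total <- sum(residue_table$volume[idx]) # A^3
  (b_total * 1e-5) / v_total
}

#' Theoretical contrast match point of a molecule
#'
#' Finds the solvent composition at which the molecule's SLD (including
#' H/D exchange, which makes the molecule SLD itself depend on the
#' solvent) equals the solvent SLD. Because the molecule SLD is affine in
#' `f_d2o` and the solvent SLD strictly decreasing in `f_h2o`, the
#' difference is strictly monotone and the root (if bracketed) unique.
#'
#' @inheritParams molecule_sld
#' @param molecule_sld_fn Optional function `f_d2o -> SLD` overriding the
#'   sequence-based calculation (e.g. a constant-SLD hypothetical
#'   molecule).
#' @return A tibble with `f_h2o`, `sld` (common SLD at match, A^-2) and
#'   `matched` (logical). When no crossing exists in `[0, 1]`, `matched`
#'   is `FALSE` and the endpoint SLD differences are reported in
#'   `delta_at_h2o` / `delta_at_d2o`.
#' @export
#' @examples
#' theoretical_match_point(molecule_sld_fn = function(f_d2o) 2.41e-6)
theoretical_match_point <- function(sequence = NULL, exchange_fraction = 0.9,
                                    residue_table = residue_scattering_table(),
                                    molecule_sld_fn = NULL) {
  if (is.null(molecule_sld_fn)) {
    if (is.null(sequence)) {
      abort("supply either `sequence` or `molecule_sld_fn`.")
    }
    molecule_sld_fn <- function(f_d2o) {
      molecule_sld(sequence, f_d2o,
        exchange_fraction = exchange_fraction,
        residue_table = residue_table
      )
    }
  }
  delta <- function(f_h2o) {
    molecule_sld_fn(1 - f_h2o) - solvent_sld(f_h2o)
  }
  d0 <- delta(0)
  d1 <- delta(1)
  if (abs(d0) < 1e-15 || abs(d1) < 1e-15) {
    f <- if (abs(d0) < 1e-15) 0 else 1
    return(tibble(
      f_h2o = f, sld = solvent_sld(f), matched = TRUE,
      delta_at_h2o = d1, delta_at_d2o = d0
    ))
  }
  if (sign(d0) == sign(d1)) {
    warn("no contrast match point in f_h2o within [0, 1].")
    return(tibble(
      f_h2o = NA_real_, sld = NA_real_, matched = FALSE,
      delta_at_h2o = d1, delta_at_d2o = d0
    ))
  }
  root <- uniroot(delta, c(0, 1), tol = 1e-12)
  tibble(
    f_h2o = root$root, sld = solvent_sld(root$root), matched = TRUE,
    delta_at_h2o = d1, delta_at_d2o = d0
  )
}

#' Experimental contrast match point from forward-scattering intensities
#'
#' Weighted linear fit of the signed square root of `I(0)` versus the H2O
#' fraction; the x-intercept estimates the match composition. Since
#' sqrt(I0) is unsigned, points beyond the crossing must flip sign to lie
#' on one line: the flip position (over the `f_h2o`-sorted points) is
#' chosen to minimise the weighted residual sum of squares.
#'
#' @param data Data frame with columns `f_h2o`, `i0` and optionally `di0`
#'   (1-sigma error on `I(0)`, used for weighting and error propagation).
#' @return A `matchpoint_fit` object; `tidy()` gives the line
#'   coefficients, `glance()` the intercept and its standard error.
#' @export
experimental_match_point <- function(data) {
  stopifnot(is.data.frame(data), all(c("f_h2o", "i0") %in% names(data)))
  data <- as_tibble(data)
  if (nrow(data) < 3) abort("need at least 3 contrast points.")
  if (any(data$i0 < 0)) abort("`i0` must be >= 0.")
  if (all(data$i0 == 0)) abort("all I(0) equal zero: degenerate fit.")
  if (length(unique(data$f_h2o)) < 2) {
    abort("need at least two distinct f_h2o values: degenerate fit.")
  }
  data <- dplyr::arrange(data, .data$f_h2o)
  y_abs <- sqrt(data$i0)
  # 1-sigma of sqrt(I0) by delta method; equal weights if no errors given
  if ("di0" %in% names(data) && all(data$di0 > 0) && any(data$i0 > 0)) {
    sy <- ifelse(data$i0 > 0, data$di0 / (2 * sqrt(data$i0)),
      max(data$di0)
    )
    w <- 1 / sy^2
  } else {
    w <- rep(1, nrow(data))
  }
  n <- nrow(data)
  best <- NULL
  for (k in 0:n) { # sign flips after position k
    s <- c(rep(1, k), rep(-1, n - k))
    fit <- lm(y ~ f, data = data.frame(y = s * y_abs, f = data$f_h2o),
      weights = w
    )
    rss <- sum(w * fit$residuals^2)
    if (is.null(best) || rss < best$rss - 1e-12) {
      best <- list(fit = fit, rss = rss, k = k, signs = s)
    }
  }
  fit <- best$fit
  b <- coef(fit)
  if (abs(b[[2]]) < .Machine$double.eps) {
    abort("zero slope: match point undefined (degenerate fit).")
  }
  x0 <- -b[[1]] / b[[2]]
  V <- suppressWarnings(vcov(fit))
  g <- c(-1 / b[[2]], b[[1]] / b[[2]]^2) # d x0 / d(b0, b1)
  se <- sqrt(drop(t(g) %*% V %*% g))
  structure(
    list(
      f_h2o = x0, se = se, fit = fit, flip_after = best$k,
      signs = best$signs,
      data = dplyr::mutate(data, sqrt_i0_signed = best$signs * y_abs)
    ),
    class = "matchpoint_fit"
  )
}

#' @export
print.matchpoint_fit <- function(x, ...) {
  cat(sprintf(
    "Contrast match point: f_H2O = %.4f +/- %.4f (SLD = %.3e A^-2)\n",
    x$f_h2o, x$se, solvent_sld(min(max(x$f_h2o, 0), 1))
  ))
  invisible(x)
}

#' @export
tidy.matchpoint_fit <- function(x, ...) {
  b <- coef(x$fit)
  se <- sqrt(diag(vcov(x$fit)))
  tibble(
    term = c("intercept", "slope"),
    estimate = unname(b), std.error = unname(se)
  )
}

#' @export
glance.matchpoint_fit <- function(x, ...) {
  tibble(
    f_h2o = x$f_h2o, std.error = x$se,
    sld = solvent_sld(min(max(x$f_h2o, 0), 1)),
    n = nrow(x$data), flip_after = x$flip_after
  )
}

#' Zero-average-contrast (ZAC) solvent for a two-component particle
#'
#' The solvent SLD at which the volume-weighted mean contrast of a
#' two-component particle vanishes:
#' `rho_s = (phi_a rho_a + phi_b rho_b) / (phi_a + phi_b)`.
#' When component A's SLD depends on the solvent composition through H/D
#' exchange, supply `sld_a` as a function of `f_h2o` and the condition is
#' solved self-consistently by 1-D root finding.
#'
#' @param sld_a SLD of component A (A^-2), a number or a function of
#'   `f_h2o`.
#' @param phi_a,phi_b Volumes or volume fractions of the two components
#'   (only their ratio matters); both must be >= 0 with `phi_a + phi_b > 0`.
#' @param sld_b SLD of component B (A^-2).
#' @return A tibble with `sld_solvent` (A^-2), `f_h2o` (NA with a warning
#'   when the required SLD is outside the pure-water range) and
#'   `attainable`.
#' @export
#' @examples
#' zac_solvent(2e-6, 1, 6e-6, 1) # arithmetic mean, 4e-6
zac_solvent <- function(sld_a, phi_a, sld_b, phi_b) {
  if (phi_a < 0 || phi_b < 0 || phi_a + phi_b <= 0) {
    abort("`phi_a`, `phi_b` must be >= 0 with a positive sum.")
  }
  mix <- function(ra) (phi_a * ra + phi_b * sld_b) / (phi_a + phi_b)
  if (is.function(sld_a)) {
    # solve solvent_sld(f) == mix(sld_a(f)) for f in [0, 1]
    delta <- function(f) solvent_sld(f) - mix(sld_a(f))
    d0 <- delta(0)
    d1 <- delta(1)
    if (sign(d0) == sign(d1) && abs(d0) > 1e-15 && abs(d1) > 1e-15) {
      warn("ZAC condition not attainable with water mixtures.")
      # report the unconstrained SLD at the closer endpoint
      f_star <- if (abs(d0) < abs(d1)) 0 else 1
      return(tibble(
        sld_solvent = mix(sld_a(f_star)), f_h2o = NA_real_,
        attainable = FALSE
      ))
    }
    root <- uniroot(delta, c(0, 1), tol = 1e-14)
    f <- root$root
    return(tibble(
      sld_solvent = solvent_sld(f), f_h2o = f, attainable = TRUE
    ))
  }
  rho_s <- mix(sld_a)
  f <- suppressWarnings(f_h2o_for_sld(rho_s))
  if (is.na(f)) {
    warn("ZAC solvent SLD lies outside the [H2O, D2O] range.")
  }
  tibble(sld_solvent = rho_s, f_h2o = f, attainable = !is.na(f))
}

#' Four-contrast scheme for a surfactant-protein SANS experiment
#'
#' Returns the per-contrast SLD bindings used in contrast-variation work
#' on a two-component complex: `protein` (surfactant matched to solvent),
#' `complex` (surfactant matched to protein), `surfactant` (protein
#' matched to solvent) and `zac` (zero-average contrast; solvent from
#' [zac_solvent()]). Defaults reproduce the hGH/SDS design: h-SDS in D2O,
#' protein-matched d-SDS, and the near-fully deuterated d-SDS for ZAC.
#'
#' @param sld_protein Named numeric vector of protein SLDs per contrast
#'   (A^-2); the ZAC entry is the protein SLD at the ZAC solvent
#'   composition.
#' @param sld_surfactant Named numeric vector of surfactant SLDs per
#'   contrast (A^-2).
#' @param sld_solvent Named numeric vector of solvent SLDs; the `zac`
#'   entry may be `NA` to be filled in from the ZAC condition by
#'   [cofit][sans_cofit()] callers via [zac_solvent()].
#' @return A tibble with one row per contrast label and SLD columns.
#' @export
contrast_scheme <- function(
    sld_protein = c(
      protein = 3.09e-6, complex = 3.09e-6,
      surfactant = 2.31e-6, zac = 2.79e-6
    ),
    sld_surfactant = c(
      protein = 6.37e-6, complex = 3.09e-6,
      surfactant = 6.37e-6, zac = 6.45e-6
    ),
    sld_solvent = c(
      protein = 6.37e-6, complex = 6.37e-6,
      surfactant = 2.31e-6, zac = NA_real_
    )) {
  labels <- names(sld_protein)
  stopifnot(
    identical(labels, names(sld_surfactant)),
    identical(labels, names(sld_solvent))
  )
  out <- tibble(
    contrast = labels,
    sld_protein = unname(sld_protein),
    sld_surfactant = unname(sld_surfactant),
    sld_solvent = unname(sld_solvent)
  )
  validate_contrast_scheme(out)
  out
}

validate_contrast_scheme <- function(scheme, tol = 1e-12) {
  stopifnot(is.data.frame(scheme))
  needed <- c("contrast", "sld_protein", "sld_surfactant", "sld_solvent")
  if (!all(needed %in% names(scheme))) {
    abort(paste("contrast scheme needs columns:", paste(needed, collapse = ", ")))
  }
  chk <- function(label, a, b, what) {
    row <- scheme[scheme$contrast == label, ]
    if (nrow(row) == 1 && !anyNA(c(row[[a]], row[[b]])) &&
      abs(row[[a]] - row[[b]]) > tol) {
      warn(sprintf(
        "contrast '%s' should have %s matched (%s == %s).",
        label, what, a, b
      ))
    }
  }
  chk("protein", "sld_surfactant", "sld_solvent", "surfactant/solvent")
  chk("complex", "sld_surfactant", "sld_protein", "surfactant/protein")
  chk("surfactant", "sld_protein", "sld_solvent", "protein/solvent")
  invisible(scheme)
}
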