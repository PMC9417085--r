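#' Spectral centre of mass of an emission spectrum
#'
#' Intensity-weighted mean wavelength over a window, the standard
#' tracker for tryptophan emission shifts during protein unfolding
#' (red shift = more solvent-exposed fluorophore).
#'
#' @param spectrum Data frame with `wavelength` (nm, increasing) and
#'   `intensity` (>= 0).
#' @param window Wavelength window (nm); default 310-450 nm covers the
#'   full Trp emission band.
#' @return Centre of mass (nm).
#' @export
#' @examples
#' center_of_mass(tibble::tibble(
#'   wavelength = c(300, 400), intensity = c(1, 3)
#' ), window = c(250, 450)) # 375
center_of_mass <- function(spectrum, window = c(310, 450)) {
  stopifnot(
    is.data.frame(spectrum),
    all(c("wavelength", "intensity") %in% names(spectrum))
  )
  if (any(spectrum$intensity < 0)) abort("intensity must be >= 0.")
  sel <- spectrum$wavelength >= window[1] & spectrum$wavelength <= window[2]
  if (!any(sel)) abort("window contains no spectral points.")
  w <- spectrum$wavelength[sel]
  i <- spectrum$intensity[sel]
  tot <- sum(i)
  if (tot <= 0) abort("zero total intensity in the window.")
  sum(w * i) / tot
}

#' Pyrene I3/I1 vibronic band ratio
#'
#' Ratio of the third (~384 nm) to the first (~373 nm) pyrene vibronic
#' emission band, each taken as the maximum intensity within +/- 3 nm of
#' the nominal band centre. The ratio rises when pyrene partitions into
#' hydrophobic micellar environments, so a concentration series locates
#' the CMC/CAC.
#'
#' @param spectrum Data frame with `wavelength`, `intensity`.
#' @param band1,band3 Nominal band centres (nm).
#' @param half_width Search half width (nm).
#' @return The I3/I1 ratio.
#' @export
pyrene_ratio <- function(spectrum, band1 = 373, band3 = 384,
                         half_width = 3) {
  stopifnot(
    is.data.frame(spectrum),
    all(c("wavelength", "intensity") %in% names(spectrum))
  )
  peak <- function(centre) {
    sel <- abs(spectrum$wavelength - centre) <= half_width
    if (!any(sel)) {
      abort(sprintf(
        "spectrum does not cover the %g +/- %g nm band.", centre, half_width
      ))
    }
    max(spectrum$intensity[sel])
  }
  peak(band3) / peak(band1)
}

#' Breakpoint of a two-segment linear trend
#'
#' Weighted two-segment linear fit with the split chosen by grid search
#' over interior break positions (each segment keeping at least 3
#' points); the reported breakpoint is the intersection abscissa of the
#' two fitted lines with its propagated standard error. Used to read
#' CMC/CAC values off pyrene I3/I1 or integrated-intensity series. If
#' splitting does not improve materially on a single line (residual sum
#' of squares reduction < `min_improvement`), the result is flagged
#' `no_breakpoint`.
#'
#' @param x,y Data (>= 6 points).
#' @param dy Optional 1-sigma errors on `y` (weights).
#' @param min_improvement Minimum fractional RSS improvement over a
#'   single line for a break to be accepted (default 0.2).
#' @return A `breakpoint_fit` object; `glance()` reports the breakpoint
#'   and segment slopes.
#' @export
breakpoint_intersection <- function(x, y, dy = NULL,
                                    min_improvement = 0.2) {
  if (length(x) < 6) abort("need at least 6 points.")
  ord <- order(x)
  x <- x[ord]
  y <- y[ord]
  w <- if (is.null(dy)) rep(1, length(x)) else 1 / dy[ord]^2
  n <- length(x)
  fit_one <- lm(y ~ x, weights = w)
  rss_one <- sum(w * fit_one$residuals^2)
  best <- NULL
  for (k in 3:(n - 3)) {
    i1 <- 1:k
    i2 <- (k + 1):n
    f1 <- lm(y ~ x, data = data.frame(x = x[i1], y = y[i1]), weights = w[i1])
    f2 <- lm(y ~ x, data = data.frame(x = x[i2], y = y[i2]), weights = w[i2])
    rss <- sum(w[i1] * f1$residuals^2) + sum(w[i2] * f2$residuals^2)
    if (is.null(best) || rss < best$rss) {
      best <- list(f1 = f1, f2 = f2, rss = rss, k = k)
    }
  }
  b1 <- coef(best$f1)
  b2 <- coef(best$f2)
  dm <- b1[[2]] - b2[[2]]
  no_break <- rss_one < 1e-300 ||
    (rss_one - best$rss) < min_improvement * rss_one ||
    abs(dm) < 1e-12
  xb <- if (abs(dm) > 1e-12) (b2[[1]] - b1[[1]]) / dm else NA_real_
  se <- NA_real_
  if (!is.na(xb)) {
    # delta method over the four independent line coefficients
    V1 <- suppressWarnings(vcov(best$f1))
    V2 <- suppressWarnings(vcov(best$f2))
    g1 <- c(-1 / dm, -xb / dm) # d xb / d(b1_0, b1_1)
    g2 <- c(1 / dm, xb / dm)
    se <- sqrt(drop(t(g1) %*% V1 %*% g1) + drop(t(g2) %*% V2 %*% g2))
  }
  inside <- !is.na(xb) && xb >= min(x) && xb <= max(x)
  structure(
    list(
      breakpoint = xb, se = se,
      slope_pre = b1[[2]], slope_post = b2[[2]],
      intercept_pre = b1[[1]], intercept_post = b2[[1]],
      no_breakpoint = no_break || !inside,
      split_index = best$k, rss_two = best$rss, rss_one = rss_one,
      data = tibble(x = x, y = y, w = w)
    ),
    class = "breakpoint_fit"
  )
}

#' @export
print.breakpoint_fit <- function(x, ...) {
  if (x$no_breakpoint) {
    cat("No breakpoint detected (data consistent with a single line).\n")
  }
  cat(sprintf(
    "Breakpoint at x = %.4g +/- %.2g (slopes %.4g -> %.4g)\n",
    x$breakpoint, x$se, x$slope_pre, x$slope_post
  ))
  invisible(x)
}

#' @export
glance.breakpoint_fit <- function(x, ...) {
  tibble(
    breakpoint = x$breakpoint, std.error = x$se,
    slope_pre = x$slope_pre, slope_post = x$slope_post,
    no_breakpoint = x$no_breakpoint,
    rss_two = x$rss_two, rss_one = x$rss_one
  )
}

#' Surfactant-to-protein ratio at an aggregation concentration
#'
#' @param cac_mM Critical association (or micelle) concentration (mM).
#' @param protein_uM Protein concentration (uM).
#' @return Tibble with the real-valued `ratio` and nearest-integer
#'   `ratio_int`.
#' @export
#' @examples
#' cac_ratio(0.43, 10.3) # ~42 surfactants per protein
cac_ratio <- function(cac_mM, protein_uM) {
  check_number(protein_uM, "protein_uM", 0, strict_lower = TRUE)
  r <- cac_mM * 1000 / protein_uM
  tibble(ratio = r, ratio_int = round(r))
}

#' Mean residue ellipticity from a raw CD signal
#'
#' `theta_MR = theta_mdeg * MRW / (10 * path_cm * conc_gL)` in
#' deg cm^2 dmol^-1, the per-peptide-bond normalisation of circular
#' dichroism spectra.
#'
#' @param theta_mdeg Measured ellipticity (millidegrees); vectorised.
#' @param mrw Mean residue molecular weight (Da).
#' @param path_cm Cell path length (cm).
#' @param conc_gL Protein concentration (g/L).
#' @return Mean residue ellipticity (deg cm^2 dmol^-1).
#' @export
#' @examples
#' mean_residue_ellipticity(10, 110, 0.1, 1) # 11000
mean_residue_ellipticity <- function(theta_mdeg, mrw, path_cm, conc_gL) {
  check_number(mrw, "mrw", 0, strict_lower = TRUE)
  check_number(path_cm, "path_cm", 0, strict_lower = TRUE)
  check_number(conc_gL, "conc_gL", 0, strict_lower = TRUE)
  theta_mdeg * mrw / (10 * path_cm * conc_gL)
}

#' Secondary- and tertiary-structure descriptors of a CD spectrum
#'
#' Interpolates the mean-residue ellipticity at 209, 220 and 292 nm.
#' The 220/209 ratio tracks alpha-helix content (secondary structure),
#' the 292 nm value the tryptophan environment (tertiary structure);
#' the parametric pairs (220 vs 209, 292 vs 209) trace denaturation
#' trajectories.
#'
#' @param spectrum Data frame with `wavelength` (nm) and `theta`
#'   (deg cm^2 dmol^-1). Far- and near-UV regions may come from
#'   different measurements; wavelengths outside the spectrum give NA
#'   for the affected descriptor (error if all are outside).
#' @param wavelengths Probe wavelengths, default `c(209, 220, 292)`.
#' @return One-row tibble: `theta_209`, `theta_220`, `theta_292`,
#'   `ratio_220_209`.
#' @export
ellipticity_descriptors <- function(spectrum,
                                    wavelengths = c(209, 220, 292)) {
  stopifnot(
    is.data.frame(spectrum),
    all(c("wavelength", "theta") %in% names(spectrum))
  )
  rng <- range(spectrum$wavelength)
  vals <- vapply(wavelengths, function(wl) {
    if (wl < rng[1] || wl > rng[2]) {
      return(NA_real_)
    }
    approx(spectrum$wavelength, spectrum$theta, xout = wl)$y
  }, numeric(1))
  if (all(is.na(vals))) {
    abort("spectrum covers none of the requested wavelengths.")
  }
  out <- tibble(
    theta_209 = vals[1], theta_220 = vals[2], theta_292 = vals[3],
    ratio_220_209 = vals[2] / vals[1]
  )
  out
}

#' Protein concentration from A280 absorbance
#'
#' Beer-Lambert: molar concentration `A / (epsilon * l)`, mass
#' concentration via the molecular weight. Defaults are the hGH
#' constants (extinction 17670 M^-1 cm^-1, 22124 Da).
#'
#' @param absorbance A280 reading; vectorised.
#' @param extinction Molar extinction coefficient (M^-1 cm^-1).
#' @param path_cm Path length (cm).
#' @param mw Molecular weight (Da).
#' @return Tibble with `molar` (mol/L) and `g_per_l`.
#' @export
#' @examples
#' conc_from_a280(1.767) # 1e-4 M hGH
conc_from_a280 <- function(absorbance, extinction = 17670, path_cm = 1,
                           mw = 22124) {
  check_number(extinction, "extinction", 0, strict_lower = TRUE)
  check_number(path_cm, "path_cm", 0, strict_lower = TRUE)
  check_number(mw, "mw", 0, strict_lower = TRUE)
  molar <- absorbance / (extinction * path_cm)
  tibble(molar = molar, g_per_l = molar * mw)
}
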