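# run code under a fixed seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      suppressWarnings(rm(".Random.seed", envir = globalenv())),
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

#' Generate a four-contrast synthetic SANS dataset
#'
#' Simulates the contrast-variation experiment on a surfactant-protein
#' complex: for each contrast of the model's scheme the smeared
#' model intensity (core-shell ellipsoid times RMSA structure factor) is
#' evaluated and counting-statistics-like noise is added with
#' `dI = noise_a * sqrt(I) + noise_b`. The contrast identities of the
#' scheme (matched components) hold by construction.
#'
#' @param model A [complex_model]; the ground truth.
#' @param q Momentum-transfer grid (A^-1).
#' @param dq_frac Relative resolution width `dq = dq_frac * q`
#'   (default 0.05); set 0 to disable smearing.
#' @param noise_a,noise_b Noise model coefficients (cm^-0.5, cm^-1).
#'   `noise_a = 0` and `noise_b = 0` return the noise-free smeared
#'   model.
#' @param seed Random seed (ignored when noise is zero).
#' @return Named list of [sans_curve]s (one per contrast), each carrying
#'   the generating model in its metadata.
#' @export
gen_sans <- function(model = complex_model(),
                     q = exp(seq(log(0.008), log(0.35), length.out = 60)),
                     dq_frac = 0.05, noise_a = 0.01, noise_b = 0.002,
                     seed = 1) {
  stopifnot(inherits(model, "complex_model"))
  labels <- model$scheme$contrast
  dq <- if (dq_frac > 0) dq_frac * q else NULL
  q_list <- setNames(rep(list(q), length(labels)), labels)
  dq_list <- if (!is.null(dq)) {
    setNames(rep(list(dq), length(labels)), labels)
  } else {
    NULL
  }
  ideal <- complex_model_intensity(model, q_list, dq_list,
    sq_quality = "fast"
  )
  noisy <- if (noise_a > 0 || noise_b > 0) {
    with_seed(seed, purrr::map(ideal, function(i) {
      di <- noise_a * sqrt(pmax(i, 0)) + noise_b
      list(i = i + stats::rnorm(length(i), 0, di), di = di)
    }))
  } else {
    purrr::map(ideal, function(i) list(i = i, di = rep(0, length(i))))
  }
  purrr::imap(noisy, function(ni, lab) {
    sans_curve(
      q = q, i = ni$i, di = ni$di, dq = dq, contrast = lab,
      metadata = list(truth = model, seed = seed)
    )
  })
}

#' Generate synthetic multi-stage ITC enthalpograms
#'
#' Builds molar-heat profiles versus cumulative surfactant concentration
#' for several protein concentrations. Stage boundaries for protein
#' concentration `c` sit at `[SDS]_unbound + N_agg * c` (the binding
#' decomposition), the heat is piecewise linear between boundary values
#' and relaxes to zero after the last stage, and seeded Gaussian noise
#' is added to the molar heat.
#'
#' @param protein_uM Protein concentrations to titrate (uM).
#' @param stages Tibble with one row per stage: `n_agg`,
#'   `sds_unbound_mM` and `heat` (molar heat at the stage boundary,
#'   kcal/mol). Defaults follow the five-stage hGH/SDS pattern.
#' @param heat0 Molar heat at zero surfactant (kcal/mol).
#' @param n_injections,injection_uL,syringe_mM,cell_uL Injection
#'   schedule (displacement dilution model).
#' @param noise Gaussian noise s.d. on the molar heat (kcal/mol).
#' @param seed Random seed.
#' @return Named list of [enthalpogram]s (names `"p<conc>"`), each with
#'   the generating stage table in attribute `"truth"`.
#' @export
gen_itc <- function(protein_uM = c(25, 37, 50, 75),
                    stages = tibble(
                      n_agg = c(6, 23, 32, 61, 61),
                      sds_unbound_mM = c(0.51, 0.81, 1.3, 4.1, 5.4),
                      heat = c(-1.45, -0.40, -1.30, -0.35, 0)
                    ),
                    heat0 = -0.9, n_injections = 70, injection_uL = 5,
                    syringe_mM = 60, cell_uL = 1400, noise = 0.03,
                    seed = 1) {
  stopifnot(all(c("n_agg", "sds_unbound_mM", "heat") %in% names(stages)))
  out <- purrr::map(protein_uM, function(cp) {
    conc <- itc_cell_concentration(
      rep(injection_uL, n_injections), syringe_mM, cell_uL
    )
    knots <- stages$sds_unbound_mM + stages$n_agg * cp / 1000
    if (is.unsorted(knots, strictly = TRUE)) {
      abort("stage boundaries must be ordered in concentration.")
    }
    prof <- approx(
      x = c(0, knots, max(conc[length(conc)], knots[length(knots)]) + 1),
      y = c(heat0, stages$heat, 0),
      xout = conc, rule = 2
    )$y
    heat <- if (noise > 0) {
      with_seed(seed + round(cp), prof + stats::rnorm(length(prof), 0, noise))
    } else {
      prof
    }
    e <- enthalpogram(seq_along(conc), conc, heat, protein_uM = cp)
    attr(e, "truth") <- stages
    e
  })
  setNames(out, paste0("p", protein_uM))
}

# Gaussian emission band helper
gauss_band <- function(wl, centre, sigma, height) {
  height * exp(-(wl - centre)^2 / (2 * sigma^2))
}

#' Generate a two-state tryptophan fluorescence titration
#'
#' Emission spectra as linear mixtures of a buried-Trp basis (centred
#' near 338 nm) and a solvent-exposed basis (red-shifted, dimmer, near
#' 352 nm); the exposed fraction follows a logistic in the
#' surfactant-to-protein ratio. Defaults place the 10-90% transition
#' between ratios of roughly 40 and 120, matching a two-stage unfolding
#' read-out.
#'
#' @param ratios Surfactant-to-protein ratios of the series.
#' @param midpoint,width Logistic midpoint and width (ratio units).
#' @param cm_native,cm_exposed Basis band centres (nm).
#' @param intensity_exposed Peak intensity of the exposed basis relative
#'   to the native basis.
#' @param wavelength Output wavelength grid (nm).
#' @param noise Additive Gaussian noise s.d. (fraction of the native
#'   peak).
#' @param seed Random seed.
#' @return Tibble with `ratio`, `fraction_exposed`, and a `spectrum`
#'   list-column of `(wavelength, intensity)` tibbles.
#' @export
gen_fluorescence <- function(ratios = c(0, 4, 8, 16, 24, 38, 56, 80,
                               110, 150, 220, 344),
                             midpoint = 80, width = 18,
                             cm_native = 338, cm_exposed = 352,
                             intensity_exposed = 0.55,
                             wavelength = seq(300, 450, by = 1),
                             noise = 0, seed = 1) {
  f_exposed <- stats::plogis((ratios - midpoint) / width)
  spectra <- purrr::map(seq_along(ratios), function(k) {
    f <- f_exposed[k]
    i <- (1 - f) * gauss_band(wavelength, cm_native, 22, 1) +
      f * gauss_band(wavelength, cm_exposed, 26, intensity_exposed)
    if (noise > 0) {
      i <- with_seed(seed + k, pmax(
        i + stats::rnorm(length(i), 0, noise), 0
      ))
    }
    tibble(wavelength = wavelength, intensity = i)
  })
  tibble(
    ratio = ratios, fraction_exposed = f_exposed, spectrum = spectra
  )
}

#' Generate a pyrene I3/I1 titration
#'
#' The vibronic ratio follows a two-plateau profile: flat at
#' `ratio_low` below the aggregation concentration, rising linearly to
#' `ratio_high` at `saturation_mM`, flat beyond. The kink at `cac_mM`
#' is the generating breakpoint that [breakpoint_intersection()] should
#' recover. Each point also carries a synthetic pyrene emission spectrum
#' whose band heights reproduce the (noisy) ratio.
#'
#' @param conc_mM Surfactant concentrations (mM).
#' @param cac_mM Generating aggregation concentration (mM); 0.43 with
#'   protein, 4.1 in pure buffer.
#' @param ratio_low,ratio_high Plateau values of I3/I1.
#' @param saturation_mM Concentration at which the upper plateau is
#'   reached (default `3 * cac_mM`).
#' @param noise Gaussian noise s.d. on the ratio.
#' @param seed Random seed.
#' @return Tibble with `conc_mM`, `ratio_true`, `ratio` (noisy) and a
#'   `spectrum` list-column.
#' @export
gen_pyrene <- function(conc_mM, cac_mM = 0.43, ratio_low = 0.62,
                       ratio_high = 0.95, saturation_mM = 3 * cac_mM,
                       noise = 0.005, seed = 1) {
  check_number(cac_mM, "cac_mM", 0, strict_lower = TRUE)
  ratio_true <- ifelse(
    conc_mM <= cac_mM, ratio_low,
    ifelse(conc_mM >= saturation_mM, ratio_high,
      ratio_low + (ratio_high - ratio_low) *
        (conc_mM - cac_mM) / (saturation_mM - cac_mM)
    )
  )
  ratio <- if (noise > 0) {
    with_seed(seed, ratio_true + stats::rnorm(length(ratio_true), 0, noise))
  } else {
    ratio_true
  }
  wl <- seq(360, 400, by = 0.5)
  # bands narrow enough that the 373/384 maxima are unpolluted by their
  # neighbours, so pyrene_ratio() returns the generating ratio
  spectra <- purrr::map(ratio, function(r) {
    i <- gauss_band(wl, 373, 1.5, 1) + gauss_band(wl, 378.5, 1.8, 0.35) +
      gauss_band(wl, 384, 1.5, r)
    tibble(wavelength = wl, intensity = i)
  })
  tibble(
    conc_mM = conc_mM, ratio_true = ratio_true, ratio = ratio,
    spectrum = spectra
  )
}

# built-in CD basis spectra (mean residue ellipticity, deg cm^2/dmol):
# native (helical far-UV + structured near-UV), molten globule (helix
# kept, near-UV lost), denatured (reduced helix)
cd_basis <- function(wavelength, state = c("native", "molten", "denatured")) {
  state <- match.arg(state)
  far <- function(a209, a222) {
    # the positive pi-pi* lobe is kept narrow so its tail does not leak
    # into the 209 nm descriptor
    gauss_band(wavelength, 193, 5, 30000) -
      gauss_band(wavelength, 209, 7.5, a209) -
      gauss_band(wavelength, 222, 9, a222)
  }
  near <- function(a292, a265) {
    -gauss_band(wavelength, 292, 5, a292) -
      gauss_band(wavelength, 265, 12, a265)
  }
  switch(state,
    native = far(11000, 10400) + near(180, 120),
    molten = far(10800, 10000) + near(25, 60),
    denatured = far(9000, 6100) + near(10, 20)
  )
}

#' Generate a CD titration from state bases
#'
#' Three-state sequential mixing (native -> molten globule ->
#' denatured) with logistic transitions in the surfactant-to-protein
#' ratio: the first transition removes tertiary structure (near-UV
#' signal), the second reduces helix content (far-UV). Default
#' midpoints/widths are chosen so the 10-90% spans are roughly 16-58
#' (near-UV) and 59-150 (far-UV) in ratio units.
#'
#' @param ratios Surfactant-to-protein ratios.
#' @param mid1,width1 Logistic midpoint/width of the tertiary
#'   transition.
#' @param mid2,width2 Logistic midpoint/width of the secondary
#'   transition.
#' @param wavelength Wavelength grid (nm), covering far- and near-UV.
#' @param noise Additive Gaussian noise s.d. (deg cm^2/dmol).
#' @param seed Random seed.
#' @return Tibble with `ratio`, state fractions and a `spectrum`
#'   list-column of `(wavelength, theta)` tibbles.
#' @export
gen_cd <- function(ratios = c(0, 4, 8, 15, 25, 40, 59, 80, 110, 145,
                     200, 300, 408),
                   mid1 = 37, width1 = 9.5, mid2 = 105, width2 = 21,
                   wavelength = seq(195, 320, by = 0.5), noise = 0,
                   seed = 1) {
  g1 <- stats::plogis((ratios - mid1) / width1)
  g2 <- stats::plogis((ratios - mid2) / width2)
  f_native <- 1 - g1
  f_molten <- g1 * (1 - g2)
  f_denat <- g1 * g2
  b_n <- cd_basis(wavelength, "native")
  b_m <- cd_basis(wavelength, "molten")
  b_d <- cd_basis(wavelength, "denatured")
  spectra <- purrr::map(seq_along(ratios), function(k) {
    th <- f_native[k] * b_n + f_molten[k] * b_m + f_denat[k] * b_d
    if (noise > 0) {
      th <- with_seed(seed + k, th + stats::rnorm(length(th), 0, noise))
    }
    tibble(wavelength = wavelength, theta = th)
  })
  tibble(
    ratio = ratios, f_native = f_native, f_molten = f_molten,
    f_denatured = f_denat, spectrum = spectra
  )
}
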