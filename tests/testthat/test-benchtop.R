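test_that("spectral centre of mass is exact on simple shapes", {
  wl <- seq(300, 400, by = 0.5)
  sym <- tibble::tibble(
    wavelength = wl, intensity = exp(-(wl - 338)^2 / 200)
  )
  expect_equal(center_of_mass(sym, c(300, 376)), 338, tolerance = 1e-6)
  two <- tibble::tibble(wavelength = c(300, 400), intensity = c(1, 3))
  expect_equal(center_of_mass(two, c(250, 450)), 375)
  # invariant under uniform intensity scaling, bounded by the window
  sc <- sym
  sc$intensity <- sc$intensity * 17
  expect_equal(center_of_mass(sc, c(300, 376)), center_of_mass(sym, c(300, 376)))
  cm <- center_of_mass(sym, c(320, 360))
  expect_gte(cm, 320)
  expect_lte(cm, 360)
  expect_error(center_of_mass(two, c(500, 600)), "window")
  zero <- tibble::tibble(wavelength = wl, intensity = 0)
  expect_error(center_of_mass(zero), "zero total")
})

test_that("CM shifts red monotonically with the exposed-state fraction", {
  series <- gen_fluorescence(
    ratios = c(0, 20, 50, 80, 120, 200, 400), noise = 0
  )
  cms <- vapply(series$spectrum, center_of_mass, numeric(1))
  expect_true(all(diff(cms) > 0))
  expect_true(all(diff(series$fraction_exposed) > 0))
})

test_that("pyrene band ratio behaves linearly and hits generator truth", {
  wl <- seq(360, 400, by = 0.5)
  eq <- tibble::tibble(
    wavelength = wl,
    intensity = exp(-(wl - 373)^2 / 4) + exp(-(wl - 384)^2 / 4)
  )
  expect_equal(pyrene_ratio(eq), 1, tolerance = 1e-9)
  dbl <- eq
  sel <- abs(wl - 384) <= 3
  dbl$intensity[sel] <- dbl$intensity[sel] * 2
  expect_equal(pyrene_ratio(dbl), 2 * pyrene_ratio(eq), tolerance = 1e-9)
  expect_error(
    pyrene_ratio(tibble::tibble(wavelength = 300:350, intensity = 1)),
    "band"
  )
  # generator round trip at the micellar plateau
  series <- gen_pyrene(conc_mM = c(5, 8), cac_mM = 0.43, noise = 0)
  r <- pyrene_ratio(series$spectrum[[1]])
  expect_equal(r, 0.95, tolerance = 0.01)
})

test_that("breakpoint intersection is exact on constructed kinks", {
  x <- seq(0.2, 2, by = 0.15)
  y <- ifelse(x < 1, 1, 2 * x - 1)
  fit <- breakpoint_intersection(x, y)
  expect_false(fit$no_breakpoint)
  expect_equal(fit$breakpoint, 1, tolerance = 1e-9)
  expect_equal(fit$slope_post, 2, tolerance = 1e-9)
  # globally linear data: flagged, not forced
  lin <- breakpoint_intersection(x, 3 * x + 0.5)
  expect_true(lin$no_breakpoint)
  expect_error(breakpoint_intersection(1:4, 1:4), "6 points")
})

test_that("breakpoint abscissa is equivariant under affine x rescaling", {
  set.seed(4)
  x <- seq(0.1, 3, length.out = 20)
  y <- ifelse(x < 1.2, 0.6, 0.6 + 0.5 * (x - 1.2)) + rnorm(20, 0, 0.01)
  b0 <- breakpoint_intersection(x, y)$breakpoint
  a <- 2.5
  b <- -0.7
  b1 <- breakpoint_intersection(a * x + b, y)$breakpoint
  expect_equal(b1, a * b0 + b, tolerance = 1e-9)
})

test_that("pyrene titration recovers the generating CAC", {
  conc <- exp(seq(log(0.05), log(1.2), length.out = 24))
  series <- gen_pyrene(conc, cac_mM = 0.43, noise = 0.005, seed = 31)
  fit <- breakpoint_intersection(series$conc_mM, series$ratio)
  expect_false(fit$no_breakpoint)
  expect_lt(abs(fit$breakpoint - 0.43), max(3 * fit$se, 0.05))
})

test_that("surfactant-to-protein ratios divide units consistently", {
  expect_equal(cac_ratio(0.43, 10.3)$ratio_int, 42)
  expect_equal(cac_ratio(4.1, 10.3)$ratio_int, 398)
  expect_equal(cac_ratio(2.5, 2500)$ratio, 1)
})

test_that("transition fit solves the binding decomposition", {
  # collinear construction from bound number 32, unbound 1.3 mM
  f <- itc_transition_fit(tibble::tibble(
    protein_uM = c(25, 50, 75), sds_mM = c(2.1, 2.9, 3.7)
  ))
  expect_equal(f$n_agg, 32, tolerance = 1e-9)
  expect_equal(f$sds_unbound_mM, 1.3, tolerance = 1e-9)
  expect_lt(f$n_agg_se, 1e-8) # exact collinear input: zero errors
  # intercept-only data
  f0 <- itc_transition_fit(tibble::tibble(
    protein_uM = c(20, 40, 60), sds_mM = c(2, 2, 2)
  ))
  expect_equal(f0$n_agg, 0, tolerance = 1e-9)
  expect_error(
    itc_transition_fit(tibble::tibble(
      protein_uM = c(50, 50), sds_mM = c(2, 3)
    )),
    "distinct"
  )
})

test_that("forward prediction reproduces the fitted line and ratios", {
  f <- list(n_agg = 32, sds_unbound_mM = 1.3)
  p <- predict_total_sds(f, 50)
  expect_equal(p$total_mM, 2.9, tolerance = 1e-9)
  expect_equal(p$ratio_int, 58)
  expect_equal(
    predict_total_sds(list(n_agg = 23, sds_unbound_mM = 0.81), 135)$total_mM,
    3.9,
    tolerance = 0.01
  )
  expect_equal(
    predict_total_sds(list(n_agg = 61, sds_unbound_mM = 5.4), 135)$total_mM,
    13.6,
    tolerance = 0.01
  )
  # any point on the fitted line is reproduced exactly
  ff <- itc_transition_fit(tibble::tibble(
    protein_uM = c(25, 50, 75), sds_mM = c(2.1, 2.9, 3.7)
  ))
  expect_equal(predict_total_sds(ff, 75)$total_mM, 3.7, tolerance = 1e-9)
  expect_true(is.na(predict_total_sds(ff, 0)$ratio))
})

test_that("enthalpogram segmentation finds constructed kinks", {
  # two-segment profile: exactly one boundary at the kink
  x <- seq(0.2, 6, by = 0.2)
  y <- ifelse(x < 3, -1 + 0.1 * x, -0.7 - 0.2 * (x - 3) + 0.3)
  e <- enthalpogram(seq_along(x), x, y)
  tr <- detect_transitions(e, n_max = 4)
  expect_equal(tr$n_segments, 2)
  expect_equal(nrow(tr$transitions), 1)
  expect_lt(abs(tr$transitions$conc_mM - 3), 0.2)
  # straight line: no interior transitions
  lin <- enthalpogram(seq_along(x), x, -0.5 + 0.05 * x)
  tr_lin <- detect_transitions(lin, n_max = 4)
  expect_equal(nrow(tr_lin$transitions), 0)
})

test_that("noise-free generator round trip recovers all five stages", {
  itcs <- gen_itc(noise = 0)
  truth <- attr(itcs[[1]], "truth")
  e <- itcs$p50
  tr <- detect_transitions(e, n_max = 6)
  knots <- truth$sds_unbound_mM + truth$n_agg * 0.05
  expect_equal(tr$n_segments, 6)
  spacing <- max(diff(e$conc_mM))
  expect_true(all(abs(tr$transitions$conc_mM - knots) < spacing))
  # per-concentration stage-iii boundaries regress back to the stage
  # parameters exactly
  pts <- purrr::map_dfr(itcs, function(en) {
    t1 <- detect_transitions(en, n_max = 6)
    tibble::tibble(
      protein_uM = attr(en, "protein_uM"),
      sds_mM = t1$transitions$conc_mM[3]
    )
  })
  fit <- itc_transition_fit(pts)
  expect_equal(fit$n_agg, truth$n_agg[3], tolerance = 1e-6)
  expect_equal(fit$sds_unbound_mM, truth$sds_unbound_mM[3], tolerance = 1e-6)
})

test_that("mean residue ellipticity conversion and scaling", {
  # theta_mdeg * MRW / (10 * l * c): 10 * 110 / (10 * 0.1 * 1)
  expect_equal(mean_residue_ellipticity(10, 110, 0.1, 1), 1100)
  expect_equal(mean_residue_ellipticity(0, 110, 0.1, 1), 0)
  expect_equal(
    mean_residue_ellipticity(10, 110, 0.2, 1),
    mean_residue_ellipticity(10, 110, 0.1, 1) / 2
  )
  expect_error(mean_residue_ellipticity(10, -1, 0.1, 1), "range")
})

test_that("CD descriptors track the denaturation trajectory", {
  wl <- seq(195, 320, by = 0.5)
  # theta(220) == theta(209): ratio 1
  flat <- tibble::tibble(wavelength = wl, theta = -5000)
  expect_equal(ellipticity_descriptors(flat)$ratio_220_209, 1)
  expect_error(
    ellipticity_descriptors(tibble::tibble(wavelength = 400:500, theta = 1)),
    "none"
  )
  series <- gen_cd(noise = 0)
  desc <- purrr::map_dfr(series$spectrum, ellipticity_descriptors)
  # near-UV signal decays with the tertiary transition, and earlier than
  # the secondary (far-UV) one
  expect_lt(abs(desc$theta_292[nrow(desc)]), abs(desc$theta_292[1]) / 3)
  # far-UV ratio decreases overall between native and final state
  expect_lt(
    desc$ratio_220_209[nrow(desc)], desc$ratio_220_209[1]
  )
  # pure-basis endpoints equal the basis descriptors
  base_native <- ellipticity_descriptors(tibble::tibble(
    wavelength = wl, theta = protsurf:::cd_basis(wl, "native")
  ))
  expect_equal(desc$theta_209[1], base_native$theta_209, tolerance = 1e-2)
  # monotone trajectory of the tertiary marker against mixing fraction
  ord <- order(series$f_native)
  expect_true(all(diff(abs(desc$theta_292[ord])) > -1))
})

test_that("A280 concentrations follow Beer-Lambert with hGH constants", {
  res <- conc_from_a280(1.767)
  expect_equal(res$molar, 1e-4, tolerance = 1e-9)
  expect_equal(res$g_per_l, 1e-4 * 22124, tolerance = 1e-9)
  expect_equal(conc_from_a280(0)$molar, 0)
  expect_error(conc_from_a280(1, extinction = -5), "range")
})
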