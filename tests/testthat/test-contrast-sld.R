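test_that("solvent SLD mixes ideally between the pure-water endpoints", {
  expect_equal(solvent_sld(1), -0.56e-6)
  expect_equal(solvent_sld(0), 6.39e-6)
  # the canonical 57.25% H2O protein-match composition
  expect_equal(solvent_sld(0.5725), 2.41e-6, tolerance = 0.02e-6 / 2.41e-6)
  # strictly decreasing in f_h2o
  f <- seq(0, 1, by = 0.05)
  expect_true(all(diff(solvent_sld(f)) < 0))
  expect_error(solvent_sld(1.2), "0, 1")
  expect_error(solvent_sld(-0.1), "0, 1")
})

test_that("molecule SLD handles H/D exchange correctly", {
  # no deuterium in the solvent: exchange fraction is irrelevant
  s1 <- molecule_sld("ACDEFGHIKL", f_d2o = 0, exchange_fraction = 0)
  s2 <- molecule_sld("ACDEFGHIKL", f_d2o = 0, exchange_fraction = 1)
  expect_equal(s1, s2)
  # exchange disabled: value equals the protonated table sum at any f_d2o
  g10 <- strrep("G", 10)
  expect_equal(
    molecule_sld(g10, f_d2o = 1, exchange_fraction = 0),
    molecule_sld(g10, f_d2o = 0, exchange_fraction = 0)
  )
  # hand-computed oracle for "GG" at f_d2o = 1, 90% exchange, from the
  # shipped composition (C2 H3 N O per glycine residue, 1 labile H,
  # 60.1 A^3) and the Sears scattering lengths
  b_gly <- 2 * 6.6511 + 3 * (-3.7406) + 9.37 + 5.803
  b_exch <- 0.9 * 1 * (6.671 - (-3.7406))
  sld_oracle <- 2 * (b_gly + b_exch) * 1e-5 / (2 * 60.1)
  expect_equal(molecule_sld("GG", 1, 0.9), sld_oracle, tolerance = 1e-12)
  # affine in f_d2o at fixed exchange fraction
  f <- c(0, 0.25, 0.5, 0.75, 1)
  v <- vapply(f, function(ff) molecule_sld("ACDW", ff, 0.9), numeric(1))
  expect_equal(diff(v, differences = 2), rep(0, 3), tolerance = 1e-18)
  expect_error(molecule_sld("AXZ", 0.5), "position")
  expect_error(molecule_sld("", 0.5), "non-empty")
})

test_that("theoretical match point satisfies its defining equality", {
  # constant-SLD molecule: invert the solvent line analytically
  mp <- theoretical_match_point(molecule_sld_fn = function(f) 2.41e-6)
  f_analytic <- (2.41e-6 - 6.39e-6) / (-0.56e-6 - 6.39e-6)
  expect_equal(mp$f_h2o, f_analytic, tolerance = 1e-9)
  expect_true(mp$matched)
  # boundary: SLD equal to pure D2O
  mp0 <- theoretical_match_point(molecule_sld_fn = function(f) 6.39e-6)
  expect_equal(mp0$f_h2o, 0)
  # above the D2O SLD: no crossing
  expect_warning(
    mp_no <- theoretical_match_point(molecule_sld_fn = function(f) 7e-6),
    "no contrast match"
  )
  expect_false(mp_no$matched)
  # defining equality for a sequence with exchange, to < 1e-9 relative
  seq_hgh <- read_protein_fasta(
    system.file("extdata/hgh.fasta", package = "protsurf")
  )
  mp_h <- theoretical_match_point(seq_hgh)
  lhs <- molecule_sld(seq_hgh, 1 - mp_h$f_h2o)
  rhs <- solvent_sld(mp_h$f_h2o)
  expect_lt(abs(lhs - rhs) / abs(rhs), 1e-9)
})

test_that("experimental match point recovers exact and noisy intercepts", {
  # exact collinear construction crossing at f = 0.6
  d <- tibble::tibble(
    f_h2o = c(0, 0.3, 0.6, 0.9), i0 = c(9, 2.25, 0, 2.25)
  )
  fit <- experimental_match_point(d)
  expect_equal(fit$f_h2o, 0.6, tolerance = 1e-9)
  # degenerate inputs
  expect_error(
    experimental_match_point(
      tibble::tibble(f_h2o = c(0.5, 0.5, 0.5), i0 = c(1, 2, 3))
    ),
    "degenerate"
  )
  expect_error(
    experimental_match_point(
      tibble::tibble(f_h2o = c(0.1, 0.5, 0.9), i0 = c(0, 0, 0))
    ),
    "degenerate"
  )
  # seeded simulation: I0 from a known contrast matching at 0.601
  set.seed(11)
  f <- c(0, 0.25, 0.45, 0.8, 1)
  i0_true <- (solvent_sld(f) - solvent_sld(0.601))^2 * 1e14
  i0 <- i0_true * (1 + 0.02 * rnorm(length(f)))
  noisy <- experimental_match_point(
    tibble::tibble(f_h2o = f, i0 = pmax(i0, 0), di0 = 0.02 * pmax(i0_true, 1e-4))
  )
  expect_lt(abs(noisy$f_h2o - 0.601), 3 * noisy$se)
})

test_that("ZAC solvent zeroes the volume-weighted mean contrast", {
  z <- zac_solvent(2e-6, 1, 6e-6, 1)
  expect_equal(z$sld_solvent, 4e-6)
  expect_equal(zac_solvent(3e-6, 2, 9e-6, 0)$sld_solvent, 3e-6)
  # self-consistent solve with a solvent-dependent protein SLD,
  # surfactant SLD as for a nearly fully deuterated SDS
  sld_prot <- function(f_h2o) 1.76e-6 + 1.37e-6 * (1 - f_h2o)
  v_prot <- 26800
  v_core <- 10712
  z2 <- zac_solvent(sld_prot, v_prot, 6.45e-6, v_core)
  expect_true(z2$attainable)
  rho_s <- z2$sld_solvent
  mean_contrast <- (v_prot * (sld_prot(z2$f_h2o) - rho_s) +
    v_core * (6.45e-6 - rho_s)) / (v_prot + v_core)
  expect_lt(abs(mean_contrast), 1e-12 * abs(6.45e-6 - rho_s))
  # unattainable compositions warn
  expect_warning(z3 <- zac_solvent(8e-6, 1, 9e-6, 1), "outside|attainable")
  expect_false(z3$attainable)
})

test_that("contrast scheme enforces the matching identities", {
  sch <- contrast_scheme()
  expect_equal(
    sch$sld_surfactant[sch$contrast == "protein"],
    sch$sld_solvent[sch$contrast == "protein"]
  )
  expect_equal(
    sch$sld_surfactant[sch$contrast == "complex"],
    sch$sld_protein[sch$contrast == "complex"]
  )
  expect_equal(
    sch$sld_protein[sch$contrast == "surfactant"],
    sch$sld_solvent[sch$contrast == "surfactant"]
  )
  expect_warning(
    contrast_scheme(sld_surfactant = c(
      protein = 5e-6, complex = 3.09e-6,
      surfactant = 6.37e-6, zac = 6.45e-6
    )),
    "matched"
  )
})
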