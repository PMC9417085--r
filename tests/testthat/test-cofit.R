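test_that("aggregation number is the core-to-surfactant volume ratio", {
  expect_equal(nagg_from_core(4120, 412)$n_agg, 10)
  expect_equal(nagg_from_core(412, 412)$n_agg, 1)
  # ellipsoidal core volume oracle: semi-axes 20.3 x 20.3 x 30.5
  v_core <- 4 / 3 * pi * 20.3 * 20.3 * 30.5
  expect_equal(
    nagg_from_core(v_core, 412)$n_agg, v_core / 412,
    tolerance = 1e-12
  )
  expect_error(nagg_from_core(-1, 412), "> 0")
})

test_that("shell coverage inverts the two-component SLD mixing", {
  expect_equal(coverage_from_shell(2.79e-6, 2.79e-6, 6.37e-6), 1)
  expect_equal(coverage_from_shell(6.37e-6, 2.79e-6, 6.37e-6), 0)
  # direct evaluation of the mixing formula at the decorated-micelle SLDs
  c_direct <- (6.37e-6 - 3.43e-6) / (6.37e-6 - 2.79e-6)
  expect_equal(
    coverage_from_shell(3.43e-6, 2.79e-6, 6.37e-6), c_direct,
    tolerance = 1e-12
  )
  expect_equal(c_direct, 0.821, tolerance = 1e-3)
  expect_warning(coverage_from_shell(2e-6, 2.79e-6, 6.37e-6), "clipped")
  expect_error(coverage_from_shell(3e-6, 5e-6, 5e-6), "undefined")
})

test_that("a matched homogeneous particle scatters nothing", {
  p <- geometry_params("core_shell_ellipsoid",
    radius = 15, axial_ratio = 1.3, shell_thickness = 8,
    sld_core = 4e-6, sld_shell = 4e-6, sld_solvent = 4e-6,
    volume_fraction = 0.01
  )
  q <- seq(0.001, 0.4, length.out = 50)
  expect_lt(max(abs(form_factor_intensity(p, q)$i)), 1e-20)
})

test_that("ZAC condition kills forward scattering but not the internal
           correlation peak", {
  m <- complex_model()
  chk <- zac_forward_check(m)
  expect_lt(abs(chk$i0), 1e-6 * chk$i_max)
  expect_gt(chk$i_max, 0)
  expect_false(is.na(chk$q_peak)) # segregation fingerprint at finite q
  expect_gt(chk$q_peak, 0.05)
  # off-ZAC solvent restores forward scattering, quadratically in the
  # detuning
  i0_at <- function(delta) {
    m2 <- m
    m2$scheme$sld_solvent[m2$scheme$contrast == "zac"] <-
      chk$sld_solvent_zac + delta
    m2$use_sq <- FALSE
    m2$background[] <- 0
    complex_model_intensity(m2, list(zac = 1e-4))$zac
  }
  i1 <- i0_at(0.2e-6)
  i2 <- i0_at(0.4e-6)
  expect_gt(i1, 0)
  expect_equal(i2 / i1, 4, tolerance = 0.05)
})

test_that("noise-free co-refinement converges to zero misfit", {
  truth <- complex_model(charge = 0, use_sq = FALSE)
  curves <- gen_sans(truth, noise_a = 0, noise_b = 0, dq_frac = 0.05)
  start <- truth
  start$radius <- truth$radius * 1.15
  start$shell_thickness <- truth$shell_thickness * 0.9
  fit <- sans_cofit(curves, start,
    free = c("radius", "shell_thickness", "coverage"),
    starts = rbind(c(1, 1)), max_iter = 30
  )
  expect_lt(fit$chi2_red_total, 1e-4)
  expect_equal(fit$model$radius, truth$radius, tolerance = 1e-3)
  expect_equal(fit$model$shell_thickness, truth$shell_thickness,
    tolerance = 1e-3
  )
})

test_that("multi-contrast refinement beats a single degenerate contrast", {
  truth <- complex_model(charge = 0, use_sq = FALSE)
  curves <- gen_sans(truth, noise_a = 0.01, noise_b = 0.002, seed = 7)
  start <- truth
  start$radius <- 13
  free <- c("radius", "shell_thickness", "coverage")
  fit4 <- sans_cofit(curves, start,
    free = free, starts = rbind(c(1, 1)),
    max_iter = 30
  )
  # complex contrast alone: core and shell SLDs are degenerate
  fit1 <- sans_cofit(curves["complex"], start,
    free = free,
    starts = rbind(c(1, 1)), max_iter = 30
  )
  se4 <- fit4$estimates$std.error[fit4$estimates$term == "shell_thickness"]
  se1 <- fit1$estimates$std.error[fit1$estimates$term == "shell_thickness"]
  expect_gt(se1, se4) # information gain from co-refinement
  # and the recovered geometry is consistent with the truth
  est <- setNames(fit4$estimates$estimate, fit4$estimates$term)
  se <- setNames(fit4$estimates$std.error, fit4$estimates$term)
  expect_lt(abs(est["radius"] - truth$radius), 3 * se["radius"])
  expect_lt(
    abs(est["shell_thickness"] - truth$shell_thickness),
    3 * se["shell_thickness"]
  )
})

test_that("derived stoichiometry is stable across contrast subsets", {
  truth <- complex_model(charge = 0, use_sq = FALSE)
  curves <- gen_sans(truth, noise_a = 0.01, noise_b = 0.002, seed = 21)
  start <- truth
  start$radius <- 13.5
  free <- c("radius", "shell_thickness", "coverage")
  fit_all <- sans_cofit(curves, start,
    free = free, starts = rbind(c(1, 1)),
    max_iter = 30
  )
  fit_sub <- sans_cofit(curves[c("complex", "surfactant")], start,
    free = free, starts = rbind(c(1, 1)), max_iter = 30
  )
  g_all <- glance(fit_all)
  g_sub <- glance(fit_sub)
  joint_se <- sqrt(g_all$n_agg_se^2 + g_sub$n_agg_se^2)
  expect_lt(abs(g_all$n_agg - g_sub$n_agg), 3 * joint_se + 1e-6)
})

test_that("reported uncertainties calibrate against seeded replicates", {
  # reduced-size calibration: geometry errors over 6 replicates should
  # be of the order of the reported 1 sigma
  truth <- complex_model(charge = 0, use_sq = FALSE)
  start <- truth
  start$radius <- 13
  free <- c("radius", "shell_thickness")
  err_r <- c()
  se_r <- c()
  for (s in 1:6) {
    curves <- gen_sans(truth,
      noise_a = 0.01, noise_b = 0.002,
      seed = 100 + s
    )
    fit <- sans_cofit(curves[c("protein", "complex")], start,
      free = free,
      starts = rbind(c(1, 1)), max_iter = 25
    )
    est <- setNames(fit$estimates$estimate, fit$estimates$term)
    se <- setNames(fit$estimates$std.error, fit$estimates$term)
    err_r <- c(err_r, abs(est["radius"] - truth$radius))
    se_r <- c(se_r, se["radius"])
  }
  expect_lt(median(err_r), 2 * median(se_r))
})

test_that("cofit reports serialise to JSON", {
  truth <- complex_model(charge = 0, use_sq = FALSE)
  curves <- gen_sans(truth, noise_a = 0, noise_b = 0)
  fit <- sans_cofit(curves, truth,
    free = c("radius"), starts = rbind(c(1, 1)),
    max_iter = 5
  )
  path <- file.path(withr::local_tempdir(), "fit.json")
  write_cofit_report(fit, path)
  rep <- jsonlite::read_json(path)
  expect_true("estimates" %in% names(rep))
  expect_true(rep$converged)
})
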