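# analytic sphere curve on an absolute scale, optionally with noise
sphere_curve <- function(radius = 25, q = seq(0.008, 0.35, length.out = 120),
                         sld = 3e-6, phi = 0.01, noise = 0, seed = 1,
                         dq_frac = 0) {
  p <- geometry_params("sphere",
    radius = radius, sld_core = sld,
    sld_solvent = 0, volume_fraction = phi
  )
  crv <- form_factor_intensity(p, q)
  if (dq_frac > 0) {
    crv$dq <- dq_frac * q
    crv$i <- gaussian_smear(function(qq) form_factor_i(p, qq),
      q = q, dq = crv$dq
    )
  }
  if (noise > 0) {
    set.seed(seed)
    di <- noise * crv$i
    crv$i <- crv$i + rnorm(length(di), 0, di)
    crv$di <- di
  } else {
    crv$di <- pmax(0.01 * crv$i, 1e-8)
  }
  crv
}

form_factor_i <- protsurf:::form_factor_i

# analytic p(r) of a homogeneous sphere of radius R (unnormalised shape)
sphere_pr <- function(r, R) {
  x <- r / (2 * R)
  ifelse(r < 0 | r > 2 * R, 0, r^2 * (1 - 3 * x / 2 + x^3 / 2))
}
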