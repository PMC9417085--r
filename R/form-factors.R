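#' Geometry parameters of a scattering particle
#'
#' Container for the monodisperse particle models used here: `sphere`,
#' uniform `ellipsoid` (rotational, semi-axes `r_eq, r_eq,
#' axial_ratio * r_eq`) and `core_shell_ellipsoid` (the same core plus a
#' shell of constant thickness on both axes).
#'
#' @param kind One of `"sphere"`, `"ellipsoid"`, `"core_shell_ellipsoid"`.
#' @param radius Core equatorial radius (A).
#' @param axial_ratio Polar/equatorial core axis ratio (1 for a sphere).
#' @param shell_thickness Shell thickness (A); 0 unless core-shell.
#' @param sld_core,sld_shell,sld_solvent SLDs (A^-2). For uniform
#'   particles `sld_shell` is ignored.
#' @param volume_fraction Particle volume fraction, in (0, 1).
#' @param background Flat incoherent background (cm^-1).
#' @return A `geometry_params` list.
#' @export
#' @examples
#' geometry_params("sphere", radius = 30, sld_core = 3.4e-6)
geometry_params <- function(kind = c("sphere", "ellipsoid", "core_shell_ellipsoid"),
                            radius, axial_ratio = 1, shell_thickness = 0,
                            sld_core, sld_shell = sld_core,
                            sld_solvent = 6.37e-6,
                            volume_fraction = 0.01, background = 0) {
  kind <- match.arg(kind)
  check_number(radius, "radius", 0, strict_lower = TRUE)
  check_number(axial_ratio, "axial_ratio", 0, strict_lower = TRUE)
  check_number(shell_thickness, "shell_thickness", 0)
  check_number(volume_fraction, "volume_fraction", 0, 1,
    strict_lower = TRUE, strict_upper = TRUE
  )
  if (kind == "sphere") axial_ratio <- 1
  if (kind != "core_shell_ellipsoid") shell_thickness <- 0
  structure(
    list(
      kind = kind, radius = radius, axial_ratio = axial_ratio,
      shell_thickness = shell_thickness, sld_core = sld_core,
      sld_shell = sld_shell, sld_solvent = sld_solvent,
      volume_fraction = volume_fraction, background = background
    ),
    class = "geometry_params"
  )
}

#' Particle volumes of a geometry
#'
#' @param params A [geometry_params].
#' @return Named list with `v_core`, `v_total` and `v_shell` (A^3).
#' @export
particle_volume <- function(params) {
  a <- params$radius
  c_ <- params$radius * params$axial_ratio
  t <- params$shell_thickness
  v_core <- 4 / 3 * pi * a^2 * c_
  v_total <- 4 / 3 * pi * (a + t)^2 * (c_ + t)
  list(v_core = v_core, v_total = v_total, v_shell = v_total - v_core)
}

# sphere amplitude shape function, 3(sin u - u cos u)/u^3, stable near 0
sphere_shape <- function(u) {
  out <- numeric(length(u))
  small <- abs(u) < 1e-2
  us <- u[small]
  out[small] <- 1 - us^2 / 10 + us^4 / 280
  ul <- u[!small]
  out[!small] <- 3 * (sin(ul) - ul * cos(ul)) / ul^3
  out
}

# orientationally averaged <A(q)^2> for the supported geometries.
# A has units A^-2 * A^3; x = cos(angle between q and symmetry axis).
orient_avg_amp2 <- function(params, q, n_quad = 76) {
  a <- params$radius
  c_ <- a * params$axial_ratio
  t <- params$shell_thickness
  vols <- particle_volume(params)
  drho_cs <- params$sld_core - params$sld_shell
  drho_ss <- params$sld_shell - params$sld_solvent
  drho_c <- params$sld_core - params$sld_solvent
  if (params$kind == "sphere") {
    u <- q * a
    return((drho_c * vols$v_core * sphere_shape(u))^2)
  }
  gl <- pracma::gaussLegendre(n_quad, 0, 1)
  x <- gl$x
  w <- gl$w
  r_core <- sqrt(a^2 * (1 - x^2) + c_^2 * x^2)
  amp2 <- matrix(0, nrow = length(q), ncol = n_quad)
  if (params$kind == "ellipsoid") {
    for (j in seq_len(n_quad)) {
      amp2[, j] <- (drho_c * vols$v_core * sphere_shape(q * r_core[j]))^2
    }
  } else { # core_shell_ellipsoid
    r_out <- sqrt((a + t)^2 * (1 - x^2) + (c_ + t)^2 * x^2)
    for (j in seq_len(n_quad)) {
      amp <- drho_cs * vols$v_core * sphere_shape(q * r_core[j]) +
        drho_ss * vols$v_total * sphere_shape(q * r_out[j])
      amp2[, j] <- amp^2
    }
  }
  drop(amp2 %*% w) # integral over x in [0,1] (weights sum to 1... see below)
}

#' Absolute-scale form-factor intensity of a particle model
#'
#' Orientationally averaged intensity
#' `I(q) = 1e8 * phi * <A(q)^2> / V_total + background` with `A` the
#' contrast-weighted scattering amplitude (A^-2 A^3); the factor 1e8
#' converts A^-1 to cm^-1 so that `I(0) = 1e8 phi V drho^2` for a
#' uniform particle. The orientational average uses Gauss-Legendre
#' quadrature over the cosine of the angle to the symmetry axis
#' (default 76 points).
#'
#' @param params A [geometry_params].
#' @param q Momentum-transfer grid (A^-1).
#' @param n_quad Quadrature order for the orientational average.
#' @param sq Optional structure-factor values on the same grid (default
#'   1, i.e. no interparticle interference).
#' @return A [sans_curve] with the model intensity (di = 0).
#' @export
#' @examples
#' p <- geometry_params("sphere", radius = 30, sld_core = 9.37e-6,
#'   sld_solvent = 6.37e-6, volume_fraction = 0.01)
#' form_factor_intensity(p, q = 0.001)$i # ~1.018 cm^-1
form_factor_intensity <- function(params, q, n_quad = 76, sq = 1) {
  i <- form_factor_i(params, q, n_quad = n_quad, sq = sq)
  sans_curve(q = q, i = i, di = 0, metadata = list(params = params))
}

# same computation on an arbitrary (unsorted) q vector, plain numeric out
form_factor_i <- function(params, q, n_quad = 76, sq = 1) {
  stopifnot(inherits(params, "geometry_params"))
  vols <- particle_volume(params)
  if (vols$v_total <= 0) abort("zero total particle volume.")
  amp2 <- orient_avg_amp2(params, q, n_quad = n_quad)
  1e8 * params$volume_fraction * amp2 / vols$v_total * sq +
    params$background
}
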