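#' Core-shell model of a surfactant-protein complex
#'
#' Shared structural model behind a multi-contrast SANS co-refinement: a
#' core-shell ellipsoid (surfactant core, protein-decorated shell) with
#' partial protein coverage of the shell, a net charge acting through
#' the RMSA structure factor, and per-contrast SLD bindings from a
#' [contrast_scheme()]. The shell SLD of contrast j is the two-component
#' mix `coverage * sld_protein[j] + (1 - coverage) * sld_solvent[j]`.
#' The particle number density follows from the protein concentration
#' (one protein per complex), so the volume fraction tracks the
#' geometry.
#'
#' If the scheme's ZAC solvent SLD is `NA` it is filled in at
#' construction from the zero-average-contrast condition for the dry
#' complex (core volume of surfactant, `coverage` of the shell volume
#' of protein) and then kept fixed, as in an experiment where the
#' solvent is prepared once.
#'
#' @param radius Core equatorial radius (A).
#' @param axial_ratio Core polar/equatorial ratio.
#' @param shell_thickness Shell thickness (A).
#' @param coverage Protein coverage fraction of the shell, in `[0, 1]`.
#' @param charge Net complex charge (elementary charges).
#' @param v_sds Molecular volume of one surfactant (A^3; default 412
#'   for SDS).
#' @param protein_mM Protein (= complex) concentration (mmol/L).
#' @param scheme Contrast scheme tibble; see [contrast_scheme()].
#' @param salt_M,temperature,dielectric Screening environment for the
#'   structure factor.
#' @param scale,background Per-contrast intensity scale factors and flat
#'   backgrounds (cm^-1); recycled over contrasts.
#' @param use_sq Apply the RMSA structure factor (default TRUE).
#' @return A `complex_model` object.
#' @export
complex_model <- function(radius = 12, axial_ratio = 1.5,
                          shell_thickness = 12, coverage = 0.66,
                          charge = -29, v_sds = 412, protein_mM = 0.135,
                          scheme = contrast_scheme(), salt_M = 0.01,
                          temperature = 298.15, dielectric = 78.3,
                          scale = 1, background = 0,
                          use_sq = TRUE) {
  check_number(coverage, "coverage", 0, 1)
  check_number(v_sds, "v_sds", 0, strict_lower = TRUE)
  validate_contrast_scheme(scheme)
  n_con <- nrow(scheme)
  model <- structure(
    list(
      radius = radius, axial_ratio = axial_ratio,
      shell_thickness = shell_thickness, coverage = coverage,
      charge = charge, v_sds = v_sds, protein_mM = protein_mM,
      scheme = scheme, salt_M = salt_M, temperature = temperature,
      dielectric = dielectric,
      scale = setNames(rep_len(scale, n_con), scheme$contrast),
      background = setNames(rep_len(background, n_con), scheme$contrast),
      use_sq = use_sq
    ),
    class = "complex_model"
  )
  if ("zac" %in% scheme$contrast &&
    is.na(scheme$sld_solvent[scheme$contrast == "zac"])) {
    zrow <- scheme[scheme$contrast == "zac", ]
    vols <- model_volumes(model)
    z <- zac_solvent(
      zrow$sld_surfactant, vols$v_core,
      zrow$sld_protein, model$coverage * vols$v_shell
    )
    model$scheme$sld_solvent[model$scheme$contrast == "zac"] <-
      z$sld_solvent
  }
  model
}

model_volumes <- function(model) {
  a <- model$radius
  c_ <- a * model$axial_ratio
  t <- model$shell_thickness
  v_core <- 4 / 3 * pi * a^2 * c_
  v_total <- 4 / 3 * pi * (a + t)^2 * (c_ + t)
  list(v_core = v_core, v_total = v_total, v_shell = v_total - v_core)
}

#' @export
print.complex_model <- function(x, ...) {
  vols <- model_volumes(x)
  cat(sprintf(
    paste0(
      "<complex_model: core %.3g x %.3g A (axial ratio %.3g), shell %.3g A,\n",
      "  coverage %.3g, charge %+.3g e, phi %.3g, N_agg %.3g>\n"
    ),
    x$radius, x$radius * x$axial_ratio, x$axial_ratio,
    x$shell_thickness, x$coverage, x$charge,
    model_volume_fraction(x), nagg_from_core(vols$v_core, x$v_sds)$n_agg
  ))
  invisible(x)
}

# particle number density (A^-3) and volume fraction from concentration
model_number_density <- function(model) {
  model$protein_mM * 6.02214e-7
}

model_volume_fraction <- function(model) {
  model_number_density(model) * model_volumes(model)$v_total
}

# geometry of one contrast as geometry_params (no background; that is
# added after the structure factor)
contrast_geometry <- function(model, contrast) {
  row <- model$scheme[model$scheme$contrast == contrast, ]
  if (nrow(row) != 1) {
    abort(sprintf("contrast '%s' not in the model's scheme.", contrast))
  }
  sld_shell <- model$coverage * row$sld_protein +
    (1 - model$coverage) * row$sld_solvent
  geometry_params(
    "core_shell_ellipsoid",
    radius = model$radius, axial_ratio = model$axial_ratio,
    shell_thickness = model$shell_thickness,
    sld_core = row$sld_surfactant, sld_shell = sld_shell,
    sld_solvent = row$sld_solvent,
    volume_fraction = min(model_volume_fraction(model), 0.7),
    background = 0
  )
}

#' Model intensities of a complex model for one or more contrasts
#'
#' Evaluates `scale * P(q) S(q) + background` per contrast. The
#' Ornstein-Zernike solve behind the structure factor is done once and
#' reused across contrasts and smearing nodes.
#'
#' @param model A [complex_model].
#' @param q_list Named list of q grids (names = contrast labels), or a
#'   single numeric grid used for every contrast in the scheme.
#' @param dq_list Optional named list of per-point resolution widths for
#'   Gaussian smearing.
#' @param sq_quality Structure-factor grid quality, see [rmsa_sq()].
#' @return Named list of intensity vectors (cm^-1).
#' @export
complex_model_intensity <- function(model, q_list, dq_list = NULL,
                                    sq_quality = "accurate") {
  if (!is.list(q_list)) {
    q_list <- setNames(
      rep(list(q_list), nrow(model$scheme)),
      model$scheme$contrast
    )
  }
  labels <- names(q_list)
  phi <- model_volume_fraction(model)
  use_sq <- isTRUE(model$use_sq) && model$charge != 0 && phi > 1e-8
  sq_fun <- function(q) rep(1, length(q))
  if (use_sq) {
    sigma <- equivalent_sphere_diameter(contrast_geometry(model, labels[1]))
    cp <- colloid_params(
      min(phi, 0.7), diameter = sigma, charge = model$charge,
      temperature = model$temperature, dielectric = model$dielectric,
      salt_M = model$salt_M
    )
    # solve once, tabulate S on a fine grid, interpolate thereafter
    rs <- rmsa_solution(cp, quality = sq_quality)
    if (is.null(rs$sol)) {
      sq_fun <- function(q) rep(1, length(q))
    } else {
      q_all <- unlist(q_list, use.names = FALSE)
      q_lo <- min(q_all) * 0.5
      q_hi <- max(q_all) * 1.5
      q_tab <- seq(q_lo, q_hi, length.out = 400)
      s_tab <- sq_from_h(rs$sol, q_tab * sigma * rs$s)
      sq_fun <- function(q) approx(q_tab, s_tab, xout = q, rule = 2)$y
    }
  }
  out <- list()
  for (lab in labels) {
    geo <- contrast_geometry(model, lab)
    q <- q_list[[lab]]
    dq <- if (!is.null(dq_list)) dq_list[[lab]] else NULL
    model_fun <- function(qq) {
      form_factor_i(geo, qq) * sq_fun(qq)
    }
    i <- if (!is.null(dq) && any(dq > 0)) {
      # vectorised +/- 3 sigma Gaussian quadrature over the q resolution
      u <- seq(-3, 3, length.out = 15)
      w0 <- exp(-u^2 / 2)
      qs <- outer(q, rep(1, length(u))) + outer(rep_len(dq, length(q)), u)
      ok <- qs > 0
      vals <- matrix(0, nrow(qs), ncol(qs))
      vals[ok] <- model_fun(qs[ok])
      wmat <- matrix(w0, nrow(qs), ncol(qs), byrow = TRUE) * ok
      rowSums(vals * wmat) / rowSums(wmat)
    } else {
      model_fun(q)
    }
    out[[lab]] <- model$scale[[lab]] * i + model$background[[lab]]
  }
  out
}

#' Aggregation number from the core volume
#'
#' `N_agg = v_core / v_surfactant`: the number of surfactant molecules
#' packed in the complex core.
#'
#' @param v_core Core volume (A^3).
#' @param v_sds Volume of one surfactant molecule (A^3).
#' @return Tibble with `n_agg` (real) and `n_agg_int` (nearest integer).
#' @export
#' @examples
#' nagg_from_core(4120, 412) # 10
nagg_from_core <- function(v_core, v_sds) {
  if (any(v_core <= 0) || any(v_sds <= 0)) abort("volumes must be > 0.")
  tibble(n_agg = v_core / v_sds, n_agg_int = round(v_core / v_sds))
}

#' Protein coverage from the fitted shell SLD
#'
#' Inverts the linear two-component mixing of protein and solvent in the
#' shell: `c = (sld_solvent - sld_shell) / (sld_solvent - sld_protein)`.
#' Values outside `[0, 1]` are clipped with a warning.
#'
#' @param sld_shell,sld_protein,sld_solvent SLDs (A^-2).
#' @return Coverage fraction in `[0, 1]`.
#' @export
coverage_from_shell <- function(sld_shell, sld_protein, sld_solvent) {
  if (abs(sld_solvent - sld_protein) < 1e-12 * max(abs(sld_solvent), 1e-30)) {
    abort("sld_solvent == sld_protein: coverage undefined.")
  }
  c_ <- (sld_solvent - sld_shell) / (sld_solvent - sld_protein)
  if (c_ < 0 || c_ > 1) {
    warn(sprintf("coverage %.3g outside [0, 1]; clipped.", c_))
    c_ <- min(max(c_, 0), 1)
  }
  c_
}

#' Zero-average-contrast forward-scattering check
#'
#' Computes the ZAC solvent for the model's dry composition, evaluates
#' the model intensity at that contrast, and reports the forward
#' intensity together with any internal-correlation maximum at finite q
#' (the segregation fingerprint expected of a core-shell complex at
#' ZAC).
#'
#' @param model A [complex_model]; its `zac` contrast row supplies the
#'   component SLDs.
#' @param q Scan grid (A^-1).
#' @return A list: `i0` (model intensity extrapolated to q -> 0, cm^-1),
#'   `sld_solvent_zac`, `q_peak`/`i_peak` (internal-correlation maximum,
#'   NA if the curve is monotone) and the scanned `curve`.
#' @export
zac_forward_check <- function(model, q = seq(1e-4, 0.5, length.out = 400)) {
  zrow <- model$scheme[model$scheme$contrast == "zac", ]
  if (nrow(zrow) != 1) abort("model scheme has no 'zac' contrast.")
  vols <- model_volumes(model)
  z <- zac_solvent(
    zrow$sld_surfactant, vols$v_core,
    zrow$sld_protein, model$coverage * vols$v_shell
  )
  m <- model
  m$scheme$sld_solvent[m$scheme$contrast == "zac"] <- z$sld_solvent
  m$background[] <- 0
  m$scale[] <- 1
  m$use_sq <- FALSE # forward-scattering property of the form factor
  i <- complex_model_intensity(m, list(zac = q))$zac
  i0 <- i[1]
  # interior local maximum
  peaks <- which(diff(sign(diff(i))) == -2) + 1
  peaks <- peaks[peaks > 2]
  list(
    i0 = i0, sld_solvent_zac = z$sld_solvent,
    q_peak = if (length(peaks)) q[peaks[which.max(i[peaks])]] else NA_real_,
    i_peak = if (length(peaks)) max(i[peaks]) else NA_real_,
    i_max = max(i),
    curve = sans_curve(q = q, i = i, di = 0, contrast = "zac")
  )
}

# --- simultaneous multi-contrast refinement -------------------------------

# raw <-> physical parameter transforms: positives on log scale,
# coverage on logit scale, charge and backgrounds unconstrained
cofit_pack <- function(model) {
  c(
    radius = log(model$radius),
    axial_ratio = log(model$axial_ratio),
    shell_thickness = log(model$shell_thickness),
    coverage = stats::qlogis(min(max(model$coverage, 1e-4), 1 - 1e-4)),
    charge = model$charge,
    setNames(log(model$scale), paste0("scale.", names(model$scale))),
    setNames(model$background, paste0("background.", names(model$background)))
  )
}

cofit_unpack <- function(p, model) {
  m <- model
  m$radius <- exp(p[["radius"]])
  m$axial_ratio <- exp(p[["axial_ratio"]])
  m$shell_thickness <- exp(p[["shell_thickness"]])
  m$coverage <- stats::plogis(p[["coverage"]])
  m$charge <- p[["charge"]]
  sc <- grep("^scale\\.", names(p), value = TRUE)
  m$scale[sub("^scale\\.", "", sc)] <- exp(p[sc])
  bk <- grep("^background\\.", names(p), value = TRUE)
  m$background[sub("^background\\.", "", bk)] <- p[bk]
  m
}

#' Simultaneous co-refinement of multi-contrast SANS curves
#'
#' Fits one shared structural model (core-shell ellipsoid geometry,
#' protein coverage, net charge) to several contrast-variation curves at
#' once by nonlinear least squares on the concatenated
#' uncertainty-weighted residuals. Geometry, coverage and charge are
#' shared across contrasts; an intensity scale factor and a flat
#' background are per contrast. Resolution smearing is applied per curve
#' when a `dq` column is present. A small deterministic grid of start
#' geometries guards against local minima.
#'
#' @param curves Named list of [sans_curve]s; names must be contrast
#'   labels of `model$scheme`.
#' @param model A [complex_model] providing start values, SLD bindings
#'   and fixed experimental conditions.
#' @param free Character vector of parameters to float, from
#'   `c("radius", "axial_ratio", "shell_thickness", "coverage",
#'   "charge", "scale", "background")` (`"scale"`/`"background"` float
#'   one value per contrast).
#' @param sq_quality Structure-factor grid quality used during
#'   optimisation (see [rmsa_sq()]); the default `"coarse"` is accurate
#'   to a few 1e-3 in S(q).
#' @param starts Deterministic start-scale grid: each row multiplies
#'   (radius, shell_thickness) of the start model.
#' @param max_iter Levenberg-Marquardt iteration cap per start.
#' @return A `sans_cofit` object; see `tidy()`, `glance()`,
#'   `augment()` and `autoplot()` methods.
#' @export
sans_cofit <- function(curves, model,
                       free = c(
                         "radius", "axial_ratio", "shell_thickness",
                         "coverage", "charge", "scale", "background"
                       ),
                       sq_quality = "coarse",
                       starts = rbind(
                         c(1, 1), c(0.75, 1.25), c(1.3, 0.8)
                       ),
                       max_iter = 60) {
  if (length(curves) < 1 || is.null(names(curves))) {
    abort("`curves` must be a named list of sans_curve objects.")
  }
  if (!all(names(curves) %in% model$scheme$contrast)) {
    abort("every curve name must match a contrast label of the model scheme.")
  }
  free <- match.arg(free, several.ok = TRUE)
  q_list <- purrr::map(curves, "q")
  dq_list <- purrr::map(curves, function(cv) {
    if ("dq" %in% names(cv)) cv$dq else NULL
  })
  y <- unlist(purrr::map(curves, "i"), use.names = FALSE)
  di <- unlist(purrr::map(curves, function(cv) {
    pmax(cv$di, 1e-10 + 1e-6 * max(cv$i))
  }), use.names = FALSE)
  p_full <- cofit_pack(model)
  is_free <- vapply(names(p_full), function(nm) {
    base <- sub("\\..*$", "", nm)
    base %in% free
  }, logical(1))
  resid_fun <- function(p_free) {
    p <- p_full
    p[is_free] <- p_free
    m <- cofit_unpack(p, model)
    i_model <- tryCatch(
      unlist(
        complex_model_intensity(m, q_list, dq_list, sq_quality = sq_quality),
        use.names = FALSE
      ),
      error = function(e) rep(1e6, length(y))
    )
    (i_model - y) / di
  }
  best <- NULL
  for (srow in seq_len(nrow(starts))) {
    m0 <- model
    m0$radius <- model$radius * starts[srow, 1]
    m0$shell_thickness <- model$shell_thickness * starts[srow, 2]
    p0 <- cofit_pack(m0)[is_free]
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = p0, fn = resid_fun,
        control = minpack.lm::nls.lm.control(maxiter = max_iter)
      ),
      error = function(e) NULL
    )
    if (!is.null(fit) && (is.null(best) || fit$deviance < best$deviance)) {
      best <- fit
    }
  }
  if (is.null(best)) abort("co-refinement failed from every start point.")
  p_hat <- p_full
  p_hat[is_free] <- best$par
  m_hat <- cofit_unpack(p_hat, model)
  # covariance of the free raw parameters from J'J at the optimum
  cov_free <- tryCatch(solve(best$hessian), error = function(e) {
    matrix(NA_real_, length(best$par), length(best$par))
  })
  # physical parameters and derived quantities as functions of raw p
  phys_fun <- function(p) {
    m <- cofit_unpack(p, model)
    vols <- model_volumes(m)
    c(
      radius = m$radius, axial_ratio = m$axial_ratio,
      shell_thickness = m$shell_thickness, coverage = m$coverage,
      charge = m$charge,
      n_agg = vols$v_core / m$v_sds,
      v_core = vols$v_core,
      setNames(m$scale, paste0("scale.", names(m$scale))),
      setNames(m$background, paste0("background.", names(m$background)))
    )
  }
  est <- phys_fun(p_hat)
  # delta method: numeric jacobian wrt the free raw parameters
  J <- matrix(0, length(est), sum(is_free))
  hstep <- 1e-5
  for (j in seq_len(sum(is_free))) {
    pp <- p_hat
    pm <- p_hat
    idx <- which(is_free)[j]
    pp[idx] <- pp[idx] + hstep
    pm[idx] <- pm[idx] - hstep
    J[, j] <- (phys_fun(pp) - phys_fun(pm)) / (2 * hstep)
  }
  se <- sqrt(pmax(rowSums((J %*% cov_free) * J), 0))
  se[rowSums(abs(J)) == 0] <- 0 # fixed parameters
  # per-contrast reduced chi-squared
  res_hat <- resid_fun(best$par)
  n_per <- lengths(q_list)
  idx_end <- cumsum(n_per)
  idx_start <- c(1, head(idx_end, -1) + 1)
  k_shared <- sum(is_free)
  chi2 <- tibble(
    contrast = names(curves),
    n = as.integer(n_per),
    chi2_red = vapply(seq_along(n_per), function(i) {
      sum(res_hat[idx_start[i]:idx_end[i]]^2) /
        max(n_per[i] - k_shared / length(n_per), 1)
    }, numeric(1))
  )
  structure(
    list(
      model = m_hat, start_model = model,
      estimates = tibble(
        term = names(est), estimate = unname(est), std.error = unname(se)
      ),
      chi2 = chi2,
      chi2_red_total = best$deviance / max(length(y) - k_shared, 1),
      deviance = best$deviance,
      free = names(p_full)[is_free],
      curves = curves, niter = best$niter,
      converged = best$info %in% 1:4,
      info = best$info, message = best$message,
      cov_free = cov_free
    ),
    class = "sans_cofit"
  )
}

#' @export
print.sans_cofit <- function(x, ...) {
  cat(sprintf(
    "<sans_cofit: %d contrasts, chi2_red = %.3g, %s after %d iterations>\n",
    nrow(x$chi2), x$chi2_red_total,
    if (x$converged) "converged" else "NOT converged", x$niter
  ))
  print(x$estimates, n = nrow(x$estimates))
  invisible(x)
}

#' @export
tidy.sans_cofit <- function(x, ...) {
  dplyr::mutate(x$estimates, fixed = !(
    .data$term %in% c(
      "n_agg", "v_core",
      x$free,
      sub("^(scale|background)$", "", x$free)
    ) |
      sub("\\..*$", "", .data$term) %in% x$free
  ))
}

#' @export
glance.sans_cofit <- function(x, ...) {
  est <- setNames(x$estimates$estimate, x$estimates$term)
  se <- setNames(x$estimates$std.error, x$estimates$term)
  tibble(
    chi2_red = x$chi2_red_total,
    n_agg = est[["n_agg"]], n_agg_se = se[["n_agg"]],
    coverage = est[["coverage"]], coverage_se = se[["coverage"]],
    charge = est[["charge"]], charge_se = se[["charge"]],
    radius = est[["radius"]], shell_thickness = est[["shell_thickness"]],
    converged = x$converged, niter = x$niter
  )
}

#' @export
augment.sans_cofit <- function(x, ...) {
  q_list <- purrr::map(x$curves, "q")
  dq_list <- purrr::map(x$curves, function(cv) {
    if ("dq" %in% names(cv)) cv$dq else NULL
  })
  fit_i <- complex_model_intensity(x$model, q_list, dq_list,
    sq_quality = "accurate"
  )
  purrr::map_dfr(names(x$curves), function(lab) {
    cv <- x$curves[[lab]]
    tibble(
      contrast = lab, q = cv$q, i = cv$i, di = cv$di,
      i_fit = fit_i[[lab]]
    )
  })
}

#' Write a co-refinement report to JSON
#'
#' Parameters with uncertainties, per-contrast goodness of fit and the
#' derived quantities, in one machine-readable file.
#'
#' @param fit A `sans_cofit`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_cofit_report <- function(fit, path) {
  jsonlite::write_json(
    list(
      estimates = fit$estimates,
      chi2_per_contrast = fit$chi2,
      chi2_red_total = fit$chi2_red_total,
      free_parameters = fit$free,
      converged = fit$converged,
      iterations = fit$niter
    ),
    path,
    auto_unbox = TRUE, digits = NA, dataframe = "rows"
  )
  invisible(path)
}
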