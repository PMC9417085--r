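#' Titrant concentration in a perfusion ITC cell
#'
#' Standard displacement model for an overfilled perfusion cell: each
#' injection of volume `v` displaces a fraction `v / V0` of the (mixed)
#' cell content, so after injections `1..k` the titrant concentration is
#' `C_syringe * (1 - prod(1 - v_i / V0))`.
#'
#' @param injection_uL Injection volumes (uL), in order.
#' @param syringe_mM Titrant concentration in the syringe (mM).
#' @param cell_uL Active cell volume (uL); default 1400 (VP-ITC).
#' @return Cumulative titrant concentration (mM) after each injection.
#' @export
itc_cell_concentration <- function(injection_uL, syringe_mM,
                                   cell_uL = 1400) {
  check_number(syringe_mM, "syringe_mM", 0, strict_lower = TRUE)
  check_number(cell_uL, "cell_uL", 0, strict_lower = TRUE)
  if (any(injection_uL <= 0)) abort("injection volumes must be > 0.")
  syringe_mM * (1 - cumprod(1 - injection_uL / cell_uL))
}

#' Construct an ITC enthalpogram table
#'
#' @param injection Injection index (1..n).
#' @param conc_mM Cumulative, dilution-corrected titrant concentration
#'   in the cell (mM), strictly increasing.
#' @param heat Molar heat per injection (kcal/mol of injectant).
#' @param protein_uM Protein concentration in the cell (uM).
#' @return An `enthalpogram` tibble.
#' @export
enthalpogram <- function(injection, conc_mM, heat, protein_uM = NA_real_) {
  if (is.unsorted(conc_mM, strictly = TRUE)) {
    abort("cumulative concentration must be strictly increasing.")
  }
  structure(
    tibble(injection = injection, conc_mM = conc_mM, heat = heat),
    class = c("enthalpogram", class(tibble())),
    protein_uM = protein_uM
  )
}

# exact weighted-OLS segment cost over points i..j (prefix sums would be
# marginally faster; n is tens of injections, so direct lm is fine)
seg_sse <- function(x, y, w, i, j) {
  xi <- x[i:j]
  yi <- y[i:j]
  wi <- w[i:j]
  if (length(unique(xi)) < 2) {
    return(sum(wi * (yi - weighted.mean(yi, wi))^2))
  }
  f <- lm(yi ~ xi, weights = wi)
  sum(wi * f$residuals^2)
}

#' Detect candidate transitions in an enthalpogram
#'
#' Segments molar heat versus cumulative titrant concentration into at
#' most `n_max` linear pieces by exact dynamic programming (minimum
#' total squared residual for each segment count), then picks the
#' segment count by BIC. Segment boundaries are returned as candidate
#' transition concentrations: the intersection of the adjacent fitted
#' lines when it falls between the flanking points, otherwise their
#' midpoint. The proposal is meant to be reviewed (and possibly pinned
#' manually) by the analyst, mirroring expert reading of enthalpograms.
#'
#' @param entha An [enthalpogram] (or data frame with `conc_mM`,
#'   `heat`), >= 15 injections.
#' @param n_max Maximum number of segments to consider.
#' @param min_seg Minimum points per segment (default 3).
#' @param weights Optional weights (default equal).
#' @return An `itc_transitions` list: `transitions` tibble (one row per
#'   interior boundary), `n_segments`, per-segment line table, and the
#'   BIC trace.
#' @export
detect_transitions <- function(entha, n_max = 6, min_seg = 3,
                               weights = NULL) {
  stopifnot(is.data.frame(entha), all(c("conc_mM", "heat") %in% names(entha)))
  x <- entha$conc_mM
  y <- entha$heat
  n <- length(x)
  if (n < 15) abort("need at least 15 injections for segmentation.")
  w <- weights %||% rep(1, n)
  n_max <- min(n_max, n %/% min_seg)
  # cost[i, j]: SSE of one segment spanning points i..j
  cost <- matrix(Inf, n, n)
  for (i in 1:(n - min_seg + 1)) {
    for (j in (i + min_seg - 1):n) {
      cost[i, j] <- seg_sse(x, y, w, i, j)
    }
  }
  # dp[k, j]: best SSE for first j points in k segments
  dp <- matrix(Inf, n_max, n)
  cut <- matrix(NA_integer_, n_max, n)
  dp[1, ] <- cost[1, ]
  if (n_max >= 2) {
    for (k in 2:n_max) {
      for (j in (k * min_seg):n) {
        ms <- ((k - 1) * min_seg):(j - min_seg)
        vals <- dp[k - 1, ms] + cost[cbind(ms + 1, j)]
        b <- which.min(vals)
        dp[k, j] <- vals[b]
        cut[k, j] <- ms[b]
      }
    }
  }
  sse_k <- dp[, n]
  bic <- n * log(pmax(sse_k, 1e-12) / n) + 3 * seq_len(n_max) * log(n)
  k_star <- which.min(bic)
  # backtrack boundaries
  bounds <- integer(0)
  j <- n
  k <- k_star
  while (k > 1) {
    b <- cut[k, j]
    bounds <- c(b, bounds)
    j <- b
    k <- k - 1
  }
  seg_start <- c(1, bounds + 1)
  seg_end <- c(bounds, n)
  lines <- purrr::map_dfr(seq_len(k_star), function(s) {
    i <- seg_start[s]:seg_end[s]
    f <- lm(y ~ x, data = data.frame(x = x[i], y = y[i]), weights = w[i])
    tibble(
      segment = s, from = x[seg_start[s]], to = x[seg_end[s]],
      intercept = coef(f)[[1]], slope = coef(f)[[2]]
    )
  })
  transitions <- if (length(bounds)) {
    purrr::map_dfr(seq_along(bounds), function(b) {
      l1 <- lines[b, ]
      l2 <- lines[b + 1, ]
      xl <- x[bounds[b]]
      xr <- x[bounds[b] + 1]
      xi <- if (abs(l1$slope - l2$slope) > 1e-12) {
        (l2$intercept - l1$intercept) / (l1$slope - l2$slope)
      } else {
        NA_real_
      }
      if (is.na(xi) || xi < xl || xi > xr) xi <- (xl + xr) / 2
      tibble(
        transition = b, conc_mM = xi,
        between = sprintf("%d-%d", bounds[b], bounds[b] + 1)
      )
    })
  } else {
    tibble(
      transition = integer(), conc_mM = numeric(), between = character()
    )
  }
  structure(
    list(
      transitions = transitions, n_segments = k_star,
      requested_max = n_max, segments = lines,
      bic = tibble(k = seq_len(n_max), sse = sse_k, bic = bic),
      found_fewer = k_star < n_max
    ),
    class = "itc_transitions"
  )
}

#' @export
print.itc_transitions <- function(x, ...) {
  cat(sprintf(
    "<itc_transitions: %d segments, %d interior transition(s)>\n",
    x$n_segments, nrow(x$transitions)
  ))
  if (nrow(x$transitions)) print(x$transitions)
  invisible(x)
}

#' Binding stoichiometry from transition concentrations
#'
#' Weighted linear regression of the surfactant concentration at which a
#' given enthalpogram transition occurs against the protein
#' concentration, following the binding decomposition
#' `[SDS] = [SDS]_unbound + N_agg [protein]`: the slope is the number of
#' surfactant molecules bound per protein, the intercept the free
#' surfactant concentration.
#'
#' @param data Data frame with `protein_uM` and `sds_mM` (one row per
#'   titration), optionally `weight`.
#' @return An `itc_transition_fit`; `glance()` gives `n_agg` and
#'   `sds_unbound_mM` with standard errors.
#' @export
#' @examples
#' itc_transition_fit(tibble::tibble(
#'   protein_uM = c(25, 50, 75), sds_mM = c(2.1, 2.9, 3.7)
#' )) # N_agg = 32, unbound = 1.3 mM
itc_transition_fit <- function(data) {
  stopifnot(
    is.data.frame(data),
    all(c("protein_uM", "sds_mM") %in% names(data))
  )
  if (length(unique(data$protein_uM)) < 2) {
    abort("need at least two distinct protein concentrations.")
  }
  w <- if ("weight" %in% names(data)) data$weight else rep(1, nrow(data))
  # protein in mM so the slope (N_agg) is dimensionless
  fit <- lm(sds_mM ~ protein_mM,
    data = data.frame(
      sds_mM = data$sds_mM, protein_mM = data$protein_uM / 1000
    ),
    weights = w
  )
  b <- coef(fit)
  se <- sqrt(diag(suppressWarnings(vcov(fit))))
  se[!is.finite(se)] <- 0
  structure(
    list(
      n_agg = b[[2]], n_agg_se = se[[2]],
      sds_unbound_mM = b[[1]], sds_unbound_se = se[[1]],
      fit = fit, data = as_tibble(data)
    ),
    class = "itc_transition_fit"
  )
}

#' @export
print.itc_transition_fit <- function(x, ...) {
  cat(sprintf(
    "ITC transition: N_agg = %.3g +/- %.2g, [SDS]_unbound = %.3g +/- %.2g mM\n",
    x$n_agg, x$n_agg_se, x$sds_unbound_mM, x$sds_unbound_se
  ))
  invisible(x)
}

#' @export
tidy.itc_transition_fit <- function(x, ...) {
  tibble(
    term = c("n_agg", "sds_unbound_mM"),
    estimate = c(x$n_agg, x$sds_unbound_mM),
    std.error = c(x$n_agg_se, x$sds_unbound_se)
  )
}

#' @export
glance.itc_transition_fit <- function(x, ...) {
  tibble(
    n_agg = x$n_agg, n_agg_se = x$n_agg_se,
    sds_unbound_mM = x$sds_unbound_mM,
    sds_unbound_se = x$sds_unbound_se,
    n = nrow(x$data)
  )
}

#' Total surfactant concentration at a transition for a given protein
#' concentration
#'
#' Applies the binding decomposition forward:
#' `[SDS]_total = [SDS]_unbound + N_agg [protein]`, and reports the
#' surfactant-to-protein ratio.
#'
#' @param fit An [itc_transition_fit], or any list/one-row data frame
#'   with `n_agg` and `sds_unbound_mM` (e.g. a published table row).
#' @param protein_uM Protein concentration(s) (uM), >= 0.
#' @return Tibble with `protein_uM`, `total_mM` and `ratio`
#'   (`NA` at zero protein), plus `ratio_int`.
#' @export
#' @examples
#' predict_total_sds(list(n_agg = 32, sds_unbound_mM = 1.3), 50)
predict_total_sds <- function(fit, protein_uM) {
  n_agg <- fit$n_agg
  unbound <- fit$sds_unbound_mM
  if (is.null(n_agg) || is.null(unbound)) {
    abort("`fit` must carry `n_agg` and `sds_unbound_mM`.")
  }
  if (any(protein_uM < 0)) abort("protein_uM must be >= 0.")
  total <- unbound + n_agg * protein_uM / 1000
  ratio <- ifelse(protein_uM > 0, total * 1000 / protein_uM, NA_real_)
  tibble(
    protein_uM = protein_uM, total_mM = total,
    ratio = ratio, ratio_int = round(ratio)
  )
}
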