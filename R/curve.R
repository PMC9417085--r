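#' Construct a reduced small-angle scattering curve
#'
#' A `sans_curve` is a tibble with columns `q` (A^-1, strictly
#' increasing, > 0), `i` (cm^-1), `di` (cm^-1, >= 0) and optionally `dq`
#' (A^-1, the 1-sigma Gaussian resolution width), plus metadata
#' attributes (contrast label, solvent composition, concentrations).
#'
#' @param q,i Momentum transfer (A^-1) and intensity (cm^-1).
#' @param di 1-sigma intensity uncertainty (cm^-1); default 0.
#' @param dq Optional 1-sigma resolution width per point (A^-1).
#' @param contrast,f_h2o,metadata Optional provenance: contrast label,
#'   solvent H2O fraction, and a free-form metadata list.
#' @return A `sans_curve` tibble.
#' @export
#' @examples
#' sans_curve(q = c(0.01, 0.02), i = c(10, 8), di = c(0.1, 0.1))
sans_curve <- function(q, i, di = 0, dq = NULL, contrast = NA_character_,
                       f_h2o = NA_real_, metadata = list()) {
  di <- rep_len(di, length(q))
  dat <- tibble(q = as.numeric(q), i = as.numeric(i), di = as.numeric(di))
  if (!is.null(dq)) dat$dq <- rep_len(as.numeric(dq), length(q))
  new_sans_curve(dat, contrast = contrast, f_h2o = f_h2o, metadata = metadata)
}

new_sans_curve <- function(dat, contrast = NA_character_, f_h2o = NA_real_,
                           metadata = list()) {
  dat <- as_tibble(dat)
  validate_sans_curve(dat)
  structure(dat,
    class = c("sans_curve", class(tibble())),
    contrast = contrast, f_h2o = f_h2o, metadata = metadata
  )
}

validate_sans_curve <- function(dat) {
  if (!all(c("q", "i", "di") %in% names(dat))) {
    abort("a sans_curve needs columns q, i, di.")
  }
  if (any(dat$q <= 0)) abort("q must be strictly positive.")
  if (is.unsorted(dat$q, strictly = TRUE)) {
    abort("q must be strictly increasing.")
  }
  if (any(dat$di < 0)) abort("di must be >= 0.")
  if ("dq" %in% names(dat) && any(dat$dq < 0)) abort("dq must be >= 0.")
  invisible(dat)
}

#' @export
print.sans_curve <- function(x, ...) {
  cat(sprintf(
    "<sans_curve: %d points, q in [%.4g, %.4g] A^-1%s%s>\n",
    nrow(x), min(x$q), max(x$q),
    if (!is.na(attr(x, "contrast"))) {
      paste0(", contrast = ", attr(x, "contrast"))
    } else "",
    if ("dq" %in% names(x)) ", with resolution column" else ""
  ))
  NextMethod()
}

#' Read an ASCII small-angle scattering file
#'
#' Parses the conventional reduced-data format: '#'-prefixed comment
#' header followed by 3 or 4 whitespace-delimited numeric columns
#' `q I dI [dq]` in A^-1 / cm^-1. The file path is recorded in the
#' curve's metadata.
#'
#' @param path File path.
#' @param contrast,f_h2o Optional labels stored as curve attributes.
#' @return A [sans_curve].
#' @export
read_sans <- function(path, contrast = NA_character_, f_h2o = NA_real_) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  body <- lines[keep]
  if (!length(body)) abort(sprintf("%s: no data rows.", path))
  rows <- strsplit(trimws(body), "[[:space:],;]+")
  ncols <- lengths(rows)
  if (any(ncols < 3)) {
    abort(sprintf(
      "%s: line %d has fewer than 3 columns.",
      path, which(keep)[which(ncols < 3)[1]]
    ))
  }
  nc <- min(ncols)
  vals <- vapply(rows, function(r) as.numeric(r[seq_len(nc)]), numeric(nc))
  vals <- if (nc == 1) matrix(vals, nrow = 1) else vals
  dat <- tibble(q = vals[1, ], i = vals[2, ], di = vals[3, ])
  if (nc >= 4) dat$dq <- vals[4, ]
  bad <- which(diff(dat$q) <= 0)
  if (length(bad)) {
    abort(sprintf(
      "%s: q not strictly increasing at data line %d.", path, bad[1] + 1L
    ))
  }
  new_sans_curve(dat,
    contrast = contrast, f_h2o = f_h2o,
    metadata = list(path = path, header = lines[!keep])
  )
}

#' Write a scattering curve to the ASCII format read by [read_sans()]
#'
#' @param curve A [sans_curve].
#' @param path Output path.
#' @param comment Optional comment line(s) for the header.
#' @return `path`, invisibly.
#' @export
write_sans <- function(curve, path, comment = NULL) {
  validate_sans_curve(curve)
  cols <- c("q", "i", "di", intersect("dq", names(curve)))
  hdr <- c(
    paste0("# ", comment %||% "protsurf sans_curve"),
    paste0("# columns: ", paste(cols, collapse = " "), " (A^-1, cm^-1)")
  )
  body <- do.call(paste, c(
    lapply(cols, function(cn) formatC(curve[[cn]], format = "g", digits = 9)),
    sep = " "
  ))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Integrated scattered intensity over a q window
#'
#' Trapezoidal integral of `I(q)` over `[qmin, qmax]`, the tracker used
#' to follow surfactant aggregation across a concentration series.
#'
#' @param curve A [sans_curve] or data frame with `q`, `i`.
#' @param qmin,qmax Integration window (A^-1); defaults to the full
#'   curve support.
#' @return The integral (cm^-1 A^-1).
#' @export
integrated_intensity <- function(curve, qmin = min(curve$q),
                                 qmax = max(curve$q)) {
  stopifnot(is.data.frame(curve), all(c("q", "i") %in% names(curve)))
  if (qmax <= qmin) abort("empty integration window (qmax <= qmin).")
  if (qmin < min(curve$q) - 1e-12 || qmax > max(curve$q) + 1e-12) {
    abort("integration window outside the curve support.")
  }
  # clip to the window, adding interpolated endpoints
  inside <- curve$q > qmin & curve$q < qmax
  qs <- c(qmin, curve$q[inside], qmax)
  is_ <- approx(curve$q, curve$i, xout = qs, rule = 2)$y
  pracma::trapz(qs, is_)
}
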