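#' Build a uniform scan grid
#'
#' Wavelength grid for a spectrophotometric scan: a closed interval sampled at
#' a constant step. The default matches a 200-350 nm scan at 0.2 nm
#' resolution (751 points), the usual configuration of a double-beam UV-Vis
#' instrument for pharmaceutical assays.
#'
#' @param start,stop Scan limits in nm; `start < stop`.
#' @param step Sampling interval in nm (> 0).
#' @return Numeric vector of strictly increasing, uniformly spaced
#'   wavelengths, `round((stop - start) / step) + 1` points.
#' @examples
#' length(scan_grid()) # 751
#' @export
scan_grid <- function(start = 200, stop = 350, step = 0.2) {
  stopifnot(is.numeric(start), is.numeric(stop), is.numeric(step))
  if (start >= stop) rlang::abort("`start` must be < `stop`.")
  if (step <= 0) rlang::abort("`step` must be > 0.")
  n <- round((stop - start) / step) + 1
  start + step * (seq_len(n) - 1)
}

grid_step <- function(wavelength) {
  d <- diff(wavelength)
  if (length(d) == 0) rlang::abort("Grid needs at least 2 points.")
  if (any(d <= 0) || diff(range(d)) > 1e-6) {
    rlang::abort("Wavelengths must be strictly increasing and uniformly spaced.")
  }
  stats::median(d)
}

same_grid <- function(a, b, tol = 1e-9) {
  length(a$wavelength) == length(b$wavelength) &&
    max(abs(a$wavelength - b$wavelength)) <= tol
}

#' Construct an absorption spectrum
#'
#' A spectrum is a tibble with columns `wavelength` (nm, uniform ascending
#' grid) and `absorbance` (AU), carrying optional metadata (`label`,
#' `concentration` in ug/mL, `solvent`) as attributes. All package verbs
#' accept any data frame with these two columns.
#'
#' @param wavelength Numeric, uniform ascending grid (nm).
#' @param absorbance Numeric, same length, all finite.
#' @param label,solvent Optional free-text metadata.
#' @param concentration Optional concentration in ug/mL.
#' @return A `uv_spectrum` tibble.
#' @examples
#' s <- new_spectrum(scan_grid(), rep(0.1, 751), label = "demo")
#' @export
new_spectrum <- function(wavelength, absorbance, label = NULL,
                         concentration = NULL, solvent = NULL) {
  wavelength <- as.numeric(wavelength)
  absorbance <- as.numeric(absorbance)
  if (length(wavelength) != length(absorbance)) {
    rlang::abort("`wavelength` and `absorbance` must have equal length.")
  }
  grid_step(wavelength)
  if (!all(is.finite(absorbance))) rlang::abort("All absorbances must be finite.")
  out <- tibble::tibble(wavelength = wavelength, absorbance = absorbance)
  class(out) <- c("uv_spectrum", class(out))
  attr(out, "label") <- label
  attr(out, "concentration") <- concentration
  attr(out, "solvent") <- solvent
  out
}

#' @export
print.uv_spectrum <- function(x, ...) {
  lab <- attr(x, "label")
  conc <- attr(x, "concentration")
  hdr <- sprintf(
    "<uv_spectrum> %s%s: %d points, %.1f-%.1f nm",
    if (is.null(lab)) "(unlabelled)" else lab,
    if (is.null(conc)) "" else sprintf(" @ %g ug/mL", conc),
    nrow(x), min(x$wavelength), max(x$wavelength)
  )
  cat(hdr, "\n")
  NextMethod()
}

spectrum_meta <- function(s) {
  list(
    label = attr(s, "label"),
    concentration = attr(s, "concentration"),
    solvent = attr(s, "solvent")
  )
}

#' Read a spectrum from file
#'
#' CSV files carry two numeric columns (wavelength in nm, absorbance in AU)
#' with an optional single header line. JCAMP-DX files are read from their
#' `##XYDATA=(X++(Y..Y))` block (affine form only, read-only). Input sampled
#' on a different grid than `grid` is linearly interpolated onto it;
#' wavelengths falling outside the requested grid are clipped with a warning.
#'
#' @param path Path to the file.
#' @param format `"auto"` (by extension), `"csv"` or `"jcamp"`.
#' @param grid Target wavelength grid; `NULL` keeps the file's own grid.
#' @inheritParams new_spectrum
#' @return A [new_spectrum()] tibble.
#' @export
read_spectrum <- function(path, format = c("auto", "csv", "jcamp"),
                          grid = NULL, label = NULL, concentration = NULL,
                          solvent = NULL) {
  format <- rlang::arg_match(format)
  if (!file.exists(path)) rlang::abort(sprintf("File not found: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.(jdx|dx|jcamp)$", tolower(path))) "jcamp" else "csv"
  }
  raw <- switch(format, csv = read_spectrum_csv(path), jcamp = read_jcamp(path))
  ord <- order(raw$wavelength)
  raw <- raw[ord, ]
  if (anyDuplicated(raw$wavelength)) {
    rlang::abort("Duplicate wavelengths in spectrum file.")
  }
  if (!is.null(grid)) {
    inside <- raw$wavelength >= min(grid) - 1e-9 & raw$wavelength <= max(grid) + 1e-9
    if (!all(inside)) {
      rlang::warn("Wavelengths outside the requested grid were clipped.")
      raw <- raw[inside, ]
    }
    if (nrow(raw) < 2) rlang::abort("Too few points inside the requested grid.")
    target <- grid[grid >= min(raw$wavelength) - 1e-9 &
                     grid <= max(raw$wavelength) + 1e-9]
    if (length(target) < length(grid)) {
      rlang::warn("Input does not cover the full grid; output truncated to coverage.")
    }
    ab <- stats::approx(raw$wavelength, raw$absorbance, xout = target)$y
    raw <- tibble::tibble(wavelength = target, absorbance = ab)
  }
  new_spectrum(raw$wavelength, raw$absorbance, label = label,
               concentration = concentration, solvent = solvent)
}

read_spectrum_csv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) rlang::abort("Empty spectrum file.")
  first <- strsplit(lines[[1]], ",", fixed = TRUE)[[1]]
  has_header <- anyNA(suppressWarnings(as.numeric(first)))
  if (has_header) lines <- lines[-1]
  if (length(lines) == 0) rlang::abort("Empty spectrum file.")
  dat <- readr::read_csv(
    I(paste(lines, collapse = "\n")),
    col_names = FALSE,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  if (ncol(dat) < 2) rlang::abort("Spectrum CSV needs two columns.")
  wl <- suppressWarnings(as.numeric(dat[[1]]))
  ab <- suppressWarnings(as.numeric(dat[[2]]))
  if (anyNA(wl) || anyNA(ab)) rlang::abort("Non-numeric rows in spectrum CSV.")
  if (length(wl) == 0) rlang::abort("Empty spectrum file.")
  tibble::tibble(wavelength = wl, absorbance = ab)
}

# Minimal JCAMP-DX reader: affine ##XYDATA=(X++(Y..Y)) blocks only.
read_jcamp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  get_field <- function(key, default = NA_real_) {
    hit <- grep(sprintf("^##%s=", key), lines, ignore.case = TRUE, value = TRUE)
    if (length(hit) == 0) return(default)
    as.numeric(sub("^##[^=]+=", "", hit[[1]]))
  }
  xf <- get_field("XFACTOR", 1)
  yf <- get_field("YFACTOR", 1)
  firstx <- get_field("FIRSTX")
  lastx <- get_field("LASTX")
  npoints <- get_field("NPOINTS")
  start <- grep("^##XYDATA=\\(X\\+\\+\\(Y\\.\\.Y\\)\\)", lines)
  if (length(start) == 0) rlang::abort("No (X++(Y..Y)) XYDATA block found.")
  stop_at <- grep("^##", lines)
  stop_at <- c(stop_at[stop_at > start[[1]]], length(lines) + 1)[1]
  body <- lines[(start[[1]] + 1):(stop_at - 1)]
  body <- body[nzchar(trimws(body))]
  dx <- if (is.finite(firstx) && is.finite(lastx) && is.finite(npoints) &&
            npoints > 1) (lastx - firstx) / (npoints - 1) else NA_real_
  rows <- lapply(body, function(ln) {
    tok <- as.numeric(strsplit(trimws(ln), "\\s+")[[1]])
    if (anyNA(tok) || length(tok) < 2) rlang::abort("Malformed XYDATA line.")
    x0 <- tok[[1]] * xf
    y <- tok[-1] * yf
    step <- if (is.finite(dx)) dx * xf else NA_real_
    if (!is.finite(step)) rlang::abort("Cannot derive DELTAX for XYDATA block.")
    tibble::tibble(wavelength = x0 + step * (seq_along(y) - 1), absorbance = y)
  })
  dplyr::bind_rows(rows)
}

#' Write a spectrum to CSV
#'
#' Columns `wavelength_nm,absorbance`, full double precision so a write/read
#' round trip reproduces the data.
#'
#' @param s A spectrum.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(s, path) {
  out <- tibble::tibble(wavelength_nm = s$wavelength, absorbance = s$absorbance)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Pointwise spectrum subtraction
#'
#' Blank correction: subtract a blank (e.g. plasma blank or solvent) scan
#' from a sample scan recorded on the identical grid.
#'
#' @param a,b Spectra on identical grids.
#' @return `a - b` as a spectrum; metadata taken from `a`.
#' @export
subtract_spectrum <- function(a, b) {
  if (!same_grid(a, b)) rlang::abort("Spectra are not on the same grid.")
  m <- spectrum_meta(a)
  new_spectrum(a$wavelength, a$absorbance - b$absorbance,
               label = m$label, concentration = m$concentration,
               solvent = m$solvent)
}

#' Ratio spectrum
#'
#' Divides a sample spectrum pointwise by a standard spectrum of one
#' component (the divisor). On the ratio trace the divisor's own component
#' contributes a wavelength-independent constant, which downstream amplitude
#' differences or derivatives remove. Points where the divisor absorbance
#' falls below `guard` are masked as invalid (`valid = FALSE`,
#' `amplitude = NA`) to keep detector noise from being amplified without
#' bound.
#'
#' @param numerator Sample spectrum.
#' @param divisor Divisor spectrum on the identical grid; its `label` and
#'   `concentration` attributes are carried onto the result.
#' @param guard Minimum divisor absorbance (AU) for a valid ratio point.
#' @return A `ratio_spectrum` tibble: `wavelength`, `amplitude`, `valid`.
#' @export
ratio_spectrum <- function(numerator, divisor, guard = 0.01) {
  if (!same_grid(numerator, divisor)) {
    rlang::abort("Numerator and divisor are not on the same grid.")
  }
  valid <- divisor$absorbance >= guard
  if (!any(valid)) rlang::abort("Divisor is below the guard threshold everywhere.")
  amp <- ifelse(valid, numerator$absorbance / divisor$absorbance, NA_real_)
  out <- tibble::tibble(wavelength = numerator$wavelength,
                        amplitude = amp, valid = valid)
  class(out) <- c("ratio_spectrum", class(out))
  attr(out, "divisor_label") <- attr(divisor, "label")
  attr(out, "divisor_concentration") <- attr(divisor, "concentration")
  attr(out, "guard") <- guard
  out
}

#' Derivative configuration
#'
#' Window and scaling of the first-derivative transform. `delta_lambda` is
#' the full differencing window in nm and must be a positive even multiple
#' of the grid step so the half-window lands on grid nodes; `scale` is the
#' dimensionless amplification the instrument software applies to derivative
#' traces. Defaults (4 nm, 10) are the usual settings for derivative-ratio
#' work on 0.2 nm scans.
#'
#' @param delta_lambda Differencing window, nm.
#' @param scale Amplitude scaling, > 0.
#' @param method `"central"` (default) for the symmetric finite difference
#'   over the window, or `"savgol"` for a Savitzky-Golay first derivative
#'   over the same window (needs the signal package).
#' @return A `deriv_config` list.
#' @export
deriv_config <- function(delta_lambda = 4, scale = 10,
                         method = c("central", "savgol")) {
  method <- rlang::arg_match(method)
  if (delta_lambda <= 0) rlang::abort("`delta_lambda` must be > 0.")
  if (scale <= 0) rlang::abort("`scale` must be > 0.")
  structure(list(delta_lambda = delta_lambda, scale = scale, method = method),
            class = "deriv_config")
}

#' First-derivative trace of a spectrum or ratio spectrum
#'
#' Symmetric finite difference over the configured window:
#' `D(w) = scale * (A(w + d/2) - A(w - d/2)) / d` with `d = delta_lambda`.
#' Points within half a window of the grid ends are masked invalid, and
#' invalid input points (masked ratio regions) propagate to every output
#' point whose stencil touches them. A constant trace differentiates to
#' exactly zero, so a divisor-matched interferent contributes nothing.
#'
#' @param x A spectrum or ratio spectrum.
#' @param config A [deriv_config()].
#' @return A `deriv_spectrum` tibble: `wavelength`, `amplitude`, `valid`.
#' @export
derivative_spectrum <- function(x, config = deriv_config()) {
  step <- grid_step(x$wavelength)
  k2 <- config$delta_lambda / step
  if (abs(k2 - round(k2)) > 1e-6 || round(k2) %% 2 != 0 || round(k2) < 2) {
    rlang::abort("`delta_lambda` must be a positive even multiple of the grid step.")
  }
  k <- round(k2) / 2
  y <- if ("absorbance" %in% names(x)) x$absorbance else x$amplitude
  v_in <- if ("valid" %in% names(x)) x$valid else rep(TRUE, length(y))
  n <- length(y)
  amp <- rep(NA_real_, n)
  valid <- rep(FALSE, n)
  idx <- (k + 1):(n - k)
  if (config$method == "central") {
    yl <- y
    yl[!v_in] <- NA_real_
    d <- (yl[idx + k] - yl[idx - k]) / config$delta_lambda * config$scale
    amp[idx] <- d
    valid[idx] <- is.finite(d)
  } else {
    if (!requireNamespace("signal", quietly = TRUE)) {
      rlang::abort("The savgol derivative needs the 'signal' package.")
    }
    # window spans the full delta_lambda; invalid inputs poison the window
    win <- 2 * k + 1
    runs <- rle(v_in)
    pos <- 1
    for (r in seq_along(runs$lengths)) {
      len <- runs$lengths[[r]]
      if (runs$values[[r]] && len >= win) {
        seg <- pos:(pos + len - 1)
        d <- signal::sgolayfilt(y[seg], p = 2, n = win, m = 1, ts = step) *
          config$scale
        inner <- seg[(k + 1):(len - k)]
        amp[inner] <- d[(k + 1):(len - k)]
        valid[inner] <- TRUE
      }
      pos <- pos + len
    }
    valid[seq_len(min(k, n))] <- FALSE
    valid[seq.int(n - k + 1, n)] <- FALSE
    amp[!valid] <- NA_real_
  }
  amp[!valid] <- NA_real_
  out <- tibble::tibble(wavelength = x$wavelength, amplitude = amp, valid = valid)
  class(out) <- c("deriv_spectrum", class(out))
  attr(out, "deriv_config") <- config
  attr(out, "divisor_label") <- attr(x, "divisor_label")
  attr(out, "divisor_concentration") <- attr(x, "divisor_concentration")
  out
}

#' Amplitude at a wavelength
#'
#' Reads a spectrum, ratio spectrum or derivative trace at one or more
#' wavelengths. Off-node wavelengths are linearly interpolated between the
#' two neighbouring grid points (measurement wavelengths such as 242.5 or
#' 238.5 nm fall between the nodes of a 0.2 nm grid). An error is raised if
#' the wavelength lies outside the grid or if the point (or either
#' interpolation neighbour) is masked invalid.
#'
#' @param s Spectrum-like tibble.
#' @param wavelength Numeric vector of wavelengths (nm).
#' @return Numeric amplitudes.
#' @export
value_at <- function(s, wavelength) {
  wl <- s$wavelength
  y <- if ("absorbance" %in% names(s)) s$absorbance else s$amplitude
  valid <- if ("valid" %in% names(s)) s$valid else rep(TRUE, length(y))
  n <- length(wl)
  vapply(wavelength, function(l) {
    if (l < wl[[1]] - 1e-9 || l > wl[[n]] + 1e-9) {
      rlang::abort(sprintf("Wavelength %g nm is outside the grid.", l))
    }
    j <- which.min(abs(wl - l))
    if (abs(wl[[j]] - l) <= 1e-9) {
      if (!valid[[j]]) rlang::abort(sprintf("Point at %g nm is masked.", l))
      return(y[[j]])
    }
    i <- findInterval(l, wl)
    if (!valid[[i]] || !valid[[i + 1]]) {
      rlang::abort(sprintf("Point at %g nm falls in a masked region.", l))
    }
    y[[i]] + (y[[i + 1]] - y[[i]]) * (l - wl[[i]]) / (wl[[i + 1]] - wl[[i]])
  }, numeric(1))
}
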