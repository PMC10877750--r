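#' Gaussian band component models
#'
#' A component's unit-concentration absorptivity profile is modelled as a sum
#' of Gaussian bands, adequate for solution-phase UV bands. `center` is the
#' band position (nm), `width` the Gaussian sigma (nm) and `height` the peak
#' response in AU per ug/mL.
#'
#' @param label Component name.
#' @param center,width,height Equal-length numeric vectors, one entry per
#'   band; `width > 0`, `height >= 0`.
#' @return A `component_model` tibble with one row per band.
#' @export
component_model <- function(label, center, width, height) {
  if (length(center) == 0) rlang::abort("At least one band is required.")
  if (any(width <= 0)) rlang::abort("Band widths must be > 0.")
  if (any(height < 0)) rlang::abort("Band heights must be >= 0.")
  out <- tibble::tibble(center = as.numeric(center), width = as.numeric(width),
                        height = as.numeric(height))
  class(out) <- c("component_model", class(out))
  attr(out, "label") <- label
  out
}

#' Unit-concentration basis spectrum of a component
#'
#' Evaluates the model's Gaussian bands on a grid:
#' `A(w) = sum_b height_b * exp(-(w - center_b)^2 / (2 width_b^2))`,
#' the absorbance of a 1 ug/mL solution.
#'
#' @param model A [component_model()].
#' @param grid Wavelength grid (see [scan_grid()]).
#' @return A spectrum with `concentration = 1`.
#' @export
basis_spectrum <- function(model, grid = scan_grid()) {
  a <- rep(0, length(grid))
  for (b in seq_len(nrow(model))) {
    a <- a + model$height[[b]] *
      exp(-(grid - model$center[[b]])^2 / (2 * model$width[[b]]^2))
  }
  new_spectrum(grid, a, label = attr(model, "label"), concentration = 1)
}

#' Default two-component overlap models
#'
#' Structural stand-ins for an aspirin-like and a rivaroxaban-like analyte:
#' both absorb strongly and overlap severely in the 220-280 nm region, but
#' only the ROX-like component keeps measurable absorbance beyond 290 nm,
#' while the ASP-like component is dark there. Band parameters were tuned so
#' that usable dual-wavelength pairs exist for each analyte against the other
#' and the two basis shapes are far from proportional (a ratio spectrum of
#' one over the other is strongly wavelength-dependent). They do not attempt
#' to reproduce the true molar absorptivities of either drug.
#'
#' @return Named list of two [component_model()]s, `asp` and `rox`.
#' @examples
#' m <- default_models()
#' value_at(basis_spectrum(m$rox), 293) * 2 # ROX-like still absorbs at 293 nm
#' @export
default_models <- function() {
  list(
    asp = component_model("ASP-like", center = c(230, 255),
                          width = c(14, 11), height = c(0.030, 0.012)),
    rox = component_model("ROX-like", center = c(250, 288),
                          width = c(13, 14), height = c(0.018, 0.014))
  )
}

#' Plasma-like blank baseline model
#'
#' A broad short-wavelength band that has decayed to negligible absorbance by
#' about 290 nm, mimicking a deproteinated blank-plasma trace. Evaluated at
#' unit weight (its spectrum is added as-is, not scaled by a concentration).
#'
#' @return A [component_model()].
#' @export
plasma_baseline_model <- function() {
  component_model("plasma-baseline", center = 204, width = 10, height = 0.5)
}

#' Simulate a Beer-Lambert mixture spectrum
#'
#' `A(w) = sum_i c_i basis_i(w) + baseline(w) + noise(w)`.
#' Additivity of the component contributions is the premise of every
#' resolution method in the package. Noise is additive Gaussian with
#' pointwise SD `sqrt(noise_sd^2 + (relative_noise * A_clean(w))^2)`:
#' `noise_sd` models wavelength-independent detector noise (AU), while
#' `relative_noise` models photometric noise proportional to the local
#' signal (e.g. 0.01 for "1% relative noise"). With the same `seed` the
#' result is bit-identical.
#'
#' @param models Named list of [component_model()]s.
#' @param concentrations Named numeric vector (ug/mL); names must appear in
#'   `models`; values >= 0.
#' @param grid Wavelength grid.
#' @param noise_sd Homoscedastic noise SD, AU (>= 0).
#' @param relative_noise Signal-proportional noise fraction (>= 0).
#' @param baseline Optional [component_model()] added at unit weight.
#' @param seed Optional integer for reproducible noise.
#' @param label Label for the resulting spectrum.
#' @return A spectrum.
#' @export
make_mixture <- function(models, concentrations, grid = scan_grid(),
                         noise_sd = 0, relative_noise = 0, baseline = NULL,
                         seed = NULL, label = "mixture") {
  if (is.null(names(concentrations)) || !all(nzchar(names(concentrations)))) {
    rlang::abort("`concentrations` must be a named vector.")
  }
  unknown <- setdiff(names(concentrations), names(models))
  if (length(unknown) > 0) {
    rlang::abort(sprintf("No model for component(s): %s",
                         paste(unknown, collapse = ", ")))
  }
  if (any(concentrations < 0)) rlang::abort("Concentrations must be >= 0.")
  if (noise_sd < 0) rlang::abort("`noise_sd` must be >= 0.")
  if (relative_noise < 0) rlang::abort("`relative_noise` must be >= 0.")
  a <- rep(0, length(grid))
  for (nm in names(concentrations)) {
    a <- a + concentrations[[nm]] * basis_spectrum(models[[nm]], grid)$absorbance
  }
  if (!is.null(baseline)) a <- a + basis_spectrum(baseline, grid)$absorbance
  point_sd <- sqrt(noise_sd^2 + (relative_noise * a)^2)
  if (any(point_sd > 0)) {
    noise <- if (is.null(seed)) {
      stats::rnorm(length(grid), 0, point_sd)
    } else {
      withr::with_seed(seed, stats::rnorm(length(grid), 0, point_sd))
    }
    a <- a + noise
  }
  new_spectrum(grid, a, label = label)
}

#' Simulate a single-component calibration set
#'
#' One spectrum per concentration level with only the named component present
#' (plus optional baseline and noise), the in-silico equivalent of scanning a
#' dilution series of one standard.
#'
#' @inheritParams make_mixture
#' @param component Which model in `models` to vary.
#' @param levels Positive, distinct concentrations (ug/mL).
#' @return A calibration tibble: `concentration` and a `spectrum` list-column.
#' @export
make_calibration_set <- function(models, component, levels,
                                 grid = scan_grid(), noise_sd = 0,
                                 relative_noise = 0, baseline = NULL,
                                 seed = NULL) {
  if (length(levels) == 0) rlang::abort("`levels` must be non-empty.")
  if (any(levels <= 0)) rlang::abort("Calibration levels must be > 0.")
  if (anyDuplicated(levels)) rlang::abort("Calibration levels must be distinct.")
  if (!component %in% names(models)) {
    rlang::abort(sprintf("No model named '%s'.", component))
  }
  gen <- function() {
    purrr::map(levels, function(cc) {
      s <- make_mixture(models, stats::setNames(cc, component), grid = grid,
                        noise_sd = noise_sd, relative_noise = relative_noise,
                        baseline = baseline,
                        label = attr(models[[component]], "label"))
      attr(s, "concentration") <- cc
      s
    })
  }
  specs <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  tibble::tibble(concentration = as.numeric(levels), spectrum = specs)
}
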