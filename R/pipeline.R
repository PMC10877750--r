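#' Default end-to-end pipeline configuration
#'
#' Study conditions for a full simulate / calibrate / predict / validate run
#' on the default two-component models: calibration levels spanning the
#' working ranges (4-40 ug/mL for the ASP-like analyte, 2-20 ug/mL for the
#' ROX-like one), a mixture grid, replicate counts and the noise level. All
#' tolerances that close gaps the methods leave open (interferent tolerance,
#' ratio guard, derivative window) are surfaced here.
#'
#' @param seed Integer seed driving every random draw in the run.
#' @param noise_fraction Signal-proportional noise fraction applied to the
#'   simulated mixtures (see [make_mixture()]); 0 gives deterministic spectra.
#' @param n_replicates Replicate determinations per mixture.
#' @param methods Which methods to run, subset of `c("dw", "rd", "dd")`.
#' @return Config list for [run_pipeline()].
#' @export
default_config <- function(seed = 1, noise_fraction = 0.01, n_replicates = 3,
                           methods = c("dw", "rd", "dd")) {
  list(
    grid = list(start = 200, stop = 350, step = 0.2),
    levels = list(asp = c(4, 8, 16, 24, 32, 40), rox = c(2, 4, 8, 12, 16, 20)),
    mixtures = list(asp = c(4, 12, 20, 30, 40), rox = c(2, 6, 10, 15, 20)),
    divisors = list(asp_divisor_of_rox = 20, rox_divisor_of_asp = 36),
    methods = methods,
    noise_fraction = noise_fraction,
    n_replicates = n_replicates,
    guard = 0.01,
    interferent_tolerance = 0.002,
    derivative = list(delta_lambda = 4, scale = 10),
    seed = seed
  )
}

#' Read a pipeline configuration from YAML
#'
#' Missing fields fall back to [default_config()] values.
#'
#' @param path YAML file.
#' @return Config list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  utils::modifyList(default_config(), user)
}

#' Run the full simulate / calibrate / predict / validate pipeline
#'
#' Generates noise-free calibration sets for both components, calibrates
#' every requested method (dual-wavelength pairs via [select_pair()],
#' ratio-difference pairs via [rd_select_pair()], derivative-ratio
#' wavelengths via [dd_candidate_wavelengths()]), simulates replicate binary
#' mixtures over the configured concentration grid, predicts every component
#' by every method, and summarises recoveries. The run is fully determined by
#' `config$seed`.
#'
#' With `config$methods` empty the run is validation-only: supplied
#' `predictions` are summarised without simulating or calibrating anything.
#'
#' @param config Config list, see [default_config()].
#' @param out_dir Optional directory; when given, predictions and the
#'   validation tables are written there as CSV together with a plain-text
#'   run log.
#' @param predictions Tibble (`analyte`, `method`, `true`, `found`) for a
#'   validation-only run.
#' @return List: `calibrations` (named list), `predictions` (tibble),
#'   `report` (see [validation_report()]), `log` (seed, config hash,
#'   package version).
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL,
                         predictions = NULL) {
  if (length(config$methods) == 0) {
    if (is.null(predictions)) {
      rlang::abort("validate: no methods requested and no predictions supplied")
    }
    report <- validation_report(predictions)
    log <- list(seed = config$seed, config_hash = rlang::hash(config),
                package_version = as.character(utils::packageVersion("uvmix")))
    return(list(calibrations = list(), predictions = predictions,
                report = report, log = log))
  }
  grid <- scan_grid(config$grid$start, config$grid$stop, config$grid$step)
  models <- default_models()
  dcfg <- deriv_config(config$derivative$delta_lambda, config$derivative$scale)

  std <- list(
    asp = make_calibration_set(models, "asp", config$levels$asp, grid = grid),
    rox = make_calibration_set(models, "rox", config$levels$rox, grid = grid)
  )
  top <- list(
    asp = std$asp$spectrum[[which.max(std$asp$concentration)]],
    rox = std$rox$spectrum[[which.max(std$rox$concentration)]]
  )
  div <- list(
    asp = make_divisor(models$rox, config$divisors$asp_divisor_of_rox, grid),
    rox = make_divisor(models$asp, config$divisors$rox_divisor_of_asp, grid)
  )

  cals <- list()
  for (an in c("asp", "rox")) {
    other <- setdiff(c("asp", "rox"), an)
    if ("dw" %in% config$methods) {
      pairs <- select_pair(std[[an]], top[[other]],
                           interferent_tolerance = config$interferent_tolerance)
      if (nrow(pairs) == 0) {
        rlang::abort(sprintf("calibrate: no dual-wavelength pair for %s", an))
      }
      cals[[paste0(an, "_dw")]] <-
        dw_calibrate(std[[an]], c(pairs$lambda_low[[1]], pairs$lambda_high[[1]]),
                     analyte = an)
    }
    if ("rd" %in% config$methods) {
      pair <- rd_select_pair(std[[an]], div[[an]], guard = config$guard)
      cals[[paste0(an, "_rd")]] <-
        rd_calibrate(std[[an]], div[[an]], pair, guard = config$guard,
                     analyte = an)
    }
    if ("dd" %in% config$methods) {
      cands <- dd_candidate_wavelengths(std[[an]], div[[an]], config = dcfg,
                                        guard = config$guard)
      if (nrow(cands) == 0 || !any(cands$qualifies)) {
        rlang::abort(sprintf("calibrate: no derivative wavelength for %s", an))
      }
      cals[[paste0(an, "_dd")]] <-
        dd_calibrate(std[[an]], div[[an]], cands$wavelength[[1]], config = dcfg,
                     guard = config$guard, analyte = an)
    }
  }

  mix_grid <- tidyr::expand_grid(asp = config$mixtures$asp,
                                 rox = config$mixtures$rox)
  predictions <- withr::with_seed(config$seed, {
    purrr::pmap_dfr(mix_grid, function(asp, rox) {
      purrr::map_dfr(seq_len(config$n_replicates), function(rep) {
        s <- make_mixture(models, c(asp = asp, rox = rox), grid = grid,
                          relative_noise = config$noise_fraction)
        truth <- c(asp = asp, rox = rox)
        purrr::map_dfr(config$methods, function(m) {
          purrr::map_dfr(c("asp", "rox"), function(an) {
            cal <- cals[[paste0(an, "_", m)]]
            tibble::tibble(analyte = an, method = m, replicate = rep,
                           true = truth[[an]],
                           found = predict_concentration(cal, s))
          })
        })
      })
    })
  })

  report <- validation_report(predictions)
  log <- list(
    seed = config$seed,
    config_hash = rlang::hash(config),
    package_version = as.character(utils::packageVersion("uvmix"))
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(predictions, file.path(out_dir, "predictions.csv"),
                     progress = FALSE)
    readr::write_csv(report$by_level, file.path(out_dir, "validation_by_level.csv"),
                     progress = FALSE)
    readr::write_csv(report$by_method, file.path(out_dir, "validation_by_method.csv"),
                     progress = FALSE)
    cal_tbl <- purrr::map_dfr(cals, glance)
    readr::write_csv(cal_tbl, file.path(out_dir, "calibrations.csv"),
                     progress = FALSE)
    writeLines(c(
      sprintf("seed: %s", log$seed),
      sprintf("config_hash: %s", log$config_hash),
      sprintf("package_version: %s", log$package_version)
    ), file.path(out_dir, "run_log.txt"))
  }

  list(calibrations = cals, predictions = predictions, report = report,
       log = log)
}
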