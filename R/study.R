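#' Simulation study configuration
#'
#' Bundles every knob of the Monte-Carlo b-value study. The defaults
#' reproduce the full reference experiment: three tissue models (brain,
#' kidney, liver), eight two-point schemes `[200,1000]`-`[900,1000]`, SNR
#' levels 40/55/80 with the `rms_db` noise calibration, the 13-point f grid
#' 0.06-0.30, and 1000 noise iterations per cell.
#'
#' @param models Tibble of tissue models ([tissue_models()] layout).
#' @param b_low Lower fit b-values of the candidate schemes, s/mm^2.
#' @param b_high Upper fit b-value, s/mm^2.
#' @param snr SNR levels.
#' @param calibration Noise calibration, see [noise_sigma()].
#' @param f_grid True perfusion fractions.
#' @param n_iter Noise realizations per (model, scheme, SNR, f).
#' @param b_grid Generation b grid.
#' @param seed Integer root seed (each cell derives its own substream).
#'
#' @return A list of class `ivim_config`.
#' @examples
#' cfg <- study_config(n_iter = 100, seed = 1)
#' @export
study_config <- function(models = tissue_models(),
                         b_low = seq(200, 900, by = 100), b_high = 1000,
                         snr = c(40, 55, 80),
                         calibration = c("rms_db", "b0_linear"),
                         f_grid = default_f_grid(), n_iter = 1000,
                         b_grid = b_generation_grid(), seed = NULL) {
  calibration <- match.arg(calibration)
  stopifnot(is.data.frame(models), all(c("name", "D", "D_star") %in% names(models)),
            all(snr > 0), n_iter >= 1, length(f_grid) >= 2)
  structure(
    list(models = models[, c("name", "D", "D_star")],
         b_low = b_low, b_high = b_high, snr = snr,
         calibration = calibration, f_grid = f_grid, n_iter = n_iter,
         b_grid = b_grid, seed = seed),
    class = "ivim_config"
  )
}

#' Read / write a study configuration as YAML
#'
#' Round-trip serialization: `write_config()` then `read_config()` returns a
#' configuration identical to the original.
#'
#' @param config An `ivim_config`.
#' @param path YAML file path.
#' @return `read_config()` returns an `ivim_config`; `write_config()`
#'   returns `path` invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "ivim_config"))
  x <- unclass(config)
  x$models <- lapply(seq_len(nrow(x$models)), function(i) as.list(x$models[i, ]))
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  models <- dplyr::bind_rows(lapply(x$models, tibble::as_tibble))
  study_config(models = models, b_low = as.numeric(x$b_low),
               b_high = as.numeric(x$b_high), snr = as.numeric(x$snr),
               calibration = x$calibration, f_grid = as.numeric(x$f_grid),
               n_iter = as.integer(x$n_iter), b_grid = as.numeric(x$b_grid),
               seed = x$seed)
}

#' Run the full Monte-Carlo b-value study
#'
#' Executes [run_monte_carlo()] for every (tissue model, scheme, SNR) cell
#' of the configuration, summarizes per-f and grid-level error statistics,
#' and derives scheme recommendations per (model, SNR).
#'
#' @param config An [study_config()] object.
#' @param keep_results Keep the raw per-iteration fits (`ivim_mc` objects)
#'   in the returned bundle; off by default to keep the object small.
#'
#' @return An object of class `ivim_study`: list with
#'   * `per_f` — long tibble of per-(parameter, f) bias/relerr/CoV,
#'   * `grid` — grid-mean table (one row per model x scheme x SNR),
#'   * `recommendations` — [recommend_scheme()] output over all cells,
#'   * `config`, and optionally `mc` (raw batches).
#' @examples
#' cfg <- study_config(models = tissue_models()[1, ], b_low = c(300, 500),
#'                     snr = 55, n_iter = 100, seed = 1)
#' study <- run_simulation_study(cfg)
#' study$grid
#' @export
run_simulation_study <- function(config = study_config(), keep_results = FALSE) {
  stopifnot(inherits(config, "ivim_config"))
  schemes <- candidate_schemes(config$b_low, config$b_high)
  cells <- tidyr::expand_grid(
    model_idx = seq_len(nrow(config$models)),
    scheme_idx = seq_along(schemes),
    snr = config$snr
  )
  batches <- purrr::pmap(cells, function(model_idx, scheme_idx, snr) {
    seed <- if (is.null(config$seed)) NULL else {
      config$seed + 1000L * (model_idx - 1L) + 100L * (scheme_idx - 1L) +
        match(snr, config$snr)
    }
    run_monte_carlo(config$models[model_idx, ], schemes[[scheme_idx]], snr,
                    calibration = config$calibration, f_grid = config$f_grid,
                    n_iter = config$n_iter, b_grid = config$b_grid,
                    seed = seed)
  })
  per_f <- dplyr::bind_rows(lapply(batches, summarize_errors))
  grid <- grid_summary(per_f)
  structure(
    list(per_f = per_f, grid = grid,
         recommendations = recommend_scheme(grid),
         config = config,
         mc = if (keep_results) batches else NULL),
    class = "ivim_study"
  )
}

#' @export
print.ivim_study <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<ivim_study> %d models x %d schemes x %d SNR levels, %d f values, N = %d (%s)\n",
              nrow(cfg$models), length(cfg$b_low), length(cfg$snr),
              length(cfg$f_grid), cfg$n_iter, cfg$calibration))
  cat("Recommended schemes (lowest overall relative error):\n")
  print(as.data.frame(x$recommendations[, c("model", "snr", "best", "overall_mean")]),
        row.names = FALSE)
  invisible(x)
}

#' Overall-relative-error table (wide rendering)
#'
#' Renders the grid-level overall relative errors as one row per scheme and
#' one `mean +/- sd` column per (model, SNR), values rounded to two
#' significant figures at render time only.
#'
#' @param study An `ivim_study`.
#' @return A tibble, schemes as rows.
#' @export
overall_error_table <- function(study) {
  stopifnot(inherits(study, "ivim_study"))
  study$grid |>
    dplyr::mutate(cell = sprintf("%s +/- %s",
                                 signif(.data$overall_mean, 2),
                                 signif(.data$overall_sd, 2)),
                  col = paste0(.data$model, "_SNR", .data$snr)) |>
    dplyr::select("scheme", "col", "cell") |>
    tidyr::pivot_wider(names_from = "col", values_from = "cell")
}

#' Export a study bundle to disk
#'
#' Writes tidy CSVs (`per_f.csv`, `grid.csv`, `recommendations.csv`, plus
#' `relerr_f_long.csv`, the f relative-error surface over scheme x f_true
#' for contour-style plots) and a JSON metadata sidecar (config, seed,
#' calibration, package version).
#'
#' @param study An `ivim_study`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
export_study <- function(study, dir) {
  stopifnot(inherits(study, "ivim_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(study$per_f, file.path(dir, "per_f.csv"), row.names = FALSE)
  utils::write.csv(study$grid, file.path(dir, "grid.csv"), row.names = FALSE)
  utils::write.csv(study$recommendations, file.path(dir, "recommendations.csv"),
                   row.names = FALSE)
  relerr_long <- study$per_f |>
    dplyr::filter(.data$parameter == "f") |>
    dplyr::select("model", "scheme", "snr", "f_true", "relerr")
  utils::write.csv(relerr_long, file.path(dir, "relerr_f_long.csv"),
                   row.names = FALSE)
  cfg <- study$config
  meta <- list(
    package = "ivimsim",
    version = as.character(utils::packageVersion("ivimsim")),
    calibration = cfg$calibration, seed = cfg$seed, n_iter = cfg$n_iter,
    snr = cfg$snr, b_low = cfg$b_low, b_high = cfg$b_high,
    f_grid = cfg$f_grid, models = cfg$models
  )
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
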