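ms_defaults <- function() {
  list(
    # landscape / climate
    n_patches = 50, extent_km = 50, width_km = 5, gradient_span_C = 6,
    elevation_span_m = 900, T_warm = 14,
    warming_C = 3, warming_years = 150, sigmoid_k = 0.08,
    # species traits
    n_species = 200, scenario = "variable", sm_mean_mg = 1.5, sm_sd_mg = 3,
    topt_extension_C = 2,
    # demography (seed-mass scaling rules)
    phi = 20, g_min = 0.3, g_max = 0.8, sm_half = 1, kappa = 2.2,
    seedling_exponent = 0.68,
    # within-year growth and competition
    r_max = 0.05, sigma_opt = 3, m = 0.001, K_max = 100,
    K_floor_frac = 1e-4, alpha = 0.5, season_days = 120,
    extinction_threshold = 0.55, native_threshold = 25,
    # dispersal kernel
    kernel_c = 0.5, kernel_a = 600, sm_exponent = -0.13, r_capture_m = 50,
    # regional pool
    pool_enabled = TRUE,
    # engine
    n_replicates = 30, base_seed = 42, max_stable_years = 400,
    stable_tol = 1e-4, stable_window = 10, settling_years = 50,
    b_init = NA_real_  # NA: K_max / (2 * n_species)
  )
}

#' Build a validated run configuration
#'
#' Starts from the documented defaults and applies any overrides given as
#' named arguments. Unknown keys and type mismatches are rejected with an
#' error naming the key.
#'
#' @param ... named overrides of the default configuration; see Details.
#' @details Keys: landscape (`n_patches`, `extent_km`, `width_km`,
#'   `gradient_span_C`, `elevation_span_m`, `T_warm`), climate forcing
#'   (`warming_C`, `warming_years`, `sigmoid_k`), species (`n_species`,
#'   `scenario`, `sm_mean_mg`, `sm_sd_mg`, `topt_extension_C`), demography
#'   (`phi`, `g_min`, `g_max`, `sm_half`, `kappa`, `seedling_exponent`),
#'   growth/competition (`r_max`, `sigma_opt`, `m`, `K_max`, `K_floor_frac`,
#'   `alpha`, `season_days`, `extinction_threshold`, `native_threshold`),
#'   kernel (`kernel_c`,
#'   `kernel_a`, `sm_exponent`, `r_capture_m`), pool (`pool_enabled`), and
#'   engine (`n_replicates`, `base_seed`, `max_stable_years`, `stable_tol`,
#'   `stable_window`, `settling_years`, `b_init`).
#' @return an object of class `ms_config` (a named list).
#' @examples
#' cfg <- ms_config(scenario = "tradeoff", alpha = 0.3)
#' cfg$alpha
#' @export
ms_config <- function(...) {
  defaults <- ms_defaults()
  overrides <- list(...)
  if (length(overrides) && is.null(names(overrides)))
    stop("configuration error: overrides must be named")
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown))
    stop("configuration error: unknown key(s): ",
         paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, overrides)
  validate_config(cfg)
}

validate_config <- function(cfg) {
  chk <- function(ok, key, what) {
    if (!ok) stop("configuration error: '", key, "' ", what)
  }
  # b_init may be NA (use K_max/(2 n_species)); serialised NA can come back
  # as logical or string depending on the format
  cfg$b_init <- suppressWarnings(as.numeric(cfg$b_init))
  if (length(cfg$b_init) == 1 && is.na(cfg$b_init)) cfg$b_init <- NA_real_
  num_keys <- setdiff(names(ms_defaults()),
                      c("scenario", "pool_enabled", "b_init"))
  for (k in num_keys)
    chk(is.numeric(cfg[[k]]) && length(cfg[[k]]) == 1, k,
        "must be a single number")
  chk(is.numeric(cfg$b_init) && length(cfg$b_init) == 1, "b_init",
      "must be a single number or NA")
  cfg$scenario <- match.arg(cfg$scenario,
                            c("uniform", "variable", "tradeoff"))
  chk(is.logical(cfg$pool_enabled), "pool_enabled", "must be logical")
  chk(cfg$n_patches >= 2, "n_patches", "must be >= 2")
  chk(cfg$n_species >= 2, "n_species", "must be >= 2")
  chk(cfg$extent_km > 0, "extent_km", "must be positive")
  chk(cfg$width_km > 0, "width_km", "must be positive")
  chk(cfg$gradient_span_C > 0, "gradient_span_C", "must be positive")
  chk(cfg$sm_mean_mg > 0, "sm_mean_mg", "must be positive")
  chk(cfg$sm_sd_mg >= 0, "sm_sd_mg", "must be >= 0")
  chk(cfg$r_max > 0, "r_max", "must be positive")
  chk(cfg$sigma_opt > 0, "sigma_opt", "must be positive")
  chk(cfg$m >= 0 && cfg$m < cfg$r_max, "m", "must satisfy 0 <= m < r_max")
  chk(cfg$alpha >= 0 && cfg$alpha < 1, "alpha", "must be in [0, 1)")
  chk(cfg$K_max > 0 && cfg$K_floor_frac > 0, "K_max", "must be positive")
  chk(cfg$kernel_c > 0 && cfg$kernel_a > 0, "kernel_c", "must be positive")
  chk(cfg$r_capture_m > 0, "r_capture_m", "must be positive")
  chk(cfg$n_replicates >= 1, "n_replicates", "must be >= 1")
  chk(cfg$season_days >= 1, "season_days", "must be >= 1")
  structure(cfg, class = "ms_config")
}

#' Load a configuration from a YAML or JSON file
#'
#' Reads the file (format chosen by extension), applies any further
#' overrides, and returns a fully resolved, validated configuration in which
#' every default is recorded. With `path = NULL` the documented defaults
#' plus overrides are returned.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` configuration file, or
#'   `NULL` for defaults-only mode.
#' @param overrides named list of overrides applied after the file.
#' @return an `ms_config` object.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  file_vals <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("configuration file not found: ", path)
    ext <- tolower(tools::file_ext(path))
    file_vals <- switch(ext,
      yaml = , yml = yaml::read_yaml(path),
      json = jsonlite::read_json(path, simplifyVector = TRUE),
      stop("configuration error: unsupported config format '.", ext, "'")
    )
    if (is.null(file_vals)) file_vals <- list()
  }
  do.call(ms_config, utils::modifyList(file_vals, overrides))
}

#' Write a configuration to a YAML or JSON file
#'
#' The round-trip `load_config(write_config(cfg, path))` reproduces the
#' configuration exactly.
#'
#' @param config an `ms_config` object.
#' @param path output path ending in `.yaml`, `.yml` or `.json`.
#' @return the path, invisibly.
#' @export
write_config <- function(config, path) {
  ext <- tolower(tools::file_ext(path))
  vals <- unclass(config)
  switch(ext,
    yaml = , yml = yaml::write_yaml(vals, path),
    json = jsonlite::write_json(vals, path, auto_unbox = TRUE,
                                digits = NA, pretty = TRUE),
    stop("configuration error: unsupported config format '.", ext, "'")
  )
  invisible(path)
}

#' @export
print.ms_config <- function(x, ...) {
  cat(sprintf(
    "metashift configuration: %s scenario, %g species, %g patches, alpha = %g\n",
    x$scenario, x$n_species, x$n_patches, x$alpha))
  cat(sprintf("  SM distribution: mean %g mg, SD %g mg\n",
              x$sm_mean_mg, x$sm_sd_mg))
  cat(sprintf("  warming: +%g degC over %g y; %g replicates, base seed %g\n",
              x$warming_C, x$warming_years, x$n_replicates, x$base_seed))
  invisible(x)
}
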