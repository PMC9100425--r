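#' Run configuration for flexible fitting
#'
#' Bundles every tunable of a fitting run. Defaults follow the reference
#' protocol for fitting a two-head-bound motor frame: renderer widths
#' `sigma_x = sigma_y = 0.5` nm and vertical softness `gamma = 0.1` nm,
#' Langevin dynamics at 300 K with step size 0.3 (reduced time units) for
#' 3e6 steps in 10 replicas, recording every 1e4 steps (300 records per
#' replica, so the latter half pooled over replicas is 1,500 snapshots).
#'
#' @param k_bias bias strength k of `V_AFM = k (1 - c.s.)` (reduced energy
#'   units; kcal/mol scale). The default 300 makes the image term dominate
#'   rigid misalignment while staying below the structure-based potential's
#'   state-switching cost, so fitting cannot silently convert one lever-arm
#'   state into the other.
#' @param sigma_x,sigma_y lateral widths of the smoothed renderer (nm).
#' @param gamma vertical softness of the smoothed renderer (nm).
#' @param temperature Langevin temperature (K).
#' @param n_steps number of MD steps per replica.
#' @param dt MD step in reduced time units.
#' @param n_replicas number of independent replicas.
#' @param seed master seed; replica r uses the independent stream (seed, r).
#' @param record_interval steps between records.
#' @param friction Langevin friction coefficient (1 / reduced time); the
#'   default decorrelates the toy system in about 1e3 steps.
#' @param fit_mask region used for the bias similarity (1-based inclusive
#'   pixels on the uncropped frame). Default `region_mask(26, 65, 1, 30)`.
#' @param neck_mask region used for state inference. Default
#'   `region_mask(33, 57, 12, 23)`.
#' @param stage_epsilon,stage_sigma Lennard-Jones stage wall depth (energy)
#'   and minimum position (nm); `stage_sigma = NULL` means "use each bead's
#'   radius".
#' @return an object of class `run_config`.
#' @export
run_config <- function(k_bias = 300, sigma_x = 0.5, sigma_y = 0.5,
                       gamma = 0.1, temperature = 300, n_steps = 3e6,
                       dt = 0.3, n_replicas = 10, seed = 1,
                       record_interval = 1e4, friction = 0.25,
                       fit_mask = region_mask(26, 65, 1, 30),
                       neck_mask = region_mask(33, 57, 12, 23),
                       stage_epsilon = 0.2, stage_sigma = NULL) {
  cfg <- structure(list(k_bias = k_bias, sigma_x = sigma_x, sigma_y = sigma_y,
                        gamma = gamma, temperature = temperature,
                        n_steps = as.integer(n_steps), dt = dt,
                        n_replicas = as.integer(n_replicas),
                        seed = as.integer(seed),
                        record_interval = as.integer(record_interval),
                        friction = friction,
                        fit_mask = fit_mask, neck_mask = neck_mask,
                        stage_epsilon = stage_epsilon,
                        stage_sigma = stage_sigma),
                   class = "run_config")
  validate_run_config(cfg)
  cfg
}

validate_run_config <- function(cfg) {
  bad <- character(0)
  chk <- function(ok, msg) if (!isTRUE(ok)) bad <<- c(bad, msg)
  chk(cfg$sigma_x > 0, "sigma_x must be > 0")
  chk(cfg$sigma_y > 0, "sigma_y must be > 0")
  chk(cfg$gamma > 0, "gamma must be > 0")
  chk(cfg$temperature >= 0, "temperature must be >= 0")
  chk(cfg$n_steps > 0, "n_steps must be > 0")
  chk(cfg$dt > 0, "dt must be > 0")
  chk(cfg$k_bias >= 0, "k_bias must be >= 0")
  chk(cfg$n_replicas >= 1, "n_replicas must be >= 1")
  chk(cfg$record_interval >= 1, "record_interval must be >= 1")
  chk(cfg$friction > 0, "friction must be > 0")
  chk(cfg$stage_epsilon >= 0, "stage_epsilon must be >= 0")
  chk(is.null(cfg$stage_sigma) || cfg$stage_sigma > 0,
      "stage_sigma must be > 0 (or NULL for per-bead radii)")
  chk(inherits(cfg$fit_mask, "region_mask"), "fit_mask must be a region_mask")
  chk(inherits(cfg$neck_mask, "region_mask"), "neck_mask must be a region_mask")
  if (length(bad) > 0)
    stop("invalid run_config:\n  - ", paste(bad, collapse = "\n  - "))
  invisible(cfg)
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf(paste0("<run_config> k_bias %g, sigma (%g, %g) nm, gamma %g nm, ",
                     "T %g K, %d steps x dt %g, %d replica(s), seed %d\n"),
              x$k_bias, x$sigma_x, x$sigma_y, x$gamma, x$temperature,
              x$n_steps, x$dt, x$n_replicas, x$seed))
  invisible(x)
}

mask_to_list <- function(m) {
  list(x_first = m$x_first, x_last = m$x_last,
       y_first = m$y_first, y_last = m$y_last)
}

#' Load a run configuration from a YAML file
#'
#' Missing optional keys take the documented defaults of [run_config()];
#' out-of-range values raise an error listing every violated invariant.
#' Masks are given as 4-element maps (`x_first`, `x_last`, `y_first`,
#' `y_last`).
#'
#' @param path path to a YAML configuration.
#' @return a `run_config`.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop("configuration file is not a key-value mapping")
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0)
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  for (mk in c("fit_mask", "neck_mask"))
    if (!is.null(raw[[mk]]))
      raw[[mk]] <- do.call(region_mask, raw[[mk]])
  do.call(run_config, raw)
}

#' Write a run configuration to a YAML file
#'
#' `dump_config` then [load_config()] round-trips the configuration
#' unchanged.
#'
#' @param cfg a `run_config`.
#' @param path output path.
#' @export
dump_config <- function(cfg, path) {
  out <- unclass(cfg)
  out$fit_mask <- mask_to_list(cfg$fit_mask)
  out$neck_mask <- mask_to_list(cfg$neck_mask)
  out <- out[!vapply(out, is.null, logical(1))]
  yaml::write_yaml(out, path)
  invisible(path)
}
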