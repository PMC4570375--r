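#' Pipeline configuration
#'
#' All tunables of the tracking pipeline with their documented defaults.
#' Values reflect the standard operating point of the method: a
#' front-detection threshold of `N = 10` robust standard deviations, a
#' foreground-cleaning multiplier `c_clean = 15`, the Gaussian
#' MAD-to-sd constant `c_mad = 1.4826`, and a 50-frame stability
#' probation for new trackers at 15 fps. Process/measurement noise
#' scales are engineering defaults (positions (0.5 px)^2, velocities
#' (1 px/frame)^2, angles (0.1 rad)^2) and can be overridden per run.
#'
#' @param ... named overrides of any default listed below.
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    # segmentation
    N = 10, c_mad = 1.4826, c_clean = 15, sigma_floor = 1,
    polarity = "dark", blur_sigma = 1, min_px = 3,
    # background fitting / updating
    warmup_frames = 100L, update_period = 100L, alpha = 0.05,
    # validation
    dN = 2, max_steps = 8, accept_floor = exp(-3), improve_tol = 0.05,
    min_sigma_frac = 0.05,
    # plate / reflections
    plate = NULL, plate_detect = TRUE, reflection_band = 12,
    # kalman
    q_pos = 0.25, q_vel = 1, q_ang = 0.01, q_w = 0.01,
    r_pos = 0.25, r_vel = 1, r_ang = 0.04, r_w = 0.04,
    merge_R_inflation = 100,
    # assignment & lifecycle
    gate = 4, probation = 50L, max_coast = 15L, max_wait = 450L,
    rebind_radius = 20, vel_window = 5L, static_speed = 0.5,
    # misc
    fps = 15, seed = NULL
  )
  dots <- list(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), names(cfg))
    if (length(unknown)) stop("unknown config keys: ", paste(unknown, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(cfg) {
  stopifnot(
    cfg$N >= 0, cfg$c_mad > 0, cfg$c_clean >= 0, cfg$sigma_floor >= 0,
    cfg$polarity %in% c("dark", "bright", "both"),
    cfg$warmup_frames >= 3, cfg$update_period >= 1,
    cfg$alpha > 0, cfg$alpha <= 1,
    cfg$dN > 0, cfg$max_steps >= 1,
    cfg$accept_floor > 0, cfg$accept_floor <= 1,
    cfg$gate > 0, cfg$probation >= 1, cfg$max_coast >= 0, cfg$max_wait >= 0,
    cfg$fps > 0,
    is.null(cfg$plate) || (is.numeric(cfg$plate) && length(cfg$plate) == 3L)
  )
  invisible(cfg)
}

#' Read a pipeline configuration from a YAML file
#'
#' Unknown keys are rejected; ranges are validated on load.
#'
#' @param path YAML file path.
#' @return a `pipeline_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  # YAML 1.1 reads a bare `N:` key as the boolean FALSE; map it back
  names(vals)[names(vals) == "FALSE"] <- "N"
  if (!is.null(vals[["plate"]])) vals[["plate"]] <- as.numeric(unlist(vals[["plate"]]))
  do.call(pipeline_config, vals)
}

process_noise <- function(cfg) {
  diag(c(cfg$q_pos, cfg$q_pos, cfg$q_vel, cfg$q_vel, cfg$q_ang, cfg$q_w))
}

measurement_noise <- function(cfg) {
  diag(c(cfg$r_pos, cfg$r_pos, cfg$r_vel, cfg$r_vel, cfg$r_ang, cfg$r_w))
}
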