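## Pipeline configuration: every stage's tunable parameters with their
## published defaults, YAML load/save with validation, unknown keys rejected.

#' Default pipeline configuration
#'
#' All stage parameters with their default values: EMA smoothing factors
#' 0.05/0.8 with a 0.05 rad rotation threshold; chrominance reference
#' (U, V) = (30, 45); magnification factor 50 at pyramid level 3 over the
#' 0.8-3.0 Hz band; 30 s episodes with 15 s overlap; modified z-score
#' threshold 3 with outlier-ratio cut 0.4; harmonic notch sigma 0.1 Hz,
#' depth 0.7, half-frequency significance 0.4; window stride 3 with 2 PCs,
#' correlation threshold 0.5, 10-component global cap, SOBI lags up to 20;
#' time-point outlier threshold 4; classifier threshold 0.35 and power-ratio
#' fallback 0.75.
#'
#' @return Nested configuration list (class `pipeline_config`).
#' @export
default_config <- function() {
  structure(list(
    video = list(target_width = 320L, target_height = 240L),
    landmarks = list(provider = "synthetic", n_reference = 15L),
    stab = list(alpha_slow = 0.05, alpha_fast = 0.8, theta_threshold = 0.05,
                ramp = 0.15, refine = TRUE),
    roi = list(reference_u = 30, reference_v = 45, kmeans_seed = 1L,
               kmeans_nstart = 10L),
    evm = list(alpha = 50, level = 3L, band = c(0.8, 3.0)),
    episode = list(length_s = 30, overlap_s = 15),
    clean = list(z_thresh = 3, ratio_thresh = 0.4, tau = 4),
    harm = list(sigma = 0.1, alpha = 0.7, half_energy_frac = 0.4),
    sep = list(stride = 3L, n_pcs = 2L, corr_thresh = 0.5, max_global = 10L,
               sobi_lags = 20L),
    select = list(p_threshold = 0.35, power_ratio_threshold = 0.75,
                  require_model = FALSE),
    hr = list(pad = 8192L, max_lag_s = 1)
  ), class = "pipeline_config")
}

.check_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) stop("validation error: ", msg,
                                         call. = FALSE)
  chk(cfg$stab$alpha_slow > 0 && cfg$stab$alpha_slow <= cfg$stab$alpha_fast &&
        cfg$stab$alpha_fast <= 1, "stab alphas must satisfy 0 < slow <= fast <= 1")
  chk(cfg$stab$theta_threshold > 0, "stab.theta_threshold must be positive")
  chk(cfg$evm$alpha >= 0, "evm.alpha must be non-negative")
  chk(cfg$evm$level >= 1, "evm.level must be >= 1")
  chk(length(cfg$evm$band) == 2L && cfg$evm$band[1L] > 0 &&
        cfg$evm$band[1L] < cfg$evm$band[2L], "evm.band must be 0 < low < high")
  chk(cfg$episode$overlap_s < cfg$episode$length_s,
      "episode overlap must be shorter than the episode")
  chk(cfg$clean$ratio_thresh >= 0 && cfg$clean$ratio_thresh <= 1,
      "clean.ratio_thresh must lie in [0, 1]")
  chk(cfg$clean$tau > 0, "clean.tau must be positive")
  chk(cfg$harm$sigma > 0 && cfg$harm$alpha >= 0 && cfg$harm$alpha <= 1,
      "harmonic notch needs sigma > 0 and depth in [0, 1]")
  chk(cfg$sep$stride >= 1 && cfg$sep$n_pcs >= 1 && cfg$sep$max_global >= 1,
      "separation parameters must be positive")
  chk(cfg$select$p_threshold > 0 && cfg$select$p_threshold < 1,
      "select.p_threshold must lie in (0, 1)")
  chk(cfg$select$power_ratio_threshold > 0 &&
        cfg$select$power_ratio_threshold < 1,
      "select.power_ratio_threshold must lie in (0, 1)")
  invisible(cfg)
}

.merge_config <- function(base, override, path = "") {
  for (nm in names(override)) {
    key <- if (path == "") nm else paste(path, nm, sep = ".")
    if (!nm %in% names(base))
      stop(sprintf("validation error: unknown configuration key '%s'", key),
           call. = FALSE)
    if (is.list(base[[nm]]) && !is.null(names(base[[nm]]))) {
      if (!is.list(override[[nm]]))
        stop(sprintf("validation error: '%s' must be a section", key),
             call. = FALSE)
      base[[nm]] <- .merge_config(base[[nm]], override[[nm]], key)
    } else {
      v <- override[[nm]]
      base[[nm]] <- if (is.list(v)) unlist(v) else v
    }
  }
  base
}

#' Load a pipeline configuration from YAML
#'
#' Missing keys take the defaults of [default_config]; unknown keys are
#' rejected; all values are range-validated.
#'
#' @param path YAML file (an empty/missing body yields the defaults).
#' @return A validated `pipeline_config`.
#' @export
load_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  if (!is.null(user) && length(user) > 0L)
    cfg <- structure(.merge_config(unclass(cfg), user),
                     class = "pipeline_config")
  .check_config(cfg)
}

#' Save a pipeline configuration as YAML
#'
#' @param config a `pipeline_config`.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
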