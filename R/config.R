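#' Default experiment configuration
#'
#' Nested list mirroring the study conditions: a 60 s dynamic scan started
#' 5 s before contrast injection, gamma-variate AIF (peak 250 HU over a
#' 40 HU baseline, arrival 4 s after injection), one-compartment tissue
#' kinetics (E = 0.6, Vd = 0.3 mL/g, density 1.05 g/mL), three phantom
#' hearts at pump flows of 1.0-1.2 L/min, six FFR stenosis grades of which
#' FFR09..FFR05 are analyzed, three scan modes at heart rates 107-115 bpm,
#' 10 HU image noise, and 10 replicates per cell. Every value can be
#' overridden via [readConfig()] or by editing the returned list.
#'
#' @return Nested configuration list.
#' @export
defaultConfig <- function() {
  list(
    acquisition = list(duration = 60, injection_start = 5, dt = 0.01),
    aif = list(baseline_hu = 40, t_arrival = 4, alpha = 3, beta = 2.5,
               peak_enhancement = 250),
    tissue = list(baseline_hu = 40, extraction_e = 0.6, dist_volume = 0.3,
                  tissue_density = 1.05),
    hearts = list(
      H1 = list(weight_g = 560, input_flow_ml_min = 1000),
      H2 = list(weight_g = 430, input_flow_ml_min = 1200),
      H3 = list(weight_g = 580, input_flow_ml_min = 1100)),
    ischemic_segments = cxTerritory(),
    grades = list(
      input_flow_factors = c(1, 1, 0.9, 0.8, 0.7, 0.7),
      analyzed = c("FFR09", "FFR08", "FFR07", "FFR06", "FFR05")),
    schemes = list(
      SHUTTLE = list(heart_rate = c(107, 115), trigger_phase = 0.35,
                     slab_revisit_beats = 4),
      NON_SHUTTLE = list(heart_rate = c(107, 115), trigger_phase = 0.35,
                         slab_revisit_beats = 1),
      CONTINUOUS = list(frame_interval = 1 / 16)),
    rotation_time = 0.25,
    rotation_window = NULL,          # point sampling by default
    noise = list(sigma_hu = 10),
    estimator = list(smoothing = "spline", baseline_window_end = 5,
                     slope_window_ecg = 3, slope_window_continuous = 17),
    methods = c("UPSLOPE", "PATLAK"),
    replicates = 10,
    include_occlusion = FALSE
  )
}

# recursive override of defaults; unknown keys raise an error naming them
mergeConfig <- function(base, override, path = "") {
  for (key in names(override)) {
    here <- if (nzchar(path)) paste0(path, "$", key) else key
    if (!key %in% names(base))
      stop("unknown configuration key: ", here, call. = FALSE)
    if (is.list(base[[key]]) && is.list(override[[key]]) &&
        !is.null(names(base[[key]])))
      base[[key]] <- mergeConfig(base[[key]], override[[key]], here)
    else
      base[[key]] <- override[[key]]
  }
  base
}

#' Read a configuration file
#'
#' Loads a YAML configuration and merges it over [defaultConfig()];
#' unknown keys are rejected with the offending key named.
#'
#' @param path YAML file path, or NULL for the defaults.
#' @return Nested configuration list.
#' @export
readConfig <- function(path = NULL) {
  cfg <- defaultConfig()
  if (!is.null(path)) {
    override <- yaml::read_yaml(path)
    cfg <- mergeConfig(cfg, override)
  }
  validateConfig(cfg)
  cfg
}

validateConfig <- function(cfg) {
  chk <- function(ok, key) if (!ok)
    stop("invalid configuration value for key: ", key, call. = FALSE)
  chk(cfg$acquisition$duration > 0, "acquisition$duration")
  chk(cfg$acquisition$injection_start >= 0 &&
        cfg$acquisition$injection_start < cfg$acquisition$duration,
      "acquisition$injection_start")
  chk(cfg$acquisition$dt > 0 && cfg$acquisition$dt <= 0.011,
      "acquisition$dt")
  chk(cfg$aif$alpha > 0, "aif$alpha")
  chk(cfg$aif$beta > 0, "aif$beta")
  chk(cfg$aif$peak_enhancement >= 0, "aif$peak_enhancement")
  chk(cfg$tissue$extraction_e > 0 && cfg$tissue$extraction_e <= 1,
      "tissue$extraction_e")
  chk(cfg$tissue$dist_volume > 0, "tissue$dist_volume")
  chk(cfg$tissue$tissue_density > 0, "tissue$tissue_density")
  chk(length(cfg$hearts) >= 1, "hearts")
  for (h in names(cfg$hearts)) {
    chk(cfg$hearts[[h]]$weight_g > 0, paste0("hearts$", h, "$weight_g"))
    chk(cfg$hearts[[h]]$input_flow_ml_min > 0,
        paste0("hearts$", h, "$input_flow_ml_min"))
  }
  chk(all(cfg$grades$analyzed %in% gradeLabels()), "grades$analyzed")
  chk(length(cfg$grades$input_flow_factors) == 6 &&
        all(diff(cfg$grades$input_flow_factors) <= 0),
      "grades$input_flow_factors")
  chk(cfg$noise$sigma_hu >= 0, "noise$sigma_hu")
  chk(cfg$replicates >= 1, "replicates")
  chk(all(cfg$methods %in% c("UPSLOPE", "PATLAK")), "methods")
  chk(cfg$estimator$smoothing %in% c("none", "ma", "spline"),
      "estimator$smoothing")
  invisible(cfg)
}

# Materialize S4 pieces from the configuration list ------------------------

configHearts <- function(cfg) {
  out <- lapply(names(cfg$hearts), function(h)
    heartPhantom(h, cfg$hearts[[h]]$weight_g,
                 cfg$hearts[[h]]$input_flow_ml_min,
                 ischemicSegments = cfg$ischemic_segments))
  names(out) <- names(cfg$hearts)
  out
}

configSchemes <- function(cfg) {
  dur <- cfg$acquisition$duration
  list(
    SHUTTLE = samplingScheme("SHUTTLE",
      heartRateRange = cfg$schemes$SHUTTLE$heart_rate,
      triggerPhase = cfg$schemes$SHUTTLE$trigger_phase,
      slabRevisitBeats = cfg$schemes$SHUTTLE$slab_revisit_beats,
      rotationTime = cfg$rotation_time, duration = dur),
    NON_SHUTTLE = samplingScheme("NON_SHUTTLE",
      heartRateRange = cfg$schemes$NON_SHUTTLE$heart_rate,
      triggerPhase = cfg$schemes$NON_SHUTTLE$trigger_phase,
      slabRevisitBeats = cfg$schemes$NON_SHUTTLE$slab_revisit_beats,
      rotationTime = cfg$rotation_time, duration = dur),
    CONTINUOUS = samplingScheme("CONTINUOUS",
      frameInterval = cfg$schemes$CONTINUOUS$frame_interval,
      rotationTime = cfg$rotation_time, duration = dur))
}

configEstimator <- function(cfg, mode) {
  upslopeConfig(
    slopeWindow = if (mode == "CONTINUOUS")
      cfg$estimator$slope_window_continuous else
        cfg$estimator$slope_window_ecg,
    baselineWindowEnd = cfg$estimator$baseline_window_end,
    smoothing = cfg$estimator$smoothing)
}
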