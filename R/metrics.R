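is_two_phage <- function(traj) {
  any(traj$P_G > 0) && any(traj$P_W > 0)
}

#' GM phage frequency through time
#'
#' Extracts the transgene (GM phage) frequency series
#' `P_G / (P_G + P_W)` from a two-phage trajectory. Time points where both
#' phage densities are zero are `NA` (the frequency is undefined there,
#' never imputed as 0).
#'
#' @param traj A `phage_trajectory` from [run_simulation()] or
#'   [run_scenario()].
#' @return Data frame with columns `time` and `gm_frequency`.
#' @export
gm_frequency_series <- function(traj) {
  stopifnot(inherits(traj, "phage_trajectory"))
  if (!is_two_phage(traj))
    stop("trajectory contains a single phage type; GM frequency is not ",
         "meaningful - use the density columns (P_G, P_W) directly")
  data.frame(time = traj$time, gm_frequency = traj$gm_frequency)
}

#' Summarize a two-phage competition run
#'
#' Collapses a trajectory to the quantities that matter for the
#' tragedy-of-the-commons question: initial and final GM frequency, the
#' depth and timing of the bacterial collapse, the peak refuge release
#' rate, and an outcome label. The outcome is `"neutral"` when
#' `|final - initial| <= neutral_tolerance`, `"gm_lost_declining"` when
#' the GM phage declined, and `"gm_winning"` when it rose.
#'
#' @param traj A two-phage `phage_trajectory`.
#' @param neutral_tolerance Frequency tolerance for calling a run neutral;
#'   the default `1e-6` is tight because exactly symmetric runs are exact.
#' @return A one-row data frame of class `competition_summary`.
#' @export
summarize_competition <- function(traj, neutral_tolerance = 1e-6) {
  stopifnot(inherits(traj, "phage_trajectory"),
            is.numeric(neutral_tolerance), neutral_tolerance >= 0)
  freq <- gm_frequency_series(traj)$gm_frequency
  def <- which(!is.na(freq))
  if (!length(def)) stop("GM frequency undefined at every output time")
  f0 <- freq[def[1L]]
  f1 <- freq[def[length(def)]]
  i_min <- which.min(traj$total_bacteria)
  i_h <- which.max(traj$h)
  outcome <- if (abs(f1 - f0) <= neutral_tolerance) "neutral"
             else if (f1 < f0) "gm_lost_declining" else "gm_winning"
  structure(data.frame(
    initial_gm_frequency = f0,
    final_gm_frequency = f1,
    min_total_bacteria = traj$total_bacteria[i_min],
    t_min_total_bacteria = traj$time[i_min],
    peak_release_rate = traj$h[i_h],
    t_peak_release_rate = traj$time[i_h],
    clamp_events = as.integer(attr(traj, "clamp_events")),
    outcome = outcome,
    stringsAsFactors = FALSE
  ), class = c("competition_summary", "data.frame"))
}

#' Compare the three burst-size presets
#'
#' Runs the two-phage competition once per burst preset
#' (`gm_disadvantaged`, `equal`, `gm_advantaged`; see [burst_presets]),
#' holding everything else fixed, and returns one [summarize_competition()]
#' row per preset. Final GM frequency is ordered
#' gm_disadvantaged < equal < gm_advantaged across any reasonable initial
#' densities: burst size alone decides the competition.
#'
#' @param base_params A [model_params()] object (burst sizes overridden
#'   per preset).
#' @param B0,R0,phage0,t_end,dt,output_thin,history_mode As in
#'   [run_scenario()].
#' @param neutral_tolerance Passed to [summarize_competition()].
#' @return Data frame with a `preset` column plus the summary columns.
#' @export
compare_burst_configs <- function(base_params = model_params(),
                                  B0 = 2.5e8, R0 = 2.5e8, phage0 = 1e4,
                                  t_end = 1500, dt = 1e-3,
                                  output_thin = round(1 / dt),
                                  history_mode = "hold-initial",
                                  neutral_tolerance = 1e-6) {
  stopifnot(inherits(base_params, "phage_model_params"))
  rows <- lapply(names(burst_presets), function(preset) {
    p <- apply_burst_preset(base_params, preset)
    init <- state_vector(B = B0, R = R0, P_G = phage0, P_W = phage0)
    spec <- simulation_spec(p, init, t_end = t_end, dt = dt,
                            history_mode = history_mode,
                            output_thin = output_thin)
    s <- summarize_competition(run_simulation(spec), neutral_tolerance)
    cbind(data.frame(preset = preset, stringsAsFactors = FALSE), s)
  })
  do.call(rbind, rows)
}
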