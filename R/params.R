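#' Parameters of the value-modulated rise-to-threshold decision process
#'
#' Container for the latent decision variable that governs when an egg is
#' laid.  After each ovulation the latent variable A(t) starts at
#' `reset_level` and evolves as dA = r(t) dt + `noise_sd` dW, where the
#' drift r(t) equals `drift_rate_high` on the substrate of higher relative
#' value and, on the other substrate, relaxes exponentially from
#' `drift_rate_low` back toward `drift_rate_high` with timescale
#' `value_adapt_tau` measured from the last visit to the favoured
#' substrate.  The abdomen bend is emitted when A crosses
#' `threshold_level`; the egg is deposited `bend_to_deposit_delay` seconds
#' later.
#'
#' @param threshold_level Threshold of the latent variable (dimensionless
#'   latent units).
#' @param drift_rate_high Drift on the higher-relative-value substrate
#'   (latent units per second).
#' @param drift_rate_low Drift on the lower-relative-value substrate just
#'   after leaving the favoured one; may be zero or negative.
#' @param noise_sd Diffusion coefficient (latent units per sqrt-second).
#' @param value_adapt_tau Relative-value re-adaptation timescale in
#'   seconds: how quickly the disfavoured substrate's effective drift
#'   recovers toward `drift_rate_high` when the favoured substrate has not
#'   been revisited.
#' @param ovulation_duration_mean Mean duration of the ovulation
#'   standstill in seconds (flies stand still for about a minute while
#'   ovulating).
#' @param bend_to_deposit_delay Seconds between completion of the abdomen
#'   bend and egg deposition.
#' @param inter_egg_refractory Refractory period after a deposition before
#'   the next ovulation can begin, in seconds.
#' @param reset_level Latent level at the start of each search.
#' @return An object of class `drift_params`.
#' @export
drift_params <- function(threshold_level = 1,
                         drift_rate_high = 0.02,
                         drift_rate_low = -0.03,
                         noise_sd = 0.03,
                         value_adapt_tau = 120,
                         ovulation_duration_mean = 60,
                         bend_to_deposit_delay = 3,
                         inter_egg_refractory = 30,
                         reset_level = 0) {
  stopifnot(is.numeric(threshold_level), is.numeric(reset_level))
  if (!(threshold_level > reset_level))
    stop("threshold_level must exceed reset_level")
  if (!(value_adapt_tau > 0)) stop("value_adapt_tau must be positive")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (bend_to_deposit_delay < 0)
    stop("bend_to_deposit_delay must be non-negative")
  if (ovulation_duration_mean <= 0)
    stop("ovulation_duration_mean must be positive")
  if (inter_egg_refractory < 0)
    stop("inter_egg_refractory must be non-negative")
  structure(list(
    threshold_level = threshold_level,
    drift_rate_high = drift_rate_high,
    drift_rate_low = drift_rate_low,
    noise_sd = noise_sd,
    value_adapt_tau = value_adapt_tau,
    ovulation_duration_mean = ovulation_duration_mean,
    bend_to_deposit_delay = bend_to_deposit_delay,
    inter_egg_refractory = inter_egg_refractory,
    reset_level = reset_level
  ), class = "drift_params")
}

#' Geometry of a two-substrate egg-laying choice chamber
#'
#' The chamber floor is split at `midline_y` into a lower and an upper
#' half, each holding a sucrose substrate; a plastic barrier strip of
#' half-width `barrier_halfwidth` straddles the midline and never receives
#' eggs.  Substrate labels are derived from the nominal sucrose
#' concentrations; the half with the LOWER concentration is the
#' higher-relative-value option.
#'
#' @param width,height Chamber dimensions in mm.
#' @param midline_y y coordinate of the barrier midline in mm.
#' @param barrier_halfwidth Half-width of the plastic barrier strip in mm
#'   (default 1.25, i.e. a ~2.5 mm barrier).
#' @param conc_lower,conc_upper Nominal sucrose concentration (mM) of the
#'   lower-y and upper-y halves.
#' @param frame_rate Video frame rate in Hz.
#' @return An object of class `chamber_spec`.
#' @export
chamber_spec <- function(width = 40, height = 40, midline_y = 20,
                         barrier_halfwidth = 1.25,
                         conc_lower = 0, conc_upper = 500,
                         frame_rate = 2) {
  if (!(midline_y > 0 && midline_y < height))
    stop("midline_y must lie strictly inside the chamber")
  if (barrier_halfwidth < 0) stop("barrier_halfwidth must be non-negative")
  if (!(frame_rate > 0)) stop("frame_rate must be positive")
  labels <- c(lower = sprintf("%gmM", conc_lower),
              upper = sprintf("%gmM", conc_upper))
  if (labels[["lower"]] == labels[["upper"]])
    labels <- c(lower = paste0(labels[["lower"]], "_lower"),
                upper = paste0(labels[["upper"]], "_upper"))
  structure(list(
    width = width, height = height, midline_y = midline_y,
    barrier_halfwidth = barrier_halfwidth,
    conc = c(lower = conc_lower, upper = conc_upper),
    labels = labels,
    frame_rate = frame_rate
  ), class = "chamber_spec")
}

#' Which substrate label has the higher relative value
#'
#' The lower sucrose concentration is favoured; with equal concentrations
#' there is no favoured option and `NA` is returned (both halves then
#' receive the high drift rate in the simulator).
#'
#' @param chamber A [chamber_spec()].
#' @return A substrate label, or `NA_character_` for equal concentrations.
#' @export
favoured_substrate <- function(chamber) {
  stopifnot(inherits(chamber, "chamber_spec"))
  if (chamber$conc[["lower"]] == chamber$conc[["upper"]]) return(NA_character_)
  side <- if (chamber$conc[["lower"]] < chamber$conc[["upper"]]) "lower" else "upper"
  unname(chamber$labels[[side]])
}

#' Walk/pause locomotion model parameters
#'
#' Locomotion is a two-state Markov process at the video frame rate: a
#' walking fly moves with a persistent-heading random walk and reflects
#' off the chamber walls; a paused fly is stationary.  Defaults give
#' midline crossings roughly every 30-120 s in the default chamber, which
#' is the only locomotor statistic the downstream analyses depend on.
#'
#' @param walk_speed_mm_s Walking speed in mm/s.
#' @param turn_sd_rad Per-frame SD of heading change while walking.
#' @param p_walk_to_pause,p_pause_to_walk Per-frame transition
#'   probabilities of the walk/pause chain outside search periods.
#' @param search_p_walk_to_pause,search_p_pause_to_walk The same
#'   probabilities during the post-ovulation search, when flies walk
#'   with only brief pauses (searching flies show elevated locomotion;
#'   without this the speed-based search-onset detector would latch onto
#'   ordinary resting pauses instead of the ovulation standstill).
#' @return An object of class `locomotion_params`.
#' @export
locomotion_params <- function(walk_speed_mm_s = 2.5,
                              turn_sd_rad = 1.0,
                              p_walk_to_pause = 0.05,
                              p_pause_to_walk = 0.05,
                              search_p_walk_to_pause = 0.0125,
                              search_p_pause_to_walk = 0.3) {
  stopifnot(walk_speed_mm_s > 0, turn_sd_rad >= 0,
            p_walk_to_pause > 0, p_walk_to_pause < 1,
            p_pause_to_walk > 0, p_pause_to_walk < 1,
            search_p_walk_to_pause > 0, search_p_walk_to_pause < 1,
            search_p_pause_to_walk > 0, search_p_pause_to_walk < 1)
  structure(list(walk_speed_mm_s = walk_speed_mm_s,
                 turn_sd_rad = turn_sd_rad,
                 p_walk_to_pause = p_walk_to_pause,
                 p_pause_to_walk = p_pause_to_walk,
                 search_p_walk_to_pause = search_p_walk_to_pause,
                 search_p_pause_to_walk = search_p_pause_to_walk),
            class = "locomotion_params")
}

#' Specification of the synthetic fluorescence generator
#'
#' Maps a latent trace A(t) to pooled cell and background fluorescence:
#' F_cell(t) = baseline_F * (1 + gain * A(t)) + background_F + drift +
#' noise, with F_background(t) = background_F + noise, sampled at
#' `volume_rate` with volume timestamps at half-volume completion.
#'
#' @param gain Fluorescence modulation per latent unit (dimensionless).
#' @param baseline_F Cell baseline fluorescence (arbitrary units).
#' @param background_F Background fluorescence (arbitrary units).
#' @param baseline_drift_sd Per-volume SD of a slow random-walk drift
#'   added to the cell baseline.
#' @param photon_noise_sd Per-volume white noise SD.
#' @param volume_rate Volumetric imaging rate in Hz.
#' @return An object of class `fluor_sim_spec`.
#' @export
fluorescence_sim_spec <- function(gain = 1, baseline_F = 100,
                                  background_F = 20,
                                  baseline_drift_sd = 0,
                                  photon_noise_sd = 0,
                                  volume_rate = 1.5) {
  if (!(baseline_F > 0)) stop("baseline_F must be positive")
  if (!(volume_rate > 0)) stop("volume_rate must be positive")
  stopifnot(baseline_drift_sd >= 0, photon_noise_sd >= 0)
  structure(list(gain = gain, baseline_F = baseline_F,
                 background_F = background_F,
                 baseline_drift_sd = baseline_drift_sd,
                 photon_noise_sd = photon_noise_sd,
                 volume_rate = volume_rate),
            class = "fluor_sim_spec")
}

#' Gentle-hyperpolarization ("Kir2.1*-mimic") parameter transform
#'
#' Models a moderate hyperpolarization of the decision neurons as a
#' uniform attenuation of their synaptic drive: both drift rates and the
#' diffusion coefficient are scaled by `factor`.  Scaling the
#' deterministic drift alone would leave the unscaled noise to dominate
#' threshold crossings and would reverse the choice effect; attenuating
#' the whole drive slows the rise-to-threshold (longer searches) while
#' giving the fly more substrate encounters per decision, which raises
#' the fraction of eggs on the preferred option.
#'
#' @param params A [drift_params()].
#' @param factor Drive attenuation factor in (0, 1].
#' @return A new `drift_params`.
#' @export
kir_mimic_params <- function(params, factor = 0.4) {
  stopifnot(inherits(params, "drift_params"), factor > 0, factor <= 1)
  drift_params(
    threshold_level = params$threshold_level,
    drift_rate_high = params$drift_rate_high * factor,
    drift_rate_low = params$drift_rate_low * factor,
    noise_sd = params$noise_sd * factor,
    value_adapt_tau = params$value_adapt_tau,
    ovulation_duration_mean = params$ovulation_duration_mean,
    bend_to_deposit_delay = params$bend_to_deposit_delay,
    inter_egg_refractory = params$inter_egg_refractory,
    reset_level = params$reset_level)
}
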