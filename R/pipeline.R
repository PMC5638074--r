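#' End-to-end phantom study
#'
#' Runs the whole method once: simulate physiology, play the ungated FLASH
#' acquisition against the beating phantom, retrospectively bin the recorded
#' k-lines using the event log, fill gaps, reconstruct the CINE stack,
#' segment the blood pool into a time-volume curve, differentiate it and read
#' off the diastolic (E/A) and systolic (EDV/ESV/SV/EF) metrics. This is the
#' in-silico analogue of scanning one animal once.
#'
#' @param phantom a [phantom_params()] object.
#' @param seq a [sequence_params()] object.
#' @param config a [recon_config()].
#' @param hr_mean,hr_sd,resp_rate,resp_window physiology, see
#'   [simulate_physio()].
#' @param noise_sd,resp_shift_px acquisition corruption, see
#'   [simulate_acquisition()].
#' @param threshold_frac,smooth_window,prominence_frac analysis settings, see
#'   [segment_lv()], [filling_rate()], [detect_ea()].
#' @param seed integer seed driving physiology (seed) and noise (seed + 1).
#' @param keep_cine keep the reconstructed `cine_stack` in the result
#'   (large); default `FALSE`.
#' @return list with `diastolic` ([detect_ea()] result), `systolic`
#'   ([systolic_metrics()]), `volume` and `filling` curves, the
#'   [coverage_stats()] report, `median_rr` and optionally `cine`.
#' @export
run_phantom_study <- function(phantom = phantom_params(),
                              seq = sequence_params(),
                              config = recon_config(nf = seq$nf),
                              hr_mean = 588, hr_sd = 38,
                              resp_rate = 55, resp_window = 200,
                              noise_sd = NULL, resp_shift_px = 2,
                              threshold_frac = 0.5, smooth_window = 3L,
                              prominence_frac = 0.1,
                              seed = 1L, keep_cine = FALSE) {
  physio <- simulate_physio(total_scan_time(seq), hr_mean = hr_mean,
                            hr_sd = hr_sd, resp_rate = resp_rate,
                            resp_window = resp_window, seed = seed)
  acq <- simulate_acquisition(phantom, physio, seq, noise_sd = noise_sd,
                              resp_shift_px = resp_shift_px, seed = seed + 1L)
  bins <- bin_kspace(acq$lines, acq$log, config)
  cov <- coverage_stats(bins, thresholds = c(1L, 3L))
  cine <- reconstruct_cine(fill_gaps(bins))
  vol <- volume_curve(cine, threshold_frac = threshold_frac)
  fill <- filling_rate(vol, smooth_window = smooth_window)
  out <- list(diastolic = detect_ea(fill, vol, prominence_frac = prominence_frac),
              systolic = systolic_metrics(vol),
              volume = vol, filling = fill, coverage = cov,
              median_rr = bins$median_rr)
  if (keep_cine) out$cine <- cine
  out
}
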