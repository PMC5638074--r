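#' FLASH sequence parameters
#'
#' Parameters of the ungated FLASH acquisition: one phase-encode line per
#' repetition time TR, full k-space swept linearly per repetition, `nr`
#' repetitions in total, later rebinned into `nf` cardiac frames. Defaults
#' follow the high-temporal-resolution CINE protocol: TR = 3.15 ms, 128
#' matrix, FOV 25.6 mm, 1 mm slice, NR = 1400, NF = 90.
#'
#' @param tr repetition time, ms.
#' @param te echo time, ms (metadata only).
#' @param fa flip angle, degrees (metadata only).
#' @param matrix readout/phase-encode matrix size (positive power of two).
#' @param fov field of view, mm.
#' @param slice_thickness mm.
#' @param nr number of sequence repetitions (full k-space sweeps).
#' @param nf number of reconstructed frames per cardiac cycle.
#' @return an object of class `sequence_params`.
#' @export
sequence_params <- function(tr = 3.15, te = 1.21, fa = 15, matrix = 128,
                            fov = 25.6, slice_thickness = 1,
                            nr = 1400, nf = 90) {
  if (!is.numeric(tr) || tr <= 0)
    htr_stop("invalid_parameter", "tr must be positive")
  if (!is_power_of_two(matrix))
    htr_stop("invalid_parameter", "matrix must be a positive power of two")
  if (nr < 1 || nf < 1)
    htr_stop("invalid_parameter", "nr and nf must be >= 1")
  structure(list(tr = tr, te = te, fa = fa, matrix = as.integer(matrix),
                 fov = fov, slice_thickness = slice_thickness,
                 nr = as.integer(nr), nf = as.integer(nf)),
            class = "sequence_params")
}

#' @export
print.sequence_params <- function(x, ...) {
  cat(sprintf("FLASH: TR %g ms, matrix %d, FOV %g mm, NR %d, NF %d (scan %.1f s)\n",
              x$tr, x$matrix, x$fov, x$nr, x$nf, total_scan_time(x) / 1000))
  invisible(x)
}

#' Total scan duration
#'
#' @param seq a [sequence_params()] object.
#' @return `nr * matrix * tr`, ms. For the default protocol this is
#'   1400 x 128 x 3.15 ms = 564,480 ms (~9.4 min).
#' @export
total_scan_time <- function(seq) {
  stopifnot(inherits(seq, "sequence_params"))
  seq$nr * seq$matrix * seq$tr
}

# Line-acquisition timestamps and indices for a whole scan: line k of
# repetition r is acquired at (r * matrix + k) * tr, linear phase-encode order.
line_schedule <- function(seq) {
  idx <- seq_len(seq$nr * seq$matrix) - 1L
  list(time = idx * seq$tr,
       rep_index = idx %/% seq$matrix,
       pe_index = idx %% seq$matrix)
}

# TRUE for times falling inside any [start, end] interval (rows of `iv`),
# optionally enlarged by `margin` on each side. Intervals are merged after
# enlargement so overlap cannot double-count.
in_intervals <- function(t, iv, margin = 0) {
  if (is.null(iv) || nrow(iv) == 0L) return(rep(FALSE, length(t)))
  lo <- iv[, 1] - margin
  hi <- iv[, 2] + margin
  o <- order(lo)
  lo <- lo[o]; hi <- hi[o]
  # merge overlapping windows
  keep_lo <- lo[1]; keep_hi <- hi[1]
  if (length(lo) > 1L) for (i in 2L:length(lo)) {
    if (lo[i] <= keep_hi[length(keep_hi)]) {
      keep_hi[length(keep_hi)] <- max(keep_hi[length(keep_hi)], hi[i])
    } else {
      keep_lo <- c(keep_lo, lo[i]); keep_hi <- c(keep_hi, hi[i])
    }
  }
  j <- findInterval(t, keep_lo)
  j >= 1L & t <= keep_hi[pmax(j, 1L)]
}

#' Simulate the ungated acquisition
#'
#' Plays the FLASH sequence against the beating phantom: every TR one
#' phase-encode line is sampled from the 2-D DFT of the phantom image at the
#' instantaneous cardiac phase (taken from a dictionary of `4 * nf`
#' precomputed phases, so phase-quantisation error is well below one
#' reconstruction bin), i.i.d. complex Gaussian noise is added per sample,
#' and every event (R-wave, respiration window, RF line) is written to the
#' event log. During respiration windows the image is bulk-shifted along the
#' readout direction by `resp_shift_px` pixels (applied as a k-space phase
#' ramp), so respiratory gating demonstrably matters downstream.
#'
#' K-space layout: phase-encode row 0 is the most negative spatial frequency;
#' DC sits at row `matrix/2` (zero-based). See [fft-layout].
#'
#' @param phantom a [phantom_params()] object.
#' @param physio a [simulate_physio()] trace covering the whole scan.
#' @param seq a [sequence_params()] object.
#' @param noise_sd per-channel standard deviation of the complex Gaussian
#'   k-space noise. The default `matrix * blood_intensity / 20` yields a
#'   blood-pool SNR of about 20 in a single-average reconstruction.
#' @param resp_shift_px bulk image shift (pixels, readout direction) applied
#'   while a respiration window is open; 0 disables motion corruption.
#' @param seed integer RNG seed for the noise.
#' @return a list with `lines` (class `kline_set`: vectors `time`,
#'   `rep_index`, `pe_index` and a complex `samples` matrix of one k-line per
#'   row) and `log` (an [event_log()] with the R-wave, respiration and RF
#'   events).
#' @export
simulate_acquisition <- function(phantom, physio, seq,
                                 noise_sd = NULL, resp_shift_px = 2,
                                 seed = 1L) {
  stopifnot(inherits(phantom, "phantom_params"),
            inherits(physio, "physio_trace"),
            inherits(seq, "sequence_params"))
  if (phantom$matrix != seq$matrix || phantom$fov != seq$fov)
    htr_stop("invalid_parameter", "phantom and sequence geometry disagree")
  if (physio$duration < total_scan_time(seq))
    htr_stop("insufficient_trace",
             "physio trace (%.0f ms) is shorter than the scan (%.0f ms)",
             physio$duration, total_scan_time(seq))
  if (is.null(noise_sd))
    noise_sd <- seq$matrix * phantom$intensities[["blood"]] / 20
  if (noise_sd < 0)
    htr_stop("invalid_parameter", "noise_sd must be >= 0")

  n <- seq$matrix
  sched <- line_schedule(seq)
  nlines <- length(sched$time)

  # nearest of 4*nf precomputed phases
  nphase <- 4L * seq$nf
  didx <- as.integer(round(cardiac_phase_at(sched$time, physio$rwave_times) * nphase)) %% nphase
  used <- sort(unique(didx))
  uof <- match(didx, used)

  # k-space rows for every used dictionary phase: array [n_used, pe, read]
  nu <- length(used)
  dict <- array(complex(real = 0), dim = c(nu, n, n))
  for (u in seq_len(nu)) {
    img <- render_frame(used[u] / nphase, phantom)
    dict[u, , ] <- image_to_kspace(img)
  }
  flat <- matrix(dict, nrow = nu * n, ncol = n)
  samples <- flat[uof + nu * sched$pe_index, , drop = FALSE]

  # respiratory bulk shift: linear phase ramp along the readout axis
  if (resp_shift_px != 0) {
    in_resp <- in_intervals(sched$time, physio$resp_intervals)
    if (any(in_resp)) {
      kx <- (seq_len(n) - 1L) - n / 2
      ramp <- exp(-2i * pi * kx * resp_shift_px / n)
      samples[in_resp, ] <- sweep(samples[in_resp, , drop = FALSE], 2, ramp, `*`)
    }
  }

  if (noise_sd > 0) {
    samples <- samples + with_seed(seed, {
      matrix(complex(real = stats::rnorm(nlines * n, sd = noise_sd),
                     imaginary = stats::rnorm(nlines * n, sd = noise_sd)),
             nlines, n)
    })
  }

  lines <- structure(list(time = sched$time, rep_index = sched$rep_index,
                          pe_index = sched$pe_index, samples = samples,
                          seq = seq),
                     class = "kline_set")
  log <- event_log(rwave_times = physio$rwave_times,
                   resp_intervals = physio$resp_intervals,
                   rf = data.frame(time = sched$time,
                                   rep_index = sched$rep_index,
                                   pe_index = sched$pe_index))
  list(lines = lines, log = log)
}

#' @export
print.kline_set <- function(x, ...) {
  cat(sprintf("kline_set: %d k-lines of %d samples (%.1f s of data)\n",
              length(x$time), ncol(x$samples),
              (max(x$time) - min(x$time)) / 1000))
  invisible(x)
}
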