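#' Reconstruction configuration
#'
#' Settings for retrospective k-space binning. `phase_mode = "relative"`
#' (default) assigns each line a frame by its fractional position within the
#' enclosing R-R interval, which absorbs beat-to-beat heart-rate variability;
#' `"absolute"` bins by elapsed time since the last R-wave in fixed-width bins
#' of `median R-R / nf` ms. Cycles whose R-R deviates from the median by more
#' than `rr_reject_frac` are discarded as presumed gating errors (mistimed or
#' missed R-waves); lines inside a respiration window (enlarged by
#' `resp_margin` ms on each side) are discarded when `resp_reject` is on.
#'
#' @param nf frames per cardiac cycle.
#' @param phase_mode `"relative"` or `"absolute"`.
#' @param resp_reject discard lines acquired during respiration windows.
#' @param resp_margin extra rejection margin around each respiration window, ms.
#' @param rr_reject_frac maximum fractional deviation of a cycle's R-R from
#'   the median before the whole cycle is discarded (default 0.2).
#' @param gap_strategy `"nearest_frame"` (copy the nearest populated frame's
#'   averaged line, see [fill_gaps()]) or `"zero_fill"`.
#' @return an object of class `recon_config`.
#' @export
recon_config <- function(nf = 90, phase_mode = c("relative", "absolute"),
                         resp_reject = TRUE, resp_margin = 0,
                         rr_reject_frac = 0.2,
                         gap_strategy = c("nearest_frame", "zero_fill")) {
  phase_mode <- match.arg(phase_mode)
  gap_strategy <- match.arg(gap_strategy)
  if (nf < 1) htr_stop("invalid_parameter", "nf must be >= 1")
  if (resp_margin < 0) htr_stop("invalid_parameter", "resp_margin must be >= 0")
  if (rr_reject_frac < 0) htr_stop("invalid_parameter", "rr_reject_frac must be >= 0")
  structure(list(nf = as.integer(nf), phase_mode = phase_mode,
                 resp_reject = isTRUE(resp_reject), resp_margin = resp_margin,
                 rr_reject_frac = rr_reject_frac, gap_strategy = gap_strategy),
            class = "recon_config")
}

#' Assign cardiac frames to timestamps
#'
#' Maps acquisition times onto frame indices `0 .. nf-1` using the recorded
#' R-wave train. In relative mode the frame is
#' `floor(nf * (t - R_i) / (R_{i+1} - R_i))` for the enclosing interval
#' `[R_i, R_{i+1})`; in absolute mode, `floor((t - R_i) / bin_ms)` with
#' `bin_ms = median R-R / nf`, rejected when the elapsed time overruns `nf`
#' bins. Times before the first or at/after the last R-wave have no enclosing
#' cycle and are rejected (`NA`).
#'
#' @param t numeric vector of timestamps, ms.
#' @param rwaves sorted R-wave times, ms.
#' @param nf frames per cycle.
#' @param mode `"relative"` or `"absolute"`.
#' @return integer vector of frame indices in `[0, nf)`, `NA` = rejected.
#' @export
assign_cardiac_phase <- function(t, rwaves, nf,
                                 mode = c("relative", "absolute")) {
  mode <- match.arg(mode)
  if (length(rwaves) == 0L)
    htr_stop("invalid_input", "rwaves must be non-empty")
  if (is.unsorted(rwaves, strictly = TRUE))
    htr_stop("invalid_input", "rwaves must be sorted strictly increasing")
  n <- length(rwaves)
  idx <- findInterval(t, rwaves)
  frame <- rep(NA_integer_, length(t))
  inside <- idx >= 1L & idx < n & t < rwaves[n]
  if (!any(inside)) return(frame)
  if (mode == "relative") {
    rr <- diff(rwaves)
    frac <- (t[inside] - rwaves[idx[inside]]) / rr[idx[inside]]
    frame[inside] <- pmin(as.integer(floor(nf * frac)), nf - 1L)
  } else {
    bin_ms <- stats::median(diff(rwaves)) / nf
    f <- as.integer(floor((t[inside] - rwaves[idx[inside]]) / bin_ms))
    f[f >= nf] <- NA_integer_
    frame[inside] <- f
  }
  frame
}

# Shared timing core: classify every line (rejection cause or frame index).
# Returns list(frame = integer NA/0..nf-1, cause = factor-ish character,
# median_rr). Rejection precedence: respiration > unassignable > arrhythmia.
classify_lines <- function(time, log, config) {
  rwaves <- log$rwave_times
  med_rr <- if (length(rwaves) >= 2L) stats::median(diff(rwaves)) else NA_real_

  n_t <- length(time)
  cause <- rep(NA_character_, n_t)

  if (config$resp_reject)
    cause[in_intervals(time, log$resp_intervals, config$resp_margin)] <- "respiration"

  frame <- if (length(rwaves) >= 2L)
    assign_cardiac_phase(time, rwaves, config$nf, config$phase_mode)
  else rep(NA_integer_, n_t)
  todo <- is.na(cause)
  cause[todo & is.na(frame)] <- "unassignable"

  if (config$rr_reject_frac < Inf && length(rwaves) >= 2L) {
    rr <- diff(rwaves)
    bad_cycle <- abs(rr - med_rr) > config$rr_reject_frac * med_rr
    if (any(bad_cycle)) {
      cyc <- findInterval(time, rwaves)
      in_bad <- cyc >= 1L & cyc < length(rwaves) & bad_cycle[pmax(cyc, 1L)]
      cause[is.na(cause) & in_bad] <- "arrhythmia"
    }
  }
  frame[!is.na(cause)] <- NA_integer_
  list(frame = frame, cause = cause, median_rr = med_rr)
}

tally_causes <- function(cause) {
  c(respiration = sum(cause == "respiration", na.rm = TRUE),
    arrhythmia = sum(cause == "arrhythmia", na.rm = TRUE),
    unassignable = sum(cause == "unassignable", na.rm = TRUE))
}

#' Bin k-space lines into cardiac frames
#'
#' The retrospective reconstruction core: every recorded k-line is either
#' rejected (acquired during a respiration window, inside an arrhythmic cycle,
#' or outside any recorded cycle) or assigned a cardiac frame from the event
#' log and summed into the `nf x matrix` accumulator for its phase-encode row,
#' with per-cell average counts tracked. Assigned plus rejected lines always
#' equal the total (conservation).
#'
#' @param lines a `kline_set` from [simulate_acquisition()] (or equivalent).
#' @param log the matching [event_log()].
#' @param config a [recon_config()].
#' @return an object of class `kspace_bins`: complex `accumulator` array
#'   `(nf, pe, read)`, integer `counts` matrix `(nf, pe)`, the sequence
#'   parameters, config, `median_rr` (ms) and a `rejected` tally by cause.
#' @export
bin_kspace <- function(lines, log, config = recon_config()) {
  stopifnot(inherits(lines, "kline_set"), inherits(log, "event_log"),
            inherits(config, "recon_config"))
  nl <- length(lines$time)
  if (nrow(log$rf) != nl ||
      any(abs(log$rf$time - lines$time) > 1e-6) ||
      any(log$rf$pe_index != lines$pe_index))
    htr_stop("consistency_error", "event log RF records do not match the k-line stream")

  seqp <- lines$seq
  npe <- seqp$matrix
  nread <- ncol(lines$samples)
  nf <- config$nf

  cls <- classify_lines(lines$time, log, config)
  keep <- !is.na(cls$frame)

  acc <- array(complex(real = 0), dim = c(nf, npe, nread))
  counts <- matrix(0L, nf, npe)
  if (any(keep)) {
    cell <- cls$frame[keep] + nf * lines$pe_index[keep] + 1L  # 1-based (frame, pe)
    counts_v <- tabulate(cell, nbins = nf * npe)
    counts <- matrix(as.integer(counts_v), nf, npe)
    sm <- lines$samples[keep, , drop = FALSE]
    re <- rowsum(Re(sm), group = cell, reorder = FALSE)
    im <- rowsum(Im(sm), group = cell, reorder = FALSE)
    rows <- as.integer(rownames(re))
    flat <- matrix(acc, nrow = nf * npe, ncol = nread)
    flat[rows, ] <- complex(real = re, imaginary = im)
    acc <- array(flat, dim = c(nf, npe, nread))
  }

  structure(list(accumulator = acc, counts = counts, seq = seqp,
                 config = config, median_rr = cls$median_rr,
                 rejected = tally_causes(cls$cause),
                 n_lines = nl, n_assigned = sum(keep)),
            class = "kspace_bins")
}

#' @export
print.kspace_bins <- function(x, ...) {
  cat(sprintf("kspace_bins: %d frames x %d pe rows, %d/%d lines assigned (mean %.1f averages/cell)\n",
              nrow(x$counts), ncol(x$counts), x$n_assigned, x$n_lines,
              mean(x$counts)))
  cat("  rejected:", paste(names(x$rejected), x$rejected, sep = "=",
                           collapse = ", "), "\n")
  invisible(x)
}

#' k-space coverage statistics
#'
#' Reports, for each minimum-average threshold, the fraction of
#' `(frame, pe)` cells holding at least that many averages -- the figure of
#' merit behind the protocol requirement that >= 99% of k-space be filled
#' with a minimum of three averages.
#'
#' @param bins a [bin_kspace()] result.
#' @param thresholds integer thresholds (default `c(1, 3)`).
#' @return an object of class `coverage_report` with `fill_fraction_at`
#'   (named numeric, non-increasing in the threshold), `mean_averages` and
#'   the `rejected_lines` tally.
#' @export
coverage_stats <- function(bins, thresholds = c(1L, 3L)) {
  stopifnot(inherits(bins, "kspace_bins"))
  fr <- vapply(thresholds, function(k) mean(bins$counts >= k), numeric(1))
  names(fr) <- as.character(thresholds)
  structure(list(fill_fraction_at = fr, mean_averages = mean(bins$counts),
                 rejected_lines = bins$rejected),
            class = "coverage_report")
}

#' @export
print.coverage_report <- function(x, ...) {
  cat("coverage:",
      paste(sprintf(">=%s: %.2f%%", names(x$fill_fraction_at),
                    100 * x$fill_fraction_at), collapse = ", "),
      sprintf("(mean %.1f averages)\n", x$mean_averages))
  invisible(x)
}

#' Coverage as a function of the number of repetitions
#'
#' Timing-only Monte-Carlo: for each candidate NR, simulates physiology,
#' classifies and bins line *timestamps* (no image synthesis), and reports the
#' fill fraction at >= 3 averages across replicates. This is how NR = 1400
#' can be justified as sufficient for a 90-frame reconstruction.
#'
#' @param seq a [sequence_params()] object (its `nr` is overridden).
#' @param physio_spec list with `hr_mean`, `hr_sd`, `resp_rate`,
#'   `resp_window` passed to [simulate_physio()].
#' @param nr_values integer vector of NR values to probe.
#' @param replicates Monte-Carlo replicates per NR.
#' @param seed base seed; replicate r of NR index i uses
#'   `seed + (i-1)*replicates + (r-1)`.
#' @param config a [recon_config()].
#' @param threshold minimum-average threshold (default 3).
#' @return a data frame with columns `nr`, `fill_fraction`, `sd`.
#' @export
nr_coverage_sweep <- function(seq, physio_spec = list(), nr_values,
                              replicates = 10L, seed = 1L,
                              config = recon_config(nf = seq$nf),
                              threshold = 3L) {
  stopifnot(inherits(seq, "sequence_params"))
  if (replicates < 1L) htr_stop("invalid_parameter", "replicates must be >= 1")
  spec <- utils::modifyList(list(hr_mean = 588, hr_sd = 38,
                                 resp_rate = 55, resp_window = 200),
                            physio_spec)
  res <- lapply(seq_along(nr_values), function(i) {
    nr <- nr_values[i]
    sq <- seq; sq$nr <- as.integer(nr)
    fills <- vapply(seq_len(replicates), function(r) {
      s <- seed + (i - 1L) * replicates + (r - 1L)
      dur <- total_scan_time(sq)
      ph <- simulate_physio(dur, hr_mean = spec$hr_mean, hr_sd = spec$hr_sd,
                            resp_rate = spec$resp_rate,
                            resp_window = spec$resp_window, seed = s)
      sched <- line_schedule(sq)
      log <- event_log(rwave_times = ph$rwave_times,
                       resp_intervals = ph$resp_intervals,
                       rf = data.frame(time = sched$time,
                                       rep_index = sched$rep_index,
                                       pe_index = sched$pe_index))
      cls <- classify_lines(sched$time, log, config)
      keep <- !is.na(cls$frame)
      cell <- cls$frame[keep] + config$nf * sched$pe_index[keep] + 1L
      counts <- tabulate(cell, nbins = config$nf * sq$matrix)
      mean(counts >= threshold)
    }, numeric(1))
    data.frame(nr = nr, fill_fraction = mean(fills),
               sd = if (replicates > 1L) stats::sd(fills) else NA_real_)
  })
  do.call(rbind, res)
}

#' Fill empty k-space cells
#'
#' With `nearest_frame` (default), every empty `(frame, pe)` cell borrows the
#' averaged line of the nearest frame -- in circular frame distance, ties
#' resolved toward the preceding frame -- holding at least one average of the
#' same phase-encode row; this preserves the spatial-frequency content that
#' zero-filling would discard. `zero_fill` leaves empty cells at zero.
#'
#' @param bins a [bin_kspace()] result.
#' @param strategy `"nearest_frame"` or `"zero_fill"` (default: the strategy
#'   in the bins' config).
#' @return `kspace_bins` with no empty cells (`nearest_frame`) and an
#'   attribute `filled_cells`; errors with class
#'   `htrcine_unrecoverable_gap` if a phase-encode row is empty at all frames.
#' @export
fill_gaps <- function(bins, strategy = NULL) {
  stopifnot(inherits(bins, "kspace_bins"))
  if (is.null(strategy)) strategy <- bins$config$gap_strategy
  strategy <- match.arg(strategy, c("nearest_frame", "zero_fill"))
  bins$config$gap_strategy <- strategy
  if (strategy == "zero_fill") {
    attr(bins, "filled_cells") <- 0L
    return(bins)
  }
  nf <- nrow(bins$counts)
  filled <- 0L
  for (pe in seq_len(ncol(bins$counts))) {
    empty <- which(bins$counts[, pe] == 0L)
    if (!length(empty)) next
    if (length(empty) == nf)
      htr_stop("unrecoverable_gap",
               "phase-encode row %d is empty at every frame", pe - 1L)
    pop <- which(bins$counts[, pe] > 0L)
    for (f in empty) {
      # circular distance; tie -> preceding frame (checked first per distance)
      best <- NA_integer_
      for (d in 1L:(nf %/% 2L + 1L)) {
        prev <- ((f - 1L - d) %% nf) + 1L
        nxt <- ((f - 1L + d) %% nf) + 1L
        if (prev %in% pop) { best <- prev; break }
        if (nxt %in% pop) { best <- nxt; break }
      }
      bins$accumulator[f, pe, ] <- bins$accumulator[best, pe, ]
      bins$counts[f, pe] <- bins$counts[best, pe]
      filled <- filled + 1L
    }
  }
  attr(bins, "filled_cells") <- filled
  bins
}

#' Reconstruct the CINE stack
#'
#' Normalises each accumulated cell by its average count, inverse-2-D-DFTs
#' each frame's k-space and takes magnitudes. Empty cells are a precondition
#' error unless the bins were produced under `zero_fill`.
#'
#' @param bins gap-filled [kspace_bins].
#' @return an object of class `cine_stack`: `frames` array `(nf, y, x)` of
#'   magnitude images, `frame_duration` (= median R-R / nf, ms), and the
#'   sequence/config provenance. Frame timestamps are bin centers with frame
#'   0 starting at the R-wave.
#' @export
reconstruct_cine <- function(bins) {
  stopifnot(inherits(bins, "kspace_bins"))
  if (any(bins$counts == 0L) && bins$config$gap_strategy != "zero_fill")
    htr_stop("precondition_error",
             "empty k-space cells present; run fill_gaps() or use zero_fill")
  nf <- nrow(bins$counts)
  n <- bins$seq$matrix
  frames <- array(0, dim = c(nf, n, n))
  for (f in seq_len(nf)) {
    k <- bins$accumulator[f, , ]
    cnt <- bins$counts[f, ]
    nz <- cnt > 0L
    k[nz, ] <- k[nz, ] / cnt[nz]
    frames[f, , ] <- Mod(kspace_to_image(k))
  }
  structure(list(frames = frames, frame_duration = bins$median_rr / nf,
                 seq = bins$seq, config = bins$config),
            class = "cine_stack")
}

#' @export
print.cine_stack <- function(x, ...) {
  cat(sprintf("cine_stack: %d frames of %dx%d, frame duration %.3f ms (R-R %.1f ms)\n",
              dim(x$frames)[1], dim(x$frames)[2], dim(x$frames)[3],
              x$frame_duration, x$frame_duration * dim(x$frames)[1]))
  invisible(x)
}

#' Export a CINE stack as multi-page TIFF
#'
#' One page per frame, intensities rescaled to the stack-wide maximum.
#' Requires the `tiff` package.
#'
#' @param cine a [reconstruct_cine()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cine_tiff <- function(cine, path) {
  stopifnot(inherits(cine, "cine_stack"))
  if (!requireNamespace("tiff", quietly = TRUE))
    htr_stop("invalid_parameter", "the 'tiff' package is required for TIFF export")
  mx <- max(cine$frames)
  pages <- lapply(seq_len(dim(cine$frames)[1]),
                  function(f) cine$frames[f, , ] / mx)
  tiff::writeTIFF(pages, path)
  invisible(path)
}
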