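#' Segment the LV blood pool in one frame
#'
#' Automated stand-in for manual blood-pool segmentation: the reference
#' intensity is the maximum over a small disc around the seed point, the
#' frame is thresholded at `threshold_frac` times that reference, and the
#' 4-connected component containing the seed is kept.
#'
#' @param frame numeric image matrix.
#' @param threshold_frac threshold as a fraction of the reference intensity,
#'   in (0, 1].
#' @param seed_point integer `(row, col)` inside the blood pool; default the
#'   image center.
#' @param ref_radius radius (pixels) of the disc used for the reference
#'   intensity.
#' @return number of pixels in the segmented component.
#' @export
segment_lv <- function(frame, threshold_frac = 0.5, seed_point = NULL,
                       ref_radius = 3) {
  if (!is.matrix(frame)) htr_stop("invalid_parameter", "frame must be a matrix")
  if (threshold_frac <= 0 || threshold_frac > 1)
    htr_stop("invalid_parameter", "threshold_frac must lie in (0, 1]")
  if (is.null(seed_point)) seed_point <- c(nrow(frame) %/% 2, ncol(frame) %/% 2)
  seed_point <- as.integer(seed_point)
  if (any(seed_point < 1L) || seed_point[1] > nrow(frame) ||
      seed_point[2] > ncol(frame))
    htr_stop("invalid_parameter", "seed_point must lie inside the image")

  ri <- max(1L, seed_point[1] - ref_radius):min(nrow(frame), seed_point[1] + ref_radius)
  ci <- max(1L, seed_point[2] - ref_radius):min(ncol(frame), seed_point[2] + ref_radius)
  disc <- outer((ri - seed_point[1])^2, (ci - seed_point[2])^2, `+`) <= ref_radius^2
  ref <- max(frame[ri, ci][disc])
  thr <- threshold_frac * ref
  if (!is.finite(thr) || frame[seed_point[1], seed_point[2]] < thr || ref <= 0)
    htr_stop("empty_segmentation", "seed pixel falls below the threshold")

  mask <- matrix(0L, nrow(frame), ncol(frame))
  mask[frame >= thr] <- 1L
  filled <- EBImage::floodFill(mask, matrix(seed_point, nrow = 1), col = 2L)
  sum(filled == 2L)
}

#' Time-volume curve from a CINE stack
#'
#' Segments the blood pool in every frame and converts pixel counts to
#' volumes as pixel count x in-plane voxel area x slice thickness
#' (`(fov/matrix)^2 * slice_thickness` mm^3 = uL). Frame times are bin
#' centers, frame 0 starting at the R-wave.
#'
#' @param cine a [reconstruct_cine()] result.
#' @param threshold_frac,seed_point,ref_radius passed to [segment_lv()].
#' @param slice_label one of `"basal"`, `"mid"`, `"apical"`, `"combined"`.
#' @return an object of class `volume_curve` with fields `times` (ms),
#'   `volumes` (uL) and `slice_label`.
#' @export
volume_curve <- function(cine, threshold_frac = 0.5, seed_point = NULL,
                         ref_radius = 3, slice_label = "basal") {
  stopifnot(inherits(cine, "cine_stack"))
  nf <- dim(cine$frames)[1]
  voxel <- (cine$seq$fov / cine$seq$matrix)^2 * cine$seq$slice_thickness
  counts <- vapply(seq_len(nf), function(f)
    segment_lv(cine$frames[f, , ], threshold_frac, seed_point, ref_radius),
    numeric(1))
  new_volume_curve((seq_len(nf) - 0.5) * cine$frame_duration,
                   counts * voxel, slice_label)
}

new_volume_curve <- function(times, volumes, slice_label = "basal") {
  if (length(times) != length(volumes))
    htr_stop("invalid_parameter", "times and volumes must have equal length")
  if (is.unsorted(times, strictly = TRUE))
    htr_stop("invalid_parameter", "times must be strictly increasing")
  if (any(volumes < 0))
    htr_stop("invalid_parameter", "volumes must be non-negative")
  structure(list(times = as.numeric(times), volumes = as.numeric(volumes),
                 slice_label = slice_label),
            class = "volume_curve")
}

#' @export
print.volume_curve <- function(x, ...) {
  cat(sprintf("volume_curve (%s): %d frames, %.1f-%.1f uL\n",
              x$slice_label, length(x$times), min(x$volumes), max(x$volumes)))
  invisible(x)
}

# Circular moving average with an odd window.
circular_ma <- function(x, window) {
  if (window <= 1L) return(x)
  h <- (window - 1L) %/% 2L
  n <- length(x)
  xp <- c(x[(n - h + 1L):n], x, x[1L:h])
  as.numeric(stats::filter(xp, rep(1 / window, window), sides = 2))[(h + 1L):(h + n)]
}

#' Filling-rate curve (dV/dt)
#'
#' First derivative of the time-volume curve: optional circular
#' moving-average smoothing of the volumes, then circular central differences
#' divided by the frame spacing. The cycle is treated as periodic, so the
#' rates integrate to ~0 over one cycle.
#'
#' @param curve a [volume_curve()].
#' @param smooth_window odd moving-average window in frames (1 = none;
#'   default 3).
#' @return an object of class `filling_curve` with `times` (ms) and `rates`
#'   (uL/ms).
#' @export
filling_rate <- function(curve, smooth_window = 3L) {
  stopifnot(inherits(curve, "volume_curve"))
  n <- length(curve$volumes)
  if (n < 5L) htr_stop("invalid_parameter", "need at least 5 frames")
  if (smooth_window %% 2L == 0L)
    htr_stop("invalid_parameter", "smooth_window must be odd")
  v <- circular_ma(curve$volumes, as.integer(smooth_window))
  dt <- mean(diff(curve$times))
  rates <- (v[c(2:n, 1)] - v[c(n, 1:(n - 1))]) / (2 * dt)
  structure(list(times = curve$times, rates = rates),
            class = "filling_curve")
}

# Peak prominence within an open (non-circular) segment: height above the
# higher of the two bases, each base being the minimum between the peak and
# the nearest higher sample (or the segment edge).
segment_peaks <- function(r) {
  n <- length(r)
  if (n < 3L) return(integer(0))
  cand <- which(r[2:(n - 1)] >= r[1:(n - 2)] & r[2:(n - 1)] > r[3:n]) + 1L
  cand
}

peak_prominence <- function(r, i) {
  n <- length(r)
  left <- if (i == 1L) r[i] else {
    higher <- which(r[1:(i - 1)] > r[i])
    lo <- if (length(higher)) max(higher) + 1L else 1L
    min(r[lo:(i - 1L)])
  }
  right <- if (i == n) r[i] else {
    higher <- which(r[(i + 1):n] > r[i]) + i
    hi <- if (length(higher)) min(higher) - 1L else n
    min(r[(i + 1L):hi])
  }
  r[i] - max(left, right)
}

#' Detect the E and A filling peaks
#'
#' End systole is located at the volume minimum; diastole runs from there to
#' the end of the cycle. Local maxima of the filling rate within diastole
#' with prominence at least `prominence_frac` times the maximum rate are
#' candidate filling waves: the earliest is the early (E) peak and the latest
#' the atrial (A) peak. If only one prominent peak exists the E and A phases
#' are considered merged (as happens at high heart rates or with impaired
#' relaxation): `merged_flag` is set and the ratio is undefined rather than
#' silently computed.
#'
#' @param fill a [filling_rate()] curve.
#' @param vol the matching [volume_curve()].
#' @param prominence_frac minimum peak prominence as a fraction of the
#'   maximum filling rate (default 0.1).
#' @return an object of class `diastolic_metrics`: `e_peak`, `a_peak`
#'   (uL/ms), `ea_ratio`, `merged_flag`, plus the peak times `e_time`,
#'   `a_time` (ms).
#' @export
detect_ea <- function(fill, vol, prominence_frac = 0.1) {
  stopifnot(inherits(fill, "filling_curve"), inherits(vol, "volume_curve"))
  if (length(fill$rates) != length(vol$volumes) ||
      any(abs(fill$times - vol$times) > 1e-9))
    htr_stop("alignment_error", "filling and volume curves are not aligned")
  es <- which.min(vol$volumes)
  dia <- es:length(vol$volumes)
  r <- fill$rates[dia]
  if (all(r <= 0))
    htr_stop("no_filling", "no positive filling rates in diastole")
  cand <- segment_peaks(r)
  if (length(cand)) {
    prom <- vapply(cand, function(i) peak_prominence(r, i), numeric(1))
    cand <- cand[prom >= prominence_frac * max(r)]
  }
  if (length(cand) == 0L) cand <- which.max(r)  # single unresolved wave

  mk <- function(i) list(height = r[i], time = fill$times[dia[i]])
  if (length(cand) == 1L) {
    pk <- mk(cand)
    return(structure(list(e_peak = pk$height, a_peak = NA_real_,
                          ea_ratio = NA_real_, merged_flag = TRUE,
                          e_time = pk$time, a_time = NA_real_),
                     class = "diastolic_metrics"))
  }
  e <- mk(min(cand)); a <- mk(max(cand))
  structure(list(e_peak = e$height, a_peak = a$height,
                 ea_ratio = e$height / a$height, merged_flag = FALSE,
                 e_time = e$time, a_time = a$time),
            class = "diastolic_metrics")
}

#' @export
print.diastolic_metrics <- function(x, ...) {
  if (x$merged_flag)
    cat(sprintf("diastolic_metrics: merged E/A (single peak %.3f uL/ms at %.1f ms)\n",
                x$e_peak, x$e_time))
  else
    cat(sprintf("diastolic_metrics: E %.3f, A %.3f uL/ms -> E/A %.3f\n",
                x$e_peak, x$a_peak, x$ea_ratio))
  invisible(x)
}

#' Average volume curves across slices
#'
#' Frame-wise mean of aligned per-slice volume curves, producing the combined
#' curve that represents the whole imaging volume.
#'
#' @param curves list of [volume_curve()] objects with identical frame counts
#'   and times.
#' @return a `volume_curve` labelled `"combined"`.
#' @export
combine_slices <- function(curves) {
  if (!length(curves) || !all(vapply(curves, inherits, logical(1), "volume_curve")))
    htr_stop("invalid_parameter", "curves must be a non-empty list of volume_curve")
  n <- length(curves[[1]]$times)
  for (cu in curves) {
    if (length(cu$times) != n || any(abs(cu$times - curves[[1]]$times) > 1e-9))
      htr_stop("alignment_error", "volume curves are not aligned")
  }
  vols <- rowMeans(vapply(curves, `[[`, numeric(n), "volumes"))
  new_volume_curve(curves[[1]]$times, vols, "combined")
}

#' Systolic function metrics
#'
#' EDV and ESV are the maximum and minimum of the time-volume curve;
#' SV = EDV - ESV and EF = 100 SV / EDV. A list of per-slice curves is summed
#' frame-wise before taking extrema (whole-stack volumes).
#'
#' @param curve a [volume_curve()] or a list of aligned per-slice curves.
#' @return an object of class `systolic_metrics` with `edv`, `esv`, `sv`
#'   (uL) and `ef` (percent).
#' @export
systolic_metrics <- function(curve) {
  if (inherits(curve, "volume_curve")) {
    v <- curve$volumes
  } else {
    if (!length(curve) || !all(vapply(curve, inherits, logical(1), "volume_curve")))
      htr_stop("invalid_parameter", "curve must be a volume_curve or list thereof")
    n <- length(curve[[1]]$times)
    for (cu in curve)
      if (length(cu$times) != n || any(abs(cu$times - curve[[1]]$times) > 1e-9))
        htr_stop("alignment_error", "volume curves are not aligned")
    v <- rowSums(vapply(curve, `[[`, numeric(n), "volumes"))
  }
  if (!length(v)) htr_stop("invalid_parameter", "empty volume curve")
  edv <- max(v); esv <- min(v)
  if (edv == 0) htr_stop("undefined_ef", "EDV is zero; EF undefined")
  structure(list(edv = edv, esv = esv, sv = edv - esv,
                 ef = 100 * (edv - esv) / edv),
            class = "systolic_metrics")
}

#' @export
print.systolic_metrics <- function(x, ...) {
  cat(sprintf("EDV %.1f uL, ESV %.1f uL, SV %.1f uL, EF %.1f%%\n",
              x$edv, x$esv, x$sv, x$ef))
  invisible(x)
}

#' Mild-impairment cohort filter
#'
#' Applies the exclusion rule for unsuccessful infarction surgery: subjects
#' with preserved ejection fraction (`ef > ef_min`, strictly) *and* minor
#' enhancement (`lge_lv < lge_max`, strictly) are excluded from downstream
#' diastolic analysis; everyone else is included.
#'
#' @param records data frame with columns `subject_id`, `ef` (percent) and
#'   `lge_lv` (infarct volume as percent of LV volume).
#' @param ef_min EF threshold, percent (default 50).
#' @param lge_max LGE/LV threshold, percent (default 10).
#' @return a list with data frames `included` and `excluded` (the latter
#'   with a `reason` column) and the corresponding subject-id vectors.
#' @export
cohort_filter <- function(records, ef_min = 50, lge_max = 10) {
  need <- c("subject_id", "ef", "lge_lv")
  if (!all(need %in% names(records)))
    htr_stop("format_error", "records must have columns %s",
             paste(need, collapse = ", "))
  records <- as.data.frame(records)
  excl <- records$ef > ef_min & records$lge_lv < lge_max
  excluded <- records[excl, , drop = FALSE]
  if (nrow(excluded))
    excluded$reason <- sprintf("mild impairment (EF %.1f > %g & LGE/LV %.1f < %g)",
                               excluded$ef, ef_min, excluded$lge_lv, lge_max)
  list(included = records[!excl, , drop = FALSE],
       excluded = excluded,
       included_ids = records$subject_id[!excl],
       excluded_ids = records$subject_id[excl])
}
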