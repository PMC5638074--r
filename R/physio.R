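#' Simulate a physiological event trace
#'
#' Generates the cardiac and respiratory event record that retrospective
#' gating relies on: a train of R-wave times and a set of respiration windows
#' over a scan of given duration. Each R-R interval is drawn as `60000 / h`
#' with `h ~ Normal(hr_mean, hr_sd)` truncated at `hr_mean +/- 3 hr_sd`
#' (per-beat i.i.d. variability); respiration windows of length `resp_window`
#' are placed periodically every `60000 / resp_rate` ms starting at time 0,
#' keeping windows that end within the trace. Mouse defaults: heart rate
#' 588 +/- 38 bpm, 55 breaths/min with a 200 ms inspiration window.
#'
#' @param duration total trace length, ms.
#' @param hr_mean,hr_sd heart-rate mean and standard deviation, beats/min.
#' @param resp_rate respiration rate, breaths/min.
#' @param resp_window length of each respiration (motion) window, ms; 0
#'   disables respiration windows.
#' @param seed integer RNG seed; the trace is bit-reproducible for a fixed
#'   seed and leaves the caller's RNG state untouched.
#' @return an object of class `physio_trace` with fields `rwave_times` (ms,
#'   strictly increasing, first beat at 0), `resp_intervals` (two-column
#'   matrix of start/end ms), `duration` and `seed`.
#' @examples
#' tr <- simulate_physio(1000, hr_mean = 600, hr_sd = 0, seed = 1)
#' tr$rwave_times  # 0, 100, ..., 900
#' @export
simulate_physio <- function(duration, hr_mean = 588, hr_sd = 38,
                            resp_rate = 55, resp_window = 200, seed = 1L) {
  if (!is.numeric(duration) || duration <= 0)
    htr_stop("invalid_parameter", "duration must be positive")
  if (hr_mean <= 0 || resp_rate <= 0)
    htr_stop("invalid_parameter", "hr_mean and resp_rate must be positive")
  if (hr_sd < 0 || resp_window < 0)
    htr_stop("invalid_parameter", "hr_sd and resp_window must be non-negative")

  rwaves <- with_seed(seed, {
    ts <- numeric(0)
    t <- 0
    while (t < duration) {
      ts <- c(ts, t)
      h <- if (hr_sd == 0) hr_mean else {
        repeat {
          h <- stats::rnorm(1, hr_mean, hr_sd)
          if (abs(h - hr_mean) <= 3 * hr_sd && h > 0) break
        }
        h
      }
      t <- t + 60000 / h
    }
    ts
  })

  resp <- matrix(numeric(0), ncol = 2,
                 dimnames = list(NULL, c("start", "end")))
  if (resp_window > 0) {
    spacing <- 60000 / resp_rate
    starts <- seq(0, duration, by = spacing)
    keep <- starts + resp_window <= duration
    if (any(keep))
      resp <- cbind(start = starts[keep], end = starts[keep] + resp_window)
  }

  structure(list(rwave_times = rwaves, resp_intervals = resp,
                 duration = duration, seed = as.integer(seed)),
            class = "physio_trace")
}

#' @export
print.physio_trace <- function(x, ...) {
  rr <- diff(x$rwave_times)
  cat(sprintf("physio_trace: %.0f ms, %d R-waves (mean R-R %.2f ms, HR %.0f bpm), %d respiration windows\n",
              x$duration, length(x$rwave_times),
              mean(rr), 60000 / mean(rr), nrow(x$resp_intervals)))
  invisible(x)
}

# Instantaneous cardiac phase in [0,1) at times t. Inside the trace the phase
# is the fractional position within the enclosing R-R interval; beyond the
# last (or before the first) R-wave it is extrapolated with the nearest
# interval, so the phantom beats continuously for the whole scan.
cardiac_phase_at <- function(t, rwaves) {
  n <- length(rwaves)
  if (n < 2L)
    htr_stop("invalid_parameter", "need at least two R-waves to define a phase")
  rr <- diff(rwaves)
  idx <- findInterval(t, rwaves)
  phase <- numeric(length(t))
  inside <- idx >= 1L & idx < n
  phase[inside] <- (t[inside] - rwaves[idx[inside]]) / rr[idx[inside]]
  before <- idx < 1L
  phase[before] <- ((t[before] - rwaves[1L]) / rr[1L]) %% 1
  after <- idx >= n
  phase[after] <- ((t[after] - rwaves[n]) / rr[n - 1L]) %% 1
  pmin(phase, 1 - .Machine$double.eps)
}
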