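# Shared fixtures, all generated in code.

# Small geometry for fast acquisition/reconstruction tests.
small_seq <- function(nr = 4L, nf = 8L, matrix = 32L) {
  sequence_params(tr = 3.15, matrix = matrix, nr = nr, nf = nf)
}

small_phantom <- function(matrix = 32L, ...) {
  phantom_params(matrix = matrix, ...)
}

# Quasi-static phantom: volume varies by <= 1e-9 uL so every rendered frame
# is pixel-identical; lets single-repetition data be treated as motion-free.
static_phantom <- function(matrix = 128L) {
  phantom_params(edv = 9 + 1e-9, esv = 9, matrix = matrix)
}

# Construct a kspace_bins object directly (for gap-fill / coverage tests).
make_bins <- function(counts, seq = small_seq(matrix = ncol(counts)),
                      config = recon_config(nf = nrow(counts)),
                      median_rr = 102, fill_value = 1 + 0i) {
  nf <- nrow(counts); npe <- ncol(counts)
  acc <- array(complex(real = 0), dim = c(nf, npe, seq$matrix))
  for (f in seq_len(nf)) for (pe in seq_len(npe)) {
    if (counts[f, pe] > 0)
      acc[f, pe, ] <- fill_value * counts[f, pe] * (f + 10 * pe)
  }
  structure(list(accumulator = acc, counts = counts, seq = seq,
                 config = config, median_rr = median_rr,
                 rejected = c(respiration = 0L, arrhythmia = 0L,
                              unassignable = 0L),
                 n_lines = sum(counts), n_assigned = sum(counts)),
            class = "kspace_bins")
}

# cine_stack wrapper around a list of frame matrices.
make_cine <- function(frames, seq = small_seq(matrix = nrow(frames[[1]])),
                      frame_duration = 1.1) {
  nf <- length(frames)
  n <- nrow(frames[[1]])
  arr <- array(0, dim = c(nf, n, n))
  for (f in seq_len(nf)) arr[f, , ] <- frames[[f]]
  structure(list(frames = arr, frame_duration = frame_duration,
                 seq = seq, config = recon_config(nf = nf)),
            class = "cine_stack")
}

# Sample the phantom's analytic volume model at nf bin centers of one cycle.
analytic_volume_curve <- function(params, nf = 90L, rr_ms = 102) {
  phases <- (seq_len(nf) - 0.5) / nf
  htrcine:::new_volume_curve((seq_len(nf) - 0.5) * rr_ms / nf,
                             lv_volume(phases, params))
}
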