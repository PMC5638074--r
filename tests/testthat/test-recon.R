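test_that("phase assignment maps boundaries, midpoints and strays correctly", {
  rw <- c(0, 100, 200, 300)
  expect_equal(assign_cardiac_phase(0, rw, 90), 0L)
  expect_equal(assign_cardiac_phase(150, rw, 90), 45L)  # midpoint -> floor(90 * 0.5)
  expect_true(is.na(assign_cardiac_phase(300, rw, 90)))  # at/after the last R-wave
  expect_true(is.na(assign_cardiac_phase(-1, rw, 90)))
  expect_equal(assign_cardiac_phase(99.999999, rw, 90), 89L)
  expect_error(assign_cardiac_phase(10, c(5, 1), 90),
               class = "htrcine_invalid_input")
  # absolute mode: fixed bins of median R-R / nf
  expect_equal(assign_cardiac_phase(150, rw, 10, mode = "absolute"), 5L)
  # a long cycle overruns the absolute grid
  rw2 <- c(0, 100, 300, 400)
  expect_true(is.na(assign_cardiac_phase(280, rw2, 10, mode = "absolute")))
})

test_that("relative binning is invariant to a global time shift", {
  rw <- cumsum(c(0, 95, 103, 99, 101, 98))
  t <- seq(1, 480, by = 3.7)
  # drop samples within floating-point reach of a bin edge, where a uniform
  # shift can legitimately flip the floor() by one
  idx <- findInterval(t, rw)
  frac <- 90 * (t - rw[idx]) / diff(rw)[idx]
  safe <- abs(frac - round(frac)) > 1e-9
  f0 <- assign_cardiac_phase(t, rw, 90)
  for (shift in c(-1234.5, 1e5))
    expect_identical(assign_cardiac_phase(t + shift, rw + shift, 90)[safe],
                     f0[safe])
})

test_that("binned line counts are conserved across rejection causes", {
  seq <- small_seq(nr = 6L, matrix = 32L)
  ph <- simulate_physio(total_scan_time(seq) + 200, hr_mean = 588, hr_sd = 38,
                        resp_rate = 120, resp_window = 80, seed = 9)
  acq <- simulate_acquisition(small_phantom(), ph, seq, noise_sd = 0)
  for (cfg in list(recon_config(nf = 8),
                   recon_config(nf = 8, resp_reject = FALSE),
                   recon_config(nf = 8, rr_reject_frac = 0.01),
                   recon_config(nf = 8, resp_margin = 30),
                   recon_config(nf = 8, phase_mode = "absolute"))) {
    bins <- bin_kspace(acq$lines, acq$log, cfg)
    expect_equal(bins$n_assigned + sum(bins$rejected), bins$n_lines)
    expect_equal(sum(bins$counts), bins$n_assigned)
  }
  # tighter respiratory rejection can only discard more
  loose <- bin_kspace(acq$lines, acq$log, recon_config(nf = 8))
  tight <- bin_kspace(acq$lines, acq$log, recon_config(nf = 8, resp_margin = 40))
  expect_gte(tight$rejected[["respiration"]], loose$rejected[["respiration"]])
})

test_that("single-cycle binning with nf = 1 counts acquisitions per phase encode", {
  seq <- small_seq(nr = 3L, matrix = 32L)
  ph <- simulate_physio(total_scan_time(seq) + 400, hr_mean = 150, hr_sd = 0,
                        resp_window = 0, seed = 1)  # R-R = 400 ms
  acq <- simulate_acquisition(small_phantom(), ph, seq, noise_sd = 0)
  bins <- bin_kspace(acq$lines, acq$log, recon_config(nf = 1))
  in_cycle <- acq$lines$time < max(ph$rwave_times)
  expected <- tabulate(acq$lines$pe_index[in_cycle] + 1L, nbins = 32)
  expect_equal(as.integer(bins$counts[1, ]), expected)
})

test_that("a mismatched stream and log raise a consistency error", {
  seq <- small_seq(nr = 2L, matrix = 32L)
  ph <- simulate_physio(total_scan_time(seq) + 100, hr_mean = 600, hr_sd = 0,
                        seed = 1)
  acq <- simulate_acquisition(small_phantom(), ph, seq, noise_sd = 0)
  bad <- acq$log
  bad$rf <- bad$rf[-1, ]
  expect_error(bin_kspace(acq$lines, bad, recon_config(nf = 4)),
               class = "htrcine_consistency_error")
})

test_that("coverage statistics are exact on constructed grids and monotone", {
  bins <- make_bins(matrix(5L, 4, 8))
  expect_equal(unname(coverage_stats(bins, 3)$fill_fraction_at), 1.0)
  bins2 <- make_bins(matrix(c(0L, 1L, 2L, 3L), 2, 2))
  cov <- coverage_stats(bins2, c(1, 3))
  expect_equal(unname(cov$fill_fraction_at[["3"]]), 0.25)
  expect_equal(unname(cov$fill_fraction_at[["1"]]), 0.75)
  expect_true(all(diff(unname(cov$fill_fraction_at)) <= 0))
  expect_equal(cov$mean_averages, 1.5)
})

test_that("coverage grows with NR and collapses at NR = 1", {
  seq <- small_seq(matrix = 64L, nf = 45L)
  sweep <- nr_coverage_sweep(seq, nr_values = c(1L, 150L, 400L),
                             replicates = 10L, seed = 5)
  expect_equal(sweep$fill_fraction[1], 0)  # one repetition cannot give 3 averages
  expect_true(all(diff(sweep$fill_fraction) > 0))
})

test_that("gap filling copies the nearest populated frame, preceding on ties", {
  counts <- matrix(1L, 16, 4)
  counts[c(10, 11, 12), 2] <- 0L   # frames 10..12 of pe row 1 empty
  counts[11, 2 + 1] <- 0L
  bins <- make_bins(counts, config = recon_config(nf = 16))
  filled <- fill_gaps(bins, "nearest_frame")
  expect_true(all(filled$counts > 0))
  # frame 10 empty with 9 and 13 populated: distance 1 beats 3 -> frame 9
  expect_equal(filled$accumulator[10, 2, ], bins$accumulator[9, 2, ])
  # frame 11 is equidistant from 9... no: nearest populated are 9 (d=2) and 13 (d=2): tie -> preceding
  expect_equal(filled$accumulator[11, 2, ], bins$accumulator[9, 2, ])
  expect_equal(filled$accumulator[12, 2, ], bins$accumulator[13, 2, ])
  # single empty cell with both neighbours present takes the preceding frame
  expect_equal(filled$accumulator[11, 3, ], bins$accumulator[10, 3, ])
  # identity when nothing is empty
  full <- make_bins(matrix(2L, 8, 4))
  expect_equal(fill_gaps(full, "nearest_frame")$accumulator, full$accumulator)
  # a pe row empty at every frame is unrecoverable
  counts2 <- matrix(1L, 8, 4); counts2[, 3] <- 0L
  expect_error(fill_gaps(make_bins(counts2), "nearest_frame"),
               class = "htrcine_unrecoverable_gap")
})

test_that("noiseless motion-free reconstruction matches the rendered frame", {
  seq <- sequence_params(nr = 2, nf = 1, matrix = 128)
  ph <- simulate_physio(total_scan_time(seq) + 300, hr_mean = 60, hr_sd = 0,
                        resp_window = 0, seed = 1)  # one long cycle
  p <- static_phantom()
  acq <- simulate_acquisition(p, ph, seq, noise_sd = 0, resp_shift_px = 0)
  bins <- bin_kspace(acq$lines, acq$log, recon_config(nf = 1))
  cine <- reconstruct_cine(fill_gaps(bins))
  ref <- render_frame(0, p)
  expect_lt(max(abs(cine$frames[1, , ] - ref)) / max(ref), 1e-6)
})

test_that("reconstruction is linear in k-space scale and guards empty cells", {
  seq <- small_seq(nr = 2L, matrix = 32L)
  ph <- simulate_physio(total_scan_time(seq) + 300, hr_mean = 400, hr_sd = 0,
                        resp_window = 0, seed = 1)
  acq <- simulate_acquisition(small_phantom(), ph, seq, noise_sd = 0)
  bins <- fill_gaps(bin_kspace(acq$lines, acq$log, recon_config(nf = 2)))
  cine <- reconstruct_cine(bins)
  scaled <- bins
  scaled$accumulator <- scaled$accumulator * (-3 + 4i)
  expect_equal(reconstruct_cine(scaled)$frames, cine$frames * 5,
               tolerance = 1e-9)
  # empty cells without zero_fill are a precondition error
  holey <- make_bins(matrix(c(0L, rep(1L, 31)), 4, 8))
  expect_error(reconstruct_cine(holey), class = "htrcine_precondition_error")
  holey$config$gap_strategy <- "zero_fill"
  expect_s3_class(reconstruct_cine(holey), "cine_stack")
})
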