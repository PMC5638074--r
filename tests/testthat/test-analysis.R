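test_that("segmentation recovers disc areas and rejects empty seeds", {
  p <- phantom_params()
  img <- render_frame(0, p)
  cnt <- segment_lv(img, threshold_frac = 0.5)
  r_px <- sqrt(p$edv / (pi * p$slice_thickness)) / (p$fov / p$matrix)
  expect_lt(abs(cnt - pi * r_px^2), 2 * pi * r_px + 4)  # within one boundary ring
  expect_gte(segment_lv(img, threshold_frac = 1.0), 1)
  expect_error(segment_lv(matrix(0, 32, 32)),
               class = "htrcine_empty_segmentation")
  # 4-connectivity: a diagonal-only neighbour is not part of the component
  m <- matrix(0, 9, 9); m[5, 5] <- 1; m[4, 4] <- 1
  expect_equal(segment_lv(m, threshold_frac = 0.5, seed_point = c(5, 5),
                          ref_radius = 1), 1)
})

test_that("volume conversion is the voxel-volume product", {
  # 100 bright pixels, fov 25.6 / matrix 128 -> 0.2 mm pixels, 1 mm slice
  fr <- matrix(0, 128, 128)
  fr[60:69, 60:69] <- 1
  cine <- make_cine(list(fr, fr, fr, fr, fr),
                    seq = sequence_params(matrix = 128),
                    frame_duration = 1.1)
  vc <- volume_curve(cine, seed_point = c(64, 64))
  expect_equal(vc$volumes, rep(100 * 0.2 * 0.2 * 1, 5))  # 4.0 uL
  expect_equal(vc$times, (1:5 - 0.5) * 1.1)
})

test_that("pipeline volume curve brackets EDV and ESV within 5%", {
  st <- run_phantom_study(seq = sequence_params(nr = 350), seed = 3)
  p <- phantom_params()
  expect_equal(max(st$volume$volumes), p$edv, tolerance = 0.05)
  expect_equal(min(st$volume$volumes), p$esv, tolerance = 0.05)
})

test_that("filling rates differentiate the curve circularly", {
  # constant volume -> zero rate everywhere
  vc <- htrcine:::new_volume_curve((1:10 - 0.5) * 2, rep(7, 10))
  expect_equal(filling_rate(vc, 1)$rates, rep(0, 10))
  # circular sawtooth: constant slope on the ramp interior
  v <- c(1:9, 0) * 2
  vc2 <- htrcine:::new_volume_curve((1:10 - 0.5) * 2, v + 10)
  fr <- filling_rate(vc2, 1)
  expect_equal(fr$rates[2:8], rep(1, 7))
  expect_error(filling_rate(vc2, 2), class = "htrcine_invalid_parameter")
  expect_error(filling_rate(htrcine:::new_volume_curve(1:3, 1:3), 1),
               class = "htrcine_invalid_parameter")
  # closed cycle: rates integrate to ~0
  p <- phantom_params()
  ac <- analytic_volume_curve(p, nf = 90, rr_ms = 102)
  rates <- filling_rate(ac, 3)$rates
  expect_equal(sum(rates) * mean(diff(ac$times)), 0, tolerance = 1e-9)
})

test_that("sampled phantom curves reproduce the closed-form peak rates", {
  p <- phantom_params()
  rr <- 102
  ac <- analytic_volume_curve(p, nf = 900, rr_ms = rr)  # fine grid, no smoothing
  fr <- filling_rate(ac, 1)
  dia <- ac$times > p$phi_es * rr
  e_reg <- dia & ac$times < (p$e_center + p$e_width / 2) * rr
  a_reg <- ac$times > (p$a_center - p$a_width / 2) * rr
  e_true <- p$e_amp * (p$edv - p$esv) * pi / (2 * p$e_width) / rr
  a_true <- (1 - p$e_amp) * (p$edv - p$esv) * pi / (2 * p$a_width) / rr
  expect_equal(max(fr$rates[e_reg]), e_true, tolerance = 0.05)
  expect_equal(max(fr$rates[a_reg]), a_true, tolerance = 0.05)
})

test_that("E/A detection ratios clean peaks and flags merged ones", {
  p <- phantom_params(e_amp = 2 / 3, e_width = 0.1, a_width = 0.1)  # E/A = 2
  ac <- analytic_volume_curve(p, nf = 90)
  dm <- detect_ea(filling_rate(ac, 1), ac)
  expect_false(dm$merged_flag)
  expect_equal(dm$ea_ratio, 2.0, tolerance = 0.05)
  expect_lt(dm$e_time, dm$a_time)
  # scale invariance of the ratio
  ac2 <- htrcine:::new_volume_curve(ac$times, ac$volumes * 3.7)
  dm2 <- detect_ea(filling_rate(ac2, 1), ac2)
  expect_equal(dm2$ea_ratio, dm$ea_ratio, tolerance = 1e-9)
  # overlapping waves merge into a single flagged peak: build the volume
  # model directly since the phantom constructor forbids wave overlap
  step <- function(phi, c, w) ifelse(phi <= c - w / 2, 0,
                                     ifelse(phi >= c + w / 2, 1,
                                            (1 + sin(pi * (phi - c) / w)) / 2))
  phi <- (1:90 - 0.5) / 90
  ej <- ifelse(phi <= 0.3, (1 + cos(pi * phi / 0.3)) / 2, 0)
  vol <- 9 + 27 * (ej + 0.5 * step(phi, 0.6, 0.3) + 0.5 * step(phi, 0.7, 0.3))
  aco <- htrcine:::new_volume_curve(phi * 102, vol)
  dmo <- detect_ea(filling_rate(aco, 3), aco)
  expect_true(dmo$merged_flag)
  expect_true(is.na(dmo$ea_ratio))
  # a systole-only curve has no diastolic filling
  vc <- htrcine:::new_volume_curve(1:10, c(10:1))
  fake_fill <- structure(list(times = vc$times, rates = rep(-1, 10)),
                         class = "filling_curve")
  expect_error(detect_ea(fake_fill, vc), class = "htrcine_no_filling")
})

test_that("slice combination is a frame-wise mean with checks", {
  t <- (1:6 - 0.5)
  c1 <- htrcine:::new_volume_curve(t, rep(2, 6))
  c2 <- htrcine:::new_volume_curve(t, rep(4, 6))
  expect_equal(combine_slices(list(c1, c2))$volumes, rep(3, 6))
  expect_equal(combine_slices(list(c1, c1, c1))$volumes, c1$volumes)
  expect_equal(combine_slices(list(c2, c1))$volumes,
               combine_slices(list(c1, c2))$volumes)
  expect_equal(combine_slices(list(c1, c2))$slice_label, "combined")
  c3 <- htrcine:::new_volume_curve(t[1:5], rep(1, 5))
  expect_error(combine_slices(list(c1, c3)), class = "htrcine_alignment_error")
})

test_that("systolic metrics follow their defining arithmetic", {
  t <- (1:4 - 0.5)
  vc <- htrcine:::new_volume_curve(t, c(36, 20, 9, 30))
  sm <- systolic_metrics(vc)
  expect_equal(sm$edv, 36); expect_equal(sm$esv, 9)
  expect_equal(sm$sv, 27); expect_equal(sm$ef, 75)
  # constant curve: no stroke
  sm0 <- systolic_metrics(htrcine:::new_volume_curve(t, rep(5, 4)))
  expect_equal(sm0$sv, 0); expect_equal(sm0$ef, 0)
  # EF is scale invariant
  smx <- systolic_metrics(htrcine:::new_volume_curve(t, c(36, 20, 9, 30) * 2.5))
  expect_equal(smx$ef, 75)
  # slice list is summed frame-wise before extrema
  sm2 <- systolic_metrics(list(vc, vc))
  expect_equal(sm2$edv, 72)
  expect_equal(sm2$ef, 75)
  expect_error(systolic_metrics(htrcine:::new_volume_curve(t, rep(0, 4))),
               class = "htrcine_undefined_ef")
})

test_that("the mild-impairment filter excludes EF > 50 & LGE/LV < 10 subjects", {
  rec <- data.frame(subject_id = sprintf("i%02d", 1:13),
                    ef = c(62, 55, 58, 51, 45, 40, 38, 52, 30, 44, 48, 35, 41),
                    lge_lv = c(4, 8, 6, 9, 20, 25, 30, 15, 43, 18, 12, 28, 22))
  out <- cohort_filter(rec)
  expect_equal(nrow(out$excluded), 4L)
  expect_equal(nrow(out$included), 9L)
  expect_setequal(out$excluded_ids, c("i01", "i02", "i03", "i04"))
  # boundary convention: strict inequalities keep EF = 50 and LGE/LV = 10
  b <- cohort_filter(data.frame(subject_id = c("a", "b"),
                                ef = c(50, 60), lge_lv = c(5, 10)))
  expect_equal(nrow(b$excluded), 0L)
  # empty table -> empty sets
  e <- cohort_filter(data.frame(subject_id = character(0),
                                ef = numeric(0), lge_lv = numeric(0)))
  expect_equal(nrow(e$included), 0L)
  expect_equal(nrow(e$excluded), 0L)
  expect_error(cohort_filter(data.frame(subject_id = "a", ef = 50)),
               class = "htrcine_format_error")
})
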