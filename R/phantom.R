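#' Parametric left-ventricular phantom
#'
#' Defines a single-slice, short-axis digital phantom of the left ventricle
#' (LV): a circular blood pool whose slice volume follows a prescribed cardiac
#' cycle, surrounded by a myocardial annulus on a dark background. The volume
#' model is a raised-cosine ejection from end-diastolic volume (EDV) down to
#' end-systolic volume (ESV), followed by two raised-cosine filling steps --
#' the early (E) and atrial (A) waves -- whose peak filling rates, and hence
#' the E/A ratio, have a closed form (see [analytic_ea()]). That makes the
#' phantom an exact oracle for diastolic-function recovery through the full
#' acquisition/reconstruction pipeline.
#'
#' Phase is expressed as a fraction of the cardiac cycle in `[0, 1)` with the
#' R-wave at 0. The constraints ensure ejection and the two filling waves
#' occupy disjoint phase intervals so E and A are distinct.
#'
#' @param edv end-diastolic slice volume (uL; 1 uL = 1 mm^3).
#' @param esv end-systolic slice volume (uL); must be < `edv`.
#' @param phi_es phase fraction of end systole, in (0, 1).
#' @param e_center,e_width phase center and width of the early filling wave.
#' @param a_center,a_width phase center and width of the atrial filling wave.
#' @param e_amp fraction of the total refill (EDV - ESV) carried by the E
#'   wave, in (0, 1); the A wave carries `1 - e_amp`.
#' @param outer_radius epicardial (outer myocardial) radius, mm.
#' @param intensities named numeric vector with elements `blood`, `myocardium`
#'   and `background`: signal levels (arbitrary units) mimicking bright-blood
#'   FLASH contrast.
#' @param matrix image matrix size (pixels per side).
#' @param fov field of view, mm.
#' @param slice_thickness slice thickness, mm.
#'
#' @return an object of class `phantom_params`.
#' @examples
#' p <- phantom_params()
#' lv_volume(0, p)       # == edv
#' analytic_ea(p)
#' @export
phantom_params <- function(edv = 36, esv = 9, phi_es = 0.35,
                           e_center = 0.52, e_width = 0.10,
                           a_center = 0.80, a_width = 0.10,
                           e_amp = 0.6, outer_radius = 5,
                           intensities = c(blood = 1.0, myocardium = 0.35,
                                           background = 0.02),
                           matrix = 128, fov = 25.6, slice_thickness = 1) {
  if (!is.numeric(edv) || !is.numeric(esv) || esv <= 0 || esv >= edv)
    htr_stop("invalid_parameter", "need 0 < esv < edv (got esv=%g, edv=%g)", esv, edv)
  if (phi_es <= 0 || phi_es >= 1)
    htr_stop("invalid_parameter", "phi_es must lie in (0,1)")
  if (phi_es >= e_center - e_width / 2)
    htr_stop("invalid_parameter",
             "end systole (phi_es=%g) must precede the E wave onset (%g)",
             phi_es, e_center - e_width / 2)
  if (e_center + e_width / 2 > a_center - a_width / 2)
    htr_stop("invalid_parameter", "E and A waves overlap")
  if (a_center + a_width / 2 > 1)
    htr_stop("invalid_parameter", "A wave extends past the end of the cycle")
  if (e_amp <= 0 || e_amp >= 1)
    htr_stop("invalid_parameter", "e_amp must lie in (0,1)")
  if (e_width <= 0 || a_width <= 0)
    htr_stop("invalid_parameter", "filling wave widths must be positive")
  need <- c("blood", "myocardium", "background")
  if (!all(need %in% names(intensities)))
    htr_stop("invalid_parameter", "intensities must name blood, myocardium, background")
  if (!is_power_of_two(matrix))
    htr_stop("invalid_parameter", "matrix must be a positive power of two")
  r_edv <- sqrt(edv / (pi * slice_thickness))
  if (r_edv >= outer_radius)
    htr_stop("invalid_geometry",
             "blood-pool radius at EDV (%.2f mm) must be < outer_radius (%g mm)",
             r_edv, outer_radius)
  if (outer_radius >= fov / 2)
    htr_stop("invalid_geometry", "outer_radius must fit inside the FOV")
  structure(list(edv = edv, esv = esv, phi_es = phi_es,
                 e_center = e_center, e_width = e_width,
                 a_center = a_center, a_width = a_width,
                 e_amp = e_amp, outer_radius = outer_radius,
                 intensities = intensities[need], matrix = as.integer(matrix),
                 fov = fov, slice_thickness = slice_thickness),
            class = "phantom_params")
}

#' @export
print.phantom_params <- function(x, ...) {
  cat("LV phantom: EDV", x$edv, "uL, ESV", x$esv, "uL (EF",
      sprintf("%.1f%%),", 100 * (x$edv - x$esv) / x$edv),
      "analytic E/A", sprintf("%.3f\n", analytic_ea(x)))
  cat(sprintf("  matrix %d, FOV %g mm, slice %g mm, epicardial radius %g mm\n",
              x$matrix, x$fov, x$slice_thickness, x$outer_radius))
  invisible(x)
}

# Raised-cosine step: 0 below center-width/2, 1 above center+width/2,
# (1 + sin(pi (phi - center)/width))/2 in between.
raised_cos_step <- function(phi, center, width) {
  lo <- center - width / 2
  hi <- center + width / 2
  out <- numeric(length(phi))
  out[phi >= hi] <- 1
  mid <- phi > lo & phi < hi
  out[mid] <- (1 + sin(pi * (phi[mid] - center) / width)) / 2
  out
}

#' LV slice volume at a cardiac phase
#'
#' Evaluates the phantom's volume model
#' `V(phi) = esv + (edv - esv) * f(phi)` where `f` is a raised-cosine fall
#' from 1 to 0 over the ejection interval `[0, phi_es]` plus the two
#' raised-cosine filling steps weighted `e_amp` and `1 - e_amp`. By
#' construction `V(0) = edv`, `V(phi_es) = esv` and `V(phi) -> edv` as
#' `phi -> 1`.
#'
#' @param phase cardiac phase fraction(s) in `[0, 1)`; vectorised.
#' @param params a [phantom_params()] object.
#' @return LV slice volume(s), uL.
#' @export
lv_volume <- function(phase, params) {
  stopifnot(inherits(params, "phantom_params"))
  if (any(phase < 0 | phase >= 1))
    htr_stop("domain_error", "phase must lie in [0,1)")
  ej <- numeric(length(phase))
  sys <- phase <= params$phi_es
  ej[sys] <- (1 + cos(pi * phase[sys] / params$phi_es)) / 2
  f <- ej +
    params$e_amp * raised_cos_step(phase, params$e_center, params$e_width) +
    (1 - params$e_amp) * raised_cos_step(phase, params$a_center, params$a_width)
  params$esv + (params$edv - params$esv) * f
}

#' Analytic E/A ratio of the phantom
#'
#' The peak filling rate of a raised-cosine step `a * S(phi; c, w)` in
#' `dV/dphi` is `a * (edv - esv) * pi / (2 w)`, attained at the wave center,
#' so the ratio of the E- and A-wave peak rates reduces to
#' `(e_amp / e_width) / ((1 - e_amp) / a_width)` -- independent of volumes and
#' heart rate. This is the ground truth that pipeline recovery is judged
#' against.
#'
#' @param params a [phantom_params()] object.
#' @return the E/A ratio (dimensionless). A value of `Inf` would correspond to
#'   an absent A wave (restrictive-filling regime); `e_amp` is constrained to
#'   (0,1) so the ratio is always finite and positive.
#' @export
analytic_ea <- function(params) {
  stopifnot(inherits(params, "phantom_params"))
  (params$e_amp / params$e_width) / ((1 - params$e_amp) / params$a_width)
}

#' Phantom with a prescribed E/A ratio
#'
#' Convenience constructor: keeps the wave widths equal so the target E/A is
#' obtained purely through the refill split `e_amp = ea / (1 + ea)`.
#'
#' @param ea target E/A ratio (> 0).
#' @param ... further arguments passed to [phantom_params()] (must not include
#'   `e_amp`; widths default to 0.10 each).
#' @return a `phantom_params` object with `analytic_ea(x) == ea`.
#' @export
phantom_for_ea <- function(ea, ...) {
  if (!is.numeric(ea) || ea <= 0)
    htr_stop("invalid_parameter", "ea must be a positive number")
  phantom_params(e_amp = ea / (1 + ea), e_width = 0.10, a_width = 0.10, ...)
}

# Supersampled radial distance grid (mm from FOV center), cached per geometry.
.render_cache <- new.env(parent = emptyenv())
render_grid <- function(matrix, fov, ss) {
  key <- sprintf("%d_%g_%d", matrix, fov, ss)
  if (!is.null(.render_cache[[key]])) return(.render_cache[[key]])
  n <- matrix * ss
  px <- fov / n
  coord <- (seq_len(n) - 0.5) * px - fov / 2
  d <- sqrt(outer(coord^2, coord^2, `+`))
  .render_cache[[key]] <- d
  d
}

# Average ss x ss blocks of a supersampled image down to matrix x matrix.
block_downsample <- function(img_ss, ss) {
  n <- nrow(img_ss) / ss
  dim(img_ss) <- c(ss, n, ss, n)
  colMeans(aperm(img_ss, c(1, 3, 2, 4)), dims = 2)
}

#' Render one phantom frame
#'
#' Produces the image-domain slice at a given cardiac phase: a blood-pool disc
#' of radius `sqrt(V(phase) / (pi * slice_thickness))`, a myocardial annulus
#' out to `outer_radius`, and background elsewhere, centered in the FOV.
#' Boundary pixels get area-weighted (partial-volume) intensities via
#' `supersample`-fold supersampling per pixel axis, which keeps pixel-counted
#' volume curves smooth.
#'
#' @param phase cardiac phase fraction in `[0, 1)`.
#' @param params a [phantom_params()] object.
#' @param supersample sub-pixel grid factor per axis (default 4).
#' @return a `matrix x matrix` numeric image.
#' @export
render_frame <- function(phase, params, supersample = 4L) {
  stopifnot(inherits(params, "phantom_params"))
  if (length(phase) != 1L || phase < 0 || phase >= 1)
    htr_stop("domain_error", "phase must be a single value in [0,1)")
  v <- lv_volume(phase, params)
  r_blood <- sqrt(v / (pi * params$slice_thickness))
  if (r_blood >= params$outer_radius)
    htr_stop("invalid_geometry", "blood-pool radius exceeds the epicardial radius")
  d <- render_grid(params$matrix, params$fov, as.integer(supersample))
  ints <- params$intensities
  img <- matrix(ints[["background"]], nrow(d), ncol(d))
  img[d < params$outer_radius] <- ints[["myocardium"]]
  img[d < r_blood] <- ints[["blood"]]
  block_downsample(img, as.integer(supersample))
}
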