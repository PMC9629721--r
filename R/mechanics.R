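# Tensile / viscoelastic mechanics of engineered tendon specimens:
# engineering stress-strain, failure metrics, Young's modulus from the
# linear region, hysteresis energy loss and the 60 s stress-relaxation rate.

#' Cross-sectional area from a single projected diameter
#'
#' The specimen cross-section is assumed circular, `A = pi d^2 / 4`; only a
#' single projected diameter per specimen is measured.
#'
#' @param d_mm diameter in mm (> 0).
#' @return area in mm^2.
#' @export
area_from_diameter <- function(d_mm) {
  stop_if_not_scalar_num(d_mm, "d_mm")
  if (d_mm <= 0) stop("`d_mm` must be > 0", call. = FALSE)
  pi * d_mm^2 / 4
}

#' Specimen geometry
#'
#' @param l0_mm initial length, mm (default 8).
#' @param diameter_mm specimen diameter, mm; used to derive `area_mm2`
#'   when the latter is not supplied.
#' @param area_mm2 cross-sectional area, mm^2 (optional override).
#' @return an object of class `tendon_geometry`.
#' @export
tendon_geometry <- function(l0_mm = 8, diameter_mm = 2.43,
                            area_mm2 = NULL) {
  stop_if_not_scalar_num(l0_mm, "l0_mm", lower = 1e-9)
  stop_if_not_scalar_num(diameter_mm, "diameter_mm", lower = 1e-9)
  if (is.null(area_mm2)) area_mm2 <- area_from_diameter(diameter_mm)
  stop_if_not_scalar_num(area_mm2, "area_mm2", lower = 1e-12)
  structure(list(l0_mm = l0_mm, diameter_mm = diameter_mm,
                 area_mm2 = area_mm2,
                 assumption = "circular cross-section, A = pi d^2 / 4"),
            class = "tendon_geometry")
}

#' Convert a load trace to an engineering stress-strain curve
#'
#' Engineering definitions with the pre-load cross-section:
#' `sigma = F / A` (reported in kPa; force in N, area in mm^2) and
#' `epsilon = dl / l0` (dimensionless).
#'
#' @param trace data frame with columns `time_s`, `force_N`,
#'   `displacement_mm` and optionally `phase`.
#' @param geom a [tendon_geometry()] object.
#' @return a data frame (class `stress_strain_curve`) with `time_s`,
#'   `strain`, `stress_kPa` and `phase`.
#' @export
to_stress_strain <- function(trace, geom) {
  stopifnot(inherits(geom, "tendon_geometry"))
  req <- c("time_s", "force_N", "displacement_mm")
  miss <- setdiff(req, names(trace))
  if (length(miss)) {
    stop("trace is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(trace$force_N)) ||
      any(!is.finite(trace$displacement_mm))) {
    stop("trace contains non-finite force or displacement", call. = FALSE)
  }
  if (is.unsorted(trace$time_s)) {
    stop("trace time must be monotone non-decreasing", call. = FALSE)
  }
  phase <- if ("phase" %in% names(trace)) as.character(trace$phase)
           else rep(NA_character_, nrow(trace))
  out <- data.frame(
    time_s = trace$time_s,
    strain = trace$displacement_mm / geom$l0_mm,
    stress_kPa = trace$force_N / geom$area_mm2 * 1000,  # N/mm^2 = MPa -> kPa
    phase = phase,
    stringsAsFactors = FALSE
  )
  class(out) <- c("stress_strain_curve", class(out))
  out
}

#' Maximum stress and strain at rupture
#'
#' `sigma_max` is the global stress maximum. `epsilon_max` defaults to the
#' strain at that maximum; pass `rupture_index` to use a user-defined
#' rupture point instead (the rupture criterion of destructive tests is
#' protocol-specific).
#'
#' @param curve a stress-strain curve from [to_stress_strain()].
#' @param rupture_index optional row index of the rupture point.
#' @return a list with `sigma_max_kPa`, `epsilon_max` and
#'   `epsilon_at_sigma_max`.
#' @export
failure_metrics <- function(curve, rupture_index = NULL) {
  if (nrow(curve) < 2L) stop("curve needs at least 2 points", call. = FALSE)
  i_max <- which.max(curve$stress_kPa)
  i_rup <- if (is.null(rupture_index)) i_max else as.integer(rupture_index)
  if (i_rup < 1L || i_rup > nrow(curve)) {
    stop("rupture_index out of range", call. = FALSE)
  }
  list(sigma_max_kPa = curve$stress_kPa[i_max],
       epsilon_max = curve$strain[i_rup],
       epsilon_at_sigma_max = curve$strain[i_max])
}

#' Young's modulus from the linear region
#'
#' Slides a contiguous window of `window_fraction` of the loading-phase
#' points along the curve and keeps the window maximising the R^2 of an
#' ordinary-least-squares line of stress on strain; the modulus is that
#' line's slope. Windows with (numerically) zero strain variance are
#' skipped.
#'
#' @param curve a stress-strain curve; rows with `phase == "loading"` are
#'   used when phase labels are present.
#' @param window_fraction fraction (0, 1] of loading points per window.
#' @return a list with `E_kPa`, `region` (start/end indices into the
#'   loading points), `r_squared` and `low_r2` flag (R^2 < 0.9).
#' @export
youngs_modulus <- function(curve, window_fraction = 0.2) {
  stop_if_not_scalar_num(window_fraction, "window_fraction", lower = 1e-6,
                         upper = 1)
  sel <- if (all(is.na(curve$phase))) rep(TRUE, nrow(curve))
         else curve$phase == "loading"
  eps <- curve$strain[sel]
  sig <- curve$stress_kPa[sel]
  n <- length(eps)
  if (n < 10L) stop("need at least 10 loading-phase points", call. = FALSE)
  w <- max(5L, ceiling(window_fraction * n))
  best <- list(r2 = -Inf, slope = NA_real_, i0 = NA_integer_)
  for (i0 in seq_len(n - w + 1L)) {
    x <- eps[i0:(i0 + w - 1L)]
    y <- sig[i0:(i0 + w - 1L)]
    sxx <- sum((x - mean(x))^2)
    if (sxx < .Machine$double.eps * max(1, mean(x)^2) * w) next
    sxy <- sum((x - mean(x)) * (y - mean(y)))
    syy <- sum((y - mean(y))^2)
    slope <- sxy / sxx
    r2 <- if (syy <= 0) 1 else (sxy^2) / (sxx * syy)
    if (r2 > best$r2) best <- list(r2 = r2, slope = slope, i0 = i0)
  }
  if (!is.finite(best$r2)) stop("no window with strain variation", call. = FALSE)
  list(E_kPa = best$slope,
       region = c(start = best$i0, end = best$i0 + w - 1L),
       r_squared = best$r2,
       low_r2 = best$r2 < 0.9)
}

#' Hysteresis and percentage energy loss
#'
#' Trapezoidal areas under the loading and unloading stress-strain branches
#' (each over its own samples): `hysteresis = area_loading -
#' area_unloading` (kPa strain, i.e. kJ/m^3) and `percentage energy loss =
#' hysteresis / area_loading * 100`.
#'
#' @param curve a stress-strain curve with `phase` labels containing both
#'   "loading" and "unloading".
#' @return a list with `area_loading`, `area_unloading`, `hysteresis_kJ_m3`
#'   and `energy_loss_pct`.
#' @export
hysteresis_metrics <- function(curve) {
  ld <- curve[curve$phase == "loading", , drop = FALSE]
  ul <- curve[curve$phase == "unloading", , drop = FALSE]
  if (nrow(ld) < 2L || nrow(ul) < 2L) {
    stop("curve must contain loading and unloading phases", call. = FALSE)
  }
  trapz <- function(x, y) {
    o <- order(x)
    x <- x[o]; y <- y[o]
    sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  }
  a_ld <- trapz(ld$strain, ld$stress_kPa)
  a_ul <- trapz(ul$strain, ul$stress_kPa)
  if (abs(a_ld) <= .Machine$double.eps) {
    stop("zero area under the loading curve", call. = FALSE)
  }
  hys <- a_ld - a_ul
  list(area_loading = a_ld, area_unloading = a_ul,
       hysteresis_kJ_m3 = hys,
       energy_loss_pct = hys / a_ld * 100)
}

#' Stress-relaxation rate over a T-second hold
#'
#' `rate = (sigma_0 - sigma_T) / T` with `sigma_0` the first hold-phase
#' stress and `sigma_T` the stress at `T` seconds into the hold (linear
#' interpolation between samples).
#'
#' @param curve a stress-strain curve whose `phase` contains "hold" (or any
#'   curve, treated wholly as hold when labels are absent).
#' @param T_s relaxation window in seconds (default 60).
#' @return a list with `rate_kPa_s`, `sigma_0_kPa`, `sigma_T_kPa`, `T_s`.
#' @export
stress_relaxation_rate <- function(curve, T_s = 60) {
  stop_if_not_scalar_num(T_s, "T_s", lower = 1e-9)
  hold <- if (all(is.na(curve$phase))) curve
          else curve[curve$phase == "hold", , drop = FALSE]
  if (nrow(hold) < 2L) stop("no hold phase in curve", call. = FALSE)
  t <- hold$time_s - hold$time_s[1]
  span <- max(t)
  if (span < T_s) {
    stop(sprintf("hold phase spans only %.3f s; %.0f s required", span, T_s),
         call. = FALSE)
  }
  s0 <- hold$stress_kPa[1]
  sT <- stats::approx(t, hold$stress_kPa, xout = T_s, ties = "ordered")$y
  list(rate_kPa_s = (s0 - sT) / T_s, sigma_0_kPa = s0, sigma_T_kPa = sT,
       T_s = T_s)
}

#' Full mechanical summary of one specimen
#'
#' Converts a load trace to stress-strain and assembles every metric that
#' the trace's phases support (failure, modulus, hysteresis, relaxation);
#' metrics whose phase is absent are `NULL`.
#'
#' @param trace a load trace data frame (`time_s, force_N, displacement_mm,
#'   phase`).
#' @param geom a [tendon_geometry()] object.
#' @param window_fraction passed to [youngs_modulus()].
#' @param relax_T passed to [stress_relaxation_rate()].
#' @return an object of class `mechanical_summary`.
#' @export
mechanical_summary <- function(trace, geom, window_fraction = 0.2,
                               relax_T = 60) {
  curve <- to_stress_strain(trace, geom)
  phases <- unique(curve$phase)
  fm <- failure_metrics(curve)
  ym <- tryCatch(youngs_modulus(curve, window_fraction),
                 error = function(e) NULL)
  hy <- if (all(c("loading", "unloading") %in% phases)) {
    hysteresis_metrics(curve)
  } else NULL
  rx <- if ("hold" %in% phases) {
    tryCatch(stress_relaxation_rate(curve, relax_T), error = function(e) NULL)
  } else NULL
  structure(list(
    sigma_max_kPa = fm$sigma_max_kPa,
    epsilon_max = fm$epsilon_max,
    E_kPa = if (is.null(ym)) NA_real_ else ym$E_kPa,
    modulus_fit = ym,
    hysteresis = hy,
    relaxation = rx,
    geometry = geom,
    curve = curve
  ), class = "mechanical_summary")
}

#' @export
print.mechanical_summary <- function(x, ...) {
  cat("Mechanical summary\n")
  cat(sprintf("  sigma_max: %.3f kPa at strain %.4f\n",
              x$sigma_max_kPa, x$epsilon_max))
  if (is.finite(x$E_kPa)) {
    cat(sprintf("  Young's modulus: %.3f kPa (R^2 = %.4f)\n",
                x$E_kPa, x$modulus_fit$r_squared))
  }
  if (!is.null(x$hysteresis)) {
    cat(sprintf("  energy loss: %.2f %%\n", x$hysteresis$energy_loss_pct))
  }
  if (!is.null(x$relaxation)) {
    cat(sprintf("  relaxation rate: %.5f kPa/s over %g s\n",
                x$relaxation$rate_kPa_s, x$relaxation$T_s))
  }
  invisible(x)
}
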