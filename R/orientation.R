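# Structure-tensor fibre orientation analysis: per-pixel orientation,
# energy and coherence; angular histograms relative to the strain axis
# (0 degrees = vertical); and an alignment-percentage summary.

#' Per-pixel structure tensor orientation field
#'
#' Gaussian-derivative gradients (sigma `sigma_grad`) are combined into the
#' structure tensor J = G_sigma_window * (grad I grad I^T). The per-pixel
#' orientation is the direction of least intensity variation (the fibre
#' direction), reported in degrees from the vertical strain axis in
#' (-90, 90], positive clockwise on screen. `energy = Jxx + Jyy`;
#' `coherence = (l1 - l2) / (l1 + l2)` (0 where the energy is 0).
#'
#' @param image numeric matrix with finite values.
#' @param sigma_grad gradient (derivative-of-Gaussian) sigma, px.
#' @param sigma_window tensor-smoothing window sigma, px.
#' @return an object of class `orientation_field` with matrices
#'   `angle_deg`, `energy`, `coherence`, plus `degenerate` flag and the
#'   sigmas used.
#' @export
structure_tensor_field <- function(image, sigma_grad = 1, sigma_window = 4) {
  check_image(image)
  stop_if_not_scalar_num(sigma_grad, "sigma_grad", lower = 0.1)
  stop_if_not_scalar_num(sigma_window, "sigma_window", lower = 0)
  gk <- gaussian_kernel(sigma_grad)
  dk <- gaussian_deriv_kernel(sigma_grad)
  # d/d(col): derivative along rows of t(m); rows increase downward
  g_r <- conv_sep(image, dk, gk)   # derivative along rows (vertical)
  g_c <- conv_sep(image, gk, dk)   # wait for orientation: see below
  # conv_sep(m, krow, kcol): krow filters columns (i.e. along rows index),
  # so krow = derivative kernel differentiates in the row direction.
  Jrr <- gaussian_blur(g_r * g_r, sigma_window)
  Jcc <- gaussian_blur(g_c * g_c, sigma_window)
  Jrc <- gaussian_blur(g_r * g_c, sigma_window)
  energy <- Jrr + Jcc
  degenerate <- max(energy) <= .Machine$double.eps
  # dominant (max-variation) eigenvector angle from the col-axis, in the
  # (col, row) frame; the fibre direction is perpendicular to it.
  theta_grad <- 0.5 * atan2(2 * Jrc, Jcc - Jrr)
  # fibre angle from vertical (= row axis), positive clockwise on screen:
  fibre_from_vertical <- wrap_axial(-theta_grad * 180 / pi)
  disc <- sqrt((Jcc - Jrr)^2 + 4 * Jrc^2)
  coh <- ifelse(energy > .Machine$double.eps, disc / energy, 0)
  structure(list(angle_deg = fibre_from_vertical, energy = energy,
                 coherence = pmin(pmax(coh, 0), 1),
                 degenerate = degenerate,
                 sigma_grad = sigma_grad, sigma_window = sigma_window),
            class = "orientation_field")
}

# Global dominant orientation from the energy-weighted mean tensor,
# computed in axial (angle-doubled) space.
dominant_orientation <- function(field) {
  stopifnot(inherits(field, "orientation_field"))
  w <- field$energy
  tot <- sum(w)
  if (tot <= 0) return(list(angle_deg = 0, mean_coherence = 0))
  a2 <- field$angle_deg * 2 * pi / 180
  cbar <- sum(w * cos(a2)) / tot
  sbar <- sum(w * sin(a2)) / tot
  list(angle_deg = wrap_axial(atan2(sbar, cbar) * 90 / pi),
       mean_coherence = sum(w * field$coherence) / tot)
}

#' Orientation histogram relative to the strain axis
#'
#' Bins the per-pixel orientations into fixed-width bins tiling (-90, 90],
#' after excluding pixels below a coherence floor, weighting each pixel by
#' gradient energy (default), energy times coherence, or nothing. Mass is
#' normalised to percent (sums to 100).
#'
#' @param field an [structure_tensor_field()] result.
#' @param bin_width bin width in degrees (must divide 180; default 2).
#' @param weighting "energy", "coherence_energy" or "unweighted".
#' @param coherence_min pixels with coherence below this are excluded.
#' @return an object of class `orientation_histogram` with `angle_deg`
#'   (bin centres), `mass_pct`, `bin_width`, counts of included/excluded
#'   pixels and the parameters used.
#' @export
orientation_histogram <- function(field, bin_width = 2,
                                  weighting = c("energy", "coherence_energy",
                                                "unweighted"),
                                  coherence_min = 0.1) {
  stopifnot(inherits(field, "orientation_field"))
  weighting <- match.arg(weighting)
  stop_if_not_scalar_num(bin_width, "bin_width", lower = 1e-3, upper = 180)
  if (abs(180 / bin_width - round(180 / bin_width)) > 1e-9) {
    stop("`bin_width` must divide 180 exactly", call. = FALSE)
  }
  keep <- field$coherence >= coherence_min & field$energy > 0
  n_total <- length(field$angle_deg)
  n_inc <- sum(keep)
  if (n_inc == 0L) {
    stop("all pixels excluded; lower `coherence_min`", call. = FALSE)
  }
  a <- field$angle_deg[keep]
  w <- switch(weighting,
              energy = field$energy[keep],
              coherence_energy = field$energy[keep] * field$coherence[keep],
              unweighted = rep(1, n_inc))
  nb <- as.integer(round(180 / bin_width))
  # bins tile (-90, 90]: bin k covers (-90 + (k-1)*bw, -90 + k*bw]
  bin <- ceiling((a + 90) / bin_width)
  bin[bin < 1L] <- 1L
  bin[bin > nb] <- nb
  mass <- vapply(split(w, factor(bin, levels = seq_len(nb))), sum, numeric(1))
  mass[is.na(mass)] <- 0
  mass_pct <- 100 * mass / sum(mass)
  centres <- -90 + (seq_len(nb) - 0.5) * bin_width
  structure(list(angle_deg = centres, mass_pct = as.numeric(mass_pct),
                 bin_width = bin_width, weighting = weighting,
                 coherence_min = coherence_min,
                 n_included = n_inc, n_excluded = n_total - n_inc),
            class = "orientation_histogram")
}

#' Alignment percentage about the modal orientation
#'
#' Locates the histogram mode (ties broken by the first bin in angle
#' order, with a message) and sums the mass within `halfwidth` degrees of
#' the modal bin centre, circularly on the 180-degree axial domain. Bins
#' partially covered by the window contribute in proportion to their
#' overlap (assuming uniform mass within a bin), so a uniform histogram
#' yields exactly `2 * halfwidth` degrees' worth of mass. This
#' mode-centred window is the mode-normalisation used before group
#' comparisons.
#'
#' @param hist an [orientation_histogram()].
#' @param halfwidth window half-width in degrees (default 10).
#' @return an object of class `alignment_summary` with `mode_angle_deg`,
#'   `alignment_pct`, `halfwidth`.
#' @export
alignment_percentage <- function(hist, halfwidth = 10) {
  stopifnot(inherits(hist, "orientation_histogram"))
  stop_if_not_scalar_num(halfwidth, "halfwidth", lower = 0, upper = 90)
  mx <- max(hist$mass_pct)
  modes <- which(hist$mass_pct == mx)
  if (length(modes) > 1L) {
    message("multi-modal orientation histogram; using first mode by angle")
  }
  k <- modes[1]
  mode_angle <- hist$angle_deg[k]
  # circular distance on the axial (180 deg) domain
  delta <- (hist$angle_deg - mode_angle + 90) %% 180 - 90
  bw2 <- hist$bin_width / 2
  overlap <- pmax(0, pmin(delta + bw2, halfwidth) -
                     pmax(delta - bw2, -halfwidth)) / hist$bin_width
  structure(list(mode_angle_deg = mode_angle,
                 alignment_pct = sum(hist$mass_pct * overlap),
                 halfwidth = halfwidth,
                 n_bins_in_window = sum(overlap > 0)),
            class = "alignment_summary")
}

#' One-call orientation analysis of an image
#'
#' @param image numeric matrix.
#' @param sigma_grad,sigma_window passed to [structure_tensor_field()].
#' @param bin_width,weighting,coherence_min passed to
#'   [orientation_histogram()].
#' @param halfwidth passed to [alignment_percentage()].
#' @return a list with `field`, `histogram`, `summary`.
#' @export
orientation_analysis <- function(image, sigma_grad = 1, sigma_window = 4,
                                 bin_width = 2, weighting = "energy",
                                 coherence_min = 0.1, halfwidth = 10) {
  field <- structure_tensor_field(image, sigma_grad, sigma_window)
  if (field$degenerate) {
    stop("degenerate (constant) image: no orientation signal", call. = FALSE)
  }
  h <- orientation_histogram(field, bin_width, weighting, coherence_min)
  s <- alignment_percentage(h, halfwidth)
  list(field = field, histogram = h, summary = s)
}
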