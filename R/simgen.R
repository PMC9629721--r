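# Synthetic-data generators: fibre-field images (SHG-like), fibril
# cross-section masks (TEM-like) and standard-linear-solid load traces.
# Every generator is a pure function of (params, seed) and returns its
# ground truth alongside the rendered data.

#' Parameters for a synthetic fibre-field image
#'
#' Describes a field of wavy, preferentially oriented fibres emulating a
#' second-harmonic-generation image of engineered tendon collagen. Fibre
#' base orientations are drawn from an axial von Mises distribution on
#' (-90, 90] degrees (0 degrees = vertical strain axis); each fibre is a
#' sinusoidally undulating line with a Gaussian cross-profile. Frame
#' averaging of the acquisition is emulated by a low additive noise level,
#' and acquisition blur by a Gaussian blur (default sigma 0.5 px).
#'
#' @param image_size side of the square image in pixels (>= 64).
#' @param pixel_size_um pixel size in micrometres (default 0.066 so that
#'   50 px is about 3.3 um).
#' @param n_fibres number of fibres rendered.
#' @param mean_angle_deg mean fibre orientation, degrees from the vertical
#'   strain axis in (-90, 90].
#' @param kappa axial von Mises concentration (>= 0; 0 = uniform).
#' @param undulation_amplitude_px,undulation_wavelength_px fibre waviness.
#' @param fibre_width_px Gaussian cross-profile sigma in pixels.
#' @param intensity_peak peak intensity of a single fibre (image is on a
#'   [0, 1] scale; overlaps add and saturate at 1).
#' @param noise_sd additive Gaussian noise sigma.
#' @param blur_sigma_px acquisition blur sigma in pixels.
#' @param seed integer seed; identical params + seed give a bit-identical
#'   image.
#' @return an object of class `fibre_field_params`.
#' @export
fibre_field_params <- function(image_size = 512, pixel_size_um = 0.066,
                               n_fibres = 120, mean_angle_deg = 0,
                               kappa = 4,
                               undulation_amplitude_px = 3,
                               undulation_wavelength_px = 60,
                               fibre_width_px = 2,
                               intensity_peak = 0.6, noise_sd = 0.02,
                               blur_sigma_px = 0.5, seed = 1L) {
  stop_if_not_scalar_num(image_size, "image_size", lower = 64)
  stop_if_not_scalar_num(pixel_size_um, "pixel_size_um", lower = 1e-6)
  stop_if_not_scalar_num(n_fibres, "n_fibres", lower = 1)
  stop_if_not_scalar_num(mean_angle_deg, "mean_angle_deg", lower = -90,
                         upper = 90)
  stop_if_not_scalar_num(kappa, "kappa", lower = 0)
  stop_if_not_scalar_num(undulation_amplitude_px, "undulation_amplitude_px",
                         lower = 0)
  stop_if_not_scalar_num(undulation_wavelength_px, "undulation_wavelength_px",
                         lower = 1e-6)
  stop_if_not_scalar_num(fibre_width_px, "fibre_width_px", lower = 0.2)
  stop_if_not_scalar_num(intensity_peak, "intensity_peak", lower = 1e-6,
                         upper = 1)
  stop_if_not_scalar_num(noise_sd, "noise_sd", lower = 0)
  stop_if_not_scalar_num(blur_sigma_px, "blur_sigma_px", lower = 0)
  stop_if_not_scalar_num(seed, "seed")
  structure(list(
    image_size = as.integer(image_size), pixel_size_um = pixel_size_um,
    n_fibres = as.integer(n_fibres), mean_angle_deg = mean_angle_deg,
    kappa = kappa,
    undulation_amplitude_px = undulation_amplitude_px,
    undulation_wavelength_px = undulation_wavelength_px,
    fibre_width_px = fibre_width_px, intensity_peak = intensity_peak,
    noise_sd = noise_sd, blur_sigma_px = blur_sigma_px,
    seed = as.integer(seed)
  ), class = "fibre_field_params")
}

# Axial von Mises sample on (-90, 90]: draw phi ~ von Mises(2*mu, kappa) on
# the circle and halve. kappa = 0 reduces to the uniform axial law.
sample_axial_von_mises <- function(n, mean_angle_deg, kappa) {
  if (kappa == 0) {
    return(wrap_axial(stats::runif(n, -90, 90)))
  }
  mu <- 2 * mean_angle_deg * pi / 180
  phi <- vapply(seq_len(n), function(i) rvonmises1(mu, kappa), numeric(1))
  wrap_axial(phi * 90 / pi)
}

# Best-Fisher (1979) rejection sampler for one von Mises draw.
rvonmises1 <- function(mu, kappa) {
  if (kappa < 1e-8) return(stats::runif(1, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  repeat {
    u1 <- stats::runif(1); u2 <- stats::runif(1); u3 <- stats::runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    if (c0 * (2 - c0) - u2 > 0 || log(c0 / u2) + 1 - c0 >= 0) {
      th <- mu + sign(u3 - 0.5) * acos(f)
      return(atan2(sin(th), cos(th)))
    }
  }
}

#' Generate a synthetic fibre-field image
#'
#' Renders `params$n_fibres` undulating fibres with orientations drawn from
#' an axial von Mises law, adds Gaussian noise, applies acquisition blur and
#' clips to [0, 1].
#'
#' @param params a [fibre_field_params()] object.
#' @return a list with `image` (numeric matrix in [0, 1]), `truth` (data
#'   frame with one row per fibre: `fibre`, `angle_deg`) and `params`.
#' @export
gen_fibre_image <- function(params) {
  stopifnot(inherits(params, "fibre_field_params"))
  p <- params
  n <- p$image_size
  with_seed(p$seed, {
    angles <- sample_axial_von_mises(p$n_fibres, p$mean_angle_deg, p$kappa)
    img <- matrix(0, n, n)
    step <- 0.5
    half_len <- n * sqrt(2) / 2 + p$undulation_amplitude_px + 2
    tt <- seq(-half_len, half_len, by = step)
    rs <- cs <- ws <- vector("list", p$n_fibres)
    for (f in seq_len(p$n_fibres)) {
      a <- angles[f] * pi / 180
      dr <- cos(a); dc <- sin(a)      # along-fibre direction (0 deg = vertical)
      nr <- -dc; nc <- dr             # unit normal
      ctr_r <- stats::runif(1, 1, n)
      ctr_c <- stats::runif(1, 1, n)
      phase <- stats::runif(1, 0, 2 * pi)
      u <- p$undulation_amplitude_px *
        sin(2 * pi * tt / p$undulation_wavelength_px + phase)
      rs[[f]] <- ctr_r + tt * dr + u * nr
      cs[[f]] <- ctr_c + tt * dc + u * nc
    }
    r_all <- round(unlist(rs)); c_all <- round(unlist(cs))
    keep <- r_all >= -10 & r_all <= n + 10 & c_all >= -10 & c_all <= n + 10
    r_all <- r_all[keep]; c_all <- c_all[keep]
    sig <- p$fibre_width_px
    rad <- ceiling(3 * sig)
    amp <- p$intensity_peak * step / (sig * sqrt(2 * pi))
    acc <- numeric(n * n)
    for (dy in -rad:rad) {
      for (dx in -rad:rad) {
        w <- exp(-(dx^2 + dy^2) / (2 * sig^2))
        if (w < 1e-4) next
        rr <- r_all + dy; cc <- c_all + dx
        ok <- rr >= 1 & rr <= n & cc >= 1 & cc <= n
        if (!any(ok)) next
        idx <- rr[ok] + (cc[ok] - 1L) * n
        acc <- acc + w * tabulate(idx, nbins = n * n)
      }
    }
    img <- matrix(amp * acc, n, n)
    if (p$noise_sd > 0) img <- img + stats::rnorm(n * n, sd = p$noise_sd)
    img <- gaussian_blur(img, p$blur_sigma_px)
    img <- pmin(pmax(img, 0), 1)
    list(image = img,
         truth = data.frame(fibre = seq_len(p$n_fibres), angle_deg = angles),
         params = p)
  })
}

#' Group recipe: one synthetic imaging condition
#'
#' @param label unique group name, e.g. "control", "3pct".
#' @param params a [fibre_field_params()] object (its `seed` is overridden
#'   per image by [gen_group_dataset()]).
#' @param n_images number of images to generate for this group (default 8:
#'   two replicates of four analysed images each).
#' @return an object of class `group_recipe`.
#' @export
group_recipe <- function(label, params, n_images = 8L) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  stopifnot(inherits(params, "fibre_field_params"))
  stop_if_not_scalar_num(n_images, "n_images", lower = 1)
  structure(list(label = label, params = params,
                 n_images = as.integer(n_images)),
            class = "group_recipe")
}

#' Default four-group fibre recipes
#'
#' Emulates the four culture conditions (static control and 3/5/10% cyclic
#' strain) as clearly separated groups: orientation concentration `kappa`
#' increases geometrically with strain (alignment increases with strain),
#' fibre width decreases (fibre edges sharpen with strain) and fibre
#' waviness decreases (waves are visible without strain, fibres straighten
#' with strain), so texture and orientation effects jointly drive
#' downstream group separation.
#'
#' Fibre count scales linearly with the image side (fibres span the whole
#' field, so constant linear density keeps coverage and saturation constant
#' across scales; the reference density is 120 fibres at 256 px).
#'
#' @param image_size image side in pixels.
#' @param n_images images per group.
#' @return a named list of [group_recipe()] objects.
#' @export
default_group_recipes <- function(image_size = 512, n_images = 8L) {
  kappas <- c(control = 1, `3pct` = 4, `5pct` = 16, `10pct` = 64)
  widths <- c(control = 3.0, `3pct` = 2.4, `5pct` = 1.8, `10pct` = 1.2)
  waves <- c(control = 5, `3pct` = 3.5, `5pct` = 2, `10pct` = 1)
  n_fibres <- max(20L, as.integer(round(image_size * 120 / 256)))
  out <- lapply(names(kappas), function(lab) {
    group_recipe(lab, fibre_field_params(
      image_size = image_size, n_fibres = n_fibres, kappa = kappas[[lab]],
      fibre_width_px = widths[[lab]],
      undulation_amplitude_px = waves[[lab]]), n_images = n_images)
  })
  names(out) <- names(kappas)
  out
}

#' Generate a labelled multi-group image dataset
#'
#' Per-image seeds are derived deterministically from `master_seed`, so the
#' whole dataset is reproducible from one integer.
#'
#' @param recipes list of at least two [group_recipe()] objects with unique
#'   labels.
#' @param master_seed integer master seed.
#' @return a list with `images` (list of matrices), `labels` (character),
#'   `truth` (list of per-image truth data frames), `image_ids` and `seeds`.
#' @export
gen_group_dataset <- function(recipes, master_seed = 1L) {
  stopifnot(is.list(recipes), length(recipes) >= 2L)
  labs <- vapply(recipes, function(r) r$label, character(1))
  if (anyDuplicated(labs)) {
    stop("duplicate group labels: ",
         paste(unique(labs[duplicated(labs)]), collapse = ", "),
         call. = FALSE)
  }
  n_total <- sum(vapply(recipes, function(r) r$n_images, integer(1)))
  seeds <- derive_seeds(master_seed, n_total)
  images <- vector("list", n_total)
  truth <- vector("list", n_total)
  labels <- character(n_total)
  ids <- character(n_total)
  k <- 0L
  for (r in recipes) {
    for (i in seq_len(r$n_images)) {
      k <- k + 1L
      p <- r$params
      p$seed <- seeds[k]
      res <- gen_fibre_image(p)
      images[[k]] <- res$image
      truth[[k]] <- res$truth
      labels[k] <- r$label
      ids[k] <- sprintf("%s_%02d", r$label, i)
    }
  }
  list(images = images, labels = labels, truth = truth,
       image_ids = ids, seeds = seeds)
}

#' Parameters for a synthetic fibril cross-section mask
#'
#' Emulates a transverse TEM field of non-touching elliptical collagen
#' fibril profiles. Minor-axis diameters follow a lognormal law specified by
#' its median; elongation (major/minor) is uniform on `axial_ratio_range`.
#'
#' @param image_size side in pixels.
#' @param pixel_size_nm nanometres per pixel.
#' @param n_fibrils number of fibrils to place (dart throwing with a retry
#'   cap; an error names the achievable count if the field is too dense).
#' @param diameter_median_nm median of the lognormal minor-diameter law.
#' @param diameter_log_sd standard deviation of log diameter.
#' @param min_gap_px minimum edge-to-edge separation between fibrils.
#' @param axial_ratio_range length-2 numeric, `c(1, r_max)`.
#' @param seed integer seed.
#' @return an object of class `fibril_field_params`.
#' @export
fibril_field_params <- function(image_size = 512, pixel_size_nm = 1,
                                n_fibrils = 60, diameter_median_nm = 36.3,
                                diameter_log_sd = 0.15, min_gap_px = 2,
                                axial_ratio_range = c(1, 1.6), seed = 1L) {
  stop_if_not_scalar_num(image_size, "image_size", lower = 32)
  stop_if_not_scalar_num(pixel_size_nm, "pixel_size_nm", lower = 1e-9)
  stop_if_not_scalar_num(n_fibrils, "n_fibrils", lower = 1)
  stop_if_not_scalar_num(diameter_median_nm, "diameter_median_nm",
                         lower = 1e-9)
  stop_if_not_scalar_num(diameter_log_sd, "diameter_log_sd", lower = 0)
  stop_if_not_scalar_num(min_gap_px, "min_gap_px", lower = 0)
  stopifnot(length(axial_ratio_range) == 2L, axial_ratio_range[1] >= 1,
            axial_ratio_range[2] >= axial_ratio_range[1])
  stop_if_not_scalar_num(seed, "seed")
  structure(list(
    image_size = as.integer(image_size), pixel_size_nm = pixel_size_nm,
    n_fibrils = as.integer(n_fibrils),
    diameter_median_nm = diameter_median_nm,
    diameter_log_sd = diameter_log_sd, min_gap_px = min_gap_px,
    axial_ratio_range = as.numeric(axial_ratio_range),
    seed = as.integer(seed)
  ), class = "fibril_field_params")
}

#' Generate a synthetic fibril cross-section mask
#'
#' @param params a [fibril_field_params()] object.
#' @return a list with `mask` (logical matrix), `truth` (data frame with
#'   `fibril`, `minor_nm`, `major_nm`, `angle_deg`, `centre_r`, `centre_c`)
#'   and `params`.
#' @export
gen_fibril_mask <- function(params) {
  stopifnot(inherits(params, "fibril_field_params"))
  p <- params
  n <- p$image_size
  ps <- p$pixel_size_nm
  with_seed(p$seed, {
    placed <- 0L
    tries <- 0L
    max_tries <- 300L * p$n_fibrils
    ctr_r <- ctr_c <- b_px <- a_px <- ang <- numeric(p$n_fibrils)
    while (placed < p$n_fibrils && tries < max_tries) {
      tries <- tries + 1L
      d_nm <- p$diameter_median_nm * exp(stats::rnorm(1, 0, p$diameter_log_sd))
      q <- stats::runif(1, p$axial_ratio_range[1], p$axial_ratio_range[2])
      b <- d_nm / (2 * ps)          # semi-minor in px
      a <- b * q                    # semi-major in px
      th <- stats::runif(1, 0, pi)
      margin <- a + 2
      if (2 * margin >= n) next
      r0 <- stats::runif(1, margin, n - margin + 1)
      c0 <- stats::runif(1, margin, n - margin + 1)
      if (placed > 0L) {
        i <- seq_len(placed)
        dmin <- sqrt((ctr_r[i] - r0)^2 + (ctr_c[i] - c0)^2) - a_px[i] - a
        if (any(dmin < p$min_gap_px + 1)) next
      }
      placed <- placed + 1L
      ctr_r[placed] <- r0; ctr_c[placed] <- c0
      b_px[placed] <- b; a_px[placed] <- a; ang[placed] <- th
    }
    if (placed < p$n_fibrils) {
      stop(sprintf(paste0("could only place %d of %d fibrils at this ",
                          "density; reduce n_fibrils or enlarge the field"),
                   placed, p$n_fibrils), call. = FALSE)
    }
    mask <- matrix(FALSE, n, n)
    for (f in seq_len(p$n_fibrils)) {
      rad <- ceiling(a_px[f]) + 1L
      rr <- max(1L, floor(ctr_r[f] - rad)):min(n, ceiling(ctr_r[f] + rad))
      cc <- max(1L, floor(ctr_c[f] - rad)):min(n, ceiling(ctr_c[f] + rad))
      dr <- rep(rr, times = length(cc)) - ctr_r[f]
      dc <- rep(cc, each = length(rr)) - ctr_c[f]
      x <- dr * cos(ang[f]) + dc * sin(ang[f])
      y <- -dr * sin(ang[f]) + dc * cos(ang[f])
      inside <- (x / a_px[f])^2 + (y / b_px[f])^2 <= 1
      sub <- mask[rr, cc]
      sub[inside] <- TRUE
      mask[rr, cc] <- sub
    }
    truth <- data.frame(
      fibril = seq_len(p$n_fibrils),
      minor_nm = 2 * b_px * ps,
      major_nm = 2 * a_px * ps,
      angle_deg = ang * 180 / pi,
      centre_r = ctr_r, centre_c = ctr_c
    )
    list(mask = mask, truth = truth, params = p)
  })
}

#' Parameters for a standard-linear-solid load trace
#'
#' Standard linear solid (SLS): an equilibrium spring `E_eq` in parallel
#' with a Maxwell arm (spring `E_m` in series with dashpot `eta`); the
#' relaxation time is `tau = eta / E_m`. Supply either `eta` or `tau`.
#' Protocols: `ramp_hold` (strain ramp to `hold_strain`, then hold) and
#' `triangle` (ramp up then down at `ramp_rate`).
#'
#' @param E_eq equilibrium modulus, kPa.
#' @param E_m Maxwell-arm modulus, kPa.
#' @param eta Maxwell-arm viscosity, kPa s (derived from `tau` if missing).
#' @param tau relaxation time, s (derived from `eta` if missing).
#' @param protocol "ramp_hold" or "triangle".
#' @param ramp_rate strain per second; `Inf` for an instantaneous step
#'   (ramp_hold only).
#' @param hold_strain peak strain (dimensionless).
#' @param hold_duration_s hold duration, s (default 60, spanning the 60 s
#'   relaxation read-out).
#' @param sample_rate_hz sampling rate, Hz.
#' @param l0_mm initial specimen length, mm (default 8).
#' @param diameter_mm specimen diameter, mm (default 2.43, the cohort mean);
#'   the cross-section is assumed circular.
#' @return an object of class `sls_params`.
#' @export
sls_params <- function(E_eq = 50, E_m = 30, eta = NULL, tau = NULL,
                       protocol = c("ramp_hold", "triangle"),
                       ramp_rate = 0.01, hold_strain = 0.1,
                       hold_duration_s = 90, sample_rate_hz = 100,
                       l0_mm = 8, diameter_mm = 2.43) {
  protocol <- match.arg(protocol)
  stop_if_not_scalar_num(E_eq, "E_eq", lower = 1e-12)
  stop_if_not_scalar_num(E_m, "E_m", lower = 0)
  if (is.null(tau) && is.null(eta)) tau <- 20
  if (is.null(tau)) tau <- eta / E_m
  if (is.null(eta)) eta <- tau * E_m
  stop_if_not_scalar_num(tau, "tau", lower = 1e-12, allow_inf = TRUE)
  if (is.finite(tau) && is.finite(eta) && E_m > 0 &&
      abs(tau - eta / E_m) > 1e-9 * tau) {
    stop("`tau` must equal `eta / E_m`", call. = FALSE)
  }
  stop_if_not_scalar_num(ramp_rate, "ramp_rate", lower = 1e-12,
                         allow_inf = TRUE)
  if (protocol == "triangle" && !is.finite(ramp_rate)) {
    stop("triangle protocol needs a finite ramp_rate", call. = FALSE)
  }
  stop_if_not_scalar_num(hold_strain, "hold_strain", lower = 1e-12)
  stop_if_not_scalar_num(hold_duration_s, "hold_duration_s", lower = 0)
  stop_if_not_scalar_num(sample_rate_hz, "sample_rate_hz", lower = 1e-6)
  stop_if_not_scalar_num(l0_mm, "l0_mm", lower = 1e-6)
  stop_if_not_scalar_num(diameter_mm, "diameter_mm", lower = 1e-6)
  structure(list(E_eq = E_eq, E_m = E_m, eta = eta, tau = tau,
                 protocol = protocol, ramp_rate = ramp_rate,
                 hold_strain = hold_strain,
                 hold_duration_s = hold_duration_s,
                 sample_rate_hz = sample_rate_hz, l0_mm = l0_mm,
                 diameter_mm = diameter_mm),
            class = "sls_params")
}

# SLS stress (kPa) under a constant-rate ramp starting from a relaxed state:
# sigma(t) = E_eq*rate*t + eta*rate*(1 - exp(-t/tau)).
sls_ramp_stress <- function(t, rate, E_eq, E_m, tau) {
  eta <- tau * E_m
  E_eq * rate * t + eta * rate * (1 - exp(-t / tau))
}

#' Generate a standard-linear-solid load trace
#'
#' Samples the closed-form SLS response on a regular time grid and
#' back-computes force (N) from stress via the circular cross-section
#' `A = pi d^2 / 4`. The returned object carries the closed-form expected
#' mechanical summary so analysis can be checked against an exact oracle.
#'
#' @param params an [sls_params()] object.
#' @param relax_T relaxation read-out window, s (default 60).
#' @return a list with `trace` (data frame `time_s, force_N,
#'   displacement_mm, phase`), `expected` (closed-form `sigma_max_kPa`,
#'   `relax_rate_kPa_s`, `E_fast_kPa`), `geometry`, `undersampled` flag and
#'   `params`.
#' @export
gen_sls_trace <- function(params, relax_T = 60) {
  stopifnot(inherits(params, "sls_params"))
  p <- params
  dt <- 1 / p$sample_rate_hz
  eps0 <- p$hold_strain
  A_mm2 <- area_from_diameter(p$diameter_mm)
  undersampled <- is.finite(p$tau) && (p$tau * p$sample_rate_hz < 10)
  if (undersampled) {
    warning("sample rate resolves fewer than 10 samples per tau",
            call. = FALSE)
  }
  if (p$protocol == "ramp_hold") {
    if (is.finite(p$ramp_rate)) {
      t1 <- eps0 / p$ramp_rate
      t_ramp <- seq(0, t1, by = dt)
      t_ramp <- t_ramp[t_ramp < t1]
      t_hold <- seq(0, p$hold_duration_s, by = dt)
      # Maxwell-arm stress reached at the end of the ramp
      sig_m1 <- if (is.finite(p$tau)) {
        p$eta * p$ramp_rate * (1 - exp(-t1 / p$tau))
      } else p$E_m * eps0
      strain <- c(p$ramp_rate * t_ramp, rep(eps0, length(t_hold)))
      decay <- if (is.finite(p$tau)) exp(-t_hold / p$tau) else rep(1, length(t_hold))
      stress <- c(sls_ramp_stress(t_ramp, p$ramp_rate, p$E_eq, p$E_m, p$tau),
                  p$E_eq * eps0 + sig_m1 * decay)
      time <- c(t_ramp, t1 + t_hold)
      phase <- c(rep("loading", length(t_ramp)),
                 rep("hold", length(t_hold)))
    } else {
      t1 <- 0
      sig_m1 <- p$E_m * eps0
      t_hold <- seq(0, p$hold_duration_s, by = dt)
      decay <- if (is.finite(p$tau)) exp(-t_hold / p$tau) else rep(1, length(t_hold))
      strain <- rep(eps0, length(t_hold))
      stress <- p$E_eq * eps0 + sig_m1 * decay
      time <- t_hold
      phase <- rep("hold", length(t_hold))
    }
    rate_expect <- if (p$hold_duration_s >= relax_T) {
      if (is.finite(p$tau)) {
        sig_m1 * (1 - exp(-relax_T / p$tau)) / relax_T
      } else 0
    } else NA_real_
    expected <- list(sigma_max_kPa = max(stress),
                     relax_rate_kPa_s = rate_expect,
                     E_fast_kPa = p$E_eq + p$E_m)
  } else { # triangle
    t1 <- eps0 / p$ramp_rate
    t_up <- seq(0, t1, by = dt)
    t_dn <- seq(dt, t1, by = dt)
    strain_up <- p$ramp_rate * t_up
    strain_dn <- eps0 - p$ramp_rate * t_dn
    sig_up <- sls_ramp_stress(t_up, p$ramp_rate, p$E_eq, p$E_m, p$tau)
    sig_m1 <- if (is.finite(p$tau)) {
      p$eta * p$ramp_rate * (1 - exp(-t1 / p$tau))
    } else p$E_m * eps0
    decay <- if (is.finite(p$tau)) exp(-t_dn / p$tau) else rep(1, length(t_dn))
    relax_term <- if (is.finite(p$tau)) {
      p$eta * p$ramp_rate * (1 - decay)
    } else p$E_m * p$ramp_rate * t_dn
    sig_dn <- p$E_eq * strain_dn + sig_m1 * decay - relax_term
    time <- c(t_up, t1 + t_dn)
    strain <- c(strain_up, strain_dn)
    stress <- c(sig_up, sig_dn)
    phase <- c(rep("loading", length(t_up)),
               rep("unloading", length(t_dn)))
    expected <- list(sigma_max_kPa = max(stress),
                     relax_rate_kPa_s = NA_real_,
                     E_fast_kPa = p$E_eq + p$E_m)
  }
  trace <- data.frame(
    time_s = time,
    force_N = stress * A_mm2 / 1000,   # kPa * mm^2 = mN
    displacement_mm = strain * p$l0_mm,
    phase = phase,
    stringsAsFactors = FALSE
  )
  list(trace = trace, expected = expected,
       geometry = tendon_geometry(l0_mm = p$l0_mm,
                                  diameter_mm = p$diameter_mm),
       undersampled = undersampled, params = p)
}
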