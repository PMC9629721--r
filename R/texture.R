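# GLCM texture analysis: 20-level quantization, co-occurrence matrices at
# 0/45/90/135 degrees and distances up to ~50 px (~3.3 um), the four
# Haralick measures, and dominant-axis correction so that fibres run
# vertically before features are extracted.

glcm_angles <- c(0, 45, 90, 135)
glcm_measures <- c("contrast", "correlation", "energy", "homogeneity")

#' Quantize an image into L grey levels
#'
#' Linear binning of pixel intensities into `L` levels spanning the
#' per-image min-max range (the binning range is recorded for audit). A
#' constant image quantizes to all-zero levels with `degenerate = TRUE`.
#'
#' @param image numeric matrix with finite values.
#' @param L number of grey levels (default 20).
#' @param range_mode only "per_image" is implemented.
#' @param pixel_size_um pixel size carried through to the texture profile.
#' @return an object of class `quantized_image` with fields `levels`
#'   (integer matrix in 0..L-1), `L`, `source_range`, `degenerate`,
#'   `pixel_size_um`.
#' @export
quantize <- function(image, L = 20, range_mode = "per_image",
                     pixel_size_um = 0.066) {
  check_image(image)
  stop_if_not_scalar_num(L, "L", lower = 2)
  range_mode <- match.arg(range_mode, "per_image")
  L <- as.integer(L)
  lo <- min(image); hi <- max(image)
  degenerate <- hi <= lo
  if (degenerate) {
    lev <- matrix(0L, nrow(image), ncol(image))
  } else {
    lev <- floor((image - lo) / (hi - lo) * L)
    lev <- matrix(as.integer(pmin(pmax(lev, 0), L - 1L)),
                  nrow(image), ncol(image))
  }
  structure(list(levels = lev, L = L, source_range = c(lo, hi),
                 degenerate = degenerate, range_mode = range_mode,
                 pixel_size_um = pixel_size_um),
            class = "quantized_image")
}

# Row/col offset for a GLCM angle (rows increase downward).
glcm_offset <- function(angle_deg, distance_px) {
  d <- as.integer(distance_px)
  switch(as.character(angle_deg),
         "0"   = c(0L, d),
         "45"  = c(-d, d),
         "90"  = c(-d, 0L),
         "135" = c(-d, -d),
         stop("angle must be one of 0, 45, 90, 135", call. = FALSE))
}

#' Grey-level co-occurrence matrix
#'
#' Counts co-occurring level pairs at the given angle and pixel distance.
#' Offsets (row, col) with rows increasing downward: 0 deg -> (0, d);
#' 45 deg -> (-d, d); 90 deg -> (-d, 0); 135 deg -> (-d, -d). Only fully
#' in-bounds pairs are counted; with `symmetric = TRUE` each unordered pair
#' contributes in both orders (counts = counts + t(counts)).
#'
#' @param q a [quantize()]d image.
#' @param angle_deg one of 0, 45, 90, 135.
#' @param distance_px pair distance in pixels (>= 1).
#' @param symmetric accumulate symmetrically (default TRUE).
#' @return an object of class `cooccurrence_matrix` with `counts` (L x L),
#'   `n_pairs`, `angle_deg`, `distance_px`, `symmetric`.
#' @export
cooccurrence <- function(q, angle_deg, distance_px, symmetric = TRUE) {
  stopifnot(inherits(q, "quantized_image"))
  stop_if_not_scalar_num(distance_px, "distance_px", lower = 1)
  off <- glcm_offset(angle_deg, distance_px)
  lev <- q$levels
  n <- nrow(lev); m <- ncol(lev)
  r0 <- max(1L, 1L - off[1]):min(n, n - off[1])
  c0 <- max(1L, 1L - off[2]):min(m, m - off[2])
  if (length(r0) < 1L || length(c0) < 1L ||
      (n - abs(off[1])) < 1L || (m - abs(off[2])) < 1L) {
    stop("no in-bounds pixel pairs at this distance", call. = FALSE)
  }
  i <- lev[r0, c0, drop = FALSE]
  j <- lev[r0 + off[1], c0 + off[2], drop = FALSE]
  L <- q$L
  counts <- matrix(tabulate(as.integer(i) * L + as.integer(j) + 1L,
                            nbins = L * L), L, L, byrow = TRUE)
  if (symmetric) counts <- counts + t(counts)
  structure(list(counts = counts, n_pairs = sum(counts),
                 angle_deg = angle_deg, distance_px = as.integer(distance_px),
                 symmetric = symmetric, L = L),
            class = "cooccurrence_matrix")
}

#' The four Haralick measures of a co-occurrence matrix
#'
#' With `p = counts / n_pairs` and marginal means/sds `mu_i, mu_j, sigma_i,
#' sigma_j`: contrast `sum((i-j)^2 p)`, correlation
#' `sum((i-mu_i)(j-mu_j) p) / (sigma_i sigma_j)`, energy `sum(p^2)`,
#' homogeneity `sum(p / (1 + |i-j|))`. Correlation is `NA` (an explicit
#' undefined marker, never a fabricated number) when either marginal has
#' zero variance.
#'
#' @param m a [cooccurrence()] matrix.
#' @return a list with `contrast`, `correlation`, `energy`, `homogeneity`,
#'   plus the normalised matrix `p` and marginals.
#' @export
haralick <- function(m) {
  stopifnot(inherits(m, "cooccurrence_matrix"))
  if (m$n_pairs <= 0) stop("cannot normalise: n_pairs is 0", call. = FALSE)
  p <- m$counts / m$n_pairs
  L <- nrow(p)
  idx <- seq_len(L) - 1
  pi_ <- rowSums(p)     # marginal over i (rows)
  pj_ <- colSums(p)
  mu_i <- sum(idx * pi_)
  mu_j <- sum(idx * pj_)
  var_i <- sum((idx - mu_i)^2 * pi_)
  var_j <- sum((idx - mu_j)^2 * pj_)
  ii <- matrix(idx, L, L)
  jj <- t(ii)
  contrast <- sum((ii - jj)^2 * p)
  energy <- sum(p^2)
  homogeneity <- sum(p / (1 + abs(ii - jj)))
  correlation <- if (var_i <= 0 || var_j <= 0) NA_real_ else {
    sum((ii - mu_i) * (jj - mu_j) * p) / sqrt(var_i * var_j)
  }
  list(contrast = contrast, correlation = correlation, energy = energy,
       homogeneity = homogeneity, p = p, mu_i = mu_i, mu_j = mu_j,
       sigma_i = sqrt(var_i), sigma_j = sqrt(var_j))
}

#' Full GLCM texture profile of an image
#'
#' Computes the four Haralick measures over the full grid of 4 angles and
#' distances 1..D px from one 20-level quantization of the image. Undefined
#' correlations propagate as `NA`.
#'
#' @param image numeric matrix (or an already [quantize()]d image).
#' @param L grey levels (default 20).
#' @param D maximum pair distance in pixels (default 50, about 3.3 um at
#'   0.066 um/px).
#' @param pixel_size_um pixel size in micrometres.
#' @param image_id identifier carried into tidy output.
#' @return an object of class `texture_profile`: a 3-d array
#'   `values[measure, angle, distance]` plus metadata. The canonical
#'   flattening order (see [profile_vector()]) is measure-major, then
#'   angle, then distance.
#' @export
texture_profile <- function(image, L = 20, D = 50, pixel_size_um = 0.066,
                            image_id = "image") {
  q <- if (inherits(image, "quantized_image")) image
       else quantize(image, L = L, pixel_size_um = pixel_size_um)
  if (q$degenerate) {
    stop("degenerate (constant) image has no texture", call. = FALSE)
  }
  if (min(dim(q$levels)) <= D) {
    stop("image dimensions must exceed the maximum distance D", call. = FALSE)
  }
  vals <- array(NA_real_,
                dim = c(4L, 4L, D),
                dimnames = list(measure = glcm_measures,
                                angle = as.character(glcm_angles),
                                distance = as.character(seq_len(D))))
  for (ai in seq_along(glcm_angles)) {
    for (d in seq_len(D)) {
      h <- haralick(cooccurrence(q, glcm_angles[ai], d))
      vals["contrast", ai, d] <- h$contrast
      vals["correlation", ai, d] <- h$correlation
      vals["energy", ai, d] <- h$energy
      vals["homogeneity", ai, d] <- h$homogeneity
    }
  }
  structure(list(values = vals, L = q$L, D = as.integer(D),
                 pixel_size_um = q$pixel_size_um, image_id = image_id),
            class = "texture_profile")
}

#' Flatten a texture profile to a named feature vector
#'
#' Fixed order: measure-major, then angle, then distance, with names
#' `measure_a<angle>_d<distance>`.
#'
#' @param profile a [texture_profile()].
#' @return a named numeric vector of length `4 * 4 * D`.
#' @export
profile_vector <- function(profile) {
  stopifnot(inherits(profile, "texture_profile"))
  v <- profile$values
  out <- numeric(0)
  nms <- character(0)
  for (m in glcm_measures) {
    for (a in as.character(glcm_angles)) {
      x <- v[m, a, ]
      out <- c(out, x)
      nms <- c(nms, sprintf("%s_a%s_d%d", m, a, seq_len(profile$D)))
    }
  }
  names(out) <- nms
  out
}

#' Tidy data frame of a texture profile
#'
#' @param x a [texture_profile()].
#' @param ... unused.
#' @return data frame `image_id, measure, angle_deg, distance_px, value`.
#' @export
as.data.frame.texture_profile <- function(x, ...) {
  g <- expand.grid(distance_px = seq_len(x$D), angle_deg = glcm_angles,
                   measure = glcm_measures, stringsAsFactors = FALSE)
  g <- g[, c("measure", "angle_deg", "distance_px")]
  vals <- numeric(nrow(g))
  k <- 0L
  for (m in glcm_measures) for (a in as.character(glcm_angles)) {
    vals[k + seq_len(x$D)] <- x$values[m, a, ]
    k <- k + x$D
  }
  data.frame(image_id = x$image_id, measure = g$measure,
             angle_deg = g$angle_deg, distance_px = g$distance_px,
             value = vals, stringsAsFactors = FALSE)
}

#' Feature matrix from a set of images
#'
#' Quantizes, optionally aligns the dominant fibre axis vertically, and
#' stacks flattened texture profiles row-wise. Features that are undefined
#' (`NA` correlation) in any image are dropped consistently across the
#' dataset, and the dropped names recorded.
#'
#' @param images list of numeric matrices.
#' @param labels optional character vector of class labels.
#' @param image_ids optional ids (default `img_01`...).
#' @param align rotate each image so its dominant axis is vertical first.
#' @param L,D,pixel_size_um passed to [texture_profile()].
#' @return a list with `X` (matrix, rownames = ids), `labels`,
#'   `dropped_features`, `rotations_deg`.
#' @export
texture_feature_matrix <- function(images, labels = NULL, image_ids = NULL,
                                   align = TRUE, L = 20, D = 50,
                                   pixel_size_um = 0.066) {
  stopifnot(is.list(images), length(images) >= 1L)
  if (is.null(image_ids)) {
    image_ids <- sprintf("img_%02d", seq_along(images))
  }
  rots <- numeric(length(images))
  rows <- vector("list", length(images))
  for (i in seq_along(images)) {
    img <- images[[i]]
    if (align) {
      al <- align_dominant_axis(img)
      img <- al$image
      rots[i] <- al$applied_rotation_deg
    }
    rows[[i]] <- profile_vector(
      texture_profile(img, L = L, D = D, pixel_size_um = pixel_size_um,
                      image_id = image_ids[i]))
  }
  X <- do.call(rbind, rows)
  rownames(X) <- image_ids
  bad <- colnames(X)[colSums(is.na(X)) > 0]
  if (length(bad)) X <- X[, setdiff(colnames(X), bad), drop = FALSE]
  list(X = X, labels = labels, dropped_features = bad,
       rotations_deg = rots)
}

#' Rotate an image so the dominant fibre axis is vertical
#'
#' The dominant orientation is estimated from the global (image-averaged)
#' structure tensor; the image is rotated by minus that angle (bilinear
#' interpolation) and centrally cropped to the largest square valid under
#' any rotation, so padding never contaminates GLCM statistics. The stated
#' outcome of the correction — GLCM correlation at 90 degrees is the
#' maximum over angles at the reference distance — is verified post hoc;
#' if the verification fails or the image is nearly isotropic (mean
#' coherence below `coherence_min`), the unrotated (cropped) image is
#' returned with `anisotropy_flag = TRUE`.
#'
#' @param image numeric matrix.
#' @param reference_distance_px distance used for the verification.
#' @param coherence_min minimum mean coherence treated as anisotropic.
#' @return a list with `image` (rotated and cropped),
#'   `applied_rotation_deg`, `dominant_angle_deg`, `anisotropy_flag`,
#'   `verified`.
#' @export
align_dominant_axis <- function(image, reference_distance_px = 4,
                                coherence_min = 0.1) {
  check_image(image)
  field <- structure_tensor_field(image)
  if (field$degenerate) {
    stop("degenerate (constant) image has no dominant axis", call. = FALSE)
  }
  dom <- dominant_orientation(field)
  side <- central_crop_side(nrow(image), ncol(image))
  if (dom$mean_coherence < coherence_min) {
    return(list(image = crop_center(image, side),
                applied_rotation_deg = 0,
                dominant_angle_deg = dom$angle_deg,
                anisotropy_flag = TRUE, verified = FALSE))
  }
  rot <- -dom$angle_deg
  rotated <- crop_center(rotate_image(image, rot), side)
  q <- quantize(rotated)
  ok <- !q$degenerate && {
    cors <- vapply(glcm_angles, function(a) {
      haralick(cooccurrence(q, a, reference_distance_px))$correlation
    }, numeric(1))
    !any(is.na(cors)) && which.max(cors) == 3L  # 90 degrees
  }
  if (!ok) {
    return(list(image = crop_center(image, side),
                applied_rotation_deg = 0,
                dominant_angle_deg = dom$angle_deg,
                anisotropy_flag = TRUE, verified = FALSE))
  }
  list(image = rotated, applied_rotation_deg = rot,
       dominant_angle_deg = dom$angle_deg,
       anisotropy_flag = FALSE, verified = TRUE)
}
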