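#' @keywords internal
"_PACKAGE"

# Run expr with a local RNG seed, restoring the caller's RNG state afterwards.
# Every stochastic operation in the package routes through this so that
# generators are pure functions of (params, seed).
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Derive a stream of child seeds from a master seed (keeps values < 2^31).
derive_seeds <- function(master_seed, n) {
  with_seed(master_seed, sample.int(.Machine$integer.max - 1L, n))
}

stop_if_not_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                                   allow_inf = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      (!allow_inf && !is.finite(x))) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (x < lower || x > upper) {
    stop(sprintf("`%s` must be in [%s, %s], got %s", name,
                 format(lower), format(upper), format(x)), call. = FALSE)
  }
  invisible(x)
}

check_image <- function(image, arg = "image") {
  if (!is.matrix(image) || !is.numeric(image)) {
    stop(sprintf("`%s` must be a numeric matrix", arg), call. = FALSE)
  }
  nbad <- sum(!is.finite(image))
  if (nbad > 0L) {
    stop(sprintf("`%s` contains %d non-finite pixel(s)", arg, nbad),
         call. = FALSE)
  }
  invisible(image)
}

# 1-D Gaussian kernel (normalised); radius 4 sigma.
gaussian_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# First-derivative-of-Gaussian kernel; responds to a unit ramp with slope 1.
gaussian_deriv_kernel <- function(sigma) {
  r <- max(1L, ceiling(4 * sigma))
  x <- -r:r
  g <- exp(-x^2 / (2 * sigma^2))
  k <- x * g
  k / sum(x * k)  # correlation of this kernel with a unit ramp gives 1
}

# Convolve each column of `m` with kernel `k`, reflecting at the borders.
conv_cols <- function(m, k) {
  r <- (length(k) - 1L) %/% 2L
  if (r == 0L) return(m * k)
  n <- nrow(m)
  top <- m[pmin(pmax(2L - (r:1), 1L), n), , drop = FALSE]
  bot <- m[pmin(pmax(n - 1L - 0:(r - 1L), 1L), n), , drop = FALSE]
  padded <- rbind(top, m, bot)
  out <- matrix(0, nrow = n, ncol = ncol(m))
  for (i in seq_along(k)) {
    out <- out + k[i] * padded[i:(i + n - 1L), , drop = FALSE]
  }
  out
}

# Separable 2-D convolution with reflection padding.
conv_sep <- function(m, krow, kcol = krow) {
  t(conv_cols(t(conv_cols(m, krow)), kcol))
}

gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  conv_sep(m, gaussian_kernel(sigma))
}

# Map an angle (degrees) into the axial orientation range (-90, 90].
wrap_axial <- function(a) {
  a <- (a + 90) %% 180
  a[a == 0] <- 180
  a - 90
}

#' Rotate an image about its centre
#'
#' Bilinear interpolation; positive angles rotate the image content clockwise
#' on screen (rows increase downward). Output pixels whose pre-image falls
#' outside the input are set to `fill`.
#'
#' @param image numeric matrix.
#' @param angle_deg rotation angle in degrees.
#' @param fill value for out-of-bounds pixels.
#' @return a numeric matrix of the same dimensions.
#' @export
rotate_image <- function(image, angle_deg, fill = 0) {
  check_image(image)
  th <- -angle_deg * pi / 180  # positive = fibre orientation angle increases
  n <- nrow(image); m <- ncol(image)
  cr <- (n + 1) / 2; cc <- (m + 1) / 2
  rr <- rep(seq_len(n), times = m) - cr
  cs <- rep(seq_len(m), each = n) - cc
  # inverse mapping: rotate output coords by -angle to find source
  ct <- cos(-th); st <- sin(-th)
  # screen-clockwise rotation by a of (col, row) with row down is the
  # ordinary CCW rotation matrix in (col, row):
  src_c <- ct * cs - st * rr + cc
  src_r <- st * cs + ct * rr + cr
  c0 <- floor(src_c); r0 <- floor(src_r)
  fc <- src_c - c0; fr <- src_r - r0
  valid <- r0 >= 1 & r0 + 1 <= n & c0 >= 1 & c0 + 1 <= m
  out <- rep(fill, n * m)
  i00 <- (c0 - 1) * n + r0
  v <- which(valid)
  i <- i00[v]
  out[v] <- (1 - fr[v]) * (1 - fc[v]) * image[i] +
    fr[v] * (1 - fc[v]) * image[i + 1] +
    (1 - fr[v]) * fc[v] * image[i + n] +
    fr[v] * fc[v] * image[i + n + 1]
  matrix(out, n, m)
}

# Largest centred square crop valid under any rotation of an n x m image.
central_crop_side <- function(n, m = n) {
  floor(min(n, m) / sqrt(2))
}

crop_center <- function(image, side) {
  n <- nrow(image); m <- ncol(image)
  r0 <- floor((n - side) / 2)
  c0 <- floor((m - side) / 2)
  image[(r0 + 1):(r0 + side), (c0 + 1):(c0 + side), drop = FALSE]
}
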