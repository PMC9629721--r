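# Shared fixtures and independent oracles, all built in code.

# Brute-force GLCM oracle: enumerate every pixel pair at the offset.
# Deliberately written as plain loops, independent of cooccurrence().
oracle_glcm <- function(levels, L, angle_deg, d, symmetric = TRUE) {
  off <- switch(as.character(angle_deg),
                "0" = c(0, d), "45" = c(-d, d),
                "90" = c(-d, 0), "135" = c(-d, -d))
  counts <- matrix(0L, L, L)
  for (r in seq_len(nrow(levels))) {
    for (c in seq_len(ncol(levels))) {
      r2 <- r + off[1]; c2 <- c + off[2]
      if (r2 >= 1 && r2 <= nrow(levels) && c2 >= 1 && c2 <= ncol(levels)) {
        i <- levels[r, c] + 1L; j <- levels[r2, c2] + 1L
        counts[i, j] <- counts[i, j] + 1L
        if (symmetric) counts[j, i] <- counts[j, i] + 1L
      }
    }
  }
  counts
}

# Haralick oracle from raw counts, via explicit double sums.
oracle_haralick <- function(counts) {
  p <- counts / sum(counts)
  L <- nrow(p)
  contrast <- 0; energy <- 0; homog <- 0
  mu_i <- 0; mu_j <- 0
  for (i in 1:L) for (j in 1:L) {
    mu_i <- mu_i + (i - 1) * p[i, j]
    mu_j <- mu_j + (j - 1) * p[i, j]
  }
  v_i <- 0; v_j <- 0; cov <- 0
  for (i in 1:L) for (j in 1:L) {
    contrast <- contrast + (i - j)^2 * p[i, j]
    energy <- energy + p[i, j]^2
    homog <- homog + p[i, j] / (1 + abs(i - j))
    v_i <- v_i + (i - 1 - mu_i)^2 * p[i, j]
    v_j <- v_j + (j - 1 - mu_j)^2 * p[i, j]
    cov <- cov + (i - 1 - mu_i) * (j - 1 - mu_j) * p[i, j]
  }
  corr <- if (v_i <= 0 || v_j <= 0) NA_real_ else cov / sqrt(v_i * v_j)
  list(contrast = contrast, correlation = corr, energy = energy,
       homogeneity = homog)
}

# Sinusoidal grating whose stripes run at `angle_deg` from vertical
# (same axial convention as the orientation module).
make_grating <- function(angle_deg, n = 128, period = 8) {
  th <- angle_deg * pi / 180
  rr <- row(matrix(0, n, n)); cc <- col(matrix(0, n, n))
  x <- -rr * sin(th) + cc * cos(th)   # coordinate across the stripes
  matrix(0.5 + 0.5 * sin(2 * pi * x / period), n, n)
}

# Four tight clusters at orthogonal-simplex corners in 3 signal features.
# With planted = TRUE the first class-"a" sample sits at class "b"'s centre.
make_cluster_toy <- function(n_per = 8, sd = 1e-3, planted = FALSE,
                             seed = 1) {
  set.seed(seed)
  centers <- matrix(c(0, 0, 0, 10, 0, 0, 0, 10, 0, 0, 0, 10),
                    4, 3, byrow = TRUE)
  X <- do.call(rbind, lapply(1:4, function(k) {
    sweep(matrix(rnorm(n_per * 3, sd = sd), n_per, 3), 2, centers[k, ], "+")
  }))
  colnames(X) <- paste0("f", 1:3)
  if (planted) X[1, ] <- centers[2, ]
  list(X = X, labels = rep(c("a", "b", "c", "d"), each = n_per))
}

# Filled disc mask of radius r (px) centred in an n x n image.
make_disc_mask <- function(r, n = 2 * ceiling(r) + 21) {
  ctr <- (n + 1) / 2
  m <- matrix(FALSE, n, n)
  m[(row(m) - ctr)^2 + (col(m) - ctr)^2 <= r^2] <- TRUE
  m
}

# Filled rotated-ellipse mask with semi-axes (a, b) px.
make_ellipse_mask <- function(a, b, angle_deg = 0, n = 2 * ceiling(a) + 21) {
  th <- angle_deg * pi / 180
  ctr <- (n + 1) / 2
  rr <- row(matrix(0, n, n)) - ctr
  cc <- col(matrix(0, n, n)) - ctr
  x <- rr * cos(th) + cc * sin(th)
  y <- -rr * sin(th) + cc * cos(th)
  (x / a)^2 + (y / b)^2 <= 1
}
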