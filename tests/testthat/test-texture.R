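# Quantization, co-occurrence, Haralick measures, texture profiles and
# dominant-axis correction.

test_that("quantize bins linearly over the per-image range", {
  # ramp 0..19 at L = 20 is the identity
  q <- quantize(matrix(rep(0:19, each = 2), 2, 20), L = 20)
  expect_equal(q$levels[1, ], 0:19)
  expect_false(q$degenerate)
  expect_equal(q$source_range, c(0, 19))
  # two values, two levels
  q2 <- quantize(matrix(c(0, 255, 255, 0), 2, 2), L = 2)
  expect_setequal(unique(as.vector(q2$levels)), c(0L, 1L))
  # constant image: degenerate, all level 0
  q3 <- quantize(matrix(5, 4, 4))
  expect_true(q3$degenerate)
  expect_true(all(q3$levels == 0L))
  expect_error(quantize(matrix(c(1, NA, 2, 3), 2, 2)), "non-finite")
})

test_that("cooccurrence counts match the spec's worked example", {
  q <- quantize(matrix(c(0, 0, 1, 1), 2, 2), L = 2)  # [[0,1],[0,1]]
  m <- cooccurrence(q, 0, 1, symmetric = TRUE)
  expect_equal(m$counts, matrix(c(0, 2, 2, 0), 2, 2))
  expect_equal(m$n_pairs, 4)
  expect_equal(m$counts, t(m$counts))
  # asymmetric counts each ordered pair once
  ma <- cooccurrence(q, 0, 1, symmetric = FALSE)
  expect_equal(sum(ma$counts), 2)
  # d at the image extent leaves no pairs
  expect_error(cooccurrence(q, 0, 2), "no in-bounds")
})

test_that("checkerboard diagonal is empty and Haralick values are exact", {
  cb <- matrix((row(matrix(0, 8, 8)) + col(matrix(0, 8, 8))) %% 2, 8, 8)
  m <- cooccurrence(quantize(cb, L = 2), 0, 1)
  expect_true(all(diag(m$counts) == 0))
  h <- haralick(m)
  expect_equal(h$contrast, 1)
  expect_equal(h$correlation, -1)
  expect_equal(h$energy, 0.5)
  expect_equal(h$homogeneity, 0.5)
})

test_that("single-cell GLCM: correlation is undefined, not fabricated", {
  q <- quantize(matrix(0, 4, 4), L = 2)  # degenerate quantization is fine here
  m <- cooccurrence(q, 0, 1)
  h <- haralick(m)
  expect_equal(h$contrast, 0)
  expect_equal(h$energy, 1)
  expect_equal(h$homogeneity, 1)
  expect_true(is.na(h$correlation))
})

test_that("counts and measures match the brute-force oracle", {
  set.seed(31)
  for (rep in 1:30) {
    lev <- matrix(sample(0:3, 64, replace = TRUE), 8, 8)
    q <- structure(list(levels = lev, L = 4L, degenerate = FALSE,
                        source_range = c(0, 3), range_mode = "per_image",
                        pixel_size_um = 1), class = "quantized_image")
    for (a in c(0, 45, 90, 135)) {
      d <- sample(1:3, 1)
      m <- cooccurrence(q, a, d)
      expect_identical(m$counts, oracle_glcm(lev, 4L, a, d))
      h <- haralick(m)
      o <- oracle_haralick(m$counts)
      for (k in c("contrast", "correlation", "energy", "homogeneity")) {
        expect_equal(h[[k]], o[[k]], tolerance = 1e-12)
      }
    }
  }
})

test_that("normalised GLCM sums to one and profiles form a complete grid", {
  set.seed(4)
  img <- matrix(runif(64 * 64), 64, 64)
  m <- cooccurrence(quantize(img), 45, 3)
  expect_equal(sum(haralick(m)$p), 1, tolerance = 1e-12)
  tp <- texture_profile(img, D = 10)
  expect_equal(dim(tp$values), c(4, 4, 10))
  expect_false(anyNA(tp$values))
  v <- profile_vector(tp)
  expect_length(v, 4 * 4 * 10)
  expect_equal(unname(v["contrast_a0_d3"]),
               haralick(cooccurrence(quantize(img), 0, 3))$contrast)
  td <- as.data.frame(tp)
  expect_equal(td$value, unname(v))
})

test_that("vertical stripes give unit correlation along 90 degrees", {
  img <- matrix(rep(runif(40), each = 64), 64, 40)  # constant down columns
  tp <- texture_profile(img, D = 5)
  expect_true(all(abs(tp$values["correlation", "90", ] - 1) < 1e-9))
})

test_that("white-noise correlation vanishes at distance", {
  vals <- replicate(20, {
    img <- matrix(runif(64 * 64), 64, 64)
    tp <- texture_profile(img, D = 5)
    mean(abs(tp$values["correlation", , 3:5]))
  })
  expect_lt(mean(vals), 0.05)
})

test_that("degenerate images are refused by texture_profile", {
  expect_error(texture_profile(matrix(1, 64, 64), D = 5), "degenerate")
})

test_that("exact 90-degree rotation swaps 0/90 and 45/135 curves", {
  set.seed(9)
  img <- gen_fibre_image(fibre_field_params(image_size = 64, n_fibres = 30,
                                            kappa = 8, seed = 9))$image
  rot <- t(img)[, rev(seq_len(nrow(img)))]  # lossless 90-degree rotation
  a <- texture_profile(img, D = 6)$values
  b <- texture_profile(rot, D = 6)$values
  expect_equal(a[, "0", ], b[, "90", ], tolerance = 1e-12)
  expect_equal(a[, "90", ], b[, "0", ], tolerance = 1e-12)
  expect_equal(a[, "45", ], b[, "135", ], tolerance = 1e-12)
  expect_equal(a[, "135", ], b[, "45", ], tolerance = 1e-12)
})

test_that("intensity shifts do not change the texture profile", {
  set.seed(12)
  img <- matrix(runif(64 * 64), 64, 64)
  a <- texture_profile(img, D = 4)$values
  b <- texture_profile(img + 37.5, D = 4)$values
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("dominant-axis correction is a fixed point for vertical fibres", {
  p <- fibre_field_params(image_size = 256, n_fibres = 80, kappa = 1e6,
                          mean_angle_deg = 0, undulation_amplitude_px = 1,
                          seed = 21)
  al <- align_dominant_axis(gen_fibre_image(p)$image)
  expect_lt(abs(al$applied_rotation_deg), 1)
  expect_false(al$anisotropy_flag)
})

test_that("tilted fibres are rotated back and verified", {
  p <- fibre_field_params(image_size = 192, n_fibres = 70, kappa = 1e6,
                          mean_angle_deg = 60, seed = 22)
  al <- align_dominant_axis(gen_fibre_image(p)$image)
  expect_lt(abs(al$applied_rotation_deg - (-60)), 2)
  expect_true(al$verified)
  q <- quantize(al$image)
  cors <- vapply(c(0, 45, 90, 135), function(a) {
    haralick(cooccurrence(q, a, 4))$correlation
  }, numeric(1))
  expect_equal(which.max(cors), 3L)
})

test_that("isotropic noise sets the anisotropy flag and is left unrotated", {
  set.seed(30)
  img <- matrix(runif(128 * 128), 128, 128)
  al <- align_dominant_axis(img)
  expect_true(al$anisotropy_flag)
  expect_equal(al$applied_rotation_deg, 0)
})

test_that("feature matrices drop undefined features consistently", {
  set.seed(2)
  imgs <- replicate(3, matrix(runif(64 * 64), 64, 64), simplify = FALSE)
  fm <- texture_feature_matrix(imgs, align = FALSE, D = 5)
  expect_equal(nrow(fm$X), 3)
  expect_false(anyNA(fm$X))
})
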