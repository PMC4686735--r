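test_that("gaussian kernels are normalized, symmetric and correctly shaped", {
  for (sigma in c(0.5, 1, 10 / 3)) {
    for (r in c(1L, 3L, 5L)) {
      k <- gaussian_kernel(sigma, r)
      expect_equal(dim(k), c(2L * r + 1L, 2L * r + 1L))
      expect_lt(abs(sum(k) - 1), 1e-9)
      expect_equal(k, t(k), ignore_attr = TRUE)
      expect_equal(k, k[rev(seq_len(nrow(k))), rev(seq_len(ncol(k)))],
                   ignore_attr = TRUE)
      # centre is the maximum and weights decay with distance along axes
      expect_equal(which.max(k), (2L * r + 1L) * r + r + 1L)
      expect_true(all(diff(k[r + 1L, (r + 1L):(2L * r + 1L)]) < 0))
    }
  }
  # off-centre to centre ratio is renormalization-invariant: exp(-1/(2 sigma^2))
  k <- gaussian_kernel(1, 3)
  expect_equal(k[4L, 5L] / k[4L, 4L], exp(-0.5), tolerance = 1e-12)
  expect_error(gaussian_kernel(0), class = "rh_validation_error")
  expect_error(gaussian_kernel(1, 0), class = "rh_validation_error")
})

test_that("convolution preserves constants and reproduces impulse responses", {
  k <- gaussian_kernel(1, 3)
  const <- matrix(0.37, 9, 11)
  expect_equal(convolve_plane(const, k), const, tolerance = 1e-12)
  imp <- matrix(0, 15, 15)
  imp[8, 8] <- 1
  out <- convolve_plane(imp, k)
  expect_equal(out[5:11, 5:11], unclass(k)[7:1, 7:1], ignore_attr = TRUE,
               tolerance = 1e-14)
})

test_that("convolution matches the direct-sum oracle", {
  cases <- expand.grid(h = c(5L, 9L, 16L), w = c(7L, 16L), r = c(1L, 3L, 5L))
  for (i in seq_len(nrow(cases))) {
    h <- cases$h[i]; w <- cases$w[i]; r <- cases$r[i]
    p <- rand_plane(h, w, seed = 100 + i)
    k <- gaussian_kernel(r / 2, r)
    expect_lt(max(abs(convolve_plane(p, k) - conv_oracle(p, k))), 1e-10)
  }
})

test_that("convolution is linear", {
  k <- gaussian_kernel(0.8, 2)
  a <- rand_plane(12, 10, 1)
  b <- rand_plane(12, 10, 2)
  expect_equal(convolve_plane(a + b, k),
               convolve_plane(a, k) + convolve_plane(b, k), tolerance = 1e-10)
  expect_equal(convolve_plane(3.7 * a, k), 3.7 * convolve_plane(a, k),
               tolerance = 1e-10)
})

test_that("convolution is equivariant under flips for symmetric kernels", {
  k <- gaussian_kernel(1, 2)
  p <- rand_plane(11, 11, 3)
  flip <- function(m) m[rev(seq_len(nrow(m))), ]
  expect_equal(convolve_plane(flip(p), k), flip(convolve_plane(p, k)),
               tolerance = 1e-12)
  expect_equal(convolve_plane(t(p), k), t(convolve_plane(p, k)),
               tolerance = 1e-12)
})

test_that("oversized kernels are rejected", {
  p <- matrix(runif(9), 3, 3)
  expect_error(convolve_plane(p, gaussian_kernel(2, 4)),
               class = "rh_structural_error")
})

test_that("joint-maximum normalization rescales all channels together", {
  img <- array(0, dim = c(2, 2, 3))
  img[, , 1] <- 0.5; img[, , 2] <- 0.25; img[, , 3] <- 0.1
  out <- normalize_joint_max(img)
  expect_equal(max(out[, , 1]), 1)
  expect_equal(max(out[, , 2]), 0.5)
  expect_equal(max(out[, , 3]), 0.2)
  # already normalized image is unchanged; constants map to 1
  expect_equal(normalize_joint_max(out), out)
  expect_equal(normalize_joint_max(array(0.4, c(3, 3, 3))),
               array(1, c(3, 3, 3)))
  expect_error(normalize_joint_max(array(0, c(2, 2, 3))),
               class = "rh_degenerate_error")
})

test_that("image round trips through PNG, TIFF and PPM preserve values", {
  img <- rand_image(9, 7, 42)
  for (ext in c("png", "tiff", "ppm")) {
    path <- file.path(tempdir(), paste0("roundtrip.", ext))
    save_image(img, path)
    back <- load_image(path)
    expect_equal(dim(back), dim(img))
    expect_lt(max(abs(back - img)), 1 / 255)  # 8-bit quantization
  }
  # 16-bit PPM is near-exact
  path16 <- file.path(tempdir(), "roundtrip16.ppm")
  save_image(img, path16, bits = 16L)
  expect_lt(max(abs(load_image(path16) - img)), 1 / 65535)
})

test_that("grayscale images are replicated to three identical planes", {
  path <- file.path(tempdir(), "gray.png")
  png::writePNG(matrix(c(0, 1, 0.5, 0.25), 2, 2), path)
  img <- load_image(path)
  expect_equal(dim(img), c(2L, 2L, 3L))
  expect_identical(img[, , 1], img[, , 2])
  expect_identical(img[, , 1], img[, , 3])
  # full-scale and zero 8-bit pixels map to exactly 1 and 0
  expect_equal(sort(unique(as.vector(img))), c(0, 64, 128, 255) / 255)
})

test_that("ASCII PPM files are parsed", {
  path <- file.path(tempdir(), "ascii.ppm")
  writeLines(c("P3", "# comment", "2 1", "255", "255 0 0   0 128 255"), path)
  img <- load_image(path)
  expect_equal(img[1, 1, ], c(1, 0, 0))
  expect_equal(img[1, 2, ], c(0, 128 / 255, 1))
})

test_that("unreadable and unsupported files raise I/O errors", {
  expect_error(load_image(file.path(tempdir(), "nope.png")),
               class = "rh_io_error")
  bad <- file.path(tempdir(), "bad.xyz")
  writeLines("x", bad)
  expect_error(load_image(bad), class = "rh_io_error")
})
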