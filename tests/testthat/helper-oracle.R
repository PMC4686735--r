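# Independent brute-force oracle for the convolution contract: a direct
# double-loop sum over the mirror-padded neighbourhood.  Deliberately naive
# and kept free of any code shared with convolve_plane().

reflect_index <- function(i, n) {
  if (i < 1L) return(1L - i)
  if (i > n) return(2L * n + 1L - i)
  i
}

conv_oracle <- function(plane, kernel) {
  H <- nrow(plane)
  W <- ncol(plane)
  r <- (nrow(kernel) - 1L) %/% 2L
  out <- matrix(0, H, W)
  for (x in seq_len(H)) {
    for (y in seq_len(W)) {
      acc <- 0
      for (di in -r:r) {
        for (dj in -r:r) {
          acc <- acc + kernel[di + r + 1L, dj + r + 1L] *
            plane[reflect_index(x + di, H), reflect_index(y + dj, W)]
        }
      }
      out[x, y] <- acc
    }
  }
  out
}

# Small deterministic random helpers
rand_plane <- function(h, w, seed) {
  set.seed(seed)
  matrix(runif(h * w), h, w)
}

rand_image <- function(h, w, seed) {
  set.seed(seed)
  array(runif(h * w * 3), dim = c(h, w, 3L))
}

# Mean local standard deviation of a plane over odd square windows,
# computed from box-filter moments.
mean_local_sd <- function(plane, window = 5L) {
  box <- matrix(1 / window^2, window, window)
  m1 <- conv_oracle_box(plane, box)
  m2 <- conv_oracle_box(plane^2, box)
  mean(sqrt(pmax(m2 - m1^2, 0)))
}

# box filtering via the package convolution (the quantity under test is the
# image, not the filter)
conv_oracle_box <- function(plane, box) {
  convolve_plane(plane, box)
}

luminance_of <- function(img) {
  (img[, , 1L] + img[, , 2L] + img[, , 3L]) / 3
}
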