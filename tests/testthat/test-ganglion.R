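test_that("ganglion parameter invariants are enforced", {
  expect_error(ganglion_params(r_cen = 0), class = "rh_validation_error")
  expect_error(ganglion_params(r_sur = 1, r_cen = 1),
               class = "rh_validation_error")
  expect_error(ganglion_params(A_cen = 0), class = "rh_validation_error")
  expect_error(ganglion_params(A_u = -0.1), class = "rh_validation_error")
  p <- ganglion_params(r_cen = 3, r_sur = 10, r_sub = 3)
  expect_equal(p$sigma_cen, 1)
  expect_equal(p$sigma_sur, 10 / 3)
  expect_equal(p$sigma_sub, 1)
})

test_that("subunit response reduces to the input when A_u = 0", {
  p <- rand_plane(9, 9, 50)
  expect_identical(subunit_response(p, ganglion_params(A_u = 0)), p)
})

test_that("a constant plane fully self-inhibits at A_u = 1", {
  const <- matrix(0.7, 10, 10)
  out <- subunit_response(const, ganglion_params(A_u = 1))
  expect_equal(out, matrix(0, 10, 10), tolerance = 1e-12)
})

test_that("subunit response matches the direct-sum oracle", {
  p <- rand_plane(9, 9, 51)
  params <- ganglion_params(r_sub = 2, A_u = 0.5)
  expected <- pmax(p - 0.5 * conv_oracle(p, gaussian_kernel(2 / 3, 2)), 0)
  expect_lt(max(abs(subunit_response(p, params) - expected)), 1e-10)
})

test_that("surround pooling preserves constants and total impulse mass", {
  params <- ganglion_params()
  const <- matrix(0.42, 9, 9)
  expect_equal(surround_pool(const, params), const, tolerance = 1e-12)
  expect_equal(surround_pool(matrix(0, 7, 7), params), matrix(0, 7, 7))
  imp <- matrix(0, 15, 15)
  imp[8, 8] <- 1
  blob <- surround_pool(imp, params)
  expect_equal(sum(blob), 1, tolerance = 1e-12)
  expect_equal(which.max(blob), 113L)  # column-major (8, 8) in 15 x 15
})

test_that("opponent subtraction behaves at its limits", {
  params <- ganglion_params(A_cen = 2, A_s = 2)
  centre <- rand_plane(8, 8, 52)
  zero <- matrix(0, 8, 8)
  # no surround: pure (scaled, blurred) excitation
  expect_equal(ganglion_opponent(centre, zero, params),
               2 * convolve_plane(centre, gaussian_kernel(1 / 3, 1)),
               tolerance = 1e-12)
  # no centre: rectified to zero
  expect_equal(ganglion_opponent(zero, centre, params), zero)
  # equal constants with A_s >= 1: full suppression
  const <- matrix(0.5, 8, 8)
  expect_equal(ganglion_opponent(const, const, params), zero)
  expect_error(ganglion_opponent(centre, matrix(0, 4, 4), params),
               class = "rh_structural_error")
})

make_mbp <- function(h, w, seed) {
  set.seed(seed)
  chans <- c("R", "G", "B", "Y")
  list(
    on = lapply(setNames(nm = chans), function(ch) matrix(runif(h * w), h, w)),
    off = lapply(setNames(nm = chans), function(ch) matrix(runif(h * w), h, w))
  )
}

test_that("ganglion layer wires the single-opponent channels", {
  mbp <- make_mbp(10, 10, 60)
  params <- ganglion_params()
  gc <- ganglion_layer(mbp, params, params)
  expect_named(gc$on, c("R", "G", "B"))
  expect_named(gc$off, c("R", "G", "B"))
  # R centre is inhibited by the pooled G subunits, B by Y
  s_g <- surround_pool(subunit_response(mbp$on$G, params), params)
  expect_equal(gc$on$R, ganglion_opponent(mbp$on$R, s_g, params))
  s_y <- surround_pool(subunit_response(mbp$on$Y, params), params)
  expect_equal(gc$on$B, ganglion_opponent(mbp$on$B, s_y, params))
  # OFF polarity uses the OFF planes for centre and surround alike
  s_r_off <- surround_pool(subunit_response(mbp$off$R, params), params)
  expect_equal(gc$off$G, ganglion_opponent(mbp$off$G, s_r_off, params))
  expect_true(all(vapply(c(gc$on, gc$off), function(p) all(p >= 0), TRUE)))
  mbp$on$Y <- NULL
  expect_error(ganglion_layer(mbp, params, params),
               class = "rh_structural_error")
})

test_that("uniform input passes through the full stack to constant outputs", {
  img <- array(0.5, dim = c(24, 24, 3))
  pr <- photoreceptor_layer(normalize_joint_max(img))
  bp <- bipolar_layer(pr)
  mbp <- amacrine_modulate(bp)
  gc <- ganglion_layer(mbp)
  for (p in c(gc$on, gc$off)) {
    expect_lt(diff(range(p)), 1e-12)
  }
})

test_that("strong classical surround without disinhibition suppresses the output", {
  mbp <- make_mbp(12, 12, 61)
  weak <- ganglion_layer(mbp, ganglion_params(A_u = 0, A_s = 8),
                         ganglion_params(A_u = 0, A_s = 8))
  strong <- ganglion_layer(mbp, ganglion_params(A_u = 0.9, A_s = 8),
                           ganglion_params(A_u = 0.9, A_s = 8))
  expect_lt(mean(weak$on$R), mean(strong$on$R))
  expect_lt(max(weak$on$R), 1e-6)
})

test_that("responses are non-decreasing in the subunit sensitivity", {
  mbp <- make_mbp(12, 12, 62)
  resp <- lapply(c(0, 0.3, 0.6, 0.9), function(au) {
    params <- ganglion_params(A_u = au)
    ganglion_layer(mbp, params, params)$on$R
  })
  for (i in seq_len(length(resp) - 1L)) {
    expect_true(all(resp[[i + 1L]] - resp[[i]] >= -1e-12))
  }
})
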