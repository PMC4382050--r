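rev2 <- function(m) m[nrow(m):1, ncol(m):1]

test_that("log-norm quadrature kernels satisfy their symmetry and DC invariants", {
  pp <- phase_params()
  for (n in 1:2) {
    for (th in pp$orientations) {
      f <- make_lognorm_quadrature(n, th, pp)
      expect_lt(max(abs(f$even - rev2(f$even))), 1e-6)   # point symmetry
      expect_lt(max(abs(f$odd + rev2(f$odd))), 1e-6)     # antisymmetry
      expect_lt(abs(sum(f$even)), 1e-3 * max(abs(f$even)))
      expect_lt(abs(sum(f$odd)), 1e-3 * max(abs(f$odd)))
    }
  }
})

test_that("realized response peak sits near the design center frequency", {
  f <- make_lognorm_quadrature(1, 0, phase_params())
  G <- 256
  km <- matrix(0 + 0i, G, G)
  km[1:15, 1:15] <- f$even + 1i * f$odd
  fr <- 2 * pi * ifelse(0:(G - 1) < G / 2, 0:(G - 1), 0:(G - 1) - G) / G
  rho <- sqrt(outer(fr^2, fr^2, "+"))
  peak <- rho[which.max(Mod(fft(km)))]
  expect_lt(abs(peak - 5 * pi / 7) / (5 * pi / 7), 0.15)
})

test_that("rotating the orientation by 90 degrees transposes the kernels", {
  f0 <- make_lognorm_quadrature(1, 0, phase_params())
  f90 <- make_lognorm_quadrature(1, pi / 2, phase_params())
  expect_lt(max(abs(f90$even - t(f0$even))), 1e-12)
  expect_lt(min(max(abs(f90$odd - t(f0$odd))),
                max(abs(f90$odd + t(f0$odd)))), 1e-12)
})

test_that("FFT convolution equals direct spatial convolution with mirrored borders", {
  set.seed(1)
  img <- matrix(runif(256), 16, 16)
  ker <- matrix(rnorm(25), 5, 5) + 1i * matrix(rnorm(25), 5, 5)
  expect_equal(conv2_reflect(img, ker), conv_oracle(img, ker), tolerance = 1e-8)
  expect_error(conv2_reflect(matrix(0.1, 4, 4), matrix(1, 5, 5)), "fit")
})

test_that("quadrature responses behave as designed on canonical structures", {
  f <- make_lognorm_quadrature(1, 0, phase_params())
  # constant image: DC-free kernels respond with ~0
  cst <- matrix(0.6, 30, 30)
  q0 <- apply_quadrature(cst, f)
  expect_lt(max(Mod(q0)), 1e-10)
  # step edge (vertical, variation along columns): |o| peaks at the edge,
  # e changes sign across it (zero crossing at the edge)
  img <- cbind(matrix(0, 40, 30), matrix(1, 40, 30))
  q <- apply_quadrature(img, f)
  expect_true(which.max(abs(Im(q[20, ]))) %in% c(30L, 31L))
  expect_lt(Re(q[20, 30]) * Re(q[20, 31]), 0)
  expect_lt(abs(Re(q[20, 30]) + Re(q[20, 31])), 1e-8)  # antisymmetric about edge
  # thin bright line: |e| peaks on the line with positive sign, o ~ 0 there
  img2 <- matrix(0, 40, 60); img2[, 30] <- 1
  q2 <- apply_quadrature(img2, f)
  expect_equal(which.max(abs(Re(q2[20, ]))), 30L)
  expect_gt(Re(q2[20, 30]), 0)
  expect_lt(abs(Im(q2[20, 30])), 1e-8)
})

test_that("local energy and phase match their definitions", {
  q <- matrix(complex(real = c(3, 1, 0), imaginary = c(4, 0, 0)), 1, 3)
  ep <- local_energy_and_phase(q)
  expect_equal(as.vector(ep$energy), c(5, 1, 0))
  expect_equal(as.vector(ep$phase), c(atan2(4, 3), 0, 0))
  set.seed(4)
  qr <- matrix(complex(real = rnorm(36), imaginary = rnorm(36)), 6, 6)
  ep2 <- local_energy_and_phase(qr)
  for (k in seq_along(qr)) {
    expect_equal(ep2$energy[k], sqrt(Re(qr[k])^2 + Im(qr[k])^2))
    expect_equal(ep2$phase[k], atan2(Im(qr[k]), Re(qr[k])))
  }
})

test_that("orientation combination rectifies the odd part and sums responses", {
  e <- matrix(rnorm(16), 4, 4); o <- -abs(matrix(rnorm(16), 4, 4))
  q <- complex(real = e, imaginary = o); dim(q) <- c(4, 4)
  single <- combine_orientations(list(q))
  expect_equal(Im(single), abs(o))
  expect_equal(combine_orientations(list(q, q, q)), 3 * single)
  set.seed(5)
  qs <- replicate(4, matrix(complex(real = rnorm(16), imaginary = rnorm(16)), 4, 4),
                  simplify = FALSE)
  acc <- matrix(0 + 0i, 4, 4)
  for (qq in qs) acc <- acc + complex(real = Re(qq), imaginary = abs(Im(qq)))
  expect_equal(combine_orientations(qs), acc)
})

test_that("scale combination is the magnitude-weighted normalized sum", {
  set.seed(6)
  q1 <- matrix(complex(real = rnorm(25), imaginary = rnorm(25)), 5, 5)
  expect_equal(combine_scales(list(q1), beta = 1), q1)  # single scale identity
  zero <- matrix(0 + 0i, 5, 5)
  expect_equal(combine_scales(list(q1, zero), beta = 1), q1)
  q2 <- matrix(complex(real = rnorm(25), imaginary = rnorm(25)), 5, 5)
  q3 <- matrix(complex(real = rnorm(25), imaginary = rnorm(25)), 5, 5)
  P <- combine_scales(list(q1, q2, q3), beta = 1)
  for (k in seq_along(P)) {  # scalar oracle
    w <- c(Mod(q1[k]), Mod(q2[k]), Mod(q3[k]))
    expect_equal(P[k], (q1[k] * w[1] + q2[k] * w[2] + q3[k] * w[3]) / sum(w))
  }
  expect_true(all(Mod(P) <= pmax(Mod(q1), Mod(q2), Mod(q3)) + 1e-12))
})

test_that("vesselness normalization attains 1/2 at |P| = a and is sign-faithful", {
  a <- 0.3
  expect_equal(vesselness(matrix(a + 0i, 1, 1), a)[1, 1], 0.5)
  expect_equal(vesselness(matrix(0 + 0i, 1, 1), a)[1, 1], 0)
  set.seed(8)
  P <- matrix(complex(real = rnorm(64), imaginary = rnorm(64)), 8, 8)
  lp <- vesselness(P, max(Mod(P)))
  expect_true(all(abs(lp) <= 0.5 + 1e-12))
  expect_true(all(sign(lp) == sign(Re(P))))
  expect_error(vesselness(P, -1), "positive")
})

test_that("enhancement is positive in tubes, negative in background, bounded by 1/2", {
  ph <- vessel_phantom(fig_phantom_spec(seed = 3, noise_sigma = 0))
  vm <- enhance(ph$image)
  expect_true(all(abs(vm$map) <= 0.5 + 1e-9))
  expect_gt(mean(vm$map[ph$truth == 1]), 0)
  expect_lt(mean(vm$map[ph$truth == 0]), 0)
  # constant image maps to ~0 everywhere
  expect_lt(max(abs(enhance(matrix(0.5, 32, 32))$map)), 1e-8)
})

test_that("tube ends respond at least half as strongly as the tube middle", {
  sp <- phantom_spec(60, 80,
                     data.frame(r0 = 30, c0 = 15, r1 = 30, c1 = 60,
                                width = 4, contrast = 0.8),
                     background = 0.1, noise_sigma = 0)
  ph <- vessel_phantom(sp)
  lp <- enhance(ph$image)$map
  end_resp <- mean(lp[30, 58:60])
  mid_resp <- mean(lp[30, 30:45])
  expect_gte(end_resp, 0.5 * mid_resp)
})

test_that("enhancement commutes with 90-degree rotation for the default bank", {
  set.seed(5)
  img <- matrix(runif(48 * 48), 48, 48)
  pp <- phase_params(a = 0.3)  # fixed a so both paths use the same constant
  e1 <- enhance(img, pp)$map
  e2 <- enhance(rot90ccw(img), pp)$map
  expect_lt(max(abs(e2 - rot90ccw(e1))), 1e-6)
})
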