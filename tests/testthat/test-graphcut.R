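test_that("region means follow their definition with the empty-region fallback", {
  checker <- outer(1:4, 1:4, function(i, j) (i + j) %% 2)
  m <- region_means(checker, checker)
  expect_equal(m$c1, 1); expect_equal(m$c2, 0)
  set.seed(1)
  img <- matrix(runif(36), 6, 6)
  all1 <- matrix(1, 6, 6)
  m2 <- region_means(img, all1)
  expect_equal(m2$c1, mean(img)); expect_equal(m2$c2, mean(img))  # fallback
  lab <- matrix(sample(0:1, 36, TRUE) + 0, 6, 6)
  m3 <- region_means(img, lab)
  expect_equal(m3$c1, mean(img[lab == 1]))
  expect_equal(m3$c2, mean(img[lab == 0]))
})

test_that("Cauchy-Crofton neighbor weights match the geo-cuts discretization", {
  w4 <- neighbor_weights(c(3, 3), connectivity = 4)
  expect_true(all(abs(w4$w - pi / 4) < 1e-12))
  expect_equal(nrow(w4), 12L)  # 2 * 3 * 2 edges on a 3x3 grid
  w8 <- neighbor_weights(c(4, 4), connectivity = 8)
  ax <- w8$w[abs(w8$w - pi / 8) < 1e-12]
  dg <- w8$w[abs(w8$w - pi / (8 * sqrt(2))) < 1e-12]
  expect_equal(length(ax) + length(dg), nrow(w8))
  expect_equal((pi / 8) / (pi / (8 * sqrt(2))), sqrt(2))
  # an isolated foreground pixel pays ~its true perimeter under 4-connectivity
  expect_equal(4 * pi / 4, pi)
  expect_error(neighbor_weights(c(3, 3), connectivity = 6), "connectivity")
})

test_that("min cut with mu = 0 is the per-pixel argmin with ties to background", {
  img <- matrix(c(0.1, 0.5, 0.9, 0.5), 2, 2)
  en <- cv_energy(img, c1 = 0.9, c2 = 0.1, cv_params(lambda1 = 1, lambda2 = 1, mu = 0))
  cut <- min_cut(en)
  manual <- (en$cost1 < en$cost0) + 0   # ties (0.5 pixels) -> 0
  expect_equal(as.vector(cut$labeling), manual)
  expect_equal(cut$labeling[2, 1], 0)   # tied pixel resolved to background
  expect_equal(cut$labeling[2, 2], 0)
})

test_that("min cut returns the exhaustive minimum on seeded 3x3 instances", {
  for (s in 1:10) {
    set.seed(s)
    img <- matrix(runif(9), 3, 3)
    p <- cv_params(lambda1 = runif(1, 0.2, 2), lambda2 = runif(1, 0.2, 2),
                   mu = runif(1, 0, 0.5),
                   connectivity = sample(c(4L, 8L), 1))
    en <- cv_energy(img, runif(1), runif(1), p)
    expect_equal(min_cut(en)$energy, enumerate_min(en), tolerance = 1e-9)
  }
})

test_that("min cut agrees with an independent max-flow implementation", {
  skip_if_not_installed("igraph")
  set.seed(3)
  img <- matrix(runif(36), 6, 6)
  en <- cv_energy(img, 0.7, 0.3, cv_params(lambda1 = 1, lambda2 = 2, mu = 0.1))
  M <- 36L
  el <- rbind(cbind(rep(M + 1L, M), 1:M), cbind(1:M, rep(M + 2L, M)),
              cbind(en$pairs$i, en$pairs$j), cbind(en$pairs$j, en$pairs$i))
  cap <- c(en$cost0, en$cost1, en$pairs$w, en$pairs$w)
  g <- igraph::add_edges(igraph::make_empty_graph(M + 2L, directed = TRUE), t(el))
  mf <- igraph::max_flow(g, M + 1L, M + 2L, capacity = cap)
  expect_equal(min_cut(en)$energy, mf$value, tolerance = 1e-9)
})

test_that("uniform unaries admit a constant minimizer under any mu", {
  en <- cv_energy(matrix(0.5, 3, 3), 0.7, 0.3, cv_params(mu = 2))
  cut <- min_cut(en)
  expect_equal(length(unique(as.vector(cut$labeling))), 1L)
  expect_equal(cut$energy, sum(pmin(en$cost0, en$cost1)))
})

test_that("a noise-free two-region disk is recovered exactly", {
  tr <- two_region_phantom(c(64, 64))
  seg <- segment_cv_graphcut(tr$image, cv_params(lambda1 = 1, lambda2 = 1, mu = 0.02))
  expect_identical(seg$labeling, tr$mask)
  expect_lte(seg$n_iter, 30L)
})

test_that("an overwhelming length penalty forces a constant labeling", {
  tr <- two_region_phantom(c(32, 32))
  seg <- segment_cv_graphcut(tr$image, cv_params(mu = 1e6))
  expect_equal(length(unique(as.vector(seg$labeling))), 1L)
})

test_that("the energy trace is non-increasing and runs are deterministic", {
  for (s in 1:5) {
    set.seed(s)
    tr <- two_region_phantom(c(40, 40), fg = 0.8, bg = 0.2)
    noisy <- clamp_img <- pmin(pmax(tr$image + matrix(rnorm(1600, sd = 0.15), 40, 40), 0), 1)
    seg <- segment_cv_graphcut(noisy)
    expect_true(all(diff(seg$energy_trace) <= 1e-9))
    seg2 <- segment_cv_graphcut(noisy)
    expect_identical(seg$labeling, seg2$labeling)
  }
})

test_that("degenerate constant input yields an all-background labeling with warning", {
  expect_warning(seg <- segment_cv_graphcut(matrix(0.4, 8, 8)), "variation")
  expect_true(all(seg$labeling == 0))
})

test_that("the field-of-view mask forces outside pixels to background", {
  tr <- two_region_phantom(c(32, 32))
  fov <- matrix(0, 32, 32); fov[1:16, ] <- 1
  seg <- segment_cv_graphcut(tr$image, cv_params(lambda1 = 1, lambda2 = 1, mu = 0.02),
                             fov = fov)
  expect_true(all(seg$labeling[fov == 0] == 0))
})

test_that("parameter validation rejects invalid CV settings", {
  expect_error(cv_params(lambda1 = -1), "non-negative")
  expect_error(cv_params(connectivity = 5), "connectivity")
  expect_error(cv_params(tol = 0), "tol")
})
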