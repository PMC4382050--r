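# Independent oracles and shared fixtures, all generated in code.

# explicit-loop bilateral illumination (normalized-domain spatial distance,
# window clipped at borders) — kept deliberately naive
bilateral_oracle <- function(img, sigma_d = 0.3, sigma_r = 0.3, window = 3L) {
  h <- (window - 1L) %/% 2L
  nr <- nrow(img); nc <- ncol(img)
  dscale <- sqrt(nr^2 + nc^2)
  out <- matrix(0, nr, nc)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      num <- 0; den <- 0
      for (rr in max(1, r - h):min(nr, r + h)) {
        for (cc in max(1, c - h):min(nc, c + h)) {
          g <- exp(-0.5 * ((rr - r)^2 + (cc - c)^2) / (dscale * sigma_d)^2)
          s <- exp(-0.5 * ((img[rr, cc] - img[r, c]) / sigma_r)^2)
          num <- num + img[rr, cc] * g * s
          den <- den + g * s
        }
      }
      out[r, c] <- num / den
    }
  }
  out
}

# direct spatial convolution with mirrored borders (kernel flipped)
conv_oracle <- function(img, ker) {
  h <- (nrow(ker) - 1L) %/% 2L
  nr <- nrow(img); nc <- ncol(img)
  refl <- function(i, n) ifelse(i < 1L, 1L - i, ifelse(i > n, 2L * n + 1L - i, i))
  out <- matrix(0 + 0i, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    s <- 0 + 0i
    for (dr in -h:h) for (dc in -h:h)
      s <- s + img[refl(r - dr, nr), refl(c - dc, nc)] * ker[dr + h + 1L, dc + h + 1L]
    out[r, c] <- s
  }
  if (is.complex(ker)) out else Re(out)
}

# exhaustive minimizer of a discrete energy on tiny grids
enumerate_min <- function(energy) {
  M <- prod(energy$shape)
  stopifnot(M <= 12L)
  best <- Inf
  for (k in 0:(2^M - 1)) {
    x <- as.integer(intToBits(k))[seq_len(M)]
    e <- sum(energy$cost0[x == 0]) + sum(energy$cost1[x == 1]) +
      sum(energy$pairs$w[x[energy$pairs$i] != x[energy$pairs$j]])
    if (e < best) best <- e
  }
  best
}

rot90ccw <- function(m) t(m)[ncol(m):1, , drop = FALSE]

# retinal-style phantom: thin low-contrast vessels, optional shading/disc
retinal_phantom <- function(seed = 3L, noise_sigma = 0.01, shading = NULL,
                            with_disc = FALSE) {
  vessel_phantom(retinal_phantom_spec(seed = seed, noise_sigma = noise_sigma,
                                      shading = shading,
                                      with_disc = with_disc))
}
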