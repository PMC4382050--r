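#' Parameters for bilateral-filter Retinex correction
#'
#' The Retinex model decomposes an image into reflectance and illumination,
#' `I = R * L`. The illumination is estimated with a bilateral filter whose
#' weights are Gaussians of spatial distance (spread `sigma_d`, in pixels)
#' and of intensity difference (spread `sigma_r`, on the `[0, 1]` intensity
#' scale), evaluated over a square window. Defaults: `sigma_d = sigma_r = 0.3`
#' and a 3x3 window.
#'
#' @param sigma_d spatial Gaussian spread in pixels, `> 0`.
#' @param sigma_r intensity-range Gaussian spread on `[0, 1]`, `> 0`.
#' @param window odd window side length `>= 3`.
#' @return a `retinex_params` list.
#' @export
retinex_params <- function(sigma_d = 0.3, sigma_r = 0.3, window = 3L) {
  window <- as.integer(window)
  if (sigma_d <= 0 || sigma_r <= 0)
    stop("sigma_d and sigma_r must be strictly positive", call. = FALSE)
  if (window < 3L || window %% 2L == 0L)
    stop("window must be an odd integer >= 3", call. = FALSE)
  structure(list(sigma_d = sigma_d, sigma_r = sigma_r, window = window),
            class = "retinex_params")
}

# shift a matrix by (dr, dc), exposing NA outside the original support
shift_matrix <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(NA_real_, nr, nc)
  rs <- seq_len(nr) - dr
  cs <- seq_len(nc) - dc
  ok_r <- rs >= 1L & rs <= nr
  ok_c <- cs >= 1L & cs <= nc
  out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
  out
}

#' Bilateral-filter illumination estimate
#'
#' Computes, at every pixel `x`, the normalized bilateral average
#' `L(x) = M(x)^-1 * sum_l I(l) g(l, x) s(l, x)` over the window, where
#' `g = exp(-d(l,x)^2 / (2 sigma_d^2))` weights spatial closeness
#' (Euclidean pixel distance) and `s = exp(-(I(l)-I(x))^2 / (2 sigma_r^2))`
#' weights intensity similarity; `M` is the sum of the weights, so they sum
#' to one after normalization. At image borders the window is clipped and
#' `M` renormalizes automatically. Each output value is a convex
#' combination of the input values in its window, so it stays within their
#' range; a constant image is a fixed point.
#'
#' @param img intensity matrix in `[0, 1]`.
#' @param params a [retinex_params()] object.
#' @return illumination matrix, same shape as `img`.
#' @export
bilateral_illumination <- function(img, params = retinex_params()) {
  check_unit_image(img)
  stopifnot(inherits(params, "retinex_params"))
  w <- params$window
  if (w > nrow(img) && w > ncol(img))
    stop("window larger than both image dimensions", call. = FALSE)
  h <- (w - 1L) %/% 2L
  # spatial distances on the unit-normalized image domain, mirroring the
  # unit-normalized intensity scale of sigma_r; with sigma_d ~ 0.3 the
  # spatial kernel is nearly flat inside a small window and the range
  # kernel provides the edge-preserving selectivity
  dscale <- sqrt(nrow(img)^2 + ncol(img)^2)
  num <- matrix(0, nrow(img), ncol(img))
  den <- matrix(0, nrow(img), ncol(img))
  for (dr in -h:h) {
    for (dc in -h:h) {
      g <- exp(-0.5 * (dr * dr + dc * dc) / (dscale * params$sigma_d)^2)
      sh <- shift_matrix(img, dr, dc)
      s <- exp(-0.5 * ((sh - img) / params$sigma_r)^2)
      wgt <- g * s
      wgt[is.na(sh)] <- 0
      sh[is.na(sh)] <- 0
      num <- num + sh * wgt
      den <- den + wgt
    }
  }
  num / den
}

#' Log-reflectance of an image given its illumination
#'
#' The raw reflectance is the difference of logarithms
#' `R(x) = log(I(x) + 1) - log(L(x) + 1)` evaluated on the native 8-bit
#' intensity scale (values in 0..255), then min-max normalized to `[0, 1]`
#' per image. The scale matters: with intensities well above 1 the "+1"
#' only guards `log(0)` and the difference is the log *ratio* `log(I/L)`,
#' so multiplicative illumination cancels — the point of the Retinex
#' decomposition. (On `[0, 1]`-scaled intensities `log(1 + I)` is nearly
#' linear and the operator would degenerate to an additive residual that
#' retains shading.) If the raw reflectance is constant (e.g. a constant
#' input, where `L = I`), the normalization is degenerate and the
#' information-free midpoint image 0.5 is returned.
#'
#' @param img intensity matrix.
#' @param illum illumination matrix of the same shape (see
#'   [bilateral_illumination()]).
#' @return reflectance matrix in `[0, 1]`.
#' @export
reflectance <- function(img, illum) {
  check_image(img); check_image(illum, "illum")
  if (!identical(dim(img), dim(illum)))
    stop("img and illum must have the same shape", call. = FALSE)
  raw <- log(255 * img + 1) - log(255 * illum + 1)
  rng <- range(raw)
  if (diff(rng) < 1e-12)
    return(matrix(0.5, nrow(img), ncol(img)))
  (raw - rng[1]) / diff(rng)
}

#' Retinex intensity-inhomogeneity correction
#'
#' Composition of [bilateral_illumination()] and [reflectance()]: the
#' bilateral filter estimates the slowly-varying illumination while
#' preserving vessel edges, and the normalized log-reflectance is returned
#' as the corrected image. Output is in `[0, 1]`, with range exactly
#' `[0, 1]` for any non-constant input (min-max normalization) and the
#' all-0.5 image for a constant input.
#'
#' @inheritParams bilateral_illumination
#' @return corrected intensity matrix in `[0, 1]`.
#' @export
retinex_correct <- function(img, params = retinex_params()) {
  reflectance(img, bilateral_illumination(img, params))
}
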