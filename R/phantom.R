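#' Specification of a synthetic vessel phantom
#'
#' Describes a test image of vessel-like tubes: straight constant-intensity
#' bands of given width and contrast over a uniform background, optionally
#' shaded by a smooth multiplicative illumination field, with additive
#' Gaussian noise (default `sigma = 0.2`) clipped to `[0, 1]`. All
#' randomness is controlled by `seed`, making generators pure functions of
#' their spec.
#'
#' @param height,width image size in pixels.
#' @param segments data frame with one tube per row and columns `r0`, `c0`,
#'   `r1`, `c1` (endpoints, rows/cols), `width` (pixels, `>= 1`) and
#'   `contrast` (added intensity, in `(0, 1]`).
#' @param background background intensity level.
#' @param noise_sigma standard deviation of the additive Gaussian noise.
#' @param shading optional [shading_field()] matrix (or `NULL`).
#' @param blobs optional data frame of optic-disc-like structures, one per
#'   row, with columns `r`, `c` (center), `radius`, `contrast` and
#'   `edge_width` (pixels over which the rim ramps smoothly). Blobs mimic
#'   the large soft-edged bright regions of fundus images (optic disc);
#'   they are added to the image but never to the ground truth.
#' @param seed RNG seed.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(height, width, segments, background = 0.1,
                         noise_sigma = 0.2, shading = NULL, blobs = NULL,
                         seed = 1L) {
  stopifnot(is.data.frame(segments),
            all(c("r0", "c0", "r1", "c1", "width", "contrast") %in% names(segments)))
  if (any(segments$width < 1)) stop("tube widths must be >= 1", call. = FALSE)
  if (any(segments$contrast <= 0 | segments$contrast > 1))
    stop("contrasts must lie in (0, 1]", call. = FALSE)
  if (noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  if (background < 0 || background > 1)
    stop("background must lie in [0, 1]", call. = FALSE)
  if (!is.null(blobs))
    stopifnot(is.data.frame(blobs),
              all(c("r", "c", "radius", "contrast", "edge_width") %in% names(blobs)))
  structure(list(height = as.integer(height), width = as.integer(width),
                 segments = segments, background = background,
                 noise_sigma = noise_sigma, shading = shading, blobs = blobs,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# squared distance from every pixel center to the segment (r0,c0)-(r1,c1)
segment_dist2 <- function(nr, nc, r0, c0, r1, c1) {
  R <- matrix(seq_len(nr), nr, nc)
  C <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  vr <- r1 - r0; vc <- c1 - c0
  len2 <- vr * vr + vc * vc
  t <- ((R - r0) * vr + (C - c0) * vc) / len2
  t <- pmin(pmax(t, 0), 1)
  (R - (r0 + t * vr))^2 + (C - (c0 + t * vc))^2
}

#' Render a vessel-tube phantom with ground truth
#'
#' A pixel belongs to a tube when its center lies within `width/2` of the
#' segment axis (round caps at the endpoints). Tubes are drawn over the
#' background at intensity `background + contrast` (overlaps take the
#' larger value), then multiplied by the shading field (if any), then
#' Gaussian noise is added and the image clipped to `[0, 1]`. The ground
#' truth is fixed before shading and noise.
#'
#' @param spec a [phantom_spec()] object.
#' @return list with `image` (noisy intensity matrix), `truth` (0/1
#'   matrix), `clean` (noise-free, unshaded image).
#' @export
vessel_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  nr <- spec$height; nc <- spec$width
  truth <- matrix(0, nr, nc)
  clean <- matrix(spec$background, nr, nc)
  for (k in seq_len(nrow(spec$segments))) {
    s <- spec$segments[k, ]
    if (s$r0 == s$r1 && s$c0 == s$c1)
      stop("degenerate zero-length segment in phantom spec", call. = FALSE)
    d2 <- segment_dist2(nr, nc, s$r0, s$c0, s$r1, s$c1)
    inside <- d2 <= (s$width / 2)^2
    truth[inside] <- 1
    clean[inside] <- pmax(clean[inside], spec$background + s$contrast)
  }
  if (!is.null(spec$blobs)) {
    R <- matrix(seq_len(nr), nr, nc)
    C <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    for (k in seq_len(nrow(spec$blobs))) {
      b <- spec$blobs[k, ]
      d <- sqrt((R - b$r)^2 + (C - b$c)^2)
      # cosine ramp from 1 (inside) to 0 across [radius - e/2, radius + e/2]
      s <- 0.5 + 0.5 * cos(pi * pmin(pmax((d - b$radius) / b$edge_width + 0.5, 0), 1))
      clean <- clean + b$contrast * s
    }
  }
  clean <- clamp01(clean)
  img <- clean
  if (!is.null(spec$shading)) img <- img * spec$shading
  if (spec$noise_sigma > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(spec$seed)
    img <- img + matrix(stats::rnorm(nr * nc, sd = spec$noise_sigma), nr, nc)
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  }
  list(image = clamp01(img), truth = truth, clean = clean)
}

#' Preset phantom: vessel-like symbol with varying width and orientation
#'
#' A fixed arrangement of four tubes (widths 2 to 10 pixels, orientations
#' 0, 45, 90 and 135 degrees) with contrast 0.8 over a 0.1 background and
#' additive Gaussian noise, emulating the classic synthetic test image for
#' tubular-structure enhancement.
#'
#' @param seed RNG seed for the noise.
#' @param noise_sigma noise standard deviation (default 0.2).
#' @param height,width image size.
#' @param shading optional multiplicative field.
#' @return a [phantom_spec()] object (pass to [vessel_phantom()]).
#' @export
fig_phantom_spec <- function(seed = 1L, noise_sigma = 0.2, height = 160L,
                             width = 160L, shading = NULL) {
  segs <- data.frame(
    r0 = c(25, 20, 60, 140), c0 = c(15, 120, 20, 145),
    r1 = c(25, 140, 140, 60), c1 = c(145, 120, 100, 65),
    width = c(10, 4, 7, 2), contrast = c(0.8, 0.8, 0.8, 0.8))
  phantom_spec(height, width, segs, background = 0.1,
               noise_sigma = noise_sigma, shading = shading, seed = seed)
}

#' Preset phantom: retinal-style thin vessels
#'
#' Four thin tubes (2-3 pixels wide, the typical vessel caliber of fundus
#' photographs at screening resolution) with moderate contrast 0.25 over a
#' mid-gray background and mild sensor noise, optionally with a
#' multiplicative shading field and an optic-disc-like bright blob. This is
#' the regime the full pipeline is designed for: thin structures that the
#' 3x3 Retinex window can pass and the high center-frequency filter bank
#' resolves.
#'
#' @param seed RNG seed for the noise.
#' @param noise_sigma noise standard deviation (default 0.01, realistic
#'   sensor noise for fundus photography).
#' @param shading optional multiplicative field ([shading_field()]).
#' @param with_disc add an optic-disc-like blob (soft-edged bright disk).
#' @return a [phantom_spec()] object.
#' @export
retinal_phantom_spec <- function(seed = 1L, noise_sigma = 0.01,
                                 shading = NULL, with_disc = FALSE) {
  segs <- data.frame(
    r0 = c(25, 20, 60, 140), c0 = c(15, 120, 20, 145),
    r1 = c(25, 140, 140, 60), c1 = c(145, 120, 100, 65),
    width = c(2, 2, 3, 2), contrast = rep(0.25, 4))
  blobs <- if (with_disc)
    data.frame(r = 95, c = 55, radius = 16, contrast = 0.35, edge_width = 2)
  phantom_spec(160L, 160L, segs, background = 0.5,
               noise_sigma = noise_sigma, shading = shading, blobs = blobs,
               seed = seed)
}

#' Smooth multiplicative shading field in [1 - amplitude, 1]
#'
#' A broad Gaussian bump (or linear ramp) emulating the slowly varying
#' illumination that Retinex correction removes. With `amplitude <= 0.5`
#' the field stays within `[0.5, 1]`; `amplitude = 0` gives the constant
#' field 1. Deterministic (no randomness).
#'
#' @param height,width field size.
#' @param amplitude maximum attenuation, in `[0, 0.5]`.
#' @param center bump center `c(row, col)`; default lower-right third.
#' @param sigma bump spread in pixels; default `0.6 * min(height, width)`.
#' @param type `"gaussian"` bump or `"linear"` left-to-right ramp.
#' @return matrix with values in `[1 - amplitude, 1]`.
#' @export
shading_field <- function(height, width, amplitude = 0.4, center = NULL,
                          sigma = NULL, type = c("gaussian", "linear")) {
  type <- match.arg(type)
  if (amplitude < 0 || amplitude > 0.5)
    stop("amplitude must lie in [0, 0.5]", call. = FALSE)
  if (type == "linear") {
    ramp <- matrix(seq(0, 1, length.out = width), height, width, byrow = TRUE)
    return(1 - amplitude * ramp)
  }
  if (is.null(center)) center <- c(2 * height / 3, 2 * width / 3)
  if (is.null(sigma)) sigma <- 0.6 * min(height, width)
  R <- matrix(seq_len(height), height, width)
  C <- matrix(seq_len(width), height, width, byrow = TRUE)
  bump <- exp(-((R - center[1])^2 + (C - center[2])^2) / (2 * sigma^2))
  1 - amplitude * bump
}

#' Piecewise-constant two-region phantom
#'
#' An exact two-valued image (foreground region over background) with its
#' mask, for testing the Chan-Vese solver in isolation.
#'
#' @param shape `c(rows, cols)`.
#' @param fg,bg foreground/background intensities in `[0, 1]`.
#' @param kind `"disk"` (centered, radius `0.25 * min(shape)` by default)
#'   or `"rect"`.
#' @param radius disk radius in pixels (disk only).
#' @param rect rectangle `c(r0, c0, r1, c1)` inclusive (rect only); default
#'   the central half.
#' @return list with `image` and `mask` (0/1 matrix).
#' @export
two_region_phantom <- function(shape, fg = 0.9, bg = 0.1,
                               kind = c("disk", "rect"), radius = NULL,
                               rect = NULL) {
  kind <- match.arg(kind)
  nr <- shape[1L]; nc <- shape[2L]
  if (kind == "disk") {
    if (is.null(radius)) radius <- 0.25 * min(nr, nc)
    R <- matrix(seq_len(nr), nr, nc)
    C <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    mask <- ((R - (nr + 1) / 2)^2 + (C - (nc + 1) / 2)^2 <= radius^2) * 1
  } else {
    if (is.null(rect)) rect <- round(c(nr / 4, nc / 4, 3 * nr / 4, 3 * nc / 4))
    mask <- matrix(0, nr, nc)
    mask[rect[1]:rect[3], rect[2]:rect[4]] <- 1
  }
  if (sum(mask) == 0) stop("foreground region is empty", call. = FALSE)
  img <- matrix(bg, nr, nc)
  img[mask == 1] <- fg
  list(image = img, mask = mask)
}
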