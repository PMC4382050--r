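#' Load a raster image as an intensity matrix in [0, 1]
#'
#' Reads a PNG, TIFF or JPEG file and rescales it linearly from the
#' container's integer range to `[0, 1]` (8-bit by 255, 16-bit by 65535;
#' EBImage performs the rescale on decode). Grayscale files yield a
#' `[row, col]` matrix; color files yield a `[row, col, channel]` array
#' (use [extract_working_channel()] to reduce to one channel). Images with
#' an alpha channel are accepted and the alpha channel is dropped.
#'
#' @param path path to an image file.
#' @param downsample integer area-averaging factor `>= 1`; each output pixel
#'   is the mean of a `factor x factor` block (trailing rows/columns that do
#'   not fill a block are discarded). Intended for very large images such as
#'   ultra-wide-field angiograms.
#' @return numeric matrix or 3-channel array with values in `[0, 1]`.
#' @seealso [load_mask()], [save_mask()]
#' @export
load_image <- function(path, downsample = 1L) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    stop("cannot read image file: ", path, call. = FALSE)
  img <- tryCatch(
    EBImage::imageData(EBImage::readImage(path)),
    error = function(e) stop("failed to decode image '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  # EBImage stores (x, y[, channel]); transpose to the [row, col] convention
  if (length(dim(img)) == 2L) {
    out <- t(img)
  } else if (length(dim(img)) == 3L) {
    if (dim(img)[3] == 4L) img <- img[, , 1:3, drop = FALSE] # drop alpha
    if (dim(img)[3] == 2L) img <- img[, , 1L, drop = FALSE]  # gray + alpha
    out <- aperm(img, c(2L, 1L, 3L))
    if (dim(out)[3] == 1L) out <- out[, , 1L]
  } else {
    stop("unsupported image layout in '", path, "'", call. = FALSE)
  }
  out <- clamp01(out)
  if (downsample > 1L) out <- downsample_image(out, downsample)
  out
}

#' Reduce a possibly-color image to the working grayscale channel
#'
#' Color fundus photographs are reduced to the green channel, which has the
#' highest vessel/background contrast; grayscale images (e.g. fluorescein
#' angiograms) pass through unchanged. No luma conversion is performed.
#'
#' @param img matrix (grayscale) or `[row, col, 3]` array (RGB).
#' @return numeric matrix in `[0, 1]`.
#' @export
extract_working_channel <- function(img) {
  if (is.matrix(img)) return(check_unit_image(img))
  if (is.array(img) && length(dim(img)) == 3L && dim(img)[3] == 3L)
    return(img[, , 2L])
  stop("image must have 1 or 3 channels", call. = FALSE)
}

#' Load a binary mask from a raster file
#'
#' Pixels above the midpoint of the container range become 1, all others 0
#' (robust to antialiased mask edges). Color masks use their first channel.
#'
#' @inheritParams load_image
#' @return 0/1 matrix.
#' @export
load_mask <- function(path) {
  img <- load_image(path)
  if (!is.matrix(img)) img <- img[, , 1L]
  (img > 0.5) * 1
}

#' Write a binary mask as an 8-bit PNG (0 -> 0, 1 -> 255)
#'
#' `load_mask(save_mask(x, f))` is the identity.
#'
#' @param labels 0/1 matrix.
#' @param path output path (PNG).
#' @return `path`, invisibly.
#' @export
save_mask <- function(labels, path) {
  check_labeling(labels)
  storage.mode(labels) <- "double"
  tryCatch(png::writePNG(labels, target = path),
           error = function(e) stop("cannot write mask to '", path, "': ",
                                    conditionMessage(e), call. = FALSE))
  invisible(path)
}

#' Write an intensity image as an 8-bit PNG
#'
#' @param img matrix in `[0, 1]`.
#' @param path output path (PNG).
#' @return `path`, invisibly.
#' @export
save_image <- function(img, path) {
  check_unit_image(img)
  png::writePNG(img, target = path)
  invisible(path)
}

#' Save / load a vesselness map as a 32-bit float TIFF
#'
#' Vesselness values lie in `[-1/2, 1/2]`; they are stored shifted by +0.5
#' into `[0, 1]` as 32-bit float samples (the shift is undone on load).
#'
#' @param map numeric matrix with values in `[-0.5, 0.5]`, or a
#'   `vesselness_map` object from [enhance()].
#' @param path TIFF path.
#' @return `path` invisibly (save); numeric matrix (load).
#' @export
save_vesselness <- function(map, path) {
  if (inherits(map, "vesselness_map")) map <- map$map
  check_image(map, "map")
  if (max(abs(map)) > 0.5 + 1e-9)
    stop("vesselness values must lie in [-1/2, 1/2]", call. = FALSE)
  tiff::writeTIFF(clamp01(map + 0.5), where = path, bits.per.sample = 32L,
                  reduce = FALSE)
  invisible(path)
}

#' @rdname save_vesselness
#' @export
load_vesselness <- function(path) {
  if (!file.exists(path))
    stop("cannot read vesselness file: ", path, call. = FALSE)
  tiff::readTIFF(path) - 0.5
}

#' Downsample an image by integer-factor block averaging
#'
#' @param img matrix or 3-channel array.
#' @param factor integer `>= 1`.
#' @return downsampled image (same type).
#' @export
downsample_image <- function(img, factor) {
  factor <- as.integer(factor)
  if (factor < 1L) stop("downsample factor must be >= 1", call. = FALSE)
  if (factor == 1L) return(img)
  if (!is.matrix(img)) {
    ch <- lapply(seq_len(dim(img)[3]), function(k) downsample_image(img[, , k], factor))
    return(array(unlist(ch), dim = c(dim(ch[[1]]), length(ch))))
  }
  nr <- nrow(img) %/% factor
  nc <- ncol(img) %/% factor
  if (nr < 1L || nc < 1L) stop("image smaller than downsampling block", call. = FALSE)
  x <- img[seq_len(nr * factor), seq_len(nc * factor), drop = FALSE]
  # average factor x factor blocks
  x <- array(x, dim = c(factor, nr, factor * nc))
  x <- colMeans(x)                       # nr x (factor*nc)
  x <- array(x, dim = c(nr, factor, nc))
  x <- apply(x, c(1L, 3L), mean)
  matrix(x, nr, nc)
}

#' Invert image intensities (v -> 1 - v)
#'
#' Angiograms show bright vessels on a dark background, fundus photographs
#' the opposite; inversion lets one sign convention serve both.
#'
#' @param img matrix in `[0, 1]`.
#' @return inverted matrix.
#' @export
invert_image <- function(img) {
  check_unit_image(img)
  1 - img
}

#' Pair DRIVE-style dataset files by shared numeric prefix
#'
#' Scans the image, ground-truth and (optionally) field-of-view directories
#' and pairs files whose names share the same first number (e.g. `21_training.tif`,
#' `21_manual1.gif`, `21_training_mask.gif`). Unpaired files are reported via
#' warnings and skipped.
#'
#' @param images_dir,truth_dir directories of images and manual annotations.
#' @param fov_dir optional directory of field-of-view masks.
#' @return data frame with columns `id`, `image`, `truth` and optionally `fov`.
#' @export
pair_dataset_files <- function(images_dir, truth_dir, fov_dir = NULL) {
  index <- function(dir) {
    files <- list.files(dir, full.names = TRUE)
    files <- files[!dir.exists(files)]
    ids <- regmatches(basename(files), regexpr("[0-9]+", basename(files)))
    keep <- lengths(regmatches(basename(files), gregexpr("[0-9]+", basename(files)))) > 0
    data.frame(id = as.character(ids), path = files[keep],
               stringsAsFactors = FALSE)
  }
  imgs <- index(images_dir)
  trth <- index(truth_dir)
  ids <- intersect(imgs$id, trth$id)
  dropped <- setdiff(union(imgs$id, trth$id), ids)
  if (length(dropped))
    warning("unpaired files skipped for ids: ", paste(dropped, collapse = ", "))
  out <- data.frame(id = ids,
                    image = imgs$path[match(ids, imgs$id)],
                    truth = trth$path[match(ids, trth$id)],
                    stringsAsFactors = FALSE)
  if (!is.null(fov_dir)) {
    fov <- index(fov_dir)
    out$fov <- fov$path[match(out$id, fov$id)]
  }
  if (nrow(out) == 0L) stop("no paired image/truth files found", call. = FALSE)
  out[order(out$id), , drop = FALSE]
}
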