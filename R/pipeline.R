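#' Run the full vessel-segmentation pipeline on one image
#'
#' Executes the three stages in their fixed order — Retinex
#' inhomogeneity correction, local-phase enhancement, graph-cut Chan-Vese
#' segmentation — and, when a reference standard is supplied, evaluates
#' the result. All stage parameters default to the package defaults
#' (`sigma_d = sigma_r = 0.3`, 3x3 window; `rho0 = 5*pi/7`, 2 octaves,
#' 15x15 kernels, 4 orientations, `beta = 1`, 2 scales; `lambda1 = 1`,
#' `lambda2 = 4`, `mu = 1`, `max_iter = 30`, `tol = 0.001`).
#'
#' @param image path to an image file, or an intensity matrix / RGB array.
#' @param retinex logical; disable to ablate the correction stage.
#' @param invert invert intensities after loading (bright-vessel
#'   angiograms vs dark-vessel fundus photographs).
#' @param downsample integer block-averaging factor applied on load.
#' @param rparams,pparams,cparams stage parameters ([retinex_params()],
#'   [phase_params()], [cv_params()]).
#' @param fov optional field-of-view mask (path or 0/1 matrix).
#' @param truth optional reference segmentation (path or 0/1 matrix).
#' @param dump_dir optional directory; when given, the corrected image
#'   (PNG), vesselness map (32-bit float TIFF) and mask (PNG) are written
#'   there.
#' @param verbose print per-stage progress.
#' @return list with `segmentation` (a `cv_segmentation`), `mask`
#'   (0/1 matrix), `vesselness` (a `vesselness_map`), `corrected`,
#'   `metrics` (or `NULL`), and `config` (all effective parameters).
#' @export
run_pipeline <- function(image, retinex = TRUE, invert = FALSE,
                         downsample = 1L,
                         rparams = retinex_params(),
                         pparams = phase_params(),
                         cparams = cv_params(),
                         fov = NULL, truth = NULL, dump_dir = NULL,
                         verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  img <- stage("load", {
    x <- if (is.character(image)) load_image(image, downsample) else image
    x <- extract_working_channel(x)
    if (!is.character(image) && downsample > 1L)
      x <- downsample_image(x, downsample)
    if (invert) x <- invert_image(x)
    x
  })
  if (is.character(fov)) fov <- load_mask(fov)
  if (is.character(truth)) truth <- load_mask(truth)
  if (downsample > 1L) {
    if (!is.null(fov)) fov <- (downsample_image(fov, downsample) > 0.5) * 1
    if (!is.null(truth)) truth <- (downsample_image(truth, downsample) > 0.5) * 1
  }
  say("retinex correction (", if (retinex) "on" else "off", ")")
  corrected <- if (retinex) stage("retinex", retinex_correct(img, rparams)) else img
  say("local-phase enhancement")
  vm <- stage("enhance", enhance(corrected, pparams))
  say("graph-cut segmentation")
  seg <- stage("segment", segment_cv_graphcut(vm, cparams, fov = fov))
  metrics <- NULL
  if (!is.null(truth))
    metrics <- stage("evaluate", compute_metrics(confusion(seg$labeling, truth, fov)))
  if (!is.null(dump_dir)) {
    dir.create(dump_dir, showWarnings = FALSE, recursive = TRUE)
    save_image(corrected, file.path(dump_dir, "corrected.png"))
    save_vesselness(vm, file.path(dump_dir, "vesselness.tiff"))
    save_mask(seg$labeling, file.path(dump_dir, "mask.png"))
  }
  list(segmentation = seg, mask = seg$labeling, vesselness = vm,
       corrected = corrected, metrics = metrics,
       config = list(retinex = retinex, invert = invert,
                     downsample = downsample, rparams = rparams,
                     pparams = pparams, cparams = cparams,
                     version = as.character(utils::packageVersion("vesselseg"))))
}

#' Run the pipeline over a paired dataset directory
#'
#' Pairs image, ground-truth and (optionally) FOV files by shared numeric
#' prefix ([pair_dataset_files()]), processes each image independently with
#' [run_pipeline()], and tabulates per-image metrics plus the mean row.
#'
#' @param images_dir,truth_dir,fov_dir dataset directories (DRIVE-style
#'   layout; `fov_dir` optional).
#' @param csv optional output CSV path.
#' @param ... further arguments passed to [run_pipeline()].
#' @return metrics data frame (see [evaluate_pairs()]).
#' @export
run_dataset <- function(images_dir, truth_dir, fov_dir = NULL, csv = NULL,
                        ...) {
  files <- pair_dataset_files(images_dir, truth_dir, fov_dir)
  pairs <- lapply(seq_len(nrow(files)), function(k) {
    fov <- if (!is.null(files$fov) && !is.na(files$fov[k]))
      load_mask(files$fov[k]) else NULL
    res <- run_pipeline(files$image[k], fov = fov, ...)
    list(pred = res$mask, truth = load_mask(files$truth[k]), fov = fov)
  })
  names(pairs) <- files$id
  evaluate_pairs(pairs, csv = csv)
}
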