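#' Pixel-wise confusion counts between a segmentation and a reference
#'
#' Label 1 is "vessel". When a field-of-view mask is supplied only pixels
#' inside it are counted (standard practice for fundus datasets, whose
#' image corners carry no retina).
#'
#' @param pred predicted 0/1 matrix.
#' @param truth reference 0/1 matrix of the same shape.
#' @param fov optional 0/1 field-of-view mask.
#' @return list of non-negative integers `tp`, `tn`, `fp`, `fn` summing to
#'   the number of evaluated pixels.
#' @export
confusion <- function(pred, truth, fov = NULL) {
  check_labeling(pred, "pred")
  check_labeling(truth, "truth", ref = pred)
  keep <- if (is.null(fov)) TRUE else {
    check_labeling(fov, "fov", ref = pred)
    fov == 1
  }
  p <- pred[keep]; t <- truth[keep]
  list(tp = sum(p == 1 & t == 1), tn = sum(p == 0 & t == 0),
       fp = sum(p == 1 & t == 0), fn = sum(p == 0 & t == 1))
}

#' Sensitivity, specificity, accuracy and two-point AUC
#'
#' `Se = tp/(tp+fn)`, `Sp = tn/(tn+fp)`, `Acc = (tp+tn)/total` and the
#' two-point AUC surrogate `AUC = (Se + Sp)/2` (not a threshold sweep).
#'
#' @param counts confusion counts from [confusion()] (or any list with
#'   `tp`, `tn`, `fp`, `fn`).
#' @return list with `se`, `sp`, `acc`, `auc`, all in `[0, 1]`.
#' @export
compute_metrics <- function(counts) {
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  if (any(c(tp, tn, fp, fn) < 0)) stop("counts must be non-negative", call. = FALSE)
  if (tp + fn == 0)
    stop("sensitivity undefined: no positive reference pixels (tp + fn = 0)",
         call. = FALSE)
  if (tn + fp == 0)
    stop("specificity undefined: no negative reference pixels (tn + fp = 0)",
         call. = FALSE)
  se <- tp / (tp + fn)
  sp <- tn / (tn + fp)
  list(se = se, sp = sp, acc = (tp + tn) / (tp + tn + fp + fn),
       auc = auc_two_point(se, sp))
}

#' Two-point AUC from sensitivity and specificity
#'
#' @param se,sp sensitivity and specificity in `[0, 1]`.
#' @return `(se + sp) / 2`.
#' @export
auc_two_point <- function(se, sp) {
  if (any(se < 0 | se > 1) || any(sp < 0 | sp > 1))
    stop("se and sp must lie in [0, 1]", call. = FALSE)
  (se + sp) / 2
}

#' Dice overlap between two binary masks
#'
#' `2 |A intersect B| / (|A| + |B|)`; defined as 1 when both masks are
#' empty.
#'
#' @param a,b 0/1 matrices of the same shape.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice <- function(a, b) {
  check_labeling(a, "a"); check_labeling(b, "b", ref = a)
  s <- sum(a) + sum(b)
  if (s == 0) return(1)
  2 * sum(a == 1 & b == 1) / s
}

#' Evaluate a list of segmentation/reference pairs
#'
#' Computes per-image confusion counts and metrics plus an unweighted mean
#' row (per-image metrics averaged, the convention of dataset summary
#' tables).
#'
#' @param pairs list whose elements are lists with components `pred`,
#'   `truth` and optionally `fov`; elements may be named to label the rows.
#' @param csv optional path; when given the table is also written as CSV.
#' @return data frame with columns `image_id`, `tp`, `tn`, `fp`, `fn`,
#'   `se`, `sp`, `acc`, `auc`; the final row is the mean (counts summed,
#'   metrics averaged).
#' @export
evaluate_pairs <- function(pairs, csv = NULL) {
  if (!is.list(pairs) || length(pairs) == 0L)
    stop("pairs must be a non-empty list", call. = FALSE)
  ids <- names(pairs)
  if (is.null(ids)) ids <- as.character(seq_along(pairs))
  rows <- lapply(seq_along(pairs), function(k) {
    p <- pairs[[k]]
    cts <- confusion(p$pred, p$truth, p$fov)
    met <- compute_metrics(cts)
    data.frame(image_id = ids[k], tp = cts$tp, tn = cts$tn, fp = cts$fp,
               fn = cts$fn, se = met$se, sp = met$sp, acc = met$acc,
               auc = met$auc, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  mean_row <- data.frame(image_id = "mean", tp = sum(tab$tp), tn = sum(tab$tn),
                         fp = sum(tab$fp), fn = sum(tab$fn),
                         se = mean(tab$se), sp = mean(tab$sp),
                         acc = mean(tab$acc), auc = mean(tab$auc),
                         stringsAsFactors = FALSE)
  out <- rbind(tab, mean_row)
  rownames(out) <- NULL
  if (!is.null(csv)) utils::write.csv(out, csv, row.names = FALSE)
  out
}
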