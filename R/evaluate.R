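## Edge-map evaluation protocol.
##
## Predicted border probability maps are thresholded over a grid; at
## each threshold precision, recall, the F-measure (their harmonic
## mean) and the Pratt Figure of Merit are computed per image and
## averaged across images.  Summary scalars are the area under the
## mean precision-recall curve, the maximum mean F-measure, and the
## maximum mean Figure of Merit.

#' Threshold a probability map into a binary edge map
#'
#' A pixel is predicted border when its probability is greater than or
#' equal to the threshold (ties count as edge); the conventional
#' operating point is 50%.
#'
#' @param probs numeric matrix of probabilities.
#' @param threshold scalar in `[0, 1]`.
#' @return Binary integer matrix.
#' @export
threshold_map <- function(probs, threshold = 0.5) {
  if (threshold < 0 || threshold > 1)
    stop_config("threshold must be in [0, 1]")
  m <- (probs >= threshold) * 1L
  matrix(as.integer(m), nrow(probs), ncol(probs))
}

#' Precision and recall of a binary edge map
#'
#' Precision is the fraction of predicted border pixels that are true
#' border pixels; recall is the fraction of true border pixels that are
#' predicted.  An empty prediction has precision 1; an empty truth has
#' recall 1 (nothing was missed).
#'
#' @param pred binary matrix (predicted edges).
#' @param truth binary matrix or [border_mask] (ground truth).
#' @return Named numeric vector `c(precision, recall)`.
#' @export
precision_recall <- function(pred, truth) {
  if (inherits(truth, "border_mask")) truth <- truth$mask
  if (!identical(dim(pred), dim(truth)))
    stop_input("prediction and truth must have the same shape")
  pb <- pred != 0; tb <- truth != 0
  tp <- sum(pb & tb)
  n_pred <- sum(pb); n_truth <- sum(tb)
  precision <- if (n_pred == 0L) 1 else tp / n_pred
  recall <- if (n_truth == 0L) 1 else tp / n_truth
  c(precision = precision, recall = recall)
}

#' F-measure
#'
#' Harmonic mean of precision and recall, `2pr / (p + r)`, defined as 0
#' when both are 0.
#'
#' @param precision,recall scalars in `[0, 1]`.
#' @return Scalar in `[0, 1]`.
#' @export
f_measure <- function(precision, recall) {
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

#' Pratt Figure of Merit
#'
#' `R = 1 / max(I_I, I_A) * sum_i 1 / (1 + a d_i^2)` where `I_I` and
#' `I_A` are the numbers of ideal (ground-truth) and actual (predicted)
#' edge pixels, the sum runs over predicted edge pixels, and `d_i` is
#' the Euclidean distance from predicted pixel `i` to the nearest ideal
#' edge pixel (computed by distance transform).  `R = 1` for a perfect
#' edge map; conventions for degenerate maps: 1 when both maps are
#' empty, 0 when exactly one is empty.
#'
#' @param pred binary matrix (predicted edges).
#' @param truth binary matrix or [border_mask] (ideal edges).
#' @param a scaling constant, conventionally `1/9`.
#' @return Scalar in `[0, 1]`.
#' @export
pratt_fom <- function(pred, truth, a = 1 / 9) {
  if (inherits(truth, "border_mask")) truth <- truth$mask
  if (!identical(dim(pred), dim(truth)))
    stop_input("prediction and truth must have the same shape")
  if (a <= 0) stop_config("the scaling constant a must be positive")
  pb <- pred != 0; tb <- truth != 0
  II <- sum(tb); IA <- sum(pb)
  if (II == 0L && IA == 0L) return(1)
  if (II == 0L || IA == 0L) return(0)
  # distance of every pixel to the nearest ideal edge pixel
  d <- t(as.array(EBImage::distmap(t(1 - (tb * 1)), metric = "euclidean")))
  sum(1 / (1 + a * d[pb]^2)) / max(II, IA)
}

#' Gradient-magnitude edge baseline
#'
#' Central-difference gradient magnitude of the grayscale image,
#' rescaled to `[0, 1]`, as an untrained reference "probability" map
#' for boundary detection.
#'
#' @param image numeric array `(H, W, 3)`.
#' @return Numeric matrix `(H, W)` in `[0, 1]`.
#' @export
gradient_magnitude_baseline <- function(image) {
  g <- 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
  H <- nrow(g); W <- ncol(g)
  gy <- (g[pmin(seq_len(H) + 1L, H), ] - g[pmax(seq_len(H) - 1L, 1L), ]) / 2
  gx <- (g[, pmin(seq_len(W) + 1L, W)] - g[, pmax(seq_len(W) - 1L, 1L)]) / 2
  mag <- sqrt(gy^2 + gx^2)
  if (max(mag) > 0) mag <- mag / max(mag)
  mag
}

#' Evaluate a model (or predictor) over a test set
#'
#' For every image and every threshold on the grid, computes precision,
#' recall, F-measure and Pratt Figure of Merit of the thresholded
#' probability map against the ground-truth mask, then averages across
#' images at each threshold (macro average; micro-averaging of the
#' confusion counts is available via `average = "micro"`).  Summary
#' scalars: `auc_pr`, the trapezoidal area under the (mean recall, mean
#' precision) curve sorted by recall and anchored at the
#' empty-prediction limit (recall 0, precision 1); `max_mean_f` and
#' `max_mean_fom`, the maxima of the mean curves over the grid.
#'
#' @param model a `texbound_model`, or a function `image -> probability
#'   matrix` (e.g. [gradient_magnitude_baseline], or an oracle).
#' @param manifest a `dataset_manifest`, or a list of samples
#'   `list(image, mask)`.
#' @param thresholds strictly increasing grid in `[0, 1]` (default 101
#'   evenly spaced values).
#' @param a Pratt scaling constant.
#' @param average `"macro"` (per-image metrics averaged) or `"micro"`
#'   (confusion counts pooled across images before the metrics).
#' @param f_mode `"mean_f"` (default: maximum of the mean per-image
#'   F-curve) or `"f_of_means"` (F of the mean precision/recall).
#' @return An object of class `eval_report`: list with `curves` (data
#'   frame threshold/precision/recall/f_measure/fom), `auc_pr`,
#'   `max_mean_f`, `max_mean_fom`, `n_images`.
#' @export
evaluate_testset <- function(model, manifest,
                             thresholds = seq(0, 1, length.out = 101),
                             a = 1 / 9,
                             average = c("macro", "micro"),
                             f_mode = c("mean_f", "f_of_means")) {
  average <- match.arg(average)
  f_mode <- match.arg(f_mode)
  if (any(diff(thresholds) <= 0) || min(thresholds) < 0 ||
      max(thresholds) > 1)
    stop_config("thresholds must be strictly increasing within [0, 1]")
  samples <- if (inherits(manifest, "dataset_manifest")) {
    if (nrow(manifest$entries) == 0L) stop_input("empty test manifest")
    load_manifest_samples(manifest)
  } else {
    if (length(manifest) == 0L) stop_input("empty test set")
    manifest
  }
  predict_fun <- if (is.function(model)) model else
    function(img) predict(model, img)

  nt <- length(thresholds); ni <- length(samples)
  P <- R <- F_ <- FOM <- matrix(0, ni, nt)
  TPs <- FPs <- FNs <- matrix(0, ni, nt)
  for (i in seq_len(ni)) {
    probs <- predict_fun(samples[[i]]$image)
    truth <- samples[[i]]$mask
    tb <- truth != 0
    II <- sum(tb)
    # the FOM distance term depends only on the truth: transform once
    dmap <- if (II > 0L)
      t(as.array(EBImage::distmap(t(1 - (tb * 1)), metric = "euclidean")))
    fom_weight <- if (II > 0L) 1 / (1 + a * dmap^2)
    for (j in seq_len(nt)) {
      pred <- probs >= thresholds[j]
      tp <- sum(pred & tb); np <- sum(pred)
      P[i, j] <- if (np == 0L) 1 else tp / np
      R[i, j] <- if (II == 0L) 1 else tp / II
      F_[i, j] <- f_measure(P[i, j], R[i, j])
      FOM[i, j] <- if (II == 0L && np == 0L) 1
        else if (II == 0L || np == 0L) 0
        else sum(fom_weight[pred]) / max(II, np)
      TPs[i, j] <- tp
      FPs[i, j] <- np - tp
      FNs[i, j] <- II - tp
    }
  }
  if (average == "macro") {
    mp <- colMeans(P); mr <- colMeans(R)
  } else {
    tp <- colSums(TPs); fp <- colSums(FPs); fn <- colSums(FNs)
    mp <- ifelse(tp + fp == 0, 1, tp / (tp + fp))
    mr <- ifelse(tp + fn == 0, 1, tp / (tp + fn))
  }
  mf <- colMeans(F_); mfom <- colMeans(FOM)
  curves <- data.frame(threshold = thresholds, precision = mp,
                       recall = mr, f_measure = mf, fom = mfom)
  # integrate along the threshold path (recall is non-increasing in the
  # threshold), anchored at the empty-prediction limit (recall 0,
  # precision 1); vertical segments of the path contribute nothing
  rs <- c(0, rev(mr)); ps <- c(1, rev(mp))
  auc_pr <- sum(diff(rs) * (ps[-1] + ps[-(nt + 1)]) / 2)
  max_mean_f <- if (f_mode == "mean_f") max(mf) else
    max(mapply(f_measure, mp, mr))
  structure(list(curves = curves, auc_pr = auc_pr,
                 max_mean_f = max_mean_f, max_mean_fom = max(mfom),
                 n_images = ni),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(paste0("<eval_report over %d images>\n",
                     "  area under mean PR curve: %.4f\n",
                     "  maximum mean F-measure:   %.4f\n",
                     "  maximum mean Pratt FOM:   %.4f\n"),
              x$n_images, x$auc_pr, x$max_mean_f, x$max_mean_fom))
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' JSON summary plus a CSV table of the per-threshold mean curves, and
#' optionally a PNG plot of the mean precision-recall curve.
#'
#' @param report an `eval_report`.
#' @param out_dir output directory.
#' @param plot also write `pr_curve.png`.
#' @return Invisibly, the paths written.
#' @export
write_eval_report <- function(report, out_dir, plot = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  json_path <- file.path(out_dir, "report.json")
  csv_path <- file.path(out_dir, "curves.csv")
  jsonlite::write_json(list(auc_pr = report$auc_pr,
                            max_mean_f = report$max_mean_f,
                            max_mean_fom = report$max_mean_fom,
                            n_images = report$n_images),
                       json_path, auto_unbox = TRUE, digits = NA)
  write.csv(report$curves, csv_path, row.names = FALSE)
  paths <- c(json_path, csv_path)
  if (plot) {
    png_path <- file.path(out_dir, "pr_curve.png")
    grDevices::png(png_path, width = 600, height = 600)
    graphics::plot(report$curves$recall, report$curves$precision,
                   type = "l", xlim = c(0, 1), ylim = c(0, 1),
                   xlab = "Recall", ylab = "Precision",
                   main = sprintf("Mean PR curve (AUC = %.3f)",
                                  report$auc_pr))
    grDevices::dev.off()
    paths <- c(paths, png_path)
  }
  invisible(paths)
}
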