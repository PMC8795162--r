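# Evaluation metrics and the feature-map leakage audit.

new_metric <- function(name, value, n, higher_is_better) {
  structure(list(name = name, value = value, n = n,
                 higher_is_better = higher_is_better),
            class = "metric_result")
}

#' @export
print.metric_result <- function(x, ...) {
  cat(sprintf("<metric> %s = %.6g (n = %d, %s is better)\n", x$name, x$value,
              x$n, if (x$higher_is_better) "higher" else "lower"))
  invisible(x)
}

#' Classification accuracy in percent
#'
#' `100 * mean(1[p >= threshold] == label)`; a probability exactly at the
#' threshold predicts the positive class.
#'
#' @param prob Predicted probabilities.
#' @param labels 0/1 labels of the same length.
#' @param threshold Decision threshold (default 0.5).
#' @return A `metric_result` with `value` in \[0, 100\].
#' @examples
#' accuracy(c(0.9, 0.1), c(1, 0))$value  # 100
#' @export
accuracy <- function(prob, labels, threshold = 0.5) {
  n <- length(prob)
  if (n == 0L) stopf("accuracy of an empty prediction vector is undefined")
  if (length(labels) != n) stopf("prob/labels length mismatch")
  if (!all(labels %in% c(0, 1))) stopf("labels must be 0/1")
  new_metric("accuracy_percent",
             100 * mean(as.integer(prob >= threshold) == labels), n, TRUE)
}

#' Root mean squared logarithmic error
#'
#' `sqrt(mean((log1p(pred) - log1p(actual))^2))`, the standard regression
#' error on a relative scale; symmetric in its arguments and invariant
#' under a common permutation of both vectors.
#'
#' @param pred,actual Numeric vectors of equal length, all values > -1.
#' @return A `metric_result` (lower is better).
#' @examples
#' rmsle(exp(1) - 1, 0)$value  # 1
#' rmsle(3, 1)$value           # log(2)
#' @export
rmsle <- function(pred, actual) {
  n <- length(pred)
  if (n == 0L || length(actual) != n) stopf("pred/actual must be equal, non-zero length")
  if (any(pred <= -1) || any(actual <= -1))
    stopf("RMSLE is undefined for values <= -1 (log1p)")
  new_metric("rmsle", sqrt(mean((log1p(pred) - log1p(actual))^2)), n, FALSE)
}

#' Binary cross-entropy and mean squared error
#'
#' Batch-mean loss values; probabilities are clipped to
#' \[1e-7, 1 - 1e-7\] before taking logs.
#'
#' @param prob,labels Probabilities and 0/1 labels.
#' @param pred,actual Numeric vectors for MSE.
#' @return The scalar loss.
#' @examples
#' binary_crossentropy(0.5, 1)  # log(2)
#' mse(c(1, 2), c(1, 2))        # 0
#' @export
binary_crossentropy <- function(prob, labels) {
  if (length(prob) != length(labels)) stopf("prob/labels length mismatch")
  loss_forward("binary_crossentropy", prob, labels)$loss
}

#' @rdname binary_crossentropy
#' @export
mse <- function(pred, actual) {
  if (length(pred) != length(actual)) stopf("pred/actual length mismatch")
  loss_forward("mse", pred, actual)$loss
}

# ---- leakage audit ---------------------------------------------------------

# Bilinear upsampling of a matrix to (H, W).
bilinear_upsample <- function(m, H, W) {
  h <- nrow(m); w <- ncol(m)
  if (h == H && w == W) return(m)
  # map target pixel centres into source coordinates
  ys <- if (h == 1L) rep(1, H) else (seq_len(H) - 0.5) / H * h + 0.5
  xs <- if (w == 1L) rep(1, W) else (seq_len(W) - 0.5) / W * w + 0.5
  y0 <- pmin(pmax(floor(ys), 1L), h); y1 <- pmin(y0 + 1L, h)
  x0 <- pmin(pmax(floor(xs), 1L), w); x1 <- pmin(x0 + 1L, w)
  fy <- pmin(pmax(ys - y0, 0), 1); fx <- pmin(pmax(xs - x0, 0), 1)
  a <- m[y0, x0, drop = FALSE]; b <- m[y0, x1, drop = FALSE]
  c_ <- m[y1, x0, drop = FALSE]; d <- m[y1, x1, drop = FALSE]
  wy <- matrix(fy, H, W); wx <- matrix(fx, H, W, byrow = TRUE)
  a * (1 - wy) * (1 - wx) + b * (1 - wy) * wx + c_ * wy * (1 - wx) + d * wy * wx
}

safe_cor <- function(a, b) {
  if (stats::sd(a) < 1e-12 || stats::sd(b) < 1e-12) return(0)
  stats::cor(a, b)
}

#' Quantify how much of an input image a feature map leaks
#'
#' The split protocol's privacy argument is that the transmitted cut-layer
#' feature map is too distorted to trace back to the original image. This
#' audit makes that claim quantitative with two scores: (1) the per-channel
#' maximum absolute Pearson correlation between each bilinearly upsampled
#' feature-map channel and the input image, and (2) the normalised RMSE of
#' the best pixel-wise least-squares reconstruction of the image from the
#' upsampled channels (plus intercept), relative to the mean-image
#' baseline, so an uninformative map scores exactly 1 and a perfect linear
#' reconstruction scores 0. A side-by-side PNG (original | first channel)
#' can be exported.
#'
#' @param input_image 2-D numeric matrix (one grayscale image).
#' @param feature_map 3-D array `[h, w, channels]`, e.g. one sample of a
#'   convolutional client's output with the batch dimension dropped.
#' @param figure_path Optional path for the side-by-side PNG export.
#' @param report_path Optional path for a JSON report.
#' @return An object of class `privacy_report`: `channel_correlations`,
#'   `max_correlation`, `inversion_nrmse`, `figure_path`, `report_path`.
#' @examples
#' img <- matrix(runif(64), 8, 8)
#' fm <- array(rnorm(4 * 4 * 2), c(4, 4, 2))
#' audit_leakage(img, fm)
#' @export
audit_leakage <- function(input_image, feature_map, figure_path = NULL,
                          report_path = NULL) {
  if (length(dim(input_image)) != 2L) stopf("'input_image' must be a 2-D matrix")
  if (length(dim(feature_map)) != 3L)
    stopf("'feature_map' must be a 3-D array [h, w, channels]")
  H <- nrow(input_image); W <- ncol(input_image)
  C <- dim(feature_map)[3L]
  img_v <- as.numeric(input_image)

  ups <- lapply(seq_len(C), function(ch)
    bilinear_upsample(feature_map[, , ch], H, W))
  cors <- vapply(ups, function(u) abs(safe_cor(as.numeric(u), img_v)), numeric(1L))

  # pixel-wise linear inversion: image ~ intercept + upsampled channels
  X <- cbind(1, do.call(cbind, lapply(ups, as.numeric)))
  keep <- c(TRUE, vapply(ups, function(u) stats::sd(u) > 1e-12, logical(1L)))
  beta <- tryCatch(qr.coef(qr(X[, keep, drop = FALSE]), img_v),
                   error = function(e) NULL)
  recon <- if (is.null(beta)) rep(mean(img_v), length(img_v)) else {
    beta[is.na(beta)] <- 0
    as.numeric(X[, keep, drop = FALSE] %*% beta)
  }
  rms <- function(v) sqrt(mean(v^2))
  baseline <- rms(img_v - mean(img_v))
  nrmse <- if (baseline < 1e-12) 0 else rms(img_v - recon) / baseline

  if (!is.null(figure_path)) export_leakage_figure(input_image, feature_map, figure_path)
  rep <- structure(list(
    channel_correlations = cors,
    max_correlation = if (C) max(cors) else 0,
    inversion_nrmse = nrmse,
    figure_path = figure_path, report_path = report_path
  ), class = "privacy_report")
  if (!is.null(report_path)) {
    jsonlite::write_json(list(channel_correlations = cors,
                              max_correlation = rep$max_correlation,
                              inversion_nrmse = nrmse,
                              figure = figure_path %||% NA),
                         report_path, auto_unbox = TRUE, digits = NA)
  }
  rep
}

#' @export
print.privacy_report <- function(x, ...) {
  cat("<privacy_report>\n")
  cat(sprintf("  channels: %d | max |cor| with input: %.4f\n",
              length(x$channel_correlations), x$max_correlation))
  cat(sprintf("  linear-inversion nRMSE (1 = uninformative): %.4f\n",
              x$inversion_nrmse))
  if (!is.null(x$figure_path)) cat("  figure:", x$figure_path, "\n")
  invisible(x)
}

to_unit <- function(m) {
  r <- range(m)
  if (diff(r) < 1e-12) return(matrix(0.5, nrow(m), ncol(m)))
  (m - r[1L]) / diff(r)
}

# Side-by-side export: original image | first feature-map channel
# (upsampled to the input size), separated by a white gutter.
export_leakage_figure <- function(input_image, feature_map, path) {
  H <- nrow(input_image); W <- ncol(input_image)
  ch1 <- bilinear_upsample(feature_map[, , 1L], H, W)
  panel <- cbind(to_unit(input_image), matrix(1, H, 2L), to_unit(ch1))
  png::writePNG(panel, path)
  invisible(path)
}
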