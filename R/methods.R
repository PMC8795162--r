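# S3 methods for fitted split models.

#' @export
print.split_fit <- function(x, ...) {
  cat(sprintf("<split_fit> %s, %d end-systems (ratio %s)%s\n",
              x$spec$architecture, length(x$clients), ratio_label(x$ratio),
              if (x$sync) ", synchronised" else ""))
  cat(sprintf("  %d epochs x %d rounds, global batch %d (%s local sizes: %s)\n",
              x$epochs, x$rounds_per_epoch, x$global_batch, x$batch_policy,
              paste(x$local_batch_sizes, collapse = "/")))
  if (nrow(x$history)) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  final training loss %.5f | held-out %s %.4f (n=%d)\n",
                last$loss, if (x$classify) "accuracy %" else "RMSLE",
                last$metric, length(x$test_idx)))
  } else cat("  untrained (epochs = 0)\n")
  invisible(x)
}

#' Summarise a fitted split model
#'
#' @param object A [split_train()] fit.
#' @param ... Unused.
#' @return A `summary.split_fit` list: configuration, partition sizes,
#'   epoch history and final held-out metric.
#' @export
summary.split_fit <- function(object, ...) {
  out <- list(
    architecture = object$spec$architecture,
    task = object$spec$task,
    n_clients = length(object$clients),
    ratio = ratio_label(object$ratio),
    sync = object$sync,
    partition_sizes = lengths(object$partition$indices),
    local_batch_sizes = object$local_batch_sizes,
    epochs = object$epochs,
    n_train = length(object$train_idx),
    n_test = length(object$test_idx),
    metric_name = if (object$classify) "accuracy_percent" else "rmsle",
    final_loss = if (nrow(object$history)) object$history$loss[nrow(object$history)] else NA_real_,
    final_metric = if (nrow(object$history)) object$history$metric[nrow(object$history)] else NA_real_,
    history = object$history)
  class(out) <- "summary.split_fit"
  out
}

#' @export
print.summary.split_fit <- function(x, ...) {
  cat(sprintf("Multi-site split learning fit: %s (%s)\n", x$architecture, x$task))
  cat(sprintf("  end-systems: %d, ratio %s%s\n", x$n_clients, x$ratio,
              if (x$sync) " (synchronised weights)" else ""))
  cat(sprintf("  partition sizes: %s | local batches: %s\n",
              paste(x$partition_sizes, collapse = "/"),
              paste(x$local_batch_sizes, collapse = "/")))
  cat(sprintf("  train/test: %d/%d, epochs: %d\n", x$n_train, x$n_test, x$epochs))
  cat(sprintf("  final training loss: %.5f | held-out %s: %.4f\n",
              x$final_loss, x$metric_name, x$final_metric))
  invisible(x)
}

#' Extract model parameters
#'
#' @param object A `split_fit`.
#' @param ... Unused.
#' @return Named list: `clients` (one parameter list per end-system) and
#'   `server`.
#' @export
coef.split_fit <- function(object, ...) {
  list(clients = lapply(object$clients, `[[`, "params"),
       server = object$server$params)
}

#' Predict from a fitted split model
#'
#' New samples are embedded through every end-system's hidden layer and
#' the server head is applied to each embedding; predictions are the mean
#' over end-systems (for synchronised fits all end-systems agree exactly).
#' Regression predictions are returned on the original target scale.
#'
#' @param object A [split_train()] fit.
#' @param newdata Samples, batch-first, matching the spec's input shape.
#'   Defaults to the fit's held-out test set.
#' @param type `"response"` (probabilities / values) or `"class"`
#'   (thresholded 0/1 labels, classification only).
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.split_fit <- function(object, newdata = NULL, type = c("response", "class"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    # re-predict the held-out set is not possible without the data; require it
    stopf("supply 'newdata' (the fit does not store the training arrays)")
  }
  x <- newdata
  if (!is.null(object$scaling)) {
    x <- as.matrix(x)
    x <- sweep(sweep(x, 2L, object$scaling$x_mean), 2L, object$scaling$x_sd, "/")
  } else if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  pred <- predict_states(object$clients, object$server, x)
  if (type == "class") {
    if (!object$classify) stopf("type = 'class' applies to classification fits")
    return(as.integer(pred >= 0.5))
  }
  unscale_y(pred, object$scaling)
}

#' Residuals of a regression split fit
#'
#' @param object A regression `split_fit`.
#' @param newdata,y Evaluation samples and their observed targets.
#' @param ... Unused.
#' @return Observed minus predicted, on the original target scale.
#' @export
residuals.split_fit <- function(object, newdata, y, ...) {
  if (object$classify) stopf("residuals are defined for regression fits")
  y - predict(object, newdata)
}

#' Simulate responses from a fitted split model
#'
#' Classification fits draw Bernoulli labels from the predicted
#' probabilities; regression fits add Gaussian noise with the residual
#' standard deviation estimated from `y`.
#'
#' @param object A `split_fit`.
#' @param nsim Number of simulated response vectors.
#' @param seed Integer seed.
#' @param newdata Samples to simulate responses for.
#' @param y Observed targets (regression only; sets the noise scale).
#' @param ... Unused.
#' @return A data frame with `nsim` columns.
#' @export
simulate.split_fit <- function(object, nsim = 1, seed = NULL, newdata, y = NULL, ...) {
  pred <- predict(object, newdata)
  n <- length(pred)
  sims <- with_seed_(seed %||% 1L, {
    if (object$classify) {
      replicate(nsim, as.integer(stats::runif(n) < pred), simplify = FALSE)
    } else {
      sigma <- if (is.null(y)) 0 else stats::sd(y - pred)
      replicate(nsim, pred + stats::rnorm(n, 0, sigma), simplify = FALSE)
    }
  })
  out <- as.data.frame(sims, col.names = paste0("sim_", seq_len(nsim)))
  attr(out, "seed") <- seed
  out
}

#' Plot training curves of a split fit
#'
#' Loss (and held-out metric, when evaluated) against epoch.
#'
#' @param x A `split_fit`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.split_fit <- function(x, ...) {
  h <- x$history
  if (!nrow(h)) stopf("nothing to plot: the fit has no completed epochs")
  op <- graphics::par(mfrow = c(1L, if (any(is.finite(h$metric))) 2L else 1L))
  on.exit(graphics::par(op))
  graphics::plot(h$epoch, h$loss, type = "l", xlab = "epoch",
                 ylab = paste(x$spec$loss_name, "loss"),
                 main = "training loss", ...)
  if (any(is.finite(h$metric))) {
    ok <- is.finite(h$metric)
    graphics::plot(h$epoch[ok], h$metric[ok], type = "b", xlab = "epoch",
                   ylab = if (x$classify) "held-out accuracy (%)" else "held-out RMSLE",
                   main = "held-out metric", ...)
  }
  invisible(x)
}

#' Write the epoch history of a fit to CSV
#'
#' @param fit A `split_fit` or `central_fit`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_history <- function(fit, path) {
  utils::write.csv(fit$history, path, row.names = FALSE)
  invisible(path)
}
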