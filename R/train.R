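# Top-level training: the split protocol loop and its centralized
# (monolithic) counterpart, which trains the identical layer stack on the
# pooled data and serves as the exact reference for synchronised split
# training.

prepare_data <- function(spec, x, y, test_fraction, seed) {
  if (spec$architecture == "custom_mlp") {
    x <- as.matrix(x)
    if (ncol(x) != spec$input_shape)
      stopf("expected %d features, got %d", spec$input_shape, ncol(x))
  } else {
    if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
    if (length(dim(x)) != 4L || !identical(as.integer(dim(x)[-1L]), spec$input_shape))
      stopf("expected images [n, %s], got dims [%s]",
            paste(spec$input_shape, collapse = ", "),
            paste(dim(x), collapse = ", "))
  }
  n <- dim(x)[1L]
  if (length(y) != n) stopf("length(y) (%d) != number of samples (%d)", length(y), n)
  classify <- spec$task == "classification"
  if (classify && !all(y %in% c(0, 1)))
    stopf("classification labels must be 0/1")
  tt <- train_test_split(n, labels = if (classify) y else NULL,
                         test_fraction = test_fraction, seed = seed)
  scaling <- NULL
  if (spec$task == "regression") {
    mu <- colMeans(x[tt$train, , drop = FALSE])
    sd_ <- apply(x[tt$train, , drop = FALSE], 2L, stats::sd)
    sd_[sd_ < 1e-12] <- 1
    x <- sweep(sweep(x, 2L, mu), 2L, sd_, "/")
    ymu <- mean(y[tt$train]); ysd <- stats::sd(y[tt$train])
    if (!is.finite(ysd) || ysd < 1e-12) ysd <- 1
    scaling <- list(x_mean = mu, x_sd = sd_, y_mean = ymu, y_sd = ysd)
    y <- (y - ymu) / ysd
  }
  list(x = x, y = y, train = tt$train, test = tt$test,
       classify = classify, scaling = scaling, n = n)
}

take_rows <- function(x, rows) {
  if (length(dim(x)) == 2L) x[rows, , drop = FALSE]
  else x[rows, , , , drop = FALSE]
}

unscale_y <- function(yhat, scaling) {
  if (is.null(scaling)) yhat else yhat * scaling$y_sd + scaling$y_mean
}

# Held-out metric: accuracy (%) for classifiers, RMSLE on the original
# scale for regression (predictions clamped at zero: the target is a
# non-negative concentration).
eval_metric <- function(pred, y, classify, scaling) {
  if (classify) {
    accuracy(pred, y)$value
  } else {
    rmsle(pmax(unscale_y(pred, scaling), 0), unscale_y(y, scaling))$value
  }
}

predict_states <- function(clients, server, x) {
  preds <- 0
  for (cl in clients) {
    fw <- stack_forward(cl$layers, cl$params, x, keep_cache = FALSE)
    sv <- stack_forward(server$layers, server$params, fw$out, keep_cache = FALSE)
    preds <- preds + as.numeric(sv$out)
  }
  preds / length(clients)
}

#' Train a split model across multiple end-systems
#'
#' The main fitting function. Carves out a stratified held-out test set,
#' partitions the remaining samples across end-systems according to the
#' split ratio, and runs the multi-site split learning protocol: every
#' round each client forwards a local mini-batch through its hidden layer,
#' the server concatenates the feature maps, trains the remaining layers,
#' and returns cut-layer gradients that each client applies to its own
#' parameters.
#'
#' With `sync = TRUE` all end-systems share one hidden-layer parameter set:
#' their cut-layer gradients are summed into a single optimiser, which
#' makes the run mathematically identical to centralized training of the
#' monolithic network on the pooled data (see [train_centralized()]). By
#' default clients are independent, as hospitals would be.
#'
#' @param spec A [model_spec()] (e.g. [builtin_spec()]).
#' @param x Samples, batch-first: images `[n, H, W, C]` (or `[n, H, W]`) or
#'   a numeric matrix `[n, features]`.
#' @param y Targets: 0/1 labels for classification, numeric for regression
#'   (features and target are z-scored internally using training-set
#'   statistics for regression).
#' @param ratio Split-ratio string or [parse_ratio()] object, e.g.
#'   `"8:1:1"`.
#' @param seed Integer seed governing initialisation, the test split, the
#'   partition and batch shuffling (via independent derived streams).
#' @param epochs Override of `spec$epochs`.
#' @param global_batch Override of `spec$global_batch_size`.
#' @param lr Adam learning rate for all parameter sets.
#' @param sync Share client hidden-layer weights (see above).
#' @param batch_policy Local batch apportionment: `"proportional"` to local
#'   dataset sizes (default) or `"equal"`.
#' @param test_fraction Fraction held out globally before partitioning.
#' @param eval_every Evaluate the held-out metric every this many epochs.
#' @param keep_round_losses,keep_batch_log Retain per-round training losses
#'   / the exact global batch composition of every round.
#' @param audit_messages Record a log of every message that crossed the
#'   client/server boundary (type, shape, payload checksum).
#' @param verbose Print one line per epoch.
#' @return An object of class `split_fit`; see [predict.split_fit()],
#'   [summary.split_fit()], [plot.split_fit()].
#' @examples
#' d <- make_image_set(80, 16, lesion_contrast = 0.6, noise_sd = 0.05, seed = 1)
#' sp <- model_spec("classification", "custom_cnn", epochs = 2,
#'                  global_batch_size = 16, loss_name = "binary_crossentropy",
#'                  activation_name = "sigmoid", input_shape = c(16, 16, 1),
#'                  n_server_layers = 4)
#' fit <- split_train(sp, d$images, d$labels, ratio = "1:1:1", seed = 1)
#' fit$history
#' @export
split_train <- function(spec, x, y, ratio = "1:1:1", seed = 1L,
                        epochs = NULL, global_batch = NULL, lr = 1e-3,
                        sync = FALSE,
                        batch_policy = c("proportional", "equal"),
                        test_fraction = 0.2, eval_every = 1L,
                        keep_round_losses = FALSE, keep_batch_log = FALSE,
                        audit_messages = FALSE, verbose = FALSE) {
  stopifnot(inherits(spec, "model_spec"))
  batch_policy <- match.arg(batch_policy)
  ratio <- parse_ratio(ratio)
  seed <- check_count(seed, "seed", min = 0L)
  epochs <- if (is.null(epochs)) spec$epochs else check_count(epochs, "epochs", min = 0L)
  B <- if (is.null(global_batch)) spec$global_batch_size
       else check_count(global_batch, "global_batch")
  sync <- check_flag(sync, "sync")

  pd <- prepare_data(spec, x, y, test_fraction, seed)
  K <- length(ratio)
  part <- stratified_partition(if (pd$classify) pd$y[pd$train] else NULL,
                               length(pd$train), ratio, seed = seed)
  # partition indices refer to positions within the training subset;
  # map to global sample indices once.
  part$indices <- lapply(part$indices, function(ii) pd$train[ii])

  model <- build_split_model(spec, seed = seed)
  clients <- make_end_systems(model, part, seed = seed, lr = lr)
  server <- model$server
  server_opt <- adam_init(server$params, lr = lr)
  shared_opt <- if (sync) adam_init(model$client_template$params, lr = lr) else NULL

  n_train <- length(pd$train)
  B_eff <- min(B, max(n_train, K))
  rounds_per_epoch <- max(1L, as.integer(ceiling(n_train / B_eff)))
  lbs <- local_batch_sizes(B_eff, part, policy = batch_policy)

  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        metric = numeric(0), seconds = numeric(0))
  round_losses <- numeric(0)
  batch_log <- if (keep_batch_log) list() else NULL
  messages <- if (audit_messages) list() else NULL
  round_id <- 0L

  for (ep in seq_len(epochs)) {
    t0 <- proc.time()[["elapsed"]]
    ep_losses <- numeric(rounds_per_epoch)
    for (r in seq_len(rounds_per_epoch)) {
      round_id <- round_id + 1L
      maps <- vector("list", K)
      for (k in seq_len(K)) {
        db <- draw_local_batch(clients[[k]], lbs[k])
        clients[[k]] <- db$state
        gidx <- clients[[k]]$local_indices[db$positions]
        clients[[k]]$last_global_idx <- gidx
        cf <- client_forward(clients[[k]], take_rows(pd$x, gidx),
                             pd$y[gidx], batch_index = round_id)
        clients[[k]] <- cf$state
        maps[[k]] <- cf$message
        if (audit_messages)
          messages[[length(messages) + 1L]] <- audit_record(cf$message)
      }
      joined <- concatenate_feature_maps(maps)
      if (keep_batch_log)
        batch_log[[round_id]] <- unlist(lapply(clients, `[[`, "last_global_idx"),
                                        use.names = FALSE)
      st <- server_step(server, server_opt, joined, spec$loss_name)
      server <- st$server; server_opt <- st$opt_state
      ep_losses[r] <- st$loss
      if (sync) {
        total_grads <- NULL
        for (k in seq_len(K)) {
          cb <- client_backward(clients[[k]], st$slices[[k]], update = FALSE)
          clients[[k]] <- cb$state
          total_grads <- grads_add(total_grads, cb$grads)
          if (audit_messages)
            messages[[length(messages) + 1L]] <- audit_record(st$slices[[k]])
        }
        up <- adam_step(shared_opt, clients[[1L]]$params, total_grads)
        shared_opt <- up$state
        for (k in seq_len(K)) clients[[k]]$params <- up$params
      } else {
        for (k in seq_len(K)) {
          cb <- client_backward(clients[[k]], st$slices[[k]], update = TRUE)
          clients[[k]] <- cb$state
          if (audit_messages)
            messages[[length(messages) + 1L]] <- audit_record(st$slices[[k]])
        }
      }
    }
    if (keep_round_losses) round_losses <- c(round_losses, ep_losses)
    metric <- NA_real_
    if (ep %% eval_every == 0L || ep == epochs) {
      pred <- predict_states(clients, server, take_rows(pd$x, pd$test))
      metric <- eval_metric(pred, pd$y[pd$test], pd$classify, pd$scaling)
    }
    history <- rbind(history, data.frame(
      epoch = ep, loss = mean(ep_losses), metric = metric,
      seconds = proc.time()[["elapsed"]] - t0))
    if (verbose)
      message(sprintf("epoch %3d | loss %.5f | %s %.4f", ep, mean(ep_losses),
                      if (pd$classify) "acc%" else "rmsle", metric))
  }

  structure(list(
    spec = spec, ratio = ratio, partition = part, sync = sync,
    lr = lr, global_batch = B_eff, batch_policy = batch_policy,
    seed = seed, epochs = epochs, rounds_per_epoch = rounds_per_epoch,
    local_batch_sizes = lbs,
    clients = clients, server = server,
    scaling = pd$scaling, classify = pd$classify,
    train_idx = pd$train, test_idx = pd$test,
    history = history,
    round_losses = if (keep_round_losses) round_losses else NULL,
    batch_log = batch_log, messages = messages,
    fingerprint = paste(spec$architecture, ratio_label(ratio), seed, epochs,
                        B_eff, lr, sync, batch_policy, sep = "|")
  ), class = "split_fit")
}

# Checksum-bearing record of one message crossing the client/server
# boundary; payloads themselves are not retained.
audit_record <- function(msg) {
  if (inherits(msg, "feature_map")) {
    list(type = "feature_map", client_id = msg$client_id,
         batch_index = msg$batch_index, shape = dim(msg$activations),
         n_labels = length(msg$labels),
         fields = sort(names(msg)),
         checksum = sum(msg$activations))
  } else {
    list(type = "gradient_slice", client_id = msg$client_id,
         shape = dim(msg$grad), fields = sort(names(msg)),
         checksum = sum(msg$grad))
  }
}

#' Centralized (monolithic) training of the same network
#'
#' Trains the identical layer stack — client hidden layer followed by the
#' server layers — as one network on the pooled data. Used both as a
#' baseline and as the exact reference for synchronised split training:
#' given the same seed, learning rate and batch composition, per-step
#' losses agree with [split_train()]`(sync = TRUE)` to floating-point
#' accuracy.
#'
#' @inheritParams split_train
#' @param batch_plan Optional list of global sample-index vectors, one per
#'   round (e.g. the `batch_log` of a [split_train()] run) to replay an
#'   exact batch composition. When `NULL`, batches are drawn from a seeded
#'   cyclic shuffle of the pooled training set.
#' @return An object of class `central_fit` with `history`,
#'   `round_losses`, the fitted `model` (layers + params) and the data
#'   split.
#' @export
train_centralized <- function(spec, x, y, seed = 1L, epochs = NULL,
                              global_batch = NULL, lr = 1e-3,
                              test_fraction = 0.2, batch_plan = NULL,
                              eval_every = 1L, verbose = FALSE) {
  stopifnot(inherits(spec, "model_spec"))
  seed <- check_count(seed, "seed", min = 0L)
  epochs <- if (is.null(epochs)) spec$epochs else check_count(epochs, "epochs", min = 0L)
  B <- if (is.null(global_batch)) spec$global_batch_size
       else check_count(global_batch, "global_batch")
  pd <- prepare_data(spec, x, y, test_fraction, seed)

  model <- build_split_model(spec, seed = seed)
  layers <- c(model$client_template$layers, model$server$layers)
  params <- c(model$client_template$params, model$server$params)
  opt <- adam_init(params, lr = lr)

  n_train <- length(pd$train)
  B_eff <- min(B, n_train)
  rounds_per_epoch <- if (!is.null(batch_plan))
    as.integer(ceiling(length(batch_plan) / max(epochs, 1L)))
  else max(1L, as.integer(ceiling(n_train / B_eff)))

  perm <- integer(0); cursor <- 1L; reshuffles <- 0L
  next_batch <- function(b) {
    out <- integer(0)
    while (length(out) < b) {
      if (cursor > length(perm)) {
        reshuffles <<- reshuffles + 1L
        perm <<- with_seed_(child_seed(seed, 5000L + reshuffles),
                            sample.int(n_train))
        cursor <<- 1L
      }
      take <- min(b - length(out), length(perm) - cursor + 1L)
      out <- c(out, perm[cursor:(cursor + take - 1L)])
      cursor <<- cursor + take
    }
    pd$train[out]
  }

  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        metric = numeric(0), seconds = numeric(0))
  round_losses <- numeric(0)
  round_id <- 0L
  for (ep in seq_len(epochs)) {
    t0 <- proc.time()[["elapsed"]]
    ep_losses <- numeric(0)
    for (r in seq_len(rounds_per_epoch)) {
      round_id <- round_id + 1L
      gidx <- if (!is.null(batch_plan)) {
        if (round_id > length(batch_plan)) break
        batch_plan[[round_id]]
      } else next_batch(B_eff)
      fw <- stack_forward(layers, params, take_rows(pd$x, gidx), keep_cache = TRUE)
      lf <- loss_forward(spec$loss_name, as.numeric(fw$out), pd$y[gidx])
      bw <- stack_backward(layers, params, fw$caches, matrix(lf$dpred, ncol = 1L))
      st <- adam_step(opt, params, bw$dparams)
      params <- st$params; opt <- st$state
      ep_losses <- c(ep_losses, lf$loss)
      round_losses <- c(round_losses, lf$loss)
    }
    metric <- NA_real_
    if (ep %% eval_every == 0L || ep == epochs) {
      pred <- as.numeric(stack_forward(layers, params, take_rows(pd$x, pd$test),
                                       keep_cache = FALSE)$out)
      metric <- eval_metric(pred, pd$y[pd$test], pd$classify, pd$scaling)
    }
    history <- rbind(history, data.frame(
      epoch = ep, loss = mean(ep_losses), metric = metric,
      seconds = proc.time()[["elapsed"]] - t0))
    if (verbose)
      message(sprintf("epoch %3d | loss %.5f | metric %.4f", ep,
                      mean(ep_losses), metric))
  }
  structure(list(
    spec = spec, seed = seed, epochs = epochs, lr = lr,
    global_batch = B_eff, model = list(layers = layers, params = params),
    scaling = pd$scaling, classify = pd$classify,
    train_idx = pd$train, test_idx = pd$test,
    history = history, round_losses = round_losses
  ), class = "central_fit")
}

#' @export
predict.central_fit <- function(object, newdata, ...) {
  x <- newdata
  if (!is.null(object$scaling)) {
    x <- as.matrix(x)
    x <- sweep(sweep(x, 2L, object$scaling$x_mean), 2L, object$scaling$x_sd, "/")
  } else if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  pred <- as.numeric(stack_forward(object$model$layers, object$model$params,
                                   x, keep_cache = FALSE)$out)
  unscale_y(pred, object$scaling)
}
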