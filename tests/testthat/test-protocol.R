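# Protocol-level operations: local batching, the feature-map message
# boundary, server steps, client updates, and the full training loop.

make_tiny_world <- function(size = 16L, n = 48L, ratio = "1:1:1", seed = 1L) {
  d <- make_image_set(n, size, lesion_contrast = 0.6, noise_sd = 0.05, seed = seed)
  sp <- tiny_cnn_spec(size)
  model <- build_split_model(sp, seed = seed)
  part <- stratified_partition(d$labels, n, ratio, seed = seed)
  clients <- make_end_systems(model, part, seed = seed)
  list(d = d, sp = sp, model = model, part = part, clients = clients)
}

test_that("local batch sizes follow largest-remainder apportionment with a floor of one", {
  expect_equal(local_batch_sizes(64L, c(800L, 100L, 100L)), c(51L, 7L, 6L))
  expect_equal(local_batch_sizes(64L, rep(250L, 4L)), rep(16L, 4L))
  expect_equal(local_batch_sizes(5L, c(1000L, 1L)), c(4L, 1L))
  expect_equal(local_batch_sizes(64L, c(800L, 100L, 100L), policy = "equal"),
               c(22L, 21L, 21L))
  expect_error(local_batch_sizes(2L, c(10L, 10L, 10L)), "smaller than the number")
})

test_that("client forward transmits post-activation feature maps, not raw samples", {
  w <- make_tiny_world()
  cl <- w$clients[[1L]]
  x <- w$d$images[cl$local_indices[1:4], , , , drop = FALSE]
  y <- w$d$labels[cl$local_indices[1:4]]
  cf <- client_forward(cl, x, y, batch_index = 1L)
  expect_s3_class(cf$message, "feature_map")
  expect_equal(sort(names(cf$message)),
               c("activations", "batch_index", "client_id", "labels"))
  expect_equal(dim(cf$message$activations), c(4L, client_output_shape(w$sp)))
  expect_equal(cf$message$labels, y)

  # zero-weight hidden layer: post-ReLU activations are exactly zero
  cl0 <- cl
  cl0$params[[1L]]$W[] <- 0
  cl0$params[[1L]]$b[] <- 0
  cf0 <- client_forward(cl0, x, y)
  expect_true(all(cf0$message$activations == 0))

  # identical parameters on two clients give identical activations
  cl2 <- w$clients[[2L]]
  cl2$params <- cl$params
  cf2 <- client_forward(cl2, x, y)
  expect_identical(cf2$message$activations, cf$message$activations)
})

test_that("concatenation is ordered, conservative and exactly invertible", {
  w <- make_tiny_world()
  sizes <- c(6L, 3L, 2L)
  maps <- lapply(seq_along(sizes), function(k) {
    cl <- w$clients[[k]]
    idx <- cl$local_indices[seq_len(sizes[k])]
    client_forward(cl, w$d$images[idx, , , , drop = FALSE], w$d$labels[idx])$message
  })
  joined <- concatenate_feature_maps(rev(maps))   # order by client id, not input order
  expect_equal(dim(joined$activations)[1L], sum(sizes))
  expect_equal(joined$boundaries$client_id, 1:3)
  expect_equal(joined$boundaries$end - joined$boundaries$start + 1L, sizes)
  blocks <- splitsite:::slice_at_boundaries(joined$activations, joined$boundaries)
  for (k in 1:3) expect_identical(blocks[[k]], maps[[k]]$activations)

  single <- concatenate_feature_maps(maps[1L])
  expect_identical(single$activations, maps[[1L]]$activations)

  bad <- maps
  bad[[2L]]$activations <- bad[[2L]]$activations[, 1:4, , , drop = FALSE]
  expect_error(concatenate_feature_maps(bad), "client 2")
  dup <- maps; dup[[2L]]$client_id <- 1
  expect_error(concatenate_feature_maps(dup), "duplicate")
})

test_that("server step computes the stated losses and exact cut gradients", {
  # a server that always predicts 0.5: zero-weight dense + sigmoid
  server <- list(layers = list(layer_flatten(), layer_dense(1L),
                               layer_activation("sigmoid")),
                 params = list(NULL,
                               list(W = matrix(0, 4L, 1L), b = 0),
                               NULL))
  joined <- structure(list(
    activations = array(runif(8L), c(2L, 2L, 2L, 1L)),
    labels = c(1, 1),
    boundaries = data.frame(client_id = 1L, start = 1L, end = 2L)),
    class = "joined_batch")
  st <- server_step(server, NULL, joined, "binary_crossentropy", update = FALSE)
  expect_equal(st$loss, log(2), tolerance = 1e-12)

  # perfect MSE predictions: zero loss and zero gradient at the cut
  server2 <- list(layers = list(layer_dense(1L), layer_activation("linear")),
                  params = list(list(W = matrix(1, 1L, 1L), b = 0), NULL))
  joined2 <- structure(list(activations = matrix(c(0.3, -1.2), 2L),
                            labels = c(0.3, -1.2),
                            boundaries = data.frame(client_id = 1L, start = 1L, end = 2L)),
                       class = "joined_batch")
  st2 <- server_step(server2, NULL, joined2, "mse", update = FALSE)
  expect_equal(st2$loss, 0)
  expect_true(all(st2$slices[[1L]]$grad == 0))

  # finite differences at the cut layer on a small random server
  sp <- tiny_cnn_spec()
  m <- build_split_model(sp, seed = 2L)
  act <- array(runif(prod(c(3L, m$cut_shape))), c(3L, m$cut_shape))
  joined3 <- structure(list(activations = act, labels = c(1, 0, 1),
                            boundaries = data.frame(client_id = 1L, start = 1L, end = 3L)),
                       class = "joined_batch")
  st3 <- server_step(m$server, NULL, joined3, "binary_crossentropy", update = FALSE)
  loss_at <- function(a) {
    j <- joined3; j$activations <- a
    server_step(m$server, NULL, j, "binary_crossentropy", update = FALSE)$loss
  }
  set.seed(3)
  maxrel <- 0
  for (j in sample(length(act), 25L)) {
    eps <- 1e-5
    ap <- act; ap[j] <- act[j] + eps; lp <- loss_at(ap)
    ap[j] <- act[j] - eps; lm <- loss_at(ap)
    fd <- (lp - lm) / (2 * eps)
    g <- st3$slices[[1L]]$grad[j]
    maxrel <- max(maxrel, abs(fd - g) / max(abs(fd), abs(g), 1e-6))
  }
  expect_lt(maxrel, 1e-3)
})

test_that("client backward applies the chain rule and guards its cache", {
  w <- make_tiny_world()
  cl <- w$clients[[1L]]
  idx <- cl$local_indices[1:4]
  cf <- client_forward(cl, w$d$images[idx, , , , drop = FALSE], w$d$labels[idx])
  cl <- cf$state

  # zero gradient slice: Adam with zero moments leaves parameters unchanged
  zero <- splitsite:::new_gradient_slice(1L, array(0, dim(cf$message$activations)))
  cb <- client_backward(cl, zero)
  expect_true(params_identical(cb$state$params, w$clients[[1L]]$params))

  # shape mismatch and missing cache are rejected
  bad <- splitsite:::new_gradient_slice(1L, array(0, c(2L, client_output_shape(w$sp))))
  expect_error(client_backward(cb$state, bad), "no cached batch")
  cf2 <- client_forward(cb$state, w$d$images[idx, , , , drop = FALSE], w$d$labels[idx])
  expect_error(client_backward(cf2$state, bad), "stale batch cache")
  wrong_owner <- splitsite:::new_gradient_slice(2L, array(0, dim(cf$message$activations)))
  expect_error(client_backward(cf2$state, wrong_owner), "client 2")
})

test_that("weight synchronisation averages, broadcasts and is idempotent", {
  w <- make_tiny_world()
  clients <- w$clients[1:2]
  clients[[2L]]$params[[1L]]$W <- -clients[[1L]]$params[[1L]]$W
  clients[[2L]]$params[[1L]]$b <- -clients[[1L]]$params[[1L]]$b
  synced <- sync_client_weights(clients, mode = "mean")
  expect_true(all(synced[[1L]]$params[[1L]]$W == 0))
  expect_true(params_identical(synced[[1L]]$params, synced[[2L]]$params))
  again <- sync_client_weights(synced, mode = "mean")
  expect_true(params_identical(again[[1L]]$params, synced[[1L]]$params))

  bcast <- sync_client_weights(clients, mode = "broadcast")
  expect_true(params_identical(bcast[[2L]]$params, clients[[1L]]$params))

  clients[[2L]]$params[[1L]]$W <- matrix(0, 2L, 2L)
  expect_error(sync_client_weights(clients), "different layer template")
})

test_that("training reduces the loss on a separable set and is deterministic", {
  d <- make_image_set(120L, 16L, lesion_contrast = 0.7, noise_sd = 0.05, seed = 5L)
  sp <- tiny_cnn_spec(16L, epochs = 8L, batch = 24L)
  fit <- split_train(sp, d$images, d$labels, ratio = "1:1:1", seed = 2L)
  expect_lt(fit$history$loss[nrow(fit$history)], fit$history$loss[1L])

  fit2 <- split_train(sp, d$images, d$labels, ratio = "1:1:1", seed = 2L)
  expect_identical(fit$history[c("epoch", "loss", "metric")],
                   fit2$history[c("epoch", "loss", "metric")])
  expect_true(params_identical(coef(fit), coef(fit2)))
})

test_that("zero-epoch training returns the initialisation and empty history", {
  d <- make_image_set(48L, 16L, lesion_contrast = 0.6, noise_sd = 0.05, seed = 1L)
  sp <- tiny_cnn_spec(16L)
  fit <- split_train(sp, d$images, d$labels, ratio = "1:1:1", seed = 3L, epochs = 0L)
  expect_equal(nrow(fit$history), 0L)
  m <- build_split_model(sp, seed = 3L)
  expect_true(params_identical(fit$server$params, m$server$params))
  for (cl in fit$clients)
    expect_true(params_identical(cl$params, m$client_template$params))
})

test_that("only feature maps and gradient slices cross the boundary", {
  d <- make_image_set(48L, 16L, lesion_contrast = 0.6, noise_sd = 0.05, seed = 1L)
  sp <- tiny_cnn_spec(16L, epochs = 2L, batch = 12L)
  fit <- split_train(sp, d$images, d$labels, ratio = "1:1:1", seed = 1L,
                     audit_messages = TRUE)
  types <- vapply(fit$messages, `[[`, character(1L), "type")
  expect_setequal(unique(types), c("feature_map", "gradient_slice"))
  cut <- client_output_shape(sp)
  for (msg in fit$messages) {
    if (msg$type == "feature_map") {
      expect_identical(msg$fields, c("activations", "batch_index", "client_id", "labels"))
      expect_equal(msg$shape[-1L], cut)          # never the raw input shape
      expect_equal(msg$shape[1L], msg$n_labels)
    } else {
      expect_identical(msg$fields, c("client_id", "grad"))
      expect_equal(msg$shape[-1L], cut)
    }
  }
  # conservation: per round, joined batch size equals the sum of local batches
  fmaps <- Filter(function(m) m$type == "feature_map", fit$messages)
  per_round <- split(vapply(fmaps, function(m) m$shape[1L], integer(1L)),
                     rep(seq_len(length(fmaps) / 3L), each = 3L))
  for (r in per_round) expect_equal(sum(r), fit$global_batch)
})

test_that("synchronised split training matches the centralized network step for step", {
  d <- make_image_set(96L, 16L, lesion_contrast = 0.6, noise_sd = 0.05, seed = 4L)
  sp <- tiny_cnn_spec(16L, epochs = 3L, batch = 24L)
  fs <- split_train(sp, d$images, d$labels, ratio = "1:1:1", seed = 7L, sync = TRUE,
                    keep_round_losses = TRUE, keep_batch_log = TRUE)
  fc <- train_centralized(sp, d$images, d$labels, seed = 7L, epochs = 3L,
                          global_batch = 24L, batch_plan = fs$batch_log)
  rel <- abs(fs$round_losses - fc$round_losses) / pmax(abs(fc$round_losses), 1e-12)
  expect_lt(max(rel), 1e-8)
})

test_that("gradient slice element counts add up to the joined gradient", {
  w <- make_tiny_world()
  sizes <- c(5L, 4L, 3L)
  maps <- lapply(1:3, function(k) {
    idx <- w$clients[[k]]$local_indices[seq_len(sizes[k])]
    client_forward(w$clients[[k]], w$d$images[idx, , , , drop = FALSE],
                   w$d$labels[idx])$message
  })
  joined <- concatenate_feature_maps(maps)
  st <- server_step(w$model$server, NULL, joined, "binary_crossentropy")
  total <- sum(vapply(st$slices, function(s) length(s$grad), integer(1L)))
  expect_equal(total, length(joined$activations))
})
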