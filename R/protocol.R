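# The multi-site split learning protocol.
#
# Each end-system holds one hidden layer and its own slice of the training
# data. Every round, all clients forward a local mini-batch through their
# hidden layer and send the resulting feature map (plus the labels for
# those samples) to the server. The server concatenates the maps along the
# sample axis, runs the remaining layers, computes the loss, updates its
# own parameters, and returns to each client the gradient of the loss with
# respect to that client's transmitted activations. Clients complete
# backpropagation through their hidden layer locally. The message boundary
# is explicit: the only objects that cross it are `feature_map` and
# `gradient_slice` values.

new_feature_map <- function(client_id, activations, labels, batch_index) {
  structure(list(client_id = client_id, activations = activations,
                 labels = labels, batch_index = batch_index),
            class = "feature_map")
}

new_gradient_slice <- function(client_id, grad) {
  structure(list(client_id = client_id, grad = grad), class = "gradient_slice")
}

#' @export
print.feature_map <- function(x, ...) {
  cat(sprintf("<feature_map> client %d, batch %d, activations %s\n",
              x$client_id, x$batch_index, paste(dim(x$activations), collapse = "x")))
  invisible(x)
}

# ---- end-system state ------------------------------------------------------

new_end_system <- function(client_id, layers, params, local_indices, seed, lr) {
  structure(list(
    client_id = client_id, layers = layers, params = params,
    local_indices = local_indices,
    perm = integer(0), cursor = 1L, reshuffles = 0L, seed = seed,
    opt = adam_init(params, lr = lr),
    cache = NULL, last_batch_index = NA_integer_
  ), class = "end_system")
}

# Draw the next b local sample positions from a cyclic, seeded shuffle.
draw_local_batch <- function(state, b) {
  n <- length(state$local_indices)
  out <- integer(0)
  while (length(out) < b) {
    if (state$cursor > length(state$perm)) {
      state$reshuffles <- state$reshuffles + 1L
      state$perm <- with_seed_(
        child_seed(state$seed, 1000L + state$client_id * 131L + state$reshuffles),
        sample.int(n))
      state$cursor <- 1L
    }
    take <- min(b - length(out), length(state$perm) - state$cursor + 1L)
    out <- c(out, state$perm[state$cursor:(state$cursor + take - 1L)])
    state$cursor <- state$cursor + take
  }
  list(state = state, positions = out)
}

#' Per-client local batch sizes
#'
#' Apportions the global batch across end-systems by largest remainder,
#' either proportionally to local dataset sizes (so one epoch traverses
#' each client's data about once) or equally, with a minimum of one sample
#' per client.
#'
#' @param global_batch Global batch size shared by all clients each round.
#' @param partition A [stratified_partition()] or an integer vector of
#'   per-client dataset sizes.
#' @param policy `"proportional"` (default) or `"equal"`.
#' @return Integer vector of per-client batch sizes summing to
#'   `global_batch`.
#' @examples
#' local_batch_sizes(64, c(800, 100, 100))  # 51 7 6
#' @export
local_batch_sizes <- function(global_batch, partition,
                              policy = c("proportional", "equal")) {
  policy <- match.arg(policy)
  sizes <- if (inherits(partition, "partition")) lengths(partition$indices)
           else as.integer(partition)
  if (any(sizes < 1L)) stopf("every client must hold at least one sample")
  K <- length(sizes)
  global_batch <- check_count(global_batch, "global_batch")
  if (global_batch < K)
    stopf("global_batch (%d) is smaller than the number of clients (%d)",
          global_batch, K)
  shares <- if (policy == "proportional") sizes else rep(1L, K)
  allocate_counts(global_batch, structure(shares, n_clients = K,
                                          class = "split_ratio"))
}

# ---- protocol operations ---------------------------------------------------

#' Client forward pass: local batch to feature map
#'
#' Runs a batch of the client's own samples through its single hidden layer
#' and packages the resulting activations (with the batch labels) as the
#' message sent to the server. The raw samples are not part of the message.
#'
#' @param state An end-system state (see [split_train()] internals or
#'   [make_end_systems()]).
#' @param batch_samples Array/matrix of samples, batch-first.
#' @param batch_labels Targets for those samples.
#' @param batch_index Round counter carried in the message.
#' @return List with `message` (a `feature_map`) and the updated `state`
#'   (which caches what backpropagation needs).
#' @export
client_forward <- function(state, batch_samples, batch_labels, batch_index = 1L) {
  stopifnot(inherits(state, "end_system"))
  fw <- stack_forward(state$layers, state$params, batch_samples, keep_cache = TRUE)
  if (!all_finite(fw$out))
    stopf("client %d produced non-finite activations at batch %d",
          state$client_id, batch_index)
  state$cache <- fw$caches
  state$last_batch_index <- batch_index
  state$last_out_dim <- dim(fw$out)
  list(message = new_feature_map(state$client_id, fw$out, batch_labels, batch_index),
       state = state)
}

bind_samples <- function(blocks) {
  d1 <- dim(blocks[[1L]])
  rest <- d1[-1L]
  n <- sum(vapply(blocks, function(b) dim(b)[1L], integer(1L)))
  out <- array(0, c(n, rest))
  at <- 1L
  for (b in blocks) {
    nb <- dim(b)[1L]
    if (length(rest) == 1L) out[at:(at + nb - 1L), ] <- b
    else if (length(rest) == 3L) out[at:(at + nb - 1L), , , ] <- b
    else stopf("unsupported activation rank %d", length(rest) + 1L)
    at <- at + nb
  }
  out
}

#' Concatenate client feature maps into the server input
#'
#' Joins feature maps along the sample axis in ascending client id order
#' and records slice boundaries so the inverse (slicing the joined tensor
#' back into per-client blocks) is exact.
#'
#' @param maps List of `feature_map` messages with distinct client ids and
#'   identical per-sample shapes.
#' @return Object of class `joined_batch`: `activations`, `labels`,
#'   and a `boundaries` data frame (`client_id`, `start`, `end`).
#' @export
concatenate_feature_maps <- function(maps) {
  if (!length(maps)) stopf("no feature maps to concatenate")
  ids <- vapply(maps, function(m) m$client_id, numeric(1L))
  if (anyDuplicated(ids)) stopf("duplicate client ids in feature maps")
  maps <- maps[order(ids)]
  shp <- dim(maps[[1L]]$activations)[-1L]
  for (m in maps) {
    if (!identical(dim(m$activations)[-1L], shp))
      stopf("client %d sent activations of shape %s; expected %s",
            m$client_id, paste(dim(m$activations)[-1L], collapse = "x"),
            paste(shp, collapse = "x"))
  }
  sizes <- vapply(maps, function(m) dim(m$activations)[1L], integer(1L))
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1L) + 1L)
  structure(list(
    activations = bind_samples(lapply(maps, `[[`, "activations")),
    labels = unlist(lapply(maps, `[[`, "labels"), use.names = FALSE),
    boundaries = data.frame(client_id = sort(ids), start = starts, end = ends)
  ), class = "joined_batch")
}

# Slice a joined tensor (activations or gradients) back into per-client
# blocks at the recorded boundaries; exact inverse of concatenation.
slice_at_boundaries <- function(x, boundaries) {
  rank <- length(dim(x))
  out <- vector("list", nrow(boundaries))
  for (i in seq_len(nrow(boundaries))) {
    rows <- boundaries$start[i]:boundaries$end[i]
    out[[i]] <- if (rank == 2L) x[rows, , drop = FALSE]
                else x[rows, , , , drop = FALSE]
  }
  names(out) <- paste0("client_", boundaries$client_id)
  out
}

#' One server training step on a concatenated batch
#'
#' Runs the server layer stack on the joined activations, computes the
#' batch-mean loss, updates the server parameters with the configured
#' optimiser, and returns per-client gradient slices (the loss gradient at
#' the cut layer, sliced at the recorded boundaries).
#'
#' @param server List with `layers` and `params` (see
#'   [build_split_model()]).
#' @param opt_state Adam state for the server parameters (created
#'   internally on first use if `NULL`).
#' @param joined A `joined_batch` from [concatenate_feature_maps()].
#' @param loss_name `"binary_crossentropy"` or `"mse"`.
#' @param update Apply the optimiser update (set `FALSE` to inspect
#'   gradients only).
#' @return List: `loss`, `server` (updated), `opt_state`, `slices` (list of
#'   `gradient_slice`), `predictions`.
#' @export
server_step <- function(server, opt_state, joined, loss_name, update = TRUE) {
  stopifnot(inherits(joined, "joined_batch"))
  if (is.null(opt_state)) opt_state <- adam_init(server$params)
  fw <- stack_forward(server$layers, server$params, joined$activations,
                      keep_cache = TRUE)
  pred <- as.numeric(fw$out)
  lf <- loss_forward(loss_name, pred, joined$labels)
  if (!is.finite(lf$loss))
    stopf("non-finite %s loss on a joined batch of %d samples",
          loss_name, length(pred))
  dout <- matrix(lf$dpred, ncol = 1L)
  bw <- stack_backward(server$layers, server$params, fw$caches, dout)
  if (update) {
    st <- adam_step(opt_state, server$params, bw$dparams)
    server$params <- st$params
    opt_state <- st$state
  }
  blocks <- slice_at_boundaries(bw$dx, joined$boundaries)
  slices <- lapply(seq_len(nrow(joined$boundaries)), function(i)
    new_gradient_slice(joined$boundaries$client_id[i], blocks[[i]]))
  list(loss = lf$loss, server = server, opt_state = opt_state,
       slices = slices, predictions = pred)
}

#' Client backward pass at the cut layer
#'
#' Completes backpropagation through the client's hidden layer using the
#' gradient slice returned by the server for its last transmitted feature
#' map, and (optionally) applies the client's own optimiser update.
#'
#' @param state An end-system state that has just run [client_forward()].
#' @param slice A `gradient_slice` whose shape matches the client's last
#'   transmitted activations.
#' @param update Apply the Adam update (`FALSE` returns gradients only, as
#'   used by synchronised training).
#' @return List with the updated `state` and the parameter `grads`.
#' @export
client_backward <- function(state, slice, update = TRUE) {
  stopifnot(inherits(state, "end_system"), inherits(slice, "gradient_slice"))
  if (is.null(state$cache))
    stopf("client %d has no cached batch; run client_forward first", state$client_id)
  if (slice$client_id != state$client_id)
    stopf("gradient slice for client %d given to client %d",
          slice$client_id, state$client_id)
  if (!identical(dim(slice$grad), state$last_out_dim))
    stopf("stale batch cache: slice shape %s does not match last feature map %s",
          paste(dim(slice$grad), collapse = "x"),
          paste(state$last_out_dim, collapse = "x"))
  bw <- stack_backward(state$layers, state$params, state$cache, slice$grad)
  if (update) {
    st <- adam_step(state$opt, state$params, bw$dparams)
    state$params <- st$params
    state$opt <- st$state
  }
  state$cache <- NULL
  list(state = state, grads = bw$dparams)
}

#' Synchronise client hidden-layer parameters
#'
#' Sets every client's parameters to the element-wise mean (or to client
#' 1's copy with `mode = "broadcast"`). Idempotent.
#'
#' @param clients List of end-system states with identical layer templates.
#' @param mode `"mean"` or `"broadcast"`.
#' @return The list of clients with identical parameters.
#' @export
sync_client_weights <- function(clients, mode = c("mean", "broadcast")) {
  mode <- match.arg(mode)
  if (length(clients) < 2L) stopf("need at least 2 clients to synchronise")
  shapes <- lapply(clients, function(cl) lapply(cl$params, function(p)
    if (is.null(p)) NULL else lapply(p, dim)))
  for (k in 2:length(clients))
    if (!identical(shapes[[1L]], shapes[[k]]))
      stopf("client %d has a different layer template", k)
  target <- if (mode == "mean") params_mean(lapply(clients, `[[`, "params"))
            else clients[[1L]]$params
  for (k in seq_along(clients)) clients[[k]]$params <- target
  clients
}

#' Construct end-system states for a partition
#'
#' Every client starts from the same initial hidden-layer template (the
#' one drawn by [build_split_model()]); in independent training their
#' parameters then diverge.
#'
#' @param model A [build_split_model()] result.
#' @param partition A [stratified_partition()] over the training set.
#' @param seed Integer seed for local batch shuffling.
#' @param lr Adam learning rate.
#' @return List of `end_system` states.
#' @export
make_end_systems <- function(model, partition, seed = 1L, lr = 1e-3) {
  stopifnot(inherits(model, "split_model"), inherits(partition, "partition"))
  lapply(seq_along(partition$indices), function(k)
    new_end_system(k, model$client_template$layers, model$client_template$params,
                   partition$indices[[k]], seed, lr))
}
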