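# Split architectures: one hidden layer per end-system, remaining layers on
# the server. Three reference configurations are provided: a small custom
# CNN classifier, a VGG19-style split classifier, and a small regression
# network for tabular cholesterol data.

ARCHITECTURES <- c("custom_cnn", "vgg19_split", "custom_mlp")
LOSSES <- c("binary_crossentropy", "mse")

#' Create and validate a split-model specification
#'
#' A model spec fixes the task, architecture, training hyperparameters and
#' input shape of a split network. Every end-system holds exactly one hidden
#' layer (`n_client_layers = 1`); for image architectures that hidden layer
#' is a Conv2D + 2x2 MaxPool group, for the tabular architecture a dense
#' layer with leaky-ReLU.
#'
#' @param task `"classification"` or `"regression"`.
#' @param architecture One of `"custom_cnn"`, `"vgg19_split"`, `"custom_mlp"`.
#' @param epochs,global_batch_size Positive integers; the global batch is
#'   shared by all end-systems each round.
#' @param loss_name `"binary_crossentropy"` or `"mse"`.
#' @param activation_name Output/head activation family: `"sigmoid"` for the
#'   classifiers, `"leaky_relu"` for the regression network.
#' @param input_shape Per-sample shape: `c(H, W, C)` for images or a single
#'   feature count for tabular data.
#' @param n_server_layers Number of server-side hidden layers (fixed per
#'   architecture: 4 for `custom_cnn`, 19 for `vgg19_split`, 2 for
#'   `custom_mlp`).
#' @param client_filters,client_units Width of the client hidden layer
#'   (convolution filter count / dense unit count).
#' @return An object of class `model_spec`.
#' @seealso [builtin_spec()] for the three reference configurations.
#' @export
model_spec <- function(task, architecture, epochs, global_batch_size,
                       loss_name, activation_name, input_shape,
                       n_server_layers,
                       client_filters = 8L, client_units = 32L) {
  task <- match.arg(task, c("classification", "regression"))
  architecture <- match.arg(architecture, ARCHITECTURES)
  loss_name <- match.arg(loss_name, LOSSES)
  activation_name <- match.arg(activation_name, c("sigmoid", "leaky_relu"))
  epochs <- check_count(epochs, "epochs")
  global_batch_size <- check_count(global_batch_size, "global_batch_size")
  n_server_layers <- check_count(n_server_layers, "n_server_layers")
  input_shape <- as.integer(input_shape)
  if (!length(input_shape) %in% c(1L, 3L) || any(input_shape < 1L))
    stopf("'input_shape' must be c(H, W, C) or a positive feature count")
  if (architecture %in% c("custom_cnn", "vgg19_split") && length(input_shape) != 3L)
    stopf("architecture '%s' needs an image input shape c(H, W, C)", architecture)
  if (architecture == "custom_mlp" && length(input_shape) != 1L)
    stopf("architecture 'custom_mlp' needs a tabular feature count")
  want <- c(custom_cnn = 4L, vgg19_split = 19L, custom_mlp = 2L)[[architecture]]
  if (n_server_layers != want)
    stopf("architecture '%s' requires n_server_layers = %d", architecture, want)
  structure(list(
    task = task, architecture = architecture, epochs = epochs,
    global_batch_size = global_batch_size, loss_name = loss_name,
    activation_name = activation_name, input_shape = input_shape,
    n_client_layers = 1L, n_server_layers = n_server_layers,
    client_filters = check_count(client_filters, "client_filters"),
    client_units = check_count(client_units, "client_units")
  ), class = "model_spec")
}

#' Reference model specifications
#'
#' The three published configurations: `"covid"` (custom CNN classifier,
#' 100 epochs, batch 64, 64x64x1 input, binary cross-entropy, sigmoid,
#' 4 server hidden layers), `"mura"` (VGG19-style split classifier, 50
#' epochs, batch 128, 224x224x1 input, 19 server layers) and
#' `"cholesterol"` (regression network, 200 epochs, batch 2048, MSE,
#' leaky-ReLU, 7 tabular features, 2 server layers).
#'
#' @param name `"covid"`, `"mura"` or `"cholesterol"`.
#' @return A [model_spec()].
#' @examples
#' builtin_spec("covid")$epochs        # 100
#' builtin_spec("cholesterol")$loss_name
#' @export
builtin_spec <- function(name) {
  if (length(name) != 1L || !name %in% c("covid", "mura", "cholesterol"))
    stopf("unknown spec '%s'; valid names: covid, mura, cholesterol",
          paste(name, collapse = ","))
  switch(name,
    covid = model_spec("classification", "custom_cnn", epochs = 100L,
                       global_batch_size = 64L, loss_name = "binary_crossentropy",
                       activation_name = "sigmoid", input_shape = c(64L, 64L, 1L),
                       n_server_layers = 4L),
    mura = model_spec("classification", "vgg19_split", epochs = 50L,
                      global_batch_size = 128L, loss_name = "binary_crossentropy",
                      activation_name = "sigmoid", input_shape = c(224L, 224L, 1L),
                      n_server_layers = 19L, client_filters = 64L),
    cholesterol = model_spec("regression", "custom_mlp", epochs = 200L,
                             global_batch_size = 2048L, loss_name = "mse",
                             activation_name = "leaky_relu", input_shape = 7L,
                             n_server_layers = 2L))
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s / %s\n", x$task, x$architecture))
  cat(sprintf("  input %s | epochs %d | batch %d | loss %s | activation %s\n",
              paste(x$input_shape, collapse = "x"), x$epochs,
              x$global_batch_size, x$loss_name, x$activation_name))
  cat(sprintf("  layers: %d client + %d server\n",
              x$n_client_layers, x$n_server_layers))
  invisible(x)
}

# ---- layer plans -----------------------------------------------------------

# Client hidden layer: Conv2D + activation + 2x2 MaxPool for images,
# Dense + leaky-ReLU for tabular data. The transmitted feature map is
# post-activation, post-pool.
client_layers <- function(spec) {
  if (spec$architecture == "custom_mlp") {
    list(layer_dense(spec$client_units), layer_activation("leaky_relu"))
  } else {
    list(layer_conv2d(spec$client_filters, 3L),
         layer_activation("relu"),
         layer_maxpool2d())
  }
}

vgg19_server_layers <- function() {
  blocks <- list(c(64L, 64L) , c(128L, 128L),
                 c(256L, 256L, 256L, 256L),
                 c(512L, 512L, 512L, 512L),
                 c(512L, 512L, 512L, 512L))
  out <- list()
  for (bl in blocks) {
    for (f in bl) {
      out <- c(out, list(layer_conv2d(f, 3L), layer_activation("relu")))
    }
    out <- c(out, list(layer_maxpool2d()))
  }
  c(out, list(layer_flatten(),
              layer_dense(4096L), layer_activation("relu"),
              layer_dense(4096L), layer_activation("relu"),
              layer_dense(1L), layer_activation("sigmoid")))
}

server_layers <- function(spec) {
  switch(spec$architecture,
    custom_cnn = list(
      layer_conv2d(16L, 3L), layer_activation("relu"), layer_maxpool2d(),
      layer_conv2d(32L, 3L), layer_activation("relu"), layer_maxpool2d(),
      layer_conv2d(64L, 3L), layer_activation("relu"), layer_maxpool2d(),
      layer_flatten(), layer_dense(1L), layer_activation("sigmoid")),
    vgg19_split = vgg19_server_layers(),
    custom_mlp = list(
      layer_dense(16L), layer_activation("leaky_relu"),
      layer_dense(1L), layer_activation("linear")))
}

# Weight-bearing layer count (the unit in which "n layers" is stated).
n_weight_layers <- function(layers) sum(vapply(layers, function(l)
  l$kind %in% c("conv2d", "dense"), logical(1L)))

#' Per-sample shape of the client's transmitted feature map
#'
#' For image architectures the client applies a same-padding convolution and
#' one 2x2 max-pool, so spatial dimensions are halved and the channel count
#' equals the client filter count; for the tabular architecture the shape is
#' the client dense width.
#'
#' @param spec A [model_spec()].
#' @return Integer vector: `c(H/2, W/2, filters)` or the dense unit count.
#' @examples
#' client_output_shape(builtin_spec("covid"))  # 32 32 8
#' @export
client_output_shape <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  stack_output_shape(client_layers(spec), spec$input_shape)
}

#' Build and initialise a split model
#'
#' Materialises the client hidden-layer template and the server layer stack
#' for a spec, with Glorot-uniform weights drawn deterministically from
#' `seed`. The client template is the single parameter set every end-system
#' starts from; the server stack ends in a 1-unit output head (sigmoid for
#' classification, linear for regression).
#'
#' @param spec A [model_spec()].
#' @param seed Integer seed governing initialisation.
#' @return An object of class `split_model`: list with `spec`,
#'   `client_template` (layers + params), `server` (layers + params), and
#'   the cut-layer shape `cut_shape`.
#' @examples
#' m <- build_split_model(builtin_spec("cholesterol"), seed = 1)
#' m$cut_shape
#' @export
build_split_model <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "model_spec"))
  seed <- check_count(seed, "seed", min = 0L)
  cl <- client_layers(spec)
  sl <- server_layers(spec)
  cut <- tryCatch(stack_output_shape(cl, spec$input_shape), error = function(e)
    stopf("input shape %s is incompatible with architecture '%s': %s",
          paste(spec$input_shape, collapse = "x"), spec$architecture,
          conditionMessage(e)))
  tryCatch(stack_output_shape(sl, cut), error = function(e)
    stopf("input shape %s is incompatible with architecture '%s': %s",
          paste(spec$input_shape, collapse = "x"), spec$architecture,
          conditionMessage(e)))
  ini <- with_seed_(child_seed(seed, 1L), {
    ci <- init_stack_params_(cl, spec$input_shape)
    si <- init_stack_params_(sl, ci$out_shape)
    list(ci = ci, si = si)
  })
  if (length(ini$si$out_shape) != 1L || ini$si$out_shape != 1L)
    stopf("server stack must end in a single output unit")
  structure(list(
    spec = spec,
    client_template = list(layers = cl, params = ini$ci$params),
    server = list(layers = sl, params = ini$si$params),
    cut_shape = cut
  ), class = "split_model")
}

#' @export
print.split_model <- function(x, ...) {
  cat(sprintf("<split_model> %s: %d client + %d server weight layers, cut shape %s\n",
              x$spec$architecture,
              n_weight_layers(x$client_template$layers),
              n_weight_layers(x$server$layers),
              paste(x$cut_shape, collapse = "x")))
  invisible(x)
}

# ---- serialisation ---------------------------------------------------------

#' Read/write a model spec as YAML
#'
#' @param spec A [model_spec()].
#' @param path File path; for `spec_to_yaml` omit to get the YAML string.
#' @return `spec_to_yaml` returns the path (or YAML text invisibly);
#'   `spec_from_yaml` returns a [model_spec()].
#' @export
spec_to_yaml <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  txt <- yaml::as.yaml(unclass(spec))
  if (is.null(path)) return(invisible(txt))
  writeLines(txt, path)
  invisible(path)
}

#' @rdname spec_to_yaml
#' @export
spec_from_yaml <- function(path) {
  v <- yaml::read_yaml(path)
  model_spec(v$task, v$architecture, v$epochs, v$global_batch_size,
             v$loss_name, v$activation_name, v$input_shape, v$n_server_layers,
             client_filters = v$client_filters %||% 8L,
             client_units = v$client_units %||% 32L)
}

#' Save or load model parameters
#'
#' Checkpoints are written as R array archives (RDS) holding the client
#' template parameters, per-client parameters and server parameters.
#'
#' @param object A `split_model` or `split_fit`.
#' @param path Destination file.
#' @return `save_checkpoint` returns `path`; `load_checkpoint` the stored list.
#' @export
save_checkpoint <- function(object, path) {
  saveRDS(object, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stopf("checkpoint file '%s' does not exist", path)
  readRDS(path)
}
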