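test_that("builtin specs carry the published configuration values", {
  covid <- builtin_spec("covid")
  expect_equal(covid$epochs, 100L)
  expect_equal(covid$global_batch_size, 64L)
  expect_equal(covid$input_shape, c(64L, 64L, 1L))
  expect_equal(covid$loss_name, "binary_crossentropy")
  expect_equal(covid$activation_name, "sigmoid")
  expect_equal(covid$n_server_layers, 4L)

  mura <- builtin_spec("mura")
  expect_equal(mura$epochs, 50L)
  expect_equal(mura$global_batch_size, 128L)
  expect_equal(mura$input_shape, c(224L, 224L, 1L))
  expect_equal(mura$n_client_layers + mura$n_server_layers, 20L)

  chol <- builtin_spec("cholesterol")
  expect_equal(chol$epochs, 200L)
  expect_equal(chol$global_batch_size, 2048L)
  expect_equal(chol$loss_name, "mse")
  expect_equal(chol$activation_name, "leaky_relu")
  expect_equal(chol$n_server_layers, 2L)

  expect_error(builtin_spec("nope"), "covid, mura, cholesterol")
})

test_that("layer plans have the stated weight-layer counts", {
  n_wl <- splitsite:::n_weight_layers
  covid <- builtin_spec("covid")
  expect_equal(n_wl(splitsite:::client_layers(covid)), 1L)
  expect_equal(n_wl(splitsite:::server_layers(covid)), 4L)

  mura <- builtin_spec("mura")
  expect_equal(n_wl(splitsite:::client_layers(mura)), 1L)
  expect_equal(n_wl(splitsite:::server_layers(mura)), 19L)

  chol <- builtin_spec("cholesterol")
  expect_equal(n_wl(splitsite:::client_layers(chol)), 1L)
  expect_equal(n_wl(splitsite:::server_layers(chol)), 2L)
})

test_that("client output shape halves spatial dims and sets the channel count", {
  expect_equal(client_output_shape(builtin_spec("covid")), c(32L, 32L, 8L))
  expect_equal(client_output_shape(builtin_spec("mura")), c(112L, 112L, 64L))
  expect_equal(client_output_shape(builtin_spec("cholesterol")), 32L)
  sp <- builtin_spec("covid"); sp$client_filters <- 5L
  expect_equal(client_output_shape(sp), c(32L, 32L, 5L))
})

test_that("model construction is deterministic per seed and shape-checked", {
  sp <- tiny_cnn_spec()
  m1 <- build_split_model(sp, seed = 7L)
  m2 <- build_split_model(sp, seed = 7L)
  expect_true(params_identical(m1$client_template$params, m2$client_template$params))
  expect_true(params_identical(m1$server$params, m2$server$params))
  m3 <- build_split_model(sp, seed = 8L)
  expect_false(params_identical(m1$client_template$params, m3$client_template$params))

  bad <- sp; bad$input_shape <- c(8L, 8L, 1L)
  expect_error(build_split_model(bad), "incompatible")
})

test_that("a sample forwards through client then server to one scalar", {
  for (name in c("covid", "cholesterol")) {
    sp <- builtin_spec(name)
    m <- build_split_model(sp, seed = 1L)
    x <- if (name == "covid") array(runif(prod(sp$input_shape)), c(1L, sp$input_shape))
         else matrix(rnorm(sp$input_shape), 1L)
    cut <- splitsite:::stack_forward(m$client_template$layers,
                                     m$client_template$params, x)$out
    expect_equal(dim(cut), c(1L, m$cut_shape))
    out <- splitsite:::stack_forward(m$server$layers, m$server$params, cut)$out
    expect_equal(length(out), 1L)
    expect_true(is.finite(out))
  }
  # VGG19 split checked by shape propagation (224x224x1 -> ... -> scalar)
  mura <- builtin_spec("mura")
  cut <- splitsite:::stack_output_shape(splitsite:::client_layers(mura),
                                        mura$input_shape)
  expect_equal(cut, c(112L, 112L, 64L))
  out <- splitsite:::stack_output_shape(splitsite:::server_layers(mura), cut)
  expect_equal(out, 1L)
})

test_that("analytic gradients match central finite differences on a tiny net", {
  layers <- list(layer_conv2d(2L, 3L), layer_activation("relu"),
                 layer_maxpool2d(), layer_flatten(),
                 layer_dense(1L), layer_activation("sigmoid"))
  ini <- splitsite:::init_stack_params(layers, c(8L, 8L, 1L), seed = 3L)
  set.seed(11)
  x <- array(runif(4L * 8L * 8L), c(4L, 8L, 8L, 1L))
  y <- c(1, 0, 1, 0)
  loss_of <- function(params) {
    fw <- splitsite:::stack_forward(layers, params, x, keep_cache = FALSE)
    splitsite:::loss_forward("binary_crossentropy", as.numeric(fw$out), y)$loss
  }
  fw <- splitsite:::stack_forward(layers, ini$params, x)
  lf <- splitsite:::loss_forward("binary_crossentropy", as.numeric(fw$out), y)
  bw <- splitsite:::stack_backward(layers, ini$params, fw$caches,
                                   matrix(lf$dpred, ncol = 1L))
  expect_lt(fd_grad_check(loss_of, ini$params, bw$dparams), 1e-3)

  # MSE / leaky-ReLU dense path
  layers2 <- list(layer_dense(3L), layer_activation("leaky_relu"),
                  layer_dense(1L), layer_activation("linear"))
  ini2 <- splitsite:::init_stack_params(layers2, 5L, seed = 4L)
  x2 <- matrix(rnorm(20L), 4L)
  y2 <- rnorm(4L)
  loss_of2 <- function(params) {
    fw <- splitsite:::stack_forward(layers2, params, x2, keep_cache = FALSE)
    splitsite:::loss_forward("mse", as.numeric(fw$out), y2)$loss
  }
  fw2 <- splitsite:::stack_forward(layers2, ini2$params, x2)
  lf2 <- splitsite:::loss_forward("mse", as.numeric(fw2$out), y2)
  bw2 <- splitsite:::stack_backward(layers2, ini2$params, fw2$caches,
                                    matrix(lf2$dpred, ncol = 1L))
  expect_lt(fd_grad_check(loss_of2, ini2$params, bw2$dparams), 1e-3)
})

test_that("model specs round-trip through YAML", {
  sp <- builtin_spec("covid")
  path <- withr::local_tempfile(fileext = ".yaml")
  spec_to_yaml(sp, path)
  expect_equal(spec_from_yaml(path), sp)
})

test_that("checkpoints round-trip", {
  m <- build_split_model(tiny_mlp_spec(), seed = 2L)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  expect_true(params_identical(load_checkpoint(path)$server$params, m$server$params))
  expect_error(load_checkpoint(file.path(tempdir(), "no-such.rds")), "does not exist")
})
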