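# Minimal dense/convolutional layer engine.
#
# There is deliberately no external deep-learning dependency: the protocol's
# whole point is explicit control over what crosses the client/server cut,
# so forward and backward passes are written out against plain R arrays.
# Convolutions are expressed as k*k shifted BLAS matrix multiplies, which is
# fast enough for the desk-scale experiments the package targets.
#
# Tensor layout: image batches are arrays [batch, H, W, C]; tabular batches
# are matrices [batch, features]. Per-sample shapes are c(H, W, C) or a
# single feature count.

ACTIVATIONS <- c("sigmoid", "leaky_relu", "relu", "linear")
LEAKY_ALPHA <- 0.01

#' Layer definitions
#'
#' Constructors for the layer vocabulary used by the split architectures:
#' 2-D convolution (stride 1, 'same' zero padding), 2x2 max-pooling
#' (stride 2, odd trailing rows/columns dropped), flatten, dense, and an
#' elementwise activation. A model is an ordered list of these definitions.
#'
#' @param filters,units Number of convolution filters / dense output units.
#' @param kernel Odd convolution kernel size in pixels.
#' @param name Activation name: one of `"sigmoid"`, `"leaky_relu"`,
#'   `"relu"`, `"linear"`.
#' @return A `layer_def` object (a tagged list).
#' @examples
#' layer_conv2d(8)
#' layer_dense(32)
#' @name layer_def
NULL

new_layer <- function(kind, ...) {
  structure(c(list(kind = kind), list(...)), class = "layer_def")
}

#' @rdname layer_def
#' @export
layer_conv2d <- function(filters, kernel = 3L) {
  filters <- check_count(filters, "filters")
  kernel <- check_count(kernel, "kernel")
  if (kernel %% 2L == 0L) stopf("'kernel' must be odd (same padding)")
  new_layer("conv2d", filters = filters, kernel = kernel,
            stride = 1L, padding = "same")
}

#' @rdname layer_def
#' @export
layer_maxpool2d <- function() new_layer("maxpool2d", pool = 2L, stride = 2L)

#' @rdname layer_def
#' @export
layer_flatten <- function() new_layer("flatten")

#' @rdname layer_def
#' @export
layer_dense <- function(units) {
  new_layer("dense", units = check_count(units, "units"))
}

#' @rdname layer_def
#' @export
layer_activation <- function(name) {
  name <- match.arg(name, ACTIVATIONS)
  new_layer("activation", activation = name)
}

#' @export
print.layer_def <- function(x, ...) {
  extra <- switch(x$kind,
    conv2d = sprintf("(%d filters, %dx%d, same)", x$filters, x$kernel, x$kernel),
    maxpool2d = "(2x2, stride 2)",
    dense = sprintf("(%d units)", x$units),
    activation = sprintf("(%s)", x$activation),
    "")
  cat("<layer>", x$kind, extra, "\n")
  invisible(x)
}

# ---- shape propagation -----------------------------------------------------

layer_output_shape <- function(layer, in_shape) {
  switch(layer$kind,
    conv2d = {
      if (length(in_shape) != 3L)
        stopf("conv2d expects an image shape [H, W, C], got length %d", length(in_shape))
      if (any(in_shape < 1L)) stopf("conv2d input has a zero-sized dimension")
      c(in_shape[1L], in_shape[2L], layer$filters)
    },
    maxpool2d = {
      if (length(in_shape) != 3L) stopf("maxpool2d expects an image shape")
      if (in_shape[1L] < 2L || in_shape[2L] < 2L)
        stopf("maxpool2d input %dx%d is too small to pool",
              in_shape[1L], in_shape[2L])
      c(in_shape[1L] %/% 2L, in_shape[2L] %/% 2L, in_shape[3L])
    },
    flatten = prod(in_shape),
    dense = {
      if (length(in_shape) != 1L) stopf("dense expects a flat input; add layer_flatten()")
      layer$units
    },
    activation = in_shape,
    stopf("unknown layer kind '%s'", layer$kind))
}

stack_output_shape <- function(layers, in_shape) {
  for (ly in layers) in_shape <- layer_output_shape(ly, in_shape)
  in_shape
}

# ---- parameter initialisation ---------------------------------------------

glorot_uniform <- function(dims, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -lim, lim), dim = dims)
}

# Returns list(params, out_shape); params parallel to layers (NULL entries
# for parameter-free layers). Call inside with_seed_() for determinism.
init_stack_params_ <- function(layers, in_shape) {
  params <- vector("list", length(layers))
  shape <- in_shape
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    if (ly$kind == "conv2d") {
      k <- ly$kernel; cin <- shape[3L]; cout <- ly$filters
      params[[i]] <- list(
        W = glorot_uniform(c(k, k, cin, cout), k * k * cin, k * k * cout),
        b = numeric(cout))
    } else if (ly$kind == "dense") {
      d <- shape; u <- ly$units
      params[[i]] <- list(W = glorot_uniform(c(d, u), d, u), b = numeric(u))
    }
    shape <- layer_output_shape(ly, shape)
  }
  list(params = params, out_shape = shape)
}

init_stack_params <- function(layers, in_shape, seed) {
  with_seed_(seed, init_stack_params_(layers, in_shape))
}

# ---- activations -----------------------------------------------------------

act_forward <- function(name, z) {
  switch(name,
    sigmoid = 1 / (1 + exp(-z)),
    relu = { z[z < 0] <- 0; z },
    leaky_relu = { neg <- z < 0; z[neg] <- z[neg] * LEAKY_ALPHA; z },
    linear = z)
}

# dy is gradient w.r.t. output; z the pre-activation, y the output.
act_backward <- function(name, dy, z, y) {
  switch(name,
    sigmoid = dy * y * (1 - y),
    relu = dy * (z > 0),
    leaky_relu = dy * ifelse(z > 0, 1, LEAKY_ALPHA),
    linear = dy)
}

# ---- conv2d ----------------------------------------------------------------

pad_hw <- function(x, p) {
  d <- dim(x)
  xp <- array(0, c(d[1L], d[2L] + 2L * p, d[3L] + 2L * p, d[4L]))
  xp[, (p + 1L):(p + d[2L]), (p + 1L):(p + d[3L]), ] <- x
  xp
}

conv2d_forward <- function(x, W, b) {
  d <- dim(x)                       # [n, H, W, Cin]
  k <- dim(W)[1L]; cin <- dim(W)[3L]; cout <- dim(W)[4L]
  if (d[4L] != cin) stopf("conv2d: input has %d channels, kernel expects %d", d[4L], cin)
  p <- (k - 1L) %/% 2L
  n <- d[1L]; H <- d[2L]; Wd <- d[3L]
  xp <- pad_hw(x, p)
  out <- matrix(0, n * H * Wd, cout)
  for (di in seq_len(k)) {
    for (dj in seq_len(k)) {
      slab <- xp[, di:(di + H - 1L), dj:(dj + Wd - 1L), , drop = FALSE]
      dim(slab) <- c(n * H * Wd, cin)
      out <- out + slab %*% matrix(W[di, dj, , ], cin, cout)
    }
  }
  out <- out + rep(b, each = n * H * Wd)
  dim(out) <- c(n, H, Wd, cout)
  list(out = out, x = x)
}

conv2d_backward <- function(cache, W, dout) {
  x <- cache$x
  d <- dim(x); n <- d[1L]; H <- d[2L]; Wd <- d[3L]; cin <- d[4L]
  k <- dim(W)[1L]; cout <- dim(W)[4L]
  p <- (k - 1L) %/% 2L
  xp <- pad_hw(x, p)
  dxp <- array(0, dim(xp))
  dmat <- dout; dim(dmat) <- c(n * H * Wd, cout)
  dW <- array(0, dim(W))
  for (di in seq_len(k)) {
    for (dj in seq_len(k)) {
      slab <- xp[, di:(di + H - 1L), dj:(dj + Wd - 1L), , drop = FALSE]
      dim(slab) <- c(n * H * Wd, cin)
      dW[di, dj, , ] <- crossprod(slab, dmat)
      dslab <- dmat %*% t(matrix(W[di, dj, , ], cin, cout))
      dim(dslab) <- c(n, H, Wd, cin)
      dxp[, di:(di + H - 1L), dj:(dj + Wd - 1L), ] <-
        dxp[, di:(di + H - 1L), dj:(dj + Wd - 1L), , drop = FALSE] + dslab
    }
  }
  db <- colSums(dmat)
  dx <- dxp[, (p + 1L):(p + H), (p + 1L):(p + Wd), , drop = FALSE]
  list(dW = dW, db = db, dx = dx)
}

# ---- maxpool2d -------------------------------------------------------------

maxpool_forward <- function(x) {
  d <- dim(x); n <- d[1L]; H <- d[2L]; Wd <- d[3L]; C <- d[4L]
  Ho <- H %/% 2L; Wo <- Wd %/% 2L
  ri <- seq.int(1L, by = 2L, length.out = Ho)
  ci <- seq.int(1L, by = 2L, length.out = Wo)
  offs <- list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L))
  m <- x[, ri, ci, , drop = FALSE]
  arg <- array(1L, dim(m))
  for (kk in 2:4) {
    cand <- x[, ri + offs[[kk]][1L], ci + offs[[kk]][2L], , drop = FALSE]
    upd <- cand > m              # strict: first maximum wins on ties
    m[upd] <- cand[upd]
    arg[upd] <- kk
  }
  list(out = m, arg = arg, in_dim = d, offs = offs, ri = ri, ci = ci)
}

maxpool_backward <- function(cache, dout) {
  dx <- array(0, cache$in_dim)
  for (kk in 1:4) {
    o <- cache$offs[[kk]]
    sel <- (cache$arg == kk) * dout
    dx[, cache$ri + o[1L], cache$ci + o[2L], ] <- sel
  }
  dx
}

# ---- full stack forward / backward ----------------------------------------

stack_forward <- function(layers, params, x, keep_cache = TRUE) {
  caches <- if (keep_cache) vector("list", length(layers)) else NULL
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    if (ly$kind == "conv2d") {
      fw <- conv2d_forward(x, params[[i]]$W, params[[i]]$b)
      if (keep_cache) caches[[i]] <- fw["x"]
      x <- fw$out
    } else if (ly$kind == "maxpool2d") {
      fw <- maxpool_forward(x)
      if (keep_cache) caches[[i]] <- fw[c("arg", "in_dim", "offs", "ri", "ci")]
      x <- fw$out
    } else if (ly$kind == "flatten") {
      d <- dim(x)
      if (keep_cache) caches[[i]] <- list(in_dim = d)
      dim(x) <- c(d[1L], prod(d[-1L]))
    } else if (ly$kind == "dense") {
      if (keep_cache) caches[[i]] <- list(x = x)
      x <- x %*% params[[i]]$W + rep(params[[i]]$b, each = nrow(x))
    } else if (ly$kind == "activation") {
      z <- x
      x <- act_forward(ly$activation, z)
      if (keep_cache) caches[[i]] <- list(z = z, y = x)
    }
  }
  list(out = x, caches = caches)
}

# dout: gradient of the scalar loss w.r.t. the stack output.
# Returns list(dparams, dx); dparams parallel to params.
stack_backward <- function(layers, params, caches, dout) {
  dparams <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    ly <- layers[[i]]; ca <- caches[[i]]
    if (ly$kind == "conv2d") {
      bw <- conv2d_backward(ca, params[[i]]$W, dout)
      dparams[[i]] <- list(W = bw$dW, b = bw$db)
      dout <- bw$dx
    } else if (ly$kind == "maxpool2d") {
      dout <- maxpool_backward(ca, dout)
    } else if (ly$kind == "flatten") {
      dim(dout) <- ca$in_dim
    } else if (ly$kind == "dense") {
      dparams[[i]] <- list(W = crossprod(ca$x, dout), b = colSums(dout))
      dout <- dout %*% t(params[[i]]$W)
    } else if (ly$kind == "activation") {
      dout <- act_backward(ly$activation, dout, ca$z, ca$y)
    }
  }
  list(dparams = dparams, dx = dout)
}

# ---- losses ----------------------------------------------------------------

BCE_EPS <- 1e-7

# Mean loss over the batch plus gradient w.r.t. predictions.
loss_forward <- function(loss_name, pred, y) {
  n <- length(pred)
  if (length(y) != n) stopf("loss: prediction/label length mismatch (%d vs %d)", n, length(y))
  if (loss_name == "binary_crossentropy") {
    p <- pmin(pmax(pred, BCE_EPS), 1 - BCE_EPS)
    loss <- -mean(y * log(p) + (1 - y) * log(1 - p))
    dpred <- (p - y) / (p * (1 - p)) / n
  } else if (loss_name == "mse") {
    r <- pred - y
    loss <- mean(r * r)
    dpred <- 2 * r / n
  } else stopf("unknown loss '%s'", loss_name)
  list(loss = loss, dpred = dpred)
}
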