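# Shared fixtures and independent oracles, all built in code.

# Small CNN spec at an arbitrary (valid) input size.
tiny_cnn_spec <- function(size = 16L, epochs = 3L, batch = 16L) {
  model_spec("classification", "custom_cnn", epochs = epochs,
             global_batch_size = batch, loss_name = "binary_crossentropy",
             activation_name = "sigmoid", input_shape = c(size, size, 1L),
             n_server_layers = 4L)
}

tiny_mlp_spec <- function(d = 7L, epochs = 3L, batch = 32L) {
  model_spec("regression", "custom_mlp", epochs = epochs,
             global_batch_size = batch, loss_name = "mse",
             activation_name = "leaky_relu", input_shape = d,
             n_server_layers = 2L)
}

# Brute-force apportionment oracle: enumerate every count vector >= 1
# summing to n and return all minimisers of the L1 distance to the ideal
# quotas (ties between minimisers are a convention, not part of optimality).
brute_force_counts <- function(n, shares) {
  K <- length(shares)
  quota <- n * shares / sum(shares)
  parts <- if (K == 2L) {
    c1 <- seq_len(n - 1L)
    cbind(c1, n - c1)
  } else if (K == 3L) {
    g <- expand.grid(c1 = seq_len(n - 2L), c2 = seq_len(n - 2L))
    g$c3 <- n - g$c1 - g$c2
    as.matrix(g[g$c3 >= 1L, ])
  } else {
    g <- expand.grid(c1 = seq_len(n - 3L), c2 = seq_len(n - 3L),
                     c3 = seq_len(n - 3L))
    g$c4 <- n - g$c1 - g$c2 - g$c3
    as.matrix(g[g$c4 >= 1L, ])
  }
  obj <- rowSums(abs(sweep(parts, 2L, quota)))
  unname(parts[obj <= min(obj) + 1e-9, , drop = FALSE])
}

# TRUE if counts is one of the L1-optimal apportionments.
is_optimal_apportionment <- function(counts, n, shares) {
  best <- brute_force_counts(n, shares)
  any(apply(best, 1L, function(b) all(b == counts)))
}

# Central finite-difference gradient of a scalar-valued function of a
# parameter list, at sampled coordinates.
fd_grad_check <- function(loss_of, params, analytic, n_coords = 15L, eps = 1e-5) {
  maxrel <- 0
  for (i in seq_along(params)) {
    if (is.null(params[[i]])) next
    for (nm in names(params[[i]])) {
      p <- params[[i]][[nm]]
      idx <- sample(length(p), min(n_coords, length(p)))
      for (j in idx) {
        pp <- params; pp[[i]][[nm]][j] <- p[j] + eps
        lp <- loss_of(pp)
        pp[[i]][[nm]][j] <- p[j] - eps
        lm <- loss_of(pp)
        fd <- (lp - lm) / (2 * eps)
        g <- analytic[[i]][[nm]][j]
        maxrel <- max(maxrel, abs(fd - g) / max(abs(fd), abs(g), 1e-6))
      }
    }
  }
  maxrel
}

# Flattened cholesterol design matrix (predictors only).
chol_x <- function(d) {
  as.matrix(as.data.frame(d)[, c("age", "sex", "height", "weight",
                                 "TC", "HDL_C", "TG")])
}

params_identical <- function(a, b) isTRUE(all.equal(a, b, tolerance = 0))
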