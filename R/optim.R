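# Adam optimiser over a layer stack's parameter list.
# State is kept per parameter array (first/second moments + shared step
# counter); client and server stacks each own an independent state, except
# in synchronised training where one client state is shared by design.

adam_init <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  m <- lapply(params, function(p) {
    if (is.null(p)) return(NULL)
    lapply(p, function(a) { a[] <- 0; a })   # zero moments, same shape class
  })
  list(m = m, v = m, t = 0L, lr = lr, beta1 = beta1, beta2 = beta2, eps = eps)
}

# Returns list(params, state). grads has the same nesting as params; NULL
# gradient entries leave the corresponding parameters untouched.
adam_step <- function(state, params, grads) {
  state$t <- state$t + 1L
  b1 <- state$beta1; b2 <- state$beta2
  corr1 <- 1 - b1^state$t
  corr2 <- 1 - b2^state$t
  for (i in seq_along(params)) {
    if (is.null(params[[i]]) || is.null(grads[[i]])) next
    for (nm in names(params[[i]])) {
      g <- grads[[i]][[nm]]
      state$m[[i]][[nm]] <- b1 * state$m[[i]][[nm]] + (1 - b1) * g
      state$v[[i]][[nm]] <- b2 * state$v[[i]][[nm]] + (1 - b2) * g * g
      mhat <- state$m[[i]][[nm]] / corr1
      vhat <- state$v[[i]][[nm]] / corr2
      params[[i]][[nm]] <- params[[i]][[nm]] - state$lr * mhat / (sqrt(vhat) + state$eps)
    }
  }
  list(params = params, state = state)
}

# Elementwise sum of two gradient lists with params nesting.
grads_add <- function(a, b) {
  if (is.null(a)) return(b)
  for (i in seq_along(b)) {
    if (is.null(b[[i]])) next
    if (is.null(a[[i]])) { a[[i]] <- b[[i]]; next }
    for (nm in names(b[[i]])) a[[i]][[nm]] <- a[[i]][[nm]] + b[[i]][[nm]]
  }
  a
}

params_mean <- function(plists) {
  K <- length(plists)
  out <- plists[[1L]]
  for (i in seq_along(out)) {
    if (is.null(out[[i]])) next
    for (nm in names(out[[i]])) {
      acc <- out[[i]][[nm]]
      for (k in 2:K) acc <- acc + plists[[k]][[i]][[nm]]
      out[[i]][[nm]] <- acc / K
    }
  }
  out
}
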