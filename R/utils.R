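# Internal helpers: seeded evaluation without touching the caller's RNG,
# derived seed streams, and small argument checks.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores the global `.Random.seed`, so seeded internals never
#' perturb the caller's random number stream.
#' @noRd
with_seed_ <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derived, collision-avoiding child seed kept below 2^31 - 1.
child_seed <- function(seed, k) {
  s <- (as.double(seed) %% 1000003) + 1
  as.integer((s * 8191 + as.double(k) * 127 + 1) %% 2147483647)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

# sample() that never interprets a length-1 x as 1:x
resample <- function(x, k = length(x)) x[sample.int(length(x), k)]

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != as.integer(x) || x < min)
    stopf("'%s' must be a single integer >= %d", name, min)
  as.integer(x)
}

check_flag <- function(x, name) {
  if (length(x) != 1L || !is.logical(x) || is.na(x))
    stopf("'%s' must be TRUE or FALSE", name)
  x
}

all_finite <- function(x) all(is.finite(x))

# Stable numeric formatting used wherever byte-reproducible text output is
# promised (grid CSVs).
fmt_num <- function(x) formatC(x, digits = 12, format = "g")
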