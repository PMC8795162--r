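# Synthetic desk-scale stand-ins for the three study datasets: two-class
# grayscale medical-style images (lesion present / absent) and a
# cholesterol table whose target follows the clinical Friedewald relation
# LDL-C = TC - HDL-C - TG/5, so the regression ground truth is known
# exactly and nuisance covariates (age, sex, height, weight) carry no
# signal.

gaussian_kernel <- function(sigma) {
  k <- 2L * as.integer(ceiling(2 * sigma)) + 1L
  ax <- seq_len(k) - (k + 1L) / 2
  g <- exp(-outer(ax^2, ax^2, "+") / (2 * sigma^2))
  g / sum(g)
}

#' Generate a two-class synthetic grayscale image set
#'
#' Negative-class images are a smoothed Gaussian background texture with
#' per-image pixel mean fixed at 0.3; positive-class images additionally
#' contain 1-3 bright elliptical blobs of the stated contrast at random
#' in-frame positions (a crude lesion). Optional white pixel noise is
#' added and values are clipped to \[0, 1\]. Classes are balanced to
#' within one sample and the whole set is deterministic per seed.
#'
#' @param n Number of images (>= 4).
#' @param size Image side in pixels (>= 8); images are `size x size x 1`.
#' @param lesion_contrast Peak added intensity of a blob (> 0).
#' @param noise_sd Standard deviation of added white pixel noise.
#' @param seed Integer seed.
#' @return Object of class `synthetic_image_set`: `images` `[n, size,
#'   size, 1]` in \[0, 1\], binary `labels` (1 = lesion present), and the
#'   generation parameters.
#' @examples
#' d <- make_image_set(20, 16, lesion_contrast = 0.5, noise_sd = 0.1, seed = 1)
#' table(d$labels)
#' @export
make_image_set <- function(n, size = 32L, lesion_contrast = 0.5,
                           noise_sd = 0.1, seed = 1L) {
  n <- check_count(n, "n", min = 4L)
  size <- check_count(size, "size", min = 8L)
  if (lesion_contrast <= 0)
    stopf("'lesion_contrast' must be > 0; the classes would be indistinguishable")
  if (noise_sd < 0) stopf("'noise_sd' must be >= 0")
  seed <- check_count(seed, "seed", min = 0L)

  base_mean <- 0.3
  texture_amp <- 0.08
  n_pos <- n %/% 2L

  with_seed_(child_seed(seed, 101L), {
    labels <- integer(n)
    labels[sample.int(n, n_pos)] <- 1L

    raw <- array(stats::rnorm(n * size * size), c(n, size, size, 1L))
    gk <- gaussian_kernel(size / 16)
    sm <- conv2d_forward(raw, array(gk, c(dim(gk), 1L, 1L)), 0)$out
    # fix each image's background mean exactly at base_mean
    for (i in seq_len(n)) {
      m <- sm[i, , , 1L]
      m <- (m - mean(m)) / max(stats::sd(m), 1e-12)
      sm[i, , , 1L] <- base_mean + texture_amp * m
    }
    imgs <- sm

    for (i in which(labels == 1L)) {
      n_blobs <- sample(1:3, 1L)
      gy <- matrix(seq_len(size), size, size)
      gx <- t(gy)
      for (b in seq_len(n_blobs)) {
        cy <- stats::runif(1, 0.25, 0.75) * size
        cx <- stats::runif(1, 0.25, 0.75) * size
        a <- stats::runif(1, size / 10, size / 5)
        bb <- stats::runif(1, size / 10, size / 5)
        th <- stats::runif(1, 0, pi)
        u <- (gy - cy) * cos(th) + (gx - cx) * sin(th)
        v <- -(gy - cy) * sin(th) + (gx - cx) * cos(th)
        imgs[i, , , 1L] <- imgs[i, , , 1L] +
          lesion_contrast * exp(-((u / a)^2 + (v / bb)^2))
      }
    }
    if (noise_sd > 0)
      imgs <- imgs + array(stats::rnorm(length(imgs), 0, noise_sd), dim(imgs))
    imgs[imgs < 0] <- 0
    imgs[imgs > 1] <- 1

    structure(list(images = imgs, labels = labels,
                   params = list(n = n, size = size,
                                 lesion_contrast = lesion_contrast,
                                 noise_sd = noise_sd, seed = seed)),
              class = "synthetic_image_set")
  })
}

#' @export
print.synthetic_image_set <- function(x, ...) {
  p <- x$params
  cat(sprintf("<synthetic_image_set> %d images %dx%dx1, %d positive, contrast %.2f, noise sd %.2f, seed %d\n",
              p$n, p$size, p$size, sum(x$labels), p$lesion_contrast,
              p$noise_sd, p$seed))
  invisible(x)
}

rtrunc_norm <- function(n, mean, sd, lower, upper = Inf) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out <= lower | out >= upper)
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] <= lower | out[bad] >= upper]
  }
  out
}

#' Generate a synthetic cholesterol table
#'
#' Covariates: age ~ Uniform(20, 80) years, sex ~ Bernoulli(0.5), height ~
#' Normal(165, 10) cm, weight ~ Normal(70, 15) kg, TC ~ Normal(190, 35)
#' mg/dL (truncated positive), HDL-C ~ Normal(55, 12) truncated into (0,
#' TC), TG ~ LogNormal(log 120, 0.4) mg/dL. The target follows the
#' Friedewald relation `LDL_C = TC - HDL_C - TG/5 + e`, `e ~ Normal(0,
#' noise_sd)`, floored at zero. Age, sex, height and weight are nuisance
#' covariates with no effect on the target.
#'
#' @param n Number of rows (>= 10).
#' @param noise_sd Noise standard deviation in mg/dL (>= 0).
#' @param seed Integer seed.
#' @return A data frame of class `synthetic_cholesterol_set` with columns
#'   `age, sex, height, weight, TC, HDL_C, TG, LDL_C`.
#' @examples
#' d <- make_cholesterol_set(100, noise_sd = 0, seed = 1)
#' all.equal(d$LDL_C, pmax(d$TC - d$HDL_C - d$TG / 5, 0))
#' @export
make_cholesterol_set <- function(n, noise_sd = 5, seed = 1L) {
  n <- check_count(n, "n", min = 10L)
  if (noise_sd < 0) stopf("'noise_sd' must be >= 0")
  seed <- check_count(seed, "seed", min = 0L)
  with_seed_(child_seed(seed, 202L), {
    TC <- rtrunc_norm(n, 190, 35, lower = 1)
    d <- data.frame(
      age = stats::runif(n, 20, 80),
      sex = stats::rbinom(n, 1L, 0.5),
      height = stats::rnorm(n, 165, 10),
      weight = stats::rnorm(n, 70, 15),
      TC = TC,
      HDL_C = vapply(TC, function(tc) rtrunc_norm(1L, 55, 12, 0, tc), numeric(1L)),
      TG = stats::rlnorm(n, log(120), 0.4))
    d$LDL_C <- pmax(d$TC - d$HDL_C - d$TG / 5 +
                      if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else 0, 0)
    structure(d, noise_sd = noise_sd, seed = seed,
              class = c("synthetic_cholesterol_set", "data.frame"))
  })
}

CHOLESTEROL_COLUMNS <- c("age", "sex", "height", "weight", "TC", "HDL_C", "TG", "LDL_C")

# ---- fixtures --------------------------------------------------------------

#' Save or load a synthetic dataset fixture
#'
#' Image sets round-trip bitwise through an R array archive (RDS);
#' cholesterol tables through CSV with the canonical attribute header
#' `age,sex,height,weight,TC,HDL_C,TG,LDL_C` (values exact to at least six
#' decimals). Missing and corrupt files raise distinguishable errors.
#'
#' @param set A `synthetic_image_set` or `synthetic_cholesterol_set`.
#' @param path Destination: `.rds` for image sets, `.csv` for tables.
#' @return `save_fixture` returns `path`; `load_fixture` the restored set.
#' @export
save_fixture <- function(set, path) {
  if (inherits(set, "synthetic_image_set")) {
    saveRDS(set, path)
  } else if (inherits(set, "synthetic_cholesterol_set")) {
    utils::write.csv(as.data.frame(set)[CHOLESTEROL_COLUMNS], path,
                     row.names = FALSE)
  } else stopf("don't know how to save an object of class '%s'", class(set)[1L])
  invisible(path)
}

#' @rdname save_fixture
#' @export
load_fixture <- function(path) {
  if (!file.exists(path)) stopf("fixture file '%s' does not exist", path)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    d <- tryCatch(utils::read.csv(path),
                  error = function(e) stopf("corrupt fixture '%s': %s", path, conditionMessage(e)))
    if (!identical(names(d), CHOLESTEROL_COLUMNS))
      stopf("corrupt fixture '%s': header %s does not match %s", path,
            paste(names(d), collapse = ","), paste(CHOLESTEROL_COLUMNS, collapse = ","))
    class(d) <- c("synthetic_cholesterol_set", "data.frame")
    d
  } else {
    out <- tryCatch(readRDS(path),
                    error = function(e) stopf("corrupt fixture '%s': %s", path, conditionMessage(e)))
    if (!inherits(out, "synthetic_image_set"))
      stopf("corrupt fixture '%s': not a synthetic_image_set archive", path)
    out
  }
}
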