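# Split-ratio parsing and sample-to-end-system assignment.
#
# Integer allocation uses largest-remainder (Hamilton) apportionment with
# ties broken toward the lower client index, which reproduces the printed
# ratios of the imbalance grid exactly (e.g. 1000 samples at 8:1:1 ->
# 800/100/100) and is exactly optimal in L1 distance to the ideal quotas.

#' Parse a split-ratio string
#'
#' Ratios are written as colon-separated positive integers, e.g. `"8:1:1"`
#' or `"6:1:1:1:1"`; order is significant (client 1 receives the first
#' share).
#'
#' @param text A single ratio string.
#' @return An object of class `split_ratio`: integer vector of shares with
#'   attribute `n_clients`.
#' @examples
#' parse_ratio("8:1:1")
#' @export
parse_ratio <- function(text) {
  if (inherits(text, "split_ratio")) return(text)
  if (length(text) != 1L || !is.character(text) || is.na(text))
    stopf("ratio must be a single string like '8:1:1'")
  toks <- strsplit(text, ":", fixed = TRUE)[[1L]]
  if (length(toks) < 2L || length(toks) > 16L)
    stopf("ratio must have between 2 and 16 fields, got %d", length(toks))
  shares <- integer(length(toks))
  for (i in seq_along(toks)) {
    v <- suppressWarnings(as.numeric(toks[i]))
    if (!nzchar(toks[i]) || is.na(v) || v != as.integer(v) || v < 1)
      stopf("ratio field %d ('%s') is not a positive integer", i, toks[i])
    shares[i] <- as.integer(v)
  }
  structure(shares, n_clients = length(shares), class = "split_ratio")
}

#' @export
print.split_ratio <- function(x, ...) {
  cat("<split_ratio>", paste(unclass(x), collapse = ":"),
      sprintf("(%d clients)\n", attr(x, "n_clients")))
  invisible(x)
}

ratio_label <- function(ratio) paste(as.integer(ratio), collapse = ":")

#' Apportion a sample count across end-systems
#'
#' Largest-remainder apportionment of `n_samples` by the ratio shares:
#' each client gets the floor of its ideal quota, leftovers go to the
#' largest fractional remainders (ties to the lower client index), and a
#' minimum of one sample per client is enforced by taking units from the
#' clients with the largest excess over their ideal quota, which keeps the
#' allocation optimal in L1 distance to the quotas.
#'
#' @param n_samples Total number of samples (must be at least the number of
#'   clients).
#' @param ratio A `split_ratio` or ratio string.
#' @return Integer vector of per-client counts summing to `n_samples`.
#' @examples
#' allocate_counts(1000, "8:1:1")  # 800 100 100
#' allocate_counts(10, "1:1:1")    # 4 3 3
#' @export
allocate_counts <- function(n_samples, ratio) {
  ratio <- parse_ratio(ratio)
  K <- length(ratio)
  n_samples <- check_count(n_samples, "n_samples", min = 0L)
  if (n_samples < K)
    stopf("n_samples (%d) is smaller than the number of clients (%d)", n_samples, K)
  shares <- as.numeric(ratio)
  S <- sum(shares)
  # exact integer arithmetic: quota_i = n * s_i / S, remainder kept as the
  # integer numerator (n * s_i) mod S so ties are exact, not float noise
  num <- n_samples * shares
  counts <- as.integer(num %/% S)
  rem_num <- num %% S
  leftover <- n_samples - sum(counts)
  if (leftover > 0L) {
    take <- order(-rem_num, seq_len(K))[seq_len(leftover)]
    counts[take] <- counts[take] + 1L
  }
  # enforce a minimum of one sample per client; each unit is taken from the
  # donor with the largest excess over its ideal quota (the L1-optimal
  # repair), ties to the lower client index
  quota <- num / S
  while (any(counts == 0L)) {
    excess <- counts - quota
    excess[counts < 2L] <- -Inf
    donor <- which.max(excess)
    counts[donor] <- counts[donor] - 1L
    counts[which(counts == 0L)[1L]] <- 1L
  }
  counts
}

# Per-client-per-class count matrix [K, n_classes]: row sums exhaust the
# given capacities exactly, columns track capacity proportions within +/- 1.
class_allocation <- function(cap, class_sizes) {
  K <- length(cap)
  ncls <- length(class_sizes)
  M <- matrix(0L, K, ncls)
  for (j in seq_len(ncls)) {
    if (j == ncls) { M[, j] <- cap; break }
    quota <- pmin(cap, class_sizes[j] * cap / sum(cap))
    base <- as.integer(floor(quota))
    rem <- quota - base
    left <- class_sizes[j] - sum(base)
    ord <- order(-rem, seq_len(K))
    for (i in ord) {
      if (left == 0L) break
      if (base[i] < cap[i]) { base[i] <- base[i] + 1L; left <- left - 1L }
    }
    M[, j] <- base
    cap <- cap - base
  }
  M
}

#' Partition samples across end-systems
#'
#' Deterministically assigns sample indices `1:n_samples` to clients in the
#' proportions of `ratio`. With class labels supplied (the default for
#' classification data) the assignment is stratified: each client's class
#' mix matches the global mix to within one sample per class. Classes with
#' fewer members than clients are dealt round-robin with a warning.
#'
#' @param labels Per-sample class labels, or `NULL` for unstratified
#'   assignment.
#' @param n_samples Number of samples to partition.
#' @param ratio A `split_ratio` or ratio string.
#' @param seed Integer seed; identical inputs and seed give an identical
#'   partition.
#' @return An object of class `partition`: list of per-client index
#'   vectors, with the ratio, seed and stratification flag attached.
#' @examples
#' p <- stratified_partition(rep(0:1, 50), 100, "8:1:1", seed = 1)
#' lengths(p$indices)
#' @export
stratified_partition <- function(labels, n_samples, ratio, seed = 1L) {
  ratio <- parse_ratio(ratio)
  n_samples <- check_count(n_samples, "n_samples")
  seed <- check_count(seed, "seed", min = 0L)
  if (!is.null(labels) && length(labels) != n_samples)
    stopf("length(labels) (%d) != n_samples (%d)", length(labels), n_samples)
  K <- length(ratio)
  counts <- allocate_counts(n_samples, ratio)
  idx <- vector("list", K)
  if (is.null(labels)) {
    perm <- with_seed_(child_seed(seed, 11L), sample.int(n_samples))
    ends <- cumsum(counts)
    starts <- c(1L, head(ends, -1L) + 1L)
    for (i in seq_len(K)) idx[[i]] <- sort(perm[starts[i]:ends[i]])
  } else {
    f <- factor(labels)
    lv <- levels(f)
    cls_sizes <- as.integer(table(f))
    small <- cls_sizes < K
    if (any(small))
      warning(sprintf("class(es) %s have fewer samples than clients; assigned round-robin",
                      paste(lv[small], collapse = ", ")), call. = FALSE)
    cap <- counts
    assigned <- vector("list", K)
    # degenerate classes first: round-robin over clients with free capacity
    for (j in which(small)) {
      members <- with_seed_(child_seed(seed, 20L + j), resample(which(f == lv[j])))
      k <- 1L
      for (s in members) {
        while (cap[k] == 0L) k <- (k %% K) + 1L
        assigned[[k]] <- c(assigned[[k]], s)
        cap[k] <- cap[k] - 1L
        k <- (k %% K) + 1L
      }
    }
    big <- which(!small)
    if (length(big)) {
      M <- class_allocation(cap, cls_sizes[big])
      for (jj in seq_along(big)) {
        j <- big[jj]
        members <- with_seed_(child_seed(seed, 20L + j), resample(which(f == lv[j])))
        pos <- 1L
        for (i in seq_len(K)) {
          take <- M[i, jj]
          if (take > 0L) {
            assigned[[i]] <- c(assigned[[i]], members[pos:(pos + take - 1L)])
            pos <- pos + take
          }
        }
      }
    }
    for (i in seq_len(K)) idx[[i]] <- sort(assigned[[i]])
  }
  structure(list(indices = idx, ratio = ratio, seed = seed,
                 stratified = !is.null(labels), n_samples = n_samples),
            class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("<partition> %d samples over %d clients (ratio %s, seed %d%s)\n",
              x$n_samples, length(x$indices), ratio_label(x$ratio), x$seed,
              if (x$stratified) ", stratified" else ""))
  cat("  sizes:", paste(lengths(x$indices), collapse = " "), "\n")
  invisible(x)
}

#' Stratified train/test split
#'
#' Carves a global held-out test set before any end-system partitioning.
#'
#' @param n Number of samples.
#' @param labels Optional class labels for stratification.
#' @param test_fraction Fraction held out (default 0.2).
#' @param seed Integer seed.
#' @return List with integer vectors `train` and `test`.
#' @export
train_test_split <- function(n, labels = NULL, test_fraction = 0.2, seed = 1L) {
  n <- check_count(n, "n", min = 2L)
  if (test_fraction <= 0 || test_fraction >= 1)
    stopf("'test_fraction' must be in (0, 1)")
  n_test <- max(1L, as.integer(round(n * test_fraction)))
  test <- if (is.null(labels)) {
    with_seed_(child_seed(seed, 31L), sample.int(n, n_test))
  } else {
    f <- factor(labels)
    picks <- integer(0)
    quota <- as.integer(round(table(f) * test_fraction))
    for (j in seq_along(levels(f))) {
      members <- which(f == levels(f)[j])
      k <- min(length(members), quota[j])
      if (k > 0L)
        picks <- c(picks, with_seed_(child_seed(seed, 40L + j), resample(members, k)))
    }
    picks
  }
  test <- sort(test)
  list(train = setdiff(seq_len(n), test), test = test)
}

#' Serialise a partition to JSON
#'
#' @param partition A [stratified_partition()] result.
#' @param path Optional output file.
#' @return JSON text (invisibly if written to `path`).
#' @export
partition_to_json <- function(partition, path = NULL) {
  stopifnot(inherits(partition, "partition"))
  obj <- list(
    ratio = ratio_label(partition$ratio),
    seed = partition$seed,
    stratified = partition$stratified,
    n_samples = partition$n_samples,
    clients = stats::setNames(partition$indices,
                              paste0("client_", seq_along(partition$indices))))
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE)
  if (!is.null(path)) { writeLines(txt, path); return(invisible(txt)) }
  txt
}

#' @rdname partition_to_json
#' @export
partition_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  structure(list(indices = unname(lapply(obj$clients, as.integer)),
                 ratio = parse_ratio(obj$ratio), seed = as.integer(obj$seed),
                 stratified = isTRUE(obj$stratified),
                 n_samples = as.integer(obj$n_samples)),
            class = "partition")
}
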