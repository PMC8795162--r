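# Experiment grid runner over {number of end-systems} x {split ratio},
# reproducing the structure of the published imbalance tables on synthetic
# or user-supplied data.

DEFAULT_RATIOS <- list(
  `3` = c("1:1:1", "7:2:1", "8:1:1"),
  `4` = c("1:1:1:1", "4:3:2:1", "7:1:1:1"),
  `5` = c("1:1:1:1:1", "4:2:2:1:1", "6:1:1:1:1"))

#' Define an experiment grid
#'
#' The default grid is the published nine-cell design: 3, 4 and 5
#' end-systems, each with an equal, imbalanced and extreme-imbalanced
#' split ratio.
#'
#' @param counts Client counts to test.
#' @param ratios Named list mapping each count (as character) to its ratio
#'   strings; every ratio must have as many shares as its count.
#' @param seeds Integer seeds; each cell is run once per seed.
#' @param epochs Per-cell epoch override (`NULL` = the model spec's).
#' @return An object of class `grid_spec`.
#' @examples
#' grid_spec()            # the nine published cells
#' grid_spec(counts = 3, seeds = 1:2)
#' @export
grid_spec <- function(counts = c(3L, 4L, 5L), ratios = DEFAULT_RATIOS,
                      seeds = 1L, epochs = NULL) {
  counts <- as.integer(counts)
  if (!length(counts)) stopf("grid must contain at least one client count")
  for (ct in counts) {
    key <- as.character(ct)
    if (is.null(ratios[[key]]) || !length(ratios[[key]]))
      stopf("no ratios given for %d end-systems", ct)
    for (rt in ratios[[key]]) {
      pr <- parse_ratio(rt)
      if (length(pr) != ct)
        stopf("ratio '%s' has %d shares but is listed under %d end-systems",
              rt, length(pr), ct)
    }
  }
  if (!is.null(epochs)) epochs <- check_count(epochs, "epochs", min = 0L)
  structure(list(counts = counts, ratios = ratios[as.character(counts)],
                 seeds = as.integer(seeds), epochs = epochs),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  n_cells <- sum(lengths(x$ratios))
  cat(sprintf("<grid_spec> %d cells x %d seed(s)\n", n_cells, length(x$seeds)))
  for (key in names(x$ratios))
    cat(sprintf("  %s end-systems: %s\n", key, paste(x$ratios[[key]], collapse = ", ")))
  invisible(x)
}

cell_marker <- function(out_dir, count, ratio, seed) {
  file.path(out_dir, sprintf("cell_%d_%s_seed%d.json", count,
                             gsub(":", "-", ratio, fixed = TRUE), seed))
}

#' Run an experiment grid
#'
#' For every (count, ratio, seed) cell: carve a stratified test split,
#' partition the training set by the ratio, train via [split_train()] and
#' record the final held-out metric. Completed cells leave a JSON marker
#' in `out_dir` and are skipped on re-runs; a failed cell is recorded and
#' the remaining cells continue. Two CSVs are written: `results.csv` (one
#' row per cell) and `results_table.csv` in the published wide layout
#' (end-systems / split ratio / metric); both are byte-reproducible for a
#' fixed grid and seed.
#'
#' @param grid A [grid_spec()].
#' @param spec A [model_spec()] for every cell.
#' @param x,y The full dataset (see [split_train()]).
#' @param out_dir Output directory for markers, per-cell histories and
#'   result CSVs.
#' @param lr,global_batch,test_fraction,sync Passed to [split_train()].
#' @param verbose Print one line per cell.
#' @return An object of class `grid_result` with `cells` (per-run rows),
#'   `aggregate` (mean/sd across seeds) and `out_dir`.
#' @export
run_grid <- function(grid, spec, x, y, out_dir, lr = 1e-3,
                     global_batch = NULL, test_fraction = 0.2,
                     sync = FALSE, verbose = FALSE) {
  stopifnot(inherits(grid, "grid_spec"), inherits(spec, "model_spec"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (count in grid$counts) {
    for (ratio in grid$ratios[[as.character(count)]]) {
      for (seed in grid$seeds) {
        marker <- cell_marker(out_dir, count, ratio, seed)
        if (file.exists(marker)) {
          rows[[length(rows) + 1L]] <-
            as.data.frame(jsonlite::fromJSON(marker), stringsAsFactors = FALSE)
          next
        }
        res <- tryCatch({
          fit <- split_train(spec, x, y, ratio = ratio, seed = seed,
                             epochs = grid$epochs, global_batch = global_batch,
                             lr = lr, sync = sync,
                             test_fraction = test_fraction)
          hist_path <- sub("\\.json$", "_history.csv", marker)
          utils::write.csv(
            data.frame(epoch = fit$history$epoch,
                       loss = fmt_num(fit$history$loss),
                       metric = fmt_num(fit$history$metric)),
            hist_path, row.names = FALSE, quote = FALSE)
          if (nrow(fit$history)) {
            last_metric <- fit$history$metric[nrow(fit$history)]
            last_loss <- fit$history$loss[nrow(fit$history)]
          } else {
            # zero-epoch cell: evaluate the untrained model on its test split
            pred <- predict(fit, take_rows(x, fit$test_idx))
            last_metric <- if (fit$classify) accuracy(pred, y[fit$test_idx])$value
                           else rmsle(pmax(pred, 0), y[fit$test_idx])$value
            last_loss <- NA_real_
          }
          data.frame(n_clients = count, ratio = ratio, seed = seed,
                     final_metric = last_metric, final_loss = last_loss,
                     status = "ok", history = basename(hist_path),
                     stringsAsFactors = FALSE)
        }, error = function(e) {
          data.frame(n_clients = count, ratio = ratio, seed = seed,
                     final_metric = NA_real_, final_loss = NA_real_,
                     status = paste("error:", conditionMessage(e)),
                     history = NA_character_, stringsAsFactors = FALSE)
        })
        if (res$status == "ok")
          jsonlite::write_json(as.list(res), marker, auto_unbox = TRUE, digits = NA)
        if (verbose)
          message(sprintf("[grid] %d clients %-11s seed %d -> %s (%s)",
                          count, ratio, seed, fmt_num(res$final_metric), res$status))
        rows[[length(rows) + 1L]] <- res
      }
    }
  }
  cells <- do.call(rbind, rows)
  ok <- cells[cells$status == "ok", , drop = FALSE]
  agg <- if (nrow(ok)) {
    sp <- split(ok, paste(ok$n_clients, ok$ratio, sep = "_"))
    out <- do.call(rbind, lapply(sp, function(g) data.frame(
      n_clients = g$n_clients[1L], ratio = g$ratio[1L],
      mean_metric = mean(g$final_metric), sd_metric = stats::sd(g$final_metric),
      mean_loss = mean(g$final_loss), n_seeds = nrow(g),
      stringsAsFactors = FALSE)))
    out[order(out$n_clients, match(out$ratio, unlist(grid$ratios))), , drop = FALSE]
  } else NULL

  metric_name <- if (spec$task == "classification") "accuracy_percent" else "rmsle"
  write_grid_csvs(cells, agg, metric_name, out_dir)
  structure(list(cells = cells, aggregate = agg, out_dir = out_dir,
                 metric_name = metric_name,
                 higher_is_better = spec$task == "classification"),
            class = "grid_result")
}

write_grid_csvs <- function(cells, agg, metric_name, out_dir) {
  stable <- cells
  stable$final_metric <- fmt_num(stable$final_metric)
  stable$final_loss <- fmt_num(stable$final_loss)
  utils::write.csv(stable, file.path(out_dir, "results.csv"),
                   row.names = FALSE, quote = FALSE)
  if (!is.null(agg)) {
    wide <- rbind(c("n_end_systems", as.character(agg$n_clients)),
                  c("split_ratio", agg$ratio),
                  c(metric_name, fmt_num(agg$mean_metric)))
    utils::write.table(wide, file.path(out_dir, "results_table.csv"),
                       sep = ",", row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  }
  invisible(out_dir)
}

#' @export
print.grid_result <- function(x, ...) {
  cat(sprintf("<grid_result> %d runs (%d ok), metric: %s\n", nrow(x$cells),
              sum(x$cells$status == "ok"), x$metric_name))
  if (!is.null(x$aggregate)) print(x$aggregate, row.names = FALSE)
  invisible(x)
}

imbalance_score <- function(ratio) {
  sh <- as.integer(parse_ratio(ratio))
  max(sh) / sum(sh)
}

#' Summarise a grid result and name the best cell
#'
#' Ranks cells by mean held-out metric; ties are broken toward more
#' end-systems, then toward more imbalance (the published preference for
#' inclusive configurations). Adds a delta-to-best column so near-ties
#' (e.g. a 0.9-point gap) are visible.
#'
#' @param result A [run_grid()] result.
#' @param markdown_path Optional path for a markdown rendering.
#' @return A data frame sorted best-first with columns `n_clients`,
#'   `ratio`, `mean_metric`, `sd_metric`, `delta_to_best`, `best`.
#' @export
summarize_grid <- function(result, markdown_path = NULL) {
  stopifnot(inherits(result, "grid_result"))
  agg <- result$aggregate
  if (is.null(agg) || !nrow(agg)) stopf("no successful cells to summarise")
  dir_ <- if (result$higher_is_better) 1 else -1
  key <- order(-dir_ * agg$mean_metric, -agg$n_clients,
               -vapply(agg$ratio, imbalance_score, numeric(1L)))
  out <- agg[key, c("n_clients", "ratio", "mean_metric", "sd_metric"), drop = FALSE]
  out$delta_to_best <- abs(out$mean_metric - out$mean_metric[1L])
  out$best <- seq_len(nrow(out)) == 1L
  rownames(out) <- NULL
  if (!is.null(markdown_path)) {
    lines <- c(sprintf("| n_clients | ratio | %s | sd | delta_to_best |",
                       result$metric_name),
               "|---|---|---|---|---|",
               sprintf("| %d | %s | %s | %s | %s |", out$n_clients, out$ratio,
                       fmt_num(out$mean_metric), fmt_num(out$sd_metric),
                       fmt_num(out$delta_to_best)))
    writeLines(lines, markdown_path)
  }
  out
}
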