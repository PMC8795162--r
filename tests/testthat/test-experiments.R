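test_that("the default grid is the published nine-cell imbalance design", {
  g <- grid_spec()
  expect_equal(g$counts, c(3L, 4L, 5L))
  expect_equal(g$ratios[["3"]], c("1:1:1", "7:2:1", "8:1:1"))
  expect_equal(g$ratios[["4"]], c("1:1:1:1", "4:3:2:1", "7:1:1:1"))
  expect_equal(g$ratios[["5"]], c("1:1:1:1:1", "4:2:2:1:1", "6:1:1:1:1"))
  expect_equal(sum(lengths(g$ratios)), 9L)

  expect_error(grid_spec(counts = 3L, ratios = list(`3` = "1:1")), "2 shares")
  expect_error(grid_spec(counts = 7L), "no ratios")
})

test_that("a small grid runs, resumes from markers and reproduces byte-identically", {
  d <- make_image_set(60L, 16L, lesion_contrast = 0.6, noise_sd = 0.05, seed = 1L)
  sp <- tiny_cnn_spec(16L)
  g <- grid_spec(counts = c(2L, 3L),
                 ratios = list(`2` = c("1:1", "3:1"), `3` = "1:1:1"),
                 seeds = 1L, epochs = 1L)
  out1 <- withr::local_tempdir()
  res <- run_grid(g, sp, d$images, d$labels, out_dir = out1, global_batch = 12L)
  expect_equal(nrow(res$cells), 3L)
  expect_setequal(paste(res$cells$n_clients, res$cells$ratio),
                  c("2 1:1", "2 3:1", "3 1:1:1"))
  expect_true(all(res$cells$status == "ok"))
  expect_true(file.exists(file.path(out1, "results.csv")))
  expect_true(file.exists(file.path(out1, "results_table.csv")))
  tab <- read.csv(file.path(out1, "results_table.csv"), header = FALSE)
  expect_equal(nrow(tab), 3L)            # end-systems / ratio / metric rows
  expect_equal(ncol(tab), 4L)            # label + three cells

  # resume: markers short-circuit retraining and leave identical results
  marker <- file.path(out1, "cell_2_1-1_seed1.json")
  expect_true(file.exists(marker))
  before <- file.mtime(marker)
  res2 <- run_grid(g, sp, d$images, d$labels, out_dir = out1, global_batch = 12L)
  expect_equal(file.mtime(marker), before)
  expect_equal(res2$cells$final_metric, res$cells$final_metric)

  # fresh directory, same seeds: byte-identical CSVs
  out2 <- withr::local_tempdir()
  run_grid(g, sp, d$images, d$labels, out_dir = out2, global_batch = 12L)
  expect_identical(readLines(file.path(out1, "results.csv")),
                   readLines(file.path(out2, "results.csv")))
})

test_that("a zero-epoch cell reports the untrained-model metric", {
  d <- make_image_set(40L, 16L, lesion_contrast = 0.6, noise_sd = 0.05, seed = 2L)
  sp <- tiny_cnn_spec(16L)
  g <- grid_spec(counts = 2L, ratios = list(`2` = "1:1"), seeds = 4L, epochs = 0L)
  out <- withr::local_tempdir()
  res <- run_grid(g, sp, d$images, d$labels, out_dir = out, global_batch = 8L)
  fit <- split_train(sp, d$images, d$labels, ratio = "1:1", seed = 4L,
                     epochs = 0L, global_batch = 8L)
  pred <- predict(fit, d$images[fit$test_idx, , , , drop = FALSE])
  expect_equal(res$cells$final_metric, accuracy(pred, d$labels[fit$test_idx])$value)
})

test_that("failed cells are recorded without stopping the grid", {
  d <- make_image_set(40L, 16L, lesion_contrast = 0.6, noise_sd = 0.05, seed = 3L)
  sp <- tiny_cnn_spec(16L)
  # 40 samples -> 32 train; a 16-client-worth batch of 2 cannot feed 3 clients
  g <- grid_spec(counts = c(2L, 3L), ratios = list(`2` = "1:1", `3` = "1:1:1"),
                 seeds = 1L, epochs = 1L)
  out <- withr::local_tempdir()
  res <- run_grid(g, sp, d$images, d$labels, out_dir = out, global_batch = 2L)
  expect_true(any(res$cells$status == "ok"))
  expect_true(any(grepl("error", res$cells$status)))
})

test_that("the summary ranks cells with the published tie-break preferences", {
  fake <- structure(list(
    aggregate = data.frame(
      n_clients = c(3L, 5L), ratio = c("8:1:1", "6:1:1:1:1"),
      mean_metric = c(91.4, 90.5), sd_metric = c(0, 0),
      mean_loss = c(0.2, 0.25), n_seeds = c(1L, 1L)),
    metric_name = "accuracy_percent", higher_is_better = TRUE),
    class = "grid_result")
  s <- summarize_grid(fake)
  expect_equal(s$ratio[1L], "8:1:1")
  expect_true(s$best[1L])
  expect_equal(s$delta_to_best[2L], 0.9, tolerance = 1e-9)

  # all-equal metrics: tie broken toward more clients, then more imbalance
  fake$aggregate$mean_metric <- c(90, 90)
  s2 <- summarize_grid(fake)
  expect_equal(s2$n_clients[1L], 5L)

  single <- fake
  single$aggregate <- fake$aggregate[1L, ]
  s3 <- summarize_grid(single)
  expect_equal(nrow(s3), 1L)
  expect_equal(s3$delta_to_best, 0)

  md <- withr::local_tempfile(fileext = ".md")
  summarize_grid(fake, markdown_path = md)
  expect_true(any(grepl("8:1:1", readLines(md))))
})
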