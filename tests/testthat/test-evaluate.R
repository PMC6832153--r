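trained_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      iset <- separable_images(n = 24)
      m <- train(build_model(tiny_spec(), seed = 1), iset,
                 train_config(epochs = 8, batch_size = 8, learning_rate = 5e-3, seed = 1))
      cache <<- list(model = m, iset = iset)
    }
    cache
  }
})

test_that("a perfect classifier scores 100 on every fold with zero dispersion", {
  fx <- trained_fixture()
  rep <- evaluate_kfold(fx$model, fx$iset, k = 4, subject_id = "sep")
  expect_equal(rep$per_fold_accuracy, rep(100, 4))
  expect_equal(rep$mean, 100)
  expect_equal(rep$std, 0)
})

test_that("fold accuracies are reproduced by explicit counting", {
  fx <- trained_fixture()
  small <- image_set(array(fx$iset$x[, 1:4], c(12, 14, 4)),
                     c(fx$iset$y[1:3], 3L - fx$iset$y[4]))  # force one mistake
  rep <- evaluate_kfold(fx$model, small, k = 2, mode = "plain", subject_id = "cnt")
  pred <- predict(fx$model, small, type = "class")
  oracle <- c(mean(pred[1:2] == small$y[1:2]), mean(pred[3:4] == small$y[3:4])) * 100
  expect_equal(rep$per_fold_accuracy, oracle)
  # pooled correct count equals the sum over folds in plain mode
  sizes <- c(2, 2)
  expect_equal(sum(rep$per_fold_accuracy / 100 * sizes), sum(pred == small$y))
})

test_that("fold bookkeeping validates k and distributes remainders first", {
  fx <- trained_fixture()
  expect_error(evaluate_kfold(fx$model, fx$iset, k = 1), class = "mipipe_error_parameter")
  expect_error(evaluate_kfold(fx$model, fx$iset, k = 25), class = "mipipe_error_parameter")
  rep <- evaluate_kfold(fx$model, fx$iset, k = 5)   # 24 samples: folds 5,5,5,5,4
  expect_length(rep$per_fold_accuracy, 5)
  # max-over-epochs mode never scores below plain mode
  plain <- evaluate_kfold(fx$model, fx$iset, k = 5, mode = "plain")
  expect_true(all(rep$per_fold_accuracy >= plain$per_fold_accuracy - 1e-9))
})

test_that("eval reports validate and tidy into tibbles", {
  r <- eval_report(c(95, 100, 90), subject_id = "demo")
  expect_equal(r$mean, 95)
  expect_equal(r$std, 5)
  expect_error(eval_report(c(95, 104)), class = "mipipe_error_parameter")
  td <- tidy(r)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$accuracy, c(95, 100, 90))
  gl <- glance(r)
  expect_equal(gl$k, 3L)
  # stored mean/std always match a recomputation from the folds
  expect_lt(abs(r$mean - mean(r$per_fold_accuracy)), 0.005)
  expect_lt(abs(r$std - sd(r$per_fold_accuracy)), 0.005)
})

test_that("summaries pool fold means and average per-report stds", {
  r1 <- eval_report(c(90, 94), "s1")   # std 2.828
  r2 <- eval_report(c(80, 100), "s2")  # std 14.14
  s <- summarize_report(list(r1, r2))
  expect_equal(s$mean, mean(c(90, 94, 80, 100)))
  expect_equal(s$std, mean(c(sd(c(90, 94)), sd(c(80, 100)))))
  # the documented convention: stds 2 and 4 average to 3
  ra <- eval_report(c(94, 96, 98), "a")           # sd = 2
  rb <- eval_report(c(88, 92, 96), "b")           # sd = 4
  expect_equal(summarize_report(list(ra, rb))$std, 3)
  expect_equal(summarize_report(list(eval_report(rep(90, 5))))$std, 0)
  expect_error(summarize_report(list()), class = "mipipe_error_parameter")
})

test_that("report tables are written deterministically in k-fold layout", {
  r1 <- eval_report(c(95.2, 100, 88.4), "subject a")
  r2 <- eval_report(c(90, 91, 92), "subject b")
  dir <- withr::local_tempdir()
  p1 <- file.path(dir, "a.csv"); p2 <- file.path(dir, "b.csv")
  write_eval_reports(list(r1, r2), p1)
  write_eval_reports(list(r1, r2), p2)
  expect_identical(readBin(p1, "raw", file.size(p1)), readBin(p2, "raw", file.size(p2)))
  tab <- read.csv(p1, check.names = FALSE)
  expect_identical(names(tab), c("Subject", "k=1", "k=2", "k=3", "Average", "Std"))
  expect_equal(nrow(tab), 3)                      # 2 subjects + pooled average row
  expect_identical(tab$Subject[3], "Average")
})
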