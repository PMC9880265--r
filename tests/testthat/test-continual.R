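test_that("split streams pair consecutive classes and never recycle train data", {
  stream <- build_task_stream("synthetic", "split", seed = 1)
  expect_length(stream$tasks, 5)
  expect_equal(lapply(stream$tasks, `[[`, "classes"),
               list(c(1, 2), c(3, 4), c(5, 6), c(7, 8), c(9, 10)))
  for (t in stream$tasks) {
    expect_setequal(unique(t$train$y), 1:2)
    expect_equal(nrow(t$train$x), 1000)
    expect_equal(nrow(t$test$x), 200)
  }
  # same seed, same stream
  s2 <- build_task_stream("synthetic", "split", seed = 1)
  expect_identical(stream$tasks[[3]]$train$x, s2$tasks[[3]]$train$x)
})

test_that("permuted streams use the identity permutation for task one", {
  stream <- build_task_stream("synthetic", "permuted", seed = 2, n_tasks = 4)
  expect_length(stream$tasks, 4)
  expect_equal(stream$tasks[[1]]$permutation, seq_len(stream$input_dim))
  expect_false(identical(stream$tasks[[2]]$permutation,
                         seq_len(stream$input_dim)))
  # task 2 is a column permutation of task 1
  expect_identical(stream$tasks[[2]]$train$x,
                   stream$tasks[[1]]$train$x[, stream$tasks[[2]]$permutation])
  expect_setequal(unique(stream$tasks[[1]]$train$y), 1:10)
})

test_that("the IDX reader round-trips a generated MNIST-layout file", {
  img_path <- tempfile(fileext = ".idx3-ubyte")
  set.seed(1)
  vals <- sample(0:255, 2 * 28 * 28, replace = TRUE)
  con <- file(img_path, "wb")
  writeBin(as.raw(c(0, 0, 8, 3)), con)
  writeBin(c(2L, 28L, 28L), con, size = 4, endian = "big")
  writeBin(as.raw(vals), con)
  close(con)
  arr <- read_idx(img_path)
  expect_equal(dim(arr), c(28, 28, 2))
  expect_equal(as.integer(arr), vals)
  expect_error(read_idx(tempfile()), "no such file")
})

test_that("a single synthetic task is learnable well above chance", {
  stream <- build_task_stream("synthetic", "split", seed = 3)
  one_task <- stream
  one_task$tasks <- stream$tasks[1]
  for (m in c("sgd", "fn_sgd", "adam")) {
    r <- train_stream(one_task, m, seed = 3)
    expect_gt(r[1, 1], 0.75)
  }
})

test_that("a fresh FN synapse realizes approximately its requested update", {
  net <- fnsynapse:::mlp_new(c(4, 3, 2), seed = 1)
  fnw <- fn_weights_new(net)
  step <- 0.01
  before <- fn_weights_read(fnw)$W[[1]][1, 1]
  stepW <- lapply(net$W, function(w) w * 0); stepb <- lapply(net$b, `*`, 0)
  stepW[[1]][1, 1] <- step
  fnw2 <- fn_apply_gradient(fnw, stepW, stepb)
  realized <- fn_weights_read(fnw2)$W[[1]][1, 1] - before
  expect_gt(realized / step, 0.9)
  expect_lt(realized / step, 1.1)
  # nothing else moved
  expect_equal(fn_weights_read(fnw2)$W[[2]], fn_weights_read(fnw)$W[[2]])
})

test_that("zero gradients leave weights and usage untouched", {
  net <- fnsynapse:::mlp_new(c(4, 3, 2), seed = 1)
  fnw <- fn_weights_new(net)
  zeroW <- lapply(net$W, `*`, 0); zerob <- lapply(net$b, `*`, 0)
  fnw2 <- fn_apply_gradient(fnw, zeroW, zerob)
  expect_identical(fn_weights_read(fnw2), fn_weights_read(fnw))
  expect_identical(fnw2$wc_W, fnw$wc_W)
})

test_that("repeated identical steps realize strictly shrinking weight changes", {
  net <- fnsynapse:::mlp_new(c(2, 2, 2), seed = 1)
  fnw <- fn_weights_new(net)
  stepW <- lapply(net$W, function(w) w * 0); stepb <- lapply(net$b, `*`, 0)
  stepW[[1]][] <- 0.05
  realized <- numeric(40)
  prev <- fn_weights_read(fnw)$W[[1]][1, 1]
  for (i in 1:40) {
    fnw <- fn_apply_gradient(fnw, stepW, stepb)
    cur <- fn_weights_read(fnw)$W[[1]][1, 1]
    realized[i] <- cur - prev
    prev <- cur
  }
  expect_true(all(realized > 0))
  expect_true(all(diff(realized) < 0))
})

test_that("training works and the FN network keeps weight/voltage coherence", {
  stream <- build_task_stream("synthetic", "split", seed = 4)
  stream$tasks <- stream$tasks[1:2]
  r <- train_stream(stream, "fn_sgd", seed = 4)
  fnw <- attr(r, "fn_weights")
  # coherence: every stored wd times the gain is a finite weight
  re <- fn_weights_read(fnw)
  expect_true(all(vapply(re$W, function(w) all(is.finite(w)), logical(1))))
  expect_equal(re$W[[1]], fnw$gain * fnw$wd_W[[1]])
  # usage decreased from the initial potential
  expect_lt(mean(usage_histogram(r, 3)), fnw$params$Wc0)
})

test_that("usage histograms start as a delta and shift left with training", {
  net <- fnsynapse:::mlp_new(c(4, 3, 2), seed = 1)
  fnw <- fn_weights_new(net)
  h <- usage_histogram(fnw, 1)
  expect_length(h, 4 * 3)  # mass conservation: one entry per weight
  expect_true(all(h == fnw$params$Wc0))
  stream <- build_task_stream("synthetic", "split", seed = 5)
  stream$tasks <- stream$tasks[1:2]
  r <- train_stream(stream, "fn_sgd", seed = 5)
  expect_lt(mean(usage_histogram(r, 3)), mean(usage_histogram(fnw, 1)))
})

test_that("FN usage consolidates layer by layer across tasks", {
  stream <- build_task_stream("synthetic", "split", seed = 1)
  r <- train_stream(stream, "fn_sgd", seed = 1)
  wc <- attr(r, "wc_by_task")
  mean_wc <- sapply(wc, function(d) d$mean_wc)   # layers x tasks
  # per-layer mean usage potential decreases monotonically with tasks
  expect_true(all(apply(mean_wc, 1, function(v) all(diff(v) < 0))))
  # the output layer is the most used and more spread than the input layer
  final <- wc[[length(wc)]]
  expect_lt(final$mean_wc[3], final$mean_wc[1])
  expect_gt(final$sd_wc[3], final$sd_wc[1])
})

test_that("EWC baselines run and anchor earlier tasks", {
  stream <- build_task_stream("synthetic", "split", seed = 6)
  stream$tasks <- stream$tasks[1:2]
  r1 <- train_stream(stream, "ewc", seed = 6)
  r2 <- train_stream(stream, "online_ewc", seed = 6)
  expect_gt(r1[1, 1], 0.7)
  expect_gt(r2[1, 1], 0.7)
  expect_true(all(is.finite(r1[2, 1:2])))
})

test_that("the accuracy matrix has the triangular shape and sane average", {
  stream <- build_task_stream("synthetic", "split", seed = 7)
  stream$tasks <- stream$tasks[1:3]
  r <- train_stream(stream, "sgd", seed = 7)
  expect_true(all(is.na(r[upper.tri(r)])))
  expect_true(all(!is.na(r[lower.tri(r, diag = TRUE)])))
  expect_equal(attr(r, "overall_average"), mean(r[3, ]))
  expect_error(train_stream(stream, "newton"), "arg")
})
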