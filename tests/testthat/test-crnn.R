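tiny_cfg <- function(seed = 9)
  crnn_config(conv_filters = c(2, 3, 3, 4), gru_units = 3,
              fc_sizes = c(5, 4, NA), batch_size = 8, seed = seed)

test_that("build_model wires the architecture and reports shape problems", {
  model <- build_model(crnn_config(), c(43, 298), n_classes = 7)
  # time axis after four 2x2 poolings: 298 -> 149 -> 74 -> 37 -> 18
  expect_identical(model$seq_len, 18L)
  # feature axis: 43 -> 21 -> 10 -> 5 -> 2, collapsed into the GRU input
  expect_identical(model$seq_dim, 2L * 128L)
  expect_identical(model$n_classes, 7L)

  expect_error(build_model(crnn_config(), c(4, 298), 7), "feature axis")
  expect_error(build_model(crnn_config(), c(43, 8), 7), "time axis")
})

test_that("softmax outputs are valid probability vectors over batches", {
  model <- build_model(tiny_cfg(), c(43, 20), n_classes = 7)
  set.seed(2)
  x <- lapply(1:5, function(i) matrix(rnorm(43 * 20), 43, 20))
  P <- predict(model, x, type = "prob")
  expect_identical(dim(P), c(7L, 5L))
  expect_true(all(P >= 0))
  expect_equal(colSums(P), rep(1, 5), tolerance = 1e-6)
})

test_that("analytic gradients agree with numerical differentiation", {
  model <- build_model(tiny_cfg(), c(43, 18), n_classes = 3)
  set.seed(14)
  B <- 3
  X <- matrix(rnorm(43 * 18 * B), 43 * 18, B)
  y <- c(1L, 2L, 3L)
  fwd <- imemd:::crnn_forward(model, X, training = TRUE)
  ls <- imemd:::xent_loss(fwd$logits, y)
  g <- imemd:::crnn_backward(model, fwd, ls$dZ)
  flat_g <- unlist(g)
  flat_p <- unlist(model$params)
  set.seed(15)
  pick <- sample(length(flat_p), 40)
  eps <- 1e-5
  num <- vapply(pick, function(i) {
    m <- model
    p <- flat_p; p[i] <- p[i] + eps
    m$params <- utils::relist(p, model$params)
    f1 <- imemd:::xent_loss(imemd:::crnn_forward(m, X, training = TRUE)$logits, y)$loss
    p[i] <- p[i] - 2 * eps
    m$params <- utils::relist(p, model$params)
    f0 <- imemd:::xent_loss(imemd:::crnn_forward(m, X, training = TRUE)$logits, y)$loss
    (f1 - f0) / (2 * eps)
  }, numeric(1))
  rel <- abs(num - flat_g[pick]) / pmax(abs(num) + abs(flat_g[pick]), 1e-8)
  expect_lt(max(rel), 1e-4)
})

test_that("training overfits separable classes and is seeded", {
  set.seed(5)
  mk <- function(n, mu) lapply(seq_len(n), function(i)
    matrix(rnorm(43 * 20, mean = mu), 43, 20))
  x <- c(mk(16, 0), mk(16, 0.8))
  y <- rep(c("a", "b"), each = 16)
  model <- build_model(tiny_cfg(seed = 3), c(43, 20), 2)
  trained <- train_crnn(model, x, y, epochs = 20)
  expect_length(trained$loss_history, 20L)
  expect_identical(mean(predict(trained, x) == y), 1)

  # identical seed and data reproduce the loss trajectory
  trained2 <- train_crnn(build_model(tiny_cfg(seed = 3), c(43, 20), 2),
                         x, y, epochs = 20)
  expect_equal(trained$loss_history, trained2$loss_history, tolerance = 1e-10)

  expect_error(train_crnn(model, x, rep("a", 32)), "at least 2 classes")
})

test_that("unweighted accuracy is the mean of per-class recalls", {
  expect_equal(unweighted_accuracy(c("a", "b", "c"), c("a", "b", "c")), 100)

  # recalls 0.9, 0.8, 1.0 -> UA = 90
  labels <- c(rep("a", 10), rep("b", 10), rep("c", 10))
  preds <- labels
  preds[1] <- "b"                      # a: 9/10
  preds[11:12] <- "c"                  # b: 8/10
  expect_equal(unweighted_accuracy(labels, preds), 90)

  # invariance under joint relabeling
  map <- c(a = "z", b = "x", c = "y")
  expect_equal(unweighted_accuracy(map[labels], map[preds]), 90)

  # equals overall accuracy for balanced support
  expect_equal(unweighted_accuracy(labels, preds), 100 * mean(labels == preds))

  expect_error(unweighted_accuracy(labels, rep("q", 30)), NA)
  expect_error(unweighted_accuracy(c("a", "a"), c("a", "b")), NA)
})

test_that("eval_report assembles confusion, recall and UA coherently", {
  labels <- rep(c("a", "b"), each = 5)
  preds <- c(rep("a", 4), "b", rep("b", 5))
  r <- eval_report(labels, preds)
  expect_equal(unname(rowSums(r$confusion)), c(5, 5))
  expect_equal(unname(r$recall), c(0.8, 1.0))
  expect_equal(r$ua, 90)
  expect_true(r$ua >= 0 && r$ua <= 100)
})

test_that("cross_validate builds valid loso and stratified k-fold partitions", {
  set.seed(8)
  n <- 36
  feats <- lapply(seq_len(n), function(i)
    matrix(rnorm(43 * 18, mean = ifelse(i %% 2 == 0, 0, 0.8)), 43, 18))
  labels <- ifelse(seq_len(n) %% 2 == 0, "a", "b")
  speakers <- rep(sprintf("s%d", 1:4), each = 9)

  cfg <- tiny_cfg()
  cv <- cross_validate(feats, labels, speakers, scheme = "loso", cfg = cfg,
                       epochs = 2)
  expect_length(cv$reports, 4L)   # one fold per speaker
  expect_true(cv$ua >= 0 && cv$ua <= 100)

  cvk <- cross_validate(feats, labels, scheme = "random_kfold", k = 3,
                        cfg = cfg, epochs = 2)
  expect_length(cvk$reports, 3L)
  # the union of test folds is the dataset: every sample tested exactly once
  sizes <- vapply(cvk$reports, function(r) sum(r$confusion), numeric(1))
  expect_equal(sum(sizes), n)

  expect_error(cross_validate(feats, labels, speakers = rep("s1", n),
                              scheme = "loso"), "at least 3 speakers")
})
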