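#' CRNN configuration
#'
#' Architecture and optimizer settings of the convolutional-recurrent
#' classifier: four 2D convolution blocks (conv, batch normalization, ReLU,
#' 2x2 max pooling), a reshape collapsing the feature axis into the
#' recurrent input, three bidirectional GRU layers, and three fully
#' connected layers ending in a softmax. Trained with Adam on cross-entropy.
#' The published training protocol fixes 60 epochs, batch 512 and an
#' initial learning rate of 0.001; layer widths are configuration-driven.
#'
#' @param conv_filters Four filter counts (default 16, 32, 64, 128).
#' @param kernel 2D kernel size (default `c(3, 3)`), same padding.
#' @param pool 2D pooling size (default `c(2, 2)`), floor semantics.
#' @param gru_units Hidden units per GRU direction in each of the three
#'   bidirectional layers (default 128).
#' @param fc_sizes Output sizes of the three fully connected layers; the
#'   last entry is replaced by the class count at build time
#'   (default 256, 128, NA).
#' @param lr Initial Adam learning rate (default 0.001).
#' @param epochs Training epochs (default 60).
#' @param batch_size Mini-batch size (default 512).
#' @param seed Integer seed for initialization and batching.
#' @return An object of class `crnn_config`.
#' @export
crnn_config <- function(conv_filters = c(16L, 32L, 64L, 128L),
                        kernel = c(3L, 3L), pool = c(2L, 2L),
                        gru_units = 128L, fc_sizes = c(256L, 128L, NA),
                        lr = 0.001, epochs = 60L, batch_size = 512L,
                        seed = 1L) {
  stopifnot(length(conv_filters) == 4L, all(conv_filters >= 1),
            length(kernel) == 2L, length(pool) == 2L, gru_units >= 1,
            length(fc_sizes) == 3L, lr > 0, epochs >= 1, batch_size >= 1)
  structure(list(conv_filters = as.integer(conv_filters),
                 kernel = as.integer(kernel), pool = as.integer(pool),
                 gru_units = as.integer(gru_units), fc_sizes = fc_sizes,
                 lr = lr, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "crnn_config")
}

#' Build a CRNN model
#'
#' Instantiates seeded parameters and the fixed index tables for a given
#' input shape (feature rows x frames, one channel). The input must survive
#' four poolings on both axes.
#'
#' @param cfg A [crnn_config()].
#' @param input_shape Integer `c(n_features, n_frames)`, typically
#'   `c(43, frames)`.
#' @param n_classes Number of output classes (>= 2).
#' @return An object of class `crnn_model` (parameters, index tables,
#'   batch-normalization running statistics, shape metadata).
#' @export
build_model <- function(cfg, input_shape, n_classes) {
  stopifnot(length(input_shape) == 2L, n_classes >= 2L)
  H <- as.integer(input_shape[1L]); W <- as.integer(input_shape[2L])
  kh <- cfg$kernel[1L]; kw <- cfg$kernel[2L]
  pad <- (kh - 1L) %/% 2L
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(cfg$seed)
  conv <- list(); bn <- list(); ci <- list(); pi_ <- list()
  C_in <- 1L; h <- H; w <- W
  for (l in 1:4) {
    C_out <- cfg$conv_filters[l]
    if (h %/% cfg$pool[1L] < 1L)
      stop(sprintf("input feature axis too small: %d rows left before block %d", h, l))
    if (w %/% cfg$pool[2L] < 1L)
      stop(sprintf("input time axis too small: %d frames left before block %d", w, l))
    sdw <- sqrt(2 / (C_in * kh * kw))
    conv[[l]] <- list(W = matrix(stats::rnorm(C_out * C_in * kh * kw, sd = sdw),
                                 C_out, C_in * kh * kw),
                      b = numeric(C_out))
    bn[[l]] <- list(gamma = rep(1, C_out), beta = numeric(C_out))
    ci[[l]] <- conv_index(C_in, h, w, kh, kw, pad)
    pi_[[l]] <- pool_index(C_out, h, w, cfg$pool[1L], cfg$pool[2L])
    h <- h %/% cfg$pool[1L]; w <- w %/% cfg$pool[2L]
    C_in <- C_out
  }
  D <- C_in * h                              # features per timestep after reshape
  U <- cfg$gru_units
  gru <- list()
  d_in <- D
  for (l in 1:3) {
    sdg <- sqrt(1 / d_in)
    gru[[l]] <- list(f = gru_init(d_in, U, sdg), b = gru_init(d_in, U, sdg))
    d_in <- 2L * U
  }
  fc_sizes <- cfg$fc_sizes
  fc_sizes[3L] <- n_classes
  fc <- list(); d_in <- 2L * U
  for (l in 1:3) {
    d_out <- as.integer(fc_sizes[l])
    fc[[l]] <- list(W = matrix(stats::rnorm(d_out * d_in, sd = sqrt(2 / d_in)),
                               d_out, d_in),
                    b = numeric(d_out))
    d_in <- d_out
  }
  run_stats <- lapply(1:4, function(l)
    list(mean = numeric(cfg$conv_filters[l]), var = rep(1, cfg$conv_filters[l])))
  structure(list(params = list(conv = conv, bn = bn, gru = gru, fc = fc),
                 run_stats = run_stats, ci = ci, pi = pi_,
                 cfg = cfg, input_shape = c(H, W), n_classes = as.integer(n_classes),
                 seq_len = w, seq_dim = D),
            class = "crnn_model")
}

# Forward pass. X: [H*W, B] matrix (one channel, H fastest). Returns logits
# and (in training mode) all caches needed for backprop.
crnn_forward <- function(model, X, training = FALSE) {
  p <- model$params
  caches <- list(conv = list(), bn = list(), relu = list(), pool = list())
  A <- X
  for (l in 1:4) {
    cf <- conv_forward(A, p$conv[[l]]$W, p$conv[[l]]$b, model$ci[[l]])
    bf <- bn_forward(cf$out, p$bn[[l]]$gamma, p$bn[[l]]$beta,
                     model$run_stats[[l]]$mean, model$run_stats[[l]]$var,
                     C = length(p$conv[[l]]$b), training = training)
    if (training) {
      model$run_stats[[l]]$mean <- bf$run_mean
      model$run_stats[[l]]$var <- bf$run_var
    }
    R <- pmax(bf$out, 0)
    pf <- pool_forward(R, model$pi[[l]])
    caches$conv[[l]] <- cf; caches$bn[[l]] <- bf
    caches$relu[[l]] <- bf$out > 0; caches$pool[[l]] <- pf
    A <- pf$out
  }
  # reshape to sequence: rows of A are [C*h, w] with w slow
  T_ <- model$seq_len; D <- model$seq_dim
  B <- ncol(A)
  S <- lapply(seq_len(T_), function(t)
    A[((t - 1L) * D + 1L):(t * D), , drop = FALSE])
  gcaches <- list()
  for (l in 1:3) {
    bg <- bigru_forward(S, p$gru[[l]]$f, p$gru[[l]]$b)
    gcaches[[l]] <- bg
    S <- bg$out
  }
  M <- Reduce(`+`, S) / T_                   # temporal mean pooling
  fc_caches <- list()
  A2 <- M
  for (l in 1:3) {
    Z <- p$fc[[l]]$W %*% A2 + p$fc[[l]]$b
    fc_caches[[l]] <- list(input = A2, pre = Z)
    A2 <- if (l < 3L) pmax(Z, 0) else Z
  }
  list(logits = A2, caches = caches, gcaches = gcaches, fc_caches = fc_caches,
       model = model, B = B)
}

crnn_backward <- function(model, fwd, dZ) {
  p <- model$params
  g <- list(conv = list(), bn = list(), gru = list(), fc = list())
  dA <- dZ
  for (l in 3:1) {
    cc <- fc_caches_l <- fwd$fc_caches[[l]]
    if (l < 3L) dA <- dA * (cc$pre > 0)
    g$fc[[l]] <- list(W = dA %*% t(cc$input), b = rowSums(dA))
    dA <- t(p$fc[[l]]$W) %*% dA
  }
  T_ <- model$seq_len
  dS <- lapply(seq_len(T_), function(t) dA / T_)
  for (l in 3:1) {
    bb <- bigru_backward(dS, p$gru[[l]]$f, p$gru[[l]]$b, fwd$gcaches[[l]])
    g$gru[[l]] <- list(f = bb$gf, b = bb$gb)
    dS <- bb$dX
  }
  D <- model$seq_dim
  dPooled <- do.call(rbind, dS)
  for (l in 4:1) {
    dR <- pool_backward(dPooled, model$pi[[l]], fwd$caches$pool[[l]])
    dBN <- dR * fwd$caches$relu[[l]]
    bb <- bn_backward(dBN, p$bn[[l]]$gamma, fwd$caches$bn[[l]])
    g$bn[[l]] <- list(gamma = bb$dgamma, beta = bb$dbeta)
    cb <- conv_backward(bb$dX, p$conv[[l]]$W, model$ci[[l]],
                        fwd$caches$conv[[l]])
    g$conv[[l]] <- list(W = cb$dW, b = cb$db)
    dPooled <- cb$dX
  }
  g
}

#' Train a CRNN
#'
#' Mini-batch Adam training on cross-entropy loss. Feature matrices are
#' used as-is; standardize beforehand (see [standardize_features()]).
#'
#' @param model A [build_model()] result.
#' @param x List of feature matrices (`n_features x n_frames` each) or a
#'   3D array `n_features x n_frames x n`.
#' @param labels Factor or character vector of length `n`.
#' @param epochs,batch_size,lr Optional overrides of the config values.
#' @param verbose Print per-epoch loss.
#' @return The trained model with `$loss_history` (one mean loss per epoch)
#'   and `$classes` (level order used for the output layer).
#' @export
train_crnn <- function(model, x, labels, epochs = NULL, batch_size = NULL,
                       lr = NULL, verbose = FALSE) {
  X <- stack_features(x, model$input_shape)
  labels <- factor(labels)
  if (nlevels(labels) < 2L) stop("need at least 2 classes present")
  if (nlevels(labels) != model$n_classes)
    stop("label count does not match the model's class count")
  y <- as.integer(labels)
  cfg <- model$cfg
  epochs <- if (is.null(epochs)) cfg$epochs else as.integer(epochs)
  batch_size <- if (is.null(batch_size)) cfg$batch_size else as.integer(batch_size)
  lr <- if (is.null(lr)) cfg$lr else lr
  n <- ncol(X)
  if (n == 0L) stop("empty dataset")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(cfg$seed + 1L)
  opt <- adam_init(model$params)
  loss_hist <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    losses <- c()
    for (start in seq(1L, n, by = batch_size)) {
      sel <- ord[start:min(start + batch_size - 1L, n)]
      fwd <- crnn_forward(model, X[, sel, drop = FALSE], training = TRUE)
      model$run_stats <- fwd$model$run_stats
      ls <- xent_loss(fwd$logits, y[sel])
      grads <- crnn_backward(model, fwd, ls$dZ)
      st <- adam_step(model$params, grads, opt, lr)
      model$params <- st$params
      opt <- st$state
      losses <- c(losses, ls$loss)
    }
    loss_hist[ep] <- mean(losses)
    if (verbose) message(sprintf("epoch %d/%d loss %.4f", ep, epochs, loss_hist[ep]))
  }
  model$loss_history <- loss_hist
  model$classes <- levels(labels)
  model
}

#' Class probabilities / predictions from a trained CRNN
#'
#' @param object A trained `crnn_model`.
#' @param x Feature matrices as in [train_crnn()].
#' @param type `"class"` (default) or `"prob"`.
#' @param ... Unused.
#' @return Character vector of predicted labels, or an `n_classes x n`
#'   probability matrix.
#' @export
predict.crnn_model <- function(object, x, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  X <- stack_features(x, object$input_shape)
  fwd <- crnn_forward(object, X, training = FALSE)
  P <- softmax_cols(fwd$logits)
  if (type == "prob") return(P)
  cls <- if (!is.null(object$classes)) object$classes
         else as.character(seq_len(object$n_classes))
  cls[max.col(t(P))]
}

stack_features <- function(x, input_shape) {
  if (is.array(x) && length(dim(x)) == 3L) {
    stopifnot(dim(x)[1L] == input_shape[1L], dim(x)[2L] == input_shape[2L])
    return(matrix(x, prod(input_shape), dim(x)[3L]))
  }
  stopifnot(is.list(x), length(x) >= 1L)
  mats <- lapply(x, function(m) {
    stopifnot(nrow(m) == input_shape[1L], ncol(m) == input_shape[2L])
    as.vector(m)
  })
  do.call(cbind, mats)
}

#' Per-row feature standardization
#'
#' z-scores every feature row using statistics estimated on a training set
#' only, so heterogeneous feature scales (Hz, log-energy) do not dominate
#' training; apply the returned transform to held-out data.
#'
#' @param train List of training feature matrices.
#' @return List with `transform(x)` (a function mapping a feature-matrix
#'   list to its standardized version), `mean` and `sd` per row.
#' @export
standardize_features <- function(train) {
  all_rows <- do.call(cbind, train)
  mu <- rowMeans(all_rows)
  sdv <- apply(all_rows, 1L, stats::sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  transform <- function(x) lapply(x, function(m) (m - mu) / sdv)
  list(transform = transform, mean = mu, sd = sdv)
}

#' Unweighted accuracy
#'
#' Mean of per-class recalls, in percent; the class-imbalance-insensitive
#' accuracy used to compare emotion classifiers. Every true class must be
#' represented.
#'
#' @param labels True labels.
#' @param predictions Predicted labels, same length.
#' @return Scalar in `[0, 100]`.
#' @export
unweighted_accuracy <- function(labels, predictions) {
  labels <- as.character(labels)
  predictions <- as.character(predictions)
  if (length(labels) != length(predictions))
    stop("labels and predictions differ in length")
  classes <- unique(labels)
  recalls <- vapply(classes, function(cl) {
    sup <- labels == cl
    if (!any(sup)) stop("undefined recall: class with zero support: ", cl)
    mean(predictions[sup] == cl)
  }, numeric(1))
  100 * mean(recalls)
}

#' Evaluation report
#'
#' Confusion matrix, per-class recall and unweighted accuracy for one
#' evaluation fold.
#'
#' @param labels True labels.
#' @param predictions Predicted labels.
#' @return List of class `imemd_eval_report` with `confusion` (true x
#'   predicted), `recall`, `ua`.
#' @export
eval_report <- function(labels, predictions) {
  labels <- factor(labels)
  predictions <- factor(predictions, levels = levels(labels))
  cm <- table(true = labels, predicted = predictions)
  recall <- diag(cm) / rowSums(cm)
  structure(list(confusion = cm, recall = recall,
                 ua = unweighted_accuracy(labels, predictions)),
            class = "imemd_eval_report")
}

#' @export
print.imemd_eval_report <- function(x, ...) {
  cat(sprintf("<eval report> UA = %.2f%%\n", x$ua))
  print(x$confusion)
  invisible(x)
}

#' Cross-validated training and evaluation
#'
#' `loso`: leave-one-speaker-out rotation — per fold one speaker is the
#' test set, the next speaker in rotation is the validation set (reserved
#' for hyperparameter inspection, not used for fitting), and the remaining
#' speakers train the model. `random_kfold`: seeded, label-stratified
#' k-fold partition.
#'
#' @param features List of feature matrices.
#' @param labels Label vector, same length.
#' @param speakers Speaker ids (required for `loso`).
#' @param scheme `"loso"` or `"random_kfold"`.
#' @param k Folds for `random_kfold` (default 10).
#' @param cfg A [crnn_config()].
#' @param epochs,batch_size Optional training overrides.
#' @return List with per-fold `reports` (see [eval_report()]) and `ua`
#'   (mean UA over folds, percent).
#' @export
cross_validate <- function(features, labels, speakers = NULL,
                           scheme = c("loso", "random_kfold"), k = 10L,
                           cfg = crnn_config(), epochs = NULL,
                           batch_size = NULL) {
  scheme <- match.arg(scheme)
  labels <- as.character(labels)
  n <- length(features)
  stopifnot(length(labels) == n)
  if (scheme == "loso") {
    if (is.null(speakers)) stop("loso requires speaker ids")
    spk <- unique(speakers)
    if (length(spk) < 3L) stop("loso requires at least 3 speakers")
    folds <- lapply(seq_along(spk), function(i) {
      test_spk <- spk[i]
      val_spk <- spk[if (i == length(spk)) 1L else i + 1L]
      list(test = which(speakers == test_spk),
           train = which(!speakers %in% c(test_spk, val_spk)))
    })
  } else {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(cfg$seed + 2L)
    fold_of <- integer(n)
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      fold_of[idx] <- rep_len(seq_len(k), length(idx))
    }
    folds <- lapply(seq_len(k), function(i)
      list(test = which(fold_of == i), train = which(fold_of != i)))
  }
  shape <- dim(features[[1L]])
  reports <- lapply(folds, function(fd) {
    std <- standardize_features(features[fd$train])
    tr <- std$transform(features[fd$train])
    te <- std$transform(features[fd$test])
    model <- build_model(cfg, shape, n_classes = length(unique(labels)))
    model <- train_crnn(model, tr, factor(labels[fd$train],
                                          levels = sort(unique(labels))),
                        epochs = epochs, batch_size = batch_size)
    eval_report(labels[fd$test], predict(model, te))
  })
  list(reports = reports,
       ua = mean(vapply(reports, function(r) r$ua, numeric(1))))
}
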