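#' Network training configuration
#'
#' Training protocol for the patch classifiers: mini-batches of 32 patches,
#' 100 epochs, and either leave-one-patient-out folds or a random 30%
#' held-out split. Architectures are configuration, not code: `hidden`
#' gives the dense layer widths of the classifier, `encoder` the widths of
#' the autoencoder's encoder (mirrored in the decoder), and `pool` an
#' average-pooling front end that reduces each standardized patch to a
#' coarse grid before the dense layers.
#'
#' @param hidden Integer vector of classifier hidden-layer widths.
#' @param encoder Integer vector of encoder layer widths (last entry is the
#'   feature dimension).
#' @param batch_size Mini-batch size.
#' @param epochs Training epochs.
#' @param lr SGD learning rate for the classifiers.
#' @param ae_lr SGD learning rate for the autoencoder stage; reconstruction
#'   regression needs a smaller step than the bounded-output classifier.
#' @param l2 L2 weight penalty.
#' @param pool `c(lateral, axial)` average-pooling block size.
#' @param test_fraction Held-out fraction for the random-split mode.
#' @param seed RNG seed for initialization, shuffling and the split.
#' @return An object of class `nn_config`.
#' @export
nn_config <- function(hidden = c(32L), encoder = c(32L, 8L),
                      batch_size = 32L, epochs = 100L, lr = 0.2,
                      ae_lr = 0.02, l2 = 1e-4, pool = c(8L, 8L),
                      test_fraction = 0.3, seed = 1L) {
  if (batch_size < 1L || epochs < 1L) {
    stopf("'batch_size' and 'epochs' must be >= 1")
  }
  structure(
    list(hidden = as.integer(hidden), encoder = as.integer(encoder),
         batch_size = as.integer(batch_size), epochs = as.integer(epochs),
         lr = lr, ae_lr = ae_lr, l2 = l2, pool = as.integer(pool),
         test_fraction = test_fraction, seed = as.integer(seed)),
    class = "nn_config"
  )
}

# Block-average pooling of a matrix; trailing partial blocks are averaged
# over their actual extent.
pool_matrix <- function(m, pool) {
  ri <- (seq_len(nrow(m)) - 1L) %/% pool[1]
  ci <- (seq_len(ncol(m)) - 1L) %/% pool[2]
  tapply(as.vector(m), list(ri[row(m)], ci[col(m)]), mean)
}

#' Featurize patches for network training
#'
#' Standardizes each patch (z-score) and average-pools it to a coarse grid,
#' returning one flattened feature row per patch.
#'
#' @param patches List of `oct_patch` objects.
#' @param pool `c(lateral, axial)` pooling block.
#' @return Numeric matrix, one row per patch.
#' @export
patches_to_features <- function(patches, pool = c(8L, 8L)) {
  rows <- lapply(patches, function(p) {
    as.vector(pool_matrix(normalize_patch(p)$data, pool))
  })
  do.call(rbind, rows)
}

mlp_init <- function(sizes) {
  lapply(seq_len(length(sizes) - 1L), function(i) {
    list(
      w = matrix(stats::rnorm(sizes[i] * sizes[i + 1L],
                              sd = sqrt(1 / sizes[i])),
                 sizes[i], sizes[i + 1L]),
      b = rep(0, sizes[i + 1L])
    )
  })
}

mlp_forward <- function(layers, x, output) {
  a <- list(x)
  nl <- length(layers)
  for (i in seq_len(nl)) {
    z <- sweep(a[[i]] %*% layers[[i]]$w, 2, layers[[i]]$b, "+")
    a[[i + 1L]] <- if (i < nl) tanh(z) else z
  }
  if (output == "sigmoid") a[[nl + 1L]] <- 1 / (1 + exp(-a[[nl + 1L]]))
  a
}

# One SGD step on a mini-batch; returns updated layers.
mlp_step <- function(layers, x, y, lr, l2, output) {
  a <- mlp_forward(layers, x, output)
  nl <- length(layers)
  n <- nrow(x)
  # both BCE+sigmoid and MSE+linear give (prediction - target) at the top
  delta <- (a[[nl + 1L]] - y) / n
  if (output == "linear") delta <- 2 * delta
  for (i in rev(seq_len(nl))) {
    gw <- crossprod(a[[i]], delta) + l2 * layers[[i]]$w
    gb <- colSums(delta)
    if (i > 1L) {
      delta <- (delta %*% t(layers[[i]]$w)) * (1 - a[[i]]^2)
    }
    layers[[i]]$w <- layers[[i]]$w - lr * gw
    layers[[i]]$b <- layers[[i]]$b - lr * gb
  }
  layers
}

mlp_loss <- function(layers, x, y, output) {
  p <- mlp_forward(layers, x, output)[[length(layers) + 1L]]
  if (output == "sigmoid") {
    eps <- 1e-12
    -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps))
  } else {
    mean((p - y)^2)
  }
}

# Train a dense network by mini-batch SGD. y is a numeric matrix
# (n x output-dim). Returns layers + per-epoch mean loss.
mlp_train <- function(x, y, sizes, cfg, output, lr = cfg$lr) {
  layers <- mlp_init(sizes)
  n <- nrow(x)
  loss <- numeric(cfg$epochs)
  for (e in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    starts <- seq.int(1L, n, by = cfg$batch_size)
    for (s in starts) {
      idx <- ord[s:min(s + cfg$batch_size - 1L, n)]
      layers <- mlp_step(layers, x[idx, , drop = FALSE],
                         y[idx, , drop = FALSE], lr, cfg$l2, output)
    }
    loss[e] <- mlp_loss(layers, x, y, output)
  }
  list(layers = layers, loss = loss, output = output)
}

mlp_predict <- function(model, x) {
  mlp_forward(model$layers, x, model$output)[[length(model$layers) + 1L]]
}

#' Leave-one-patient-out patch-classifier training
#'
#' Trains one small dense network per held-out patient on standardized,
#' average-pooled patches (mini-batch SGD with the configured batch size
#' and epoch count) and aggregates per-fold sensitivity/specificity by the
#' mean over folds, balanced accuracy from the means. Deterministic given
#' the configuration seed. Folds with single-class training data are
#' skipped with a warning.
#'
#' @param patches List of `oct_patch` objects.
#' @param positive Logical pathological-class indicator per patch.
#' @param patient_ids Patient identity per patch.
#' @param cfg An [nn_config()].
#' @return An `eval_report` (as for [loo_svm_evaluate()]) whose settings
#'   record the protocol.
#' @export
train_patch_classifier_loo <- function(patches, positive, patient_ids,
                                       cfg = nn_config()) {
  x <- patches_to_features(patches, cfg$pool)
  positive <- as.logical(positive)
  stopifnot(nrow(x) == length(positive), nrow(x) == length(patient_ids))
  set.seed(cfg$seed)
  patients <- unique(patient_ids)
  if (length(patients) < 2L) stopf("need at least 2 patients")
  sizes <- c(ncol(x), cfg$hidden, 1L)
  folds <- list(); skipped <- character()
  for (p in patients) {
    test <- patient_ids == p
    ytr <- positive[!test]
    if (length(unique(ytr)) < 2L) {
      warning(sprintf("fold %s skipped: single-class training data", p))
      skipped <- c(skipped, p)
      next
    }
    model <- mlp_train(x[!test, , drop = FALSE],
                       matrix(as.numeric(ytr), ncol = 1L),
                       sizes, cfg, output = "sigmoid")
    pred <- mlp_predict(model, x[test, , drop = FALSE])[, 1L] >= 0.5
    cm <- fold_confusion(pred, positive[test])
    sens <- if (cm["tp"] + cm["fn"] > 0) {
      100 * cm["tp"] / (cm["tp"] + cm["fn"])
    } else NA_real_
    spec <- if (cm["tn"] + cm["fp"] > 0) {
      100 * cm["tn"] / (cm["tn"] + cm["fp"])
    } else NA_real_
    folds[[length(folds) + 1L]] <- data.frame(
      patient_id = p, n_test = sum(test),
      tp = cm[["tp"]], fp = cm[["fp"]], tn = cm[["tn"]], fn = cm[["fn"]],
      sensitivity = unname(sens), specificity = unname(spec)
    )
  }
  if (!length(folds)) stopf("no evaluable folds")
  folds <- do.call(rbind, folds)
  mean_sens <- mean(folds$sensitivity, na.rm = TRUE)
  mean_spec <- mean(folds$specificity, na.rm = TRUE)
  bal <- (mean_sens + mean_spec) / 2
  structure(
    list(
      folds = folds, mean_sensitivity = mean_sens,
      mean_specificity = mean_spec, balanced_accuracy = bal,
      balanced_accuracy_rounded = round_half_out(bal),
      skipped_folds = skipped,
      settings = list(model = "dense_net",
                      split = "leave_one_patient_out",
                      hidden = cfg$hidden, pool = cfg$pool,
                      batch_size = cfg$batch_size, epochs = cfg$epochs,
                      lr = cfg$lr, seed = cfg$seed,
                      patch_normalization = "zscore",
                      aggregation = "mean_of_folds")
    ),
    class = "eval_report"
  )
}

#' Autoencoder features plus dense classifier
#'
#' Unsupervised stage first: a mirror-symmetric dense autoencoder is
#' trained (mini-batch SGD, MSE) on the training portion of a seeded
#' random split with `test_fraction` (30%) held out. The encoder output
#' then feeds a dense classifier trained with the same protocol, and
#' diagnostic metrics are computed on the held-out split.
#'
#' @inheritParams train_patch_classifier_loo
#' @return List of class `ae_report`: `metrics` ([compute_metrics()]),
#'   `ae_loss` (per-epoch reconstruction loss), `test_index`, and settings.
#' @export
train_ae_classifier <- function(patches, positive, cfg = nn_config()) {
  x <- patches_to_features(patches, cfg$pool)
  positive <- as.logical(positive)
  stopifnot(nrow(x) == length(positive))
  set.seed(cfg$seed)
  n <- nrow(x)
  test <- sort(sample.int(n, max(1L, round(cfg$test_fraction * n))))
  train <- setdiff(seq_len(n), test)
  if (length(unique(positive[train])) < 2L) {
    stopf("single-class training split")
  }
  ae_sizes <- c(ncol(x), cfg$encoder, rev(cfg$encoder)[-1], ncol(x))
  ae <- mlp_train(x[train, , drop = FALSE], x[train, , drop = FALSE],
                  ae_sizes, cfg, output = "linear", lr = cfg$ae_lr)
  n_enc <- length(cfg$encoder)
  encode <- function(xx) {
    mlp_forward(ae$layers, xx, "linear")[[n_enc + 1L]]
  }
  ztr <- encode(x[train, , drop = FALSE])
  zte <- encode(x[test, , drop = FALSE])
  # standardize the learned features with training statistics before the
  # classifier; raw encoder outputs can sit at an arbitrarily small scale
  zmu <- colMeans(ztr)
  zsd <- apply(ztr, 2, stats::sd)
  zsd[!is.finite(zsd) | zsd == 0] <- 1
  ztr <- sweep(sweep(ztr, 2, zmu, "-"), 2, zsd, "/")
  zte <- sweep(sweep(zte, 2, zmu, "-"), 2, zsd, "/")
  fc <- mlp_train(ztr, matrix(as.numeric(positive[train]), ncol = 1L),
                  c(ncol(ztr), cfg$hidden, 1L), cfg, output = "sigmoid")
  pred <- mlp_predict(fc, zte)[, 1L] >= 0.5
  cm <- fold_confusion(pred, positive[test])
  structure(
    list(
      metrics = compute_metrics(cm[["tp"]], cm[["fp"]], cm[["tn"]],
                                cm[["fn"]]),
      ae_loss = ae$loss,
      test_index = test,
      encode = encode,
      settings = list(model = "autoencoder_fc",
                      split = sprintf("random_split_%d",
                                      round(100 * cfg$test_fraction)),
                      encoder = cfg$encoder, hidden = cfg$hidden,
                      pool = cfg$pool, batch_size = cfg$batch_size,
                      epochs = cfg$epochs, lr = cfg$lr, seed = cfg$seed,
                      patch_normalization = "zscore")
    ),
    class = "ae_report"
  )
}
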