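#' 1D-CNN regressor architecture and training protocol
#'
#' Four 1D convolutional layers (22, 22, 44, 44 filters, kernel 7, stride 1,
#' same padding, ReLU), each followed by batch normalization and 20%
#' dropout; flatten plus dropout; a 22-unit ReLU dense layer with L2 weight
#' penalty 0.001; one linear output unit. Trained with Adam on mean squared
#' error, batch size 44, at most 35 epochs, early stopping with patience 10
#' on validation loss. The input is the 22 PCA scores of one spectrum and
#' the target the log-decade class index (0 for control up to 9 for Cr6+ or
#' 13 for As3+); predictions are not clipped to that range.
#'
#' @param input_len Input length (PCA scores; default 22).
#' @param conv_filters Filters of the four conv layers.
#' @param kernel_size Convolution kernel length.
#' @param dropout_rate Dropout after each conv block and after flatten.
#' @param dense_units Hidden dense layer width.
#' @param l2 L2 penalty on the hidden dense layer weights.
#' @param batch_size,max_epochs,patience,learning_rate Training protocol.
#' @param seed Seed for initialization, shuffling and dropout.
#' @return A list of class `cnn_spec`.
#' @export
cnn_spec <- function(input_len = 22L, conv_filters = c(22L, 22L, 44L, 44L),
                     kernel_size = 7L, dropout_rate = 0.2, dense_units = 22L,
                     l2 = 0.001, batch_size = 44L, max_epochs = 35L,
                     patience = 10L, learning_rate = 0.001, seed = 1L) {
  if (length(conv_filters) != 4L) abort("The architecture uses exactly 4 conv layers.")
  if (kernel_size %% 2L == 0L) abort("`kernel_size` must be odd for same padding.")
  structure(list(input_len = as.integer(input_len),
                 conv_filters = as.integer(conv_filters),
                 kernel_size = as.integer(kernel_size),
                 dropout_rate = dropout_rate, dense_units = as.integer(dense_units),
                 l2 = l2, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = if (is.null(patience)) NULL else as.integer(patience),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "cnn_spec")
}

#' Build a (untrained) 1D CNN
#'
#' @param spec A [cnn_spec()].
#' @param head `"regression"` (linear unit, MSE loss) or `"binary"`
#'   (single sigmoid unit on the flattened features, binary cross-entropy),
#'   the latter used for the above/below-limit transfer models.
#' @return An object of class `sers_cnn` holding the layer stack; weight
#'   initialization is deterministic given `spec$seed`.
#' @export
build_cnn <- function(spec = cnn_spec(), head = c("regression", "binary")) {
  head <- match.arg(head)
  with_seed(derive_seed(spec$seed, "init"), {
    layers <- list()
    cin <- 1L
    for (i in seq_along(spec$conv_filters)) {
      cout <- spec$conv_filters[i]
      layers <- c(layers, list(layer_conv1d(cin, cout, spec$kernel_size),
                               layer_batchnorm(cout),
                               layer_dropout(spec$dropout_rate)))
      cin <- cout
    }
    layers <- c(layers, list(layer_flatten(), layer_dropout(spec$dropout_rate)))
    flat <- spec$input_len * cin
    if (head == "regression") {
      layers <- c(layers, list(layer_dense(flat, spec$dense_units, "relu", spec$l2),
                               layer_dense(spec$dense_units, 1L, "linear")))
    } else {
      layers <- c(layers, list(layer_dense(flat, 1L, "linear")))
    }
    structure(list(layers = layers, spec = spec, head = head,
                   loss = if (head == "regression") "mse" else "bce",
                   trained = FALSE, history = NULL),
              class = "sers_cnn")
  })
}

#' Parameter count per layer of a CNN
#'
#' @param model A `sers_cnn`.
#' @return Tibble with layer type and number of parameters.
#' @export
count_parameters <- function(model) {
  tibble::tibble(
    layer = vapply(model$layers, `[[`, "", "type"),
    n_parameters = vapply(model$layers, function(l) {
      sum(vapply(intersect(c("W", "b", "gamma", "beta"), names(l)),
                 function(nm) length(l[[nm]]), 1L))
    }, 1L)
  )
}

#' Train a 1D CNN
#'
#' Splits off a stratified validation fraction, then runs mini-batch Adam
#' with the protocol in the spec (batch size, epoch budget, early stopping
#' when the validation loss has risen for more than `patience` consecutive
#' epochs). Fully deterministic given `seed`.
#'
#' @param model A [build_cnn()] model.
#' @param fm Training `sers_features` tibble.
#' @param target Column with the regression target (default `class_index`)
#'   or 0/1 labels for a binary head.
#' @param val_frac Stratified validation fraction (default 0.2).
#' @param epochs Epoch budget (default `spec$max_epochs`).
#' @param patience Early-stopping patience (default `spec$patience`);
#'   `NULL` disables early stopping.
#' @param trainable Optional logical vector over layers to freeze a subset
#'   (used by transfer learning).
#' @param seed Seed; defaults to the spec seed.
#' @return The trained `sers_cnn` with an epoch-wise `history` tibble.
#' @export
train_cnn <- function(model, fm, target = "class_index", val_frac = 0.2,
                      epochs = NULL, patience = model$spec$patience,
                      trainable = NULL, seed = NULL) {
  if (nrow(fm) == 0L) abort("Training set is empty.")
  spec <- model$spec
  epochs <- epochs %||% spec$max_epochs
  if (epochs == 0L) return(model)
  if (!is.null(trainable)) {
    for (i in seq_along(model$layers)) {
      if (model$layers[[i]]$type %in% c("conv1d", "dense", "batchnorm")) {
        model$layers[[i]]$trainable <- trainable[i]
      }
    }
  }
  y <- as.numeric(fm[[target]])
  X <- score_matrix(fm)
  with_seed(seed %||% derive_seed(spec$seed, "train"), {
    if (val_frac > 0) {
      sp <- stratified_split(tibble::tibble(class_index = fm[[target]],
                                            row = seq_len(nrow(fm))),
                             holdout_frac = val_frac)
      tr <- sp$train$row
      va <- sp$holdout$row
    } else {
      tr <- seq_len(nrow(fm)); va <- integer(0)
    }
    fit <- nn_train(model$layers, X[tr, , drop = FALSE], y[tr],
                    X[va, , drop = FALSE], y[va], loss = model$loss,
                    batch_size = spec$batch_size, epochs = epochs,
                    patience = patience, lr = spec$learning_rate)
    model$layers <- fit$layers
    model$history <- fit$history
    model$trained <- TRUE
    model
  })
}

#' @export
predict.sers_cnn <- function(object, newdata, ...) {
  X <- if (is.matrix(newdata)) newdata else score_matrix(newdata)
  out <- nn_forward(object$layers, X, training = FALSE)$out
  if (object$loss == "bce") sigmoid(out) else out
}

#' Regression metrics on a holdout set
#'
#' `MSE = mean((pred - truth)^2)`; `R2 = 1 - SS_res / SS_tot`.
#'
#' @param model A trained `sers_cnn`.
#' @param fm Nonempty holdout `sers_features`.
#' @param target Target column.
#' @return Tibble with `mse`, `r_squared` and `n`.
#' @export
evaluate_regression <- function(model, fm, target = "class_index") {
  if (nrow(fm) == 0L) abort("Holdout set is empty.")
  truth <- as.numeric(fm[[target]])
  if (stats::var(truth) == 0) abort("R-squared is undefined for zero-variance truth.")
  pred <- predict(model, fm)
  regression_metrics(truth, pred)
}

regression_metrics <- function(truth, pred) {
  tibble::tibble(
    mse = mean((pred - truth)^2),
    r_squared = 1 - sum((pred - truth)^2) / sum((truth - mean(truth))^2),
    n = length(truth)
  )
}

#' Learning-curve study over training-set size
#'
#' For each requested per-class size, draws that many training rows per
#' class (sampling down, or SMOTE-augmenting up when the size exceeds the
#' real count), trains a fresh CNN and evaluates it on the fixed holdout;
#' repeats `n_repeats` times to report mean and SD of MSE and R2. Sizes
#' beyond the largest class count (the augmentation ceiling) are an error.
#'
#' @param train,holdout `sers_features` partitions from [stratified_split()].
#' @param spec A [cnn_spec()].
#' @param sizes Per-class training sizes.
#' @param n_repeats Repeats per size.
#' @param epochs Epoch budget per fit.
#' @param seed Top-level seed.
#' @return Tibble: size, mean/SD of MSE and R2 over repeats.
#' @export
learning_curve <- function(train, holdout, spec = cnn_spec(),
                           sizes = c(100L, 1000L, 3000L, 7680L),
                           n_repeats = 10L, epochs = spec$max_epochs,
                           seed = 1L) {
  max_size <- max(table(train$class_index))
  if (any(sizes > max_size)) {
    abort(sprintf("Sizes beyond the augmentation ceiling (%d per class).", max_size))
  }
  res <- list()
  for (s in sizes) {
    runs <- list()
    for (r in seq_len(n_repeats)) {
      rs <- derive_seed(seed, sprintf("lc_%d_%d", s, r))
      sub <- with_seed(rs, {
        parts <- lapply(split(seq_len(nrow(train)), train$class_index), function(idx) {
          if (length(idx) >= s) sample(idx, s) else idx
        })
        train[sort(unlist(parts)), ]
      })
      counts <- table(sub$class_index)
      if (any(counts < s)) {
        sub <- smote_oversample(sub, stats::setNames(rep(s, length(counts)), names(counts)),
                                seed = derive_seed(rs, "smote"))
      }
      sp2 <- spec; sp2$seed <- rs
      mod <- build_cnn(sp2)
      mod <- train_cnn(mod, sub, epochs = epochs, seed = derive_seed(rs, "fit"))
      runs[[r]] <- evaluate_regression(mod, holdout)
    }
    runs <- dplyr::bind_rows(runs)
    res[[length(res) + 1L]] <- tibble::tibble(
      size = s, mse_mean = mean(runs$mse),
      mse_sd = if (n_repeats > 1L) stats::sd(runs$mse) else 0,
      r2_mean = mean(runs$r_squared),
      r2_sd = if (n_repeats > 1L) stats::sd(runs$r_squared) else 0,
      n_repeats = n_repeats
    )
  }
  dplyr::bind_rows(res)
}

#' Empirical LOB / LOD / LOQ from per-class prediction distributions
#'
#' Per class, the central 99% prediction interval `[P0.5, P99.5]` is taken
#' with linear interpolation between order statistics. The limit of blank
#' (LOB) is the control interval on the prediction scale. The LOD is the
#' smallest concentration whose class — and every higher class — has fewer
#' than `alpha` (0.5%) of its predictions inside the LOB. The LOQ is the
#' smallest concentration whose class and every higher class overlap each
#' existing neighbour's interval by less than `alpha`. The dynamic range
#' runs from the LOQ to the largest concentration. Box-plot statistics
#' (quartiles, median, 99% whiskers) use the same percentile definitions.
#'
#' @param predictions Tibble with `class_index` and `prediction` columns
#'   (control rows have class_index 0); at least `min_n` rows per class.
#' @param concentrations mol/L of the nonzero classes in ascending order.
#' @param alpha Overlap gate (default 0.005).
#' @param min_n Minimum predictions per class (default 20).
#' @return An object of class `sers_limits`.
#' @export
determine_limits <- function(predictions, concentrations, alpha = 0.005,
                             min_n = 20L) {
  cls <- sort(unique(predictions$class_index))
  if (!0L %in% cls) abort("Control predictions (class_index 0) are required.")
  nz <- setdiff(cls, 0L)
  if (length(nz) != length(concentrations)) {
    abort("`concentrations` must match the nonzero classes present.")
  }
  split_preds <- split(predictions$prediction, predictions$class_index)
  n_per <- vapply(split_preds, length, 1L)
  if (any(n_per < min_n)) abort(sprintf("Every class needs >= %d predictions.", min_n))
  probs <- c(alpha, 0.25, 0.5, 0.75, 1 - alpha)
  qs <- t(vapply(split_preds, quantile, numeric(5), probs = probs, type = 7,
                 names = FALSE))
  colnames(qs) <- c("lower", "q25", "median", "q75", "upper")
  key <- as.character(cls)
  lob <- qs[key == "0", c("lower", "upper")]
  inside <- function(x, iv) mean(x >= iv[1] & x <= iv[2])
  frac_in_lob <- vapply(as.character(nz), function(k) inside(split_preds[[k]], lob), 1)
  # LOD: class and all larger stay out of the blank interval.
  pass_lod <- frac_in_lob < alpha
  ok_lod <- rev(cumprod(rev(pass_lod))) > 0
  i_lod <- which(ok_lod)[1]
  # LOQ: class and all larger overlap existing neighbours below alpha.
  ladder <- c(0L, nz)  # control is the lower neighbour of the lowest class
  pass_loq <- vapply(seq_along(nz), function(j) {
    k <- as.character(nz[j])
    below <- as.character(ladder[j])
    ok <- inside(split_preds[[k]], qs[key == below, c("lower", "upper")]) < alpha
    if (j < length(nz)) {
      up <- as.character(nz[j + 1L])
      ok <- ok && inside(split_preds[[k]], qs[key == up, c("lower", "upper")]) < alpha
    }
    ok
  }, TRUE)
  pass_loq <- pass_loq & pass_lod  # quantification implies detection
  ok_loq <- rev(cumprod(rev(pass_loq))) > 0
  i_loq <- which(ok_loq)[1]
  intervals <- tibble::as_tibble(qs)
  intervals$class <- cls
  intervals$concentration_molar <- c(0, concentrations)
  intervals$n <- as.integer(n_per[key])
  intervals$frac_in_lob <- c(NA_real_, frac_in_lob)
  intervals <- intervals[, c("class", "concentration_molar", "n", "lower", "q25",
                             "median", "q75", "upper", "frac_in_lob")]
  structure(list(
    lob = as.numeric(lob),
    lod = if (!is.na(i_lod)) concentrations[i_lod] else NA_real_,
    lod_class = if (!is.na(i_lod)) nz[i_lod] else NA_integer_,
    loq = if (!is.na(i_loq)) concentrations[i_loq] else NA_real_,
    loq_class = if (!is.na(i_loq)) nz[i_loq] else NA_integer_,
    dynamic_range = c(if (!is.na(i_loq)) concentrations[i_loq] else NA_real_,
                      max(concentrations)),
    intervals = intervals, alpha = alpha
  ), class = "sers_limits")
}
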