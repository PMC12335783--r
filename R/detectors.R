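# Public detector interface: one training/prediction contract over the SVM
# baseline and the five neural sequence labelers.

#' Detector model specification
#'
#' @param family One of `"svm"`, `"cnn1d"`, `"transformer"`, `"unet"`,
#'   `"cnn_gru"`, `"cnn_lstm"`.
#' @param threshold Probability cut for binarizing per-sample QE
#'   probabilities (mask = 1 iff probability >= threshold).
#' @param width_scale Multiplier applied to layer widths (convolution
#'   filters, recurrent units). 1 keeps the reference architecture
#'   (convolutions with 64/128 filters, recurrent stacks of 200/100/50
#'   units, UNet encoder 64/128/256); smaller values give proportionally
#'   narrower desk-scale models.
#' @param heads Attention heads (transformer only).
#' @param l2 L2 regularization weight on recurrent weight matrices
#'   (cnn_gru/cnn_lstm).
#' @param cost,gamma SVM hyperparameters (RBF kernel).
#' @param context Half-width (in samples) of an optional context window
#'   around each timepoint used as extra SVM features; 0 (default) uses the
#'   single standardized amplitude, with each time point treated as a
#'   separate sample.
#' @param max_train_points Cap on the number of timepoints used to train the
#'   SVM (stratified subsample); per-timepoint training sets grow as
#'   segments x segment length and full kernel fits are quadratic in that.
#' @return A `detector_spec` object.
#' @examples
#' detector_spec("cnn_lstm")
#' detector_spec("svm", cost = 2)
#' @export
detector_spec <- function(family = c("cnn_lstm", "cnn_gru", "unet",
                                     "transformer", "cnn1d", "svm"),
                          threshold = 0.5, width_scale = 1, heads = 4L,
                          l2 = 0.001, cost = 1, gamma = 1, context = 0L,
                          max_train_points = 4000L) {
  family <- match.arg(family)
  if (threshold <= 0 || threshold >= 1) abort("`threshold` must be in (0,1).")
  if (width_scale <= 0) abort("`width_scale` must be positive.")
  structure(list(family = family, threshold = threshold,
                 width_scale = width_scale, heads = as.integer(heads),
                 l2 = l2, cost = cost, gamma = gamma,
                 context = as.integer(context),
                 max_train_points = as.integer(max_train_points)),
            class = "detector_spec")
}

#' @export
print.detector_spec <- function(x, ...) {
  cat(sprintf("<detector_spec> %s (threshold %.2f, width x%g)\n",
              x$family, x$threshold, x$width_scale))
  invisible(x)
}

#' Training settings
#'
#' @param epochs Training epochs (>= 1). The reference recipe is 50 epochs;
#'   desk-scale runs use fewer.
#' @param learning_rate Adam learning rate.
#' @param batch_size Minibatch size in segments.
#' @param seed Integer seed controlling initialization order, shuffling and
#'   the validation split; fits are reproducible given the seed.
#' @param validation_fraction Fraction of training segments held out to track
#'   validation loss/accuracy per epoch (0 disables the holdout).
#' @param clip_norm Global gradient-norm ceiling. Gradients whose overall
#'   norm exceeds it are rescaled before the Adam step, which stabilizes the
#'   recurrent stacks late in training; `Inf` disables clipping.
#' @return A `train_config` object. Loss is per-sample binary cross-entropy;
#'   the optimizer is Adam.
#' @export
train_config <- function(epochs = 50L, learning_rate = 0.001,
                         batch_size = 8L, seed = 1L,
                         validation_fraction = 0.2, clip_norm = 1) {
  epochs <- as.integer(epochs)
  if (is.na(epochs) || epochs < 1L) abort("`epochs` must be >= 1.")
  if (learning_rate <= 0) abort("`learning_rate` must be > 0.")
  if (validation_fraction < 0 || validation_fraction >= 1) {
    abort("`validation_fraction` must be in [0, 1).")
  }
  structure(list(epochs = epochs, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 validation_fraction = validation_fraction,
                 clip_norm = clip_norm,
                 loss = "binary_cross_entropy", optimizer = "adam"),
            class = "train_config")
}

#' Build an untrained detector
#'
#' Instantiates the family's architecture for a given segment length.
#' Sequence lengths that are not divisible by the family's pooling depth are
#' handled by symmetric zero-padding before pooling and cropping after
#' upsampling, so the output trace always matches the input length.
#'
#' @param spec A [detector_spec()].
#' @param input_length Segment length in samples (1700 at the default window
#'   and 200 Hz).
#' @param seed Seed for parameter initialization.
#' @return A `qe_detector` object.
#' @export
build_detector <- function(spec, input_length, seed = 1L) {
  input_length <- as.integer(input_length)
  if (input_length < 8L) abort("`input_length` must be at least 8 samples.")
  net <- if (spec$family == "svm") {
    list(family = "svm", input_length = input_length)
  } else {
    with_local_seed(seed, .net_build(spec, input_length))
  }
  structure(list(spec = spec, net = net, input_length = input_length,
                 fitted = FALSE, norm = list(mean = 0, sd = 1),
                 log = NULL),
            class = "qe_detector")
}

#' @export
print.qe_detector <- function(x, ...) {
  cat(sprintf("<qe_detector> %s, input length %d, %s\n", x$spec$family,
              x$input_length, if (x$fitted) "fitted" else "untrained"))
  invisible(x)
}

.check_segments_for_model <- function(model, segments) {
  if (ncol(segments$x) != model$input_length) {
    abort(sprintf("Segment length %d does not match model input length %d.",
                  ncol(segments$x), model$input_length))
  }
}

# Lagged-context design matrix for the per-timepoint SVM.
.svm_features <- function(xstd, context) {
  L <- ncol(xstd)
  flat <- as.numeric(t(xstd)) # time-major within segment
  if (context == 0L) return(matrix(flat, ncol = 1L))
  idx <- -context:context
  n_seg <- nrow(xstd)
  out <- matrix(0, length(flat), length(idx))
  for (j in seq_along(idx)) {
    for (s in seq_len(n_seg)) {
      src <- pmin(pmax(seq_len(L) + idx[j], 1L), L)
      out[(s - 1L) * L + seq_len(L), j] <- xstd[s, src]
    }
  }
  out
}

#' Fit a detector on training segments
#'
#' Neural families minimize per-sample binary cross-entropy with Adam,
#' recording per-epoch training (and optionally validation) loss and
#' accuracy. The SVM baseline standardizes amplitudes and fits an RBF-kernel
#' classifier treating each timepoint as a separate sample. Normalization
#' statistics are computed from the training segments only. All-one-class
#' training masks trigger a warning but training proceeds.
#'
#' @param model A [build_detector()] result.
#' @param segments Training `qe_segments`.
#' @param cfg A [train_config()].
#' @return A fitted `qe_detector` with a `log` tibble (`epoch`, `loss`,
#'   `accuracy`, and validation columns when a holdout is configured).
#' @examples
#' \donttest{
#' segs <- extract_segments(simulate_recording(sim_config(seed = 5)))
#' det <- build_detector(detector_spec("cnn1d", width_scale = 0.1), 1700)
#' det <- fit_detector(det, segs, train_config(epochs = 2))
#' }
#' @export
fit_detector <- function(model, segments, cfg = train_config()) {
  .check_segments_for_model(model, segments)
  if (n_segments(segments) < 1L) abort("Training set is empty.")
  if (all(segments$mask == 1L) || all(segments$mask == 0L)) {
    warn("Training masks contain a single class; training proceeds.")
  }
  mu <- mean(segments$x)
  sdv <- sd(as.numeric(segments$x))
  if (!is.finite(sdv) || sdv == 0) sdv <- 1
  model$norm <- list(mean = mu, sd = sdv)
  xstd <- (segments$x - mu) / sdv
  y <- segments$mask
  if (model$spec$family == "svm") {
    model <- .fit_svm(model, xstd, y, cfg)
  } else {
    model <- .fit_net(model, xstd, y, cfg)
  }
  model$fitted <- TRUE
  model
}

.fit_svm <- function(model, xstd, y, cfg) {
  spec <- model$spec
  feats <- .svm_features(xstd, spec$context)
  labs <- as.integer(t(y))
  with_local_seed(cfg$seed, {
    n <- nrow(feats)
    take <- if (n > spec$max_train_points) {
      # stratified subsample keeps the QE / non-QE ratio
      pos <- which(labs == 1L); neg <- which(labs == 0L)
      npos <- max(1L, round(spec$max_train_points * length(pos) / n))
      sort(c(sample(pos, min(npos, length(pos))),
             sample(neg, min(spec$max_train_points - npos, length(neg)))))
    } else {
      seq_len(n)
    }
    fit <- e1071::svm(feats[take, , drop = FALSE],
                      factor(labs[take], levels = c(0L, 1L)),
                      kernel = "radial", cost = spec$cost,
                      gamma = spec$gamma, scale = FALSE)
    model$net <- list(family = "svm", fit = fit,
                      input_length = model$input_length)
    model$log <- tibble(epoch = 1L, loss = NA_real_,
                        accuracy = mean(predict(fit, feats[take, , drop = FALSE]) ==
                                          factor(labs[take], levels = c(0L, 1L))))
    model
  })
}

.fit_net <- function(model, xstd, y, cfg) {
  spec <- model$spec
  with_local_seed(cfg$seed, {
    net <- model$net
    n <- nrow(xstd)
    val_idx <- integer(0)
    if (cfg$validation_fraction > 0 && n >= 5L) {
      val_idx <- sort(sample(n, max(1L, round(cfg$validation_fraction * n))))
    }
    tr_idx <- setdiff(seq_len(n), val_idx)
    if (length(tr_idx) == 0L) tr_idx <- seq_len(n)
    # start the sigmoid head at the training base rate so early epochs are
    # spent on signal, not on calibrating the class prior
    base_rate <- min(max(mean(y[tr_idx, ] == 1L), 1e-4), 1 - 1e-4)
    net$params$head$b <- rep(stats::qlogis(base_rate),
                             length(net$params$head$b))
    opt <- .adam_init(net$params)
    log <- vector("list", cfg$epochs)
    l2 <- spec$l2 %||% 0
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample(tr_idx)
      ep_loss <- 0; ep_acc <- 0; nb <- 0L
      for (start in seq.int(1L, length(ord), by = cfg$batch_size)) {
        bi <- ord[start:min(start + cfg$batch_size - 1L, length(ord))]
        Xb <- xstd[bi, , drop = FALSE]
        Yb <- y[bi, , drop = FALSE]
        fw <- .net_forward(net, Xb, train = TRUE)
        net$state <- fw$state
        ls <- .bce_with_logits(fw$logits, Yb)
        grads <- .net_backward(net, fw$cache, ls$dZ)
        if (l2 > 0 && net$family %in% c("cnn_gru", "cnn_lstm")) {
          for (nm in c("rnn1", "rnn2", "rnn3")) {
            for (dir in c("f", "b")) {
              grads[[nm]][[dir]]$W <- grads[[nm]][[dir]]$W +
                l2 * net$params[[nm]][[dir]]$W
              grads[[nm]][[dir]]$U <- grads[[nm]][[dir]]$U +
                l2 * net$params[[nm]][[dir]]$U
            }
          }
        }
        clip <- cfg$clip_norm %||% Inf
        if (is.finite(clip)) {
          gn <- sqrt(.grad_sq_sum(grads))
          if (gn > clip) grads <- .grad_scale(grads, clip / gn)
        }
        step <- .adam_step(net$params, grads, opt, cfg$learning_rate)
        net$params <- step$params
        opt <- step$opt
        ep_loss <- ep_loss + ls$loss
        ep_acc <- ep_acc + mean((ls$probs >= spec$threshold) == (Yb == 1L))
        nb <- nb + 1L
      }
      row <- tibble(epoch = ep, loss = ep_loss / nb, accuracy = ep_acc / nb)
      if (length(val_idx) > 0L) {
        fv <- .net_forward(net, xstd[val_idx, , drop = FALSE], train = FALSE)
        lv <- .bce_with_logits(fv$logits, y[val_idx, , drop = FALSE])
        row$val_loss <- lv$loss
        row$val_accuracy <- mean((lv$probs >= spec$threshold) ==
                                   (y[val_idx, , drop = FALSE] == 1L))
      }
      log[[ep]] <- row
    }
    model$net <- net
    model$log <- dplyr::bind_rows(log)
    model
  })
}

#' Predict per-sample QE probabilities and masks
#'
#' @param object A fitted `qe_detector`.
#' @param segments `qe_segments` with the model's input length.
#' @param ... Unused.
#' @return A `qe_predictions` object: `probs` and `mask` matrices (segments
#'   in rows), the `threshold`, and the source metadata. Prediction is
#'   deterministic: repeated calls give identical output.
#' @export
predict.qe_detector <- function(object, segments, ...) {
  if (!object$fitted) abort("Model must be fitted before prediction.")
  .check_segments_for_model(object, segments)
  xstd <- (segments$x - object$norm$mean) / object$norm$sd
  probs <- if (object$spec$family == "svm") {
    pr <- predict(object$net$fit, .svm_features(xstd, object$spec$context),
                  decision.values = TRUE)
    dv_attr <- attr(pr, "decision.values")
    dv <- as.numeric(dv_attr)
    # libsvm orients the decision value towards the first-listed class
    if (identical(colnames(dv_attr)[1L], "0/1")) dv <- -dv
    matrix(stats::plogis(dv), nrow = nrow(xstd), byrow = TRUE)
  } else {
    fw <- .net_forward(object$net, xstd, train = FALSE)
    stats::plogis(fw$logits)
  }
  structure(list(probs = probs,
                 mask = matrix(as.integer(probs >= object$spec$threshold),
                               nrow = nrow(probs)),
                 threshold = object$spec$threshold,
                 meta = segments$meta, fs = segments$fs),
            class = "qe_predictions")
}

#' @export
print.qe_predictions <- function(x, ...) {
  cat(sprintf("<qe_predictions> %d segment(s) x %d samples, threshold %.2f\n",
              nrow(x$probs), ncol(x$probs), x$threshold))
  invisible(x)
}

#' @describeIn fit_detector Per-epoch training log of a fitted detector.
#' @param x A fitted `qe_detector`.
#' @param ... Unused.
#' @export
tidy.qe_detector <- function(x, ...) {
  if (is.null(x$log)) abort("Model has no training log; fit it first.")
  x$log
}

#' @describeIn fit_detector One-row fit summary (family, final loss/accuracy).
#' @export
glance.qe_detector <- function(x, ...) {
  lg <- x$log
  tibble(family = x$spec$family, fitted = x$fitted,
         epochs = if (is.null(lg)) 0L else max(lg$epoch),
         final_loss = if (is.null(lg)) NA_real_ else lg$loss[nrow(lg)],
         final_accuracy = if (is.null(lg)) NA_real_ else lg$accuracy[nrow(lg)])
}

#' @describeIn fit_detector Training/validation learning curves.
#' @param object A fitted `qe_detector`.
#' @export
autoplot.qe_detector <- function(object, ...) {
  lg <- tidy(object)
  df <- tidyr::pivot_longer(lg, -"epoch", names_to = "metric")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value,
                                   colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = NULL,
                  title = sprintf("%s learning curves", object$spec$family)) +
    ggplot2::theme_minimal()
}
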