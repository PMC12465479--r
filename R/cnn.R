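#' CNN model configuration
#'
#' The default architecture is the deep 2D-CNN used for hotspot coordinate
#' regression: four convolution blocks of (2, 2, 3, 3) stride-1 7x7
#' convolutions with (16, 32, 64, 128) filters, each block followed by a
#' 2x2/stride-2 max-pool, then three dense layers ending in a linear
#' 3-unit output - 17 weight-bearing/pooling layers in total (10
#' convolutions, 4 pools, 3 dense). All hidden activations are ReLU.
#' Training uses ADAM (learning rate 0.001), MSE loss, batch size 10, up to
#' 1000 epochs with early stopping after 20 epochs without improvement of
#' the validation loss, restoring the best-epoch weights.
#'
#' The two intermediate dense widths are configurable (256 and 64 by
#' default); smaller `conv_blocks`/`dense_sizes` profiles can be supplied
#' for cheap experiments.
#'
#' @param conv_blocks List of `c(n_convs, n_filters)` per block.
#' @param kernel Convolution kernel `c(height, width)`.
#' @param dense_sizes Dense layer widths; the last must be 3 (x, y, z).
#' @param lr ADAM learning rate.
#' @param batch_size Mini-batch size.
#' @param max_epochs Epoch cap.
#' @param patience Early-stopping patience (epochs without validation
#'   improvement).
#' @param seed Optional integer seed for weight initialization and
#'   shuffling.
#' @return An object of class `cnn_config`.
#' @export
model_config <- function(conv_blocks = list(c(2, 16), c(2, 32), c(3, 64), c(3, 128)),
                         kernel = c(7, 7), dense_sizes = c(256, 64, 3),
                         lr = 0.001, batch_size = 10, max_epochs = 1000,
                         patience = 20, seed = NULL) {
  stopifnot(length(dense_sizes) >= 1, lr > 0, batch_size >= 1,
            max_epochs >= 1, patience >= 1)
  if (dense_sizes[length(dense_sizes)] != 3)
    stop("the final dense layer must have width 3 (x, y, z coordinates)")
  structure(list(conv_blocks = conv_blocks, kernel = kernel,
                 dense_sizes = dense_sizes, lr = lr,
                 batch_size = batch_size, max_epochs = max_epochs,
                 patience = patience, seed = seed),
            class = "cnn_config")
}

n_layers <- function(config) {
  sum(vapply(config$conv_blocks, `[`, numeric(1), 1)) +
    length(config$conv_blocks) + length(config$dense_sizes)
}

# Internal layer spec shared with the C++ engine (types: 0 conv, 1 pool,
# 2 flatten, 3 dense).
layer_spec <- function(config, input_shape) {
  h <- input_shape[1]; w <- input_shape[2]
  if (h < 5 || w < 5)
    stop("input shape (", h, ", ", w,
         ") too small; minimum 5 x 5 to survive the pooling stack")
  layers <- list()
  in_ch <- 1L
  for (blk in config$conv_blocks) {
    for (i in seq_len(blk[1])) {
      layers[[length(layers) + 1]] <- list(
        type = 0L, in_ch = in_ch, out_ch = as.integer(blk[2]),
        kh = as.integer(config$kernel[1]), kw = as.integer(config$kernel[2]),
        in_h = as.integer(h), in_w = as.integer(w))
      in_ch <- as.integer(blk[2])
    }
    layers[[length(layers) + 1]] <- list(
      type = 1L, in_ch = in_ch, in_h = as.integer(h), in_w = as.integer(w))
    h <- ceiling(h / 2); w <- ceiling(w / 2)
  }
  layers[[length(layers) + 1]] <- list(
    type = 2L, in_ch = in_ch, in_h = as.integer(h), in_w = as.integer(w))
  len <- in_ch * h * w
  for (i in seq_along(config$dense_sizes)) {
    layers[[length(layers) + 1]] <- list(
      type = 3L, in_len = as.integer(len),
      out_len = as.integer(config$dense_sizes[i]),
      act = if (i == length(config$dense_sizes)) 0L else 1L)
    len <- config$dense_sizes[i]
  }
  layers
}

layer_report <- function(config, input_shape) {
  layers <- layer_spec(config, input_shape)
  rows <- list(data.frame(layer = 0, name = "Input", kernel = "-",
                          n_filters = NA, stride = NA,
                          output_shape = paste0(input_shape[1], "x",
                                                input_shape[2], "x1")))
  ci <- 0; pi_ <- 0; di <- 0
  for (L in layers) {
    n <- length(rows)
    if (L$type == 0) {
      ci <- ci + 1
      rows[[n + 1]] <- data.frame(
        layer = n, name = paste0("Conv", ci),
        kernel = paste0(L$kh, "x", L$kw), n_filters = L$out_ch, stride = 1,
        output_shape = paste0(L$in_h, "x", L$in_w, "x", L$out_ch))
    } else if (L$type == 1) {
      pi_ <- pi_ + 1
      oh <- ceiling(L$in_h / 2); ow <- ceiling(L$in_w / 2)
      rows[[n + 1]] <- data.frame(
        layer = n, name = paste0("Max-pooling", pi_), kernel = "2x2",
        n_filters = L$in_ch, stride = 2,
        output_shape = paste0(oh, "x", ow, "x", L$in_ch))
    } else if (L$type == 2) {
      rows[[n + 1]] <- data.frame(
        layer = n, name = "Flatten", kernel = "-", n_filters = NA,
        stride = NA, output_shape = as.character(L$in_ch * L$in_h * L$in_w))
    } else {
      di <- di + 1
      rows[[n + 1]] <- data.frame(
        layer = n, name = paste0("Dense", di), kernel = "-", n_filters = NA,
        stride = NA, output_shape = as.character(L$out_len))
    }
  }
  do.call(rbind, rows)
}

#' Build an (untrained) hotspot CNN and audit its architecture
#'
#' Constructs the layer stack for a given input shape and returns the model
#' skeleton together with a layer report (name, kernel, filters, stride,
#' output shape per layer) for auditing the architecture. Convolutions are
#' stride-1 with shape-preserving padding; pools are 2x2/stride-2 with
#' ceiling (zero-padded) semantics.
#'
#' @param config A `cnn_config`.
#' @param input_shape `c(channels, width)` of one trial.
#' @return An untrained object of class `hotspot_cnn` with a
#'   `layer_report` data.frame.
#' @examples
#' m <- build_model(model_config(), c(63, 200))
#' m$layer_report
#' @export
build_model <- function(config = model_config(), input_shape) {
  stopifnot(inherits(config, "cnn_config"), length(input_shape) == 2)
  structure(list(config = config, input_shape = as.integer(input_shape),
                 layers = layer_spec(config, input_shape),
                 layer_report = layer_report(config, input_shape),
                 weights = NULL, trained = FALSE),
            class = "hotspot_cnn")
}

init_weights <- function(layers) {
  lapply(layers, function(L) {
    if (L$type == 0) {
      fan_in <- L$in_ch * L$kh * L$kw
      list(W = matrix(stats::rnorm(L$out_ch * fan_in, 0, sqrt(2 / fan_in)),
                      L$out_ch, fan_in),
           b = numeric(L$out_ch))
    } else if (L$type == 3) {
      list(W = matrix(stats::rnorm(L$out_len * L$in_len, 0,
                                   sqrt(2 / L$in_len)),
                      L$out_len, L$in_len),
           b = numeric(L$out_len))
    } else NULL
  })
}

#' Per-channel standardization with training-set statistics
#'
#' Computes per-channel mean and SD over the training tensor (across trials
#' and samples) and z-scores the training tensor and any additional tensors
#' with those statistics, so no information leaks from validation or test
#' trials into the scaling. Channels with zero variance get unit scale with
#' a warning.
#'
#' @param train trials x channels x width array (or `model_input`).
#' @param ... Further tensors to scale with the training statistics.
#' @return List with `train`, `applied` (list of scaled `...` tensors), and
#'   `scaler` (`mean`, `sd` per channel).
#' @export
standardize_inputs <- function(train, ...) {
  x <- if (inherits(train, "model_input")) train$tensor else train
  mu <- apply(x, 2, mean)
  sd_ <- apply(x, 2, stats::sd)
  zero <- sd_ < .Machine$double.eps
  if (any(zero)) {
    warning(sum(zero), " zero-variance channel(s); using unit scale")
    sd_[zero] <- 1
  }
  scaler <- list(mean = mu, sd = sd_)
  others <- lapply(list(...), apply_scaler, scaler = scaler)
  list(train = apply_scaler(x, scaler), applied = others, scaler = scaler)
}

apply_scaler <- function(x, scaler) {
  if (inherits(x, "model_input")) x <- x$tensor
  out <- sweep(x, 2, scaler$mean)
  sweep(out, 2, scaler$sd, "/")
}

#' Fit the hotspot CNN
#'
#' Trains the 2D-CNN to regress the 3D hotspot coordinates (mm, Cz origin)
#' from single-trial channel x time (or channel x PSD) images. Inputs are
#' per-channel standardized with training statistics; targets are scaled to
#' head-radius units internally so that ADAM's scale-invariant steps can
#' reach mm-scale coordinates quickly, and all reported losses and
#' predictions are mapped back to mm. Training minimizes MSE with ADAM and
#' stops early once the validation loss has not improved for
#' `config$patience` epochs, restoring the best-epoch weights.
#'
#' @param x Training trials: trials x channels x width array or
#'   `model_input`.
#' @param y Targets in mm: one 3-vector (shared by all trials of a subject)
#'   or a trials x 3 matrix.
#' @param val_x,val_y Validation data; if omitted, a seeded 4:1
#'   train/validation split of `x` is used.
#' @param config A `cnn_config`.
#' @param scale_mm Coordinate unit used internally (head radius, mm).
#' @return A trained object of class `hotspot_cnn` with elements `weights`,
#'   `history` (per-epoch train/validation MSE, mm^2), `best_epoch`,
#'   `stopped_epoch`, `scaler`, `layer_report`, `fitted` (training-trial
#'   predictions, mm).
#' @seealso [predict.hotspot_cnn()], [build_model()]
#' @export
hotspot_cnn <- function(x, y, val_x = NULL, val_y = NULL,
                        config = model_config(), scale_mm = 90) {
  if (inherits(x, "model_input")) x <- x$tensor
  stopifnot(length(dim(x)) == 3)
  n <- dim(x)[1]
  y <- as_target_matrix(y, n)
  if (!is.null(config$seed)) set.seed(config$seed)

  if (is.null(val_x)) {
    n_val <- max(1, floor(n / 5))
    vi <- sample(n, n_val)
    val_x <- x[vi, , , drop = FALSE]
    val_y <- y[vi, , drop = FALSE]
    x <- x[-vi, , , drop = FALSE]
    y <- y[-vi, , drop = FALSE]
    n <- dim(x)[1]
  } else {
    if (inherits(val_x, "model_input")) val_x <- val_x$tensor
    val_y <- as_target_matrix(val_y, dim(val_x)[1])
  }
  if (n < 1 || dim(val_x)[1] < 1) stop("train and validation sets must be non-empty")

  std <- standardize_inputs(x, val_x)
  model <- build_model(config, dim(x)[2:3])
  w0 <- init_weights(model$layers)
  orders <- t(vapply(seq_len(config$max_epochs), function(e) sample(n),
                     integer(n)))
  if (n == 1) orders <- matrix(1L, config$max_epochs, 1)

  fit <- cnn_train_cpp(model$layers, w0, std$train, y / scale_mm,
                       std$applied[[1]], val_y / scale_mm, orders,
                       config$lr, as.integer(config$batch_size),
                       as.integer(config$max_epochs),
                       as.integer(config$patience))

  model$weights <- fit$weights
  model$trained <- TRUE
  model$scaler <- std$scaler
  model$scale_mm <- scale_mm
  model$history <- data.frame(
    epoch = seq_along(fit$train_loss),
    train_mse = fit$train_loss * scale_mm^2,
    val_mse = fit$val_loss * scale_mm^2)
  model$best_epoch <- fit$best_epoch
  model$stopped_epoch <- fit$stopped_epoch
  model$best_val_mse <- fit$best_val_loss * scale_mm^2
  model$y_train <- y
  model$fitted <- predict_tensor(model, x, standardized = FALSE)
  model
}

as_target_matrix <- function(y, n) {
  if (inherits(y, "hotspot_location")) y <- as_coord(y)
  if (is.null(dim(y))) {
    if (length(y) != 3) stop("target must be a 3-vector or n x 3 matrix")
    y <- matrix(y, n, 3, byrow = TRUE)
  }
  y <- as.matrix(y)
  if (ncol(y) != 3 || nrow(y) != n)
    stop("target matrix must be ", n, " x 3 (got ", nrow(y), " x ", ncol(y), ")")
  unname(y)
}

predict_tensor <- function(object, x, standardized = FALSE) {
  if (!standardized) x <- apply_scaler(x, object$scaler)
  p <- cnn_predict_cpp(object$layers, object$weights, x) * object$scale_mm
  colnames(p) <- c("x", "y", "z")
  p
}

#' Predict hotspot coordinates from new trials
#'
#' @param object A trained `hotspot_cnn`.
#' @param newdata trials x channels x width array or `model_input` matching
#'   the model's input shape.
#' @param type `"trials"` for one 3-vector per trial (matrix), `"subject"`
#'   for the trial-averaged subject-level coordinate.
#' @param ... Unused.
#' @return A trials x 3 matrix (mm), or a length-3 vector for
#'   `type = "subject"`.
#' @export
predict.hotspot_cnn <- function(object, newdata, type = c("trials", "subject"),
                                ...) {
  type <- match.arg(type)
  if (!isTRUE(object$trained)) stop("model is not trained")
  if (inherits(newdata, "model_input")) newdata <- newdata$tensor
  if (length(dim(newdata)) == 2)
    newdata <- array(newdata, c(1, dim(newdata)))
  if (!all(dim(newdata)[2:3] == object$input_shape))
    stop("input shape mismatch: expected (", object$input_shape[1], ", ",
         object$input_shape[2], "), got (", dim(newdata)[2], ", ",
         dim(newdata)[3], ")")
  p <- predict_tensor(object, newdata)
  if (type == "subject") colMeans(p) else p
}

#' Subject-level hotspot prediction
#'
#' Averages the per-trial coordinate predictions and returns them as a
#' `hotspot_location`.
#'
#' @inheritParams predict.hotspot_cnn
#' @return A `hotspot_location` with `source = "predicted"`.
#' @export
predict_hotspot <- function(object, newdata) {
  p <- predict(object, newdata, type = "subject")
  hotspot_location(p[1], p[2], p[3], source = "predicted", head_radius = Inf)
}

#' @export
print.hotspot_cnn <- function(x, ...) {
  cfg <- x$config
  cat("<hotspot_cnn> ", if (isTRUE(x$trained)) "trained" else "untrained",
      ", input ", x$input_shape[1], " x ", x$input_shape[2], ", ",
      n_layers(cfg), " layers (",
      sum(vapply(cfg$conv_blocks, `[`, numeric(1), 1)), " conv, ",
      length(cfg$conv_blocks), " pool, ", length(cfg$dense_sizes),
      " dense)\n", sep = "")
  if (isTRUE(x$trained))
    cat(sprintf("  best epoch %d/%d, validation MSE %.3f mm^2\n",
                x$best_epoch, x$stopped_epoch, x$best_val_mse))
  invisible(x)
}

#' @export
summary.hotspot_cnn <- function(object, ...) {
  print(object)
  print(object$layer_report, row.names = FALSE)
  invisible(object$layer_report)
}

#' @export
coef.hotspot_cnn <- function(object, ...) object$weights

#' @export
residuals.hotspot_cnn <- function(object, ...) {
  if (!isTRUE(object$trained)) stop("model is not trained")
  object$y_train - object$fitted
}

#' @export
plot.hotspot_cnn <- function(x, ...) {
  if (!isTRUE(x$trained)) stop("model is not trained")
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_mse, h$val_mse), type = "l",
                    lty = 1, col = c("grey40", "firebrick"),
                    xlab = "epoch", ylab = "MSE (mm^2)", log = "y", ...)
  graphics::abline(v = x$best_epoch, lty = 3)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("grey40", "firebrick"), bty = "n")
  invisible(x)
}
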