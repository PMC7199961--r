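# Vectorized implementation of the 1-D CNN: forward and backward passes are
# expressed as dense matrix products (im2col) so all heavy lifting goes
# through BLAS. Layout conventions:
#   activations  : array (n, L, C) until flatten, then matrix (n, d)
#   conv weights : matrix (kernel_size * in_channels, filters), the row for
#                  tap t, channel c is (t - 1) * C + c; bias length filters
#   dense weights: matrix (in_dim, units); bias length units
# "Same" convolution pads (k-1) zeros, floor((k-1)/2) on the left; pooling
# of size 2 uses ceiling semantics (a trailing odd position forms its own
# window), matching the declared output shapes.

#' Training configuration for the CNN
#'
#' @param learning_rate Adam step size (default 1e-3).
#' @param beta1,beta2,epsilon Adam moment decay rates and stabilizer
#'   (defaults 0.9, 0.999, 1e-8).
#' @param batch_size minibatch size (default 32).
#' @param max_epochs upper bound on epochs (default 100).
#' @param early_stop_patience stop after this many epochs without
#'   validation-loss improvement, restoring the best weights (default 10).
#' @param lr_decay_factor multiply the learning rate by this factor when
#'   the validation loss plateaus (default 0.5; set 1 to disable).
#' @param lr_decay_patience epochs without improvement before decaying the
#'   learning rate (default 4).
#' @param monitor quantity watched for early stopping and best-weight
#'   restoration: `"loss"` (validation cross entropy, the default) or
#'   `"accuracy"` (validation accuracy at threshold 0.5).
#' @param seed integer seed governing weight init, shuffling and dropout.
#' @return a list of class `training_config`.
#' @export
training_config <- function(learning_rate = 1e-3, beta1 = 0.9,
                            beta2 = 0.999, epsilon = 1e-8,
                            batch_size = 32L, max_epochs = 100L,
                            early_stop_patience = 10L,
                            lr_decay_factor = 0.5,
                            lr_decay_patience = 4L,
                            monitor = c("loss", "accuracy"), seed = 1L) {
  monitor <- match.arg(monitor)
  stopifnot(batch_size >= 1L, early_stop_patience >= 1L, max_epochs >= 1L,
            lr_decay_factor > 0, lr_decay_factor <= 1,
            lr_decay_patience >= 1L)
  structure(list(learning_rate = learning_rate, beta1 = beta1,
                 beta2 = beta2, epsilon = epsilon,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 lr_decay_factor = lr_decay_factor,
                 lr_decay_patience = as.integer(lr_decay_patience),
                 monitor = monitor, seed = as.integer(seed)),
            class = "training_config")
}

# Glorot-uniform initial weights for every parameterized layer.
init_weights <- function(arch) {
  ch <- arch$input_channels
  len <- arch$input_length
  ws <- list()
  li <- 0L
  for (ly in arch$layers) {
    li <- li + 1L
    if (ly$kind == "conv") {
      fan_in <- ly$kernel_size * ch
      fan_out <- ly$kernel_size * ly$filters
      lim <- sqrt(6 / (fan_in + fan_out))
      ws[[paste0("L", li)]] <- list(
        W = matrix(stats::runif(fan_in * ly$filters, -lim, lim),
                   fan_in, ly$filters),
        b = numeric(ly$filters))
      ch <- ly$filters
    } else if (ly$kind == "maxpool") {
      len <- as.integer(ceiling(len / ly$pool_size))
    } else if (ly$kind == "flatten") {
      ch <- len * ch
    } else if (ly$kind == "dense") {
      lim <- sqrt(6 / (ch + ly$units))
      ws[[paste0("L", li)]] <- list(
        W = matrix(stats::runif(ch * ly$units, -lim, lim), ch, ly$units),
        b = numeric(ly$units))
      ch <- ly$units
    }
  }
  ws
}

# im2col: (n, L, C) + kernel k -> matrix (n*L, k*C) under "same" padding.
im2col <- function(X, k) {
  d <- dim(X); n <- d[1]; L <- d[2]; C <- d[3]
  left <- (k - 1L) %/% 2L
  Xp <- array(0, dim = c(n, L + k - 1L, C))
  Xp[, (left + 1L):(left + L), ] <- X
  blocks <- vector("list", k)
  for (t in seq_len(k)) {
    blk <- Xp[, t:(t + L - 1L), , drop = FALSE]
    dim(blk) <- c(n * L, C)
    blocks[[t]] <- blk
  }
  do.call(cbind, blocks)
}

# Inverse scatter of im2col for gradients: (n*L, k*C) -> (n, L, C).
col2im <- function(dM, n, L, C, k) {
  left <- (k - 1L) %/% 2L
  dXp <- array(0, dim = c(n, L + k - 1L, C))
  for (t in seq_len(k)) {
    blk <- dM[, ((t - 1L) * C + 1L):(t * C), drop = FALSE]
    dim(blk) <- c(n, L, C)
    dXp[, t:(t + L - 1L), ] <- dXp[, t:(t + L - 1L), , drop = FALSE] + blk
  }
  dXp[, (left + 1L):(left + L), , drop = FALSE]
}

pool_indices <- function(L) {
  i1 <- seq(1L, L, by = 2L)
  list(i1 = i1, i2 = pmin(i1 + 1L, L))
}

# Forward pass. training=TRUE applies inverted dropout (fresh masks from
# the ambient RNG) and returns the caches needed for the backward pass.
cnn_forward <- function(weights, arch, X, training = FALSE) {
  caches <- vector("list", length(arch$layers))
  cur <- X
  li <- 0L
  for (ly in arch$layers) {
    li <- li + 1L
    key <- paste0("L", li)
    if (ly$kind == "conv") {
      d <- dim(cur)
      M <- im2col(cur, ly$kernel_size)
      Z <- M %*% weights[[key]]$W
      Z <- Z + rep(weights[[key]]$b, each = nrow(M))
      mask <- Z > 0
      A <- Z * mask
      dim(A) <- c(d[1], d[2], ly$filters)
      caches[[li]] <- list(M = M, mask = mask, in_dim = d)
      cur <- A
    } else if (ly$kind == "maxpool") {
      d <- dim(cur)
      pidx <- pool_indices(d[2])
      A1 <- cur[, pidx$i1, , drop = FALSE]
      A2 <- cur[, pidx$i2, , drop = FALSE]
      take1 <- A1 >= A2
      caches[[li]] <- list(take1 = take1, in_dim = d, pidx = pidx)
      cur <- ifelse(take1, A1, A2)
      dim(cur) <- c(d[1], length(pidx$i1), d[3])
    } else if (ly$kind == "flatten") {
      d <- dim(cur)
      caches[[li]] <- list(in_dim = d)
      dim(cur) <- c(d[1], d[2] * d[3])
    } else if (ly$kind == "dropout") {
      if (training && ly$dropout_rate > 0) {
        keep <- 1 - ly$dropout_rate
        mask <- (matrix(stats::runif(length(cur)), nrow(cur)) < keep) / keep
        caches[[li]] <- list(mask = mask)
        cur <- cur * mask
      }
    } else if (ly$kind == "dense") {
      Z <- cur %*% weights[[key]]$W
      Z <- Z + rep(weights[[key]]$b, each = nrow(Z))
      if (ly$activation == "relu") {
        mask <- Z > 0
        caches[[li]] <- list(Ain = cur, mask = mask)
        cur <- Z * mask
      } else if (ly$activation == "sigmoid") {
        A <- 1 / (1 + exp(-Z))
        caches[[li]] <- list(Ain = cur, A = A)
        cur <- A
      } else {
        caches[[li]] <- list(Ain = cur)
        cur <- Z
      }
    }
  }
  list(out = as.vector(cur), caches = caches)
}

# Backward pass for sigmoid output + binary cross entropy (mean over the
# batch). Returns gradients with the same shapes as `weights`.
cnn_backward <- function(weights, arch, fwd, y) {
  n <- length(y)
  grads <- list()
  nl <- length(arch$layers)
  last <- arch$layers[[nl]]
  stopifnot(last$kind == "dense", last$activation == "sigmoid")
  p <- fwd$out
  delta <- matrix((p - y) / n, n, 1)  # dL/dZ for sigmoid + BCE
  for (li in nl:1) {
    ly <- arch$layers[[li]]
    key <- paste0("L", li)
    cache <- fwd$caches[[li]]
    if (ly$kind == "dense") {
      if (ly$activation == "relu") delta <- delta * cache$mask
      dW <- crossprod(cache$Ain, delta)
      if (!is.null(ly$l2_coefficient) && ly$l2_coefficient > 0) {
        dW <- dW + 2 * ly$l2_coefficient * weights[[key]]$W
      }
      grads[[key]] <- list(W = dW, b = colSums(delta))
      delta <- delta %*% t(weights[[key]]$W)
    } else if (ly$kind == "dropout") {
      if (!is.null(cache)) delta <- delta * cache$mask
    } else if (ly$kind == "flatten") {
      dim(delta) <- cache$in_dim
    } else if (ly$kind == "maxpool") {
      d <- cache$in_dim
      dX <- array(0, dim = d)
      dY1 <- delta * cache$take1
      dY2 <- delta * !cache$take1
      dX[, cache$pidx$i1, ] <- dY1
      dX[, cache$pidx$i2, ] <- dX[, cache$pidx$i2, , drop = FALSE] + dY2
      delta <- dX
    } else if (ly$kind == "conv") {
      d <- cache$in_dim
      dim(delta) <- c(d[1] * d[2], ly$filters)
      delta <- delta * cache$mask  # relu
      grads[[key]] <- list(W = crossprod(cache$M, delta),
                           b = colSums(delta))
      dM <- delta %*% t(weights[[key]]$W)
      delta <- col2im(dM, d[1], d[2], d[3], ly$kernel_size)
    }
  }
  grads
}

bce_loss <- function(p, y) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

l2_penalty <- function(weights, arch) {
  pen <- 0
  li <- 0L
  for (ly in arch$layers) {
    li <- li + 1L
    if (ly$kind == "dense" && !is.null(ly$l2_coefficient) &&
        ly$l2_coefficient > 0) {
      pen <- pen + ly$l2_coefficient *
        sum(weights[[paste0("L", li)]]$W^2)
    }
  }
  pen
}

#' Train the CNN on an encoded chimera batch
#'
#' Minimizes binary cross entropy with the Adam optimizer; training stops
#' when the validation loss has not improved for
#' `config$early_stop_patience` consecutive epochs (or at
#' `config$max_epochs`), and the weights from the best validation epoch are
#' restored. Fully reproducible under `config$seed` on a fixed platform.
#'
#' @param arch a [build_architecture()] spec.
#' @param train_set,validation_set encoded batches from [encode_batch()]
#'   (lists with `data`: n x 110 x 4 array, `labels`: 0/1 vector).
#' @param config a [training_config()].
#' @param verbose print per-epoch losses? Default `FALSE`.
#' @return a list of class `mircnn_model`: `arch`, `weights`,
#'   `training_log` (`data.frame` of epoch, train_loss, val_loss),
#'   `config`, `best_epoch`.
#' @export
train_cnn <- function(arch, train_set, validation_set,
                      config = training_config(), verbose = FALSE) {
  stopifnot(inherits(arch, "cnn_arch"), inherits(config, "training_config"))
  n <- dim(train_set$data)[1]
  if (n < 1L || dim(validation_set$data)[1] < 1L) {
    stop("training and validation sets must be non-empty", call. = FALSE)
  }
  stopifnot(all(train_set$labels %in% 0:1),
            all(validation_set$labels %in% 0:1))
  with_seed_(config$seed, {
    weights <- init_weights(arch)
    mstate <- rapply(weights, function(x) x * 0, how = "replace")
    vstate <- mstate
    tstep <- 0
    lr <- config$learning_rate
    best_val <- Inf; best_weights <- weights; best_epoch <- 0L
    stale <- 0L; lr_stale <- 0L
    log_rows <- list()
    for (epoch in seq_len(config$max_epochs)) {
      perm <- sample.int(n)
      epoch_loss <- 0; nb <- 0L
      for (start in seq(1L, n, by = config$batch_size)) {
        idx <- perm[start:min(start + config$batch_size - 1L, n)]
        Xb <- train_set$data[idx, , , drop = FALSE]
        yb <- train_set$labels[idx]
        fwd <- cnn_forward(weights, arch, Xb, training = TRUE)
        if (!all(is.finite(fwd$out))) {
          stop("non-finite network output during training (epoch ",
               epoch, ")", call. = FALSE)
        }
        loss <- bce_loss(fwd$out, yb) + l2_penalty(weights, arch)
        if (!is.finite(loss)) {
          stop("non-finite training loss at epoch ", epoch, call. = FALSE)
        }
        grads <- cnn_backward(weights, arch, fwd, yb)
        tstep <- tstep + 1
        bc1 <- 1 - config$beta1^tstep
        bc2 <- 1 - config$beta2^tstep
        for (key in names(grads)) {
          for (part in c("W", "b")) {
            g <- grads[[key]][[part]]
            mstate[[key]][[part]] <- config$beta1 * mstate[[key]][[part]] +
              (1 - config$beta1) * g
            vstate[[key]][[part]] <- config$beta2 * vstate[[key]][[part]] +
              (1 - config$beta2) * g^2
            weights[[key]][[part]] <- weights[[key]][[part]] -
              lr * (mstate[[key]][[part]] / bc1) /
              (sqrt(vstate[[key]][[part]] / bc2) + config$epsilon)
          }
        }
        epoch_loss <- epoch_loss + loss; nb <- nb + 1L
      }
      val_p <- predict_array(weights, arch, validation_set$data)
      val_loss <- bce_loss(val_p, validation_set$labels)
      val_acc <- mean((val_p > 0.5) == (validation_set$labels == 1L))
      log_rows[[epoch]] <- data.frame(epoch = epoch,
                                      train_loss = epoch_loss / nb,
                                      val_loss = val_loss,
                                      val_accuracy = val_acc, lr = lr)
      if (verbose) {
        message(sprintf("epoch %3d  train %.4f  val %.4f  vacc %.3f  lr %.2g",
                        epoch, epoch_loss / nb, val_loss, val_acc, lr))
      }
      monitored <- if (config$monitor == "accuracy") -val_acc else val_loss
      if (monitored < best_val - 1e-12) {
        best_val <- monitored; best_weights <- weights
        best_epoch <- epoch; stale <- 0L; lr_stale <- 0L
      } else {
        stale <- stale + 1L
        lr_stale <- lr_stale + 1L
        if (stale >= config$early_stop_patience) break
        if (config$lr_decay_factor < 1 &&
            lr_stale >= config$lr_decay_patience) {
          lr <- lr * config$lr_decay_factor
          lr_stale <- 0L
        }
      }
    }
    structure(list(arch = arch, weights = best_weights,
                   training_log = do.call(rbind, log_rows),
                   config = config, best_epoch = best_epoch),
              class = "mircnn_model")
  })
}

# Chunked inference on a raw (n, 110, 4) array.
predict_array <- function(weights, arch, X, chunk = 1024L) {
  n <- dim(X)[1]
  out <- numeric(n)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    out[idx] <- cnn_forward(weights, arch,
                            X[idx, , , drop = FALSE],
                            training = FALSE)$out
  }
  out
}

#' Predict interaction probabilities for encoded chimeras
#'
#' @param object a trained `mircnn_model`.
#' @param batch an [encode_batch()] list, or a bare n x 110 x 4 array.
#' @param ... unused.
#' @return a numeric vector of probabilities in (0, 1), one per input row,
#'   in input order.
#' @export
predict.mircnn_model <- function(object, batch, ...) {
  X <- if (is.list(batch)) batch$data else batch
  if (length(dim(X)) != 3L || dim(X)[2] != object$arch$input_length ||
      dim(X)[3] != object$arch$input_channels) {
    stop(sprintf("batch must be n x %d x %d", object$arch$input_length,
                 object$arch$input_channels), call. = FALSE)
  }
  predict_array(object$weights, object$arch, X)
}

#' Total number of weights actually held by a trained model
#'
#' @param model a `mircnn_model`.
#' @return integer count; equals `count_parameters(model$arch)$total`.
#' @export
n_weights <- function(model) {
  sum(vapply(model$weights,
             function(w) length(w$W) + length(w$b), numeric(1)))
}

#' @export
print.mircnn_model <- function(x, ...) {
  cat(sprintf("mircnn model: %s trainable weights, best epoch %d\n",
              format(n_weights(x), big.mark = ","), x$best_epoch))
  if (!is.null(x$training_log)) {
    last <- x$training_log[nrow(x$training_log), ]
    cat(sprintf("  final train loss %.4f, val loss %.4f (%d epochs run)\n",
                last$train_loss, last$val_loss, nrow(x$training_log)))
  }
  invisible(x)
}

#' Save a trained model to a directory artifact
#'
#' Writes `manifest.json` (architecture and training configuration),
#' `weights.rds` (exact numeric weights) and `training_log.tsv`.
#'
#' @param model a `mircnn_model`.
#' @param path directory to create/overwrite.
#' @return `path`, invisibly.
#' @seealso [load_model()]
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "mircnn_model"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    format = "mircnn-model-1",
    arch = list(input_length = model$arch$input_length,
                input_channels = model$arch$input_channels,
                layers = model$arch$layers),
    config = unclass(model$config),
    best_epoch = model$best_epoch)
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  saveRDS(model$weights, file.path(path, "weights.rds"))
  if (!is.null(model$training_log)) {
    utils::write.table(model$training_log,
                       file.path(path, "training_log.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Load a model artifact written by [save_model()]
#'
#' @param path artifact directory.
#' @return a `mircnn_model`; predictions are bitwise identical to the
#'   saved model's.
#' @export
load_model <- function(path) {
  mf <- file.path(path, "manifest.json")
  wf <- file.path(path, "weights.rds")
  if (!file.exists(mf) || !file.exists(wf)) {
    stop("not a model artifact (missing manifest.json or weights.rds): ",
         path, call. = FALSE)
  }
  manifest <- tryCatch(jsonlite::read_json(mf),
                       error = function(e) stop("corrupt model manifest: ",
                                                conditionMessage(e),
                                                call. = FALSE))
  if (!identical(manifest$format, "mircnn-model-1")) {
    stop("unrecognized model artifact format", call. = FALSE)
  }
  weights <- tryCatch(readRDS(wf),
                      error = function(e) stop("corrupt model weights: ",
                                               conditionMessage(e),
                                               call. = FALSE))
  layers <- lapply(manifest$arch$layers, function(ly) {
    ly <- lapply(ly, function(v) if (is.numeric(v) &&
                                     v == round(v)) as.integer(v) else v)
    ly
  })
  arch <- structure(list(
    input_length = as.integer(manifest$arch$input_length),
    input_channels = as.integer(manifest$arch$input_channels),
    layers = layers), class = "cnn_arch")
  cfg <- manifest$config
  config <- training_config(
    learning_rate = cfg$learning_rate, beta1 = cfg$beta1,
    beta2 = cfg$beta2, epsilon = cfg$epsilon,
    batch_size = cfg$batch_size, max_epochs = cfg$max_epochs,
    early_stop_patience = cfg$early_stop_patience,
    lr_decay_factor = cfg$lr_decay_factor,
    lr_decay_patience = cfg$lr_decay_patience,
    monitor = if (is.null(cfg$monitor)) "loss" else cfg$monitor,
    seed = cfg$seed)
  log_path <- file.path(path, "training_log.tsv")
  tlog <- if (file.exists(log_path)) utils::read.delim(log_path) else NULL
  structure(list(arch = arch, weights = weights, training_log = tlog,
                 config = config,
                 best_epoch = as.integer(manifest$best_epoch)),
            class = "mircnn_model")
}
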