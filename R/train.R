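## Training: pixel-wise binary cross-entropy minimized with Adam.
##
## The objective is the binary cross-entropy between the border target
## t and the predicted probability y, summed over pixels; the
## implementation reports and optimizes the per-pixel mean so the
## default learning rate is independent of the image and batch size
## (the sum is recoverable as mean * N).  Probabilities are clipped to
## [eps, 1 - eps] before the logarithms.

#' Training configuration
#'
#' @param n_train_mosaics number of training mosaics to generate or use.
#' @param image_size mosaic height/width (divisible by 8).
#' @param batch_size minibatch size.
#' @param epochs number of passes over the training set.
#' @param learning_rate,beta1,beta2,adam_eps Adam hyper-parameters
#'   (defaults 0.001, 0.9, 0.999, 1e-7 -- the optimizer's standard
#'   defaults).
#' @param master_seed seed controlling shuffling and initialization.
#' @param checkpoint_dir directory for per-epoch checkpoints; `NULL`
#'   disables checkpointing.
#' @return An object of class `train_config`.
#' @export
train_config <- function(n_train_mosaics = 100L,
                         image_size = 256L,
                         batch_size = 8L,
                         epochs = 5L,
                         learning_rate = 0.001,
                         beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-7,
                         master_seed = 0L,
                         checkpoint_dir = NULL) {
  if (n_train_mosaics < 1L || batch_size < 1L || epochs < 0L)
    stop_config("counts in the training configuration must be positive")
  if (image_size %% 8L != 0L)
    stop_config("image_size must be divisible by 8")
  structure(list(n_train_mosaics = as.integer(n_train_mosaics),
                 image_size = as.integer(image_size),
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 beta1 = beta1, beta2 = beta2, adam_eps = adam_eps,
                 master_seed = as.integer(master_seed),
                 checkpoint_dir = checkpoint_dir),
            class = "train_config")
}

#' Binary cross-entropy loss
#'
#' Mean over pixels of `-(t * log(y) + (1 - t) * log(1 - y))`, with `y`
#' clipped to `[1e-7, 1 - 1e-7]`.  Zero exactly when the classification
#' is perfect (up to the clip).
#'
#' @param targets numeric array/matrix of targets in `{0, 1}`.
#' @param probs numeric array/matrix of probabilities, same shape.
#' @param eps clipping constant.
#' @return A list with `J` (the mean loss) and `N` (number of pixels).
#' @export
bce_loss <- function(targets, probs, eps = 1e-7) {
  dt <- dim(targets) %||% length(targets)
  dy <- dim(probs) %||% length(probs)
  if (!identical(as.integer(dt), as.integer(dy)))
    stop_input("targets and probabilities must have the same shape")
  t <- as.numeric(targets); y <- as.numeric(probs)
  y <- pmin(pmax(y, eps), 1 - eps)
  J <- -mean(t * log(y) + (1 - t) * log(1 - y))
  list(J = J, N = length(t))
}

# Adam state mirroring the parameter structure.
adam_init <- function(params) {
  rapply(params, function(p) p * 0, how = "replace")
}

adam_step <- function(params, grads, state, t, cfg) {
  for (layer in names(grads)) {
    for (slot in names(grads[[layer]])) {
      gslot <- grads[[layer]][[slot]]
      m <- state$m[[layer]][[slot]] <-
        cfg$beta1 * state$m[[layer]][[slot]] + (1 - cfg$beta1) * gslot
      v <- state$v[[layer]][[slot]] <-
        cfg$beta2 * state$v[[layer]][[slot]] + (1 - cfg$beta2) * gslot^2
      mhat <- m / (1 - cfg$beta1^t)
      vhat <- v / (1 - cfg$beta2^t)
      params[[layer]][[slot]] <- params[[layer]][[slot]] -
        cfg$learning_rate * mhat / (sqrt(vhat) + cfg$adam_eps)
    }
  }
  list(params = params, state = state)
}

# Load every image/mask pair of a manifest into memory.
load_manifest_samples <- function(manifest) {
  n <- nrow(manifest$entries)
  samples <- vector("list", n)
  for (i in seq_len(n)) {
    img <- read_image_rgb(manifest$entries$image[i])
    msk <- read_image_gray(manifest$entries$mask[i])
    vals <- unique(round(as.vector(msk), 6))
    if (!all(vals %in% c(0, 1)))
      msk <- (msk > 0.5) * 1
    samples[[i]] <- list(image = img, mask = msk)
  }
  samples
}

#' Train the boundary network
#'
#' Minimizes the mean binary cross-entropy over the manifest's mosaics
#' with Adam.  Shuffling, batching and (when requested) per-epoch
#' checkpointing are fully determined by `cfg$master_seed`.
#'
#' @param model a `texbound_model` (freshly built or resumed).
#' @param manifest a `dataset_manifest` from [build_dataset()], or a
#'   list of in-memory samples (each `list(image, mask)`).
#' @param cfg a [train_config].
#' @param verbose print per-epoch losses.
#' @return A list with the trained `model` and `history`, a data frame
#'   of per-epoch mean training loss.
#' @export
train <- function(model, manifest, cfg = train_config(),
                  verbose = FALSE) {
  samples <- if (inherits(manifest, "dataset_manifest")) {
    if (nrow(manifest$entries) == 0L)
      stop_input("training manifest is empty")
    load_manifest_samples(manifest)
  } else {
    if (length(manifest) == 0L) stop_input("training set is empty")
    manifest
  }
  for (s in samples) {
    if (!all(unique(as.vector(s$mask)) %in% c(0, 1)))
      stop_input("training masks must be binary {0, 1}")
  }
  n <- length(samples)
  if (cfg$epochs == 0L)
    return(list(model = model,
                history = data.frame(epoch = integer(0),
                                     loss = numeric(0))))
  H <- dim(samples[[1]]$image)[1]; W <- dim(samples[[1]]$image)[2]
  state <- list(m = adam_init(model$params), v = adam_init(model$params))
  step_t <- 0L
  losses <- numeric(cfg$epochs)
  if (!is.null(cfg$checkpoint_dir))
    dir.create(cfg$checkpoint_dir, recursive = TRUE, showWarnings = FALSE)

  with_seed(cfg$master_seed, {
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      batch_losses <- c()
      for (b0 in seq(1L, n, by = cfg$batch_size)) {
        idx <- ord[b0:min(b0 + cfg$batch_size - 1L, n)]
        nb <- length(idx)
        x <- array(0, dim = c(H, W, 3L, nb))
        t_ <- array(0, dim = c(H, W, 1L, nb))
        for (j in seq_len(nb)) {
          x[, , , j] <- samples[[idx[j]]]$image
          t_[, , 1L, j] <- samples[[idx[j]]]$mask
        }
        fwd <- network_forward(model, x, training = TRUE,
                               keep_acts = TRUE)
        loss <- bce_loss(t_, fwd$probs)
        batch_losses <- c(batch_losses, loss$J)
        # d(mean BCE)/d(logits) = (y - t) / N
        dlogits <- (fwd$probs - t_) / length(t_)
        grads <- network_backward(model, fwd, dlogits)
        step_t <- step_t + 1L
        upd <- adam_step(model$params, grads, state, step_t, cfg)
        model$params <- upd$params
        state <- upd$state
        for (key in names(fwd$bn_updates)) {
          model$params[[key]]$rmean <- fwd$bn_updates[[key]]$rmean
          model$params[[key]]$rvar <- fwd$bn_updates[[key]]$rvar
        }
      }
      losses[epoch] <- mean(batch_losses)
      if (verbose)
        message(sprintf("epoch %d/%d: loss %.5f", epoch, cfg$epochs,
                        losses[epoch]))
      if (!is.null(cfg$checkpoint_dir))
        save_model(model, file.path(cfg$checkpoint_dir,
                                    sprintf("epoch_%03d.rds", epoch)))
    }
  })
  list(model = model,
       history = data.frame(epoch = seq_len(cfg$epochs), loss = losses))
}
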