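## Encoder-decoder boundary network.
##
## A small fully convolutional network: three compression blocks (three
## 3x3 convolutions, batch norm + ReLU, 2x max pooling) with 32/64/128
## filters, a 128-filter block at the bottom, then three expansion
## blocks (three convolutions, batch norm + ReLU, bilinear 2x
## upsampling) with 128/64/32 filters whose outputs are merged with the
## same-resolution encoder features by element-wise sum, a final
## 32-filter processing block, and a single-filter 3x3 convolution with
## a sigmoid that emits the per-pixel border probability.  The default
## model has 1,138,081 parameters (convolution weights and biases plus
## four batch-normalization parameters per channel).

conv_row <- function(no, filters) list(no = no, type = "conv",
                                       filters = filters)
bn_row   <- function(no) list(no = no, type = "bn_relu")
pool_row <- function(no) list(no = no, type = "pool")
up_row   <- function(no) list(no = no, type = "up")
sum_row  <- function(no, with) list(no = no, type = "sum",
                                    sum_with = with)

#' The 38-row layer table of the boundary network
#'
#' @return A list of 38 layer descriptors in execution order; sum rows
#'   carry the row number whose output they merge with.
#' @export
network_architecture <- function() {
  c(lapply(1:3, function(i) conv_row(i, 32L)),
    list(bn_row(4L), pool_row(5L)),
    lapply(6:8, function(i) conv_row(i, 64L)),
    list(bn_row(9L), pool_row(10L)),
    lapply(11:13, function(i) conv_row(i, 128L)),
    list(bn_row(14L), pool_row(15L)),
    lapply(16:18, function(i) conv_row(i, 128L)),
    list(bn_row(19L), up_row(20L), sum_row(21L, 14L)),
    lapply(22:24, function(i) conv_row(i, 64L)),
    list(bn_row(25L), up_row(26L), sum_row(27L, 9L)),
    lapply(28:30, function(i) conv_row(i, 32L)),
    list(bn_row(31L), up_row(32L), sum_row(33L, 4L)),
    lapply(34:36, function(i) conv_row(i, 32L)),
    list(bn_row(37L), conv_row(38L, 1L)))
}

# Annotate each row with its input/output channel count for a given
# number of input channels, checking that sum junctions pair layers
# with equal channel counts.
arch_channels <- function(arch, in_channels = 3L) {
  ch <- in_channels
  ch_out_of <- integer(length(arch) + 1L)  # index no + 1; [1] = input
  ch_out_of[1] <- in_channels
  for (i in seq_along(arch)) {
    row <- arch[[i]]
    cin <- ch
    if (row$type == "conv") ch <- row$filters
    if (row$type == "sum") {
      other <- ch_out_of[row$sum_with + 1L]
      if (other != ch)
        stop_config("sum junction at row %d pairs unequal channel counts (%d vs %d)",
                    row$no, ch, other)
    }
    arch[[i]]$cin <- cin
    arch[[i]]$cout <- ch
    ch_out_of[row$no + 1L] <- ch
  }
  arch
}

#' Build the boundary-detection model
#'
#' Constructs the 38-row architecture for RGB input and initializes its
#' weights (variance-scaling normal for convolutions, ones/zeros for
#' batch-norm scale/offset, zeros/ones for the moving mean/variance).
#' The network is fully convolutional: a model built at one size runs
#' unchanged on any input whose height and width are divisible by 8.
#'
#' @param input_size default `(H, W)` the model is intended for; both
#'   must be divisible by 8 (three 2x poolings).
#' @param in_channels number of input channels (3 for RGB).
#' @param seed optional seed for weight initialization.
#' @return An object of class `texbound_model`.
#' @export
build_model <- function(input_size = c(256L, 256L), in_channels = 3L,
                        seed = NULL) {
  input_size <- as.integer(input_size)
  if (any(input_size %% 8L != 0L))
    stop_config(paste("input size %d x %d is not divisible by 8;",
                      "pad or crop the input (or use auto_pad at",
                      "prediction time)"),
                input_size[1], input_size[2])
  arch <- arch_channels(network_architecture(), in_channels)
  init <- function() {
    params <- list()
    for (row in arch) {
      key <- sprintf("L%02d", row$no)
      if (row$type == "conv") {
        sd <- sqrt(2 / (9 * row$cin))
        params[[key]] <- list(
          w = array(rnorm(row$cin * row$cout * 9L, 0, sd),
                    dim = c(row$cin, row$cout, 9L)),
          b = numeric(row$cout))
      } else if (row$type == "bn_relu") {
        C <- row$cout
        params[[key]] <- list(gamma = rep(1, C), beta = numeric(C),
                              rmean = numeric(C), rvar = rep(1, C))
      }
    }
    params
  }
  params <- if (is.null(seed)) init() else with_seed(seed, init())
  structure(list(arch = arch, params = params,
                 in_channels = as.integer(in_channels),
                 input_size = input_size,
                 bn_eps = 1e-3, bn_momentum = 0.99),
            class = "texbound_model")
}

#' Count model parameters
#'
#' Convolution weights and biases plus four batch-normalization
#' parameters per channel (scale, offset, moving mean, moving
#' variance).  The default RGB model totals 1,138,081.
#'
#' @param model a `texbound_model`.
#' @return Integer parameter count.
#' @export
count_parameters <- function(model) {
  total <- 0L
  for (row in model$arch) {
    if (row$type == "conv")
      total <- total + 9L * row$cin * row$cout + row$cout
    else if (row$type == "bn_relu")
      total <- total + 4L * row$cout
  }
  total
}

#' @export
print.texbound_model <- function(x, ...) {
  cat(sprintf("<texbound_model: %d layers, %s parameters, input %dch>\n",
              length(x$arch),
              format(count_parameters(x), big.mark = ","),
              x$in_channels))
  invisible(x)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# Forward pass over a batch `x` of dim (H, W, C, N).  Returns the
# sigmoid output plus, when `keep_acts`, everything the backward pass
# needs.  In training mode batch statistics are used and the updated
# moving statistics are reported in `bn_updates`.
network_forward <- function(model, x, training = FALSE,
                            keep_acts = FALSE) {
  acts <- vector("list", length(model$arch) + 1L)
  caches <- vector("list", length(model$arch))
  bn_updates <- list()
  acts[[1]] <- x
  for (i in seq_along(model$arch)) {
    row <- model$arch[[i]]
    key <- sprintf("L%02d", row$no)
    prev <- acts[[row$no]]
    out <- switch(row$type,
      conv = .conv3x3_fwd(prev, model$params[[key]]$w,
                          model$params[[key]]$b),
      bn_relu = {
        p <- model$params[[key]]
        res <- .bn_relu_fwd(prev, p$gamma, p$beta, p$rmean, p$rvar,
                            model$bn_momentum, model$bn_eps, training)
        caches[[i]] <- list(mean = res$mean, invstd = res$invstd)
        if (training)
          bn_updates[[key]] <- list(rmean = res$rmean, rvar = res$rvar)
        res$y
      },
      pool = {
        res <- .maxpool2_fwd(prev)
        caches[[i]] <- list(idx = res$idx, H = dim(prev)[1],
                            W = dim(prev)[2])
        res$y
      },
      up = .upsample2_fwd(prev),
      sum = prev + acts[[row$sum_with + 1L]])
    acts[[row$no + 1L]] <- out
  }
  logits <- acts[[length(model$arch) + 1L]]
  probs <- sigmoid(logits)
  if (keep_acts)
    list(probs = probs, logits = logits, acts = acts, caches = caches,
         bn_updates = bn_updates)
  else
    list(probs = probs, logits = logits, bn_updates = bn_updates)
}

# Backward pass from the gradient w.r.t. the logits.  Returns per-layer
# parameter gradients (same shapes as `model$params`).
network_backward <- function(model, fwd, dlogits) {
  n_rows <- length(model$arch)
  g <- vector("list", n_rows + 1L)
  g[[n_rows + 1L]] <- dlogits
  grads <- list()
  accum <- function(slot, val) {
    if (is.null(g[[slot]])) g[[slot]] <<- val
    else g[[slot]] <<- g[[slot]] + val
  }
  for (i in rev(seq_len(n_rows))) {
    row <- model$arch[[i]]
    key <- sprintf("L%02d", row$no)
    gout <- g[[row$no + 1L]]
    switch(row$type,
      conv = {
        res <- .conv3x3_bwd(fwd$acts[[row$no]], model$params[[key]]$w,
                            gout)
        grads[[key]] <- list(w = res$dw, b = res$db)
        accum(row$no, res$dx)
      },
      bn_relu = {
        cc <- fwd$caches[[i]]
        res <- .bn_relu_bwd(fwd$acts[[row$no]], fwd$acts[[row$no + 1L]],
                            gout, model$params[[key]]$gamma,
                            cc$mean, cc$invstd)
        grads[[key]] <- list(gamma = res$dgamma, beta = res$dbeta)
        accum(row$no, res$dx)
      },
      pool = {
        cc <- fwd$caches[[i]]
        accum(row$no, .maxpool2_bwd(cc$idx, gout, cc$H, cc$W))
      },
      up = accum(row$no, .upsample2_bwd(gout)),
      sum = {
        accum(row$no, gout)
        accum(row$sum_with + 1L, gout)
      })
  }
  grads
}

check_predict_input <- function(image) {
  d <- dim(image)
  if (is.null(d) || length(d) != 3L || d[3] != 3L)
    stop_input("expected an H x W x 3 image array")
  if (min(image) < 0 || max(image) > 1)
    stop_input("image values must lie in [0, 1]")
  d
}

#' Predict the border probability map of an image
#'
#' Runs the network in inference mode (batch normalization uses its
#' moving statistics), returning one border probability per pixel.
#'
#' @param object a `texbound_model`.
#' @param image numeric array `(H, W, 3)` with values in `[0, 1]`; `H`
#'   and `W` must be divisible by 8 unless `auto_pad` is set.
#' @param auto_pad if `TRUE`, mirror-pad the image to the next multiple
#'   of 8 and crop the output back to the input size.
#' @param ... unused.
#' @return Numeric matrix `(H, W)` of probabilities in `(0, 1)`.
#' @export
predict.texbound_model <- function(object, image, auto_pad = FALSE, ...) {
  d <- check_predict_input(image)
  H <- d[1]; W <- d[2]
  pad <- c((8L - H %% 8L) %% 8L, (8L - W %% 8L) %% 8L)
  if (any(pad > 0L)) {
    if (!auto_pad)
      stop_config(paste("image size %d x %d is not divisible by 8;",
                        "pad or crop it, or set auto_pad = TRUE"), H, W)
    idx_y <- c(seq_len(H), H - seq_len(pad[1]))
    idx_x <- c(seq_len(W), W - seq_len(pad[2]))
    if (pad[1] == 0L) idx_y <- seq_len(H)
    if (pad[2] == 0L) idx_x <- seq_len(W)
    image <- image[idx_y, idx_x, , drop = FALSE]
  }
  x <- array(image, dim = c(dim(image)[1:2], 3L, 1L))
  probs <- network_forward(object, x, training = FALSE)$probs
  # keep the sigmoid output in the open interval even when the logits
  # saturate double precision
  probs <- pmin(pmax(probs, 1e-12), 1 - 1e-12)
  matrix(probs, dim(image)[1], dim(image)[2])[seq_len(H), seq_len(W)]
}

#' Save / load a model checkpoint
#'
#' Checkpoints are plain RDS serializations of the model object.
#'
#' @param model a `texbound_model`.
#' @param path file path.
#' @return `save_model` returns `path` invisibly; `load_model` returns
#'   the model.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "texbound_model"))
    stop_input("'%s' is not a texbound model checkpoint", path)
  model
}

#' Write an architecture summary as JSON
#'
#' One record per layer row (number, type, filters, parameter count),
#' for auditing a built model against the layer table.
#'
#' @param model a `texbound_model`.
#' @param path output JSON file.
#' @return The summary data frame, invisibly.
#' @export
model_summary_json <- function(model, path) {
  rows <- lapply(model$arch, function(row) {
    n_par <- switch(row$type,
                    conv = 9L * row$cin * row$cout + row$cout,
                    bn_relu = 4L * row$cout, 0L)
    list(number = row$no,
         layer = switch(row$type, conv = "Convolution 3x3",
                        bn_relu = "Batch Normalization + ReLU Activation",
                        pool = "MaxPooling", up = "Bilinear Upsampling",
                        sum = sprintf("Sum (outputs from layers %d and %d)",
                                      row$no - 1L, row$sum_with)),
         filters = if (row$type == "conv") row$filters else NA,
         parameters = n_par)
  })
  jsonlite::write_json(rows, path, auto_unbox = TRUE, pretty = TRUE,
                       na = "null")
  invisible(do.call(rbind, lapply(rows, as.data.frame)))
}
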