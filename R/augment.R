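## Per-texture augmentation chain.
##
## Every texture placed in a mosaic region is independently transformed
## before assembly: a random affine (rotation, translation, shear,
## scale), additive uniform noise, and one randomly chosen photometric
## operation.  All random parameters are drawn from uniform
## distributions over fixed interval limits.

.photometric_menu <- c("adaptive_equalization", "histogram_equalization",
                       "log_adjust", "sigmoid_adjust", "gamma",
                       "gaussian_blur", "invert")

#' Augmentation configuration
#'
#' Interval limits for the uniform parameter draws of the augmentation
#' chain.  Defaults: rotation 0-360 degrees, translation -12..12 pixels,
#' scale 0.5x-1.5x, shear -30..30 degrees, uniform-noise amplitude
#' 0-0.02, Gaussian-blur sigma 0-5, gamma 0.5-1.5.  The photometric
#' menu holds seven operations, one of which is drawn uniformly per
#' texture; equalization, log and sigmoid adjustments use fixed
#' conventional parameters (adaptive equalization with 8 x 8 tiles,
#' log gain 1, sigmoid cutoff 0.5 / gain 10), recorded here so runs are
#' fully specified.
#'
#' @param enabled logical; a disabled config makes the chain an
#'   identity (textures are only center-cropped).
#' @param rotation_deg,translation_px,scale,shear_deg,noise_amplitude,gaussian_sigma,gamma
#'   length-2 numeric intervals (lower, upper).
#' @param photometric_menu character vector of operations to draw from.
#' @return An object of class `augment_config`.
#' @export
augment_config <- function(enabled = TRUE,
                           rotation_deg = c(0, 360),
                           translation_px = c(-12, 12),
                           scale = c(0.5, 1.5),
                           shear_deg = c(-30, 30),
                           noise_amplitude = c(0, 0.02),
                           gaussian_sigma = c(0, 5),
                           gamma = c(0.5, 1.5),
                           photometric_menu = .photometric_menu) {
  cfg <- list(enabled = isTRUE(enabled),
              rotation_deg = as.numeric(rotation_deg),
              translation_px = as.numeric(translation_px),
              scale = as.numeric(scale),
              shear_deg = as.numeric(shear_deg),
              noise_amplitude = as.numeric(noise_amplitude),
              gaussian_sigma = as.numeric(gaussian_sigma),
              gamma = as.numeric(gamma),
              photometric_menu = photometric_menu,
              adaptive_eq_tiles = c(8L, 8L),
              log_gain = 1, sigmoid_cutoff = 0.5, sigmoid_gain = 10)
  for (f in c("rotation_deg", "translation_px", "scale", "shear_deg",
              "noise_amplitude", "gaussian_sigma", "gamma")) {
    iv <- cfg[[f]]
    if (length(iv) != 2L || iv[2] < iv[1])
      stop_config("augment interval '%s' must be (lower, upper)", f)
    if (cfg$enabled && iv[2] == iv[1] &&
        !f %in% c("noise_amplitude", "gaussian_sigma"))
      stop_config("augment interval '%s' is degenerate", f)
  }
  structure(cfg, class = "augment_config")
}

#' Draw one full set of augmentation parameters
#'
#' Samples every random parameter of the augmentation chain uniformly
#' from its configured interval (and the photometric operation
#' uniformly from the menu), consuming the session RNG.  Used
#' internally by the chain; exposed so the sampling distribution can be
#' audited directly.
#'
#' @param cfg an [augment_config].
#' @return Named list with `rotation`, `translation` (length 2),
#'   `scale`, `shear`, `noise_amplitude`, `op`, `gamma`, `sigma`.
#' @export
sample_augment_params <- function(cfg) {
  list(rotation = runif(1, cfg$rotation_deg[1], cfg$rotation_deg[2]),
       translation = runif(2, cfg$translation_px[1],
                           cfg$translation_px[2]),
       scale = runif(1, cfg$scale[1], cfg$scale[2]),
       shear = runif(1, cfg$shear_deg[1], cfg$shear_deg[2]),
       noise_amplitude = runif(1, cfg$noise_amplitude[1],
                               cfg$noise_amplitude[2]),
       op = cfg$photometric_menu[
         sample.int(length(cfg$photometric_menu), 1L)],
       gamma = runif(1, cfg$gamma[1], cfg$gamma[2]),
       sigma = runif(1, cfg$gaussian_sigma[1], cfg$gaussian_sigma[2]))
}

# Bilinear sampling of `pixels` at fractional (row, col) coordinates
# with mirror-reflect handling of out-of-support positions.
bilinear_sample <- function(pixels, ry, rx) {
  H <- dim(pixels)[1]; W <- dim(pixels)[2]
  reflect <- function(v, n) {
    if (n == 1L) return(rep(0, length(v)))
    p <- 2 * (n - 1)
    v <- v %% p
    ifelse(v > (n - 1), p - v, v)
  }
  y0 <- floor(ry); x0 <- floor(rx)
  fy <- ry - y0;   fx <- rx - x0
  iy0 <- reflect(y0, H) + 1; iy1 <- reflect(y0 + 1, H) + 1
  ix0 <- reflect(x0, W) + 1; ix1 <- reflect(x0 + 1, W) + 1
  sample_ch <- function(m) {
    m[cbind(iy0, ix0)] * (1 - fy) * (1 - fx) +
      m[cbind(iy1, ix0)] * fy * (1 - fx) +
      m[cbind(iy0, ix1)] * (1 - fy) * fx +
      m[cbind(iy1, ix1)] * fy * fx
  }
  sample_ch
}

#' Random affine (geometric) augmentation
#'
#' Applies one random rotation, shear, isotropic scaling and
#' translation, drawn uniformly from the configured intervals, as a
#' single composed affine map about the image center, with bilinear
#' interpolation and mirror-reflect padding, then center-crops to
#' `out_size`.
#'
#' @param image a [texture_image].
#' @param cfg an [augment_config].
#' @param out_size `(H, W)` of the returned crop; defaults to the input
#'   size.
#' @param draw optional named list forcing parameter values
#'   (`rotation`, `shear`, `scale` scalars, `translation` length-2),
#'   used for calibration and testing.
#' @return A [texture_image] of size `out_size`.
#' @export
geometric_augment <- function(image, cfg, out_size = NULL, draw = list()) {
  px <- image$pixels
  H <- dim(px)[1]; W <- dim(px)[2]
  if (is.null(out_size)) out_size <- c(H, W)
  oh <- out_size[1]; ow <- out_size[2]
  if (oh > H || ow > W)
    stop_input("texture (%d x %d) is smaller than the requested crop (%d x %d)",
               H, W, oh, ow)
  th <- (draw$rotation %||% runif(1, cfg$rotation_deg[1],
                                  cfg$rotation_deg[2])) * pi / 180
  sh <- (draw$shear %||% runif(1, cfg$shear_deg[1],
                               cfg$shear_deg[2])) * pi / 180
  sc <- draw$scale %||% runif(1, cfg$scale[1], cfg$scale[2])
  tr <- draw$translation %||% runif(2, cfg$translation_px[1],
                                    cfg$translation_px[2])
  # forward map: src -> rotate . shear . scale (about centers) + t
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  S <- matrix(c(1, 0, tan(sh), 1), 2, 2)      # shear along x
  A <- R %*% S * sc
  Ainv <- solve(A)
  c_src <- c((H - 1) / 2, (W - 1) / 2)
  c_out <- c((oh - 1) / 2, (ow - 1) / 2)
  gy <- rep(seq_len(oh) - 1, times = ow) - c_out[1] - tr[1]
  gx <- rep(seq_len(ow) - 1, each = oh) - c_out[2] - tr[2]
  src <- Ainv %*% rbind(gy, gx)
  ry <- src[1, ] + c_src[1]
  rx <- src[2, ] + c_src[2]
  out <- array(0, dim = c(oh, ow, 3L))
  sample_ch <- bilinear_sample(px, ry, rx)
  for (ch in 1:3)
    out[, , ch] <- matrix(sample_ch(px[, , ch]), oh, ow)
  new_texture_image(clamp01(out), image$source_id)
}

#' Additive uniform pixel noise
#'
#' Adds i.i.d. noise uniform in `[-A, A]` per pixel and channel, with
#' the amplitude itself drawn as `A ~ U(0, 0.02)` (configurable), then
#' clips to `[0, 1]`.
#'
#' @inheritParams geometric_augment
#' @param amplitude optional forced amplitude (overrides the draw).
#' @return A [texture_image].
#' @export
add_uniform_noise <- function(image, cfg, amplitude = NULL) {
  A <- amplitude %||% runif(1, cfg$noise_amplitude[1],
                            cfg$noise_amplitude[2])
  if (A == 0) return(image)
  px <- image$pixels + runif(length(image$pixels), -A, A)
  new_texture_image(clamp01(array(px, dim = dim(image$pixels))),
                image$source_id)
}

# The seven photometric operations, each mapping an (H, W, 3) array in
# [0, 1] to the same.
apply_photometric <- function(px, op, cfg, gamma_val = NULL,
                              sigma_val = NULL) {
  switch(op,
    adaptive_equalization = {
      img <- as_ebimage(px)
      out <- EBImage::clahe(img, nx = cfg$adaptive_eq_tiles[1],
                            ny = cfg$adaptive_eq_tiles[2])
      clamp01(from_ebimage(out))
    },
    histogram_equalization = {
      out <- px
      for (ch in 1:3) {
        v <- px[, , ch]
        out[, , ch] <- matrix(rank(v, ties.method = "average") / length(v),
                              nrow(v), ncol(v))
      }
      out
    },
    log_adjust = clamp01(cfg$log_gain * log2(1 + px)),
    sigmoid_adjust = 1 / (1 + exp(cfg$sigmoid_gain *
                                    (cfg$sigmoid_cutoff - px))),
    gamma = {
      g <- gamma_val %||% runif(1, cfg$gamma[1], cfg$gamma[2])
      px^g
    },
    gaussian_blur = {
      s <- sigma_val %||% runif(1, cfg$gaussian_sigma[1],
                                cfg$gaussian_sigma[2])
      out <- px
      if (s > 1e-8) for (ch in 1:3)
        out[, , ch] <- gauss_blur_mat(px[, , ch], s)
      out
    },
    invert = 1 - px,
    stop_config("unknown photometric operation '%s'", op))
}

#' Random photometric augmentation
#'
#' Draws exactly one operation uniformly from the configured menu --
#' adaptive histogram equalization, global histogram equalization,
#' logarithmic adjustment, sigmoid adjustment, random gamma correction
#' (`gamma ~ U(0.5, 1.5)`), random Gaussian blur (`sigma ~ U(0, 5)`),
#' or image inversion -- and applies it.
#'
#' @inheritParams geometric_augment
#' @param op optional forced operation name (overrides the draw).
#' @param gamma_val,sigma_val optional forced parameter values.
#' @return A [texture_image].
#' @export
random_photometric <- function(image, cfg, op = NULL, gamma_val = NULL,
                               sigma_val = NULL) {
  menu <- cfg$photometric_menu
  op <- op %||% menu[sample.int(length(menu), 1L)]
  px <- apply_photometric(image$pixels, op, cfg, gamma_val, sigma_val)
  new_texture_image(clamp01(array(px, dim = dim(image$pixels))),
                image$source_id)
}

#' Full augmentation chain
#'
#' Composition geometric -> uniform noise -> one photometric operation.
#' A disabled config reduces to a plain central crop to `out_size` (or
#' the identity when no crop is requested).
#'
#' @inheritParams geometric_augment
#' @return A [texture_image] of size `out_size`.
#' @export
augment_texture <- function(image, cfg, out_size = NULL) {
  if (!isTRUE(cfg$enabled)) {
    if (is.null(out_size)) return(image)
    H <- dim(image$pixels)[1]; W <- dim(image$pixels)[2]
    if (out_size[1] > H || out_size[2] > W)
      stop_input("texture (%d x %d) is smaller than the requested crop (%d x %d)",
                 H, W, out_size[1], out_size[2])
    y0 <- floor((H - out_size[1]) / 2); x0 <- floor((W - out_size[2]) / 2)
    return(new_texture_image(image$pixels[y0 + seq_len(out_size[1]),
                                      x0 + seq_len(out_size[2]), ,
                                      drop = FALSE],
                         image$source_id))
  }
  out <- geometric_augment(image, cfg, out_size)
  out <- add_uniform_noise(out, cfg)
  random_photometric(out, cfg)
}
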