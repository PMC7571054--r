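# Exhaustive brute-force reference implementations used to validate
# the vectorized/compiled paths, plus small shared fixtures.

# nearest-centroid labeling by explicit per-pixel comparison
brute_voronoi <- function(size, centroids) {
  H <- size[1]; W <- size[2]
  lab <- matrix(0L, H, W)
  for (r in 0:(H - 1)) for (c in 0:(W - 1)) {
    d2 <- (r - centroids[, 1])^2 + (c - centroids[, 2])^2
    lab[r + 1, c + 1] <- which.min(d2) - 1L  # which.min takes lowest index
  }
  lab
}

# per-pixel circle membership test in draw order
brute_circular <- function(size, circles) {
  H <- size[1]; W <- size[2]
  lab <- matrix(0L, H, W)
  for (r in 0:(H - 1)) for (c in 0:(W - 1)) {
    for (i in seq_len(nrow(circles))) {
      if ((r - circles[i, 1])^2 + (c - circles[i, 2])^2 <=
            circles[i, 3]^2)
        lab[r + 1, c + 1] <- i
    }
  }
  lab
}

# explicit Chebyshev-window scan for the border labeling rule
brute_border_mask <- function(labels, r) {
  H <- nrow(labels); W <- ncol(labels)
  mask <- matrix(0L, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    win <- labels[max(1, i - r):min(H, i + r),
                  max(1, j - r):min(W, j + r)]
    mask[i, j] <- as.integer(length(unique(as.vector(win))) >= 2L)
  }
  mask
}

# confusion counting pixel by pixel
brute_precision_recall <- function(pred, truth) {
  tp <- fp <- fn <- 0L
  for (i in seq_along(pred)) {
    if (pred[i] != 0 && truth[i] != 0) tp <- tp + 1L
    if (pred[i] != 0 && truth[i] == 0) fp <- fp + 1L
    if (pred[i] == 0 && truth[i] != 0) fn <- fn + 1L
  }
  c(precision = if (tp + fp == 0L) 1 else tp / (tp + fp),
    recall = if (tp + fn == 0L) 1 else tp / (tp + fn))
}

# figure of merit by direct nearest-ideal-pixel enumeration
brute_pratt <- function(pred, truth, a = 1 / 9) {
  tpix <- which(truth != 0, arr.ind = TRUE)
  ppix <- which(pred != 0, arr.ind = TRUE)
  II <- nrow(tpix); IA <- nrow(ppix)
  if (II == 0L && IA == 0L) return(1)
  if (II == 0L || IA == 0L) return(0)
  s <- 0
  for (i in seq_len(IA)) {
    d2 <- min((ppix[i, 1] - tpix[, 1])^2 + (ppix[i, 2] - tpix[, 2])^2)
    s <- s + 1 / (1 + a * d2)
  }
  s / max(II, IA)
}

# constant-color texture, valid at any size >= 32
const_texture <- function(color, size = c(64L, 64L), id = NULL) {
  px <- array(rep(color, each = prod(size)), dim = c(size, 3L))
  texture_image(px, id %||% paste0("const_", paste(round(color, 2),
                                                   collapse = "_")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

two_tone_library <- function(size = c(64L, 64L)) {
  texture_library(list(const_texture(c(0.2, 0.2, 0.2), size, "dark"),
                       const_texture(c(0.8, 0.8, 0.8), size, "light")),
                  "two_tone")
}

# small procedural library large enough to fill 32x32 and 64x64 mosaics
small_proc_library <- function(size = c(96L, 96L)) {
  texture_library(list(
    generate_procedural_texture("stripes", size, seed = 11),
    generate_procedural_texture("blob_noise", size, seed = 22)),
    "small_proc")
}
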