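## Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's stream afterwards.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Deterministic per-item child seed derived from a master seed; kept
# within the 32-bit signed integer range expected by set.seed().
child_seed <- function(master, i) {
  as.integer((as.double(master) * 48271 + i * 16807) %% 2147483647)
}

clamp01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

stop_config <- function(...) stop(sprintf(...), call. = FALSE)
stop_input  <- function(...) stop(sprintf(...), call. = FALSE)

# Conversions between the internal (H, W, 3) row-major-ish array
# convention (first index = image row) and EBImage's (x, y, channel)
# layout.  All pixel values are kept in [0, 1].
as_ebimage <- function(pixels) {
  if (length(dim(pixels)) == 2L) {
    EBImage::Image(t(pixels), colormode = "Grayscale")
  } else {
    EBImage::Image(aperm(pixels, c(2L, 1L, 3L)), colormode = "Color")
  }
}

from_ebimage <- function(img) {
  a <- as.array(img)
  if (length(dim(a)) == 2L) return(t(a))
  if (dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]  # drop alpha
  aperm(a, c(2L, 1L, 3L))
}

write_image_png <- function(pixels, path, bits = 8L) {
  EBImage::writeImage(as_ebimage(clamp01(pixels)), path, type = "png",
                      bits.per.sample = as.integer(bits))
  invisible(path)
}

read_image_rgb <- function(path) {
  a <- from_ebimage(EBImage::readImage(path))
  if (length(dim(a)) == 2L) a <- array(rep(a, 3L), dim = c(dim(a), 3L))
  clamp01(a)
}

read_image_gray <- function(path) {
  a <- as.array(EBImage::readImage(path))
  if (length(dim(a)) == 3L) a <- a[, , 1L]
  t(a)
}
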