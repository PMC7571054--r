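## Texture inputs: procedural fixture textures and folder loaders.
##
## Textures are the atomic fill unit for mosaic regions.  Real texture
## collections (photographic texture benchmarks) are loaded from folders of
## PNG/TIFF files; the procedural generator provides fully synthetic
## stand-ins so the whole pipeline can run without any external data.

#' Construct a texture image
#'
#' @param pixels numeric array of dim `(H, W, 3)` with values in `[0, 1]`.
#' @param source_id character tag identifying the texture's origin.
#' @return An object of class `texture_image`.
#' @export
texture_image <- function(pixels, source_id) {
  d <- dim(pixels)
  if (length(d) != 3L || d[3] != 3L)
    stop_input("texture pixels must be an H x W x 3 array")
  if (d[1] < 32L || d[2] < 32L)
    stop_input("texture must be at least 32 x 32, got %d x %d", d[1], d[2])
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 1)
    stop_input("texture pixel values must lie in [0, 1]")
  structure(list(pixels = pixels, source_id = as.character(source_id)),
            class = "texture_image")
}

# Internal constructor for derived images (augmented crops sized to the
# mosaic): range and shape are enforced, but not the minimum source
# size.
new_texture_image <- function(pixels, source_id) {
  structure(list(pixels = pixels, source_id = as.character(source_id)),
            class = "texture_image")
}

#' @export
print.texture_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<texture_image '%s' %d x %d>\n", x$source_id, d[1], d[2]))
  invisible(x)
}

#' Construct a texture library
#'
#' An ordered, non-empty collection of [texture_image] objects with
#' unique source ids.
#'
#' @param textures list of [texture_image] objects.
#' @param name character label for the collection.
#' @return An object of class `texture_library`.
#' @export
texture_library <- function(textures, name = "library") {
  if (length(textures) == 0L)
    stop_input("texture library must be non-empty")
  ids <- vapply(textures, function(t) t$source_id, character(1))
  if (anyDuplicated(ids))
    stop_input("texture source ids must be unique")
  structure(list(textures = textures, name = name),
            class = "texture_library")
}

#' @export
length.texture_library <- function(x) length(x$textures)

#' @export
print.texture_library <- function(x, ...) {
  cat(sprintf("<texture_library '%s': %d textures>\n", x$name,
              length(x$textures)))
  invisible(x)
}

# Separable Gaussian blur with mirror ("reflect") boundary handling.
gauss_blur_mat <- function(m, sigma) {
  if (sigma <= 1e-8) return(m)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  blur1d <- function(mm) {  # along rows (first index)
    n <- nrow(mm)
    idx <- seq(1L - r, n + r)
    idx <- ifelse(idx < 1L, 1L - idx, idx)          # mirror low side
    idx <- ifelse(idx > n, 2L * n + 1L - idx, idx)  # mirror high side
    padded <- mm[idx, , drop = FALSE]
    out <- matrix(0, n, ncol(mm))
    for (j in seq_along(k))
      out <- out + k[j] * padded[j:(j + n - 1L), , drop = FALSE]
    out
  }
  t(blur1d(t(blur1d(m))))
}

.texture_kinds <- c("stripes", "checkerboard", "grating", "blob_noise",
                    "cellular")

#' Generate a procedural fixture texture
#'
#' Five synthetic texture families with clearly distinct spatial
#' statistics, used in place of photographic texture datasets for
#' self-contained experiments: two-color `stripes`, a two-color
#' `checkerboard`, a sinusoidal `grating`, Gaussian-smoothed
#' `blob_noise`, and a `cellular` nearest-seed mosaic.
#'
#' @param kind one of `"stripes"`, `"checkerboard"`, `"grating"`,
#'   `"blob_noise"`, `"cellular"`.
#' @param size integer vector `(H, W)`, both at least 32.
#' @param params named list of kind-specific parameters: `period` and
#'   `angle` (stripes/grating), `cell` (checkerboard), `sigma`
#'   (blob_noise), `n_cells` (cellular).
#' @param seed integer; output is fully determined by
#'   `(kind, size, params, seed)`.
#' @return A [texture_image].
#' @export
generate_procedural_texture <- function(kind, size = c(64L, 64L),
                                        params = list(), seed = 0L) {
  kind <- as.character(kind)
  if (!kind %in% .texture_kinds)
    stop_config("unknown procedural texture kind '%s' (choose from: %s)",
                kind, paste(.texture_kinds, collapse = ", "))
  H <- as.integer(size[1]); W <- as.integer(size[2])
  if (H < 32L || W < 32L)
    stop_config("procedural texture size must be at least 32 x 32")
  p <- function(name, default)
    if (!is.null(params[[name]])) params[[name]] else default

  px <- with_seed(seed, {
    rr <- matrix(seq_len(H) - 1L, H, W)
    cc <- matrix(seq_len(W) - 1L, H, W, byrow = TRUE)
    col_a <- runif(3, 0.05, 0.95)
    col_b <- runif(3, 0.05, 0.95)
    # guarantee a visible two-color contrast
    if (mean(abs(col_a - col_b)) < 0.25) col_b <- 1 - col_a
    two_tone <- function(sel) {
      out <- array(0, dim = c(H, W, 3L))
      for (ch in 1:3) out[, , ch] <- ifelse(sel, col_a[ch], col_b[ch])
      out
    }
    switch(kind,
      stripes = {
        period <- p("period", 8); angle <- p("angle", 0) * pi / 180
        u <- cc * cos(angle) + rr * sin(angle)
        two_tone((floor(u / (period / 2)) %% 2) == 0)
      },
      checkerboard = {
        cell <- p("cell", 8)
        two_tone(((floor(rr / cell) + floor(cc / cell)) %% 2) == 0)
      },
      grating = {
        period <- p("period", 6); angle <- p("angle", 30) * pi / 180
        u <- cc * cos(angle) + rr * sin(angle)
        g <- 0.5 + 0.5 * sin(2 * pi * u / period)
        out <- array(0, dim = c(H, W, 3L))
        for (ch in 1:3) out[, , ch] <- col_a[ch] * g + col_b[ch] * (1 - g)
        out
      },
      blob_noise = {
        sigma <- p("sigma", 3)
        out <- array(0, dim = c(H, W, 3L))
        for (ch in 1:3) {
          z <- gauss_blur_mat(matrix(rnorm(H * W), H, W), sigma)
          # smoothing shrinks the variance by roughly 1/(4*pi*sigma^2)
          sd_theo <- 1 / sqrt(max(4 * pi * sigma^2, 1))
          out[, , ch] <- clamp01(0.5 + z / (6 * sd_theo))
        }
        out
      },
      cellular = {
        n_cells <- p("n_cells", 12)
        sy <- runif(n_cells, 0, H - 1); sx <- runif(n_cells, 0, W - 1)
        cols <- matrix(runif(3 * n_cells, 0.05, 0.95), n_cells, 3)
        d2 <- matrix(Inf, H, W); lab <- matrix(1L, H, W)
        for (k in seq_len(n_cells)) {
          dk <- (rr - sy[k])^2 + (cc - sx[k])^2
          upd <- dk < d2
          d2[upd] <- dk[upd]; lab[upd] <- k
        }
        shade <- clamp01(1 - sqrt(d2) / (0.5 * min(H, W)))
        out <- array(0, dim = c(H, W, 3L))
        for (ch in 1:3)
          out[, , ch] <- matrix(cols[lab, ch], H, W) * (0.6 + 0.4 * shade)
        out
      })
  })
  texture_image(clamp01(px),
                sprintf("%s_s%d_%dx%d", kind, as.integer(seed), H, W))
}

#' Build a library of procedural textures
#'
#' Convenience constructor cycling through the requested kinds with
#' per-texture derived seeds.
#'
#' @param n number of textures.
#' @param size `(H, W)` of each texture.
#' @param kinds character vector of kinds to cycle through.
#' @param seed master seed; texture `i` uses a derived child seed.
#' @return A [texture_library].
#' @export
procedural_texture_library <- function(n = 10L, size = c(128L, 128L),
                                       kinds = .texture_kinds, seed = 0L) {
  textures <- lapply(seq_len(n), function(i) {
    k <- kinds[((i - 1L) %% length(kinds)) + 1L]
    tx <- generate_procedural_texture(k, size, seed = child_seed(seed, i))
    tx$source_id <- sprintf("%02d_%s", i, tx$source_id)
    tx
  })
  texture_library(textures, name = sprintf("procedural_%d", n))
}

#' Load a folder of texture images
#'
#' Reads every PNG/TIFF file in `path` (lexicographic filename order)
#' into a [texture_library].  8- and 16-bit inputs are scaled to
#' `[0, 1]`; grayscale images are replicated to three channels.
#' Undecodable files are skipped with a warning.
#'
#' @param path directory containing at least one readable image.
#' @param name library name; defaults to the folder name.
#' @return A [texture_library].
#' @export
load_texture_folder <- function(path, name = basename(path)) {
  if (!dir.exists(path))
    stop_input("texture folder '%s' does not exist", path)
  files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                           ignore.case = TRUE, full.names = TRUE))
  if (length(files) == 0L)
    stop_input("texture folder '%s' contains no PNG/TIFF images", path)
  textures <- list()
  for (f in files) {
    px <- tryCatch(read_image_rgb(f), error = function(e) {
      warning(sprintf("skipping undecodable texture '%s': %s",
                      basename(f), conditionMessage(e)), call. = FALSE)
      NULL
    })
    if (!is.null(px))
      textures[[length(textures) + 1L]] <- texture_image(px, basename(f))
  }
  if (length(textures) == 0L)
    stop_input("no decodable images in texture folder '%s'", path)
  texture_library(textures, name = name)
}

#' Sample a texture uniformly from a library
#'
#' Draws from the session RNG, so results are reproducible under
#' `set.seed()`.
#'
#' @param library a [texture_library].
#' @return A [texture_image].
#' @export
sample_texture <- function(library) {
  stopifnot(inherits(library, "texture_library"))
  library$textures[[sample.int(length(library$textures), 1L)]]
}
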