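## Mosaic structures, border-band ground truth, and mosaic assembly.
##
## A mosaic structure is a per-pixel partition of the image into region
## ids.  Three generators are provided: Voronoi (nearest of 2-10 random
## centroids), random-walk (two monotone jittered paths crossing the
## image), and circular (up to four random disks over a background).
## Ground truth marks every pixel whose Chebyshev neighbourhood touches
## two or more regions, producing a border band strictly wider than two
## pixels across any straight boundary.

#' Construct a region label map
#'
#' @param labels integer matrix `(H, W)` with values in
#'   `0:(n_regions - 1)`; every label must occur at least once.
#' @param structure_type optional character tag (`"voronoi"`,
#'   `"random_walk"`, `"circular"`).
#' @return An object of class `region_label_map` with fields `labels`
#'   and `n_regions`.
#' @export
region_label_map <- function(labels, structure_type = NA_character_) {
  labels <- matrix(as.integer(labels), nrow(labels), ncol(labels))
  present <- sort(unique(as.vector(labels)))
  n <- length(present)
  if (!identical(present, 0:(n - 1L)))
    stop_input("region labels must be consecutive integers starting at 0")
  structure(list(labels = labels, n_regions = n,
                 structure_type = structure_type),
            class = "region_label_map")
}

#' @export
print.region_label_map <- function(x, ...) {
  cat(sprintf("<region_label_map %s %d x %d, %d regions>\n",
              x$structure_type, nrow(x$labels), ncol(x$labels),
              x$n_regions))
  invisible(x)
}

#' Voronoi mosaic structure
#'
#' Places `n_centroids` (2-10) centroids at distinct random pixel
#' positions and assigns every pixel to its nearest centroid (Euclidean
#' distance between pixel centers, ties broken toward the lowest
#' centroid index).  Consumes the session RNG.
#'
#' @param size integer `(H, W)`.
#' @param n_centroids number of regions, between 2 and 10.
#' @return A [region_label_map] with the centroid coordinates attached
#'   as attribute `"centroids"` (0-based `(row, col)` matrix).
#' @export
voronoi_structure <- function(size, n_centroids) {
  H <- as.integer(size[1]); W <- as.integer(size[2])
  n_centroids <- as.integer(n_centroids)
  if (n_centroids < 2L || n_centroids > 10L)
    stop_config("n_centroids must be between 2 and 10, got %d", n_centroids)
  repeat {
    cy <- sample.int(H, n_centroids, replace = TRUE) - 1L
    cx <- sample.int(W, n_centroids, replace = TRUE) - 1L
    if (!anyDuplicated(cbind(cy, cx))) break
  }
  rr <- matrix(seq_len(H) - 1L, H, W)
  cc <- matrix(seq_len(W) - 1L, H, W, byrow = TRUE)
  d2 <- matrix(0, H * W, n_centroids)
  for (k in seq_len(n_centroids))
    d2[, k] <- as.vector((rr - cy[k])^2 + (cc - cx[k])^2)
  lab <- max.col(-d2, ties.method = "first") - 1L
  out <- region_label_map(matrix(lab, H, W), "voronoi")
  attr(out, "centroids") <- cbind(row = cy, col = cx)
  out
}

# One monotone jittered path across the image.  For a vertical walk the
# path advances one row per step starting from a random top-edge column,
# moving laterally by a draw from `jitter_choices` (clipped to the
# image).  Returns the per-row column of the path.
walk_path <- function(n_steps, width, jitter_choices = -1:1) {
  pos <- integer(n_steps)
  pos[1] <- sample.int(width, 1L) - 1L
  if (n_steps > 1L) {
    for (i in 2:n_steps) {
      step <- jitter_choices[sample.int(length(jitter_choices), 1L)]
      pos[i] <- min(max(pos[i - 1L] + step, 0L), width - 1L)
    }
  }
  pos
}

#' Random-walk mosaic structure
#'
#' Two monotone random-walk paths -- one entering on the top edge and
#' advancing one row per step with lateral jitter, one entering on the
#' left edge and advancing one column per step -- each split the image
#' in two; their intersection yields 2-4 regions.  `mode = "single"`
#' uses one walk (random orientation) and yields 2 regions.  Consumes
#' the session RNG.
#'
#' @param size integer `(H, W)`, both at least 16.
#' @param mode `"double"` (default) or `"single"`.
#' @param jitter_choices integer steps the path may take sideways per
#'   advance; the default `-1:1` keeps the path 8-connected.
#' @return A [region_label_map]; walk paths are attached as attribute
#'   `"paths"`.
#' @export
random_walk_structure <- function(size, mode = c("double", "single"),
                                  jitter_choices = -1:1) {
  mode <- match.arg(mode)
  H <- as.integer(size[1]); W <- as.integer(size[2])
  if (H < 16L || W < 16L)
    stop_config("random-walk structures need at least a 16 x 16 image")
  rr <- matrix(seq_len(H) - 1L, H, W)
  cc <- matrix(seq_len(W) - 1L, H, W, byrow = TRUE)
  for (attempt in 1:100) {
    if (mode == "double") {
      vpath <- walk_path(H, W, jitter_choices)  # column per row
      hpath <- walk_path(W, H, jitter_choices)  # row per column
      side_v <- cc >= vpath[rr + 1L]
      side_h <- rr >= hpath[cc + 1L]
      code <- 2L * side_v + side_h
      paths <- list(vertical = vpath, horizontal = hpath)
    } else {
      if (sample.int(2L, 1L) == 1L) {
        vpath <- walk_path(H, W, jitter_choices)
        code <- (cc >= vpath[rr + 1L]) * 1L
        paths <- list(vertical = vpath)
      } else {
        hpath <- walk_path(W, H, jitter_choices)
        code <- (rr >= hpath[cc + 1L]) * 1L
        paths <- list(horizontal = hpath)
      }
    }
    # relabel to consecutive ids in order of first appearance
    ids <- unique(as.vector(code))
    if (length(ids) >= 2L) {
      lab <- matrix(match(code, ids) - 1L, H, W)
      out <- region_label_map(lab, "random_walk")
      attr(out, "paths") <- paths
      return(out)
    }
  }
  stop_input("failed to produce a multi-region random-walk structure")
}

#' Circular mosaic structure
#'
#' Draws `k ~ Uniform{1..4}` circles with random centers and radii in
#' `[min(H, W)/8, min(H, W)/3]` over a background region.  Later circles
#' overwrite earlier ones where they overlap; a circle left without any
#' visible pixel is re-drawn so every region survives.  Consumes the
#' session RNG.
#'
#' @param size integer `(H, W)`, both at least 16.
#' @return A [region_label_map] with the circle parameters attached as
#'   attribute `"circles"` (matrix of `cy, cx, r`).
#' @export
circular_structure <- function(size) {
  H <- as.integer(size[1]); W <- as.integer(size[2])
  if (H < 16L || W < 16L)
    stop_config("circular structures need at least a 16 x 16 image")
  rr <- matrix(seq_len(H) - 1L, H, W)
  cc <- matrix(seq_len(W) - 1L, H, W, byrow = TRUE)
  m <- min(H, W)
  k <- sample.int(4L, 1L)
  draw <- function() c(runif(1, 0, H - 1), runif(1, 0, W - 1),
                       runif(1, m / 8, m / 3))
  circles <- t(replicate(k, draw()))
  paint <- function(circles) {
    lab <- matrix(0L, H, W)
    for (i in seq_len(nrow(circles)))
      lab[(rr - circles[i, 1])^2 + (cc - circles[i, 2])^2 <=
            circles[i, 3]^2] <- i
    lab
  }
  for (attempt in 1:1000) {
    lab <- paint(circles)
    missing <- setdiff(0:k, unique(as.vector(lab)))
    if (length(missing) == 0L) break
    if (missing[1] == 0L) {          # background fully covered: redo all
      circles <- t(replicate(k, draw()))
    } else {
      circles[missing[1], ] <- draw()
    }
  }
  out <- region_label_map(lab, "circular")
  colnames(circles) <- c("cy", "cx", "r")
  attr(out, "circles") <- circles
  out
}

# Running min/max of a matrix over a (2r+1)^2 Chebyshev window, clipped
# at the image edges (edge replication equals window clipping for
# min/max).  Separable in rows and columns.
window_range <- function(m, r) {
  H <- nrow(m); W <- ncol(m)
  lo <- m; hi <- m
  for (d in seq_len(r)) {
    up <- m[pmin(seq_len(H) + d, H), , drop = FALSE]
    dn <- m[pmax(seq_len(H) - d, 1L), , drop = FALSE]
    lo <- pmin(lo, up, dn); hi <- pmax(hi, up, dn)
  }
  lo2 <- lo; hi2 <- hi
  for (d in seq_len(r)) {
    lo2 <- pmin(lo2, lo[, pmin(seq_len(W) + d, W), drop = FALSE],
                lo[, pmax(seq_len(W) - d, 1L), drop = FALSE])
    hi2 <- pmax(hi2, hi[, pmin(seq_len(W) + d, W), drop = FALSE],
                hi[, pmax(seq_len(W) - d, 1L), drop = FALSE])
  }
  list(min = lo2, max = hi2)
}

#' Border-band ground truth of a mosaic structure
#'
#' A pixel is labeled border (1) exactly when the
#' `(2 * border_radius + 1)^2` Chebyshev window centered on it (clipped
#' at the image edges) contains two or more distinct region labels.
#' With the default radius 2, a straight axis-aligned boundary produces
#' a band 4 pixels wide, i.e. always more than two pixels.
#'
#' @param structure a [region_label_map].
#' @param border_radius Chebyshev radius of the labeling window
#'   (integer, at least 1; default 2).
#' @return An object of class `border_mask` with fields `mask`
#'   (binary `(H, W)` matrix) and `border_radius`.
#' @export
border_mask <- function(structure, border_radius = 2L) {
  stopifnot(inherits(structure, "region_label_map"))
  border_radius <- as.integer(border_radius)
  if (border_radius < 1L)
    stop_config("border_radius must be at least 1")
  wr <- window_range(structure$labels, border_radius)
  mask <- (wr$max != wr$min) * 1L
  structure(list(mask = matrix(as.integer(mask), nrow(mask), ncol(mask)),
                 border_radius = border_radius),
            class = "border_mask")
}

#' @export
print.border_mask <- function(x, ...) {
  cat(sprintf("<border_mask %d x %d, radius %d, %.1f%% border>\n",
              nrow(x$mask), ncol(x$mask), x$border_radius,
              100 * mean(x$mask)))
  invisible(x)
}

#' Assemble a textured mosaic with its ground truth
#'
#' Each region of the structure is filled with an independently sampled
#' and independently augmented texture from the library (regions may
#' reuse the same source texture).  The target is the [border_mask] of
#' the structure.  Consumes the session RNG.
#'
#' @param structure a [region_label_map].
#' @param library a [texture_library]; every texture must be at least as
#'   large as the mosaic.
#' @param augment an [augment_config]; disabled configs take a plain
#'   central crop of each texture.
#' @param border_radius radius forwarded to [border_mask()].
#' @return An object of class `mosaic_sample` with fields `image`
#'   (`(H, W, 3)` array), `target`, `structure` and `provenance`.
#' @export
assemble_mosaic <- function(structure, library,
                            augment = augment_config(enabled = FALSE),
                            border_radius = 2L) {
  stopifnot(inherits(structure, "region_label_map"),
            inherits(library, "texture_library"))
  H <- nrow(structure$labels); W <- ncol(structure$labels)
  img <- array(0, dim = c(H, W, 3L))
  ids <- character(structure$n_regions)
  for (lab in 0:(structure$n_regions - 1L)) {
    tex <- sample_texture(library)
    td <- dim(tex$pixels)
    if (td[1] < H || td[2] < W)
      stop_input("texture '%s' (%d x %d) is smaller than the mosaic (%d x %d)",
                 tex$source_id, td[1], td[2], H, W)
    filled <- augment_texture(tex, augment, out_size = c(H, W))
    sel <- structure$labels == lab
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[sel] <- filled$pixels[, , ch][sel]
      img[, , ch] <- plane
    }
    ids[lab + 1L] <- tex$source_id
  }
  structure(list(image = img,
                 target = border_mask(structure, border_radius),
                 structure = structure,
                 provenance = list(structure_type = structure$structure_type,
                                   texture_ids = ids)),
            class = "mosaic_sample")
}

# Draw one structure of the given type at `size`, consuming the session
# RNG.  `walk_mode` configures the random-walk generator.
draw_structure <- function(type, size, walk_mode = "double") {
  switch(type,
    voronoi = voronoi_structure(size, sample(2:10, 1L)),
    random_walk = random_walk_structure(size, mode = walk_mode),
    circular = circular_structure(size),
    stop_config("unknown structure type '%s'", type))
}

#' Generate one complete mosaic sample
#'
#' Draws a structure type uniformly from `structures`, generates the
#' structure, and fills it from the library.  Fully determined by
#' `seed`.
#'
#' @inheritParams assemble_mosaic
#' @param size integer `(H, W)` of the mosaic.
#' @param structures structure types to draw from.
#' @param walk_mode forwarded to [random_walk_structure()].
#' @param seed integer seed for this sample.
#' @return A `mosaic_sample`; `provenance$seed` records the seed.
#' @export
generate_mosaic <- function(size, library,
                            augment = augment_config(),
                            structures = c("voronoi", "random_walk",
                                           "circular"),
                            border_radius = 2L, walk_mode = "double",
                            seed = 0L) {
  with_seed(seed, {
    type <- structures[sample.int(length(structures), 1L)]
    st <- draw_structure(type, size, walk_mode)
    s <- assemble_mosaic(st, library, augment, border_radius)
    s$provenance$seed <- as.integer(seed)
    s
  })
}

#' Build a mosaic dataset on disk
#'
#' Writes `n` mosaic/mask pairs (8-bit RGB PNG images, single-channel
#' `{0, 255}` PNG masks) plus a JSON-Lines manifest.  Each sample draws
#' its structure type uniformly from `config$structures` and uses a
#' unique per-sample seed derived from `seed`.
#'
#' @param n number of mosaics (at least 1).
#' @param library a [texture_library].
#' @param config list with elements `image_size` (default `c(256, 256)`),
#'   `structures`, `border_radius`, `walk_mode` and `augment` (an
#'   [augment_config]).
#' @param seed master seed for the dataset.
#' @param out_dir output directory (created if needed).
#' @param split `"train"` or `"test"`, recorded in the manifest.
#' @return A `dataset_manifest`: list with `entries` (data frame),
#'   `split`, `seed`, `dir` and `path` of the manifest file.
#' @export
build_dataset <- function(n, library, config = list(), seed = 0L,
                          out_dir = tempfile("mosaics"),
                          split = c("train", "test")) {
  split <- match.arg(split)
  if (n < 1L) stop_input("n must be at least 1")
  size <- config$image_size %||% c(256L, 256L)
  structures <- config$structures %||% c("voronoi", "random_walk",
                                         "circular")
  border_radius <- config$border_radius %||% 2L
  walk_mode <- config$walk_mode %||% "double"
  aug <- config$augment %||% augment_config()
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop_input("cannot create '%s'", out_dir)

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    s_i <- child_seed(seed, i)
    smp <- generate_mosaic(size, library, aug, structures, border_radius,
                           walk_mode, seed = s_i)
    img_path <- file.path(out_dir, sprintf("img_%05d.png", i))
    msk_path <- file.path(out_dir, sprintf("mask_%05d.png", i))
    write_image_png(smp$image, img_path)
    write_image_png(smp$target$mask, msk_path)
    rows[[i]] <- data.frame(
      image = img_path, mask = msk_path,
      structure_type = smp$provenance$structure_type,
      seed = s_i,
      texture_ids = paste(smp$provenance$texture_ids, collapse = ";"),
      stringsAsFactors = FALSE)
  }
  entries <- do.call(rbind, rows)
  manifest_path <- file.path(out_dir, "manifest.jsonl")
  con <- file(manifest_path, "w")
  for (i in seq_len(n))
    writeLines(jsonlite::toJSON(as.list(entries[i, ]), auto_unbox = TRUE),
               con)
  close(con)
  structure(list(entries = entries, split = split, seed = as.integer(seed),
                 dir = out_dir, path = manifest_path),
            class = "dataset_manifest")
}

#' Read a dataset manifest written by [build_dataset()]
#'
#' @param path path to a `manifest.jsonl` file.
#' @param split split tag to record.
#' @return A `dataset_manifest`.
#' @export
read_manifest <- function(path, split = c("train", "test")) {
  split <- match.arg(split)
  if (!file.exists(path)) stop_input("manifest '%s' does not exist", path)
  lines <- readLines(path)
  entries <- do.call(rbind, lapply(lines, function(l)
    as.data.frame(jsonlite::fromJSON(l), stringsAsFactors = FALSE)))
  structure(list(entries = entries, split = split,
                 seed = NA_integer_, dir = dirname(path), path = path),
            class = "dataset_manifest")
}

#' @export
print.dataset_manifest <- function(x, ...) {
  cat(sprintf("<dataset_manifest [%s]: %d samples in %s>\n", x$split,
              nrow(x$entries), x$dir))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
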