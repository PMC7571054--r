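test_that("voronoi structures match the nearest-centroid rule", {
  # two centroids on row 0: perpendicular bisector splits the columns
  set.seed(1)
  st <- voronoi_structure(c(8, 8), 2)
  # replace with the documented deterministic case via the oracle
  cent <- rbind(c(0, 0), c(0, 7))
  lab <- brute_voronoi(c(8, 8), cent)
  expect_true(all(lab[, 1:4] == 0L))
  expect_true(all(lab[, 5:8] == 1L))

  set.seed(7)
  st <- voronoi_structure(c(16, 16), 3)
  expect_identical(st$labels,
                   brute_voronoi(c(16, 16), attr(st, "centroids")))
  expect_equal(st$n_regions, 3L)

  for (k in c(2L, 5L, 10L)) {
    set.seed(k)
    st <- voronoi_structure(c(24, 24), k)
    expect_equal(length(unique(as.vector(st$labels))), k)
  }
  expect_error(voronoi_structure(c(16, 16), 1), "between 2 and 10")
  expect_error(voronoi_structure(c(16, 16), 11), "between 2 and 10")
})

test_that("random-walk structures produce 2-4 regions whose paths span the image", {
  counts <- integer(0)
  for (s in 1:100) {
    set.seed(s)
    st <- random_walk_structure(c(24, 24))
    counts <- c(counts, st$n_regions)
    paths <- attr(st, "paths")
    # each walk advances one step per row/column: it spans its axis
    expect_length(paths$vertical, 24L)
    expect_length(paths$horizontal, 24L)
    expect_true(all(paths$vertical >= 0 & paths$vertical <= 23))
    expect_true(all(abs(diff(paths$vertical)) <= 1))
  }
  expect_true(all(counts %in% 2:4))
  expect_true(length(unique(counts)) > 1)  # not degenerate

  # degenerate single-walk mode with zero jitter is a straight split
  set.seed(3)
  st <- random_walk_structure(c(16, 16), mode = "single",
                              jitter_choices = 0L)
  paths <- attr(st, "paths")
  expect_equal(st$n_regions, 2L)
  p <- c(paths$vertical, paths$horizontal)  # whichever orientation
  expect_equal(length(unique(p)), 1L)
  if (!is.null(paths$vertical)) {
    c0 <- paths$vertical[1]
    rr <- matrix(0:15, 16, 16)
    cc <- t(rr)
    expect_identical(st$labels, matrix(as.integer(cc >= c0), 16, 16))
  }
})

test_that("circular structures match per-pixel membership and stay within 5 regions", {
  for (s in 1:25) {
    set.seed(s)
    st <- circular_structure(c(32, 32))
    expect_lte(st$n_regions, 5L)
    expect_gte(st$n_regions, 2L)
    expect_identical(st$labels,
                     brute_circular(c(32, 32), attr(st, "circles")))
  }
  # one deterministic circle: disk plus background
  lab <- brute_circular(c(32, 32), cbind(16, 16, 8))
  st <- region_label_map(lab, "circular")
  expect_equal(st$n_regions, 2L)
  expect_equal(sum(lab == 1L), sum((outer(0:31, rep(1, 32)) - 16)^2 +
                                     t(outer(0:31, rep(1, 32)) - 16)^2 <= 64))
})

test_that("every structure generator partitions the image", {
  for (s in 1:20) {
    set.seed(s)
    for (st in list(voronoi_structure(c(24, 24), sample(2:10, 1)),
                    random_walk_structure(c(24, 24)),
                    circular_structure(c(24, 24)))) {
      labs <- sort(unique(as.vector(st$labels)))
      expect_identical(labs, 0:(st$n_regions - 1L))
    }
  }
})

test_that("border masks equal the explicit window scan and widen with radius", {
  # single region: no border
  one <- region_label_map(matrix(0L, 16, 16))
  expect_true(all(border_mask(one)$mask == 0L))

  # vertical split at column 4 (0-based), radius 2: band on columns 2-5
  lab <- matrix(0L, 8, 8); lab[, 5:8] <- 1L
  bm <- border_mask(region_label_map(lab), 2)
  expected <- matrix(0L, 8, 8); expected[, 3:6] <- 1L
  expect_identical(bm$mask, expected)
  # straight-boundary band width is 2r = 4 > 2
  expect_equal(unique(rowSums(bm$mask)), 4)

  # random label maps against the brute-force scan, several radii
  for (s in 1:5) {
    set.seed(s)
    lab <- matrix(sample(0:2, 20 * 20, replace = TRUE), 20, 20)
    lab[1, 1:3] <- 0:2  # force all labels present
    st <- region_label_map(lab)
    for (r in 1:3)
      expect_identical(border_mask(st, r)$mask, brute_border_mask(lab, r))
  }
  expect_error(border_mask(one, 0), "at least 1")
})

test_that("border masks are invariant under label permutations", {
  set.seed(9)
  st <- voronoi_structure(c(24, 24), 4)
  perm <- c(2L, 3L, 0L, 1L)
  st_perm <- region_label_map(matrix(perm[st$labels + 1L], 24, 24))
  expect_identical(border_mask(st)$mask, border_mask(st_perm)$mask)
})

test_that("assembled mosaics are piecewise-constant fills of the structure", {
  lab <- matrix(0L, 32, 32); lab[, 17:32] <- 1L
  st <- region_label_map(lab)
  lib <- two_tone_library(c(64, 64))
  set.seed(2)
  smp <- assemble_mosaic(st, lib, augment_config(enabled = FALSE))
  expect_s3_class(smp, "mosaic_sample")
  expect_equal(dim(smp$image), c(32L, 32L, 3L))
  # each region is a constant block equal to one of the two tones
  for (lv in 0:1) {
    vals <- unique(as.vector(smp$image[, , 1][lab == lv]))
    expect_length(vals, 1L)
    expect_true(round(vals, 3) %in% c(0.2, 0.8))
  }
  # target accompanies the structure
  expect_identical(smp$target$mask, border_mask(st)$mask)

  # undersized texture is rejected by name
  tiny <- texture_library(list(const_texture(c(0.5, 0.5, 0.5),
                                             c(32, 32), "tiny")), "t")
  big <- region_label_map(matrix(c(rep(0L, 32 * 64), rep(1L, 32 * 64)),
                                 64, 64))
  expect_error(assemble_mosaic(big, tiny, augment_config(enabled = FALSE)),
               "tiny")
})

test_that("mosaic generation is reproducible and regions are independent", {
  lib <- small_proc_library()
  s1 <- generate_mosaic(c(32, 32), lib, augment_config(), seed = 5)
  s2 <- generate_mosaic(c(32, 32), lib, augment_config(), seed = 5)
  expect_identical(s1$image, s2$image)
  expect_identical(s1$target$mask, s2$target$mask)
  s3 <- generate_mosaic(c(32, 32), lib, augment_config(), seed = 6)
  expect_false(identical(s1$image, s3$image))

  # interior pixels of a region depend only on that region's draw:
  # swap out the texture that filled region 1 and region 0 is unchanged
  lab <- matrix(0L, 32, 32); lab[, 17:32] <- 1L
  st <- region_label_map(lab)
  libA <- two_tone_library(c(64, 64))
  ids <- vapply(libA$textures, function(t) t$source_id, character(1))
  for (seed in 11:40) {  # find a seed where the regions drew different entries
    set.seed(seed)
    mA <- assemble_mosaic(st, libA, augment_config(enabled = FALSE))
    used <- mA$provenance$texture_ids
    if (used[1] != used[2]) break
  }
  expect_false(used[1] == used[2])
  libB <- libA
  swap <- which(ids == used[2])
  libB$textures[[swap]] <- const_texture(c(0.4, 0.9, 0.1), c(64, 64),
                                         "other")
  set.seed(seed)
  mB <- assemble_mosaic(st, libB, augment_config(enabled = FALSE))
  expect_identical(mA$image[, 1:16, ], mB$image[, 1:16, ])   # region 0
  expect_false(identical(mA$image[, 17:32, ], mB$image[, 17:32, ]))
})

test_that("build_dataset writes consistent files with uniform structure types", {
  dir <- withr::local_tempdir()
  lib <- small_proc_library()
  man <- build_dataset(10, lib,
                       config = list(image_size = c(32L, 32L)),
                       seed = 3, out_dir = dir)
  expect_equal(nrow(man$entries), 10L)
  expect_true(all(file.exists(man$entries$image)))
  expect_true(all(file.exists(man$entries$mask)))
  expect_false(anyDuplicated(man$entries$image) > 0)
  expect_false(anyDuplicated(man$entries$seed) > 0)

  # round trip through the manifest
  man2 <- read_manifest(man$path)
  expect_equal(man2$entries$image, man$entries$image)
  expect_equal(man2$entries$structure_type, man$entries$structure_type)

  # masks on disk obey the border invariants: zeroing the border and
  # labeling the remainder yields components inside single regions
  for (i in 1:3) {
    msk <- texbound:::read_image_gray(man$entries$mask[i])
    expect_true(all(round(as.vector(msk), 6) %in% c(0, 1)))
    smp <- generate_mosaic(c(32, 32), lib, augment_config(),
                           seed = man$entries$seed[i])
    expect_identical((smp$target$mask == 1), (msk > 0.5))
    interior <- (smp$target$mask == 0) * 1
    comp <- t(as.array(EBImage::bwlabel(t(interior))))
    for (k in setdiff(unique(as.vector(comp)), 0)) {
      labs <- unique(smp$structure$labels[comp == k])
      expect_length(labs, 1L)
    }
  }
})
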