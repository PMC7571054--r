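test_that("forced identity transforms reproduce the input", {
  tex <- small_proc_library()$textures[[2]]
  idt <- list(rotation = 0, translation = c(0, 0), scale = 1, shear = 0)
  out <- geometric_augment(tex, augment_config(), draw = idt)
  expect_lt(max(abs(out$pixels - tex$pixels)), 1e-6)

  full_turn <- geometric_augment(tex, augment_config(),
                                 draw = modifyList(idt,
                                                   list(rotation = 360)))
  expect_lt(max(abs(full_turn$pixels - tex$pixels)), 1e-6)

  # undersized crop request is rejected
  expect_error(geometric_augment(tex, augment_config(),
                                 out_size = c(128, 128)),
               "smaller than the requested crop")
})

test_that("augmentation parameters honor their interval limits", {
  cfg <- augment_config()
  set.seed(31)
  draws <- replicate(1000, sample_augment_params(cfg), simplify = FALSE)
  g <- function(f) sapply(draws, function(d) d[[f]])
  expect_true(all(g("rotation") >= 0 & g("rotation") <= 360))
  tr <- sapply(draws, function(d) d$translation)
  expect_true(all(tr >= -12 & tr <= 12))
  expect_true(all(g("scale") >= 0.5 & g("scale") <= 1.5))
  expect_true(all(g("shear") >= -30 & g("shear") <= 30))
  expect_true(all(g("noise_amplitude") >= 0 & g("noise_amplitude") <= 0.02))
  expect_true(all(g("sigma") >= 0 & g("sigma") <= 5))
  expect_true(all(g("gamma") >= 0.5 & g("gamma") <= 1.5))
  # uniform scale draw: sample mean within 4 standard errors of 1.0
  se <- (1 / sqrt(12)) / sqrt(1000)
  expect_lt(abs(mean(g("scale")) - 1.0), 4 * se)
  expect_true(all(sapply(draws, function(d) d$op) %in%
                    cfg$photometric_menu))
})

test_that("uniform noise respects its amplitude and clipping", {
  tex <- const_texture(c(0.5, 0.5, 0.5))
  cfg <- augment_config()
  expect_identical(add_uniform_noise(tex, cfg, amplitude = 0)$pixels,
                   tex$pixels)
  set.seed(4)
  noisy <- add_uniform_noise(tex, cfg, amplitude = 0.02)
  dev <- abs(noisy$pixels - tex$pixels)
  expect_lte(max(dev), 0.02)
  expect_gt(max(dev), 0)

  bright <- const_texture(c(0.999, 0.999, 0.999))
  set.seed(4)
  clipped <- add_uniform_noise(bright, cfg, amplitude = 0.02)
  expect_lte(max(clipped$pixels), 1)
  expect_gte(min(clipped$pixels), 0)
})

test_that("photometric operations have their identities and involutions", {
  tex <- small_proc_library()$textures[[1]]
  cfg <- augment_config()
  inv <- random_photometric(tex, cfg, op = "invert")
  expect_equal(inv$pixels, 1 - tex$pixels, tolerance = 1e-12)
  expect_equal(random_photometric(inv, cfg, op = "invert")$pixels,
               tex$pixels, tolerance = 1e-12)
  expect_equal(random_photometric(tex, cfg, op = "gamma",
                                  gamma_val = 1)$pixels,
               tex$pixels, tolerance = 1e-12)
  expect_equal(random_photometric(tex, cfg, op = "gaussian_blur",
                                  sigma_val = 0)$pixels,
               tex$pixels, tolerance = 1e-12)
  # every menu operation runs and stays in range
  for (op in cfg$photometric_menu) {
    set.seed(1)
    out <- random_photometric(tex, cfg, op = op)
    expect_gte(min(out$pixels), 0)
    expect_lte(max(out$pixels), 1)
  }
})

test_that("the full chain is seed-reproducible, bounded, and optional", {
  tex <- small_proc_library()$textures[[2]]
  cfg <- augment_config()
  off <- augment_config(enabled = FALSE)
  expect_identical(augment_texture(tex, off), tex)
  crop <- augment_texture(tex, off, out_size = c(64, 64))
  expect_equal(dim(crop$pixels), c(64L, 64L, 3L))

  set.seed(12); a1 <- augment_texture(tex, cfg, out_size = c(64, 64))
  set.seed(12); a2 <- augment_texture(tex, cfg, out_size = c(64, 64))
  expect_identical(a1$pixels, a2$pixels)

  set.seed(99)
  for (i in 1:100) {
    out <- augment_texture(tex, cfg, out_size = c(64, 64))
    expect_gte(min(out$pixels), 0)
    expect_lte(max(out$pixels), 1)
    expect_equal(dim(out$pixels), c(64L, 64L, 3L))
  }
})
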