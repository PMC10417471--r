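test_that("single-class composition fills the germ area with pca stages", {
  spec <- section_spec(width = 400, height = 300, px_per_um = 0.3,
                       composition = c(pca = 1.0), seed = 5)
  img <- generate_section(spec)
  germ_labels <- img$labels[img$labels >= 10L & img$labels < 30L]
  leg <- img$legend
  stages_seen <- leg$structure[match(unique(germ_labels), leg$label)]
  expect_true(all(stages_seen %in% c("og", "po1", "po2")))
  expect_equal(unname(img$truth_groups["pca"]), 1.0)
})

test_that("truth map equals brute-force pixel counting", {
  for (which in c("mixed", "phaseC")) {
    img <- fixture_section(which)
    expect_equal(unname(img$truth[germ_structures()]),
                 pixel_count_oracle(img), tolerance = 1e-12)
    expect_equal(sum(img$truth), 1, tolerance = 1e-9)
    expect_equal(sum(img$truth_groups), 1, tolerance = 1e-9)
  }
})

test_that("phase-C composition is realized within tolerance", {
  img <- fixture_section("phaseC")
  tg <- img$truth_groups
  target <- c(pca = 0, cao = 0, vit = 0.14, pho = 0.70, ho = 0.15,
              POF = 0.01)
  expect_true(all(abs(tg[names(target)] - target) <= 0.02))
})

test_that("regenerating with the same seed is bit-identical", {
  spec <- section_spec(width = 300, height = 240, px_per_um = 0.2,
                       composition = c(pca = 0.6, cao = 0.4), seed = 77)
  img1 <- generate_section(spec)
  img2 <- generate_section(spec)
  expect_identical(img1$labels, img2$labels)
  expect_identical(img1$truth, img2$truth)
})

test_that("unreachable composition errors and reports achieved fractions", {
  # a canvas too small to host a single hydrated oocyte (144 px across)
  spec <- section_spec(width = 120, height = 100, px_per_um = 0.15,
                       composition = c(ho = 1.0), seed = 9,
                       max_attempts = 500)
  expect_error(generate_section(spec), "achieved fractions")
})

test_that("composition validation rejects bad targets", {
  expect_error(section_spec(composition = c(pca = 0.6, cao = 0.5), seed = 1),
               "sum to 1")
  expect_error(section_spec(composition = c(pca = 1.2, cao = -0.2), seed = 1),
               ">= 0")
  expect_error(section_spec(composition = c(bogus = 1), seed = 1),
               "unknown composition entry")
  expect_error(section_spec(composition = c(pca = 1)), "seed")
})

test_that("render_grayscale is deterministic and palette-checked", {
  img <- fixture_section("mixed")
  gray <- render_grayscale(img)
  pal <- default_palette()
  expect_true(all(gray %in% pal))              # noise-free: exact levels
  expect_identical(gray, render_grayscale(img))
  noisy <- render_grayscale(img, noise_sd = 5, seed = 3)
  expect_identical(noisy, render_grayscale(img, noise_sd = 5, seed = 3))
  expect_false(identical(gray, noisy))
  expect_true(all(noisy >= 0 & noisy <= 255))
  expect_error(render_grayscale(img, palette = c(background = 240)),
               "palette is missing")
})

test_that("zona pellucida annuli surround stages that have one", {
  img <- fixture_section("phaseC")   # vit/pho/ho carry a zp
  zp_labels <- unique(img$labels[img$labels >= 30L])
  expect_true(length(zp_labels) > 0)
  leg <- img$legend
  owners <- leg$owner_stage[match(zp_labels, leg$label)]
  expect_true(all(owners %in% c("vit2", "vit3", "pho", "ho")))
})
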