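test_that("generate_phantom paints background, rings and chambers", {
  # no structures: constant background
  spec <- phantom_spec(32, 32, background_level = 0.2, chambers = list())
  img <- generate_phantom(spec)
  expect_true(all(as.matrix(img) == 0.2))

  # deterministic: identical calls give bit-identical images
  spec2 <- phantom_spec(48, 48)
  expect_identical(as.matrix(generate_phantom(spec2)),
                   as.matrix(generate_phantom(spec2)))

  # one ellipse a = 10, b = 5 in 64 x 64: chamber-intensity pixel count
  # matches the brute-force inequality count and is within 10% of
  # pi * a * b
  spec3 <- phantom_spec(64, 64, background_level = 0.2,
                        chambers = list(c(32, 32, 10, 5, 0.9)),
                        myocardium_ring_width = 2,
                        myocardium_intensity = 0.5)
  img3 <- generate_phantom(spec3)
  n_chamber <- sum(as.matrix(img3) == 0.9)
  expect_identical(n_chamber, oracle_ellipse_count(64, 64, 32, 32, 10, 5))
  expect_lt(abs(n_chamber - pi * 10 * 5), 0.1 * pi * 10 * 5)
})

test_that("phantom validation rejects bad geometry and intensities", {
  expect_error(phantom_spec(8, 64), "at least 16")
  expect_error(phantom_spec(64, 64, background_level = 1.2), "\\[0, 1\\]")
  # ellipse (with its ring) leaking outside the bounds
  expect_error(phantom_spec(64, 64,
                            chambers = list(c(5, 32, 10, 5, 0.5)),
                            myocardium_ring_width = 2),
               "outside the image bounds")
})

test_that("degrade is the identity at zero sigmas and seeded otherwise", {
  img <- generate_phantom(tiny_spec())
  deg0 <- degradation_spec(0, 0, 0, seed = 3)
  expect_equal(as.matrix(degrade(img, deg0)), as.matrix(img))

  deg <- degradation_spec(0.2, 1.0, 0.02, seed = 5)
  a <- degrade(img, deg)
  b <- degrade(img, deg)
  expect_identical(as.matrix(a), as.matrix(b))
  expect_false(identical(as.matrix(degrade(img, deg, seed = 6)),
                         as.matrix(a)))
  expect_true(min(a) >= 0 && max(a) <= 1)

  expect_error(degradation_spec(-0.1, 0, 0), ">= 0")
})

test_that("speckle is unit-mean and damage grows with its scale", {
  flat <- echo_image(matrix(0.5, 128, 128))
  sp <- degrade(flat, degradation_spec(0.3, 0, 0, seed = 11))
  expect_lt(abs(mean(sp) - 0.5), 0.02)

  img <- generate_phantom(tiny_spec(48))
  p1 <- psnr(img, degrade(img, degradation_spec(0.1, 0, 0, seed = 9)))
  p2 <- psnr(img, degrade(img, degradation_spec(0.4, 0, 0, seed = 9)))
  expect_gt(p1, p2)
})

test_that("make_paired_dataset builds seeded, shape-consistent pairs", {
  spec <- tiny_spec()
  deg <- degradation_spec(0.2, 1.0, 0.01, seed = 2)
  expect_identical(make_paired_dataset(0, spec, deg), list())

  pairs <- make_paired_dataset(5, spec, deg, jitter_seed = 1)
  expect_length(pairs, 5)
  for (p in pairs) {
    expect_identical(dim(as.matrix(p$clean)), c(32L, 32L))
    expect_identical(dim(as.matrix(p$noisy)), c(32L, 32L))
  }
  # noisy member is degrade() of its clean member, seed deg$seed + i - 1
  expect_identical(as.matrix(pairs[[3]]$noisy),
                   as.matrix(degrade(pairs[[3]]$clean, deg,
                                     seed = deg$seed + 2L)))
  # jitter seeds matter
  pairs2 <- make_paired_dataset(5, spec, deg, jitter_seed = 2)
  diffs <- vapply(seq_len(5), function(i)
    !identical(as.matrix(pairs[[i]]$clean),
               as.matrix(pairs2[[i]]$clean)), logical(1))
  expect_true(any(diffs))
})
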