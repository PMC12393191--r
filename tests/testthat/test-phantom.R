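# Phantom construction and the spoiled-GRE forward model.

test_that("Ernst angle limits and the hand-checked value", {
  expect_equal(ernst_angle(1e9, 100), 90, tolerance = 1e-6)
  expect_equal(ernst_angle(3000, 4300), 60.2, tolerance = 0.1)
  expect_lt(ernst_angle(1e-6, 4300), 0.1)
  expect_error(ernst_angle(-1, 100), class = "es_validation_error")
})

test_that("steady-state amplitude: limits, Ernst maximality and the 34% TR gain", {
  expect_equal(steady_state_amplitude(1, 0, 3000, 4300), 0)
  expect_equal(steady_state_amplitude(5, 90, 1e9, 100), 5, tolerance = 1e-6)
  # grid search confirms the Ernst angle maximizes the amplitude
  angles <- seq(1, 90, by = 0.5)
  amps <- steady_state_amplitude(1, angles, 3000, 4300)
  expect_equal(angles[which.max(amps)], ernst_angle(3000, 4300),
               tolerance = 0.5)
  # doubling TR at matched Ernst angles buys only a 34% signal increase
  a3 <- steady_state_amplitude(1, ernst_angle(3000, 4300), 3000, 4300)
  a6 <- steady_state_amplitude(1, ernst_angle(6000, 4300), 6000, 4300)
  expect_equal(a6 / a3, 1.34, tolerance = 0.005)
})

test_that("voxel signal follows the forward model exactly when noiseless", {
  tr <- fx$train64; cfg <- fx$cfg64
  tis <- list(M0 = 2, T1 = 1000, T2star = 80, D = 0, delta_f = 0, phi0 = 0.3)
  s <- simulate_voxel_signal(tis, tr, cfg)
  amp <- steady_state_amplitude(2, cfg$flip_angle, cfg$TR, 1000)
  expect_equal(Mod(s), amp * exp(-tr$te / 80), tolerance = 1e-12)
  # phase term phi0 + 2 pi df TE
  tis$delta_f <- 7
  s2 <- simulate_voxel_signal(tis, tr, cfg)
  expected <- (0.3 + 2 * pi * 7 * tr$te * 1e-3) %% (2 * pi)
  expect_equal(Arg(s2) %% (2 * pi), expected %% (2 * pi), tolerance = 1e-9)
  # log-ratio of two echoes isolates decay and diffusion terms
  tis$D <- 2; tis$delta_f <- 0
  s3 <- Mod(simulate_voxel_signal(tis, tr, cfg))
  n <- 50; m <- 10
  lhs <- log(s3[n]) - log(s3[m])
  rhs <- -(tr$te[n] - tr$te[m]) / 80 - (tr$b[n] - tr$b[m]) * 2 * 1e-3
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("noisy draws are reproducible under a fixed seed", {
  tis <- tissue_row("GM")
  s1 <- simulate_voxel_signal(tis, fx$train64, fx$cfg64, es_noise(0.01, seed = 7))
  s2 <- simulate_voxel_signal(tis, fx$train64, fx$cfg64, es_noise(0.01, seed = 7))
  expect_identical(s1, s2)
})

test_that("phantom blocks are rectangular, non-overlapping, CSF extreme, background silent", {
  ph <- fx$phantom
  for (i in seq_len(nrow(ph$tissues))) {
    mask <- ph$labels == i
    expect_gt(sum(mask), 0)
    rows <- range(which(rowSums(mask) > 0))
    cols <- range(which(colSums(mask) > 0))
    # axis-aligned rectangle: the bounding box is fully filled
    expect_equal(sum(mask), diff(rows + c(0, 1)) * diff(cols + c(0, 1)))
  }
  csf <- ph$tissues[ph$tissues$label == "CSF", ]
  expect_equal(csf$T2star, max(ph$tissues$T2star))
  expect_equal(csf$D, max(ph$tissues$D))
  imgs <- phantom_echo_images(ph, fx$train64)
  bg <- ph$labels == 0
  expect_true(all(Mod(imgs[, , 1][bg]) == 0))
  expect_true(all(Mod(imgs[, , 64][bg]) == 0))
})

test_that("noiseless magnitude decays monotonically with TE within each block", {
  tr <- fx$train64
  for (lab in fx$tissues$label) {
    s <- Mod(simulate_voxel_signal(tissue_row(lab), tr, fx$cfg64))
    expect_true(all(diff(s[!tr$shifted]) < 0))
    expect_true(all(diff(s[tr$shifted]) < 0))
  }
})

test_that("Monte-Carlo noise-only magnitude matches the Rayleigh mean", {
  set.seed(11)
  sigma <- 3.7
  draws <- Mod(complex(real = rnorm(2e5, 0, sigma),
                       imaginary = rnorm(2e5, 0, sigma)))
  expect_equal(mean(draws), sigma * sqrt(pi / 2), tolerance = 0.01)
})

test_that("shifted-echo signal decreases monotonically with K for fixed tissue", {
  csf <- tissue_row("CSF")
  sig_by_k <- vapply(c(4, 8, 10, 12, 16), function(K) {
    cfg <- es_protocol(K = K)
    tr <- build_echo_train(cfg)
    mean(Mod(simulate_voxel_signal(csf, tr, cfg))[tr$shifted])
  }, 1)
  expect_true(all(diff(sig_by_k) < 0))
})

test_that("tissue-table invariants are enforced", {
  bad <- es_tissue_defaults()
  bad$T1[1] <- 10                      # T1 < T2star
  expect_error(build_figure2_phantom(fx$cfg64, bad),
               class = "es_validation_error")
  bad2 <- es_tissue_defaults()
  bad2$D[2] <- -1
  expect_error(build_figure2_phantom(fx$cfg64, bad2),
               class = "es_validation_error")
})
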