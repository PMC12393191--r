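# K-space acquisition, fluctuation corruption and navigator correction.

ref_mag <- reconstruct_magnitude(acquire_kspace(fx$phantom, fx$train64))

test_that("fluctuation-free acquisition round-trips to the phantom images", {
  imgs <- Mod(phantom_echo_images(fx$phantom, fx$train64))
  expect_lt(nrmse(ref_mag, imgs), 1e-12)
  # Parseval: energy conserved between k-space and image
  ks <- acquire_kspace(fx$phantom, fx$train64)
  n <- prod(dim(ks$echoes)[1:2])
  expect_equal(sum(Mod(ks$echoes[, , 1])^2) / n, sum(ref_mag[, , 1]^2),
               tolerance = 1e-9)
})

test_that("a constant frequency offset is a pure global phase per echo", {
  # sin(2 pi p / 1e9 + pi/2) is flat to ~1e-12: a ~4 Hz constant offset
  fl <- fluctuation_model(amplitude_hz = 4, period_lines = 1e9, phase = pi / 2)
  ks <- acquire_kspace(fx$phantom, fx$train64, fluctuation = fl)
  expect_lt(max(abs(diff(ks$fluct$df0_hz))), 1e-6)
  expect_lt(nrmse(reconstruct_magnitude(ks), ref_mag), 1e-9)
})

test_that("sinusoidal fluctuation ghosts along phase encode; two-step correction restores images", {
  fl <- fluctuation_model(amplitude_hz = 5, period_lines = 24)
  ks <- acquire_kspace(fx$phantom, fx$train64, fluctuation = fl)
  mag_bad <- reconstruct_magnitude(ks)
  expect_gt(ghost_energy(mag_bad, ks$support), 0.05)
  fixed <- correct_step2(correct_step1(ks))
  mag_fix <- reconstruct_magnitude(fixed)
  expect_lt(nrmse(mag_fix, ref_mag), 1e-6)
  expect_lt(ghost_energy(mag_fix, ks$support), 1e-10)
})

test_that("step-1 correction phase scales with TE and is the identity on clean data", {
  ks <- acquire_kspace(fx$phantom, fx$train64)
  fixed <- correct_step1(ks)
  expect_lt(nrmse(fixed$echoes, ks$echoes), 1e-10)
  # applied phase proportional to TE_n: check on a corrupted set by
  # comparing hybrid-space phase changes of two echoes at fixed (x, line)
  fl <- fluctuation_model(amplitude_hz = 3, period_lines = 16)
  ksc <- acquire_kspace(fx$phantom, fx$train64, fluctuation = fl)
  c1 <- correct_step1(ksc)
  h_before <- esmgre:::hybrid(ksc$echoes[, , 10])
  h_after <- esmgre:::hybrid(c1$echoes[, , 10])
  h_before2 <- esmgre:::hybrid(ksc$echoes[, , 30])
  h_after2 <- esmgre:::hybrid(c1$echoes[, , 30])
  x <- 32; p <- 20
  d1 <- Arg(h_after[x, p] * Conj(h_before[x, p]))
  d2 <- Arg(h_after2[x, p] * Conj(h_before2[x, p]))
  expect_equal(d1 / fx$train64$te[10], d2 / fx$train64$te[30],
               tolerance = 1e-6)
})

test_that("step 1 is idempotent and preserves hybrid-space magnitudes", {
  fl <- fluctuation_model(amplitude_hz = 5, period_lines = 24)
  ks <- acquire_kspace(fx$phantom, fx$train64, fluctuation = fl)
  once <- correct_step1(ks)
  twice <- correct_step1(once)
  expect_lt(nrmse(twice$echoes, once$echoes), 1e-10)
  h0 <- esmgre:::hybrid(ks$echoes[, , 5])
  h1 <- esmgre:::hybrid(once$echoes[, , 5])
  expect_equal(Mod(h1), Mod(h0), tolerance = 1e-12)
})

test_that("step 2 touches only shifted echoes and removes a shifted-block-only component", {
  fl <- fluctuation_model(amplitude_hz = 5, period_lines = 24,
                          shifted_extra_hz = 1)
  ks <- acquire_kspace(fx$phantom, fx$train64, fluctuation = fl)
  c1 <- correct_step1(ks)
  expect_gt(nrmse(reconstruct_magnitude(c1), ref_mag), 1e-3)
  c2 <- correct_step2(c1)
  prompt <- which(!fx$train64$shifted)
  expect_identical(c2$echoes[, , prompt], c1$echoes[, , prompt])
  expect_lt(nrmse(reconstruct_magnitude(c2), ref_mag), 1e-6)
  # with zero residual after step 1, step 2 is the identity
  clean <- correct_step1(acquire_kspace(fx$phantom, fx$train64))
  c2b <- correct_step2(clean)
  expect_lt(nrmse(c2b$echoes, clean$echoes), 1e-10)
})

test_that("step ordering and missing navigators raise the documented conditions", {
  ks <- acquire_kspace(fx$phantom, fx$train64)
  expect_error(correct_step2(ks), class = "es_runtime_error")
  cfg_nonav <- es_protocol(navigator_slots = integer(0))
  tr_nonav <- build_echo_train(cfg_nonav, with_b = FALSE)
  tr_nonav$b <- 0
  ks2 <- acquire_kspace(build_figure2_phantom(cfg_nonav), tr_nonav, cfg_nonav)
  expect_error(correct_step1(ks2), class = "es_runtime_error")
  # only a prompt navigator: step 2 warns and no-ops
  cfg1 <- es_protocol(navigator_slots = 22L)
  tr1 <- build_echo_train(cfg1)
  ks3 <- correct_step1(acquire_kspace(build_figure2_phantom(cfg1), tr1, cfg1))
  expect_warning(out <- correct_step2(ks3), "no-op")
  expect_identical(out$echoes, ks3$echoes)
})

test_that("ghost energy strictly decreases after correction over a seeded noisy ensemble", {
  fl <- fluctuation_model(amplitude_hz = 5, period_lines = 24)
  improved <- vapply(1:20, function(seed) {
    ks <- acquire_kspace(fx$phantom, fx$train64, fluctuation = fl,
                         noise = es_noise(fx$sigma50, seed = seed))
    before <- ghost_energy(reconstruct_magnitude(ks), ks$support)
    fixed <- correct_step2(correct_step1(ks))
    after <- ghost_energy(reconstruct_magnitude(fixed), ks$support)
    after < before
  }, TRUE)
  expect_true(all(improved))
})

test_that("navigator assignment follows the block scheme for long trains", {
  a <- assign_navigators_qute(128, 4)
  expect_equal(unique(a$step2_nav[1:32]), NA_integer_)
  expect_equal(unique(a$step2_nav[33:64]), 2L)
  expect_equal(unique(a$step2_nav[65:96]), 3L)
  expect_equal(unique(a$step2_nav[97:128]), 4L)
  expect_true(all(a$step1_nav == 1L))
  a1 <- assign_navigators_qute(64, 1)
  expect_true(all(is.na(a1$step2_nav)))
  a2 <- assign_navigators_qute(64, 2)
  expect_true(all(is.na(a2$step2_nav[1:32])))
  expect_equal(unique(a2$step2_nav[33:64]), 2L)
})

test_that("low-SNR fallback replaces only below-mean positions", {
  phase <- c(0.1, 0.12, 0.11, 3.0, 0.09)
  snr <- c(10, 11, 9, 0.5, 12)
  out <- low_snr_fallback(phase, snr)
  expect_equal(out[4], median(phase[-4]))
  expect_equal(out[-4], phase[-4])
  # uniform SNR: nothing is strictly below the mean, nothing changes
  expect_equal(low_snr_fallback(phase, rep(5, 5)), phase)
  expect_warning(low_snr_fallback(c(1, 2), c(-1, -1) + c(0, -1e-9)),
                 NA)  # two unequal values: one above mean, no warning
})
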