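# Noise estimation, signal model, voxelwise fitting, delta correction, cAIC.

test_that("corner-ROI sigma estimate recovers a known Rayleigh background", {
  set.seed(5)
  img <- matrix(Mod(complex(real = rnorm(96^2, 0, 5),
                            imaginary = rnorm(96^2, 0, 5))), 96, 96)
  est <- estimate_noise_sigma(img, corner_size = 20)
  expect_equal(est$n_voxels, 1600)
  expect_lt(abs(est$sigma - 5) / 5, 0.05)
  est2 <- estimate_noise_sigma(img, corner_size = 20, method = "second_moment")
  expect_lt(abs(est2$sigma - 5) / 5, 0.05)
  expect_warning(z <- estimate_noise_sigma(matrix(0, 60, 60)), "all-zero")
  expect_equal(z$sigma, 0)
  # an object leaking into one corner is flagged
  img2 <- img; img2[1:20, 1:20] <- 100
  expect_warning(estimate_noise_sigma(img2), "brighter")
})

test_that("signal model reduces to mono-exponential and carries the bipolar factor", {
  tr <- fx$train64
  base <- model_signal(list(M0 = 1, T2star = 100), tr)
  expect_equal(base, exp(-tr$te / 100), tolerance = 1e-12)
  mod <- model_signal(list(M0 = 1, T2star = 100, delta = 0.05), tr)
  expect_equal(mod / base, exp(tr$polarity * 0.05), tolerance = 1e-12)
  # adjacent echoes at (almost) equal decay carry the e^{+-2 delta} ratio
  expect_equal(mod[2] / mod[1] * base[1] / base[2], exp(-2 * 0.05),
               tolerance = 1e-12)
  # diffusion scales the shifted block by exp(-b D)
  modd <- model_signal(list(M0 = 1, T2star = 100, D = 2), tr)
  expect_equal(modd / base, exp(-tr$b * 2e-3), tolerance = 1e-12)
})

test_that("noiseless forward data are recovered to better than 0.1%", {
  tr <- fx$train64
  cases <- list(list(M0 = 1.4, T2star = 60, D = 0.7),
                list(M0 = 0.6, T2star = 1500, D = 3),
                list(M0 = 2.0, T2star = 35, D = 0))
  for (truth in cases) {
    s <- model_signal(truth, tr)
    f <- fit_voxel(s, tr, fit_model(noise_model = "gaussian"), sigma = NULL)
    expect_lt(abs(f$M0 - truth$M0) / truth$M0, 1e-3)
    expect_lt(abs(f$T2star - truth$T2star) / truth$T2star, 1e-3)
    expect_lt(abs(f$D - truth$D), 1e-3 * max(truth$D, 1))
  }
  # with delta as a free parameter
  truth <- list(M0 = 1, T2star = 90, D = 1, delta = 0.04)
  s <- model_signal(truth, tr)
  f <- fit_voxel(s, tr, fit_model(include_delta = TRUE,
                                  noise_model = "gaussian"), sigma = NULL)
  expect_lt(abs(f$delta - 0.04), 1e-4)
  expect_lt(abs(f$T2star - 90) / 90, 1e-3)
})

test_that("optimizer matches a brute-force Rician likelihood grid search", {
  # brute-force lattice oracle on random instances: coarse 20 x 20 lattice
  # in (T2*, D) with M0 profiled over a fine axis (M0 trades off against
  # both decay parameters, so it must be resolved finely for the lattice
  # arg-max location to be meaningful). The optimizer must reach at least
  # the likelihood of the best lattice node and land within one cell of it.
  tr <- fx$train64
  set.seed(99)
  sigma <- 0.003
  grid_nll <- function(grid, s) {
    # vectorized: nu for all lattice nodes at once, Rician NLL rowwise
    nu <- grid$M0 * exp(-outer(1 / grid$T2star, tr$te) -
                          outer(grid$D, tr$b * 1e-3))
    z <- sweep(nu, 2, s, `*`) / sigma^2
    li0 <- matrix(esmgre:::log_bessel_i0(z), nrow(nu))
    -rowSums(sweep(-nu^2 / (2 * sigma^2) + li0, 2,
                   log(s / sigma^2) - s^2 / (2 * sigma^2), `+`))
  }
  for (i in 1:20) {
    truth <- list(M0 = runif(1, 0.5, 2), T2star = runif(1, 100, 400),
                  D = runif(1, 0.5, 3))
    s <- pmax(Mod(model_signal(truth, tr) +
                    complex(real = rnorm(64, 0, sigma),
                            imaginary = rnorm(64, 0, sigma))), 1e-12)
    m0g <- seq(truth$M0 * 0.95, truth$M0 * 1.05, length.out = 200)
    t2g <- seq(truth$T2star * 0.7, truth$T2star * 1.4, length.out = 20)
    dg <- seq(0, 4, length.out = 20)
    grid <- expand.grid(M0 = m0g, T2star = t2g, D = dg)
    nll <- grid_nll(grid, s)
    best <- grid[which.min(nll), ]
    f <- fit_voxel(s, tr, fit_model(), sigma)
    nll_fit <- esmgre:::rician_nll(s, model_signal(f, tr), sigma)
    expect_lte(nll_fit, min(nll) + 1e-6)
    expect_lt(abs(f$T2star - best$T2star), diff(t2g[1:2]) * 1.5)
    expect_lt(abs(f$D - best$D), diff(dg[1:2]) * 1.5)
  }
})

test_that("iterative delta correction recovers delta and respects symmetry", {
  tr <- fx$train64
  truth <- list(M0 = 1, T2star = 70, D = 0.8)
  clean <- model_signal(truth, tr)
  s <- clean * exp(tr$polarity * 0.05)
  res <- iterative_delta_correction(s, tr, fit_model(noise_model = "gaussian"))
  expect_lt(abs(res$delta - 0.05) / 0.05, 0.01)
  expect_true(res$converged)
  expect_lt(max(abs(res$corrected - rbind(clean)) / clean), 1e-3)
  # delta-free data give delta ~ 0
  res0 <- iterative_delta_correction(clean, tr,
                                     fit_model(noise_model = "gaussian"))
  expect_lt(abs(res0$delta), 1e-3)
  # swapping even/odd polarity labels flips the sign
  tr_sw <- tr; tr_sw$polarity <- -tr$polarity
  res_sw <- iterative_delta_correction(s, tr_sw,
                                       fit_model(noise_model = "gaussian"))
  expect_equal(res_sw$delta, -res$delta, tolerance = 1e-3)
  # per-voxel variant agrees on identical rows
  two <- rbind(s, s)
  res_pv <- iterative_delta_correction(two, tr,
                                       fit_model(noise_model = "gaussian"),
                                       per_voxel = TRUE)
  expect_equal(res_pv$delta, rep(res$delta, 2), tolerance = 1e-6)
})

test_that("cAIC penalizes complexity and compares models sanely", {
  expect_equal(caic(-10, 2, 64), 20 + 4 + 12 / 61)
  expect_true(is.na(caic(-10, 3, 4)))
  # identical likelihoods: the simpler model wins
  f_simple <- structure(list(caic = caic(-10, 2, 64)), class = "es_fit")
  f_complex <- structure(list(caic = caic(-10, 3, 64)), class = "es_fit")
  expect_false(caic_compare(f_complex, f_simple)$prefers_diffusion)
  # equal k reduces to a likelihood comparison
  expect_lt(caic(-9, 3, 64), caic(-10, 3, 64))
})

test_that("fit_map equals fit_voxel per voxel, masks background, is order-independent", {
  tr <- fx$train64
  stack <- array(0, dim = c(4, 4, 64))
  truth <- list(M0 = 1, T2star = 120, D = 1.5)
  set.seed(3)
  s <- Mod(model_signal(truth, tr) +
             complex(real = rnorm(64, 0, 0.01),
                     imaginary = rnorm(64, 0, 0.01)))
  stack[2, 3, ] <- s
  m <- fit_map(stack, tr, fit_model(), sigma = 0.01)
  expect_equal(sum(m$mask), 1)
  f <- fit_voxel(s, tr, fit_model(), 0.01)
  expect_equal(m$T2star[2, 3], f$T2star)
  expect_equal(m$D[2, 3], f$D)
  expect_true(is.na(m$T2star[1, 1]))
  # all-background stack: fully masked
  m0 <- fit_map(array(0, dim = c(4, 4, 64)), tr, fit_model(), sigma = 0.01)
  expect_equal(sum(m0$mask), 0)
})

test_that("shape mismatches and insufficient data raise errors", {
  expect_error(fit_voxel(rep(1, 10), fx$train64, fit_model(), 0.01),
               class = "es_runtime_error")
  expect_error(fit_voxel(rep(1, 64), fx$train64, fit_model(), NULL),
               class = "es_validation_error")
  expect_error(fit_map(array(0, dim = c(4, 4, 3)), fx$train64, fit_model(),
                       0.01), class = "es_runtime_error")
})
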